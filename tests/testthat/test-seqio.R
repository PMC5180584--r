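test_that("tag design satisfies the pairwise Hamming invariant", {
  # single tag: invariant vacuous
  expect_length(design_tags(1, seed = 1), 1)

  tg <- design_tags(96, length = 8, min_hamming = 3, seed = 4)
  expect_length(tg, 96)
  expect_true(all(nchar(tg) == 8))
  # exhaustive brute-force pair check
  mat <- do.call(rbind, strsplit(tg, ""))
  prs <- combn(96, 2)
  hd <- apply(prs, 2, function(p) sum(mat[p[1], ] != mat[p[2], ]))
  expect_true(all(hd >= 3))

  # determinism
  expect_identical(tg, design_tags(96, seed = 4))

  # impossible request: Hamming distance cannot exceed tag length
  expect_error(design_tags(5, length = 2, min_hamming = 3), "capacity")
})

test_that("pair merging scores overlaps as constructed and rejects low scores", {
  set.seed(11)
  insert <- random_seq(140)                     # 100 + 100 - 60 overlap
  fwd <- substr(insert, 1, 100)
  rev <- revcomp(substr(insert, 41, 140))
  m <- merge_pair(fwd, rev)
  expect_true(m$accepted)
  expect_equal(m$score, 60)
  expect_equal(m$sequence, insert)

  # a perfect 20-base overlap scores 20 < 40 and is discarded
  insert2 <- random_seq(180)
  f2 <- substr(insert2, 1, 100)
  r2 <- revcomp(substr(insert2, 81, 180))
  m2 <- merge_pair(f2, r2)
  expect_false(m2$accepted)
  expect_equal(m2$reason, "low_score")
  expect_equal(m2$score, 20)
})

test_that("merge scoring agrees with the exhaustive all-offsets oracle", {
  set.seed(22)
  for (i in 1:25) {
    a <- random_seq(sample(60:120, 1))
    b <- random_seq(sample(60:120, 1))
    m <- sedimotu:::cpp_merge_overlap(a, b, strrep("I", nchar(a)),
                                      strrep("I", nchar(b)))
    expect_equal(m$score, oracle_overlap_score(a, b))
  }
})

test_that("consensus takes the higher-quality base at overlap conflicts", {
  insert <- paste(rep("A", 120), collapse = "")
  fwd <- substr(insert, 1, 80)
  rv <- substr(insert, 41, 120)
  substr(rv, 1, 1) <- "G"     # conflict at insert position 41
  m <- merge_pair(fwd, revcomp(rv),
                  fwd_qual = strrep("I", 80),       # Q40
                  rev_qual = strrep("5", 80))       # Q20
  expect_true(m$accepted)
  expect_equal(substr(m$sequence, 41, 41), "A")
})

test_that("demultiplexing assigns matched tags, discards chimeras, and partitions input", {
  tg <- design_tags(6, seed = 2)
  map <- setNames(tg[1:3], c("s1", "s2", "s3"))
  fp <- gsub("S", "G", PRIMER_FWD)
  rp <- PRIMER_REV
  ins <- vapply(1:4, function(i) random_seq(90), character(1))
  mk <- function(t5, t3, insert)
    paste0(t5, fp, insert, revcomp(rp), revcomp(t3))
  reads <- c(ok1 = mk(tg[1], tg[1], ins[1]),
             ok2 = mk(tg[2], tg[2], ins[2]),
             chi = mk(tg[1], tg[2], ins[3]),        # two valid, different
             unk = mk("AAAAAAAA", "AAAAAAAA", ins[4]),
             shrt = mk(tg[3], tg[3], substr(ins[1], 1, 60)))
  d <- demultiplex(reads, map, PRIMER_FWD, PRIMER_REV, min_len = 75)
  expect_equal(d$samples$s1, ins[1])
  expect_equal(d$samples$s2, ins[2])
  expect_equal(unname(d$log$outcome),
               c("assigned", "assigned", "chimera", "untagged", "short"))
  # partition property
  expect_equal(nrow(d$log), length(reads))

  # duplicate tag in the map is a configuration error
  expect_error(demultiplex(reads, setNames(tg[c(1, 1)], c("a", "b")),
                           PRIMER_FWD, PRIMER_REV), "duplicate")

  # reverse-orientation reads are recognised too
  d2 <- demultiplex(setNames(revcomp(reads["ok1"]), "rc1"), map,
                    PRIMER_FWD, PRIMER_REV)
  expect_equal(d2$samples$s1, ins[1])
})

test_that("simulated tag chimeras appear at the configured rate", {
  des <- rna_dna_design(stations = c(BC1200 = 1.232), corers = 2,
                        n_blanks = 0, n_negatives = 0)
  cm <- sim_community(des, community_params(n_motus = 100, seed = 3))
  tr <- sim_taxonomy_refs(100, seed = 3)
  tg <- design_tags(nrow(des), seed = 3)
  sim <- sim_reads(cm, tr$refs, tg,
                   read_params(reads_per_sample = 850, per_base_error = 0,
                               singleton_rate = 0, cross_contam_rate = 0,
                               tag_chimera_rate = 0.05, seed = 9))
  n <- sim$log$n_reads
  expect_gt(n, 5000)
  mg <- merge_pairs(sim$fwd, sim$rev)
  d <- demultiplex(mg$sequences, sim$tag_map, PRIMER_FWD, PRIMER_REV)
  frac <- mean(d$log$outcome == "chimera")
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac - 0.05), 3 * se + 1e-9)
})

test_that("dereplication counts strictly identical sequences per sample", {
  u <- dereplicate(list(s1 = c("AAA", "AAA", "AAA", "CCC"), s2 = "AAA"))
  expect_equal(nrow(u), 2)
  expect_equal(u$total[u$sequence == "AAA"], 4L)
  expect_equal(u$s1[u$sequence == "AAA"], 3L)
  expect_equal(u$s2[u$sequence == "CCC"], 0L)

  # empty input
  expect_equal(nrow(dereplicate(list(s1 = character(0)))), 0)

  # conservation property on a random batch
  set.seed(5)
  reads <- list(a = sample(c("AA", "CC", "GG"), 50, replace = TRUE),
                b = sample(c("AA", "TT"), 30, replace = TRUE))
  u2 <- dereplicate(reads)
  expect_equal(sum(u2$total), 80L)
  expect_equal(sum(u2$a), 50L)
  expect_equal(sum(u2$b), 30L)
})

test_that("singleton removal drops exactly the total-count-one sequences", {
  u <- make_uniq(s1 = c("A", "C", "G", "G", "T", "T", "T", "T", "T", "T"))
  out <- remove_singletons(u)
  expect_setequal(out$total, c(2L, 6L))
  # all >= 2: identity
  expect_equal(nrow(remove_singletons(out)), 2)
  # all singletons: empty
  u2 <- make_uniq(s1 = c("AA", "CC"))
  expect_equal(nrow(remove_singletons(u2)), 0)
})

test_that("FASTQ round-trips through Biostrings wrappers", {
  tmp <- tempfile(fileext = ".fastq")
  seqs <- setNames(c("ACGTACGT", "GGGTTTAA"), c("r1", "r2"))
  quals <- setNames(c("IIIIIIII", "IIII5555"), c("r1", "r2"))
  write_fastq(seqs, quals, tmp)
  back <- read_fastq(tmp)
  expect_equal(back$sequences, seqs)
  expect_equal(back$qualities, quals)
  unlink(tmp)
})
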