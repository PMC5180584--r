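pres_fixture <- function(seed = 42, n_motu = 30, n_samp = 12, p = 0.4) {
  set.seed(seed)
  m <- matrix(rbinom(n_motu * n_samp, 1, p), n_motu, n_samp,
              dimnames = list(sprintf("m%02d", 1:n_motu),
                              sprintf("s%02d", 1:n_samp)))
  m[rowSums(m) == 0, 1] <- 1
  m
}

test_that("Jaccard distances match set arithmetic and vegan", {
  # {a,b,c} vs {b,c,d}: intersection 2, union 4 -> similarity 50%
  pres <- cbind(s1 = c(1, 1, 1, 0), s2 = c(0, 1, 1, 1))
  rownames(pres) <- letters[1:4]
  d <- jaccard_matrix(pres)
  expect_equal(as.numeric(d), 0.5)
  expect_equal(jaccard_similarity(d), 50)
  # identical and disjoint samples
  p2 <- cbind(s1 = c(1, 1, 0, 0), s2 = c(1, 1, 0, 0), s3 = c(0, 0, 1, 1))
  d2 <- as.matrix(jaccard_matrix(p2))
  expect_equal(d2["s1", "s2"], 0)
  expect_equal(d2["s1", "s3"], 1)

  pres3 <- pres_fixture()
  expect_equal(as.numeric(jaccard_matrix(pres3)),
               as.numeric(vegan::vegdist(t(pres3), "jaccard",
                                         binary = TRUE)))
})

test_that("Jaccard distance satisfies the triangle inequality", {
  pres <- pres_fixture(seed = 7)
  dm <- as.matrix(jaccard_matrix(pres))
  n <- ncol(pres)
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    expect_lte(dm[i, j], dm[i, k] + dm[k, j] + 1e-12)
})

test_that("PERMANOVA partition matches the one-way closed form and adonis2", {
  pres <- pres_fixture()
  d <- jaccard_matrix(pres)
  grp <- rep(c("a", "b", "c"), each = 4)
  pr <- permanova(d, data.frame(g = grp), "g", n_perms = 199, seed = 1)
  cf <- permanova_oneway_ss(d, grp)
  expect_equal(pr$F[1], cf$F)
  expect_equal(pr$SumOfSqs[1], cf$ss_between)
  expect_equal(pr$SumOfSqs[2], cf$ss_within)

  av <- vegan::adonis2(d ~ g, data = data.frame(g = grp),
                       permutations = 199)
  expect_equal(pr$F[1], av$F[1])
  expect_equal(pr$SumOfSqs[1:2], av$SumOfSqs[1:2])

  # two-factor sequential partition against adonis2 (by = "terms")
  dat <- data.frame(g = grp, h = rep(c("x", "y"), 6))
  pr2 <- permanova(d, dat, c("g", "h"), n_perms = 99, seed = 1)
  av2 <- vegan::adonis2(d ~ g + h, data = dat, permutations = 99,
                        by = "terms")
  expect_equal(pr2$F[1:2], av2$F[1:2])
  expect_equal(pr2$SumOfSqs[1:3], av2$SumOfSqs[1:3])
})

test_that("complete separation reaches the minimal permutation p-value", {
  # within-group distance 0, between 1
  dm <- matrix(1, 6, 6); dm[1:3, 1:3] <- 0; dm[4:6, 4:6] <- 0; diag(dm) <- 0
  rownames(dm) <- colnames(dm) <- paste0("s", 1:6)
  pr <- permanova(stats::as.dist(dm), data.frame(g = rep(c("a", "b"),
                                                         each = 3)),
                  "g", n_perms = 199, seed = 3)
  # permutations that keep the partition intact tie with the observed F:
  # 6!/(3!3!)-relabellings contain 1/10 such splits, so p ~ 0.1, never less
  expect_lte(pr$p[1], 0.15)
  pe <- permanova(stats::as.dist(dm), data.frame(g = rep(c("a", "b"),
                                                         each = 3)),
                  "g", exact = TRUE)
  expect_equal(pe$p[1], 0.1)
})

test_that("permutation p equals exact enumeration on a small design", {
  pres <- pres_fixture(seed = 17, n_samp = 6)
  d <- jaccard_matrix(pres)
  grp <- rep(c("a", "b"), each = 3)
  pe <- permanova(d, data.frame(g = grp), "g", exact = TRUE)
  # independent oracle: enumerate the 20 distinct relabellings via combn
  dm <- as.matrix(d)
  Fs <- apply(combn(6, 3), 2, function(ix) {
    g <- rep("b", 6); g[ix] <- "a"
    permanova_oneway_ss(stats::as.dist(dm), g)$F
  })
  F_obs <- permanova_oneway_ss(d, grp)$F
  expect_equal(pe$p[1], mean(Fs >= F_obs - 1e-12))
})

test_that("restricted permutations respect strata", {
  pres <- pres_fixture(seed = 23, n_samp = 12)
  d <- jaccard_matrix(pres)
  blocks <- rep(c("b1", "b2"), each = 6)
  grp <- rep(rep(c("a", "b"), each = 3), 2)
  pr <- permanova(d, data.frame(g = grp), "g", n_perms = 99, seed = 5,
                  strata = blocks)
  expect_true(pr$p[1] > 0 && pr$p[1] <= 1)
  # block permutation requires equal block sizes
  expect_error(permanova(d, data.frame(g = grp), "g", n_perms = 9,
                         blocks = c(rep("b1", 5), rep("b2", 7))),
               "unequal block sizes")
})

test_that("PERMDISP matches betadisper and flags degenerate groups", {
  pres <- pres_fixture(seed = 29)
  d <- jaccard_matrix(pres)
  grp <- rep(c("a", "b", "c"), each = 4)
  pd <- permdisp(d, grp, n_perms = 99, seed = 1)
  bd <- vegan::betadisper(d, grp, type = "centroid")
  expect_equal(pd$F, stats::anova(bd)[1, "F value"])
  expect_equal(unname(sort(pd$distances)), unname(sort(bd$distances)),
               tolerance = 1e-8)
  # identical groups: F collapses to zero
  dm <- matrix(1, 6, 6); diag(dm) <- 0
  rownames(dm) <- colnames(dm) <- paste0("s", 1:6)
  pd0 <- permdisp(stats::as.dist(dm), rep(c("a", "b"), 3), n_perms = 49,
                  seed = 1)
  expect_lt(pd0$F, 1e-8)
  # singleton group excluded with a warning
  expect_warning(permdisp(d, c("z", grp[-1]), n_perms = 9, seed = 1),
                 "size 1")
})

test_that("dispersion differences are detected with reasonable power", {
  set.seed(211)
  hits <- 0
  for (i in 1:20) {
    x1 <- matrix(rnorm(10 * 2, sd = 1), 10, 2)
    x2 <- matrix(rnorm(10 * 2, sd = 2.5), 10, 2)
    d <- dist(rbind(x1, x2))
    pd <- permdisp(d, rep(c("a", "b"), each = 10), n_perms = 99, seed = i)
    hits <- hits + (pd$p <= 0.05)
  }
  expect_gt(hits / 20, 0.5)
})

test_that("pairwise tests apply the Benjamini-Yekutieli correction", {
  # hand computation: m = 3, c(3) = 1 + 1/2 + 1/3
  raw <- c(0.01, 0.02, 0.5)
  expect_equal(round(p.adjust(raw, "BY"), 4), c(0.055, 0.055, 0.9167))

  pres <- pres_fixture(seed = 37)
  d <- jaccard_matrix(pres)
  grp <- rep(c("a", "b", "c"), each = 4)
  pw <- pairwise_tests(d, grp, n_perms = 99, seed = 2)
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adj, p.adjust(pw$p_raw, "BY"))
  # adjusted p monotone in raw-p order
  o <- order(pw$p_raw)
  expect_true(all(diff(pw$p_adj[o]) >= -1e-12))
  expect_equal(pw$t, sqrt(vapply(seq_len(3), function(k) {
    sel <- grp %in% strsplit(pw$pair[k], " vs ")[[1]]
    permanova_oneway_ss(stats::as.dist(as.matrix(d)[sel, sel]),
                        grp[sel])$F
  }, numeric(1))))
})

test_that("nMDS embeds exactly embeddable configurations and not others", {
  x <- c(0, 1, 2, 3.5, 5, 7.2, 9)
  nm <- nmds(dist(cbind(x, 0)), k = 2, n_starts = 10, seed = 2)
  expect_lt(nm$stress, 0.01)
  # four equidistant points cannot embed in the plane
  d4 <- stats::as.dist(matrix(1, 4, 4) - diag(4))
  expect_gt(nmds(d4, k = 2, n_starts = 10, seed = 2)$stress, 0)
  # determinism
  pres <- pres_fixture(seed = 43)
  d <- jaccard_matrix(pres)
  n1 <- nmds(d, n_starts = 15, seed = 9)
  n2 <- nmds(d, n_starts = 15, seed = 9)
  expect_identical(n1$points, n2$points)
  # comparable stress to vegan on the same matrix
  mm <- vegan::metaMDS(d, k = 2, trymax = 15, trace = 0)
  expect_lt(nm_stress_gap <- n1$stress - mm$stress, 0.05)
})

test_that("environmental vector fitting recovers perfect and null structure", {
  set.seed(222)
  X <- matrix(rnorm(24), 12, 2)
  # variable equal to axis-1 coordinate: r2 = 1
  fe <- fit_env_vector(X, X[, 1], n_perms = 99, seed = 1)
  expect_equal(fe$r2, 1.0)
  expect_lte(fe$p, 0.05)
  # agreement with vegan::envfit r2 on a generic variable
  v <- rnorm(12)
  fe2 <- fit_env_vector(X, v, n_perms = 199, seed = 1)
  ef <- vegan::envfit(X, data.frame(v = v), permutations = 199)
  expect_equal(fe2$r2, unname(ef$vectors$r))
  expect_error(fit_env_vector(X, rep(1, 12)), "constant")
})

test_that("analytic rarefaction matches endpoints, vegan and Monte-Carlo", {
  counts <- c(50, 30, 10, 5, 3, 2)
  N <- sum(counts)
  rc <- rarefaction_curve(counts, m = c(1, 10, 50, N))
  # endpoints
  expect_equal(rc$richness[rc$m == N], 6)
  expect_equal(rarefaction_curve(c(5, 5), m = 1)$richness, 1)
  # vegan cross-check
  expect_equal(rc$richness,
               suppressWarnings(as.numeric(vegan::rarefy(counts,
                                                         c(1, 10, 50, N)))))
  # curve is non-decreasing
  full <- rarefaction_curve(counts, step = 5)
  expect_true(all(diff(full$richness) >= -1e-9))
  # Monte-Carlo oracle at m = 20
  set.seed(55)
  pool <- rep(seq_along(counts), counts)
  sims <- replicate(10000, length(unique(sample(pool, 20))))
  mc <- mean(sims); se <- sd(sims) / sqrt(10000)
  expect_lt(abs(rarefaction_curve(counts, m = 20)$richness - mc),
            4 * se)
  expect_error(rarefaction_curve(counts, m = N + 1), "invalid")
})

test_that("richness t-tests cover pooled, paired and degenerate cases", {
  # identical groups: t = 0, p = 1
  r <- richness_tests(c(5, 5, 5, 5), rep(c("a", "b"), each = 2))
  expect_equal(r$t, 0); expect_equal(r$p, 1)
  # textbook 5-pair hand example against the closed form
  x1 <- c(12, 15, 11, 18, 14); x2 <- c(10, 14, 12, 15, 11)
  d <- x1 - x2
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  rp <- richness_tests(c(x1, x2), rep(c("a", "b"), each = 5), paired = TRUE)
  expect_equal(rp$t, t_hand)
  expect_equal(rp$df, 4)
  # label swap flips the sign, p unchanged
  r1 <- richness_tests(c(x1, x2), rep(c("a", "b"), each = 5))
  r2 <- richness_tests(c(x2, x1), rep(c("a", "b"), each = 5))
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
})

test_that("pooling unions presence before distances", {
  des <- rna_dna_design(stations = c(BC1200 = 1.232), corers = 2,
                        n_blanks = 0, n_negatives = 0)
  cm <- sim_community(des, community_params(n_motus = 50, seed = 5))
  tab <- motu_table(cm$detected, samples = des)
  d_lay <- jaccard_matrix(tab, pooling = "layers")
  meta <- attr(d_lay, "meta")
  # one pooled unit per station x corer x season x template:
  # 1 station x 2 corers x 1 season x 2 templates
  expect_equal(attr(d_lay, "Size"), 4L)
  expect_equal(nrow(meta), 4)
  # the first pooled distance equals the Jaccard of the presence unions
  key <- paste(des$station, des$corer, des$season, des$template, sep = ":")
  u1 <- rowSums(cm$detected[, key == unique(key)[1], drop = FALSE]) > 0
  u2 <- rowSums(cm$detected[, key == unique(key)[2], drop = FALSE]) > 0
  expect_equal(as.numeric(d_lay)[1],
               1 - sum(u1 & u2) / sum(u1 | u2))
})
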