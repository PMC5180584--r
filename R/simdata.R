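#' Default primers of the 18S v7 marker
#'
#' The universal "18S_allshorts" primer pair amplifying a ~76-140 nt
#' hypervariable fragment of the 18S rRNA gene.
#' @export
PRIMER_FWD <- "TTTGTCTGSTTAATTSCG"
#' @rdname PRIMER_FWD
#' @export
PRIMER_REV <- "TCACAGACCTGTTATTGC"

#' Build the sediment sampling design
#'
#' Emulates a stratified deep-sea sampling campaign: stations along a
#' canyon-slope depth gradient, three corer replicates per station, three
#' sediment layers per core (A: first cm, B: second cm, C: third-fifth cm),
#' two seasons, plus PCR blanks and extraction negative controls.
#' `rna_dna_design()` builds the autumn co-extraction subset in which every
#' core yields both a DNA and an RNA sample.
#'
#' @param stations named numeric vector station -> depth (km); names starting
#'   with "OS" are open-slope stations, the rest canyon.
#' @param corers number of corer replicates per station (default 3).
#' @param seasons character vector of seasons (default autumn, spring).
#' @param n_blanks,n_negatives number of control samples (default 4 each).
#' @return data.frame with one row per sequencing sample: `sample_id`,
#'   `zone`, `station`, `depth_km`, `corer`, `layer`, `season`, `template`,
#'   `role`.
#' @export
sediment_design <- function(stations = c(BC900 = 0.874, BC1200 = 1.232,
                                         BC1500 = 1.45, BC1750 = 1.746,
                                         OS1500 = 1.454),
                            corers = 3,
                            seasons = c("autumn", "spring"),
                            n_blanks = 4, n_negatives = 4) {
  g <- expand.grid(layer = c("A", "B", "C"),
                   corer = seq_len(corers),
                   station = names(stations),
                   season = seasons,
                   stringsAsFactors = FALSE)
  g$depth_km <- unname(stations[g$station])
  g$zone <- ifelse(startsWith(g$station, "OS"), "slope", "canyon")
  g$template <- "DNA"
  g$role <- "sample"
  g$sample_id <- sprintf("%s_%s_c%d_%s_%s", g$season, g$station, g$corer,
                         g$layer, g$template)
  ctrl <- function(role, n) {
    if (n == 0) return(NULL)
    data.frame(layer = NA, corer = NA, station = NA,
               season = rep(seasons, length.out = n),
               depth_km = NA, zone = NA, template = "DNA", role = role,
               sample_id = sprintf("%s_%02d", role, seq_len(n)),
               stringsAsFactors = FALSE)
  }
  out <- rbind(g, ctrl("blank", n_blanks), ctrl("negative", n_negatives))
  rownames(out) <- NULL
  out[c("sample_id", "zone", "station", "depth_km", "corer", "layer",
        "season", "template", "role")]
}

#' @rdname sediment_design
#' @export
rna_dna_design <- function(stations = c(BC1200 = 1.232, BC1500 = 1.45,
                                        BC1750 = 1.746, OS1500 = 1.454),
                           corers = 3, n_blanks = 2, n_negatives = 2) {
  base <- sediment_design(stations, corers, seasons = "autumn",
                          n_blanks = 0, n_negatives = 0)
  rna <- base
  rna$template <- "RNA"
  rna$sample_id <- sub("_DNA$", "_RNA", rna$sample_id)
  ctrl <- sediment_design(stations, corers, seasons = "autumn",
                          n_blanks = n_blanks, n_negatives = n_negatives)
  ctrl <- ctrl[ctrl$role != "sample", , drop = FALSE]
  out <- rbind(base, rna, ctrl)
  rownames(out) <- NULL
  out
}

#' Simulate a taxonomy and reference database
#'
#' Generates a rooted taxonomy (root, supergroups including Metazoa with
#' several phyla, genera, species) with per-species marine flags, and one
#' reference sequence of 76-140 nt per species.  Reference sequences are
#' drawn independently, hence pairwise well separated, except for the
#' requested number of within-genus species pairs that share an identical
#' sequence (mirroring real markers in which distinct species can be
#' molecularly indistinguishable).
#'
#' @param n_species number of species (>= 2).
#' @param seed integer seed.
#' @param p_nonmarine probability a species is flagged non-marine
#'   (default 0.1).
#' @param shared_sequence_pairs number of species pairs forced to share one
#'   sequence (default 0).
#' @return list with `taxonomy` (a [taxonomy_tree()]) and `refs`
#'   (data.frame: ref_id, taxon_id, sequence).
#' @export
sim_taxonomy_refs <- function(n_species, seed = 1, p_nonmarine = 0.1,
                              shared_sequence_pairs = 0) {
  if (n_species < 2) stop("invalid parameter: n_species must be >= 2")
  stopifnot(shared_sequence_pairs * 2 <= n_species)
  with_seed(seed, {
    supergroups <- c("Metazoa", "Alveolata", "Rhizaria", "Stramenopiles",
                     "Hacrobia", "Amoebozoa", "Archaeplastida", "Excavata")
    metazoan_phyla <- c("Nematoda", "Arthropoda", "Annelida", "Chordata",
                        "Cnidaria", "Mollusca", "Platyhelminthes",
                        "Echinodermata")
    n_sg <- max(2, min(length(supergroups), ceiling(n_species / 8)))
    sg <- supergroups[seq_len(n_sg)]
    nodes <- data.frame(taxon_id = 1L, parent_id = NA_integer_,
                        rank = "root", name = "Eukaryota", marine = TRUE,
                        stringsAsFactors = FALSE)
    nid <- 1L
    add_node <- function(parent, rank, name, marine = TRUE) {
      nid <<- nid + 1L
      nodes <<- rbind(nodes, data.frame(taxon_id = nid, parent_id = parent,
                                        rank = rank, name = name,
                                        marine = marine,
                                        stringsAsFactors = FALSE))
      nid
    }
    sg_ids <- vapply(sg, function(s) add_node(1L, "supergroup", s), integer(1))
    # phyla: Metazoa gets >= 2 named phyla, other supergroups one generic each
    ph_ids <- integer(0); ph_parent <- integer(0)
    n_mz_ph <- max(2, min(length(metazoan_phyla), ceiling(n_species / n_sg / 3)))
    for (p in metazoan_phyla[seq_len(n_mz_ph)]) {
      ph_ids <- c(ph_ids, add_node(sg_ids[["Metazoa"]], "phylum", p))
      ph_parent <- c(ph_parent, sg_ids[["Metazoa"]])
    }
    for (s in setdiff(sg, "Metazoa")) {
      ph_ids <- c(ph_ids, add_node(sg_ids[[s]], "phylum", paste0(s, "_ph1")))
      ph_parent <- c(ph_parent, sg_ids[[s]])
    }
    # species spread round-robin over phyla, grouped into genera of <= 3
    ph_of_species <- rep(ph_ids, length.out = n_species)
    genus_of <- integer(n_species)
    genus_cache <- list()
    for (i in seq_len(n_species)) {
      key <- as.character(ph_of_species[i])
      gl <- genus_cache[[key]] %||% integer(0)
      if (length(gl) == 0 || sum(genus_of == gl[length(gl)]) >= 3) {
        g <- add_node(ph_of_species[i], "genus",
                      sprintf("genus_%03d", length(genus_cache) + i))
        gl <- c(gl, g)
        genus_cache[[key]] <- gl
      }
      genus_of[i] <- gl[length(gl)]
    }
    sp_ids <- integer(n_species)
    marine <- runif(n_species) > p_nonmarine
    for (i in seq_len(n_species))
      sp_ids[i] <- add_node(genus_of[i], "species",
                            sprintf("species_%03d", i), marine[i])
    # reference sequences, pairwise distinct unless shared on purpose
    len <- sample(76:140, n_species, replace = TRUE)
    seqs <- random_dna(n_species, len)
    while (anyDuplicated(seqs)) {
      d <- which(duplicated(seqs))
      seqs[d] <- random_dna(length(d), len[d])
    }
    if (shared_sequence_pairs > 0) {
      # share within a genus where possible so the LCA stays shallow
      pairs <- 0
      for (g in unique(genus_of)) {
        mem <- which(genus_of == g)
        if (length(mem) >= 2 && pairs < shared_sequence_pairs) {
          seqs[mem[2]] <- seqs[mem[1]]
          pairs <- pairs + 1
        }
      }
      extra <- shared_sequence_pairs - pairs
      if (extra > 0)
        for (k in seq_len(extra)) seqs[2 * k] <- seqs[2 * k - 1]
    }
    refs <- data.frame(ref_id = sprintf("ref_%03d", seq_len(n_species)),
                       taxon_id = sp_ids, sequence = seqs,
                       stringsAsFactors = FALSE)
    list(taxonomy = taxonomy_tree(nodes), refs = refs)
  })
}

#' Community simulation parameters
#'
#' Defaults encode the study conditions the pipeline is meant to recover:
#' occupancy decays with sediment layer, falls along the depth gradient,
#' differs between canyon and slope and between seasons; DNA re-detects
#' locally extinct MOTUs (legacy DNA) while RNA sees only the active
#' fraction.
#'
#' @param n_motus number of MOTUs in the regional pool.
#' @param b0 occupancy intercept on the log-odds scale (default -2,
#'   i.e. ~12\% baseline occupancy).
#' @param beta_layer log-odds change per layer step A->B->C (default -1).
#' @param beta_depth log-odds change per km of depth (default -1.5).
#' @param beta_zone slope-vs-canyon offset (default 1).
#' @param beta_season spring-vs-autumn offset (default 1).
#' @param legacy_rate probability a MOTU absent from a core but present
#'   elsewhere at the same station is still detected in DNA (default 0.2).
#' @param activity_rate probability a present MOTU is active, i.e.
#'   RNA-detectable (default 0.7).
#' @param motu_sd SD of the MOTU-level random intercept (default 1).
#' @param seed integer seed.
#' @return a `community_params` list.
#' @export
community_params <- function(n_motus = 500, b0 = -2, beta_layer = -1,
                             beta_depth = -1.5, beta_zone = 1,
                             beta_season = 1, legacy_rate = 0.2,
                             activity_rate = 0.7, motu_sd = 1, seed = 1) {
  stopifnot(n_motus >= 1,
            legacy_rate >= 0, legacy_rate <= 1,
            activity_rate >= 0, activity_rate <= 1, motu_sd >= 0)
  structure(list(n_motus = n_motus, b0 = b0, beta_layer = beta_layer,
                 beta_depth = beta_depth, beta_zone = beta_zone,
                 beta_season = beta_season, legacy_rate = legacy_rate,
                 activity_rate = activity_rate, motu_sd = motu_sd,
                 seed = seed),
            class = "community_params")
}

#' Simulate a structured sediment community
#'
#' Occupancy of MOTU i in core s is Bernoulli with
#' logit p = b0 + u_i + beta_layer*layer + beta_depth*depth + beta_zone*zone
#' + beta_season*season (layer A/B/C coded 0/1/2, zone slope = 1,
#' season spring = 1, depth centred at the design mean).  Presence and
#' activity are drawn once per physical core, so DNA and RNA samples from
#' the same core describe the same underlying community: RNA detects
#' present-and-active MOTUs (activity has a MOTU-level and a core-level
#' component with marginal rate `activity_rate`); DNA detects all present
#' MOTUs plus, with probability `legacy_rate`, MOTUs that were present at
#' the same station/corer/layer location in a different season (legacy DNA
#' persisting in the sediment).  Control samples receive zero abundance.
#'
#' @param design a design data.frame (see [sediment_design()]).
#' @param params a [community_params()] object.
#' @param abundance_mu,abundance_sigma lognormal parameters of the abundance
#'   weight given detection (defaults 1 and 1).
#' @return list of class `sim_community`: `detected` (MOTUs x samples 0/1
#'   matrix), `weights` (abundance weights, 0 where undetected), `design`.
#' @export
sim_community <- function(design, params = community_params(),
                          abundance_mu = 1, abundance_sigma = 1) {
  stopifnot(nrow(design) >= 1)
  smp <- design$role == "sample"
  lay <- match(design$layer, c("A", "B", "C")) - 1L
  if (any(smp & is.na(lay)))
    stop("invalid metadata: unknown layer level")
  if (!all(design$zone[smp] %in% c("canyon", "slope")))
    stop("invalid metadata: unknown zone level")
  if (!all(design$template %in% c("DNA", "RNA")))
    stop("invalid metadata: unknown template level")
  if (anyNA(design[smp, c("station", "corer", "season", "depth_km")]))
    stop("invalid metadata: incomplete sample annotation")
  with_seed(params$seed, {
    n <- params$n_motus
    motu_ids <- sprintf("sim_%04d", seq_len(n))
    u <- rnorm(n, 0, params$motu_sd)
    core_key <- ifelse(smp, paste(design$station, design$corer,
                                  design$layer, design$season, sep = ":"),
                       NA)
    cores <- unique(core_key[smp])
    ci <- match(core_key, cores)
    core_row <- match(cores, core_key)   # one design row per core
    dz <- design$depth_km[core_row] - mean(design$depth_km[smp])
    eta_core <- params$b0 +
      params$beta_layer * lay[core_row] +
      params$beta_depth * dz +
      params$beta_zone * (design$zone[core_row] == "slope") +
      params$beta_season * (design$season[core_row] == "spring")
    p <- plogis(outer(u, eta_core, "+"))
    Z <- matrix(rbinom(length(p), 1, p), n, length(cores))      # presence
    # activity has a MOTU-level component (some taxa occur mainly as
    # dormant or dead DNA and are rarely active anywhere) and a core-level
    # component; the symmetric square-root split keeps the marginal
    # probability of a present MOTU being RNA-detectable at activity_rate
    a_part <- sqrt(params$activity_rate)
    cap <- rbinom(n, 1, a_part)
    A <- cap * matrix(rbinom(n * length(cores), 1, a_part), n,
                      length(cores))
    # legacy pool: MOTU present at the same station/corer/layer location in
    # a different season (persistent DNA from a previous community)
    loc_key <- paste(design$station[core_row], design$corer[core_row],
                     design$layer[core_row], sep = ":")
    legacy_pool <- matrix(0L, n, length(cores))
    for (k in seq_along(cores)) {
      other <- which(loc_key == loc_key[k])
      other <- setdiff(other, k)
      if (length(other))
        legacy_pool[, k] <- as.integer(
          rowSums(Z[, other, drop = FALSE]) > 0)
    }
    det <- matrix(0L, n, nrow(design),
                  dimnames = list(motu_ids, design$sample_id))
    for (j in which(smp)) {
      z <- Z[, ci[j]]
      if (design$template[j] == "RNA") {
        det[, j] <- z * A[, ci[j]]
      } else {
        leg <- as.integer(legacy_pool[, ci[j]] == 1 & z == 0 &
                            runif(n) < params$legacy_rate)
        det[, j] <- pmax(z, leg)
      }
    }
    w <- matrix(0, n, nrow(design),
                dimnames = dimnames(det))
    nz <- det == 1
    w[nz] <- rlnorm(sum(nz), abundance_mu, abundance_sigma)
    structure(list(detected = det, weights = w, design = design,
                   params = params),
              class = "sim_community")
  })
}

#' Read simulation parameters
#'
#' @param reads_per_sample reads generated per non-control sample
#'   (default 1000).
#' @param per_base_error substitution error rate per base (default 0.01).
#' @param singleton_rate expected fraction of extra one-off random reads
#'   (default 0.005).
#' @param tag_chimera_rate fraction of reads whose two tags come from
#'   different samples (default 0.01).
#' @param cross_contam_rate fraction of reads reassigned wholesale to a
#'   random other sample before tagging (default 0.005).
#' @param read_len sequenced read length (default 120).
#' @param seed integer seed.
#' @return a `read_params` list.
#' @export
read_params <- function(reads_per_sample = 1000, per_base_error = 0.01,
                        singleton_rate = 0.005, tag_chimera_rate = 0.01,
                        cross_contam_rate = 0.005, read_len = 120,
                        seed = 1) {
  for (r in c(per_base_error, singleton_rate, tag_chimera_rate,
              cross_contam_rate))
    stopifnot(r >= 0, r <= 1)
  stopifnot(reads_per_sample >= 1, read_len >= 30)
  structure(list(reads_per_sample = reads_per_sample,
                 per_base_error = per_base_error,
                 singleton_rate = singleton_rate,
                 tag_chimera_rate = tag_chimera_rate,
                 cross_contam_rate = cross_contam_rate,
                 read_len = read_len, seed = seed),
            class = "read_params")
}

.mutate_seq <- function(x, rate) {
  if (rate <= 0) return(x)
  chars <- strsplit(x, "", fixed = TRUE)
  vapply(chars, function(s) {
    hit <- runif(length(s)) < rate
    if (any(hit))
      s[hit] <- vapply(s[hit], function(b)
        sample(setdiff(DNA_BASES, b), 1), character(1))
    paste(s, collapse = "")
  }, character(1))
}

#' Simulate tagged paired-end amplicon reads
#'
#' Each sample's reads are allocated to detected MOTUs in proportion to
#' their abundance weights; every read is the construct
#' tag + forward primer + fragment + revcomp(reverse primer) + revcomp(tag),
#' sequenced from both ends at `read_len` with uniform substitution errors.
#' Tag chimeras carry a mismatched 3' tag; cross-sample contamination
#' reassigns whole reads to a random other sample's tag; extra unique
#' one-off sequences model singleton noise.  Deterministic given the seed.
#'
#' @param community a `sim_community` (see [sim_community()]).
#' @param refs reference data.frame (ref_id, taxon_id, sequence); row i is
#'   the fragment of MOTU i.
#' @param tags a `tag_set` or character vector, one tag per design row.
#' @param params a [read_params()] object.
#' @param primer_fwd,primer_rev primer pair (IUPAC degeneracies are
#'   instantiated at random per read).
#' @return list of class `sim_reads`: `fwd`, `rev`, `fwd_qual`, `rev_qual`
#'   (named character vectors), `tag_map` (sample id -> tag), `truth`
#'   (realised MOTU x sample read counts before contamination effects) and
#'   `log` counters.
#' @export
sim_reads <- function(community, refs, tags, params = read_params(),
                      primer_fwd = PRIMER_FWD, primer_rev = PRIMER_REV) {
  design <- community$design
  if (length(tags) < nrow(design))
    stop("configuration error: a tag is required for every sample")
  tag_map <- setNames(as.character(tags[seq_len(nrow(design))]),
                      design$sample_id)
  frag <- refs$sequence
  stopifnot(length(frag) >= nrow(community$weights))
  with_seed(params$seed, {
    n_motu <- nrow(community$weights)
    truth <- matrix(0L, n_motu, nrow(design),
                    dimnames = dimnames(community$weights))
    src_motu <- integer(0); src_sample <- integer(0)
    for (j in seq_len(nrow(design))) {
      if (design$role[j] != "sample") next
      w <- community$weights[, j]
      if (sum(w) == 0) next
      cnt <- as.integer(rmultinom(1, params$reads_per_sample, w))
      truth[, j] <- cnt
      src_motu <- c(src_motu, rep(seq_len(n_motu), cnt))
      src_sample <- c(src_sample, rep(j, sum(cnt)))
    }
    n_reads <- length(src_motu)
    # cross-sample contamination: the read is tagged as another sample
    tag_sample <- src_sample
    contam <- runif(n_reads) < params$cross_contam_rate
    if (any(contam)) {
      pool <- which(design$role == "sample")
      tag_sample[contam] <- vapply(tag_sample[contam], function(s)
        sample(setdiff(pool, s), 1), integer(1))
    }
    # instantiate primers (resolve IUPAC degeneracies once per read batch)
    inst <- function(p) {
      s <- strsplit(p, "", fixed = TRUE)[[1]]
      amb <- !(s %in% DNA_BASES)
      s[amb] <- vapply(s[amb], function(b)
        sample(DNA_BASES[bitwAnd(.iupac_mask[b], 2^(0:3)) > 0], 1),
        character(1))
      paste(s, collapse = "")
    }
    fragments <- .mutate_seq(frag[src_motu], params$per_base_error)
    t5 <- tag_map[design$sample_id[tag_sample]]
    t3 <- t5
    chim <- runif(n_reads) < params$tag_chimera_rate
    if (any(chim)) {
      all_tags <- unname(tag_map)
      t3[chim] <- vapply(t3[chim], function(tg)
        sample(setdiff(all_tags, tg), 1), character(1))
    }
    pf <- vapply(seq_len(n_reads), function(i) inst(primer_fwd), character(1))
    pr <- vapply(seq_len(n_reads), function(i) inst(primer_rev), character(1))
    construct <- paste0(t5, pf, fragments, revcomp(pr), revcomp(t3))
    # singleton injections: unique random fragments, one read each
    n_single <- rbinom(1, n_reads, params$singleton_rate)
    if (n_single > 0) {
      sl <- sample(76:140, n_single, replace = TRUE)
      sfrag <- random_dna(n_single, sl)
      stag <- tag_map[sample(design$sample_id[design$role == "sample"],
                             n_single, replace = TRUE)]
      pf_s <- vapply(seq_len(n_single), function(i) inst(primer_fwd),
                     character(1))
      pr_s <- vapply(seq_len(n_single), function(i) inst(primer_rev),
                     character(1))
      construct <- c(construct,
                     paste0(stag, pf_s, sfrag, revcomp(pr_s), revcomp(stag)))
      chim <- c(chim, rep(FALSE, n_single))
    }
    rl <- params$read_len
    fwd <- substr(construct, 1, pmin(rl, nchar(construct)))
    rev_ <- revcomp(substr(construct,
                           pmax(1, nchar(construct) - rl + 1),
                           nchar(construct)))
    ids <- sprintf("read_%06d", seq_along(construct))
    qual <- strrep("I", nchar(fwd))
    qual_r <- strrep("I", nchar(rev_))
    structure(list(fwd = setNames(fwd, ids), rev = setNames(rev_, ids),
                   fwd_qual = setNames(qual, ids),
                   rev_qual = setNames(qual_r, ids),
                   tag_map = tag_map, truth = truth,
                   log = list(n_reads = length(construct),
                              n_chimera = sum(chim),
                              n_contam = sum(contam),
                              n_singleton = n_single)),
              class = "sim_reads")
  })
}

#' Write the simulated inputs of a pipeline run
#'
#' Writes paired FASTQ, reference FASTA (with `taxid=<int>` headers),
#' taxonomy TSV, sample sheet TSV and tag sheet TSV under `dir`.
#'
#' @param reads a `sim_reads` object.
#' @param taxrefs output of [sim_taxonomy_refs()].
#' @param design the design data.frame.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_inputs <- function(reads, taxrefs, design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(reads$fwd, reads$fwd_qual, file.path(dir, "reads_R1.fastq"))
  write_fastq(reads$rev, reads$rev_qual, file.path(dir, "reads_R2.fastq"))
  refs <- taxrefs$refs
  write_fasta(setNames(refs$sequence,
                       sprintf("%s taxid=%d", refs$ref_id, refs$taxon_id)),
              file.path(dir, "refs.fasta"))
  write_taxonomy(taxrefs$taxonomy, file.path(dir, "taxonomy.tsv"))
  write.table(design, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(reads$tag_map),
                         tag = unname(reads$tag_map)),
              file.path(dir, "tags.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
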