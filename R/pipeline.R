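#' Default pipeline parameters
#'
#' @param min_score paired-end merge score threshold (default 40).
#' @param min_len minimum insert length after trimming (default 75).
#' @param max_primer_mismatch primer mismatches tolerated (default 2).
#' @param min_identity reference-cleaning identity threshold (default 0.8).
#' @param init_similarity,lower_l,upper_u clustering parameters
#'   (defaults 0.99, 0.3, 0.5).
#' @param cum_threshold cumulative-frequency filter threshold (default 0.03).
#' @param neighbour_rule LCA co-assignment rule, see [lca_assign()].
#' @param seed global seed.
#' @return a named list of stage parameters.
#' @export
pipeline_params <- function(min_score = 40, min_len = 75,
                            max_primer_mismatch = 2, min_identity = 0.8,
                            init_similarity = 0.99, lower_l = 0.3,
                            upper_u = 0.5, cum_threshold = 0.03,
                            neighbour_rule = "besthit", seed = 1) {
  list(min_score = min_score, min_len = min_len,
       max_primer_mismatch = max_primer_mismatch,
       min_identity = min_identity, init_similarity = init_similarity,
       lower_l = lower_l, upper_u = upper_u, cum_threshold = cum_threshold,
       neighbour_rule = neighbour_rule, seed = seed)
}

#' Run the full pipeline on in-memory inputs
#'
#' Executes merge -> demultiplex -> dereplicate -> singleton removal ->
#' similarity cleaning -> MOTU clustering -> taxonomic assignment ->
#' table filters, returning the final `motu_table` (whose stage log records
#' sequences and reads in/out per stage) plus intermediate artefacts.
#'
#' @param fwd,rev named character vectors of raw mate sequences (or a
#'   `sim_reads` object passed as `fwd`).
#' @param tag_map named character vector sample id -> tag.
#' @param design sample design data.frame (see [sediment_design()]).
#' @param refs reference data.frame (ref_id, taxon_id, sequence).
#' @param tree a `taxonomy_tree`.
#' @param params a [pipeline_params()] list.
#' @param primer_fwd,primer_rev primer pair.
#' @return list of class `pipeline_result`: `table` (filtered `motu_table`),
#'   `table_unfiltered`, `motus`, `assignments`, `logs`.
#' @export
run_pipeline <- function(fwd, rev = NULL, tag_map = NULL, design, refs,
                         tree, params = pipeline_params(),
                         primer_fwd = PRIMER_FWD, primer_rev = PRIMER_REV) {
  if (inherits(fwd, "sim_reads")) {
    sim <- fwd
    fwd <- sim$fwd; rev <- sim$rev
    tag_map <- tag_map %||% sim$tag_map
  }
  stopifnot(length(fwd) == length(rev), !is.null(tag_map))
  logs <- list()

  mg <- merge_pairs(fwd, rev, min_score = params$min_score)
  logs$merge <- mg$log
  dmx <- demultiplex(mg$sequences, tag_map, primer_fwd, primer_rev,
                     max_primer_mismatch = params$max_primer_mismatch,
                     min_len = params$min_len)
  logs$demux <- dmx$log
  uniq <- dereplicate(dmx$samples)
  uniq <- remove_singletons(uniq)
  if (nrow(uniq) == 0) stop("data error: no sequences left after filtering")
  cl <- clean_by_similarity(uniq, setNames(refs$sequence, refs$ref_id),
                            min_identity = params$min_identity)
  logs$clean <- cl$summary
  if (nrow(cl$kept) == 0) stop("data error: no sequences pass cleaning")
  motus <- cluster_motus(cl$kept, init_similarity = params$init_similarity,
                         lower_l = params$lower_l, upper_u = params$upper_u,
                         seed = params$seed)
  assignments <- assign_motus(motus, refs, tree,
                              neighbour_rule = params$neighbour_rule)
  counts <- t(vapply(motus, function(m) m$counts,
                     numeric(length(motus[[1]]$counts))))
  rownames(counts) <- vapply(motus, function(m) m$motu_id, character(1))
  # all design samples as columns, zero-filling those with no reads
  full <- matrix(0L, nrow(counts), nrow(design),
                 dimnames = list(rownames(counts), design$sample_id))
  shared <- intersect(colnames(counts), design$sample_id)
  full[, shared] <- counts[, shared]
  tab0 <- motu_table(full, motus = assignments, samples = design)

  tab <- cumulative_frequency_filter(tab0, params$cum_threshold)
  if (any(design$role %in% c("blank", "negative")))
    tab <- remove_control_motus(tab)
  tab <- remove_unassignable(tab)
  tab <- remove_nonmarine(tab)

  structure(list(table = tab, table_unfiltered = tab0, motus = motus,
                 assignments = assignments, logs = logs),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  print(x$table)
  invisible(x)
}

#' Simulate inputs and run the pipeline end to end
#'
#' One-command synthetic demonstration: simulates a taxonomy/reference
#' database, a structured community on the given design, tagged paired
#' reads, and pushes them through [run_pipeline()].
#'
#' @param design sampling design (default [rna_dna_design()]).
#' @param n_species reference species count (default 40).
#' @param cparams a [community_params()]; its `n_motus` is forced to
#'   `n_species`.
#' @param rparams a [read_params()].
#' @param params a [pipeline_params()].
#' @param seed global seed, offset per stage.
#' @return list: `result` (a `pipeline_result`), `sim` (reads), `community`,
#'   `taxrefs`, `tags`.
#' @export
simulate_and_run <- function(design = rna_dna_design(), n_species = 40,
                             cparams = community_params(),
                             rparams = read_params(),
                             params = pipeline_params(), seed = 1) {
  cparams$n_motus <- n_species
  cparams$seed <- seed + 1
  rparams$seed <- seed + 2
  taxrefs <- sim_taxonomy_refs(n_species, seed = seed)
  comm <- sim_community(design, cparams)
  tags <- design_tags(nrow(design), seed = seed + 3)
  sim <- sim_reads(comm, taxrefs$refs, tags, rparams)
  res <- run_pipeline(sim, design = design, refs = taxrefs$refs,
                      tree = taxrefs$taxonomy, params = params)
  list(result = res, sim = sim, community = comm, taxrefs = taxrefs,
       tags = tags)
}

#' Text report of a pipeline run
#'
#' Summarises the filtered table the way the analysis is usually presented:
#' stage log, MOTU richness by Super-Group (and metazoan Phylum), the
#' seven-region layer partition, and — when both templates are present —
#' the DNA/RNA comparison block.
#'
#' @param res a `pipeline_result`.
#' @param file optional path; the report is also returned as a character
#'   vector.
#' @return character vector of report lines, invisibly when `file` given.
#' @export
report <- function(res, file = NULL) {
  tab <- res$table
  ln <- c("== Pipeline report ==", "",
          "-- Stage log --",
          utils::capture.output(print(tab$log, row.names = FALSE)), "")
  if (!is.null(tab$motus) && "supergroup" %in% names(tab$motus)) {
    sg <- table(tab$motus$supergroup)
    ln <- c(ln, "-- MOTUs per Super-Group --",
            sprintf("%-20s %d", names(sg), as.integer(sg)), "")
    mz <- tab$motus$phylum[!is.na(tab$motus$phylum)]
    if (length(mz)) {
      ph <- table(mz)
      ln <- c(ln, "-- Metazoan MOTUs per Phylum --",
              sprintf("%-20s %d", names(ph), as.integer(ph)), "")
    }
  }
  if (!is.null(tab$samples) && "layer" %in% names(tab$samples) &&
      !all(is.na(tab$samples$layer))) {
    lp <- layer_partition(tab)
    ln <- c(ln, "-- Layer partition (Venn regions) --",
            sprintf("%-10s %d", names(lp), as.integer(unlist(lp))), "")
  }
  if (!is.null(tab$samples) && "template" %in% names(tab$samples) &&
      all(c("DNA", "RNA") %in% tab$samples$template)) {
    dna <- .subset_samples(tab, tab$samples$template == "DNA")
    rna <- .subset_samples(tab, tab$samples$template == "RNA")
    cmp <- compare_datasets(dna, rna)
    ln <- c(ln, "-- DNA vs RNA --",
            sprintf("total MOTUs: DNA %d, RNA %d (+%.1f%%)",
                    cmp$total_x, cmp$total_y, cmp$pct_increase_total),
            sprintf("mean per-sample richness: DNA %.1f, RNA %.1f (+%.1f%%)",
                    cmp$mean_per_sample_x, cmp$mean_per_sample_y,
                    cmp$pct_increase_per_sample),
            sprintf("shared MOTUs: %d (%.1f%% of union)", cmp$shared,
                    cmp$shared_fraction), "")
  }
  if (!is.null(file)) {
    writeLines(ln, file)
    return(invisible(ln))
  }
  ln
}

#' Run the pipeline from files on disk
#'
#' Reads the inputs laid out by [write_sim_inputs()] — paired FASTQ,
#' reference FASTA with `taxid=<int>` headers, taxonomy TSV, sample sheet
#' TSV and tag sheet TSV — and calls [run_pipeline()].
#'
#' @param dir directory containing `reads_R1.fastq`, `reads_R2.fastq`,
#'   `refs.fasta`, `taxonomy.tsv`, `samples.tsv`, `tags.tsv`.
#' @param params a [pipeline_params()] list.
#' @param primer_fwd,primer_rev primer pair.
#' @return a `pipeline_result`, see [run_pipeline()].
#' @export
run_pipeline_dir <- function(dir, params = pipeline_params(),
                             primer_fwd = PRIMER_FWD,
                             primer_rev = PRIMER_REV) {
  need <- c("reads_R1.fastq", "reads_R2.fastq", "refs.fasta",
            "taxonomy.tsv", "samples.tsv", "tags.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("configuration error: missing input file(s): ",
         paste(missing, collapse = ", "))
  r1 <- read_fastq(file.path(dir, "reads_R1.fastq"))
  r2 <- read_fastq(file.path(dir, "reads_R2.fastq"))
  fa <- read_fasta(file.path(dir, "refs.fasta"))
  hdr <- names(fa)
  refs <- data.frame(ref_id = sub(" .*", "", hdr),
                     taxon_id = as.integer(sub(".*taxid=([0-9]+).*", "\\1",
                                               hdr)),
                     sequence = unname(fa), stringsAsFactors = FALSE)
  tree <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  design <- read.delim(file.path(dir, "samples.tsv"),
                       stringsAsFactors = FALSE)
  tags <- read.delim(file.path(dir, "tags.tsv"), stringsAsFactors = FALSE)
  tag_map <- setNames(tags$tag, tags$sample_id)
  run_pipeline(r1$sequences, r2$sequences, tag_map, design, refs, tree,
               params, primer_fwd, primer_rev)
}
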