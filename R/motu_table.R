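#' Construct a MOTU table
#'
#' The central container of the analysis: a MOTUs x samples count matrix
#' plus MOTU annotations (taxonomic assignment) and sample annotations
#' (the design sheet).  A stage log records (MOTUs, reads) through the
#' filtering cascade.
#'
#' @param counts non-negative integer matrix, MOTUs in rows, samples in
#'   columns (both dimnames required).
#' @param motus data.frame of MOTU annotations with a `motu_id` column
#'   matching rownames(counts); may be NULL.
#' @param samples data.frame of sample annotations with a `sample_id` column
#'   matching colnames(counts); may be NULL.
#' @return object of class `motu_table`.
#' @export
motu_table <- function(counts, motus = NULL, samples = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 0 || !is.null(rownames(counts)),
            !is.null(colnames(counts)), all(counts >= 0))
  if (!is.null(motus)) {
    stopifnot("motu_id" %in% names(motus))
    motus <- motus[match(rownames(counts), motus$motu_id), , drop = FALSE]
    rownames(motus) <- NULL
  }
  if (!is.null(samples)) {
    stopifnot("sample_id" %in% names(samples))
    samples <- samples[match(colnames(counts), samples$sample_id), ,
                       drop = FALSE]
    rownames(samples) <- NULL
  }
  structure(list(counts = counts, motus = motus, samples = samples,
                 log = data.frame(stage = "initial",
                                  motus = nrow(counts),
                                  reads = sum(counts),
                                  stringsAsFactors = FALSE)),
            class = "motu_table")
}

#' @export
print.motu_table <- function(x, ...) {
  cat("MOTU table:", nrow(x$counts), "MOTUs x", ncol(x$counts),
      "samples,", sum(x$counts), "reads\n")
  if (nrow(x$log) > 1) {
    cat("stages:\n")
    print(x$log, row.names = FALSE)
  }
  invisible(x)
}

#' @export
dim.motu_table <- function(x) dim(x$counts)

.log_stage <- function(tab, stage) {
  tab$log <- rbind(tab$log,
                   data.frame(stage = stage, motus = nrow(tab$counts),
                              reads = sum(tab$counts),
                              stringsAsFactors = FALSE))
  tab
}

.subset_motus <- function(tab, keep) {
  tab$counts <- tab$counts[keep, , drop = FALSE]
  if (!is.null(tab$motus)) {
    tab$motus <- tab$motus[keep, , drop = FALSE]
    rownames(tab$motus) <- NULL
  }
  tab
}

.subset_samples <- function(tab, keep) {
  tab$counts <- tab$counts[, keep, drop = FALSE]
  if (!is.null(tab$samples)) {
    tab$samples <- tab$samples[keep, , drop = FALSE]
    rownames(tab$samples) <- NULL
  }
  tab
}

#' Cumulative-frequency contamination filter
#'
#' For every MOTU the per-sample counts are ordered from lowest to highest
#' and the entries whose running cumulative sum (including the entry itself)
#' stays below `cum_threshold` of the row total are set to zero.  Ties among
#' equal counts are zeroed together if and only if the cumulative fraction
#' through the last tied entry is below the threshold, so the result does
#' not depend on sort order.  Rows that become all-zero are dropped (and
#' logged).  This strips low-level cross-sample bleed introduced during
#' library preparation.
#'
#' @param tab a `motu_table`.
#' @param cum_threshold cumulative-frequency threshold in \[0, 1)
#'   (default 0.03).
#' @return the filtered `motu_table`.
#' @export
cumulative_frequency_filter <- function(tab, cum_threshold = 0.03) {
  stopifnot(inherits(tab, "motu_table"),
            cum_threshold >= 0, cum_threshold < 1)
  cnt <- tab$counts
  if (cum_threshold > 0 && nrow(cnt) > 0) {
    for (i in seq_len(nrow(cnt))) {
      x <- cnt[i, ]
      tot <- sum(x)
      if (tot == 0) next
      vals <- sort(unique(x))
      cum <- 0
      for (v in vals) {
        grp <- x == v
        cum <- cum + v * sum(grp)
        if (cum / tot < cum_threshold) x[grp] <- 0 else break
      }
      cnt[i, ] <- x
    }
  }
  tab$counts <- cnt
  keep <- rowSums(cnt) > 0
  tab <- .subset_motus(tab, keep)
  .log_stage(tab, sprintf("cumulative_frequency_filter(%g)", cum_threshold))
}

#' Remove MOTUs detected in blanks or negative controls
#'
#' Any MOTU with a nonzero count in any control sample (role `blank` or
#' `negative`) is removed from the whole table; the control samples are then
#' dropped.
#'
#' @param tab a `motu_table` with a `role` column in its sample annotation.
#' @return the filtered `motu_table`.
#' @export
remove_control_motus <- function(tab) {
  stopifnot(inherits(tab, "motu_table"), !is.null(tab$samples),
            "role" %in% names(tab$samples))
  ctrl <- tab$samples$role %in% c("blank", "negative")
  if (!any(ctrl)) {
    warning("no control samples present; table returned unchanged")
    return(.log_stage(tab, "remove_control_motus(no-op)"))
  }
  bad <- rowSums(tab$counts[, ctrl, drop = FALSE] > 0) > 0
  tab <- .subset_motus(tab, !bad)
  tab <- .subset_samples(tab, !ctrl)
  .log_stage(tab, "remove_control_motus")
}

#' Remove MOTUs assigned to non-marine taxa
#'
#' @param tab a `motu_table` whose MOTU annotation carries a logical
#'   `marine` column.
#' @return the filtered `motu_table`.
#' @export
remove_nonmarine <- function(tab) {
  stopifnot(inherits(tab, "motu_table"), !is.null(tab$motus),
            "marine" %in% names(tab$motus))
  keep <- tab$motus$marine %in% TRUE
  tab <- .subset_motus(tab, keep)
  .log_stage(tab, "remove_nonmarine")
}

#' Remove MOTUs not assignable at the Super-Group level
#'
#' @param tab a `motu_table` whose MOTU annotation carries an
#'   `unassignable` column.
#' @return the filtered `motu_table`.
#' @export
remove_unassignable <- function(tab) {
  stopifnot(inherits(tab, "motu_table"), !is.null(tab$motus),
            "unassignable" %in% names(tab$motus))
  tab <- .subset_motus(tab, !(tab$motus$unassignable %in% TRUE))
  .log_stage(tab, "remove_unassignable")
}

#' Presence matrix of a MOTU table
#'
#' @param tab a `motu_table` or count matrix.
#' @return logical matrix of the same shape (count >= 1).
#' @export
presence <- function(tab) {
  m <- if (inherits(tab, "motu_table")) tab$counts else as.matrix(tab)
  m >= 1
}

#' Seven-region layer partition (Venn counts)
#'
#' Pools samples by sediment layer (presence = any nonzero count in any
#' sample of that layer) and partitions the MOTUs into the seven Venn
#' regions of layers A, B, C.
#'
#' @param tab a `motu_table` with a `layer` column in its sample annotation.
#' @return named list: `A_only`, `B_only`, `C_only`, `AB`, `AC`, `BC`,
#'   `ABC`, per-layer totals `A`, `B`, `C`, and `union`.
#' @export
layer_partition <- function(tab) {
  stopifnot(inherits(tab, "motu_table"), !is.null(tab$samples),
            "layer" %in% names(tab$samples))
  lay <- tab$samples$layer
  if (!all(lay[!is.na(lay)] %in% c("A", "B", "C")))
    stop("invalid metadata: layer must be A, B or C")
  pres <- presence(tab)
  inL <- vapply(c("A", "B", "C"), function(l)
    rowSums(pres[, !is.na(lay) & lay == l, drop = FALSE]) > 0,
    logical(nrow(pres)))
  a <- inL[, "A"]; b <- inL[, "B"]; cc <- inL[, "C"]
  list(A_only = sum(a & !b & !cc), B_only = sum(!a & b & !cc),
       C_only = sum(!a & !b & cc),
       AB = sum(a & b & !cc), AC = sum(a & !b & cc), BC = sum(!a & b & cc),
       ABC = sum(a & b & cc),
       A = sum(a), B = sum(b), C = sum(cc),
       union = sum(a | b | cc))
}

#' Dataset union by inclusion-exclusion from printed layer counts
#'
#' Recovers the size of the three-layer union from the usual published
#' summary of a layer Venn diagram: per-layer totals, per-layer exclusive
#' counts and the triple intersection.  The sum of the three pairwise-only
#' regions equals (sum of totals - sum of exclusives - 3 x triple) / 2.
#'
#' @param totals per-layer totals (length 3).
#' @param exclusives per-layer exclusive counts (length 3).
#' @param triple MOTUs shared by all three layers.
#' @return list with `pairwise_only_sum` and `union`.
#' @export
layer_union_from_counts <- function(totals, exclusives, triple) {
  stopifnot(length(totals) == 3, length(exclusives) == 3, triple >= 0)
  pw <- (sum(totals) - sum(exclusives) - 3 * triple) / 2
  if (pw < 0 || pw != round(pw))
    stop("inconsistent Venn counts")
  list(pairwise_only_sum = pw,
       union = sum(exclusives) + pw + triple)
}

#' Compare two MOTU datasets (e.g. DNA vs RNA)
#'
#' @param x,y `motu_table`s over the same MOTU id space, or presence
#'   matrices with shared rownames.
#' @return list (values rounded to one decimal where percentages):
#'   `total_x`, `total_y`, `shared`, `only_x`, `only_y`, `union`,
#'   `pct_increase_total`, `pct_increase_per_sample`, `shared_fraction`,
#'   `mean_per_sample_x`, `mean_per_sample_y`.
#' @export
compare_datasets <- function(x, y) {
  px <- presence(x); py <- presence(y)
  if (nrow(px) == 0 || nrow(py) == 0) stop("invalid input: empty table")
  ids <- union(rownames(px), rownames(py))
  in_x <- ids %in% rownames(px)[rowSums(px) > 0]
  in_y <- ids %in% rownames(py)[rowSums(py) > 0]
  mx <- mean(colSums(px)); my <- mean(colSums(py))
  out <- compare_counts(sum(in_x), sum(in_y), mx, my,
                        union_total = sum(in_x | in_y))
  out$shared <- sum(in_x & in_y)
  out$only_x <- sum(in_x & !in_y)
  out$only_y <- sum(in_y & !in_x)
  out
}

#' @rdname compare_datasets
#' @param total_x,total_y dataset MOTU totals.
#' @param mean_per_sample_x,mean_per_sample_y mean per-sample richness.
#' @param union_total MOTUs in the union of the datasets.
#' @export
compare_counts <- function(total_x, total_y, mean_per_sample_x = NA,
                           mean_per_sample_y = NA, union_total = NA) {
  stopifnot(total_x > 0, total_y > 0)
  shared <- if (is.na(union_total)) NA else total_x + total_y - union_total
  list(total_x = total_x, total_y = total_y, union = union_total,
       shared = shared,
       only_x = if (is.na(union_total)) NA else union_total - total_y,
       only_y = if (is.na(union_total)) NA else union_total - total_x,
       mean_per_sample_x = mean_per_sample_x,
       mean_per_sample_y = mean_per_sample_y,
       pct_increase_total = round(100 * (total_x - total_y) / total_y, 1),
       pct_increase_per_sample =
         round(100 * (mean_per_sample_x - mean_per_sample_y) /
                 mean_per_sample_y, 1),
       shared_fraction = if (is.na(union_total)) NA else
         round(100 * shared / union_total, 1))
}

#' Per-sample MOTU richness
#'
#' @param tab a `motu_table`.
#' @return named integer vector (MOTUs present per sample).
#' @export
sample_richness <- function(tab) colSums(presence(tab))

#' Write a MOTU table and its annotations as TSV
#' @param tab a `motu_table`; `dir` output directory.
#' @export
write_motu_table <- function(tab, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(motu_id = rownames(tab$counts), tab$counts,
                         check.names = FALSE),
              file.path(dir, "motu_counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(tab$motus))
    write.table(tab$motus, file.path(dir, "motu_annotations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(tab$samples))
    write.table(tab$samples, file.path(dir, "sample_annotations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tab$log, file.path(dir, "stage_log.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
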