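#' Pairwise sequence identity
#'
#' Global end-to-end alignment maximising the number of matched bases
#' (match +1, mismatch and gap 0); identity is matches divided by the
#' alignment length (the shortest alignment achieving the maximal match
#' count).  This normalisation penalises length outliers: a short query
#' against a long reference cannot score high even if fully contained.
#' An alternative normalisation by the query length is available.
#'
#' @param a,b sequences; `a` may be a character vector (identity of each
#'   element against scalar `b`).
#' @param normalise `"alignment"` (default) or `"query"`.
#' @return numeric identity value(s) in \[0, 1\].
#' @export
seq_identity <- function(a, b, normalise = c("alignment", "query")) {
  normalise <- match.arg(normalise)
  stopifnot(all(nzchar(a)), nzchar(b))
  if (normalise == "alignment") {
    as.numeric(cpp_identity_matrix(a, b))
  } else {
    vapply(a, function(x) {
      r <- cpp_identity_pair(x, b)
      unname(r["matches"]) / nchar(x)
    }, numeric(1), USE.NAMES = FALSE)
  }
}

#' Identity of every query against every reference
#'
#' @param queries,refs character vectors of sequences.
#' @return numeric matrix, queries in rows.
#' @export
identity_matrix <- function(queries, refs) {
  stopifnot(length(queries) > 0, length(refs) > 0)
  m <- cpp_identity_matrix(queries, refs)
  dimnames(m) <- list(names(queries), names(refs))
  m
}

#' Cleaning by similarity against a reference database
#'
#' Removes unique sequences whose best identity against the reference set
#' falls below `min_identity` (default 0.8).  Highly divergent sequences —
#' typically long chimeras, sequencing artefacts or non-specific products —
#' fail to reach the threshold and are pruned before clustering.  The
#' best-hit identity of every kept sequence is retained for reuse by the
#' taxonomic assignment step.
#'
#' @param seqs a `unique_seqs` data.frame (see [dereplicate()]).
#' @param refs named character vector of reference sequences.
#' @param min_identity minimum best-hit identity to keep (default 0.8);
#'   sequences at exactly the threshold are kept.
#' @param normalise identity normalisation, see [seq_identity()].
#' @param length_bin width (nt) of the length bins in the summary.
#' @return list with `kept` and `removed` (`unique_seqs` with an extra
#'   `best_identity` column) and `summary`, a data.frame of kept/removed
#'   counts per sequence-length bin.
#' @export
clean_by_similarity <- function(seqs, refs, min_identity = 0.8,
                                normalise = c("alignment", "query"),
                                length_bin = 10) {
  if (length(refs) == 0) stop("configuration error: empty reference set")
  normalise <- match.arg(normalise)
  stopifnot(min_identity >= 0, min_identity <= 1)
  if (nrow(seqs) == 0) {
    seqs$best_identity <- numeric(0)
    return(list(kept = seqs, removed = seqs,
                summary = data.frame(length_bin = numeric(0),
                                     kept = integer(0), removed = integer(0))))
  }
  if (normalise == "alignment") {
    idm <- cpp_identity_matrix(seqs$sequence, unname(refs))
    best <- apply(idm, 1, max)
  } else {
    best <- apply(vapply(unname(refs), function(r)
      seq_identity(seqs$sequence, r, normalise = "query"),
      numeric(nrow(seqs))), 1, max)
  }
  seqs$best_identity <- as.numeric(best)
  keep <- seqs$best_identity >= min_identity
  len <- nchar(seqs$sequence)
  bins <- length_bin * (len %/% length_bin)
  summ <- aggregate(cbind(kept = keep, removed = !keep),
                    by = list(length_bin = bins), FUN = sum)
  kept <- seqs[keep, , drop = FALSE]; rownames(kept) <- NULL
  removed <- seqs[!keep, , drop = FALSE]; rownames(removed) <- NULL
  list(kept = kept, removed = removed, summary = summ)
}
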