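#' Design a set of sample tags
#'
#' Greedy construction of short oligonucleotide tags used to label samples at
#' both ends of the amplicon.  Every pair of tags differs at a minimum number
#' of positions so that sequencing errors cannot convert one sample's tag
#' into another's.
#'
#' @param n number of tags required.
#' @param length tag length in bases (default 8).
#' @param min_hamming minimum pairwise Hamming distance (default 3).
#' @param seed integer seed; the accepted set is deterministic given the seed.
#' @return an object of class `tag_set`: character vector of tags with
#'   attributes `length` and `min_hamming`.
#' @export
design_tags <- function(n, length = 8, min_hamming = 3, seed = 1) {
  stopifnot(n >= 1, length >= 1, min_hamming >= 1)
  if (min_hamming > length || 4^length < n)
    stop("capacity error: cannot fit ", n, " tags of length ", length,
         " at minimum Hamming distance ", min_hamming)
  with_seed(seed, {
    # enumerate the full 4^length code book (length <= 8 keeps this small),
    # visit it in random order, accept greedily
    grid <- as.matrix(expand.grid(rep(list(seq_len(4)), length)))
    grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
    acc <- matrix(integer(0), nrow = 0, ncol = length)
    for (i in seq_len(nrow(grid))) {
      cand <- grid[i, ]
      if (nrow(acc) == 0 ||
          min(rowSums(acc != rep(cand, each = nrow(acc)))) >= min_hamming)
        acc <- rbind(acc, cand)
      if (nrow(acc) == n) break
    }
    if (nrow(acc) < n)
      stop("capacity error: greedy search exhausted after ",
           nrow(acc), " tags")
    tags <- apply(acc, 1, function(r) paste(DNA_BASES[r], collapse = ""))
    structure(unname(tags), class = "tag_set",
              length = length, min_hamming = min_hamming)
  })
}

#' Merge one read pair by best ungapped overlap
#'
#' Aligns the forward read against the reverse-complemented mate at every
#' relative offset, scoring +1 per matching base and -1 per mismatch over the
#' overlap.  The consensus takes the higher-quality base at conflicting
#' positions.  Pairs scoring below `min_score` are rejected (`low_score`);
#' merged inserts shorter than `min_len` after primer/tag removal are
#' rejected downstream (`short`, see [demultiplex()]).
#'
#' @param fwd,rev forward/reverse read sequences (character scalars).
#' @param fwd_qual,rev_qual Phred+33 quality strings (default constant Q40).
#' @param min_score minimum alignment score to accept a merge (default 40).
#' @return a list with `accepted`, `sequence`, `quality`, `score`, `overlap`
#'   and, when rejected, `reason`.
#' @export
merge_pair <- function(fwd, rev, fwd_qual = NULL, rev_qual = NULL,
                       min_score = 40) {
  stopifnot(nzchar(fwd), nzchar(rev))
  if (is.null(fwd_qual)) fwd_qual <- strrep("I", nchar(fwd))
  if (is.null(rev_qual)) rev_qual <- strrep("I", nchar(rev))
  rrc <- revcomp(rev)
  rqr <- vapply(strsplit(rev_qual, "", fixed = TRUE),
                function(s) paste(rev(s), collapse = ""), character(1))
  m <- cpp_merge_overlap(fwd, rrc, fwd_qual, rqr)
  if (m$score < min_score)
    return(list(accepted = FALSE, reason = "low_score", score = m$score,
                overlap = m$overlap))
  list(accepted = TRUE, sequence = m$sequence, quality = m$quality,
       score = m$score, overlap = m$overlap)
}

#' Merge many read pairs
#'
#' Vectorised driver for [merge_pair()].
#'
#' @param fwd,rev character vectors of mate sequences.
#' @param fwd_qual,rev_qual optional quality strings.
#' @param min_score score threshold (default 40).
#' @return list with `sequences`, `qualities` (accepted merges, names kept)
#'   and `log`, a data.frame of (read, accepted, score, reason).
#' @export
merge_pairs <- function(fwd, rev, fwd_qual = NULL, rev_qual = NULL,
                        min_score = 40) {
  stopifnot(length(fwd) == length(rev))
  ids <- names(fwd) %||% as.character(seq_along(fwd))
  out_seq <- character(0); out_q <- character(0)
  acc <- logical(length(fwd)); sc <- integer(length(fwd))
  reason <- rep(NA_character_, length(fwd))
  for (i in seq_along(fwd)) {
    m <- merge_pair(fwd[i], rev[i],
                    if (is.null(fwd_qual)) NULL else fwd_qual[i],
                    if (is.null(rev_qual)) NULL else rev_qual[i],
                    min_score = min_score)
    acc[i] <- m$accepted; sc[i] <- m$score
    if (m$accepted) {
      out_seq <- c(out_seq, setNames(m$sequence, ids[i]))
      out_q <- c(out_q, m$quality)
    } else reason[i] <- m$reason
  }
  list(sequences = out_seq, qualities = out_q,
       log = data.frame(read = ids, accepted = acc, score = sc,
                        reason = reason, stringsAsFactors = FALSE))
}

#' Assign merged reads to samples by their terminal tags
#'
#' A read is assigned when both terminal tags match (exactly) the same
#' sample's tag and both primers are recognised with at most
#' `max_primer_mismatch` mismatches (IUPAC-aware).  Reads carrying two
#' different valid tags are inter-sample PCR chimeras and are discarded;
#' the identical-tags-at-both-ends design makes them detectable here.
#' Both orientations of each read are tried; the first that assigns wins.
#'
#' @param reads character vector of merged reads.
#' @param tag_map named character vector, sample id -> tag (injective).
#' @param primer_fwd,primer_rev primer sequences (IUPAC allowed), given in
#'   the orientation in which they were synthesised.
#' @param max_primer_mismatch mismatches tolerated per primer (default 2).
#' @param min_len minimum insert length after trimming (default 75).
#' @return a list: `samples` named list of character vectors of trimmed
#'   inserts per sample id, and `log` data.frame (read, outcome) with
#'   outcomes assigned / chimera / untagged / primer_fail / short.
#' @export
demultiplex <- function(reads, tag_map, primer_fwd, primer_rev,
                        max_primer_mismatch = 2, min_len = 75) {
  if (anyDuplicated(tag_map))
    stop("configuration error: duplicate tag in tag map")
  tl <- nchar(tag_map[1])
  fl <- nchar(primer_fwd); rl <- nchar(primer_rev)
  ids <- names(reads) %||% as.character(seq_along(reads))
  samples <- setNames(vector("list", length(tag_map)), names(tag_map))
  for (s in names(samples)) samples[[s]] <- character(0)
  outcome <- character(length(reads)); assigned_to <- rep(NA_character_, length(reads))
  inserts <- rep(NA_character_, length(reads))

  classify <- function(x) {
    n <- nchar(x)
    if (n < 2 * tl + fl + rl + 1) return(list(outcome = "untagged"))
    t5 <- substr(x, 1, tl)
    t3 <- revcomp(substr(x, n - tl + 1, n))
    i5 <- match(t5, tag_map); i3 <- match(t3, tag_map)
    if (is.na(i5) || is.na(i3)) return(list(outcome = "untagged"))
    if (i5 != i3) return(list(outcome = "chimera"))
    p5 <- substr(x, tl + 1, tl + fl)
    p3 <- revcomp(substr(x, n - tl - rl + 1, n - tl))
    if (.iupac_mismatches(p5, primer_fwd) > max_primer_mismatch ||
        .iupac_mismatches(p3, primer_rev) > max_primer_mismatch)
      return(list(outcome = "primer_fail"))
    ins <- substr(x, tl + fl + 1, n - tl - rl)
    if (nchar(ins) < min_len) return(list(outcome = "short"))
    list(outcome = "assigned", sample = names(tag_map)[i5], insert = ins)
  }

  for (i in seq_along(reads)) {
    r <- classify(reads[i])
    if (r$outcome != "assigned") {
      r2 <- classify(revcomp(reads[i]))
      # keep the more informative outcome; an assignment in either
      # orientation wins, otherwise the forward classification stands
      if (r2$outcome == "assigned") r <- r2
    }
    outcome[i] <- r$outcome
    if (r$outcome == "assigned") {
      assigned_to[i] <- r$sample
      inserts[i] <- r$insert
    }
  }
  for (s in names(samples)) {
    keep <- !is.na(assigned_to) & assigned_to == s
    samples[[s]] <- unname(inserts[keep])
  }
  list(samples = samples,
       log = data.frame(read = ids, outcome = outcome,
                        sample = assigned_to, stringsAsFactors = FALSE))
}

#' Dereplicate strictly identical sequences
#'
#' @param per_sample named list (sample id -> character vector of sequences).
#' @return data.frame of class `unique_seqs`: `sequence`, one integer count
#'   column per sample, and `total`.
#' @export
dereplicate <- function(per_sample) {
  stopifnot(is.list(per_sample))
  snames <- names(per_sample)
  all_seq <- unlist(per_sample, use.names = FALSE)
  if (length(all_seq) == 0) {
    out <- data.frame(sequence = character(0), total = integer(0),
                      stringsAsFactors = FALSE)
    for (s in snames) out[[s]] <- integer(0)
    out <- out[c("sequence", snames, "total")]
    class(out) <- c("unique_seqs", "data.frame")
    return(out)
  }
  uniq <- sort(unique(all_seq))
  counts <- vapply(per_sample, function(v)
    tabulate(match(v, uniq), nbins = length(uniq)), integer(length(uniq)))
  counts <- matrix(counts, nrow = length(uniq),
                   dimnames = list(NULL, snames))
  out <- data.frame(sequence = uniq, stringsAsFactors = FALSE)
  for (s in snames) out[[s]] <- counts[, s]
  out$total <- as.integer(rowSums(counts))
  class(out) <- c("unique_seqs", "data.frame")
  out
}

#' Remove singleton sequences
#'
#' Drops unique sequences whose summed count over all samples equals one.
#'
#' @param seqs a `unique_seqs` data.frame from [dereplicate()].
#' @return the filtered `unique_seqs`.
#' @export
remove_singletons <- function(seqs) {
  out <- seqs[seqs$total > 1, , drop = FALSE]
  rownames(out) <- NULL
  out
}

sample_cols <- function(seqs) setdiff(names(seqs), c("sequence", "total"))

#' Read / write FASTQ pairs
#'
#' Thin wrappers over Biostrings for the paired FASTQ files the simulator
#' writes and the pipeline consumes.
#'
#' @param path file path.
#' @return `read_fastq`: list with `sequences` and `qualities` (named
#'   character vectors).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(sequences = setNames(as.character(x), names(x)),
       qualities = setNames(as.character(S4Vectors::mcols(x)$qualities),
                            names(x)))
}

#' @rdname read_fastq
#' @param sequences,qualities named character vectors of equal length.
#' @export
write_fastq <- function(sequences, qualities, path) {
  x <- Biostrings::DNAStringSet(sequences)
  q <- Biostrings::BStringSet(qualities)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname read_fastq
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' @rdname read_fastq
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
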