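#' @noRd
DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a character vector of DNA strings
#'
#' IUPAC degeneracy codes are complemented as well, so primer strings can be
#' passed through unchanged.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# IUPAC code -> 4-bit mask over A,C,G,T
.iupac_mask <- local({
  codes <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  m <- integer(0)
  for (nm in names(codes))
    m[nm] <- sum(2L^(match(codes[[nm]], DNA_BASES) - 1L))
  m
})

# number of positions of `seqs` (plain ACGT[N]) incompatible with the IUPAC
# pattern `pat`; seqs shorter than pat count as all-mismatch
.iupac_mismatches <- function(seqs, pat) {
  pm <- .iupac_mask[strsplit(pat, "", fixed = TRUE)[[1]]]
  np <- length(pm)
  vapply(strsplit(seqs, "", fixed = TRUE), function(s) {
    if (length(s) < np) return(np)
    sm <- .iupac_mask[s[seq_len(np)]]
    sm[is.na(sm)] <- 0L
    sum(bitwAnd(sm, pm) == 0L)
  }, integer(1))
}

# run `expr` under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(DNA_BASES, len[min(i, length(len))], replace = TRUE),
          collapse = ""), character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
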