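# Independent oracles and small fixture builders used across the suite.

# Brute-force dynamic-programming identity oracle: maximise matched bases
# (free gaps/mismatches), minimise alignment length among optima; written
# in plain R, independent of the compiled implementation.
oracle_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0L, n + 1, m + 1)
  L <- matrix(0L, n + 1, m + 1)
  L[1, ] <- 0:m; L[, 1] <- 0:n
  for (i in 1:n) for (j in 1:m) {
    cand_m <- c(M[i, j] + (A[i] == B[j]), M[i, j + 1], M[i + 1, j])
    cand_l <- c(L[i, j], L[i, j + 1], L[i + 1, j]) + 1L
    best <- max(cand_m)
    M[i + 1, j + 1] <- best
    L[i + 1, j + 1] <- min(cand_l[cand_m == best])
  }
  M[n + 1, m + 1] / L[n + 1, m + 1]
}

# Exhaustive all-offsets ungapped overlap scorer (merge oracle)
oracle_overlap_score <- function(fwd, rrc) {
  A <- strsplit(fwd, "")[[1]]; B <- strsplit(rrc, "")[[1]]
  best <- -Inf
  for (s in (-(length(B) - 1)):(length(A) - 1)) {
    i <- max(1, s + 1):min(length(A), s + length(B))
    if (length(i) == 0) next
    j <- i - s
    sc <- sum(ifelse(A[i] == B[j], 1, -1))
    best <- max(best, sc)
  }
  best
}

# Single-linkage clustering at an identity threshold (partition oracle)
oracle_single_linkage <- function(seqs, threshold = 0.99) {
  n <- length(seqs)
  idm <- identity_matrix(seqs, seqs)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (idm[i, j] >= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  vapply(seq_len(n), find, integer(1))
}

# LCA oracle: intersect full ancestor vectors, take the deepest common one
oracle_lca <- function(tree, taxon_ids) {
  paths <- lapply(taxon_ids, function(t) taxo_path(tree, t))
  common <- Reduce(intersect, paths)
  common[which.max(tree$depth[match(common, tree$taxon_id)])]
}

# Hand-built taxonomy with an NCBI-style Opisthokonta supergroup holding
# Metazoa and Fungi below it, for testing the rollup split
toy_taxonomy <- function() {
  taxonomy_tree(data.frame(
    taxon_id  = 1:13,
    parent_id = c(NA, 1, 1, 2, 2, 2, 4, 5, 7, 8, 3, 11, 6),
    rank = c("root", "supergroup", "supergroup",
             "phylum", "phylum", "class",
             "genus", "genus", "species", "species",
             "phylum", "species", "species"),
    name = c("Eukaryota", "Opisthokonta", "Alveolata",
             "Metazoa", "Fungi", "choano_cl",
             "genus_met", "genus_fun", "met_sp", "fun_sp",
             "alv_ph", "alv_sp", "choano_sp"),
    marine = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
               TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE))
}

# Random taxonomy for LCA property tests
random_taxonomy <- function(n_nodes, seed) {
  set.seed(seed)
  ranks <- c("root", "supergroup", "phylum", "class", "order",
             "family", "genus", "species")
  id <- 1L
  nodes <- data.frame(taxon_id = 1L, parent_id = NA_integer_,
                      rank = "root", name = "root", marine = TRUE,
                      stringsAsFactors = FALSE)
  pick1 <- function(x) x[sample.int(length(x), 1)]
  while (nrow(nodes) < n_nodes) {
    p <- pick1(seq_len(nrow(nodes)))
    pr <- match(nodes$rank[p], ranks)
    if (pr >= length(ranks)) next
    r <- pick1((pr + 1):length(ranks))
    id <- id + 1L
    nodes <- rbind(nodes, data.frame(
      taxon_id = id, parent_id = nodes$taxon_id[p], rank = ranks[r],
      name = paste0("n", id), marine = TRUE, stringsAsFactors = FALSE))
  }
  taxonomy_tree(nodes)
}

# unique_seqs builder from a named list sample -> reads
make_uniq <- function(...) dereplicate(list(...))

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

# mutate a sequence at exactly k positions (deterministic given RNG state)
mutate_k <- function(seq, k) {
  s <- strsplit(seq, "")[[1]]
  pos <- sample(length(s), k)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}
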