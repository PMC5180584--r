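RANK_LEVELS <- c("root", "supergroup", "phylum", "class", "order",
                 "family", "genus", "species")

#' Build a taxonomy tree
#'
#' @param nodes data.frame with columns `taxon_id`, `parent_id` (NA for the
#'   root), `rank` (one of root, supergroup, phylum, class, order, family,
#'   genus, species), `name`, `marine` (logical).
#' @return object of class `taxonomy_tree` (the validated data.frame plus a
#'   depth column).
#' @export
taxonomy_tree <- function(nodes) {
  req <- c("taxon_id", "parent_id", "rank", "name", "marine")
  stopifnot(all(req %in% names(nodes)))
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!all(nodes$rank %in% RANK_LEVELS))
    stop("unknown rank value(s): ",
         paste(setdiff(nodes$rank, RANK_LEVELS), collapse = ", "))
  root <- which(is.na(nodes$parent_id))
  if (length(root) != 1) stop("taxonomy must have exactly one root")
  if (anyDuplicated(nodes$taxon_id)) stop("duplicate taxon_id")
  pidx <- match(nodes$parent_id, nodes$taxon_id)
  if (any(is.na(pidx[-root]))) stop("parent_id not in tree")
  # depth by pointer chasing; also detects cycles / unreachable nodes
  depth <- rep(NA_integer_, nrow(nodes))
  depth[root] <- 0L
  for (pass in seq_len(nrow(nodes))) {
    todo <- which(is.na(depth) & !is.na(depth[pidx]))
    if (length(todo) == 0) break
    depth[todo] <- depth[pidx[todo]] + 1L
  }
  if (anyNA(depth)) stop("taxonomy contains cycles or unreachable nodes")
  rk <- match(nodes$rank, RANK_LEVELS)
  bad <- which(!is.na(pidx) & rk <= rk[pidx])
  if (length(bad))
    stop("ranks must strictly descend from parent to child")
  nodes$depth <- depth
  class(nodes) <- c("taxonomy_tree", "data.frame")
  nodes
}

tax_index <- function(tree, taxon_id) {
  i <- match(taxon_id, tree$taxon_id)
  if (anyNA(i)) stop("integrity error: taxon not in tree: ",
                     paste(taxon_id[is.na(i)], collapse = ", "))
  i
}

#' Ancestor path of a taxon (root first, the taxon itself last)
#' @param tree a `taxonomy_tree`.
#' @param taxon_id a single taxon id.
#' @return integer vector of taxon ids.
#' @export
taxo_path <- function(tree, taxon_id) {
  i <- tax_index(tree, taxon_id)
  path <- integer(0)
  while (!is.na(i)) {
    path <- c(tree$taxon_id[i], path)
    i <- match(tree$parent_id[i], tree$taxon_id)
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' Pairwise LCA by climbing to equal depth and then in lock-step; folded
#' over the set.
#'
#' @param tree a `taxonomy_tree`.
#' @param taxon_ids vector of taxon ids.
#' @return the LCA taxon id.
#' @export
taxo_lca <- function(tree, taxon_ids) {
  stopifnot(length(taxon_ids) >= 1)
  lca2 <- function(a, b) {
    ia <- tax_index(tree, a); ib <- tax_index(tree, b)
    while (tree$depth[ia] > tree$depth[ib])
      ia <- match(tree$parent_id[ia], tree$taxon_id)
    while (tree$depth[ib] > tree$depth[ia])
      ib <- match(tree$parent_id[ib], tree$taxon_id)
    while (ia != ib) {
      ia <- match(tree$parent_id[ia], tree$taxon_id)
      ib <- match(tree$parent_id[ib], tree$taxon_id)
    }
    tree$taxon_id[ia]
  }
  Reduce(lca2, unique(taxon_ids))
}

#' Best-hit / LCA taxonomic assignment of one query sequence
#'
#' Finds the best hit of the query in the reference database, builds the set
#' of references that are at least as similar to the best hit as the query
#' is, and assigns the lowest common ancestor of their taxa.  The assigned
#' rank therefore rises (becomes less precise) as the query's similarity to
#' the database falls.
#'
#' @param query query sequence (character scalar).
#' @param refs data.frame with columns `ref_id`, `taxon_id`, `sequence`.
#' @param tree a `taxonomy_tree` containing every reference taxon.
#' @param neighbour_rule how the co-assignment set is built:
#'   `"besthit"` (default) collects references r with
#'   identity(r, besthit) >= identity(query, besthit); `"query"` collects
#'   references r with identity(r, query) >= best identity.
#' @return one-row data.frame: `best_identity`, `best_ref`,
#'   `assigned_taxon_id`, `assigned_rank`, `assigned_name`, `marine`.
#' @export
lca_assign <- function(query, refs, tree,
                       neighbour_rule = c("besthit", "query")) {
  if (!nzchar(query)) stop("invalid input: empty query")
  stopifnot(nrow(refs) >= 1)
  neighbour_rule <- match.arg(neighbour_rule)
  idq <- as.numeric(cpp_identity_matrix(query, refs$sequence))
  s_star <- max(idq)
  best <- which(idq == s_star)
  best <- best[order(refs$ref_id[best])][1]   # tie -> lowest ref id
  if (neighbour_rule == "besthit") {
    idb <- as.numeric(cpp_identity_matrix(refs$sequence[best], refs$sequence))
    set <- unique(c(best, which(idb >= s_star)))
  } else {
    set <- unique(c(best, which(idq >= s_star)))
  }
  lca <- taxo_lca(tree, refs$taxon_id[set])
  i <- tax_index(tree, lca)
  data.frame(best_identity = s_star,
             best_ref = refs$ref_id[best],
             assigned_taxon_id = lca,
             assigned_rank = tree$rank[i],
             assigned_name = tree$name[i],
             marine = tree$marine[i],
             stringsAsFactors = FALSE)
}

#' Roll an assignment up to Super-Group and Phylum
#'
#' Walks the path from the root to the assigned taxon and reports the
#' supergroup-rank ancestor.  Within Opisthokonta, Metazoa or Fungi are
#' reported when they lie on the path, otherwise "other Opisthokonta".
#' For metazoans the phylum-rank ancestor is reported; otherwise phylum is
#' NA.  Assignments with no supergroup-rank ancestor (e.g. at the root) are
#' flagged unassignable and are meant to be dropped from analyses.
#'
#' @param taxon_id assigned taxon id.
#' @param tree a `taxonomy_tree`.
#' @return list with `supergroup` (NA when unassignable), `phylum`,
#'   `unassignable` (logical).
#' @export
rollup <- function(taxon_id, tree) {
  path <- taxo_path(tree, taxon_id)
  idx <- tax_index(tree, path)
  ranks <- tree$rank[idx]; nm <- tree$name[idx]
  sg_i <- which(ranks == "supergroup")
  if (length(sg_i) == 0)
    return(list(supergroup = NA_character_, phylum = NA_character_,
                unassignable = TRUE))
  sg <- nm[sg_i[1]]
  if (sg == "Opisthokonta") {
    sg <- if ("Metazoa" %in% nm) "Metazoa"
          else if ("Fungi" %in% nm) "Fungi"
          else "other Opisthokonta"
  }
  ph <- NA_character_
  if (sg == "Metazoa") {
    ph_i <- which(ranks == "phylum")
    if (length(ph_i)) ph <- nm[ph_i[1]]
  }
  list(supergroup = sg, phylum = ph, unassignable = FALSE)
}

#' Assign a whole MOTU set
#'
#' Applies [lca_assign()] to every MOTU representative and rolls the result
#' up to Super-Group/Phylum.
#'
#' @param motus a `motu_set` (see [cluster_motus()]).
#' @param refs,tree,neighbour_rule see [lca_assign()].
#' @return data.frame with one row per MOTU (motu_id, best_identity,
#'   assigned_taxon_id, assigned_rank, assigned_name, supergroup, phylum,
#'   marine, unassignable).
#' @export
assign_motus <- function(motus, refs, tree,
                         neighbour_rule = c("besthit", "query")) {
  neighbour_rule <- match.arg(neighbour_rule)
  rows <- lapply(motus, function(m) {
    a <- lca_assign(m$representative, refs, tree, neighbour_rule)
    r <- rollup(a$assigned_taxon_id, tree)
    cbind(data.frame(motu_id = m$motu_id, stringsAsFactors = FALSE), a,
          data.frame(supergroup = r$supergroup, phylum = r$phylum,
                     unassignable = r$unassignable, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write / read a taxonomy as TSV
#' @param tree a `taxonomy_tree`; `path` a file path.
#' @export
write_taxonomy <- function(tree, path) {
  write.table(as.data.frame(tree)[c("taxon_id", "parent_id", "rank",
                                    "name", "marine")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  taxonomy_tree(read.delim(path, stringsAsFactors = FALSE))
}
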