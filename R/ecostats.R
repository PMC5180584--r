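#' Jaccard distance matrix on presence/absence
#'
#' d(i, j) = 1 - |P_i intersect P_j| / |P_i union P_j| over the presence
#' sets of two samples.  Optional pooling merges samples (by union of
#' presence) before computing distances: `"replicates"` pools the corer
#' replicates within station x layer x season x template, `"layers"` pools
#' the three sediment layers within station x corer x season x template.
#'
#' @param tab a `motu_table` or presence/count matrix (MOTUs x samples).
#' @param pooling `"none"` (default), `"replicates"` or `"layers"`.
#' @return a `dist` object; pooled sample metadata (when a `motu_table` was
#'   given) is attached as attribute `"meta"`.
#' @export
jaccard_matrix <- function(tab, pooling = c("none", "replicates", "layers")) {
  pooling <- match.arg(pooling)
  pres <- presence(tab)
  meta <- if (inherits(tab, "motu_table")) tab$samples else NULL
  if (pooling != "none") {
    if (is.null(meta)) stop("pooling requires sample metadata")
    key_cols <- switch(pooling,
                       replicates = c("station", "layer", "season", "template"),
                       layers = c("station", "corer", "season", "template"))
    key <- do.call(paste, c(meta[key_cols], sep = ":"))
    groups <- unique(key)
    pres <- vapply(groups, function(g)
      rowSums(pres[, key == g, drop = FALSE]) > 0, logical(nrow(pres)))
    meta <- meta[match(groups, key), , drop = FALSE]
    meta$sample_id <- groups
    rownames(meta) <- NULL
    colnames(pres) <- groups
  }
  n <- ncol(pres)
  sz <- colSums(pres)
  inter <- crossprod(pres)           # |P_i ∩ P_j|
  uni <- outer(sz, sz, "+") - inter
  d <- 1 - inter / uni
  if (any(uni == 0)) {
    warning("distance undefined for pairs of empty samples; set to NA")
    d[uni == 0] <- NA
  }
  diag(d) <- 0
  out <- stats::as.dist(d)
  attr(out, "Labels") <- colnames(pres)
  attr(out, "meta") <- meta
  out
}

#' Jaccard similarity (percent) from a distance object
#' @param d a Jaccard `dist`.
#' @return numeric vector of similarities, 100 * (1 - d).
#' @export
jaccard_similarity <- function(d) 100 * (1 - as.numeric(d))

# Gower-centred inner-product matrix of a distance matrix
.gower <- function(d) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% D2 %*% J
}

.hat <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

# all permutations of 1..n (Heap's algorithm), n small
.all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Distance-based permutational multivariate ANOVA
#'
#' Partitions a distance matrix over a sequential model (McArdle-Anderson:
#' Gower-centred inner-product matrix projected on the hat matrix of each
#' added term).  Pseudo-F uses the residual mean square as denominator.
#' Significance by permutation of samples: free, within strata (for tests
#' below a blocking factor), or of whole blocks (for tests of a factor
#' constant within blocks).  With `exact = TRUE` all n! relabellings are
#' enumerated instead (small n only).
#'
#' @param d a `dist` object.
#' @param data data.frame of factors/covariates, rows aligned with `d`.
#' @param terms character vector of model terms, tested sequentially
#'   (interactions as `"a:b"`).
#' @param n_perms number of permutations (default 999).
#' @param seed integer seed.
#' @param strata optional factor: permutations are restricted within its
#'   levels.
#' @param blocks optional factor: whole blocks are permuted as units
#'   (requires equal block sizes).
#' @param exact enumerate all permutations (n <= 8).
#' @return object of class `permanova`: data.frame with Df, SumOfSqs,
#'   MeanSqs, F and p per term plus Residual and Total rows.
#' @export
permanova <- function(d, data, terms, n_perms = 999, seed = 1,
                      strata = NULL, blocks = NULL, exact = FALSE) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(n >= 4, nrow(data) == n)
  if (!is.null(strata) && !is.null(blocks))
    stop("unsupported design: use either strata or blocks")
  G <- .gower(dm)
  ss_total <- sum(diag(G))
  if (abs(ss_total) < 1e-300) ss_total <- 1

  forms <- lapply(seq_along(terms), function(k)
    stats::as.formula(paste("~", paste(terms[seq_len(k)], collapse = "+"))))
  Hs <- lapply(forms, function(f) .hat(model.matrix(f, data)))
  ranks <- vapply(forms, function(f) qr(model.matrix(f, data))$rank,
                  integer(1))
  df <- diff(c(1L, ranks))
  if (any(df < 1))
    stop("unsupported design: a term adds no degrees of freedom")
  df_res <- n - ranks[length(ranks)]
  if (df_res < 1) stop("unsupported design: no residual degrees of freedom")

  tol0 <- 1e-12 * max(abs(ss_total), 1)
  stat <- function(Gp) {
    tr <- vapply(Hs, function(H) sum(H * Gp), numeric(1))
    ss <- diff(c(0, tr))
    ss_res <- sum(diag(Gp)) - tr[length(tr)]
    # guard against cancellation driving a zero residual slightly negative
    if (ss_res < tol0) ss_res <- 0
    (ss / df) / (ss_res / df_res)
  }
  F_obs <- stat(G)

  perm_indices <- function() {
    if (!is.null(strata)) {
      idx <- seq_len(n)
      for (lev in unique(strata)) {
        w <- which(strata == lev)
        idx[w] <- w[sample.int(length(w))]
      }
      idx
    } else if (!is.null(blocks)) {
      lev <- unique(blocks)
      sz <- table(blocks)
      if (length(unique(sz)) != 1)
        stop("unsupported design: unequal block sizes for block permutation")
      shuf <- sample(lev)
      idx <- integer(n)
      for (k in seq_along(lev)) idx[which(blocks == lev[k])] <-
          which(blocks == shuf[k])
      idx
    } else sample.int(n)
  }

  if (exact) {
    if (n > 8) stop("exact enumeration limited to n <= 8")
    P <- .all_perms(n)
    Fp <- apply(P, 1, function(p) stat(G[p, p]))
    Fp <- matrix(Fp, nrow = length(terms))
    p_val <- rowMeans(Fp >= F_obs - 1e-12)
    n_used <- nrow(P)
  } else {
    p_ge <- rep(1L, length(terms))   # observed counts as one permutation
    with_seed(seed, {
      for (b in seq_len(n_perms)) {
        p <- perm_indices()
        Fp <- stat(G[p, p])
        p_ge <- p_ge + (Fp >= F_obs - 1e-12)
      }
    })
    p_val <- p_ge / (n_perms + 1)
    n_used <- n_perms
  }

  tr <- vapply(Hs, function(H) sum(H * G), numeric(1))
  ss <- diff(c(0, tr))
  ss_res <- ss_total - tr[length(tr)]
  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    Df = c(df, df_res, n - 1L),
    SumOfSqs = c(ss, ss_res, ss_total),
    MeanSqs = c(ss / df, ss_res / df_res, NA),
    F = c(F_obs, NA, NA),
    p = c(p_val, NA, NA),
    stringsAsFactors = FALSE)
  structure(out, class = c("permanova", "data.frame"),
            n_perms = n_used, exact = exact)
}

#' @export
print.permanova <- function(x, ...) {
  cat("Permutational multivariate ANOVA (",
      if (isTRUE(attr(x, "exact"))) "exact enumeration"
      else paste(attr(x, "n_perms"), "permutations"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' One-way PERMANOVA sum of squares by the closed form
#'
#' SS_total = (1/n) sum_{i<j} d_ij^2 and
#' SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2; exposed for the one-way
#' case so the projection-based partition can be verified against it.
#'
#' @param d a `dist`; `groups` a factor.
#' @return list with `ss_total`, `ss_within`, `ss_between`, `F`.
#' @export
permanova_oneway_ss <- function(d, groups) {
  dm <- as.matrix(d)^2
  n <- nrow(dm)
  a <- length(unique(groups))
  ss_total <- sum(dm[upper.tri(dm)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    w <- which(groups == g)
    ss_within <- ss_within +
      sum(dm[w, w][upper.tri(dm[w, w])]) / length(w)
  }
  ss_between <- ss_total - ss_within
  list(ss_total = ss_total, ss_within = ss_within,
       ss_between = ss_between,
       F = (ss_between / (a - 1)) / (ss_within / (n - a)))
}

# principal-coordinate embedding retaining real and imaginary axes
.pcoa_axes <- function(d) {
  G <- .gower(as.matrix(d))
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- abs(e$values) > max(abs(e$values)) * 1e-10
  v <- e$values[keep]
  X <- sweep(e$vectors[, keep, drop = FALSE], 2, sqrt(abs(v)), "*")
  list(pos = X[, v > 0, drop = FALSE], neg = X[, v < 0, drop = FALSE])
}

.centroid_dist <- function(ax, groups) {
  z <- numeric(length(groups))
  for (g in unique(groups)) {
    w <- which(groups == g)
    cp <- colMeans(ax$pos[w, , drop = FALSE])
    dn2 <- 0
    dp2 <- rowSums(sweep(ax$pos[w, , drop = FALSE], 2, cp)^2)
    if (ncol(ax$neg) > 0) {
      cn <- colMeans(ax$neg[w, , drop = FALSE])
      dn2 <- rowSums(sweep(ax$neg[w, , drop = FALSE], 2, cn)^2)
    }
    z[w] <- sqrt(pmax(dp2 - dn2, 0))   # imaginary-part correction
  }
  z
}

.anova_F <- function(z, groups) {
  gm <- tapply(z, groups, mean)
  ng <- tapply(z, groups, length)
  a <- length(gm)
  ssb <- sum(ng * (gm - mean(z))^2)
  ssw <- sum((z - gm[as.character(groups)])^2)
  # all distances (numerically) equal: no dispersion signal at all
  if (ssb + ssw <= 1e-10 * max(1, sum(z^2))) return(0)
  (ssb / (a - 1)) / (ssw / (length(z) - a))
}

#' Homogeneity of multivariate dispersions (PERMDISP)
#'
#' Embeds the distance matrix by principal coordinates (negative eigenvalues
#' handled by subtracting the imaginary-part contribution from centroid
#' distances), computes each sample's distance to its group centroid and
#' tests the one-way F on those distances by permutation of group labels
#' (centroid distances recomputed under each relabelling).
#'
#' @param d a `dist`; `groups` a factor (groups of size 1 are excluded with
#'   a warning).
#' @param n_perms permutations (default 999); `seed` integer seed.
#' @return list with `F`, `p`, `distances` (to own-group centroid),
#'   `group_means`.
#' @export
permdisp <- function(d, groups, n_perms = 999, seed = 1) {
  groups <- as.character(groups)
  sz <- table(groups)
  if (any(sz < 2)) {
    warning("excluding groups of size 1: ",
            paste(names(sz)[sz < 2], collapse = ", "))
    keep <- groups %in% names(sz)[sz >= 2]
    d <- stats::as.dist(as.matrix(d)[keep, keep])
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) stop("need at least two groups")
  ax <- .pcoa_axes(d)
  z <- .centroid_dist(ax, groups)
  F_obs <- .anova_F(z, groups)
  ge <- 1L
  with_seed(seed, {
    for (b in seq_len(n_perms)) {
      gp <- sample(groups)
      Fp <- .anova_F(.centroid_dist(ax, gp), gp)
      ge <- ge + (Fp >= F_obs - 1e-12)
    }
  })
  list(F = F_obs, p = ge / (n_perms + 1), distances = z,
       group_means = tapply(z, groups, mean))
}

#' Pairwise permutation tests between factor levels
#'
#' For every pair of levels the corresponding sub-matrix is tested with a
#' one-way PERMANOVA; the pseudo-t is sqrt(F).  Raw p-values are adjusted
#' with the Benjamini-Yekutieli FDR correction.
#'
#' @param d a `dist`; `f` a factor over the samples.
#' @param n_perms permutations per pair; `seed` integer seed.
#' @return data.frame: pair, t, p_raw, p_adj (BY).
#' @export
pairwise_tests <- function(d, f, n_perms = 999, seed = 1) {
  f <- as.character(f)
  lev <- sort(unique(f))
  stopifnot(length(lev) >= 2)
  dm <- as.matrix(d)
  prs <- combn(lev, 2)
  res <- lapply(seq_len(ncol(prs)), function(k) {
    sel <- f %in% prs[, k]
    sub <- stats::as.dist(dm[sel, sel])
    pr <- permanova(sub, data.frame(g = f[sel]), "g",
                    n_perms = n_perms, seed = seed + k)
    data.frame(pair = paste(prs[, k], collapse = " vs "),
               t = sqrt(pr$F[1]), p_raw = pr$p[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- p.adjust(out$p_raw, method = "BY")
  out
}

# isotonic fit of y against the order of x with secondary tie treatment:
# tied x values share one fitted disparity (their pooled mean), enforced by
# weighted pool-adjacent-violators over the tie groups
.isotone <- function(x, y) {
  grp <- match(x, sort(unique(x)))
  ybar <- tapply(y, grp, mean)
  w <- tabulate(grp)
  # weighted PAVA over the group means
  v <- as.numeric(ybar); wts <- as.numeric(w)
  i <- 1
  while (i < length(v)) {
    if (v[i] > v[i + 1] + 1e-15) {
      m <- (wts[i] * v[i] + wts[i + 1] * v[i + 1]) / (wts[i] + wts[i + 1])
      v[i] <- m; wts[i] <- wts[i] + wts[i + 1]
      v <- v[-(i + 1)]; wts <- wts[-(i + 1)]
      # merged blocks keep their span via repetition bookkeeping below
      attr(v, "span") <- NULL
      i <- max(1, i - 1)
    } else i <- i + 1
  }
  # expand merged blocks back to groups
  fitted_group <- numeric(length(ybar))
  gi <- 1
  for (k in seq_along(v)) {
    take <- 0; wsum <- 0
    while (wsum < wts[k] - 1e-9) {
      fitted_group[gi] <- v[k]
      wsum <- wsum + w[gi]
      gi <- gi + 1; take <- take + 1
    }
  }
  fitted_group[grp]
}

#' Non-metric multidimensional scaling
#'
#' Minimises Kruskal stress-1 by alternating monotone (isotonic) regression
#' of the configuration distances on the dissimilarity ranks with a Guttman
#' majorization update, over `n_starts` random starts (the first start is
#' the principal-coordinate configuration).  The best-stress solution is
#' centred and rotated to its principal axes.
#'
#' @param d a `dist`.
#' @param k target dimension (default 2).
#' @param n_starts number of starts (default 500, matching common practice
#'   for published ordinations; reduce for quick work).
#' @param max_iter iterations per start (default 200).
#' @param tol stress-improvement convergence tolerance (default 1e-6).
#' @param seed integer seed.
#' @return object of class `nmds`: list with `points` (n x k), `stress`,
#'   `n_starts`, `seed`.
#' @export
nmds <- function(d, k = 2, n_starts = 500, max_iter = 200, tol = 1e-6,
                 seed = 1) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  stopifnot(n >= k + 2)
  lt <- lower.tri(dm)
  dv <- dm[lt]
  run_start <- function(X) {
    stress_prev <- Inf
    for (it in seq_len(max_iter)) {
      cd <- as.matrix(dist(X))[lt]
      dhat <- .isotone(dv, cd)
      num <- sum((cd - dhat)^2); den <- sum(cd^2)
      stress <- sqrt(num / den)
      if (is.nan(stress)) return(list(X = X, stress = Inf))
      if (stress_prev - stress < tol) break
      stress_prev <- stress
      # Guttman transform with ratios dhat/cd
      CD <- matrix(0, n, n); CD[lower.tri(CD)] <- cd; CD <- CD + t(CD)
      DH <- matrix(0, n, n); DH[lower.tri(DH)] <- dhat; DH <- DH + t(DH)
      R <- ifelse(CD > 0, DH / CD, 0)
      B <- -R
      diag(B) <- rowSums(R)
      X <- (B %*% X) / n
    }
    list(X = X, stress = stress)
  }
  best <- NULL
  with_seed(seed, {
    # classical-scaling start, then random starts
    ax <- .pcoa_axes(dm)
    X0 <- ax$pos
    if (ncol(X0) < k) X0 <- cbind(X0, matrix(0, n, k - ncol(X0)))
    starts <- c(list(X0[, seq_len(k), drop = FALSE]),
                lapply(seq_len(max(0, n_starts - 1)), function(i)
                  matrix(rnorm(n * k), n, k)))
    for (X in starts) {
      r <- run_start(X)
      if (is.null(best) || r$stress < best$stress) best <- r
    }
  })
  if (is.null(best) || !is.finite(best$stress))
    stop("nMDS failed to converge in any start")
  X <- scale(best$X, scale = FALSE)
  X <- X %*% svd(X)$v                      # principal-axis rotation
  dimnames(X) <- list(attr(d, "Labels"), paste0("MDS", seq_len(k)))
  structure(list(points = X, stress = best$stress, n_starts = n_starts,
                 seed = seed),
            class = "nmds")
}

#' @export
print.nmds <- function(x, ...) {
  cat("nMDS ordination:", nrow(x$points), "samples, k =", ncol(x$points),
      ", stress =", signif(x$stress, 4), "\n")
  invisible(x)
}

#' @export
plot.nmds <- function(x, groups = NULL, ...) {
  cols <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(x$points, col = cols, pch = 19, asp = 1, ...)
  graphics::legend("bottomleft", bty = "n",
                   legend = sprintf("stress = %.3f", x$stress))
  invisible(x)
}

#' Fit an environmental vector to an ordination
#'
#' Least-squares regression of a numeric variable on the ordination axes;
#' the fitted direction is the normalised coefficient vector, r2 the squared
#' multiple correlation, and significance comes from permuting the variable.
#'
#' @param ord an `nmds` object or a coordinate matrix.
#' @param v numeric variable, one value per sample (no missing values).
#' @param n_perms permutations (default 999); `seed` integer seed.
#' @return list with `direction`, `r2`, `p`.
#' @export
fit_env_vector <- function(ord, v, n_perms = 999, seed = 1) {
  X <- if (inherits(ord, "nmds")) ord$points else as.matrix(ord)
  stopifnot(is.numeric(v), length(v) == nrow(X), !anyNA(v))
  if (var(v) == 0) stop("undefined: constant variable")
  Xc <- scale(X, scale = FALSE)
  H <- .hat(Xc)
  r2_of <- function(u) {
    uc <- u - mean(u)
    sum((H %*% uc)^2) / sum(uc^2)
  }
  r2 <- r2_of(v)
  beta <- qr.coef(qr(Xc), v - mean(v))
  dir <- beta / sqrt(sum(beta^2))
  ge <- 1L
  with_seed(seed, {
    for (b in seq_len(n_perms))
      ge <- ge + (r2_of(sample(v)) >= r2 - 1e-12)
  })
  list(direction = dir, r2 = r2, p = ge / (n_perms + 1))
}

#' Analytic rarefaction curve
#'
#' Expected MOTU richness in a random subsample of m reads,
#' E\[S_m\] = sum_i (1 - C(N - N_i, m) / C(N, m)); computed on the log scale
#' for stability.  The curve is non-decreasing and reaches the observed
#' richness at m = N.
#'
#' @param counts integer vector of per-MOTU read counts in one sample.
#' @param step spacing of subsample sizes (default N/50, at least 1).
#' @param m optional explicit vector of subsample sizes.
#' @return data.frame with `m` and `richness`.
#' @export
rarefaction_curve <- function(counts, step = NULL, m = NULL) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (N < 1) stop("invalid input: no reads")
  if (is.null(m)) {
    step <- step %||% max(1, floor(N / 50))
    m <- unique(c(seq(1, N, by = step), N))
  }
  if (any(m > N) || any(m < 1)) stop("invalid input: m outside 1..N")
  rich <- vapply(m, function(mm) {
    keep <- N - counts >= mm
    miss <- numeric(length(counts))
    miss[keep] <- exp(lchoose(N - counts[keep], mm) - lchoose(N, mm))
    sum(1 - miss)
  }, numeric(1))
  data.frame(m = m, richness = rich)
}

#' Two-group richness t-tests
#'
#' Student's two-sample t-test with pooled variance, or a paired t-test when
#' the observations are matched (e.g. DNA vs RNA from the same core).
#' Groups with zero variance and equal means return t = 0, p = 1.
#'
#' @param x numeric per-sample richness values.
#' @param g grouping with exactly two levels, or for `paired = TRUE` two
#'   matched blocks in the same order.
#' @param paired paired test (default FALSE).
#' @return list with `t`, `df`, `p`, `estimate`.
#' @export
richness_tests <- function(x, g, paired = FALSE) {
  g <- factor(g)
  stopifnot(nlevels(g) == 2)
  x1 <- x[g == levels(g)[1]]; x2 <- x[g == levels(g)[2]]
  stopifnot(length(x1) >= 2, length(x2) >= 2)
  if (paired) stopifnot(length(x1) == length(x2))
  degenerate <- if (paired) var(x1 - x2) == 0 && mean(x1 - x2) == 0
                else var(x1) == 0 && var(x2) == 0 && mean(x1) == mean(x2)
  if (degenerate) {
    df <- if (paired) length(x1) - 1 else length(x) - 2
    return(list(t = 0, df = df, p = 1,
                estimate = if (paired) 0 else c(mean(x1), mean(x2))))
  }
  tt <- t.test(x1, x2, paired = paired, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, estimate = unname(tt$estimate))
}
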