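# Brownian-motion simulation on a tree: preorder accumulation of normal
# increments with variance = branch length. Returns tips x n matrix.
sim_bm <- function(tree, n = 1) {
  nt <- length(tree$tip.label)
  x <- matrix(0, nt + tree$Nnode, n)
  e <- stats::reorder(tree, "cladewise")
  len <- e$edge.length %||% numeric(nrow(e$edge))
  for (k in seq_len(nrow(e$edge))) {
    s <- sqrt(len[k])
    x[e$edge[k, 2], ] <- x[e$edge[k, 1], ] +
      (if (s > 0) stats::rnorm(n, 0, s) else 0)
  }
  out <- x[seq_len(nt), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

# Restrict a tree and a named trait vector to their common species,
# warning if either side loses entries.
align_trait <- function(tree, trait) {
  if (is.null(names(trait))) stop("trait vector must be named by species")
  common <- intersect(tree$tip.label, names(trait))
  if (length(common) < length(tree$tip.label) ||
      length(common) < length(trait)) {
    warning("trait and tree tips differ; using their intersection (",
            length(common), " species)")
  }
  if (length(common) < 3) stop("fewer than 3 species shared by tree and trait")
  tr <- if (length(common) < length(tree$tip.label)) {
    prune_to(tree, common, include_root = FALSE)
  } else tree
  list(tree = tr, values = trait[tr$tip.label])
}

# K statistics for many trait columns at once (shared tree covariance).
# The observed/expected MSE0/MSE ratio; (n-1) factors cancel.
kstat_columns <- function(V, Vi, Y) {
  sVi <- sum(Vi)
  ahat <- colSums(Vi %*% Y) / sVi
  R <- sweep(Y, 2, ahat)
  mse0 <- colSums(R^2)
  mse <- colSums(R * (Vi %*% R))
  n <- nrow(V)
  expected <- (sum(diag(V)) - n / sVi) / (n - 1)
  (mse0 / mse) / expected
}

inv_or_pinv <- function(V) {
  tryCatch(solve(V), error = function(e) {
    if (!requireNamespace("MASS", quietly = TRUE)) {
      stop("singular phylogenetic covariance and MASS not available")
    }
    warning("singular phylogenetic covariance (identical tips?); ",
            "using a pseudoinverse")
    MASS::ginv(V)
  })
}

#' Blomberg's K for a continuous trait
#'
#' Ratio of the observed mean squared error structure (from the
#' phylogenetically corrected mean, relative to the GLS error under the
#' tree's Brownian covariance) to its Brownian-motion expectation. K is
#' about 1 for traits evolved by Brownian motion on the tree and falls
#' toward 0 for traits shuffled independently of phylogeny.
#'
#' @param tree a `phylo` with branch lengths (zero-length edges allowed).
#' @param trait named numeric vector (species -> value), variance > 0.
#' @return scalar K >= 0.
#' @export
blomberg_k <- function(tree, trait) {
  al <- align_trait(tree, trait)
  y <- al$values
  n <- length(y)
  if (n < 4) stop("need at least 4 species")
  if (stats::var(y) == 0) stop("trait has zero variance")
  V <- ape::vcv(al$tree)
  if (sum(diag(V)) <= 0) stop("tree has zero total depth")
  Vi <- inv_or_pinv(V)
  as.numeric(kstat_columns(V, Vi, matrix(y, ncol = 1)))
}

new_signal_test <- function(...) structure(list(...), class = "signal_test")

#' @export
print.signal_test <- function(x, ...) {
  cat("Phylogenetic signal test (", x$statistic_name, "): observed ",
      format(x$observed, digits = 4), "\n", sep = "")
  cat("  p vs. random (tip shuffle):", format(x$p_vs_random, digits = 4), "\n")
  if (!is.null(x$p_vs_clumped)) {
    cat("  p vs. clumped (Brownian threshold):",
        format(x$p_vs_clumped, digits = 4), "\n")
  }
  invisible(x)
}

#' Randomization test for Blomberg's K
#'
#' Null distribution built by permuting trait values across the tips
#' (signal-free null, K near 0); `p_vs_random = (#\{K_perm >= K_obs\} + 1) /
#' (n + 1)`.
#'
#' @inheritParams blomberg_k
#' @param n_permutations number of tip shuffles (>= 99 recommended).
#' @param seed integer seed.
#' @return a `signal_test` with fields `observed`, `null_random`,
#'   `p_vs_random`, `n_replicates`, `seed`.
#' @export
k_randomization_test <- function(tree, trait, n_permutations = 1000, seed = 1) {
  if (n_permutations < 99) warning("fewer than 99 permutations gives coarse p-values")
  al <- align_trait(tree, trait)
  y <- al$values
  if (stats::var(y) == 0) stop("trait has zero variance")
  V <- ape::vcv(al$tree)
  Vi <- inv_or_pinv(V)
  k_obs <- as.numeric(kstat_columns(V, Vi, matrix(y, ncol = 1)))
  set.seed(derive_seed(seed, "k_perm"))
  Y <- vapply(seq_len(n_permutations), function(i) sample(y), numeric(length(y)))
  k_null <- kstat_columns(V, Vi, Y)
  new_signal_test(
    statistic_name = "K", observed = k_obs, null_random = k_null,
    p_vs_random = (sum(k_null >= k_obs) + 1) / (n_permutations + 1),
    n_replicates = n_permutations, seed = seed)
}

# Linear operator taking tip values to per-edge differences
# (child nodal value minus parent nodal value), where each internal node's
# value is the unweighted mean of its children's values. Summing absolute
# rows x trait = the trait's total sister-clade disparity.
disparity_operator <- function(tree) {
  nt <- length(tree$tip.label)
  ntot <- nt + tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  W <- matrix(0, ntot, nt)
  W[cbind(seq_len(nt), seq_len(nt))] <- 1
  po <- stats::reorder(tree, "postorder")
  internals <- unique(po$edge[, 1])
  for (v in internals) {
    ch <- kids[[as.character(v)]]
    W[v, ] <- colMeans(W[ch, , drop = FALSE])
  }
  W[tree$edge[, 2], , drop = FALSE] - W[tree$edge[, 1], , drop = FALSE]
}

sum_disparity <- function(A, Y) colSums(abs(A %*% Y))

#' Fritz & Purvis' D for a binary trait
#'
#' The trait's sum of sister-clade disparities on the tree (nodal values
#' estimated by equal-weights averaging of daughter values), rescaled
#' between its expectations under two nulls: tip permutation preserving
#' prevalence (D = 1, phylogenetically random) and a Brownian liability
#' thresholded at the observed prevalence (D = 0, clumped). Both one-sided
#' p-values are reported, each toward its named null.
#'
#' @param tree a `phylo` (polytomies allowed).
#' @param trait named 0/1 vector with both states present.
#' @param n_permutations tip-permutation null replicates.
#' @param n_brownian Brownian-threshold null replicates.
#' @param seed integer seed.
#' @return a `signal_test` with `observed` (the D estimate), `sum_d_observed`,
#'   raw null disparity sums `null_random` and `null_brownian`,
#'   `p_vs_random` (H0: D = 1) and `p_vs_clumped` (H0: D = 0).
#' @export
fritz_purvis_d <- function(tree, trait, n_permutations = 1000,
                           n_brownian = 1000, seed = 1) {
  al <- align_trait(tree, trait)
  y <- al$values
  tree <- al$tree
  if (!all(y %in% c(0, 1))) stop("trait must be binary 0/1")
  k1 <- sum(y == 1)
  if (k1 == 0 || k1 == length(y)) stop("trait is monomorphic")
  if (length(y) < 10) warning("fewer than 10 species; D is unreliable")
  A <- disparity_operator(tree)
  d_obs <- sum_disparity(A, matrix(y, ncol = 1))
  set.seed(derive_seed(seed, "d_perm"))
  Yr <- vapply(seq_len(n_permutations), function(i) sample(y), numeric(length(y)))
  d_r <- sum_disparity(A, Yr)
  set.seed(derive_seed(seed, "d_brownian"))
  L <- sim_bm(tree, n_brownian)
  Yb <- apply(L, 2, function(l) {
    v <- numeric(length(l))
    v[order(l, decreasing = TRUE)[seq_len(k1)]] <- 1  # prevalence matched
    v
  })
  d_b <- sum_disparity(A, Yb)
  D <- (d_obs - mean(d_b)) / (mean(d_r) - mean(d_b))
  new_signal_test(
    statistic_name = "D", observed = as.numeric(D),
    sum_d_observed = as.numeric(d_obs),
    null_random = d_r, null_brownian = d_b,
    p_vs_random = (sum(d_r <= d_obs) + 1) / (n_permutations + 1),
    p_vs_clumped = (sum(d_b >= d_obs) + 1) / (n_brownian + 1),
    n_replicates = n_permutations, seed = seed)
}

#' Phylogenetically independent contrasts and trait correlation
#'
#' Felsenstein's pruning recursion: at each internal node the standardized
#' contrast is `(x_i - x_j) / sqrt(v_i + v_j)`, the nodal value is the
#' inverse-variance-weighted mean, and the branch below is lengthened by
#' `v_i v_j / (v_i + v_j)`. The association between two traits is the
#' regression through the origin of y-contrasts on x-contrasts, with the
#' slope's t-test p-value.
#'
#' Zero-length branches (routine after polytomy resolution and zero
#' terminal assignment) break the standardization; they are replaced, for
#' the contrasts only, by a small constant (`epsilon`, default 1e-6 times
#' tree depth).
#'
#' @param tree fully bifurcating `phylo` (resolve polytomies first).
#' @param x,y named numeric trait vectors.
#' @param epsilon replacement for zero branch lengths; `NULL` for the
#'   default.
#' @return object of class `contrasts_result`: `contrasts_x`,
#'   `contrasts_y`, `slope`, `se`, `t`, `p_value`, `correlation`,
#'   `n_contrasts`.
#' @export
independent_contrasts <- function(tree, x, y, epsilon = NULL) {
  stopifnot_phylo(tree)
  if (!is_bifurcating(tree)) {
    stop("tree contains polytomies; resolve them first (resolve_polytomies)")
  }
  common <- Reduce(intersect, list(tree$tip.label, names(x), names(y)))
  if (length(common) < length(tree$tip.label)) {
    warning("pruning tree to the ", length(common), " species shared with traits")
    tree <- prune_to(tree, common, include_root = FALSE)
  }
  if (length(common) < 2) stop("need at least 2 species")
  nt <- length(tree$tip.label)
  len <- tree$edge.length %||% numeric(nrow(tree$edge))
  if (any(len < 0)) stop("negative branch lengths")
  if (is.null(epsilon)) {
    depth <- max(node_depths(tree))
    epsilon <- if (depth > 0) 1e-6 * depth else 1e-6
  }
  nz <- sum(len == 0)
  if (nz > 0) {
    message(nz, " zero-length branch(es) set to epsilon = ",
            format(epsilon, digits = 3), " for contrasts")
    len[len == 0] <- epsilon
  }
  ntot <- nt + tree$Nnode
  v <- numeric(ntot)
  v[tree$edge[, 2]] <- len
  xv <- yv <- numeric(ntot)
  xv[seq_len(nt)] <- x[tree$tip.label]
  yv[seq_len(nt)] <- y[tree$tip.label]
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  po <- stats::reorder(tree, "postorder")
  internals <- unique(po$edge[, 1])
  cx <- cy <- numeric(length(internals))
  for (i in seq_along(internals)) {
    nd <- internals[i]
    ch <- kids[[as.character(nd)]]
    va <- v[ch[1]]; vb <- v[ch[2]]
    s <- sqrt(va + vb)
    cx[i] <- (xv[ch[1]] - xv[ch[2]]) / s
    cy[i] <- (yv[ch[1]] - yv[ch[2]]) / s
    xv[nd] <- (xv[ch[1]] * vb + xv[ch[2]] * va) / (va + vb)
    yv[nd] <- (yv[ch[1]] * vb + yv[ch[2]] * va) / (va + vb)
    v[nd] <- v[nd] + va * vb / (va + vb)
  }
  sxx <- sum(cx^2); sxy <- sum(cx * cy); syy <- sum(cy^2)
  slope <- sxy / sxx
  df <- length(cx) - 1
  rss <- syy - slope * sxy
  se <- if (df > 0) sqrt(max(rss, 0) / df / sxx) else NA_real_
  tstat <- if (is.na(se)) NA_real_ else if (se > 0) slope / se else sign(slope) * Inf
  p <- if (df > 0 && !is.na(tstat)) 2 * stats::pt(-abs(tstat), df) else NA_real_
  structure(list(contrasts_x = cx, contrasts_y = cy, slope = slope, se = se,
                 t = tstat, p_value = p,
                 correlation = sxy / sqrt(sxx * syy),
                 n_contrasts = length(cx)),
            class = "contrasts_result")
}

#' @export
print.contrasts_result <- function(x, ...) {
  cat("Independent contrasts:", x$n_contrasts, "contrasts; slope",
      format(x$slope, digits = 4), "(p =", format(x$p_value, digits = 4),
      "), correlation", format(x$correlation, digits = 4), "\n")
  invisible(x)
}

#' Contrast correlation for binary traits
#'
#' Identical machinery to [independent_contrasts()] with 0/1 states treated
#' as reals; the sign of the slope is the reported direction of
#' association.
#'
#' @inheritParams independent_contrasts
#' @export
binary_contrast_correlation <- function(tree, x, y, epsilon = NULL) {
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) {
    stop("traits must be binary 0/1")
  }
  independent_contrasts(tree, x, y, epsilon = epsilon)
}

#' Re-run a signal test within strata of species
#'
#' Generic subset re-run (for abundance classes or source-tree
#' representation counts): the tree is pruned to each stratum and the
#' requested test repeated. Strata in which the test is undefined (too few
#' species, or a monomorphic binary trait) are skipped with a recorded
#' reason rather than an error.
#'
#' @param tree a `phylo`.
#' @param trait named trait vector.
#' @param strata named character vector, species -> stratum label.
#' @param test `"D"` (binary) or `"K"` (continuous).
#' @param ... passed to [fritz_purvis_d()] or [k_randomization_test()].
#' @return named list per stratum: a `signal_test`, or a character string
#'   giving the skip reason.
#' @export
stratified_signal <- function(tree, trait, strata, test = c("D", "K"), ...) {
  test <- match.arg(test)
  out <- list()
  for (lev in unique(strata)) {
    sp <- intersect(names(strata)[strata == lev],
                    intersect(tree$tip.label, names(trait)))
    if (length(sp) < 4) {
      out[[lev]] <- sprintf("skipped: only %d species", length(sp))
      next
    }
    tv <- trait[sp]
    if (test == "D" && length(unique(tv)) < 2) {
      out[[lev]] <- "skipped: trait monomorphic in stratum"
      next
    }
    if (test == "K" && stats::var(tv) == 0) {
      out[[lev]] <- "skipped: trait has zero variance in stratum"
      next
    }
    sub <- if (length(sp) < length(tree$tip.label)) {
      prune_to(tree, sp, include_root = FALSE)
    } else tree
    out[[lev]] <- switch(test,
      D = fritz_purvis_d(sub, tv, ...),
      K = k_randomization_test(sub, tv, ...))
  }
  out
}
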