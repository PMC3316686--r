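#' Faith's phylogenetic diversity of a taxon set
#'
#' Sum of the branch lengths of the subtree spanning the taxa. With
#' `include_root = TRUE` (default, the rooted convention) the path from
#' the taxa's MRCA back to the root is included, so PD of the full tip set
#' equals the total branch length and PD is additive over nested subsets.
#'
#' @param tree a `phylo` with branch lengths.
#' @param taxa character vector of tip labels (nonempty).
#' @param include_root include the MRCA-to-root path?
#' @return nonnegative real.
#' @export
faith_pd <- function(tree, taxa, include_root = TRUE) {
  stopifnot_phylo(tree)
  taxa <- unique(taxa)
  if (length(taxa) == 0) stop("empty taxon set")
  idx <- match(taxa, tree$tip.label)
  if (anyNA(idx)) stop("unknown taxa: ", paste(taxa[is.na(idx)], collapse = ", "))
  nt <- length(tree$tip.label)
  keep <- logical(nt + tree$Nnode)
  keep[idx] <- TRUE
  len <- tree$edge.length %||% numeric(nrow(tree$edge))
  po <- stats::reorder(tree, "postorder")
  cnt <- numeric(nt + tree$Nnode)
  cnt[idx] <- 1
  e <- po$edge
  for (k in seq_len(nrow(e))) cnt[e[k, 1]] <- cnt[e[k, 1]] + cnt[e[k, 2]]
  len_po <- po$edge.length %||% numeric(nrow(e))
  ccol <- cnt[e[, 2]]
  if (include_root) {
    sum(len_po[ccol >= 1]) + (tree$root.edge %||% 0)
  } else {
    sum(len_po[ccol >= 1 & ccol < length(taxa)])
  }
}

new_pd_loss_result <- function(...) structure(list(...), class = "pd_loss_result")

#' @export
print.pd_loss_result <- function(x, ...) {
  cat("PD-loss scenario '", x$scenario_name, "': ", x$n_removed,
      " species removed\n", sep = "")
  cat("  PD of survivors:", format(x$pd_observed, digits = 6),
      "| random-pruning null mean:", format(mean(x$null_pd), digits = 6),
      "+/- SD", format(stats::sd(x$null_pd), digits = 4), "\n")
  cat("  one-sample t =", format(x$t_statistic, digits = 4),
      ", p =", format(x$p_value, digits = 4),
      "| empirical p (<= null) =", format(x$p_empirical, digits = 4),
      "| direction:", x$direction, "\n")
  invisible(x)
}

pd_loss_compare <- function(tree, removed, scenario_name, n_null, seed,
                            include_root = TRUE, alpha = 0.05) {
  tips <- tree$tip.label
  survivors <- setdiff(tips, removed)
  if (length(removed) == 0 || length(survivors) == 0) {
    stop("degenerate scenario: must remove at least one and fewer than all species")
  }
  pd_obs <- faith_pd(tree, survivors, include_root = include_root)
  set.seed(derive_seed(seed, "pd_null"))
  null_pd <- vapply(seq_len(n_null), function(i) {
    keep <- sample(tips, length(survivors))
    faith_pd(tree, keep, include_root = include_root)
  }, numeric(1))
  if (stats::sd(null_pd) < 1e-12) {
    # degenerate null (e.g. single survivor on an ultrametric tree)
    same <- abs(mean(null_pd) - pd_obs) < 1e-12
    tt <- list(statistic = NA_real_, p.value = if (same) 1 else 0,
               parameter = n_null - 1)
    p_less <- NA_real_
  } else {
    tt <- stats::t.test(null_pd, mu = pd_obs)
    p_less <- stats::pt(unname(tt$statistic), tt$parameter)
  }
  # empirical (rank) p: probability a random pruning retains no more PD
  # than the scenario; uniform when the scenario itself is a random draw
  p_emp <- (sum(null_pd <= pd_obs) + 1) / (n_null + 1)
  direction <- if (tt$p.value >= alpha) "indistinct"
               else if (pd_obs < mean(null_pd)) "greater_loss"
               else "smaller_loss"
  new_pd_loss_result(
    scenario_name = scenario_name, n_removed = length(removed),
    pd_observed = pd_obs, null_pd = null_pd,
    t_statistic = unname(tt$statistic), p_value = tt$p.value,
    p_less = p_less,
    p_empirical = p_emp, direction = direction,
    include_root = include_root, seed = seed)
}

threat_threshold_sets <- list(
  EN_and_above = c("CR", "EN"),
  VU_and_above = c("CR", "EN", "VU"),
  NT_and_above = c("CR", "EN", "VU", "NT")
)

#' PD loss under an extinction scenario versus equal-richness random pruning
#'
#' Removes the species selected by a Red List threshold (or an explicit
#' set), measures the survivors' PD, and compares it against `n_null`
#' random removals of the same number of species (uniform, without
#' replacement, ignoring category). Reports the paper-style one-sample
#' t-test of the null sample against the observed PD, plus a rank-based
#' empirical p-value (which, unlike the t-test, is calibrated when the
#' scenario itself is random).
#'
#' @param tree a `phylo` with branch lengths.
#' @param categories named species -> Red List code vector (needed for
#'   threshold scenarios).
#' @param scenario one of `"EN_and_above"`, `"VU_and_above"`,
#'   `"NT_and_above"`, or a character vector of species to remove.
#' @param n_null number of random prunings (default 1000).
#' @param seed integer seed.
#' @param include_root rooted-PD convention flag, logged in the result.
#' @return a `pd_loss_result`.
#' @export
extinction_scenario_test <- function(tree, categories = NULL, scenario,
                                     n_null = 1000, seed = 1,
                                     include_root = TRUE) {
  stopifnot_phylo(tree)
  if (length(scenario) == 1 && scenario %in% names(threat_threshold_sets)) {
    if (is.null(categories)) stop("threshold scenarios need 'categories'")
    cats <- categories[tree$tip.label]
    removed <- tree$tip.label[cats %in% threat_threshold_sets[[scenario]]]
    name <- scenario
  } else {
    removed <- intersect(scenario, tree$tip.label)
    if (length(removed) < length(scenario)) {
      stop("scenario species absent from tree: ",
           paste(setdiff(scenario, tree$tip.label), collapse = ", "))
    }
    name <- sprintf("explicit_%d_species", length(removed))
  }
  pd_loss_compare(tree, removed, name, n_null, seed, include_root)
}

#' PD loss if the top-k EDGE species went extinct
#'
#' @param tree a `phylo` with branch lengths.
#' @param ranking an [edge_scores()] data.frame.
#' @param k number of top-ranked species to remove (1 <= k < n).
#' @inheritParams extinction_scenario_test
#' @export
top_k_loss_test <- function(tree, ranking, k, n_null = 1000, seed = 1,
                            include_root = TRUE) {
  if (k < 1 || k > nrow(ranking)) stop("k must be between 1 and the number of ranked species")
  top <- ranking$species[order(ranking$rank)][seq_len(k)]
  res <- pd_loss_compare(tree, top, sprintf("top_%d_edge", k), n_null, seed,
                         include_root)
  res
}

#' Colless imbalance index
#'
#' Sum over internal nodes of the absolute difference in descendant tip
#' counts of the two child subtrees. Requires a fully bifurcating tree.
#'
#' @param tree a bifurcating `phylo`.
#' @return nonnegative integer; 0 only for maximally balanced shapes.
#' @export
colless_index <- function(tree) {
  stopifnot_phylo(tree)
  if (!is_bifurcating(tree)) {
    stop("tree contains polytomies; resolve them first (resolve_polytomies)")
  }
  cnt <- node_tip_counts(tree)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  sum(vapply(kids, function(ch) abs(cnt[ch[1]] - cnt[ch[2]]), numeric(1)))
}

# Colless index of Yule topologies simulated by the random-join process
# (cluster sizes only; no tree object needed). The Yule and Kingman
# coalescent share the same topology law.
yule_colless_null <- function(n_tips, n_sim) {
  vapply(seq_len(n_sim), function(s) {
    sizes <- rep.int(1L, n_tips)
    total <- 0L
    while (length(sizes) > 1) {
      ij <- sample.int(length(sizes), 2)
      total <- total + abs(sizes[ij[1]] - sizes[ij[2]])
      sizes <- c(sizes[-ij], sizes[ij[1]] + sizes[ij[2]])
    }
    total
  }, integer(1))
}

#' Tree imbalance versus the Yule null
#'
#' Simulates pure-birth (Yule) topologies with the observed tip count and
#' compares the observed Colless index against the simulated distribution:
#' `p = (#\{null >= observed\} + 1) / (n + 1)` (small p = more imbalanced
#' than Yule). Branch lengths play no role.
#'
#' @param tree a bifurcating `phylo` with >= 4 tips.
#' @param n_simulations Yule replicates.
#' @param seed integer seed.
#' @return object of class `imbalance_result`: `colless_observed`,
#'   `null_colless`, `p_value`.
#' @export
yule_imbalance_test <- function(tree, n_simulations = 1000, seed = 1) {
  stopifnot_phylo(tree)
  nt <- length(tree$tip.label)
  if (nt < 4) stop("need at least 4 tips")
  obs <- colless_index(tree)
  set.seed(derive_seed(seed, "yule"))
  null <- yule_colless_null(nt, n_simulations)
  structure(list(colless_observed = obs, null_colless = null,
                 p_value = (sum(null >= obs) + 1) / (n_simulations + 1),
                 seed = seed),
            class = "imbalance_result")
}

#' @export
print.imbalance_result <- function(x, ...) {
  cat("Colless imbalance:", x$colless_observed, "| Yule null mean:",
      format(mean(x$null_colless), digits = 5), "| p =",
      format(x$p_value, digits = 4), "\n")
  invisible(x)
}
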