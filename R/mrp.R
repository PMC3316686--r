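#' Source tree for supertree assembly
#'
#' Wraps a rooted `phylo` with provenance and per-node support weights.
#' Supports are taken from numeric internal node labels (bootstrap
#' percentages). Nodes of taxonomy-derived trees are all given weight 1 so
#' that analyses are driven primarily by data; nodes of molecular or
#' morphological trees lacking a numeric support also get weight 1, with a
#' message.
#'
#' @param tree rooted `phylo`.
#' @param provenance one of `"molecular"`, `"morphological"`, `"taxonomic"`.
#' @param name identifier used as character provenance in the MRP matrix.
#' @return object of class `source_tree`.
#' @export
source_tree <- function(tree, provenance = c("molecular", "morphological",
                                             "taxonomic"),
                        name = "source") {
  provenance <- match.arg(provenance)
  stopifnot_phylo(tree)
  sup <- node_supports(tree)
  if (provenance == "taxonomic") {
    sup[] <- 1
  } else if (anyNA(sup)) {
    n_inf <- sum(is.na(sup[-1]))  # root (first internal node) is never a character
    if (n_inf > 0) {
      message("source '", name, "': ", n_inf,
              " node(s) without numeric support; weight 1 used")
    }
    sup[is.na(sup)] <- 1
  }
  if (any(sup <= 0 | !is.finite(sup))) stop("node supports must be positive and finite")
  structure(list(tree = tree, provenance = provenance, name = name,
                 node_supports = sup),
            class = "source_tree")
}

#' Encode source trees as a weighted matrix representation (MRP)
#'
#' Baum–Ragan coding: every non-root internal node (a clade of size >= 2
#' and smaller than its source's tip count) becomes one binary character —
#' descendants 1, other taxa of that source 0, taxa absent from that source
#' missing (`NA`). The character weight is the node's support (bootstrap
#' percentage), or 1 for taxonomy-derived nodes. Duplicate characters
#' across sources are kept separate.
#'
#' @param sources list of [source_tree()] objects (bare `phylo` objects are
#'   accepted and treated as molecular sources).
#' @param all_taxa character vector of the full taxon universe; defaults to
#'   the union of source-tree tips.
#' @return object of class `mrp_matrix`: list with `matrix` (taxa x
#'   characters, values 0/1/NA), `weights`, `provenance` (source name per
#'   character), `taxa`.
#' @export
encode_mrp <- function(sources, all_taxa = NULL) {
  if (length(sources) == 0) stop("empty source list")
  sources <- lapply(seq_along(sources), function(i) {
    s <- sources[[i]]
    if (inherits(s, "phylo")) s <- source_tree(s, "molecular", paste0("source", i))
    if (!inherits(s, "source_tree")) stop("sources must be source_tree or phylo")
    s
  })
  if (is.null(all_taxa)) {
    all_taxa <- sort(unique(unlist(lapply(sources, function(s) s$tree$tip.label))))
  }
  cols <- list(); wts <- numeric(0); prov <- character(0)
  for (s in sources) {
    tr <- s$tree
    extra <- setdiff(tr$tip.label, all_taxa)
    if (length(extra)) stop("source '", s$name, "' has taxa outside the universe: ",
                            paste(extra, collapse = ", "))
    nt <- length(tr$tip.label)
    if (nt < 3) {
      warning("source '", s$name, "' has fewer than 3 tips; contributes no characters")
      next
    }
    sets <- clade_tip_sets(tr)
    node_ids <- as.integer(names(sets))
    for (k in seq_along(sets)) {
      clade <- sets[[k]]
      if (length(clade) < 2 || length(clade) >= nt) next
      states <- rep(NA_integer_, length(all_taxa))
      names(states) <- all_taxa
      states[tr$tip.label] <- 0L
      states[clade] <- 1L
      cols[[length(cols) + 1L]] <- states
      wts <- c(wts, s$node_supports[node_ids[k] - nt])
      prov <- c(prov, s$name)
    }
  }
  if (length(cols) == 0) stop("no informative characters in any source tree")
  m <- do.call(cbind, cols)
  rownames(m) <- all_taxa
  colnames(m) <- paste0(prov, ".", stats::ave(seq_along(prov), prov, FUN = seq_along))
  structure(list(matrix = m, weights = wts, provenance = prov, taxa = all_taxa),
            class = "mrp_matrix")
}

#' @export
print.mrp_matrix <- function(x, ...) {
  cat("MRP matrix:", length(x$taxa), "taxa x", ncol(x$matrix),
      "weighted binary characters from", length(unique(x$provenance)),
      "source tree(s)\n")
  invisible(x)
}

# Tip cost matrices for the two-state parsimony DP: cost of assigning state
# 0 (T0) or 1 (T1) at each taxon row; missing = {0,1} ambiguity (0 cost both).
tip_cost_matrices <- function(states) {
  T0 <- ifelse(is.na(states) | states == 0L, 0, Inf)
  T1 <- ifelse(is.na(states) | states == 1L, 0, Inf)
  list(T0 = T0, T1 = T1)
}

#' Weighted parsimony length of a tree on an MRP matrix
#'
#' Exact minimum number of state changes per character (two-state Sankoff
#' dynamic programme with unit symmetric costs), weighted and summed.
#' Missing states are full ambiguities, equivalent to scoring each
#' character on the subtree induced by its non-missing taxa. Handles
#' polytomies exactly.
#'
#' @param tree a `phylo` whose tips include every matrix taxon.
#' @param matrix_obj an [encode_mrp()] result.
#' @return nonnegative real score.
#' @export
fitch_score <- function(tree, matrix_obj) {
  stopifnot_phylo(tree)
  if (!inherits(matrix_obj, "mrp_matrix")) stop("matrix_obj must be an mrp_matrix")
  missing_taxa <- setdiff(matrix_obj$taxa, tree$tip.label)
  if (length(missing_taxa)) {
    stop("matrix taxa absent from tree: ", paste(missing_taxa, collapse = ", "))
  }
  nt <- length(tree$tip.label)
  nc <- ncol(matrix_obj$matrix)
  states <- matrix(NA_integer_, nt, nc)
  hit <- tree$tip.label %in% matrix_obj$taxa
  states[hit, ] <- matrix_obj$matrix[tree$tip.label[hit], , drop = FALSE]
  tc <- tip_cost_matrices(states)
  po <- stats::reorder(tree, "postorder")
  ntot <- nt + tree$Nnode
  c0 <- matrix(0, ntot, nc); c1 <- matrix(0, ntot, nc)
  c0[seq_len(nt), ] <- tc$T0
  c1[seq_len(nt), ] <- tc$T1
  e <- po$edge
  for (k in seq_len(nrow(e))) {
    p <- e[k, 1]; v <- e[k, 2]
    c0[p, ] <- c0[p, ] + pmin(c0[v, ], c1[v, ] + 1)
    c1[p, ] <- c1[p, ] + pmin(c1[v, ], c0[v, ] + 1)
  }
  root <- nt + 1L
  sum(matrix_obj$weights * pmin(c0[root, ], c1[root, ]))
}

## ---- internal parent-vector machinery for tree search ------------------

# Score a partial/complete tree held as a parent vector. par[v] = parent id,
# 0 for the root, NA for inactive nodes. Tips are ids 1..nrow(T0).
score_partree <- function(par, T0, T1, w) {
  n <- length(par)
  root <- which(!is.na(par) & par == 0L)
  act <- which(!is.na(par) & par != 0L)
  d <- rep(NA_integer_, n); d[root] <- 0L
  remaining <- act
  while (length(remaining)) {
    ready <- remaining[!is.na(d[par[remaining]])]
    d[ready] <- d[par[ready]] + 1L
    remaining <- remaining[is.na(d[remaining])]
  }
  ord <- act[order(d[act], decreasing = TRUE)]
  nc <- ncol(T0); ntip <- nrow(T0)
  c0 <- matrix(0, n, nc); c1 <- matrix(0, n, nc)
  c0[seq_len(ntip), ] <- T0
  c1[seq_len(ntip), ] <- T1
  for (v in ord) {
    p <- par[v]
    c0[p, ] <- c0[p, ] + pmin(c0[v, ], c1[v, ] + 1)
    c1[p, ] <- c1[p, ] + pmin(c1[v, ], c0[v, ] + 1)
  }
  sum(w * pmin(c0[root, ], c1[root, ]))
}

# Attach tip t above node v (v non-root), using fresh internal id u.
attach_tip <- function(par, t, v, u) {
  par[u] <- par[v]
  par[v] <- u
  par[t] <- u
  par
}

# All NNI neighbours of a complete binary parent-vector tree.
nni_moves <- function(par) {
  n <- length(par)
  kids <- split(which(!is.na(par) & par != 0L), par[!is.na(par) & par != 0L])
  internal <- as.integer(names(kids))
  root <- which(!is.na(par) & par == 0L)
  moves <- list()
  for (v in internal) {
    if (v == root) next
    u <- par[v]
    sibs <- kids[[as.character(u)]]
    w <- sibs[sibs != v]
    vkids <- kids[[as.character(v)]]
    if (length(vkids) != 2 || length(w) != 1) next
    for (x in vkids) {
      p2 <- par
      p2[x] <- u
      p2[w] <- v
      moves[[length(moves) + 1L]] <- p2
    }
  }
  moves
}

partree_to_phylo <- function(par, tip_labels) {
  kids <- split(which(!is.na(par) & par != 0L), par[!is.na(par) & par != 0L])
  root <- which(!is.na(par) & par == 0L)
  rec <- function(v) {
    if (v <= length(tip_labels)) return(tip_labels[v])
    paste0("(", paste(vapply(kids[[as.character(v)]], rec, character(1)),
                      collapse = ","), ")")
  }
  ape::read.tree(text = paste0(rec(root), ";"))
}

#' Search tree space under weighted parsimony
#'
#' Desk-scale re-implementation of weighted MRP tree search. By default the
#' matrix is augmented with an implicit all-zero root taxon (Baum–Ragan
#' rooting) so that rooted clade information in the characters determines
#' the rooting of the result; the root taxon is removed before returning.
#'
#' `branch_and_bound` enumerates addition sequences with score-bound
#' pruning and is exact (all equally best topologies); it is guarded to
#' <= 15 taxa. `hill_climb` uses random-addition greedy starting trees
#' followed by first-improvement NNI rearrangements.
#'
#' @param matrix_obj an [encode_mrp()] result with >= 4 taxa.
#' @param strategy `"branch_and_bound"` or `"hill_climb"`.
#' @param n_starts random-addition starts (hill climb).
#' @param rearrangement_limit maximum NNI evaluations per start.
#' @param seed integer seed (addition orders, tie order).
#' @param ragan_root add the implicit all-zero root taxon? If `FALSE` the
#'   search explores rooted topologies with no rooting information beyond
#'   the characters themselves (scores are root-invariant, so rootings tie).
#' @return object of class `parsimony_result`: list with `trees` (list of
#'   rooted `phylo`, equally best, deduplicated), `score`,
#'   `n_rearrangements`, `search_log`.
#' @export
parsimony_search <- function(matrix_obj,
                             strategy = c("hill_climb", "branch_and_bound"),
                             n_starts = 10, rearrangement_limit = 1e5,
                             seed = 1, ragan_root = TRUE) {
  strategy <- match.arg(strategy)
  if (!inherits(matrix_obj, "mrp_matrix")) stop("matrix_obj must be an mrp_matrix")
  if (length(matrix_obj$taxa) < 4) stop("matrix must contain at least 4 taxa")
  if (rearrangement_limit <= 0) stop("rearrangement_limit must be positive")
  root_label <- "__mrp_root__"
  taxa <- matrix_obj$taxa
  X <- matrix_obj$matrix
  if (ragan_root) {
    if (root_label %in% taxa) stop("taxon name '", root_label, "' is reserved")
    X <- rbind(X, rep(0L, ncol(X)))
    taxa <- c(taxa, root_label)
  }
  tc <- tip_cost_matrices(X)
  w <- matrix_obj$weights
  m <- length(taxa)
  if (strategy == "branch_and_bound" && length(matrix_obj$taxa) > 15) {
    stop("branch_and_bound is guarded to <= 15 taxa; use hill_climb")
  }
  tol <- 1e-9
  n_evals <- 0L

  candidates <- function(par) {
    v <- which(!is.na(par) & par != 0L)
    if (ragan_root) v <- v[v != m] else v
    v
  }

  if (strategy == "branch_and_bound") {
    best <- Inf; best_trees <- list()
    ord <- if (ragan_root) c(m, seq_len(m - 1L)) else seq_len(m)
    recurse <- function(par, next_taxon_i, next_internal) {
      if (next_taxon_i > m) {
        sc <- score_partree(par, tc$T0, tc$T1, w)
        n_evals <<- n_evals + 1L
        if (sc < best - tol) {
          best <<- sc; best_trees <<- list(par)
        } else if (sc <= best + tol) {
          best_trees <<- c(best_trees, list(par))
        }
        return(invisible(NULL))
      }
      t <- ord[next_taxon_i]
      for (v in candidates(par)) {
        p2 <- attach_tip(par, t, v, next_internal)
        sc <- score_partree(p2, tc$T0, tc$T1, w)
        n_evals <<- n_evals + 1L
        if (sc <= best + tol) recurse(p2, next_taxon_i + 1L, next_internal + 1L)
      }
      invisible(NULL)
    }
    par0 <- rep(NA_integer_, 2L * m)
    root_id <- m + 1L
    par0[root_id] <- 0L
    par0[ord[1]] <- root_id
    par0[ord[2]] <- root_id
    recurse(par0, 3L, m + 2L)
    finals <- best_trees
    log_txt <- sprintf("branch_and_bound: %d scored trees, best %.6g", n_evals, best)
  } else {
    best <- Inf; finals <- list()
    for (s in seq_len(n_starts)) {
      set.seed(derive_seed(seed, "mrp_start", s))
      ingroup <- sample(seq_len(if (ragan_root) m - 1L else m))
      ord <- if (ragan_root) c(m, ingroup) else ingroup
      par <- rep(NA_integer_, 2L * m)
      root_id <- m + 1L
      par[root_id] <- 0L
      par[ord[1]] <- root_id
      par[ord[2]] <- root_id
      nxt <- m + 2L
      for (i in seq.int(3L, m)) {
        cand <- resample(candidates(par))
        sc_best <- Inf; par_best <- NULL
        for (v in cand) {
          p2 <- attach_tip(par, ord[i], v, nxt)
          sc <- score_partree(p2, tc$T0, tc$T1, w)
          if (sc < sc_best - tol) { sc_best <- sc; par_best <- p2 }
        }
        par <- par_best
        nxt <- nxt + 1L
      }
      cur <- score_partree(par, tc$T0, tc$T1, w)
      improved <- TRUE
      while (improved && n_evals < rearrangement_limit) {
        improved <- FALSE
        mv <- nni_moves(par)
        for (k in sample(seq_along(mv))) {
          sc <- score_partree(mv[[k]], tc$T0, tc$T1, w)
          n_evals <- n_evals + 1L
          if (sc < cur - tol) {
            par <- mv[[k]]; cur <- sc; improved <- TRUE
            break
          }
          if (n_evals >= rearrangement_limit) break
        }
      }
      if (cur < best - tol) {
        best <- cur; finals <- list(par)
      } else if (cur <= best + tol) {
        finals <- c(finals, list(par))
      }
    }
    log_txt <- sprintf("hill_climb: %d starts, %d NNI evaluations, best %.6g",
                       n_starts, n_evals, best)
  }

  trees <- lapply(finals, partree_to_phylo, tip_labels = taxa)
  if (ragan_root) {
    trees <- lapply(trees, function(tr) ape::drop.tip(tr, root_label))
  }
  sigs <- vapply(trees, topology_signature, character(1))
  trees <- trees[!duplicated(sigs)]
  scores <- vapply(trees, fitch_score, numeric(1), matrix_obj = matrix_obj)
  if (any(abs(scores - best) > 1e-6)) {
    stop("internal error: returned tree score disagrees with fitch_score")
  }
  structure(list(trees = trees, score = best, n_rearrangements = n_evals,
                 search_log = log_txt),
            class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat("Parsimony result:", length(x$trees), "equally best tree(s), score",
      format(x$score), "\n", x$search_log, "\n")
  invisible(x)
}

#' Strict consensus of rooted trees
#'
#' Contains exactly the clades present in every input tree; disagreement
#' collapses to polytomies.
#'
#' @param trees list of rooted `phylo` objects sharing one tip set (a
#'   `parsimony_result` is accepted).
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "parsimony_result")) trees <- trees$trees
  if (length(trees) == 0) stop("empty tree list")
  tipsets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(tipsets, identical, logical(1), y = tipsets[[1]]))) {
    stop("trees must share an identical tip set")
  }
  if (length(trees) == 1) return(trees[[1]])
  ape::consensus(trees, p = 1, rooted = TRUE)
}

#' Does a rooted tree contain a given clade?
#'
#' @param tree rooted `phylo`.
#' @param tips character vector of tip labels.
#' @return `TRUE` if some internal node's descendant tip set equals `tips`.
#' @export
contains_clade <- function(tree, tips) {
  tips <- sort(unique(tips))
  sets <- clade_tip_sets(tree)
  any(vapply(sets, identical, logical(1), y = tips))
}
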