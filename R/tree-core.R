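#' Read a rooted tree from Newick text or file
#'
#' Thin wrapper around [ape::read.tree()] that validates tip-label
#' uniqueness and keeps internal node labels (conventionally bootstrap
#' support percentages) available via [node_supports()].
#'
#' @param x Newick string (anything containing `"("`) or a file path.
#' @return An object of class `phylo`. Polytomies are preserved.
#' @examples
#' tr <- read_newick("((A:1,B:1)80:1,C:2);")
#' node_supports(tr)
#' @export
read_newick <- function(x) {
  tree <- if (length(x) == 1 && grepl("(", x, fixed = TRUE)) {
    ape::read.tree(text = x)
  } else {
    ape::read.tree(file = x)
  }
  if (is.null(tree)) stop("could not parse Newick input")
  stopifnot_phylo(tree)
  tree
}

#' Write a tree to Newick
#'
#' @param tree a `phylo` object.
#' @param file optional path; if `NULL` the Newick string is returned.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot_phylo(tree)
  if (is.null(file)) ape::write.tree(tree) else ape::write.tree(tree, file = file)
}

#' Numeric node supports from internal node labels
#'
#' Internal labels that parse as numbers are interpreted as supports (for
#' bootstrap percentages, values in \[0, 100\]); others yield `NA`.
#'
#' @param tree a `phylo` object.
#' @return numeric vector of length `tree$Nnode`.
#' @export
node_supports <- function(tree) {
  stopifnot_phylo(tree)
  lab <- tree$node.label
  if (is.null(lab)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(lab))
}

## ---- nested-list representation used by the polytomy resolver ----------

phylo_to_nested <- function(tree) {
  nt <- length(tree$tip.label)
  len <- numeric(nt + tree$Nnode)
  if (!is.null(tree$edge.length)) len[tree$edge[, 2]] <- tree$edge.length
  len[nt + 1L] <- tree$root.edge %||% 0
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  nlab <- tree$node.label
  rec <- function(v) {
    if (v <= nt) {
      list(label = tree$tip.label[v], len = len[v], children = NULL)
    } else {
      lb <- if (!is.null(nlab)) nlab[v - nt] else NULL
      list(label = lb, len = len[v],
           children = lapply(kids[[as.character(v)]], rec))
    }
  }
  rec(nt + 1L)
}

nested_to_newick <- function(nd) {
  rec <- function(n) {
    if (is.null(n$children)) {
      paste0(n$label, ":", format(n$len, digits = 15, scientific = FALSE))
    } else {
      paste0("(", paste(vapply(n$children, rec, character(1)), collapse = ","),
             ")", if (!is.null(n$label) && nzchar(n$label)) n$label else "",
             ":", format(n$len, digits = 15, scientific = FALSE))
    }
  }
  paste0(rec(nd), ";")
}

# Resolve one node's children (a list of nested subtrees) into a binary
# arrangement. New internal nodes get branch length 0 and no label.
resolve_children_sequential <- function(children) {
  while (length(children) > 2) {
    idx <- sample.int(length(children), 2)
    joined <- list(label = NULL, len = 0, children = children[idx])
    children <- c(children[-idx], list(joined))
  }
  children
}

# Exact-uniform sampler over the (2k-3)!! rooted binary arrangements of k
# atomic items: item i+1 is attached at one of the 2i-1 stems (including the
# root stem) of the growing arrangement, chosen uniformly. Each topology has
# exactly one construction sequence, hence the law is uniform.
uniform_arrangement <- function(k) {
  cur <- 1L
  for (i in 2:k) {
    j <- sample.int(2L * (i - 1L) - 1L, 1)
    cnt <- 0L
    item <- i
    attach <- function(x) {
      cnt <<- cnt + 1L
      if (cnt == j) return(list(x, item))
      if (!is.list(x)) return(x)
      x[[1]] <- attach(x[[1]])
      if (cnt >= j) return(x)
      x[[2]] <- attach(x[[2]])
      x
    }
    cur <- attach(cur)
  }
  cur
}

resolve_children_uniform <- function(children) {
  arr <- uniform_arrangement(length(children))
  conv <- function(x) {
    if (!is.list(x)) return(children[[x]])
    list(label = NULL, len = 0, children = list(conv(x[[1]]), conv(x[[2]])))
  }
  list(conv(arr[[1]]), conv(arr[[2]]))
}

resolve_nested <- function(nd, method) {
  if (is.null(nd$children)) return(nd)
  nd$children <- lapply(nd$children, resolve_nested, method = method)
  if (length(nd$children) > 2) {
    nd$children <- switch(method,
      sequential = resolve_children_sequential(nd$children),
      uniform    = resolve_children_uniform(nd$children))
  }
  nd
}

#' Randomly resolve polytomies into fully bifurcating replicates
#'
#' Each polytomy of degree k is resolved independently in every replicate;
#' newly created internal edges get branch length 0, so total branch length
#' is conserved. Replicate i is reproducible from `seed` and independent of
#' `n_replicates` (per-replicate derived seeds).
#'
#' @param tree a `phylo`, possibly with polytomies.
#' @param n_replicates number of resolved replicates (>= 1).
#' @param seed integer seed.
#' @param method `"sequential"` (default): iteratively join two random
#'   children under a zero-length node. `"uniform"`: exact-uniform sampling
#'   over the (2k-3)!! rooted binary arrangements of each polytomy's
#'   children. The sequential scheme is uniform for k = 3 but weights
#'   balanced shapes more heavily for k >= 4.
#' @return a `resolution_set`: list with `base`, `replicates` (list of
#'   bifurcating `phylo`), `seed`, `method`.
#' @export
resolve_polytomies <- function(tree, n_replicates, seed,
                               method = c("sequential", "uniform")) {
  method <- match.arg(method)
  stopifnot_phylo(tree)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  base_nested <- phylo_to_nested(tree)
  already_binary <- is_bifurcating(tree)
  reps <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    if (already_binary) {
      reps[[i]] <- tree
      next
    }
    set.seed(derive_seed(seed, "resolve", i))
    nd <- resolve_nested(base_nested, method)
    reps[[i]] <- ape::read.tree(text = nested_to_newick(nd))
  }
  structure(list(base = tree, replicates = reps, seed = seed, method = method),
            class = "resolution_set")
}

#' @export
print.resolution_set <- function(x, ...) {
  cat("Resolution set:", length(x$replicates), "replicates of a",
      length(x$base$tip.label), "tip base tree (method:", x$method,
      ", seed:", x$seed, ")\n")
  invisible(x)
}

# Depth (sum of branch lengths from the root) of every node.
node_depths <- function(tree) {
  nt <- length(tree$tip.label)
  d <- numeric(nt + tree$Nnode)
  e <- tree$edge
  len <- tree$edge.length %||% numeric(nrow(e))
  for (k in seq_len(nrow(e))) d[e[k, 2]] <- d[e[k, 1]] + len[k]
  d
}

#' Prune a tree to a set of tips
#'
#' Unbranched internal nodes are suppressed with their branch lengths
#' summed. With `include_root = TRUE` (default, the rooted-PD convention)
#' the path from the MRCA of the kept tips back to the original root is
#' retained as the result's `root.edge`, so
#' `total length(pruned) = Faith PD of the kept set`.
#'
#' @param tree a `phylo`.
#' @param keep character vector of tip labels to retain.
#' @param include_root keep the MRCA-to-root path length as `root.edge`?
#' @export
prune_to <- function(tree, keep, include_root = TRUE) {
  stopifnot_phylo(tree)
  keep <- unique(keep)
  if (length(keep) == 0) stop("empty keep set")
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) stop("unknown tip labels: ", paste(unknown, collapse = ", "))
  nt <- length(tree$tip.label)
  if (length(keep) == 1) {
    tip <- match(keep, tree$tip.label)
    len <- if (include_root) node_depths(tree)[tip] + (tree$root.edge %||% 0)
           else tree$edge.length[tree$edge[, 2] == tip]
    out <- structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = keep,
                          edge.length = len, Nnode = 1L), class = "phylo")
    attr(out, "order") <- "cladewise"
    return(out)
  }
  pruned <- ape::keep.tip(tree, keep)
  if (include_root && length(keep) < nt) {
    mrca <- ape::getMRCA(tree, keep)
    pruned$root.edge <- (tree$root.edge %||% 0) + node_depths(tree)[mrca]
  } else if (include_root) {
    pruned$root.edge <- tree$root.edge %||% 0
  }
  pruned
}

#' Set terminal branch lengths to zero for species without data
#'
#' Species lacking underlying character data get terminal branch length
#' exactly 0 while remaining represented by their ancestral branches — a
#' conservative lower limit on their distinctiveness.
#'
#' @param tree a `phylo` with branch lengths.
#' @param species_without_data character vector of tip labels.
#' @export
assign_missing_terminal_lengths <- function(tree, species_without_data) {
  stopifnot_phylo(tree)
  if (length(species_without_data) == 0) return(tree)
  idx <- match(species_without_data, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown tip labels: ",
         paste(species_without_data[is.na(idx)], collapse = ", "))
  }
  rows <- tree$edge[, 2] %in% idx
  tree$edge.length[rows] <- 0
  tree
}
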