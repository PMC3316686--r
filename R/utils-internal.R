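# Internal helpers shared across modules. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 numeric as 1:n; this never does.
resample <- function(x) x[sample.int(length(x))]

#' Derive a reproducible sub-seed from a top-level seed
#'
#' Stage seeds are a deterministic function of (seed, stage, index) so that
#' replicate i is identical regardless of how many replicates are requested.
#' Kept below 2^31 - 1 so it is always a valid R integer seed.
#' @noRd
derive_seed <- function(seed, stage, i = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  s <- (as.numeric(seed) %% 2147483647) * 48271 + h * 69621 + as.numeric(i)
  as.integer(s %% 2147483647L)
}

# Tip-count below every node (tips count 1), indexed by ape node id.
node_tip_counts <- function(tree) {
  nt <- length(tree$tip.label)
  po <- stats::reorder(tree, "postorder")
  cnt <- numeric(nt + tree$Nnode)
  cnt[seq_len(nt)] <- 1
  e <- po$edge
  for (k in seq_len(nrow(e))) cnt[e[k, 1]] <- cnt[e[k, 1]] + cnt[e[k, 2]]
  cnt
}

# List of tip-label sets, one per internal node (excluding trivial root set
# optionally). Returns list named by node id.
clade_tip_sets <- function(tree, drop_root = FALSE) {
  nt <- length(tree$tip.label)
  root <- nt + 1L
  po <- stats::reorder(tree, "postorder")
  sets <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) sets[[i]] <- tree$tip.label[i]
  e <- po$edge
  for (k in seq_len(nrow(e))) {
    sets[[e[k, 1]]] <- c(sets[[e[k, 1]]], sets[[e[k, 2]]])
  }
  out <- sets[(nt + 1L):(nt + tree$Nnode)]
  names(out) <- as.character((nt + 1L):(nt + tree$Nnode))
  if (drop_root) out[["as.character(root)"]] <- NULL
  lapply(out, sort)
}

# Canonical string for a rooted topology: sorted "clade signatures".
topology_signature <- function(tree) {
  sets <- clade_tip_sets(tree)
  sig <- vapply(sets, function(s) paste(s, collapse = ","), character(1))
  paste(sort(sig), collapse = ";")
}

# Total branch length including any root edge.
total_branch_length <- function(tree) {
  sum(tree$edge.length %||% 0) + (tree$root.edge %||% 0)
}

is_bifurcating <- function(tree) {
  tab <- tabulate(tree$edge[, 1])
  all(tab[tab > 0] == 2)
}

stopifnot_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("expected an object of class 'phylo'")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  invisible(tree)
}
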