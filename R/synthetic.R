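# Scale a census of counts to a new total, preserving proportions exactly
# in total (largest-remainder apportionment).
scale_counts <- function(counts, n) {
  raw <- counts / sum(counts) * n
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  stats::setNames(as.integer(base), names(counts))
}

# Red List census of the 837 reef-building corals used as the default
# category frequency profile.
coral_census <- c(CR = 4L, EN = 23L, VU = 198L, NT = 174L, LC = 289L, DD = 149L)

#' Specification for one synthetic binary trait
#'
#' @param name trait name.
#' @param prevalence fraction of species in state 1, strictly inside (0,1);
#'   realized as an exact count, not Bernoulli draws.
#' @param structure `"clumped"` (Brownian liability thresholded at the
#'   prevalence quantile; D near 0) or `"random"` (tip permutation; D near
#'   1).
#' @param group optional liability-group label: clumped traits sharing a
#'   label share one Brownian liability (different thresholds), inducing
#'   positive cross-trait association.
#' @export
trait_spec <- function(name, prevalence, structure = c("clumped", "random"),
                       group = NULL) {
  structure <- match.arg(structure)
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be inside (0, 1)")
  list(name = name, prevalence = prevalence, structure = structure,
       group = group)
}

default_trait_specs <- function() {
  list(
    trait_spec("bleaching_susceptible", 0.419, "clumped", group = "impact"),
    trait_spec("bleaching_resistant",   0.116, "clumped"),
    trait_spec("disease_susceptible",   0.310, "clumped", group = "impact"),
    trait_spec("disease_resistant",     0.058, "clumped"),
    trait_spec("quick_recovery",        0.134, "clumped"),
    trait_spec("cots_susceptible",      0.273, "clumped", group = "impact"),
    trait_spec("restricted_range",      0.124, "random"),
    trait_spec("collected",             0.157, "clumped")
  )
}

#' Configuration of a synthetic coral study
#'
#' Bundles every knob of the generator. Defaults emulate the study
#' conditions: the printed Red List census (4 CR, 23 EN, 198 VU, 174 NT,
#' 289 LC, 149 DD among 837 species, rescaled exactly to `n_species`),
#' eight binary traits at the reported prevalences (clumped
#' susceptibility/resistance/recovery traits, a random restricted-range
#' trait, and a shared liability group linking bleaching, disease and
#' seastar-predation susceptibility), a Yule tree with a fraction of
#' internal edges collapsed into polytomies, and 56% of terminals set to
#' zero length (the fraction of reef species without sequence data).
#'
#' @param n_species number of species (>= 4).
#' @param tree_model `"yule"` or `"birth_death"`.
#' @param birth_rate,death_rate birth-death rates (death must be below
#'   birth).
#' @param category_frequencies named counts over CR, EN, VU, NT, LC, DD
#'   summing to `n_species` (the default census is rescaled for you).
#' @param trait_specs list of [trait_spec()] entries.
#' @param polytomy_fraction fraction of internal edges collapsed in \[0, 1).
#' @param missing_data_fraction fraction of terminals set to length 0.
#' @param n_source_trees number of extracted source trees.
#' @param seed integer master seed; all stage seeds derive from it.
#' @return list of class `synthetic_study_config`.
#' @export
synthetic_study_config <- function(n_species = 837,
                                   tree_model = c("yule", "birth_death"),
                                   birth_rate = 1, death_rate = 0,
                                   category_frequencies = NULL,
                                   trait_specs = default_trait_specs(),
                                   polytomy_fraction = 0.3,
                                   missing_data_fraction = 0.56,
                                   n_source_trees = 15,
                                   seed = 1) {
  tree_model <- match.arg(tree_model)
  if (n_species < 4) stop("n_species must be >= 4")
  if (tree_model == "birth_death" && death_rate >= birth_rate) {
    stop("death_rate must be below birth_rate")
  }
  if (polytomy_fraction < 0 || polytomy_fraction >= 1) {
    stop("polytomy_fraction must be in [0, 1)")
  }
  if (missing_data_fraction < 0 || missing_data_fraction >= 1) {
    stop("missing_data_fraction must be in [0, 1)")
  }
  if (is.null(category_frequencies)) {
    category_frequencies <- scale_counts(coral_census, n_species)
  }
  if (sum(category_frequencies) != n_species) {
    stop("category_frequencies must sum to n_species")
  }
  structure(list(n_species = n_species, tree_model = tree_model,
                 birth_rate = birth_rate, death_rate = death_rate,
                 category_frequencies = category_frequencies,
                 trait_specs = trait_specs,
                 polytomy_fraction = polytomy_fraction,
                 missing_data_fraction = missing_data_fraction,
                 n_source_trees = n_source_trees, seed = seed),
            class = "synthetic_study_config")
}

# Collapse the given internal (non-root) edges: children reattach to the
# grandparent; the collapsed edge's length is dropped (the node becomes an
# unresolved polytomy).
collapse_internal_edges <- function(tree, frac) {
  if (frac <= 0) return(tree)
  nt <- length(tree$tip.label)
  internal_rows <- which(tree$edge[, 2] > nt)
  n_drop <- floor(frac * length(internal_rows))
  if (n_drop == 0) return(tree)
  rows <- sample(internal_rows, n_drop)
  tree$edge.length[rows] <- 0
  # di2multi collapses branches strictly below tol; pick one far below any
  # surviving positive length
  tol <- min(tree$edge.length[tree$edge.length > 0]) * 1e-8
  ape::di2multi(tree, tol = tol)
}

#' Simulate the study tree (birth-death, polytomies, zero terminals)
#'
#' A birth-death (default pure-birth) tree with `n_species` tips is
#' degraded to emulate a consensus supertree: a fraction of internal edges
#' is collapsed into polytomies, and a fraction of terminals (species
#' without sequence data) gets branch length 0. The zero-length tips are
#' recorded in `attr(tree, "no_data_species")`.
#'
#' @param config a [synthetic_study_config()].
#' @return a `phylo` with tips `s001`, `s002`, ...
#' @export
simulate_tree <- function(config) {
  set.seed(derive_seed(config$seed, "tree"))
  tree <- ape::rphylo(config$n_species, config$birth_rate,
                      if (config$tree_model == "yule") 0 else config$death_rate)
  tree$tip.label <- sprintf("s%0*d", nchar(config$n_species),
                            seq_len(config$n_species))
  tree$node.label <- NULL
  tree <- collapse_internal_edges(tree, config$polytomy_fraction)
  n_missing <- floor(config$missing_data_fraction * config$n_species)
  no_data <- sort(sample(tree$tip.label, n_missing))
  tree <- assign_missing_terminal_lengths(tree, no_data)
  attr(tree, "no_data_species") <- no_data
  tree
}

#' Assign Red List categories to the tips
#'
#' `clustering = "none"` permutes the category census uniformly across tips
#' (the negligible-signal situation reported for coral extinction risk);
#' `"brownian"` simulates a liability on the tree and cuts the
#' liability-ranked species into category blocks (CR highest liability,
#' then EN, VU, NT, LC, DD), producing phylogenetically clumped risk for
#' power testing. Counts are exact.
#'
#' @param tree a `phylo`.
#' @param config a [synthetic_study_config()] (counts must sum to the tip
#'   count).
#' @param clustering `"none"` or `"brownian"`.
#' @return named character vector, species -> category code.
#' @export
simulate_categories <- function(tree, config,
                                clustering = c("none", "brownian")) {
  clustering <- match.arg(clustering)
  counts <- config$category_frequencies
  nt <- length(tree$tip.label)
  if (sum(counts) != nt) stop("category counts must sum to the tip count")
  codes <- rep(names(counts), counts)
  set.seed(derive_seed(config$seed, paste0("categories_", clustering)))
  cats <- if (clustering == "none") {
    sample(codes)
  } else {
    liab <- sim_bm(tree, 1)[, 1]
    codes[match(seq_len(nt), order(liab, decreasing = TRUE))]
  }
  stats::setNames(cats, tree$tip.label)
}

#' Simulate binary traits with controlled phylogenetic structure
#'
#' Clumped traits are a Brownian liability thresholded so that exactly
#' `round(prevalence * n)` species are in state 1 (ties broken by rank);
#' traits sharing a liability group share one liability with different
#' thresholds, which induces positive association between them. Random
#' traits are exact-prevalence 0/1 vectors permuted across tips.
#'
#' @param tree a `phylo`.
#' @param config a [synthetic_study_config()].
#' @return data.frame, one row per species (column `species`), one 0/1
#'   column per trait.
#' @export
simulate_binary_traits <- function(tree, config) {
  nt <- length(tree$tip.label)
  set.seed(derive_seed(config$seed, "traits"))
  groups <- unique(stats::na.omit(vapply(config$trait_specs,
                                         function(s) s$group %||% NA_character_,
                                         character(1))))
  liabilities <- list()
  for (g in groups) liabilities[[g]] <- sim_bm(tree, 1)[, 1]
  out <- data.frame(species = tree$tip.label, stringsAsFactors = FALSE)
  for (sp in config$trait_specs) {
    k <- max(1L, min(nt - 1L, round(sp$prevalence * nt)))
    v <- numeric(nt)
    if (sp$structure == "clumped") {
      liab <- if (!is.null(sp$group)) liabilities[[sp$group]] else sim_bm(tree, 1)[, 1]
      v[order(liab, decreasing = TRUE)[seq_len(k)]] <- 1
    } else {
      v[sample.int(nt, k)] <- 1
    }
    out[[sp$name]] <- v
  }
  out
}

# One random NNI perturbation of a bifurcating tree (topology only;
# branch lengths are dropped, which is fine for MRP sources).
nni_perturb <- function(tree) {
  nt <- length(tree$tip.label)
  par <- rep(NA_integer_, nt + tree$Nnode)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  par[nt + 1L] <- 0L
  mv <- nni_moves(par)
  if (length(mv) == 0) return(tree)
  partree_to_phylo(mv[[sample.int(length(mv), 1)]], tree$tip.label)
}

#' Extract source trees from a model tree
#'
#' Each source tree is the induced subtree on a random taxon subset; with
#' probability `conflict_rate` a source gets one random NNI perturbation
#' (emulating conflicting phylogenetic hypotheses). Node supports are drawn
#' uniformly from `support_range` and written as internal node labels. One
#' source can be flagged taxonomic (all node weights 1).
#'
#' @param tree the model `phylo`.
#' @param config a [synthetic_study_config()] (gives `n_source_trees` and
#'   the seed).
#' @param conflict_rate probability in \[0, 1) of perturbing a source.
#' @param support_range length-2 numeric, bootstrap percentage range.
#' @param size_range length-2 integer, taxon subset size range (>= 3).
#' @param include_taxonomic flag the first source as taxonomy-derived?
#' @return list of [source_tree()] objects.
#' @export
extract_source_trees <- function(tree, config, conflict_rate = 0,
                                 support_range = c(50, 100),
                                 size_range = NULL,
                                 include_taxonomic = FALSE) {
  stopifnot_phylo(tree)
  if (conflict_rate < 0 || conflict_rate >= 1) stop("conflict_rate must be in [0, 1)")
  nt <- length(tree$tip.label)
  if (is.null(size_range)) {
    size_range <- c(max(4, floor(nt / 3)), max(5, floor(2 * nt / 3)))
  }
  if (size_range[1] < 3) stop("source subsets need at least 3 taxa")
  set.seed(derive_seed(config$seed, "sources"))
  out <- vector("list", config$n_source_trees)
  for (i in seq_len(config$n_source_trees)) {
    size <- sample(seq(size_range[1], size_range[2]), 1)
    taxa <- sample(tree$tip.label, size)
    sub <- prune_to(tree, taxa, include_root = FALSE)
    sub$root.edge <- NULL
    perturbed <- FALSE
    if (conflict_rate > 0 && stats::runif(1) < conflict_rate &&
        is_bifurcating(sub)) {
      sub <- nni_perturb(sub)
      perturbed <- TRUE
    }
    sub$node.label <- as.character(round(stats::runif(sub$Nnode,
                                                      support_range[1],
                                                      support_range[2])))
    prov <- if (include_taxonomic && i == 1) "taxonomic" else
      if (i %% 2 == 0) "morphological" else "molecular"
    if (prov == "taxonomic") sub$node.label <- NULL
    st <- source_tree(sub, prov, sprintf("src%02d", i))
    attr(st, "perturbed") <- perturbed
    out[[i]] <- st
  }
  out
}
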