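#' Fair-proportion evolutionary distinctiveness
#'
#' Each branch length is divided equally among the tips descending from it;
#' a species' ED is the sum of its shares along the root path (terminal
#' branch plus species-weighted allocation of ancestral branches). The ED
#' values of all species sum exactly to the total branch length. Works on
#' polytomies; any `root.edge` is shared equally by all tips.
#'
#' @param tree a `phylo`. Absent branch lengths are treated as 0 with a
#'   warning (a conservative lower limit on distinctiveness).
#' @return named numeric vector, one ED value per tip.
#' @examples
#' evolutionary_distinctiveness(read_newick("((A:1,B:1):1,C:2);"))
#' @export
evolutionary_distinctiveness <- function(tree) {
  stopifnot_phylo(tree)
  nt <- length(tree$tip.label)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; treated as 0")
    tree$edge.length <- numeric(nrow(tree$edge))
  }
  cnt <- node_tip_counts(tree)
  share <- numeric(nt + tree$Nnode)
  share[nt + 1L] <- (tree$root.edge %||% 0) / nt
  e <- stats::reorder(tree, "cladewise")
  for (k in seq_len(nrow(e$edge))) {
    share[e$edge[k, 2]] <- share[e$edge[k, 1]] +
      e$edge.length[k] / cnt[e$edge[k, 2]]
  }
  ed <- share[seq_len(nt)]
  names(ed) <- tree$tip.label
  ed
}

#' Red List category to extinction-probability transforms
#'
#' Probability of extinction over a 100-year horizon per IUCN Red List
#' category. The default `IUCN100` table uses PE(LC) = 0.001 (at most about
#' one of the 289 LC corals lost in 100 years) and PE(NT) = 0.01; the
#' CR/EN/VU values (0.999 / 0.667 / 0.1) follow the transformation family
#' of Mooers and colleagues and are editable. DD species get a value
#' between LC and NT: the midpoint 0.0055 by default, or the geometric mean
#' (`dd = "geometric"`, about 0.0032). `Isaac` and `Pessimistic` tables are
#' provided as alternatives but drive no default output.
#'
#' @param name transform name, or `"custom"` with `mapping` supplied.
#' @param dd imputation rule for DD: `"midpoint"` or `"geometric"`.
#' @param mapping named probability vector over CR, EN, VU, NT, LC (and
#'   optionally DD) for `name = "custom"`.
#' @return object of class `pe_transform`: named probability vector over
#'   CR, EN, VU, NT, LC, DD with attributes `name` and `horizon` (years).
#' @export
pe_transform <- function(name = c("IUCN100", "Isaac", "Pessimistic", "custom"),
                         dd = c("midpoint", "geometric"), mapping = NULL) {
  name <- match.arg(name)
  dd <- match.arg(dd)
  tab <- switch(name,
    IUCN100     = c(CR = 0.999, EN = 0.667, VU = 0.1, NT = 0.01, LC = 0.001),
    Isaac       = c(CR = 0.4, EN = 0.2, VU = 0.1, NT = 0.05, LC = 0.025),
    Pessimistic = c(CR = 0.999, EN = 0.99, VU = 0.9, NT = 0.8, LC = 0.4),
    custom      = {
      if (is.null(mapping)) stop("custom transform requires 'mapping'")
      mapping
    })
  need <- c("CR", "EN", "VU", "NT", "LC")
  if (!all(need %in% names(tab))) {
    stop("mapping must name ", paste(need, collapse = ", "))
  }
  if (any(tab < 0 | tab > 1)) stop("probabilities must lie in [0, 1]")
  if (any(diff(tab[need]) > 0)) stop("mapping must be monotone CR >= EN >= VU >= NT >= LC")
  if (!"DD" %in% names(tab)) {
    tab["DD"] <- switch(dd,
      midpoint  = (tab["LC"] + tab["NT"]) / 2,
      geometric = sqrt(tab["LC"] * tab["NT"]))
  }
  structure(tab[c("CR", "EN", "VU", "NT", "LC", "DD")],
            name = name, horizon = 100, class = "pe_transform")
}

#' Extinction probability for a Red List category
#'
#' @param cat character vector of category codes (CR, EN, VU, NT, LC, DD,
#'   NE).
#' @param transform a [pe_transform()] (default IUCN100).
#' @param ne_action `"error"` (strict) or a probability to assign NE.
#' @return probabilities, vectorized over `cat`.
#' @export
pe_from_category <- function(cat, transform = pe_transform("IUCN100"),
                             ne_action = "error") {
  cat <- as.character(cat)
  known <- c("CR", "EN", "VU", "NT", "LC", "DD", "NE")
  bad <- setdiff(unique(cat), known)
  if (length(bad)) stop("unknown Red List categories: ", paste(bad, collapse = ", "))
  if (any(cat == "NE")) {
    if (identical(ne_action, "error")) stop("NE (Not Evaluated) species present")
    transform <- c(unclass(transform), NE = as.numeric(ne_action))
  }
  unname(unclass(transform)[cat])
}

#' EDGE scores over polytomy resolutions
#'
#' For each resolved replicate, compute fair-proportion ED per species and
#' EDGE = ED x PE; report the mean and SD over replicates, and rank by mean
#' EDGE (ties broken by mean ED, then label).
#'
#' @param resolutions a `resolution_set` from [resolve_polytomies()], or a
#'   single `phylo` (treated as one replicate).
#' @param categories named character vector, species -> Red List code.
#' @param transform a [pe_transform()].
#' @return data.frame with columns species, ed_mean, ed_sd, pe, edge_mean,
#'   edge_sd, rank (1 = highest mean EDGE), ordered by rank.
#' @export
edge_scores <- function(resolutions, categories,
                        transform = pe_transform("IUCN100")) {
  if (inherits(resolutions, "phylo")) {
    resolutions <- list(base = resolutions, replicates = list(resolutions))
  }
  reps <- resolutions$replicates
  species <- reps[[1]]$tip.label
  missing_cat <- setdiff(species, names(categories))
  if (length(missing_cat)) {
    stop("species without Red List category: ", paste(missing_cat, collapse = ", "))
  }
  pe <- pe_from_category(categories[species], transform)
  ed_mat <- vapply(reps, function(tr) evolutionary_distinctiveness(tr)[species],
                   numeric(length(species)))
  ed_mat <- matrix(ed_mat, nrow = length(species))
  edge_mat <- ed_mat * pe
  sd0 <- function(m) {
    if (ncol(m) < 2) return(numeric(nrow(m)))
    apply(m, 1, stats::sd)
  }
  out <- data.frame(
    species = species,
    ed_mean = rowMeans(ed_mat),
    ed_sd = sd0(ed_mat),
    pe = pe,
    edge_mean = rowMeans(edge_mat),
    edge_sd = sd0(edge_mat),
    stringsAsFactors = FALSE
  )
  ord <- order(-out$edge_mean, -out$ed_mean, out$species)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Mean rank variation between two EDGE rankings
#'
#' Diagnostic for ranking robustness (for example, full analysis versus a
#' reduced taxon set): the mean absolute rank difference over the top-k
#' species of the full ranking, and over all shared species.
#'
#' @param full,subset data.frames from [edge_scores()]; `subset`'s species
#'   must be contained in `full`'s.
#' @param top_k number of top-ranked (in `full`) species for the first
#'   summary.
#' @return named numeric vector `c(top_k = ..., all = ...)`.
#' @export
rank_stability <- function(full, subset, top_k = 30) {
  shared <- intersect(full$species, subset$species)
  if (!all(subset$species %in% full$species)) {
    stop("subset contains species absent from the full ranking")
  }
  if (top_k > length(shared)) stop("top_k exceeds the number of shared species")
  rf <- full$rank[match(shared, full$species)]
  rs <- subset$rank[match(shared, subset$species)]
  delta <- abs(rf - rs)
  topset <- shared[order(rf)][seq_len(top_k)]
  c(top_k = mean(delta[match(topset, shared)]), all = mean(delta))
}
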