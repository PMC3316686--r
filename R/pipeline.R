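#' Red List category proportions at threat thresholds
#'
#' For each cumulative threshold (EN and above, VU and above, NT and
#' above) the fraction of species over ALL species (denominator includes
#' DD), rounded to 3 decimals, plus the percentage of threatened species
#' (CR + EN + VU) among assessed species (denominator excludes DD and NE),
#' rounded to 1 decimal. The two denominator conventions are both reported
#' because both are standard.
#'
#' @param categories named species -> code vector, or a named count table
#'   over codes (e.g. `c(CR = 4, EN = 23, ...)`).
#' @return list with `proportions` (data.frame threshold / n_species /
#'   proportion, denominator = all species) and `threatened_pct`
#'   (percentage among assessed).
#' @examples
#' category_proportions(c(CR = 4, EN = 23, VU = 198, NT = 174,
#'                        LC = 289, DD = 149))
#' @export
category_proportions <- function(categories) {
  counts <- if (all(names(categories) %in%
                    c("CR", "EN", "VU", "NT", "LC", "DD", "NE")) &&
                is.numeric(categories)) {
    categories
  } else {
    table(factor(categories, levels = c("CR", "EN", "VU", "NT", "LC", "DD", "NE")))
  }
  get <- function(code) if (code %in% names(counts)) as.numeric(counts[[code]]) else 0
  total <- sum(as.numeric(counts))
  if (total == 0) stop("empty category map")
  cum <- vapply(names(threat_threshold_sets), function(th) {
    sum(vapply(threat_threshold_sets[[th]], get, numeric(1)))
  }, numeric(1))
  assessed <- total - get("DD") - get("NE")
  threatened <- sum(vapply(c("CR", "EN", "VU"), get, numeric(1)))
  list(
    proportions = data.frame(
      threshold = names(threat_threshold_sets),
      n_species = as.integer(cum),
      proportion = round(cum / total, 3),
      row.names = NULL
    ),
    threatened_pct = if (assessed > 0) round(100 * threatened / assessed, 1) else NA_real_,
    n_total = as.integer(total),
    n_assessed = as.integer(assessed)
  )
}

#' Run the full synthetic study end to end
#'
#' Orchestrates the pipeline on generated data: simulate the study tree,
#' Red List categories and binary traits; optionally verify the MRP
#' supertree machinery on extracted source trees (desk scale only);
#' resolve polytomies; score and rank EDGE; run the phylogenetic signal
#' battery (K for PE, D for the three threat thresholds and every binary
#' trait); run PD-loss scenarios and the top-k EDGE loss test; test
#' imbalance against the Yule null. Writes delimited tables and a
#' machine-readable JSON summary echoing every seed and setting.
#'
#' @param config a [synthetic_study_config()].
#' @param out_dir output directory (created); `NULL` for no files.
#' @param n_resolutions polytomy resolutions (default 1000).
#' @param n_null null replicates for signal and PD tests (default 1000).
#' @param transform a [pe_transform()].
#' @param top_k size of the top-EDGE extinction scenario (default 30).
#' @param run_mrp run the supertree search on extracted sources? Defaults
#'   to `TRUE` only for small studies (<= 25 species).
#' @return invisible list with all stage results (`tree`, `categories`,
#'   `traits`, `edge`, `signal`, `pd_loss`, `imbalance`, `proportions`,
#'   `mrp`, `summary`).
#' @export
run_study <- function(config, out_dir = NULL, n_resolutions = 1000,
                      n_null = 1000, transform = pe_transform("IUCN100"),
                      top_k = 30, run_mrp = config$n_species <= 25) {
  if (!inherits(config, "synthetic_study_config")) {
    stop("config must be a synthetic_study_config")
  }
  seed <- config$seed
  tree <- simulate_tree(config)
  categories <- simulate_categories(tree, config, "none")
  traits <- simulate_binary_traits(tree, config)

  mrp <- NULL
  if (run_mrp) {
    sources <- extract_source_trees(tree, config)
    mat <- encode_mrp(sources, all_taxa = tree$tip.label)
    search <- parsimony_search(mat, "hill_climb", n_starts = 10,
                               seed = derive_seed(seed, "search"))
    mrp <- list(matrix = mat, result = search,
                consensus = strict_consensus(search))
  }

  res <- resolve_polytomies(tree, n_resolutions, seed = derive_seed(seed, "res"))
  edge <- edge_scores(res, categories, transform)

  pe <- stats::setNames(pe_from_category(categories[tree$tip.label], transform),
                        tree$tip.label)
  rep1 <- res$replicates[[1]]
  signal <- list(
    pe_K = k_randomization_test(rep1, pe, n_permutations = n_null,
                                seed = derive_seed(seed, "sigK"))
  )
  for (th in names(threat_threshold_sets)) {
    ind <- stats::setNames(
      as.numeric(categories[tree$tip.label] %in% threat_threshold_sets[[th]]),
      tree$tip.label)
    signal[[th]] <- if (length(unique(ind)) < 2) "skipped: monomorphic" else
      fritz_purvis_d(rep1, ind, n_permutations = n_null, n_brownian = n_null,
                     seed = derive_seed(seed, th))
  }
  for (tn in setdiff(names(traits), "species")) {
    tv <- stats::setNames(traits[[tn]], traits$species)
    signal[[tn]] <- fritz_purvis_d(rep1, tv, n_permutations = n_null,
                                   n_brownian = n_null,
                                   seed = derive_seed(seed, tn))
  }

  pd_loss <- list()
  for (th in names(threat_threshold_sets)) {
    removed <- sum(categories %in% threat_threshold_sets[[th]])
    if (removed >= 1 && removed < length(categories)) {
      pd_loss[[th]] <- extinction_scenario_test(
        tree, categories, th, n_null = n_null,
        seed = derive_seed(seed, paste0("pd_", th)))
    }
  }
  ktop <- min(top_k, nrow(edge) - 1)
  pd_loss[[paste0("top_", ktop, "_edge")]] <-
    top_k_loss_test(tree, edge, ktop, n_null = n_null,
                    seed = derive_seed(seed, "pd_top"))

  imbalance <- yule_imbalance_test(rep1, n_simulations = n_null,
                                   seed = derive_seed(seed, "imb"))
  proportions <- category_proportions(categories)

  signal_table <- do.call(rbind, lapply(names(signal), function(nm) {
    s <- signal[[nm]]
    if (!inherits(s, "signal_test")) return(NULL)
    data.frame(trait = nm, statistic = s$statistic_name,
               observed = s$observed, p_vs_random = s$p_vs_random,
               p_vs_clumped = s$p_vs_clumped %||% NA_real_,
               row.names = NULL)
  }))
  pd_table <- do.call(rbind, lapply(names(pd_loss), function(nm) {
    r <- pd_loss[[nm]]
    data.frame(scenario = nm, n_removed = r$n_removed,
               pd_observed = r$pd_observed, null_mean = mean(r$null_pd),
               null_sd = stats::sd(r$null_pd), t = r$t_statistic,
               p = r$p_value, p_empirical = r$p_empirical,
               direction = r$direction, row.names = NULL)
  }))

  summary <- list(
    config = unclass(config)[c("n_species", "tree_model", "birth_rate",
                               "death_rate", "polytomy_fraction",
                               "missing_data_fraction", "n_source_trees",
                               "seed")],
    n_resolutions = n_resolutions, n_null = n_null,
    pe_transform = attr(transform, "name"),
    category_counts = as.list(config$category_frequencies),
    proportions = proportions,
    colless = imbalance$colless_observed,
    colless_p = imbalance$p_value,
    top_edge_species = edge$species[seq_len(min(10, nrow(edge)))]
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(edge, file.path(out_dir, "edge_ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(signal_table, file.path(out_dir, "signal_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pd_table, file.path(out_dir, "pd_loss.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(species = names(categories), category = unname(categories)),
      file.path(out_dir, "species_table.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(traits, file.path(out_dir, "traits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_newick(tree, file.path(out_dir, "supertree.nwk"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(tree = tree, categories = categories, traits = traits,
                 mrp = mrp, resolutions = res, edge = edge, signal = signal,
                 signal_table = signal_table, pd_loss = pd_loss,
                 pd_table = pd_table, imbalance = imbalance,
                 proportions = proportions, summary = summary))
}
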