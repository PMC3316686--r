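test_that("generators are bit-reproducible from the seed", {
  cfg <- synthetic_study_config(n_species = 30, seed = 17)
  t1 <- simulate_tree(cfg)
  t2 <- simulate_tree(cfg)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_identical(simulate_categories(t1, cfg), simulate_categories(t2, cfg))
  expect_identical(simulate_binary_traits(t1, cfg),
                   simulate_binary_traits(t2, cfg))
})

test_that("tree degradation creates the requested polytomies and zero tips", {
  cfg0 <- synthetic_study_config(n_species = 100, polytomy_fraction = 0,
                                 missing_data_fraction = 0, seed = 3)
  t0 <- simulate_tree(cfg0)
  expect_true(reefedge:::is_bifurcating(t0))
  expect_true(all(t0$edge.length > 0))
  expect_equal(t0$Nnode, 99)

  cfg <- synthetic_study_config(n_species = 100, polytomy_fraction = 0.3,
                                missing_data_fraction = 0.4, seed = 3)
  tr <- simulate_tree(cfg)
  # ~30% of the 98 internal (non-root) edges collapsed
  expect_equal(tr$Nnode, 99 - floor(0.3 * 98))
  nodata <- attr(tr, "no_data_species")
  expect_length(nodata, 40)
  term <- tr$edge.length[match(match(nodata, tr$tip.label), tr$edge[, 2])]
  expect_true(all(term == 0))
})

test_that("category assignment hits the census exactly in both modes", {
  cfg <- synthetic_study_config(n_species = 837, seed = 5)
  expect_equal(unname(cfg$category_frequencies[c("CR", "EN", "VU", "NT", "LC", "DD")]),
               c(4L, 23L, 198L, 174L, 289L, 149L))
  # rescaling keeps the total exact
  cfg2 <- synthetic_study_config(n_species = 120, seed = 5)
  expect_equal(sum(cfg2$category_frequencies), 120)
  tr <- simulate_tree(cfg2)
  for (mode in c("none", "brownian")) {
    cats <- simulate_categories(tr, cfg2, mode)
    expect_equal(as.vector(table(factor(cats, names(cfg2$category_frequencies)))),
                 unname(cfg2$category_frequencies))
  }
})

test_that("brownian category mode clumps threat, none mode does not", {
  cfg <- synthetic_study_config(n_species = 128, seed = 23,
                                polytomy_fraction = 0,
                                missing_data_fraction = 0)
  tr <- simulate_tree(cfg)
  ind <- function(cats) {
    stats::setNames(as.numeric(cats %in% c("CR", "EN", "VU")), names(cats))
  }
  d_none <- fritz_purvis_d(tr, ind(simulate_categories(tr, cfg, "none")),
                           200, 200, seed = 1)$observed
  d_bm <- fritz_purvis_d(tr, ind(simulate_categories(tr, cfg, "brownian")),
                         200, 200, seed = 1)$observed
  expect_gt(d_none, 0.6)
  expect_lt(d_bm, 0.4)
})

test_that("trait prevalences are exact and liability groups induce association", {
  cfg <- synthetic_study_config(n_species = 200, seed = 29)
  tr <- simulate_tree(cfg)
  traits <- simulate_binary_traits(tr, cfg)
  for (sp in cfg$trait_specs) {
    expect_equal(sum(traits[[sp$name]]), round(sp$prevalence * 200))
  }
  # shared-liability traits are nested by construction at these prevalences
  shared <- traits$disease_susceptible[traits$bleaching_susceptible == 0]
  expect_true(mean(shared) < mean(traits$disease_susceptible))
})

test_that("extracted sources are induced subtrees unless conflicted", {
  cfg <- synthetic_study_config(n_species = 16, n_source_trees = 6, seed = 31,
                                polytomy_fraction = 0,
                                missing_data_fraction = 0)
  model <- simulate_tree(cfg)
  srcs <- extract_source_trees(model, cfg, conflict_rate = 0,
                               support_range = c(70, 100),
                               size_range = c(5, 10))
  expect_length(srcs, 6)
  for (s in srcs) {
    induced <- prune_to(model, s$tree$tip.label, include_root = FALSE)
    expect_equal(reefedge:::topology_signature(s$tree),
                 reefedge:::topology_signature(induced))
    expect_true(all(s$node_supports >= 70 & s$node_supports <= 100))
  }
  # constant supports translate to constant character weights
  srcs2 <- extract_source_trees(model, cfg, support_range = c(100, 100),
                                size_range = c(5, 10))
  m <- encode_mrp(srcs2, all_taxa = model$tip.label)
  expect_true(all(m$weights == 100))
  # a taxonomic source gets unit weights
  srcs3 <- extract_source_trees(model, cfg, include_taxonomic = TRUE,
                                size_range = c(5, 10))
  expect_equal(srcs3[[1]]$provenance, "taxonomic")
  expect_true(all(srcs3[[1]]$node_supports == 1))
})

test_that("conflict_rate perturbs roughly the stated share of sources", {
  cfg <- synthetic_study_config(n_species = 20, n_source_trees = 40, seed = 37,
                                polytomy_fraction = 0,
                                missing_data_fraction = 0)
  model <- simulate_tree(cfg)
  srcs <- extract_source_trees(model, cfg, conflict_rate = 0.5,
                               size_range = c(6, 12))
  n_pert <- sum(vapply(srcs, function(s) isTRUE(attr(s, "perturbed")),
                       logical(1)))
  expect_gt(n_pert, 10)
  expect_lt(n_pert, 30)
})
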