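test_that("Baum-Ragan coding: states, weights, missing, no merging", {
  src <- source_tree(read_newick("((A,B)80,C);"), "molecular", "m1")
  m <- encode_mrp(list(src), all_taxa = c("A", "B", "C", "D"))
  expect_equal(ncol(m$matrix), 1)
  expect_equal(unname(m$matrix[, 1]), c(1L, 1L, 0L, NA))
  expect_equal(m$weights, 80)

  # taxonomy-derived nodes are all weight 1
  tx <- source_tree(read_newick("((A,B)99,(C,D)99);"), "taxonomic", "tax")
  mt <- encode_mrp(list(tx))
  expect_equal(mt$weights, c(1, 1))
  expect_equal(ncol(mt$matrix), 2)

  # identical sources with different supports stay separate characters
  s1 <- source_tree(read_newick("((A,B)80,C);"), "molecular", "a")
  s2 <- source_tree(read_newick("((A,B)60,C);"), "molecular", "b")
  m2 <- encode_mrp(list(s1, s2))
  expect_equal(ncol(m2$matrix), 2)
  expect_equal(sort(m2$weights), c(60, 80))
  expect_identical(m2$matrix[, 1], m2$matrix[, 2])

  expect_error(encode_mrp(list()), "empty")
  expect_warning(encode_mrp(list(source_tree(read_newick("(A,B);"),
                                             "molecular", "tiny"),
                                 s1)),
                 "fewer than 3 tips")
})

test_that("weighted Fitch length matches hand computations and is invariant", {
  src <- source_tree(read_newick("((A,B)80,C);"), "molecular", "m1")
  m <- encode_mrp(list(src), all_taxa = c("A", "B", "C"))
  expect_equal(fitch_score(read_newick("((A,B),C);"), m), 80)
  expect_equal(fitch_score(read_newick("((A,C),B);"), m), 80)
  # with an all-zero fourth taxon the split becomes informative
  m4 <- encode_mrp(list(src), all_taxa = c("A", "B", "C", "D"))
  # D is missing for this character, so it is ignored wherever it sits
  expect_equal(fitch_score(read_newick("(((A,B),C),D);"), m4), 80)
  expect_equal(fitch_score(read_newick("(((A,C),B),D);"), m4), 80)
  # characters over all four taxa can need two changes each
  s4 <- source_tree(read_newick("((A,B)80,(C,D)90);"), "molecular", "s4")
  mm4 <- encode_mrp(list(s4))
  expect_equal(fitch_score(read_newick("((A,C),(B,D));"), mm4), 2 * 80 + 2 * 90)
  expect_equal(fitch_score(read_newick("((A,B),(C,D));"), mm4), 80 + 90)

  # invariance to character order and global weight scaling
  s1 <- source_tree(read_newick("(((A,B)70,C)50,D);"), "molecular", "s1")
  s2 <- source_tree(read_newick("((A,C)30,(B,D)60);"), "molecular", "s2")
  mm <- encode_mrp(list(s1, s2))
  tr <- read_newick("((A,D),(B,C));")
  base <- fitch_score(tr, mm)
  perm <- sample(ncol(mm$matrix))
  mperm <- mm
  mperm$matrix <- mm$matrix[, perm, drop = FALSE]
  mperm$weights <- mm$weights[perm]
  expect_equal(fitch_score(tr, mperm), base)
  mscale <- mm
  mscale$weights <- mm$weights * 3.5
  expect_equal(fitch_score(tr, mscale), base * 3.5)

  expect_error(fitch_score(read_newick("((A,B),Z);"), m), "absent")
})

test_that("Fitch length agrees with phangorn on random cases with missing data", {
  skip_if_not_installed("phangorn")
  set.seed(202)
  for (i in 1:8) {
    n <- sample(6:10, 1)
    tr <- ape::rtree(n)
    tr$edge.length <- NULL
    states <- replicate(8, sample(c(0L, 1L, NA), n, replace = TRUE,
                                  prob = c(0.4, 0.4, 0.2)))
    rownames(states) <- tr$tip.label
    ok <- apply(states, 2, function(s) length(unique(stats::na.omit(s))) == 2)
    states <- states[, ok, drop = FALSE]
    if (ncol(states) == 0) next
    mo <- structure(list(matrix = states, weights = rep(1, ncol(states)),
                         provenance = rep("x", ncol(states)),
                         taxa = tr$tip.label),
                    class = "mrp_matrix")
    ch <- states
    ch[is.na(ch)] <- "?"
    pd <- phangorn::phyDat(apply(ch, c(1, 2), as.character), type = "USER",
                           levels = c("0", "1"), ambiguity = "?")
    expect_equal(fitch_score(tr, mo),
                 as.numeric(phangorn::parsimony(tr, pd, method = "fitch")))
  }
})

test_that("a single binary source is recovered exactly by branch and bound", {
  src <- source_tree(read_newick("(((A,B)70,(C,D)90)80,E);"), "molecular", "s")
  m <- encode_mrp(list(src))
  res <- parsimony_search(m, "branch_and_bound", seed = 2)
  expect_equal(res$score, sum(m$weights))  # every character changes once
  expect_length(res$trees, 1)
  expect_equal(reefedge:::topology_signature(res$trees[[1]]),
               reefedge:::topology_signature(src$tree))
})

test_that("conflicting equal-weight sources tie and collapse in consensus", {
  c1 <- source_tree(read_newick("(((A,B)50,C)50,D);"), "molecular", "c1")
  c2 <- source_tree(read_newick("(((A,C)50,B)50,D);"), "molecular", "c2")
  m <- encode_mrp(list(c1, c2))
  res <- parsimony_search(m, "branch_and_bound", seed = 5)
  expect_gte(length(res$trees), 2)
  cons <- strict_consensus(res)
  expect_false(contains_clade(cons, c("A", "B")))
  expect_false(contains_clade(cons, c("A", "C")))
  expect_true(contains_clade(cons, c("A", "B", "C")))  # both agree on this
})

test_that("the heavier of two conflicting groupings wins", {
  s1 <- source_tree(read_newick("((A,B)90,C,D);"), "molecular", "w90")
  s2 <- source_tree(read_newick("((A,C)10,B,D);"), "molecular", "w10")
  m <- encode_mrp(list(s1, s2))
  res <- parsimony_search(m, "branch_and_bound", seed = 5)
  for (tr in res$trees) expect_true(contains_clade(tr, c("A", "B")))
  expect_true(contains_clade(strict_consensus(res), c("A", "B")))
})

test_that("strict consensus: identity, full collapse, shared clades", {
  t1 <- read_newick("((A,B),C);")
  expect_identical(write_newick(strict_consensus(list(t1))), write_newick(t1))
  t2 <- read_newick("((A,C),B);")
  star <- strict_consensus(list(t1, t2))
  expect_equal(star$Nnode, 1)
  trio <- list(read_newick("(((A,B),C),D);"), read_newick("(((A,B),D),C);"),
               read_newick("((A,B),(C,D));"))
  expect_true(contains_clade(strict_consensus(trio), c("A", "B")))
  expect_error(strict_consensus(list(t1, read_newick("((A,B),D);"))),
               "tip set")
})

test_that("hill climb recovers compatible sources from a model tree", {
  cfg <- synthetic_study_config(n_species = 10, n_source_trees = 4, seed = 21,
                                polytomy_fraction = 0, missing_data_fraction = 0)
  model <- simulate_tree(cfg)
  srcs <- extract_source_trees(model, cfg, conflict_rate = 0,
                               size_range = c(5, 8))
  m <- encode_mrp(srcs, all_taxa = model$tip.label)
  res <- parsimony_search(m, "hill_climb", n_starts = 8, seed = 3)
  expect_equal(res$score, sum(m$weights))  # compatible: one change per character
  # every source clade is present in the consensus of the best trees
  # restricted to that source's taxa
  for (s in srcs) {
    pruned <- lapply(res$trees, prune_to, keep = s$tree$tip.label,
                     include_root = FALSE)
    sub <- strict_consensus(pruned)
    for (cl in reefedge:::clade_tip_sets(s$tree)) {
      if (length(cl) >= 2 && length(cl) < length(s$tree$tip.label)) {
        expect_true(contains_clade(sub, cl))
      }
    }
  }
})
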