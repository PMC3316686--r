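test_that("K equals 1 on a star tree and matches an independent implementation", {
  set.seed(5)
  star <- ape::stree(8, "star")
  star$edge.length <- rep(2, 8)
  y <- tipvec(star, rnorm(8))
  expect_equal(blomberg_k(star, y), 1)
  skip_if_not_installed("picante")
  for (i in 1:4) {
    tr <- ape::rtree(20 + i)
    y <- tipvec(tr, rnorm(20 + i))
    expect_equal(blomberg_k(tr, y),
                 as.numeric(picante::Kcalc(y[tr$tip.label], tr)),
                 tolerance = 1e-8)
  }
})

test_that("K is invariant to trait affine transforms and branch rescaling", {
  set.seed(8)
  tr <- rand_yule(24)
  y <- tipvec(tr, reefedge:::sim_bm(tr, 1)[, 1])
  k0 <- blomberg_k(tr, y)
  expect_equal(blomberg_k(tr, 3 * y - 10), k0, tolerance = 1e-10)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 7
  expect_equal(blomberg_k(tr2, y), k0, tolerance = 1e-10)
  expect_error(blomberg_k(tr, tipvec(tr, rep(1, 24))), "variance")
})

test_that("K randomization test is deterministic and p-values are proper", {
  set.seed(9)
  tr <- rand_yule(32)
  y <- tipvec(tr, reefedge:::sim_bm(tr, 1)[, 1])
  r1 <- k_randomization_test(tr, y, n_permutations = 199, seed = 4)
  r2 <- k_randomization_test(tr, y, n_permutations = 199, seed = 4)
  expect_identical(r1$p_vs_random, r2$p_vs_random)
  expect_gt(r1$p_vs_random, 0)
  expect_lte(r1$p_vs_random, 1)
  expect_length(r1$null_random, 199)
  expect_warning(k_randomization_test(tr, y, n_permutations = 50, seed = 1),
                 "permutations")
})

test_that("D detects a clumped clade trait and calibrates near 1 when random", {
  set.seed(10)
  tr <- make_balanced(32)
  # indicator of one half of the tree: maximally clumped
  half <- reefedge:::clade_tip_sets(tr)[[2]]  # a large clade
  y <- tipvec(tr, as.numeric(tr$tip.label %in% half))
  r <- fritz_purvis_d(tr, y, n_permutations = 200, n_brownian = 200, seed = 3)
  expect_lt(r$observed, 0.5)
  expect_lt(r$p_vs_random, 0.05)     # rejects the random null
  expect_gt(r$p_vs_clumped, 0.05)    # compatible with the clumped null
  # coin-flip traits: mean D near 1 (tight calibration in the acceptance suite)
  ds <- replicate(40, {
    tr <- rand_yule(64)
    y <- tipvec(tr, 0 * seq_len(64))
    y[sample(64, 20)] <- 1
    fritz_purvis_d(tr, y, 60, 60, seed = sample.int(1e6, 1))$observed
  })
  expect_gt(mean(ds), 0.75)
  expect_lt(mean(ds), 1.25)
  expect_error(fritz_purvis_d(tr, tipvec(tr, rep(1, 32))), "monomorphic")
})

test_that("permutation p-values respect the plus-one rule (never zero)", {
  set.seed(12)
  tr <- rand_yule(24)
  y <- tipvec(tr, reefedge:::sim_bm(tr, 1)[, 1])
  r <- k_randomization_test(tr, y, n_permutations = 99, seed = 1)
  expect_gte(r$p_vs_random, 1 / 100)
  b <- tipvec(tr, as.numeric(y > stats::median(y)))
  d <- fritz_purvis_d(tr, b, n_permutations = 99, n_brownian = 99, seed = 1)
  expect_gte(d$p_vs_random, 1 / 100)
  expect_gte(d$p_vs_clumped, 1 / 100)
})

test_that("independent contrasts match the closed form and ape::pic", {
  # two-tip tree: single contrast (4 - 2) / sqrt(1 + 1)
  t2 <- read_newick("(A:1,B:1);")
  r2 <- independent_contrasts(t2, c(A = 4, B = 2), c(A = 1, B = 0))
  expect_equal(abs(r2$contrasts_x), 2 / sqrt(2), tolerance = 1e-6)
  # y = 2x: slope exactly 2
  set.seed(13)
  tr <- rand_yule(20)
  x <- tipvec(tr, rnorm(20))
  ry <- independent_contrasts(tr, x, 2 * x)
  expect_equal(ry$slope, 2, tolerance = 1e-10)
  expect_equal(ry$contrasts_y, 2 * ry$contrasts_x, tolerance = 1e-10)
  # against ape::pic on clean trees
  y <- tipvec(tr, rnorm(20))
  mine <- independent_contrasts(tr, x, y)
  px <- ape::pic(x[tr$tip.label], tr)
  py <- ape::pic(y[tr$tip.label], tr)
  expect_equal(mine$slope, sum(px * py) / sum(px^2), tolerance = 1e-10)
  expect_equal(sort(abs(mine$contrasts_x)), sort(abs(unname(px))),
               tolerance = 1e-10)
  expect_equal(mine$n_contrasts, 19)
  expect_error(independent_contrasts(read_newick("((A:1,B:1,C:1):1,D:2);"),
                                     c(A = 1, B = 2, C = 3, D = 4),
                                     c(A = 1, B = 2, C = 3, D = 4)),
               "polytomies")
})

test_that("zero-length branches get an epsilon for contrasts only", {
  tr <- read_newick("(((A:1,B:0):1,C:2):0,D:3);")
  x <- c(A = 1, B = 2, C = 3, D = 4)
  expect_message(r <- independent_contrasts(tr, x, x), "zero-length")
  expect_true(all(is.finite(r$contrasts_x)))
  expect_equal(r$slope, 1, tolerance = 1e-10)
})

test_that("binary contrasts: identity gives slope 1, complement slope -1", {
  set.seed(14)
  tr <- rand_yule(16)
  x <- tipvec(tr, as.numeric(reefedge:::sim_bm(tr, 1)[, 1] > 0))
  if (length(unique(x)) == 1) x[1:2] <- c(0, 1)
  expect_equal(binary_contrast_correlation(tr, x, x)$slope, 1, tolerance = 1e-10)
  expect_equal(binary_contrast_correlation(tr, x, 1 - x)$slope, -1,
               tolerance = 1e-10)
  expect_error(binary_contrast_correlation(tr, x + 0.5, x), "binary")
})

test_that("stratified runs partition species, skip degenerate strata", {
  set.seed(15)
  tr <- rand_yule(40)
  y <- tipvec(tr, as.numeric(seq_len(40) %in% sample(40, 15)))
  strata <- tipvec(tr, rep(c("common", "rare"), each = 20))
  res <- stratified_signal(tr, y, strata, test = "D",
                           n_permutations = 99, n_brownian = 99, seed = 2)
  expect_named(res, c("common", "rare"))
  # a stratum where the trait is monomorphic is skipped with a reason
  y2 <- y
  y2[names(strata)[strata == "rare"]] <- 0
  y2[names(strata)[strata == "common"][1:10]] <- 1
  res2 <- stratified_signal(tr, y2, strata, test = "D",
                            n_permutations = 99, n_brownian = 99, seed = 2)
  expect_match(res2$rare, "monomorphic")
  expect_s3_class(res2$common, "signal_test")
  # single all-species stratum reproduces the unstratified result
  all1 <- stratified_signal(tr, y, tipvec(tr, rep("all", 40)), test = "D",
                            n_permutations = 99, n_brownian = 99, seed = 5)
  direct <- fritz_purvis_d(tr, y, n_permutations = 99, n_brownian = 99, seed = 5)
  expect_equal(all1$all$observed, direct$observed)
})
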