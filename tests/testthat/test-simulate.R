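test_that("tree simulation is ultrametric, normalized and reproducible", {
  t2 <- simulate_tree(2, 3)
  expect_equal(sort(unname(tip_depths(t2))), c(1, 1))
  for (seed in 1:3) {
    tr <- simulate_tree(25, seed)
    expect_true(is_ultrametric(tr, tol = 1e-10))
    expect_equal(max(tip_depths(tr)), 1)
  }
  expect_identical(ape::write.tree(simulate_tree(40, 11)),
                   ape::write.tree(simulate_tree(40, 11)))
  expect_error(simulate_tree(1, 1), "at least 2")
})

test_that("trait simulation is exact without noise and calibrated with it", {
  tr <- simulate_tree(30, 2)
  cfg <- sim_config(n_tips = 30, seed = 2, sigma2 = 0)
  td <- simulate_traits(tr, cfg)
  mu <- cfg$beta[1] + cfg$beta[2] * td$group + cfg$beta[3] * td$log10_mass
  expect_equal(td$response, mu, tolerance = 1e-12)
  expect_identical(td, simulate_traits(tr, cfg))

  # clade-based assignment yields exactly two monophyletic state-1 clades
  st <- setNames(td$group, td$tree_name)
  org <- count_origins(tr, st, root_state = 0)
  expect_equal(c(org$score, org$gains, org$losses), c(2L, 2L, 0L))
})

test_that("simulated residual covariance matches sigma2 * V_lambda", {
  tr <- grafen_lengths(read_phylogeny(text = "(((A,B),(C,D)),E);"))
  cfg <- sim_config(n_tips = 5, seed = 1, lambda = 0.6, sigma2 = 1)
  V <- lambda_transform(phylo_covariance(tr), 0.6)
  resid <- matrix(0, 2000, 5)
  for (i in 1:2000) {
    cfg$seed <- i
    td <- simulate_traits(tr, cfg)
    mu <- cfg$beta[1] + cfg$beta[2] * td$group + cfg$beta[3] * td$log10_mass
    resid[i, ] <- (td$response - mu)[match(rownames(V), td$tree_name)]
  }
  emp <- crossprod(resid) / 2000
  expect_true(all(abs(emp - V) < 0.1 * max(diag(V))))
  expect_equal(unname(diag(emp)), unname(diag(V)), tolerance = 0.1)
})

test_that("binary simulation follows the Mk1 flip probabilities", {
  tr <- read_phylogeny(text = "(A:1,B:1);")
  st0 <- simulate_binary(tr, q = 0, seed = 1)
  expect_equal(st0[["A"]], st0[["B"]])
  expect_identical(simulate_binary(tr, 1, seed = 9),
                   simulate_binary(tr, 1, seed = 9))

  # discordance frequency of a cherry: 2 p (1 - p), p = (1 - e^-2)/2
  disc <- vapply(1:10000, function(s) {
    st <- simulate_binary(tr, q = 1, seed = s)
    st[["A"]] != st[["B"]]
  }, logical(1))
  p <- (1 - exp(-2)) / 2
  expect_equal(mean(disc), 2 * p * (1 - p), tolerance = 0.02)
})

test_that("table-style generator matches the target structure", {
  sim <- make_table1_like(8)
  expect_identical(nrow(validate_traits(sim$traits)), 0L)
  expect_equal(nrow(sim$traits), 28)
  expect_equal(sum(is.na(sim$traits$fmr)), 1)
  expect_equal(sum(is.na(sim$traits$wing_loading_g_cm2)), 4)
  expect_true(all(sim$traits$manipulation %in% 0:1))
  st <- setNames(sim$traits$manipulation, sim$traits$tree_name)
  org <- count_origins(sim$tree, st, root_state = 0)
  expect_equal(c(org$gains, org$losses), c(2L, 0L))
  # both manipulation groups exist among prey feeders (wasp-only subsets)
  expect_equal(sort(unique(sim$traits$manipulation[sim$traits$diet ==
                                                     "prey"])), c(0, 1))
})

test_that("generator calibration reproduces the target effect sizes", {
  seeds <- 1:60
  stats <- vapply(seeds, function(s) {
    sim <- make_table1_like(s)
    gs <- group_stats(sim$traits$fmr, sim$traits$manipulation)
    af <- allometry_fit(sim$traits$body_mass_g,
                        sim$traits$wing_loading_g_cm2)
    c(diff = gs$mean[1] - gs$mean[2], expo = af$exponent)
  }, numeric(2))
  expect_true(abs(mean(stats["diff", ]) - 0.06) < 0.02)
  expect_true(abs(mean(stats["expo", ]) - 0.394) < 0.05)
})

test_that("the planted group effect is recovered end to end", {
  hits <- 0
  for (seed in 1:40) {
    sim <- make_table1_like(seed)
    f <- pgls(fmr ~ manipulation + log10(body_mass_g), sim$traits, sim$tree)
    hits <- hits + (coef(f)[["manipulation"]] < 0)
  }
  expect_gte(hits / 40, 0.95)
})
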