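test_that("GLS with identity covariance reproduces OLS exactly", {
  set.seed(42)
  n <- 15
  X <- cbind(1, rnorm(n), rnorm(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  y <- X %*% c(1, 2, -0.5) + rnorm(n)
  g <- gls_fit(y, X, diag(n))
  ols <- lm(y ~ X - 1)
  expect_equal(unname(g$coefficients), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(g$se), unname(summary(ols)$coefficients[, 2]),
               tolerance = 1e-10)
  expect_equal(g$logLik, as.numeric(logLik(ols)), tolerance = 1e-8)
})

test_that("noise-free data are recovered exactly", {
  set.seed(7)
  tr <- grafen_lengths(ape::rtree(12))
  V <- phylo_covariance(tr)
  X <- cbind(1, rnorm(12))
  y <- X %*% c(0.3, 1.7)
  g <- gls_fit(y, X, V)
  expect_equal(unname(g$coefficients), c(0.3, 1.7), tolerance = 1e-9)
  expect_equal(g$sigma2, 0, tolerance = 1e-16)
})

test_that("GLS matches a direct likelihood-maximization oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    tr <- grafen_lengths(ape::rtree(6))
    V <- phylo_covariance(tr)
    X <- cbind(1, rnorm(6))
    y <- as.numeric(X %*% c(1, 0.5) + t(chol(0.2 * V)) %*% rnorm(6))
    g <- gls_fit(y, X, V)
    o <- bf_gls_ml(y, X, V)
    expect_equal(unname(g$coefficients), unname(o$coefficients),
                 tolerance = 1e-5)
    expect_equal(g$sigma2, o$sigma2, tolerance = 1e-4)
    expect_equal(g$logLik, o$logLik, tolerance = 1e-6)
  }
})

test_that("singular inputs raise errors naming the offender", {
  X <- cbind(`(Intercept)` = 1, dup = rep(2, 6), dup2 = rep(4, 6))
  expect_error(gls_fit(rnorm(6), X, diag(6)), "dup")
  expect_error(gls_fit(rnorm(3), cbind(1, 1:3), matrix(1, 3, 3)),
               "positive definite")
})

test_that("pgls at lambda = 0 equals OLS, and ML lambda beats a fine grid", {
  d <- hymeflight_table1()
  tr <- hymeflight_tree()
  f0 <- pgls(fmr ~ manipulation + log10(body_mass_g), d, tr, lambda = 0)
  ols <- lm(fmr ~ manipulation + log10(body_mass_g), d)
  expect_equal(unname(coef(f0)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(f0$se), unname(summary(ols)$coefficients[, 2]),
               tolerance = 1e-10)

  fml <- pgls(log10(wing_loading_g_cm2) ~ manipulation + log10(body_mass_g),
              d, tr)
  grid <- pgls_profile(fml, seq(0, 1, length.out = 1001))
  expect_true(all(fml$logLik >= grid - 1e-7))
  expect_equal(fml$logLik, max(pgls_profile(fml, fml$lambda)))
})

test_that("pgls agrees with the nlme/corPagel implementation", {
  skip_if_not_installed("nlme")
  d <- hymeflight_table1()
  tr <- hymeflight_tree()
  d2 <- d[!is.na(d$wing_loading_g_cm2), ]
  rownames(d2) <- d2$tree_name
  tr2 <- ape::drop.tip(tr, setdiff(tr$tip.label, d2$tree_name))
  fit <- pgls(log10(wing_loading_g_cm2) ~ manipulation + log10(body_mass_g),
              d, tr)
  ref <- nlme::gls(log10(wing_loading_g_cm2) ~ manipulation +
                     log10(body_mass_g),
                   data = d2,
                   correlation = ape::corPagel(fit$lambda, tr2,
                                               form = ~tree_name,
                                               fixed = TRUE),
                   method = "ML")
  tab <- summary(ref)$tTable
  expect_equal(unname(coef(fit)), unname(tab[, "Value"]), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(tab[, "Std.Error"]), tolerance = 1e-6)
  expect_equal(fit$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
})

test_that("listwise deletion, species matching and small-n errors", {
  d <- hymeflight_table1()
  tr <- hymeflight_tree()
  f <- pgls(fmr ~ manipulation + log10(body_mass_g), d, tr)
  expect_equal(f$n, 27)
  expect_false("Amegilla_asserta" %in% f$species)

  d_bad <- d; d_bad$tree_name[3] <- "Apis_melliferaX"
  expect_error(pgls(fmr ~ manipulation + log10(body_mass_g), d_bad, tr),
               "Apis_melliferaX")
  expect_error(pgls(fmr ~ manipulation + log10(body_mass_g), d[1:4, ], tr),
               "insufficient")
})

test_that("lambda LR test behaves at the boundary and at chi-square quantiles", {
  d <- hymeflight_table1()
  tr <- hymeflight_tree()
  f <- pgls(fmr ~ manipulation + log10(body_mass_g), d, tr)
  expect_lt(f$lambda, 0.02)             # FMR shows almost no signal
  expect_equal(lr_lambda(f)$statistic, 0, tolerance = 1e-6)
  expect_equal(lr_lambda(f)$p_value, 1, tolerance = 1e-4)
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.0500, tolerance = 1e-3)
})

test_that("ML lambda is detected under strong and absent signal", {
  # lambda = 0: estimates should concentrate near zero
  hits <- 0
  for (seed in 1:40) {
    tr <- simulate_tree(100, seed)
    td <- simulate_traits(tr, sim_config(n_tips = 100, seed = seed,
                                         lambda = 0))
    f <- pgls(response ~ group + log10_mass, td, tr)
    hits <- hits + (f$lambda < 0.1)
  }
  expect_gte(hits / 40, 0.9)
  # strong signal: the LR test should reject lambda = 0
  rej <- 0
  for (seed in 1:40) {
    tr <- simulate_tree(200, seed)
    td <- simulate_traits(tr, sim_config(n_tips = 200, seed = seed,
                                         lambda = 0.9))
    f <- pgls(response ~ group + log10_mass, td, tr)
    rej <- rej + (lr_lambda(f)$p_value < 0.05)
  }
  expect_gte(rej / 40, 0.9)
})

test_that("heteroscedastic extension estimates the variance ratio", {
  # equal variances: multiplier near 1, LR statistic non-negative
  tr <- simulate_tree(200, 31)
  td <- simulate_traits(tr, sim_config(n_tips = 200, seed = 31, lambda = 0.5))
  f <- pgls(response ~ group + log10_mass, td, tr, var_group = "group")
  expect_gte(f$var_group$lr_statistic, 0)
  expect_true(f$var_group$gamma > 0.5 && f$var_group$gamma < 2)

  # group 1 residual variance inflated fourfold: the LR test should see it
  rej <- 0
  nrep <- 40
  for (seed in 1:nrep) {
    tr <- simulate_tree(200, seed + 500)
    cfg <- sim_config(n_tips = 200, seed = seed + 500, lambda = 0.5,
                      sigma2 = 0)
    td <- simulate_traits(tr, cfg)            # response = X beta exactly
    W <- lambda_transform(phylo_covariance(tr), 0.5)[td$tree_name,
                                                     td$tree_name]
    s <- ifelse(td$group == 1, 2, 1)
    set.seed(seed)
    e <- crossprod(chol(0.01 * (W * tcrossprod(s))), rnorm(200))
    td$response <- td$response + as.numeric(e)
    f <- pgls(response ~ group + log10_mass, td, tr, var_group = "group")
    rej <- rej + (f$var_group$lr_p_value < 0.05)
  }
  expect_gte(rej / nrep, 0.8)
  expect_error(pgls(response ~ log10_mass, td, tr, var_group = "tree_name"),
               "two levels")
})

test_that("pgls methods are coherent", {
  d <- hymeflight_table1()
  tr <- hymeflight_tree()
  f <- pgls(fmr ~ manipulation + log10(body_mass_g), d, tr)
  expect_equal(unname(f$tstat), unname(f$coefficients / f$se))
  expect_equal(f$df_residual, f$n - length(f$coefficients))
  expect_equal(predict(f), fitted(f))
  expect_equal(unname(predict(f, d[2:5, ])),
               unname(as.numeric(cbind(1, d$manipulation[2:5],
                                       log10(d$body_mass_g[2:5])) %*%
                                   coef(f))))
  sims <- simulate(f, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(27, 3))
  expect_identical(sims, simulate(f, nsim = 3, seed = 1))
  s <- summary(f)
  expect_s3_class(s, "summary.pgls")
  expect_equal(unname(s$coefficients[, 1]), unname(coef(f)))
})
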