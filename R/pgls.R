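#' Generalized least squares with a fixed error covariance
#'
#' Low-level engine behind [pgls()].  Fits `y = X beta + e`,
#' `e ~ N(0, sigma2 * V)` by GLS: `beta = (X' V^-1 X)^-1 X' V^-1 y`.  The
#' variance scale is estimated by maximum likelihood
#' (`sigma2 = RSS_V / n`); standard errors carry the usual `n/(n - p)`
#' small-sample correction so that with `V = I` they reproduce ordinary
#' least squares exactly.  Inference uses Student's t with `n - p` df.
#'
#' @param y numeric response vector.
#' @param X design matrix (including the intercept column).
#' @param V symmetric positive-definite covariance matrix aligned with `y`.
#' @return a list with elements `coefficients`, `se`, `tstat`, `pval`,
#'   `df_residual`, `sigma2` (ML), `sigma2_unbiased`, `logLik`, `fitted`,
#'   `residuals`, `normalized_residuals`, `cov_coef`, `n`.
#' @export
gls_fit <- function(y, X, V) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  if (nrow(X) != n || nrow(V) != n || ncol(V) != n)
    stop("y, X and V dimensions do not match", call. = FALSE)
  if (n <= p) stop("need more observations than coefficients", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):p]]
    stop("design matrix is singular; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ch <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix V is not positive definite", call. = FALSE))
  # whiten: solve L' z = x  with V = L'L (R chol returns upper factor)
  Ly <- backsolve(ch, y, transpose = TRUE)
  LX <- backsolve(ch, X, transpose = TRUE)
  fit <- qr(LX)
  beta <- qr.coef(fit, Ly)
  res_w <- Ly - LX %*% beta          # whitened residuals
  rss <- sum(res_w^2)
  sigma2 <- rss / n
  sigma2_u <- rss / (n - p)
  XtViX_inv <- chol2inv(qr.R(fit))
  cov_coef <- sigma2_u * XtViX_inv
  se <- sqrt(diag(cov_coef))
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df = n - p)
  logdetV <- 2 * sum(log(diag(ch)))
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdetV + n)
  fitted <- as.numeric(X %*% beta)
  nm <- colnames(X)
  names(beta) <- names(se) <- names(tstat) <- names(pval) <- nm
  dimnames(cov_coef) <- list(nm, nm)
  list(coefficients = beta, se = se, tstat = tstat, pval = pval,
       df_residual = n - p, sigma2 = sigma2, sigma2_unbiased = sigma2_u,
       logLik = ll, fitted = fitted, residuals = y - fitted,
       normalized_residuals = as.numeric(res_w) / sqrt(sigma2),
       cov_coef = cov_coef, n = n)
}

#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits a linear model across species whose error covariance is the
#' Brownian phylogenetic covariance matrix with its off-diagonals scaled
#' by Pagel's lambda.  `lambda = 0` is phylogenetic independence
#' (ordinary least squares); `lambda = 1` is full Brownian covariance.
#' With `lambda = "ML"` the profile log-likelihood is maximized over
#' \[0, 1\] by a 0.01-step grid pre-scan followed by bounded refinement to
#' tolerance 1e-8.  A likelihood-ratio test of `lambda-hat` against
#' `lambda = 0` (df 1, chi-squared reference) is always reported.
#'
#' Species with missing values in any model variable are dropped listwise;
#' the species actually used are recorded in the fit.  Rows are matched to
#' tree tips through the `species` column (default `"tree_name"`, falling
#' back to row names); unmatched names are an error, never a silent drop.
#'
#' With `var_group` (the name of a two-level column) the two groups are
#' allowed different residual variances: the error covariance becomes
#' `sigma2 * S V_lambda S` with `S` diagonal, 1 for the first level and a
#' jointly ML-estimated multiplier for the second.  A likelihood-ratio
#' test against the homoscedastic fit (df 1) is stored in `$var_group`.
#'
#' @param formula model formula, e.g. `fmr ~ manipulation + log10(body_mass_g)`.
#' @param data data.frame of species traits.
#' @param tree rooted `"phylo"` tree with branch lengths covering all species.
#' @param lambda `"ML"` (default) or a fixed value in \[0, 1\].
#' @param species name of the column holding tree tip labels; default
#'   `"tree_name"` if present, else row names.
#' @param var_group optional name of a two-level grouping column for the
#'   heteroscedastic extension.
#' @return an object of class `"pgls"`; see [summary.pgls()].
#' @examples
#' d <- hymeflight_table1()
#' fit <- pgls(fmr ~ manipulation + log10(body_mass_g), d, hymeflight_tree())
#' summary(fit)
#' @seealso [gls_fit()], [lr_test()], [pgls_profile()]
#' @export
pgls <- function(formula, data, tree, lambda = "ML", species = NULL,
                 var_group = NULL) {
  cl <- match.call()
  validate_phylogeny(tree)
  if (!has_branch_lengths(tree))
    stop("tree has no branch lengths; assign them first, e.g. with grafen_lengths()",
         call. = FALSE)
  if (is.null(species))
    species <- if ("tree_name" %in% names(data)) "tree_name" else NA
  sp_all <- if (is.na(species[1])) rownames(data) else
    trimws(as.character(data[[species]]))
  if (is.null(sp_all) || !length(sp_all))
    stop("cannot identify species labels: supply a 'species' column or row names",
         call. = FALSE)

  mf <- model.frame(formula, data, na.action = na.pass)
  keep <- complete.cases(mf)
  if (!is.null(var_group)) {
    gall <- data[[var_group]]
    if (is.null(gall)) stop("var_group column '", var_group, "' not found",
                            call. = FALSE)
    keep <- keep & !is.na(gall)
  }
  mf <- mf[keep, , drop = FALSE]
  sp <- sp_all[keep]
  if (anyDuplicated(sp))
    stop("duplicate species labels after listwise deletion: ",
         paste(unique(sp[duplicated(sp)]), collapse = ", "), call. = FALSE)
  missing_tips <- setdiff(sp, tree$tip.label)
  if (length(missing_tips))
    stop("species not found among tree tips: ",
         paste(missing_tips, collapse = ", "), call. = FALSE)

  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  n <- length(y); p <- ncol(X)
  if (n < p + 2)
    stop("insufficient data: ", n, " species after listwise deletion for ",
         p, " coefficients", call. = FALSE)
  V <- phylo_covariance(tree)[sp, sp]

  grp <- NULL
  if (!is.null(var_group)) {
    grp <- factor(gall[keep])
    if (nlevels(grp) != 2)
      stop("var_group must have exactly two levels among the species used (got ",
           nlevels(grp), ")", call. = FALSE)
  }

  fit_at <- function(lam, log_gamma = 0) {
    W <- lambda_transform(V, lam)
    if (!is.null(grp)) {
      s <- ifelse(grp == levels(grp)[1], 1, exp(log_gamma))
      W <- W * tcrossprod(s)
    }
    gls_fit(y, X, W)
  }

  profile_ll <- function(lam) fit_at(lam)$logLik

  optimize_lambda <- function(ll_fun) {
    grid <- seq(0, 1, by = 0.01)
    llg <- vapply(grid, ll_fun, numeric(1))
    i <- which.max(llg)
    lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
    opt <- optimize(ll_fun, c(lo, hi), maximum = TRUE, tol = 1e-8)
    # the grid best can beat the local refinement at the boundary
    if (llg[i] > opt$objective) list(maximum = grid[i], objective = llg[i])
    else opt
  }

  gamma_hat <- NULL
  if (is.null(grp)) {
    if (identical(lambda, "ML")) {
      opt <- optimize_lambda(profile_ll)
      lam_hat <- opt$maximum
    } else {
      if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
        stop("lambda must be \"ML\" or a value in [0, 1]", call. = FALSE)
      lam_hat <- lambda
    }
    fit <- fit_at(lam_hat)
    ll0 <- if (lam_hat == 0) fit$logLik else fit_at(0)$logLik
  } else {
    obj <- function(par) -fit_at(par[1], par[2])$logLik
    if (identical(lambda, "ML")) {
      hom_lam <- optimize_lambda(profile_ll)
      op <- optim(c(hom_lam$maximum, 0), obj, method = "L-BFGS-B",
                  lower = c(0, -8), upper = c(1, 8),
                  control = list(factr = 1e4))
      lam_hat <- op$par[1]; lg <- op$par[2]
      ll_hom <- hom_lam$objective
    } else {
      if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
        stop("lambda must be \"ML\" or a value in [0, 1]", call. = FALSE)
      op <- optimize(function(lg) obj(c(lambda, lg)), c(-8, 8), tol = 1e-8)
      lam_hat <- lambda; lg <- op$minimum
      ll_hom <- profile_ll(lambda)
    }
    gamma_hat <- exp(lg)
    fit <- fit_at(lam_hat, lg)
    ll0 <- if (lam_hat == 0) fit$logLik else fit_at(0, lg)$logLik
  }

  lr <- list(statistic = max(0, 2 * (fit$logLik - ll0)), df = 1L)
  lr$p_value <- pchisq(lr$statistic, df = 1, lower.tail = FALSE)

  out <- list(call = cl, formula = formula,
              coefficients = fit$coefficients, se = fit$se,
              tstat = fit$tstat, pval = fit$pval,
              df_residual = fit$df_residual, n = n,
              lambda = lam_hat, lambda_ml = identical(lambda, "ML"),
              sigma2 = fit$sigma2, sigma2_unbiased = fit$sigma2_unbiased,
              logLik = fit$logLik, logLik_lambda0 = ll0, lr_lambda = lr,
              cov_coef = fit$cov_coef,
              fitted = setNames(fit$fitted, sp),
              residuals = setNames(fit$residuals, sp),
              normalized_residuals = setNames(fit$normalized_residuals, sp),
              species = sp, y = y, X = X, V = V, grp = grp)
  if (!is.null(grp)) {
    lr_het <- max(0, 2 * (fit$logLik - ll_hom))
    out$var_group <- list(
      column = var_group, levels = levels(grp), gamma = gamma_hat,
      logLik_homoscedastic = ll_hom,
      lr_statistic = lr_het, lr_df = 1L,
      lr_p_value = pchisq(lr_het, 1, lower.tail = FALSE))
  }
  class(out) <- "pgls"
  out
}

#' Profile log-likelihood of a pgls fit over lambda
#'
#' Recomputes the profile log-likelihood at given lambda values using the
#' data stored in the fit (for heteroscedastic fits, the estimated group
#' variance multiplier is held fixed).
#'
#' @param object a `"pgls"` fit.
#' @param lambdas numeric vector in \[0, 1\].
#' @return numeric vector of log-likelihoods.
#' @export
pgls_profile <- function(object, lambdas = seq(0, 1, by = 0.01)) {
  stopifnot(inherits(object, "pgls"))
  s2 <- if (!is.null(object$grp)) {
    g <- object$grp
    ifelse(g == levels(g)[1], 1, object$var_group$gamma)
  } else rep(1, object$n)
  vapply(lambdas, function(l) {
    W <- lambda_transform(object$V, l) * tcrossprod(s2)
    gls_fit(object$y, object$X, W)$logLik
  }, numeric(1))
}

#' Likelihood-ratio test between two nested fits
#'
#' @param full the larger model (a `"pgls"` fit or anything with a
#'   `logLik` component/method).
#' @param null the nested model.
#' @param df degrees of freedom of the test; default 1.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(full, null, df = 1L) {
  ll <- function(m) if (inherits(m, "pgls")) m$logLik else as.numeric(logLik(m))
  stat <- 2 * (ll(full) - ll(null))
  if (is.na(stat)) stop("log-likelihoods unavailable", call. = FALSE)
  if (stat < -1e-6)
    warning("negative LR statistic: models may not be nested or fitted on different data")
  stat <- max(0, stat)
  list(statistic = stat, df = as.integer(df),
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Likelihood-ratio test of phylogenetic signal (lambda)
#'
#' Compares the fitted model with the same model at `lambda = 0`
#' (phylogenetic independence), df 1.
#'
#' @param object a `"pgls"` fit.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
lr_lambda <- function(object) {
  stopifnot(inherits(object, "pgls"))
  object$lr_lambda
}

#' @export
print.pgls <- function(x, digits = 4, ...) {
  cat("Phylogenetic GLS (Pagel's lambda)\n")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat("n =", x$n, " lambda =", signif(x$lambda, digits),
      if (x$lambda_ml) "(ML)" else "(fixed)",
      " logLik =", signif(x$logLik, digits + 2), "\n")
  print(signif(x$coefficients, digits))
  invisible(x)
}

#' Summarize a pgls fit
#'
#' @param object a `"pgls"` fit.
#' @param ... unused.
#' @return an object of class `"summary.pgls"` holding the coefficient
#'   table (estimate, s.e., t, p at `n - p` df), lambda and its LR test,
#'   and a Kolmogorov-Smirnov normality statistic of the normalized
#'   residuals (advisory only).
#' @export
summary.pgls <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$tstat, `Pr(>|t|)` = object$pval)
  ks <- suppressWarnings(
    ks.test(scale(object$normalized_residuals), "pnorm"))
  out <- list(call = object$call, coefficients = tab, n = object$n,
              df_residual = object$df_residual, lambda = object$lambda,
              lambda_ml = object$lambda_ml, logLik = object$logLik,
              lr_lambda = object$lr_lambda, sigma2 = object$sigma2,
              var_group = object$var_group,
              ks_normality = c(statistic = unname(ks$statistic),
                               p_value = ks$p.value))
  class(out) <- "summary.pgls"
  out
}

#' @export
print.summary.pgls <- function(x, digits = 4, ...) {
  cat("Phylogenetic GLS (Pagel's lambda)\n")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  printCoefmat(x$coefficients, digits = digits, P.values = TRUE,
               has.Pvalue = TRUE)
  cat("\nn =", x$n, "  residual df =", x$df_residual,
      "  sigma2 (ML) =", signif(x$sigma2, digits), "\n")
  cat("lambda =", signif(x$lambda, digits),
      if (x$lambda_ml) "(ML)" else "(fixed)",
      "  logLik =", signif(x$logLik, digits + 2), "\n")
  cat("LR test lambda = 0: stat =", signif(x$lr_lambda$statistic, digits),
      " df =", x$lr_lambda$df, " p =", signif(x$lr_lambda$p_value, digits),
      "\n")
  if (!is.null(x$var_group))
    cat("Group variances (", x$var_group$column, "): multiplier for level '",
        x$var_group$levels[2], "' = ", signif(x$var_group$gamma, digits),
        "; LR vs equal variances p = ",
        signif(x$var_group$lr_p_value, digits), "\n", sep = "")
  cat("Normalized-residual normality (KS): D =",
      signif(x$ks_normality["statistic"], 3), ", p =",
      signif(x$ks_normality["p_value"], 3), "(advisory)\n")
  invisible(x)
}

#' @export
coef.pgls <- function(object, ...) object$coefficients

#' @export
vcov.pgls <- function(object, ...) object$cov_coef

#' @export
logLik.pgls <- function(object, ...) {
  p <- length(object$coefficients) + 2L + (!is.null(object$var_group))
  structure(object$logLik, df = p, nobs = object$n, class = "logLik")
}

#' @export
fitted.pgls <- function(object, ...) object$fitted

#' @export
residuals.pgls <- function(object, type = c("response", "normalized"), ...) {
  type <- match.arg(type)
  if (type == "response") object$residuals else object$normalized_residuals
}

#' Predict from a pgls fit
#'
#' Population-level predictions `X beta` for new data (no phylogenetic
#' correction of individual predictions is attempted).
#'
#' @param object a `"pgls"` fit.
#' @param newdata data.frame with the model's predictor columns; if
#'   omitted, fitted values are returned.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  tt <- delete.response(terms(object$formula))
  mf <- model.frame(tt, newdata, na.action = na.pass)
  X <- model.matrix(tt, mf)
  as.numeric(X %*% object$coefficients)
}

#' Simulate responses from a fitted pgls model
#'
#' Draws from `N(X beta, sigma2 * V_lambda)` at the fitted parameter
#' values (including the group variance multipliers, if any).
#'
#' @param object a `"pgls"` fit.
#' @param nsim number of replicate response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns, rows named by species.
#' @export
simulate.pgls <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  W <- lambda_transform(object$V, object$lambda)
  if (!is.null(object$grp)) {
    s <- ifelse(object$grp == levels(object$grp)[1], 1,
                object$var_group$gamma)
    W <- W * tcrossprod(s)
  }
  L <- chol(object$sigma2 * W)
  z <- matrix(rnorm(object$n * nsim), object$n, nsim)
  out <- as.data.frame(object$fitted + crossprod(L, z))
  rownames(out) <- object$species
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Diagnostic plot for a pgls fit
#'
#' Left: phylogenetically normalized residuals against fitted values.
#' Right: profile log-likelihood over lambda with the optimum marked.
#'
#' @param x a `"pgls"` fit.
#' @param ... passed to [plot()].
#' @export
plot.pgls <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(x$fitted, x$normalized_residuals, xlab = "Fitted values",
       ylab = "Normalized residuals", main = "Residuals", ...)
  abline(h = 0, lty = 2)
  lam <- seq(0, 1, by = 0.02)
  plot(lam, pgls_profile(x, lam), type = "l", xlab = expression(lambda),
       ylab = "Profile log-likelihood", main = "Pagel's lambda")
  abline(v = x$lambda, lty = 2)
  invisible(x)
}
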