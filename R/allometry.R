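#' Allometric scaling fit on the log10-log10 scale
#'
#' Fits the power law `y = c * x^b` by ordinary least squares of
#' `log10(y)` on `log10(x)`; the slope is the allometric exponent.  The
#' regression F statistic (1, n-2 df), r-squared and the two-sided p-value
#' of the slope are reported.  Fitting is delegated to [stats::lm()].
#'
#' @param x positive predictor (e.g. body mass in g).
#' @param y positive response (e.g. wing loading in g/cm^2).
#' @return object of class `"allometry_fit"` with elements `exponent`,
#'   `intercept` (log10 scale), `F`, `df`, `r2`, `p_value`, `n`, and the
#'   underlying `lm` fit.
#' @examples
#' a <- allometry_fit(1:10, 2 * (1:10)^0.5)
#' a$exponent   # 0.5
#' @export
allometry_fit <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (any(x <= 0) || any(y <= 0))
    stop("allometric fit requires strictly positive values", call. = FALSE)
  f <- lm(log10(y) ~ log10(x))
  s <- suppressWarnings(summary(f))   # exact power laws fit perfectly
  out <- list(exponent = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
              F = unname(s$fstatistic[1]),
              df = unname(s$fstatistic[2:3]),
              r2 = s$r.squared,
              p_value = s$coefficients[2, 4],
              n = length(x), lm = f)
  class(out) <- "allometry_fit"
  out
}

#' @export
print.allometry_fit <- function(x, digits = 3, ...) {
  cat("Allometric fit: log10(y) = ", signif(x$intercept, digits), " + ",
      signif(x$exponent, digits), " * log10(x)\n", sep = "")
  cat("exponent = ", signif(x$exponent, digits), ", F(", x$df[1], ",",
      x$df[2], ") = ", signif(x$F, digits + 1), ", r2 = ",
      signif(x$r2, digits), ", p = ", format.pval(x$p_value, digits),
      ", n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Per-group mean, standard error and sample size
#'
#' Missing values are dropped per group; a single-value group gets `se =
#' NA`, a constant group `se = 0`.
#'
#' @param values numeric vector.
#' @param groups grouping vector of the same length.
#' @return data.frame with columns `group`, `mean`, `se`, `n`,
#'   `n_missing`.
#' @export
group_stats <- function(values, groups) {
  if (length(values) != length(groups))
    stop("values and groups must have the same length", call. = FALSE)
  g <- factor(groups)
  if (any(tapply(!is.na(values), g, sum) == 0))
    stop("every group must contain at least one non-missing value",
         call. = FALSE)
  out <- do.call(rbind, lapply(levels(g), function(lv) {
    v <- values[g == lv]
    miss <- sum(is.na(v)); v <- v[!is.na(v)]
    data.frame(group = lv, mean = mean(v),
               se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v), n_missing = miss)
  }))
  rownames(out) <- NULL
  out
}

#' Pearson correlation with t-based p-value
#'
#' Wrapper around [stats::cor.test()] returning the sample correlation and
#' its two-sided p-value from the t transform with n - 2 df.
#'
#' @param x,y numeric vectors (pairs with missing values are dropped).
#' @return list with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Welch two-sample t test from summary statistics
#'
#' For re-analysing published group summaries when raw data are
#' unavailable: `t = (m1 - m2) / sqrt(se1^2 + se2^2)` with
#' Welch-Satterthwaite degrees of freedom
#' `(se1^2 + se2^2)^2 / (se1^4/(n1-1) + se2^4/(n2-1))`.
#'
#' @param m1,m2 group means.
#' @param se1,se2 standard errors of the means (must be positive).
#' @param n1,n2 group sample sizes (>= 2).
#' @return list with `t`, `df`, `p_value` (two-sided).
#' @export
welch_t_summary <- function(m1, se1, n1, m2, se2, n2) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive",
                                 call. = FALSE)
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2", call. = FALSE)
  tval <- (m1 - m2) / sqrt(se1^2 + se2^2)
  df <- (se1^2 + se2^2)^2 / (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
  list(t = tval, df = df, p_value = 2 * pt(-abs(tval), df))
}
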