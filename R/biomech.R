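#' Flight muscle ratio
#'
#' FMR is the flight muscle mass divided by wet body mass, with flight
#' muscle taken as 95% of thorax mass: `0.95 * M_t / M_b`.  It is the main
#' morphological determinant of load-lifting ability at take-off.
#'
#' @param thorax_mass thorax mass in grams (`M_t`), 0 < `M_t` < `M_b`.
#' @param body_mass wet body mass in grams (`M_b`).
#' @return dimensionless ratio in (0, 0.95).
#' @examples
#' fmr(0.05, 0.1)   # 0.475
#' @export
fmr <- function(thorax_mass, body_mass) {
  if (any(!is.finite(thorax_mass)) || any(!is.finite(body_mass)))
    stop("masses must be finite", call. = FALSE)
  if (any(thorax_mass <= 0) || any(body_mass <= 0))
    stop("masses must be positive", call. = FALSE)
  if (any(thorax_mass >= body_mass))
    stop("thorax mass must be smaller than body mass", call. = FALSE)
  0.95 * thorax_mass / body_mass
}

#' Wing loading
#'
#' Body mass per unit wing area, `M_b / A_w`, in g/cm^2.  Lower wing
#' loading means cheaper, more manoeuvrable flight.
#'
#' @param body_mass wet body mass in grams.
#' @param wing_area total wing area (both wing pairs) in cm^2.
#' @return wing loading in g/cm^2.
#' @export
wing_loading <- function(body_mass, wing_area) {
  if (any(!is.finite(body_mass)) || any(!is.finite(wing_area)))
    stop("inputs must be finite", call. = FALSE)
  if (any(body_mass <= 0) || any(wing_area <= 0))
    stop("body mass and wing area must be positive", call. = FALSE)
  body_mass / wing_area
}

#' Lift-regression coefficients for load-capacity prediction
#'
#' The maximum liftable mass is predicted from flight muscle mass through
#' an empirical log-log regression of maximum lift (expressed in
#' mass-equivalent grams) on flight muscle mass:
#' `log10(M_max) = a + b * log10(muscle mass)`.  The coefficients come from
#' published load-lifting experiments on bees and wasps and must be
#' supplied by the caller; there is deliberately no default.  If your
#' source reports lift as a force in newtons, divide by g = 9.81 m/s^2 to
#' convert to mass-equivalent kilograms (then to grams) before deriving
#' `a`.
#'
#' @param a intercept of the log10 regression (log10 grams).
#' @param b slope on log10 flight muscle mass (grams).
#' @return object of class `"lift_params"`.
#' @export
lift_params <- function(a, b) {
  if (missing(a) || missing(b) || !is.finite(a) || !is.finite(b))
    stop(paste("load-capacity prediction needs the lift-regression",
               "coefficients (intercept 'a', slope 'b') from load-lifting",
               "experiments on bees and wasps; supply them via lift_params()"),
         call. = FALSE)
  structure(list(a = as.numeric(a), b = as.numeric(b)), class = "lift_params")
}

#' @export
print.lift_params <- function(x, ...) {
  cat("Lift regression: log10(M_max [g]) =", x$a, "+", x$b,
      "* log10(muscle mass [g])\n")
  invisible(x)
}

#' Predicted load-lifting capacity
#'
#' Given body mass and FMR, predicts flight muscle mass
#' (`FMR * M_b`), the maximum total liftable mass
#' `M_max = 10^(a + b log10(muscle))`, the maximum food load
#' `Load_max = M_max - M_b`, and the load as a percentage of body mass.
#' A negative `Load_max` (species predicted unable to lift even its own
#' body) is permitted but flagged.
#'
#' @param body_mass wet body mass in grams (vectorized).
#' @param fmr_value flight muscle ratio (vectorized).
#' @param params a [lift_params()] object; required.
#' @return data.frame with columns `muscle_mass`, `M_max`, `Load_max`,
#'   `pct_load`, `flagged` (TRUE where `Load_max < 0`).
#' @examples
#' load_capacity(1, 0.5, lift_params(log10(4), 1))
#' @export
load_capacity <- function(body_mass, fmr_value, params) {
  if (missing(params) || !inherits(params, "lift_params"))
    stop(paste("load-capacity prediction needs the lift-regression",
               "coefficients; supply them via lift_params(a, b)"),
         call. = FALSE)
  if (any(body_mass <= 0, na.rm = TRUE) ||
      any(fmr_value <= 0, na.rm = TRUE))
    stop("body mass and FMR must be positive", call. = FALSE)
  muscle <- fmr_value * body_mass
  m_max <- 10^(params$a + params$b * log10(muscle))
  load_max <- m_max - body_mass
  data.frame(muscle_mass = muscle,
             M_max = m_max,
             Load_max = load_max,
             pct_load = 100 * load_max / body_mass,
             flagged = !is.na(load_max) & load_max < 0)
}
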