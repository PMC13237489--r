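#' Fluorophore standard-curve calibration
#'
#' Linear fit of fluorescence signal against product concentration on
#' the standard grid (0-50 uM preset: 0, 2.5, 5, 10, 20, 30, 40, 50).
#' The intercept is retained by default since the grid includes 0.
#'
#' @param concentrations Standard concentrations (uM).
#' @param signals Measured fluorescence (RFU).
#' @param through_origin Force a zero intercept.
#' @return A `standard_curve` with `slope` (RFU per uM), `intercept`
#'   and a `to_concentration(signal)` converter.
#' @export
fit_standard_curve <- function(concentrations, signals,
                               through_origin = FALSE) {
  stopifnot(length(concentrations) == length(signals),
            length(concentrations) >= 2L)
  fit <- if (through_origin) lm(signals ~ concentrations + 0)
    else lm(signals ~ concentrations)
  slope <- unname(coef(fit)[["concentrations"]])
  intercept <- if (through_origin) 0 else unname(coef(fit)[[1]])
  if (slope <= 0) stop("invalid calibration: non-positive slope")
  structure(list(slope = slope, intercept = intercept,
                 to_concentration = function(signal)
                   (signal - intercept) / slope),
            class = "standard_curve")
}

#' Initial velocity from the linear window of a progress curve
#'
#' Converts the signal to product concentration through the standard
#' curve and takes the ordinary least-squares slope of concentration
#' versus time over the window, reported in uM/min.  The preset window
#' (1620-1905 s) is the linear region used for rate determination.
#'
#' @param time Time points in seconds (strictly increasing).
#' @param signal Blank-subtracted fluorescence (RFU).
#' @param window Length-2 numeric `[t0, t1]` in seconds.
#' @param calibration A [fit_standard_curve()] result.
#' @return Initial velocity in uM/min.
#' @export
initial_velocity <- function(time, signal, window = c(1620, 1905),
                             calibration) {
  stopifnot(length(time) == length(signal), length(time) >= 2L,
            !is.unsorted(time, strictly = TRUE))
  sel <- time >= window[1] & time <= window[2]
  if (sum(sel) < 2L) stop("window outside the sampled time range")
  conc <- calibration$to_concentration(signal[sel])
  slope_per_s <- unname(coef(lm(conc ~ time[sel]))[[2]])
  slope_per_s * 60
}

#' Fit the Michaelis-Menten model
#'
#' Nonlinear least squares of `v = vmax * S / (km + S)` with multi-start
#' initialization from the data (`vmax0 = max(v)`, `km0` = substrate at
#' half-maximal velocity, plus scaled perturbations of both).
#'
#' @param substrate Substrate concentrations in mM (>= 3 distinct
#'   levels); the reference assay grid is 0.05-20 mM over 10 levels.
#' @param v0 Initial velocities in uM/min.
#' @return An `mm_fit` with `vmax` (uM/min), `km` (mM), standard
#'   errors, residual sum of squares and the underlying `nls` fit;
#'   or an object with `converged = FALSE` if every start fails.
#' @export
fit_michaelis_menten <- function(substrate, v0) {
  stopifnot(length(substrate) == length(v0))
  if (length(unique(substrate)) < 3L) {
    stop("at least 3 distinct substrate levels required")
  }
  vmax0 <- max(v0)
  km0 <- substrate[which.min(abs(v0 - vmax0 / 2))]
  if (km0 <= 0) km0 <- median(substrate)
  starts <- expand.grid(vmax = vmax0 * c(1, 1.5),
                        km = km0 * c(0.3, 1, 3))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(v0 ~ vmax * substrate / (km + substrate),
                        start = list(vmax = starts$vmax[s],
                                     km = starts$km[s]),
                        lower = c(1e-12, 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(converged = FALSE), class = "mm_fit"))
  }
  co <- coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) c(vmax = NA_real_, km = NA_real_))
  structure(list(vmax = unname(co[["vmax"]]), km = unname(co[["km"]]),
                 se = c(vmax = unname(se[["vmax"]]), km = unname(se[["km"]])),
                 rss = best$rss, fit = best$fit, converged = TRUE),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat("Michaelis-Menten fit: did not converge\n")
    return(invisible(x))
  }
  cat("Michaelis-Menten fit\n")
  cat(sprintf("  Vmax = %.4g uM/min (se %.3g)\n", x$vmax, x$se[["vmax"]]))
  cat(sprintf("  Km   = %.4g mM (se %.3g)\n", x$km, x$se[["km"]]))
  cat(sprintf("  RSS  = %.4g\n", x$rss))
  invisible(x)
}

#' @export
predict.mm_fit <- function(object, substrate, ...) {
  stopifnot(isTRUE(object$converged))
  object$vmax * substrate / (object$km + substrate)
}

#' Turnover number from Vmax
#'
#' `kcat = vmax / enzyme_total / 60`, converting uM/min at a given total
#' enzyme concentration (uM) to per-second turnover.  All unit
#' conversion is centralized here.
#'
#' @param vmax Maximal velocity in uM/min.
#' @param enzyme_total Total enzyme concentration in uM (> 0).
#' @return kcat in 1/s.
#' @export
turnover_number <- function(vmax, enzyme_total) {
  if (enzyme_total <= 0) stop("enzyme concentration must be positive")
  vmax / enzyme_total / 60
}
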