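# Shared constructor for log-log / sqrt-N exponent fits. `x` and `y` are the
# already-transformed regression axes; the slope is the exponent of interest.
new_scaling_fit <- function(x, y, xlab, ylab, kind) {
  fit <- stats::lm(y ~ x)
  # exact power laws trip lm's "essentially perfect fit" warning; a zero
  # stderr is the correct answer there
  sm <- suppressWarnings(summary(fit))$coefficients
  stderr_slope <- if (nrow(sm) >= 2L && ncol(sm) >= 2L && is.finite(sm[2L, 2L]))
    sm[2L, 2L] else 0
  structure(
    list(
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      stderr_slope = stderr_slope,
      n_points = length(x),
      x = x, y = y, xlab = xlab, ylab = ylab, kind = kind,
      lm = fit
    ),
    class = "scaling_fit"
  )
}

#' Fit a scaling exponent from an (N, Rg) ensemble table
#'
#' Ordinary least squares of \eqn{\ln R_g} on \eqn{\ln N}; the slope
#' estimates the scaling exponent \eqn{\alpha} in \eqn{R_g \sim a N^\alpha}.
#' Unfolded proteins cluster near \eqn{\alpha \approx 0.6} (excluded-volume
#' coil), ideal chains at 1/2, compact globules at 1/3.
#'
#' @param n Chain lengths (counts), or a two-column data frame / matrix with
#'   columns N and mean Rg, in which case `rg` is taken from the second
#'   column.
#' @param rg Mean radii of gyration in Angstrom (omit when `n` is a table).
#' @return A `scaling_fit` object: list with `slope` (the exponent),
#'   `intercept` (log prefactor), `stderr_slope`, `n_points`, plus the
#'   transformed regression data and the underlying [stats::lm] fit.
#'   Supports `print()`, `summary()`, `coef()`, `predict()`, `plot()`,
#'   `residuals()` and `fitted()`.
#' @examples
#' n <- c(10, 30, 100, 300, 1000)
#' fit_scaling_exponent(n, 0.7 * n^0.7)$slope # 0.7 exactly
#' @export
fit_scaling_exponent <- function(n, rg = NULL) {
  if (is.null(rg)) {
    tab <- as.data.frame(n)
    if (ncol(tab) < 2L)
      abort_domain("table input must have two columns: N and Rg")
    rg <- as.numeric(tab[[2L]])
    n <- as.numeric(tab[[1L]])
  }
  if (length(n) != length(rg))
    abort_domain("`n` and `rg` must have the same length")
  if (length(n) < 3L)
    abort_domain("need at least 3 (N, Rg) pairs")
  if (anyDuplicated(n))
    abort_domain("chain lengths must be distinct")
  if (any(!is.finite(n)) || any(!is.finite(rg)) || any(n <= 0) || any(rg <= 0))
    abort_domain("all N and Rg values must be positive and finite")
  new_scaling_fit(log(n), log(rg), xlab = "ln N", ylab = "ln Rg",
                  kind = "rg_scaling")
}

#' Fit the folding-time scaling law
#'
#' Folding times scale with chain length as \eqn{\ln T \propto N^{1/2}};
#' this fits \eqn{\ln T} against \eqn{\sqrt{N}} by ordinary least squares.
#'
#' @param n_list Chain lengths (residue counts).
#' @param log_times \eqn{\ln T} values, same length as `n_list`.
#' @return A `scaling_fit` object (see [fit_scaling_exponent()]); `slope` is
#'   the coefficient on \eqn{\sqrt{N}}.
#' @export
folding_time_fit <- function(n_list, log_times) {
  if (length(n_list) != length(log_times))
    abort_domain("`n_list` and `log_times` must have the same length")
  if (length(n_list) < 2L)
    abort_domain("need at least 2 points")
  if (any(!is.finite(n_list)) || any(n_list <= 0) || any(!is.finite(log_times)))
    abort_domain("inputs must be finite and chain lengths positive")
  new_scaling_fit(sqrt(n_list), log_times, xlab = "sqrt(N)", ylab = "ln T",
                  kind = "folding_time")
}

#' @export
print.scaling_fit <- function(x, digits = 4L, ...) {
  label <- switch(x$kind,
    rg_scaling = "Scaling-exponent fit (ln Rg ~ ln N)",
    flory = "Flory exponent fit (ln L* ~ ln N)",
    folding_time = "Folding-time fit (ln T ~ sqrt(N))",
    "Scaling fit")
  cat(label, "\n")
  cat(sprintf("  slope     = %.*f (se %.*f)\n", digits, x$slope,
              digits, x$stderr_slope))
  cat(sprintf("  intercept = %.*f\n", digits, x$intercept))
  cat(sprintf("  n points  = %d\n", x$n_points))
  invisible(x)
}

#' @export
summary.scaling_fit <- function(object, ...) {
  print(object)
  cat("\nUnderlying linear model:\n")
  print(summary(object$lm, ...))
  invisible(object)
}

#' @export
coef.scaling_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.scaling_fit <- function(object, ...) stats::residuals(object$lm)

#' @export
fitted.scaling_fit <- function(object, ...) stats::fitted(object$lm)

#' Predict from a scaling fit
#'
#' @param object A `scaling_fit`.
#' @param n New chain lengths. For `rg_scaling` and `flory` fits the return
#'   is on the original (Angstrom) scale; for `folding_time` fits it is
#'   \eqn{\ln T}.
#' @param ... Unused.
#' @export
predict.scaling_fit <- function(object, n, ...) {
  if (missing(n)) return(stats::fitted(object$lm))
  if (object$kind == "folding_time")
    object$intercept + object$slope * sqrt(n)
  else
    exp(object$intercept) * n^object$slope
}

#' @export
plot.scaling_fit <- function(x, ...) {
  graphics::plot(x$x, x$y, xlab = x$xlab, ylab = x$ylab,
                 pch = 19, ...)
  graphics::abline(x$intercept, x$slope, col = "red3")
  invisible(x)
}
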