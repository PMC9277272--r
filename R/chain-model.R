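#' Chain scaling model parameters
#'
#' Bundles the scalar parameters of the scaling theory for one chain:
#' segment count \eqn{N}, segment length \eqn{a}, contour length
#' \eqn{L = N a}, per-segment excluded volume \eqn{v} (default \eqn{a^3}),
#' and the derived stretched-chain radius of gyration
#' \eqn{R_{g0} = L/\sqrt{12}}. Supply `n_segments` together with at least
#' one of `segment_length` or `contour_length`; the missing one is derived.
#'
#' @param n_segments Number of segments \eqn{N} (>= 2).
#' @param segment_length Segment length \eqn{a} in Angstrom.
#' @param contour_length Contour length \eqn{L} in Angstrom.
#' @param excluded_volume Excluded volume \eqn{v} in cubic Angstrom
#'   (default \eqn{a^3}).
#' @return A `chain_model` object.
#' @examples
#' m <- chain_model(20, contour_length = 73.61) # extended Trp-cage backbone
#' predict(m, alpha = c(1, 0.6, 0.5, 1 / 3))
#' @export
chain_model <- function(n_segments, segment_length = NULL, contour_length = NULL,
                        excluded_volume = NULL) {
  n_segments <- check_count(n_segments, "n_segments", min = 2L)
  if (is.null(segment_length) && is.null(contour_length))
    abort_domain("supply `segment_length` or `contour_length`")
  if (is.null(segment_length))
    segment_length <- contour_length / n_segments
  segment_length <- check_positive(segment_length, "segment_length")
  if (is.null(contour_length)) {
    contour_length <- n_segments * segment_length
  } else {
    contour_length <- check_positive(contour_length, "contour_length")
    rel <- abs(contour_length - n_segments * segment_length) / contour_length
    if (rel > 1e-9)
      abort_domain("`contour_length` must equal n_segments * segment_length")
  }
  if (is.null(excluded_volume)) excluded_volume <- segment_length^3
  excluded_volume <- check_positive(excluded_volume, "excluded_volume")
  structure(
    list(n_segments = n_segments, segment_length = segment_length,
         contour_length = contour_length, excluded_volume = excluded_volume,
         rg_stretched = contour_length / sqrt(12)),
    class = "chain_model"
  )
}

#' @export
print.chain_model <- function(x, ...) {
  cat("Chain scaling model\n")
  cat(sprintf("  N   = %d segments\n", x$n_segments))
  cat(sprintf("  a   = %.4f A\n", x$segment_length))
  cat(sprintf("  L   = %.4f A\n", x$contour_length))
  cat(sprintf("  v   = %.4f A^3\n", x$excluded_volume))
  cat(sprintf("  Rg0 = %.4f A\n", x$rg_stretched))
  invisible(x)
}

#' @export
coef.chain_model <- function(object, ...) {
  c(N = object$n_segments, a = object$segment_length,
    L = object$contour_length, v = object$excluded_volume,
    Rg0 = object$rg_stretched)
}

#' Predict the radius of gyration at given scaling exponents
#'
#' Evaluates the scaling interpolation [rg_from_alpha()] under the model's
#' parameters.
#'
#' @param object A [chain_model].
#' @param alpha Scaling exponent(s) in (0, Inf).
#' @param ... Unused.
#' @return Radii of gyration in Angstrom.
#' @export
predict.chain_model <- function(object, alpha, ...) {
  rg_from_alpha(alpha, object$n_segments, object$segment_length)
}

#' Estimate the scaling exponent of an observed chain under a model
#'
#' Convenience wrapper around [alpha_from_rg()] taking the contour length
#' and segment count from a [chain_model].
#'
#' @param rg Observed radius of gyration in Angstrom.
#' @param model A [chain_model].
#' @return A `scaling_estimate` (see [alpha_from_rg()]).
#' @examples
#' estimate_alpha(6.97, chain_model(20, contour_length = 73.61))
#' @export
estimate_alpha <- function(rg, model) {
  if (!inherits(model, "chain_model"))
    abort_domain("`model` must be a chain_model")
  alpha_from_rg(rg, model$contour_length, model$n_segments)
}
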