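#' Radius of gyration of a fully stretched chain
#'
#' A fully extended (rod-like) chain of contour length \eqn{L} has radius of
#' gyration \eqn{R_{g0} = L/\sqrt{12}}, the one-dimensional anchor of the
#' scaling interpolation (exponent \eqn{\alpha = 1}).
#'
#' @param contour_length Contour length \eqn{L} in Angstrom (>= 0).
#' @return Radius of gyration in Angstrom.
#' @examples
#' stretched_rg(73.61) # 21.25 A, extended Trp-cage backbone
#' @seealso [rg_from_alpha()], [ideal_chain_rg()]
#' @export
stretched_rg <- function(contour_length) {
  contour_length <- check_positive(contour_length, "contour_length", allow_zero = TRUE)
  contour_length / sqrt(12)
}

#' Radius of gyration of an ideal (freely jointed) chain
#'
#' For the ideal chain the exponent is \eqn{\alpha = 1/2} and
#' \eqn{R_g = a\sqrt{N/6}}.
#'
#' @param n_segments Number of Kuhn segments \eqn{N} (>= 1).
#' @param segment_length Segment (Kuhn) length \eqn{a} in Angstrom.
#' @return Radius of gyration in Angstrom.
#' @examples
#' ideal_chain_rg(20, 73.61 / 20) # about 6.72 A
#' @export
ideal_chain_rg <- function(n_segments, segment_length) {
  n_segments <- check_count(n_segments, "n_segments", min = 1L)
  segment_length <- check_positive(segment_length, "segment_length")
  segment_length * sqrt(n_segments / 6)
}

#' Mean end-to-end distance of an ideal chain
#'
#' Random-walk scaling: \eqn{\langle L \rangle = a N^{1/2}}.
#'
#' @inheritParams ideal_chain_rg
#' @return Mean end-to-end distance in Angstrom.
#' @export
ideal_end_to_end <- function(n_segments, segment_length) {
  n_segments <- check_count(n_segments, "n_segments", min = 1L)
  segment_length <- check_positive(segment_length, "segment_length")
  segment_length * sqrt(n_segments)
}

#' Radius of gyration of a solid sphere
#'
#' About-centre gyration radius of a uniform solid sphere,
#' \eqn{R_g = \sqrt{3/5}\,R}. This is the prefactor consistent with the
#' unweighted second-moment definition of \eqn{R_g} (the about-an-axis value
#' \eqn{\sqrt{2/5}\,R} is a different quantity).
#'
#' @param radius Sphere radius in Angstrom (>= 0).
#' @return Radius of gyration in Angstrom.
#' @examples
#' sphere_rg(6.19) # 4.8 A
#' @export
sphere_rg <- function(radius) {
  radius <- check_positive(radius, "radius", allow_zero = TRUE)
  sqrt(3 / 5) * radius
}

#' Radius of the compact-globule sphere
#'
#' Radius of the sphere whose volume equals the total excluded volume
#' \eqn{N v} of the chain: \eqn{R = (3 N v / 4\pi)^{1/3}}.
#'
#' @param n_segments Number of segments \eqn{N} (>= 1).
#' @param excluded_volume Per-segment excluded volume \eqn{v} in cubic
#'   Angstrom.
#' @return Sphere radius in Angstrom.
#' @examples
#' a <- 73.61 / 20
#' globule_radius(20, a^3) # 6.19 A
#' @export
globule_radius <- function(n_segments, excluded_volume) {
  n_segments <- check_count(n_segments, "n_segments", min = 1L)
  excluded_volume <- check_positive(excluded_volume, "excluded_volume")
  (3 * n_segments * excluded_volume / (4 * pi))^(1 / 3)
}

#' Scaling prefactor k(alpha)
#'
#' Interpolated prefactor \eqn{k(\alpha) = 1/\sqrt{12\alpha}} in
#' \eqn{R_g = k a N^\alpha}, anchored at the stretched chain
#' (\eqn{k(1) = 1/\sqrt{12}}) and the ideal chain
#' (\eqn{k(1/2) = 1/\sqrt{6}}).
#'
#' @param alpha Scaling exponent (> 0), may be a vector.
#' @return Dimensionless prefactor, same length as `alpha`.
#' @export
prefactor_k <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) < 1L || any(!is.finite(alpha)) || any(alpha <= 0))
    abort_domain("`alpha` must be positive and finite")
  1 / sqrt(12 * alpha)
}

#' Radius of gyration predicted by the scaling interpolation
#'
#' \eqn{R_g(\alpha) = k(\alpha)\, a N^\alpha
#'   = R_{g0}\, \alpha^{-1/2} N^{\alpha - 1}} with
#' \eqn{R_{g0} = a N/\sqrt{12}}. Reduces exactly to [stretched_rg()] at
#' \eqn{\alpha = 1} and to [ideal_chain_rg()] at \eqn{\alpha = 1/2}.
#'
#' @param alpha Scaling exponent (> 0), may be a vector.
#' @param n_segments Number of segments \eqn{N} (>= 2).
#' @param segment_length Segment length \eqn{a} in Angstrom.
#' @return Radius of gyration in Angstrom, same length as `alpha`.
#' @examples
#' rg_from_alpha(0.6, 20, 73.61 / 20) # 8.28 A, excluded-volume coil
#' rg_from_alpha(1 / 3, 20, 73.61 / 20) # 4.99 A, compact globule
#' @export
rg_from_alpha <- function(alpha, n_segments, segment_length) {
  if (!is.numeric(alpha) || length(alpha) < 1L || any(!is.finite(alpha)) || any(alpha <= 0))
    abort_domain("`alpha` must be positive and finite")
  n_segments <- check_count(n_segments, "n_segments", min = 2L)
  segment_length <- check_positive(segment_length, "segment_length")
  rg0 <- segment_length * n_segments / sqrt(12)
  rg0 * alpha^(-0.5) * n_segments^(alpha - 1)
}

#' Fractal dimensionality of a chain
#'
#' \eqn{D = 1/\alpha}: \eqn{D = 1} for the stretched chain, \eqn{D = 2} at
#' the theta point (ideal chain), \eqn{D = 3} for the compact globule.
#'
#' @param alpha Scaling exponent (> 0), may be a vector.
#' @return Dimensionality, same length as `alpha`.
#' @export
dimensionality <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) < 1L || any(!is.finite(alpha)) || any(alpha <= 0))
    abort_domain("`alpha` must be positive and finite")
  1 / alpha
}

# Left-hand side of the log scaling relation,
# ln(Rg/Rg0) = -0.5 ln(alpha) + (alpha - 1) ln(N),
# as a function of alpha for fixed N.
scaling_lhs <- function(alpha, log_n) {
  -0.5 * log(alpha) + (alpha - 1) * log_n
}

#' Estimate the scaling exponent from an observed radius of gyration
#'
#' Numerically inverts the log scaling relation
#' \eqn{\ln(R_g/R_{g0}) = -0.5\ln\alpha + (\alpha - 1)\ln N} for
#' \eqn{\alpha}, where \eqn{R_{g0} = L/\sqrt{12}} is the stretched-chain
#' radius of gyration. The left-hand side is monotone increasing only for
#' \eqn{\alpha > 1/(2\ln N)}; root-finding is restricted to the bracket
#' \eqn{[\max(1/(2\ln N) + 0.01,\ 0.20),\ 1.25]}. Observed \eqn{R_g} values
#' outside the attainable range of that branch are clamped to the bracket
#' edge and flagged (trajectory frames can transiently exceed the stretched
#' \eqn{R_g}), rather than raising an error.
#'
#' Exponents slightly above 1 (over-stretched frames) are returned as found,
#' but the reported dimensionality is capped at \eqn{D = 1} and the estimate
#' is flagged `"clamped_high"`; \eqn{D = 1/\alpha} is only meaningful for
#' \eqn{\alpha \le 1}.
#'
#' @param rg Observed radius of gyration in Angstrom (> 0).
#' @param contour_length Contour length \eqn{L} in Angstrom (> 0).
#' @param n_segments Number of segments \eqn{N} (>= 2).
#' @return A `scaling_estimate` object: list with elements `alpha`,
#'   `dimensionality`, `rg`, `rg0`, `residual` (absolute equation residual at
#'   the returned root) and `flag` (one of `"ok"`, `"clamped_low"`,
#'   `"clamped_high"`).
#' @examples
#' est <- alpha_from_rg(6.97, 73.61, 20)
#' round(est$alpha, 2) # 0.52
#' @export
alpha_from_rg <- function(rg, contour_length, n_segments) {
  rg <- check_positive(rg, "rg")
  contour_length <- check_positive(contour_length, "contour_length")
  n_segments <- check_count(n_segments, "n_segments", min = 2L)
  log_n <- log(n_segments)
  if (log_n <= 0.5)
    abort_domain("`n_segments` too small: no monotone branch for the inversion")

  rg0 <- contour_length / sqrt(12)
  target <- log(rg / rg0)
  lo <- max(1 / (2 * log_n) + 0.01, 0.20)
  hi <- 1.25
  f <- function(a) scaling_lhs(a, log_n) - target

  if (f(lo) >= 0) {
    alpha <- lo
    flag <- "clamped_low"
  } else if (f(hi) <= 0) {
    alpha <- hi
    flag <- "clamped_high"
  } else {
    alpha <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
    flag <- if (alpha > 1) "clamped_high" else "ok"
  }
  dim <- if (alpha > 1) 1.0 else 1 / alpha
  structure(
    list(alpha = alpha, dimensionality = dim, rg = rg, rg0 = rg0,
         residual = abs(f(alpha)), flag = flag),
    class = "scaling_estimate"
  )
}

#' @export
print.scaling_estimate <- function(x, digits = 4L, ...) {
  cat("Chain scaling estimate\n")
  cat(sprintf("  Rg       = %.*f A (Rg0 = %.*f A)\n", digits, x$rg, digits, x$rg0))
  cat(sprintf("  alpha    = %.*f\n", digits, x$alpha))
  cat(sprintf("  D        = %.*f\n", digits, x$dimensionality))
  cat(sprintf("  residual = %.3g, flag = %s\n", x$residual, x$flag))
  invisible(x)
}

#' Flory excluded-volume free energy (proportional form)
#'
#' Dimensionless free energy of a swollen chain,
#' \eqn{F(L) \sim N^2 v / L^3 + L^2/(N a^2)}: excluded-volume repulsion plus
#' entropic elasticity. Only the location of the minimum is physically
#' meaningful; temperature prefactors are dropped.
#'
#' @param end_to_end Chain extension \eqn{L} in Angstrom (> 0), may be a
#'   vector.
#' @param n_segments Number of segments \eqn{N} (>= 1).
#' @param excluded_volume Per-segment excluded volume \eqn{v} in cubic
#'   Angstrom.
#' @param segment_length Segment length \eqn{a} in Angstrom.
#' @return Dimensionless free energy, same length as `end_to_end`.
#' @export
flory_free_energy <- function(end_to_end, n_segments, excluded_volume, segment_length) {
  if (!is.numeric(end_to_end) || length(end_to_end) < 1L ||
      any(!is.finite(end_to_end)) || any(end_to_end <= 0))
    abort_domain("`end_to_end` must be positive and finite")
  n_segments <- check_count(n_segments, "n_segments", min = 1L)
  excluded_volume <- check_positive(excluded_volume, "excluded_volume")
  segment_length <- check_positive(segment_length, "segment_length")
  n_segments^2 * excluded_volume / end_to_end^3 +
    end_to_end^2 / (n_segments * segment_length^2)
}

#' Minimize the Flory free energy over chain extension
#'
#' Finds the extension \eqn{L^*} minimizing [flory_free_energy()]
#' numerically (coarse log-spaced bracket scan followed by
#' [stats::optimize()]), and reports alongside it the analytic stationary
#' point \eqn{L^* = ((3/2) N^3 v a^2)^{1/5}} for cross-checking.
#'
#' @inheritParams flory_free_energy
#' @return A `flory_fit` object: list with `l_star` (numerical minimizer,
#'   Angstrom), `free_energy_min`, and `analytic_l_star`.
#' @examples
#' flory_minimize(20, (73.61 / 20)^3, 73.61 / 20)
#' @export
flory_minimize <- function(n_segments, excluded_volume, segment_length) {
  n_segments <- check_count(n_segments, "n_segments", min = 1L)
  excluded_volume <- check_positive(excluded_volume, "excluded_volume")
  segment_length <- check_positive(segment_length, "segment_length")
  f <- function(l) flory_free_energy(l, n_segments, excluded_volume, segment_length)
  # generic bracket: L* lies well inside (0, 10 a N] for any positive v
  grid <- exp(seq(log(1e-3 * segment_length),
                  log(10 * segment_length * n_segments), length.out = 400L))
  i <- which.min(f(grid))
  if (i == 1L || i == length(grid))
    abort_numeric("failed to bracket a free-energy minimum")
  opt <- stats::optimize(f, lower = grid[i - 1L], upper = grid[i + 1L],
                         tol = 1e-10 * grid[i])
  analytic <- (1.5 * n_segments^3 * excluded_volume * segment_length^2)^(1 / 5)
  structure(
    list(l_star = opt$minimum, free_energy_min = opt$objective,
         analytic_l_star = analytic),
    class = "flory_fit"
  )
}

#' @export
print.flory_fit <- function(x, ...) {
  cat("Flory free-energy minimum\n")
  cat(sprintf("  L* (numeric)  = %.6f A\n", x$l_star))
  cat(sprintf("  L* (analytic) = %.6f A\n", x$analytic_l_star))
  cat(sprintf("  F(L*)         = %.6g\n", x$free_energy_min))
  invisible(x)
}

#' Flory scaling exponent from numerical minimization
#'
#' Minimizes the Flory free energy for each chain length in `n_list` and
#' fits \eqn{\ln L^*} against \eqn{\ln N} by ordinary least squares. The
#' relation is an exact power law with slope 3/5.
#'
#' @param n_list Integer vector of chain lengths (>= 3 distinct values,
#'   each >= 2).
#' @inheritParams flory_free_energy
#' @return A [scaling_fit] object with slope approximately 0.6.
#' @examples
#' flory_exponent(c(50, 100, 200, 400, 800, 1600, 3200), 3.8^3, 3.8)
#' @export
flory_exponent <- function(n_list, excluded_volume, segment_length) {
  if (!is.numeric(n_list) || length(unique(n_list)) < 3L || any(n_list < 2))
    abort_domain("`n_list` must contain >= 3 distinct chain lengths >= 2")
  l_star <- vapply(n_list, function(n)
    flory_minimize(n, excluded_volume, segment_length)$l_star, numeric(1))
  new_scaling_fit(log(n_list), log(l_star),
                  xlab = "ln N", ylab = "ln L*", kind = "flory")
}
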