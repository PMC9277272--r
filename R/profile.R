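#' Analysis configuration for trajectory profiling
#'
#' Parameters controlling [analyze_trajectory()]: the atom selection used by
#' the readers, overrides for the chain model parameters (\eqn{N}, \eqn{a},
#' \eqn{L}) and the reporting mode. Under `report_mode = "paper_rounding"`
#' the exponent is rounded to 2 decimals before the dimensionality
#' \eqn{D = 1/\alpha} is formed (so an exponent of 0.52 reports
#' \eqn{D = 1.92}); `"full_precision"` carries the unrounded values.
#'
#' @param selection Atom selection for PDB input, `"ca"` or `"all"`.
#' @param n_segments Optional segment count \eqn{N}; defaults to the frame
#'   bead count.
#' @param segment_length Optional segment length \eqn{a} in Angstrom.
#' @param contour_length Optional contour length \eqn{L} in Angstrom.
#' @param report_mode `"full_precision"` (default) or `"paper_rounding"`.
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(selection = c("ca", "all"), n_segments = NULL,
                            segment_length = NULL, contour_length = NULL,
                            report_mode = c("full_precision", "paper_rounding")) {
  selection <- match.arg(selection)
  report_mode <- match.arg(report_mode)
  if (!is.null(n_segments)) n_segments <- check_count(n_segments, "n_segments", min = 2L)
  if (!is.null(segment_length))
    segment_length <- check_positive(segment_length, "segment_length")
  if (!is.null(contour_length))
    contour_length <- check_positive(contour_length, "contour_length")
  structure(list(selection = selection, n_segments = n_segments,
                 segment_length = segment_length, contour_length = contour_length,
                 report_mode = report_mode),
            class = "analysis_config")
}

#' Per-frame scaling analysis of a folding trajectory
#'
#' For every frame computes the radius of gyration, the end-to-end distance,
#' the superposed RMSD against an optional reference conformation, the
#' scaling exponent \eqn{\alpha} obtained by inverting the scaling relation
#' with \eqn{R_{g0} = L/\sqrt{12}} (see [alpha_from_rg()]), and the
#' dimensionality \eqn{D}.
#'
#' The chain parameters are resolved in order of preference: explicit
#' `contour_length`, then `n_segments * segment_length`, and finally the
#' maximum observed end-to-end distance (reported via a message, since the
#' exponent estimates depend on \eqn{R_{g0}}). `n_segments` defaults to the
#' frame bead count.
#'
#' @param traj A [structure_ensemble].
#' @param reference Optional reference [conformation] for the RMSD column.
#' @param config An [analysis_config].
#' @return A `folding_profile`: a data frame with one row per frame and
#'   columns `frame` (0-based), `time_ps`, `rg_A`, `ree_A`, `rmsd_A` (NA
#'   without a reference), `alpha`, `dimension`, `flag`.
#' @examples
#' cfg <- generator_config(20, 73.61 / 20, seed = 1)
#' traj <- make_folding_trajectory(cfg, alpha_schedule(0:4, seq(1, 0.5, length.out = 5)))
#' analyze_trajectory(traj, config = analysis_config(n_segments = 20, contour_length = 73.61))
#' @export
analyze_trajectory <- function(traj, reference = NULL, config = analysis_config()) {
  if (inherits(traj, "conformation")) traj <- structure_ensemble(list(traj))
  if (!inherits(traj, "structure_ensemble"))
    abort_domain("`traj` must be a structure_ensemble")
  if (!inherits(config, "analysis_config"))
    abort_domain("`config` must be an analysis_config")
  members <- traj$members
  nb <- n_beads(members[[1L]])
  n <- if (!is.null(config$n_segments)) config$n_segments else nb
  rg <- vapply(members, radius_of_gyration, numeric(1))
  ree <- if (nb >= 2L) vapply(members, end_to_end_distance, numeric(1)) else
    rep(NA_real_, length(members))
  if (!is.null(config$contour_length)) {
    contour <- config$contour_length
  } else if (!is.null(config$segment_length)) {
    contour <- n * config$segment_length
  } else {
    contour <- max(ree)
    message(sprintf(
      "contour length not supplied; using max end-to-end distance L = %.3f A (Rg0 = %.3f A)",
      contour, contour / sqrt(12)))
  }
  rmsd_col <- rep(NA_real_, length(members))
  if (!is.null(reference)) {
    reference <- as_conformation(reference)
    if (n_beads(reference) != nb)
      abort_domain("reference bead count differs from the trajectory")
    rmsd_col <- vapply(members, function(m) rmsd(m, reference, superpose = TRUE),
                       numeric(1))
  }
  est <- lapply(rg, alpha_from_rg, contour_length = contour, n_segments = n)
  alpha <- vapply(est, `[[`, numeric(1), "alpha")
  flag <- vapply(est, `[[`, character(1), "flag")
  if (config$report_mode == "paper_rounding") {
    alpha <- round(alpha, 2L)
    dim <- ifelse(alpha > 1, 1, 1 / alpha)
  } else {
    dim <- vapply(est, `[[`, numeric(1), "dimensionality")
  }
  times <- vapply(seq_along(members), function(i) {
    t <- members[[i]]$time
    if (is.null(t)) i - 1 else t
  }, numeric(1))
  structure(
    data.frame(frame = seq_along(members) - 1L, time_ps = times, rg_A = rg,
               ree_A = ree, rmsd_A = rmsd_col, alpha = alpha, dimension = dim,
               flag = flag, stringsAsFactors = FALSE),
    class = c("folding_profile", "data.frame"),
    contour_length = contour, n_segments = n,
    report_mode = config$report_mode
  )
}

#' @export
print.folding_profile <- function(x, ...) {
  cat(sprintf("Folding profile: %d frames (N = %d, L = %.3f A, %s)\n",
              nrow(x), attr(x, "n_segments"), attr(x, "contour_length"),
              attr(x, "report_mode")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
summary.folding_profile <- function(object, ...) {
  ok <- object$flag == "ok"
  cat(sprintf("Folding profile over %d frames (%d flagged ok)\n",
              nrow(object), sum(ok)))
  cat(sprintf("  Rg    : %.3f .. %.3f A\n", min(object$rg_A), max(object$rg_A)))
  cat(sprintf("  alpha : %.3f .. %.3f\n", min(object$alpha), max(object$alpha)))
  cat(sprintf("  D     : %.3f .. %.3f\n", min(object$dimension), max(object$dimension)))
  invisible(object)
}

#' Plot a folding profile
#'
#' Two panels: the radius of gyration versus time, and the dimensionality
#' versus the radius of gyration (the folding curve from line to globule).
#'
#' @param x A `folding_profile`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.folding_profile <- function(x, ...) {
  op <- graphics::par(mfrow = c(1L, 2L))
  on.exit(graphics::par(op))
  graphics::plot(x$time_ps, x$rg_A, type = "l", xlab = "time (ps)",
                 ylab = "Rg (A)", ...)
  ord <- order(x$rg_A)
  graphics::plot(x$rg_A[ord], x$dimension[ord], type = "l", xlab = "Rg (A)",
                 ylab = "dimensionality D", ylim = c(1, 3), ...)
  invisible(x)
}

#' Write a folding profile as TSV
#'
#' Tab-separated with the fixed header
#' `frame time_ps rg_A ree_A rmsd_A alpha dimension flag`; floating-point
#' columns are written with 4 decimals and a missing RMSD column as `NA`.
#'
#' @param profile A `folding_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_tsv <- function(profile, path) {
  if (!inherits(profile, "folding_profile"))
    abort_domain("`profile` must be a folding_profile")
  num <- function(v) ifelse(is.na(v), "NA", sprintf("%.4f", v))
  lines <- c(
    paste(c("frame", "time_ps", "rg_A", "ree_A", "rmsd_A", "alpha",
            "dimension", "flag"), collapse = "\t"),
    paste(profile$frame, num(profile$time_ps), num(profile$rg_A),
          num(profile$ree_A), num(profile$rmsd_A), num(profile$alpha),
          num(profile$dimension), profile$flag, sep = "\t")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
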