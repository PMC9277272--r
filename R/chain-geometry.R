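#' Chain conformation
#'
#' One snapshot of a chain: an ordered set of 3-D bead coordinates in
#' Angstrom, with optional per-bead labels (residue names/numbers) and an
#' optional frame time in picoseconds.
#'
#' @param xyz Numeric matrix with 3 columns (x, y, z) or a length-3 vector
#'   for a single bead.
#' @param labels Optional character/integer vector, one entry per bead.
#' @param time Optional frame time in ps.
#' @return A `conformation` object.
#' @export
conformation <- function(xyz, labels = NULL, time = NULL) {
  if (is.null(dim(xyz))) {
    if (length(xyz) != 3L) abort_domain("`xyz` vector must have length 3")
    xyz <- matrix(xyz, nrow = 1L)
  }
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) abort_domain("`xyz` must have 3 columns")
  if (nrow(xyz) < 1L) abort_domain("a conformation needs at least one bead")
  if (any(!is.finite(xyz))) abort_domain("all coordinates must be finite")
  if (!is.null(labels) && length(labels) != nrow(xyz))
    abort_domain("`labels` must have one entry per bead")
  if (!is.null(time)) time <- check_positive(time, "time", allow_zero = TRUE)
  dimnames(xyz) <- NULL
  structure(list(xyz = xyz, labels = labels, time = time),
            class = "conformation")
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("Conformation: %d beads", nrow(x$xyz)))
  if (!is.null(x$time)) cat(sprintf(", t = %g ps", x$time))
  cat(sprintf(", Rg = %.3f A\n", radius_of_gyration(x)))
  invisible(x)
}

#' @export
as.matrix.conformation <- function(x, ...) x$xyz

n_beads <- function(conf) nrow(conf$xyz)

as_conformation <- function(x) {
  if (inherits(x, "conformation")) x else conformation(x)
}

#' Structure ensemble
#'
#' An ordered collection of [conformation]s with identical bead counts:
#' a time-ordered trajectory, an NMR model set, or an unordered sample set.
#'
#' @param members List of [conformation]s (or bare coordinate matrices).
#' @param kind One of `"sample_set"`, `"trajectory"`, `"nmr_ensemble"`.
#'   Trajectory members must have non-decreasing frame times (when set).
#' @return A `structure_ensemble` object (list with `members`, `kind`).
#' @export
structure_ensemble <- function(members,
                               kind = c("sample_set", "trajectory", "nmr_ensemble")) {
  kind <- match.arg(kind)
  if (length(members) < 1L) abort_domain("ensemble needs at least one member")
  members <- lapply(members, as_conformation)
  counts <- vapply(members, n_beads, integer(1))
  if (length(unique(counts)) != 1L)
    abort_domain("all ensemble members must have the same bead count")
  if (kind == "trajectory") {
    times <- vapply(members, function(m) if (is.null(m$time)) NA_real_ else m$time,
                    numeric(1))
    tt <- times[!is.na(times)]
    if (length(tt) > 1L && any(diff(tt) < 0))
      abort_domain("trajectory frame times must be non-decreasing")
  }
  structure(list(members = members, kind = kind), class = "structure_ensemble")
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat(sprintf("Structure ensemble (%s): %d members x %d beads\n",
              x$kind, length(x$members), n_beads(x$members[[1L]])))
  invisible(x)
}

#' @export
length.structure_ensemble <- function(x) length(x$members)

#' @export
`[[.structure_ensemble` <- function(x, i) x$members[[i]]

#' Centre of mass of a conformation
#'
#' Arithmetic mean of the bead coordinates (equal bead masses).
#'
#' @param conf A [conformation].
#' @return Length-3 numeric vector (Angstrom).
#' @export
center_of_mass <- function(conf) {
  conf <- as_conformation(conf)
  colMeans(conf$xyz)
}

#' Radius of gyration of a conformation
#'
#' Root-mean-square distance of the beads from their common centroid
#' (unweighted): \eqn{R_g^2 = \frac{1}{N}\sum_k (r_k - r_C)^2}.
#' Invariant under rigid rotation and translation.
#'
#' @param conf A [conformation].
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(conf) {
  conf <- as_conformation(conf)
  ctr <- colMeans(conf$xyz)
  sqrt(mean(rowSums(sweep(conf$xyz, 2L, ctr)^2)))
}

#' End-to-end distance of a conformation
#'
#' Euclidean distance between the first and last bead.
#'
#' @param conf A [conformation] with at least 2 beads.
#' @return Distance in Angstrom.
#' @export
end_to_end_distance <- function(conf) {
  conf <- as_conformation(conf)
  n <- n_beads(conf)
  if (n < 2L) abort_domain("end-to-end distance needs at least 2 beads")
  sqrt(sum((conf$xyz[n, ] - conf$xyz[1L, ])^2))
}

# Core Kabsch solution: optimal proper rotation U and translation t such
# that P %*% t(U) + t best matches Q in least squares. Reflections are
# corrected by flipping the axis of the smallest singular value.
kabsch_core <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2L, cp)
  Q0 <- sweep(Q, 2L, cq)
  s <- svd(crossprod(P0, Q0))
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  U <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- P0 %*% t(U)
  rmsd <- sqrt(mean(rowSums((aligned - Q0)^2)))
  list(rotation = U, translation = as.numeric(cq - U %*% cp), rmsd = rmsd,
       aligned = sweep(aligned, 2L, cq, "+"))
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares rigid superposition of `mobile` onto `target`: returns the
#' proper rotation (determinant +1; reflections are corrected), the
#' translation, and the post-superposition RMSD. The transform maps a
#' coordinate row x to `x %*% t(rotation) + translation`.
#'
#' @param mobile,target [conformation]s with equal bead counts (>= 3).
#' @return List with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (Angstrom).
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as_conformation(mobile)
  target <- as_conformation(target)
  if (n_beads(mobile) != n_beads(target))
    abort_domain("bead counts differ")
  if (n_beads(mobile) < 3L)
    abort_domain("superposition needs at least 3 beads")
  res <- kabsch_core(mobile$xyz, target$xyz)
  res[c("rotation", "translation", "rmsd")]
}

#' Root-mean-square deviation between two conformations
#'
#' With `superpose = TRUE` (default), the Kabsch-minimal RMSD after optimal
#' rigid superposition; otherwise the raw coordinate RMSD (useful as a
#' trajectory drift diagnostic).
#'
#' @param a,b [conformation]s with equal bead counts.
#' @param superpose Superpose before measuring? Default `TRUE`.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, superpose = TRUE) {
  a <- as_conformation(a)
  b <- as_conformation(b)
  if (n_beads(a) != n_beads(b)) abort_domain("bead counts differ")
  if (superpose) {
    if (n_beads(a) == 1L) return(0)
    kabsch_core(a$xyz, b$xyz)$rmsd
  } else {
    sqrt(mean(rowSums((a$xyz - b$xyz)^2)))
  }
}

#' Per-bead root-mean-square fluctuation
#'
#' Superposes every ensemble member onto the reference, then reports for
#' each bead the root-mean-square deviation of its position across members
#' from its mean position.
#'
#' @param ensemble A [structure_ensemble].
#' @param reference Reference [conformation]; defaults to the first member.
#' @return Numeric vector of per-bead RMSF values in Angstrom.
#' @export
rmsf <- function(ensemble, reference = NULL) {
  if (!inherits(ensemble, "structure_ensemble"))
    abort_domain("`ensemble` must be a structure_ensemble")
  if (is.null(reference)) reference <- ensemble$members[[1L]]
  reference <- as_conformation(reference)
  nb <- n_beads(ensemble$members[[1L]])
  if (n_beads(reference) != nb)
    abort_domain("reference bead count differs from the ensemble")
  aligned <- lapply(ensemble$members, function(m)
    kabsch_core(m$xyz, reference$xyz)$aligned)
  arr <- array(unlist(aligned), dim = c(nb, 3L, length(aligned)))
  mean_pos <- apply(arr, c(1L, 2L), mean)
  dev2 <- sweep(arr, c(1L, 2L), mean_pos)^2
  sqrt(apply(dev2, 1L, function(slice) mean(colSums(matrix(slice, nrow = 3L)))))
}

#' Classify B-factors into confidence classes
#'
#' Temperature factors below 30 signify high confidence in the atomic
#' position, above 60 disorder; values in between (boundaries included) are
#' intermediate.
#'
#' @param values Non-negative numeric vector of per-atom B-factors.
#' @return Factor with levels `confident`, `intermediate`, `disordered`.
#' @export
bfactor_classify <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values)) || any(values < 0))
    abort_domain("B-factors must be finite and non-negative")
  cls <- ifelse(values < 30, "confident",
                ifelse(values > 60, "disordered", "intermediate"))
  factor(cls, levels = c("confident", "intermediate", "disordered"))
}
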