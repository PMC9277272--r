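#' Read a (multi-frame) XYZ file
#'
#' Standard XYZ layout: an atom-count line, a comment line, then
#' `element x y z` rows; multiple frames are concatenated. A `t= <ps>` token
#' in the comment line is parsed into the frame time.
#'
#' @param path Path to an XYZ file.
#' @return A [structure_ensemble]. Files with non-decreasing frame times (or
#'   none) are returned as kind `"trajectory"`.
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!length(lines)) abort_format(sprintf("empty XYZ file: %s", path))
  members <- list()
  i <- 1L
  while (i <= length(lines)) {
    count <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(count) || count < 1L)
      abort_format(sprintf("%s: malformed atom-count line at line %d", path, i))
    if (i + 1L + count > length(lines))
      abort_format(sprintf("%s: truncated frame starting at line %d", path, i))
    comment <- lines[i + 1L]
    time <- NULL
    tm <- regmatches(comment, regexec("t=\\s*([-0-9.eE+]+)", comment))[[1L]]
    if (length(tm) == 2L) time <- as.numeric(tm[2L])
    rows <- lines[(i + 2L):(i + 1L + count)]
    fields <- strsplit(trimws(rows), "\\s+")
    bad <- which(vapply(fields, length, integer(1)) < 4L)
    if (length(bad))
      abort_format(sprintf("%s: malformed coordinate row at line %d",
                           path, i + 1L + bad[1L]))
    xyz <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      abort_format(sprintf("%s: non-numeric coordinates in frame at line %d", path, i))
    labels <- vapply(fields, `[[`, character(1), 1L)
    members[[length(members) + 1L]] <- conformation(xyz, labels = labels, time = time)
    i <- i + 2L + count
  }
  kind <- "trajectory"
  times <- vapply(members, function(m) if (is.null(m$time)) NA_real_ else m$time,
                  numeric(1))
  tt <- times[!is.na(times)]
  if (length(tt) > 1L && any(diff(tt) < 0)) kind <- "sample_set"
  structure_ensemble(members, kind = kind)
}

#' Write a structure ensemble to an XYZ file
#'
#' Coordinates are written with 6 decimals, so a write/read round trip
#' reproduces them to within 1e-6 Angstrom. Frame times, when present, are
#' stored as a `t= <ps>` token in the comment line.
#'
#' @param ensemble A [structure_ensemble] (or a single [conformation]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_xyz <- function(ensemble, path) {
  if (inherits(ensemble, "conformation"))
    ensemble <- structure_ensemble(list(ensemble))
  if (!inherits(ensemble, "structure_ensemble"))
    abort_domain("`ensemble` must be a structure_ensemble or conformation")
  out <- unlist(lapply(seq_along(ensemble$members), function(j) {
    m <- ensemble$members[[j]]
    labels <- if (is.null(m$labels)) rep("C", n_beads(m)) else as.character(m$labels)
    comment <- sprintf("frame %d", j - 1L)
    if (!is.null(m$time)) comment <- sprintf("%s t= %.6f", comment, m$time)
    c(sprintf("%d", n_beads(m)), comment,
      sprintf("%s %.6f %.6f %.6f", labels, m$xyz[, 1L], m$xyz[, 2L], m$xyz[, 3L]))
  }))
  writeLines(out, path)
  invisible(path)
}
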