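#' Read a (multi-MODEL) PDB file as a structure ensemble
#'
#' Parses a PDB file via [bio3d::read.pdb()] and returns one [conformation]
#' per MODEL (a file without MODEL records yields a single member). With
#' `selection = "ca"` only atoms named `CA` with blank or `'A'` alternate
#' location are kept (bio3d already drops non-`A` altlocs); residue numbers
#' are preserved as printed. Frame times are set to the 1-based MODEL index
#' (PDB files carry no times).
#'
#' @param path Path to a PDB file.
#' @param selection `"ca"` (default) for C-alpha beads or `"all"` for every
#'   ATOM record.
#' @return A [structure_ensemble] of kind `"trajectory"` for multi-MODEL
#'   files (`"sample_set"` for single models).
#' @export
read_pdb_models <- function(path, selection = c("ca", "all")) {
  selection <- match.arg(selection)
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) abort_format(sprintf("%s: %s", path, conditionMessage(e)))
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  atoms <- pdb$atom
  if (ncol(xyz) != 3L * nrow(atoms) || any(!is.finite(xyz)))
    abort_format(sprintf("%s: inconsistent atom counts across MODEL records", path))
  keep <- atoms$type == "ATOM"
  if (selection == "ca")
    keep <- keep & atoms$elety == "CA" &
      (is.na(atoms$alt) | atoms$alt %in% c("", "A"))
  if (!any(keep))
    abort_format(sprintf("%s: no atoms left after '%s' selection", path, selection))
  cols <- as.vector(rbind(3L * which(keep) - 2L, 3L * which(keep) - 1L,
                          3L * which(keep)))
  labels <- paste0(atoms$resid[keep], atoms$resno[keep])
  members <- lapply(seq_len(nrow(xyz)), function(i) {
    conformation(matrix(xyz[i, cols], ncol = 3L, byrow = TRUE),
                 labels = labels, time = i)
  })
  structure_ensemble(members,
                     kind = if (length(members) > 1L) "trajectory" else "sample_set")
}

#' Write a structure ensemble as a multi-MODEL PDB file
#'
#' Beads are written as C-alpha atoms of consecutively numbered glycine
#' residues, one MODEL per ensemble member, via [bio3d::write.pdb()].
#'
#' @param ensemble A [structure_ensemble] (or single [conformation]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pdb_models <- function(ensemble, path) {
  if (inherits(ensemble, "conformation"))
    ensemble <- structure_ensemble(list(ensemble))
  if (!inherits(ensemble, "structure_ensemble"))
    abort_domain("`ensemble` must be a structure_ensemble or conformation")
  nb <- n_beads(ensemble$members[[1L]])
  xyz <- do.call(rbind, lapply(ensemble$members, function(m) as.vector(t(m$xyz))))
  bio3d::write.pdb(file = path, xyz = xyz, resno = seq_len(nb),
                   resid = rep("GLY", nb), elety = rep("CA", nb))
  invisible(path)
}
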