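# Shared fixture builders: all test inputs are generated in code.

# Trp-cage-scale chain parameters used throughout.
trp <- list(n = 20L, L = 73.61, a = 73.61 / 20)

# A random proper rotation (det +1) drawn from the seeded stream.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3L, 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# Apply a rigid transform (rotation rows convention: x' = x R^T + t).
rigid_transform <- function(conf, rotation, translation) {
  conformation(sweep(conf$xyz %*% t(rotation), 2L, translation, "+"),
               labels = conf$labels, time = conf$time)
}

# Fixed-width PDB ATOM line.
pdb_atom_line <- function(serial, name, resn, resno, x, y, z, alt = " ", b = 0) {
  sprintf("ATOM  %5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4L, paste0(" ", name), name), alt,
          resn, "A", resno, x, y, z, 1.0, b, substr(name, 1L, 1L))
}

# Write a small multi-MODEL PDB file; `models` is a list of coordinate
# matrices (one row per CA atom). Extra non-CA and altloc-B atoms can be
# interleaved to exercise the selection rules.
write_pdb_fixture <- function(models, path, with_extras = FALSE) {
  lines <- character()
  for (m in seq_along(models)) {
    lines <- c(lines, sprintf("MODEL %8d", m))
    xyz <- models[[m]]
    serial <- 0L
    for (i in seq_len(nrow(xyz))) {
      if (with_extras) {
        serial <- serial + 1L
        lines <- c(lines, pdb_atom_line(serial, "N", "GLY", i,
                                        xyz[i, 1] - 0.5, xyz[i, 2], xyz[i, 3]))
      }
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(serial, "CA", "GLY", i,
                                      xyz[i, 1], xyz[i, 2], xyz[i, 3],
                                      alt = if (with_extras) "A" else " "))
      if (with_extras) {
        serial <- serial + 1L
        lines <- c(lines, pdb_atom_line(serial, "CA", "GLY", i,
                                        xyz[i, 1] + 9, xyz[i, 2], xyz[i, 3],
                                        alt = "B"))
      }
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# Pairwise self-avoidance check: no two beads closer than `min_sep`.
all_beads_distinct <- function(conf, min_sep = 1e-6) {
  d <- stats::dist(conf$xyz)
  min(d) > min_sep
}

expect_domain_error <- function(expr) {
  expect_error(expr, class = "chainscaling_domain_error")
}
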