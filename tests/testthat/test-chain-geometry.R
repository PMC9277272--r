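test_that("centroid, Rg and end-to-end distance match direct geometry", {
  two <- conformation(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(center_of_mass(two), c(1, 0, 0))
  expect_equal(radius_of_gyration(two), 1.0)
  expect_equal(center_of_mass(conformation(c(3, -1, 2))), c(3, -1, 2))
  expect_equal(radius_of_gyration(conformation(c(3, -1, 2))), 0)
  cube <- conformation(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  expect_equal(center_of_mass(cube), c(0.5, 0.5, 0.5))
  expect_equal(radius_of_gyration(cube), sqrt(3) / 2)
  expect_equal(end_to_end_distance(conformation(rbind(c(0, 0, 0), c(3, 4, 0)))), 5)
  loop <- conformation(rbind(c(0, 0, 0), c(1, 1, 0), c(0, 0, 0)))
  expect_equal(end_to_end_distance(loop), 0)
  rod <- make_stretched(12, 2.5)
  expect_equal(end_to_end_distance(rod), 30)
  expect_domain_error(end_to_end_distance(conformation(c(1, 2, 3))))
  expect_domain_error(conformation(rbind(c(0, 0, 0), c(NA, 0, 0))))
  expect_domain_error(conformation(matrix(1, 2, 2)))
})

test_that("Rg and superposed RMSD are invariant under rigid transforms", {
  withr::with_seed(101, {
    for (i in 1:10) {
      conf <- conformation(matrix(rnorm(30, sd = 4), 10L, 3L))
      moved <- rigid_transform(conf, random_rotation(), rnorm(3, sd = 50))
      expect_lt(abs(radius_of_gyration(moved) - radius_of_gyration(conf)), 1e-9)
      expect_lt(rmsd(conf, moved, superpose = TRUE), 1e-9)
    }
  })
})

test_that("kabsch superposition recovers rigid transforms exactly", {
  withr::with_seed(33, {
    conf <- conformation(matrix(rnorm(24, sd = 3), 8L, 3L))
    same <- kabsch_superpose(conf, conf)
    expect_equal(same$rotation, diag(3), tolerance = 1e-10)
    expect_lt(same$rmsd, 1e-12)
    R <- random_rotation()
    t <- c(12, -7, 3)
    moved <- rigid_transform(conf, R, t)
    fit <- kabsch_superpose(conf, moved)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(fit$rotation, R, tolerance = 1e-9)
    # rotation is orthogonal with determinant +1, even for noisy pairs
    noisy <- conformation(moved$xyz + matrix(rnorm(24, sd = 0.3), 8L, 3L))
    nfit <- kabsch_superpose(conf, noisy)
    expect_equal(crossprod(nfit$rotation), diag(3), tolerance = 1e-10)
    expect_equal(det(nfit$rotation), 1, tolerance = 1e-10)
  })
  expect_domain_error(kabsch_superpose(conformation(matrix(0, 3, 3)),
                                       conformation(matrix(0, 4, 3))))
  expect_domain_error(kabsch_superpose(conformation(rbind(c(0, 0, 0), c(1, 0, 0))),
                                       conformation(rbind(c(0, 0, 0), c(0, 1, 0)))))
})

test_that("kabsch RMSD matches a brute-force planar rotation search", {
  # planar 4-bead toys: optimum is a rotation about z, so a 1-D grid over
  # the angle is an exhaustive oracle
  a <- conformation(cbind(c(0, 1, 2, 1), c(0, 0, 1, 2), 0))
  b <- conformation(cbind(c(0.1, 1.2, 1.9, 0.8), c(-0.1, 0.1, 1.2, 1.9), 0))
  grid_rmsd <- function(p, q) {
    p0 <- sweep(p, 2L, colMeans(p))
    q0 <- sweep(q, 2L, colMeans(q))
    best <- Inf
    for (th in seq(0, 2 * pi, by = 1e-3)) {
      rot <- p0[, 1:2] %*% t(matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L))
      best <- min(best, sqrt(mean(rowSums((cbind(rot, p0[, 3]) - q0)^2))))
    }
    best
  }
  expect_equal(kabsch_superpose(a, b)$rmsd, grid_rmsd(a$xyz, b$xyz),
               tolerance = 1e-3)
})

test_that("kabsch RMSD agrees with the bio3d reference implementation", {
  withr::with_seed(55, {
    p <- matrix(rnorm(36, sd = 5), 12L, 3L)
    q <- matrix(rnorm(36, sd = 5), 12L, 3L)
    ours <- rmsd(conformation(p), conformation(q), superpose = TRUE)
    theirs <- bio3d::rmsd(as.vector(t(p)), as.vector(t(q)), fit = TRUE)
    expect_equal(ours, theirs, tolerance = 1e-3) # bio3d rounds to 3 decimals
  })
})

test_that("rmsd is symmetric, separates translation modes and handles toys", {
  withr::with_seed(9, {
    a <- conformation(matrix(rnorm(15), 5L, 3L))
    b <- conformation(matrix(rnorm(15), 5L, 3L))
    expect_equal(rmsd(a, b), rmsd(b, a), tolerance = 1e-12)
    expect_equal(rmsd(a, a), 0)
    shifted <- conformation(sweep(a$xyz, 2L, c(5, 0, 0), "+"))
    expect_equal(rmsd(a, shifted, superpose = FALSE), 5.0)
    expect_lt(rmsd(a, shifted, superpose = TRUE), 1e-9)
  })
  toy_a <- conformation(rbind(c(0, 0, 0), c(1, 0, 0)))
  toy_b <- conformation(rbind(c(0, 0, 0), c(0, 1, 0)))
  expect_equal(rmsd(toy_a, toy_b, superpose = FALSE), 1.0)
  expect_domain_error(rmsd(toy_a, conformation(c(0, 0, 0))))
})

test_that("rmsf vanishes for rigid copies and localizes a moved bead", {
  withr::with_seed(77, {
    base <- conformation(matrix(rnorm(60, sd = 3), 20L, 3L))
    copies <- lapply(1:5, function(i)
      rigid_transform(base, random_rotation(), rnorm(3, sd = 10)))
    ens <- structure_ensemble(copies, kind = "nmr_ensemble")
    expect_true(all(rmsf(ens) < 1e-9))
    # move one bead by 2 A between two members: its RMSF approaches 1 A
    # (exactly 1 up to the small re-superposition correction)
    big <- conformation(matrix(rnorm(120, sd = 6), 40L, 3L))
    moved <- big
    moved$xyz[13L, ] <- moved$xyz[13L, ] + c(2, 0, 0)
    two <- structure_ensemble(list(big, moved))
    r <- rmsf(two, reference = big)
    expect_lt(abs(r[13L] - 1.0), 0.05)
    expect_true(all(r[-13L] < 0.05))
    # member order does not matter
    expect_equal(r, rmsf(structure_ensemble(list(moved, big)), reference = big),
                 tolerance = 1e-9)
  })
})

test_that("rmsf matches the bio3d fit-then-fluctuate route", {
  withr::with_seed(88, {
    base <- matrix(rnorm(45, sd = 3), 15L, 3L)
    members <- lapply(1:6, function(i) conformation(base + matrix(rnorm(45, sd = 0.4), 15L, 3L)))
    ens <- structure_ensemble(members)
    ours <- rmsf(ens, reference = members[[1L]])
    xyz <- do.call(rbind, lapply(members, function(m) as.vector(t(m$xyz))))
    fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xyz[1L, ], mobile = xyz))
    theirs <- bio3d::rmsf(fitted)
    # bio3d uses the sample (n - 1) variance; we use the population mean,
    # so the two differ by exactly sqrt(m / (m - 1))
    expect_equal(ours * sqrt(6 / 5), theirs, tolerance = 1e-3)
  })
})

test_that("B-factor classes use strict 30/60 thresholds", {
  cls <- bfactor_classify(c(25, 65, 45, 30, 60, 0, 29.999, 60.001))
  expect_equal(as.character(cls),
               c("confident", "disordered", "intermediate", "intermediate",
                 "intermediate", "confident", "confident", "disordered"))
  expect_domain_error(bfactor_classify(c(10, -1)))
})

test_that("ensembles enforce matching bead counts and ordered times", {
  a <- conformation(matrix(0, 3L, 3L), time = 1)
  b <- conformation(matrix(1, 3L, 3L), time = 2)
  expect_silent(structure_ensemble(list(a, b), kind = "trajectory"))
  expect_domain_error(structure_ensemble(list(a, conformation(matrix(1, 4L, 3L)))))
  expect_domain_error(structure_ensemble(list(b, a), kind = "trajectory"))
})
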