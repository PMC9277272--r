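test_that("closed forms reproduce the Trp-cage worked-example values", {
  # extended backbone: L = 73.61 A, N = 20
  expect_equal(round(stretched_rg(trp$L), 2), 21.25)
  expect_equal(round(ideal_chain_rg(20, 3.68), 2), 6.72)
  expect_equal(globule_radius(20, 3.68^3), 6.19, tolerance = 2e-3)
  expect_equal(round(sphere_rg(6.19), 1), 4.8)
  # at the printed segment length a = 3.68 the globule prediction is 4.99
  expect_equal(round(rg_from_alpha(0.6, 20, 3.68), 2), 8.28)
  expect_equal(round(rg_from_alpha(1 / 3, 20, 3.68), 2), 4.99)
})

test_that("closed forms match independent arithmetic and zero cases", {
  expect_equal(stretched_rg(0), 0)
  expect_equal(stretched_rg(sqrt(12)), 1.0)
  expect_equal(ideal_chain_rg(6, 1.0), 1.0)
  expect_equal(ideal_chain_rg(100, 2.0), 2 * sqrt(100 / 6))
  expect_equal(ideal_end_to_end(100, 1.0), 10.0)
  expect_equal(ideal_end_to_end(20, 3.6805), 3.6805 * sqrt(20))
  expect_equal(ideal_end_to_end(1, 2.5), 2.5)
  expect_equal(sphere_rg(0), 0)
  expect_equal(sphere_rg(1.0), sqrt(3 / 5))
  expect_equal(globule_radius(1, 4 * pi / 3), 1.0)
  expect_equal(globule_radius(160, 4 * pi / 3), 160^(1 / 3))
  expect_equal(prefactor_k(1.0), 1 / sqrt(12))
  expect_equal(prefactor_k(0.5), 1 / sqrt(6))
  expect_equal(prefactor_k(0.25), 1 / sqrt(3))
  expect_equal(dimensionality(1.0), 1.0)
  expect_equal(dimensionality(1 / 3), 3.0)
  expect_equal(round(dimensionality(0.52), 2), 1.92)
})

test_that("scaling interpolation hits its stretched and ideal anchors", {
  for (n in c(2L, 5L, 20L, 400L, 10000L)) {
    a <- 3.1
    expect_equal(rg_from_alpha(1, n, a), stretched_rg(a * n), tolerance = 1e-12)
    expect_equal(rg_from_alpha(0.5, n, a), ideal_chain_rg(n, a), tolerance = 1e-12)
  }
})

test_that("rg_from_alpha is strictly increasing on the monotone branch", {
  for (n in c(5L, 20L, 100L, 1000L)) {
    lo <- 1 / (2 * log(n)) + 1e-3
    alphas <- seq(lo, 1, length.out = 200L)
    rg <- rg_from_alpha(alphas, n, 2.0)
    expect_true(all(diff(rg) > 0))
  }
})

test_that("exponent inversion reproduces the folded Trp-cage estimate", {
  est <- alpha_from_rg(6.97, 73.61, 20)
  expect_equal(round(est$alpha, 2), 0.52)
  expect_identical(est$flag, "ok")
  expect_lt(est$residual, 1e-9)
  expect_equal(est$alpha * est$dimensionality, 1, tolerance = 1e-12)
  # stretched anchor: Rg = Rg0 gives alpha = 1 exactly
  rg0 <- 73.61 / sqrt(12)
  expect_equal(alpha_from_rg(rg0, 73.61, 20)$alpha, 1.0, tolerance = 1e-9)
})

test_that("alpha -> Rg -> alpha round trip is exact to 1e-8", {
  for (n in c(10L, 20L, 50L, 100L)) {
    a <- 3.6805
    for (alpha in seq(0.35, 1.0, by = 0.05)) {
      est <- alpha_from_rg(rg_from_alpha(alpha, n, a), a * n, n)
      expect_lt(abs(est$alpha - alpha), 1e-8)
      expect_lt(est$residual, 1e-9)
    }
  }
})

test_that("out-of-range radii are clamped and flagged, not errors", {
  # above the stretched branch end
  high <- alpha_from_rg(45, 73.61, 20)
  expect_identical(high$flag, "clamped_high")
  expect_equal(high$alpha, 1.25)
  # below the globule end of the branch
  low <- alpha_from_rg(0.5, 73.61, 20)
  expect_identical(low$flag, "clamped_low")
  expect_equal(low$alpha, max(1 / (2 * log(20)) + 0.01, 0.20))
  # slightly over-stretched: root exists but D is capped at 1
  over <- alpha_from_rg(22.0, 73.61, 20)
  expect_identical(over$flag, "clamped_high")
  expect_gt(over$alpha, 1)
  expect_equal(over$dimensionality, 1.0)
})

test_that("flory free energy matches direct arithmetic and diverges at large L", {
  expect_equal(flory_free_energy(1, 1, 1, 1), 2.0)
  expect_equal(flory_free_energy(2, 1, 1, 1), 1 / 8 + 4)
  f <- flory_free_energy(c(10, 100, 1000, 10000), 50, 30, 3)
  expect_true(all(diff(f[-1]) > 0)) # elastic term dominates, monotone growth
})

test_that("flory minimization agrees with the analytic stationary point", {
  withr::with_seed(42, {
    for (i in 1:20) {
      n <- sample(5:5000, 1)
      v <- runif(1, 0.1, 200)
      a <- runif(1, 0.5, 10)
      res <- flory_minimize(n, v, a)
      expect_lt(abs(res$l_star - res$analytic_l_star) / res$analytic_l_star, 1e-6)
    }
  })
  expect_equal(flory_minimize(1, 1, 1)$l_star, 1.5^(1 / 5), tolerance = 1e-6)
})

test_that("flory exponent is 3/5 and invariant to prefactor rescaling", {
  ns <- c(50, 100, 200, 400, 800, 1600, 3200)
  fit <- flory_exponent(ns, 3.8^3, 3.8)
  expect_equal(fit$slope, 0.6, tolerance = 1e-6)
  fit2 <- flory_exponent(ns, 12 * 3.8^3, 0.5 * 3.8)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(fit2$intercept, fit$intercept)))
  # brute-force grid oracle on a small ladder
  grid_lstar <- function(n, v, a) {
    l <- seq(0.1, 50, by = 1e-4)
    l[which.min(n^2 * v / l^3 + l^2 / (n * a^2))]
  }
  ns_small <- c(5, 10, 20)
  oracle <- stats::coef(stats::lm(log(sapply(ns_small, grid_lstar, v = 1, a = 1)) ~
                                    log(ns_small)))[2]
  small_fit <- flory_exponent(ns_small, 1, 1)
  expect_equal(small_fit$slope, unname(oracle), tolerance = 1e-3)
})

test_that("log-log regression recovers exact and near-exact power laws", {
  n <- round(exp(seq(log(10), log(1000), length.out = 8)))
  fit <- fit_scaling_exponent(n, 0.7 * n^0.7)
  expect_equal(fit$slope, 0.7, tolerance = 1e-10)
  expect_equal(exp(fit$intercept), 0.7, tolerance = 1e-10)
  expect_lt(fit$stderr_slope, 1e-10)
  # discrete stretched-chain table tends to slope 1
  n2 <- seq(100, 1000, by = 100)
  fit2 <- fit_scaling_exponent(n2, 2.5 * sqrt(n2 * (n2 + 2) / 12))
  expect_lt(abs(fit2$slope - 1), 0.01)
  # table input form
  fit3 <- fit_scaling_exponent(data.frame(n = n, rg = 0.7 * n^0.7))
  expect_equal(fit3$slope, fit$slope)
})

test_that("folding-time fit recovers the sqrt(N) law", {
  n <- c(10, 20, 40, 80, 160)
  exact <- folding_time_fit(n, 2 * sqrt(n))
  expect_equal(exact$slope, 2.0, tolerance = 1e-12)
  expect_equal(exact$intercept, 0.0, tolerance = 1e-10)
  withr::with_seed(7, {
    noisy <- folding_time_fit(n, 1.5 * sqrt(n) + 3 + rnorm(length(n), sd = 0.01))
    expect_lt(abs(noisy$slope - 1.5), 0.05)
  })
  expect_domain_error(folding_time_fit(100, 4.0))
  expect_domain_error(folding_time_fit(c(10, 20), 1))
})

test_that("chain model resolves, validates and predicts consistently", {
  m <- chain_model(20, contour_length = 73.61)
  expect_equal(m$segment_length, 3.6805)
  expect_equal(m$rg_stretched, 73.61 / sqrt(12))
  expect_equal(m$excluded_volume, 3.6805^3)
  expect_equal(unname(coef(m)["Rg0"]), m$rg_stretched)
  expect_equal(predict(m, 1), stretched_rg(73.61), tolerance = 1e-12)
  est <- estimate_alpha(6.97, m)
  expect_equal(round(est$alpha, 2), 0.52)
  expect_domain_error(chain_model(20, segment_length = 2, contour_length = 50))
  expect_domain_error(chain_model(20))
  expect_domain_error(chain_model(1, segment_length = 2))
})

test_that("scaling-core functions reject invalid domains", {
  expect_domain_error(stretched_rg(-1))
  expect_domain_error(ideal_chain_rg(0, 1))
  expect_domain_error(ideal_chain_rg(10, 0))
  expect_domain_error(sphere_rg(-0.1))
  expect_domain_error(globule_radius(2, -5))
  expect_domain_error(prefactor_k(0))
  expect_domain_error(rg_from_alpha(-0.5, 20, 1))
  expect_domain_error(rg_from_alpha(0.5, 1, 1))
  expect_domain_error(alpha_from_rg(-1, 73.61, 20))
  expect_domain_error(alpha_from_rg(5, 0, 20))
  expect_domain_error(alpha_from_rg(5, 73.61, 1))
  expect_domain_error(dimensionality(0))
  expect_domain_error(flory_free_energy(-1, 1, 1, 1))
  expect_domain_error(flory_exponent(c(10, 20), 1, 1))
  expect_domain_error(fit_scaling_exponent(c(1, 2), c(1, 2)))
  expect_domain_error(fit_scaling_exponent(c(10, 10, 20), c(1, 2, 3)))
  expect_domain_error(fit_scaling_exponent(c(10, 20, 30), c(1, -2, 3)))
})
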