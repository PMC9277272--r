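#' Generator configuration
#'
#' Common knobs for the synthetic chain generators: chain length, segment
#' length, RNG seed, number of independent samples, and (for the pivot
#' sampler) burn-in and stride. Identical configuration and seed give
#' bit-identical output; per-sample RNG streams are derived from the root
#' seed by fixed increments, so increasing `n_samples` extends an ensemble
#' without reshuffling earlier samples.
#'
#' @param n_segments Number of bonds \eqn{N} (chains have \eqn{N + 1} beads).
#' @param segment_length Bond length \eqn{a} in Angstrom.
#' @param seed Integer RNG seed.
#' @param n_samples Number of independent chains to generate.
#' @param burn_in Pivot steps discarded before sampling (default
#'   \eqn{10 N}).
#' @param stride Pivot steps between retained samples (default \eqn{N}).
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_segments, segment_length = 1, seed = 1L,
                             n_samples = 1L, burn_in = NULL, stride = NULL) {
  n_segments <- check_count(n_segments, "n_segments", min = 1L)
  segment_length <- check_positive(segment_length, "segment_length")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    abort_domain("`seed` must be a single integer")
  n_samples <- check_count(n_samples, "n_samples", min = 1L)
  if (is.null(burn_in)) burn_in <- 10L * n_segments
  if (is.null(stride)) stride <- n_segments
  burn_in <- check_count(burn_in, "burn_in", min = 0L)
  stride <- check_count(stride, "stride", min = 0L)
  structure(
    list(n_segments = n_segments, segment_length = segment_length,
         seed = as.integer(seed), n_samples = n_samples,
         burn_in = burn_in, stride = stride),
    class = "generator_config"
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf(
    "Generator config: N = %d, a = %g A, seed = %d, samples = %d, burn-in = %d, stride = %d\n",
    x$n_segments, x$segment_length, x$seed, x$n_samples, x$burn_in, x$stride))
  invisible(x)
}

check_config <- function(config) {
  if (!inherits(config, "generator_config"))
    abort_domain("`config` must be a generator_config")
  config
}

# Derived per-sample seed; fixed increment keeps earlier samples stable when
# n_samples changes.
sample_seed <- function(root, i) (as.numeric(root) + 104729 * i) %% 2147483647

#' Fully stretched chain
#'
#' \eqn{N + 1} collinear beads spaced `segment_length` along +x. End-to-end
#' distance is exactly \eqn{N a}; the discrete radius of gyration is exactly
#' \eqn{a \sqrt{N (N + 2) / 12}} (slightly above the continuous
#' \eqn{N a / \sqrt{12}}).
#'
#' @param n_segments Number of bonds \eqn{N} (>= 1).
#' @param segment_length Bond length \eqn{a} in Angstrom.
#' @return A [conformation].
#' @examples
#' end_to_end_distance(make_stretched(20, 73.61 / 20)) # 73.61 A
#' @export
make_stretched <- function(n_segments, segment_length) {
  n_segments <- check_count(n_segments, "n_segments", min = 1L)
  segment_length <- check_positive(segment_length, "segment_length")
  conformation(cbind((0:n_segments) * segment_length, 0, 0))
}

# n random unit vectors, rows.
runif_sphere <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Freely jointed chain ensemble
#'
#' Each chain has \eqn{N} bonds of exact length \eqn{a} with independent
#' uniformly distributed orientations. Ensemble means converge to
#' \eqn{\langle R_{ee}^2 \rangle = N a^2} and
#' \eqn{\langle R_g^2 \rangle = N a^2 / 6} for large \eqn{N} and sample
#' counts.
#'
#' @param config A [generator_config].
#' @return A [structure_ensemble] of kind `"sample_set"`.
#' @export
make_fjc <- function(config) {
  config <- check_config(config)
  n <- config$n_segments
  a <- config$segment_length
  with_seed(config$seed, {
    members <- lapply(seq_len(config$n_samples), function(i) {
      set.seed(sample_seed(config$seed, i))
      steps <- a * runif_sphere(n)
      conformation(rbind(c(0, 0, 0), apply(steps, 2L, cumsum)))
    })
    structure_ensemble(members, kind = "sample_set")
  })
}

# The 48 signed-permutation matrices of the octahedral group; element 1 is
# the identity, so pivots draw from indices 2..48.
octahedral_group <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  out <- vector("list", 48L)
  k <- 0L
  for (p in perms) for (s in seq_len(nrow(signs))) {
    m <- matrix(0, 3L, 3L)
    for (j in 1:3) m[j, p[j]] <- signs[s, j]
    k <- k + 1L
    out[[k]] <- m
  }
  ident <- vapply(out, function(m) all(m == diag(3)), logical(1))
  c(out[ident], out[!ident])
})

# Integer site keys for duplicate detection; `sites` is 3 x n_beads and
# coordinates stay within [-N, N] because the first bead is pinned at the
# origin.
site_keys <- function(sites, n) {
  m <- 2 * n + 1
  (sites[1L, ] + n) + m * ((sites[2L, ] + n) + m * (sites[3L, ] + n))
}

#' Self-avoiding walk ensemble (pivot algorithm)
#'
#' Samples self-avoiding walks of \eqn{N} steps on the simple cubic lattice
#' by the pivot algorithm: starting from a straight rod, a random lattice
#' symmetry (one of the 47 non-identity octahedral symmetries) is applied to
#' the chain suffix beyond a random pivot site, and the proposal is rejected
#' if any two beads coincide. Every `stride`-th state after `burn_in` steps
#' is retained, and coordinates are scaled by `segment_length` on output.
#' Mean sizes of the retained ensembles scale as \eqn{R_g \sim N^{\nu}} with
#' \eqn{\nu \approx 0.588} (excluded-volume exponent).
#'
#' @param config A [generator_config]; `n_segments` >= 2.
#' @return A [structure_ensemble] of kind `"sample_set"`; every member
#'   visits distinct lattice sites.
#' @export
make_saw <- function(config) {
  config <- check_config(config)
  n <- config$n_segments
  if (n < 2L) abort_domain("self-avoiding walks need `n_segments` >= 2")
  a <- config$segment_length
  group <- octahedral_group
  with_seed(config$seed, {
    sites <- rbind(0:n, 0L, 0L)           # 3 x (n + 1), beads as columns
    keys <- site_keys(sites, n)
    members <- vector("list", config$n_samples)
    collected <- 0L
    step <- 0L
    stride <- max(1L, config$stride)
    total_needed <- config$burn_in + config$n_samples * stride
    repeat {
      step <- step + 1L
      p <- sample.int(n, 1L)              # pivot about bead p (1-based)
      g <- group[[sample.int(47L, 1L) + 1L]]
      idx <- (p + 1L):(n + 1L)
      pivot <- sites[, p]
      suffix <- g %*% (sites[, idx, drop = FALSE] - pivot) + pivot
      cand_keys <- keys
      cand_keys[idx] <- site_keys(suffix, n)
      if (anyDuplicated(cand_keys) == 0L) {
        sites[, idx] <- suffix
        keys <- cand_keys
      }
      if (step > config$burn_in && (step - config$burn_in) %% stride == 0L) {
        collected <- collected + 1L
        members[[collected]] <- conformation(t(sites) * a)
        if (collected == config$n_samples) break
      }
      if (step > 100L * total_needed + 1000L)
        abort_numeric("pivot sampler failed to collect the requested samples")
    }
    structure_ensemble(members, kind = "sample_set")
  })
}

# Deterministic spherical space-filling spiral used as the globule fallback.
# Beads are laid along band-limited spherical spirals on concentric shells
# (spacing `gap`), stepping exactly `a` along the curve by root-finding, and
# each candidate must clear the 0.8 a non-bonded separation before it is
# accepted; candidates that fail are skipped and the scan continues along
# the spiral (and onto the next shell).
globule_spiral <- function(n_beads, a, r_max, gap = 0.85, phi_band = 0.40) {
  gap <- gap * a
  radii <- seq(gap, r_max, by = gap)
  if (length(radii) == 0L)
    abort_numeric("confinement sphere too small for the spiral fallback")
  spiral_point <- function(r, n_turns, phi) {
    theta <- 2 * n_turns * phi
    r * c(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  }
  coords <- matrix(NA_real_, n_beads, 3L)
  placed <- 0L
  prev <- NULL
  forward <- TRUE
  for (r in radii) {
    n_turns <- max(1L, floor(pi * r / gap))
    phis <- seq(phi_band, pi - phi_band, length.out = max(200L, 40L * n_turns))
    # alternate sweep direction so the hop from the previous shell lands near
    # the start of this shell's scan
    if (!forward) phis <- rev(phis)
    forward <- !forward
    start_j <- 1L
    if (is.null(prev)) {               # first bead: start of this shell's spiral
      placed <- 1L
      coords[1L, ] <- spiral_point(r, n_turns, phis[1L])
      prev <- coords[1L, ]
      start_j <- 2L
    }
    dist_prev <- function(phi) sqrt(sum((spiral_point(r, n_turns, phi) - prev)^2)) - a
    j <- start_j
    d_last <- dist_prev(phis[max(1L, j - 1L)])
    while (j <= length(phis) && placed < n_beads) {
      d_here <- dist_prev(phis[j])
      if (d_last < 0 && d_here >= 0) {
        root <- stats::uniroot(dist_prev, sort(c(phis[j - 1L], phis[j])),
                               tol = 1e-13)$root
        cand <- spiral_point(r, n_turns, root)
        ok <- TRUE
        if (placed > 1L) {
          others <- coords[seq_len(placed - 1L), , drop = FALSE]
          ok <- min(sqrt(rowSums(sweep(others, 2L, cand)^2))) >= 0.8 * a - 1e-9
        }
        if (ok) {
          placed <- placed + 1L
          coords[placed, ] <- cand
          prev <- cand
          d_here <- dist_prev(phis[j])  # distance target moved
        }
      }
      d_last <- d_here
      j <- j + 1L
    }
    if (placed >= n_beads) break
  }
  if (placed < n_beads)
    abort_numeric("spiral fallback could not place all beads inside the confinement sphere")
  coords
}

# One stochastic globule chain; returns NULL when the attempt budget is
# exhausted.
globule_chain_attempt <- function(n_beads, a, r_max, max_attempts) {
  coords <- matrix(NA_real_, n_beads, 3L)
  coords[1L, ] <- c(0, 0, 0)
  i <- 2L
  attempts <- 0L
  while (i <= n_beads) {
    placed_ok <- FALSE
    for (try in seq_len(40L)) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) return(NULL)
      cand <- coords[i - 1L, ] + a * runif_sphere(1L)[1L, ]
      if (sum(cand^2) > r_max^2) next
      if (i > 2L) {
        others <- coords[seq_len(i - 2L), , drop = FALSE]
        if (min(rowSums(sweep(others, 2L, cand)^2)) < (0.8 * a)^2) next
      }
      coords[i, ] <- cand
      placed_ok <- TRUE
      break
    }
    if (placed_ok) {
      i <- i + 1L
    } else {
      i <- max(2L, i - 5L)  # backtrack and retry from an earlier bead
    }
  }
  coords
}

#' Compact globule ensemble
#'
#' Sequentially grows chains with exact bond length \eqn{a}, a minimum
#' non-bonded separation of \eqn{0.8 a}, confined to a sphere of radius
#' \eqn{1.1 \times} [globule_radius()] (with \eqn{v = a^3}) centred on the
#' first bead. Placement retries with backtracking; if the stochastic search
#' exhausts its attempt budget the chain falls back to a deterministic
#' spherical space-filling spiral satisfying the same constraints. Across
#' chain lengths the ensemble-mean \eqn{R_g} scales with an exponent close
#' to the compact value 1/3.
#'
#' @param config A [generator_config]; `n_segments` >= 2.
#' @return A [structure_ensemble] of kind `"sample_set"`.
#' @export
make_globule <- function(config) {
  config <- check_config(config)
  n <- config$n_segments
  if (n < 2L) abort_domain("globules need `n_segments` >= 2")
  a <- config$segment_length
  r_max <- 1.1 * globule_radius(n, a^3)
  with_seed(config$seed, {
    members <- lapply(seq_len(config$n_samples), function(i) {
      set.seed(sample_seed(config$seed, i))
      coords <- globule_chain_attempt(n + 1L, a, r_max, max_attempts = 400L * n)
      if (is.null(coords)) coords <- globule_spiral(n + 1L, a, r_max)
      conformation(coords)
    })
    structure_ensemble(members, kind = "sample_set")
  })
}

#' Scaling-exponent schedule for a synthetic folding trajectory
#'
#' Prescribes the per-frame scaling exponent \eqn{\alpha(t)} that a
#' synthetic folding trajectory should follow; folding sweeps
#' \eqn{\alpha} from 1 (stretched) down towards 1/3 (globule).
#'
#' @param frame_times Non-decreasing frame times in ps.
#' @param alpha_values Exponents in (0, 1.25], same length.
#' @return An `alpha_schedule` object.
#' @export
alpha_schedule <- function(frame_times, alpha_values) {
  if (length(frame_times) != length(alpha_values))
    abort_domain("`frame_times` and `alpha_values` must have the same length")
  if (length(frame_times) < 1L) abort_domain("schedule must not be empty")
  if (any(!is.finite(frame_times)) || any(diff(frame_times) < 0))
    abort_domain("`frame_times` must be finite and non-decreasing")
  if (any(!is.finite(alpha_values)) || any(alpha_values <= 0) ||
      any(alpha_values > 1.25))
    abort_domain("`alpha_values` must lie in (0, 1.25]")
  structure(list(frame_times = as.numeric(frame_times),
                 alpha_values = as.numeric(alpha_values)),
            class = "alpha_schedule")
}

# Rotate beads strictly between i and k about the i--k axis by `angle`
# (Rodrigues formula); degenerate axes are left untouched.
crankshaft <- function(xyz, i, k, angle) {
  axis <- xyz[k, ] - xyz[i, ]
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) return(xyz)
  u <- axis / nrm
  idx <- (i + 1L):(k - 1L)
  rel <- sweep(xyz[idx, , drop = FALSE], 2L, xyz[i, ])
  cosA <- cos(angle)
  sinA <- sin(angle)
  dot <- as.numeric(rel %*% u)
  crossu <- cbind(u[2] * rel[, 3] - u[3] * rel[, 2],
                  u[3] * rel[, 1] - u[1] * rel[, 3],
                  u[1] * rel[, 2] - u[2] * rel[, 1])
  rot <- rel * cosA + crossu * sinA + outer(dot, u) * (1 - cosA)
  xyz[idx, ] <- sweep(rot, 2L, xyz[i, ], "+")
  xyz
}

#' Synthetic folding trajectory following an alpha schedule
#'
#' Builds a trajectory whose per-frame radius of gyration follows a
#' prescribed exponent schedule: each frame applies seeded random crankshaft
#' perturbations (plus a small Gaussian jitter, sigma = 0.02 a, which lets
#' the crankshaft moves act on the initially collinear chain) to the
#' previous frame and then rescales radially about the centroid so the frame
#' \eqn{R_g} equals [rg_from_alpha()] at the scheduled \eqn{\alpha}. The
#' rescaling does not preserve bond lengths; only \eqn{R_g} feeds the
#' exponent estimator, so the trajectory is a faithful test signal for it.
#'
#' @param config A [generator_config]; `n_segments` >= 2.
#' @param schedule An [alpha_schedule].
#' @return A [structure_ensemble] of kind `"trajectory"`, one frame per
#'   schedule point with `frame_time` copied from the schedule.
#' @examples
#' cfg <- generator_config(20, 73.61 / 20, seed = 7)
#' sched <- alpha_schedule(0:9, seq(1, 1 / 3, length.out = 10))
#' traj <- make_folding_trajectory(cfg, sched)
#' @export
make_folding_trajectory <- function(config, schedule) {
  config <- check_config(config)
  if (!inherits(schedule, "alpha_schedule"))
    abort_domain("`schedule` must be an alpha_schedule")
  n <- config$n_segments
  if (n < 2L) abort_domain("folding trajectories need `n_segments` >= 2")
  a <- config$segment_length
  xyz <- as.matrix(make_stretched(n, a))
  nb <- n + 1L
  with_seed(config$seed, {
    frames <- vector("list", length(schedule$alpha_values))
    for (j in seq_along(frames)) {
      set.seed(sample_seed(config$seed, j))
      xyz <- xyz + matrix(stats::rnorm(nb * 3L, sd = 0.02 * a), nb, 3L)
      for (m in seq_len(max(10L, n %/% 2L))) {
        ik <- sort(sample.int(nb, 2L))
        if (diff(ik) < 2L) next
        xyz <- crankshaft(xyz, ik[1L], ik[2L], stats::runif(1, -pi, pi))
      }
      ctr <- colMeans(xyz)
      target <- rg_from_alpha(schedule$alpha_values[j], n, a)
      cur <- sqrt(mean(rowSums(sweep(xyz, 2L, ctr)^2)))
      xyz <- sweep(sweep(xyz, 2L, ctr) * (target / cur), 2L, ctr, "+")
      frames[[j]] <- conformation(xyz, time = schedule$frame_times[j])
    }
    structure_ensemble(frames, kind = "trajectory")
  })
}
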