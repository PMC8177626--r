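# Deterministic synthetic-data generators.
#
# These build the known-truth inputs used by the test-suite oracles: a random
# stable linear system (for identification round trips), rotation-vector
# clouds with controlled torsional scatter (for plane-fit recovery),
# analytic triangular-velocity saccades (for metric identities), and the
# bundled plant configuration.

#' Random stable discrete linear system
#'
#' Draws a random `order`-state, 3-input, 3-output discrete system with the
#' requested spectral radius; used as ground truth for identification tests.
#'
#' @param seed integer seed.
#' @param order state dimension.
#' @param spectral_radius target spectral radius of `A` (< 1: stable).
#' @param feedthrough scale of the direct `E` term (0 for none).
#' @return an `ss_model` (with zero initial state).
#' @export
make_linear_system <- function(seed = 1, order = 6, spectral_radius = 0.85,
                               feedthrough = 0.05) {
  set.seed(substream_seed(seed, "linear-system"))
  A <- matrix(rnorm(order^2), order)
  A <- A * (spectral_radius / max(Mod(eigen(A, only.values = TRUE)$values)))
  fit <- list(A = A,
              B = matrix(rnorm(order * 3, sd = 0.5), order, 3),
              C = matrix(rnorm(3 * order, sd = 0.5), 3, order),
              E = matrix(rnorm(9, sd = feedthrough), 3, 3),
              x0 = numeric(order), dt = 0.01, order = order,
              method = "synthetic")
  class(fit) <- "ss_model"
  fit
}

#' Rotation-vector cloud with controlled torsional scatter
#'
#' Samples orientations on a plane `rx = a ry + b rz` (normal proportional
#' to `(1, -a, -b)`) plus Gaussian torsional noise of the requested standard
#' deviation; the known-truth input for plane-fit recovery tests.
#'
#' @param n number of points.
#' @param normal plane normal (any scale).
#' @param sd_torsion torsional scatter SD, half-radians.
#' @param range_deg horizontal/vertical extent (uniform), degrees.
#' @param seed integer seed.
#' @return n x 3 matrix of rotation vectors (columns rx, ry, rz).
#' @export
make_rotvec_cloud <- function(n = 2000, normal = c(1, 0, 0),
                              sd_torsion = 0.015, range_deg = 40, seed = 1) {
  stopifnot(abs(normal[1]) > 1e-6)
  set.seed(substream_seed(seed, "rotvec-cloud"))
  a <- -normal[2] / normal[1]
  b <- -normal[3] / normal[1]
  ry <- deg_to_hr(runif(n, -range_deg, range_deg))
  rz <- deg_to_hr(runif(n, -range_deg, range_deg))
  rx <- a * ry + b * rz + rnorm(n, sd = sd_torsion)
  cbind(rx = rx, ry = ry, rz = rz)
}

#' Analytic triangular-velocity saccades
#'
#' Generates single-axis saccades whose speed profile is an exact triangle
#' (so that `Vpk * D = 2 * amplitude` holds identically), sampled at the
#' control tick; known truth for the main-sequence and amplitude-relation
#' metrics.
#'
#' @param amplitudes_deg vector of amplitudes, degrees.
#' @param vpk_deg_s peak speeds, deg/s (recycled).
#' @param direction unit 3-vector rotation axis (default horizontal).
#' @param dt tick, s.
#' @return list of `eye_trajectory`-like data frames with attribute
#'   `D_ms` (the triangle base) on each.
#' @export
make_triangular_saccades <- function(amplitudes_deg = c(5, 10, 20, 30),
                                     vpk_deg_s = 400,
                                     direction = c(0, 0, 1), dt = 0.01) {
  direction <- direction / sqrt(sum(direction^2))
  vpk <- rep_len(vpk_deg_s, length(amplitudes_deg))
  lapply(seq_along(amplitudes_deg), function(i) {
    A <- amplitudes_deg[i]
    D <- 2 * A / vpk[i]                      # triangle base, s
    nD <- max(2, round(D / dt))
    tt <- seq(0, nD) * dt
    spd <- vpk[i] * (1 - abs(2 * tt / (nD * dt) - 1))   # deg/s, triangle
    ang <- cumsum(c(0, (spd[-1] + spd[-length(spd)]) / 2 * dt))  # deg
    ang <- ang * A / max(ang)
    r <- t(sapply(ang, function(a) tan(a * pi / 360) * direction))
    w <- spd * pi / 180                      # rad/s along the fixed axis
    traj <- data.frame(t = tt, rx = r[, 1], ry = r[, 2], rz = r[, 3],
                       wx = w * direction[1], wy = w * direction[2],
                       wz = w * direction[3],
                       u1 = NA_real_, u2 = NA_real_, u3 = NA_real_)
    attr(traj, "dt") <- dt
    attr(traj, "D_ms") <- nD * dt * 1e3
    class(traj) <- c("eye_trajectory", "data.frame")
    traj
  })
}

#' Saccade-like tanh position traces
#'
#' Smooth single-axis saccades with `sech^2` velocity profiles at
#' main-sequence-realistic durations, used to assess the size of the
#' gyroscopic term: position steps `A/2 * (1 + tanh((t - t0)/tau))` with
#' `tau = A / (2 Vpk)` and `Vpk` from a saturating main sequence.
#'
#' @param amplitudes_deg amplitudes, degrees.
#' @param v0,alpha main-sequence parameters (deg/s, deg): `Vpk = v0 (1 -
#'   exp(-A/alpha))`.
#' @param axis unit rotation axis.
#' @param window_s half-width of the simulated window around the saccade, s.
#' @param dt sample step, s.
#' @return list of data frames with columns `t, theta_deg, omega, alpha_vec`
#'   (angular velocity and acceleration 3-vectors, rad/s and rad/s^2).
#' @export
make_tanh_saccades <- function(amplitudes_deg = seq(2, 60, by = 2),
                               v0 = 600, alpha = 20, axis = c(0, 0, 1),
                               window_s = 0.15, dt = 1e-3) {
  axis <- axis / sqrt(sum(axis^2))
  lapply(amplitudes_deg, function(A) {
    vpk <- v0 * (1 - exp(-A / alpha))                 # deg/s
    tau <- A / (2 * vpk)                              # s
    tt <- seq(-window_s, window_s, by = dt)
    th <- A / 2 * (1 + tanh(tt / tau))                # deg
    spd <- (A / (2 * tau)) * sech2(tt / tau)          # deg/s
    acc <- -(A / tau^2) * sech2(tt / tau) * tanh(tt / tau)  # deg/s^2
    w <- outer(spd * pi / 180, axis)
    al <- outer(acc * pi / 180, axis)
    data.frame(t = tt, theta_deg = th,
               wx = w[, 1], wy = w[, 2], wz = w[, 3],
               ax = al[, 1], ay = al[, 2], az = al[, 3])
  })
}

sech2 <- function(x) 1 / cosh(x)^2

#' Write the bundled fixture files
#'
#' Regenerates the plain-text fixtures shipped with the package (currently
#' the default plant configuration).
#'
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
make_fixtures <- function(dir = ".") {
  p <- file.path(dir, "table1.yaml")
  write_plant_config(eye_plant(), p)
  invisible(p)
}
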