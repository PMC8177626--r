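# Discrete-time forward simulation of the nonlinear plant.
#
# The control/sampling tick is plant$dt (10 ms by default); each tick is
# integrated with plant$substeps semi-implicit inner substeps during which
# the inertia tensor is frozen per substep and the muscle geometry refreshed.
# A pure-R single-tick reference (plant_step) mirrors the compiled core and
# serves as its cross-check in the test suite.

#' Eye state
#'
#' A plant state is the pair (orientation, angular velocity); motor commands
#' are supplied separately.
#'
#' @param q unit quaternion orientation.
#' @param omega angular velocity, rad/s.
#' @export
eye_state <- function(q = quat(1, c(0, 0, 0)), omega = c(0, 0, 0)) {
  structure(list(q = quat(q), omega = as.numeric(omega)), class = "eye_state")
}

#' Advance the plant by one control tick (reference implementation)
#'
#' Pure-R mirror of the compiled integrator, advancing one tick of
#' `plant$dt` seconds with the motor command held constant.  Used as the
#' readable reference and numerical cross-check; use [simulate_plant()] for
#' anything longer than a few ticks.
#'
#' @param state an [eye_state()].
#' @param u motor command, rad (3-vector).
#' @param plant an [eye_plant()].
#' @param gyroscopic include the gyroscopic torque term?
#' @return the new [eye_state()].
#' @export
plant_step <- function(state, u, plant, gyroscopic = FALSE) {
  h <- plant$dt / plant$substeps
  q <- state$q; w <- state$omega
  P <- driver_insertions(u, plant)
  for (s in seq_len(plant$substeps)) {
    R <- quat_to_matrix(q)
    tel <- c(0, 0, 0)
    for (i in 1:6) {
      Qi <- drop(R %*% plant$Q0[, i])
      anchor <- if (plant$has_via[i]) plant$X[, i] else P[, i]
      seg1 <- anchor - Qi
      n1 <- sqrt(sum(seg1^2))
      len <- n1 + if (plant$has_via[i]) sqrt(sum((P[, i] - plant$X[, i])^2)) else 0
      mag <- plant$kappa[i] * max(len - plant$l0[i], 0)
      tel <- tel + cross3(Qi, (mag / n1) * seg1)
    }
    tdyn <- -plant$chi_dyn * w
    tcomp <- tel + tdyn
    if (sqrt(sum(w^2)) < plant$eps_stat &&
        sqrt(sum(tcomp^2)) < plant$chi_stat) {
      w <- c(0, 0, 0)
      next
    }
    Iw <- R %*% plant$I0 %*% t(R)
    tau <- tcomp
    if (gyroscopic) tau <- tau - cross3(w, drop(Iw %*% w))
    alpha <- drop(solve(Iw, tau))
    w <- w + h * alpha
    q <- quat(q + h * quat_rate(q, w))
    if (sqrt(sum(w^2)) > 1e3)
      stop("simulation unstable: |omega| > 1e3 rad/s")
  }
  eye_state(q, w)
}

#' Simulate the nonlinear plant over an input series
#'
#' Plays a motor-command series sampled at the control tick through the
#' compiled plant integrator.  Deterministic given `(U, state0, plant)`.
#'
#' @param plant an [eye_plant()].
#' @param U input series: n x 3 matrix of motor commands (rad), one row per
#'   tick, or a length-3 vector (a single tick).
#' @param state0 initial [eye_state()].
#' @param gyroscopic include the gyroscopic torque term?
#' @return an `eye_trajectory`: data frame with columns `t, rx, ry, rz, wx,
#'   wy, wz, u1, u2, u3` (n + 1 rows; inputs are NA on the final row) and the
#'   quaternion series in `attr(, "q")`.
#' @export
simulate_plant <- function(plant, U, state0 = eye_state(), gyroscopic = FALSE) {
  if (is.null(dim(U))) U <- matrix(U, ncol = 3)
  U <- as.matrix(U)
  stopifnot(ncol(U) == 3L)
  out <- cpp_simulate(plant_pack(plant), U, state0$q, state0$omega, gyroscopic)
  n <- nrow(U)
  traj <- data.frame(
    t = seq(0, n) * plant$dt,
    rx = out$r[, 1], ry = out$r[, 2], rz = out$r[, 3],
    wx = out$omega[, 1], wy = out$omega[, 2], wz = out$omega[, 3],
    u1 = c(U[, 1], NA), u2 = c(U[, 2], NA), u3 = c(U[, 3], NA))
  attr(traj, "q") <- out$q
  attr(traj, "dt") <- plant$dt
  class(traj) <- c("eye_trajectory", "data.frame")
  traj
}

#' @export
print.eye_trajectory <- function(x, ...) {
  cat(sprintf("eye trajectory: %d ticks of %g ms\n",
              nrow(x) - 1L, attr(x, "dt") * 1e3))
  print.data.frame(head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}

#' Final state of a simulated trajectory
#' @param traj an `eye_trajectory`.
#' @export
final_state <- function(traj) {
  q <- attr(traj, "q")[nrow(traj), ]
  eye_state(q, as.numeric(traj[nrow(traj), c("wx", "wy", "wz")]))
}

#' Settle the plant under a constant motor command
#'
#' Holds `u` until the speed stays below `tol_deg_s` for `hold_ms`
#' milliseconds, or until timeout.
#'
#' @param plant an [eye_plant()].
#' @param u motor command, rad.
#' @param state0 initial [eye_state()].
#' @param tol_deg_s settling speed threshold, deg/s.
#' @param hold_ms time the speed must stay below threshold, ms.
#' @param timeout_s giving-up time, s.
#' @return list with `state` (an [eye_state()]), `r` (settled rotation
#'   vector), `settled` (logical), `t` (simulated time, s) and `tension`
#'   (total static tendon tension, N).
#' @export
settle_plant <- function(plant, u, state0 = eye_state(), tol_deg_s = 0.5,
                         hold_ms = 100, timeout_s = 5) {
  out <- cpp_settle(plant_pack(plant), u, state0$q, state0$omega,
                    tol = tol_deg_s * pi / 180, hold_s = hold_ms / 1e3,
                    timeout_s = timeout_s)
  list(state = eye_state(out$q, drop(out$omega)), r = drop(out$r),
       settled = as.logical(out$settled), t = out$t, tension = out$tension)
}

#' Static motor-to-orientation map over a command grid
#'
#' Settles the plant at every combination of `n_per_axis` motor angles per
#' axis spanning `[-u_range_deg, +u_range_deg]`, and returns the settled
#' orientations: the model's attainable oculomotor range.  The grid is
#' traversed in a snake order with warm starts (each settle starts from the
#' previous settled state), which is much faster than settling each
#' combination from rest and lands on the same equilibria for this
#' overdamped plant.
#'
#' @param plant an [eye_plant()].
#' @param n_per_axis grid points per motor axis (>= 1).
#' @param u_range_deg half-range of motor angles, degrees.
#' @param warm warm-start each settle from the previous one?
#' @param tol_deg_s,timeout_s settling controls (see [settle_plant()]).
#' @return data frame with motor commands (`u1, u2, u3`, rad), settled
#'   orientation (`rx, ry, rz`, half-radians), total tension (N) and a
#'   `settled` flag.
#' @export
motor_range_grid <- function(plant, n_per_axis = 7, u_range_deg = 35,
                             warm = TRUE, tol_deg_s = 0.5, timeout_s = 5) {
  stopifnot(n_per_axis >= 1)
  u1 <- if (n_per_axis == 1) 0 else
    seq(-u_range_deg, u_range_deg, length.out = n_per_axis) * pi / 180
  grid <- expand.grid(u1 = u1, u2 = u1, u3 = u1, KEEP.OUT.ATTRS = FALSE)
  # snake ordering: reverse alternate runs of the fastest-varying axis so
  # consecutive grid points are neighbours (warm starts stay warm)
  n <- n_per_axis
  idx <- seq_len(nrow(grid))
  if (n > 1) {
    blk <- matrix(idx, nrow = n)          # columns: runs of u1
    for (j in seq_len(ncol(blk))) {
      lvl2 <- ((j - 1) %% n) + 1          # u2 level of this run
      lvl3 <- ((j - 1) %/% n) + 1         # u3 level
      flip <- (lvl2 + lvl3) %% 2 == 0
      if (flip) blk[, j] <- rev(blk[, j])
    }
    idx <- as.vector(blk)
  }
  grid <- grid[idx, , drop = FALSE]
  out <- cpp_settle_grid(plant_pack(plant), as.matrix(grid),
                         tol = tol_deg_s * pi / 180, hold_s = 0.1,
                         timeout_s = timeout_s, warm = warm)
  res <- cbind(grid,
               rx = out$r[, 1], ry = out$r[, 2], rz = out$r[, 3],
               tension = drop(out$tension),
               settled = as.logical(drop(out$settled)))
  rownames(res) <- NULL
  if (!all(res$settled))
    warning(sprintf("%d of %d grid combinations did not settle",
                    sum(!res$settled), nrow(res)))
  res
}

#' Trajectory CSV input/output
#'
#' Writes/reads the plain-text trajectory schema
#' (`t, rx, ry, rz, wx, wy, wz, u1, u2, u3`).
#'
#' @param traj an `eye_trajectory` (or compatible data frame).
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj)[, c("t", "rx", "ry", "rz",
                                    "wx", "wy", "wz", "u1", "u2", "u3")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param dt tick length (s) to attach when reading.
#' @export
read_trajectory <- function(path, dt = 0.01) {
  traj <- read.csv(path)
  attr(traj, "dt") <- dt
  class(traj) <- c("eye_trajectory", "data.frame")
  traj
}
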