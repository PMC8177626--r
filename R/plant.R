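# The mechanical eye plant: a rigid globe driven by six elastic tendons
# ("muscles") actuated in antagonistic pairs by three motor drivers.
#
# Geometry convention: eye-centered head-fixed frame, coordinates in cm in
# user-facing configuration (matching the published insertion-point table for
# the scaled robotic prototype), converted to SI meters internally.  Each
# antagonistic pair is attached to the two ends of a rigid rod fixed to one
# motor; rotating motor k by u_k (rad) moves the two cranial attachment
# points in opposite directions along a circle of radius half the rod length.

# Default muscle geometry (cm): globe insertion Q0, optional craniocentric
# via point X ("pulley"; the horizontal recti attach directly), cranial rod
# end-insertion P0 at rest, and the motor driver each pair belongs to.
default_muscle_table <- function() {
  list(
    MR = list(Q0 = c(-0.7,  7.5,   0.0), X = NULL,
              P0 = c(-32.3, 14.0,  0.5), driver = 2L),
    LR = list(Q0 = c(-0.7, -7.5,   0.0), X = NULL,
              P0 = c(-32.3, -14.0, 0.5), driver = 2L),
    SR = list(Q0 = c(-0.7,  0.53,  5.3), X = c(-20.6, -7.5, -5.3),
              P0 = c(-43.6, -8.4, -7.9), driver = 1L),
    IR = list(Q0 = c(-0.7,  0.53, -5.3), X = c(-20.6, -7.5,  5.3),
              P0 = c(-43.6, -8.4, 12.1), driver = 1L),
    SO = list(Q0 = c(-0.7, -0.53,  5.3), X = c(-15.0, 15.0,  6.3),
              P0 = c(-43.6,  8.4, 12.1), driver = 3L),
    IO = list(Q0 = c(-0.7, -0.53, -5.3), X = c(-15.0, 15.0, -6.3),
              P0 = c(-43.6,  8.4, -7.9), driver = 3L))
}

# Moment-of-inertia tensor of the prototype eye (kg m^2), primary frame.
default_inertia <- function() {
  matrix(c(4.759, -0.010, 0.111,
           -0.010, 4.316, 0.000,
           0.111,  0.000, 3.956), nrow = 3, byrow = TRUE) * 1e-4
}

#' Construct the tendon-driven eye plant
#'
#' Builds the full mechanical description of the model eye: six elastic
#' tendons with the default insertion-point geometry of the scaled robotic
#' prototype (7 cm globe radius), linear elasticity, dynamic (viscous) and
#' static friction, and an orientation-dependent inertia tensor.  Tendon rest
#' lengths are not part of the published geometry; they default to
#' `(1 - pretension)` times the path length in the straight-ahead rest pose,
#' so that all tendons are taut at rest and, by the near-symmetry of the
#' geometry, the straight-ahead orientation is (close to) an equilibrium.
#'
#' @param dz common vertical (z) shift of all cranial insertion points, cm;
#'   used to study asymmetric muscle arrangements.  Via points co-move by
#'   default (`via_comove`).
#' @param pretension fractional tendon stretch at the rest pose (dimensionless).
#' @param kappa tendon elasticity, N/m (same for all six).
#' @param chi_dyn dynamic (viscous) friction coefficient, N m s/rad.
#' @param chi_stat static friction torque bound, N m.
#' @param eps_stat static-friction velocity cutoff, rad/s.
#' @param dt control/sampling tick, s.
#' @param substeps inner integration substeps per tick.
#' @param via_comove should via points shift along with `dz`?
#' @param muscles optional replacement muscle table (same structure as the
#'   default; coordinates in cm).
#' @param I0 optional 3x3 inertia tensor, kg m^2 (symmetric positive definite).
#' @return an object of class `eye_plant`.
#' @examples
#' pl <- eye_plant()
#' rest_torque_table(pl)
#' @export
eye_plant <- function(dz = 0, pretension = 0.05, kappa = 6.0,
                      chi_dyn = 0.02, chi_stat = 0.006, eps_stat = 0.01,
                      dt = 0.01, substeps = 10L, via_comove = TRUE,
                      muscles = NULL, I0 = NULL) {
  mus <- if (is.null(muscles)) default_muscle_table() else muscles
  stopifnot(length(mus) == 6L, !is.null(names(mus)))
  I0 <- if (is.null(I0)) default_inertia() else I0
  stopifnot(isTRUE(all.equal(I0, t(I0), tolerance = 1e-8)),
            all(eigen(I0, symmetric = TRUE, only.values = TRUE)$values > 0))

  # apply the vertical shift (cm) to cranial geometry
  for (nm in names(mus)) {
    mus[[nm]]$P0[3] <- mus[[nm]]$P0[3] + dz
    if (via_comove && !is.null(mus[[nm]]$X))
      mus[[nm]]$X[3] <- mus[[nm]]$X[3] + dz
  }

  nm <- names(mus)
  cm <- 1e-2
  Q0 <- sapply(mus, function(m) m$Q0) * cm            # 3 x 6, meters
  P0 <- sapply(mus, function(m) m$P0) * cm
  has_via <- vapply(mus, function(m) !is.null(m$X), logical(1))
  X <- sapply(mus, function(m) if (is.null(m$X)) rep(NA_real_, 3) else m$X * cm)
  driver <- vapply(mus, function(m) as.integer(m$driver), integer(1))

  # rod geometry: each driver's two muscles attach to the ends of one rod
  rod_center <- sapply(1:3, function(k) rowMeans(P0[, driver == k, drop = FALSE]))
  rod_offset <- P0 - rod_center[, driver]
  # rotation axes: the rod for the horizontal recti lies along y and turns
  # about z; the vertical-rectus and oblique rods lie along z and turn about y
  rod_axis <- cbind(c(0, 1, 0), c(0, 0, 1), c(0, 1, 0))
  # senses chosen so that u1 > 0 moves the SR end toward +x, u2 > 0 rotates
  # the eye leftward (+z), u3 > 0 moves the SO end toward +x
  rod_sense <- c(-1, 1, 1)

  pl <- structure(list(
    muscle_names = nm, Q0 = Q0, P0 = P0, X = X, has_via = has_via,
    driver = driver, rod_center = rod_center, rod_offset = rod_offset,
    rod_axis = rod_axis, rod_sense = rod_sense,
    kappa = rep(kappa, length.out = 6L), l0 = rep(NA_real_, 6L),
    pretension = pretension, chi_dyn = chi_dyn, chi_stat = chi_stat,
    eps_stat = eps_stat, dt = dt, substeps = as.integer(substeps),
    I0 = I0, dz = dz, via_comove = via_comove, eye_radius_cm = 7,
    table_cm = mus), class = "eye_plant")

  rest <- muscle_lengths(quat(1, c(0, 0, 0)), c(0, 0, 0), pl)
  pl$l0 <- (1 - pretension) * rest
  pl
}

#' @export
print.eye_plant <- function(x, ...) {
  cat("Tendon-driven eye plant\n")
  cat(sprintf("  muscles: %s\n", paste(x$muscle_names, collapse = " ")))
  cat(sprintf("  kappa = %.2f N/m, pretension = %.3f, dz = %+.1f cm\n",
              x$kappa[1], x$pretension, x$dz))
  cat(sprintf("  chi_dyn = %.3f N m s/rad, chi_stat = %.4f N m, dt = %g ms (%d substeps)\n",
              x$chi_dyn, x$chi_stat, x$dt * 1e3, x$substeps))
  invisible(x)
}

#' Cranial insertion points for a motor command
#'
#' Rotating motor k by `u[k]` (rad) turns its rod about the motor axis, moving
#' the pair's two cranial attachment points in opposite directions (the
#' vertical-rectus and oblique rods move in x and z; the horizontal-rectus
#' rod moves in x and y).
#'
#' @param u motor command, 3-vector in radians (`|u| <= pi/2` per axis).
#' @param plant an [eye_plant()].
#' @return 3 x 6 matrix of cranial insertion points, meters, columns named by
#'   muscle.
#' @export
driver_insertions <- function(u, plant) {
  stopifnot(length(u) == 3L, all(abs(u) <= pi / 2 + 1e-12))
  P <- matrix(NA_real_, 3, 6, dimnames = list(NULL, plant$muscle_names))
  for (i in 1:6) {
    k <- plant$driver[i]
    R <- axis_angle_matrix(plant$rod_axis[, k], plant$rod_sense[k] * u[k])
    P[, i] <- plant$rod_center[, k] + R %*% plant$rod_offset[, i]
  }
  P
}

#' Globe insertion points at an orientation
#'
#' @param q unit quaternion eye orientation.
#' @param plant an [eye_plant()].
#' @return 3 x 6 matrix `Q = R(q) Q0`, meters.
#' @export
eye_insertions <- function(q, plant) {
  R <- quat_to_matrix(q)
  Q <- R %*% plant$Q0
  dimnames(Q) <- list(NULL, plant$muscle_names)
  Q
}

# Tendon path lengths (m): globe insertion -> via point -> cranial insertion
# for the pulleyed muscles, direct otherwise.
muscle_lengths <- function(q, u, plant) {
  Q <- eye_insertions(q, plant)
  P <- driver_insertions(u, plant)
  vapply(1:6, function(i) {
    if (plant$has_via[i]) {
      seg1 <- plant$X[, i] - Q[, i]
      seg2 <- P[, i] - plant$X[, i]
      sqrt(sum(seg1^2)) + sqrt(sum(seg2^2))
    } else {
      sqrt(sum((P[, i] - Q[, i])^2))
    }
  }, numeric(1))
}

#' Tendon forces at a plant state
#'
#' Hooke's-law tension along the first path segment (globe insertion toward
#' the via point, or directly toward the cranial insertion for the horizontal
#' recti), clamped at zero when a tendon is slack (`l < l0`): an elastic
#' string cannot push.
#'
#' @param q unit quaternion eye orientation.
#' @param u motor command, rad.
#' @param plant an [eye_plant()].
#' @return list with `F` (3 x 6 force vectors on the globe, N), `tension`
#'   (magnitudes, N), `lengths` (path lengths, m), `t_hat` (unit pulling
#'   directions), `Q` (globe insertions, m).
#' @export
muscle_forces <- function(q, u, plant) {
  Q <- eye_insertions(q, plant)
  P <- driver_insertions(u, plant)
  lens <- numeric(6); Fm <- matrix(0, 3, 6); that <- matrix(0, 3, 6)
  for (i in 1:6) {
    anchor <- if (plant$has_via[i]) plant$X[, i] else P[, i]
    seg1 <- anchor - Q[, i]
    n1 <- sqrt(sum(seg1^2))
    if (n1 < 1e-9) stop("degenerate tendon geometry: coincident points")
    lens[i] <- n1 + if (plant$has_via[i]) sqrt(sum((P[, i] - plant$X[, i])^2)) else 0
    that[, i] <- seg1 / n1
    Fm[, i] <- plant$kappa[i] * max(lens[i] - plant$l0[i], 0) * that[, i]
  }
  dimnames(Fm) <- list(NULL, plant$muscle_names)
  list(F = Fm, tension = plant$kappa * pmax(lens - plant$l0, 0),
       lengths = lens, t_hat = that, Q = Q)
}

#' Elastic torques on the globe
#'
#' Each tendon contributes `tau_i = Q_i x F_i` (N m) about the eye center.
#'
#' @inheritParams muscle_forces
#' @return list with `torques` (3 x 6), `total` (3-vector sum), and `unit`
#'   (normalized per-muscle torque directions; NA for a slack tendon).
#' @export
elastic_torques <- function(q, u, plant) {
  mf <- muscle_forces(q, u, plant)
  tq <- sapply(1:6, function(i) cross3(mf$Q[, i], mf$F[, i]))
  dimnames(tq) <- list(NULL, plant$muscle_names)
  unit <- apply(tq, 2, function(v) {
    n <- sqrt(sum(v^2)); if (n > 0) v / n else rep(NA_real_, 3)
  })
  list(torques = tq, total = rowSums(tq), unit = unit)
}

#' Normalized rest-pose torque directions
#'
#' Unit torque directions of the six tendons with the eye at the primary
#' position and motors at zero, for comparison with the published geometry
#' table.
#'
#' @param plant an [eye_plant()].
#' @return 6 x 3 matrix (rows = muscles, columns tau_x, tau_y, tau_z).
#' @export
rest_torque_table <- function(plant = eye_plant()) {
  et <- elastic_torques(quat(1, c(0, 0, 0)), c(0, 0, 0), plant)
  out <- t(et$unit)
  colnames(out) <- c("tau_x", "tau_y", "tau_z")
  out
}

#' Friction torque
#'
#' Dynamic (viscous) part `-chi_dyn * omega` always acts; the static part
#' exactly cancels the compensated torque `tau_comp = tau_el + tau_dyn` when
#' the eye is (nearly) at rest and `|tau_comp|` is below the stiction bound,
#' and vanishes otherwise.
#'
#' @param omega angular velocity, rad/s.
#' @param tau_el total elastic torque, N m.
#' @param plant an [eye_plant()].
#' @return list with `dyn`, `stat` and `total` torque 3-vectors (N m).
#' @export
friction_torque <- function(omega, tau_el, plant) {
  tdyn <- -plant$chi_dyn * omega
  tcomp <- tau_el + tdyn
  stat <- if (sqrt(sum(omega^2)) < plant$eps_stat &&
              sqrt(sum(tcomp^2)) < plant$chi_stat) -tcomp else c(0, 0, 0)
  list(dyn = tdyn, stat = stat, total = tdyn + stat)
}

#' Inertia tensor in the head frame
#'
#' `I(q) = R I0 R^T`: the primary-frame tensor conjugated by the current
#' rotation (trace and eigenvalues invariant).
#'
#' @inheritParams eye_insertions
#' @export
inertia_world <- function(q, plant) {
  R <- quat_to_matrix(q)
  R %*% plant$I0 %*% t(R)
}

#' Angular acceleration of the globe
#'
#' Solves the rigid-body equation `tau = I(q) alpha + omega x (I(q) omega)`
#' for `alpha`.  The gyroscopic cross-product term is negligible for
#' saccade-scale motion of this plant (see [gyroscopic_ratio()]) and is
#' excluded by default.
#'
#' @param q unit quaternion orientation.
#' @param omega angular velocity, rad/s.
#' @param u motor command, rad.
#' @param plant an [eye_plant()].
#' @param gyroscopic include the `omega x (I omega)` term?
#' @return angular acceleration, rad/s^2.
#' @export
angular_acceleration <- function(q, omega, u, plant, gyroscopic = FALSE) {
  tel <- elastic_torques(q, u, plant)$total
  fr <- friction_torque(omega, tel, plant)
  Iw <- inertia_world(q, plant)
  tau <- tel + fr$total
  if (gyroscopic) tau <- tau - cross3(omega, Iw %*% omega)
  drop(solve(Iw, tau))
}

#' Relative power of the gyroscopic term
#'
#' Ratio of mean squared magnitudes of the neglected gyroscopic torque
#' `|omega x (I omega)|` versus the inertial torque `|I alpha|` over a
#' trajectory, used to justify dropping the cross-product term from the
#' rigid-body equation for saccade-scale motion.
#'
#' @param omega_traj n x 3 matrix of angular velocities, rad/s.
#' @param alpha_traj n x 3 matrix of angular accelerations, rad/s^2.
#' @param I inertia tensor (3x3) or an [eye_plant()] (its `I0` is used).
#' @return scalar power ratio.
#' @export
gyroscopic_ratio <- function(omega_traj, alpha_traj, I = eye_plant()) {
  if (inherits(I, "eye_plant")) I <- I$I0
  omega_traj <- as.matrix(omega_traj); alpha_traj <- as.matrix(alpha_traj)
  stopifnot(ncol(omega_traj) == 3L, nrow(omega_traj) == nrow(alpha_traj))
  gy <- t(apply(omega_traj, 1, function(w) cross3(w, I %*% w)))
  ia <- alpha_traj %*% t(I)
  denom <- mean(rowSums(ia^2))
  if (denom == 0) stop("all-zero angular acceleration: ratio undefined")
  mean(rowSums(gy^2)) / denom
}

#' Total static tendon tension
#'
#' Sum of the six tension magnitudes (N) at an orientation/command pair; the
#' quantity whose quadratic dependence on eye orientation defines the
#' fixation-force cost.
#'
#' @inheritParams muscle_forces
#' @export
total_tension <- function(q, u, plant) sum(muscle_forces(q, u, plant)$tension)

# --- configuration serialization -------------------------------------------

#' Read and write plant configurations
#'
#' The plant geometry and mechanical parameters are serialized as YAML with
#' coordinates in cm, reproducing the default insertion-point table verbatim;
#' a bundled copy ships as `system.file("extdata", "table1.yaml", package =
#' "saccade3d")`.
#'
#' @param plant an [eye_plant()].
#' @param path file path.
#' @return `read_plant_config` returns an [eye_plant()].
#' @export
write_plant_config <- function(plant, path) {
  cfg <- list(
    schema = "saccade3d-plant/1",
    eye_radius_cm = plant$eye_radius_cm,
    kappa_N_per_m = plant$kappa[1],
    pretension = plant$pretension,
    chi_dyn = plant$chi_dyn, chi_stat = plant$chi_stat,
    eps_stat = plant$eps_stat,
    dt_s = plant$dt, substeps = plant$substeps,
    dz_cm = plant$dz, via_comove = plant$via_comove,
    inertia_kg_m2 = apply(plant$I0, 1, as.numeric, simplify = FALSE),
    muscles = lapply(plant$table_cm, function(m) {
      out <- list(Q0 = as.numeric(m$Q0), P0 = as.numeric(m$P0),
                  driver = as.integer(m$driver))
      if (!is.null(m$X)) out$X <- as.numeric(m$X)
      out
    }))
  # serialize the *unshifted* table so that re-reading with dz re-applies it
  if (plant$dz != 0) {
    for (nm in names(cfg$muscles)) {
      cfg$muscles[[nm]]$P0[3] <- cfg$muscles[[nm]]$P0[3] - plant$dz
      if (plant$via_comove && !is.null(cfg$muscles[[nm]]$X))
        cfg$muscles[[nm]]$X[3] <- cfg$muscles[[nm]]$X[3] - plant$dz
    }
  }
  yaml::write_yaml(cfg, path, precision = 12L)
  invisible(path)
}

#' @rdname write_plant_config
#' @export
read_plant_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(identical(cfg$schema, "saccade3d-plant/1"))
  mus <- lapply(cfg$muscles, function(m) {
    list(Q0 = as.numeric(m$Q0),
         X = if (is.null(m$X)) NULL else as.numeric(m$X),
         P0 = as.numeric(m$P0), driver = as.integer(m$driver))
  })
  I0 <- do.call(rbind, lapply(cfg$inertia_kg_m2, as.numeric))
  eye_plant(dz = cfg$dz_cm, pretension = cfg$pretension,
            kappa = cfg$kappa_N_per_m, chi_dyn = cfg$chi_dyn,
            chi_stat = cfg$chi_stat, eps_stat = cfg$eps_stat,
            dt = cfg$dt_s, substeps = cfg$substeps,
            via_comove = cfg$via_comove, muscles = mus, I0 = I0)
}

# Pack the plant into flat arrays for the compiled simulator core.
plant_pack <- function(plant) {
  X <- plant$X; X[is.na(X)] <- 0
  list(Q0 = plant$Q0, X = X, has_via = as.integer(plant$has_via),
       rod_center = plant$rod_center, rod_offset = plant$rod_offset,
       rod_axis = plant$rod_axis, rod_sense = plant$rod_sense,
       driver = as.integer(plant$driver - 1L), kappa = plant$kappa,
       l0 = plant$l0, chi_dyn = plant$chi_dyn, chi_stat = plant$chi_stat,
       eps = plant$eps_stat, dt = plant$dt, substeps = plant$substeps,
       I0 = plant$I0)
}
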