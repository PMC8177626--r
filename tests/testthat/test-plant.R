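# Mechanical plant: driver geometry, forces, torques, friction, inertia.

test_that("driver insertions follow the rod geometry", {
  pl <- test_plant()
  P0 <- driver_insertions(c(0, 0, 0), pl)
  expect_equal(P0, pl$P0, ignore_attr = TRUE, tolerance = 1e-12)
  # u1 = 0.1: SR moves +x by (L/2) sin(0.1), IR opposite (rod half = 0.10 m)
  P <- driver_insertions(c(0.1, 0, 0), pl)
  expect_equal(unname(P[1, "SR"] - P0[1, "SR"]), 0.10 * sin(0.1),
               tolerance = 1e-12)
  expect_equal(unname(P[1, "IR"] - P0[1, "IR"]), -0.10 * sin(0.1),
               tolerance = 1e-12)
  # rigid rod: end-to-end distance preserved
  expect_equal(sqrt(sum((P[, "SR"] - P[, "IR"])^2)), 0.20,
               tolerance = 1e-12)
  # u2 moves the horizontal recti in x and y only
  P2 <- driver_insertions(c(0, 0.1, 0), pl)
  expect_equal(P2[3, c("MR", "LR")], P0[3, c("MR", "LR")])
  expect_false(isTRUE(all.equal(P2[1, "MR"], P0[1, "MR"])))
  expect_error(driver_insertions(c(2, 0, 0), pl))
})

test_that("globe insertions rotate rigidly", {
  pl <- test_plant()
  expect_equal(eye_insertions(quat(1, c(0, 0, 0)), pl), pl$Q0,
               ignore_attr = TRUE)
  set.seed(21)
  for (i in 1:10) {
    q <- quat(rnorm(4))
    Q <- eye_insertions(q, pl)
    expect_equal(colSums(Q^2), colSums(pl$Q0^2), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
  # 10 degree horizontal rotation against the rotation-matrix oracle
  q <- quat_from_axis_angle(c(0, 0, 1), 10 * pi / 180)
  expect_equal(eye_insertions(q, pl)[, "MR"],
               drop(quat_to_matrix(q) %*% pl$Q0[, "MR"]),
               ignore_attr = TRUE, tolerance = 1e-14)
  # MR insertion has z = 0: it stays in the z = 0 plane under z-rotations
  expect_equal(unname(eye_insertions(q, pl)[3, "MR"]), 0,
               tolerance = 1e-15)
})

test_that("tendon forces: Hooke's law with slack clamping", {
  pl <- test_plant()
  q0 <- quat(1, c(0, 0, 0)); u0 <- c(0, 0, 0)
  mf <- muscle_forces(q0, u0, pl)
  # rest tension is kappa * pretension * rest length, per construction
  expect_equal(mf$tension,
               pl$kappa * pl$pretension / (1 - pl$pretension) * pl$l0,
               tolerance = 1e-9, ignore_attr = TRUE)
  # 0.01 m of stretch at kappa = 6 N/m is 0.06 N
  pl2 <- pl; pl2$l0 <- mf$lengths - 0.01
  expect_equal(muscle_forces(q0, u0, pl2)$tension, rep(0.06, 6),
               tolerance = 1e-9, ignore_attr = TRUE)
  # exactly at rest length: zero force; shorter than rest: slack, no pushing
  pl2$l0 <- mf$lengths
  expect_equal(muscle_forces(q0, u0, pl2)$tension, rep(0, 6),
               ignore_attr = TRUE)
  pl2$l0 <- mf$lengths + 0.05
  expect_equal(muscle_forces(q0, u0, pl2)$tension, rep(0, 6),
               ignore_attr = TRUE)
  expect_equal(elastic_torques(q0, u0, pl2)$total, c(0, 0, 0))
})

test_that("rest-pose torque directions reproduce the published geometry", {
  tab <- rest_torque_table(test_plant())
  published <- rbind(
    MR = c(-0.01, 0.00, 1.00), LR = c(0.01, 0.00, -1.00),
    SR = c(0.35, -0.93, -0.05), IR = c(-0.31, 0.94, 0.13),
    SO = c(-0.71, -0.70, -0.02), IO = c(0.73, 0.66, -0.16))
  # horizontal recti: dominant z-component within 0.02 of +/- 1
  expect_lt(abs(tab["MR", "tau_z"] - 1), 0.02)
  expect_lt(abs(tab["LR", "tau_z"] + 1), 0.02)
  # dominant components (|tau| >= 0.3) within 0.15 with matching signs
  dom <- abs(published) >= 0.3
  expect_true(all(abs(tab[dom] - published[dom]) < 0.15))
  expect_true(all(sign(tab[dom]) == sign(published[dom])))
})

test_that("friction torque branches", {
  pl <- test_plant()
  fr <- friction_torque(c(1, 0, 0), c(0, 0, 0), pl)
  expect_equal(fr$dyn, c(-0.02, 0, 0))   # chi_dyn = 0.02 N m s/rad
  expect_equal(fr$stat, c(0, 0, 0))      # moving: no stiction
  # at rest with sub-threshold torque, stiction cancels it exactly
  fr2 <- friction_torque(c(0, 0, 0), c(0.003, 0, 0), pl)
  expect_equal(fr2$total, c(-0.003, 0, 0))
  expect_equal(fr2$stat + c(0.003, 0, 0), c(0, 0, 0))
  # at rest with super-threshold torque, stiction releases
  fr3 <- friction_torque(c(0, 0, 0), c(0.01, 0, 0), pl)
  expect_equal(fr3$stat, c(0, 0, 0))
})

test_that("inertia tensor conjugation preserves trace and spectrum", {
  pl <- test_plant()
  expect_equal(inertia_world(quat(1, c(0, 0, 0)), pl), pl$I0)
  set.seed(22)
  ev0 <- sort(eigen(pl$I0, symmetric = TRUE, only.values = TRUE)$values)
  for (i in 1:100) {
    Iw <- inertia_world(quat(rnorm(4)), pl)
    expect_equal(sum(diag(Iw)), sum(diag(pl$I0)), tolerance = 1e-12)
    expect_equal(sort(eigen(Iw, symmetric = TRUE, only.values = TRUE)$values),
                 ev0, tolerance = 1e-12)
    expect_equal(Iw, t(Iw), tolerance = 1e-12)
  }
})

cross3_test <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

test_that("angular acceleration solves the rigid-body equation", {
  pl <- test_plant()
  # at rest the (small) residual elastic torque sits inside the stiction
  # band, so the net acceleration is exactly zero
  expect_equal(angular_acceleration(quat(1, c(0, 0, 0)), c(0, 0, 0),
                                    c(0, 0, 0), pl), c(0, 0, 0))
  # pure torque against a direct linear solve
  q <- quat(1, c(0, 0, 0)); w <- c(0.5, -0.2, 0.1); u <- c(0, 0.2, 0)
  tel <- elastic_torques(q, u, pl)$total
  tau <- tel - pl$chi_dyn * w
  expect_equal(angular_acceleration(q, w, u, pl),
               drop(solve(pl$I0, tau)), tolerance = 1e-10)
  # gyroscopic flag adds exactly -I^-1 (w x (I w))
  diffg <- angular_acceleration(q, w, u, pl, gyroscopic = TRUE) -
    angular_acceleration(q, w, u, pl)
  expect_equal(diffg, drop(-solve(pl$I0, cross3_test(w, pl$I0 %*% w))),
               tolerance = 1e-12)
})

test_that("gyroscopic ratio: degenerate and symmetric cases", {
  pl <- test_plant()
  al <- matrix(rnorm(30), 10, 3)
  expect_equal(gyroscopic_ratio(matrix(0, 10, 3), al, pl), 0)
  expect_error(gyroscopic_ratio(matrix(1, 10, 3), matrix(0, 10, 3), pl),
               "undefined")
  # spherically symmetric inertia: w x (a I w) = 0 identically
  w <- outer(seq(0, 1, length.out = 10), c(0, 0.6, 0.8))
  expect_equal(gyroscopic_ratio(w, al, diag(3) * 4e-4), 0)
})

test_that("mirror-symmetric geometry is in equilibrium at the origin", {
  pl <- eye_plant(muscles = symmetric_muscle_table())
  et <- elastic_torques(quat(1, c(0, 0, 0)), c(0, 0, 0), pl)
  single <- sqrt(sum(et$torques[, 1]^2))
  # the z-mirror symmetry cancels torsional and vertical residuals exactly
  expect_lt(abs(et$total[1]), 0.01 * single)
  expect_lt(abs(et$total[2]), 0.01 * single)
  # a horizontal residual remains (the vertical muscles' small tau_z
  # components add within each mirror pair); it stays inside the stiction
  # band, so the origin is a genuine rest point of the full dynamics
  expect_lt(sqrt(sum(et$total^2)), pl$chi_stat)
  st <- plant_step(eye_state(), c(0, 0, 0), pl)
  expect_equal(st$omega, c(0, 0, 0))
})

test_that("elastic torque is equivariant under whole-geometry rotation", {
  pl <- test_plant()
  Rz <- axis_angle_matrix(c(0, 0, 1), 0.4)
  mus <- saccade3d:::default_muscle_table()
  for (nm in names(mus)) {
    mus[[nm]]$Q0 <- drop(Rz %*% mus[[nm]]$Q0)
    mus[[nm]]$P0 <- drop(Rz %*% mus[[nm]]$P0)
    if (!is.null(mus[[nm]]$X)) mus[[nm]]$X <- drop(Rz %*% mus[[nm]]$X)
  }
  plR <- eye_plant(muscles = mus)
  q <- quat_from_axis_angle(c(0, 1, 0), 0.3)       # some eye orientation
  # eye-fixed geometry conjugates: q' = Rz q Rz^-1
  qz <- quat_from_axis_angle(c(0, 0, 1), 0.4)
  qR <- quat_compose(quat_compose(qz, q), quat_conjugate(qz))
  tau <- elastic_torques(q, c(0, 0, 0), pl)$total
  tauR <- elastic_torques(qR, c(0, 0, 0), plR)$total
  expect_equal(tauR, drop(Rz %*% tau), tolerance = 1e-10)
})

test_that("energy dissipates under constant input without stiction", {
  pl <- eye_plant(chi_stat = 0)
  U <- matrix(rep(c(0.1, 0.25, -0.1), each = 80), ncol = 3)
  traj <- simulate_plant(pl, U)
  qs <- attr(traj, "q")
  E <- vapply(seq_len(nrow(traj)), function(t) {
    q <- qs[t, ]; w <- as.numeric(traj[t, c("wx", "wy", "wz")])
    mf <- muscle_forces(quat(q), U[1, ], pl)
    0.5 * drop(w %*% inertia_world(quat(q), pl) %*% w) +
      sum(0.5 * pl$kappa * pmax(mf$lengths - pl$l0, 0)^2)
  }, numeric(1))
  expect_true(all(diff(E) <= 1e-6 * max(E)))
})

test_that("plant configuration round-trips through YAML", {
  pl <- test_plant()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_plant_config(pl, path)
  pl2 <- read_plant_config(path)
  expect_equal(pl2$Q0, pl$Q0, tolerance = 1e-9)
  expect_equal(pl2$P0, pl$P0, tolerance = 1e-9)
  expect_equal(pl2$l0, pl$l0, tolerance = 1e-9)
  expect_equal(pl2$I0, pl$I0, tolerance = 1e-12)
  # shifted plant round-trips with its shift re-applied
  pl8 <- eye_plant(dz = 8)
  write_plant_config(pl8, path)
  expect_equal(read_plant_config(path)$P0, pl8$P0, tolerance = 1e-9)
})
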