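# Cost assembly, quadratic program, duration search.

test_that("weight sets zero out terms absent from each functional", {
  expect_equal(cost_weights("AD")$lambda_E, 0)
  expect_equal(cost_weights("AE")$lambda_D, 0)
  expect_equal(cost_weights("AED")$lambda_LP1, 0)
  expect_gt(cost_weights("AEDL1")$lambda_LP1, 0)
  expect_gt(cost_weights("Force")$lambda_F, 0)
  expect_equal(cost_weights("Force")$lambda_LP1, 0)
  w <- cost_weights("AEDL2", lambda_LP2 = 7)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_weights(w, path)
  expect_equal(read_weights(path), w)
})

test_that("cost terms evaluate to their closed forms", {
  w <- cost_weights("AEDL1")
  R <- matrix(0, 6, 3); U <- matrix(0.3, 6, 3)
  tgt <- c(0, 0)
  J <- evaluate_costs(R, U, 5, w, target = tgt, u_hold = c(0.3, 0.3, 0.3))
  expect_equal(J$J_A, 0)              # endpoint exactly on target
  expect_equal(J$J_E, 0)              # constant input at hold: no increments
  expect_equal(J$J_LP1, 0)            # no torsion anywhere
  expect_equal(J$J_LP2, 0)
  expect_equal(J$J_D, 1 - 1 / (1 + w$beta * 5))
  expect_equal(evaluate_costs(R, U, 5, w, target = tgt,
                              u_hold = c(0, 0, 0))$J_E, 3 * 0.3^2)
  # duration-cost limits
  expect_equal(evaluate_costs(R[1, , drop = FALSE],
                              U[1, , drop = FALSE], 0, w)$J_D, 0)
  expect_gt(1 - 1 / (1 + w$beta * 1e6), 0.999)
  # literal energy convention charges the first input block itself
  wl <- cost_weights("AED", energy_mode = "literal")
  expect_equal(evaluate_costs(R, U, 5, wl, target = tgt,
                              u_hold = c(0.3, 0.3, 0.3))$J_E, 3 * 0.3^2)
})

test_that("holding solution is a steady state of the linear model", {
  m <- test_model()
  r0 <- deg_to_hr(c(2, 8, -12))
  h <- holding_solution(m, r0)
  U <- matrix(h$u, 60, 3, byrow = TRUE)
  out <- predict(m, sweep(U, 2, m$u_op), x0 = h$x)
  r_pred <- out[60, ] + m$y_op
  expect_equal(r_pred, r0, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("zero-displacement problems cost (almost) nothing but duration", {
  m <- test_model()
  pr <- control_problem(saccade_planner(m, cost_weights("AED")),
                        r0 = c(0, 0, 0), target_deg = c(0, 0))
  s <- solve_fixed_duration(pr, 10)
  expect_lt(s$costs$J_E, 1e-8)
  expect_lt(s$costs$J_A, 1e-12)
  expect_equal(s$costs$total,
               cost_weights("AED")$lambda_D * s$costs$J_D,
               tolerance = 1e-6)
  # optimal inputs sit at the holding input throughout
  expect_lt(max(abs(sweep(s$U, 2, holding_solution(m, c(0, 0, 0))$u))),
            1e-4)
})

test_that("terminal conditions: hard constraints vs penalties", {
  m <- test_model()
  prp <- control_problem(saccade_planner(m, cost_weights("AED")),
                         target_deg = c(0, 10))
  prc <- control_problem(
    saccade_planner(m, cost_weights("AED", terminal = "constraint")),
    target_deg = c(0, 10))
  sp <- solve_fixed_duration(prp, 12)
  sc <- solve_fixed_duration(prc, 12)
  # constraint mode satisfies the gaze equality to numerical precision
  expect_lt(max(abs(sc$endpoint_residual)), 1e-10)
  expect_lt(max(abs(sc$stationarity_residual)), 1e-9)
  # penalty mode agrees with constraint mode to a small fraction of a degree
  expect_lt(hr_to_deg(max(abs(sp$R[13, ] - sc$R[13, ]))), 0.1)
  # returned costs match an independent recomputation
  w <- cost_weights("AED")
  J <- evaluate_costs(sp$R, sp$U_dev, 12, w, target = prp$target,
                      u_hold = holding_solution(m, c(0, 0, 0))$u_dev)
  expect_equal(J$total, sp$costs$total, tolerance = 1e-8)
})

test_that("solutions are stationary points of the quadratic objective", {
  m <- test_model()
  pln <- saccade_planner(m, cost_weights("AED"))
  pr <- control_problem(pln, target_deg = c(5, -8))
  s <- solve_fixed_duration(pr, 10)
  cache <- pln$caches[[10]]
  U <- as.vector(t(s$U_dev))
  set.seed(51)
  for (i in 1:5) {
    dU <- rnorm(length(U), sd = 1e-4)
    # perturbation must not lower the penalty-mode objective
    obj <- function(u) {
      Um <- matrix(u, ncol = 3, byrow = TRUE)
      Rm <- matrix(drop(cache$G %*% u + cache$Fx %*% s$x0), ncol = 3,
                   byrow = TRUE) + matrix(rep(m$y_op, 11), ncol = 3,
                                          byrow = TRUE)
      J <- evaluate_costs(Rm, Um, 10, pln$weights, target = pr$target,
                          u_hold = holding_solution(m, c(0, 0, 0))$u_dev)
      pw <- pln$weights$penalty_weight
      J$total + pw * (sum((Rm[11, 2:3] - pr$target)^2) +
                        sum((cache$Ms %*% u + cache$Fms %*% s$x0)^2) +
                        sum((cache$Pu %*% u)^2))
    }
    expect_gte(obj(U + dU) - obj(U), -1e-9)
  }
})

test_that("relaxing a cost term never increases the optimum", {
  m <- test_model()
  tgt <- c(-6, 12)
  s_full <- solve_fixed_duration(
    control_problem(saccade_planner(m, cost_weights("AEDL1")),
                    target_deg = tgt), 15)
  s_rel <- solve_fixed_duration(
    control_problem(saccade_planner(m, cost_weights("AED")),
                    target_deg = tgt), 15)
  # shared terms only (the AED total is the AEDL1 total without torsion)
  w <- cost_weights("AED")
  tot <- function(s) w$lambda_A * s$costs$J_A + w$lambda_E * s$costs$J_E +
    w$lambda_D * s$costs$J_D
  expect_lte(tot(s_rel), tot(s_full) + 1e-10)
})

test_that("duration search: interior optimum at the calibration anchor", {
  m <- test_model()
  pr <- control_problem(saccade_planner(m, cost_weights("AED")),
                        target_deg = c(0, 10))
  sol <- plan_saccade(pr)
  # the shipped weights anchor a 10 degree horizontal saccade at 130 ms
  expect_true(sol$D_star >= 11 && sol$D_star <= 15)
  curve <- sol$cost_curve$objective
  k <- which.min(curve)
  expect_gt(k, 1); expect_lt(k, nrow(sol$cost_curve))   # interior, U-shaped
  expect_true(all(diff(curve[k:length(curve)]) > 0))
})

test_that("dropping the duration cost pushes saccades to the grid maximum", {
  m <- test_model()
  pr <- control_problem(saccade_planner(m, cost_weights("AE")),
                        target_deg = c(0, 10))
  expect_equal(suppressWarnings(plan_saccade(pr))$D_star, 40L)
})

test_that("optimal duration grows with amplitude; peak velocity saturates", {
  m <- test_model(); pl <- test_plant()
  pln <- saccade_planner(m, cost_weights("AED"))
  amps <- c(2, 5, 10, 20, 40)
  sols <- lapply(amps, function(A)
    suppressWarnings(plan_saccade(control_problem(pln,
                                                  target_deg = c(0, A)),
                                  plant = pl)))
  D <- vapply(sols, function(s) s$D_star, integer(1))
  expect_true(all(diff(D) >= 0))
  vpk <- vapply(sols, function(s)
    max(sqrt(rowSums(as.matrix(
      s$trajectory[, c("wx", "wy", "wz")])^2))) * 180 / pi, numeric(1))
  expect_lt(vpk[5] / vpk[3], 4)        # sublinear amplitude scaling
})

test_that("force quadratic: symmetry, positivity, grid minimum near origin", {
  HF <- test_HF()
  expect_equal(HF, t(HF), tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(eigen(HF, symmetric = TRUE,
                        only.values = TRUE)$values >= 0))
  # the fitted quadratic-plus-constant form is minimized at the origin by
  # construction; the raw tension surface has a flat basin there: the grid
  # point nearest the origin sits within a sliver of the global minimum
  grid <- attr(HF, "grid")
  near0 <- which.min(grid$rx^2 + grid$ry^2 + grid$rz^2)
  expect_lt(grid$tension[near0] - min(grid$tension),
            0.02 * diff(range(grid$tension)))
  # torsion-gaze coupling of the fitted form shifts monotonically with the
  # vertical insertion offset (plane pitch tracks the geometry)
  pitches <- vapply(c(-8, 0, 8), function(dz) {
    H <- suppressWarnings(estimate_force_hessian(eye_plant(dz = dz)))
    atan2(H[1, 3] / H[1, 1], 1) * 180 / pi
  }, numeric(1))
  expect_true(all(diff(pitches) > 0) || all(diff(pitches) < 0))
  expect_gt(abs(pitches[3] - pitches[1]), 5)
})
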