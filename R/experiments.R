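# Scripted experiment designs: chained random-saccade batches, fixed-
# direction component-stretching sets, and vertical-shift geometry sweeps.

#' Chained random saccade targets
#'
#' Draws a sequence of gaze displacements with Gaussian vertical and
#' horizontal components (SD `sd_deg` degrees); the first saccade starts at
#' the straight-ahead fixation point and each subsequent one starts from the
#' previous (intended) end position.  Absolute targets are clipped to
#' `clip_deg` per component to stay inside the calibrated range; clip events
#' are counted in `attr(, "clipped")`.
#'
#' @param n number of saccades.
#' @param sd_deg component SD, degrees.
#' @param seed integer seed (substream `targets`).
#' @param clip_deg absolute per-component clip, degrees.
#' @return data frame with intended start and target gaze components
#'   (degrees): `start_y, start_z, target_y, target_z`.
#' @export
random_target_sequence <- function(n, sd_deg = 15, seed = 1, clip_deg = 40) {
  stopifnot(n >= 1)
  set.seed(substream_seed(seed, "targets"))
  start <- c(0, 0)
  out <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("start_y", "start_z",
                                        "target_y", "target_z")))
  clipped <- 0L
  for (i in seq_len(n)) {
    tgt <- start + rnorm(2, sd = sd_deg)
    if (any(abs(tgt) > clip_deg)) clipped <- clipped + 1L
    tgt <- pmin(pmax(tgt, -clip_deg), clip_deg)
    out[i, ] <- c(start, tgt)
    start <- tgt
  }
  out <- as.data.frame(out)
  attr(out, "clipped") <- clipped
  out
}

#' Run a batch of planned and simulated saccades
#'
#' Plans every saccade of a chained random-target sequence with the given
#' cost functional, plays each optimal input series through the nonlinear
#' plant, and carries the realized (settled) state into the next saccade.
#' Per-saccade planning failures are recorded, not fatal.
#'
#' @param plant an [eye_plant()].
#' @param model identified `ss_model` for the plant.
#' @param weights a [cost_weights()].
#' @param n number of saccades.
#' @param seed target-sequence seed.
#' @param sd_deg target component SD, degrees.
#' @param HF force quadratic (required for the `Force` functional).
#' @param D_grid duration grid, ticks.
#' @param settle_ticks post-movement hold per saccade, ticks.
#' @param keep_trajectories retain every realized trajectory (memory).
#' @return a `saccade_batch`: list with `metrics` (one row per saccade; see
#'   [saccade_metrics()]), `orientations` (all realized rotation-vector
#'   samples, movement plus fixation), `trajectories` (optional), and
#'   provenance (`config`).
#' @export
run_batch <- function(plant, model, weights, n = 300, seed = 1, sd_deg = 15,
                      HF = NULL, D_grid = 2:40, settle_ticks = 30,
                      keep_trajectories = FALSE) {
  planner <- saccade_planner(model, weights, D_grid = D_grid, HF = HF)
  targets <- random_target_sequence(n, sd_deg = sd_deg, seed = seed)
  state <- settle_plant(plant, holding_solution(model, c(0, 0, 0))$u)$state
  metrics <- vector("list", n)
  trajs <- if (keep_trajectories) vector("list", n) else NULL
  orient <- vector("list", n)
  failures <- 0L
  for (i in seq_len(n)) {
    r0 <- quat_to_rotvec(state$q)
    tgt_hr <- deg_to_hr(as.numeric(targets[i, c("target_y", "target_z")]))
    sol <- tryCatch(suppressWarnings(
      plan_saccade(control_problem(planner, r0 = r0, target_hr = tgt_hr),
                   plant = plant, state0 = state,
                   settle_ticks = settle_ticks)),
      error = function(e) e)
    if (inherits(sol, "error")) {
      failures <- failures + 1L
      metrics[[i]] <- NULL
      next
    }
    met <- saccade_metrics(sol$trajectory, sol$D_star)
    met$saccade <- i
    met$start_y <- targets$start_y[i]; met$start_z <- targets$start_z[i]
    met$target_y <- targets$target_y[i]; met$target_z <- targets$target_z[i]
    met$end_x <- hr_to_deg(sol$r_end[1])
    met$end_y <- hr_to_deg(sol$r_end[2])
    met$end_z <- hr_to_deg(sol$r_end[3])
    metrics[[i]] <- as.data.frame(met)
    orient[[i]] <- as.matrix(sol$trajectory[, c("rx", "ry", "rz")])
    if (keep_trajectories) trajs[[i]] <- sol$trajectory
    state <- sol$state_final
  }
  structure(list(
    metrics = do.call(rbind, metrics),
    orientations = do.call(rbind, orient),
    trajectories = trajs, failures = failures,
    config = run_config(weights$functional, n, seed, plant$dz, sd_deg,
                        model_hash = config_hash(coef(model)))),
    class = "saccade_batch")
}

#' @export
print.saccade_batch <- function(x, ...) {
  cat(sprintf("saccade batch: %s, %d saccades (%d failures)\n",
              x$config$functional, nrow(x$metrics), x$failures))
  invisible(x)
}

#' Component-stretching experiment
#'
#' Plans saccades from the primary position with the horizontal component
#' fixed (`H_amp` degrees) while the vertical component steps through
#' `V_amps`, and extracts per-component velocity profiles and the peak
#' horizontal-component velocity as a function of the saccade direction
#' angle `Phi = atan2(V, H)`.
#'
#' @param plant an [eye_plant()].
#' @param model identified `ss_model`.
#' @param weights a [cost_weights()].
#' @param H_amp fixed horizontal component, degrees.
#' @param V_amps vertical components, degrees.
#' @param HF,D_grid see [run_batch()].
#' @return data frame (one row per direction) with `Phi_deg`,
#'   `vpk_H` and `vpk_V` (peak component speeds, deg/s), `D_ms`; the full
#'   velocity profiles are in `attr(, "profiles")`.
#' @export
stretching_experiment <- function(plant, model, weights, H_amp = 8,
                                  V_amps = seq(0, 30, by = 5), HF = NULL,
                                  D_grid = 2:40) {
  planner <- saccade_planner(model, weights, D_grid = D_grid, HF = HF)
  state0 <- settle_plant(plant, holding_solution(model, c(0, 0, 0))$u)$state
  profiles <- list()
  rows <- lapply(V_amps, function(V) {
    sol <- suppressWarnings(
      plan_saccade(control_problem(planner, r0 = quat_to_rotvec(state0$q),
                                   target_deg = c(V, H_amp)),
                   plant = plant, state0 = state0))
    tr <- sol$trajectory
    win <- seq_len(sol$D_star + 1)            # movement window
    vy <- diff(tr$ry) / plant$dt; vz <- diff(tr$rz) / plant$dt
    # component angular velocities (deg/s) via the small-angle factor 2
    prof <- data.frame(t = tr$t[win],
                       vH = 2 * c(vz[win[-length(win)]], NA) * 180 / pi,
                       vV = 2 * c(vy[win[-length(win)]], NA) * 180 / pi)
    profiles[[length(profiles) + 1]] <<- prof
    data.frame(V_amp = V, Phi_deg = atan2(V, H_amp) * 180 / pi,
               vpk_H = max(abs(prof$vH), na.rm = TRUE),
               vpk_V = max(abs(prof$vV), na.rm = TRUE),
               D_ms = sol$D_ms)
  })
  out <- do.call(rbind, rows)
  attr(out, "profiles") <- profiles
  out
}

#' Vertical-shift geometry sweep
#'
#' For each vertical shift `dz` of the cranial insertion points: rebuild the
#' plant, re-identify the linear model (fixed PRBS seed, so sweep
#' differences reflect geometry rather than excitation), re-estimate the
#' force quadratic, run a saccade batch, fit the orientation plane and
#' report its pitch.
#'
#' @param dz_values shifts, cm.
#' @param functional cost functional (default `Force`).
#' @param n saccades per batch.
#' @param seed master seed (fans out to PRBS and target substreams).
#' @param reidentify re-identify the model per shift (recommended: the
#'   geometry changes the dynamics); if `FALSE` the `dz = 0` model is
#'   reused.
#' @param grid_n settling-grid resolution for the force quadratic.
#' @param ... further arguments to [run_batch()].
#' @return data frame with one row per shift: plane normal, angle to the
#'   straight-ahead direction, pitch angle (degrees, negative = downward),
#'   torsional width (degrees); batches in `attr(, "batches")`.
#' @export
dz_sweep <- function(dz_values = seq(-8, 8, by = 2), functional = "Force",
                     n = 300, seed = 1, reidentify = TRUE, grid_n = 7, ...) {
  base_model <- NULL
  batches <- list()
  rows <- lapply(dz_values, function(dz) {
    pl <- eye_plant(dz = dz)
    model <- if (reidentify || is.null(base_model)) {
      identify_plant(pl, seed = substream_seed(seed, "prbs-sweep"))
    } else base_model
    if (is.null(base_model)) base_model <<- model
    HF <- estimate_force_hessian(pl, n_per_axis = grid_n)
    w <- cost_weights(functional)
    batch <- run_batch(pl, model, w, n = n, seed = seed, HF = HF, ...)
    batches[[as.character(dz)]] <<- batch
    fit <- fit_listing_plane(batch$orientations)
    data.frame(dz = dz, n_x = fit$normal[1], n_y = fit$normal[2],
               n_z = fit$normal[3], angle_deg = fit$angle_deg,
               pitch_deg = fit$pitch_deg, width_deg = fit$width_deg)
  })
  out <- do.call(rbind, rows)
  attr(out, "batches") <- batches
  out
}
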