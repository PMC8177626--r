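# Population analyses: Listing-plane fit, Listing-frame transform,
# per-saccade metrics, main-sequence fits, component stretching and the
# amplitude versus peak-velocity-times-duration relation.

#' Best-fit plane through rotation-vector data
#'
#' Least-squares fit of `rx = a ry + b rz` (through the origin, as the
#' plane's normal direction is the quantity of interest), with unit normal
#' proportional to `(1, -a, -b)`.  The torsional width is the standard
#' deviation of the residuals converted to degrees by the small-angle
#' factor 2 (a half-radian residual `d` is `2 d 180/pi` degrees).
#'
#' @param R n x 3 matrix of rotation vectors (columns rx, ry, rz).
#' @return a `listing_plane`: list with `a`, `b`, unit `normal` (first
#'   component positive), `angle_deg` (to the straight-ahead direction
#'   `P = (1,0,0)`), `pitch_deg` (tilt of the plane in the xz view,
#'   negative = downward pitch), and `width_deg`.
#' @export
fit_listing_plane <- function(R) {
  R <- as.matrix(R)
  stopifnot(ncol(R) == 3L, nrow(R) >= 3L)
  yz <- R[, 2:3, drop = FALSE]
  if (qr(cbind(yz))$rank < 2)
    stop("degenerate (collinear) orientation data: plane undetermined")
  ab <- unname(qr.solve(yz, R[, 1]))
  res <- R[, 1] - drop(yz %*% ab)
  n <- c(1, -ab[1], -ab[2])
  n <- n / sqrt(sum(n^2))
  structure(list(a = unname(ab[1]), b = unname(ab[2]), normal = unname(n),
                 angle_deg = acos(n[1]) * 180 / pi,
                 pitch_deg = atan2(n[3], n[1]) * 180 / pi,
                 width_deg = 2 * sd(res) * 180 / pi,
                 n_points = nrow(R)),
            class = "listing_plane")
}

#' @export
print.listing_plane <- function(x, ...) {
  cat(sprintf(
    "best-fit plane: normal [%.3f, %.3f, %.3f], %.1f deg from P, width %.2f deg\n",
    x$normal[1], x$normal[2], x$normal[3], x$angle_deg, x$width_deg))
  invisible(x)
}

#' @export
coef.listing_plane <- function(object, ...) c(a = object$a, b = object$b)

#' Express orientations in Listing's frame of reference
#'
#' Rotates rotation-vector data by the [listing_frame()] rotation of a
#' fitted plane normal, so that the primary direction (the plane normal)
#' maps onto `(1, 0, 0)`; refitting the transformed data yields a normal
#' within a fraction of a degree of the primary direction.
#'
#' @param R n x 3 rotation vectors.
#' @param fit a `listing_plane` (fitted from `R` by default).
#' @return transformed n x 3 matrix.
#' @export
listing_transform <- function(R, fit = fit_listing_plane(R)) {
  R <- as.matrix(R)
  t(listing_frame(fit$normal)$R %*% t(R))
}

#' Per-saccade kinematic metrics
#'
#' Amplitude is the exact single-axis rotation angle (quaternion geodesic)
#' from the start orientation to the settled end orientation; peak speed is
#' the largest angular-velocity magnitude inside the planned movement
#' window; straightness is the Pearson correlation of the vertical and
#' horizontal rotation-vector velocity profiles (absolute values, so that a
#' straight movement scores +1 in every direction quadrant) over that
#' window.
#'
#' @param traj an `eye_trajectory` (movement plus post-movement settle).
#' @param D planned duration, ticks.
#' @return list with `amplitude_deg`, `D_ms`, `vpk_deg_s`,
#'   `vpk_y`, `vpk_z` (peak component speeds, deg/s), `straightness`, and a
#'   `fixation` flag (amplitude below half a degree).
#' @export
saccade_metrics <- function(traj, D) {
  dt <- attr(traj, "dt") %||% 0.01
  if (nrow(traj) < D + 1 || D < 1)
    stop("trajectory shorter than the planned movement window")
  qs <- attr(traj, "q")
  r_start <- as.numeric(traj[1, c("rx", "ry", "rz")])
  r_end <- as.numeric(traj[nrow(traj), c("rx", "ry", "rz")])
  qrel <- quat_compose(rotvec_to_quat(r_end),
                       quat_conjugate(rotvec_to_quat(r_start)))
  amp <- 2 * atan2(sqrt(sum(qrel[2:4]^2)), qrel[1]) * 180 / pi
  win <- seq_len(D + 1)
  w <- as.matrix(traj[win, c("wx", "wy", "wz")])
  vy <- diff(traj$ry[win]) / dt
  vz <- diff(traj$rz[win]) / dt
  straight <- if (sd(vy) > 1e-9 && sd(vz) > 1e-9)
    cor(abs(vy), abs(vz)) else NA_real_
  list(amplitude_deg = amp, D_ms = D * dt * 1e3,
       vpk_deg_s = max(sqrt(rowSums(w^2))) * 180 / pi,
       vpk_y = 2 * max(abs(vy)) * 180 / pi,
       vpk_z = 2 * max(abs(vz)) * 180 / pi,
       straightness = straight, fixation = amp < 0.5)
}

#' Saturating main-sequence fit
#'
#' Fits `Vpk = V0 (1 - exp(-amplitude / alpha))` by nonlinear least squares
#' (a profiled grid over `alpha` — where `V0` is a linear subproblem —
#' refined by Levenberg-Marquardt), plus the affine duration-amplitude
#' regression `D = a amplitude + b`.  Near-linear data push `alpha` beyond
#' the sampled amplitude range; the fit is then flagged `near_linear`.
#'
#' @param metrics data frame with columns `amplitude_deg`, `vpk_deg_s`,
#'   `D_ms` (e.g. a batch's `$metrics`).
#' @param min_amplitude discard fixation-scale movements below this, deg.
#' @return a `main_sequence`: `V0` (deg/s), `alpha` (deg), `duration_slope`
#'   (ms/deg), `duration_intercept` (ms), `r2_vpk`, `near_linear`.
#' @export
fit_main_sequence <- function(metrics, min_amplitude = 0.5) {
  d <- metrics[metrics$amplitude_deg >= min_amplitude, , drop = FALSE]
  if (nrow(d) < 8) stop("too few saccades for a main-sequence fit")
  if (max(d$amplitude_deg) < 4 * min(d$amplitude_deg))
    warning("amplitude range spans less than a factor 4; fit is fragile")
  A <- d$amplitude_deg; V <- d$vpk_deg_s
  alphas <- exp(seq(log(0.5), log(5e3), length.out = 240))
  sse <- vapply(alphas, function(al) {
    x <- 1 - exp(-A / al)
    v0 <- sum(x * V) / sum(x^2)
    sum((V - v0 * x)^2)
  }, numeric(1))
  al <- alphas[which.min(sse)]
  v0 <- { x <- 1 - exp(-A / al); sum(x * V) / sum(x^2) }
  fit <- tryCatch(
    minpack.lm::nlsLM(V ~ V0 * (1 - exp(-A / alpha)),
                      start = list(V0 = v0, alpha = al),
                      lower = c(1, 0.1), upper = c(1e5, 1e4),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    v0 <- coef(fit)[["V0"]]; al <- coef(fit)[["alpha"]]
  }
  pred <- v0 * (1 - exp(-A / al))
  dur <- lm(D_ms ~ amplitude_deg, data = d)
  structure(list(
    V0 = v0, alpha = al,
    r2_vpk = 1 - sum((V - pred)^2) / sum((V - mean(V))^2),
    duration_slope = unname(coef(dur)[2]),
    duration_intercept = unname(coef(dur)[1]),
    near_linear = al > max(A), n = nrow(d)),
    class = "main_sequence")
}

#' @export
print.main_sequence <- function(x, ...) {
  cat(sprintf(
    "main sequence: V0 = %.0f deg/s, alpha = %.1f deg%s; D = %.2f A + %.0f ms\n",
    x$V0, x$alpha, if (x$near_linear) " (near-linear)" else "",
    x$duration_slope, x$duration_intercept))
  invisible(x)
}

#' @export
coef.main_sequence <- function(object, ...) {
  c(V0 = object$V0, alpha = object$alpha,
    duration_slope = object$duration_slope,
    duration_intercept = object$duration_intercept)
}

#' @export
predict.main_sequence <- function(object, amplitude_deg, ...) {
  object$V0 * (1 - exp(-amplitude_deg / object$alpha))
}

#' Component-stretching correlation
#'
#' Pearson correlation between the fixed horizontal component's peak
#' velocity and the cosine of the saccade direction angle across a
#' [stretching_experiment()]: +1 when the fixed component slows exactly as
#' the cosine prediction of a common vectorial drive, near 0 when its
#' velocity is direction-independent, negative when it speeds up with
#' direction angle.
#'
#' @param stretch output of [stretching_experiment()] (needs >= 5
#'   directions).
#' @return scalar correlation.
#' @export
component_stretch_corr <- function(stretch) {
  stopifnot(nrow(stretch) >= 5)
  if (sd(stretch$vpk_H) < 1e-9) return(0)  # direction-independent peaks
  cor(stretch$vpk_H, cos(stretch$Phi_deg * pi / 180))
}

#' Amplitude versus peak-velocity-times-duration relation
#'
#' Ordinary least squares of saccade amplitude (deg) on the product of peak
#' velocity (deg/s) and duration (s).  Single-peaked "triangular" velocity
#' profiles give a slope of one half and an r-squared of one.
#'
#' @param metrics data frame with `amplitude_deg`, `vpk_deg_s`, `D_ms`.
#' @param min_amplitude discard fixation-scale movements, deg.
#' @return list with `slope`, `intercept`, `r2`, `n`.
#' @export
vpk_duration_relation <- function(metrics, min_amplitude = 0.5) {
  d <- metrics[metrics$amplitude_deg >= min_amplitude, , drop = FALSE]
  if (nrow(d) < 10) stop("too few saccades")
  x <- d$vpk_deg_s * d$D_ms / 1e3
  fit <- lm(d$amplitude_deg ~ x)
  # exact (noise-free) inputs are legitimate here; silence the perfect-fit note
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r2 = r2, n = nrow(d))
}

#' Summary table across cost functionals
#'
#' One row per batch: plane normal, angle to the straight-ahead direction,
#' torsional width, main-sequence parameters, and (when a matching
#' stretching experiment is supplied) the component-stretching correlation.
#'
#' @param batches named list of `saccade_batch` objects.
#' @param stretches optional named list of [stretching_experiment()]
#'   outputs (names matching `batches`).
#' @param path optional CSV output path.
#' @return data frame.
#' @export
table3_report <- function(batches, stretches = NULL, path = NULL) {
  if (!length(batches)) {
    out <- data.frame(functional = character(), n_x = numeric(),
                      n_y = numeric(), n_z = numeric(),
                      angle_deg = numeric(), width_deg = numeric(),
                      V0 = numeric(), alpha = numeric(), r_CS = numeric())
  } else {
    rows <- lapply(names(batches), function(nm) {
      b <- batches[[nm]]
      pf <- fit_listing_plane(b$orientations)
      ms <- fit_main_sequence(b$metrics)
      data.frame(functional = nm, n_x = pf$normal[1], n_y = pf$normal[2],
                 n_z = pf$normal[3], angle_deg = pf$angle_deg,
                 width_deg = pf$width_deg, V0 = ms$V0, alpha = ms$alpha,
                 r_CS = if (!is.null(stretches[[nm]]))
                   component_stretch_corr(stretches[[nm]]) else NA_real_)
    })
    out <- do.call(rbind, rows)
  }
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
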