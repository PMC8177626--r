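# 3D rotational kinematics for eye orientations.
#
# Conventions (fixed throughout the package): head-fixed right-handed frame
# with +x = torsion (clockwise from the subject's point of view), +y =
# vertical (downward rotation positive), +z = horizontal (leftward rotation
# positive).  A quaternion is a numeric vector c(q0, qx, qy, qz) with unit
# norm; a rotation vector r = tan(rho/2) * nhat is a numeric 3-vector in
# half-radian units.  r = c(0,0,0) is the primary position.

QUAT_TOL <- 1e-6

#' Construct and validate a unit quaternion
#'
#' Quaternions parametrize a single-axis rotation by angle `rho` about unit
#' axis `nhat` as `q = c(cos(rho/2), sin(rho/2) * nhat)`.  The sign ambiguity
#' (`q` and `-q` encode the same orientation) is resolved by canonicalizing
#' the scalar part to be non-negative.
#'
#' @param q0 scalar part, or a length-4 numeric vector holding the whole
#'   quaternion (in which case `qv` must be missing).
#' @param qv imaginary 3-vector part (x = torsion, y = vertical, z = horizontal).
#' @param normalize if `TRUE` (default) renormalize to unit length; if `FALSE`
#'   a non-unit input beyond tolerance is an error.
#' @return numeric length-4 unit quaternion, scalar part first, `q0 >= 0`.
#' @examples
#' quat(1, c(0, 0, 0))                     # identity
#' quat_from_axis_angle(c(0, 0, 1), pi/2)  # 90 deg leftward
#' @export
quat <- function(q0, qv, normalize = TRUE) {
  q <- if (missing(qv)) as.numeric(q0) else c(q0, qv)
  stopifnot(length(q) == 4L, all(is.finite(q)))
  nrm <- sqrt(sum(q^2))
  if (nrm < QUAT_TOL) stop("quaternion norm is (near) zero")
  if (!normalize && abs(nrm - 1) > QUAT_TOL)
    stop(sprintf("non-unit quaternion (norm %.6g)", nrm))
  q <- q / nrm
  if (q[1] < 0) q <- -q
  q
}

#' @rdname quat
#' @param axis rotation axis (any nonzero 3-vector; normalized internally).
#' @param angle rotation angle in radians.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  stopifnot(length(axis) == 3L)
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0 && angle != 0) stop("zero axis with nonzero angle")
  a <- if (nrm > 0) axis / nrm else c(1, 0, 0)
  quat(cos(angle / 2), sin(angle / 2) * a)
}

#' Quaternion product
#'
#' Composes two orientations: `quat_compose(p, q)` is the rotation `q`
#' followed by `p` (Hamilton product `p * q`).  Non-commutative in general.
#'
#' @param p,q unit quaternions.
#' @return unit quaternion (renormalized).
#' @export
quat_compose <- function(p, q) {
  p <- quat(p, normalize = FALSE)
  q <- quat(q, normalize = FALSE)
  pv <- p[2:4]; qv <- q[2:4]
  quat(p[1] * q[1] - sum(pv * qv),
       p[1] * qv + q[1] * pv + cross3(pv, qv))
}

#' @rdname quat_compose
#' @export
quat_conjugate <- function(q) {
  q <- quat(q, normalize = FALSE)
  c(q[1], -q[2:4])
}

#' Rotation matrix of a quaternion
#'
#' @param q unit quaternion.
#' @return 3x3 orthonormal rotation matrix `R` with `R %*% v` the rotated
#'   vector.
#' @export
quat_to_matrix <- function(q) {
  q <- quat(q, normalize = FALSE)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
}

#' Convert between quaternions and rotation vectors
#'
#' The Euler-Rodrigues rotation vector is `r = qv / q0 = tan(rho/2) * nhat`,
#' in half-radian units; its inverse rotation is `-r` and `r = 0` is the
#' primary position.  `quat_to_rotvec` requires `rho < 180` degrees
#' (`q0 > 0`); the round trip is an identity to better than 1e-9 for
#' `rho < 170` degrees.
#'
#' @param q unit quaternion.
#' @param r rotation vector (half-radians).
#' @return the other representation.
#' @export
quat_to_rotvec <- function(q) {
  q <- quat(q, normalize = FALSE)
  if (q[1] < 1e-8)
    stop("orientation at or beyond 180 deg: rotation vector undefined")
  q[2:4] / q[1]
}

#' @rdname quat_to_rotvec
#' @export
rotvec_to_quat <- function(r) {
  stopifnot(length(r) == 3L, all(is.finite(r)))
  quat(1, r)  # c(1, r) / sqrt(1 + |r|^2): quat() normalizes
}

#' Degree helpers for rotation-vector components
#'
#' Componentwise conversion between degrees and half-radian rotation-vector
#' coordinates, `x = tan(theta/2)`; the rotation angle of a full vector is
#' `rho = 2 * atan(|r|)`.
#'
#' @param deg angle(s) in degrees.
#' @param x half-radian coordinate(s).
#' @param r rotation vector.
#' @export
deg_to_hr <- function(deg) tan(deg * pi / 360)

#' @rdname deg_to_hr
#' @export
hr_to_deg <- function(x) 2 * atan(x) * 180 / pi

#' @rdname deg_to_hr
#' @export
rotvec_angle_deg <- function(r) 2 * atan(sqrt(sum(r^2))) * 180 / pi

#' Coordinate velocity maps
#'
#' `quat_rate` maps an angular velocity (rad/s, head-fixed frame) to the
#' quaternion rate `qdot = (omega * q) / 2`, with `omega` treated as a pure
#' imaginary quaternion; `omega_from_quat_rate` is its exact inverse
#' `omega = 2 * qdot * q^-1`.
#'
#' @param q unit quaternion.
#' @param omega angular velocity, rad/s.
#' @param qdot quaternion rate (length 4).
#' @export
quat_rate <- function(q, omega) {
  q <- quat(q, normalize = FALSE)
  stopifnot(length(omega) == 3L)
  qv <- q[2:4]
  0.5 * c(-sum(omega * qv), q[1] * omega + cross3(omega, qv))
}

#' @rdname quat_rate
#' @export
omega_from_quat_rate <- function(q, qdot) {
  q <- quat(q, normalize = FALSE)
  stopifnot(length(qdot) == 4L)
  qi <- quat_conjugate(q)  # inverse of a unit quaternion
  w <- 2 * quat_raw_product(qdot, qi)
  w[2:4]
}

# Hamilton product without unit-norm enforcement (rates are not unit).
quat_raw_product <- function(p, q) {
  pv <- p[2:4]; qv <- q[2:4]
  c(p[1] * q[1] - sum(pv * qv),
    p[1] * qv + q[1] * pv + cross3(pv, qv))
}

#' Rotation-vector rates
#'
#' `rotvec_rate` gives the exact rotation-vector rate
#' `rdot = (omega + omega x r + (omega . r) r) / 2`.  The inverse map is
#' available in two forms: the small-angle approximation
#' `omega ~ 2 (rdot + r x rdot)` (error exactly `|r|^2 * omega`, i.e. third
#' order in a jointly scaled (orientation, velocity) configuration) and the
#' exact inverse `omega = 2 (rdot + r x rdot) / (1 + |r|^2)`.
#'
#' @param r rotation vector (half-radians).
#' @param omega angular velocity (rad/s).
#' @param rdot rotation-vector rate.
#' @param exact use the exact inverse (default `FALSE`: the approximation).
#' @export
rotvec_rate <- function(r, omega) {
  stopifnot(length(r) == 3L, length(omega) == 3L)
  0.5 * (omega + cross3(omega, r) + sum(omega * r) * r)
}

#' @rdname rotvec_rate
#' @export
omega_from_rotvec_rate <- function(r, rdot, exact = FALSE) {
  stopifnot(length(r) == 3L, length(rdot) == 3L)
  w <- 2 * (rdot + cross3(r, rdot))
  if (exact) w / (1 + sum(r^2)) else w
}

#' Saccade axis and its torsional tilt
#'
#' The single-axis rotation-vector increment that carries the eye from
#' orientation `rA` to `rB` is, to third order, `s = d + rA x d` with
#' `d = rB - rA`.  For start and end in Listing's plane (`rA_x = rB_x = 0`)
#' the cross term is purely torsional and the axis tilts out of the plane by
#' `eta = atan2(s_x, |d|)`, bounded by half the eccentricity angle of `rA`
#' (the half-angle rule).
#'
#' @param rA,rB start and end rotation vectors (half-radians).
#' @return list with `s` (axis increment), `d` (difference vector) and
#'   `eta` (torsional tilt out of Listing's plane, radians).
#' @export
saccade_axis <- function(rA, rB) {
  stopifnot(length(rA) == 3L, length(rB) == 3L)
  d <- rB - rA
  s <- d + cross3(rA, d)
  dn <- sqrt(sum(d^2))
  eta <- if (dn == 0) 0 else atan2(s[1], dn)
  list(s = s, d = d, eta = eta)
}

#' Straight rotation-vector path
#'
#' Linear interpolation `r(sigma) = rA + sigma * d` in rotation-vector space;
#' a good (third-order) approximation to the exact single-axis rotation path
#' between `rA` and `rA + d`, and exact at the endpoints.
#'
#' @param rA start rotation vector.
#' @param d displacement (half-radians).
#' @param sigma interpolation fraction(s) in `[0, 1]`.
#' @return a rotation vector, or a matrix with one row per `sigma`.
#' @export
straight_path <- function(rA, d, sigma) {
  stopifnot(length(rA) == 3L, length(d) == 3L)
  if (any(sigma < 0 | sigma > 1)) stop("sigma must lie in [0, 1]")
  out <- outer(sigma, d) + rep(rA, each = length(sigma))
  if (length(sigma) == 1L) drop(out) else out
}

#' Exact single-axis interpolation between two orientations
#'
#' The exact rotation-vector path of a constant-axis rotation from `rA` to
#' `rB` (the quaternion geodesic); used as the oracle against which the
#' straight-line approximation of [straight_path()] is assessed.
#'
#' @param rA,rB endpoint rotation vectors.
#' @param sigma fraction(s) in `[0, 1]`.
#' @export
geodesic_path <- function(rA, rB, sigma) {
  if (any(sigma < 0 | sigma > 1)) stop("sigma must lie in [0, 1]")
  qA <- rotvec_to_quat(rA)
  qB <- rotvec_to_quat(rB)
  qrel <- quat_compose(qB, quat_conjugate(qA))
  ang <- 2 * atan2(sqrt(sum(qrel[2:4]^2)), qrel[1])
  axis <- if (ang > 1e-12) qrel[2:4] / sqrt(sum(qrel[2:4]^2)) else c(1, 0, 0)
  out <- t(vapply(sigma, function(s) {
    quat_to_rotvec(quat_compose(quat_from_axis_angle(axis, s * ang), qA))
  }, numeric(3)))
  if (length(sigma) == 1L) drop(out) else out
}

#' Rotation carrying a fitted plane normal onto the primary direction
#'
#' Given the unit normal `nhat` of a best-fit plane through rotation-vector
#' data, returns the rotation about axis `normalize(nhat x P)` by angle
#' `acos(nhat . P)` that maps `nhat` onto the straight-ahead direction
#' `P = (1, 0, 0)`.  Applying the returned matrix to rotation vectors
#' expresses them in Listing's frame of reference.
#'
#' @param normal plane normal (normalized internally; must be nonzero).
#' @return list with `axis` (unit 3-vector), `angle` (radians),
#'   `angle_deg`, and the 3x3 rotation matrix `R` (identity when `normal`
#'   is already along `P`).
#' @export
listing_frame <- function(normal) {
  stopifnot(length(normal) == 3L, all(is.finite(normal)))
  nrm <- sqrt(sum(normal^2))
  if (nrm == 0) stop("zero normal")
  n <- normal / nrm
  P <- c(1, 0, 0)
  ax <- cross3(n, P)
  axn <- sqrt(sum(ax^2))
  ang <- acos(max(-1, min(1, sum(n * P))))
  if (axn < 1e-12) {
    axis <- c(0, 1, 0)  # arbitrary for the parallel case; angle is 0 (or pi)
    R <- diag(3)
  } else {
    axis <- ax / axn
    R <- axis_angle_matrix(axis, ang)
  }
  list(axis = axis, angle = ang, angle_deg = ang * 180 / pi, R = R)
}

#' Rodrigues rotation matrix
#' @param axis unit rotation axis.
#' @param angle rotation angle, radians.
#' @export
axis_angle_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Cross product of two 3-vectors.
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
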