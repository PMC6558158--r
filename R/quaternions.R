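#' Quaternion utilities
#'
#' Minimal Hamilton-quaternion toolbox used by the orientation filter and the
#' synthetic-data generator. Quaternions are stored scalar-first as numeric
#' vectors `c(w, x, y, z)`; series of quaternions are `n x 4` matrices, one
#' row per sample. All rotations are active: `quat_rotate(q, v)` rotates the
#' vector `v` by the rotation that `q` encodes, so for a unit quaternion built
#' from axis `n` and angle `theta`, `quat_rotate(q, v)` turns `v` about `n` by
#' `theta` following the right-hand rule.
#'
#' @param axis unit 3-vector (or `n x 3` matrix) rotation axis
#' @param angle rotation angle(s), radians
#' @return `quat_from_axis_angle()` returns a quaternion (or `n x 4` matrix).
#' @examples
#' q <- quat_from_axis_angle(c(0, 0, 1), pi / 2)
#' quat_rotate(q, c(1, 0, 0)) # ~ (0, 1, 0)
#' @export
quat_from_axis_angle <- function(axis, angle) {
  if (is.null(dim(axis))) axis <- matrix(axis, nrow = 1L)
  stopifnot(ncol(axis) == 3L)
  angle <- rep_len(angle, nrow(axis))
  half <- angle / 2
  q <- cbind(cos(half), sin(half) * axis[, 1L], sin(half) * axis[, 2L],
             sin(half) * axis[, 3L])
  drop_quat(q)
}

#' @rdname quat_from_axis_angle
#' @param q,q1,q2 quaternions, length-4 vectors or `n x 4` matrices
#' @export
quat_multiply <- function(q1, q2) {
  q1 <- as_quat_matrix(q1); q2 <- as_quat_matrix(q2)
  n <- max(nrow(q1), nrow(q2))
  if (nrow(q1) == 1L) q1 <- q1[rep(1L, n), , drop = FALSE]
  if (nrow(q2) == 1L) q2 <- q2[rep(1L, n), , drop = FALSE]
  w1 <- q1[, 1L]; x1 <- q1[, 2L]; y1 <- q1[, 3L]; z1 <- q1[, 4L]
  w2 <- q2[, 1L]; x2 <- q2[, 2L]; y2 <- q2[, 3L]; z2 <- q2[, 4L]
  drop_quat(cbind(
    w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2))
}

#' @rdname quat_from_axis_angle
#' @export
quat_conjugate <- function(q) {
  q <- as_quat_matrix(q)
  drop_quat(cbind(q[, 1L], -q[, 2L], -q[, 3L], -q[, 4L]))
}

#' @rdname quat_from_axis_angle
#' @export
quat_inverse <- function(q) {
  q <- as_quat_matrix(q)
  n2 <- rowSums(q^2)
  drop_quat(cbind(q[, 1L], -q[, 2L], -q[, 3L], -q[, 4L]) / n2)
}

#' @rdname quat_from_axis_angle
#' @export
quat_normalize <- function(q) {
  q <- as_quat_matrix(q)
  drop_quat(q / sqrt(rowSums(q^2)))
}

#' @rdname quat_from_axis_angle
#' @param v 3-vector or `n x 3` matrix of vectors to rotate
#' @export
quat_rotate <- function(q, v) {
  q <- as_quat_matrix(q)
  single_v <- is.null(dim(v))
  if (single_v) v <- matrix(v, nrow = 1L)
  n <- max(nrow(q), nrow(v))
  if (nrow(q) == 1L) q <- q[rep(1L, n), , drop = FALSE]
  if (nrow(v) == 1L) v <- v[rep(1L, n), , drop = FALSE]
  w <- q[, 1L]; u <- q[, 2:4, drop = FALSE]
  # v' = v + 2 w (u x v) + 2 u x (u x v)
  uxv <- row_cross(u, v)
  out <- v + 2 * w * uxv + 2 * row_cross(u, uxv)
  if (single_v && nrow(out) == 1L) out <- drop(out)
  out
}

#' Rotation angle and axis of a quaternion
#'
#' @param q unit quaternion(s)
#' @return `quat_angle()` returns the rotation angle in `[0, pi]`;
#'   `quat_axis()` the unit rotation axis (arbitrary for the identity).
#' @keywords internal
quat_angle <- function(q) {
  q <- as_quat_matrix(q)
  2 * atan2(sqrt(rowSums(q[, 2:4, drop = FALSE]^2)), abs(q[, 1L]))
}

#' Geodesic distance between orientations
#'
#' Angle of the shortest rotation connecting two orientations,
#' `d = acos(2 <q1, q2>^2 - 1)`, in radians within `[0, pi]`. The distance is
#' invariant to a sign flip of either quaternion (q and -q encode the same
#' rotation). Non-unit inputs are normalized with a warning.
#'
#' @param q1,q2 unit quaternions, length-4 vectors or `n x 4` matrices
#' @return numeric vector of angles, radians
#' @examples
#' geodesic_distance(c(1, 0, 0, 0), quat_from_axis_angle(c(1, 0, 0), pi))
#' @export
geodesic_distance <- function(q1, q2) {
  q1 <- as_quat_matrix(q1); q2 <- as_quat_matrix(q2)
  n1 <- sqrt(rowSums(q1^2)); n2 <- sqrt(rowSums(q2^2))
  if (any(abs(n1 - 1) > 1e-6) || any(abs(n2 - 1) > 1e-6)) {
    warning("non-unit quaternion input; normalizing")
  }
  q1 <- q1 / n1; q2 <- q2 / n2
  n <- max(nrow(q1), nrow(q2))
  if (nrow(q1) == 1L) q1 <- q1[rep(1L, n), , drop = FALSE]
  if (nrow(q2) == 1L) q2 <- q2[rep(1L, n), , drop = FALSE]
  dot <- rowSums(q1 * q2)
  acos(pmin(1, pmax(-1, 2 * dot^2 - 1)))
}

as_quat_matrix <- function(q) {
  if (is.null(dim(q))) {
    stopifnot(length(q) == 4L)
    q <- matrix(q, nrow = 1L)
  }
  stopifnot(ncol(q) == 4L)
  q
}

drop_quat <- function(q) {
  if (nrow(q) == 1L) drop(q) else q
}

row_cross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' Minimal (yaw-free) rotation aligning gravity
#'
#' Quaternion `R(n, theta)` with axis `n = g_w x g` and angle
#' `theta = acos(<g_w, g>)`: the shortest rotation taking the world vertical
#' `g_w` onto the measured gravity direction `g`. Rotating by its inverse maps
#' sensor-frame vectors into the gravity-aligned frame. By construction the
#' rotation axis is horizontal, so the transform carries no yaw.
#'
#' @param g unit gravity direction(s) in sensor coordinates (`n x 3` or 3-vector)
#' @param g_world unit world vertical, default `c(0, 0, 1)`
#' @return quaternion(s)
#' @keywords internal
tilt_quaternion <- function(g, g_world = c(0, 0, 1)) {
  single <- is.null(dim(g))
  if (single) g <- matrix(g, nrow = 1L)
  gw <- matrix(g_world, nrow = nrow(g), ncol = 3L, byrow = TRUE)
  n <- row_cross(gw, g)
  nn <- sqrt(rowSums(n^2))
  theta <- acos(pmin(1, pmax(-1, rowSums(gw * g))))
  axis <- n / ifelse(nn > 1e-12, nn, 1)
  # degenerate (parallel/antiparallel): identity axis, angle 0 or pi about x
  deg <- nn <= 1e-12
  if (any(deg)) axis[deg, ] <- matrix(c(1, 0, 0), sum(deg), 3, byrow = TRUE)
  q <- quat_from_axis_angle(axis, theta)
  q
}
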