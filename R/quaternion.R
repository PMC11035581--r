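# Quaternion algebra and strapdown gyro integration.
#
# Convention used throughout the package: Hamilton quaternions, scalar-first
# (w, x, y, z), right-handed frames.  q represents the rotation from the
# sensor frame S to the user (ground-fixed) frame U, i.e. v_U = R(q) v_S.
# The canonical ("northern hemisphere") representative of {q, -q} has w >= 0.

#' Construct a unit quaternion
#'
#' @param w,x,y,z Components (scalar part first). A length-4 vector may be
#'   passed as `w` with the others missing.
#' @param normalize Renormalize to unit length (default `TRUE`).
#' @return Numeric vector of length 4, class `quaternion`.
#' @export
quaternion <- function(w, x = NULL, y = NULL, z = NULL, normalize = TRUE) {
  q <- if (is.null(x)) as.numeric(w) else c(w, x, y, z)
  if (length(q) != 4L || !all(is.finite(q)))
    stop("quaternion requires 4 finite components", call. = FALSE)
  if (normalize) {
    n <- sqrt(sum(q^2))
    if (n < 1e-12) stop("cannot normalize a zero quaternion", call. = FALSE)
    q <- q / n
  }
  structure(q, class = "quaternion")
}

#' Identity quaternion
#' @return The identity rotation `(1, 0, 0, 0)`.
#' @export
quat_identity <- function() quaternion(c(1, 0, 0, 0), normalize = FALSE)

#' Canonical (northern hemisphere) representative
#'
#' Maps `q` and `-q` to the same representative with nonnegative scalar part.
#' When `w` is exactly zero the first nonzero component is made positive so
#' canonicalization stays a function.
#' @param q Unit quaternion.
#' @return Unit quaternion with `w >= 0`.
#' @export
quat_canonical <- function(q) {
  q <- unclass(q)
  if (q[1] < 0) q <- -q
  else if (q[1] == 0) {
    i <- which(q != 0)[1]
    if (!is.na(i) && q[i] < 0) q <- -q
  }
  structure(q, class = "quaternion")
}

#' Quaternion conjugate
#' @param q Unit quaternion.
#' @return The conjugate (inverse rotation for unit quaternions).
#' @export
quat_conjugate <- function(q)
  structure(c(q[1], -q[2], -q[3], -q[4]), class = "quaternion")

#' Hamilton product of two quaternions
#'
#' Composes rotations so that `R(quat_product(a, b)) = R(a) %*% R(b)`.
#' @param a,b Unit quaternions.
#' @param normalize Renormalize the product (default `TRUE`).
#' @return Unit quaternion `a` \eqn{\otimes} `b`.
#' @export
quat_product <- function(a, b, normalize = TRUE) {
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("non-finite quaternion input", call. = FALSE)
  w <- a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4]
  x <- a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3]
  y <- a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2]
  z <- a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  quaternion(c(w, x, y, z), normalize = normalize)
}

#' Rotation matrix of a unit quaternion
#' @param q Unit quaternion.
#' @return 3x3 rotation matrix `R(q)` with `v_U = R(q) v_S`.
#' @export
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Unit quaternion from a rotation matrix
#'
#' Shepperd's method: picks the numerically largest of the four candidate
#' pivots. Result is canonicalized (`w >= 0`).
#' @param R 3x3 rotation matrix.
#' @return Unit quaternion.
#' @export
matrix_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_canonical(quaternion(q))
}

#' Axis-angle quaternion
#' @param axis Rotation axis (length-3, need not be unit).
#' @param angle Rotation angle in radians.
#' @return Unit quaternion rotating by `angle` about `axis`.
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-15) return(quat_identity())
  quaternion(c(cos(angle / 2), sin(angle / 2) * axis / n), normalize = FALSE)
}

#' Rotate a 3-vector by a unit quaternion
#'
#' Computes `R(q) %*% v` (sensor frame to user frame for q = q_S^U).
#' @param q Unit quaternion.
#' @param v Numeric vector of length 3, or an n x 3 matrix of row vectors.
#' @return Rotated vector(s), same shape as `v`.
#' @export
quat_rotate <- function(q, v) {
  if (!all(is.finite(q)) || !all(is.finite(v)))
    stop("non-finite input", call. = FALSE)
  R <- quat_to_matrix(q)
  if (is.matrix(v)) v %*% t(R) else drop(R %*% v)
}

#' Angle between two rotations
#'
#' The rotation angle of the relative quaternion `qa^{-1} (x) qb` in
#' axis-angle form, computed with `atan2` of the vector-part norm against the
#' absolute scalar part so the result lies in `[0, pi]`, is symmetric in its
#' arguments and is invariant to sign flips of either argument.
#' @param qa,qb Unit quaternions.
#' @return Angle in radians, in `[0, pi]`.
#' @export
quat_angle_error <- function(qa, qb) {
  d <- quat_product(quat_conjugate(qa), qb)
  2 * atan2(sqrt(sum(d[2:4]^2)), abs(d[1]))
}

#' Quaternion distance loss
#'
#' `1 - |q_true . q_est|` (4-dimensional dot product). Zero iff the two
#' quaternions represent the same rotation; invariant under the q/-q double
#' cover; equals `1 - |cos(theta/2)|` where `theta` is [quat_angle_error()].
#' @param q_true,q_est Unit quaternions.
#' @return Scalar in `[0, 1]`.
#' @export
quat_distance_loss <- function(q_true, q_est)
  1 - abs(sum(unclass(q_true) * unclass(q_est)))

#' Average rotation of a set of quaternions
#'
#' The rotation average: the principal eigenvector of the accumulated outer
#' product matrix `sum(q_i q_i^T)`, which maximizes `sum((q . q_i)^2)` and is
#' therefore insensitive to the sign of each input.
#' @param qs List of unit quaternions, or an n x 4 numeric matrix.
#' @return Canonical unit quaternion.
#' @export
mean_quaternion <- function(qs) {
  Q <- if (is.matrix(qs)) qs else do.call(rbind, lapply(qs, unclass))
  if (is.null(Q) || nrow(Q) == 0L)
    stop("mean_quaternion requires at least one quaternion", call. = FALSE)
  A <- crossprod(Q)                        # sum of outer products
  v <- eigen(A, symmetric = TRUE)$vectors[, 1]
  quat_canonical(quaternion(v))
}

#' Strapdown integration of gyroscope samples
#'
#' Propagates orientation with the first-order update
#' `q(t+1) = q(t) + (1/2) (q(t) (x) omega(t)) dt`, the angular velocity
#' embedded as a pure quaternion `(0, omega)`, followed by renormalization at
#' every step (the raw first-order update is not norm-preserving).  The
#' body-frame (right-multiplication) form is used, consistent with q = q_S^U.
#'
#' @param q0 Initial unit quaternion.
#' @param gyro n x 3 matrix of angular velocity samples (rad/s, sensor
#'   frame); row `i` is taken as constant over step `i`.
#' @param dt Sampling interval in seconds (> 0).
#' @return `orientation_series`: list with `t` (seconds, starting at 0) and
#'   `q` ((n+1) x 4 matrix of unit quaternions); first row equals `q0`.
#' @export
integrate_gyro <- function(q0, gyro, dt) {
  if (!(dt > 0)) stop("dt must be positive", call. = FALSE)
  if (is.null(gyro)) gyro <- matrix(numeric(0), ncol = 3)
  if (!is.matrix(gyro)) gyro <- matrix(gyro, ncol = 3, byrow = TRUE)
  n <- nrow(gyro)
  Q <- matrix(NA_real_, n + 1L, 4L)
  Q[1L, ] <- unclass(quaternion(q0))
  if (n > 0L) {
    for (i in seq_len(n)) {
      q <- Q[i, ]
      w <- gyro[i, ]
      # q (x) (0, w), expanded
      dq <- c(-q[2] * w[1] - q[3] * w[2] - q[4] * w[3],
               q[1] * w[1] + q[3] * w[3] - q[4] * w[2],
               q[1] * w[2] - q[2] * w[3] + q[4] * w[1],
               q[1] * w[3] + q[2] * w[2] - q[3] * w[1])
      qn <- q + 0.5 * dq * dt
      Q[i + 1L, ] <- qn / sqrt(sum(qn^2))
    }
  }
  orientation_series(t = dt * (0:n), q = Q)
}

#' Orientation time series
#'
#' @param t Timestamps in seconds, strictly increasing with a uniform step.
#' @param q n x 4 matrix of unit quaternions (rows renormalized).
#' @return List of class `orientation_series` with elements `t` and `q`.
#' @export
orientation_series <- function(t, q) {
  q <- as.matrix(q)
  if (length(t) != nrow(q)) stop("t and q lengths differ", call. = FALSE)
  if (length(t) > 1L) {
    dtv <- diff(t)
    if (any(dtv <= 0) || diff(range(dtv)) > 1e-6)
      stop("timestamps must increase with a uniform step", call. = FALSE)
  }
  q <- q / sqrt(rowSums(q^2))
  structure(list(t = as.numeric(t), q = q), class = "orientation_series")
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<orientation_series: %d samples, %.4g s>\n",
              length(x$t), if (length(x$t)) diff(range(x$t)) else 0))
  invisible(x)
}

#' @export
print.quaternion <- function(x, ...) {
  cat(sprintf("<quaternion w=% .4f x=% .4f y=% .4f z=% .4f>\n",
              x[1], x[2], x[3], x[4]))
  invisible(x)
}
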