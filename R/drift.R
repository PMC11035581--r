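# Drift removal for the double-integrated wrist trajectory.
#
# Two kinematic constraints of the golf swing are exploited:
#  * the wrist speed is (near) zero at the address (ADD), backswing top
#    (BST) and finish (FIN) events -> time-based linear velocity correction
#    anchored at those events;
#  * the wrist path closely follows a circle in the swing plane -> the
#    trajectory endpoint at FIN is pulled onto a least-squares "virtual
#    circle", and the implied constant sensor-frame acceleration bias is
#    estimated and removed.

#' Swing plane and virtual circle
#' @param v_n Unit plane normal (sign convention: nonnegative Z component,
#'   ties broken toward nonnegative X).
#' @param c_circ Circle centre, m (lies in the plane).
#' @param r_circ Circle radius, m (> 0).
#' @return List of class `swing_plane`.
#' @export
swing_plane <- function(v_n, c_circ, r_circ) {
  v_n <- as.numeric(v_n)
  n <- sqrt(sum(v_n^2))
  if (abs(n - 1) > 1e-9) v_n <- v_n / n
  if (!(r_circ > 0)) stop("r_circ must be positive", call. = FALSE)
  structure(list(v_n = v_n, c_circ = as.numeric(c_circ), r_circ = r_circ),
            class = "swing_plane")
}

#' @export
print.swing_plane <- function(x, ...) {
  cat(sprintf("<swing_plane: n=(%.3f, %.3f, %.3f), r=%.3f m>\n",
              x$v_n[1], x$v_n[2], x$v_n[3], x$r_circ))
  invisible(x)
}

cumtrapz3 <- function(t, X) pracma::cumtrapz(as.numeric(t), as.matrix(X))

#' Rotate sensor-frame acceleration into the user frame and remove gravity
#'
#' The accelerometer measures specific force; after rotating into the user
#' frame the constant gravity vector `g_vec = (0, 0, -9.80665)` m/s^2 is
#' added back, so a stationary sensor yields (near-)zero output.
#'
#' @param rec `imu_recording` (sensor-frame specific force in `rec$accel`).
#' @param orient [orientation_series] aligned sample-by-sample with `rec`
#'   (or with the index window the series was propagated over).
#' @param idx Optional index vector into `rec` matching `orient` (defaults
#'   to the first `length(orient$t)` samples).
#' @return n x 3 matrix of user-frame acceleration, m/s^2.
#' @export
acceleration_to_user_frame <- function(rec, orient, idx = NULL) {
  if (is.null(idx)) idx <- seq_along(orient$t)
  if (length(idx) != nrow(orient$q))
    stop("recording window and orientation series lengths differ",
         call. = FALSE)
  A <- rec$accel[idx, , drop = FALSE]
  out <- matrix(NA_real_, nrow(A), 3L)
  for (j in seq_len(nrow(A))) {
    R <- quat_to_matrix(quaternion(orient$q[j, ], normalize = FALSE))
    out[j, ] <- drop(R %*% A[j, ])
  }
  sweep(out, 2, c(0, 0, -GRAVITY), "+")
}

#' Integrate user-frame acceleration to velocity
#'
#' Cumulative trapezoidal integration from ADD; the velocity at ADD is zero
#' by definition of the integral.
#'
#' @param a_user n x 3 user-frame acceleration over `[t_ADD, t_FIN]`, m/s^2.
#' @param dt Sampling interval, s.
#' @return n x 3 velocity, m/s, first row zero.
#' @export
integrate_velocity <- function(a_user, dt) {
  n <- nrow(a_user)
  cumtrapz3(dt * (0:(n - 1L)), a_user)
}

#' Zero-velocity anchored linear drift correction
#'
#' Subtracts a piecewise-linear (in time) drift model so the velocity is
#' exactly zero at ADD, BST and FIN.  On `(ADD, BST]` the ramp removes the
#' residual at BST; on `(BST, FIN]` the BST offset is first removed and a
#' second ramp removes the remaining residual at FIN.  The `"literal"`
#' variant instead ramps the raw FIN residual (which leaves a nonzero value
#' at FIN whenever the BST residual is nonzero).
#'
#' @param v_ori n x 3 velocity over `[t_ADD, t_FIN]` with first row zero.
#' @param events [swing_events()] (only the relative positions of BST and
#'   FIN within the window are used).
#' @param variant `"anchored"` (default) or `"literal"`.
#' @return n x 3 corrected velocity `v_Vcal`.
#' @export
correct_velocity <- function(v_ori, events, variant = c("anchored",
                                                        "literal")) {
  variant <- match.arg(variant)
  n <- nrow(v_ori)
  i_bst <- events[["bst"]] - events[["add"]] + 1L
  i_fin <- events[["fin"]] - events[["add"]] + 1L
  if (i_bst <= 1L || i_fin <= i_bst || i_fin > n)
    stop("invalid events for velocity correction", call. = FALSE)
  out <- v_ori
  ramp1 <- (seq_len(n) - 1) / (i_bst - 1)          # (t - ADD)/(BST - ADD)
  seg1 <- 2:i_bst
  v_bst <- v_ori[i_bst, ]
  out[seg1, ] <- v_ori[seg1, ] - outer(ramp1[seg1], v_bst)
  seg2 <- (i_bst + 1L):i_fin
  ramp2 <- (seg2 - i_bst) / (i_fin - i_bst)        # (t - BST)/(FIN - BST)
  v_fin_resid <- if (variant == "anchored") v_ori[i_fin, ] - v_bst
                 else v_ori[i_fin, ]
  out[seg2, ] <- v_ori[seg2, ] - matrix(v_bst, length(seg2), 3,
                                        byrow = TRUE) -
    outer(ramp2, v_fin_resid)
  out
}

#' Integrate velocity to trajectory
#' @param v n x 3 velocity over `[t_ADD, t_FIN]`, m/s.
#' @param dt Sampling interval, s.
#' @return n x 3 trajectory, m, starting at the origin.
#' @export
integrate_trajectory <- function(v, dt) {
  n <- nrow(v)
  cumtrapz3(dt * (0:(n - 1L)), v)
}

#' Fit the swing plane normal by SVD
#'
#' The plane minimizing the sum of squared orthogonal distances to the
#' points: its normal is the right singular vector of the centred point
#' cloud with the smallest singular value.  Sign convention: nonnegative Z
#' component, ties broken toward nonnegative X.
#'
#' @param points m x 3 matrix (typically the backswing segment of the
#'   velocity-corrected trajectory).
#' @return Unit normal vector, length 3.
#' @export
fit_swing_plane <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 points", call. = FALSE)
  X <- sweep(points, 2, colMeans(points), "-")
  sv <- svd(X)
  if (sv$d[2] < 1e-6 * sv$d[1])
    stop("degenerate (collinear) point cloud", call. = FALSE)
  v_n <- sv$v[, 3]
  if (v_n[3] < 0 || (v_n[3] == 0 && v_n[1] < 0)) v_n <- -v_n
  v_n
}

#' Fit the virtual circle in the swing plane
#'
#' Points are projected onto the plane through their centroid with normal
#' `v_n`; the algebraic (Kasa) least-squares circle is solved in 2D plane
#' coordinates and the centre mapped back to 3D.  An optional Gauss-Newton
#' refinement of the geometric fit is available.
#'
#' @param points m x 3 matrix.
#' @param v_n Unit plane normal from [fit_swing_plane()].
#' @param refine Run Gauss-Newton geometric refinement (default `FALSE`).
#' @return [swing_plane()].
#' @export
fit_virtual_circle <- function(points, v_n, refine = FALSE) {
  points <- as.matrix(points)
  ctr <- colMeans(points)
  # in-plane basis
  a <- if (abs(v_n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unit3(a - sum(a * v_n) * v_n)
  e2 <- cross3(v_n, e1)
  X <- sweep(points, 2, ctr, "-")
  u <- drop(X %*% e1); v <- drop(X %*% e2)
  A <- cbind(2 * u, 2 * v, 1)
  qrA <- qr(A)
  if (qrA$rank < 3L)
    stop("degenerate (collinear) projected points", call. = FALSE)
  sol <- qr.coef(qrA, u^2 + v^2)
  cu <- sol[1]; cv <- sol[2]
  r <- sqrt(sol[3] + cu^2 + cv^2)
  if (refine) {
    for (it in 1:20) {
      du <- u - cu; dv <- v - cv
      d <- sqrt(du^2 + dv^2)
      ok <- d > 1e-12
      J <- cbind(-du[ok] / d[ok], -dv[ok] / d[ok], -1)
      res <- d[ok] - r
      step <- tryCatch(qr.solve(J, -res), error = function(e) NULL)
      if (is.null(step)) break
      cu <- cu + step[1]; cv <- cv + step[2]; r <- r + step[3]
      if (max(abs(step)) < 1e-12) break
    }
  }
  c3 <- ctr + cu * e1 + cv * e2
  swing_plane(v_n, c3, r)
}

#' Project the trajectory endpoint onto the virtual circle
#'
#' Decomposes the FIN endpoint into its out-of-plane component `d_FIN`, its
#' in-plane projection `r_cal`, and the corrected endpoint `ep`: the radial
#' projection of `r_cal` onto the circle.  `ep` is the closest circle point
#' to the endpoint.
#'
#' @param traj_fin Endpoint `Traj_Vcal(t_FIN)`, length 3.
#' @param plane [swing_plane()].
#' @return List with `d_FIN`, `r_cal`, `ep` (each length 3).
#' @export
project_endpoint <- function(traj_fin, plane) {
  v_n <- plane$v_n; cc <- plane$c_circ
  d_fin <- sum((traj_fin - cc) * v_n) * v_n
  r_cal <- traj_fin - d_fin
  u <- r_cal - cc
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12)
    stop("endpoint projects onto the circle centre", call. = FALSE)
  ep <- cc + plane$r_circ * u / nu
  list(d_FIN = d_fin, r_cal = r_cal, ep = ep)
}

# cumulative double trapezoidal integral of the rotated unit-bias series:
# columns j of the result at time i give [int int R(q) e_j] (i-th sample)
bias_response <- function(orient, dt) {
  n <- nrow(orient$q)
  Rcols <- array(NA_real_, c(n, 3, 3))
  for (i in seq_len(n))
    Rcols[i, , ] <- quat_to_matrix(quaternion(orient$q[i, ],
                                              normalize = FALSE))
  tt <- dt * (0:(n - 1L))
  D <- array(NA_real_, c(n, 3, 3))          # [time, space, bias axis]
  for (j in 1:3) {
    vj <- cumtrapz3(tt, Rcols[, , j])
    D[, , j] <- cumtrapz3(tt, vj)
  }
  D
}

#' Estimate the constant sensor-frame acceleration bias
#'
#' Finds the bias vector `b` (sensor x-y-z) whose removal moves the
#' double-integrated endpoint from `Traj_Vcal(t_FIN)` to the circle point
#' `ep`.  The endpoint is linear in `b`, so `b` solves the 3 x 3 system
#' `M b = Traj_Vcal(t_FIN) - ep`, where column j of `M` is the double
#' integral (same trapezoidal quadrature as the trajectory) of the rotated
#' unit bias `R(q(t)) e_j`.  A least-squares solve is used when `M` is
#' ill-conditioned.
#'
#' @param traj_fin Endpoint `Traj_Vcal(t_FIN)`.
#' @param ep Corrected endpoint from [project_endpoint()].
#' @param orient [orientation_series] over `[t_ADD, t_FIN]`.
#' @param dt Sampling interval, s.
#' @return List with `a_bias` (length 3, sensor frame, m/s^2) and the
#'   response array `D` for reuse in [apply_bias_and_reintegrate()].
#' @export
estimate_sensor_bias <- function(traj_fin, ep, orient, dt) {
  D <- bias_response(orient, dt)
  n <- dim(D)[1]
  M <- D[n, , ]                              # 3 x 3 endpoint response
  rhs <- as.numeric(traj_fin - ep)
  k <- tryCatch(kappa(M, exact = TRUE), error = function(e) Inf)
  if (!is.finite(k) || k > 1e8) {
    sv <- svd(M)
    if (sv$d[1] < 1e-12)
      stop("singular bias response matrix", call. = FALSE)
    pos <- sv$d > 1e-10 * sv$d[1]
    b <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], rhs)) / sv$d[pos])
    b <- drop(b)
  } else {
    b <- drop(solve(M, rhs))
  }
  list(a_bias = b, D = D)
}

#' Remove the estimated bias and re-integrate the trajectory
#'
#' The bias enters the double integral linearly, so the corrected trajectory
#' is computed as `Traj_Tcal(t) = Traj_Vcal(t) - D(t) b`, where `D(t)` is
#' the cumulative double integral of the rotated unit biases under the same
#' trapezoidal quadrature.  This is the bias-subtracted re-integration
#' evaluated without a numerically inconsistent differentiate-reintegrate
#' round trip, and it lands the endpoint on `ep` exactly.  The sensor-frame
#' corrected acceleration `a_Tcal` is also reported (central-difference
#' derivative of `v_Vcal`, rotated back, minus the bias).
#'
#' @param traj_vcal n x 3 velocity-corrected trajectory.
#' @param v_vcal n x 3 velocity-corrected velocity (for `a_Tcal`).
#' @param orient [orientation_series] over the same window.
#' @param dt Sampling interval, s.
#' @param a_bias Bias vector from [estimate_sensor_bias()].
#' @param D Optional precomputed response array.
#' @return List with `traj_tcal` (n x 3) and `a_tcal` (n x 3, sensor frame).
#' @export
apply_bias_and_reintegrate <- function(traj_vcal, v_vcal, orient, dt, a_bias,
                                       D = NULL) {
  if (is.null(D)) D <- bias_response(orient, dt)
  n <- nrow(traj_vcal)
  corr <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) corr[i, ] <- D[i, , ] %*% a_bias
  traj_tcal <- traj_vcal - corr
  # sensor-frame acceleration consistent with v_Vcal, minus the bias
  a_vcal_user <- apply(v_vcal, 2, function(col) {
    d <- numeric(n)
    if (n > 2L) d[2:(n - 1L)] <- (col[3:n] - col[1:(n - 2L)]) / (2 * dt)
    d[1] <- (col[2] - col[1]) / dt
    d[n] <- (col[n] - col[n - 1L]) / dt
    d
  })
  a_tcal <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    R <- quat_to_matrix(quaternion(orient$q[i, ], normalize = FALSE))
    a_tcal[i, ] <- drop(crossprod(R, a_vcal_user[i, ])) - a_bias
  }
  list(traj_tcal = traj_tcal, a_tcal = a_tcal)
}

#' Full drift-corrected wrist tracking of one swing
#'
#' Orchestrates the pipeline over `[t_ADD, t_FIN]`: orientation propagation
#' from the address quaternion, rotation of the specific force into the user
#' frame, velocity integration, zero-velocity anchored correction, plane and
#' virtual-circle fitting on the backswing segment, endpoint projection,
#' bias estimation and re-integration.  The uncorrected ("IMU only") double
#' integration is returned alongside for comparison.
#'
#' @param rec Preprocessed `imu_recording`.
#' @param events [swing_events()].
#' @param q_add Unit quaternion: sensor orientation at ADD.
#' @param ramp_variant Variant of the second velocity ramp (see
#'   [correct_velocity()]).
#' @param refine_circle Gauss-Newton refinement of the circle fit.
#' @return List of class `swing_track` with elements `idx` (sample indices
#'   of the window), `orient`, `a_user`, `v_ori`, `v_vcal`, `traj_ori`,
#'   `traj_vcal`, `traj_tcal`, `a_tcal`, `a_bias`, `d_FIN`, `r_cal`, `ep`
#'   and `plane`.
#' @export
track_swing <- function(rec, events, q_add,
                        ramp_variant = c("anchored", "literal"),
                        refine_circle = FALSE) {
  ramp_variant <- match.arg(ramp_variant)
  dt <- 1 / sampling_rate(rec)
  idx <- events[["add"]]:events[["fin"]]
  orient <- propagate_orientation(q_add, rec, events)
  a_user <- acceleration_to_user_frame(rec, orient, idx)
  v_ori <- integrate_velocity(a_user, dt)
  traj_ori <- integrate_trajectory(v_ori, dt)
  v_vcal <- correct_velocity(v_ori, events, variant = ramp_variant)
  traj_vcal <- integrate_trajectory(v_vcal, dt)
  nb <- events[["bst"]] - events[["add"]] + 1L
  back <- traj_vcal[seq_len(nb), , drop = FALSE]
  v_n <- fit_swing_plane(back)
  plane <- fit_virtual_circle(back, v_n, refine = refine_circle)
  n <- nrow(traj_vcal)
  pe <- project_endpoint(traj_vcal[n, ], plane)
  bias <- estimate_sensor_bias(traj_vcal[n, ], pe$ep, orient, dt)
  reint <- apply_bias_and_reintegrate(traj_vcal, v_vcal, orient, dt,
                                      bias$a_bias, D = bias$D)
  structure(list(idx = idx, orient = orient, a_user = a_user,
                 v_ori = v_ori, v_vcal = v_vcal,
                 traj_ori = traj_ori, traj_vcal = traj_vcal,
                 traj_tcal = reint$traj_tcal, a_tcal = reint$a_tcal,
                 a_bias = bias$a_bias, d_FIN = pe$d_FIN, r_cal = pe$r_cal,
                 ep = pe$ep, plane = plane),
            class = "swing_track")
}

#' @export
print.swing_track <- function(x, ...) {
  cat(sprintf(
    "<swing_track: %d samples, |a_bias|=%.3f m/s^2, r_circ=%.3f m>\n",
    length(x$idx), sqrt(sum(x$a_bias^2)), x$plane$r_circ))
  invisible(x)
}
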