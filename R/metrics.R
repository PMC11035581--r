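# Evaluation metrics for velocity/trajectory series and the circle fit.

#' Mean absolute error between two 3D series
#'
#' @param est,ref n x 3 matrices (same length).
#' @param mode `"vector"`: mean Euclidean norm of the error vectors;
#'   `"per-axis"`: mean absolute error per component.
#' @return Scalar (vector mode) or named length-3 vector (per-axis mode).
#' @export
mae <- function(est, ref, mode = c("vector", "per-axis")) {
  mode <- match.arg(mode)
  est <- as.matrix(est); ref <- as.matrix(ref)
  if (!all(dim(est) == dim(ref)))
    stop("series lengths differ", call. = FALSE)
  d <- est - ref
  if (mode == "vector") mean(sqrt(rowSums(d^2)))
  else c(X = mean(abs(d[, 1])), Y = mean(abs(d[, 2])), Z = mean(abs(d[, 3])))
}

#' Coefficient of determination of a trajectory against the virtual circle
#'
#' `1 - SS_res / SS_tot`, where the residual of each point is its 3D
#' distance to the nearest point of the circle (out-of-plane and radial
#' components combined) and `SS_tot` uses squared distances from the point
#' centroid.  Can be negative for trajectories unrelated to the circle.
#'
#' @param traj n x 3 trajectory, m.
#' @param plane [swing_plane()].
#' @return Scalar R-squared (<= 1).
#' @export
circle_r_squared <- function(traj, plane) {
  traj <- as.matrix(traj)
  if (nrow(traj) < 3L) stop("need at least 3 points", call. = FALSE)
  ctr <- colMeans(traj)
  ss_tot <- sum(sweep(traj, 2, ctr, "-")^2)
  if (ss_tot <= 0) stop("zero total variance", call. = FALSE)
  X <- sweep(traj, 2, plane$c_circ, "-")
  z <- drop(X %*% plane$v_n)                    # out-of-plane component
  inp <- X - outer(z, plane$v_n)
  rad <- sqrt(rowSums(inp^2)) - plane$r_circ    # radial residual in plane
  ss_res <- sum(z^2 + rad^2)
  1 - ss_res / ss_tot
}

#' Relative wrist speed at the three zero-velocity anchors
#'
#' @param v n x 3 velocity over `[t_ADD, t_FIN]`, m/s.
#' @param events [swing_events()].
#' @return Named percentages `c(add, bst, fin)`: anchor speed relative to
#'   the maximum swing speed.
#' @export
relative_anchor_speed <- function(v, events) {
  speed <- sqrt(rowSums(as.matrix(v)^2))
  vmax <- max(speed)
  if (!(vmax > 0)) stop("zero maximum speed", call. = FALSE)
  i <- c(add = 1L,
         bst = events[["bst"]] - events[["add"]] + 1L,
         fin = events[["fin"]] - events[["add"]] + 1L)
  100 * speed[i] / vmax
}

#' Percent error reduction
#' @param err_before,err_after Error magnitudes (before > 0).
#' @return `100 * (before - after) / before`.
#' @export
percent_error_reduction <- function(err_before, err_after) {
  if (any(err_before <= 0)) stop("err_before must be positive", call. = FALSE)
  100 * (err_before - err_after) / err_before
}

#' Per-phase MAE breakdown
#'
#' Splits the window `[t_ADD, t_FIN]` into backswing `[ADD, BST]`, downswing
#' `(BST, IMP]` and follow-through `(IMP, FIN]` and reports the 3D vector
#' MAE of each.
#'
#' @param est,ref n x 3 series over `[t_ADD, t_FIN]`.
#' @param events [swing_events()].
#' @return Named length-4 vector: `backswing`, `downswing`,
#'   `follow_through`, `entire`.
#' @export
phase_mae <- function(est, ref, events) {
  i_b <- events[["bst"]] - events[["add"]] + 1L
  i_i <- events[["imp"]] - events[["add"]] + 1L
  i_f <- events[["fin"]] - events[["add"]] + 1L
  c(backswing = mae(est[1:i_b, , drop = FALSE], ref[1:i_b, , drop = FALSE]),
    downswing = mae(est[(i_b + 1L):i_i, , drop = FALSE],
                    ref[(i_b + 1L):i_i, , drop = FALSE]),
    follow_through = mae(est[(i_i + 1L):i_f, , drop = FALSE],
                         ref[(i_i + 1L):i_f, , drop = FALSE]),
    entire = mae(est[1:i_f, , drop = FALSE], ref[1:i_f, , drop = FALSE]))
}
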