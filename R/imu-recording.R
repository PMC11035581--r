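# The core data container: a uniformly sampled 6-channel inertial recording.

GRAVITY <- 9.80665  # m/s^2

#' IMU recording container
#'
#' @param t Timestamps in seconds, uniform step (200 Hz nominal).
#' @param accel n x 3 matrix, m/s^2, sensor frame (specific force).
#' @param gyro n x 3 matrix, rad/s, sensor frame.
#' @param accel_range Full-scale accelerometer range, m/s^2
#'   (default 16 g).
#' @param gyro_range Full-scale gyroscope range, rad/s (default 2000 deg/s).
#' @return List of class `imu_recording`.
#' @export
imu_recording <- function(t, accel, gyro,
                          accel_range = 16 * GRAVITY,
                          gyro_range = 2000 * pi / 180) {
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  n <- length(t)
  if (nrow(accel) != n || nrow(gyro) != n || ncol(accel) != 3L ||
      ncol(gyro) != 3L)
    stop("accel and gyro must be n x 3 with n = length(t)", call. = FALSE)
  if (n >= 2L) {
    dtv <- diff(t)
    if (any(dtv <= 0) || diff(range(dtv)) > 1e-6)
      stop("timestamps must be strictly increasing and uniform",
           call. = FALSE)
  }
  structure(list(t = as.numeric(t), accel = accel, gyro = gyro,
                 accel_range = accel_range, gyro_range = gyro_range),
            class = "imu_recording")
}

#' Sampling rate of a recording
#' @param rec `imu_recording`.
#' @return Samples per second.
#' @export
sampling_rate <- function(rec) 1 / (rec$t[2] - rec$t[1])

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording: %d samples @ %.6g Hz, %.3g s>\n",
              length(x$t), sampling_rate(x), diff(range(x$t))))
  invisible(x)
}

#' Swing event indices
#'
#' The four swing events: address (ADD), backswing top (BST), impact (IMP)
#' and finish (FIN), as 1-based sample indices into a recording.
#' @param add,bst,imp,fin Sample indices with `add < bst < imp < fin`.
#' @param n_samples Optional recording length for a bounds check.
#' @return Named integer vector of class `swing_events`.
#' @export
swing_events <- function(add, bst, imp, fin, n_samples = NULL) {
  e <- c(add = as.integer(add), bst = as.integer(bst),
         imp = as.integer(imp), fin = as.integer(fin))
  if (any(is.na(e)) || !(e[1] < e[2] && e[2] < e[3] && e[3] < e[4]))
    stop("events must satisfy add < bst < imp < fin", call. = FALSE)
  if (e[1] < 1L || (!is.null(n_samples) && e[4] > n_samples))
    stop("events out of recording bounds", call. = FALSE)
  structure(e, class = "swing_events")
}

#' @export
print.swing_events <- function(x, ...) {
  cat(sprintf("<swing_events: ADD=%d BST=%d IMP=%d FIN=%d>\n",
              x[1], x[2], x[3], x[4]))
  invisible(x)
}

as_channel_matrix <- function(rec) cbind(rec$accel, rec$gyro)

channel_names <- c("ax", "ay", "az", "gx", "gy", "gz")
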