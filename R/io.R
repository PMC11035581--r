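# CSV/JSON input-output.
#
# IMU CSV dialect: optional comment lines starting with '#' (notably
# '# units: rad/s' or '# units: deg/s' for the gyro columns), then a header
# 't,ax,ay,az,gx,gy,gz'; t in seconds, accel in m/s^2; UTF-8, '.' decimal
# point, ',' separator.

#' Read an IMU recording from CSV
#'
#' @param path File path.
#' @param accel_range,gyro_range Sensor ranges to attach (m/s^2, rad/s).
#' @return `imu_recording` (gyro converted to rad/s if the file declares
#'   deg/s).
#' @export
read_imu_csv <- function(path, accel_range = 16 * GRAVITY,
                         gyro_range = 2000 * pi / 180) {
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  unit <- "rad/s"
  unit_line <- grep("^\\s*#\\s*units\\s*:", lines, value = TRUE)
  if (length(unit_line)) {
    u <- trimws(sub("^\\s*#\\s*units\\s*:", "", unit_line[1]))
    if (grepl("deg", u, ignore.case = TRUE)) unit <- "deg/s"
    else if (!grepl("rad", u, ignore.case = TRUE))
      stop(sprintf("unknown gyro unit declaration '%s'", u), call. = FALSE)
  } else {
    warning("no '# units:' comment; assuming gyro in rad/s", call. = FALSE)
  }
  body_start <- which(!is_comment)[1]
  header <- trimws(strsplit(lines[body_start], ",")[[1]])
  if (!identical(header, c("t", "ax", "ay", "az", "gx", "gy", "gz")))
    stop(sprintf("line %d: malformed header (expected t,ax,ay,az,gx,gy,gz)",
                 body_start), call. = FALSE)
  dat <- utils::read.csv(textConnection(lines[-seq_len(body_start)]),
                         header = FALSE,
                         col.names = header)
  off <- body_start                       # data row i is file line off + i
  if (nrow(dat) < 2L) stop("fewer than 2 samples", call. = FALSE)
  bad <- which(!stats::complete.cases(dat) |
                 apply(dat, 1, function(r) any(!is.finite(r))))
  if (length(bad))
    stop(sprintf("line %d: non-finite or missing value", off + bad[1]),
         call. = FALSE)
  nonmono <- which(diff(dat$t) <= 0)
  if (length(nonmono))
    stop(sprintf("line %d: non-monotone timestamp", off + nonmono[1] + 1L),
         call. = FALSE)
  gyro <- unname(as.matrix(dat[, 5:7]))
  if (unit == "deg/s") gyro <- gyro * pi / 180
  imu_recording(dat$t, unname(as.matrix(dat[, 2:4])), gyro,
                accel_range, gyro_range)
}

#' Write an IMU recording to CSV
#' @param rec `imu_recording`.
#' @param path File path.
#' @param gyro_unit `"rad/s"` (default) or `"deg/s"`.
#' @export
write_imu_csv <- function(rec, path, gyro_unit = c("rad/s", "deg/s")) {
  gyro_unit <- match.arg(gyro_unit)
  gyro <- rec$gyro
  if (gyro_unit == "deg/s") gyro <- gyro * 180 / pi
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", gyro_unit), con)
  writeLines("t,ax,ay,az,gx,gy,gz", con)
  M <- cbind(rec$t, rec$accel, gyro)
  writeLines(apply(M, 1, function(r)
    paste(sprintf("%.15g", r), collapse = ",")), con)
  invisible(path)
}

#' Write a tracked swing to CSV
#'
#' One row per sample of the `[t_ADD, t_FIN]` window with the uncorrected
#' (`ori`), velocity-corrected (`vcal`) and fully corrected (`tcal`)
#' trajectories.
#' @param track `swing_track` from [track_swing()].
#' @param rec The source `imu_recording` (for timestamps).
#' @param path File path.
#' @export
write_trajectory_csv <- function(track, rec, path) {
  M <- cbind(rec$t[track$idx], track$traj_ori, track$traj_vcal,
             track$traj_tcal)
  colnames(M) <- c("t", "X_ori", "Y_ori", "Z_ori",
                   "X_vcal", "Y_vcal", "Z_vcal",
                   "X_tcal", "Y_tcal", "Z_tcal")
  utils::write.csv(as.data.frame(M), path, row.names = FALSE)
  invisible(path)
}

#' Write a JSON sidecar with events, plane, bias and optional metrics
#' @param track `swing_track`.
#' @param events [swing_events()].
#' @param path File path.
#' @param metrics Optional named list of extra metrics.
#' @export
write_track_json <- function(track, events, path, metrics = NULL) {
  obj <- list(events = as.list(unclass(events)),
              plane = list(v_n = track$plane$v_n,
                           c_circ = track$plane$c_circ,
                           r_circ = track$plane$r_circ),
              a_bias = track$a_bias,
              ep = track$ep)
  if (!is.null(metrics)) obj$metrics <- metrics
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
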