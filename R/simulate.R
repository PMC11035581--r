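# Synthetic golf-swing generator with full ground truth.
#
# The wrist follows a virtual circle in a tilted swing plane, with a small
# smooth out-of-plane excursion.  The phase angle along the circle is built
# from smooth polynomial (minimum-jerk family) segments with zero angular
# speed at the address (ADD), backswing top (BST) and finish (FIN) events and
# peak speed at impact (IMP).  Sensor orientation is a path-following frame
# composed with a forearm-roll term and a fixed sensor-mount offset.  The
# accelerometer model is specific force: f = R(q)^T (a_user - g_vec) with
# g_vec = (0, 0, -9.80665) m/s^2.
#
# Discretization contract (what makes the generator a usable oracle):
# * the ideal gyro sample for step i is derived from the exact relative
#   quaternion between consecutive true orientations through the tangent
#   map, so first-order strapdown integration reproduces the true
#   orientation to machine precision;
# * ground-truth velocity and trajectory are the exact integrals of the
#   piecewise-linear interpolant of the sampled user-frame acceleration, so
#   trapezoidal (re-)integration of the ideal signals reproduces them to
#   well below a millimetre.

# ---- tiny polynomial helpers (ascending coefficients) ----------------------

poly_eval <- function(p, s) {
  out <- rep(p[length(p)], length(s))
  for (k in rev(seq_len(length(p) - 1L))) out <- out * s + p[k]
  out
}
poly_deriv <- function(p) {
  if (length(p) <= 1L) return(0)
  p[-1L] * seq_len(length(p) - 1L)
}

SS5   <- c(0, 0, 0, 10, -15, 6)          # smooth step, zero vel/acc at ends
SS5I  <- c(0, 0, 0, 0, 2.5, -3, 1)       # its integral (value 1/2 at s = 1)

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

unit3 <- function(v) v / sqrt(sum(v^2))

rot_z <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1),
                            3, 3)
rot_x <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)),
                            3, 3)

plane_basis <- function(tilt, azimuth) {
  n <- c(sin(tilt) * cos(azimuth), sin(tilt) * sin(azimuth), cos(tilt))
  if (n[3] < 0) n <- -n
  e1 <- cross3(c(0, 0, 1), n)
  if (sqrt(sum(e1^2)) < 1e-8) e1 <- c(1, 0, 0) else e1 <- unit3(e1)
  e2 <- cross3(n, e1)
  list(n = n, e1 = e1, e2 = e2, P = cbind(e1, e2, n))
}

#' Synthetic swing specification
#'
#' Defaults emulate the kinematic regime of an adult full swing recorded at
#' the wrist: about 2.14 s between address and finish, peak specific force
#' near 110 m/s^2, peak angular rate near 1600 deg/s, roughly 4.4 m of wrist
#' path on a 1.1 m-radius virtual circle in a plane tilted about 55 degrees
#' from horizontal, with zero wrist speed at ADD, BST and FIN.
#'
#' @param plane_normal_angles `c(tilt, azimuth)` of the swing-plane normal,
#'   radians (tilt measured from vertical).
#' @param circle_center Raw circle centre, m (outputs are re-expressed
#'   relative to the address wrist position, so this only anchors the
#'   internal geometry).
#' @param circle_radius Circle radius, m.
#' @param phase_durations `c(address_hold, backswing, downswing_to_impact,
#'   follow_through)` seconds; backswing + downswing + follow_through is the
#'   ADD-to-FIN swing duration.
#' @param pre_address_pad Stationary padding before the address hold,
#'   seconds (>= 0.1 so orientation input windows fit).
#' @param post_fin_pad Stationary padding after FIN, seconds.
#' @param sweep_back,sweep_down Circle-angle sweeps (rad) of backswing and
#'   downswing; the peak angular speed is `2 * sweep_down /
#'   downswing_duration`.
#' @param omega_low Angular speed (rad/s) at the hand-over point inside the
#'   follow-through deceleration.
#' @param follow_split Fractions of the follow-through spent in the fast and
#'   slow deceleration sub-phases (summing to 1).
#' @param roll_angles Forearm-roll increments (rad) over backswing,
#'   downswing, early and late follow-through.
#' @param sensor_mount Unit quaternion: wrist-to-sensor mounting offset.
#' @param out_of_plane_amplitude Peak out-of-plane excursion, m.
#' @param peak_targets `c(max |accel| m/s^2, max |gyro| deg/s)` the default
#'   profile was tuned to (documentation of the emulated regime).
#' @param noise `c(accel_sd, gyro_sd)` Gaussian noise, m/s^2 and rad/s.
#' @param accel_bias,gyro_bias Constant sensor-frame biases (m/s^2, rad/s).
#' @param clipping_enabled Saturate signals at the sensor ranges.
#' @param accel_range,gyro_range Sensor full-scale values (m/s^2, rad/s).
#' @param rate Sampling rate, Hz.
#' @param seed Integer seed for the noise realization (`NULL`: ambient RNG).
#' @return List of class `swing_spec`.
#' @export
swing_spec <- function(plane_normal_angles = c(tilt = 0.96, azimuth = 0.15),
                       circle_center = c(0, 0, 0),
                       circle_radius = 1.1,
                       phase_durations = c(address_hold = 0.30,
                                           backswing = 1.05,
                                           downswing = 0.30,
                                           follow_through = 0.79),
                       pre_address_pad = 0.25,
                       post_fin_pad = 0.15,
                       sweep_back = 1.3,
                       sweep_down = 1.4,
                       omega_low = 0.8,
                       follow_split = c(0.30, 0.70),
                       roll_angles = c(backswing = -1.2, downswing = 4.2,
                                       follow_a = 0.8, follow_b = 0.2),
                       sensor_mount = quat_from_axis_angle(c(1, 0.5, 0.3),
                                                           0.35),
                       out_of_plane_amplitude = 0.02,
                       peak_targets = c(accel = 111, gyro = 1627),
                       noise = c(accel = 0.25, gyro = 0.008),
                       accel_bias = c(0.3, -0.2, 0.25),
                       gyro_bias = c(0.004, -0.003, 0.002),
                       clipping_enabled = TRUE,
                       accel_range = 16 * GRAVITY,
                       gyro_range = 2000 * pi / 180,
                       rate = 200,
                       seed = NULL) {
  spec <- list(plane_normal_angles = plane_normal_angles,
               circle_center = circle_center,
               circle_radius = circle_radius,
               phase_durations = phase_durations,
               pre_address_pad = pre_address_pad,
               post_fin_pad = post_fin_pad,
               sweep_back = sweep_back, sweep_down = sweep_down,
               omega_low = omega_low, follow_split = follow_split,
               roll_angles = roll_angles, sensor_mount = sensor_mount,
               out_of_plane_amplitude = out_of_plane_amplitude,
               peak_targets = peak_targets, noise = noise,
               accel_bias = accel_bias, gyro_bias = gyro_bias,
               clipping_enabled = clipping_enabled,
               accel_range = accel_range, gyro_range = gyro_range,
               rate = rate, seed = seed)
  validate_swing_spec(spec)
  structure(spec, class = "swing_spec")
}

validate_swing_spec <- function(spec) {
  stopifnot(spec$circle_radius > 0,
            all(spec$phase_durations > 0),
            spec$pre_address_pad >= 0.1,
            all(is.finite(spec$noise)), all(spec$noise >= 0),
            all(is.finite(spec$accel_bias)), all(is.finite(spec$gyro_bias)),
            spec$sweep_back > 0, spec$sweep_down > 0, spec$omega_low > 0,
            abs(sum(spec$follow_split) - 1) < 1e-9,
            spec$rate > 0)
  invisible(spec)
}

# Build the motion segment table: for each segment, sample count and the
# polynomials in normalized time s of the circle angle offset, roll offset
# and absolute out-of-plane excursion.
swing_segments <- function(spec) {
  fs <- spec$rate
  d <- spec$phase_durations
  # grid-aligned durations so angular speed is exactly continuous at impact
  Tn <- function(T) max(1L, round(T * fs)) / fs
  Tf <- vapply(d[["follow_through"]] * spec$follow_split, Tn, 1)
  Td <- Tn(d[["downswing"]])
  w_imp <- 2 * spec$sweep_down / Td
  if (spec$omega_low >= w_imp)
    stop("omega_low must be below the impact angular speed", call. = FALSE)
  amp_op <- 0.95 * spec$out_of_plane_amplitude
  bump <- 16 * c(0, 0, 1, -2, 1)           # 16 s^2 (1-s)^2, peak 1 at s=1/2
  zero <- 0
  seg <- list()
  seg$pad  <- list(T = spec$pre_address_pad, dth = zero, dph = zero,
                   op = zero)
  seg$hold <- list(T = d[["address_hold"]], dth = zero, dph = zero, op = zero)
  seg$back <- list(T = d[["backswing"]], dth = -spec$sweep_back * SS5,
                   dph = spec$roll_angles[["backswing"]] * SS5,
                   op = amp_op * bump)
  seg$down <- list(T = Td, dth = 2 * spec$sweep_down * SS5I,
                   dph = spec$roll_angles[["downswing"]] * SS5,
                   op = -0.7 * amp_op * bump)
  # follow a: angular speed w_imp -> omega_low,
  # theta(s) = T * (w_imp * s - (w_imp - omega_low) * SS5I(s))
  pa <- Tf[1] * c(0, w_imp, rep(0, length(SS5I) - 2)) -
    Tf[1] * (w_imp - spec$omega_low) * SS5I
  seg$follow_a <- list(T = Tf[1], dth = pa,
                       dph = spec$roll_angles[["follow_a"]] * SS5,
                       op = 0.5 * amp_op * bump)
  # follow b: angular speed omega_low -> 0
  pb <- Tf[2] * c(0, spec$omega_low, rep(0, length(SS5I) - 2)) -
    Tf[2] * spec$omega_low * SS5I
  seg$follow_b <- list(T = Tf[2], dth = pb,
                       dph = spec$roll_angles[["follow_b"]] * SS5,
                       op = 0 * bump)
  seg$post <- list(T = spec$post_fin_pad, dth = zero, dph = zero, op = zero)
  for (k in seq_along(seg)) seg[[k]]$n <- max(1L, round(seg[[k]]$T * fs))
  seg
}

#' Generate one synthetic swing
#'
#' @param spec A [swing_spec()].
#' @return List with `rec` (`imu_recording`, noisy and possibly clipped) and
#'   `truth` (class `swing_truth`): `trajectory` and `velocity` (n x 3, user
#'   frame, origin and at rest at address), `orientation`
#'   ([orientation_series] of the true sensor-to-user quaternion),
#'   `events` ([swing_events]), `plane` ([swing_plane]), `clipped_mask`,
#'   plus the ideal (noise-free) signals `ideal_accel`, `ideal_gyro`
#'   (sensor frame) and `ideal_accel_user`.
#' @export
generate_swing <- function(spec) {
  validate_swing_spec(spec)
  fs <- spec$rate
  dt <- 1 / fs
  pb <- plane_basis(spec$plane_normal_angles[[1]], spec$plane_normal_angles[[2]])
  r <- spec$circle_radius
  # address point: lowest point of the circle (in-plane direction of -Z)
  edown <- -c(0, 0, 1) + pb$n[3] * pb$n
  edown <- unit3(edown)
  th0 <- atan2(sum(edown * pb$e2), sum(edown * pb$e1))

  seg <- swing_segments(spec)
  n_tot <- 1L + sum(vapply(seg, function(s) as.integer(s$n), 1L))
  th <- thd <- thdd <- ph <- op <- opd <- opdd <- numeric(n_tot)
  th[1] <- th0
  i <- 1L
  bounds <- integer(0)
  th_off <- th0; ph_off <- 0
  for (k in seq_along(seg)) {
    sg <- seg[[k]]
    s <- seq_len(sg$n) / sg$n
    idx <- i + seq_len(sg$n)
    Tn <- sg$n * dt                         # actual segment duration on grid
    dthp <- sg$dth; dphp <- sg$dph; opp <- sg$op
    th[idx]   <- th_off + poly_eval(dthp, s)
    thd[idx]  <- poly_eval(poly_deriv(dthp), s) / Tn
    thdd[idx] <- poly_eval(poly_deriv(poly_deriv(dthp)), s) / Tn^2
    ph[idx]   <- ph_off + poly_eval(dphp, s)
    op[idx]   <- poly_eval(opp, s)
    opd[idx]  <- poly_eval(poly_deriv(opp), s) / Tn
    opdd[idx] <- poly_eval(poly_deriv(poly_deriv(opp)), s) / Tn^2
    th_off <- th[idx[sg$n]]; ph_off <- ph[idx[sg$n]]
    i <- i + sg$n
    bounds <- c(bounds, i)
  }
  names(bounds) <- names(seg)
  i_add <- bounds[["hold"]]
  i_bst <- bounds[["back"]]
  i_imp <- bounds[["down"]]
  i_fin <- bounds[["follow_b"]]
  events <- swing_events(i_add, i_bst, i_imp, i_fin, n_tot)

  t <- dt * (0:(n_tot - 1L))
  e1 <- pb$e1; e2 <- pb$e2; vn <- pb$n
  cth <- cos(th); sth <- sin(th)
  radial <- cbind(cth, sth) %*% rbind(e1, e2)          # n x 3
  tangent <- cbind(-sth, cth) %*% rbind(e1, e2)
  a_user <- tangent * (r * thdd) - radial * (r * thd^2) +
    outer(opdd, vn)

  # true orientation: plane frame * circle angle * forearm roll * mount
  M <- quat_to_matrix(spec$sensor_mount)
  Q <- matrix(NA_real_, n_tot, 4L)
  for (j in seq_len(n_tot)) {
    C <- pb$P %*% rot_z(th[j]) %*% rot_x(ph[j]) %*% M
    q <- unclass(matrix_to_quat(C))
    if (j > 1L && sum(q * Q[j - 1L, ]) < 0) q <- -q
    Q[j, ] <- q
  }

  # ideal gyro from exact per-step increments through the tangent map:
  # omega_i = (2/dt) * vec(q_i^-1 q_{i+1}) / scal(q_i^-1 q_{i+1})
  gyro_ideal <- matrix(0, n_tot, 3L)
  for (j in seq_len(n_tot - 1L)) {
    qa <- Q[j, ]; qb <- Q[j + 1L, ]
    rq <- unclass(quat_product(quat_conjugate(quaternion(qa, normalize = FALSE)),
                               quaternion(qb, normalize = FALSE),
                               normalize = TRUE))
    if (rq[1] < 0) rq <- -rq
    gyro_ideal[j, ] <- (2 / dt) * rq[2:4] / rq[1]
  }

  g_vec <- c(0, 0, -GRAVITY)
  accel_ideal <- matrix(NA_real_, n_tot, 3L)
  for (j in seq_len(n_tot)) {
    C <- quat_to_matrix(quaternion(Q[j, ], normalize = FALSE))
    accel_ideal[j, ] <- drop(crossprod(C, a_user[j, ] - g_vec))
  }

  # ground-truth velocity / trajectory: exact integrals of the
  # piecewise-linear interpolant of a_user (starts at rest at sample 1)
  v_gt <- matrix(0, n_tot, 3L)
  p_gt <- matrix(0, n_tot, 3L)
  for (j in seq_len(n_tot - 1L)) {
    a0 <- a_user[j, ]; a1 <- a_user[j + 1L, ]
    p_gt[j + 1L, ] <- p_gt[j, ] + v_gt[j, ] * dt + (2 * a0 + a1) * dt^2 / 6
    v_gt[j + 1L, ] <- v_gt[j, ] + (a0 + a1) * dt / 2
  }

  # plane/circle ground truth, re-expressed with the address point at origin
  c_rel <- -r * (cos(th0) * e1 + sin(th0) * e2)
  plane <- swing_plane(vn, c_rel, r)

  noisy <- with_seed(spec$seed, {
    acc <- accel_ideal +
      matrix(stats::rnorm(3L * n_tot, 0, spec$noise[[1]]), n_tot, 3L)
    gyr <- gyro_ideal +
      matrix(stats::rnorm(3L * n_tot, 0, spec$noise[[2]]), n_tot, 3L)
    list(acc = sweep(acc, 2, spec$accel_bias, "+"),
         gyr = sweep(gyr, 2, spec$gyro_bias, "+"))
  })
  acc <- noisy$acc; gyr <- noisy$gyr
  clipped <- rep(FALSE, n_tot)
  if (isTRUE(spec$clipping_enabled)) {
    clipped <- rowSums(abs(acc) > spec$accel_range) > 0 |
      rowSums(abs(gyr) > spec$gyro_range) > 0
    acc <- pmin(pmax(acc, -spec$accel_range), spec$accel_range)
    gyr <- pmin(pmax(gyr, -spec$gyro_range), spec$gyro_range)
  }

  rec <- imu_recording(t, acc, gyr, spec$accel_range, spec$gyro_range)
  truth <- structure(list(
    trajectory = p_gt, velocity = v_gt,
    orientation = orientation_series(t, Q),
    events = events, plane = plane, clipped_mask = clipped,
    ideal_accel = accel_ideal, ideal_gyro = gyro_ideal,
    ideal_accel_user = a_user), class = "swing_truth")
  list(rec = rec, truth = truth)
}

#' Generate a synthetic population of subjects and swings
#'
#' Draws one base specification per subject (between-subject variation in
#' swing-plane pose, sensor mounting, geometry and tempo) and smaller
#' per-swing jitter, so within-subject spread is below between-subject
#' spread.  Sensor biases are redrawn per swing.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param swings_per_subject Swings per subject.
#' @param variability `c(between, within)` multipliers on the default
#'   between-/within-subject jitter scales.
#' @param seed Integer seed (all draws flow from it).
#' @param base Base [swing_spec()] to perturb.
#' @return List of class `swing_population`: elements `swings` (list of
#'   `generate_swing()` outputs), `subject` (integer label per swing).
#' @export
generate_population <- function(n_subjects, swings_per_subject,
                                variability = c(between = 1, within = 1),
                                seed = 1L, base = swing_spec()) {
  if (n_subjects < 2L) stop("need at least 2 subjects", call. = FALSE)
  vb <- variability[[1]]; vw <- variability[[2]]
  with_seed(seed, {
    swings <- list(); subject <- integer(0)
    for (s in seq_len(n_subjects)) {
      sub <- list(
        tilt = base$plane_normal_angles[[1]] + stats::rnorm(1, 0, 0.10 * vb),
        az   = base$plane_normal_angles[[2]] + stats::rnorm(1, 0, 0.04 * vb),
        radius = base$circle_radius * exp(stats::rnorm(1, 0, 0.05 * vb)),
        tempo  = exp(stats::rnorm(1, 0, 0.05 * vb)),
        roll_down = base$roll_angles[["downswing"]] +
          stats::rnorm(1, 0, 0.25 * vb),
        mount_axis = stats::rnorm(3),
        mount_angle = stats::rnorm(1, 0, 0.15 * vb))
      for (w in seq_len(swings_per_subject)) {
        tilt <- sub$tilt + stats::rnorm(1, 0, 0.04 * vw)
        az <- sub$az + stats::rnorm(1, 0, 0.015 * vw)
        radius <- sub$radius * exp(stats::rnorm(1, 0, 0.0125 * vw))
        tempo <- sub$tempo * exp(stats::rnorm(1, 0, 0.0125 * vw))
        roll_down <- sub$roll_down + stats::rnorm(1, 0, 0.06 * vw)
        # trial-to-trial wrist posture / strap shift: a small extra rotation
        # on top of the subject's mounting offset
        mount <- quat_product(
          quat_from_axis_angle(stats::rnorm(3), stats::rnorm(1, 0, 0.08 * vw)),
          quat_product(
            quat_from_axis_angle(sub$mount_axis, sub$mount_angle),
            base$sensor_mount))
        durations <- base$phase_durations * tempo
        names(durations) <- names(base$phase_durations)
        sp <- base
        sp$plane_normal_angles <- c(tilt = tilt, azimuth = az)
        sp$circle_radius <- radius
        sp$phase_durations <- durations
        sp$roll_angles[["downswing"]] <- roll_down
        sp$sensor_mount <- mount
        sp$accel_bias <- stats::rnorm(3, 0, 0.25)
        sp$gyro_bias <- stats::rnorm(3, 0, 0.004)
        sp$seed <- sample.int(.Machine$integer.max, 1L)
        class(sp) <- "swing_spec"
        swings[[length(swings) + 1L]] <- generate_swing(sp)
        subject <- c(subject, s)
      }
    }
    structure(list(swings = swings, subject = subject),
              class = "swing_population")
  })
}

#' Path length of a trajectory
#' @param traj n x 3 matrix of positions.
#' @return Total arc length, m.
#' @export
path_length <- function(traj)
  sum(sqrt(rowSums(diff(traj)^2)))
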