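# Input windows, CNN mechanics, baseline and orientation propagation.
# (The leave-one-out population benchmark lives in the acceptance suite.)

test_that("input windows are left-aligned, padded and mode-dependent", {
  sw <- ideal_swing()
  st <- channel_stats(list(sw$rec))
  ev <- sw$truth$events
  w <- build_input_window(sw$rec, ev, st)
  expect_equal(dim(w$mat), c(6L, 1000L))
  fs <- sampling_rate(sw$rec)
  expect_equal(w$window_start, ev[["add"]] - round(0.1 * fs))
  expect_equal(w$valid_length,
               ev[["bst"]] - w$window_start + 1L)
  # padded region is zero
  expect_equal(max(abs(w$mat[, (w$valid_length + 1L):1000L])), 0)
  # pre-ADD-only window: static gravity in accel rows, constant gyro rows
  # (the final column sits on the ADD boundary where motion begins)
  w0 <- build_input_window(sw$rec, ev, st, "pre_add_only")
  expect_lt(max(apply(w0$mat[, 1:(w0$valid_length - 1L)], 1, stats::sd)),
            1e-9)
  # longer modes are longer (until truncation)
  w_fin <- build_input_window(sw$rec, ev, st, "to_fin")
  expect_gt(w_fin$valid_length, w$valid_length)
  # window start before the recording start is rejected
  ev_bad <- c(add = 5L, bst = 50L, imp = 60L, fin = 80L)
  expect_error(build_input_window(sw$rec, ev_bad, st), "precedes")
})

test_that("windows longer than 5 s are truncated at 1000 columns", {
  spec <- ideal_spec(phase_durations = c(address_hold = 0.3,
                                         backswing = 5.4, downswing = 0.3,
                                         follow_through = 0.79))
  sw <- generate_swing(spec)
  st <- channel_stats(list(sw$rec))
  w <- build_input_window(sw$rec, sw$truth$events, st)
  expect_equal(w$valid_length, 1000L)
})

test_that("CNN output contract and constant-label convergence", {
  set.seed(41)
  wins <- lapply(1:8, function(i) matrix(stats::rnorm(6000, 0, 0.5), 6,
                                         1000))
  q0 <- unclass(quat_canonical(quaternion(c(0.8, 0.2, -0.5, 0.1))))
  labs <- matrix(q0, 8, 4, byrow = TRUE)
  m <- train_orientation_cnn(wins, labs, hyper = list(epochs = 80L,
                                                      patience = 80L),
                             seed = 2L)
  for (w in wins[1:3]) {
    q <- estimate_address_orientation(m, w)
    expect_equal(sum(unclass(q)^2), 1, tolerance = 1e-6)
    expect_gte(unclass(q)[1], 0)
  }
  expect_lt(quat_distance_loss(estimate_address_orientation(m, wins[[1]]),
                               quaternion(q0, normalize = FALSE)), 0.01)
  # training reduced the loss below the untrained level
  m0 <- train_orientation_cnn(wins, labs, hyper = list(epochs = 1L),
                              seed = 2L)
  expect_lt(min(m$history$val), m0$history$val[1] + 1e-9)
})

test_that("early stopping halts before the epoch cap on a plateau", {
  set.seed(43)
  wins <- lapply(1:6, function(i) matrix(stats::rnorm(6000, 0, 0.5), 6,
                                         1000))
  labs <- matrix(c(1, 0, 0, 0), 6, 4, byrow = TRUE)
  m <- train_orientation_cnn(wins, labs,
                             hyper = list(epochs = 400L, patience = 5L),
                             seed = 3L)
  expect_lt(nrow(m$history), 400L)
})

test_that("baseline is the leave-one-out mean quaternion", {
  q1 <- quat_canonical(quaternion(c(0.9, 0.1, 0.2, 0.1)))
  expect_equal(unclass(baseline_address_orientation(list(q1))),
               unclass(q1), tolerance = 1e-12)
  expect_error(baseline_address_orientation(list()), "empty")
  # zero population variability: baseline nails every subject
  pop0 <- generate_population(3, 2, variability = c(0, 0), seed = 51L)
  labs <- t(vapply(pop0$swings, function(sw)
    unclass(quat_canonical(q_add_true(sw))), numeric(4)))
  b <- baseline_address_orientation(labs[1:4, ])
  expect_lt(quat_angle_error(b, quaternion(labs[5, ])) * 180 / pi, 1)
})

test_that("propagation error starts at the initial offset and grows with bias", {
  sw <- ideal_swing()
  ev <- sw$truth$events
  # exact start: < 0.5 degrees everywhere (noiseless)
  os <- propagate_orientation(q_add_true(sw), sw$rec, ev)
  e_end <- quat_angle_error(
    quaternion(os$q[nrow(os$q), ], normalize = FALSE),
    quaternion(sw$truth$orientation$q[ev[["fin"]], ], normalize = FALSE))
  expect_lt(e_end * 180 / pi, 0.5)
  # 10-degree initial offset: error at ADD exactly 10 degrees
  off <- quat_from_axis_angle(c(0, 1, 0), 10 * pi / 180)
  q_off <- quat_product(q_add_true(sw), off)
  os2 <- propagate_orientation(q_off, sw$rec, ev)
  e_add <- quat_angle_error(quaternion(os2$q[1, ], normalize = FALSE),
                            q_add_true(sw))
  expect_equal(e_add * 180 / pi, 10, tolerance = 1e-6)
  # zero-length window: single-element series
  os3 <- propagate_orientation(q_add_true(sw), sw$rec,
                               c(add = ev[["add"]], fin = ev[["add"]]))
  expect_equal(nrow(os3$q), 1L)
})
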