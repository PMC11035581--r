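# Quaternion algebra and strapdown integration.

# independent oracle: rotation matrix built directly from axis-angle
# (Rodrigues formula), no package quaternion code involved
rodrigues <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

test_that("quaternion constructor normalizes and validates", {
  q <- quaternion(c(1, 1, 1, 1))
  expect_equal(sum(unclass(q)^2), 1, tolerance = 1e-12)
  expect_error(quaternion(c(1, NA, 0, 0)), "finite")
  expect_error(quaternion(c(0, 0, 0, 0)), "zero")
})

test_that("canonicalization maps q and -q to one representative", {
  q <- quaternion(c(-0.5, 0.5, 0.5, 0.5), normalize = FALSE)
  expect_gte(unclass(quat_canonical(q))[1], 0)
  expect_equal(unclass(quat_canonical(q)),
               unclass(quat_canonical(quaternion(-unclass(q),
                                                 normalize = FALSE))))
  # w exactly zero: first nonzero component made positive
  qz <- quaternion(c(0, -1, 0, 0), normalize = FALSE)
  expect_equal(unclass(quat_canonical(qz)), c(0, 1, 0, 0))
})

test_that("Hamilton product matches rotation-matrix composition", {
  expect_equal(unclass(quat_product(quat_identity(), quaternion(c(1, 2, 3, 4)))),
               unclass(quaternion(c(1, 2, 3, 4))))
  q <- quaternion(c(0.3, -0.5, 0.7, 0.2))
  expect_equal(unclass(quat_product(q, quat_conjugate(q))),
               c(1, 0, 0, 0), tolerance = 1e-12)
  # (sqrt(1/2), sqrt(1/2), 0, 0) x (sqrt(1/2), 0, sqrt(1/2), 0):
  # 90 deg about x composed with 90 deg about y
  a <- quaternion(c(sqrt(0.5), sqrt(0.5), 0, 0), normalize = FALSE)
  b <- quaternion(c(sqrt(0.5), 0, sqrt(0.5), 0), normalize = FALSE)
  Rab <- rodrigues(c(1, 0, 0), pi / 2) %*% rodrigues(c(0, 1, 0), pi / 2)
  expect_equal(quat_to_matrix(quat_product(a, b)), Rab, tolerance = 1e-12)
  # generic random pairs against matrix composition
  set.seed(11)
  for (i in 1:20) {
    ax1 <- stats::rnorm(3); ax2 <- stats::rnorm(3)
    an1 <- stats::runif(1, -pi, pi); an2 <- stats::runif(1, -pi, pi)
    qa <- quat_from_axis_angle(ax1, an1)
    qb <- quat_from_axis_angle(ax2, an2)
    expect_equal(quat_to_matrix(quat_product(qa, qb)),
                 rodrigues(ax1, an1) %*% rodrigues(ax2, an2),
                 tolerance = 1e-10)
  }
})

test_that("quat_rotate matches the quaternion sandwich product", {
  expect_equal(quat_rotate(quat_identity(), c(1, 2, 3)), c(1, 2, 3))
  q90z <- quat_from_axis_angle(c(0, 0, 1), pi / 2)
  expect_equal(quat_rotate(q90z, c(1, 0, 0)), c(0, 1, 0),
               tolerance = 1e-12)
  set.seed(7)
  for (i in 1:20) {
    q <- quaternion(stats::rnorm(4))
    v <- stats::rnorm(3)
    # sandwich product q (x) (0, v) (x) q*, expanded independently
    pv <- c(0, v)
    hp <- function(a, b) c(
      a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
      a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
      a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
      a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
    sand <- hp(hp(unclass(q), pv), c(q[1], -q[2], -q[3], -q[4]))
    expect_equal(quat_rotate(q, v), sand[2:4], tolerance = 1e-12)
    expect_equal(sqrt(sum(quat_rotate(q, v)^2)), sqrt(sum(v^2)),
                 tolerance = 1e-12)
  }
})

test_that("gyro integration reproduces closed-form constant rotations", {
  # zero angular velocity: constant series
  os <- integrate_gyro(quat_identity(), matrix(0, 10, 3), 0.005)
  expect_equal(nrow(os$q), 11L)
  for (i in 1:11) expect_equal(os$q[i, ], c(1, 0, 0, 0))
  # empty gyro: just q0
  os0 <- integrate_gyro(quaternion(c(1, 1, 0, 0)), NULL, 0.005)
  expect_equal(nrow(os0$q), 1L)
  # pi rad/s about z for 1 s at 200 Hz: 180 deg about z
  os <- integrate_gyro(quat_identity(),
                       matrix(rep(c(0, 0, pi), 200), ncol = 3, byrow = TRUE),
                       1 / 200)
  qf <- quaternion(os$q[201, ], normalize = FALSE)
  qref <- quat_from_axis_angle(c(0, 0, 1), pi)
  expect_lt(quat_angle_error(qf, qref) * 180 / pi, 0.1)
  # two constant segments about different axes: product of closed forms
  g <- rbind(matrix(rep(c(2, 0, 0), 100), ncol = 3, byrow = TRUE),
             matrix(rep(c(0, -1.5, 0.5), 100), ncol = 3, byrow = TRUE))
  os2 <- integrate_gyro(quat_identity(), g, 1 / 200)
  # body-frame composition: R_total = R1 %*% R2
  Rref <- rodrigues(c(1, 0, 0), 2 * 0.5) %*%
    rodrigues(c(0, -1.5, 0.5), sqrt(1.5^2 + 0.5^2) * 0.5)
  qf2 <- quaternion(os2$q[201, ], normalize = FALSE)
  ang <- quat_angle_error(qf2, matrix_to_quat(Rref)) * 180 / pi
  expect_lt(ang, 0.2)
  # halving dt reduces the closed-form error
  half <- integrate_gyro(quat_identity(),
                         g[rep(seq_len(200), each = 2), ], 1 / 400)
  ang_half <- quat_angle_error(quaternion(half$q[401, ], normalize = FALSE),
                               matrix_to_quat(Rref)) * 180 / pi
  expect_lt(ang_half, ang)
  expect_error(integrate_gyro(quat_identity(), matrix(0, 2, 3), 0), "dt")
})

test_that("angle error uses atan2, lies in [0, pi], sign/sym invariant", {
  q <- quaternion(c(0.2, 0.5, -0.3, 0.1))
  expect_equal(quat_angle_error(q, q), 0)
  expect_equal(quat_angle_error(quat_identity(),
                                quat_from_axis_angle(c(1, 0, 0), pi / 2)),
               pi / 2, tolerance = 1e-12)
  qn <- quaternion(-unclass(q), normalize = FALSE)
  expect_equal(quat_angle_error(q, qn), 0, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    qa <- quaternion(stats::rnorm(4)); qb <- quaternion(stats::rnorm(4))
    e <- quat_angle_error(qa, qb)
    expect_gte(e, 0); expect_lte(e, pi)
    expect_equal(e, quat_angle_error(qb, qa), tolerance = 1e-12)
    expect_equal(e, quat_angle_error(
      quaternion(-unclass(qa), normalize = FALSE), qb), tolerance = 1e-12)
  }
})

test_that("distance loss is 1 - |dot| and relates to the angle error", {
  q <- quaternion(c(0.6, 0.1, -0.7, 0.2))
  expect_equal(quat_distance_loss(q, q), 0)
  expect_equal(quat_distance_loss(q, quaternion(-unclass(q),
                                                normalize = FALSE)), 0)
  expect_equal(quat_distance_loss(quat_identity(),
                                  quat_from_axis_angle(c(0, 1, 0), pi)), 1)
  set.seed(5)
  for (i in 1:10) {
    qa <- quaternion(stats::rnorm(4)); qb <- quaternion(stats::rnorm(4))
    expect_equal(quat_distance_loss(qa, qb),
                 1 - abs(cos(quat_angle_error(qa, qb) / 2)),
                 tolerance = 1e-12)
  }
})

test_that("mean quaternion is the eigenvector rotation average", {
  q0 <- quaternion(c(0.8, 0.4, -0.3, 0.33))
  expect_equal(unclass(mean_quaternion(list(q0, q0, q0))),
               unclass(quat_canonical(q0)), tolerance = 1e-12)
  # antipodal pair: still the same rotation
  m <- mean_quaternion(list(q0, quaternion(-unclass(q0), normalize = FALSE)))
  expect_equal(quat_angle_error(m, q0), 0, tolerance = 1e-9)
  expect_error(mean_quaternion(list()), "at least one")
  # perturbed cluster: close to q0 and to a grid-search minimizer of the
  # summed squared angle error
  set.seed(9)
  qs <- lapply(1:12, function(i)
    quat_product(q0, quat_from_axis_angle(stats::rnorm(3),
                                          stats::runif(1, 0, 5 * pi / 180))))
  m <- mean_quaternion(qs)
  expect_lt(quat_angle_error(m, q0) * 180 / pi, 5)
  # brute-force local grid around m: no nearby rotation does better
  obj <- function(q) sum(vapply(qs, function(x)
    quat_angle_error(q, x)^2, 1))
  f0 <- obj(m)
  best_off <- 0
  for (i in 1:200) {
    qq <- quat_product(m, quat_from_axis_angle(stats::rnorm(3),
                                               stats::runif(1, 0, 0.02)))
    if (obj(qq) < f0) best_off <- max(best_off, quat_angle_error(qq, m))
  }
  expect_lt(best_off * 180 / pi, 0.5)
})
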