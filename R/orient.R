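# Address-orientation estimation.
#
# A small 1-D convolutional network maps a standardized 6 x 1000 IMU window
# around the address to the unit quaternion q_S^U at ADD, trained with the
# quaternion-distance loss 1 - |q_true . q_est|.  The statistical baseline
# is the average (eigenvector-mean) quaternion of the other subjects'
# address orientations.  The estimate seeds strapdown propagation of the
# orientation over the swing.

WINDOW_COLS <- 1000L

#' Build the CNN input window
#'
#' Extracts `[t_ADD - 0.1 s, t_end]` from the recording, standardizes the
#' six channels and places them (3 accel rows, then 3 gyro rows) into a
#' 6 x 1000 matrix, left-aligned, zero-padded or truncated on the right.
#' The end point depends on `range_mode`: the default `"pre_add_to_bst"`
#' covers the static pre-address data plus the backswing, which carries the
#' most orientation information; `"pre_add_only"`, `"to_imp"` and
#' `"to_fin"` support the input-range ablation.
#'
#' @param rec Preprocessed `imu_recording`.
#' @param events [swing_events()].
#' @param stats [channel_stats()] from the training population.
#' @param range_mode One of `"pre_add_to_bst"`, `"pre_add_only"`,
#'   `"to_imp"`, `"to_fin"`.
#' @return List of class `orientation_window`: `mat` (6 x 1000),
#'   `window_start`, `valid_length`, `range_mode`.
#' @export
build_input_window <- function(rec, events, stats,
                               range_mode = c("pre_add_to_bst",
                                              "pre_add_only",
                                              "to_imp", "to_fin")) {
  range_mode <- match.arg(range_mode)
  fs <- sampling_rate(rec)
  start <- events[["add"]] - as.integer(round(0.1 * fs))
  if (start < 1L)
    stop("window start precedes the recording start", call. = FALSE)
  end <- switch(range_mode,
                pre_add_only = events[["add"]],
                pre_add_to_bst = events[["bst"]],
                to_imp = events[["imp"]],
                to_fin = events[["fin"]])
  X <- t(standardize(rec, stats)[start:end, , drop = FALSE])  # 6 x len
  len <- ncol(X)
  mat <- matrix(0, 6L, WINDOW_COLS)
  use <- min(len, WINDOW_COLS)
  mat[, seq_len(use)] <- X[, seq_len(use)]
  structure(list(mat = mat, window_start = start,
                 valid_length = use, range_mode = range_mode),
            class = "orientation_window")
}

# ---- small 1-D CNN ---------------------------------------------------------

im2col_idx <- function(n_ch, len, k, stride) {
  starts <- seq(1L, len - k + 1L, by = stride)
  # column j: flatten of X[, starts[j] + 0:(k-1)] (column-major: ch fastest)
  offs <- as.vector(outer(seq_len(n_ch), (0:(k - 1L)) * n_ch, "+"))
  idx <- outer(offs, (starts - 1L) * n_ch, "+")
  list(idx = idx, L = length(starts))
}

cnn_init <- function(hyper, seed) {
  with_seed(seed, {
    g <- function(r, c, fan) matrix(stats::rnorm(r * c, 0, sqrt(1 / fan)),
                                    r, c)
    L1 <- floor((WINDOW_COLS - hyper$k1) / hyper$s1) + 1L
    L2 <- L1 - hyper$k2 + 1L
    L3 <- L2 %/% hyper$pool
    list(W1 = g(hyper$C1, 6L * hyper$k1, 6L * hyper$k1),
         b1 = numeric(hyper$C1),
         W2 = g(hyper$C2, hyper$C1 * hyper$k2, hyper$C1 * hyper$k2),
         b2 = numeric(hyper$C2),
         W4 = g(4L, hyper$C2 * L3, hyper$C2 * L3),
         b4 = numeric(4L))
  })
}

cnn_geometry <- function(hyper) {
  L1 <- floor((WINDOW_COLS - hyper$k1) / hyper$s1) + 1L
  L2 <- L1 - hyper$k2 + 1L
  L3 <- L2 %/% hyper$pool
  i1 <- im2col_idx(6L, WINDOW_COLS, hyper$k1, hyper$s1)
  i2 <- im2col_idx(hyper$C1, L1, hyper$k2, 1L)
  list(L1 = L1, L2 = L2, L3 = L3, i1 = i1, i2 = i2)
}

cnn_forward <- function(par, hyper, geo, X, keep = FALSE) {
  Xc <- matrix(X[geo$i1$idx], nrow(geo$i1$idx), geo$L1)
  z1 <- par$W1 %*% Xc + par$b1
  a1 <- tanh(z1)                                  # C1 x L1
  Ac <- matrix(a1[geo$i2$idx], nrow(geo$i2$idx), geo$L2)
  z2 <- par$W2 %*% Ac + par$b2
  a2 <- tanh(z2)                                  # C2 x L2
  P <- hyper$pool
  a2p <- array(a2[, seq_len(geo$L3 * P)], c(hyper$C2, P, geo$L3))
  m <- apply(a2p, c(1, 3), max)
  am <- apply(a2p, c(1, 3), which.max)
  a3 <- tanh(m)                                   # C2 x L3
  z4 <- drop(par$W4 %*% as.vector(a3)) + par$b4
  nz <- sqrt(sum(z4^2))
  if (!is.finite(nz) || nz < 1e-12)
    stop("model failure: non-finite or zero network output", call. = FALSE)
  q <- z4 / nz
  out <- list(q = q)
  if (keep) out <- c(out, list(Xc = Xc, a1 = a1, Ac = Ac, a2 = a2, m = m,
                               am = am, a3 = a3, z4 = z4, nz = nz))
  out
}

cnn_grad <- function(par, hyper, geo, X, y) {
  fw <- cnn_forward(par, hyper, geo, X, keep = TRUE)
  q <- fw$q
  dp <- sum(q * y)
  loss <- 1 - abs(dp)
  gu <- -sign(dp) * y
  gz4 <- (gu - sum(gu * q) * q) / fw$nz
  gW4 <- outer(gz4, as.vector(fw$a3))
  gb4 <- gz4
  ga3 <- matrix(drop(crossprod(par$W4, gz4)), hyper$C2, geo$L3)
  gm <- ga3 * (1 - fw$a3^2)
  P <- hyper$pool
  ga2 <- matrix(0, hyper$C2, geo$L2)
  cols <- (rep(seq_len(geo$L3), each = hyper$C2) - 1L) * P +
    as.vector(fw$am)
  ga2[cbind(rep(seq_len(hyper$C2), geo$L3), cols)] <- as.vector(gm)
  gz2 <- ga2 * (1 - fw$a2^2)
  gW2 <- tcrossprod(gz2, fw$Ac)
  gb2 <- rowSums(gz2)
  gAc <- crossprod(par$W2, gz2)                   # (C1*k2) x L2
  ga1 <- matrix(0, hyper$C1, geo$L1)
  for (o in 0:(hyper$k2 - 1L)) {
    rows <- o * hyper$C1 + seq_len(hyper$C1)
    ga1[, (seq_len(geo$L2)) + o] <- ga1[, (seq_len(geo$L2)) + o] +
      gAc[rows, , drop = FALSE]
  }
  gz1 <- ga1 * (1 - fw$a1^2)
  gW1 <- tcrossprod(gz1, fw$Xc)
  gb1 <- rowSums(gz1)
  list(loss = loss,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    W4 = gW4, b4 = gb4))
}

default_cnn_hyper <- function() {
  list(C1 = 8L, k1 = 15L, s1 = 4L, C2 = 12L, k2 = 9L, pool = 4L,
       lr = 5e-3, batch = 16L, epochs = 400L, patience = 40L,
       weight_decay = 0.05)
}

#' Train the address-orientation CNN
#'
#' Two 1-D convolutional layers (tanh), a max-pooling layer (tanh) and a
#' fully connected layer producing four outputs renormalized to a unit
#' quaternion, trained with the quaternion-distance loss `1 - |q . q_hat|`
#' under Adam.  A random fraction of the swings is held out as a validation
#' set for early stopping; the parameters with the best validation loss are
#' returned.
#'
#' @param windows List of [build_input_window()] outputs (or bare 6 x 1000
#'   matrices).
#' @param labels n x 4 matrix of canonical (w >= 0) unit quaternion labels.
#' @param val_fraction Fraction of swings held out for validation
#'   (default 0.10).
#' @param hyper Hyperparameter list; see `default_cnn_hyper()` in the
#'   sources for fields (channel counts, kernel sizes, stride, pooling,
#'   learning rate, batch size, epoch cap, early-stopping patience).
#' @param seed RNG seed (initialization, split, shuffling).
#' @return List of class `orientation_model`: parameters, geometry and the
#'   per-epoch training/validation loss history.
#' @export
train_orientation_cnn <- function(windows, labels, val_fraction = 0.10,
                                  hyper = list(), seed = 1L) {
  hy <- utils::modifyList(default_cnn_hyper(), hyper)
  mats <- lapply(windows, function(w)
    if (inherits(w, "orientation_window")) w$mat else w)
  n <- length(mats)
  if (n < 2L) stop("need at least 2 training swings", call. = FALSE)
  labels <- as.matrix(labels)
  labels <- labels / sqrt(rowSums(labels^2))
  geo <- cnn_geometry(hy)
  par <- cnn_init(hy, seed)
  st <- adam_state(par)
  n_val <- max(1L, round(val_fraction * n))
  hist_train <- hist_val <- numeric(0)
  best <- list(par = par, val = Inf, epoch = 0L)
  with_seed(seed + 1L, {
    val_idx <- sample(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    wait <- 0L
    for (ep in seq_len(hy$epochs)) {
      ord <- sample(tr_idx)
      tr_loss <- 0
      bs <- hy$batch
      for (b0 in seq(1L, length(ord), by = bs)) {
        bidx <- ord[b0:min(b0 + bs - 1L, length(ord))]
        acc <- NULL
        bloss <- 0
        for (i in bidx) {
          g <- cnn_grad(par, hy, geo, mats[[i]], labels[i, ])
          bloss <- bloss + g$loss
          acc <- if (is.null(acc)) g$grads
                 else mapply(`+`, acc, g$grads, SIMPLIFY = FALSE)
        }
        acc <- lapply(acc, function(x) x / length(bidx))
        upd <- adam_step(par, acc, st, hy$lr,
                         weight_decay = hy$weight_decay)
        par <- upd$par; st <- upd$st
        tr_loss <- tr_loss + bloss
      }
      tr_loss <- tr_loss / length(ord)
      val_loss <- mean(vapply(val_idx, function(i)
        1 - abs(sum(cnn_forward(par, hy, geo, mats[[i]])$q * labels[i, ])),
        1))
      hist_train <- c(hist_train, tr_loss)
      hist_val <- c(hist_val, val_loss)
      if (val_loss < best$val - 1e-6) {
        best <- list(par = par, val = val_loss, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= hy$patience) break
      }
    }
  })
  structure(list(par = best$par, hyper = hy, geo = geo,
                 history = data.frame(epoch = seq_along(hist_train),
                                      train = hist_train, val = hist_val),
                 best_epoch = best$epoch),
            class = "orientation_model")
}

#' @export
print.orientation_model <- function(x, ...) {
  cat(sprintf(
    "<orientation_model: %d epochs run, best val loss %.5f (epoch %d)>\n",
    nrow(x$history), min(x$history$val), x$best_epoch))
  invisible(x)
}

#' Estimate the address orientation from a window
#' @param model `orientation_model`.
#' @param window [build_input_window()] output (same stats/range as
#'   training) or a bare 6 x 1000 matrix.
#' @return Canonical unit [quaternion()].
#' @export
estimate_address_orientation <- function(model, window) {
  X <- if (inherits(window, "orientation_window")) window$mat else window
  q <- cnn_forward(model$par, model$hyper, model$geo, X)$q
  quat_canonical(quaternion(q))
}

#' Statistical baseline address orientation
#'
#' The average quaternion of the address orientations of all *other*
#' participants (leave-one-out population prior).
#' @param others_labels List of quaternions or n x 4 matrix.
#' @return Canonical unit [quaternion()].
#' @export
baseline_address_orientation <- function(others_labels) {
  if ((is.matrix(others_labels) && nrow(others_labels) == 0L) ||
      (!is.matrix(others_labels) && length(others_labels) == 0L))
    stop("empty label set", call. = FALSE)
  mean_quaternion(others_labels)
}

#' Propagate orientation over the swing by gyro integration
#'
#' Strapdown integration of the gyro samples from ADD to FIN starting at the
#' (estimated) address quaternion; sample `i` of the result corresponds to
#' recording sample `ADD + i - 1`.
#'
#' @param q_add Unit quaternion at ADD.
#' @param rec `imu_recording`.
#' @param events [swing_events()] (or any list with `add` and `fin`).
#' @return [orientation_series] of length `FIN - ADD + 1`.
#' @export
propagate_orientation <- function(q_add, rec, events) {
  i0 <- events[["add"]]; i1 <- events[["fin"]]
  if (is.na(i0) || is.na(i1) || i0 < 1L || i1 > length(rec$t) || i1 < i0)
    stop("invalid events", call. = FALSE)
  dt <- 1 / sampling_rate(rec)
  if (i1 == i0) return(integrate_gyro(q_add, NULL, dt))
  integrate_gyro(q_add, rec$gyro[i0:(i1 - 1L), , drop = FALSE], dt)
}
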