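# Swing-phase segmentation: a speed-profile heuristic (usable when a speed
# signal or ground truth is available) and a bidirectional recurrent
# sequence labeller operating on the standardized 6-channel IMU signal.

#' Locate the four swing events on a wrist-speed profile
#'
#' ADD is the last local minimum before the first sustained speed rise, BST
#' the deepest local minimum between ADD and impact (after the backswing
#' peak), IMP the global speed maximum (or a supplied ball-crossing index)
#' and FIN the first local minimum terminating the follow-through
#' deceleration.  Plateau edges count as local minima.
#'
#' @param speed Non-negative speed series, m/s (length > 50).
#' @param ball_crossing Optional known impact index.
#' @param smooth Moving-average half-width used before extremum search.
#' @return [swing_events()].
#' @export
events_from_speed_profile <- function(speed, ball_crossing = NULL,
                                      smooth = 2L) {
  n <- length(speed)
  if (n <= 50L) stop("speed profile too short", call. = FALSE)
  if (any(speed < 0)) stop("speed must be non-negative", call. = FALSE)
  sp <- as.numeric(stats::filter(speed, rep(1, 2 * smooth + 1) /
                                   (2 * smooth + 1), sides = 2))
  sp[is.na(sp)] <- speed[is.na(sp)]
  raw <- as.numeric(speed)
  vmax <- max(sp)
  if (!(vmax > 0)) stop("flat speed profile", call. = FALSE)
  i_imp <- if (!is.null(ball_crossing)) as.integer(ball_crossing)
           else which.max(raw)

  # sustained rise: first index from which speed stays above 10% for a bit
  above <- sp > 0.1 * vmax
  rise <- NA_integer_
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= 5L) { rise <- i - 4L; break }
  }
  if (is.na(rise) || rise >= i_imp)
    stop("segmentation failure: no sustained speed rise", call. = FALSE)
  # ADD: walk back down the rise to the last (plateau-edge) local minimum
  i <- rise
  while (i > 1L && raw[i - 1L] < raw[i]) i <- i - 1L
  i_add <- i

  if (i_imp - i_add < 4L)
    stop("segmentation failure: no backswing interval", call. = FALSE)
  # backswing peak: first local maximum of the smoothed profile after ADD
  i <- i_add + 1L
  while (i < i_imp && sp[i + 1L] > sp[i]) i <- i + 1L
  pk <- i
  # BST: deepest minimum after the backswing peak and before impact
  if (pk >= i_imp - 1L) {
    i_bst <- i_add + 1L                 # single-peak profile (no backswing)
  } else {
    interior <- (pk + 1L):(i_imp - 1L)
    i_bst <- interior[which.min(raw[interior])]
    if (raw[i_bst] > 0.5 * vmax)
      stop("segmentation failure: no backswing-top minimum", call. = FALSE)
  }

  # FIN: walk down the tail of the follow-through deceleration to the
  # first (plateau-edge) local minimum
  last_hi <- max(which(sp > 0.1 * vmax))
  i <- max(last_hi, i_imp)
  while (i < n && raw[i + 1L] < raw[i]) i <- i + 1L
  i_fin <- i
  if (!(i_add < i_bst && i_bst < i_imp && i_imp < i_fin))
    stop("segmentation failure: events out of order", call. = FALSE)
  swing_events(i_add, i_bst, i_imp, i_fin, n)
}

#' Per-sample phase labels from events
#'
#' Five phases: 1 pre-address, 2 backswing, 3 downswing, 4 follow-through,
#' 5 post-finish.
#' @param events [swing_events()].
#' @param n Recording length.
#' @return Integer vector of length `n` with values 1..5.
#' @export
phase_labels <- function(events, n) {
  lab <- integer(n)
  lab[1:events[["add"]]] <- 1L
  lab[(events[["add"]] + 1L):events[["bst"]]] <- 2L
  lab[(events[["bst"]] + 1L):events[["imp"]]] <- 3L
  lab[(events[["imp"]] + 1L):events[["fin"]]] <- 4L
  if (events[["fin"]] < n) lab[(events[["fin"]] + 1L):n] <- 5L
  lab
}

# ---- bidirectional Elman network ------------------------------------------

rnn_init <- function(n_in, hidden, n_out, seed) {
  with_seed(seed, {
    g <- function(r, c, sc) matrix(stats::rnorm(r * c, 0, sc), r, c)
    list(Wx_f = g(hidden, n_in, 0.3), Wh_f = g(hidden, hidden, 0.2),
         b_f = numeric(hidden),
         Wx_b = g(hidden, n_in, 0.3), Wh_b = g(hidden, hidden, 0.2),
         b_b = numeric(hidden),
         Wo = g(n_out, 2 * hidden, 0.3), bo = numeric(n_out))
  })
}

rnn_forward_dir <- function(X, Wx, Wh, b) {
  # X: T x n_in; returns H: T x hidden (tanh Elman states)
  Tn <- nrow(X); hidden <- nrow(Wx)
  H <- matrix(0, Tn, hidden)
  XW <- X %*% t(Wx)
  h <- numeric(hidden)
  for (t in seq_len(Tn)) {
    h <- tanh(XW[t, ] + drop(Wh %*% h) + b)
    H[t, ] <- h
  }
  H
}

rnn_forward <- function(par, X) {
  Hf <- rnn_forward_dir(X, par$Wx_f, par$Wh_f, par$b_f)
  Hb <- rnn_forward_dir(X[nrow(X):1, , drop = FALSE],
                        par$Wx_b, par$Wh_b, par$b_b)
  Hb <- Hb[nrow(Hb):1, , drop = FALSE]
  H <- cbind(Hf, Hb)
  Z <- H %*% t(par$Wo) + matrix(par$bo, nrow(H), length(par$bo),
                                byrow = TRUE)
  Zs <- Z - apply(Z, 1, max)
  E <- exp(Zs)
  P <- E / rowSums(E)
  list(Hf = Hf, Hb = Hb, P = P)
}

rnn_backward_dir <- function(X, H, dH, Wx, Wh) {
  # accumulates grads for one direction given dLoss/dH (T x hidden)
  Tn <- nrow(X)
  gWx <- matrix(0, nrow(Wx), ncol(Wx))
  gWh <- matrix(0, nrow(Wh), ncol(Wh))
  gb <- numeric(nrow(Wx))
  dh_next <- numeric(nrow(Wx))
  for (t in rev(seq_len(Tn))) {
    dh <- dH[t, ] + dh_next
    dz <- dh * (1 - H[t, ]^2)
    gWx <- gWx + outer(dz, X[t, ])
    hprev <- if (t > 1L) H[t - 1L, ] else numeric(nrow(Wx))
    gWh <- gWh + outer(dz, hprev)
    gb <- gb + dz
    dh_next <- drop(crossprod(Wh, dz))
  }
  list(Wx = gWx, Wh = gWh, b = gb)
}

rnn_grad <- function(par, X, y) {
  fw <- rnn_forward(par, X)
  Tn <- nrow(X)
  Y <- matrix(0, Tn, ncol(fw$P))
  Y[cbind(seq_len(Tn), y)] <- 1
  dZ <- (fw$P - Y) / Tn
  H <- cbind(fw$Hf, fw$Hb)
  hidden <- ncol(fw$Hf)
  gWo <- crossprod(dZ, H)
  gbo <- colSums(dZ)
  dH <- dZ %*% par$Wo
  gf <- rnn_backward_dir(X, fw$Hf, dH[, seq_len(hidden), drop = FALSE],
                         par$Wx_f, par$Wh_f)
  Xr <- X[Tn:1, , drop = FALSE]
  dHb <- dH[, hidden + seq_len(hidden), drop = FALSE][Tn:1, , drop = FALSE]
  gb <- rnn_backward_dir(Xr, fw$Hb[Tn:1, , drop = FALSE], dHb,
                         par$Wx_b, par$Wh_b)
  loss <- -mean(log(pmax(fw$P[cbind(seq_len(Tn), y)], 1e-12)))
  list(loss = loss,
       grads = list(Wx_f = gf$Wx, Wh_f = gf$Wh, b_f = gf$b,
                    Wx_b = gb$Wx, Wh_b = gb$Wh, b_b = gb$b,
                    Wo = gWo, bo = gbo))
}

adam_state <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0), t = 0)
}

adam_step <- function(par, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  st$t <- st$t + 1
  for (k in names(par)) {
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * grads[[k]]
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * grads[[k]]^2
    mh <- st$m[[k]] / (1 - beta1^st$t)
    vh <- st$v[[k]] / (1 - beta2^st$t)
    par[[k]] <- par[[k]] - lr * mh / (sqrt(vh) + eps)
    # decoupled weight decay (matrices only, biases exempt)
    if (weight_decay > 0 && is.matrix(par[[k]]))
      par[[k]] <- par[[k]] * (1 - lr * weight_decay)
  }
  list(par = par, st = st)
}

#' Train the bidirectional recurrent swing-phase segmenter
#'
#' A bidirectional tanh recurrent network labels every sample of the
#' (downsampled, standardized) 6-channel IMU signal with one of five swing
#' phases.  Trained with per-sample cross-entropy and Adam; per-sequence
#' stochastic updates; seeded and reproducible.
#'
#' @param dataset List of elements `list(x = n x 6 standardized matrix,
#'   labels = integer phase labels 1..5)`.
#' @param hidden Hidden units per direction.
#' @param downsample Temporal downsampling factor applied to inputs and
#'   labels (predictions are mapped back to full rate).
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param seed RNG seed.
#' @param stats The [channel_stats()] the inputs were standardized with
#'   (stored so [segment_swing()] can reproduce the preprocessing).
#' @return List of class `segmenter_model` (parameters + history).
#' @export
train_segmenter <- function(dataset, hidden = 16L, downsample = 4L,
                            epochs = 80L, lr = 0.01, seed = 1L,
                            stats = NULL) {
  if (length(dataset) == 0L) stop("empty dataset", call. = FALSE)
  ds <- lapply(dataset, function(d) {
    pos <- seq(1L, nrow(d$x), by = downsample)
    list(x = d$x[pos, , drop = FALSE], y = d$labels[pos])
  })
  par <- rnn_init(6L, hidden, 5L, seed)
  st <- adam_state(par)
  history <- numeric(epochs)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(ds))
      tot <- 0
      for (i in ord) {
        g <- rnn_grad(par, ds[[i]]$x, ds[[i]]$y)
        upd <- adam_step(par, g$grads, st, lr)
        par <- upd$par; st <- upd$st
        tot <- tot + g$loss
      }
      history[ep] <- tot / length(ds)
    }
  })
  structure(list(par = par, hidden = hidden, downsample = downsample,
                 history = history, stats = stats),
            class = "segmenter_model")
}

#' @export
print.segmenter_model <- function(x, ...) {
  cat(sprintf(
    "<segmenter_model: %d hidden/dir, ds=%d, final loss %.4f>\n",
    x$hidden, x$downsample, utils::tail(x$history, 1)))
  invisible(x)
}

#' Per-sample phase posteriors for a standardized signal
#' @param model `segmenter_model`.
#' @param x n x 6 standardized matrix (full rate; downsampled internally).
#' @return List with `P` (coarse posteriors), `pos` (full-rate indices of
#'   the coarse samples).
#' @export
segmenter_posteriors <- function(model, x) {
  pos <- seq(1L, nrow(x), by = model$downsample)
  fw <- rnn_forward(model$par, x[pos, , drop = FALSE])
  list(P = fw$P, pos = pos)
}

# left-to-right constrained Viterbi over 5 ordered phases; returns the
# phase boundaries (coarse indices of the last sample of phases 1..4)
ordered_decode <- function(P) {
  Tn <- nrow(P); K <- ncol(P)
  logp <- log(pmax(P, 1e-12))
  C <- matrix(-Inf, Tn, K)
  B <- matrix(0L, Tn, K)
  C[1, 1] <- logp[1, 1]
  for (t in 2:Tn) {
    C[t, 1] <- C[t - 1, 1] + logp[t, 1]
    for (k in 2:K) {
      stay <- C[t - 1, k]
      move <- C[t - 1, k - 1]
      if (move > stay) { C[t, k] <- move + logp[t, k]; B[t, k] <- 1L }
      else C[t, k] <- stay + logp[t, k]
    }
  }
  if (!is.finite(C[Tn, K])) stop("decoding failed", call. = FALSE)
  path <- integer(Tn)
  k <- K
  for (t in Tn:1) {
    path[t] <- k
    if (t > 1L && B[t, k] == 1L) k <- k - 1L
  }
  path
}

#' Segment a swing with a trained model
#'
#' Runs the recurrent labeller and converts the constrained (monotone
#' phase-order) decoding into event indices; the ordering invariant holds by
#' construction.  Fails when the decoded path explains the posteriors poorly
#' (e.g. a recording with no swing).
#'
#' @param model `segmenter_model` (with stored `stats`).
#' @param rec `imu_recording` preprocessed like the training data.
#' @param stats Optional [channel_stats()] override.
#' @param min_peak_gyro A recording whose peak angular rate (rad/s) is
#'   below this cannot contain a swing and is rejected (default 3, an
#'   order of magnitude below a slow swing's peak).
#' @return [swing_events()].
#' @export
segment_swing <- function(model, rec, stats = NULL, min_peak_gyro = 3) {
  stats <- stats %||% model$stats
  if (is.null(stats))
    stop("segment_swing needs the training channel_stats", call. = FALSE)
  if (max(sqrt(rowSums(rec$gyro^2))) < min_peak_gyro)
    stop("segmentation failure: no swing-scale motion in the recording",
         call. = FALSE)
  x <- standardize(rec, stats)
  ps <- segmenter_posteriors(model, x)
  path <- ordered_decode(ps$P)
  conf <- mean(ps$P[cbind(seq_along(path), path)])
  mid <- path %in% 2:4
  if (!any(mid) || mean(ps$P[cbind(which(mid), path[mid])]) < 0.2 ||
      conf < 0.3)
    stop("segmentation failure: no confident swing found", call. = FALSE)
  bnd <- vapply(1:4, function(k) max(which(path == k)), 1L)
  idx <- ps$pos[bnd]
  swing_events(idx[1], idx[2], idx[3], idx[4], nrow(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-sample phase accuracy of a segmenter
#' @param model `segmenter_model`.
#' @param x n x 6 standardized matrix.
#' @param labels Integer labels 1..5 (full rate).
#' @return Fraction of coarse samples labelled correctly.
#' @export
segmenter_accuracy <- function(model, x, labels) {
  ps <- segmenter_posteriors(model, x)
  pred <- max.col(ps$P)
  mean(pred == labels[ps$pos])
}
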