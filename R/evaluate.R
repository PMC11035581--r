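# Benchmark harnesses over the synthetic population: leave-one-out
# orientation estimation, drift-correction efficacy, segmentation accuracy
# and bias-monotonicity curves.  These drive the test suite, the acceptance
# script and the command-line `evaluate` command.

truth_q_add <- function(sw)
  quat_canonical(quaternion(sw$truth$orientation$q[sw$truth$events[["add"]], ]))

subject_channel_stats <- function(pop, exclude) {
  recs <- lapply(pop$swings[pop$subject != exclude], `[[`, "rec")
  channel_stats(recs)
}

#' Leave-one-out benchmark of address-orientation estimation
#'
#' For each subject: channel statistics and CNN training use the remaining
#' subjects only; the trained CNN and the average-quaternion baseline are
#' evaluated on the held-out subject's swings.  Angle errors (degrees) are
#' reported at ADD and, through gyro propagation from the estimated address
#' quaternion, at BST, IMP, FIN and averaged over the swing.
#'
#' @param pop [generate_population()] output.
#' @param range_mode Input window mode (see [build_input_window()]).
#' @param hyper CNN hyperparameter overrides.
#' @param seed RNG seed for training.
#' @param propagate Also evaluate propagated errors (slower).
#' @return Data frame: one row per swing with columns `subject`,
#'   `cnn_add`, `baseline_add` and (if `propagate`) `cnn_bst`, `cnn_imp`,
#'   `cnn_fin`, `cnn_swing`, `baseline_swing`.
#' @export
loo_orientation_benchmark <- function(pop, range_mode = "pre_add_to_bst",
                                      hyper = list(), seed = 1L,
                                      propagate = FALSE) {
  subjects <- sort(unique(pop$subject))
  rows <- list()
  for (s in subjects) {
    stats <- subject_channel_stats(pop, s)
    tr <- which(pop$subject != s)
    te <- which(pop$subject == s)
    win <- function(i) build_input_window(pop$swings[[i]]$rec,
                                          pop$swings[[i]]$truth$events,
                                          stats, range_mode)
    labs <- t(vapply(pop$swings, function(sw) unclass(truth_q_add(sw)),
                     numeric(4)))
    model <- train_orientation_cnn(lapply(tr, win), labs[tr, , drop = FALSE],
                                   hyper = hyper, seed = seed + s)
    q_base <- baseline_address_orientation(labs[tr, , drop = FALSE])
    for (i in te) {
      sw <- pop$swings[[i]]
      q_true <- truth_q_add(sw)
      q_cnn <- estimate_address_orientation(model, win(i))
      row <- list(subject = s,
                  cnn_add = quat_angle_error(q_cnn, q_true) * 180 / pi,
                  baseline_add = quat_angle_error(q_base, q_true) * 180 / pi)
      if (propagate) {
        ev <- sw$truth$events
        qt <- sw$truth$orientation$q
        err_series <- function(q0) {
          os <- propagate_orientation(q0, sw$rec, ev)
          vapply(seq_len(nrow(os$q)), function(j)
            quat_angle_error(quaternion(os$q[j, ], normalize = FALSE),
                             quaternion(qt[ev[["add"]] + j - 1L, ],
                                        normalize = FALSE)) * 180 / pi, 1)
        }
        e_cnn <- err_series(q_cnn)
        e_base <- err_series(q_base)
        at <- function(e, name) e[ev[[name]] - ev[["add"]] + 1L]
        row <- c(row, list(cnn_bst = at(e_cnn, "bst"),
                           cnn_imp = at(e_cnn, "imp"),
                           cnn_fin = at(e_cnn, "fin"),
                           cnn_swing = mean(e_cnn),
                           baseline_swing = mean(e_base)))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, lapply(rows, as.data.frame))
}

#' Drift-correction benchmark over a seeded synthetic batch
#'
#' Generates a population of noisy, biased swings, preprocesses each
#' (low-pass filter; clipping repair when saturation occurred), tracks it
#' with the true address orientation and true events (so the benchmark
#' isolates the drift-correction stage) and reports corrected versus
#' uncorrected trajectory errors against ground truth.
#'
#' @param n_subjects,swings_per_subject Batch shape (default 5 x 4 = 20).
#' @param seed Batch seed.
#' @param base Base [swing_spec()].
#' @return Data frame, one row per swing: `mae_uncorrected`, `mae_corrected`
#'   (3D vector MAE, m), `reduction_pct`, per-phase improvements
#'   `impr_backswing`, `impr_follow` (m), velocity MAEs and `r2_circle`.
#' @export
drift_benchmark <- function(n_subjects = 5L, swings_per_subject = 4L,
                            seed = 42L, base = swing_spec()) {
  pop <- generate_population(n_subjects, swings_per_subject, seed = seed,
                             base = base)
  rows <- lapply(pop$swings, function(sw) {
    rec <- sw$rec
    if (any(sw$truth$clipped_mask))
      rec <- repair_clipping(rec, detect_clipping(rec))
    rec <- lowpass_filter(rec)
    ev <- sw$truth$events
    tr <- track_swing(rec, ev, truth_q_add_exact(sw))
    idx <- ev[["add"]]:ev[["fin"]]
    ref <- sw$truth$trajectory[idx, , drop = FALSE]
    ref <- sweep(ref, 2, ref[1, ], "-")
    vref <- sw$truth$velocity[idx, , drop = FALSE]
    m_unc <- mae(tr$traj_ori, ref)
    m_cor <- mae(tr$traj_tcal, ref)
    ph_unc <- phase_mae(tr$traj_ori, ref, ev)
    ph_cor <- phase_mae(tr$traj_tcal, ref, ev)
    data.frame(
      mae_uncorrected = m_unc, mae_corrected = m_cor,
      reduction_pct = percent_error_reduction(m_unc, m_cor),
      impr_backswing = ph_unc[["backswing"]] - ph_cor[["backswing"]],
      impr_follow = ph_unc[["follow_through"]] - ph_cor[["follow_through"]],
      vel_mae_uncorrected = mae(tr$v_ori, vref),
      vel_mae_corrected = mae(tr$v_vcal, vref),
      r2_circle = circle_r_squared(ref, tr$plane))
  })
  do.call(rbind, rows)
}

truth_q_add_exact <- function(sw)
  quaternion(sw$truth$orientation$q[sw$truth$events[["add"]], ],
             normalize = FALSE)

#' Segmentation benchmark on held-out synthetic subjects
#'
#' Trains the recurrent segmenter on all but the last `n_test_subjects`
#' subjects of a synthetic population and reports per-event absolute timing
#' errors on the held-out swings.
#'
#' @param pop [generate_population()] output.
#' @param n_test_subjects Held-out subjects (default 1).
#' @param hidden,downsample,epochs,lr,seed Segmenter hyperparameters.
#' @return List with `errors` (data frame of per-swing event errors in ms)
#'   and `model`.
#' @export
segmentation_benchmark <- function(pop, n_test_subjects = 1L, hidden = 16L,
                                   downsample = 4L, epochs = 80L, lr = 0.01,
                                   seed = 1L) {
  subjects <- sort(unique(pop$subject))
  te_sub <- utils::tail(subjects, n_test_subjects)
  tr_idx <- which(!(pop$subject %in% te_sub))
  te_idx <- which(pop$subject %in% te_sub)
  stats <- channel_stats(lapply(pop$swings[tr_idx], `[[`, "rec"))
  dataset <- lapply(tr_idx, function(i) {
    sw <- pop$swings[[i]]
    list(x = standardize(sw$rec, stats),
         labels = phase_labels(sw$truth$events, length(sw$rec$t)))
  })
  model <- train_segmenter(dataset, hidden = hidden,
                           downsample = downsample, epochs = epochs,
                           lr = lr, seed = seed, stats = stats)
  rows <- lapply(te_idx, function(i) {
    sw <- pop$swings[[i]]
    ms_per_sample <- 1000 / sampling_rate(sw$rec)
    ev <- tryCatch(segment_swing(model, sw$rec),
                   error = function(e) NULL)
    if (is.null(ev)) return(data.frame(add = NA_real_, bst = NA_real_,
                                       imp = NA_real_, fin = NA_real_))
    d <- abs(unclass(ev) - unclass(sw$truth$events)) * ms_per_sample
    data.frame(add = d[["add"]], bst = d[["bst"]],
               imp = d[["imp"]], fin = d[["fin"]])
  })
  list(errors = do.call(rbind, rows), model = model)
}

#' Error growth under increasing sensor bias
#'
#' Regenerates the same swing (fixed seed) with the accelerometer and gyro
#' bias vectors scaled by each factor and reports trajectory MAEs (corrected
#' and uncorrected, true address orientation) and the orientation error at
#' FIN under gyro-only propagation.
#'
#' @param scales Bias scale factors (default `c(1, 3, 6)`).
#' @param seed Swing seed.
#' @return Data frame with one row per scale.
#' @export
bias_monotonicity <- function(scales = c(1, 3, 6), seed = 7L) {
  rows <- lapply(scales, function(sc) {
    spec <- swing_spec(accel_bias = sc * c(0.12, -0.08, 0.1),
                       gyro_bias = sc * c(0.003, -0.002, 0.0025),
                       seed = seed)
    sw <- generate_swing(spec)
    ev <- sw$truth$events
    tr <- track_swing(sw$rec, ev, truth_q_add_exact(sw))
    idx <- ev[["add"]]:ev[["fin"]]
    ref <- sw$truth$trajectory[idx, , drop = FALSE]
    os <- propagate_orientation(truth_q_add_exact(sw), sw$rec, ev)
    q_fin_true <- quaternion(sw$truth$orientation$q[ev[["fin"]], ],
                             normalize = FALSE)
    data.frame(
      scale = sc,
      mae_uncorrected = mae(tr$traj_ori, ref),
      mae_corrected = mae(tr$traj_tcal, ref),
      orient_err_fin = quat_angle_error(
        quaternion(os$q[nrow(os$q), ], normalize = FALSE),
        q_fin_true) * 180 / pi)
  })
  do.call(rbind, rows)
}
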