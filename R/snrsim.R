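#' Cross-decoding over signal-to-noise levels on simulated tuning data
#'
#' Tests whether differences in signal-to-noise ratio alone mimic dynamic
#' coding. Per iteration, training orientations are drawn without
#' replacement from the 1..180 degree grid of the tuned voxel population,
#' and test orientations are drawn independently (so orientations may be
#' shared between sets, as in the empirical design). White Gaussian noise
#' scales each side independently to the requested SNR (variance ratio),
#' the periodic decoder is trained at each training level and evaluated
#' at each test level, and accuracies are averaged over iterations.
#'
#' @param tuning a `vwm_tuning` population spanning 1..180 degrees.
#' @param levels SNR levels (> 0). The default grid spans the regime in
#'   which decoding rises from near chance to near ceiling for a
#'   200-voxel population; saturated grids hide the train/test asymmetry
#'   the simulation is meant to expose.
#' @param n_iter iterations (default 7).
#' @param n_train,n_test orientations sampled per side per iteration
#'   (default 108; at most 180, sampling is without replacement).
#' @param hyper decoder hyperparameters.
#' @param seed integer seed.
#' @return a levels x levels matrix of class `vwm_snrmat` (rows = train
#'   SNR, columns = test SNR) with attributes `levels` and `n_iter`.
#' @export
snr_cross_decode <- function(tuning,
                             levels = c(0.01, 0.02, 0.05, 0.1, 0.25, 0.5),
                             n_iter = 7, n_train = 108, n_test = 108,
                             hyper = psvr_hyperparams(), seed = 1L) {
  stopifnot(inherits(tuning, "vwm_tuning"))
  if (any(!is.finite(levels)) || any(levels <= 0))
    stop("SNR levels must be positive")
  if (n_train > 180 || n_test > 180)
    stop("at most 180 orientations can be sampled without replacement")
  set.seed(seed)
  nl <- length(levels)
  acc <- matrix(0, nl, nl)
  for (it in seq_len(n_iter)) {
    tr_ori <- sample(180, n_train)
    te_ori <- sample(180, n_test)
    x_tr <- tuning$responses[tr_ori, , drop = FALSE]
    x_te <- tuning$responses[te_ori, , drop = FALSE]
    # one base noise draw per side, rescaled per level so that levels
    # differ only in noise amplitude
    noise_tr <- matrix(stats::rnorm(length(x_tr)), nrow(x_tr))
    noise_te <- matrix(stats::rnorm(length(x_te)), nrow(x_te))
    sd_tr <- apply(x_tr, 2, stats::sd)
    sd_te <- apply(x_te, 2, stats::sd)
    theta_tr <- wrap_orientation(tr_ori)
    theta_te <- wrap_orientation(te_ori)
    for (i in seq_len(nl)) {
      xi <- x_tr + noise_tr *
        rep(sd_tr / sqrt(levels[i]), each = nrow(x_tr))
      model <- fit_psvr(xi, theta_tr, hyper)
      for (j in seq_len(nl)) {
        xj <- x_te + noise_te *
          rep(sd_te / sqrt(levels[j]), each = nrow(x_te))
        dev <- angular_deviation(theta_te,
                                 predict_orientation(model, xj))
        acc[i, j] <- acc[i, j] + fca(dev)
      }
    }
  }
  structure(acc / n_iter, class = c("vwm_snrmat", "matrix"),
            levels = levels, n_iter = n_iter)
}

#' Cross-decoding across a pseudo-time noise schedule
#'
#' Builds a pseudo-time axis by re-noising the same base patterns with a
#' per-timepoint noise amplitude and runs the full temporal cross-decoding
#' on the result. Because the underlying code is identical at every
#' pseudo-timepoint, any apparent temporal structure in the matrix is due
#' to noise level alone; the dynamic-element conjunction test should find
#' nothing.
#'
#' @param dataset a `vwm_dataset` providing the base patterns.
#' @param noise_schedule per-pseudo-timepoint noise scale (> 0), in units
#'   of the per-voxel base-pattern standard deviation (so the pseudo-time
#'   SNR is 1 / scale^2).
#' @param condition optional condition filter for the base patterns.
#' @param base_window time window (seconds) averaged to form the base
#'   patterns, mirroring the early-delay averaging of the empirical
#'   simulations.
#' @param hyper decoder hyperparameters.
#' @param seed integer seed (fresh noise per pseudo-timepoint).
#' @return a `vwm_xdecode` matrix over the pseudo-time axis.
#' @export
schedule_cross_decode <- function(dataset, noise_schedule,
                                  condition = NULL,
                                  base_window = c(5.6, 8.8),
                                  hyper = psvr_hyperparams(),
                                  seed = 1L) {
  if (any(!is.finite(noise_schedule)) || any(noise_schedule <= 0))
    stop("noise schedule entries must be positive")
  w <- window_average(dataset, base_window, condition)
  base <- w$patterns
  set.seed(seed)
  n_tp <- length(noise_schedule)
  sig_sd <- apply(base, 2, stats::sd)
  bold <- array(NA_real_, c(nrow(base), ncol(base), n_tp))
  for (t in seq_len(n_tp)) {
    bold[, , t] <- base +
      matrix(stats::rnorm(length(base)), nrow(base)) *
        rep(sig_sd * noise_schedule[t], each = nrow(base))
  }
  pseudo <- list(trials = w$trials, bold = bold,
                 tr_seconds = dataset$tr_seconds,
                 time_s = seq_len(n_tp) - 1)
  class(pseudo) <- "vwm_dataset"
  cond <- if (is.null(condition)) unique(w$trials$condition)[1]
          else condition
  cross_decode_matrix(pseudo, cond, hyper = hyper)
}

#' Train- versus test-axis dependence of a cross-decoding matrix
#'
#' Summarizes how strongly accuracy varies along the training axis
#' relative to the test axis: the mean absolute difference between
#' adjacent cells down each column (train gradient) and along each row
#' (test gradient). For noise-schedule matrices built on a shared code,
#' accuracy depends more strongly on the training than the test noise
#' level, so the train gradient exceeds the test gradient.
#'
#' @param matrix a T x T cross-decoding matrix.
#' @return list with `train_gradient`, `test_gradient`.
#' @export
axis_dependence <- function(matrix) {
  m <- as.matrix(matrix)
  list(train_gradient = mean(abs(diff(m))),
       test_gradient = mean(abs(t(diff(t(m))))))
}
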