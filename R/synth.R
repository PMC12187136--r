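#' Design of a synthetic orientation working-memory experiment
#'
#' Describes the trial structure of a delayed-estimation orientation task:
#' sessions, conditions, trials per condition and session, orientation
#' binning, and the sampling grid of the delay period. Defaults mirror a
#' three-session design with 36 trials per condition per session (108 per
#' condition in total), six 30-degree orientation bins, a 0.5 s target
#' followed by a 13 s delay, and an fMRI repetition time of 0.8 s.
#'
#' @param n_sessions number of scanning sessions (also the cross-validation
#'   folds downstream), at least 2.
#' @param n_trials_per_condition_per_session trials per condition within one
#'   session; must be divisible by `orientation_bins` so that orientation
#'   sampling can be stratified.
#' @param conditions character vector of condition names. Names containing
#'   `"orientation_distractor"` receive a distractor orientation label.
#' @param orientation_bins number of equal orientation bins spanning 180
#'   degrees.
#' @param bin_width_deg width of one orientation bin in degrees; together
#'   with `orientation_bins` it must tile the 180-degree space exactly.
#' @param tr_seconds repetition time (sampling period of the time axis).
#' @param target_seconds duration of the target presentation.
#' @param delay_seconds duration of the memory delay.
#' @param timepoints number of sampled timepoints (TR bins) per trial,
#'   starting at delay onset.
#' @return an object of class `vwm_design`.
#' @export
design_spec <- function(n_sessions = 3,
                        n_trials_per_condition_per_session = 36,
                        conditions = c("no_distractor",
                                       "noise_distractor",
                                       "orientation_distractor"),
                        orientation_bins = 6,
                        bin_width_deg = 180 / orientation_bins,
                        tr_seconds = 0.8,
                        target_seconds = 0.5,
                        delay_seconds = 13,
                        timepoints = 18) {
  stopifnot(n_sessions >= 2, length(conditions) >= 1, timepoints >= 1)
  if (abs(orientation_bins * bin_width_deg - 180) > 1e-9)
    stop("orientation_bins * bin_width_deg must equal 180 degrees")
  if (n_trials_per_condition_per_session %% orientation_bins != 0)
    stop("trials per condition per session must be divisible by the ",
         "number of orientation bins (stratified sampling)")
  structure(list(
    n_sessions = as.integer(n_sessions),
    n_trials_per_condition_per_session =
      as.integer(n_trials_per_condition_per_session),
    conditions = as.character(conditions),
    orientation_bins = as.integer(orientation_bins),
    bin_width_deg = bin_width_deg,
    tr_seconds = tr_seconds,
    target_seconds = target_seconds,
    delay_seconds = delay_seconds,
    timepoints = as.integer(timepoints)
  ), class = "vwm_design")
}

#' Ground-truth dynamics of a synthetic dataset
#'
#' Controls the generative knobs that the analyses are meant to recover:
#' how much the population code rotates into an orthogonal basis over time,
#' how much the distractor code overlaps the target code, and the
#' signal-to-noise ratio at each timepoint.
#'
#' @param rotation_schedule per-timepoint mixing weight in \[0, 1\] between
#'   coding basis A (weight 0) and an orthogonal basis B (weight 1); a
#'   scalar is recycled over timepoints. 0 everywhere gives a perfectly
#'   stationary code.
#' @param distractor_subspace_overlap scalar in \[0, 1\]: 1 makes the
#'   distractor load on the target coding plane, 0 on an orthogonal plane.
#' @param snr_schedule per-timepoint signal-to-noise ratio (> 0), defined as
#'   the ratio of per-voxel signal variance to noise variance; a scalar is
#'   recycled.
#' @return an object of class `vwm_dynamics`.
#' @export
dynamics_spec <- function(rotation_schedule = 0,
                          distractor_subspace_overlap = 0,
                          snr_schedule = 1) {
  if (any(!is.finite(rotation_schedule)) ||
      any(rotation_schedule < 0 | rotation_schedule > 1))
    stop("rotation_schedule weights must lie in [0, 1]")
  if (length(distractor_subspace_overlap) != 1 ||
      !is.finite(distractor_subspace_overlap) ||
      distractor_subspace_overlap < 0 || distractor_subspace_overlap > 1)
    stop("distractor_subspace_overlap must be a scalar in [0, 1]")
  if (any(!is.finite(snr_schedule)) || any(snr_schedule <= 0))
    stop("snr_schedule values must be > 0")
  structure(list(
    rotation_schedule = as.numeric(rotation_schedule),
    distractor_subspace_overlap = distractor_subspace_overlap,
    snr_schedule = as.numeric(snr_schedule)
  ), class = "vwm_dynamics")
}

#' Generate a population of orientation-tuned voxels
#'
#' Each voxel responds to orientation with a sine or a cosine of the
#' doubled angle (so that responses are 180-degree periodic), circularly
#' shifted by a voxel-specific amount so that preferred orientations tile
#' the feature space. Responses are tabulated at all integer orientations
#' 1..180 degrees and have unit amplitude.
#'
#' @param n_voxels number of voxels, at least 2 (a single basis function
#'   cannot span the sine/cosine coding plane).
#' @param seed integer seed; the same seed reproduces the same population.
#' @return an object of class `vwm_tuning` with elements `responses`
#'   (180 x n_voxels matrix, row i = response to i degrees), `basis`
#'   (`"sine"` or `"cosine"` per voxel) and `shifts` (degrees in \[0, 180)).
#' @export
generate_tuned_voxels <- function(n_voxels, seed = 1L) {
  if (n_voxels < 2)
    stop("n_voxels must be at least 2 to span the sine/cosine plane")
  set.seed(seed)
  basis <- sample(c("sine", "cosine"), n_voxels, replace = TRUE)
  shifts <- stats::runif(n_voxels, 0, 180)
  tuning <- structure(list(
    basis = basis, shifts = shifts, n_voxels = as.integer(n_voxels),
    seed = as.integer(seed)
  ), class = "vwm_tuning")
  tuning$responses <- tuning_response(tuning, 1:180)
  tuning
}

#' Evaluate tuning curves at arbitrary orientations
#'
#' @param tuning a `vwm_tuning` object.
#' @param theta_deg orientations in degrees (any real values; 180-periodic).
#' @return matrix of length(theta_deg) x n_voxels responses.
#' @export
tuning_response <- function(tuning, theta_deg) {
  stopifnot(inherits(tuning, "vwm_tuning"))
  # doubled angle: 180 deg of orientation sweeps a full 2*pi cycle
  d <- outer(theta_deg, tuning$shifts, `-`) * pi / 90
  out <- matrix(NA_real_, length(theta_deg), tuning$n_voxels)
  s <- tuning$basis == "sine"
  out[, s] <- sin(d[, s, drop = FALSE])
  out[, !s] <- cos(d[, !s, drop = FALSE])
  dimnames(out) <- NULL
  out
}

# Population coding plane of a tuned voxel set: pattern(theta) =
# sin(d) * a + cos(d) * b with d the doubled angle. Returns the loading
# vectors a and b (length n_voxels).
coding_plane <- function(tuning) {
  ds <- tuning$shifts * pi / 90
  a <- ifelse(tuning$basis == "sine", cos(ds), sin(ds))
  b <- ifelse(tuning$basis == "sine", -sin(ds), cos(ds))
  list(a = a, b = b)
}

# Orthonormal directions orthogonal to the columns of m (n x k), drawn
# reproducibly from the current RNG stream. Returns n x n_new.
orthogonal_complement_basis <- function(m, n_new) {
  n <- nrow(m)
  k <- ncol(m)
  if (n < k + n_new)
    stop("not enough dimensions for an orthogonal complement; ",
         "increase the number of voxels")
  q <- qr.Q(qr(cbind(m, matrix(stats::rnorm(n * n_new), n, n_new))))
  q[, (k + 1):(k + n_new), drop = FALSE]
}

#' Generate a synthetic working-memory experiment with known ground truth
#'
#' Builds per-trial voxel patterns over the delay period from orientation
#' tuning curves, with optional rotation of the code into an orthogonal
#' basis over time, optional distractor loadings in a controllable
#' subspace, and additive Gaussian noise at a controllable
#' signal-to-noise ratio. The population sine/cosine loading vectors are
#' orthonormalized (and given a common norm) before building signals, so
#' that pattern norms carry no orientation information and orthogonal
#' coding bases share no transferable signal by construction. Orientations are sampled stratified over bins
#' within each session and condition. Voxel time series are z-scored per
#' voxel (across all trials and timepoints) as a final step, emulating the
#' normalization applied to empirical pattern data.
#'
#' @param design a `vwm_design`.
#' @param dynamics a `vwm_dynamics`; scalar schedules are recycled to the
#'   design's number of timepoints, but explicit schedules must match it.
#' @param tuning a `vwm_tuning`; its voxel count sets the pattern dimension.
#' @param seed integer seed; identical inputs and seed give bit-identical
#'   datasets.
#' @param distractor_conditions condition names whose trials carry an
#'   (orientation) distractor label and loadings; defaults to conditions
#'   named `"orientation_distractor"`.
#' @param distractor_amplitude amplitude of distractor loadings relative to
#'   target loadings.
#' @return an object of class `vwm_dataset`: `trials` (data frame with
#'   columns trial, session, condition, target_deg, distractor_deg, bin),
#'   `bold` (trials x voxels x timepoints array), `tr_seconds`, `time_s`
#'   (seconds from delay onset per timepoint), `truth` (generative bases
#'   and the dynamics spec) and `seed`.
#' @export
generate_experiment <- function(design, dynamics, tuning, seed = 1L,
                                distractor_conditions = NULL,
                                distractor_amplitude = 1) {
  stopifnot(inherits(design, "vwm_design"),
            inherits(dynamics, "vwm_dynamics"),
            inherits(tuning, "vwm_tuning"))
  tp <- design$timepoints
  rot <- dynamics$rotation_schedule
  if (length(rot) == 1) rot <- rep(rot, tp)
  snr <- dynamics$snr_schedule
  if (length(snr) == 1) snr <- rep(snr, tp)
  if (length(rot) != tp || length(snr) != tp)
    stop("rotation and SNR schedule lengths must equal the design's ",
         "number of timepoints (", tp, ")")
  if (is.null(distractor_conditions))
    distractor_conditions <-
      grep("orientation_distractor", design$conditions, value = TRUE)

  set.seed(seed)
  nb <- design$orientation_bins
  bw <- design$bin_width_deg
  per_bin <- design$n_trials_per_condition_per_session / nb

  draw_stratified <- function() {
    lo <- rep((0:(nb - 1)) * bw, each = per_bin)
    theta <- lo + stats::runif(length(lo), 0, bw)
    sample(theta)  # shuffle trial order within session x condition
  }

  rows <- list()
  k <- 0L
  for (s in seq_len(design$n_sessions)) {
    for (cond in design$conditions) {
      theta <- draw_stratified()
      dist <- if (cond %in% distractor_conditions) draw_stratified()
              else rep(NA_real_, length(theta))
      rows[[length(rows) + 1L]] <- data.frame(
        session = s, condition = cond, target_deg = theta,
        distractor_deg = dist)
    }
  }
  trials <- do.call(rbind, rows)
  trials$trial <- seq_len(nrow(trials)) - 1L
  trials$bin <- orientation_bin(trials$target_deg, nb)
  trials <- trials[, c("trial", "session", "condition",
                       "target_deg", "distractor_deg", "bin")]

  nv <- tuning$n_voxels
  plane <- coding_plane(tuning)
  # orthonormalize the population coding plane (finite voxel samples of
  # sine/cosine loadings are only approximately orthogonal) so pattern
  # norms are orientation-independent: otherwise the norm itself carries
  # label information that leaks across supposedly orthogonal bases
  scale_c <- sqrt((sum(plane$a^2) + sum(plane$b^2)) / 2)
  q <- qr.Q(qr(cbind(plane$a, plane$b)))
  a <- q[, 1] * scale_c; b <- q[, 2] * scale_c
  comp <- orthogonal_complement_basis(q, 4L)
  a2 <- comp[, 1] * scale_c; b2 <- comp[, 2] * scale_c  # orthogonal basis B
  ov <- dynamics$distractor_subspace_overlap
  da <- distractor_amplitude * scale_c *
    (sqrt(ov) * q[, 1] + sqrt(1 - ov) * comp[, 3])
  db <- distractor_amplitude * scale_c *
    (sqrt(ov) * q[, 2] + sqrt(1 - ov) * comp[, 4])

  dt <- trials$target_deg * pi / 90      # doubled angle
  sA <- outer(sin(dt), a) + outer(cos(dt), b)
  sB <- outer(sin(dt), a2) + outer(cos(dt), b2)
  has_dist <- !is.na(trials$distractor_deg)
  sD <- matrix(0, nrow(trials), nv)
  if (any(has_dist)) {
    dd <- trials$distractor_deg[has_dist] * pi / 90
    sD[has_dist, ] <- outer(sin(dd), da) + outer(cos(dd), db)
  }

  n_tr <- nrow(trials)
  bold <- array(NA_real_, c(n_tr, nv, tp))
  for (t in seq_len(tp))
    bold[, , t] <- (1 - rot[t]) * sA + rot[t] * sB + sD

  # per-voxel signal sd pooled over trials and timepoints; noise sd at
  # timepoint t follows the SNR (variance-ratio) schedule
  sig_sd <- apply(bold, 2, stats::sd)
  sig_sd[sig_sd < 1e-12] <- mean(sig_sd[sig_sd >= 1e-12], na.rm = TRUE)
  for (t in seq_len(tp)) {
    noise_sd <- sig_sd / sqrt(snr[t])
    bold[, , t] <- bold[, , t] +
      matrix(stats::rnorm(n_tr * nv), n_tr, nv) * rep(noise_sd, each = n_tr)
  }

  # z-score each voxel across all trials and timepoints
  for (v in seq_len(nv)) {
    x <- bold[, v, ]
    s <- stats::sd(x)
    bold[, v, ] <- (x - mean(x)) / if (s > 0) s else 1
  }

  structure(list(
    trials = trials,
    bold = bold,
    tr_seconds = design$tr_seconds,
    time_s = (seq_len(tp) - 1L) * design$tr_seconds,
    design = design,
    truth = list(dynamics = dynamics, tuning = tuning,
                 basis_a = cbind(a, b), basis_b = cbind(a2, b2),
                 distractor_basis = cbind(da, db)),
    seed = as.integer(seed)
  ), class = "vwm_dataset")
}

#' Half-open orientation bin index
#'
#' Bins orientations in degrees into `n_bins` equal half-open bins
#' \[lo, hi) spanning \[0, 180). Values are reduced modulo 180 first.
#'
#' @param theta_deg orientations in degrees.
#' @param n_bins number of bins.
#' @return integer bin indices in 1..n_bins.
#' @export
orientation_bin <- function(theta_deg, n_bins) {
  if (any(!is.finite(theta_deg))) stop("orientations must be finite")
  theta <- theta_deg %% 180
  pmin(floor(theta / (180 / n_bins)), n_bins - 1) + 1L
}

#' Add white Gaussian noise at a given signal-to-noise ratio
#'
#' Noise variance is set per voxel so that (signal variance) / (noise
#' variance) equals `snr`, with the signal variance computed per voxel over
#' all remaining dimensions (trials, and timepoints if present). Voxels
#' with zero signal variance receive noise at the population-mean scale.
#'
#' @param bold trials x voxels matrix or trials x voxels x timepoints array.
#' @param snr signal-to-noise variance ratio, > 0.
#' @param seed integer seed (same seed, same noise).
#' @return an object of the same shape with noise added.
#' @export
add_noise <- function(bold, snr, seed = 1L) {
  if (length(snr) != 1 || !is.finite(snr) || snr <= 0)
    stop("snr must be a positive scalar")
  set.seed(seed)
  d <- dim(bold)
  if (is.null(d) || !(length(d) %in% c(2, 3)))
    stop("bold must be a trials x voxels matrix or a 3-d array")
  sig_sd <- apply(bold, 2, stats::sd)
  fallback <- mean(sig_sd[sig_sd >= 1e-12])
  sig_sd[sig_sd < 1e-12] <- if (is.finite(fallback)) fallback else 1
  noise_sd <- sig_sd / sqrt(snr)
  noise <- array(stats::rnorm(length(bold)), d)
  if (length(d) == 2) {
    bold + noise * rep(noise_sd, each = d[1])
  } else {
    bold + noise * rep(rep(noise_sd, each = d[1]), times = d[3])
  }
}

#' @export
print.vwm_dataset <- function(x, ...) {
  d <- dim(x$bold)
  cat("Synthetic working-memory dataset\n")
  cat(sprintf("  %d trials x %d voxels x %d timepoints (TR = %.2f s)\n",
              d[1], d[2], d[3], x$tr_seconds))
  cat("  conditions:", paste(unique(x$trials$condition), collapse = ", "),
      "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' @export
print.vwm_tuning <- function(x, ...) {
  cat(sprintf("Orientation-tuned voxel population: %d voxels (%d sine, %d cosine)\n",
              x$n_voxels, sum(x$basis == "sine"), sum(x$basis == "cosine")))
  invisible(x)
}
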