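#' Per-voxel orientation tuning functions from a bin-regressor GLM
#'
#' Fits, per voxel, a least-squares model of trial responses on indicator
#' regressors for equidistant orientation bins (default six bins of 30
#' degrees), assuming additive i.i.d. noise across trials. When session
#' labels are provided, mean-centered sum-to-zero session regressors are
#' included as nuisance covariates; in a balanced design they are
#' orthogonal to the bin regressors, so the bin estimates equal the
#' per-bin trial means.
#'
#' @param patterns trials x voxels matrix of responses.
#' @param labels_deg orientation labels in degrees, one per trial.
#' @param n_bins number of orientation bins.
#' @param sessions optional per-trial session labels (nuisance
#'   intercepts).
#' @return n_bins x voxels matrix of tuning parameter estimates.
#' @export
tuning_glm <- function(patterns, labels_deg, n_bins = 6, sessions = NULL) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) != length(labels_deg))
    stop("one label per trial required")
  bins <- orientation_bin(labels_deg, n_bins)
  counts <- tabulate(bins, n_bins)
  if (any(counts == 0))
    stop("orientation bin ", which(counts == 0)[1], " contains no trials")
  x <- matrix(0, nrow(patterns), n_bins)
  x[cbind(seq_along(bins), bins)] <- 1
  if (!is.null(sessions) && length(unique(sessions)) > 1) {
    f <- factor(sessions)
    s <- stats::model.matrix(~f, contrasts.arg = list(f = "contr.sum"))
    s <- s[, -1, drop = FALSE]                   # drop intercept
    s <- sweep(s, 2, colMeans(s))                # center nuisance columns
    x <- cbind(x, s)
  }
  beta <- qr.coef(qr(x), patterns)
  beta <- beta[seq_len(n_bins), , drop = FALSE]
  rownames(beta) <- NULL
  beta
}

# Columnwise Pearson correlation between two matrices with matching
# dimensions; columns with zero variance give NA.
colwise_cor <- function(a, b) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  num <- colSums(a * b)
  den <- sqrt(colSums(a^2) * colSums(b^2))
  ifelse(den > 0, num / den, NA_real_)
}

# Fisher z-transform with r = +/-1 clamped to avoid infinities.
fisher_z <- function(r) {
  atanh(pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12))
}

# One split-half tuning-reliability pass: split trials stratified by bin,
# estimate tuning per half, correlate per voxel.
split_half_reliability <- function(patterns, labels_deg, n_bins,
                                   sessions) {
  bins <- orientation_bin(labels_deg, n_bins)
  sp <- stratified_split(bins)
  ta <- tuning_glm(patterns[sp$a, , drop = FALSE], labels_deg[sp$a],
                   n_bins, sessions[sp$a])
  tb <- tuning_glm(patterns[sp$b, , drop = FALSE], labels_deg[sp$b],
                   n_bins, sessions[sp$b])
  colwise_cor(ta, tb)
}

#' Split-half tuning-reliability voxel selection with a permutation null
#'
#' Selects voxels whose orientation tuning replicates across random
#' half-splits of the trials in both a memory task and a perception task.
#' Per voxel, the tuning functions of the two halves are correlated
#' (memory-memory and perception-perception); the correlations are Fisher
#' z-transformed and compared with the chosen percentile of a null
#' distribution built from label-permuted repetitions of the identical
#' analysis, pooled across voxels (one null per task). A voxel is
#' selected when both z values exceed their null threshold.
#'
#' @param memory,perception lists with elements `patterns` (trials x
#'   voxels), `labels` (degrees) and optional `sessions`.
#' @param n_bins orientation bins of the tuning function (default 6).
#' @param n_perm label permutations building the null (default 1000).
#' @param percentile null percentile both z values must exceed
#'   (default 75).
#' @param seed integer seed (split and permutations).
#' @return an object of class `vwm_reliability`: `table` (data frame with
#'   voxel, r_mm, r_pp, z_mm, z_pp, selected), `threshold_mm`,
#'   `threshold_pp`, `n_perm`, `percentile`. Zero-variance tuning gives
#'   r = -1 (never selected) with a warning.
#' @export
reliability_select <- function(memory, perception, n_bins = 6,
                               n_perm = 1000, percentile = 75,
                               seed = 1L) {
  check_task <- function(task, name) {
    if (is.null(task$patterns) || is.null(task$labels))
      stop(name, " task needs 'patterns' and 'labels'")
    if (nrow(task$patterns) != length(task$labels))
      stop(name, " task: one label per trial required")
    if (is.null(task$sessions))
      task$sessions <- rep(1L, length(task$labels))
    task
  }
  memory <- check_task(memory, "memory")
  perception <- check_task(perception, "perception")
  nv <- ncol(memory$patterns)
  if (ncol(perception$patterns) != nv)
    stop("memory and perception tasks have different voxel counts")
  set.seed(seed)

  fix_r <- function(r) {
    if (any(is.na(r))) {
      warning(sum(is.na(r)),
              " voxel(s) with zero-variance tuning; r set to -1")
      r[is.na(r)] <- -1
    }
    r
  }
  r_mm <- fix_r(split_half_reliability(memory$patterns, memory$labels,
                                       n_bins, memory$sessions))
  r_pp <- fix_r(split_half_reliability(perception$patterns,
                                       perception$labels,
                                       n_bins, perception$sessions))
  z_mm <- fisher_z(r_mm)
  z_pp <- fisher_z(r_pp)

  null_mm <- matrix(NA_real_, n_perm, nv)
  null_pp <- matrix(NA_real_, n_perm, nv)
  for (p in seq_len(n_perm)) {
    null_mm[p, ] <- split_half_reliability(
      memory$patterns, sample(memory$labels), n_bins, memory$sessions)
    null_pp[p, ] <- split_half_reliability(
      perception$patterns, sample(perception$labels), n_bins,
      perception$sessions)
  }
  thr_mm <- stats::quantile(fisher_z(null_mm), percentile / 100,
                            na.rm = TRUE, names = FALSE)
  thr_pp <- stats::quantile(fisher_z(null_pp), percentile / 100,
                            na.rm = TRUE, names = FALSE)

  selected <- z_mm > thr_mm & z_pp > thr_pp
  structure(list(
    table = data.frame(voxel = seq_len(nv) - 1L, r_mm = r_mm,
                       r_pp = r_pp, z_mm = z_mm, z_pp = z_pp,
                       selected = selected),
    threshold_mm = thr_mm, threshold_pp = thr_pp,
    n_perm = n_perm, percentile = percentile, seed = seed
  ), class = "vwm_reliability")
}

#' @export
print.vwm_reliability <- function(x, ...) {
  cat(sprintf(
    "Voxel reliability selection: %d / %d voxels selected (null %gth percentile, %d permutations)\n",
    sum(x$table$selected), nrow(x$table), x$percentile, x$n_perm))
  invisible(x)
}
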