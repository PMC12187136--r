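#' Average voxel patterns over a time window
#'
#' Selects the timepoints whose latency (seconds from delay onset) falls
#' inside a closed window and averages the bold array over them, returning
#' a trials x voxels matrix. Optionally restricted to one condition.
#'
#' @param dataset a `vwm_dataset`.
#' @param window length-2 numeric, window in seconds (inclusive).
#' @param condition optional condition filter.
#' @return list with `patterns` (trials x voxels) and `trials` (the
#'   matching rows of the trial table).
#' @export
window_average <- function(dataset, window = c(4, 17.6),
                           condition = NULL) {
  time_s <- dataset$time_s
  keep_t <- which(time_s >= window[1] - 1e-9 & time_s <= window[2] + 1e-9)
  if (length(keep_t) == 0)
    stop("no timepoints inside the window [", window[1], ", ",
         window[2], "] s")
  tr <- dataset$trials
  keep_trials <- if (is.null(condition)) seq_len(nrow(tr))
                 else which(tr$condition == condition)
  if (length(keep_trials) == 0)
    stop("no trials for condition '", condition, "'")
  sub <- dataset$bold[keep_trials, , keep_t, drop = FALSE]
  patterns <- apply(sub, c(1, 2), mean)
  list(patterns = patterns, trials = tr[keep_trials, , drop = FALSE])
}

#' Bin trial patterns by orientation and mean-center voxels
#'
#' Averages trial-wise patterns within equidistant orientation bins
#' (default four bins of 45 degrees) and mean-centers each voxel column,
#' producing the rho x upsilon data matrix underlying the subspace
#' analysis.
#'
#' @param patterns trials x voxels matrix.
#' @param labels_deg orientation labels in degrees, one per trial.
#' @param n_bins number of orientation bins (rho).
#' @return an object of class `vwm_binned`: `X` (n_bins x voxels,
#'   column-centered), `bin_edges` (degrees), `counts` (trials per bin).
#' @export
bin_and_center <- function(patterns, labels_deg, n_bins = 4) {
  patterns <- as.matrix(patterns)
  if (nrow(patterns) != length(labels_deg))
    stop("one label per trial required")
  bins <- orientation_bin(labels_deg, n_bins)
  counts <- tabulate(bins, n_bins)
  if (any(counts == 0)) {
    bad <- which(counts == 0)[1]
    w <- 180 / n_bins
    stop(sprintf("orientation bin %d ([%g, %g) degrees) contains no trials",
                 bad, (bad - 1) * w, bad * w))
  }
  x <- rowsum(patterns, bins) / counts
  x <- sweep(x, 2, colMeans(x))
  dimnames(x) <- NULL
  structure(list(X = x, bin_edges = seq(0, 180, by = 180 / n_bins),
                 counts = counts),
            class = "vwm_binned")
}

#' Two-dimensional neural subspace of binned patterns
#'
#' Principal component analysis of the binned, voxel-centered pattern
#' matrix: the subspace is spanned by the eigenvectors of the voxel
#' covariance matrix belonging to the two largest eigenvalues. The
#' eigendecomposition is computed through the singular value
#' decomposition of the (small) rho x upsilon matrix, equivalent to the
#' dual eigenproblem and costing O(rho^3) rather than O(upsilon^3).
#'
#' @param x a `vwm_binned` object or a rho x upsilon column-centered
#'   matrix with rho >= 3.
#' @return an object of class `vwm_subspace`: `V` (upsilon x 2 orthonormal
#'   basis), `eigenvalues` (top 2 of the covariance), and
#'   `explained_variance_fraction`.
#' @export
compute_subspace <- function(x) {
  m <- if (inherits(x, "vwm_binned")) x$X else as.matrix(x)
  rho <- nrow(m)
  if (rho < 3)
    stop("need at least 3 orientation bins for a rank-2 covariance")
  sv <- svd(m, nu = 0, nv = 2)
  tot <- sum(sv$d^2)
  if (tot <= 0 || sv$d[2]^2 / tot < 1e-24)
    stop("degenerate geometry: binned patterns have rank < 2")
  structure(list(
    V = sv$v,
    eigenvalues = sv$d[1:2]^2 / (rho - 1),
    explained_variance_fraction = sv$d[1:2]^2 / tot
  ), class = "vwm_subspace")
}

subspace_basis <- function(v) {
  if (inherits(v, "vwm_subspace")) v$V else as.matrix(v)
}

#' Largest principal angle between two 2-D subspaces
#'
#' Computed from the singular values of V1' V2 (the cosines of the
#' canonical angles): the angle reported is the arc cosine of the
#' smallest singular value, i.e. the largest canonical angle, between 0
#' and 90 degrees. 0 means the planes coincide; 90 means some direction
#' of one plane is orthogonal to all of the other.
#'
#' @param v1,v2 `vwm_subspace` objects or upsilon x 2 orthonormal bases
#'   over the same voxels.
#' @return angle in degrees, in \[0, 90\].
#' @export
principal_angle <- function(v1, v2) {
  b1 <- subspace_basis(v1)
  b2 <- subspace_basis(v2)
  if (nrow(b1) != nrow(b2))
    stop("subspaces live in different voxel spaces")
  s <- svd(crossprod(b1, b2), nu = 0, nv = 0)$d
  s <- pmin(pmax(s, 0), 1)
  acos(min(s)) * 180 / pi
}

#' Project binned patterns onto a subspace
#'
#' @param subspace a `vwm_subspace` (or upsilon x 2 basis).
#' @param x_test a `vwm_binned` or rho x upsilon matrix over the same
#'   voxels.
#' @return rho x 2 matrix of projected coordinates.
#' @export
project_leftout <- function(subspace, x_test) {
  v <- subspace_basis(subspace)
  m <- if (inherits(x_test, "vwm_binned")) x_test$X else as.matrix(x_test)
  if (ncol(m) != nrow(v))
    stop("voxel dimensions of the data and the subspace differ")
  m %*% v
}

# Stratified half-split of trial indices by orientation bin: within each
# bin, trials are randomly halved; odd counts give the extra trial to
# half A. Returns list(a, b) of indices.
stratified_split <- function(bins) {
  a <- integer(0); b <- integer(0)
  for (bin in sort(unique(bins))) {
    idx <- sample(which(bins == bin))
    na <- ceiling(length(idx) / 2)
    a <- c(a, idx[seq_len(na)])
    b <- c(b, idx[-seq_len(na)])
  }
  list(a = a, b = b)
}

# Shared engine for split-half above-baseline principal angles. pat1/pat2
# are trials x voxels matrices; lab1/lab2 the corresponding binning labels
# (degrees). The split is stratified on lab1's bins and shared between the
# two patterns (pat2 may be the same matrix binned by other labels, or
# the same trials at another time). Returns per-iteration aPA, between,
# within.
apa_engine <- function(pat1, lab1, pat2, lab2, n_bins, n_iter,
                       same_trials = TRUE) {
  bins <- orientation_bin(lab1, n_bins)
  if (min(tabulate(bins, n_bins)) < 4)
    stop("need at least 2 trials per orientation bin per half ",
         "(4 per bin in total)")
  apa <- between <- within <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    sp <- stratified_split(bins)
    v1a <- compute_subspace(bin_and_center(pat1[sp$a, , drop = FALSE],
                                           lab1[sp$a], n_bins))
    v1b <- compute_subspace(bin_and_center(pat1[sp$b, , drop = FALSE],
                                           lab1[sp$b], n_bins))
    v2a <- compute_subspace(bin_and_center(pat2[sp$a, , drop = FALSE],
                                           lab2[sp$a], n_bins))
    v2b <- compute_subspace(bin_and_center(pat2[sp$b, , drop = FALSE],
                                           lab2[sp$b], n_bins))
    between[it] <- (principal_angle(v1a, v2b) +
                      principal_angle(v1b, v2a)) / 2
    within[it] <- (principal_angle(v1a, v1b) +
                     principal_angle(v2a, v2b)) / 2
    apa[it] <- between[it] - within[it]
  }
  list(apa = apa, between = between, within = within)
}

#' Split-half above-baseline principal angle between two time windows
#'
#' Measures how far the orientation coding plane at one time differs from
#' the plane at another time, corrected for split-half estimation noise.
#' Per iteration, trials are randomly halved (stratified by orientation
#' bin; the same split serves both time windows); subspaces are computed
#' per half and per window; the between-window principal angle (averaged
#' over the two split crossings) minus the within-window split-half angle
#' (averaged over the two windows) is the above-baseline PA. The reported
#' value is the mean over iterations. For identical windows the aPA is
#' exactly zero by symmetry of the between and within terms.
#'
#' @param dataset a `vwm_dataset`.
#' @param window_i,window_j time windows in seconds (length-2).
#' @param condition optional condition filter.
#' @param n_bins orientation bins for the subspace (default 4, i.e. 45
#'   degrees).
#' @param n_iter number of random splits (default 1000).
#' @param seed integer seed.
#' @return an object of class `vwm_apa` with `apa_deg` (mean over
#'   iterations), `between_deg`, `within_deg`, per-iteration values, and
#'   `n_iter`.
#' @export
above_baseline_pa <- function(dataset, window_i, window_j,
                              condition = NULL, n_bins = 4,
                              n_iter = 1000, seed = 1L) {
  wi <- window_average(dataset, window_i, condition)
  wj <- window_average(dataset, window_j, condition)
  set.seed(seed)
  res <- apa_engine(wi$patterns, wi$trials$target_deg,
                    wj$patterns, wj$trials$target_deg,
                    n_bins, n_iter)
  structure(list(
    apa_deg = mean(res$apa),
    between_deg = mean(res$between),
    within_deg = mean(res$within),
    iterations = res$apa,
    n_iter = n_iter, seed = seed,
    window_i = window_i, window_j = window_j
  ), class = "vwm_apa")
}

#' Above-baseline principal angle between target and distractor subspaces
#'
#' Compares the coding plane of the remembered target orientation with
#' the plane of a concurrently presented distractor orientation, on
#' delay-averaged patterns. Trials are split in half (stratified by the
#' target's orientation bin); within each half the same trials are binned
#' once by target orientation and once by distractor orientation, giving
#' target and distractor subspaces whose cross-type principal angle,
#' baseline-corrected by the within-type split-half angles, measures the
#' separation of the two codes.
#'
#' @param dataset a `vwm_dataset` whose chosen condition carries
#'   distractor orientation labels.
#' @param delay_window delay period to average over, seconds.
#' @param condition condition with distractor labels.
#' @param n_bins orientation bins (default 4).
#' @param n_iter number of random splits.
#' @param seed integer seed.
#' @return an object of class `vwm_apa` (as [above_baseline_pa()]).
#' @export
target_distractor_apa <- function(dataset, delay_window = c(4, 17.6),
                                  condition = "orientation_distractor",
                                  n_bins = 4, n_iter = 1000, seed = 1L) {
  w <- window_average(dataset, delay_window, condition)
  if (any(is.na(w$trials$distractor_deg)))
    stop("condition '", condition, "' lacks distractor orientation labels")
  set.seed(seed)
  res <- apa_engine(w$patterns, w$trials$target_deg,
                    w$patterns, w$trials$distractor_deg,
                    n_bins, n_iter)
  structure(list(
    apa_deg = mean(res$apa),
    between_deg = mean(res$between),
    within_deg = mean(res$within),
    iterations = res$apa,
    n_iter = n_iter, seed = seed,
    delay_window = delay_window
  ), class = "vwm_apa")
}

#' @export
print.vwm_apa <- function(x, ...) {
  cat(sprintf(
    "Above-baseline principal angle: %.2f deg (between %.2f, within %.2f; %d iterations)\n",
    x$apa_deg, x$between_deg, x$within_deg, x$n_iter))
  invisible(x)
}

#' One-tailed sign-permutation test of subject-mean angles
#'
#' Group inference for above-baseline principal angles: the observed mean
#' of per-subject aPA values is compared with the distribution of means
#' under random sign flips of each subject's value. Exhaustive over all
#' 2^n flip patterns when feasible, otherwise Monte Carlo.
#'
#' @param values per-subject aPA values (degrees).
#' @param n_perm maximum number of flip patterns (default 10000).
#' @return one-tailed p-value for the mean being above zero.
#' @export
apa_sign_test <- function(values, n_perm = 10000) {
  n <- length(values)
  if (n < 2) stop("need at least 2 subjects")
  obs <- mean(values)
  if (2^n <= n_perm) {
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    means <- flips %*% values / n
    mean(means >= obs - 1e-12)
  } else {
    flips <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                    n_perm, n)
    means <- flips %*% values / n
    (1 + sum(means >= obs - 1e-12)) / (1 + n_perm)
  }
}

#' Pairwise time-bin subspace comparison with FDR correction
#'
#' Computes the above-baseline principal angle between every pair of
#' nonoverlapping time bins for each subject, tests each pair across
#' subjects with a one-tailed sign-permutation test, and adjusts the
#' p-values with the Benjamini-Hochberg procedure.
#'
#' @param datasets list of `vwm_dataset` objects (one per subject).
#' @param windows list of length-2 time windows (seconds); default six
#'   2.4 s bins spanning 4 to 18.4 s.
#' @param condition optional condition filter.
#' @param n_bins orientation bins.
#' @param n_iter split iterations per subject and pair.
#' @param seed integer seed.
#' @return list with `apa` (pairs x subjects matrix), `pairs` (data frame
#'   i, j), `p` and `q` per pair.
#' @export
apa_time_matrix <- function(datasets, windows = NULL, condition = NULL,
                            n_bins = 4, n_iter = 100, seed = 1L) {
  if (is.null(windows))
    windows <- lapply(0:5, function(k) c(4, 6.4) + 2.4 * k)
  pairs <- which(upper.tri(diag(length(windows))), arr.ind = TRUE)
  apa <- matrix(NA_real_, nrow(pairs), length(datasets))
  for (p in seq_len(nrow(pairs))) {
    for (s in seq_along(datasets)) {
      apa[p, s] <- above_baseline_pa(
        datasets[[s]], windows[[pairs[p, 1]]], windows[[pairs[p, 2]]],
        condition = condition, n_bins = n_bins, n_iter = n_iter,
        seed = seed + 1000L * p + s)$apa_deg
    }
  }
  pv <- apply(apa, 1, apa_sign_test)
  list(apa = apa,
       pairs = data.frame(i = pairs[, 1], j = pairs[, 2]),
       p = pv, q = fdr_correct(pv), windows = windows)
}
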