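#' Temporal cross-decoding matrix
#'
#' Trains the periodic decoder at each training timepoint and reconstructs
#' orientations at every test timepoint, yielding a train-time x test-time
#' matrix of mean FCA values. Folds are defined by session (train on all
#' but one session, test on the left-out one), so training and test trials
#' are disjoint at every combination of timepoints. One decoder is fitted
#' per fold and training timepoint and reused across all test timepoints.
#'
#' @param dataset a `vwm_dataset`.
#' @param condition condition whose trials are tested.
#' @param timepoints 1-based timepoint indices to include (default: all).
#' @param hyper decoder hyperparameters.
#' @param train_condition optional condition to train on instead (e.g.
#'   train on no-distractor trials, test on distractor trials); folds are
#'   identical so comparisons against within-condition matrices are
#'   paired.
#' @return a T x T matrix of class `vwm_xdecode` (rows = training time,
#'   columns = test time) with attributes `time_s` (seconds from delay
#'   onset) and `condition`.
#' @export
cross_decode_matrix <- function(dataset, condition, timepoints = NULL,
                                hyper = psvr_hyperparams(),
                                train_condition = NULL) {
  tr <- dataset$trials
  n_tp <- dim(dataset$bold)[3]
  if (is.null(timepoints)) timepoints <- seq_len(n_tp)
  if (length(timepoints) < 1 || any(timepoints < 1 | timepoints > n_tp))
    stop("timepoint indices out of range")
  train_cond <- if (is.null(train_condition)) condition else train_condition
  for (cond in unique(c(condition, train_cond))) {
    present <- unique(tr$session[tr$condition == cond])
    if (!setequal(present, unique(tr$session)))
      stop("condition '", cond, "' is missing from some sessions")
  }
  nt <- length(timepoints)
  folds <- session_folds(tr$session)
  dev_sum <- matrix(0, nt, nt)
  dev_n <- matrix(0L, nt, nt)
  for (f in folds) {
    itrain <- which(tr$condition == train_cond &
                      tr$session %in% f$train_sessions)
    itest <- which(tr$condition == condition &
                     tr$session == f$test_session)
    if (length(intersect(itrain, itest)) > 0)
      stop("leakage guard: train and test trials overlap")
    theta_test <- wrap_orientation(tr$target_deg[itest])
    for (i in seq_len(nt)) {
      model <- fit_psvr(
        slice_bold(dataset$bold, itrain, timepoints[i]),
        wrap_orientation(tr$target_deg[itrain]), hyper)
      for (j in seq_len(nt)) {
        theta_p <- predict_orientation(
          model, slice_bold(dataset$bold, itest, timepoints[j]))
        dev <- angular_deviation(theta_test, theta_p)
        dev_sum[i, j] <- dev_sum[i, j] + sum(fca_trialwise(dev))
        dev_n[i, j] <- dev_n[i, j] + length(dev)
      }
    }
  }
  out <- dev_sum / dev_n
  time_s <- if (!is.null(dataset$time_s)) dataset$time_s[timepoints]
            else timepoints
  structure(out, class = c("vwm_xdecode", "matrix"),
            time_s = time_s, condition = condition,
            train_condition = train_cond)
}

#' Stack per-subject cross-decoding matrices
#'
#' @param matrices list of equally sized T x T matrices (one per subject).
#' @return a subjects x T x T array.
#' @export
stack_subjects <- function(matrices) {
  dims <- unique(lapply(matrices, dim))
  if (length(dims) != 1) stop("matrices differ in size")
  arr <- array(NA_real_, c(length(matrices), dims[[1]]))
  for (s in seq_along(matrices)) arr[s, , ] <- as.matrix(matrices[[s]])
  arr
}

#' Identify dynamic-coding elements in a cross-decoding matrix stack
#'
#' An off-diagonal element (i, j) is *dynamic* when the code trained at
#' time i does not generalize to time j: its accuracy a_ij is
#' significantly lower than both corresponding diagonal accuracies a_ii
#' and a_jj (two cluster-based sign-permutation tests on the difference
#' maps, both p < alpha), and both diagonal elements belong to a
#' significant above-chance decoding cluster.
#'
#' @param fca_array subjects x T x T array of FCA values (see
#'   [stack_subjects()]).
#' @param chance chance accuracy subtracted for the above-chance test
#'   (50 for FCA).
#' @param n_perm permutations per cluster test.
#' @param alpha significance level of each cluster test.
#' @param seed optional seed for the permutation draws.
#' @return an object of class `vwm_dynmask`: `is_dynamic` (T x T logical,
#'   diagonal FALSE), `above_chance` (T x T logical), and the three
#'   underlying `vwm_clusters` results (`above_test`, `row_test`,
#'   `col_test`).
#' @export
dynamic_elements <- function(fca_array, chance = 50, n_perm = 1000,
                             alpha = 0.05, seed = NULL) {
  d <- dim(fca_array)
  if (length(d) != 3 || d[2] != d[3])
    stop("fca_array must be subjects x T x T")
  n_t <- d[2]
  if (!is.null(seed)) set.seed(seed)

  above <- cluster_sign_permutation_test(
    fca_array - chance, n_perm = n_perm, alpha = alpha, tail = "positive")

  # a_ij - a_ii: subtract the training-time (row) diagonal per subject
  diag_vals <- array(NA_real_, c(d[1], n_t))
  for (s in seq_len(d[1])) diag_vals[s, ] <- diag(fca_array[s, , ])
  d_row <- fca_array - array(rep(diag_vals, times = n_t), d)
  d_col <- fca_array - aperm(array(rep(diag_vals, times = n_t), d),
                             c(1, 3, 2))
  for (s in seq_len(d[1])) {
    diag(d_row[s, , ]) <- NA
    diag(d_col[s, , ]) <- NA
  }

  row_test <- cluster_sign_permutation_test(
    d_row, n_perm = n_perm, alpha = alpha, tail = "negative")
  col_test <- cluster_sign_permutation_test(
    d_col, n_perm = n_perm, alpha = alpha, tail = "negative")

  diag_above <- diag(above$sig_mask)
  is_dyn <- row_test$sig_mask & col_test$sig_mask &
    outer(diag_above, diag_above, `&`)
  diag(is_dyn) <- FALSE

  structure(list(
    is_dynamic = is_dyn,
    above_chance = above$sig_mask,
    above_test = above, row_test = row_test, col_test = col_test,
    alpha = alpha, n_perm = n_perm
  ), class = "vwm_dynmask")
}

#' Dynamicism index
#'
#' For each diagonal timepoint t, the proportion of associated
#' off-diagonal elements (row t and column t of the cross-decoding
#' matrix) flagged as dynamic, out of the 2(T - 1) such elements.
#'
#' @param mask a `vwm_dynmask` or a T x T logical matrix.
#' @return numeric vector of length T with values in \[0, 1\].
#' @export
dynamicism_index <- function(mask) {
  m <- if (inherits(mask, "vwm_dynmask")) mask$is_dynamic else mask
  n_t <- nrow(m)
  if (is.null(n_t) || n_t != ncol(m)) stop("mask must be square")
  if (n_t < 2) stop("need at least 2 timepoints")
  vapply(seq_len(n_t), function(t)
    (sum(m[t, -t]) + sum(m[-t, t])) / (2 * (n_t - 1)), numeric(1))
}

#' @export
print.vwm_dynmask <- function(x, ...) {
  cat(sprintf(
    "Dynamic-coding mask: %d / %d off-diagonal elements dynamic; %d / %d elements above chance\n",
    sum(x$is_dynamic), length(x$is_dynamic) - nrow(x$is_dynamic),
    sum(x$above_chance), length(x$above_chance)))
  invisible(x)
}

#' Long-format export of a cross-decoding matrix
#'
#' @param matrix a `vwm_xdecode` matrix (or plain T x T matrix).
#' @param subject optional subject identifier recycled into the output.
#' @return data frame with columns train_s, test_s, subject, fca.
#' @export
xdecode_long <- function(matrix, subject = NA) {
  time_s <- attr(matrix, "time_s")
  if (is.null(time_s)) time_s <- seq_len(nrow(matrix))
  data.frame(
    train_s = rep(time_s, times = ncol(matrix)),
    test_s = rep(time_s, each = nrow(matrix)),
    subject = subject,
    fca = as.vector(as.matrix(matrix)))
}
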