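#' Wrap orientation labels onto the full circle
#'
#' Orientation is 180-degree periodic; to decode it with circular
#' regression the label space \[0, 180) degrees is projected onto the full
#' cycle \[0, 2*pi) radians by doubling the angle. Inputs outside
#' \[0, 180) are reduced modulo 180 first.
#'
#' @param theta_deg orientations in degrees.
#' @return wrapped labels in radians, in \[0, 2*pi).
#' @export
wrap_orientation <- function(theta_deg) {
  if (any(!is.finite(theta_deg)))
    stop("orientation labels must be finite")
  (theta_deg %% 180) / 180 * 2 * pi
}

#' Hyperparameters for the periodic support vector regression
#'
#' The decoder uses epsilon-insensitive support vector regression with a
#' radial basis function kernel (LIBSVM, via \pkg{e1071}). `gamma = NULL`
#' uses the scale-free heuristic 1 / n_voxels at fit time.
#'
#' @param cost regularization constant C.
#' @param gamma RBF kernel width, or `NULL` for 1 / n_voxels.
#' @param epsilon epsilon-insensitive loss width.
#' @return a list of class `psvr_hyperparams`.
#' @export
psvr_hyperparams <- function(cost = 1, gamma = NULL, epsilon = 0.1) {
  stopifnot(cost > 0, epsilon >= 0, is.null(gamma) || gamma > 0)
  structure(list(cost = cost, gamma = gamma, epsilon = epsilon),
            class = "psvr_hyperparams")
}

# Rescale columns to [0, 1] using training min/max; constant columns map
# to 0.5. Returns list(x, lo, hi).
rescale_train <- function(x) {
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  const <- hi - lo < .Machine$double.eps
  if (any(const))
    warning(sum(const), " constant voxel(s) rescaled to 0.5")
  out <- rescale_apply(x, lo, hi)
  list(x = out, lo = lo, hi = hi)
}

# Apply a stored training rescaling; test values may fall outside [0, 1]
# and are deliberately not clipped.
rescale_apply <- function(x, lo, hi) {
  rng <- hi - lo
  const <- rng < .Machine$double.eps
  rng[const] <- 1
  out <- sweep(sweep(x, 2, lo), 2, rng, `/`)
  out[, const] <- 0.5
  out
}

#' Fit a periodic support vector regression decoder
#'
#' Trains two independent RBF-kernel support vector regressions predicting
#' the sine and the cosine of the wrapped orientation label from voxel
#' patterns. Each voxel is rescaled to \[0, 1\] using the training
#' minimum/maximum; the same parameters are later applied to test data.
#'
#' @param x trials x voxels matrix of training patterns (no missing
#'   values).
#' @param theta wrapped labels in radians (see [wrap_orientation()]), one
#'   per row of `x`.
#' @param hyper a [psvr_hyperparams()] object.
#' @return an object of class `psvr_model`.
#' @export
fit_psvr <- function(x, theta, hyper = psvr_hyperparams()) {
  x <- as.matrix(x)
  if (nrow(x) == 0) stop("empty training set")
  if (length(theta) != nrow(x))
    stop("number of labels must match number of training trials")
  if (any(!is.finite(x)) || any(!is.finite(theta)))
    stop("training data contain non-finite values")
  gamma <- if (is.null(hyper$gamma)) 1 / ncol(x) else hyper$gamma
  rs <- rescale_train(x)
  # degenerate targets (e.g. identical training labels) leave LIBSVM with
  # no support vectors; regress to the constant instead
  fit1 <- function(y) {
    m <- e1071::svm(rs$x, y, type = "eps-regression", kernel = "radial",
                    cost = hyper$cost, gamma = gamma,
                    epsilon = hyper$epsilon, scale = FALSE,
                    fitted = FALSE)
    if (m$tot.nSV == 0)
      structure(list(value = mean(y)), class = "psvr_constant")
    else m
  }
  structure(list(
    sine = fit1(sin(theta)),
    cosine = fit1(cos(theta)),
    lo = rs$lo, hi = rs$hi,
    hyper = list(cost = hyper$cost, gamma = gamma,
                 epsilon = hyper$epsilon),
    n_voxels = ncol(x)
  ), class = "psvr_model")
}

#' Reconstruct orientations from a fitted decoder
#'
#' Applies the training rescaling to the test patterns, obtains the
#' predicted sine (x_p) and cosine (y_p) components, and reconstructs the
#' orientation with the four-quadrant inverse tangent
#' `theta_p = atan2(x_p, y_p)`, mapped into \[0, 2*pi).
#'
#' @param model a fitted `psvr_model`.
#' @param x trials x voxels matrix of test patterns; the voxel count must
#'   match training.
#' @return predicted wrapped orientations in radians, \[0, 2*pi).
#' @export
predict_orientation <- function(model, x) {
  stopifnot(inherits(model, "psvr_model"))
  x <- as.matrix(x)
  if (ncol(x) != model$n_voxels)
    stop("test pattern has ", ncol(x), " voxels but the model was ",
         "trained on ", model$n_voxels)
  xs <- rescale_apply(x, model$lo, model$hi)
  comp <- function(m)
    if (inherits(m, "psvr_constant")) rep(m$value, nrow(xs))
    else as.numeric(stats::predict(m, xs))
  atan2(comp(model$sine), comp(model$cosine)) %% (2 * pi)
}

#' Absolute circular deviation between wrapped orientations
#'
#' Shorter-arc distance on the 2*pi circle between true and predicted
#' wrapped labels.
#'
#' @param theta,theta_p wrapped labels in radians, \[0, 2*pi).
#' @return deviations in radians, in \[0, pi\].
#' @export
angular_deviation <- function(theta, theta_p) {
  if (any(!is.finite(theta)) || any(!is.finite(theta_p)))
    stop("angles must be finite")
  d <- abs(theta %% (2 * pi) - theta_p %% (2 * pi))
  pmin(d, 2 * pi - d)
}

#' Trial-wise feature continuous accuracy
#'
#' Maps an absolute circular deviation onto a continuous accuracy scale:
#' `(pi - deviation) / pi * 100`, so 100 is a perfect prediction, 0 the
#' maximal error, and random guessing gives 50 in expectation.
#'
#' @param deviations circular deviations in radians, each in \[0, pi\].
#' @return per-trial accuracies in percent.
#' @export
fca_trialwise <- function(deviations) {
  if (length(deviations) == 0) stop("empty deviation list")
  if (any(!is.finite(deviations)) ||
      any(deviations < -1e-12 | deviations > pi + 1e-12))
    stop("deviations must lie in [0, pi]")
  (pi - deviations) / pi * 100
}

#' Mean feature continuous accuracy
#'
#' @param deviations circular deviations in radians, each in \[0, pi\].
#' @return mean accuracy in percent (chance level is 50).
#' @export
fca <- function(deviations) {
  mean(fca_trialwise(deviations))
}

# trials x voxels slice of a bold array at one timepoint, kept a matrix
# even for a single trial
slice_bold <- function(bold, idx, t) {
  m <- bold[idx, , t, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

# Session-based cross-validation folds: one fold per left-out session.
session_folds <- function(sessions) {
  lapply(sort(unique(sessions)), function(s)
    list(test_session = s,
         train_sessions = setdiff(sort(unique(sessions)), s)))
}

#' Session-wise cross-validated decoding accuracy
#'
#' Fits the periodic decoder on all but one session at the training
#' timepoint and reconstructs orientations for the left-out session at the
#' test timepoint; the accuracy is the mean trial-wise FCA pooled over the
#' test predictions of all folds. Training and test trials are disjoint
#' for every combination of training and test timepoint because folds are
#' defined by session.
#'
#' @param dataset a `vwm_dataset` (or a compatible list with `trials` and
#'   `bold`).
#' @param condition condition whose trials are decoded.
#' @param time_train,time_test 1-based timepoint indices into the bold
#'   array.
#' @param hyper decoder hyperparameters.
#' @param train_condition optional different condition to train on
#'   (cross-condition decoding); folds are still split by session so train
#'   and test trials never overlap.
#' @param labels which label column to decode, `"target_deg"` (default) or
#'   `"distractor_deg"`.
#' @return list with `fca` (mean percent accuracy) and `predictions`
#'   (data frame of per-trial test predictions).
#' @export
crossvalidated_fca <- function(dataset, condition,
                               time_train = 1L, time_test = time_train,
                               hyper = psvr_hyperparams(),
                               train_condition = NULL,
                               labels = "target_deg") {
  train_cond <- if (is.null(train_condition)) condition else train_condition
  tr <- dataset$trials
  for (cond in unique(c(condition, train_cond))) {
    present <- unique(tr$session[tr$condition == cond])
    if (!setequal(present, unique(tr$session)))
      stop("condition '", cond, "' is missing from some sessions")
  }
  folds <- session_folds(tr$session)
  preds <- lapply(folds, function(f) {
    itrain <- which(tr$condition == train_cond &
                      tr$session %in% f$train_sessions)
    itest <- which(tr$condition == condition &
                     tr$session == f$test_session)
    if (length(intersect(itrain, itest)) > 0)
      stop("internal leakage: train and test trials overlap")
    model <- fit_psvr(slice_bold(dataset$bold, itrain, time_train),
                      wrap_orientation(tr[[labels]][itrain]), hyper)
    theta <- wrap_orientation(tr[[labels]][itest])
    theta_p <- predict_orientation(
      model, slice_bold(dataset$bold, itest, time_test))
    data.frame(trial = tr$trial[itest], session = f$test_session,
               theta = theta, theta_p = theta_p,
               deviation = angular_deviation(theta, theta_p))
  })
  preds <- do.call(rbind, preds)
  preds$fca <- fca_trialwise(preds$deviation)
  list(fca = mean(preds$fca), predictions = preds)
}
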