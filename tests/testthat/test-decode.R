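test_that("orientation wrapping doubles the angle onto [0, 2*pi)", {
  expect_equal(wrap_orientation(0), 0)
  expect_equal(wrap_orientation(90), pi)
  expect_equal(wrap_orientation(179), 2 * pi * 179 / 180)
  expect_equal(wrap_orientation(185), wrap_orientation(5))
  expect_true(all(wrap_orientation(seq(-360, 539, by = 7)) >= 0))
  expect_true(all(wrap_orientation(seq(-360, 539, by = 7)) < 2 * pi))
  expect_error(wrap_orientation(NaN), "finite")
})

test_that("angular deviation is the shorter arc on the circle", {
  expect_equal(angular_deviation(0, 0), 0)
  expect_equal(angular_deviation(0, pi), pi)
  expect_equal(angular_deviation(0.1, 2 * pi - 0.1), 0.2)
  # symmetry and bounds on random pairs
  set.seed(4)
  a <- runif(500, 0, 2 * pi); b <- runif(500, 0, 2 * pi)
  expect_equal(angular_deviation(a, b), angular_deviation(b, a))
  expect_true(all(angular_deviation(a, b) >= 0))
  expect_true(all(angular_deviation(a, b) <= pi))
})

test_that("FCA maps deviations onto a 0-100 accuracy scale", {
  expect_equal(fca(rep(0, 5)), 100)
  expect_equal(fca(rep(pi, 5)), 0)
  set.seed(5)
  expect_equal(fca(runif(1e5, 0, pi)), 50, tolerance = 0.5 / 50)
  expect_error(fca(numeric(0)), "empty")
  expect_error(fca(c(0.1, 4)), "\\[0, pi\\]")
  devs <- runif(1000, 0, pi)
  tw <- fca_trialwise(devs)
  expect_true(all(tw >= 0 & tw <= 100))
})

test_that("the periodic decoder recovers orientations from tuned patterns", {
  set.seed(6)
  tun <- generate_tuned_voxels(40, seed = 6)
  theta_deg <- runif(108, 0, 180)
  x <- tuning_response(tun, theta_deg)
  x <- x + matrix(rnorm(length(x)), nrow(x)) * 0.05
  model <- fit_psvr(x, wrap_orientation(theta_deg))
  test_deg <- runif(100, 0, 180)
  xt <- tuning_response(tun, test_deg) +
    matrix(rnorm(100 * 40), 100) * 0.05
  dev <- angular_deviation(wrap_orientation(test_deg),
                           predict_orientation(model, xt))
  expect_gt(fca(dev), 95)
})

test_that("identical training labels regress to a constant prediction", {
  set.seed(7)
  x <- matrix(rnorm(120), 30, 4)
  model <- fit_psvr(x, rep(wrap_orientation(42), 30))
  pred <- predict_orientation(model, matrix(rnorm(40), 10, 4))
  expect_equal(angular_deviation(rep(wrap_orientation(42), 10), pred),
               rep(0, 10), tolerance = 1e-8)
})

test_that("training rescaling comes from the training data only", {
  set.seed(8)
  x <- matrix(rnorm(200), 50, 4)
  theta <- wrap_orientation(runif(50, 0, 180))
  expect_warning(fit_psvr(cbind(x, 3), wrap_orientation(runif(50, 0, 180))),
                 "constant voxel")
  m1 <- fit_psvr(x, theta)
  m2 <- fit_psvr(x, theta)
  expect_identical(m1$sine$coefs, m2$sine$coefs)
  expect_identical(m1$lo, apply(x, 2, min))
  # test patterns outside the training range are not clipped
  far <- matrix(10, 2, 4)
  expect_true(all(is.finite(predict_orientation(m1, far))))
  expect_error(predict_orientation(m1, matrix(0, 2, 3)), "voxels")
  expect_error(fit_psvr(x[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("decoding is invariant to adding 180 degrees to all labels", {
  ds <- make_subject(11, timepoints = 1, trials = 12, voxels = 20)
  base <- crossvalidated_fca(ds, "no_distractor", 1, 1)
  ds$trials$target_deg <- ds$trials$target_deg + 180
  shifted <- crossvalidated_fca(ds, "no_distractor", 1, 1)
  expect_identical(base$fca, shifted$fca)
  expect_identical(base$predictions$theta_p, shifted$predictions$theta_p)
})

test_that("session cross-validation pools every trial exactly once", {
  ds <- make_subject(12, timepoints = 2, trials = 12, voxels = 20)
  cv <- crossvalidated_fca(ds, "no_distractor", 1, 2)
  trials <- ds$trials$trial[ds$trials$condition == "no_distractor"]
  expect_setequal(cv$predictions$trial, trials)
  expect_equal(nrow(cv$predictions), length(trials))
  expect_equal(cv$fca, mean(cv$predictions$fca))

  # a session missing the condition is rejected
  bad <- make_subject(14, timepoints = 1, trials = 12, voxels = 20,
                      conditions = c("no_distractor", "noise_distractor"))
  drop <- bad$trials$session == 1 & bad$trials$condition == "no_distractor"
  bad$trials <- bad$trials[!drop, ]
  bad$bold <- bad$bold[!drop, , , drop = FALSE]
  expect_error(crossvalidated_fca(bad, "no_distractor", 1, 1),
               "missing from some sessions")
})

test_that("label-shuffled decoding sits at chance", {
  set.seed(13)
  ds <- make_subject(13, timepoints = 1, trials = 60, voxels = 20)
  ds$trials$target_deg <- sample(ds$trials$target_deg)
  ds$trials$bin <- orientation_bin(ds$trials$target_deg, 6)
  acc <- mean(sapply(1:3, function(i) {
    ds$trials$target_deg <- sample(ds$trials$target_deg)
    crossvalidated_fca(ds, "no_distractor", 1, 1)$fca
  }))
  expect_lt(abs(acc - 50), 6)
})
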