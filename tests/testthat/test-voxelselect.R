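test_that("tuning GLM betas equal per-bin means in balanced designs", {
  set.seed(1)
  n_bins <- 6
  labels <- rep(seq(15, 165, by = 30), each = 10)
  pat <- matrix(rnorm(60 * 8), 60, 8)
  betas <- tuning_glm(pat, labels, n_bins)
  means <- rowsum(pat, orientation_bin(labels, n_bins)) / 10
  expect_equal(betas, means, tolerance = 1e-10, ignore_attr = TRUE)

  # balanced sessions: nuisance regressors leave bin estimates untouched
  sessions <- rep(rep(1:2, each = 5), 6)
  betas_s <- tuning_glm(pat, labels, n_bins, sessions = sessions)
  expect_equal(betas_s, means, tolerance = 1e-10, ignore_attr = TRUE)

  # shifting one bin's trials shifts only that beta
  pat2 <- pat
  pat2[labels == 45, ] <- pat2[labels == 45, ] + 3
  betas2 <- tuning_glm(pat2, labels, n_bins)
  expect_equal(betas2[2, ], betas[2, ] + 3, tolerance = 1e-10)
  expect_equal(betas2[-2, ], betas[-2, ], tolerance = 1e-10)

  expect_error(tuning_glm(pat, rep(10, 60), n_bins), "bin")
})

test_that("tuning peaks fall at the preferred orientation of tuned voxels", {
  tun <- generate_tuned_voxels(30, seed = 2)
  labels <- rep(seq(0, 179, length.out = 36), 3)
  pat <- tuning_response(tun, labels)
  betas <- tuning_glm(pat, labels, n_bins = 6)
  pref <- ifelse(tun$basis == "sine", tun$shifts + 45, tun$shifts) %% 180
  centers <- seq(15, 165, by = 30)
  peak <- centers[apply(betas, 2, which.max)]
  d <- abs(peak - pref)
  expect_true(all(pmin(d, 180 - d) <= 30))
})

test_that("noiseless tuned voxels are all selected as reliable", {
  tun <- generate_tuned_voxels(25, seed = 3)
  labels <- rep(seq(0, 179, length.out = 36), 2)
  pat <- tuning_response(tun, labels)
  sel <- reliability_select(
    memory = list(patterns = pat, labels = labels),
    perception = list(patterns = pat, labels = labels),
    n_perm = 100, seed = 4)
  expect_true(all(sel$table$selected))
  expect_true(all(sel$table$r_mm > 0.9))
})

test_that("pure-noise voxels pass the joint criterion at the chance rate", {
  set.seed(5)
  n <- 108; nv <- 1000
  sel <- reliability_select(
    memory = list(patterns = matrix(rnorm(n * nv), n, nv),
                  labels = runif(n, 0, 180)),
    perception = list(patterns = matrix(rnorm(n * nv), n, nv),
                      labels = runif(n, 0, 180)),
    n_perm = 150, seed = 6)
  # two independent 25% exceedance criteria: ~6.25% joint rate
  expect_lt(abs(mean(sel$table$selected) - 0.0625), 0.02)
})

test_that("tuned voxels separate from noise voxels at high SNR", {
  rates <- sapply(1:3, function(s) {
    tun <- generate_tuned_voxels(20, seed = 10 + s)
    labels <- rep(seq(0, 179, length.out = 36), 2)
    set.seed(20 + s)
    mk <- function() {
      tuned <- tuning_response(tun, labels) +
        matrix(rnorm(72 * 20, sd = 0.15), 72)
      noise <- matrix(rnorm(72 * 20), 72)
      list(patterns = cbind(tuned, noise), labels = labels)
    }
    sel <- reliability_select(mk(), mk(), n_perm = 100, seed = 30 + s)
    c(tuned = mean(sel$table$selected[1:20]),
      noise = mean(sel$table$selected[21:40]))
  })
  expect_gte(mean(rates["tuned", ]), 0.95)
  expect_lte(mean(rates["noise", ]), 0.10)
})

test_that("selection is invariant to per-voxel affine rescaling", {
  set.seed(7)
  tun <- generate_tuned_voxels(15, seed = 8)
  labels <- rep(seq(0, 179, length.out = 24), 2)
  pat <- tuning_response(tun, labels) + matrix(rnorm(48 * 15, sd = 0.5), 48)
  scaled <- sweep(sweep(pat, 2, runif(15, 0.5, 4), `*`), 2,
                  rnorm(15), `+`)
  s1 <- reliability_select(list(patterns = pat, labels = labels),
                           list(patterns = pat, labels = labels),
                           n_perm = 60, seed = 9)
  s2 <- reliability_select(list(patterns = scaled, labels = labels),
                           list(patterns = scaled, labels = labels),
                           n_perm = 60, seed = 9)
  expect_equal(s1$table$r_mm, s2$table$r_mm, tolerance = 1e-10)
  expect_identical(s1$table$selected, s2$table$selected)
})

test_that("degenerate voxels and determinism are handled", {
  set.seed(10)
  labels <- rep(seq(0, 179, length.out = 24), 2)
  pat <- matrix(rnorm(48 * 5), 48, 5)
  pat[, 3] <- 2  # zero-variance tuning
  w <- capture_warnings(
    sel <- reliability_select(list(patterns = pat, labels = labels),
                              list(patterns = pat, labels = labels),
                              n_perm = 50, seed = 11))
  expect_true(any(grepl("zero-variance", w)))
  expect_equal(sel$table$r_mm[3], -1)
  expect_false(sel$table$selected[3])

  suppressWarnings({
    a <- reliability_select(list(patterns = pat, labels = labels),
                            list(patterns = pat, labels = labels),
                            n_perm = 50, seed = 12)
    b <- reliability_select(list(patterns = pat, labels = labels),
                            list(patterns = pat, labels = labels),
                            n_perm = 50, seed = 12)
  })
  expect_identical(a$table, b$table)
})

test_that("null thresholds rise with the percentile parameter", {
  set.seed(13)
  labels <- rep(seq(0, 179, length.out = 24), 2)
  pat <- matrix(rnorm(48 * 30), 48, 30)
  lo <- reliability_select(list(patterns = pat, labels = labels),
                           list(patterns = pat, labels = labels),
                           n_perm = 80, percentile = 50, seed = 14)
  hi <- reliability_select(list(patterns = pat, labels = labels),
                           list(patterns = pat, labels = labels),
                           n_perm = 80, percentile = 95, seed = 14)
  expect_lt(lo$threshold_mm, hi$threshold_mm)
  expect_lt(lo$threshold_pp, hi$threshold_pp)
  expect_gte(sum(lo$table$selected), sum(hi$table$selected))
})
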