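test_that("binning averages trials and centers voxels", {
  # two trials per bin with identical patterns: rows recover the bin
  # patterns minus column means
  pat <- matrix(c(1, 0, 0, 1, -1, 2, 0.5, 0.5), 4, 2, byrow = TRUE)
  trials <- pat[rep(1:4, each = 2), ]
  labels <- rep(c(10, 60, 100, 150), each = 2)
  b <- bin_and_center(trials, labels, n_bins = 4)
  expect_equal(b$X, sweep(pat, 2, colMeans(pat)))
  expect_equal(b$counts, rep(2L, 4))

  # rotating all labels by one bin width cyclically permutes the rows
  b2 <- bin_and_center(trials, (labels + 45) %% 180, n_bins = 4)
  expect_equal(b2$X, b$X[c(4, 1, 2, 3), ])

  # single voxel: centering leaves a zero-mean column
  b3 <- bin_and_center(trials[, 1, drop = FALSE], labels, n_bins = 4)
  expect_equal(dim(b3$X), c(4, 1))
  expect_equal(mean(b3$X), 0)

  expect_error(bin_and_center(trials, rep(10, 8), n_bins = 4),
               "bin 2")
})

test_that("subspaces capture the top-2 plane of binned patterns", {
  set.seed(1)
  # rows exactly in a 2-plane: the two components explain everything
  basis <- qr.Q(qr(matrix(rnorm(60), 30, 2)))
  coords <- matrix(rnorm(8), 4, 2)
  x <- sweep(coords %*% t(basis), 2,
             colMeans(coords %*% t(basis)))
  sub <- compute_subspace(x)
  expect_equal(sum(sub$explained_variance_fraction), 1, tolerance = 1e-8)
  expect_lt(principal_angle(sub$V, basis), 1e-6)
  expect_equal(crossprod(sub$V), diag(2), tolerance = 1e-8)
  expect_gte(sub$eigenvalues[1], sub$eigenvalues[2])

  # synthetic sine/cosine bins recover the generating coding plane
  tun <- generate_tuned_voxels(50, seed = 2)
  bins <- bin_and_center(tuning_response(tun, seq(0, 179, by = 1)),
                         seq(0, 179, by = 1), n_bins = 4)
  plane <- vwmdyn:::coding_plane(tun)
  expect_lt(principal_angle(compute_subspace(bins)$V,
                            qr.Q(qr(cbind(plane$a, plane$b)))), 1)

  # permuting voxels permutes the basis rows identically
  perm <- sample(30)
  sub_p <- compute_subspace(x[, perm])
  expect_lt(principal_angle(sub_p$V, basis[perm, ]), 1e-6)

  expect_error(compute_subspace(matrix(1, 4, 10)), "rank")
  expect_error(compute_subspace(matrix(rnorm(20), 2, 10)), "3 orientation")
})

test_that("principal angles match their geometric construction", {
  expect_equal(principal_angle(diag(6)[, 1:2], diag(6)[, 1:2]), 0)
  expect_equal(principal_angle(diag(6)[, 1:2], diag(6)[, 3:4]), 90)

  # rotating one in-plane direction by a known angle yields that angle
  for (ang in c(10, 30, 60, 85)) {
    g <- diag(6)
    th <- ang * pi / 180
    g[c(2, 3), c(2, 3)] <- matrix(c(cos(th), sin(th), -sin(th), cos(th)),
                                  2)
    expect_equal(principal_angle(diag(6)[, 1:2], g %*% diag(6)[, 1:2]),
                 ang, tolerance = 1e-8)
  }

  set.seed(3)
  for (i in 1:50) {
    p <- random_orthonormal_pair(20)
    pa <- principal_angle(p$v1, p$v2)
    expect_gte(pa, 0); expect_lte(pa, 90)
    expect_equal(pa, principal_angle(p$v2, p$v1), tolerance = 1e-8)
    # global orthogonal transforms of the voxel space leave angles fixed
    q <- qr.Q(qr(matrix(rnorm(400), 20, 20)))
    expect_equal(principal_angle(q %*% p$v1, q %*% p$v2), pa,
                 tolerance = 1e-6)
  }
  expect_error(principal_angle(diag(4)[, 1:2], diag(5)[, 1:2]),
               "different voxel spaces")
})

test_that("projection onto a subspace recovers planar coordinates", {
  set.seed(4)
  v <- qr.Q(qr(matrix(rnorm(80), 40, 2)))
  coords <- matrix(rnorm(8), 4, 2)
  expect_equal(project_leftout(v, coords %*% t(v)), coords)
  # data orthogonal to the plane project to zero
  comp <- qr.Q(qr(cbind(v, matrix(rnorm(80), 40, 2))))[, 3:4]
  expect_equal(project_leftout(v, matrix(rnorm(8), 4, 2) %*% t(comp)),
               matrix(0, 4, 2), tolerance = 1e-10)
  expect_error(project_leftout(v, matrix(0, 4, 39)), "dimensions")
})

test_that("projected orientation bins preserve their circular order", {
  ok <- sapply(1:5, function(s) {
    ds <- make_subject(70 + s, snr = 8, timepoints = 2, trials = 24)
    w <- window_average(ds, c(0, 1.6))
    b <- bin_and_center(w$patterns, w$trials$target_deg, n_bins = 4)
    p <- project_leftout(compute_subspace(b), b)
    d <- as.matrix(dist(p))
    adjacent <- mean(c(d[1, 2], d[2, 3], d[3, 4], d[4, 1]))
    opposite <- mean(c(d[1, 3], d[2, 4]))
    adjacent < opposite
  })
  expect_gte(mean(ok), 0.9)
})

test_that("the above-baseline angle is zero for identical windows", {
  ds <- make_subject(81, timepoints = 4, trials = 24)
  apa <- above_baseline_pa(ds, c(0, 1.6), c(0, 1.6), n_iter = 20,
                           seed = 5)
  expect_equal(apa$apa_deg, 0)
})

test_that("stationary codes give near-zero aPA, basis switches large aPA", {
  vals <- sapply(1:6, function(s) {
    ds <- make_subject(90 + s, timepoints = 4, trials = 24)
    above_baseline_pa(ds, c(0, 1.6), c(2.4, 3.2), n_iter = 40,
                      seed = s)$apa_deg
  })
  expect_lt(abs(mean(vals)), 3)

  ds <- make_subject(99, rotation = c(0, 0, 1, 1), timepoints = 4,
                     snr = 8, trials = 24)
  apa <- above_baseline_pa(ds, c(0, 0.8), c(1.6, 2.4), n_iter = 40,
                           seed = 6)
  expect_gt(apa$apa_deg, 45)

  tiny <- make_subject(100, timepoints = 2, trials = 6)
  expect_error(above_baseline_pa(tiny, c(0, 0.8), c(0.8, 1.6),
                                 n_bins = 6, n_iter = 5),
               "2 trials per orientation bin")
})

test_that("target and distractor subspaces separate by overlap", {
  ds0 <- make_distractor_subject(110, overlap = 0, snr = 8)
  apa0 <- target_distractor_apa(ds0, delay_window = c(0, 2.4),
                                n_iter = 30, seed = 7)
  expect_gt(apa0$apa_deg, 30)

  ds1 <- make_distractor_subject(111, overlap = 1, snr = 8)
  apa1 <- target_distractor_apa(ds1, delay_window = c(0, 2.4),
                                n_iter = 30, seed = 8)
  expect_lt(abs(apa1$apa_deg), 3)

  # binning by the target labels twice is a null comparison
  ds_same <- ds0
  ds_same$trials$distractor_deg <- ds_same$trials$target_deg
  apa_same <- target_distractor_apa(ds_same, delay_window = c(0, 2.4),
                                    n_iter = 30, seed = 9)
  expect_lt(abs(apa_same$apa_deg), 3)

  ds_na <- ds0
  ds_na$trials$distractor_deg <- NA_real_
  expect_error(target_distractor_apa(ds_na, delay_window = c(0, 2.4)),
               "lacks distractor")
})

test_that("group-level sign test ranks consistent positive effects", {
  expect_lt(apa_sign_test(c(5, 6, 4, 7, 5, 6)), 0.05)
  expect_gt(apa_sign_test(c(-1, 1, -2, 2, 0.5, -0.5)), 0.2)
  expect_error(apa_sign_test(3), "2 subjects")
})
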