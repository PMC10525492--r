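test_that("the toy forward model is well-formed and deterministic", {
  m <- montage(STANDARD_21)
  fwd <- build_toy_forward(m, 64L)
  expect_equal(dim(fwd$leadfield), c(21L, 64L))
  expect_equal(colSums(fwd$leadfield^2), rep(1, 64), tolerance = 1e-12)
  expect_true(all(is.finite(fwd$leadfield)))
  # sources strictly inside the unit sensor sphere
  expect_true(all(rowSums(fwd$source_pos^2) < 1))
  expect_setequal(unique(fwd$hemisphere), c("left", "right"))
  expect_identical(build_toy_forward(m, 64L)$leadfield, fwd$leadfield)
  # an absurd sigma collapses all columns -> rejected
  expect_error(build_toy_forward(m, 64L, sigma = 1e6), "rank")
  # the nearest sensor sees the largest pre-normalization gain
  raw <- exp(-as.matrix(stats::dist(rbind(m$positions_3d,
                                          fwd$source_pos)))^2 / (2 * 0.95^2))
  g <- raw[1:21, 21 + seq_len(64)]
  for (j in 1:10) {
    d <- colSums((t(m$positions_3d) - fwd$source_pos[j, ])^2)
    expect_equal(unname(which.max(g[, j])), unname(which.min(d)))
  }
})

test_that("noise covariance estimation is SPD with diagonal loading", {
  m <- montage(STANDARD_21)
  set.seed(4)
  rec <- recording(matrix(stats::rnorm(21 * 6000), 21), STANDARD_21, 250)
  ncov <- estimate_noise_cov(rec, onset_s = 24, baseline = c(-20, 0),
                             loading = 0.05)
  # white unit-variance baseline, long interval -> about (1 + loading) * I
  expect_equal(unname(diag(ncov$cov)), rep(1.05, 21), tolerance = 0.1)
  off <- ncov$cov[upper.tri(ncov$cov)]
  expect_lt(max(abs(off)), 0.1)
  expect_silent(chol(ncov$cov))

  flat <- recording(matrix(5, 21, 500), STANDARD_21, 250)
  nc2 <- estimate_noise_cov(flat, 1)
  expect_silent(chol(nc2$cov))           # pure loading, still SPD
  expect_true(all(diag(nc2$cov) > 0))

  short <- recording(matrix(stats::rnorm(21 * 250), 21), STANDARD_21, 250)
  expect_warning(estimate_noise_cov(short, 0.06, baseline = c(-0.05, 0)),
                 "fewer")
  expect_error(estimate_noise_cov(short, 0.05, baseline = c(-0.1, 0)),
               "outside")
})

test_that("noiseless single sources are recovered exactly on the grid", {
  fwd <- build_toy_forward(montage(STANDARD_21), 64L)
  s <- matrix(sin(2 * pi * 3 * seq_len(100) / 250), 1)
  hits <- vapply(seq_len(64), function(j) {
    est <- dspm_inverse(fwd, NULL, fwd$leadfield[, j, drop = FALSE] %*% s,
                        snr = 100)
    which.max(rowMeans(est$dspm)) == j
  }, logical(1))
  expect_true(all(hits))
})

test_that("localization error stays within a grid neighbor at default snr", {
  fwd <- build_toy_forward(montage(STANDARD_21), 64L)
  sp <- as.matrix(stats::dist(fwd$source_pos))
  diag(sp) <- Inf
  neighbor <- max(apply(sp, 1L, min)) * 1.5
  s <- matrix(sin(2 * pi * 3 * seq_len(100) / 250), 1)
  worst <- max(vapply(seq_len(64), function(j) {
    est <- dspm_inverse(fwd, NULL, fwd$leadfield[, j, drop = FALSE] %*% s,
                        snr = 3)
    jj <- which.max(rowMeans(est$dspm))
    sqrt(sum((fwd$source_pos[j, ] - fwd$source_pos[jj, ])^2))
  }, numeric(1)))
  expect_lte(worst, neighbor)
})

test_that("dSPM is nonnegative, homogeneous, and zero on zero data", {
  fwd <- build_toy_forward(montage(STANDARD_21), 32L)
  set.seed(6)
  data <- matrix(stats::rnorm(21 * 50), 21)
  cov <- estimate_noise_cov(recording(matrix(stats::rnorm(21 * 1000), 21),
                                      STANDARD_21, 250), 2)
  est <- dspm_inverse(fwd, cov, data)
  expect_true(all(est$dspm >= 0))
  est3 <- dspm_inverse(fwd, cov, 3 * data)
  expect_equal(est3$dspm, 3 * est$dspm, tolerance = 1e-9)
  z <- dspm_inverse(fwd, cov, matrix(0, 21, 5))
  expect_true(all(z$dspm == 0))
  expect_error(dspm_inverse(fwd, cov, matrix(0, 5, 5)), "channels")
})

test_that("identity covariance with zero loading matches the unwhitened form", {
  fwd <- build_toy_forward(montage(STANDARD_21), 32L)
  set.seed(7)
  data <- matrix(stats::rnorm(21 * 20), 21)
  est_w <- dspm_inverse(fwd,
                        structure(list(cov = diag(21)), class = "noise_cov"),
                        data, snr = 3)
  L <- fwd$leadfield
  M <- t(L) %*% solve(L %*% t(L) + (1 / 9) * diag(21))
  ref <- abs(M %*% data) / sqrt(rowSums(M^2))
  expect_equal(est_w$dspm, ref, tolerance = 1e-9)
})

test_that("dSPM is invariant to consistent channel reordering", {
  fwd <- build_toy_forward(montage(STANDARD_21), 32L)
  set.seed(9)
  data <- matrix(stats::rnorm(21 * 30), 21)
  base <- recording(matrix(stats::rnorm(21 * 1000), 21), STANDARD_21, 250)
  cov <- estimate_noise_cov(base, 2)
  est <- dspm_inverse(fwd, cov, data)
  perm <- sample(21)
  fwd2 <- fwd; fwd2$leadfield <- fwd$leadfield[perm, ]
  cov2 <- cov; cov2$cov <- cov$cov[perm, perm]
  est2 <- dspm_inverse(fwd2, cov2, data[perm, ])
  expect_equal(est2$dspm, est$dspm, tolerance = 1e-6)
})

test_that("onset averaging means over the requested window only", {
  est <- structure(list(dspm = cbind(c(1, 2), c(3, 6), c(5, 10)),
                        times = c(0, 1, 2.5)),
                   class = "source_estimate")
  expect_equal(onset_average(est, c(0, 2)), c(2, 4))
  expect_equal(onset_average(est, c(0, 3)), c(3, 6))
  expect_error(onset_average(est, c(5, 6)), "no time samples")
  const <- structure(list(dspm = matrix(2, 4, 10), times = seq(0, 1.8, 0.2)),
                     class = "source_estimate")
  expect_equal(onset_average(const), rep(2, 4))
})

test_that("lateralization index separates one-sided from symmetric maps", {
  fwd <- build_toy_forward(montage(STANDARD_21), 64L)
  left_map <- as.numeric(fwd$hemisphere == "left")
  li <- lateralization_index(left_map, fwd)
  expect_equal(li$li, 1)
  sym <- rep(1, 64)
  expect_equal(lateralization_index(sym, fwd)$li, 0, tolerance = 0.15)
  focal <- rep(0, 64); focal[5] <- 10
  expect_gt(lateralization_index(focal, fwd)$concentration, 0.9)
  nothing <- lateralization_index(rep(0, 64), fwd)
  expect_true(is.na(nothing$li) && is.na(nothing$concentration))
})

test_that("a planted right-hemisphere source maps to the right hemisphere", {
  fwd <- build_toy_forward(montage(STANDARD_21), 64L)
  right <- which(fwd$hemisphere == "right" & fwd$source_pos[, "x"] > 0.4)
  j <- right[1L]
  s <- matrix(sin(2 * pi * 5 * seq_len(250) / 250), 1)
  est <- dspm_inverse(fwd, NULL, fwd$leadfield[, j, drop = FALSE] %*% s,
                      snr = 100, times = seq_len(250) / 250 - 1 / 250)
  map <- onset_average(est, c(0, 1))
  expect_equal(unname(fwd$hemisphere[which.max(map)]), "right")
  expect_lt(lateralization_index(map, fwd)$li, 0)
})
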