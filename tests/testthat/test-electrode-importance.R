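# build windows where one electrode carries a label-dependent DC offset
planted_windows <- function(n = 300L, channels = 8L, samples = 25L,
                            planted = 3L, offset = 5, seed = 1L) {
  set.seed(seed)
  labels <- rep(c("bckg", "fnsz"), length.out = n)
  wins <- lapply(seq_len(n), function(i) {
    d <- matrix(stats::rnorm(channels * samples), channels)
    if (labels[i] == "fnsz") d[planted, ] <- d[planted, ] + offset
    list(data = d, label = labels[i], subject_id = "s1", event_index = i,
         sampling_rate_hz = 250,
         channel_names = STANDARD_21[seq_len(channels)])
  })
  wins
}

test_that("a planted label-dependent offset ranks its electrode first", {
  wins <- planted_windows(seed = 42L)
  rk <- mi_scores(wins, n_windows = 200L, n_runs = 3L, seed = 7L)
  expect_s3_class(rk, "mi_ranking")
  expect_equal(rk$electrode[1L], STANDARD_21[3L])
  expect_equal(rk$normalized[1L], 1)
  expect_equal(min(rk$normalized), 0)
})

test_that("label shuffling drives MI below the planted score", {
  wins <- planted_windows(seed = 5L)
  rk <- mi_scores(wins, n_windows = 200L, n_runs = 3L, seed = 7L)
  planted_score <- rk$raw[rk$electrode == STANDARD_21[3L]]
  set.seed(99)
  shuffled <- sample(vapply(wins, `[[`, character(1), "label"))
  rk0 <- mi_scores(wins, n_windows = 200L, n_runs = 3L, labels = shuffled,
                   seed = 7L)
  expect_true(all(rk0$raw < planted_score))
})

test_that("shuffled-label MI stays within a permutation null", {
  wins <- planted_windows(n = 200L, channels = 4L, samples = 20L,
                          offset = 0, seed = 11L)  # no signal at all
  labels <- vapply(wins, `[[`, character(1), "label")
  observed <- mi_scores(wins, n_windows = 150L, n_runs = 2L, seed = 3L)
  null_max <- replicate(20, {
    rk <- mi_scores(wins, n_windows = 150L, n_runs = 2L,
                    labels = sample(labels), seed = 3L)
    max(rk$raw)
  })
  expect_lte(max(observed$raw), stats::quantile(null_max, 0.95) * 1.5)
})

test_that("MI estimator recovers a known discrete dependence within 10%", {
  # x is essentially the label plus tiny jitter: MI -> H(label) = ln 2
  set.seed(21)
  n <- 1000L
  labels <- rep(c("a", "b"), each = n / 2)
  wins <- lapply(seq_len(n), function(i)
    list(data = matrix((labels[i] == "b") + stats::rnorm(1, sd = 1e-3), 1),
         label = labels[i], subject_id = "s", event_index = i,
         sampling_rate_hz = 1, channel_names = "Cz"))
  rk <- mi_scores(wins, n_windows = 1000L, n_runs = 1L, seed = 2L)
  expect_equal(rk$raw[1L], log(2), tolerance = 0.1)
})

test_that("constant electrodes score zero MI", {
  wins <- planted_windows(n = 100L, channels = 3L, seed = 8L)
  wins <- lapply(wins, function(w) { w$data[2L, ] <- 7; w })
  rk <- mi_scores(wins, n_windows = 80L, n_runs = 2L, seed = 1L)
  expect_equal(rk$raw[rk$electrode == STANDARD_21[2L]], 0, tolerance = 1e-9)
})

test_that("the ranking is invariant to per-electrode affine rescaling", {
  wins <- planted_windows(n = 150L, seed = 13L)
  scales <- c(0.01, 5, 100, 0.5, 3, 42, 1, 9)
  rescaled <- lapply(wins, function(w) {
    w$data <- w$data * scales + seq_len(8)
    w
  })
  a <- mi_scores(wins, n_windows = 120L, n_runs = 2L, seed = 4L)
  b <- mi_scores(rescaled, n_windows = 120L, n_runs = 2L, seed = 4L)
  expect_equal(b[order(b$electrode), c("electrode", "raw")],
               a[order(a$electrode), c("electrode", "raw")])
})

test_that("mi_scores validates inputs and is seed-deterministic", {
  wins <- planted_windows(n = 50L, seed = 2L)
  uni <- lapply(wins, function(w) { w$label <- "bckg"; w })
  expect_error(mi_scores(uni), "2 distinct")
  a <- mi_scores(wins, n_windows = 40L, n_runs = 2L, seed = 5L)
  b <- mi_scores(wins, n_windows = 40L, n_runs = 2L, seed = 5L)
  expect_identical(a, b)
})

test_that("normalize_scores maps to [0,1] preserving order", {
  expect_equal(normalize_scores(c(2, 4, 6)), c(0, 0.5, 1))
  expect_equal(normalize_scores(c(5, 5)), c(0, 0))
  x <- c(3, 1, 2, 10)
  expect_equal(order(normalize_scores(x)), order(x))
})

test_that("greedy ablation records a monotone electrode curve", {
  wins <- small_cohort_windows()
  res <- ablation_experiment(
    wins, start_channels = STANDARD_21, min_electrodes = 19L,
    tcfg = training_config(epochs = 2L, seed = 1L),
    mi_n_windows = 150L, mi_n_runs = 1L, seed = 3L)
  expect_equal(res$curve$n_electrodes, c(21L, 20L, 19L))
  expect_length(res$montages, 3L)
  # removed electrodes never reappear
  expect_true(all(res$montages[[2L]] %in% res$montages[[1L]]))
  expect_true(all(res$montages[[3L]] %in% res$montages[[2L]]))
  expect_true(all(c("sensitivity", "specificity") %in% names(res$curve)))
  expect_error(ablation_experiment(wins, min_electrodes = 1L), "at least 2")
})

test_that("the fixed 21-vs-8 comparison emits 5 values per metric per montage", {
  wins <- small_cohort_windows()
  cmp <- suppressWarnings(fixed_reduced_comparison(
    wins, models = "binary", k = 5L,
    binary_tcfg = training_config(epochs = 1L, seed = 2L), seed = 2L))
  pf <- cmp$per_fold
  expect_equal(nrow(pf), 10L)
  expect_equal(as.vector(table(pf$montage)), c(5L, 5L))
  expect_equal(max(pf$fold), 5L)
  expect_true(all(c("welch_p", "mann_whitney_p", "normality_p_a",
                    "normality_p_b") %in% names(cmp$comparison)))
  fs <- cmp$summaries[[1]]$summary
  expect_equal(unique(fs$k), 5)
})
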