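test_that("FIR low-pass passes the passband and kills the stopband", {
  t <- seq(0, 4, by = 1 / 250)[-1]
  rec <- recording(rbind(sin(2 * pi * 10 * t), sin(2 * pi * 60 * t),
                         rep(1, length(t))),
                   c("C3", "C4", "Cz"), 250)
  out <- fir_lowpass(rec, 40)
  expect_equal(dim(out$data), dim(rec$data))
  core <- 250:750                       # away from filter edge transients
  amp10 <- max(abs(out$data[1, core]))
  expect_equal(amp10, 1, tolerance = 0.01)
  amp60 <- max(abs(out$data[2, core]))
  expect_lt(20 * log10(amp60), -40)     # >= 40 dB attenuation
  expect_equal(out$data[3, core], rec$data[3, core], tolerance = 1e-6)
  expect_error(fir_lowpass(rec, 125), "Nyquist")
})

test_that("resampling scales the sample count and preserves waveforms", {
  t <- seq(0, 10, by = 1 / 500)[-1]
  rec <- recording(matrix(sin(2 * pi * 5 * t), 1), "Cz", 500)
  down <- resample_recording(rec, 250)
  expect_equal(ncol(down$data), 2500L)
  expect_equal(down$sampling_rate_hz, 250)
  expect_identical(resample_recording(rec, 500), rec)

  rec2 <- recording(matrix(sin(2 * pi * 5 * seq(1, 1250) / 250), 1), "Cz", 250)
  low <- resample_recording(rec2, 50)
  core <- 10:240
  # analytic reference, allowing for the polyphase filter's small alignment
  best <- max(vapply(-3:3, function(lag) {
    ref <- sin(2 * pi * 5 * (core + lag) / 50)
    stats::cor(low$data[1, core], ref)
  }, numeric(1)))
  expect_gt(best, 0.99)
})

test_that("window extraction tiles without overlap and labels correctly", {
  rec <- recording(matrix(stats::rnorm(21 * 2675), 21), STANDARD_21, 250,
                   subject_id = "s9")
  ann <- annotation_set(c(0, 5, 8), c(5, 8, 10.7), c("bckg", "fnsz", "bckg"))
  wins <- extract_windows(rec, ann, 1)
  expect_length(wins, 10L)               # floor(10.7)
  labs <- vapply(wins, `[[`, character(1), "label")
  expect_equal(labs, c(rep("bckg", 5), rep("fnsz", 3), "bckg", "bckg"))
  # conservation: samples partition, none reused
  n_used <- sum(vapply(wins, function(w) ncol(w$data), integer(1)))
  expect_equal(n_used, 10L * 250L)
  got <- do.call(cbind, lapply(wins, `[[`, "data"))
  expect_equal(got, rec$data[, 1:2500])
  expect_true(all(vapply(wins, `[[`, character(1), "subject_id") == "s9"))
})

test_that("a fully background record yields only bckg windows", {
  rec <- recording(matrix(0, 2, 750), c("C3", "C4"), 250)
  ann <- annotation_set(0, 3, "bckg")
  labs <- vapply(extract_windows(rec, ann), `[[`, character(1), "label")
  expect_equal(labs, rep("bckg", 3))
})

test_that("the STFT tensor has the printed 21 x 33 x 8 shape at 250 Hz", {
  w <- list(data = matrix(stats::rnorm(21 * 250), 21), label = "bckg",
            subject_id = "s", event_index = 1L, sampling_rate_hz = 250,
            channel_names = STANDARD_21)
  tens <- stft_tensor(w, nfft = 64L)
  expect_equal(dim(tens$values), c(21L, 33L, 8L))
  expect_true(all(tens$values >= 0))
  expect_error(stft_tensor(w, nfft = 63L), "even")
  w0 <- w; w0$data <- matrix(0, 21, 250)
  expect_true(all(stft_tensor(w0)$values == 0))
})

test_that("STFT timestep count is rate-independent", {
  for (sr in c(50, 100, 150, 200, 250)) {
    w <- list(data = matrix(stats::rnorm(3 * sr), 3), label = "bckg",
              subject_id = "s", event_index = 1L, sampling_rate_hz = sr,
              channel_names = c("C3", "C4", "Cz"))
    expect_equal(dim(stft_tensor(w)$values), c(3L, 33L, 8L))
  }
})

test_that("a pure tone at an FFT bin frequency peaks in that bin", {
  sr <- 250
  mk <- function(f) {
    w <- list(data = matrix(sin(2 * pi * f * seq_len(250) / sr), 1),
              label = "bckg", subject_id = "s", event_index = 1L,
              sampling_rate_hz = sr, channel_names = "Cz")
    stft_tensor(w)
  }
  # tones with at least one full cycle per 31-sample segment resolve
  # exactly in their own bin at every timestep
  for (bin in 3:8) {
    tens <- mk(bin * sr / 64)
    for (s in 1:8)
      expect_equal(which.max(tens$values[1, , s]) - 1L, bin)
  }
  # at bin 2 (7.8 Hz) a segment holds under one cycle, so the peak may
  # shift one bin at some phases; it stays within a neighbor and hits the
  # exact bin in the majority of timesteps
  tens <- mk(2 * sr / 64)
  am <- vapply(1:8, function(s) which.max(tens$values[1, , s]) - 1L,
               integer(1))
  expect_true(all(abs(am - 2) <= 1))
  expect_gte(sum(am == 2), 5L)
})

test_that("STFT satisfies Parseval on the tapered, padded segments", {
  set.seed(11)
  x <- matrix(stats::rnorm(2 * 250), 2)
  w <- list(data = x, label = "bckg", subject_id = "s", event_index = 1L,
            sampling_rate_hz = 250, channel_names = c("C3", "C4"))
  tens <- stft_tensor(w, nfft = 64L)
  seg <- 31L
  taper <- 0.5 * (1 - cos(2 * pi * seq_len(seg) / (seg + 1)))
  for (ch in 1:2) for (s in 1:8) {
    seg_x <- x[ch, ((s - 1) * seg + 1):(s * seg)] * taper
    mags <- tens$values[ch, , s]
    # reconstruct the two-sided power sum from the one-sided magnitudes
    twosided <- mags[1]^2 + mags[33]^2 + 2 * sum(mags[2:32]^2)
    expect_equal(twosided, 64 * sum(seg_x^2), tolerance = 1e-6)
  }
})

test_that("the STFT commutes with channel subsetting", {
  set.seed(12)
  w <- list(data = matrix(stats::rnorm(5 * 250), 5), label = "bckg",
            subject_id = "s", event_index = 1L, sampling_rate_hz = 250,
            channel_names = c("C3", "C4", "Cz", "F3", "F4"))
  full <- stft_tensor(w)
  w_sub <- w
  w_sub$data <- w$data[c(2, 4), , drop = FALSE]
  w_sub$channel_names <- c("C4", "F3")
  sub <- stft_tensor(w_sub)
  expect_equal(sub$values, full$values[c(2, 4), , , drop = FALSE])
})

test_that("event-grouped splits partition windows without leakage", {
  wins <- lapply(1:100, function(i)
    list(label = c("bckg", "fnsz")[1 + i %% 2], subject_id = "s1",
         event_index = i))
  sp <- make_splits(wins, c(train = .7, val = .15, test = .15), seed = 2L)
  expect_equal(lengths(sp), c(train = 70L, val = 15L, test = 15L))
  expect_equal(sort(unname(unlist(sp))), 1:100)

  # all windows of one event land in one split
  wins2 <- lapply(1:50, function(i)
    list(label = "fnsz", subject_id = "s1", event_index = 1L))
  wins2 <- c(wins2, lapply(1:10, function(i)
    list(label = "bckg", subject_id = "s1", event_index = 2L)))
  sp2 <- suppressWarnings(make_splits(wins2, seed = 1L))
  in_split <- vapply(sp2, function(idx) any(1:50 %in% idx), logical(1))
  expect_equal(sum(in_split), 1L)

  sp_a <- make_splits(wins, seed = 7L)
  expect_identical(sp_a, make_splits(wins, seed = 7L))
  expect_false(identical(sp_a, make_splits(wins, seed = 8L)))
})

test_that("k-fold indices are an event-grouped stratified partition", {
  wins <- lapply(1:50, function(i)
    list(label = SEIZURE_LABELS[1 + i %% 8], subject_id = "s1",
         event_index = i))
  folds <- kfold_indices(wins, k = 5L, seed = 3L)
  expect_length(folds, 5L)
  expect_equal(sort(unlist(lapply(folds, `[[`, "val"))), 1:50)
  expect_equal(vapply(folds, function(f) length(f$val), integer(1)),
               rep(10L, 5))
  for (f in folds) {
    expect_length(intersect(f$train, f$val), 0L)
    expect_setequal(c(f$train, f$val), 1:50)
    # every class present in every training fold
    labs <- vapply(wins[f$train], `[[`, character(1), "label")
    expect_setequal(unique(labs), SEIZURE_LABELS)
  }
})

test_that("class weights follow N / (K * n_c) and conserve mass", {
  w <- class_weights(c("A", "A", "A", "B"))
  expect_equal(w[["A"]], 4 / 6)
  expect_equal(w[["B"]], 2)
  expect_equal(sum(w * c(A = 3, B = 1)), 4)        # sum w_c n_c == N
  expect_equal(unname(class_weights(rep(c("x", "y"), 5))), c(1, 1))
  expect_equal(unname(class_weights(rep("only", 7))), 1)
  labs <- sample(SEIZURE_LABELS, 200, replace = TRUE,
                 prob = c(8, 4, 2, 1, 1, 1, 1, 1) / 19)
  w8 <- class_weights(labs)
  expect_equal(sum(w8 * table(labs)[names(w8)]), 200)
})
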