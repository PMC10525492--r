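test_that("background generator is deterministic and respects amplitudes", {
  m <- montage(STANDARD_21)
  a <- background_eeg(2, m, seed = 42L)
  b <- background_eeg(2, m, seed = 42L)
  expect_identical(a$data, b$data)
  expect_false(identical(background_eeg(2, m, seed = 43L)$data, a$data))
  z <- background_eeg(1, m, background_alpha_uv = 0, noise_uv = 0, seed = 1L)
  expect_true(all(z$data == 0))
})

test_that("alpha rhythm is posterior-dominant", {
  m <- montage(STANDARD_21)
  rec <- background_eeg(60, m, seed = 7L)
  p10 <- function(ch) {
    s <- Mod(stats::fft(rec$data[ch, ]))^2
    f <- (seq_along(s) - 1) / 60
    mean(s[f >= 9.5 & f <= 10.5])
  }
  expect_gt(p10(which(m$names == "O1")), p10(which(m$names == "Fp1")))
  expect_gt(p10(which(m$names == "O2")), p10(which(m$names == "Fz")))
})

test_that("default signatures cover all labels with the stated topographies", {
  sigs <- default_signatures()
  expect_setequal(names(sigs), SEIZURE_LABELS)
  expect_equal(vapply(sigs, `[[`, character(1), "label")[SEIZURE_LABELS],
               stats::setNames(SEIZURE_LABELS, SEIZURE_LABELS))
  expect_gte(sigs$absz$spatial_profile[["Fz"]],
             sigs$absz$spatial_profile[["T3"]])
  expect_true(sigs$fnsz$focal)
  expect_false(is.null(sigs$fnsz$focus_electrode))
  expect_equal(sigs$fnsz$spatial_profile[[sigs$fnsz$focus_electrode]], 1)
  for (s in sigs)
    if (!s$focal) expect_true(all(s$spatial_profile >= 0.7 - 1e-9))
  # pairwise distinguishable in (band, profile): no two share both
  key <- vapply(sigs, function(s)
    paste(s$waveform, round(s$base_freq_hz, 1)), character(1))
  expect_equal(anyDuplicated(key[!vapply(sigs, `[[`, logical(1), "focal")]), 0L)
})

test_that("inject_seizure adds band-limited focal power and annotations", {
  out <- single_seizure_record("fnsz", seed = 21L)
  ann <- out$annotations
  expect_equal(ann$label[ann$label != "bckg"], "fnsz")
  expect_equal(annotation_span(ann), 20)
  base <- background_eeg(20, montage(STANDARD_21), seed = 21L)
  added <- out$recording$data - base$data
  i <- 5 * 250 + (1:2000)
  bandp <- function(ch) {
    s <- Mod(stats::fft(added[ch, i]))^2
    f <- (seq_along(s) - 1) * 250 / length(s)
    mean(s[f >= 4 & f <= 8])
  }
  expect_gt(bandp(which(STANDARD_21 == "T3")),
            bandp(which(STANDARD_21 == "O2")))
  # background outside the event untouched
  expect_equal(out$recording$data[, 1:1000], base$data[, 1:1000])
})

test_that("zero-amplitude injection leaves data unchanged but annotates", {
  m <- montage(STANDARD_21)
  sig <- default_signatures(m)$gnsz
  sig$amplitude_uv <- 0
  rec <- background_eeg(10, m, seed = 9L)
  out <- inject_seizure(rec, tile_background(empty_events(), 10), sig, 2, 3)
  expect_equal(out$recording$data, rec$data)
  expect_true("gnsz" %in% out$annotations$label)
})

test_that("overlapping seizure injection errors", {
  m <- montage(STANDARD_21)
  sigs <- default_signatures(m)
  rec <- background_eeg(20, m, seed = 10L)
  out <- inject_seizure(rec, tile_background(empty_events(), 20),
                        sigs$gnsz, 5, 5)
  expect_error(inject_seizure(out$recording, out$annotations, sigs$absz, 8, 4),
               "overlap")
  expect_error(inject_seizure(rec, tile_background(empty_events(), 20),
                              sigs$absz, 18, 5), "outside")
})

test_that("injected rhythmic sine peaks in the bin nearest its frequency", {
  f <- 15.625                            # bin 4 of the 250 Hz / 64-pt grid
  sig <- seizure_signature("gnsz", "rhythmic_sine", f, 200, c(Cz = 0.9))
  rec <- recording(matrix(0, 1, 250 * 4), "Cz", 250)
  out <- inject_seizure(rec, tile_background(empty_events(), 4), sig, 0, 4,
                        seed = 3L)
  w <- extract_windows(out$recording, out$annotations)[[2]]
  tens <- stft_tensor(w)
  freqs <- tens$freq_hz
  for (s in 1:8) {
    peak <- which.max(tens$values[1, , s])
    expect_equal(which.min(abs(freqs - f)), peak)
  }
})

test_that("generate_cohort writes a reproducible, tiled cohort", {
  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  cfg <- cohort_config(n_subjects = 2, record_duration_s = 60,
                       seizures_per_record = 3, seed = 77L)
  man_a <- generate_cohort(cfg, dir_a, format = "rds")
  man_b <- generate_cohort(cfg, dir_b, format = "rds")
  expect_length(man_a$records, 2L)
  for (i in 1:2) {
    expect_equal(man_a$records[[i]]$n_seizures, 3L)
    expect_identical(man_a$records[[i]]$seizure_labels,
                     man_b$records[[i]]$seizure_labels)
    rec_a <- read_recording(file.path(dir_a, man_a$records[[i]]$recording),
                            "rds")
    rec_b <- read_recording(file.path(dir_b, man_b$records[[i]]$recording),
                            "rds")
    expect_identical(rec_a$data, rec_b$data)
    ann <- parse_tse(file.path(dir_a, man_a$records[[i]]$annotation))
    expect_equal(annotation_span(ann), 60)
    expect_true(all(abs(ann$stop_s[-nrow(ann)] - ann$start_s[-1]) < 1e-9))
  }
})

test_that("a concentrated class mix yields only that seizure type", {
  dir <- withr::local_tempdir()
  mix <- stats::setNames(rep(0, 8), SEIZURE_LABELS); mix["gnsz"] <- 1
  cfg <- cohort_config(n_subjects = 1, record_duration_s = 60,
                       seizures_per_record = 3, class_mix = mix, seed = 5L)
  man <- generate_cohort(cfg, dir, format = "rds")
  expect_true(all(unlist(man$records[[1]]$seizure_labels) == "gnsz"))
})

test_that("cohort EDF output parses back through the same reader", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_subjects = 1, record_duration_s = 30,
                       seizures_per_record = 2, seed = 31L)
  man <- generate_cohort(cfg, dir, format = "edf")
  rec <- read_recording(file.path(dir, man$records[[1]]$recording), "edf",
                        validate_labels = TRUE)
  expect_equal(rec$sampling_rate_hz, 250)
  expect_length(rec$channel_names, 21L)
  expect_equal(ncol(rec$data), 30 * 250)
})

test_that("the matched-filter oracle separates the eight classes", {
  wins <- small_cohort_windows()
  labs <- vapply(wins, `[[`, character(1), "label")
  sw <- wins[labs != "bckg"]
  pred <- oracle_classify(sw, default_signatures(),
                          wins[[1]]$channel_names)
  acc <- mean(pred == vapply(sw, `[[`, character(1), "label"))
  expect_gte(acc, 0.95)
})
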