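# a closed-form linear model exposing the gradient contract: logit_k = w_k . x
logit_and_gradient.linear_toy <- function(model, x, class_index) {
  w <- model$weights[[class_index]]
  list(value = sum(w * x), grad = array(w, dim = dim(x)))
}

registerS3method("logit_and_gradient", "linear_toy",
                 logit_and_gradient.linear_toy,
                 envir = asNamespace("seizr"))

make_linear_toy <- function(shape = c(2L, 5L, 3L), seed = 1L) {
  set.seed(seed)
  structure(list(weights = list(array(stats::rnorm(prod(shape)), shape),
                                array(stats::rnorm(prod(shape)), shape)),
                 input_shape = shape,
                 class_labels = c("a", "b")),
            class = "linear_toy")
}

test_that("AM on a linear model aligns with the weight direction", {
  model <- make_linear_toy()
  # regularized ascent fixed point of w.x - d*|x|^2 is x* = w / (2d)
  pat <- activation_maximization(model, 1L, n_runs = 3L, steps = 80L,
                                 step_size = 0.05, l2_decay = 1e-3,
                                 seed = 2L)
  w <- model$weights[[1L]]
  cosine <- sum(pat$pattern * w) / sqrt(sum(pat$pattern^2) * sum(w^2))
  expect_gte(cosine, 0.99)
  expect_gte(pat$final_activation, 0)
})

test_that("AM is reproducible and its accepted objective is monotone", {
  model <- make_linear_toy(seed = 3L)
  a <- activation_maximization(model, 2L, n_runs = 1L, steps = 40L,
                               seed = 11L)
  b <- activation_maximization(model, 2L, n_runs = 1L, steps = 40L,
                               seed = 11L)
  expect_identical(a$pattern, b$pattern)
  expect_true(all(diff(a$objective_trace) >= 0))
  expect_error(activation_maximization(model, 5L))
})

test_that("AM backpropagates through a trained CNN (eval mode)", {
  ts <- toy_tensor_set(n_per_class = 10, shape = c(4L, 33L, 8L))
  model <- build_binary_cnn(input_shape = c(4L, 33L, 8L), seed = 4L)
  model <- train_model(model, list(x = ts$x, labels = ts$labels),
                       tcfg = training_config(epochs = 8L, seed = 4L))
  pat <- activation_maximization(model, 2L, n_runs = 2L, steps = 40L,
                                 seed = 5L)
  expect_equal(dim(pat$pattern), c(4L, 33L, 8L))
  expect_true(all(is.finite(pat$pattern)))
  expect_true(all(diff(pat$objective_trace) >= 0))
  # the two class prototypes must differ
  pat1 <- activation_maximization(model, 1L, n_runs = 2L, steps = 40L,
                                  seed = 5L)
  expect_false(identical(pat1$pattern, pat$pattern))
})

test_that("channel energy normalizes and ignores pattern scale", {
  pat <- array(0, c(3, 4, 2)); pat[2, , ] <- 5
  e <- channel_energy(pat, c("C3", "C4", "Cz"))
  expect_equal(unname(e), c(0, 1, 0))
  expect_equal(channel_energy(pat * 3, c("C3", "C4", "Cz")), e)
  flat <- array(1, c(3, 4, 2))
  expect_equal(unname(channel_energy(flat)), rep(0, 3))
})

test_that("topoplots interpolate onto a masked head grid", {
  m <- montage(STANDARD_21)
  v <- stats::setNames(rep(0, 21), m$names); v["Cz"] <- 1
  tp <- topoplot(v, m)
  expect_equal(dim(tp$grid), c(64L, 64L))
  peak <- which(tp$grid == max(tp$grid, na.rm = TRUE), arr.ind = TRUE)[1, ]
  # Cz projects to the center of the disc
  expect_equal(tp$x[peak[1]], 0, tolerance = 0.05)
  expect_equal(tp$y[peak[2]], 0, tolerance = 0.05)
  expect_true(anyNA(tp$grid))            # masked corners

  const <- topoplot(stats::setNames(rep(0.7, 21), m$names), m)
  vals <- const$grid[!is.na(const$grid)]
  expect_equal(vals, rep(0.7, length(vals)), tolerance = 1e-6)
  expect_error(topoplot(c(XX = 1), m), "XX")
})

test_that("left-right symmetric values give a mirror-symmetric map", {
  m <- montage(STANDARD_21)
  v <- stats::setNames(runif(21), m$names)
  pairs <- rbind(c("C3", "C4"), c("F3", "F4"), c("F7", "F8"), c("T3", "T4"),
                 c("T5", "T6"), c("P3", "P4"), c("O1", "O2"),
                 c("Fp1", "Fp2"), c("A1", "A2"))
  for (i in seq_len(nrow(pairs))) v[pairs[i, 2]] <- v[pairs[i, 1]]
  tp <- topoplot(v, m)
  mirrored <- tp$grid[rev(seq_len(64)), ]
  ok <- !is.na(tp$grid) & !is.na(mirrored)
  expect_equal(tp$grid[ok], mirrored[ok], tolerance = 1e-6)
  p <- autoplot(tp)
  expect_s3_class(p, "ggplot")
})

test_that("AM prototypes are class-specific in frequency on the cohort", {
  fx <- acceptance_fixture()
  model <- fx$multigroup
  sigs <- default_signatures()
  freqs <- seq(0, 32) * 250 / 64
  half_bin <- (freqs[2] - freqs[1]) / 2   # band edges at bin resolution
  bands <- lapply(sigs, function(s) {
    f0 <- s$base_freq_hz
    b <- switch(s$waveform,
      spike_wave = c(0.7 * f0, 4.5 * f0),
      rhythmic_sine = c(0.6 * f0, 1.4 * f0),
      polyspike_burst = c(0.7 * f0, 3.5 * f0),
      low_voltage_fast = c(0.7 * f0, 1.7 * f0),
      evolving_chirp = c(2, 13))
    b + c(-half_bin, half_bin)
  })
  sd_arr <- model$input_stats$sd
  in_band <- vapply(seq_along(model$class_labels), function(k) {
    pat <- activation_maximization(model, k, n_runs = 2L, steps = 24L,
                                   seed = 40L + k)
    contrib <- pat$pattern * sd_arr       # back to raw magnitude units
    spec <- apply(contrib^2, 2L, sum)
    spec[1L] <- 0                         # ignore the DC bin
    dom <- freqs[which.max(spec)]
    lab <- model$class_labels[k]
    dom >= bands[[lab]][1L] && dom <= bands[[lab]][2L]
  }, logical(1))
  expect_gte(sum(in_band), 6L)            # bursts/chirps may straddle

  # the absence-seizure prototype concentrates on the midline emphasis
  pat <- activation_maximization(model,
                                 which(model$class_labels == "absz"),
                                 n_runs = 2L, steps = 24L, seed = 77L)
  en <- channel_energy(pat, STANDARD_21)
  expect_true(names(which.max(en)) %in% c("Fz", "Pz"))
})
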