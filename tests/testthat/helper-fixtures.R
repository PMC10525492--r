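# shared fixtures, memoised for the duration of one test run
.fixtures <- new.env()

# a small synthetic cohort (4 subjects), loaded as labeled windows
small_cohort_windows <- function() {
  if (is.null(.fixtures$wins)) {
    dir <- file.path(tempdir(), "seizr-small-cohort")
    if (!file.exists(file.path(dir, "manifest.json"))) {
      cfg <- cohort_config(n_subjects = 4, record_duration_s = 150,
                          seizures_per_record = 6, seed = 101L)
      generate_cohort(cfg, dir, format = "rds")
    }
    .fixtures$wins <- load_cohort_windows(dir)
  }
  .fixtures$wins
}

# a flat annotation frame for tile_background()
empty_events <- function() {
  data.frame(start_s = numeric(), stop_s = numeric(),
             label = character(), confidence = numeric())
}

# one record with a single injected seizure, returned as (recording, ann)
single_seizure_record <- function(label, duration_s = 20, onset_s = 5,
                                  seiz_s = 8, seed = 1L) {
  m <- montage(STANDARD_21)
  sigs <- default_signatures(m)
  rec <- background_eeg(duration_s, m, seed = seed)
  inject_seizure(rec, tile_background(empty_events(), duration_s),
                 sigs[[label]], onset_s, seiz_s, seed = seed + 1L)
}

# tiny separable tensors for model sanity checks: class means differ in one
# region of the tensor
toy_tensor_set <- function(n_per_class = 25, shape = c(4L, 33L, 8L),
                           classes = c("bckg", "seiz"), seed = 5L) {
  withr_seed <- get(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  n <- n_per_class * length(classes)
  x <- array(stats::rnorm(prod(shape) * n, sd = 0.5), c(shape, n))
  labels <- rep(classes, each = n_per_class)
  for (i in seq_len(n)) {
    k <- match(labels[i], classes)
    x[1, (1:6) + 6 * (k - 1), , i] <- x[1, (1:6) + 6 * (k - 1), , i] + 2
  }
  assign(".Random.seed", withr_seed, envir = globalenv())
  list(x = x, labels = labels,
       subjects = rep("s1", n),
       events = paste0("e", seq_len(n)))
}
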