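#' @title Shared pipeline plumbing
#' @description Helpers that connect cohorts, windows, tensors and models:
#'   loading a generated cohort from its manifest, running the
#'   filter/window/STFT chain, and the train-and-evaluate loops used by
#'   the ablation, montage-comparison and experiment drivers.
#' @name pipeline
NULL

#' Load a cohort directory into labeled windows
#'
#' Reads every recording/annotation pair listed in the cohort manifest,
#' optionally applies the low-pass filter and resampling, and cuts
#' labeled windows.
#'
#' @param cohort_dir directory written by [generate_cohort]
#' @param lowpass_hz FIR cutoff (`NULL` to skip filtering)
#' @param target_hz resample target (`NULL` to keep the recorded rate)
#' @param window_s window length in seconds
#' @return list of labeled windows across all records
#' @export
load_cohort_windows <- function(cohort_dir, lowpass_hz = 40,
                                target_hz = NULL, window_s = 1.0) {
  manifest <- jsonlite::read_json(file.path(cohort_dir, "manifest.json"))
  windows <- list()
  for (recinfo in manifest$records) {
    rec <- read_recording(file.path(cohort_dir, recinfo$recording),
                          format = recinfo$format)
    ann <- parse_tse(file.path(cohort_dir, recinfo$annotation))
    if (!is.null(lowpass_hz)) rec <- fir_lowpass(rec, lowpass_hz)
    if (!is.null(target_hz)) rec <- resample_recording(rec, target_hz)
    windows <- c(windows, extract_windows(rec, ann, window_s))
  }
  windows
}

# restrict every window to a channel subset, in the given order
.subset_windows <- function(windows, channels) {
  lapply(windows, function(w) {
    w$data <- w$data[channels, , drop = FALSE]
    w$channel_names <- channels
    w
  })
}

#' Convert labeled windows to a stacked tensor set
#'
#' @param windows list of labeled windows
#' @param channels optional electrode subset (order respected)
#' @param nfft FFT length for [stft_tensor]
#' @return a tensor set (see [tensor_set])
#' @export
windows_to_tensors <- function(windows, channels = NULL, nfft = 64L) {
  if (!is.null(channels)) windows <- .subset_windows(windows, channels)
  tensor_set(lapply(windows, stft_tensor, nfft = nfft))
}

# subset a tensor set by window index and optionally by channel index
.ts_subset <- function(ts, idx, ch_idx = NULL) {
  x <- ts$x[, , , idx, drop = FALSE]
  cn <- ts$channel_names
  if (!is.null(ch_idx)) {
    x <- x[ch_idx, , , , drop = FALSE]
    cn <- cn[ch_idx]
  }
  list(x = x, labels = ts$labels[idx], subjects = ts$subjects[idx],
       events = ts$events[idx], channel_names = cn)
}

# meta list for make_splits/kfold_indices from a tensor set
.ts_meta <- function(ts, labels = ts$labels) {
  lapply(seq_along(labels), function(i)
    list(label = labels[i], subject_id = ts$subjects[i],
         event_index = ts$events[i]))
}

# train the binary detector on one split of a channel subset and return
# held-out detection metrics
.train_eval_binary <- function(windows, channels, tcfg, split_fractions,
                               seed) {
  ts <- windows_to_tensors(windows, channels)
  blab <- binarize_labels(ts$labels)
  # stratify by seizure type so every type is represented in training,
  # then train on the collapsed binary label
  sp <- make_splits(.ts_meta(ts), split_fractions, seed = seed)
  test_name <- names(split_fractions)[length(split_fractions)]
  tr_idx <- sp$train
  te_idx <- sp[[test_name]]
  tcfg$class_weights <- class_weights(blab[tr_idx])
  model <- build_binary_cnn(input_shape = dim(ts$x)[1:3], seed = seed)
  model <- train_model(model,
                       list(x = ts$x[, , , tr_idx, drop = FALSE],
                            labels = blab[tr_idx]),
                       tcfg = tcfg)
  pred <- predict_labels(model, ts$x[, , , te_idx, drop = FALSE])
  cm <- confusion_matrix(blab[te_idx], pred, c("bckg", "seiz"))
  binary_metrics(cm)
}

# k-fold CV metrics for one montage and one task
.cv_metrics <- function(windows, channels, task = c("binary", "multigroup"),
                        k, tcfg, seed) {
  task <- match.arg(task)
  ts <- windows_to_tensors(windows, channels)
  if (task == "multigroup") {
    keep <- which(ts$labels != "bckg")
    ts <- .ts_subset(ts, keep)
    labels <- ts$labels
    class_labels <- SEIZURE_LABELS
  } else {
    labels <- binarize_labels(ts$labels)
    class_labels <- c("bckg", "seiz")
  }
  # folds stratified by the full type labels (binary training still sees
  # every seizure type); for the multigroup task these coincide
  folds <- kfold_indices(.ts_meta(ts), k = k, seed = seed)
  rows <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    tr <- folds[[f]]$train; va <- folds[[f]]$val
    tcfg$class_weights <- class_weights(labels[tr])
    model <- if (task == "binary")
      build_binary_cnn(input_shape = dim(ts$x)[1:3], seed = seed + f)
    else
      build_multigroup_model(input_shape = dim(ts$x)[1:3], seed = seed + f)
    model <- train_model(model,
                         list(x = ts$x[, , , tr, drop = FALSE],
                              labels = labels[tr]),
                         tcfg = tcfg)
    pred <- predict_labels(model, ts$x[, , , va, drop = FALSE])
    if (task == "binary") {
      cm <- confusion_matrix(labels[va], pred, class_labels)
      rows[[f]] <- binary_metrics(cm)
    } else {
      cm <- confusion_matrix(labels[va], pred, class_labels)
      mm <- multigroup_metrics(cm)
      rows[[f]] <- mm$macro
    }
  }
  do.call(rbind, rows)
}
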