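#' Experiment drivers
#'
#' End-to-end experiments over a synthetic cohort: seizure detection with
#' cross-validation, the sampling-rate sweep, the electrode-count
#' comparison, and the interpretability bundle (activation maximization
#' panels, MI topoplots, dSPM source maps). Each driver writes its
#' artifacts under an output directory and is resumable: a completed
#' stage whose configuration hash matches on disk is skipped.
#'
#' @name experiments
NULL

#' Assemble an experiment configuration
#'
#' Every pipeline parameter surfaces as a named key with the package's
#' reference value as default: 40 Hz low-pass cutoff, 1-s windows,
#' 64-point STFT, 5 folds, 20 epochs for the binary detector and 50 for
#' the multigroup classifier, 1000 windows and 100 runs for the MI
#' estimator, and the 50-250 Hz sweep in 50 Hz steps.
#'
#' @param path optional YAML file; keys override the defaults below
#' @param ... further overrides (named, nested lists merged shallowly)
#' @return a nested list of settings
#' @export
experiment_config <- function(path = NULL, ...) {
  cfg <- list(
    cohort = list(n_subjects = 10L, record_duration_s = 180,
                  sampling_rate_hz = 250, seizures_per_record = 6L,
                  seed = 1L),
    preprocessing = list(lowpass_hz = 40, window_s = 1, nfft = 64L),
    training = list(binary_epochs = 20L, multigroup_epochs = 50L,
                    batch_size = 32L, learning_rate = 1e-3,
                    dropout = 0.3),
    evaluation = list(k_folds = 5L),
    mi = list(n_windows = 1000L, n_runs = 100L),
    am = list(n_runs = 100L, steps = 256L, step_size = 0.1,
              l2_decay = 1e-3),
    sweep = list(rates = c(50, 100, 150, 200, 250)),
    montages = list(standard21 = STANDARD_21, reduced8 = REDUCED_8),
    seed = 1L)
  if (!is.null(path)) cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  utils::modifyList(cfg, list(...))
}

.cfg_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

.stage_path <- function(out_dir, stage) file.path(out_dir, paste0(stage, ".json"))

.stage_done <- function(out_dir, stage, cfg) {
  p <- .stage_path(out_dir, stage)
  if (!file.exists(p)) return(FALSE)
  done <- jsonlite::read_json(p)
  identical(done$config_hash, .cfg_hash(cfg))
}

.stage_write <- function(out_dir, stage, cfg, payload) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(c(list(config_hash = .cfg_hash(cfg)), payload),
                       .stage_path(out_dir, stage), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

# generate (or reuse) the configured cohort and load its windows
.cohort_windows <- function(cfg, out_dir, target_hz = NULL) {
  cohort_dir <- file.path(out_dir, "cohort")
  ccfg <- do.call(cohort_config, cfg$cohort)
  manifest_path <- file.path(cohort_dir, "manifest.json")
  reuse <- FALSE
  if (file.exists(manifest_path)) {
    man <- jsonlite::read_json(manifest_path)
    reuse <- identical(as.integer(man$seed), ccfg$seed)
  }
  if (!reuse) generate_cohort(ccfg, cohort_dir, format = "rds")
  load_cohort_windows(cohort_dir, lowpass_hz = cfg$preprocessing$lowpass_hz,
                      target_hz = target_hz,
                      window_s = cfg$preprocessing$window_s)
}

#' Run the seizure-detection experiment
#'
#' Generates (or reuses) the cohort, preprocesses it, trains the binary
#' detector under event-grouped stratified k-fold cross-validation and
#' writes the per-fold metrics and their summary.
#'
#' @param cfg an [experiment_config]
#' @param out_dir output directory
#' @return list with `per_fold` metrics tibble and `summary`
#' @export
run_detection <- function(cfg = experiment_config(), out_dir = tempfile("det")) {
  if (.stage_done(out_dir, "detection", cfg)) {
    done <- jsonlite::read_json(.stage_path(out_dir, "detection"),
                                simplifyVector = TRUE)
    return(list(per_fold = tibble::as_tibble(done$per_fold),
                summary = tibble::as_tibble(done$summary)))
  }
  windows <- .cohort_windows(cfg, out_dir)
  tcfg <- training_config(epochs = cfg$training$binary_epochs,
                          batch_size = cfg$training$batch_size,
                          learning_rate = cfg$training$learning_rate,
                          seed = cfg$seed)
  per_fold <- .cv_metrics(windows, STANDARD_21, "binary",
                          k = cfg$evaluation$k_folds, tcfg, seed = cfg$seed)
  fs <- fold_summary(per_fold)
  .stage_write(out_dir, "detection", cfg,
               list(per_fold = per_fold, summary = fs$summary))
  list(per_fold = tibble::tibble(fold = seq_len(nrow(per_fold)), per_fold),
       summary = fs$summary)
}

#' Run the sampling-rate sweep
#'
#' For each rate (ascending), resamples the cohort, preprocesses and
#' trains the requested models on one event-grouped split, recording
#' held-out metrics per rate and model. Tensor dimensions are identical
#' across rates because the STFT always cuts 8 segments and pads to the
#' same FFT length.
#'
#' @param cfg an [experiment_config]
#' @param rates sampling rates in Hz, sorted ascending, all at most the
#'   cohort rate
#' @param models which models to train at each rate
#' @param out_dir output directory
#' @return tibble: one row per rate and model with held-out metrics
#' @export
run_sr_sweep <- function(cfg = experiment_config(),
                         rates = cfg$sweep$rates,
                         models = c("binary", "multigroup"),
                         out_dir = tempfile("sweep")) {
  if (is.unsorted(rates)) stop("rates must be sorted ascending")
  if (any(rates > cfg$cohort$sampling_rate_hz))
    stop("sweep rate above the cohort sampling rate")
  scfg <- utils::modifyList(cfg, list(sweep = list(rates = rates),
                                      models = models))
  if (.stage_done(out_dir, "sr_sweep", scfg)) {
    done <- jsonlite::read_json(.stage_path(out_dir, "sr_sweep"),
                                simplifyVector = TRUE)
    return(tibble::as_tibble(done$results))
  }
  rows <- list()
  for (rate in rates) {
    windows <- .cohort_windows(cfg, out_dir, target_hz = rate)
    ts <- windows_to_tensors(windows, STANDARD_21,
                             nfft = cfg$preprocessing$nfft)
    for (model in models) {
      res <- .split_metrics(ts, model, cfg, seed = cfg$seed + round(rate))
      rows[[paste(rate, model)]] <-
        tibble::tibble(rate_hz = rate, model = model, res)
    }
  }
  results <- do.call(rbind, rows)
  .stage_write(out_dir, "sr_sweep", scfg, list(results = results))
  results
}

#' Train both pipeline models on the configured cohort
#'
#' Convenience driver used by the interpretability bundle and the
#' reproduction script: generates/loads the cohort, trains the binary
#' detector on all windows and the multigroup classifier on seizure
#' windows (event-grouped train/val/test split), and returns the trained
#' models together with their held-out metrics.
#'
#' @param cfg an [experiment_config]
#' @param out_dir working directory (cohort is cached here)
#' @return list with `binary`, `multigroup` (trained `seizr_model`s),
#'   `binary_metrics`, `multigroup_metrics`, and the `windows`
#' @export
train_cohort_models <- function(cfg = experiment_config(),
                                out_dir = tempfile("models")) {
  windows <- .cohort_windows(cfg, out_dir)
  ts <- windows_to_tensors(windows, STANDARD_21,
                           nfft = cfg$preprocessing$nfft)
  out <- list(windows = windows)
  for (task in c("binary", "multigroup")) {
    res <- .split_metrics(ts, task, cfg, seed = cfg$seed,
                          return_model = TRUE)
    out[[task]] <- res$model
    out[[paste0(task, "_metrics")]] <- res$metrics
  }
  out
}

# single-split train/evaluate for one model on a tensor set
.split_metrics <- function(ts, task, cfg, seed, return_model = FALSE) {
  if (task == "multigroup") {
    keep <- which(ts$labels != "bckg")
    ts <- .ts_subset(ts, keep)
    labels <- ts$labels
    class_labels <- SEIZURE_LABELS
    epochs <- cfg$training$multigroup_epochs
  } else {
    labels <- binarize_labels(ts$labels)
    class_labels <- c("bckg", "seiz")
    epochs <- cfg$training$binary_epochs
  }
  sp <- make_splits(.ts_meta(ts), c(train = 0.7, val = 0.15, test = 0.15),
                    seed = seed)   # stratified by seizure type
  tcfg <- training_config(epochs = epochs,
                          batch_size = cfg$training$batch_size,
                          learning_rate = cfg$training$learning_rate,
                          class_weights = class_weights(labels[sp$train]),
                          seed = seed)
  model <- if (task == "binary")
    build_binary_cnn(input_shape = dim(ts$x)[1:3], seed = seed)
  else
    build_multigroup_model(input_shape = dim(ts$x)[1:3],
                           dropout = cfg$training$dropout, seed = seed)
  model <- train_model(model, list(x = ts$x[, , , sp$train, drop = FALSE],
                                   labels = labels[sp$train]), tcfg = tcfg)
  pred <- predict_labels(model, ts$x[, , , sp$test, drop = FALSE])
  cm <- confusion_matrix(labels[sp$test], pred, class_labels)
  metrics <- if (task == "binary") binary_metrics(cm)
    else multigroup_metrics(cm)$macro
  if (return_model) list(model = model, metrics = metrics, confusion = cm)
  else metrics
}

#' Run the electrode-count comparison
#'
#' Greedy MI-guided ablation of the binary detector plus the fixed
#' 21-versus-8 cross-validated comparison of both models with the
#' statistical tests.
#'
#' @param cfg an [experiment_config]
#' @param min_electrodes ablation stop size
#' @param out_dir output directory
#' @return list with `ablation` (see [ablation_experiment]) and
#'   `comparison` (see [fixed_reduced_comparison])
#' @export
run_electrode_comparison <- function(cfg = experiment_config(),
                                     min_electrodes = 8L,
                                     out_dir = tempfile("elec")) {
  windows <- .cohort_windows(cfg, out_dir)
  abl <- ablation_experiment(
    windows, STANDARD_21, min_electrodes = min_electrodes,
    tcfg = training_config(epochs = cfg$training$binary_epochs,
                           seed = cfg$seed),
    mi_n_windows = cfg$mi$n_windows,
    mi_n_runs = max(1L, cfg$mi$n_runs %/% 20L),
    seed = cfg$seed)
  cmp <- fixed_reduced_comparison(
    windows, cfg$montages$standard21, cfg$montages$reduced8,
    k = cfg$evaluation$k_folds,
    binary_tcfg = training_config(epochs = cfg$training$binary_epochs,
                                  seed = cfg$seed),
    multi_tcfg = training_config(epochs = cfg$training$multigroup_epochs,
                                 seed = cfg$seed),
    seed = cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(abl$curve, file.path(out_dir, "ablation_curve.csv"),
                   row.names = FALSE)
  utils::write.csv(cmp$per_fold, file.path(out_dir, "montage_folds.csv"),
                   row.names = FALSE)
  utils::write.csv(cmp$comparison, file.path(out_dir, "montage_tests.csv"),
                   row.names = FALSE)
  list(ablation = abl, comparison = cmp)
}

#' Run the interpretability bundle
#'
#' Writes activation-maximization panels for both binary classes and all
#' eight seizure types, MI topoplots for the detection and typing tasks,
#' and dSPM source maps with lateralization indices for one seizure of
#' each type present in the cohort.
#'
#' @param cfg an [experiment_config]
#' @param binary_model,multigroup_model trained `seizr_model`s (or paths
#'   to [save_model] checkpoints)
#' @param out_dir output directory
#' @param am_runs,am_steps activation-maximization effort per class
#' @return list with `am` (per-class `am_pattern`s), `mi` (rankings),
#'   `dspm` (per-type lateralization tibble)
#' @export
run_interpretability <- function(cfg = experiment_config(),
                                 binary_model, multigroup_model,
                                 out_dir = tempfile("interp"),
                                 am_runs = cfg$am$n_runs,
                                 am_steps = cfg$am$steps) {
  if (is.character(binary_model)) {
    if (!file.exists(binary_model)) stop("missing checkpoint: ", binary_model)
    binary_model <- load_model(binary_model)
  }
  if (is.character(multigroup_model)) {
    if (!file.exists(multigroup_model))
      stop("missing checkpoint: ", multigroup_model)
    multigroup_model <- load_model(multigroup_model)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- montage(STANDARD_21)
  windows <- .cohort_windows(cfg, out_dir)
  # activation maximization: 2 binary panels + 8 type panels
  am <- list()
  panels <- c(stats::setNames(seq_along(binary_model$class_labels),
                              paste0("binary_", binary_model$class_labels)),
              stats::setNames(seq_along(multigroup_model$class_labels),
                              multigroup_model$class_labels))
  model_of <- c(rep(list(binary_model), length(binary_model$class_labels)),
                rep(list(multigroup_model),
                    length(multigroup_model$class_labels)))
  for (i in seq_along(panels)) {
    nm <- names(panels)[i]
    pat <- activation_maximization(model_of[[i]], panels[[i]],
                                   n_runs = am_runs, steps = am_steps,
                                   step_size = cfg$am$step_size,
                                   l2_decay = cfg$am$l2_decay,
                                   seed = cfg$seed + i)
    am[[nm]] <- pat
    tp <- topoplot(channel_energy(pat, m$names), m)
    ggplot2::ggsave(file.path(out_dir, paste0("am_", nm, ".png")),
                    autoplot(tp, title = paste("AM:", nm)),
                    width = 4, height = 4, dpi = 120)
  }
  # MI topoplots for the two tasks
  wl <- vapply(windows, `[[`, character(1), "label")
  mi <- list(
    binary = mi_scores(windows, n_windows = min(cfg$mi$n_windows,
                                                length(windows)),
                       n_runs = max(1L, cfg$mi$n_runs %/% 20L),
                       labels = binarize_labels(wl), seed = cfg$seed),
    multigroup = mi_scores(windows[wl != "bckg"],
                           n_windows = min(cfg$mi$n_windows,
                                           sum(wl != "bckg")),
                           n_runs = max(1L, cfg$mi$n_runs %/% 20L),
                           seed = cfg$seed))
  for (task in names(mi)) {
    v <- stats::setNames(mi[[task]]$normalized, mi[[task]]$electrode)
    ggplot2::ggsave(file.path(out_dir, paste0("mi_", task, ".png")),
                    autoplot(topoplot(v, m),
                             title = paste("MI:", task)),
                    width = 4, height = 4, dpi = 120)
    utils::write.csv(mi[[task]],
                     file.path(out_dir, paste0("mi_", task, ".csv")),
                     row.names = FALSE)
  }
  # dSPM per seizure type: first event of each type in the cohort
  dsp <- .dspm_by_type(cfg, out_dir)
  list(am = am, mi = mi, dspm = dsp)
}

# reconstruct sources for the first seizure of each type in the cohort
.dspm_by_type <- function(cfg, out_dir) {
  cohort_dir <- file.path(out_dir, "cohort")
  manifest <- jsonlite::read_json(file.path(cohort_dir, "manifest.json"))
  fwd <- build_toy_forward(montage(STANDARD_21))
  rows <- list()
  for (recinfo in manifest$records) {
    ann <- parse_tse(file.path(cohort_dir, recinfo$annotation))
    rec <- NULL
    for (i in which(ann$label != "bckg")) {
      type <- ann$label[i]
      if (!is.null(rows[[type]])) next
      if (ann$start_s[i] < 0.2) next
      if (is.null(rec))
        rec <- read_recording(file.path(cohort_dir, recinfo$recording),
                              format = recinfo$format)
      rec21 <- select_channels(rec, STANDARD_21)
      onset <- ann$start_s[i]
      ncov <- estimate_noise_cov(rec21, onset)
      t1 <- min(onset + 2, ann$stop_s[i])
      seg <- crop_recording(rec21, onset, t1)
      times <- seq(0, by = 1 / rec21$sampling_rate_hz,
                   length.out = ncol(seg$data))
      est <- dspm_inverse(fwd, ncov, seg$data, times = times)
      map <- onset_average(est, c(0, 2))
      li <- lateralization_index(map, fwd)
      rows[[type]] <- tibble::tibble(type = type, li)
      ggplot2::ggsave(file.path(out_dir, paste0("dspm_", type, ".png")),
                      plot_source_map(map, fwd, title = paste("dSPM:", type)),
                      width = 4, height = 4, dpi = 120)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out))
    utils::write.csv(out, file.path(out_dir, "dspm_lateralization.csv"),
                     row.names = FALSE)
  out
}
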