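#' Mutual-information electrode ranking and montage ablation
#'
#' Electrode informativeness is scored by the mutual information between
#' an electrode's raw time-domain sample values and the window label,
#' estimated with an equal-frequency 8-bin histogram per time index,
#' averaged over time indices and over repeated window draws. The
#' estimator is invariant to per-electrode affine rescaling because the
#' bins are quantile-based. The ablation experiment retrains the binary
#' detector while greedily removing the least-informative electrode.
#'
#' @name electrode-importance
NULL

# MI (nats) between an equal-frequency binning of x and integer labels
.mi_binned <- function(x, ly, n_levels, n_bins = 8L) {
  n <- length(x)
  if (x[1L] == x[n] && all(x == x[1L])) return(0)   # constant signal
  bx <- ceiling(rank(x, ties.method = "first") * n_bins / n)
  joint <- tabulate(bx + n_bins * (ly - 1L), n_bins * n_levels) / n
  dim(joint) <- c(n_bins, n_levels)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(px, py)[nz]))
}

#' Mutual-information scores per electrode
#'
#' Per run, `n_windows` windows are drawn without replacement; for each
#' electrode the MI between sample value and window label is estimated at
#' every time index and averaged, then averaged over runs. Raw scores,
#' min-max normalized scores and the descending ranking are returned.
#'
#' @param windows list of labeled windows ([extract_windows])
#' @param n_windows windows drawn per run (capped at the number available)
#' @param n_runs number of repeated draws averaged
#' @param labels optional label vector overriding the windows' own labels
#'   (e.g. [binarize_labels] for the detection task)
#' @param n_bins histogram bins of the estimator
#' @param seed integer seed
#' @return an `mi_ranking`: tibble with columns `electrode`, `raw`,
#'   `normalized`, `rank`, sorted by descending score
#' @export
mi_scores <- function(windows, n_windows = 1000L, n_runs = 100L,
                      labels = NULL, n_bins = 8L, seed = 1L) {
  stopifnot(length(windows) > 0L)
  if (is.null(labels)) labels <- vapply(windows, `[[`, character(1), "label")
  if (length(unique(labels)) < 2L)
    stop("mutual information needs at least 2 distinct labels")
  C <- nrow(windows[[1L]]$data)
  S <- ncol(windows[[1L]]$data)
  N <- length(windows)
  X <- array(0, c(C, S, N))
  for (i in seq_len(N)) X[, , i] <- windows[[i]]$data
  lv <- factor(labels)
  ly_all <- as.integer(lv)
  L <- nlevels(lv)
  n_draw <- min(n_windows, N)
  acc <- numeric(C)
  with_seed(seed, {
    for (r in seq_len(n_runs)) {
      sel <- sample.int(N, n_draw)
      ly <- ly_all[sel]
      for (ch in seq_len(C)) {
        mi_t <- 0
        for (t in seq_len(S))
          mi_t <- mi_t + .mi_binned(X[ch, t, sel], ly, L, n_bins)
        acc[ch] <- acc[ch] + mi_t / S
      }
    }
  })
  raw <- acc / n_runs
  names(raw) <- windows[[1L]]$channel_names
  norm <- normalize_scores(raw)
  out <- tibble::tibble(electrode = names(raw), raw = unname(raw),
                        normalized = unname(norm))
  out <- out[order(-out$raw), ]
  out$rank <- seq_len(nrow(out))
  class(out) <- c("mi_ranking", class(out))
  out
}

#' Min-max normalize scores to the unit interval
#'
#' @param raw numeric vector; names preserved
#' @return `(x - min) / (max - min)`; all-equal input maps to all zeros
#' @export
normalize_scores <- function(raw) {
  stopifnot(length(raw) >= 1L)
  rng <- range(raw)
  if (diff(rng) == 0) return(raw * 0)
  (raw - rng[1L]) / diff(rng)
}

#' Greedy electrode ablation of the binary detector
#'
#' Starting from the full montage, repeatedly: record held-out detection
#' metrics for the current montage, then drop the electrode with the
#' minimum MI score. Removed electrodes never reappear.
#'
#' @param windows list of labeled windows on the full montage
#' @param start_channels initial electrode set
#' @param min_electrodes stop after recording this montage size
#' @param tcfg a [training_config] for the per-step binary retraining
#' @param mi_n_windows,mi_n_runs MI estimator settings per step
#' @param split_fractions train/val/test fractions for each retraining
#' @param seed integer seed
#' @return list with `curve` (tibble: one row per montage size with
#'   detection metrics), `montages` (electrode sets used at each size) and
#'   `rankings` (per-step `mi_ranking`s)
#' @export
ablation_experiment <- function(windows, start_channels = STANDARD_21,
                                min_electrodes = 8L,
                                tcfg = training_config(epochs = 5L),
                                mi_n_windows = 500L, mi_n_runs = 5L,
                                split_fractions = c(train = 0.7, val = 0.15,
                                                    test = 0.15),
                                seed = 1L) {
  if (min_electrodes < 2L) stop("min_electrodes must be at least 2")
  channels <- start_channels
  blabels <- binarize_labels(vapply(windows, `[[`, character(1), "label"))
  rows <- list(); montages <- list(); rankings <- list()
  step <- 0L
  while (length(channels) >= min_electrodes) {
    step <- step + 1L
    res <- .train_eval_binary(windows, channels, tcfg,
                              split_fractions, seed + step)
    rows[[step]] <- tibble::tibble(n_electrodes = length(channels), res)
    montages[[step]] <- channels
    if (length(channels) == min_electrodes) break
    sub <- .subset_windows(windows, channels)
    rk <- mi_scores(sub, n_windows = mi_n_windows, n_runs = mi_n_runs,
                    labels = blabels, seed = seed + 1000L + step)
    rankings[[step]] <- rk
    worst <- rk$electrode[which.min(rk$raw)]
    channels <- setdiff(channels, worst)
  }
  list(curve = do.call(rbind, rows), montages = montages,
       rankings = rankings)
}

#' Cross-validated comparison of the full and reduced montages
#'
#' Runs event-grouped, stratified k-fold cross-validation for each montage
#' and each requested model (binary detector on all windows; multigroup
#' classifier on seizure windows only) and compares the per-fold metrics
#' between montages with [compare_montages].
#'
#' @param windows list of labeled windows on the full montage
#' @param montage_a,montage_b the two electrode sets compared
#' @param models which models to evaluate
#' @param k folds
#' @param binary_tcfg,multi_tcfg [training_config]s per model
#' @param seed integer seed
#' @return list with `per_fold` (tibble: montage, model, fold, metrics),
#'   `summaries` (per montage/model [fold_summary]) and `comparison`
#'   (tibble: model, metric, Welch/Mann-Whitney/normality results)
#' @export
fixed_reduced_comparison <- function(windows, montage_a = STANDARD_21,
                                     montage_b = REDUCED_8,
                                     models = c("binary", "multigroup"),
                                     k = 5L,
                                     binary_tcfg = training_config(epochs = 5L),
                                     multi_tcfg = training_config(epochs = 10L),
                                     seed = 1L) {
  montages <- list(a = montage_a, b = montage_b)
  montage_names <- c(a = paste0("montage", length(montage_a)),
                     b = paste0("montage", length(montage_b)))
  per_fold <- list()
  for (mk in names(montages)) {
    for (model in models) {
      tcfg <- if (model == "binary") binary_tcfg else multi_tcfg
      fm <- .cv_metrics(windows, montages[[mk]], model, k, tcfg, seed)
      per_fold[[paste(mk, model)]] <-
        tibble::tibble(montage = montage_names[[mk]], model = model,
                       fold = seq_len(k), fm)
    }
  }
  per_fold <- do.call(rbind, per_fold)
  summaries <- lapply(split(per_fold, paste(per_fold$montage, per_fold$model)),
                      function(d) fold_summary(d[, -(1:3)]))
  comparison <- list()
  if (k >= 3L) {                 # the statistical tests need >= 3 folds
    metrics <- setdiff(names(per_fold), c("montage", "model", "fold"))
    for (model in models) {
      for (metric in metrics) {
        va <- per_fold[per_fold$model == model &
                         per_fold$montage == montage_names[["a"]], ][[metric]]
        vb <- per_fold[per_fold$model == model &
                         per_fold$montage == montage_names[["b"]], ][[metric]]
        if (all(is.na(va)) || all(is.na(vb))) next
        comparison[[paste(model, metric)]] <-
          tibble::tibble(model = model, metric = metric,
                         suppressWarnings(compare_montages(va, vb)))
      }
    }
  }
  list(per_fold = per_fold, summaries = summaries,
       comparison = if (length(comparison)) do.call(rbind, comparison))
}
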