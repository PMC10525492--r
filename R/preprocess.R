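#' Preprocessing chain: filter, resample, window, spectro-tensor, splits
#'
#' The chain mirrors a standard clinical-EEG learning setup: a 40 Hz
#' zero-phase FIR low-pass, resampling to the working rate, non-overlapping
#' 1-second windows labeled by majority overlap with the annotations, and a
#' 64-point short-time Fourier transform per window giving a
#' channels x 33 frequencies x 8 timesteps tensor. Splits are grouped by
#' annotation event so no event leaks across train/validation/test.
#'
#' @name preprocessing
NULL

#' Zero-phase FIR low-pass filter
#'
#' Designs a Hamming-window FIR low-pass of order `4 * rate / cutoff`
#' (rounded to odd) and applies it forward-backward per channel, so the
#' output is zero-phase and length-preserving.
#'
#' @param rec a [recording]
#' @param cutoff_hz cutoff frequency, must be below Nyquist
#' @return the filtered [recording]
#' @export
fir_lowpass <- function(rec, cutoff_hz = 40) {
  sr <- rec$sampling_rate_hz
  if (cutoff_hz >= sr / 2)
    stop("cutoff ", cutoff_hz, " Hz is at or above Nyquist (", sr / 2, " Hz)")
  ord <- round(4 * sr / cutoff_hz)
  if (ord %% 2 == 0) ord <- ord + 1
  h <- as.numeric(signal::fir1(ord, cutoff_hz / (sr / 2), type = "low"))
  h <- h / sum(h)                       # unit DC gain exactly
  out <- t(apply(rec$data, 1L, function(x) signal::filtfilt(h, 1, x)))
  recording(out, rec$channel_names, sr, rec$subject_id, rec$record_id)
}

#' Polyphase rational resampling
#'
#' @param rec a [recording]
#' @param target_hz new sampling rate
#' @return a [recording] at `target_hz`; the sample count scales by
#'   `target_hz / sampling_rate_hz` within rounding
#' @export
resample_recording <- function(rec, target_hz) {
  stopifnot(target_hz > 0)
  sr <- rec$sampling_rate_hz
  if (abs(target_hz - sr) < 1e-9) return(rec)
  f <- .rational(target_hz / sr)
  n_out <- round(ncol(rec$data) * target_hz / sr)
  out <- t(apply(rec$data, 1L, function(x) {
    y <- signal::resample(x, f[1L], f[2L])
    length(y) <- n_out          # pad/trim boundary effects of the polyphase
    y[is.na(y)] <- 0
    y
  }))
  recording(out, rec$channel_names, target_hz, rec$subject_id, rec$record_id)
}

.rational <- function(x, tol = 1e-9) {
  for (q in 1:10000) {
    p <- x * q
    if (abs(p - round(p)) < tol * q) return(c(round(p), q))
  }
  stop("cannot express resampling ratio ", x, " as a small rational")
}

#' Cut a recording into labeled non-overlapping windows
#'
#' Consecutive windows of `window_s` seconds starting at 0; a trailing
#' remainder shorter than `window_s` is discarded. Each window is labeled
#' by [label_at]'s majority-overlap rule and tagged with the index of the
#' annotation event that won the vote.
#'
#' @param rec a [recording]
#' @param ann an [annotation_set] spanning the record
#' @param window_s window length in seconds
#' @return list of labeled windows, each a list with `data`
#'   (channels x samples), `label`, `subject_id`, `event_index`,
#'   `start_s`, `sampling_rate_hz`, `channel_names`
#' @export
extract_windows <- function(rec, ann, window_s = 1.0) {
  sr <- rec$sampling_rate_hz
  wlen <- round(window_s * sr)
  n_win <- floor(ncol(rec$data) / wlen)
  lapply(seq_len(n_win), function(i) {
    t0 <- (i - 1L) * window_s
    t1 <- t0 + window_s
    ev <- .event_at(ann, t0, t1)
    cols <- ((i - 1L) * wlen + 1L):(i * wlen)
    list(data = rec$data[, cols, drop = FALSE],
         label = if (is.na(ev)) "unlabeled" else ann$label[ev],
         subject_id = rec$subject_id,
         event_index = ev,
         start_s = t0,
         sampling_rate_hz = sr,
         channel_names = rec$channel_names)
  })
}

# index of the majority-overlap event (ties to non-bckg, then earliest)
.event_at <- function(ann, t0, t1) {
  ov <- pmin(ann$stop_s, t1) - pmax(ann$start_s, t0)
  ov[ov < 0] <- 0
  if (length(ov) == 0L || max(ov) <= 0) return(NA_integer_)
  cand <- which(ov > max(ov) - 1e-9)
  if (length(cand) > 1L) {
    sz <- cand[ann$label[cand] != "bckg"]
    if (length(sz) > 0L) cand <- sz
  }
  cand[1L]
}

#' Short-time Fourier spectro-tensor of one window
#'
#' The window's samples are split into `n_timesteps` equal non-overlapping
#' segments of `floor(n_samples / n_timesteps)` samples (trailing remainder
#' discarded). Each segment is Hann-tapered and zero-padded (or truncated)
#' to `nfft` points; its one-sided magnitude spectrum gives `nfft/2 + 1`
#' frequency bins. A 1-s window at 250 Hz with the defaults yields the
#' pipeline's 21 x 33 x 8 input tensor.
#'
#' @param w a labeled window from [extract_windows]
#' @param nfft FFT length (even), default 64
#' @param n_timesteps number of segments, default 8
#' @return a `spectro_tensor`: list with `values`
#'   (channels x frequencies x timesteps, nonnegative), `label`,
#'   `subject_id`, `event_index`, `freq_hz`
#' @export
stft_tensor <- function(w, nfft = 64L, n_timesteps = 8L) {
  if (nfft %% 2 != 0) stop("nfft must be even")
  x <- w$data
  ns <- ncol(x)
  if (ns < n_timesteps) stop("window too short: ", ns, " samples for ",
                             n_timesteps, " segments")
  seg <- floor(ns / n_timesteps)
  taper <- .hann(seg)
  nbin <- nfft / 2 + 1L
  vals <- array(0, dim = c(nrow(x), nbin, n_timesteps))
  for (s in seq_len(n_timesteps)) {
    cols <- ((s - 1L) * seg + 1L):(s * seg)
    tapered <- x[, cols, drop = FALSE] * rep(taper, each = nrow(x))
    if (seg >= nfft) tapered <- tapered[, seq_len(nfft), drop = FALSE]
    padded <- matrix(0, nrow(x), nfft)
    padded[, seq_len(ncol(tapered))] <- tapered
    sp <- Mod(t(stats::mvfft(t(padded))))
    vals[, , s] <- sp[, seq_len(nbin), drop = FALSE]
  }
  structure(list(values = vals, label = w$label, subject_id = w$subject_id,
                 event_index = w$event_index,
                 freq_hz = seq(0, nfft / 2) * w$sampling_rate_hz / nfft,
                 channel_names = w$channel_names),
            class = "spectro_tensor")
}

.hann <- function(n) {
  if (n == 1L) return(1)
  0.5 * (1 - cos(2 * pi * seq_len(n) / (n + 1)))
}

#' Stack spectro-tensors into a 4-D model input array
#'
#' @param tensors list of `spectro_tensor` objects with a common shape
#' @return list with `x` (channels x freq x time x n array), `labels`
#'   (character), `subjects`, `events` (group keys), `channel_names`
#' @export
tensor_set <- function(tensors) {
  stopifnot(length(tensors) > 0L)
  d <- dim(tensors[[1L]]$values)
  x <- array(0, dim = c(d, length(tensors)))
  for (i in seq_along(tensors)) x[, , , i] <- tensors[[i]]$values
  list(x = x,
       labels = vapply(tensors, `[[`, character(1), "label"),
       subjects = vapply(tensors, `[[`, character(1), "subject_id"),
       events = vapply(tensors, function(t)
         paste0(t$subject_id, "#", t$event_index), character(1)),
       channel_names = tensors[[1L]]$channel_names)
}

# largest-remainder quotas summing to n; ties broken toward the split
# furthest below its global target so per-class remainders balance out
.quotas <- function(n, fractions, deficit = rep(0, length(fractions))) {
  q <- n * fractions
  fl <- floor(q)
  rem <- n - sum(fl)
  if (rem > 0) {
    extra <- order(q - fl, deficit, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  }
  fl
}

# group keys for a window list or tensor_set-style inputs
.group_keys <- function(windows, grouping) {
  if (grouping == "subject")
    vapply(windows, `[[`, character(1), "subject_id")
  else
    vapply(windows, function(w)
      paste0(w$subject_id, "#", w$event_index), character(1))
}

#' Train/validation/test split grouped by annotation event
#'
#' Partitions window indices so that all windows of one annotation event
#' land in the same split (the event-grouping guarantee against leakage),
#' stratified by label and deterministic per seed.
#'
#' @param windows list of labeled windows (or any list whose elements carry
#'   `label`, `subject_id`, `event_index`)
#' @param fractions named positive fractions summing to 1
#' @param grouping `"event"` or `"subject"`
#' @param stratify allocate each class's groups proportionally
#' @param seed integer seed
#' @param labels optional label vector overriding the windows' own labels
#'   for stratification (e.g. [binarize_labels] for the detection task)
#' @return list of integer index vectors, one per fraction name
#' @export
make_splits <- function(windows,
                        fractions = c(train = 0.7, val = 0.15, test = 0.15),
                        grouping = c("event", "subject"), stratify = TRUE,
                        seed = 1L, labels = NULL) {
  grouping <- match.arg(grouping)
  stopifnot(all(fractions > 0), abs(sum(fractions) - 1) < 1e-9)
  keys <- .group_keys(windows, grouping)
  if (is.null(labels))
    labels <- vapply(windows, `[[`, character(1), "label")
  grp_label <- tapply(labels, keys, function(l) l[1L])
  grp_names <- names(grp_label)
  strata <- if (stratify) unname(grp_label) else rep("all", length(grp_label))
  assign_split <- rep(NA_character_, length(grp_names))
  assigned <- stats::setNames(rep(0, length(fractions)), names(fractions))
  with_seed(seed, {
    for (cl in unique(strata)) {
      g <- which(strata == cl)
      if (length(g) < length(fractions))
        warning("class '", cl, "' has fewer groups (", length(g),
                ") than splits; best-effort assignment")
      g <- g[sample.int(length(g))]
      deficit <- sum(assigned) * fractions - assigned
      qn <- .quotas(length(g), fractions, deficit)
      assigned <- assigned + qn
      pos <- 1L
      for (s in seq_along(fractions)) {
        if (qn[s] > 0) {
          assign_split[g[pos:(pos + qn[s] - 1L)]] <- names(fractions)[s]
          pos <- pos + qn[s]
        }
      }
      # groups left unassigned by zero quotas go to the largest split
      left <- g[is.na(assign_split[g])]
      if (length(left) > 0)
        assign_split[left] <- names(fractions)[which.max(fractions)]
    }
  })
  out <- lapply(stats::setNames(names(fractions), names(fractions)),
                function(s) which(keys %in% grp_names[assign_split == s]))
  out
}

#' Event-grouped stratified k-fold indices
#'
#' Each window appears in exactly one validation fold; all windows of one
#' annotation event share a fold; classes are dealt round-robin so every
#' fold sees every class where possible.
#'
#' @param windows as in [make_splits]
#' @param k number of folds
#' @param seed integer seed
#' @param labels optional stratification labels overriding the windows' own
#' @return list of `k` elements, each `list(train =, val =)` index vectors
#' @export
kfold_indices <- function(windows, k = 5L, seed = 1L, labels = NULL) {
  stopifnot(k >= 2L)
  keys <- .group_keys(windows, "event")
  if (is.null(labels))
    labels <- vapply(windows, `[[`, character(1), "label")
  grp_label <- tapply(labels, keys, function(l) l[1L])
  grp_names <- names(grp_label)
  fold_of <- rep(NA_integer_, length(grp_names))
  with_seed(seed, {
    offset <- 0L
    for (cl in unique(unname(grp_label))) {
      g <- which(grp_label == cl)
      g <- g[sample.int(length(g))]
      fold_of[g] <- ((seq_along(g) - 1L + offset) %% k) + 1L
      offset <- offset + length(g)   # balance fold sizes across classes
    }
  })
  lapply(seq_len(k), function(f) {
    val_groups <- grp_names[fold_of == f]
    val <- which(keys %in% val_groups)
    list(train = setdiff(seq_along(windows), val), val = val)
  })
}

#' Inverse-frequency class weights
#'
#' `w_c = N / (K * n_c)` with `N` total windows, `K` classes present and
#' `n_c` the class count, so that `sum_c w_c * n_c == N`.
#'
#' @param labels character vector of window labels
#' @return named numeric weight per class
#' @export
class_weights <- function(labels) {
  stopifnot(length(labels) > 0L)
  tab <- table(labels)
  n <- length(labels)
  k <- length(tab)
  stats::setNames(as.numeric(n / (k * tab)), names(tab))
}
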