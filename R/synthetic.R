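#' Synthetic EEG cohorts with injected seizures
#'
#' The generator emulates the structure of a clinical seizure corpus:
#' per-subject multichannel scalp EEG at 250 Hz on the 21-electrode 10/20
#' montage, background activity labeled `bckg`, and seizure intervals of
#' eight types with distinct, class-separable spatio-spectral signatures.
#' Background is 1/f ("pink") noise plus a posterior-dominant 10 Hz alpha
#' rhythm; seizures are synthetic waveforms (spike-wave, rhythmic sine,
#' polyspike bursts, low-voltage fast activity, evolving chirps) scaled by
#' a per-electrode spatial gain profile. Generalized types project broadly
#' (all gains >= 0.7); focal types peak at a focus electrode with gains
#' decaying by scalp distance.
#'
#' @name synthetic-cohort
NULL

# run expr with a private RNG stream, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}

#' Describe one seizure type's synthetic signature
#'
#' @param label seizure label (one of [SEIZURE_LABELS])
#' @param waveform one of `"spike_wave"`, `"rhythmic_sine"`,
#'   `"polyspike_burst"`, `"low_voltage_fast"`, `"evolving_chirp"`
#' @param base_freq_hz dominant frequency in Hz (for the chirp, the onset
#'   frequency; it glides down to `end_freq_hz`)
#' @param freq_range_hz optional length-2 band; each injected seizure
#'   draws its frequency uniformly from it (classes with a band overlap
#'   spectrally, so their spatial profile carries the distinction)
#' @param amplitude_uv RMS amplitude in microvolts at a unit-gain electrode
#' @param spatial_profile named per-electrode gain in `[0, 1]`
#' @param focal logical; focal signatures have gain 1 at `focus_electrode`
#' @param focus_electrode focus label for focal signatures
#' @param end_freq_hz chirp end frequency (ignored otherwise)
#' @export
seizure_signature <- function(label, waveform, base_freq_hz, amplitude_uv,
                              spatial_profile, focal = FALSE,
                              focus_electrode = NULL, end_freq_hz = NULL,
                              freq_range_hz = NULL) {
  stopifnot(label %in% SEIZURE_LABELS,
            waveform %in% c("spike_wave", "rhythmic_sine", "polyspike_burst",
                            "low_voltage_fast", "evolving_chirp"),
            base_freq_hz > 0, amplitude_uv >= 0)
  if (!is.null(freq_range_hz))
    stopifnot(length(freq_range_hz) == 2L,
              base_freq_hz >= freq_range_hz[1L],
              base_freq_hz <= freq_range_hz[2L])
  if (focal) {
    stopifnot(!is.null(focus_electrode),
              abs(spatial_profile[[focus_electrode]] - 1) < 1e-9)
  } else {
    stopifnot(all(spatial_profile >= 0.7 - 1e-9))
  }
  structure(list(label = label, waveform = waveform,
                 base_freq_hz = base_freq_hz, amplitude_uv = amplitude_uv,
                 spatial_profile = spatial_profile, focal = focal,
                 focus_electrode = focus_electrode,
                 end_freq_hz = end_freq_hz,
                 freq_range_hz = freq_range_hz),
            class = "seizure_signature")
}

.focal_profile <- function(m, focus, width = 0.40) {
  d <- scalp_distance(m, from = m$names, to = focus)[, 1L]
  g <- exp(-d^2 / (2 * width^2))
  g / max(g)
}

.emphasis_profile <- function(m, peaks, floor = 0.7, width = 0.8) {
  d <- scalp_distance(m, from = m$names, to = peaks)
  g <- apply(exp(-d^2 / (2 * width^2)), 1L, max)
  floor + (1 - floor) * g / max(g)
}

#' Default signature table for the eight seizure types
#'
#' One signature per label, pairwise distinguishable in the combination of
#' frequency band, spatial profile and envelope: absz is a generalized
#' 3 Hz spike-wave with fronto-parietal midline (Fz/Pz) emphasis; gnsz a
#' generalized 2-5 Hz rhythmic sine with a flat profile; mysz generalized
#' polyspike bursts (<= 0.5 s); tnsz generalized low-voltage fast activity
#' at 15-25 Hz with fronto-central emphasis; tcsz a generalized
#' high-amplitude chirp gliding from 10 to 3 Hz; fnsz/spsz/cpsz focal
#' rhythmic sines at 4-8 / 6-9 / 4-7 Hz with temporal foci (T3, T4, T5;
#' only T3 belongs to the reduced 8-electrode montage, so montage
#' reduction genuinely costs focal coverage). The focal bands overlap on purpose: within
#' the overlap only the spatial profile separates the classes, so typing
#' genuinely needs scalp coverage (per-seizure frequencies are drawn
#' uniformly from the band at injection time).
#'
#' @param m the recording montage (defaults to the standard 21 electrodes)
#' @return named list of [seizure_signature] objects, one per seizure label
#' @export
default_signatures <- function(m = montage(STANDARD_21)) {
  flat <- stats::setNames(rep(0.85, length(m$names)), m$names)
  sigs <- list(
    fnsz = seizure_signature("fnsz", "rhythmic_sine", 6, 60,
                             .focal_profile(m, "T3"), focal = TRUE,
                             focus_electrode = "T3",
                             freq_range_hz = c(4, 8)),
    gnsz = seizure_signature("gnsz", "rhythmic_sine", 3.5, 70, flat,
                             freq_range_hz = c(2, 5)),
    spsz = seizure_signature("spsz", "rhythmic_sine", 7.5, 55,
                             .focal_profile(m, "T4"), focal = TRUE,
                             focus_electrode = "T4",
                             freq_range_hz = c(6, 9)),
    cpsz = seizure_signature("cpsz", "rhythmic_sine", 5.5, 55,
                             .focal_profile(m, "T5"), focal = TRUE,
                             focus_electrode = "T5",
                             freq_range_hz = c(4, 7)),
    absz = seizure_signature("absz", "spike_wave", 3, 90,
                             .emphasis_profile(m, c("Fz", "Pz"))),
    tnsz = seizure_signature("tnsz", "low_voltage_fast", 20, 35,
                             .emphasis_profile(m, c("Fz", "Cz", "F3", "F4")),
                             freq_range_hz = c(15, 25)),
    tcsz = seizure_signature("tcsz", "evolving_chirp", 10, 110, flat,
                             end_freq_hz = 3),
    mysz = seizure_signature("mysz", "polyspike_burst", 18, 80, flat)
  )
  sigs[SEIZURE_LABELS]
}

# unit-RMS waveform of a signature over duration_s at rate sr
.signature_waveform <- function(sig, duration_s, sr, phase = 0) {
  t <- seq(0, duration_s - 1 / sr, by = 1 / sr)
  f <- sig$base_freq_hz
  w <- switch(sig$waveform,
    spike_wave = {
      # harmonic stack approximating a spike-and-slow-wave complex
      s <- 0
      for (h in 1:4) s <- s + sin(2 * pi * h * f * t + h * phase) / h
      s
    },
    rhythmic_sine = sin(2 * pi * f * t + phase) *
      (1 + 0.2 * sin(2 * pi * 0.5 * t + phase / 2)),
    polyspike_burst = {
      gate <- as.numeric((t %% 1) < 0.4)  # 0.4 s bursts, one per second
      s <- 0
      for (h in 1:3) s <- s + sin(2 * pi * h * f * t + h * phase) / h
      s * gate
    },
    low_voltage_fast = sin(2 * pi * f * t + phase) +
      0.3 * sin(2 * pi * 1.37 * f * t + 2.1 * phase),
    evolving_chirp = {
      f1 <- if (is.null(sig$end_freq_hz)) 3 else sig$end_freq_hz
      inst <- f + (f1 - f) * t / duration_s
      sin(2 * pi * cumsum(inst) / sr + phase)
    })
  ramp_n <- max(1L, round(min(0.5, duration_s / 4) * sr))
  env <- rep(1, length(t))
  up <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
  env[seq_len(ramp_n)] <- up
  env[length(t) + 1L - seq_len(ramp_n)] <- up
  w <- w * env
  rms <- sqrt(mean(w^2))
  if (rms > 0) w / rms else w
}

# pink (1/f amplitude) noise, unit RMS
.pink_noise <- function(n, sr) {
  white <- stats::rnorm(n)
  x <- stats::fft(white)
  f <- c(1, seq_len(n - 1))          # avoid dividing DC by zero
  f <- pmin(f, n - f + 1)            # symmetric frequency index
  shaped <- x / sqrt(f)
  shaped[1] <- 0
  out <- Re(stats::fft(shaped, inverse = TRUE)) / n
  out / sqrt(mean(out^2))
}

#' Generate background EEG
#'
#' Per-channel pink noise (RMS `noise_uv`) plus a posterior-dominant 10 Hz
#' alpha rhythm whose gain decays with scalp distance from the occipital
#' pole (largest at O1/O2). Deterministic for a fixed seed.
#'
#' @param duration_s record length in seconds
#' @param m a [montage]
#' @param background_alpha_uv RMS amplitude of the alpha rhythm at the
#'   occipital pole, microvolts
#' @param noise_uv RMS amplitude of the pink-noise floor, microvolts
#' @param sampling_rate_hz sampling rate, Hz
#' @param seed integer seed (`NULL` to use the current RNG stream)
#' @param subject_id,record_id identifiers
#' @return a [recording]
#' @export
background_eeg <- function(duration_s, m = montage(STANDARD_21),
                           background_alpha_uv = 20, noise_uv = 15,
                           sampling_rate_hz = 250, seed = NULL,
                           subject_id = "s000", record_id = "r000") {
  stopifnot(duration_s > 0)
  with_seed(seed, {
    n <- round(duration_s * sampling_rate_hz)
    nch <- length(m$names)
    t <- seq_len(n) / sampling_rate_hz
    occ <- c(0, -1, 0)  # occipital pole direction
    dot <- pmin(1, pmax(-1, as.vector(m$positions_3d %*% occ)))
    alpha_gain <- exp(-acos(dot)^2 / (2 * 0.7^2))
    dat <- matrix(0, nch, n)
    alpha_mod <- 1 + 0.3 * sin(2 * pi * 0.1 * t + stats::runif(1, 0, 2 * pi))
    for (ch in seq_len(nch)) {
      alpha <- sin(2 * pi * 10 * t + stats::runif(1, 0, 2 * pi)) * alpha_mod
      alpha <- alpha / sqrt(mean(alpha^2))
      dat[ch, ] <- noise_uv * .pink_noise(n, sampling_rate_hz) +
        background_alpha_uv * alpha_gain[ch] * alpha
    }
    recording(dat, m$names, sampling_rate_hz, subject_id, record_id)
  })
}

#' Inject one seizure into a recording
#'
#' Adds the signature waveform, scaled per channel by its spatial profile,
#' to `[start_s, start_s + duration_s)` and appends the matching annotation
#' event. Background outside the interval is untouched. Errors if the
#' interval leaves the record or overlaps an existing seizure event.
#'
#' @param rec a [recording]
#' @param ann an [annotation_set] holding the existing seizure events
#'   (background tiling is recomputed by [tile_background])
#' @param signature a [seizure_signature]
#' @param start_s onset in seconds
#' @param duration_s seizure length in seconds
#' @param seed integer seed for the waveform phase
#' @return `list(recording =, annotations =)` with annotations tiled over
#'   the full record
#' @export
inject_seizure <- function(rec, ann, signature, start_s, duration_s,
                           seed = NULL) {
  stop_s <- start_s + duration_s
  if (start_s < 0 || stop_s > duration_s(rec) + 1e-9)
    stop("seizure interval [", start_s, ", ", stop_s,
         ") is outside the record")
  seiz <- ann[ann$label != "bckg", , drop = FALSE]
  if (nrow(seiz) > 0L &&
      any(pmin(seiz$stop_s, stop_s) - pmax(seiz$start_s, start_s) > 1e-9))
    stop("seizure interval overlaps an existing seizure event")
  sr <- rec$sampling_rate_hz
  with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    if (!is.null(signature$freq_range_hz))
      signature$base_freq_hz <- stats::runif(1, signature$freq_range_hz[1L],
                                             signature$freq_range_hz[2L])
    w <- .signature_waveform(signature, duration_s, sr, phase)
    i0 <- floor(start_s * sr) + 1L
    idx <- i0:(i0 + length(w) - 1L)
    gains <- signature$spatial_profile[rec$channel_names]
    rec$data[, idx] <- rec$data[, idx] +
      signature$amplitude_uv * outer(unname(gains), w)
    events <- rbind(
      data.frame(seiz[, c("start_s", "stop_s", "label", "confidence")]),
      data.frame(start_s = start_s, stop_s = stop_s,
                 label = signature$label, confidence = 1))
    list(recording = rec,
         annotations = tile_background(events, duration_s(rec)))
  })
}

#' Fill gaps between seizure events with background annotations
#'
#' @param events data frame with `start_s`, `stop_s`, `label`, `confidence`
#'   rows for seizures only
#' @param duration_s record duration to tile over
#' @return an [annotation_set] covering `[0, duration_s)` with no gaps
#' @export
tile_background <- function(events, duration_s) {
  events <- events[order(events$start_s), , drop = FALSE]
  starts <- c(); stops <- c(); labels <- c(); confs <- c()
  cursor <- 0
  for (i in seq_len(nrow(events))) {
    if (events$start_s[i] > cursor + 1e-9) {
      starts <- c(starts, cursor); stops <- c(stops, events$start_s[i])
      labels <- c(labels, "bckg"); confs <- c(confs, 1)
    }
    starts <- c(starts, events$start_s[i]); stops <- c(stops, events$stop_s[i])
    labels <- c(labels, events$label[i]); confs <- c(confs, events$confidence[i])
    cursor <- events$stop_s[i]
  }
  if (cursor < duration_s - 1e-9) {
    starts <- c(starts, cursor); stops <- c(stops, duration_s)
    labels <- c(labels, "bckg"); confs <- c(confs, 1)
  }
  annotation_set(starts, stops, labels, confs)
}

#' Cohort generation settings
#'
#' Defaults define the package's reference synthetic cohort: 10 subjects,
#' 180-second records at 250 Hz on the 21-electrode montage, 6 seizures per
#' record of 6-10 s, and a class mix that qualitatively mirrors clinical
#' imbalance (focal and generalized non-specific seizures most frequent).
#'
#' @param n_subjects number of subjects (one record each)
#' @param record_duration_s record length, seconds
#' @param sampling_rate_hz sampling rate, Hz
#' @param seizures_per_record seizures injected per record
#' @param class_mix named probability vector over [SEIZURE_LABELS]; must sum
#'   to one
#' @param background_alpha_uv,noise_uv background amplitudes, microvolts
#' @param seizure_duration_s length-2 range of seizure durations, seconds
#' @param seed integer master seed; all randomness flows from it through
#'   per-subject substreams
#' @export
cohort_config <- function(n_subjects = 10, record_duration_s = 180,
                          sampling_rate_hz = 250, seizures_per_record = 6,
                          class_mix = c(fnsz = 0.22, gnsz = 0.20, spsz = 0.10,
                                        cpsz = 0.16, absz = 0.10, tnsz = 0.08,
                                        tcsz = 0.08, mysz = 0.06),
                          background_alpha_uv = 20, noise_uv = 15,
                          seizure_duration_s = c(6, 10), seed = 1L) {
  stopifnot(n_subjects >= 1, record_duration_s > 0, seizures_per_record >= 0,
            setequal(names(class_mix), SEIZURE_LABELS),
            abs(sum(class_mix) - 1) < 1e-6)
  structure(list(n_subjects = as.integer(n_subjects),
                 record_duration_s = record_duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 seizures_per_record = as.integer(seizures_per_record),
                 class_mix = class_mix[SEIZURE_LABELS],
                 background_alpha_uv = background_alpha_uv,
                 noise_uv = noise_uv,
                 seizure_duration_s = seizure_duration_s,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# place k non-overlapping intervals of the given durations in [0, total)
.place_intervals <- function(durations, total, margin = 1) {
  starts <- numeric(0); stops <- numeric(0)
  for (d in durations) {
    ok <- FALSE
    for (attempt in 1:200) {
      s <- stats::runif(1, 0, total - d)
      conflict <- any(s < stops + margin & (s + d) > starts - margin)
      if (!conflict) { ok <- TRUE; break }
    }
    if (!ok) break
    starts <- c(starts, s); stops <- c(stops, s + d)
  }
  ord <- order(starts)
  cbind(start = starts[ord], stop = stops[ord])
}

#' Generate a synthetic cohort on disk
#'
#' Writes one recording/annotation pair per subject (EDF + TSE by default)
#' plus a JSON manifest listing per-record seizure counts. Reproducible:
#' the master seed spawns one substream per subject.
#'
#' @param cfg a [cohort_config]
#' @param out_dir output directory (created if missing)
#' @param format recording format passed to [write_recording]
#' @param signatures signature table, defaults to [default_signatures]
#' @return the manifest as a list (invisibly also written to
#'   `manifest.json`): fields `records` (paths, seizure counts and labels)
#'   and `config` echo
#' @export
generate_cohort <- function(cfg, out_dir, format = c("edf", "rds"),
                            signatures = NULL) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- montage(STANDARD_21)
  if (is.null(signatures)) signatures <- default_signatures(m)
  sub_seeds <- with_seed(cfg$seed,
                         sample.int(.Machine$integer.max - 1L, cfg$n_subjects))
  records <- vector("list", cfg$n_subjects)
  ext <- if (format == "edf") "edf" else "rds"
  for (i in seq_len(cfg$n_subjects)) {
    sid <- sprintf("s%03d", i)
    rec_ann <- with_seed(sub_seeds[i], {
      rec <- background_eeg(cfg$record_duration_s, m,
                            cfg$background_alpha_uv, cfg$noise_uv,
                            cfg$sampling_rate_hz, seed = NULL,
                            subject_id = sid, record_id = "r001")
      labels <- sample(names(cfg$class_mix), cfg$seizures_per_record,
                       replace = TRUE, prob = cfg$class_mix)
      durs <- stats::runif(cfg$seizures_per_record,
                           cfg$seizure_duration_s[1], cfg$seizure_duration_s[2])
      iv <- .place_intervals(durs, cfg$record_duration_s)
      labels <- labels[seq_len(nrow(iv))]
      ann <- tile_background(
        data.frame(start_s = numeric(), stop_s = numeric(),
                   label = character(), confidence = numeric()),
        cfg$record_duration_s)
      for (j in seq_len(nrow(iv))) {
        out <- inject_seizure(rec, ann, signatures[[labels[j]]],
                              iv[j, "start"], iv[j, "stop"] - iv[j, "start"],
                              seed = NULL)
        rec <- out$recording; ann <- out$annotations
      }
      list(rec = rec, ann = ann, labels = labels)
    })
    rec_path <- file.path(out_dir, sprintf("%s.%s", sid, ext))
    ann_path <- file.path(out_dir, sprintf("%s.tse", sid))
    write_recording(rec_ann$rec, rec_path, format)
    write_tse(rec_ann$ann, ann_path)
    records[[i]] <- list(subject_id = sid, recording = basename(rec_path),
                         annotation = basename(ann_path),
                         format = format,
                         n_seizures = length(rec_ann$labels),
                         seizure_labels = as.list(rec_ann$labels))
  }
  manifest <- list(records = records,
                   sampling_rate_hz = cfg$sampling_rate_hz,
                   montage = m$names, seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Matched-filter oracle classifier for synthetic seizure windows
#'
#' A Bayes-style reference classifier that never sees training data: it
#' knows the generative model instead. Each class's expected channels x
#' frequencies power pattern is obtained by pushing the known unit-RMS
#' signature waveform through the same full-window periodogram as the
#' data (per 1-second position within the seizure, so evolving chirps get
#' one template per sweep position) and scaling by the signature's
#' amplitude and squared spatial gains. The expected background spectrum
#' (pink noise plus the posterior alpha bump) is regressed out of each
#' window's periodogram and the class with the nearest expected pattern
#' (least squares) wins. Used to certify that the generated learning task
#' is solvable, and as an independent check on trained models.
#'
#' @param windows list of labeled windows (see [extract_windows]) or a
#'   single window
#' @param signatures signature table from [default_signatures]
#' @param channel_names electrode labels of the window rows
#' @param sampling_rate_hz window sampling rate
#' @param noise_uv,alpha_uv background amplitudes assumed by the oracle
#'   (defaults match [cohort_config])
#' @return character vector of predicted seizure labels
#' @export
oracle_classify <- function(windows, signatures, channel_names,
                            sampling_rate_hz = 250, noise_uv = 15,
                            alpha_uv = 20) {
  if (!is.null(windows$data)) windows <- list(windows)
  sr <- sampling_rate_hz
  ns <- ncol(windows[[1L]]$data)
  nb <- floor(ns / 2) + 1L
  freqs <- seq(0, floor(ns / 2)) * sr / ns
  lowcut <- freqs < 1.5                 # drop drift/DC bins
  pspec <- function(mat) {              # channels x samples -> power units
    X <- t(stats::mvfft(t(mat)))
    p <- 2 * Mod(X[, seq_len(nb), drop = FALSE])^2 / ns^2
    p[, lowcut] <- 0
    p
  }
  pos3 <- montage(channel_names)$positions_3d
  dot <- pmax(pmin(as.vector(pos3 %*% c(0, -1, 0)), 1), -1)
  alpha_gain <- exp(-acos(dot)^2 / (2 * 0.7^2))
  pinkshape <- 1 / pmax(freqs, freqs[2L]); pinkshape[lowcut] <- 0
  pinkshape <- pinkshape / sum(pinkshape)
  alphashape <- exp(-(freqs - 10)^2 / (2 * 0.8^2))
  alphashape <- alphashape / sum(alphashape)
  bg_shape <- noise_uv^2 * outer(rep(1, length(channel_names)), pinkshape) +
    alpha_uv^2 * outer(alpha_gain^2, alphashape)
  win_s <- ns / sr
  templates <- lapply(signatures, function(sig) {
    D <- 8; phases <- c(0, pi / 3, 2 * pi / 3)
    n_pos <- floor(D / win_s)
    freqs_of <- if (is.null(sig$freq_range_hz)) sig$base_freq_hz
      else seq(sig$freq_range_hz[1L], sig$freq_range_hz[2L],
               length.out = 9L)   # ~0.4 Hz grid over the class band
    gains2 <- (sig$amplitude_uv * sig$spatial_profile[channel_names])^2
    out <- list()
    for (f in freqs_of) {
      sig$base_freq_hz <- f
      for (pos in seq_len(n_pos)) {
        sp <- 0
        for (ph in phases) {
          w <- .signature_waveform(sig, D, sr, ph)
          seg <- w[((pos - 1L) * ns + 1L):(pos * ns)]
          sp <- sp + pspec(matrix(seg, 1L))[1L, ]
        }
        base <- outer(unname(gains2), sp / length(phases))
        # full-amplitude template plus reduced variants for windows that
        # straddle the onset/offset ramps of the injected envelope
        for (a in c(1, 0.6, 0.35))
          out[[length(out) + 1L]] <- a * base
      }
    }
    out
  })
  vapply(windows, function(w) {
    p <- pspec(w$data)
    lam <- max(0, sum(p * bg_shape) / sum(bg_shape^2))
    res <- pmax(p - lam * bg_shape, 0)
    scores <- vapply(templates, function(tset)
      max(vapply(tset, function(E) -sum((res - E)^2), numeric(1))),
      numeric(1))
    names(templates)[which.max(scores)]
  }, character(1))
}
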