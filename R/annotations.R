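#' Seizure-type label vocabulary
#'
#' The eight seizure type codes plus `bckg` (background, non-seizure):
#' fnsz (focal non-specific), gnsz (generalized non-specific), spsz (simple
#' partial), cpsz (complex partial), absz (absence), tnsz (tonic), tcsz
#' (tonic-clonic), mysz (myoclonic).
#' @export
SEIZURE_LABELS <- c("fnsz", "gnsz", "spsz", "cpsz", "absz", "tnsz", "tcsz", "mysz")

#' @rdname SEIZURE_LABELS
#' @export
ANNOTATION_LABELS <- c("bckg", SEIZURE_LABELS)

#' Build an annotation set of labeled time intervals
#'
#' Intervals are half-open `[start_s, stop_s)` in seconds from record start.
#' Events are sorted by start and must not overlap.
#'
#' @param start_s,stop_s numeric vectors of interval bounds (seconds)
#' @param label character vector of labels from [ANNOTATION_LABELS]
#' @param confidence numeric in `[0, 1]`, recycled
#' @return an `annotation_set`: a data frame with columns
#'   `start_s`, `stop_s`, `label`, `confidence`
#' @export
annotation_set <- function(start_s = numeric(), stop_s = numeric(),
                           label = character(), confidence = 1) {
  n <- length(start_s)
  ev <- data.frame(start_s = as.numeric(start_s), stop_s = as.numeric(stop_s),
                   label = as.character(label),
                   confidence = rep_len(as.numeric(confidence), n))
  bad <- setdiff(ev$label, ANNOTATION_LABELS)
  if (length(bad) > 0L)
    stop("unknown annotation label(s): ", paste(unique(bad), collapse = ", "))
  if (any(ev$start_s >= ev$stop_s))
    stop("every event must satisfy start_s < stop_s")
  if (any(ev$start_s < 0)) stop("start_s must be nonnegative")
  ev <- ev[order(ev$start_s), , drop = FALSE]
  if (n > 1L && any(ev$stop_s[-n] > ev$start_s[-1L] + 1e-9))
    stop("annotation events overlap")
  rownames(ev) <- NULL
  class(ev) <- c("annotation_set", "data.frame")
  ev
}

#' Parse a TSE-dialect annotation file
#'
#' The dialect is a header line `version = tse_v1.0.0` followed by
#' whitespace-separated `start stop label confidence` lines with seconds to
#' four decimals. Blank lines are ignored. Events are returned sorted;
#' overlapping events or labels outside the vocabulary raise errors naming
#' the offending line.
#'
#' @param path file path
#' @return an [annotation_set]
#' @export
parse_tse <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty TSE file: ", path)
  if (!grepl("^\\s*version\\s*=\\s*tse", lines[1L]))
    stop("missing TSE version header in ", path)
  body <- lines[-1L]
  keep <- which(nzchar(trimws(body)))
  if (length(keep) == 0L) return(annotation_set())
  parts <- strsplit(trimws(body[keep]), "\\s+")
  nf <- lengths(parts)
  if (any(nf != 4L))
    stop("malformed TSE line(s) ", paste(keep[nf != 4L] + 1L, collapse = ", "),
         " in ", path, " (expected: start stop label confidence)")
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.numeric(m[, 1L]))
  stop_ <- suppressWarnings(as.numeric(m[, 2L]))
  conf <- suppressWarnings(as.numeric(m[, 3L + 1L]))
  if (anyNA(start) || anyNA(stop_) || anyNA(conf))
    stop("non-numeric field in TSE file ", path)
  bad <- !(m[, 3L] %in% ANNOTATION_LABELS)
  if (any(bad))
    stop("unknown label(s) in ", path, ": ",
         paste(unique(m[bad, 3L]), collapse = ", "),
         " (line(s) ", paste(keep[bad] + 1L, collapse = ", "), ")")
  ord <- order(start)
  n <- length(ord)
  if (n > 1L) {
    s <- start[ord]; e <- stop_[ord]
    ov <- which(e[-n] > s[-1L] + 1e-9)
    if (length(ov) > 0L)
      stop("overlapping events in ", path, " (lines ",
           paste(keep[ord[ov]] + 1L, collapse = ", "), " and following)")
  }
  annotation_set(start, stop_, m[, 3L], conf)
}

#' Write an annotation set in the TSE dialect
#'
#' @param ann an [annotation_set]
#' @param path output file path
#' @export
write_tse <- function(ann, path) {
  lines <- c("version = tse_v1.0.0",
             sprintf("%.4f %.4f %s %.4f", ann$start_s, ann$stop_s,
                     ann$label, ann$confidence))
  writeLines(lines, path)
  invisible(path)
}

#' Majority-overlap label of a query interval
#'
#' Returns the label of the event with the largest overlap with the
#' half-open query `[t0, t1)`. Ties are broken in favor of a non-background
#' (seizure) label, which maximizes seizure sensitivity at annotation
#' boundaries; remaining ties go to the earlier event. If no event overlaps
#' the query, the sentinel `"unlabeled"` is returned.
#'
#' @param ann an [annotation_set]
#' @param t0,t1 query interval bounds in seconds, `t0 < t1`
#' @return a single label string
#' @export
label_at <- function(ann, t0, t1) {
  if (t0 >= t1) stop("label_at requires t0 < t1")
  ov <- pmin(ann$stop_s, t1) - pmax(ann$start_s, t0)
  ov[ov < 0] <- 0
  if (length(ov) == 0L || max(ov) <= 0) return("unlabeled")
  cand <- which(ov > max(ov) - 1e-9)
  if (length(cand) > 1L) {
    sz <- cand[ann$label[cand] != "bckg"]
    if (length(sz) > 0L) cand <- sz
  }
  ann$label[cand[1L]]
}

#' Total span covered by an annotation set
#' @param ann an [annotation_set]
#' @export
annotation_span <- function(ann) {
  if (nrow(ann) == 0L) return(0)
  max(ann$stop_s)
}
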