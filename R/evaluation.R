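#' Performance metrics and montage comparison statistics
#'
#' Binary detection is summarized by sensitivity (Sn, seizure recall),
#' specificity (Sp), precision and F1; multigroup classification by
#' per-class one-vs-rest precision/recall/F1/accuracy with unweighted
#' macro averages. Metrics with a zero denominator are reported as `NA`
#' (an explicit undefined marker), never silently zero. Montage
#' comparisons use Welch's t-test, the Mann-Whitney U test, and the
#' D'Agostino-Pearson omnibus normality test on the per-fold metric
#' values.
#'
#' @name evaluation
NULL

#' Confusion matrix with row normalization
#'
#' @param y_true,y_pred character vectors of equal length
#' @param labels class vocabulary fixing the row/column order; values
#'   outside it raise an error
#' @return list with `counts` (true class in rows, predicted in columns)
#'   and `normalized` (rows sum to 1; all-zero rows for absent classes)
#' @export
confusion_matrix <- function(y_true, y_pred, labels = sort(unique(c(y_true, y_pred)))) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred differ in length")
  bad <- setdiff(unique(c(y_true, y_pred)), labels)
  if (length(bad) > 0L)
    stop("label(s) outside the vocabulary: ", paste(bad, collapse = ", "))
  counts <- table(factor(y_true, levels = labels),
                  factor(y_pred, levels = labels))
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(true = labels, predicted = labels))
  rs <- rowSums(counts)
  normalized <- counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, normalized = normalized)
}

#' Binary detection metrics from a 2x2 confusion matrix
#'
#' The positive (seizure) class must be named; by convention it is the
#' second row/column of matrices built from `c("bckg", "seiz")` labels.
#'
#' @param confusion 2x2 counts matrix (true in rows)
#' @param positive name or index of the positive class
#' @return tibble with sensitivity, specificity, precision, recall, f1
#'   and accuracy; undefined metrics (zero denominator) are `NA`
#' @export
binary_metrics <- function(confusion, positive = 2L) {
  counts <- if (is.list(confusion)) confusion$counts else confusion
  stopifnot(all(dim(counts) == c(2L, 2L)))
  pos <- if (is.character(positive)) match(positive, rownames(counts))
    else as.integer(positive)
  neg <- 3L - pos
  tp <- counts[pos, pos]; fn <- counts[pos, neg]
  tn <- counts[neg, neg]; fp <- counts[neg, pos]
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sn <- div(tp, tp + fn)
  sp <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sn) || prec + sn == 0) NA_real_
    else 2 * prec * sn / (prec + sn)
  tibble::tibble(sensitivity = sn, specificity = sp, precision = prec,
                 recall = sn, f1 = f1,
                 accuracy = div(tp + tn, sum(counts)))
}

#' Multigroup metrics from a K x K confusion matrix
#'
#' @param confusion K x K counts matrix (true in rows) or the list
#'   returned by [confusion_matrix]
#' @return list with `per_class` (tibble: one-vs-rest precision, recall,
#'   F1, accuracy, and diagonal recall as `recall`, per class) and
#'   `macro` (tibble of unweighted means across classes)
#' @export
multigroup_metrics <- function(confusion) {
  counts <- if (is.list(confusion)) confusion$counts else confusion
  K <- nrow(counts)
  stopifnot(K >= 2L, ncol(counts) == K)
  total <- sum(counts)
  div <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  tp <- unname(diag(counts))
  fn <- unname(rowSums(counts)) - tp
  fp <- unname(colSums(counts)) - tp
  tn <- total - tp - fn - fp
  prec <- div(tp, tp + fp)
  rec <- div(tp, tp + fn)
  f1 <- ifelse(is.na(prec) | is.na(rec) | (prec + rec) == 0, NA_real_,
               2 * prec * rec / (prec + rec))
  # one-vs-rest accuracy per class
  acc <- if (total == 0) rep(NA_real_, K) else (tp + tn) / total
  per_class <- tibble::tibble(class = rownames(counts),
                              precision = prec, recall = rec, f1 = f1,
                              accuracy = acc)
  macro <- tibble::tibble(precision = mean(prec, na.rm = TRUE),
                          recall = mean(rec, na.rm = TRUE),
                          f1 = mean(f1, na.rm = TRUE),
                          accuracy = mean(acc, na.rm = TRUE))
  list(per_class = per_class, macro = macro)
}

#' Summarize per-fold metric values
#'
#' @param fold_metrics tibble/data frame with one row per fold and one
#'   column per metric
#' @return list with `summary` (tibble: metric, mean, sd, k) and `raw`
#' @export
fold_summary <- function(fold_metrics) {
  fm <- as.data.frame(fold_metrics)
  num <- vapply(fm, is.numeric, logical(1))
  fm <- fm[, num, drop = FALSE]
  summary <- tibble::tibble(
    metric = names(fm),
    mean = unname(vapply(fm, function(v) mean(v, na.rm = TRUE), numeric(1))),
    sd = unname(vapply(fm, function(v) stats::sd(v, na.rm = TRUE),
                       numeric(1))),
    k = unname(vapply(fm, function(v) sum(!is.na(v)), numeric(1))))
  list(summary = summary, raw = tibble::as_tibble(fold_metrics))
}

# D'Agostino-Pearson omnibus K^2 normality test (skewness and kurtosis
# z-statistics combined, chi-squared with 2 df); requires n >= 8
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 8L) {
    warning("D'Agostino-Pearson test needs n >= 8 (got ", n, "); skipped")
    return(list(statistic = NA_real_, p_value = NA_real_))
  }
  m <- mean(x)
  s2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / s2^1.5
  g2 <- mean((x - m)^4) / s2^2 - 3
  # skewness z (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zg1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  # kurtosis z (Anscombe & Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 + 3 - Eb2) / sqrt(Vb2)
  beta <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta * (2 / beta + sqrt(1 + 4 / beta^2))
  Zg2 <- ((1 - 2 / (9 * A)) -
            ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- Zg1^2 + Zg2^2
  list(statistic = K2, p_value = stats::pchisq(K2, df = 2, lower.tail = FALSE))
}

#' Statistical comparison of two montages' per-fold metrics
#'
#' @param values_a,values_b numeric vectors (k per-fold values each)
#' @return tibble with two-sided Welch t and Mann-Whitney U p-values, the
#'   test statistics, and per-sample normality p-values (`NA` with a
#'   warning below the normality test's minimum n of 8)
#' @export
compare_montages <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 3L, length(values_b) >= 3L)
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    welch <- list(statistic = 0, p.value = 1)
  } else {
    welch <- stats::t.test(values_a, values_b, var.equal = FALSE)
  }
  mw <- suppressWarnings(stats::wilcox.test(values_a, values_b, exact = FALSE))
  na <- dagostino_pearson(values_a)
  nb <- dagostino_pearson(values_b)
  tibble::tibble(
    welch_t = unname(welch$statistic), welch_p = welch$p.value,
    mann_whitney_u = unname(mw$statistic), mann_whitney_p = mw$p.value,
    normality_p_a = na$p_value, normality_p_b = nb$p_value)
}

#' Heatmap of a (normalized) confusion matrix
#'
#' @param cm output of [confusion_matrix]
#' @param normalized plot row-normalized proportions instead of counts
#' @return a ggplot object
#' @export
plot_confusion <- function(cm, normalized = TRUE) {
  m <- if (normalized) cm$normalized else cm$counts
  df <- expand.grid(true = rownames(m), predicted = colnames(m))
  df$value <- as.vector(m)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$value, 2)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::scale_y_discrete(limits = rev(rownames(m))) +
    ggplot2::labs(x = "predicted", y = "true",
                  fill = if (normalized) "proportion" else "count") +
    ggplot2::theme_minimal()
}
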