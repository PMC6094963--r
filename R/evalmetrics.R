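#' Precision, recall and F-measure from counts
#'
#' Precision is TP/(TP+FP), the share of predicted instances that are
#' correct; recall is TP/(TP+FN), the share of expected instances that are
#' found; F is their harmonic mean. Degenerate denominators (0/0) return 0
#' with a `degenerate` attribute rather than an error, since empty folds do
#' occur in small cross-validation splits.
#'
#' @param tp,fp,fn non-negative integer counts.
#' @return a number in `[0, 1]`.
#' @export
precision <- function(tp, fp) {
  check_counts(tp, fp)
  if (tp + fp == 0) return(structure(0, degenerate = TRUE))
  tp / (tp + fp)
}

#' @rdname precision
#' @export
recall <- function(tp, fn) {
  check_counts(tp, fn)
  if (tp + fn == 0) return(structure(0, degenerate = TRUE))
  tp / (tp + fn)
}

#' @rdname precision
#' @param p,r precision and recall, both in `[0, 1]`.
#' @export
f_measure <- function(p, r) {
  if (!is.numeric(p) || !is.numeric(r) || any(p < 0 | p > 1) || any(r < 0 | r > 1))
    abort("`p` and `r` must be in [0, 1]")
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

check_counts <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)) || any(vals < 0))
    abort("counts must be non-negative finite numbers")
  invisible(TRUE)
}

#' Macro average of per-class scores
#'
#' Unweighted mean of per-class precision and recall across categories; the
#' averaged F is recomputed as the harmonic mean of the averaged precision
#' and recall.
#'
#' @param per_class a tibble/data.frame with columns `precision` and
#'   `recall` (one row per class), or a named list of such rows.
#' @return list with `precision`, `recall`, `f`.
#' @export
macro_average <- function(per_class) {
  if (is.list(per_class) && !is.data.frame(per_class))
    per_class <- dplyr::bind_rows(per_class)
  if (!nrow(per_class)) abort("`per_class` must contain at least one class")
  p <- mean(per_class$precision)
  r <- mean(per_class$recall)
  list(precision = p, recall = r, f = f_measure(p, r))
}

#' Build a score report from pooled counts
#'
#' @param tp,fp,fn pooled counts over (unit, code) or (message, class) pairs.
#' @param per_class optional tibble with columns `class`, `tp`, `fp`, `fn`;
#'   per-class precision/recall/F and their macro average are derived.
#' @return object of class `score_report`.
#' @export
score_report <- function(tp, fp, fn, per_class = NULL) {
  check_counts(tp, fp, fn)
  rep <- list(
    tp = tp, fp = fp, fn = fn,
    precision = as.numeric(precision(tp, fp)),
    recall = as.numeric(recall(tp, fn))
  )
  rep$f <- f_measure(rep$precision, rep$recall)
  if (!is.null(per_class) && nrow(per_class)) {
    per_class$precision <- mapply(function(a, b) as.numeric(precision(a, b)),
                                  per_class$tp, per_class$fp)
    per_class$recall <- mapply(function(a, b) as.numeric(recall(a, b)),
                               per_class$tp, per_class$fn)
    per_class$f <- f_measure(per_class$precision, per_class$recall)
    rep$per_class <- tibble::as_tibble(per_class)
    rep$macro <- macro_average(per_class)
  }
  structure(rep, class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("<score_report> TP=%d FP=%d FN=%d  P=%.3f R=%.3f F=%.3f\n",
              x$tp, x$fp, x$fn,
              round_half_up(x$precision), round_half_up(x$recall),
              round_half_up(x$f)))
  if (!is.null(x$macro))
    cat(sprintf("  macro: P=%.3f R=%.3f F=%.3f over %d classes\n",
                round_half_up(x$macro$precision), round_half_up(x$macro$recall),
                round_half_up(x$macro$f), nrow(x$per_class)))
  invisible(x)
}

#' Confusion matrix between two annotations
#'
#' @param a,b vectors of labels (annotator/classifier A and B/reference).
#' @param labels optional ordered label set; defaults to the sorted union.
#' @return square count matrix, rows = `a`, columns = `b`.
#' @export
confusion_matrix <- function(a, b, labels = NULL) {
  stopifnot(length(a) == length(b))
  labels <- labels %||% sort(unique(c(as.character(a), as.character(b))))
  as.matrix(table(factor(a, levels = labels), factor(b, levels = labels)))
}

#' Cohen's kappa with Landis-Koch interpretation
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e), where p_o is
#' the observed agreement (trace/total) and p_e the chance agreement from
#' the row/column marginals. The band follows the Landis-Koch cut-points,
#' closed on the upper end: <= 0 none; (0, 0.20] none-to-slight; (0.20,
#' 0.40] fair; (0.40, 0.60] moderate; (0.60, 0.80] substantial; (0.80, 1]
#' almost-perfect.
#'
#' @param m a square confusion matrix with positive total count.
#' @return object of class `kappa_result`: list with `kappa`, `band`, `p_o`,
#'   `p_e` and `undefined` (TRUE when p_e = 1, i.e. perfectly skewed
#'   marginals).
#' @export
cohen_kappa <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort("confusion matrix must be square")
  if (any(m < 0)) abort("counts must be non-negative")
  total <- sum(m)
  if (total <= 0) abort("total count must be positive")
  p_o <- sum(diag(m)) / total
  p_e <- sum(rowSums(m) * colSums(m)) / total^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) {
    return(structure(list(kappa = NA_real_, band = NA_character_,
                          p_o = p_o, p_e = p_e, undefined = TRUE),
                     class = "kappa_result"))
  }
  k <- (p_o - p_e) / (1 - p_e)
  structure(list(kappa = k, band = kappa_band(k), p_o = p_o, p_e = p_e,
                 undefined = FALSE),
            class = "kappa_result")
}

#' @rdname cohen_kappa
#' @param kappa a kappa value (<= 1).
#' @export
kappa_band <- function(kappa) {
  stopifnot(is.numeric(kappa), length(kappa) == 1, kappa <= 1 + 1e-12)
  if (kappa <= 0) "none"
  else if (kappa <= 0.20) "none-to-slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "almost-perfect"
}

#' @export
print.kappa_result <- function(x, ...) {
  if (isTRUE(x$undefined))
    cat("<kappa_result> undefined (chance agreement = 1)\n")
  else
    cat(sprintf("<kappa_result> kappa=%.3f (%s agreement)\n",
                round_half_up(x$kappa), x$band))
  invisible(x)
}

#' Score-report JSON serialization
#'
#' @param report a `score_report` (or named list of them).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass_reports(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_reports <- function(x) {
  if (inherits(x, "score_report")) {
    x <- unclass(x)
    if (!is.null(x$per_class)) x$per_class <- as.data.frame(x$per_class)
    x
  } else if (is.list(x)) lapply(x, unclass_reports) else x
}

#' Plain-text table of indexing results
#'
#' One row per (lexicon, level) with TP and 3-decimal precision, recall and
#' F, the layout used to compare indexing lexica side by side.
#'
#' @param reports named list: for each lexicon name, a list of
#'   `score_report`s keyed by level (`message`, `sentence`).
#' @return tibble with columns `lexicon`, `level`, `tp`, `p`, `r`, `f`.
#' @export
indexing_report_table <- function(reports) {
  rows <- purrr::imap(reports, function(by_level, lex) {
    purrr::imap(by_level, function(rep, level) {
      tibble::tibble(lexicon = lex, level = level, tp = rep$tp,
                     p = round_half_up(rep$precision),
                     r = round_half_up(rep$recall),
                     f = round_half_up(rep$f))
    })
  })
  dplyr::bind_rows(purrr::flatten(rows))
}
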