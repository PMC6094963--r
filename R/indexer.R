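#' Index units with disorder codes by lexicon matching
#'
#' A unit is indexed with a code when some lexicon term for that code occurs
#' in the unit as a contiguous token sequence; at each position a term token
#' may match either the unit's surface token or its lemma (exact match after
#' normalization, no fuzzy matching). All matches are recorded as spans
#' (0-based, half-open token offsets); overlapping matches are all kept,
#' since the prediction is a set of codes.
#'
#' @param units preprocessed units from [process_corpus()].
#' @param lex a `misuse_lexicon`.
#' @param level `"message"`, `"sentence"` or `"both"`: which unit granularity
#'   to index.
#' @return tibble with columns `unit_id`, `message_id`, `level`, `position`,
#'   `codes` (list of character vectors) and `spans` (list of tibbles with
#'   `term`, `code`, `start`, `end`).
#' @export
index_units <- function(units, lex, level = c("both", "message", "sentence")) {
  level <- match.arg(level)
  if (level != "both") units <- units[units$unit_kind == level, ]
  entries <- dplyr::distinct(tibble::as_tibble(lex)[, c("term", "code")])
  term_toks <- lapply(gsub("_", " ", entries$term, fixed = TRUE), tokenize)
  keep <- lengths(term_toks) > 0
  entries <- entries[keep, ]
  term_toks <- term_toks[keep]
  # first-token dispatch table
  first <- vapply(term_toks, `[`, character(1), 1)
  by_first <- split(seq_along(term_toks), first)

  res_codes <- vector("list", nrow(units))
  res_spans <- vector("list", nrow(units))
  empty_spans <- tibble::tibble(term = character(0), code = character(0),
                                start = integer(0), end = integer(0))
  for (u in seq_len(nrow(units))) {
    toks <- units$tokens[[u]]
    lems <- units$lemmas[[u]]
    n <- length(toks)
    hits <- list()
    for (pos in seq_len(n)) {
      cand <- c(by_first[[toks[pos]]], by_first[[lems[pos]]])
      if (!length(cand)) next
      for (e in unique(cand)) {
        tt <- term_toks[[e]]
        len <- length(tt)
        if (pos + len - 1L > n) next
        seg_t <- toks[pos:(pos + len - 1L)]
        seg_l <- lems[pos:(pos + len - 1L)]
        if (all(tt == seg_t | tt == seg_l)) {
          hits[[length(hits) + 1L]] <- list(term = entries$term[e],
                                            code = entries$code[e],
                                            start = pos - 1L,
                                            end = pos - 1L + len)
        }
      }
    }
    if (length(hits)) {
      spans <- tibble::tibble(
        term = vapply(hits, `[[`, character(1), "term"),
        code = vapply(hits, `[[`, character(1), "code"),
        start = vapply(hits, `[[`, integer(1), "start"),
        end = vapply(hits, `[[`, integer(1), "end")
      )
      res_spans[[u]] <- spans
      res_codes[[u]] <- sort(unique(spans$code))
    } else {
      res_spans[[u]] <- empty_spans
      res_codes[[u]] <- character(0)
    }
  }
  tibble::tibble(
    unit_id = units$unit_id,
    message_id = units$message_id,
    level = units$unit_kind,
    position = units$position,
    codes = res_codes,
    spans = res_spans
  )
}

#' Evaluate index assignments against a reference indexing
#'
#' Accumulates TP/FP/FN over (unit, code) pairs — pooled micro-counting —
#' and derives precision, recall and F. A per-code breakdown with its macro
#' average is included.
#'
#' @param pred tibble from [index_units()] (columns `unit_id`, `codes`).
#' @param gold reference indexing: tibble with columns `unit_id` and `codes`
#'   (list of character vectors); must cover exactly the predicted unit ids
#'   at the evaluated level.
#' @param level evaluate `"message"` or `"sentence"` units (ignored when
#'   `pred` has no `level` column).
#' @return a `score_report`.
#' @export
evaluate_indexing <- function(pred, gold, level = NULL) {
  if (!is.null(level) && "level" %in% names(pred))
    pred <- pred[pred$level == level, ]
  if (!setequal(pred$unit_id, gold$unit_id))
    abort("unit ids of predictions and reference do not align")
  g <- gold$codes[match(pred$unit_id, gold$unit_id)]
  per_unit <- purrr::map2(pred$codes, g, function(p, gg) {
    p <- unique(as.character(p)); gg <- unique(as.character(gg))
    c(tp = length(intersect(p, gg)),
      fp = length(setdiff(p, gg)),
      fn = length(setdiff(gg, p)))
  })
  counts <- Reduce(`+`, per_unit, accumulate = FALSE)
  codes <- sort(unique(c(unlist(pred$codes), unlist(g))))
  per_class <- NULL
  # per-code counts (pooled over units)
  if (length(codes)) {
    tab <- vapply(codes, function(cc) {
      inp <- vapply(pred$codes, function(p) cc %in% p, logical(1))
      ing <- vapply(g, function(p) cc %in% p, logical(1))
      c(tp = sum(inp & ing), fp = sum(inp & !ing), fn = sum(!inp & ing))
    }, numeric(3))
    per_class <- tibble::tibble(class = codes,
                                tp = tab["tp", ], fp = tab["fp", ], fn = tab["fn", ])
  }
  score_report(tp = unname(counts["tp"]), fp = unname(counts["fp"]),
               fn = unname(counts["fn"]), per_class = per_class)
}

#' Reference indexing from gold annotations
#'
#' Convenience constructor: a tibble `unit_id` -> gold code set.
#'
#' @param unit_id character vector of unit ids.
#' @param codes list of character vectors (gold codes per unit).
#' @return tibble usable as the `gold` argument of [evaluate_indexing()].
#' @export
reference_indexing <- function(unit_id, codes) {
  stopifnot(length(unit_id) == length(codes))
  tibble::tibble(unit_id = as.character(unit_id), codes = codes)
}
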