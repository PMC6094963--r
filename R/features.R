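#' ATC therapeutic class of a drug code
#'
#' The first three characters of an ATC code define its therapeutic class
#' (G03 sexual hormones, N06 antidepressants, ...). The class is returned as
#' a reserved feature token (`ATC_G03`) that normalization can never
#' produce, so code features cannot collide with corpus words.
#'
#' @param code ATC code string(s), at least 3 characters.
#' @return character vector of `ATC_*` class tokens.
#' @examples
#' atc_class("G03CA03")  # "ATC_G03"
#' @export
atc_class <- function(code) {
  code <- as.character(code)
  if (any(is.na(code) | nchar(code) < 3))
    abort("ATC codes must have at least 3 characters")
  paste0("ATC_", toupper(substr(code, 1, 3)))
}

#' Reserved token for an ICD-10 group code
#'
#' @param code ICD-10-style code string(s) (e.g. "F41" or "F40.0"); dots and
#'   other punctuation are removed.
#' @return character vector of `ICD_*` tokens.
#' @export
icd_token <- function(code) {
  code <- toupper(gsub("[^A-Za-z0-9]", "", as.character(code)))
  if (any(!nzchar(code))) abort("empty ICD code")
  paste0("ICD_", code)
}

#' Entity spans
#'
#' Constructor for drug/disorder mention spans within a message, with
#' 0-based half-open token offsets.
#'
#' @param message_id,start,end,kind,surface,code equal-length vectors; `kind`
#'   is `"drug"` or `"disorder"`; `code` is the full ATC code for drugs and
#'   the ICD-10 group for disorders.
#' @return tibble of spans.
#' @export
entity_spans <- function(message_id, start, end, kind, surface, code) {
  stopifnot(all(kind %in% c("drug", "disorder")), all(end >= start))
  tibble::tibble(message_id = as.character(message_id),
                 start = as.integer(start), end = as.integer(end),
                 kind = as.character(kind), surface = as.character(surface),
                 code = as.character(code))
}

#' Vectorize lemmatized units into token-count documents
#'
#' One bag-of-lemmas count document per message. The vocabulary is the set
#' of lemmas with corpus frequency at least `min_token_freq` (default 1,
#' keeping all words); reserved code tokens already present in the token
#' stream are counted like any token.
#'
#' @param units preprocessed units from [process_corpus()]; message-level
#'   rows are used (sentence-level rows are ignored).
#' @param min_token_freq minimum corpus frequency for a lemma to enter the
#'   vocabulary.
#' @param binary count each term once per document instead of its frequency?
#' @return named list (by message id) of named numeric count vectors.
#' @export
vectorize <- function(units, min_token_freq = 1, binary = FALSE) {
  msg <- units[units$unit_kind == "message", ]
  freq <- table(unlist(msg$lemmas, use.names = FALSE))
  vocab <- names(freq)[freq >= min_token_freq]
  docs <- lapply(msg$lemmas, function(l) {
    l <- l[l %in% vocab]
    if (!length(l)) return(setNames(numeric(0), character(0)))
    counts <- table(l)
    out <- as.numeric(counts)
    if (binary) out <- as.numeric(out > 0)
    setNames(out, names(counts))
  })
  names(docs) <- msg$message_id
  docs
}

#' Augment a count document with entity code features
#'
#' Appends reserved code tokens with their mention counts according to the
#' featureset: `drugs` adds one `ATC_*` class token per drug span,
#' `disorders` adds one `ICD_*` token per disorder span, `drugs+disorders`
#' adds both, and `text` leaves the document unchanged. Existing text counts
#' are never modified.
#'
#' @param doc named numeric count vector (one document).
#' @param spans entity spans of the document's message.
#' @param featureset one of `"text"`, `"drugs"`, `"disorders"`,
#'   `"drugs+disorders"`.
#' @return the augmented count vector.
#' @export
augment_with_codes <- function(doc, spans,
                               featureset = c("text", "drugs", "disorders", "drugs+disorders")) {
  featureset <- match.arg(featureset)
  if (featureset == "text" || is.null(spans) || !nrow(spans)) return(doc)
  toks <- character(0)
  if (featureset %in% c("drugs", "drugs+disorders")) {
    d <- spans[spans$kind == "drug", ]
    if (nrow(d)) toks <- c(toks, atc_class(d$code))
  }
  if (featureset %in% c("disorders", "drugs+disorders")) {
    d <- spans[spans$kind == "disorder", ]
    if (nrow(d)) toks <- c(toks, icd_token(d$code))
  }
  if (!length(toks)) return(doc)
  add <- table(toks)
  for (tok in names(add)) {
    doc[tok] <- (if (tok %in% names(doc)) doc[[tok]] else 0) + as.numeric(add[[tok]])
  }
  doc
}

#' Rewrite entity mentions in a unit (ablation configurations)
#'
#' The five entity-handling configurations: `normal` keeps the text as is;
#' `code` replaces each target-entity span by its reserved code token;
#' `normal+code` inserts the code token right after the span; `placeholder`
#' replaces the span by the single reserved token `DRUG` or `DISORDER`;
#' `deleted` removes the span tokens. Offsets of all remaining spans are
#' remapped to the rewritten token stream. Overlapping target spans are
#' resolved leftmost-longest with a warning.
#'
#' @param unit a list with `tokens` and `lemmas` (one message), or one row
#'   of [process_corpus()] output.
#' @param spans entity spans of the message (message-level offsets).
#' @param mode one of `"normal"`, `"code"`, `"normal+code"`, `"placeholder"`,
#'   `"deleted"`.
#' @param target_entity `"drugs"` or `"disorders"`: which entity kind the
#'   mode applies to.
#' @return list with `unit` (rewritten `tokens`/`lemmas`) and `spans`
#'   (remapped; deleted target spans are dropped).
#' @export
apply_name_mode <- function(unit, spans,
                            mode = c("normal", "code", "normal+code", "placeholder", "deleted"),
                            target_entity = c("drugs", "disorders")) {
  mode <- match.arg(mode)
  target_entity <- match.arg(target_entity)
  toks <- unit$tokens
  lems <- unit$lemmas
  if (is.list(toks) && length(toks) == 1) { toks <- toks[[1]]; lems <- lems[[1]] }
  spans <- if (is.null(spans)) entity_spans(character(0), integer(0), integer(0),
                                            character(0), character(0), character(0))
           else tibble::as_tibble(spans)
  if (mode == "normal")
    return(list(unit = list(tokens = toks, lemmas = lems), spans = spans))
  kind <- if (target_entity == "drugs") "drug" else "disorder"
  tgt <- spans[spans$kind == kind, , drop = FALSE]
  oth <- spans[spans$kind != kind, , drop = FALSE]
  tgt <- tgt[order(tgt$start, -(tgt$end - tgt$start)), , drop = FALSE]
  if (nrow(tgt) > 1) {
    keep <- rep(TRUE, nrow(tgt))
    last_end <- -1L
    for (i in seq_len(nrow(tgt))) {
      if (tgt$start[i] < last_end) {
        keep[i] <- FALSE
      } else last_end <- tgt$end[i]
    }
    if (any(!keep)) {
      warn("overlapping entity spans resolved leftmost-longest")
      tgt <- tgt[keep, , drop = FALSE]
    }
  }
  placeholder <- if (kind == "drug") "DRUG" else "DISORDER"
  code_tok <- function(code) if (kind == "drug") atc_class(code) else icd_token(code)

  new_toks <- character(0); new_lems <- character(0)
  new_tgt <- tgt[0, , drop = FALSE]
  # offset map: for every original position, its new position (for remapping
  # the non-target spans); built segment by segment
  remap_start <- integer(length(toks) + 1L)
  cursor <- 0L   # next original position to copy (0-based)
  out_len <- 0L
  push <- function(t, l) {
    new_toks <<- c(new_toks, t); new_lems <<- c(new_lems, l)
    out_len <<- out_len + length(t)
  }
  copy_upto <- function(stop_at) {
    while (cursor < stop_at) {
      remap_start[cursor + 1L] <<- out_len
      push(toks[cursor + 1L], lems[cursor + 1L])
      cursor <<- cursor + 1L
    }
  }
  for (i in seq_len(nrow(tgt))) {
    s <- tgt$start[i]; e <- tgt$end[i]
    copy_upto(s)
    span_start <- out_len
    ct <- code_tok(tgt$code[i])
    rep_toks <- switch(mode,
      "code" = ct,
      "normal+code" = c(toks[(s + 1L):e], ct),
      "placeholder" = placeholder,
      "deleted" = character(0))
    rep_lems <- switch(mode,
      "code" = ct,
      "normal+code" = c(lems[(s + 1L):e], ct),
      "placeholder" = placeholder,
      "deleted" = character(0))
    remap_start[(s + 1L):(e + 1L)] <- out_len
    push(rep_toks, rep_lems)
    cursor <- e
    if (mode != "deleted") {
      row <- tgt[i, , drop = FALSE]
      row$start <- span_start
      row$end <- out_len
      new_tgt <- rbind(new_tgt, row)
    }
  }
  copy_upto(length(toks))
  remap_start[length(toks) + 1L] <- out_len

  if (nrow(oth)) {
    oth$start <- remap_start[oth$start + 1L]
    oth$end <- remap_start[oth$end + 1L]
    oth <- oth[oth$end > oth$start, , drop = FALSE]
  }
  out_spans <- rbind(new_tgt, oth)
  if (nrow(out_spans)) out_spans <- out_spans[order(out_spans$start), , drop = FALSE]
  list(unit = list(tokens = new_toks, lemmas = new_lems),
       spans = tibble::as_tibble(out_spans))
}

#' Build classifier-ready documents for a feature configuration
#'
#' Applies the entity-handling mode to every message, vectorizes the
#' rewritten lemma streams and augments the counts with entity code tokens
#' per the featureset.
#'
#' @param units preprocessed units (message-level rows are used).
#' @param spans entity spans for all messages (message-level offsets).
#' @param featureset `"text"`, `"drugs"`, `"disorders"` or
#'   `"drugs+disorders"`.
#' @param name_mode entity-handling configuration (see [apply_name_mode()]).
#' @param target_entity entity kind the name mode applies to.
#' @param min_token_freq vocabulary frequency cut (see [vectorize()]).
#' @param binary binary presence instead of counts?
#' @return named list (by message id) of count documents.
#' @export
prepare_feature_docs <- function(units, spans, featureset = "text",
                                 name_mode = "normal", target_entity = "drugs",
                                 min_token_freq = 1, binary = FALSE) {
  msg <- units[units$unit_kind == "message", ]
  spans <- tibble::as_tibble(spans)
  rewritten <- lapply(seq_len(nrow(msg)), function(i) {
    sp <- spans[spans$message_id == msg$message_id[i], , drop = FALSE]
    apply_name_mode(list(tokens = msg$tokens[[i]], lemmas = msg$lemmas[[i]]),
                    sp, mode = name_mode, target_entity = target_entity)
  })
  msg2 <- msg
  msg2$tokens <- lapply(rewritten, function(r) r$unit$tokens)
  msg2$lemmas <- lapply(rewritten, function(r) r$unit$lemmas)
  docs <- vectorize(msg2, min_token_freq = min_token_freq, binary = binary)
  if (featureset != "text") {
    for (i in seq_along(docs)) {
      docs[[i]] <- augment_with_codes(docs[[i]], rewritten[[i]]$spans, featureset)
    }
  }
  docs
}

#' Export feature documents as sparse triplets
#'
#' Writes a `(doc, term, count)` TSV plus a vocabulary TSV, the plain-text
#' exchange format for feature matrices.
#'
#' @param docs named list of count documents.
#' @param path triplet TSV path; the vocabulary is written next to it with
#'   suffix `.vocab.tsv`.
#' @return `path`, invisibly.
#' @export
write_feature_docs <- function(docs, path) {
  rows <- purrr::imap(docs, function(d, id) {
    if (!length(d)) return(NULL)
    tibble::tibble(doc = id, term = names(d), count = as.numeric(d))
  })
  trip <- dplyr::bind_rows(rows)
  readr::write_tsv(trip, path, progress = FALSE)
  vocab <- sort(unique(trip$term))
  readr::write_tsv(tibble::tibble(term = vocab),
                   paste0(path, ".vocab.tsv"), progress = FALSE)
  invisible(path)
}
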