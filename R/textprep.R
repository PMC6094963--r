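#' Normalize noisy forum text
#'
#' Lowercases, strips diacritics (Unicode NFKD decomposition followed by
#' removal of combining marks, so e.g. "Anxiété" becomes "anxiete") and
#' replaces every maximal digit run by the reserved placeholder token `NUM`.
#' Reserved feature tokens already present (`NUM`, `DRUG`, `DISORDER`,
#' `ATC_*`, `ICD_*`) are preserved verbatim, which makes the function
#' idempotent. No spell-checking is performed and stopwords are kept.
#'
#' @param raw character vector of raw unicode strings.
#' @return character vector of the same length, lowercase and diacritic-free.
#' @examples
#' normalize_text("Anxiété")            # "anxiete"
#' normalize_text("3 boites de xanax")  # "NUM boites de xanax"
#' @export
normalize_text <- function(raw) {
  stopifnot(is.character(raw))
  out <- character(length(raw))
  has_res <- stringi::stri_detect_regex(raw, .reserved_token_re)
  has_res[is.na(has_res)] <- FALSE
  plain <- !has_res & !is.na(raw)
  out[plain] <- normalize_plain(raw[plain])
  out[is.na(raw)] <- NA_character_
  for (i in which(has_res)) out[i] <- normalize_one(raw[i])
  out
}

normalize_one <- function(x) {
  if (is.na(x)) return(NA_character_)
  locs <- stringi::stri_locate_all_regex(x, .reserved_token_re)[[1]]
  if (nrow(locs) == 0 || is.na(locs[1, 1])) return(normalize_plain(x))
  pieces <- character(0)
  last <- 1L
  for (i in seq_len(nrow(locs))) {
    s <- locs[i, 1]; e <- locs[i, 2]
    if (s > last) pieces <- c(pieces, normalize_plain(substr(x, last, s - 1L)))
    pieces <- c(pieces, substr(x, s, e))
    last <- e + 1L
  }
  if (last <= nchar(x)) pieces <- c(pieces, normalize_plain(substr(x, last, nchar(x))))
  paste0(pieces, collapse = "")
}

normalize_plain <- function(x) {
  x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_trans_nfkd(x)
  x <- stringi::stri_replace_all_regex(x, "\\p{Mn}+", "")
  x <- stringi::stri_trans_nfc(x)
  x <- stringi::stri_replace_all_fixed(x, "’", "'")
  stringi::stri_replace_all_regex(x, "[0-9]+", "NUM")
}

#' Split a message into sentences
#'
#' Rule-based splitter: sentence boundaries are terminal punctuation
#' (`.`, `!`, `?`, `;`) followed by whitespace. Runs of terminal punctuation
#' (ellipses, "!!!") are collapsed to a single delimiter. Empty sentences are
#' dropped; text without a terminator is returned as one sentence.
#'
#' @param text a single character string (one message).
#' @return character vector of sentences, each keeping its delimiter.
#' @examples
#' split_sentences("a. b?")  # c("a.", "b?")
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  x <- stringi::stri_replace_all_regex(text, "([.!?;])[.!?;]+", "$1")
  parts <- stringi::stri_split_regex(x, "(?<=[.!?;])\\s+")[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Tokenize normalized text
#'
#' Tokens are maximal runs of letters, digits or underscore, optionally
#' carrying a trailing apostrophe so French elisions stay separate tokens
#' ("d'angoisse" tokenizes to `d'`, `angoisse`). Punctuation is dropped unless
#' `keep_punct = TRUE`, in which case punctuation runs become tokens.
#' Reserved placeholders such as `NUM` are single tokens.
#'
#' @param text a single character string, already normalized.
#' @param keep_punct keep punctuation runs as tokens?
#' @return character vector of tokens.
#' @examples
#' tokenize("crise d'angoisse !")  # c("crise", "d'", "angoisse")
#' @export
tokenize <- function(text, keep_punct = FALSE) {
  stopifnot(is.character(text), length(text) == 1)
  if (is.na(text) || !nzchar(text)) return(character(0))
  word_re <- "[\\p{L}\\p{N}_]+'?"
  pattern <- if (keep_punct) paste0(word_re, "|[^\\p{L}\\p{N}\\s]+") else word_re
  toks <- stringi::stri_extract_all_regex(text, pattern)[[1]]
  if (length(toks) == 0 || all(is.na(toks))) character(0) else toks[!is.na(toks)]
}

#' Lemmatize tokens via a lookup table
#'
#' Deterministic table lookup standing in for a statistical tagger: forms
#' absent from the table lemmatize to themselves, so the output always has
#' the same length as the input.
#'
#' @param tokens character vector of normalized tokens.
#' @param table a lemma table from [lemma_table()] or [read_lemma_table()],
#'   or `NULL` for the identity.
#' @return character vector of lemmas, same length as `tokens`.
#' @export
lemmatize <- function(tokens, table = NULL) {
  stopifnot(is.character(tokens))
  if (is.null(table) || length(table) == 0) return(tokens)
  hit <- match(tokens, names(table))
  out <- tokens
  found <- !is.na(hit)
  out[found] <- unname(table[hit[found]])
  out
}

#' Build a lemma table from forms and lemmas
#'
#' @param form,lemma character vectors of equal length; both are normalized.
#' @return named character vector (form -> lemma) of class `lemma_table`.
#' @export
lemma_table <- function(form, lemma) {
  stopifnot(length(form) == length(lemma))
  form <- normalize_text(form)
  lemma <- normalize_text(lemma)
  keep <- !duplicated(form)
  structure(setNames(lemma[keep], form[keep]), class = "lemma_table")
}

#' Preprocess a message corpus into units
#'
#' Runs the full preprocessing chain (normalization, sentence splitting,
#' tokenization, lemmatization) and returns one row per unit: a message-level
#' unit (`unit_kind = "message"`, position 0) whose tokens are the
#' concatenation of its sentences' tokens, plus one sentence-level unit per
#' sentence (0-based positions). Raw surface text is retained alongside the
#' normalized token stream.
#'
#' @param messages a tibble with columns `id` and `text` (e.g. from
#'   [read_corpus_jsonl()] or [generate_corpus()]).
#' @param table optional lemma table.
#' @param keep_punct keep punctuation tokens?
#' @return tibble with columns `unit_id`, `message_id`, `unit_kind`,
#'   `position`, `raw`, `tokens` (list), `lemmas` (list).
#' @export
process_corpus <- function(messages, table = NULL, keep_punct = FALSE) {
  stopifnot(all(c("id", "text") %in% names(messages)))
  if (anyDuplicated(messages$id)) abort("message ids must be unique")
  ids <- as.character(messages$id)
  text_in <- ifelse(is.na(messages$text), "", messages$text)
  norm <- normalize_text(text_in)
  sents <- lapply(norm, split_sentences)
  ns <- lengths(sents)
  flat_sents <- unlist(sents, use.names = FALSE) %||% character(0)
  flat_toks <- lapply(flat_sents, tokenize, keep_punct = keep_punct)

  total <- length(ids) + sum(ns)
  unit_id <- character(total); message_id <- character(total)
  unit_kind <- character(total); position <- integer(total)
  raw <- character(total); tokens <- vector("list", total)
  r <- 0L; f <- 0L
  for (i in seq_along(ids)) {
    k <- ns[i]
    stoks <- if (k > 0) flat_toks[(f + 1L):(f + k)] else list()
    r <- r + 1L
    unit_id[r] <- ids[i]; message_id[r] <- ids[i]
    unit_kind[r] <- "message"; position[r] <- 0L
    raw[r] <- text_in[i]
    tokens[[r]] <- unlist(stoks, use.names = FALSE) %||% character(0)
    if (k > 0) {
      idx <- (r + 1L):(r + k)
      unit_id[idx] <- paste0(ids[i], ":", seq_len(k) - 1L)
      message_id[idx] <- ids[i]
      unit_kind[idx] <- "sentence"
      position[idx] <- seq_len(k) - 1L
      raw[idx] <- sents[[i]]
      tokens[idx] <- stoks
      r <- r + k
      f <- f + k
    }
  }
  tibble::tibble(
    unit_id = unit_id, message_id = message_id, unit_kind = unit_kind,
    position = position, raw = raw, tokens = tokens,
    lemmas = lapply(tokens, lemmatize, table = table)
  )
}
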