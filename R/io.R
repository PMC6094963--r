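#' Read a message corpus from JSONL
#'
#' One JSON object per line: `{"id", "text", "drugs": [{"surface","atc"}],
#' "label", "misuse_type"}`; the label fields are optional.
#'
#' @param path path to a JSONL file.
#' @return tibble with columns `id`, `text`, `drugs` (list of tibbles),
#'   `label`, `misuse_type`.
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON, simplifyDataFrame = TRUE)
  tibble::tibble(
    id = vapply(recs, function(r) as.character(r$id), character(1)),
    text = vapply(recs, function(r) as.character(r$text %||% ""), character(1)),
    drugs = lapply(recs, function(r) {
      d <- r$drugs
      if (is.null(d) || (is.data.frame(d) && nrow(d) == 0))
        tibble::tibble(surface = character(0), atc = character(0))
      else tibble::as_tibble(d)
    }),
    label = vapply(recs, function(r) as.character(r$label %||% NA_character_), character(1)),
    misuse_type = vapply(recs, function(r) as.character(r$misuse_type %||% NA_character_), character(1))
  )
}

#' Write a message corpus to JSONL
#'
#' @param messages tibble as returned by [read_corpus_jsonl()] or
#'   [generate_corpus()] (`$messages`); only `id` and `text` are required.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(messages, path) {
  lines <- vapply(seq_len(nrow(messages)), function(i) {
    rec <- list(id = messages$id[i], text = messages$text[i])
    if ("drugs" %in% names(messages)) {
      d <- messages$drugs[[i]]
      if (!is.null(d) && nrow(d) > 0) rec$drugs <- d
    }
    if ("label" %in% names(messages) && !is.na(messages$label[i]))
      rec$label <- messages$label[i]
    if ("misuse_type" %in% names(messages) && !is.na(messages$misuse_type[i]))
      rec$misuse_type <- messages$misuse_type[i]
    jsonlite::toJSON(rec, auto_unbox = TRUE, dataframe = "rows")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a seed table
#'
#' TSV with a header and columns `term`, `code` and optionally `group` (the
#' simplified code after expert grouping; defaults to `code`). Terms are
#' normalized on read.
#'
#' @param path path to the TSV file.
#' @return tibble with columns `term`, `code`, `group`.
#' @export
read_seed_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("term", "code"), "seed table")
  if (!"group" %in% names(df)) df$group <- df$code
  tibble::tibble(term = normalize_text(df$term),
                 code = as.character(df$code),
                 group = as.character(df$group))
}

#' Read a lemma table from a 2-column TSV
#'
#' UTF-8, no header: inflected form, lemma.
#'
#' @param path path to the TSV file.
#' @return a `lemma_table` (named character vector).
#' @export
read_lemma_table <- function(path) {
  df <- readr::read_tsv(path, col_names = c("form", "lemma"),
                        show_col_types = FALSE, progress = FALSE)
  lemma_table(df$form, df$lemma)
}

#' Read a morphology table (word, lemma, root)
#' @param path path to a TSV file with header columns `word`, `lemma`, `root`.
#' @return tibble with normalized columns.
#' @export
read_morphology_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("word", "lemma", "root"), "morphology table")
  tibble::tibble(word = normalize_text(df$word),
                 lemma = normalize_text(df$lemma),
                 root = normalize_text(df$root))
}

#' Read an alias table (code, label)
#' @param path path to a TSV file with header columns `code`, `label`.
#' @return tibble.
#' @export
read_alias_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("code", "label"), "alias table")
  tibble::tibble(code = as.character(df$code), label = as.character(df$label))
}

#' Read a weighted relation-graph edge list
#' @param path path to a TSV file with header columns `term1`, `term2`,
#'   `weight` and optionally `relation`.
#' @return tibble.
#' @export
read_graph_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("term1", "term2", "weight"), "graph table")
  if (!"relation" %in% names(df)) df$relation <- NA_character_
  tibble::tibble(term1 = normalize_text(df$term1),
                 term2 = normalize_text(df$term2),
                 weight = as.numeric(df$weight),
                 relation = as.character(df$relation))
}

#' Read a drug-name to ATC-code table
#' @param path path to a TSV file with header columns `surface`, `atc`.
#' @return tibble.
#' @export
read_drug_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("surface", "atc"), "drug table")
  tibble::tibble(surface = normalize_text(df$surface),
                 atc = toupper(as.character(df$atc)))
}

#' Write index predictions to JSONL
#'
#' One object per unit: `{"unit_id", "level", "codes", "spans"}` with spans
#' as `{term, code, start, end}` (token offsets, 0-based half-open).
#'
#' @param assignments tibble from [index_units()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions_jsonl <- function(assignments, path) {
  lines <- vapply(seq_len(nrow(assignments)), function(i) {
    jsonlite::toJSON(list(
      unit_id = assignments$unit_id[i],
      level = assignments$level[i],
      codes = assignments$codes[[i]],
      spans = assignments$spans[[i]]
    ), auto_unbox = TRUE, dataframe = "rows")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  invisible(df)
}
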