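#' Construct a disorder lexicon
#'
#' A lexicon is a tibble of `(term, code, source)` entries: a normalized term
#' (possibly multiword, single-spaced), the seed code it maps to, and the
#' resource that proposed it. Entries are unique on `(term, code, source)`.
#'
#' @param term,code,source character vectors (recycled to common length).
#' @param name lexicon name; defaults to the first source.
#' @return an object of class `misuse_lexicon`.
#' @export
lexicon <- function(term = character(0), code = character(0),
                    source = character(0), name = NULL) {
  df <- tibble::tibble(term = normalize_text(as.character(term)),
                       code = as.character(code),
                       source = as.character(source))
  df <- dplyr::distinct(df[nzchar(df$term), ])
  new_lexicon(df, name %||% (if (nrow(df)) df$source[1] else "empty"))
}

new_lexicon <- function(entries, name) {
  stopifnot(all(c("term", "code", "source") %in% names(entries)))
  structure(dplyr::distinct(tibble::as_tibble(entries)),
            name = name,
            class = c("misuse_lexicon", class(tibble::tibble())))
}

#' @export
print.misuse_lexicon <- function(x, ...) {
  cat(sprintf("<misuse_lexicon '%s'> %d entries, %d distinct (term, code) pairs\n",
              attr(x, "name"), nrow(x), lexicon_size(x)))
  NextMethod()
}

#' Lexicon size
#'
#' The number of distinct `(term, code)` pairs, the convention used when
#' summarising generated resources.
#'
#' @param lex a `misuse_lexicon`.
#' @return integer count.
#' @export
lexicon_size <- function(lex) {
  nrow(dplyr::distinct(tibble::as_tibble(lex)[, c("term", "code")]))
}

#' Seed lexicon
#'
#' Wraps a seed table as a lexicon (source `"seeds"`), using the simplified
#' `group` code when present.
#'
#' @param seeds tibble with columns `term` and `group` (or `code`).
#' @return a `misuse_lexicon`.
#' @export
seed_lexicon <- function(seeds) {
  code <- if ("group" %in% names(seeds)) seeds$group else seeds$code
  lexicon(seeds$term, code, "seeds", name = "seeds")
}

seed_codes <- function(seeds) {
  if ("group" %in% names(seeds)) seeds$group else seeds$code
}

#' Expand seeds through their morphological family
#'
#' For each seed, adds every word of the morphology table that shares the
#' seed's lemma or its longest-morpheme family root (e.g. "nerveux" expands
#' with "nerveusement" and "nervosité"). Seeds absent from the table
#' contribute only themselves.
#'
#' @param seeds seed table (`term`, `code`, `group`).
#' @param morph morphology table with columns `word`, `lemma`, `root`.
#' @param source source id recorded on added entries.
#' @return a `misuse_lexicon` containing the seeds plus the expansions.
#' @export
expand_morphology <- function(seeds, morph, source = "morph") {
  check_columns(morph, c("word", "lemma", "root"), "morphology table")
  morph <- tibble::tibble(word = normalize_text(morph$word),
                          lemma = normalize_text(morph$lemma),
                          root = normalize_text(morph$root))
  codes <- seed_codes(seeds)
  terms <- normalize_text(seeds$term)
  added <- purrr::map2(terms, codes, function(term, code) {
    anchors <- morph$word == term | morph$lemma == term | morph$root == term
    if (!any(anchors)) return(NULL)
    keys_l <- unique(morph$lemma[anchors])
    keys_r <- unique(morph$root[anchors])
    fam <- morph$word[morph$lemma %in% keys_l | morph$root %in% keys_r]
    tibble::tibble(term = unique(fam), code = code, source = source)
  })
  bind_lexicon(seed_lexicon(seeds), dplyr::bind_rows(added), name = source)
}

#' Extract knowledge-base aliases for seed codes
#'
#' Adds every alias-table label attached to a seed's code (fine-grained or
#' simplified). Labels whose normalized form duplicates an already-kept label
#' for the same code are dropped (diacritic-only variants collapse to one
#' entry); inflectional variants are kept.
#'
#' @param seeds seed table.
#' @param aliases alias table with columns `code`, `label`.
#' @param source source id recorded on added entries.
#' @return a `misuse_lexicon`.
#' @export
extract_aliases <- function(seeds, aliases, source = "alias") {
  check_columns(aliases, c("code", "label"), "alias table")
  codes <- seed_codes(seeds)
  added <- purrr::map2(as.character(seeds$code), codes, function(fine, grp) {
    labs <- aliases$label[aliases$code %in% unique(c(fine, grp))]
    if (!length(labs)) return(NULL)
    norm <- normalize_text(labs)
    tibble::tibble(term = norm[!duplicated(norm)], code = grp, source = source)
  })
  bind_lexicon(seed_lexicon(seeds), dplyr::bind_rows(added), name = source)
}

#' Extract top-weighted graph neighbors of seeds
#'
#' For each seed, records the `top_k` highest-weight neighbors in a weighted
#' relation graph (edges are treated as undirected), optionally restricted to
#' a relation tag (e.g. morphological relations only). Ties in weight are
#' broken lexicographically.
#'
#' @param seeds seed table.
#' @param graph edge list with columns `term1`, `term2`, `weight` and
#'   optionally `relation`.
#' @param top_k how many neighbors to keep per seed (>= 0).
#' @param relation_filter optional relation tag to keep.
#' @param source source id; defaults to `"graph"`, or `"graph_morph"` when a
#'   relation filter is given.
#' @return a `misuse_lexicon`.
#' @export
extract_graph_neighbors <- function(seeds, graph, top_k = 30,
                                    relation_filter = NULL, source = NULL) {
  if (!is.numeric(top_k) || length(top_k) != 1 || is.na(top_k) || top_k < 0)
    abort("`top_k` must be a single non-negative number")
  check_columns(graph, c("term1", "term2", "weight"), "graph table")
  if (!"relation" %in% names(graph)) graph$relation <- NA_character_
  source <- source %||% (if (is.null(relation_filter)) "graph" else "graph_morph")
  g <- tibble::tibble(term1 = normalize_text(graph$term1),
                      term2 = normalize_text(graph$term2),
                      weight = as.numeric(graph$weight),
                      relation = as.character(graph$relation))
  if (!is.null(relation_filter))
    g <- g[!is.na(g$relation) & g$relation == relation_filter, ]
  codes <- seed_codes(seeds)
  terms <- normalize_text(seeds$term)
  added <- purrr::map2(terms, codes, function(term, code) {
    nb <- rbind(
      data.frame(term = g$term2[g$term1 == term], weight = g$weight[g$term1 == term]),
      data.frame(term = g$term1[g$term2 == term], weight = g$weight[g$term2 == term])
    )
    if (!nrow(nb)) return(NULL)
    nb <- nb[order(-nb$weight, nb$term), , drop = FALSE]
    nb <- nb[!duplicated(nb$term), , drop = FALSE]
    nb <- head(nb, top_k)
    if (!nrow(nb)) return(NULL)
    tibble::tibble(term = nb$term, code = code, source = source)
  })
  bind_lexicon(seed_lexicon(seeds), dplyr::bind_rows(added), name = source)
}

#' Build a lexicon from a word clustering
#'
#' Every word sharing a cluster with a seed term is added under that seed's
#' code; when two seeds share a cluster, its words are added under both codes.
#' Underscore-joined collocation tokens are stored with single spaces.
#'
#' @param clustering a `brown_clustering` (or any list with an `assignment`
#'   named integer vector word -> cluster id).
#' @param seeds seed table.
#' @param source source id recorded on added entries.
#' @return a `misuse_lexicon`.
#' @export
lexicon_from_clusters <- function(clustering, seeds, source = "brown") {
  assignment <- clustering$assignment
  codes <- seed_codes(seeds)
  terms <- normalize_text(seeds$term)
  vocab <- names(assignment)
  added <- purrr::map2(terms, codes, function(term, code) {
    key <- c(term, gsub(" ", "_", term, fixed = TRUE))
    key <- intersect(key, vocab)
    if (!length(key)) return(NULL)
    members <- vocab[assignment %in% assignment[key]]
    members <- setdiff(members, key)
    if (!length(members)) return(NULL)
    tibble::tibble(term = gsub("_", " ", members, fixed = TRUE),
                   code = code, source = source)
  })
  bind_lexicon(seed_lexicon(seeds), dplyr::bind_rows(added), name = source)
}

#' Merge all lexica (Total combination)
#'
#' Set union of the `(term, code)` pairs of the input lexica; the source of
#' every entry is recorded as `"total"`.
#'
#' @param lexica list of `misuse_lexicon` objects (at least one).
#' @return a `misuse_lexicon` named `"total"`.
#' @export
combine_total <- function(lexica) {
  stopifnot(length(lexica) >= 1)
  all <- dplyr::bind_rows(lapply(lexica, function(l) tibble::as_tibble(l)[, c("term", "code")]))
  all <- dplyr::distinct(all)
  all$source <- "total"
  new_lexicon(all, "total")
}

#' Keep terms proposed by at least two resources (Vote combination)
#'
#' The output contains the seeds plus every `(term, code)` pair that appears
#' in at least `min_sources` distinct input lexica. Seed entries are counted
#' like any other entry but are always retained.
#'
#' @param lexica list of `misuse_lexicon` objects, each with a distinct name.
#' @param seeds seed table.
#' @param min_sources minimum number of distinct resources (>= 1).
#' @return a `misuse_lexicon` named `"vote"`.
#' @export
combine_vote <- function(lexica, seeds, min_sources = 2) {
  if (!is.numeric(min_sources) || min_sources < 1)
    abort("`min_sources` must be >= 1")
  stopifnot(length(lexica) >= 1)
  ids <- vapply(seq_along(lexica), function(i)
    attr(lexica[[i]], "name") %||% as.character(i), character(1))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  tagged <- dplyr::bind_rows(purrr::map2(lexica, ids, function(l, id) {
    df <- dplyr::distinct(tibble::as_tibble(l)[, c("term", "code")])
    df$resource <- id
    df
  }))
  votes <- tagged %>%
    dplyr::distinct(.data$term, .data$code, .data$resource) %>%
    dplyr::count(.data$term, .data$code, name = "n_sources") %>%
    dplyr::filter(.data$n_sources >= min_sources)
  kept <- tibble::tibble(term = votes$term, code = votes$code, source = "vote")
  sl <- tibble::as_tibble(seed_lexicon(seeds))
  sl$source <- "vote"
  new_lexicon(dplyr::distinct(dplyr::bind_rows(sl, kept)), "vote")
}

#' Write / read a lexicon as 3-column TSV (term, code, source)
#' @param lex a `misuse_lexicon`.
#' @param path file path.
#' @return `path` invisibly (write) or a `misuse_lexicon` (read).
#' @export
write_lexicon <- function(lex, path) {
  readr::write_tsv(tibble::as_tibble(lex), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_lexicon
#' @param name lexicon name for the read object.
#' @export
read_lexicon <- function(path, name = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("term", "code", "source"), "lexicon file")
  new_lexicon(df, name %||% (if (nrow(df)) df$source[1] else "lexicon"))
}

#' Summarise a set of lexica
#'
#' One row per lexicon with its name and size (distinct term/code pairs),
#' the summary printed when building resources with `--report`.
#'
#' @param lexica named list of `misuse_lexicon` objects.
#' @return tibble with columns `lexicon`, `size`.
#' @export
lexicon_report <- function(lexica) {
  tibble::tibble(
    lexicon = vapply(seq_along(lexica), function(i)
      names(lexica)[i] %||% attr(lexica[[i]], "name"), character(1)),
    size = unname(vapply(lexica, lexicon_size, integer(1)))
  )
}

bind_lexicon <- function(base, added, name) {
  base_df <- tibble::as_tibble(base)
  if (!is.null(added) && nrow(added)) {
    added$term <- normalize_text(added$term)
    added <- added[nzchar(added$term), ]
    # do not duplicate entries that are already seeds for the same code
    added <- dplyr::anti_join(added, base_df, by = c("term", "code"))
    base_df <- dplyr::bind_rows(base_df, added)
  }
  new_lexicon(base_df, name)
}
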