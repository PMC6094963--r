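#' Restrict a processed corpus to mood-disorder messages
#'
#' Distributional lexicon routes work best on a topical sub-corpus: this
#' filter keeps the messages that seeds-only indexing tags with at least one
#' seed code, and returns their message-level lemma sequences.
#'
#' @param units preprocessed units from [process_corpus()].
#' @param seeds seed table.
#' @return list of lemma sequences (one per retained message).
#' @export
subcorpus_sequences <- function(units, seeds) {
  msg <- units[units$unit_kind == "message", ]
  idx <- index_units(msg, seed_lexicon(seeds), level = "message")
  keep <- lengths(idx$codes) > 0
  msg$lemmas[keep]
}

#' Build the full family of enriched lexica
#'
#' Runs every configured enrichment route from one seed set — morphological
#' expansion, knowledge-base aliases, graph neighbors (with and without the
#' morphological-relation filter), Brown clusters, CBOW embedding neighbors
#' queried with seeds and with morphologically expanded seeds — and the
#' Total and Vote combinations of all individual routes.
#'
#' @param seeds seed table.
#' @param units preprocessed units (used by the distributional routes; the
#'   corpus is restricted to messages carrying at least one seed code).
#' @param morph,aliases,graph optional resource tables; routes without their
#'   table are skipped.
#' @param n_clusters Brown cluster count.
#' @param top_k neighbors kept per seed (graph and embedding routes).
#' @param dim,epochs,window CBOW hyper-parameters.
#' @param min_count collocation threshold for [merge_bigrams()] and minimum
#'   frequency for embedding vocabulary.
#' @param seed RNG seed for embedding training.
#' @return named list of `misuse_lexicon` objects, always containing
#'   `seeds`, `total` and `vote`.
#' @export
build_lexica <- function(seeds, units = NULL, morph = NULL, aliases = NULL,
                         graph = NULL, n_clusters = 40, top_k = 30,
                         dim = 40, epochs = 3, window = 10,
                         min_count = 5, seed = 1) {
  out <- list(seeds = seed_lexicon(seeds))
  if (!is.null(morph)) out$morph <- expand_morphology(seeds, morph)
  if (!is.null(aliases)) out$alias <- extract_aliases(seeds, aliases)
  if (!is.null(graph)) {
    out$graph <- extract_graph_neighbors(seeds, graph, top_k = top_k)
    out$graph_morph <- extract_graph_neighbors(seeds, graph, top_k = top_k,
                                               relation_filter = "morph")
  }
  if (!is.null(units)) {
    seqs <- subcorpus_sequences(units, seeds)
    if (length(seqs) >= 2) {
      clustering <- brown_cluster(seqs, n_clusters = n_clusters)
      out$brown <- lexicon_from_clusters(clustering, seeds)
      merged <- merge_bigrams(seqs, min_count = min_count)
      vectors <- train_embeddings(merged, dim = dim, window = window,
                                  epochs = epochs, seed = seed,
                                  min_count = min_count)
      out$emb_seeds <- suppressWarnings(
        embedding_neighbors(vectors, seeds, seeds, top_k = top_k,
                            source = "emb_seeds"))
      if (!is.null(morph)) {
        morph_lex <- out$morph
        queries <- tibble::as_tibble(morph_lex)[, c("term", "code")]
        out$emb_morph <- suppressWarnings(
          embedding_neighbors(vectors, queries, seeds, top_k = top_k,
                              source = "emb_morph"))
      }
    }
  }
  individual <- out[setdiff(names(out), c("total", "vote"))]
  out$total <- combine_total(individual)
  out$vote <- combine_vote(individual, seeds)
  out
}

#' Index a corpus with several lexica and score each against the reference
#'
#' @param units preprocessed units.
#' @param lexica named list of lexica.
#' @param gold reference indexing (tibble `unit_id` / `codes`).
#' @return named list: for each lexicon, `score_report`s keyed by level.
#' @export
evaluate_lexica <- function(units, lexica, gold) {
  lapply(lexica, function(lex) {
    idx <- index_units(units, lex, level = "both")
    list(
      message = evaluate_indexing(idx, gold[gold$unit_id %in% idx$unit_id[idx$level == "message"], ],
                                  level = "message"),
      sentence = evaluate_indexing(idx, gold[gold$unit_id %in% idx$unit_id[idx$level == "sentence"], ],
                                   level = "sentence")
    )
  })
}
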