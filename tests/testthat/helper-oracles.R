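# Independent oracles and small fixture builders used across the suite.

# Brute-force Naive Bayes posterior straight from raw training counts, in
# plain probability arithmetic (no logs): an independent route against
# predict_nb's log-space implementation.
nb_joint_oracle <- function(docs, labels, doc, alpha = 1) {
  labels <- as.character(labels)
  classes <- unique(labels)
  vocab <- sort(unique(unlist(lapply(docs, names))))
  V <- length(vocab)
  joint <- vapply(classes, function(cl) {
    in_class <- docs[labels == cl]
    counts <- setNames(numeric(V), vocab)
    for (d in in_class) for (t in names(d)) counts[t] <- counts[t] + d[[t]]
    tot <- sum(counts)
    prior <- length(in_class) / length(docs)
    p <- prior
    for (t in names(doc)) {
      c_t <- if (t %in% vocab) counts[[t]] else 0
      p <- p * ((c_t + alpha) / (tot + alpha * V))^doc[[t]]
    }
    p
  }, numeric(1))
  joint / sum(joint)
}

# Corpus AMI computed through entropies, H(L) + H(R) - H(L,R), from a raw
# bigram tabulation of the cluster-mapped token stream: an independent route
# against the p*log(p/(pl*pr)) accumulation inside brown_cluster.
ami_entropy_oracle <- function(corpus, assignment) {
  # uninserted words (NA) are dropped with adjacency closed over the gap,
  # the same convention the implementation uses
  cl <- lapply(corpus, function(s) {
    x <- unname(assignment[s])
    x[!is.na(x)]
  })
  cl <- cl[lengths(cl) >= 2]
  a <- unlist(lapply(cl, function(x) x[-length(x)]))
  b <- unlist(lapply(cl, function(x) x[-1]))
  if (!length(a)) return(0)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  n <- length(a)
  pj <- as.numeric(table(paste(a, b))) / n
  ent(as.numeric(table(a)) / n) + ent(as.numeric(table(b)) / n) - ent(pj)
}

# Exhaustive minimal-AMI-loss merge given a partial assignment: tries every
# unordered pair of active clusters via the entropy oracle.
exhaustive_best_merge <- function(corpus, assignment) {
  ids <- sort(unique(assignment[!is.na(assignment)]))
  base <- ami_entropy_oracle(corpus, assignment)
  best <- NULL
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in (which(ids == ids[i]) + 1):length(ids)) {
      merged <- assignment
      merged[merged == ids[j]] <- ids[i]
      loss <- base - ami_entropy_oracle(corpus, merged)
      if (is.null(best) || loss < best$loss - 1e-12) {
        best <- list(pair = c(ids[i], ids[j]), loss = loss)
      }
    }
  }
  best
}

# Brute-force occurrence scan: does `term` occur in `unit_tokens`/`unit_lemmas`
# as a contiguous sequence (each position matching token or lemma)?
scan_occurs <- function(term_tokens, unit_tokens, unit_lemmas) {
  L <- length(term_tokens); n <- length(unit_tokens)
  if (L == 0 || L > n) return(FALSE)
  for (s in 1:(n - L + 1)) {
    seg_t <- unit_tokens[s:(s + L - 1)]
    seg_l <- unit_lemmas[s:(s + L - 1)]
    if (all(term_tokens == seg_t | term_tokens == seg_l)) return(TRUE)
  }
  FALSE
}

# Small seed table used by lexicon tests.
toy_seeds <- function() {
  tibble::tibble(term = c("angoisse", "nerveux"),
                 code = c("F41.0", "F48.0"),
                 group = c("F41", "F48"))
}

bundled_seeds <- function() read_seed_table(misuselex_extdata("disorders.tsv"))
bundled_lemmas <- function() read_lemma_table(misuselex_extdata("lemmas.tsv"))

# Random token-count document over a tiny vocabulary.
random_doc <- function(vocab, max_len = 4) {
  n <- sample(0:max_len, 1)
  if (n == 0) return(setNames(numeric(0), character(0)))
  toks <- sample(vocab, n, replace = TRUE)
  tab <- table(toks)
  setNames(as.numeric(tab), names(tab))
}
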