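#' Merge collocations into single tokens
#'
#' Adjacent token pairs whose pointwise mutual information (PMI) exceeds
#' `score_threshold` and whose count reaches `min_count` are rewritten as one
#' underscore-joined token, left to right, so multiword expressions such as
#' "crise d'angoisse" can enter the distributional vocabulary. PMI of a pair
#' (a, b) is `log2(N * c(a,b) / (c(a) * c(b)))` with N the corpus token
#' count. The rewrite is deterministic.
#'
#' @param corpus list of character vectors (token sequences).
#' @param min_count minimum pair count for merging.
#' @param score_threshold minimal PMI (bits) for merging.
#' @return list of token sequences with collocations joined.
#' @export
merge_bigrams <- function(corpus, min_count = 5, score_threshold = 0) {
  toks <- unlist(corpus, use.names = FALSE)
  if (length(toks) < 2) return(corpus)
  N <- length(toks)
  uni <- table(toks)
  sid <- rep(seq_along(corpus), lengths(corpus))
  a <- toks[-N]; b <- toks[-1]
  ok <- sid[-N] == sid[-1]
  a <- a[ok]; b <- b[ok]
  if (!length(a)) return(corpus)
  pair_key <- paste(a, b, sep = "\r")
  pc <- table(pair_key)
  pc <- pc[pc >= min_count]
  if (!length(pc)) return(corpus)
  parts <- strsplit(names(pc), "\r", fixed = TRUE)
  ca <- as.numeric(uni[vapply(parts, `[`, character(1), 1)])
  cb <- as.numeric(uni[vapply(parts, `[`, character(1), 2)])
  pmi <- log2(as.numeric(pc) * N / (ca * cb))
  merged_set <- names(pc)[pmi > score_threshold]
  if (!length(merged_set)) return(corpus)
  lapply(corpus, function(s) {
    n <- length(s)
    if (n < 2) return(s)
    out <- character(0)
    i <- 1L
    while (i <= n) {
      if (i < n && paste(s[i], s[i + 1], sep = "\r") %in% merged_set) {
        out <- c(out, paste(s[i], s[i + 1], sep = "_"))
        i <- i + 2L
      } else {
        out <- c(out, s[i])
        i <- i + 1L
      }
    }
    out
  })
}

#' Train CBOW word embeddings
#'
#' A continuous-bag-of-words shallow network trained with negative sampling:
#' the mean of the context vectors inside a fixed `window` predicts the
#' center word against `negative` noise words drawn from the unigram
#' distribution raised to 3/4. Training is fully seeded, so the same corpus,
#' parameters and seed give identical vectors.
#'
#' @param corpus list of token sequences (after optional [merge_bigrams()]).
#' @param dim embedding dimension (> 0).
#' @param window context window half-width in words.
#' @param epochs passes over the corpus.
#' @param seed RNG seed.
#' @param min_count words below this corpus frequency get no vector.
#' @param learning_rate SGD step size.
#' @param negative number of negative samples per position.
#' @return a `vector_table`: numeric matrix, one row per vocabulary word.
#' @export
train_embeddings <- function(corpus, dim, window = 10, epochs = 5, seed = 1,
                             min_count = 1, learning_rate = 0.05, negative = 5) {
  if (!is.numeric(dim) || length(dim) != 1 || dim <= 0)
    abort("`dim` must be a positive number")
  toks <- unlist(corpus, use.names = FALSE)
  if (!length(toks)) abort("corpus has no tokens")
  freq <- table(toks)
  vocab <- names(freq)[freq >= min_count]
  if (!length(vocab)) abort("no word reaches `min_count`")
  V <- length(vocab)
  dim <- as.integer(dim)
  sents <- lapply(corpus, function(s) {
    idx <- match(s, vocab)
    idx[!is.na(idx)]
  })
  sents <- sents[lengths(sents) >= 2]
  noise_p <- as.numeric(freq[vocab])^0.75
  noise_p <- noise_p / sum(noise_p)

  with_seed(seed, {
    W_in <- matrix(stats::runif(V * dim, -0.5, 0.5) / dim, V, dim)
    W_out <- matrix(0, V, dim)
    if (length(sents)) {
      n_pos <- sum(lengths(sents))
      for (ep in seq_len(epochs)) {
        negs <- matrix(sample.int(V, n_pos * negative, replace = TRUE, prob = noise_p),
                       nrow = negative)
        p <- 0L
        for (s in sents) {
          n <- length(s)
          for (t in seq_len(n)) {
            p <- p + 1L
            lo <- max(1L, t - window); hi <- min(n, t + window)
            ctx <- s[c(if (lo < t) lo:(t - 1L), if (hi > t) (t + 1L):hi)]
            if (!length(ctx)) next
            h <- .colMeans(W_in[ctx, , drop = FALSE], length(ctx), dim)
            targets <- c(s[t], negs[, p])
            f <- 1 / (1 + exp(-(W_out[targets, , drop = FALSE] %*% h)))
            g <- (c(1, numeric(negative)) - as.numeric(f)) * learning_rate
            err <- crossprod(W_out[targets, , drop = FALSE], g)
            W_out[targets, ] <- W_out[targets, ] + tcrossprod(g, h)
            W_in[ctx, ] <- W_in[ctx, ] +
              matrix(err, nrow = length(ctx), ncol = dim, byrow = TRUE)
          }
        }
      }
    }
    rownames(W_in) <- vocab
    structure(W_in, class = c("vector_table", "matrix", "array"))
  })
}

#' @export
print.vector_table <- function(x, ...) {
  cat(sprintf("<vector_table> %d words x %d dimensions\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Nearest-neighbor lexicon from embeddings
#'
#' For each query term, the `top_k` vocabulary words nearest by cosine
#' similarity (excluding the query itself) are added under the query's code;
#' similarity ties are broken lexicographically. Multiword queries are looked
#' up as underscore-joined collocation tokens; out-of-vocabulary queries are
#' skipped with a warning. Neighbor terms are stored with underscores mapped
#' back to spaces.
#'
#' @param vectors a `vector_table` from [train_embeddings()].
#' @param queries a seed table (`term` + `code`/`group`) or a
#'   `misuse_lexicon`; every query carries the code its neighbors inherit.
#' @param seeds seed table used to guarantee the seeds are in the output.
#' @param top_k neighbors kept per query.
#' @param source source id recorded on added entries.
#' @return a `misuse_lexicon`.
#' @export
embedding_neighbors <- function(vectors, queries, seeds = queries, top_k = 30,
                                source = "emb_seeds") {
  qterm <- normalize_text(queries$term)
  qcode <- if ("group" %in% names(queries)) queries$group else queries$code
  vocab <- rownames(vectors)
  norms <- sqrt(rowSums(vectors^2))
  norms[norms == 0] <- 1
  Wn <- vectors / norms
  added <- purrr::map2(qterm, qcode, function(term, code) {
    key <- gsub(" ", "_", term, fixed = TRUE)
    pos <- match(key, vocab)
    if (is.na(pos)) pos <- match(term, vocab)
    if (is.na(pos)) {
      warn(sprintf("query '%s' not in embedding vocabulary; skipped", term))
      return(NULL)
    }
    sims <- as.numeric(Wn %*% Wn[pos, ])
    ord <- order(-sims, vocab)
    ord <- ord[ord != pos]
    keep <- head(ord, top_k)
    if (!length(keep)) return(NULL)
    tibble::tibble(term = gsub("_", " ", vocab[keep], fixed = TRUE),
                   code = code, source = source)
  })
  bind_lexicon(seed_lexicon(seeds), dplyr::bind_rows(added), name = source)
}
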