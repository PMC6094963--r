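#' Brown clustering of a token corpus
#'
#' Greedy agglomerative word clustering over a class bigram model: at each
#' step the pair of clusters whose merge loses the least average mutual
#' information (AMI) between adjacent classes is merged, until `n_clusters`
#' clusters remain. The windowed (active-cluster) variant is used: words are
#' inserted in decreasing corpus frequency (ties lexicographic) and a merge
#' is triggered whenever the number of active clusters exceeds `window`
#' (default `n_clusters + 1`). Setting `window >= vocabulary size` gives the
#' plain agglomerative algorithm, for which every merge is an exhaustive
#' search over all cluster pairs.
#'
#' Cluster bigram statistics are taken over adjacent tokens within each
#' sequence; tokens whose word is not yet inserted are skipped, with
#' adjacency closed over the gap. If `n_clusters` is at least the vocabulary
#' size, every word is a singleton and no merge is performed.
#'
#' @param corpus list of character vectors (token or lemma sequences).
#' @param n_clusters number of clusters to stop at (>= 1).
#' @param window active-cluster budget of the windowed variant.
#' @param trace record, for each merge, the assignment before the merge, the
#'   merged pair and the AMI before/after (used for auditing the greedy
#'   choice).
#' @return an object of class `brown_clustering`: list with `assignment`
#'   (named integer, word -> cluster id), `ordering` (per cluster, words by
#'   decreasing corpus frequency, ties lexicographic), `n_clusters`, and
#'   `trace` (list, possibly empty).
#' @export
brown_cluster <- function(corpus, n_clusters, window = n_clusters + 1, trace = FALSE) {
  stopifnot(is.list(corpus), length(corpus) >= 1)
  if (!is.numeric(n_clusters) || n_clusters < 1)
    abort("`n_clusters` must be >= 1")
  window <- max(as.integer(window), 2L)

  toks <- unlist(corpus, use.names = FALSE)
  if (!length(toks)) abort("corpus has no tokens")
  freq <- table(toks)
  vocab <- names(freq)
  # insertion order: frequency descending, ties lexicographic
  ord <- order(-as.integer(freq), vocab)
  vocab_ord <- vocab[ord]
  v <- length(vocab)

  # flattened corpus as word indices (into vocab_ord) with sequence ids
  widx <- match(toks, vocab_ord)
  sid <- rep(seq_along(corpus), lengths(corpus))

  assignment <- rep(NA_integer_, v)
  names(assignment) <- vocab_ord

  if (v <= n_clusters) {
    assignment <- seq_len(v)
    names(assignment) <- vocab_ord
    return(new_brown(assignment, freq, n_clusters, list()))
  }

  trace_log <- list()
  n_active <- 0L
  for (i in seq_len(v)) {
    assignment[i] <- i
    n_active <- n_active + 1L
    while (n_active > window || (i == v && n_active > n_clusters)) {
      step <- best_merge(assignment, widx, sid)
      if (trace) {
        trace_log[[length(trace_log) + 1L]] <- list(
          assignment = assignment, pair = step$pair,
          ami_before = step$ami_before, ami_after = step$ami_after,
          loss = step$loss)
      }
      assignment[assignment == step$pair[2]] <- step$pair[1]
      n_active <- n_active - 1L
    }
  }
  new_brown(assignment, freq, n_clusters, trace_log)
}

new_brown <- function(assignment, freq, n_clusters, trace_log) {
  ids <- sort(unique(assignment))
  ordering <- lapply(ids, function(id) {
    members <- names(assignment)[assignment == id]
    f <- as.integer(freq[members])
    members[order(-f, members)]
  })
  names(ordering) <- as.character(ids)
  structure(list(assignment = assignment, ordering = ordering,
                 n_clusters = n_clusters, trace = trace_log),
            class = "brown_clustering")
}

#' @export
print.brown_clustering <- function(x, ...) {
  cat(sprintf("<brown_clustering> %d words in %d clusters (requested %d)\n",
              length(x$assignment), length(x$ordering), x$n_clusters))
  invisible(x)
}

# Cluster bigram count matrix over active clusters, given a (partial)
# assignment. Uninserted words (NA) are skipped; adjacency closes over gaps
# but never crosses sequence boundaries.
cluster_bigram_counts <- function(assignment, widx, sid) {
  cl <- assignment[widx]
  keep <- !is.na(cl)
  cl <- cl[keep]; s <- sid[keep]
  ids <- sort(unique(assignment[!is.na(assignment)]))
  A <- length(ids)
  M <- matrix(0, A, A, dimnames = list(ids, ids))
  if (length(cl) >= 2) {
    a <- cl[-length(cl)]; b <- cl[-1]
    ok <- s[-length(s)] == s[-1]
    a <- match(a[ok], ids); b <- match(b[ok], ids)
    if (length(a)) {
      tab <- table(factor(a, levels = seq_len(A)), factor(b, levels = seq_len(A)))
      M <- M + as.matrix(tab)
    }
  }
  M
}

# Average mutual information of a class bigram count matrix (base-2).
ami_from_counts <- function(M) {
  N <- sum(M)
  if (N == 0) return(0)
  p <- M / N
  pl <- rowSums(p); pr <- colSums(p)
  nz <- which(p > 0)
  ri <- ((nz - 1) %% nrow(p)) + 1
  ci <- ((nz - 1) %/% nrow(p)) + 1
  sum(p[nz] * log2(p[nz] / (pl[ri] * pr[ci])))
}

# Exhaustive search over all active-cluster pairs for the merge with minimal
# AMI loss; ties broken on the (smaller id, larger id) pair lexicographically.
best_merge <- function(assignment, widx, sid) {
  M <- cluster_bigram_counts(assignment, widx, sid)
  ids <- as.integer(rownames(M))
  A <- length(ids)
  base <- ami_from_counts(M)
  best <- NULL
  for (i in seq_len(A - 1)) {
    for (j in (i + 1):A) {
      after <- ami_from_counts(merge_counts(M, i, j))
      loss <- base - after
      if (is.null(best) || loss < best$loss - 1e-12) {
        best <- list(pair = c(ids[i], ids[j]), loss = loss,
                     ami_before = base, ami_after = after)
      }
    }
  }
  best
}

merge_counts <- function(M, i, j) {
  M[i, ] <- M[i, ] + M[j, ]
  M[, i] <- M[, i] + M[, j]
  M[-j, -j, drop = FALSE]
}

#' Corpus AMI under a cluster assignment
#'
#' The average mutual information of the class bigram model induced by
#' mapping each token to its cluster. Exposed so the monotone decrease of
#' AMI along the merge sequence can be inspected.
#'
#' @param corpus list of token sequences.
#' @param assignment named integer vector, word -> cluster id.
#' @return AMI in bits.
#' @export
corpus_ami <- function(corpus, assignment) {
  toks <- unlist(corpus, use.names = FALSE)
  widx <- match(toks, names(assignment))
  sid <- rep(seq_along(corpus), lengths(corpus))
  ami_from_counts(cluster_bigram_counts(assignment, widx, sid))
}
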