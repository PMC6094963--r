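#' Build a balanced training sample for an experiment design
#'
#' Balancing rules mirror the study designs: `misuse_vs_rest` takes every
#' misuse message and the same number sampled from the union of the other
#' two classes (133 + 133 at the reference class counts); `nouse_vs_rest`
#' takes half the no-use messages and the same number from the rest (300 +
#' 300 at the reference counts); `use_vs_misuse` balances normal-use against
#' misuse at the smaller class size; `three_way` (and `cascade`, which is
#' evaluated on the same three-class sample) takes the minority-class size
#' from each class. Sampling is without replacement and seeded; `UNDECIDED`
#' messages are excluded.
#'
#' @param corpus tibble of labeled messages with columns `id` and `label`
#'   (values among `NO_USE`, `NORMAL_USE`, `MISUSE`, `UNDECIDED`).
#' @param design one of `"misuse_vs_rest"`, `"nouse_vs_rest"`,
#'   `"use_vs_misuse"`, `"three_way"`, `"cascade"`.
#' @param seed RNG seed for the subsampling (NULL = current RNG state).
#' @return tibble with columns `id`, `use_class` (original class) and
#'   `label` (design label: e.g. `MISUSE`/`REST`).
#' @export
balance_sample <- function(corpus,
                           design = c("misuse_vs_rest", "nouse_vs_rest",
                                      "use_vs_misuse", "three_way", "cascade"),
                           seed = NULL) {
  design <- match.arg(design)
  stopifnot(all(c("id", "label") %in% names(corpus)))
  corpus <- corpus[corpus$label %in% .use_classes, c("id", "label")]
  names(corpus)[names(corpus) == "label"] <- "use_class"
  n_of <- function(cls) sum(corpus$use_class %in% cls)
  need <- function(cls, n) {
    if (n_of(cls) < n || n < 1)
      abort(sprintf("not enough '%s' messages (%d available, %d required)",
                    paste(cls, collapse = "+"), n_of(cls), max(n, 1)))
  }
  take <- function(cls, n) {
    pool <- corpus[corpus$use_class %in% cls, ]
    pool[sample.int(nrow(pool), n), ]
  }
  with_seed(seed, switch(design,
    misuse_vs_rest = {
      n <- min(n_of("MISUSE"), n_of(c("NORMAL_USE", "NO_USE")))
      need("MISUSE", n); need(c("NORMAL_USE", "NO_USE"), n)
      pos <- take("MISUSE", n)
      neg <- take(c("NORMAL_USE", "NO_USE"), n)
      out <- dplyr::bind_rows(pos, neg)
      out$label <- ifelse(out$use_class == "MISUSE", "MISUSE", "REST")
      out
    },
    nouse_vs_rest = {
      n <- min(floor(n_of("NO_USE") / 2), n_of(c("NORMAL_USE", "MISUSE")))
      need("NO_USE", n); need(c("NORMAL_USE", "MISUSE"), n)
      pos <- take("NO_USE", n)
      neg <- take(c("NORMAL_USE", "MISUSE"), n)
      out <- dplyr::bind_rows(pos, neg)
      out$label <- ifelse(out$use_class == "NO_USE", "NO_USE", "REST")
      out
    },
    use_vs_misuse = {
      n <- min(n_of("NORMAL_USE"), n_of("MISUSE"))
      need("NORMAL_USE", n); need("MISUSE", n)
      out <- dplyr::bind_rows(take("NORMAL_USE", n), take("MISUSE", n))
      out$label <- out$use_class
      out
    },
    {
      # three_way and cascade share the three-class balanced sample
      n <- min(n_of("NO_USE"), n_of("NORMAL_USE"), n_of("MISUSE"))
      for (cls in .use_classes) need(cls, n)
      out <- dplyr::bind_rows(lapply(.use_classes, take, n = n))
      out$label <- out$use_class
      out
    }
  ))
}

#' Train a Naive Bayes text classifier
#'
#' Multinomial variant: `P(t|c) = (count(t,c) + alpha) / (sum_t count(t,c) +
#' alpha * V)` with Laplace/Lidstone smoothing `alpha`; priors are the class
#' frequencies. Bernoulli variant: per-class presence probabilities
#' `(docs(t,c) + alpha) / (n_c + 2 alpha)` over document-level presence.
#' Training is deterministic and invariant to document order.
#'
#' @param docs list of named numeric count vectors (one per document).
#' @param labels vector of document labels (factor or character); at least
#'   two classes must be present. A factor fixes the label order used for
#'   deterministic tie-breaking.
#' @param alpha smoothing parameter (> 0).
#' @param variant `"multinomial"` or `"bernoulli"`.
#' @return object of class `nb_model`.
#' @export
train_nb <- function(docs, labels, alpha = 1,
                     variant = c("multinomial", "bernoulli")) {
  variant <- match.arg(variant)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    abort("`alpha` must be a positive number")
  stopifnot(length(docs) == length(labels))
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels, levels = unique(labels))
  classes <- levels(labels)
  if (length(classes) < 2) abort("at least two classes must be present")
  vocab <- sort(unique(unlist(lapply(docs, names), use.names = FALSE)))
  V <- length(vocab)
  C <- length(classes)
  counts <- matrix(0, V, C, dimnames = list(vocab, classes))
  doc_presence <- matrix(0, V, C, dimnames = list(vocab, classes))
  for (i in seq_along(docs)) {
    d <- docs[[i]]
    if (!length(d)) next
    j <- match(names(d), vocab)
    cl <- as.integer(labels[i])
    counts[j, cl] <- counts[j, cl] + as.numeric(d)
    doc_presence[j, cl] <- doc_presence[j, cl] + as.numeric(d > 0)
  }
  n_c <- as.numeric(table(labels))
  prior <- n_c / sum(n_c)
  model <- list(classes = classes, vocab = vocab, alpha = alpha,
                variant = variant, log_prior = log(prior),
                n_docs = n_c)
  if (variant == "multinomial") {
    tot <- colSums(counts)
    model$log_lik <- log(sweep(counts + alpha, 2, tot + alpha * V, "/"))
    model$tot <- tot
  } else {
    p1 <- sweep(doc_presence + alpha, 2, n_c + 2 * alpha, "/")
    model$log_p1 <- log(p1)
    model$log_p0 <- log(1 - p1)
  }
  structure(model, class = "nb_model")
}

#' @export
print.nb_model <- function(x, ...) {
  cat(sprintf("<nb_model> %s Naive Bayes, %d classes (%s), vocabulary %d, alpha=%g\n",
              x$variant, length(x$classes), paste(x$classes, collapse = ", "),
              length(x$vocab), x$alpha))
  invisible(x)
}

#' Predict with a Naive Bayes model
#'
#' The label is the argmax of the posterior `log prior + sum count * log
#' P(t|c)` (multinomial) or the Bernoulli document likelihood over the
#' vocabulary; the posterior map is normalized to sum to one. Tokens unseen
#' in training contribute the count-zero smoothed probability. Ties are
#' broken by the model's fixed label order.
#'
#' @param model an `nb_model`.
#' @param doc a named numeric count vector.
#' @return list with `label` and `posterior` (named numeric, sums to 1).
#' @export
predict_nb <- function(model, doc) {
  scores <- nb_scores(model, doc)
  post <- exp(scores - max(scores))
  post <- post / sum(post)
  list(label = model$classes[which.max(scores)], posterior = post)
}

nb_scores <- function(model, doc) {
  C <- length(model$classes)
  V <- length(model$vocab)
  scores <- model$log_prior
  if (model$variant == "multinomial") {
    if (length(doc)) {
      j <- match(names(doc), model$vocab)
      known <- !is.na(j)
      if (any(known)) {
        scores <- scores + as.numeric(crossprod(model$log_lik[j[known], , drop = FALSE],
                                                as.numeric(doc[known])))
      }
      if (any(!known)) {
        # count-zero smoothed probability for out-of-vocabulary terms
        oov <- sum(doc[!known])
        scores <- scores + oov * (log(model$alpha) - log(model$tot + model$alpha * V))
      }
    }
  } else {
    base <- colSums(model$log_p0)
    scores <- scores + base
    if (length(doc)) {
      j <- match(names(doc)[doc > 0], model$vocab)
      known <- j[!is.na(j)]
      if (length(known)) {
        delta <- model$log_p1[known, , drop = FALSE] - model$log_p0[known, , drop = FALSE]
        scores <- scores + colSums(delta)
      }
      n_oov <- sum(is.na(j))
      if (n_oov > 0) {
        scores <- scores + n_oov * (log(model$alpha) - log(model$n_docs + 2 * model$alpha))
      }
    }
  }
  names(scores) <- model$classes
  scores
}

#' @rdname predict_nb
#' @param docs list of count documents.
#' @return For `predict_nb_many`: tibble with `label` and one posterior
#'   column per class.
#' @export
predict_nb_many <- function(model, docs) {
  res <- lapply(docs, predict_nb, model = model)
  post <- do.call(rbind, lapply(res, function(r) r$posterior))
  out <- tibble::tibble(label = unname(vapply(res, `[[`, character(1), "label")))
  for (cl in model$classes) out[[cl]] <- post[, cl]
  if (!is.null(names(docs))) out$id <- names(docs)
  out
}

#' Experiment specification
#'
#' Declarative description of a categorization experiment: design, feature
#' configuration, algorithm, folds and seed.
#'
#' @param design experiment design (see [balance_sample()]).
#' @param featureset,name_mode,target_entity feature configuration (see
#'   [prepare_feature_docs()]).
#' @param algorithm `"mnb"` (multinomial NB) or `"bnb"` (Bernoulli NB).
#' @param cv_folds number of stratified folds.
#' @param seed RNG seed covering balancing and fold assignment.
#' @param alpha NB smoothing.
#' @param min_token_freq vocabulary cut for vectorization.
#' @return list of class `experiment_spec`.
#' @export
experiment_spec <- function(design = "misuse_vs_rest", featureset = "text",
                            name_mode = "normal", target_entity = "drugs",
                            algorithm = c("mnb", "bnb"), cv_folds = 10,
                            seed = 42, alpha = 1, min_token_freq = 1) {
  algorithm <- match.arg(algorithm)
  structure(list(design = design, featureset = featureset,
                 name_mode = name_mode, target_entity = target_entity,
                 algorithm = algorithm, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed), alpha = alpha,
                 min_token_freq = min_token_freq),
            class = "experiment_spec")
}

#' Stratified cross-validation of a categorization experiment
#'
#' Builds the balanced sample for the design, assigns stratified folds
#' (seeded), trains the Naive Bayes variant on each training split and
#' predicts the held-out split, pooling the confusion matrix over folds.
#' For the `cascade` design each fold trains two binary models (no-use vs
#' rest, then normal-use vs misuse) and composes them with [run_cascade()].
#'
#' @param docs named list of count documents (by message id), e.g. from
#'   [prepare_feature_docs()].
#' @param labeled tibble with columns `id`, `label` (use classes).
#' @param spec an [experiment_spec()].
#' @return list of class `cv_result`: `report` (a `score_report` with macro
#'   and per-class scores), `confusion` (true x predicted), `accuracy`,
#'   `predictions` (tibble id/true/pred), `spec`.
#' @export
cross_validate <- function(docs, labeled, spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  sample_df <- balance_sample(labeled, spec$design, seed = spec$seed)
  missing <- setdiff(sample_df$id, names(docs))
  if (length(missing)) abort(sprintf("%d sampled ids have no feature document", length(missing)))
  k <- spec$cv_folds
  design_levels <- switch(spec$design,
    misuse_vs_rest = c("REST", "MISUSE"),
    nouse_vs_rest = c("NO_USE", "REST"),
    use_vs_misuse = c("NORMAL_USE", "MISUSE"),
    .use_classes)
  min_class <- min(table(sample_df$label))
  if (k > min_class) abort(sprintf("cv_folds (%d) exceeds smallest class size (%d)", k, min_class))
  folds <- with_seed(spec$seed + 1L, {
    f <- integer(nrow(sample_df))
    for (cl in unique(sample_df$label)) {
      idx <- which(sample_df$label == cl)
      f[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    f
  })
  truth <- character(0); predicted <- character(0); ids <- character(0)
  for (fold in seq_len(k)) {
    tr <- sample_df[folds != fold, ]
    te <- sample_df[folds == fold, ]
    if (!nrow(te)) next
    te_docs <- docs[te$id]
    if (spec$design == "cascade") {
      pred <- cascade_fold(docs, tr, te_docs, spec)
    } else {
      model <- train_nb(docs[tr$id], factor(tr$label, levels = design_levels),
                        alpha = spec$alpha, variant = nb_variant(spec$algorithm))
      pred <- predict_nb_many(model, te_docs)$label
    }
    truth <- c(truth, te$label); predicted <- c(predicted, pred)
    ids <- c(ids, te$id)
  }
  confusion <- confusion_matrix(truth, predicted, labels = design_levels)
  structure(list(report = report_from_confusion(confusion),
                 confusion = confusion,
                 accuracy = sum(diag(confusion)) / sum(confusion),
                 predictions = tibble::tibble(id = ids, true = truth, pred = predicted),
                 spec = spec),
            class = "cv_result")
}

nb_variant <- function(algorithm) {
  switch(algorithm, mnb = "multinomial", bnb = "bernoulli",
         abort(sprintf("unknown algorithm '%s'", algorithm)))
}

cascade_fold <- function(docs, tr, te_docs, spec) {
  lab1 <- factor(ifelse(tr$use_class == "NO_USE", "NO_USE", "REST"),
                 levels = c("NO_USE", "REST"))
  model1 <- train_nb(docs[tr$id], lab1, alpha = spec$alpha,
                     variant = nb_variant(spec$algorithm))
  tr2 <- tr[tr$use_class %in% c("NORMAL_USE", "MISUSE"), ]
  lab2 <- factor(tr2$use_class, levels = c("NORMAL_USE", "MISUSE"))
  model2 <- train_nb(docs[tr2$id], lab2, alpha = spec$alpha,
                     variant = nb_variant(spec$algorithm))
  run_cascade(te_docs, model1, model2)
}

#' Two-step cascade classification
#'
#' A message is labeled `NO_USE` when the first model (no-use vs rest) says
#' no-use; otherwise the second model (normal-use vs misuse) assigns
#' `NORMAL_USE` or `MISUSE`. The output label set is always within the three
#' use classes.
#'
#' @param docs named list of count documents.
#' @param model1 `nb_model` trained with labels `NO_USE` / `REST`.
#' @param model2 `nb_model` trained with labels `NORMAL_USE` / `MISUSE`.
#' @return character vector of labels, named by document id.
#' @export
run_cascade <- function(docs, model1, model2) {
  p1 <- predict_nb_many(model1, docs)$label
  out <- character(length(docs))
  is_nouse <- p1 == "NO_USE"
  out[is_nouse] <- "NO_USE"
  if (any(!is_nouse)) {
    out[!is_nouse] <- predict_nb_many(model2, docs[!is_nouse])$label
  }
  names(out) <- names(docs)
  out
}

report_from_confusion <- function(m) {
  classes <- rownames(m)
  per_class <- dplyr::bind_rows(lapply(classes, function(cl) {
    tp <- m[cl, cl]
    tibble::tibble(class = cl, tp = tp,
                   fp = sum(m[, cl]) - tp,
                   fn = sum(m[cl, ]) - tp)
  }))
  score_report(tp = sum(diag(m)),
               fp = sum(m) - sum(diag(m)),
               fn = sum(m) - sum(diag(m)),
               per_class = per_class)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> design=%s algo=%s folds=%d  accuracy=%.3f macro-F=%.3f\n",
              x$spec$design, x$spec$algorithm, x$spec$cv_folds,
              round_half_up(x$accuracy), round_half_up(x$report$macro$f)))
  invisible(x)
}
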