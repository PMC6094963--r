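ref_labeled <- function() {
  tibble::tibble(
    id = sprintf("r%04d", 1:1850),
    label = rep(c("NORMAL_USE", "NO_USE", "MISUSE"), c(1117, 600, 133)))
}

test_that("balanced sampling reproduces the reference design sizes", {
  corpus <- ref_labeled()
  mis <- balance_sample(corpus, "misuse_vs_rest", seed = 1)
  expect_identical(nrow(mis), 266L)
  expect_identical(sum(mis$label == "MISUSE"), 133L)
  expect_identical(sum(mis$label == "REST"), 133L)
  nou <- balance_sample(corpus, "nouse_vs_rest", seed = 1)
  expect_identical(nrow(nou), 600L)
  expect_identical(sum(nou$label == "NO_USE"), 300L)
  three <- balance_sample(corpus, "three_way", seed = 1)
  expect_identical(nrow(three), 399L)
  expect_identical(unname(table(three$label)["MISUSE"]), 133L)
  uvm <- balance_sample(corpus, "use_vs_misuse", seed = 1)
  expect_identical(nrow(uvm), 266L)
  # sampling is without replacement
  expect_false(anyDuplicated(mis$id) > 0)
  # UNDECIDED is excluded
  und <- dplyr::bind_rows(corpus, tibble::tibble(id = "u1", label = "UNDECIDED"))
  expect_false("u1" %in% balance_sample(und, "misuse_vs_rest", seed = 1)$id)
})

test_that("an already balanced binary corpus is returned unchanged up to order", {
  corpus <- tibble::tibble(id = paste0("b", 1:40),
                           label = rep(c("NORMAL_USE", "MISUSE"), each = 20))
  out <- balance_sample(corpus, "use_vs_misuse", seed = 9)
  expect_setequal(out$id, corpus$id)
  expect_error(balance_sample(corpus, "three_way", seed = 1), "NO_USE")
  expect_error(balance_sample(tibble::tibble(id = "x", label = "NORMAL_USE"),
                              "misuse_vs_rest"), "MISUSE")
})

test_that("multinomial training matches hand-computed smoothed ratios", {
  docs <- list(c(bon = 2, jour = 1), c(bon = 1), c(soir = 2), c(soir = 1, jour = 1))
  labels <- factor(c("A", "A", "B", "B"), levels = c("A", "B"))
  m <- train_nb(docs, labels, alpha = 1)
  # class A: counts bon=3, jour=1, soir=0; total 4; V=3
  expect_equal(exp(m$log_lik["bon", "A"]), (3 + 1) / (4 + 3))
  expect_equal(exp(m$log_lik["jour", "A"]), (1 + 1) / (4 + 3))
  expect_equal(exp(m$log_lik["soir", "A"]), (0 + 1) / (4 + 3))
  # class B: soir=3, jour=1, bon=0; total 4
  expect_equal(exp(m$log_lik["soir", "B"]), (3 + 1) / (4 + 3))
  expect_equal(sum(exp(m$log_lik[, "A"])), 1)
  expect_equal(sum(exp(m$log_prior)), 1)
  # single-token vocabulary: P(t|c) = 1 for every class
  m1 <- train_nb(list(c(x = 3), c(x = 1)), factor(c("A", "B")))
  expect_equal(unname(exp(m1$log_lik["x", ])), c(1, 1))
  # duplicating every document preserves the count ratios: in the unsmoothed
  # limit the likelihoods coincide, and the priors coincide exactly
  eps <- 1e-9
  m_lo <- train_nb(docs, labels, alpha = eps)
  m2 <- train_nb(c(docs, docs), factor(rep(labels, 2), levels = c("A", "B")),
                 alpha = eps)
  expect_equal(m2$log_lik["bon", "A"], m_lo$log_lik["bon", "A"], tolerance = 1e-6)
  expect_equal(m2$log_lik["soir", "B"], m_lo$log_lik["soir", "B"], tolerance = 1e-6)
  expect_equal(m2$log_prior, m_lo$log_prior)
  # document order is irrelevant
  perm <- c(3, 1, 4, 2)
  m3 <- train_nb(docs[perm], labels[perm])
  expect_equal(m3$log_lik, m$log_lik)
  expect_error(train_nb(docs, labels, alpha = 0), "positive")
  expect_error(train_nb(docs[1:2], factor(c("A", "A"))), "two classes")
})

test_that("prediction agrees with the exhaustive joint-probability oracle", {
  withr::with_seed(29, {
    vocab <- c("v1", "v2", "v3", "v4", "v5")
    for (i in 1:100) {
      n_docs <- sample(4:8, 1)
      labels <- c("A", "B", sample(c("A", "B"), n_docs - 2, replace = TRUE))
      docs <- replicate(n_docs, random_doc(vocab), simplify = FALSE)
      model <- train_nb(docs, factor(labels, levels = c("A", "B")))
      query <- random_doc(c(vocab, "oov"), max_len = 4)
      got <- predict_nb(model, query)
      want <- nb_joint_oracle(docs, labels, query)
      expect_equal(got$posterior[names(want)], want, tolerance = 1e-9)
      expect_equal(sum(got$posterior), 1, tolerance = 1e-9)
      expect_identical(got$label, names(want)[which.max(want)])
    }
  })
})

test_that("an empty document is classified by the prior, ties by label order", {
  docs <- list(c(a = 1), c(a = 1), c(b = 1))
  m <- train_nb(docs, factor(c("X", "X", "Y"), levels = c("Y", "X")))
  empty <- setNames(numeric(0), character(0))
  expect_identical(predict_nb(m, empty)$label, "X")  # prior 2/3
  m2 <- train_nb(docs[c(1, 3)], factor(c("X", "Y"), levels = c("Y", "X")))
  # equal priors and symmetric likelihoods for an empty doc: first level wins
  expect_identical(predict_nb(m2, empty)$label, "Y")
})

test_that("the Bernoulli variant uses presence probabilities", {
  docs <- list(c(a = 5, b = 1), c(a = 1), c(c = 2), c(c = 1, b = 1))
  labels <- factor(c("A", "A", "B", "B"))
  m <- train_nb(docs, labels, variant = "bernoulli")
  # P(a present | A) = (2 + 1) / (2 + 2) = 0.75
  expect_equal(exp(m$log_p1["a", "A"]), 0.75)
  expect_equal(exp(m$log_p1["a", "B"]), 0.25)
  # repeated counts do not matter, presence does
  p_multi <- predict_nb(m, c(a = 10))$posterior
  p_once <- predict_nb(m, c(a = 1))$posterior
  expect_equal(p_multi, p_once)
  expect_identical(predict_nb(m, c(a = 1))$label, "A")
})

test_that("cross-validation is deterministic and near 0.5 on signal-free data", {
  n <- 60
  labeled <- tibble::tibble(id = paste0("d", 1:n),
                            label = rep(c("NORMAL_USE", "MISUSE"), each = n / 2))
  docs <- setNames(rep(list(c(w = 1)), n), labeled$id)  # identical documents
  spec <- experiment_spec("use_vs_misuse", cv_folds = 5, seed = 3)
  cv1 <- cross_validate(docs, labeled, spec)
  cv2 <- cross_validate(docs, labeled, spec)
  expect_identical(cv1$confusion, cv2$confusion)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_equal(cv1$accuracy, 0.5, tolerance = 0.1)
  expect_error(cross_validate(docs, labeled, experiment_spec("use_vs_misuse", cv_folds = 40)),
               "exceeds")
})

test_that("the cascade short-circuits on no-use and composes the two models", {
  withr::with_seed(31, {
    # separable three-class toy data
    mk_doc <- function(cl) {
      base <- c(le = 1)
      cue <- switch(cl, NO_USE = c(jamais = 2), NORMAL_USE = c(prends = 2),
                    MISUSE = c(trop = 2))
      c(base, cue)
    }
    labels <- sample(rep(misuselex::use_classes(), each = 12))
    docs <- lapply(labels, mk_doc)
    names(docs) <- paste0("c", seq_along(docs))
    lab1 <- factor(ifelse(labels == "NO_USE", "NO_USE", "REST"),
                   levels = c("NO_USE", "REST"))
    model1 <- train_nb(docs, lab1)
    keep <- labels %in% c("NORMAL_USE", "MISUSE")
    model2 <- train_nb(docs[keep], factor(labels[keep], levels = c("NORMAL_USE", "MISUSE")))
    out <- run_cascade(docs, model1, model2)
    # label set invariant
    expect_true(all(out %in% misuselex::use_classes()))
    # composition: hand-compose the two predictors message by message
    for (i in seq_along(docs)) {
      p1 <- predict_nb(model1, docs[[i]])$label
      want <- if (p1 == "NO_USE") "NO_USE" else predict_nb(model2, docs[[i]])$label
      expect_identical(unname(out[i]), want)
    }
    # short-circuit: whenever model1 says no-use, the final label is NO_USE
    nouse_idx <- vapply(docs, function(d) predict_nb(model1, d)$label, character(1)) == "NO_USE"
    expect_true(all(out[nouse_idx] == "NO_USE"))
  })
})

test_that("misuse detection improves monotonically with cue strength", {
  strengths <- c(0, 0.25, 0.5, 0.75, 1)
  mean_f <- vapply(strengths, function(s) {
    fs <- vapply(1:5, function(seed) {
      corp <- generate_corpus(generator_config(200, cue_strength = s, seed = 100 + seed))
      units <- process_corpus(corp$messages, bundled_lemmas())
      docs <- prepare_feature_docs(units, corp$spans, featureset = "text")
      labeled <- tibble::tibble(id = corp$messages$id, label = corp$messages$label)
      cv <- cross_validate(docs, labeled,
                           experiment_spec("misuse_vs_rest", cv_folds = 5, seed = seed))
      cv$report$macro$f
    }, numeric(1))
    mean(fs)
  }, numeric(1))
  rho <- stats::cor(strengths, mean_f, method = "spearman")
  expect_gt(rho, 0.9)
})
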