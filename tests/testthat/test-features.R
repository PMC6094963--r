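test_that("ATC classes are the first three characters as reserved tokens", {
  expect_identical(atc_class("G03CA03"), "ATC_G03")
  expect_identical(atc_class("N06AB06"), "ATC_N06")
  expect_identical(atc_class("G03"), "ATC_G03")
  expect_error(atc_class("G0"), "3 characters")
  expect_identical(icd_token("F40.0"), "ICD_F400")
})

test_that("vectorization counts lemmas per message with a frequency cut", {
  units <- process_corpus(tibble::tibble(
    id = c("m1", "m2", "m3"),
    text = c("a b a.", "", "b c c. c a")))
  docs <- vectorize(units)
  expect_equal(docs$m1, c(a = 2, b = 1))
  expect_identical(length(docs$m2), 0L)
  # min_token_freq = 2: oracle over corpus frequencies (a: 3, b: 2, c: 3)
  freq <- table(unlist(units$lemmas[units$unit_kind == "message"]))
  keep <- names(freq)[freq >= 2]
  docs2 <- vectorize(units, min_token_freq = 2)
  expect_setequal(unique(unlist(lapply(docs2, names))), keep)
  # binary mode caps counts at 1
  docs3 <- vectorize(units, binary = TRUE)
  expect_equal(docs3$m1, c(a = 1, b = 1))
})

test_that("code augmentation appends counts without touching text features", {
  doc <- c(bonjour = 2, xanax = 1)
  spans <- entity_spans(c("m1", "m1", "m1"), c(0, 3, 5), c(1, 4, 6),
                        c("drug", "disorder", "disorder"),
                        c("xanax", "angoisse", "panique"),
                        c("G03CA03", "F41", "F41"))
  expect_identical(augment_with_codes(doc, spans, "text"), doc)
  d1 <- augment_with_codes(doc, spans, "drugs")
  expect_equal(d1[["ATC_G03"]], 1)
  d2 <- augment_with_codes(doc, spans, "disorders")
  expect_equal(d2[["ICD_F41"]], 2)   # two spans with the same group
  d3 <- augment_with_codes(doc, spans, "drugs+disorders")
  expect_equal(d3[["ATC_G03"]], 1)
  expect_equal(d3[["ICD_F41"]], 2)
  # existing counts never decrease
  for (d in list(d1, d2, d3)) {
    expect_true(all(d[names(doc)] >= doc))
  }
})

ablation_unit <- function() {
  list(tokens = c("je", "prends", "xanax", "contre", "la", "crise", "d'", "angoisse"),
       lemmas = c("je", "prendre", "xanax", "contre", "la", "crise", "d'", "angoisse"))
}
ablation_spans <- function() {
  entity_spans(c("m1", "m1"), c(2, 5), c(3, 8), c("drug", "disorder"),
               c("xanax", "crise d'angoisse"), c("N05BA12", "F41"))
}

test_that("name mode normal is the identity", {
  u <- ablation_unit()
  out <- apply_name_mode(u, ablation_spans(), "normal", "drugs")
  expect_identical(out$unit$tokens, u$tokens)
  expect_identical(out$unit$lemmas, u$lemmas)
  expect_identical(nrow(out$spans), 2L)
})

test_that("placeholder, code, normal+code and deleted rewrite spans correctly", {
  u <- ablation_unit(); sp <- ablation_spans()

  ph <- apply_name_mode(u, sp, "placeholder", "drugs")
  expect_length(ph$unit$tokens, length(u$tokens))   # 1-token span, count preserved
  expect_identical(ph$unit$tokens[3], "DRUG")

  cd <- apply_name_mode(u, sp, "code", "drugs")
  expect_identical(cd$unit$tokens[3], "ATC_N05")

  nc <- apply_name_mode(u, sp, "normal+code", "drugs")
  expect_identical(nc$unit$tokens[3:4], c("xanax", "ATC_N05"))
  expect_length(nc$unit$tokens, length(u$tokens) + 1)
  # downstream disorder span remapped by the insertion
  dis <- nc$spans[nc$spans$kind == "disorder", ]
  expect_identical(dis$start, 6L)
  expect_identical(dis$end, 9L)

  de <- apply_name_mode(u, sp, "deleted", "drugs")
  expect_length(de$unit$tokens, length(u$tokens) - 1)  # k spans of 1 token: -k
  expect_false("xanax" %in% de$unit$tokens)
  dis2 <- de$spans[de$spans$kind == "disorder", ]
  expect_identical(dis2$start, 4L)

  # multiword disorder target: placeholder collapses 3 tokens to 1
  ph2 <- apply_name_mode(u, sp, "placeholder", "disorders")
  expect_identical(ph2$unit$tokens[6], "DISORDER")
  expect_length(ph2$unit$tokens, length(u$tokens) - 2)
  cd2 <- apply_name_mode(u, sp, "code", "disorders")
  expect_identical(cd2$unit$tokens[6], "ICD_F41")
})

test_that("non-span tokens are preserved in order for every mode", {
  u <- ablation_unit(); sp <- ablation_spans()
  outside <- u$tokens[-c(3, 6:8)]
  for (m in c("normal", "code", "normal+code", "placeholder", "deleted")) {
    for (ent in c("drugs", "disorders")) {
      out <- apply_name_mode(u, sp, m, ent)
      kept <- out$unit$tokens[out$unit$tokens %in% outside]
      expect_identical(kept, outside)
    }
  }
})

test_that("overlapping target spans resolve leftmost-longest with a warning", {
  u <- ablation_unit()
  sp <- entity_spans(c("m1", "m1"), c(5, 6), c(8, 7), c("disorder", "disorder"),
                     c("crise d'angoisse", "d'"), c("F41", "F41"))
  expect_warning(out <- apply_name_mode(u, sp, "placeholder", "disorders"),
                 "leftmost-longest")
  expect_identical(sum(out$unit$tokens == "DISORDER"), 1L)
})

test_that("feature document preparation composes rewriting and augmentation", {
  corp <- generate_corpus(generator_config(40, seed = 8))
  units <- process_corpus(corp$messages, bundled_lemmas())
  docs <- prepare_feature_docs(units, corp$spans, featureset = "drugs",
                               name_mode = "placeholder", target_entity = "drugs")
  expect_identical(sort(names(docs)), sort(corp$messages$id))
  # drug surfaces are gone, replaced by the placeholder + class token
  all_terms <- unique(unlist(lapply(docs, names)))
  expect_false(any(corp$spans$surface[corp$spans$kind == "drug"] %in% all_terms))
  expect_true("DRUG" %in% all_terms)
  expect_true(any(grepl("^ATC_", all_terms)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_docs(docs, path)
  trip <- readr::read_tsv(path, show_col_types = FALSE)
  expect_true(all(c("doc", "term", "count") %in% names(trip)))
  expect_true(all(trip$count > 0))
})
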