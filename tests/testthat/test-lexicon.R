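test_that("morphological expansion adds the seed's family", {
  seeds <- toy_seeds()
  morph <- tibble::tibble(
    word = c("nerveux", "nerveusement", "nervosité", "calme", "calmement"),
    lemma = c("nerveux", "nerveusement", "nervosité", "calme", "calmement"),
    root = c("nerv", "nerv", "nerv", "calm", "calm"))
  lex <- expand_morphology(seeds, morph)
  got <- lex$term[lex$code == "F48"]
  expect_setequal(got, c("nerveux", "nerveusement", "nervosite"))
  # seed absent from the table contributes only itself
  expect_identical(lex$term[lex$code == "F41"], "angoisse")
  expect_error(expand_morphology(seeds, tibble::tibble(word = "x")), "missing")
})

test_that("morphological expansion equals the exhaustive closure on a toy table", {
  seeds <- toy_seeds()
  morph <- tibble::tibble(
    word  = c("angoisse", "angoissant", "angoissee", "nerveux", "nervosite"),
    lemma = c("angoisse", "angoissant", "angoisser", "nerveux", "nervosite"),
    root  = c("angoiss", "angoiss", "angoiss", "nerv", "nerv"))
  lex <- expand_morphology(seeds, morph)
  # oracle: brute-force scan over all rows
  for (i in seq_len(nrow(seeds))) {
    term <- seeds$term[i]
    anchors <- morph$word == term | morph$lemma == term | morph$root == term
    fam <- unique(morph$word[morph$lemma %in% morph$lemma[anchors] |
                             morph$root %in% morph$root[anchors]])
    expect_setequal(lex$term[lex$code == seeds$group[i]],
                    union(term, fam))
  }
})

test_that("alias extraction keeps inflections and drops diacritic-only variants", {
  seeds <- tibble::tibble(term = "agoraphobie", code = "F40.0", group = "F40")
  aliases <- tibble::tibble(code = c("F40.0", "F40.0"),
                            label = c("agoraphobe", "peur sociale"))
  lex <- extract_aliases(seeds, aliases)
  expect_setequal(lex$term, c("agoraphobie", "agoraphobe", "peur sociale"))

  tri <- tibble::tibble(code = rep("F20", 3),
                        label = c("schizophrénie", "schizophrènie", "schizophrenie"))
  seeds2 <- tibble::tibble(term = "schizophrenie", code = "F20", group = "F20")
  lex2 <- extract_aliases(seeds2, tri)
  expect_identical(lexicon_size(lex2), 1L)  # all three collapse onto the seed

  infl <- tibble::tibble(code = c("F40", "F40"), label = c("phobie", "phobies"))
  seeds3 <- tibble::tibble(term = "phobie", code = "F40", group = "F40")
  expect_setequal(extract_aliases(seeds3, infl)$term, c("phobie", "phobies"))

  empty <- tibble::tibble(code = character(0), label = character(0))
  expect_identical(sort(extract_aliases(toy_seeds(), empty)$term),
                   sort(toy_seeds()$term))
})

test_that("graph neighbors take top-k by weight with lexicographic ties", {
  seeds <- tibble::tibble(term = "angoisse", code = "F41.0", group = "F41")
  graph <- tibble::tibble(
    term1 = c("angoisse", "angoisse", "angoisse", "angoisse", "peur", "calme"),
    term2 = c("peur", "stress", "crainte", "effroi", "angoisse", "zen"),
    weight = c(10, 8, 8, 2, 12, 5),
    relation = c(NA, "morph", NA, NA, NA, NA))
  lex2 <- extract_graph_neighbors(seeds, graph, top_k = 2)
  # oracle: exhaustive sort of all (undirected) neighbors
  nb <- data.frame(term = c("peur", "stress", "crainte", "effroi", "peur"),
                   weight = c(10, 8, 8, 2, 12))
  nb <- nb[order(-nb$weight, nb$term), ]
  nb <- nb[!duplicated(nb$term), ]
  expect_setequal(setdiff(lex2$term, "angoisse"), head(nb$term, 2))
  # ties: crainte (8) beats stress (8) lexicographically
  lex3 <- extract_graph_neighbors(seeds, graph, top_k = 3)
  expect_true(all(c("peur", "crainte", "stress") %in% lex3$term))
  expect_identical(setdiff(extract_graph_neighbors(seeds, graph, top_k = 0)$term,
                           "angoisse"), character(0))
  morph_only <- extract_graph_neighbors(seeds, graph, top_k = 30,
                                        relation_filter = "morph")
  expect_setequal(setdiff(morph_only$term, "angoisse"), "stress")
  expect_error(extract_graph_neighbors(seeds, graph, top_k = -1), "non-negative")
})

test_that("cluster lexicon adds co-clustered words under each seed code", {
  seeds <- toy_seeds()
  clustering <- list(assignment = c(angoisse = 1L, peur = 1L, nerveux = 2L,
                                    zen = 3L, calme = 3L))
  lex <- lexicon_from_clusters(clustering, seeds)
  expect_setequal(lex$term[lex$code == "F41"], c("angoisse", "peur"))
  # seed alone in its cluster: no additions
  expect_identical(lex$term[lex$code == "F48"], "nerveux")
  # two seeds sharing one cluster: words added under both codes
  cl2 <- list(assignment = c(angoisse = 1L, nerveux = 1L, peur = 1L))
  lex2 <- lexicon_from_clusters(cl2, seeds)
  expect_true(all(c("peur") %in% lex2$term[lex2$code == "F41"]))
  expect_true(all(c("peur") %in% lex2$term[lex2$code == "F48"]))
})

test_that("total combination is the set union, associative and commutative", {
  a <- lexicon(c("x", "y"), c("F1", "F1"), "a")
  b <- lexicon(c("y", "z", "w"), c("F1", "F2", "F2"), "b")
  expect_identical(lexicon_size(combine_total(list(a))), lexicon_size(a))
  disj <- lexicon(c("p", "q", "r", "s"), rep("F9", 4), "c")
  expect_identical(lexicon_size(combine_total(list(a, disj))), 6L)
  u1 <- combine_total(list(a, b))
  u2 <- combine_total(list(b, a))
  u3 <- combine_total(list(combine_total(list(a, b)), disj))
  u4 <- combine_total(list(a, combine_total(list(b, disj))))
  key <- function(l) sort(paste(l$term, l$code))
  expect_identical(key(u1), key(u2))
  expect_identical(key(u3), key(u4))
  # union oracle
  expect_setequal(key(u1), unique(c(paste(a$term, a$code), paste(b$term, b$code))))
})

test_that("vote keeps items from at least two resources, plus all seeds", {
  seeds <- toy_seeds()
  mk <- function(extra, name) {
    l <- dplyr::bind_rows(tibble::as_tibble(seed_lexicon(seeds)),
                          tibble::tibble(term = extra, code = "F41", source = name))
    misuselex::lexicon(l$term, l$code, l$source, name = name)
  }
  l1 <- mk(c("peur", "stress"), "r1")
  l2 <- mk(c("peur"), "r2")
  l3 <- mk(c("effroi"), "r3")
  vote <- combine_vote(list(l1, l2, l3), seeds)
  expect_true("peur" %in% vote$term)        # in exactly 2 resources
  expect_false("stress" %in% vote$term)     # in exactly 1
  expect_false("effroi" %in% vote$term)
  expect_true(all(seeds$term %in% vote$term))
  # single input with min_sources = 2: seeds only
  solo <- combine_vote(list(l1), seeds)
  expect_setequal(solo$term, seeds$term)
  expect_error(combine_vote(list(l1), seeds, min_sources = 0), ">= 1")
})

test_that("every builder keeps the seeds, and vote is a subset of total", {
  seeds <- bundled_seeds()
  morph <- read_morphology_table(misuselex_extdata("morph.tsv"))
  aliases <- read_alias_table(misuselex_extdata("aliases.tsv"))
  graph <- read_graph_table(misuselex_extdata("graph.tsv"))
  lexica <- list(
    morph = expand_morphology(seeds, morph),
    alias = extract_aliases(seeds, aliases),
    graph = extract_graph_neighbors(seeds, graph),
    graph_morph = extract_graph_neighbors(seeds, graph, relation_filter = "morph"))
  seed_keys <- paste(normalize_text(seeds$term), seeds$group)
  for (lex in lexica) {
    expect_true(all(seed_keys %in% paste(lex$term, lex$code)))
  }
  total <- combine_total(lexica)
  vote <- combine_vote(lexica, seeds)
  expect_true(all(paste(vote$term, vote$code) %in% paste(total$term, total$code)))
})

test_that("lexicon TSV round-trips and reports sizes", {
  lex <- expand_morphology(bundled_seeds(),
                           read_morphology_table(misuselex_extdata("morph.tsv")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, path)
  back <- read_lexicon(path)
  expect_identical(lexicon_size(back), lexicon_size(lex))
  rep <- lexicon_report(list(seeds = seed_lexicon(bundled_seeds()), morph = lex))
  expect_identical(rep$lexicon, c("seeds", "morph"))
  expect_identical(rep$size[1], 15L)
})
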