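# Pseudo-French message templates with a closed vocabulary. Each template is
# a token vector; "<DRUG>"/"<DIS>" are slots, "<N>" is a digit slot.
# Elision tokens ("j'", "d'", ...) render attached to the next word, matching
# the tokenizer's treatment of apostrophes.

.tpl_filler <- list(
  c("bonjour", "a", "toutes"),
  c("merci", "pour", "vos", "reponses"),
  c("je", "suis", "nouvelle", "sur", "le", "forum"),
  c("j'", "espere", "que", "vous", "allez", "bien"),
  c("courage", "a", "toutes", "et", "a", "bientot"),
  c("ma", "journee", "a", "ete", "tres", "longue"),
  c("je", "reviens", "vers", "vous", "des", "que", "possible")
)

.tpl_disorder <- list(
  c("je", "souffre", "de", "<DIS>", "depuis", "<N>", "mois"),
  c("j'", "ai", "beaucoup", "de", "<DIS>", "en", "ce", "moment"),
  c("mon", "medecin", "parle", "de", "<DIS>"),
  c("on", "m'", "a", "diagnostique", "une", "<DIS>", "recemment")
)

.tpl_drug_neutral <- list(
  c("quelqu'", "un", "connait", "le", "<DRUG>"),
  c("mon", "docteur", "m'", "a", "parle", "du", "<DRUG>"),
  c("j'", "ai", "lu", "la", "notice", "du", "<DRUG>")
)

.tpl_cue_normal <- list(
  c("je", "prends", "<DRUG>", "tous", "les", "soirs", "et", "tout", "va", "bien"),
  c("je", "suis", "sous", "<DRUG>", "depuis", "<N>", "semaines"),
  c("mon", "traitement", "par", "<DRUG>", "se", "passe", "tres", "bien")
)

.tpl_cue_nouse <- list(
  c("il", "ne", "m'", "a", "pas", "prescrit", "de", "<DRUG>"),
  c("est", "ce", "que", "le", "<DRUG>", "est", "efficace", "pour", "vous"),
  c("ma", "soeur", "prend", "du", "<DRUG>", "mais", "pas", "moi"),
  c("je", "n'", "ai", "jamais", "pris", "de", "<DRUG>")
)

.tpl_cue_misuse <- list(
  intake_error = c("j'", "ai", "oublie", "de", "prendre", "mon", "<DRUG>", "hier", "soir"),
  dosage_error = c("j'", "ai", "pris", "<N>", "comprimes", "de", "<DRUG>", "au", "lieu", "d'", "un", "seul"),
  contraindication = c("je", "bois", "de", "l'", "alcool", "avec", "mon", "<DRUG>"),
  overlook_prescription = c("j'", "ai", "arrete", "le", "<DRUG>", "de", "moi", "meme", "sans", "avis"),
  fear_of_adr_underuse = c("par", "peur", "des", "effets", "je", "saute", "des", "prises", "de", "<DRUG>"),
  self_medication = c("j'", "ai", "pris", "le", "<DRUG>", "de", "ma", "soeur", "sans", "ordonnance"),
  seek_psychotropic_effect = c("je", "prends", "du", "<DRUG>", "juste", "pour", "planer"),
  seek_weight_loss = c("je", "prends", "du", "<DRUG>", "pour", "maigrir", "vite"),
  suicide_attempt = c("j'", "ai", "avale", "<N>", "boites", "de", "<DRUG>", "ce", "soir", "la"),
  addiction = c("je", "suis", "accro", "au", "<DRUG>", "impossible", "d'", "arreter")
)

.digit_tokens <- c("2", "3", "4", "6", "10")

#' Generator configuration for synthetic forum corpora
#'
#' The defaults reproduce the statistical conditions the pipeline assumes:
#' the class mix follows the reference annotated distribution (1117 normal
#' use, 600 no use, 133 misuse out of 1850, i.e. about 60/32/7 percent),
#' misuse subtypes are drawn uniformly from the typology, and drug mentions
#' are skewed towards birth-control (ATC class G03, ~60%) and
#' antidepressant/anxiolytic (N05/N06, ~15%) classes, as in the source
#' fora. `cue_strength` is the probability that a message carries the
#' explicit cue sentence of its class (the misuse subtype cue for misuse
#' messages, an intake statement for normal use, a negated-intake /
#' prescription-question framing for no use); at 0 the three classes are
#' distributionally identical except for their labels, giving a no-signal
#' control. `misspelling_rate` is the per-mention probability of a surface
#' variant (diacritic drop, adjacent-character swap or single-character
#' deletion).
#'
#' @param n_messages number of messages to generate.
#' @param class_mix probabilities over (NORMAL_USE, NO_USE, MISUSE); must
#'   sum to 1.
#' @param subtype_mix probabilities over the ten misuse subtypes.
#' @param cue_strength probability of the class cue sentence, in `[0, 1]`.
#' @param misspelling_rate per-term variant probability, in `[0, 1]`.
#' @param drug_table tibble (`surface`, `atc`); default: bundled table.
#' @param disorder_table tibble (`term`, `code`, `group`, `variants`);
#'   default: bundled table.
#' @param seed RNG seed; the same configuration and seed give a
#'   byte-identical corpus.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_messages,
                             class_mix = c(NORMAL_USE = 1117, NO_USE = 600, MISUSE = 133) / 1850,
                             subtype_mix = NULL,
                             cue_strength = 0.9,
                             misspelling_rate = 0.1,
                             drug_table = NULL,
                             disorder_table = NULL,
                             seed = 1) {
  stopifnot(n_messages >= 0)
  if (abs(sum(class_mix) - 1) > 1e-6) abort("`class_mix` must sum to 1")
  stopifnot(all(class_mix >= 0))
  if (is.null(names(class_mix))) names(class_mix) <- c("NORMAL_USE", "NO_USE", "MISUSE")
  if (cue_strength < 0 || cue_strength > 1) abort("`cue_strength` must be in [0, 1]")
  if (misspelling_rate < 0 || misspelling_rate > 1) abort("`misspelling_rate` must be in [0, 1]")
  subtypes <- names(.tpl_cue_misuse)
  if (is.null(subtype_mix)) subtype_mix <- setNames(rep(1 / length(subtypes), length(subtypes)), subtypes)
  drug_table <- drug_table %||% read_drug_table(misuselex_extdata("drugs.tsv"))
  disorder_table <- disorder_table %||% read_disorder_table(misuselex_extdata("disorders.tsv"))
  if (!nrow(drug_table) || !nrow(disorder_table))
    abort("drug and disorder tables must be non-empty")
  structure(list(n_messages = as.integer(n_messages), class_mix = class_mix,
                 subtype_mix = subtype_mix, cue_strength = cue_strength,
                 misspelling_rate = misspelling_rate, drug_table = drug_table,
                 disorder_table = disorder_table, seed = seed),
            class = "generator_config")
}

#' Path to a bundled resource file
#' @param file file name under the package's `extdata` directory.
#' @return absolute path.
#' @export
misuselex_extdata <- function(file) {
  system.file("extdata", file, package = "misuselex", mustWork = TRUE)
}

#' Read a disorder table with variant forms
#'
#' TSV with header columns `term`, `code`, `group`, `variants`
#' (comma-separated alternative surface forms).
#'
#' @param path path to the TSV file.
#' @return tibble; `variants` is a list column of character vectors.
#' @export
read_disorder_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_columns(df, c("term", "code", "group"), "disorder table")
  if (!"variants" %in% names(df)) df$variants <- ""
  tibble::tibble(
    term = as.character(df$term),
    code = as.character(df$code),
    group = as.character(df$group),
    variants = lapply(df$variants, function(v) {
      if (is.na(v) || !nzchar(v)) character(0)
      else trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    })
  )
}

#' Apply a surface variant to a term
#'
#' With probability `misspelling_rate`, applies one spelling perturbation —
#' diacritic drop (when the term carries diacritics), adjacent-character
#' swap, or single-character deletion — to one word of the term; otherwise
#' the term is returned unchanged. The chosen operation is recorded in the
#' `"op"` attribute (`"none"` when unchanged). Uses the current RNG state.
#'
#' @param term canonical (possibly accented) term.
#' @param misspelling_rate probability of perturbation, in `[0, 1]`.
#' @return the surface form, with attribute `op`.
#' @export
inject_variants <- function(term, misspelling_rate) {
  if (misspelling_rate < 0 || misspelling_rate > 1) abort("rate must be in [0, 1]")
  if (stats::runif(1) >= misspelling_rate)
    return(structure(term, op = "none"))
  has_diacritic <- !identical(normalize_plain_nodigits(term), term) &&
    stringi::stri_detect_regex(stringi::stri_trans_nfkd(term), "\\p{Mn}")
  ops <- c(if (has_diacritic) "diacritic_drop", "swap", "deletion")
  op <- if (length(ops) == 1) ops else sample(ops, 1)
  out <- switch(op,
    diacritic_drop = {
      x <- stringi::stri_trans_nfkd(term)
      stringi::stri_trans_nfc(stringi::stri_replace_all_regex(x, "\\p{Mn}+", ""))
    },
    swap = perturb_word(term, function(w) {
      n <- nchar(w)
      if (n < 2) return(w)
      cs <- strsplit(w, "")[[1]]
      diff <- which(cs[-n] != cs[-1])
      i <- if (length(diff)) diff[sample.int(length(diff), 1)] else sample.int(n - 1, 1)
      tmp <- cs[i]; cs[i] <- cs[i + 1]; cs[i + 1] <- tmp
      paste0(cs, collapse = "")
    }),
    deletion = perturb_word(term, function(w) {
      n <- nchar(w)
      if (n < 3) return(w)
      i <- sample.int(n, 1)
      paste0(substr(w, 1, i - 1), substr(w, i + 1, n))
    })
  )
  if (identical(out, term)) op <- "none"
  structure(out, op = op)
}

normalize_plain_nodigits <- function(x) {
  x <- stringi::stri_trans_nfkd(x)
  stringi::stri_trans_nfc(stringi::stri_replace_all_regex(x, "\\p{Mn}+", ""))
}

# apply f to one random word (>= 3 chars if possible) of a multiword term
perturb_word <- function(term, f) {
  words <- strsplit(term, " ", fixed = TRUE)[[1]]
  eligible <- which(nchar(words) >= 3)
  if (!length(eligible)) eligible <- seq_along(words)
  i <- if (length(eligible) == 1) eligible else eligible[sample.int(length(eligible), 1)]
  words[i] <- f(words[i])
  paste(words, collapse = " ")
}

#' Generate a synthetic forum corpus with gold annotations
#'
#' Messages are assembled from pseudo-French templates: filler sentences,
#' disorder-mention sentences (canonical or variant surface forms, with
#' seeded misspellings), neutral drug mentions, and — with probability
#' `cue_strength` — the class cue sentence (misuse subtype cues such as
#' forgotten intakes, overdose quantifiers, brutal quitting or alcohol
#' contraindication; intake statements for normal use; negated intake,
#' prescription questions or third-person mentions for no use). Every
#' message mentions at least one drug; drug classes are drawn with the
#' configured skew. Class counts are multinomial with the configured mix.
#' The generation is fully reproducible per seed.
#'
#' @param config a [generator_config()].
#' @return list of class `synthetic_corpus`:
#'   * `messages`: tibble `id`, `text`, `label`, `misuse_type`, `drugs`
#'     (list of `surface`/`atc` tibbles);
#'   * `gold_index`: reference indexing (message- and sentence-level unit
#'     ids with gold disorder code sets);
#'   * `spans`: gold entity spans (message-level token offsets, 0-based
#'     half-open) for drugs (full ATC codes) and disorders (group codes);
#'   * `term_table`: a `misuse_lexicon` of every planted disorder surface
#'     form (normalized), against which message-level indexing recall is 1
#'     by construction;
#'   * `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_messages
  drugs <- config$drug_table
  dis <- config$disorder_table
  drug_w <- drug_weights(drugs$atc)
  with_seed(config$seed, {
    labels <- if (n > 0)
      sample(names(config$class_mix), n, replace = TRUE, prob = config$class_mix)
    else character(0)
    texts <- character(n)
    subtypes <- rep(NA_character_, n)
    drug_surface <- vector("list", n)
    drug_atc <- vector("list", n)
    gold_uid <- vector("list", n)
    gold_codes <- vector("list", n)
    sp <- list(mid = vector("list", n), start = vector("list", n),
               end = vector("list", n), kind = vector("list", n),
               surface = vector("list", n), code = vector("list", n))
    ids <- sprintf("m%05d", seq_len(n))
    for (i in seq_len(n)) {
      id <- ids[i]
      label <- labels[i]
      subtype <- if (label == "MISUSE")
        sample(names(config$subtype_mix), 1, prob = config$subtype_mix)
      else NA_character_
      subtypes[i] <- subtype
      # each sentence: list(tokens, dis, dis_surface, drug (surface, atc) or NULL, q)
      sent <- list()
      for (k in seq_len(sample(0:2, 1)))
        sent[[length(sent) + 1]] <- list(tokens = fill_template(sample(.tpl_filler, 1)[[1]]),
                                         dis = NA_character_, drug = NULL, q = FALSE)
      if (stats::runif(1) < 0.7) {
        j <- sample.int(nrow(dis), 1)
        surface <- pick_disorder_surface(dis[j, ], config$misspelling_rate)
        tpl <- sample(.tpl_disorder, 1)[[1]]
        sent[[length(sent) + 1]] <- list(tokens = fill_template(tpl, dis_surface = surface),
                                         dis = dis$group[j], dis_surface = surface,
                                         drug = NULL, q = FALSE)
      }
      has_cue <- stats::runif(1) < config$cue_strength
      dj <- sample.int(nrow(drugs), 1, prob = drug_w)
      if (has_cue) {
        tpl <- switch(label,
          MISUSE = .tpl_cue_misuse[[subtype]],
          NORMAL_USE = sample(.tpl_cue_normal, 1)[[1]],
          NO_USE = sample(.tpl_cue_nouse, 1)[[1]])
        q <- label == "NO_USE" && tpl[1] %in% c("est", "quelqu'")
        sent[[length(sent) + 1]] <- list(tokens = fill_template(tpl, drug = drugs$surface[dj]),
                                         dis = NA_character_,
                                         drug = c(drugs$surface[dj], drugs$atc[dj]), q = q)
      } else {
        tpl <- sample(.tpl_drug_neutral, 1)[[1]]
        sent[[length(sent) + 1]] <- list(tokens = fill_template(tpl, drug = drugs$surface[dj]),
                                         dis = NA_character_,
                                         drug = c(drugs$surface[dj], drugs$atc[dj]),
                                         q = tpl[1] == "quelqu'")
      }
      sent <- sent[sample.int(length(sent))]

      # render text and compute message-level token offsets
      offset <- 0L
      stexts <- character(length(sent))
      gold_sent <- vector("list", length(sent))
      for (s in seq_along(sent)) {
        toks <- sent[[s]]$tokens
        stexts[s] <- paste0(render_tokens(toks), if (isTRUE(sent[[s]]$q)) " ?" else ".")
        if (!is.na(sent[[s]]$dis)) {
          dl <- length_rendered(sent[[s]]$dis_surface)
          pos <- attr(toks, "dis_pos")
          sp$mid[[i]] <- c(sp$mid[[i]], id)
          sp$start[[i]] <- c(sp$start[[i]], offset + pos - 1L)
          sp$end[[i]] <- c(sp$end[[i]], offset + pos - 1L + dl)
          sp$kind[[i]] <- c(sp$kind[[i]], "disorder")
          sp$surface[[i]] <- c(sp$surface[[i]], sent[[s]]$dis_surface)
          sp$code[[i]] <- c(sp$code[[i]], sent[[s]]$dis)
          gold_sent[[s]] <- sent[[s]]$dis
        } else gold_sent[[s]] <- character(0)
        if (!is.null(sent[[s]]$drug)) {
          pos <- attr(toks, "drug_pos")
          sp$mid[[i]] <- c(sp$mid[[i]], id)
          sp$start[[i]] <- c(sp$start[[i]], offset + pos - 1L)
          sp$end[[i]] <- c(sp$end[[i]], offset + pos)
          sp$kind[[i]] <- c(sp$kind[[i]], "drug")
          sp$surface[[i]] <- c(sp$surface[[i]], sent[[s]]$drug[1])
          sp$code[[i]] <- c(sp$code[[i]], sent[[s]]$drug[2])
          drug_surface[[i]] <- c(drug_surface[[i]], sent[[s]]$drug[1])
          drug_atc[[i]] <- c(drug_atc[[i]], sent[[s]]$drug[2])
        }
        offset <- offset + n_render_tokens(toks)
      }
      texts[i] <- paste(stexts, collapse = " ")
      gold_uid[[i]] <- c(id, paste0(id, ":", seq_along(sent) - 1L))
      gold_codes[[i]] <- c(list(sort(unique(unlist(gold_sent)))), gold_sent)
    }
    messages <- tibble::tibble(
      id = ids, text = texts, label = labels, misuse_type = subtypes,
      drugs = purrr::map2(drug_surface, drug_atc, function(s, a)
        tibble::tibble(surface = s %||% character(0), atc = a %||% character(0))))
    gold_index <- tibble::tibble(
      unit_id = unlist(gold_uid) %||% character(0),
      codes = do.call(c, c(gold_codes, list(list()))))
    spans <- tibble::tibble(
      message_id = unlist(sp$mid) %||% character(0),
      start = as.integer(unlist(sp$start) %||% integer(0)),
      end = as.integer(unlist(sp$end) %||% integer(0)),
      kind = unlist(sp$kind) %||% character(0),
      surface = unlist(sp$surface) %||% character(0),
      code = unlist(sp$code) %||% character(0))
    # every planted disorder surface, with its group code, via the span records
    ds <- spans[spans$kind == "disorder", , drop = FALSE]
    term_table <- if (nrow(ds))
      lexicon(normalize_text(ds$surface), ds$code, "gold", name = "gold")
    else lexicon(name = "gold")
    structure(list(messages = messages, gold_index = gold_index, spans = spans,
                   term_table = term_table, config = config),
              class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  tab <- table(x$messages$label)
  cat(sprintf("<synthetic_corpus> %d messages (%s), seed=%s\n",
              nrow(x$messages),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
              format(x$config$seed)))
  invisible(x)
}

# ATC-class weights mirroring the corpus skew: ~60% birth control (G03),
# ~15% antidepressants/anxiolytics (N05/N06), the rest elsewhere.
drug_weights <- function(atc) {
  cls <- substr(atc, 1, 3)
  grp <- ifelse(cls == "G03", "g03", ifelse(cls %in% c("N05", "N06"), "psy", "other"))
  mass <- c(g03 = 0.60, psy = 0.15, other = 0.25)
  per_grp <- table(grp)
  w <- mass[grp] / as.numeric(per_grp[grp])
  # groups absent from the table: renormalize over present groups
  w / sum(w)
}

pick_disorder_surface <- function(d, misspelling_rate) {
  variants <- d$variants[[1]]
  base <- if (length(variants) && stats::runif(1) < 0.5)
    variants[sample.int(length(variants), 1)]
  else d$term
  as.character(inject_variants(base, misspelling_rate))
}

# replace slots; record token positions of the disorder/drug mention
# (1-based over the *rendered* token sequence, where a multiword surface
# contributes its tokenized length)
fill_template <- function(tpl, dis_surface = NULL, drug = NULL) {
  out <- character(0)
  dis_pos <- NA_integer_; drug_pos <- NA_integer_
  for (t in tpl) {
    if (t == "<DIS>") {
      dis_pos <- length_rendered(out) + 1L
      out <- c(out, dis_surface)
    } else if (t == "<DRUG>") {
      drug_pos <- length_rendered(out) + 1L
      out <- c(out, drug)
    } else if (t == "<N>") {
      out <- c(out, sample(.digit_tokens, 1))
    } else out <- c(out, t)
  }
  structure(out, dis_pos = dis_pos, drug_pos = drug_pos)
}

# number of tokenizer tokens a template token (or multiword surface)
# contributes; pure-letter and pure-digit words take the fast path
length_rendered <- function(toks) {
  if (!length(toks)) return(0L)
  total <- 0L
  for (t in toks) {
    for (w in strsplit(t, " ", fixed = TRUE)[[1]]) {
      if (grepl("^(\\p{L}+|[0-9]+)$", w, perl = TRUE)) total <- total + 1L
      else total <- total + length(tokenize(tolower(w)))
    }
  }
  total
}

n_render_tokens <- function(toks) length_rendered(as.character(toks))

# join template tokens into text: elision tokens (ending in apostrophe)
# attach to the following word
render_tokens <- function(toks) {
  toks <- as.character(toks)
  if (!length(toks)) return("")
  out <- toks[1]
  for (t in toks[-1]) {
    if (grepl("'$", out[length(out)])) out[length(out)] <- paste0(out[length(out)], t)
    else out <- c(out, t)
  }
  paste(out, collapse = " ")
}
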