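## synthetic_corpus: labeled synthetic patient corpora with the statistical
## structure the extractors assume (note-type mix, longitudinal ordering,
## compact and narrative stage language, contextual noise, registry
## missingness), standing in for institutional data that cannot be shared.

#' Load the sentence template bank
#'
#' Plain-text, user-extensible bank of sentence frames used by the
#' generator: compact/narrative/ambiguous stage frames, benign-finding
#' phrasings for N0/M0, historical and hypothetical frames, and distractor
#' sentences.
#'
#' @param path TSV with columns `kind`, `axis` (`*` = any), `text`;
#'   the bundled bank by default.
#' @return Data frame of templates.
#' @export
load_templates <- function(path = NULL) {
  path <- path %||% system.file("extdata", "sentence_templates.tsv", package = "tnmstager")
  read.delim(path, comment.char = "#", header = FALSE,
             col.names = c("kind", "axis", "text"),
             colClasses = "character", quote = "")
}

DEFAULT_STAGE_DIST <- list(
  cT = c(`1` = 0.44, `2` = 0.19, `3` = 0.03, `4` = 0.01, missing = 0.33),
  cN = c(`0` = 0.61, `1` = 0.03, missing = 0.36),
  cM = c(`0` = 0.62, `1` = 0.05, missing = 0.33),
  surgery_fraction = 0.33,
  pT = c(`2` = 0.51, `3` = 0.25, `4` = 0.05, missing = 0.19),
  pN = c(`0` = 0.75, `1` = 0.03, missing = 0.22))

#' Simulation configuration
#'
#' Defaults encode the marginal stage distribution of a large US academic
#' prostate-cancer cohort: clinical T predominantly T1 (44%) and T2 (19%)
#' with 33% of registry T fields missing, N0 61%/N1 3%, M0 62%/M1 5%, about
#' a third of patients undergoing radical prostatectomy (and thus carrying
#' pathological stage: pT2 51%, pT3 25%, pT4 5%), and registry missingness
#' of 19-36% per field. The `missing` mass of each axis is the fraction of
#' patients with no true stage on record for that axis.
#'
#' @param n_patients number of patients.
#' @param seed RNG seed; the whole corpus is reproducible from it.
#' @param stage_distribution per-axis category probabilities (see default).
#' @param notes_per_patient integer range (min, max) of non-surgical notes.
#' @param p_negation_sentence rate of injected negated-mention sentences.
#' @param p_historical rate of historical re-statement sentences.
#' @param p_hypothetical rate of hypothetical stage discussion sentences.
#' @param p_ambiguous_prefix probability a documented stage is written
#'   without a clinical/pathological prefix (ambiguous phrasing).
#' @param p_compact_pattern probability a documented stage is written as a
#'   compact pattern rather than a narrative phrase.
#' @param p_missing_documentation probability a truly staged axis is never
#'   written into any note.
#' @param p_registry_missing probability a truly staged axis is blanked in
#'   the registry table, independent of note documentation (so some missing
#'   registry fields are recoverable from text and some are not).
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(n_patients = 500, seed = 1L,
                       stage_distribution = DEFAULT_STAGE_DIST,
                       notes_per_patient = c(2L, 6L),
                       p_negation_sentence = 0.10,
                       p_historical = 0.05,
                       p_hypothetical = 0.05,
                       p_ambiguous_prefix = 0.10,
                       p_compact_pattern = 0.5,
                       p_missing_documentation = 0.15,
                       p_registry_missing = 0.25) {
  cfg <- list(n_patients = as.integer(n_patients), seed = as.integer(seed),
              stage_distribution = stage_distribution,
              notes_per_patient = as.integer(notes_per_patient),
              p_negation_sentence = p_negation_sentence,
              p_historical = p_historical, p_hypothetical = p_hypothetical,
              p_ambiguous_prefix = p_ambiguous_prefix,
              p_compact_pattern = p_compact_pattern,
              p_missing_documentation = p_missing_documentation,
              p_registry_missing = p_registry_missing)
  bad <- character(0)
  if (cfg$n_patients < 1) bad <- c(bad, "n_patients")
  for (axis in c("cT", "cN", "cM", "pT", "pN")) {
    p <- cfg$stage_distribution[[axis]]
    if (is.null(p) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
      bad <- c(bad, paste0("stage_distribution$", axis))
  }
  sf <- cfg$stage_distribution$surgery_fraction
  if (is.null(sf) || sf < 0 || sf > 1) bad <- c(bad, "stage_distribution$surgery_fraction")
  if (length(cfg$notes_per_patient) != 2L || cfg$notes_per_patient[1] < 1 ||
      diff(cfg$notes_per_patient) < 0) bad <- c(bad, "notes_per_patient")
  for (r in c("p_negation_sentence", "p_historical", "p_hypothetical",
              "p_ambiguous_prefix", "p_compact_pattern",
              "p_missing_documentation", "p_registry_missing")) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) bad <- c(bad, r)
  }
  if (length(bad)) stopf("invalid simulation config field(s): %s", paste(bad, collapse = ", "))
  structure(cfg, class = "sim_config")
}

sample_axis <- function(p, n) {
  vals <- suppressWarnings(as.integer(names(p)))
  sample(vals, n, replace = TRUE, prob = p)   # NA for the "missing" entry
}

pick <- function(x) if (length(x) == 1L) x else x[sample.int(length(x), 1L)]

fill_template <- function(tpl, values) {
  for (k in names(values)) tpl <- gsub(paste0("{", k, "}"), values[[k]], tpl, fixed = TRUE)
  tpl
}

## pick a narrative term surface for axis/numeral compatible with the kind
pick_term <- function(targets, axis, numeral, kind) {
  ok <- targets$axis == axis & !is.na(targets$numeral) & targets$numeral == numeral &
    targets$kind %in% c("unspecified", kind)
  surf <- targets$surface[ok]
  if (!length(surf)) stopf("no narrative term for %s%d (%s)", axis, numeral, kind)
  pick(surf)
}

#' Render one stage-bearing sentence
#'
#' @param axis `"T"`, `"N"` or `"M"`.
#' @param numeral stage numeral, legal for the axis.
#' @param prefix `"clinical"`, `"pathological"` or `"unspecified"`.
#' @param style `"compact"` (parseable shorthand such as `"Staging: cT2a."`),
#'   `"narrative"` (a target-term phrasing; numeral 0 on N/M renders as a
#'   negated-finding sentence), or `"ambiguous"` (prefix-less phrasings such
#'   as "he has t3a prostate cancer").
#' @param subtype optional T subtype letter a-c.
#' @param templates template bank ([load_templates()]).
#' @param lexicon a `tnm_lexicon` supplying narrative term surfaces.
#' @return One sentence string. Uses the current RNG state, so output is
#'   fixed under a fixed seed.
#' @export
render_stage_sentence <- function(axis, numeral, prefix = "unspecified",
                                  style = c("compact", "narrative", "ambiguous"),
                                  subtype = NA_character_,
                                  templates = load_templates(),
                                  lexicon = load_lexicon()) {
  style <- match.arg(style)
  axis <- match.arg(axis, AXES)
  if (!(numeral %in% AXIS_RANGE[[axis]]))
    stopf("numeral %d is out of range for axis %s", numeral, axis)
  frames <- function(kind, ax = "*") {
    t <- templates[templates$kind == kind & templates$axis %in% c("*", ax), "text"]
    if (!length(t)) stopf("template bank has no '%s' frames", kind)
    t
  }
  sub <- if (!is.na(subtype)) subtype else ""
  if (style == "compact") {
    pre <- switch(prefix, clinical = "c", pathological = "p", "")
    pat <- paste0(pre, axis, numeral, if (axis == "T") sub else "")
    return(fill_template(pick(frames("compact_frame")), list(PAT = pat)))
  }
  if (style == "ambiguous") {
    pat <- paste0(tolower(axis), numeral, if (axis == "T") sub else "")
    return(fill_template(pick(frames("ambiguous_frame")), list(PAT = pat)))
  }
  ## narrative
  if (axis %in% c("N", "M") && numeral == 0) {
    kind <- if (axis == "N") "n0_phrase" else "m0_phrase"
    return(pick(frames(kind, axis)))
  }
  kind_hint <- if (prefix == "unspecified") "unspecified" else prefix
  term <- pick_term(lexicon$targets, axis, numeral, kind_hint)
  fill_template(pick(frames("narrative_frame")), list(TERM = term))
}

#' Simulate a labeled synthetic note corpus
#'
#' Generates, per patient: a true (possibly partially missing) stage vector
#' drawn from the configured distribution; a date-ordered sequence of typed
#' notes (history & physical first, then progress/radiology/discharge
#' notes, plus an operative and a pathology report for surgical patients);
#' stage-bearing sentences for each documented axis rendered in compact,
#' narrative or ambiguous style into notes eligible for the axis's stage
#' kind; contextual noise (negated, historical and hypothetical mentions,
#' overall-stage phrases) at the configured rates; and distractor sentences
#' throughout. The registry table holds dichotomized categories and blanks
#' truly-staged fields at `p_registry_missing` independent of documentation.
#'
#' @param config a `sim_config`.
#' @return A `tnm_simulation`: list with `notes` (a `tnm_corpus`), `truth`
#'   (numerals, dichotomized categories, documentation flags, surgery flag,
#'   age), `gold` (dichotomized categories, registry schema), `registry`
#'   (gold with independent missingness), `ages`, and the `config`.
#' @examples
#' sim <- simulate_corpus(sim_config(n_patients = 5, seed = 42))
#' head(sim$notes$text)
#' @export
simulate_corpus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  templates <- load_templates()
  lexicon <- load_lexicon()
  n <- config$n_patients
  dist <- config$stage_distribution
  pid <- sprintf("P%05d", seq_len(n))

  age <- pmin(90, pmax(35, round(rnorm(n, 67, 9))))
  surgery <- runif(n) < dist$surgery_fraction
  truth <- data.frame(patient_id = pid, age = age, surgery = surgery,
                      cT_num = sample_axis(dist$cT, n),
                      cN_num = sample_axis(dist$cN, n),
                      cM_num = sample_axis(dist$cM, n),
                      pT_num = NA_integer_, pN_num = NA_integer_)
  truth$pT_num[surgery] <- sample_axis(dist$pT, sum(surgery))
  truth$pN_num[surgery] <- sample_axis(dist$pN, sum(surgery))

  for (task in TASKS) {
    num <- truth[[paste0(task, "_num")]]
    truth[[task]] <- ifelse(is.na(num), NA_character_,
                            vapply(ifelse(is.na(num), 0L, num), function(v)
                              dichotomize(TASK_KIND[[task]], TASK_AXIS[[task]], v),
                              character(1)))
    truth[[paste0("doc_", task)]] <- !is.na(num) &
      runif(n) >= config$p_missing_documentation
  }

  distractors <- templates$text[templates$kind == "distractor"]
  overall_frames <- templates$text[templates$kind == "overall_stage"]
  hist_frames <- templates$text[templates$kind == "historical_frame"]
  hyp_frames <- templates$text[templates$kind == "hypothetical_frame"]
  valued <- lexicon$targets[!is.na(lexicon$targets$numeral) &
                              lexicon$targets$numeral >= 1, , drop = FALSE]

  distractor_sentence <- function() {
    fill_template(pick(distractors),
                  list(NUM = sprintf("%.1f", round(runif(1, 0.5, 15), 1)),
                       SMALLNUM = as.character(sample(2:12, 1))))
  }

  note_rows <- vector("list", n)
  for (p in seq_len(n)) {
    n_base <- sample(seq(config$notes_per_patient[1], config$notes_per_patient[2]), 1L)
    types <- c("history_physical",
               sample(c("progress", "radiology", "discharge_transfer", "other"),
                      n_base - 1L, replace = TRUE,
                      prob = c(0.55, 0.20, 0.15, 0.10)))
    if (surgery[p]) types <- c(types, "operative", "pathology")
    n_notes <- length(types)
    start <- as.Date("2010-01-01") + sample.int(3200, 1L)
    dates <- start + cumsum(c(0L, sample(5:60, n_notes - 1L, replace = TRUE)))
    sentences <- replicate(n_notes, character(0), simplify = FALSE)
    for (k in seq_len(n_notes))
      sentences[[k]] <- replicate(1L + stats::rpois(1, 1), distractor_sentence())

    place <- function(eligible_types, sentence) {
      ok <- which(types %in% eligible_types)
      k <- if (length(ok)) pick(ok) else 1L
      sentences[[k]] <<- append(sentences[[k]], sentence,
                                after = sample.int(length(sentences[[k]]) + 1L, 1L) - 1L)
    }

    for (task in TASKS) {
      if (!truth[[paste0("doc_", task)]][p]) next
      kind <- TASK_KIND[[task]]; axis <- TASK_AXIS[[task]]
      num <- truth[[paste0(task, "_num")]][p]
      subtype <- if (axis == "T" && runif(1) < 0.5) sample(c("a", "b", "c"), 1) else NA_character_
      ambiguous <- runif(1) < config$p_ambiguous_prefix
      style <- if (ambiguous) "ambiguous"
               else if (runif(1) < config$p_compact_pattern) "compact" else "narrative"
      sent <- render_stage_sentence(axis, num,
                                    prefix = if (ambiguous) "unspecified" else kind,
                                    style = style, subtype = subtype,
                                    templates = templates, lexicon = lexicon)
      eligible <- if (kind == "clinical") CLINICAL_NOTE_TYPES else "pathology"
      place(eligible, sent)
    }

    ## contextual noise
    if (runif(1) < config$p_negation_sentence) {
      kind <- pick(c("n0_phrase", "m0_phrase"))
      place(CLINICAL_NOTE_TYPES, pick(templates$text[templates$kind == kind]))
    }
    if (runif(1) < config$p_historical) {
      doc_t <- truth$doc_cT[p] && !is.na(truth$cT_num[p])
      if (doc_t) {
        term <- pick_term(lexicon$targets, "T", truth$cT_num[p], "clinical")
        place(CLINICAL_NOTE_TYPES, fill_template(pick(hist_frames), list(TERM = term)))
      }
    }
    if (runif(1) < config$p_hypothetical) {
      row <- sample.int(nrow(valued), 1L)
      place(CLINICAL_NOTE_TYPES,
            fill_template(pick(hyp_frames), list(TERM = valued$surface[row])))
    }
    if (runif(1) < config$p_ambiguous_prefix / 2) {
      place(CLINICAL_NOTE_TYPES,
            fill_template(pick(overall_frames),
                          list(OVER = as.character(sample(1:4, 1)))))
    }

    note_rows[[p]] <- data.frame(
      patient_id = pid[p],
      note_id = sprintf("%s.N%02d", pid[p], seq_len(n_notes)),
      note_type = types, date = dates,
      text = vapply(sentences, paste, character(1), collapse = " "))
  }
  notes <- new_corpus(as.data.frame(data.table::rbindlist(note_rows)))

  gold <- truth[, c("patient_id", TASKS)]
  registry <- gold
  for (task in TASKS) {
    blank <- !is.na(registry[[task]]) & runif(n) < config$p_registry_missing
    registry[[task]][blank] <- NA_character_
  }
  ages <- setNames(truth$age, truth$patient_id)
  structure(list(notes = notes, truth = truth, gold = gold,
                 registry = registry, ages = ages, config = config),
            class = "tnm_simulation")
}

#' @export
print.tnm_simulation <- function(x, ...) {
  cat(sprintf("<tnm_simulation: %d patients, %d notes (seed %d)>\n",
              x$config$n_patients, nrow(x$notes), x$config$seed))
  invisible(x)
}
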