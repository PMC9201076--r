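## rule_engine: compact TNM pattern grammar, narrative term -> stage mapping,
## ConText-style contextual flagging, and patient-level stage resolution.

## Compact pattern grammar: optional kind prefix (c/p/yp), then a non-empty
## in-order subset of T<d><a-c>?, N<d>, M<d>, contiguous or space-separated.
## The lookahead guarantees at least one component so no empty match exists;
## the trailing lookahead rejects truncated or out-of-range patterns.
COMPACT_PATTERN <- paste0(
  "(?i)(?<![[:alnum:]])",
  "(yp|c|p)?\\s?",
  "(?=[tnm][0-4])",
  "(t([0-4])([a-c])?)?\\s?",
  "(n([0-3]))?\\s?",
  "(m([01]))?",
  "(?![[:alnum:]])")

OVERALL_PATTERN <-
  "(?i)(?<![[:alnum:]])stage\\s+([1-4])\\s+prostate\\s+(?:cancer|ca)(?![[:alnum:]])"

empty_mentions <- function() {
  data.frame(sent_idx = integer(0), axis = character(0), numeral = integer(0),
             subtype = character(0), prefix = character(0), prefix_raw = character(0),
             start = integer(0), end = integer(0), source = character(0),
             pattern_id = character(0), ambiguous = logical(0), negated = logical(0),
             historical = logical(0), hypothetical = logical(0),
             experiencer_other = logical(0))
}

new_mentions <- function(sent_idx, axis, numeral, subtype, prefix, prefix_raw,
                         start, end, source, pattern_id) {
  data.frame(sent_idx = sent_idx, axis = axis, numeral = as.integer(numeral),
             subtype = subtype, prefix = prefix, prefix_raw = prefix_raw,
             start = as.integer(start), end = as.integer(end), source = source,
             pattern_id = pattern_id, ambiguous = prefix == "unspecified",
             negated = FALSE, historical = FALSE, hypothetical = FALSE,
             experiencer_other = FALSE)
}

## vectorized over a character vector of sentences
parse_compact_batch <- function(texts) {
  ms <- gregexpr(COMPACT_PATTERN, texts, perl = TRUE)
  out <- list()
  for (s in seq_along(ms)) {
    m <- ms[[s]]
    if (m[1] == -1L) next
    cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
    for (k in seq_along(m)) {
      pre_raw <- if (cl[k, 1] > 0) substr(texts[s], cs[k, 1], cs[k, 1] + cl[k, 1] - 1L) else ""
      prefix <- switch(tolower(pre_raw), p = , yp = "pathological", c = "clinical", "unspecified")
      pid <- sprintf("s%d.p%d", s, k)
      groups <- list(T = c(2L, 3L, 4L), N = c(5L, 6L, NA), M = c(7L, 8L, NA))
      for (axis in names(groups)) {
        g <- groups[[axis]]
        if (cl[k, g[1]] <= 0) next
        numeral <- as.integer(substr(texts[s], cs[k, g[2]], cs[k, g[2]] + cl[k, g[2]] - 1L))
        subtype <- NA_character_
        if (!is.na(g[3]) && cl[k, g[3]] > 0)
          subtype <- tolower(substr(texts[s], cs[k, g[3]], cs[k, g[3]] + cl[k, g[3]] - 1L))
        out[[length(out) + 1L]] <- new_mentions(
          s, axis, numeral, subtype, prefix, pre_raw,
          cs[k, g[1]] - 1L, cs[k, g[1]] - 1L + cl[k, g[1]],
          "compact_pattern", pid)
      }
    }
  }
  if (!length(out)) return(empty_mentions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Parse compact TNM patterns in a sentence
#'
#' Recognizes shorthand staging patterns such as `"pT1N2M0"`, `"cT2aN0M0"` or
#' a bare `"t3a"`: an optional kind prefix (`c`, `p` or `yp`,
#' case-insensitive) followed by any non-empty in-order subset of
#' `T<digit><a-c>?`, `N<digit>`, `M<digit>`, contiguous or
#' whitespace-separated. The prefix applies to every component of the
#' pattern; each component yields one stage mention. Out-of-range numerals
#' (e.g. `T5`) yield no mention.
#'
#' @param sentence_text raw sentence text.
#' @return A mention data frame (one row per axis component) with 0-based
#'   half-open `start`/`end` character spans; prefix-less patterns are
#'   flagged `ambiguous` because the stage kind is not stated.
#' @examples
#' parse_compact_tnm("Staging: pT1N2M0.")
#' @export
parse_compact_tnm <- function(sentence_text) {
  m <- parse_compact_batch(sentence_text)
  if (tnm_verbose() &&
      grepl("(?i)(?<![[:alnum:]])(?:yp|c|p)?\\s?[t][5-9]", sentence_text, perl = TRUE))
    tnm_log("out-of-range T numeral ignored in: ", sentence_text)
  m
}

## re-render one compact pattern (mentions sharing a pattern_id) as text
render_compact <- function(mentions) {
  mentions <- mentions[order(match(mentions$axis, AXES)), , drop = FALSE]
  comp <- vapply(seq_len(nrow(mentions)), function(i) {
    paste0(mentions$axis[i], mentions$numeral[i],
           if (!is.na(mentions$subtype[i])) mentions$subtype[i] else "")
  }, character(1))
  paste0(mentions$prefix_raw[1], paste(comp, collapse = ""))
}

narrative_batch <- function(texts, targets) {
  out <- list()
  hits <- batch_match_phrases(texts, targets)
  hits <- hits[!is.na(hits$numeral), , drop = FALSE]
  if (nrow(hits)) {
    out[[1L]] <- new_mentions(hits$sent_idx, hits$axis, hits$numeral,
                              NA_character_, hits$kind, "",
                              hits$start, hits$end, "narrative_term",
                              NA_character_)
  }
  om <- gregexpr(OVERALL_PATTERN, texts, perl = TRUE)
  for (s in seq_along(om)) {
    m <- om[[s]]
    if (m[1] == -1L) next
    cs <- attr(m, "capture.start"); cl <- attr(m, "capture.length")
    len <- attr(m, "match.length")
    for (k in seq_along(m)) {
      row <- new_mentions(s, "overall",
                          as.integer(substr(texts[s], cs[k, 1], cs[k, 1] + cl[k, 1] - 1L)),
                          NA_character_, "unspecified", "",
                          m[k] - 1L, m[k] - 1L + len[k], "narrative_term", NA_character_)
      row$ambiguous <- TRUE
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) return(empty_mentions())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect narrative stage mentions
#'
#' Matches value-bearing lexicon terms (e.g. "extracapsular extension" for
#' T3) in a sentence; each match yields a stage mention whose prefix is the
#' term's stage-kind hint (or `unspecified`). Overall-stage phrasings such
#' as "stage 1 prostate cancer" are recorded as `axis = "overall"` mentions
#' flagged ambiguous; they are never converted into TNM values.
#'
#' @param sentence_text raw sentence text.
#' @param target_terms target-term data frame (`lex$targets`).
#' @return Mention data frame.
#' @export
detect_narrative_mentions <- function(sentence_text, target_terms) {
  narrative_batch(sentence_text, target_terms)
}

## fast vectorized phrase matching over many sentences; candidates resolved
## longest-first at each scan position, non-overlapping, case-insensitive,
## at word boundaries
batch_match_phrases <- function(texts, table) {
  base <- cbind(data.frame(sent_idx = integer(0)), table[0, , drop = FALSE],
                data.frame(start = integer(0), end = integer(0)))
  if (!nrow(table) || !length(texts)) return(base)
  surf <- table$surface[order(-nchar(table$surface))]
  pat <- paste0("(?<![[:alnum:]])(?:",
                paste(regex_escape(surf), collapse = "|"),
                ")(?![[:alnum:]])")
  lower <- tolower(texts)
  ms <- gregexpr(pat, lower, perl = TRUE)
  starts <- lapply(ms, function(m) if (m[1] == -1L) integer(0) else as.integer(m) - 1L)
  lens <- lapply(ms, function(m) if (m[1] == -1L) integer(0) else attr(m, "match.length"))
  ns <- lengths(starts)
  if (!sum(ns)) return(base)
  sent_idx <- rep(seq_along(texts), ns)
  start <- unlist(starts, use.names = FALSE)
  len <- unlist(lens, use.names = FALSE)
  matched <- substring(lower[sent_idx], start + 1L, start + len)
  row <- match(matched, table$surface)
  ok <- !is.na(row)
  out <- cbind(data.frame(sent_idx = sent_idx[ok]), table[row[ok], , drop = FALSE],
               data.frame(start = start[ok], end = start[ok] + len[ok]))
  rownames(out) <- NULL
  out
}

## ConText scope computation for one sentence's triggers; returns the
## mention data frame with contextual flags set
context_flags <- function(mentions, triggers, sent_len) {
  if (!nrow(mentions) || !nrow(triggers)) return(mentions)
  live <- triggers[!(triggers$type %in% c("pseudo", "termination")), , drop = FALSE]
  terms <- triggers[triggers$type == "termination", , drop = FALSE]
  for (i in seq_len(nrow(live))) {
    typ <- live$type[i]; dir <- live$direction[i]
    same <- live[live$type == typ, , drop = FALSE]
    scopes <- list()
    if (dir %in% c("forward", "bidirectional")) {
      lim <- c(sent_len,
               terms$start[terms$start >= live$end[i]],
               same$start[same$start >= live$end[i]])
      scopes[[length(scopes) + 1L]] <- c(live$end[i], min(lim))
    }
    if (dir %in% c("backward", "bidirectional")) {
      lim <- c(0L,
               terms$end[terms$end <= live$start[i]],
               same$end[same$end <= live$start[i]])
      scopes[[length(scopes) + 1L]] <- c(max(lim), live$start[i])
    }
    col <- c(negation = "negated", historical = "historical",
             hypothetical = "hypothetical",
             experiencer_other = "experiencer_other")[[typ]]
    for (sc in scopes) {
      inside <- mentions$start < sc[2] & mentions$end > sc[1]
      if (any(inside)) mentions[[col]][inside] <- TRUE
    }
  }
  mentions
}

#' Apply ConText-style contextual flags to mentions
#'
#' Each modifier trigger opens a scope in its direction, bounded by the
#' sentence boundary, the nearest termination trigger, or the next trigger
#' of the same type; mentions inside a negation scope get `negated = TRUE`,
#' and analogously for historical, hypothetical and non-patient experiencer.
#' Pseudo-triggers consume their text but open no scope.
#'
#' @param sentence_text raw sentence text.
#' @param mentions mention data frame whose spans lie within the sentence.
#' @param modifier_triggers modifier data frame (`lex$modifiers`).
#' @return The mention data frame with contextual flag columns updated.
#' @examples
#' lex <- load_lexicon()
#' m <- detect_narrative_mentions("no evidence of nodal metastasis", lex$targets)
#' apply_context("no evidence of nodal metastasis", m, lex$modifiers)
#' @export
apply_context <- function(sentence_text, mentions, modifier_triggers) {
  trig <- batch_match_phrases(sentence_text, modifier_triggers)
  context_flags(mentions, trig, nchar(sentence_text))
}

#' Extract contextualized stage mentions from one sentence
#'
#' Runs the compact TNM parser and narrative term detection (narrative
#' matches overlapping a compact pattern are dropped), then applies
#' contextual flagging.
#'
#' @param sentence_text raw sentence text.
#' @param lexicon a `tnm_lexicon`.
#' @return Mention data frame with context flags.
#' @export
extract_mentions <- function(sentence_text, lexicon) {
  men <- combine_mentions(parse_compact_batch(sentence_text),
                          narrative_batch(sentence_text, lexicon$targets))
  apply_context(sentence_text, men, lexicon$modifiers)
}

## drop narrative mentions overlapping a compact mention in the same sentence
combine_mentions <- function(compact, narrative) {
  if (!nrow(narrative)) return(compact)
  if (!nrow(compact)) return(narrative)
  keep <- rep(TRUE, nrow(narrative))
  for (i in seq_len(nrow(narrative))) {
    same <- compact$sent_idx == narrative$sent_idx[i]
    if (any(same & compact$start < narrative$end[i] & compact$end > narrative$start[i]))
      keep[i] <- FALSE
  }
  out <- rbind(compact, narrative[keep, , drop = FALSE])
  out <- out[order(out$sent_idx, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dichotomize a stage numeral into a binary task category
#'
#' Patient-level binary categories: clinical T (`T1-2` vs `T3-4`), clinical
#' N (`N0` vs `N1`), clinical M (`M0` vs `M1`), pathological T (`T2` vs
#' `T3-4`) and pathological N (`N0` vs `N1`). Any raw nodal involvement
#' (N >= 1) collapses to `N1`. Pathological M is not supported: too few
#' patients carry a pathological M stage for a meaningful binary task.
#'
#' @param stage_kind `"clinical"` or `"pathological"`.
#' @param axis `"T"`, `"N"` or `"M"`.
#' @param numeral stage numeral, legal for the axis.
#' @return The category string.
#' @examples
#' dichotomize("clinical", "T", 1)
#' dichotomize("pathological", "T", 4)
#' @export
dichotomize <- function(stage_kind, axis, numeral) {
  stage_kind <- match.arg(stage_kind, STAGE_KINDS)
  axis <- match.arg(axis, AXES)
  if (stage_kind == "pathological" && axis == "M")
    stopf("unsupported axis: pathological M stage is excluded from the binary tasks")
  numeral <- as.integer(numeral)
  if (!(numeral %in% AXIS_RANGE[[axis]]))
    stopf("numeral %d is out of range for axis %s", numeral, axis)
  switch(axis,
         T = if (stage_kind == "clinical") {
           if (numeral <= 2) "T1-2" else "T3-4"
         } else {
           if (numeral <= 2) "T2" else "T3-4"
         },
         N = if (numeral == 0) "N0" else "N1",
         M = if (numeral == 0) "M0" else "M1")
}

## recency rank: later date wins; dateless mentions count most recent
## (they sort last in a patient record); ties broken by note_id, sentence
## index and character offset so the rank is permutation-invariant
recency_order <- function(m) {
  d <- as.numeric(m$date)
  d[is.na(d)] <- Inf
  order(d, m$note_id, m$index, m$start, decreasing = TRUE)
}

resolve_axis <- function(m, stage_kind, axis) {
  m <- m[m$axis == axis & !is.na(m$numeral), , drop = FALSE]
  ## canonical order so the result (provenance included) is invariant to
  ## the order mentions were supplied in
  m <- m[rev(recency_order(m)), , drop = FALSE]
  rownames(m) <- NULL
  missing_res <- list(category = NA_character_, numeral = NA_integer_,
                      from_negation = FALSE, ambiguous = FALSE,
                      n_support = 0L, provenance = m[0, , drop = FALSE])
  if (!nrow(m)) return(missing_res)
  routed <- ifelse(m$prefix != "unspecified", m$prefix,
                   ifelse(!is.na(m$note_type) & m$note_type == "pathology",
                          "pathological", "clinical"))
  m <- m[routed == stage_kind, , drop = FALSE]
  if (!nrow(m)) return(missing_res)
  pos <- m[!(m$negated | m$hypothetical | m$experiencer_other), , drop = FALSE]
  if (nrow(pos)) {
    counts <- table(pos$numeral)
    modal <- as.integer(names(counts)[counts == max(counts)])
    if (length(modal) > 1L) {
      rec <- pos[recency_order(pos), , drop = FALSE]
      chosen <- rec$numeral[match(TRUE, rec$numeral %in% modal)]
    } else chosen <- modal
    support <- pos[pos$numeral == chosen, , drop = FALSE]
    return(list(category = dichotomize(stage_kind, axis, chosen),
                numeral = chosen, from_negation = FALSE,
                ambiguous = any(support$ambiguous),
                n_support = nrow(support), provenance = support))
  }
  ## complementary assertion: a negated positive value on a binary axis
  ## asserts the benign value (negated M1 => M0, negated N1 => N0); never T
  neg <- m[m$negated & !m$hypothetical & !m$experiencer_other, , drop = FALSE]
  if (axis %in% c("N", "M") && any(neg$numeral >= 1)) {
    support <- neg[neg$numeral >= 1, , drop = FALSE]
    return(list(category = dichotomize(stage_kind, axis, 0L),
                numeral = 0L, from_negation = TRUE,
                ambiguous = any(support$ambiguous),
                n_support = nrow(support), provenance = support))
  }
  missing_res
}

#' Resolve a patient's stage from contextualized mentions
#'
#' Patient-level conflict resolution for one stage kind: (1) mentions
#' flagged negated, hypothetical or other-experiencer are discarded
#' (historical mentions are retained — a stage assigned in the past is still
#' the stage at diagnosis); (2) mentions are routed to a stage kind by their
#' prefix, with unspecified prefixes resolved by note type (pathology report
#' -> pathological, otherwise clinical); (3) the modal numeral wins, ties
#' broken by recency; if only negated evidence exists on a binary axis, the
#' complementary benign value is asserted (negated M1 gives M0) and flagged
#' in provenance; (4) the surviving numeral is dichotomized. No surviving
#' evidence leaves the field missing. The procedure is deterministic and
#' invariant to mention order.
#'
#' @param mentions mention data frame carrying `note_type`, `date`,
#'   `note_id`, `index` (sentence position) columns; mentions must come from
#'   notes passing [select_notes_for_stage_kind()].
#' @param stage_kind `"clinical"` or `"pathological"`.
#' @return Named list per axis (`T`, `N`, and for clinical `M`), each a list
#'   with `category`, `numeral`, `from_negation`, `ambiguous`, `n_support`
#'   and `provenance`.
#' @export
resolve_patient_stage <- function(mentions, stage_kind = c("clinical", "pathological")) {
  stage_kind <- match.arg(stage_kind)
  axes <- if (stage_kind == "clinical") c("T", "N", "M") else c("T", "N")
  for (col in c("note_type", "date", "note_id", "index")) {
    if (is.null(mentions[[col]])) {
      mentions[[col]] <- if (col == "date") as.Date(NA) else NA
    }
  }
  setNames(lapply(axes, function(a) resolve_axis(mentions, stage_kind, a)), axes)
}

#' Extract patient-level TNM stage with the rule-based engine
#'
#' End-to-end rule-based extraction: each patient's eligible notes are split
#' into sentences, stage mentions are detected (compact patterns and
#' narrative terms), contextual flags applied, and the mentions resolved to
#' dichotomized patient-level categories per stage kind.
#'
#' @param records list of `patient_record`s, or a `tnm_corpus` (which will
#'   be assembled with [assemble_patients()]).
#' @param lexicon a `tnm_lexicon`; the bundled lexicon by default.
#' @param stage_kind `"clinical"`, `"pathological"` or `"both"`.
#' @return Data frame in the registry schema (`patient_id, cT, cN, cM, pT,
#'   pN`; `NA` for unextracted fields) with attributes `"mentions"` (the
#'   full contextualized mention table) and `"details"` (per-field
#'   provenance summaries: support counts, complementary-negation and
#'   ambiguity flags).
#' @examples
#' notes <- data.frame(patient_id = "p1", note_id = "n1",
#'                     note_type = "progress", date = as.Date("2012-01-05"),
#'                     text = "Assessment. Staging: cT2aN0M0.")
#' extract_stages(assemble_patients(notes))
#' @export
extract_stages <- function(records, lexicon = load_lexicon(),
                           stage_kind = c("both", "clinical", "pathological")) {
  stage_kind <- match.arg(stage_kind)
  if (is.data.frame(records)) records <- assemble_patients(records)
  kinds <- if (stage_kind == "both") STAGE_KINDS else stage_kind

  ## sentence table over all notes of all records
  tabs <- list()
  for (rec in records) {
    notes <- rec$notes
    for (i in seq_len(nrow(notes))) {
      s <- split_sentences(notes$text[i], notes$note_id[i])
      if (!nrow(s)) next
      s$patient_id <- rec$patient_id
      s$note_type <- notes$note_type[i]
      s$date <- notes$date[i]
      tabs[[length(tabs) + 1L]] <- s
    }
  }
  out <- data.frame(patient_id = vapply(records, `[[`, character(1), "patient_id"),
                    cT = NA_character_, cN = NA_character_, cM = NA_character_,
                    pT = NA_character_, pN = NA_character_)
  rownames(out) <- NULL
  if (!length(tabs)) {
    attr(out, "mentions") <- empty_mentions()
    attr(out, "details") <- list()
    return(out)
  }
  sent <- do.call(rbind, tabs)
  rownames(sent) <- NULL

  men <- combine_mentions(parse_compact_batch(sent$text),
                          narrative_batch(sent$text, lexicon$targets))
  trig <- batch_match_phrases(sent$text, lexicon$modifiers)
  if (nrow(men) && nrow(trig)) {
    for (s in intersect(unique(men$sent_idx), unique(trig$sent_idx))) {
      sel <- men$sent_idx == s
      men[sel, ] <- context_flags(men[sel, , drop = FALSE],
                                  trig[trig$sent_idx == s, , drop = FALSE],
                                  nchar(sent$text[s]))
    }
  }
  ## join sentence metadata
  men$patient_id <- sent$patient_id[men$sent_idx]
  men$note_id <- sent$note_id[men$sent_idx]
  men$note_type <- sent$note_type[men$sent_idx]
  men$date <- sent$date[men$sent_idx]
  men$index <- sent$index[men$sent_idx]

  details <- list()
  real <- men[men$axis %in% AXES, , drop = FALSE]
  by_patient <- split(real, real$patient_id)
  for (kind in kinds) {
    allowed <- if (kind == "clinical") CLINICAL_NOTE_TYPES else PATHOLOGICAL_NOTE_TYPES
    for (pid in names(by_patient)) {
      m <- by_patient[[pid]]
      m <- m[m$note_type %in% allowed, , drop = FALSE]
      if (!nrow(m)) next
      res <- resolve_patient_stage(m, kind)
      for (axis in names(res)) {
        task <- paste0(substr(kind, 1, 1), axis)
        row <- which(out$patient_id == pid)
        out[[task]][row] <- res[[axis]]$category
        if (!is.na(res[[axis]]$category))
          details[[paste(pid, task, sep = ".")]] <-
            res[[axis]][c("numeral", "from_negation", "ambiguous", "n_support")]
      }
    }
  }
  attr(out, "mentions") <- men
  attr(out, "details") <- details
  out
}
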