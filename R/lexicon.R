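## knowledge_base: staging target-term lexicon + contextual modifier lexicon.

MODIFIER_TYPES <- c("negation", "historical", "hypothetical",
                    "experiencer_other", "pseudo", "termination")
TERM_SOURCES <- c("AJCC", "expert", "embedding_expansion")

#' Load a staging lexicon
#'
#' Loads the target-term dictionary (staging phrases, optionally mapped to a
#' TNM axis value) and the contextual-modifier dictionary (negation,
#' historical, hypothetical, experiencer, pseudo and termination triggers)
#' from tab-separated files; `#` comment lines are allowed. With no
#' arguments the bundled lexicon is loaded. Entries failing validation
#' (unknown axis, numeral outside the axis's legal range, unknown modifier
#' type) are rejected and logged; duplicate surfaces are collapsed with a
#' warning.
#'
#' @param targets_path TSV with columns `surface, axis, numeral, kind,
#'   source`; an empty numeral marks an anchor term carrying no stage value.
#' @param modifiers_path TSV with columns `surface, type, direction`.
#' @return A `tnm_lexicon` object: list with data frames `targets` and
#'   `modifiers`, plus a `rejected` data frame.
#' @examples
#' lex <- load_lexicon()
#' nrow(lex$targets)
#' @export
load_lexicon <- function(targets_path = NULL, modifiers_path = NULL) {
  targets_path <- targets_path %||%
    system.file("extdata", "target_terms.tsv", package = "tnmstager")
  modifiers_path <- modifiers_path %||%
    system.file("extdata", "context_modifiers.tsv", package = "tnmstager")
  tg <- read.delim(targets_path, comment.char = "#", header = FALSE,
                   col.names = c("surface", "axis", "numeral", "kind", "source"),
                   colClasses = "character", quote = "", strip.white = TRUE)
  md <- read.delim(modifiers_path, comment.char = "#", header = FALSE,
                   col.names = c("surface", "type", "direction"),
                   colClasses = "character", quote = "", strip.white = TRUE)
  rejected <- list()
  reject <- function(surface, why)
    rejected[[length(rejected) + 1L]] <<- data.frame(surface = surface, reason = why)

  tg$surface <- tolower(tg$surface)
  tg$numeral <- suppressWarnings(as.integer(tg$numeral))
  keep <- rep(TRUE, nrow(tg))
  for (i in seq_len(nrow(tg))) {
    if (!nzchar(tg$surface[i])) { reject(tg$surface[i], "empty surface"); keep[i] <- FALSE; next }
    if (!(tg$axis[i] %in% AXES)) { reject(tg$surface[i], "invalid axis"); keep[i] <- FALSE; next }
    if (!is.na(tg$numeral[i]) && !(tg$numeral[i] %in% AXIS_RANGE[[tg$axis[i]]])) {
      reject(tg$surface[i], "numeral out of range"); keep[i] <- FALSE; next
    }
    if (!(tg$kind[i] %in% c(STAGE_KINDS, "unspecified"))) {
      reject(tg$surface[i], "invalid kind"); keep[i] <- FALSE; next
    }
    if (!(tg$source[i] %in% TERM_SOURCES)) {
      reject(tg$surface[i], "invalid source"); keep[i] <- FALSE
    }
  }
  tg <- tg[keep, , drop = FALSE]
  dup <- duplicated(tg[, c("surface", "axis")])
  if (any(dup)) {
    warning(sprintf("%d duplicate target term(s) collapsed", sum(dup)))
    tg <- tg[!dup, , drop = FALSE]
  }

  md$surface <- tolower(md$surface)
  keep <- nzchar(md$surface) & md$type %in% MODIFIER_TYPES &
    md$direction %in% c("forward", "backward", "bidirectional")
  for (i in which(!keep)) reject(md$surface[i], "invalid modifier entry")
  md <- md[keep, , drop = FALSE]
  dup <- duplicated(md$surface)
  if (any(dup)) {
    warning(sprintf("%d duplicate modifier trigger(s) collapsed", sum(dup)))
    md <- md[!dup, , drop = FALSE]
  }
  rej <- if (length(rejected)) do.call(rbind, rejected)
         else data.frame(surface = character(0), reason = character(0))
  if (nrow(rej)) tnm_log(nrow(rej), " lexicon entr(ies) rejected", force = TRUE)
  rownames(tg) <- rownames(md) <- NULL
  structure(list(targets = tg, modifiers = md, rejected = rej),
            class = "tnm_lexicon")
}

#' @export
print.tnm_lexicon <- function(x, ...) {
  cat(sprintf("<tnm_lexicon: %d target terms (%d value-bearing), %d modifier triggers>\n",
              nrow(x$targets), sum(!is.na(x$targets$numeral)), nrow(x$modifiers)))
  invisible(x)
}

## Longest-match-wins, non-overlapping, case-insensitive phrase matching at
## word boundaries. `table` is a data frame with a `surface` column; all its
## columns are carried through to the result. Spans are 0-based half-open
## character offsets into `sentence`.
match_phrases <- function(sentence, table) {
  empty <- cbind(table[0, , drop = FALSE],
                 data.frame(start = integer(0), end = integer(0)))
  if (!nrow(table) || !nzchar(sentence)) return(empty)
  cand <- list()
  for (i in seq_len(nrow(table))) {
    pat <- paste0("(?<![[:alnum:]])", regex_escape(table$surface[i]), "(?![[:alnum:]])")
    sp <- match_spans(gregexpr(pat, sentence, perl = TRUE, ignore.case = TRUE)[[1]])
    if (nrow(sp)) cand[[length(cand) + 1L]] <- cbind(table[rep(i, nrow(sp)), , drop = FALSE], sp)
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  ## longest first, then leftmost, then table order for determinism
  cand <- cand[order(-(cand$end - cand$start), cand$start), , drop = FALSE]
  taken <- logical(nchar(sentence))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    idx <- (cand$start[i] + 1L):cand$end[i]
    if (!any(taken[idx])) { keep[i] <- TRUE; taken[idx] <- TRUE }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match target terms in a sentence
#'
#' Case-insensitive longest-match-wins matching of lexicon target terms at
#' word boundaries. Returned spans are 0-based half-open character offsets
#' into the sentence and never overlap.
#'
#' @param sentence raw sentence text.
#' @param targets target-term data frame (`lex$targets`).
#' @return Data frame of matched terms with `start`/`end` span columns.
#' @examples
#' lex <- load_lexicon()
#' match_targets("Extracapsular Extension noted", lex$targets)
#' @export
match_targets <- function(sentence, targets) {
  match_phrases(sentence, targets)
}
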