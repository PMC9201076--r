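## preprocess: deterministic text normalization feeding the ML arm.
## The rule engine consumes raw sentence text; only vectorization uses the
## normalized token streams.

## clinical abbreviations that do not end a sentence
SENT_ABBREVS <- c("dr", "mr", "mrs", "ms", "vs", "st", "jr", "sr", "prof",
                  "dept", "approx", "fig", "e.g", "i.e", "vol", "pp")

ONES_WORDS <- c("zero", "one", "two", "three", "four", "five", "six", "seven",
                "eight", "nine", "ten", "eleven", "twelve", "thirteen",
                "fourteen", "fifteen", "sixteen", "seventeen", "eighteen",
                "nineteen", "twenty")

#' Split note text into sentences
#'
#' Rule-based, abbreviation-aware sentence boundary detection: sentences end
#' at `.`, `!` or `?` followed by whitespace (unless the period terminates a
#' known clinical abbreviation or a single initial) and at line breaks.
#' Spans are 0-based half-open character offsets into the note text, and
#' slicing the note by a sentence's span reproduces its text exactly.
#'
#' @param text note text.
#' @param note_id optional note identifier carried into the result.
#' @return Data frame with columns `note_id`, `index`, `text`, `start`,
#'   `end`; empty text gives zero rows.
#' @examples
#' split_sentences("PSA is rising. Bone scan negative.")
#' @export
split_sentences <- function(text, note_id = NA_character_) {
  empty <- data.frame(note_id = character(0), index = integer(0),
                      text = character(0), start = integer(0), end = integer(0))
  if (is.na(text) || !nzchar(text)) return(empty)
  m <- gregexpr("[.!?]+(?=[[:space:]]|$)|\n", text, perl = TRUE)[[1]]
  sp <- match_spans(m)
  is_boundary <- rep(TRUE, nrow(sp))
  for (i in seq_len(nrow(sp))) {
    piece <- substr(text, sp$start[i] + 1L, sp$end[i])
    if (!startsWith(piece, ".")) next
    before <- substr(text, 1L, sp$start[i])
    word <- tolower(sub(".*?([[:alpha:]][[:alpha:].]*)$", "\\1", before))
    if (!grepl("[[:alpha:]]$", before)) next
    if (word %in% SENT_ABBREVS || nchar(word) == 1L) is_boundary[i] <- FALSE
  }
  cuts <- sp[is_boundary, , drop = FALSE]
  starts <- c(0L, cuts$end)
  ends <- c(cuts$end, nchar(text))
  out <- list()
  for (i in seq_along(starts)) {
    if (ends[i] <= starts[i]) next
    raw <- substr(text, starts[i] + 1L, ends[i])
    lead <- nchar(sub("^([[:space:]]*).*$", "\\1", raw))
    trail <- nchar(sub("^.*?([[:space:]]*)$", "\\1", raw))
    s <- starts[i] + lead; e <- ends[i] - trail
    if (e <= s) next
    out[[length(out) + 1L]] <- data.frame(
      note_id = note_id, index = NA_integer_,
      text = substr(text, s + 1L, e), start = s, end = e)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res$index <- seq_len(nrow(res)) - 1L
  res
}

#' Spell an integer as number words
#'
#' Integers 0-20 map to single number words; larger integers are spelled
#' digit by digit (`2018` becomes `two zero one eight`), so the spelled form
#' always parses back to the original numeral via [words_to_number()].
#'
#' @param n non-negative integer.
#' @return Character vector of number-word tokens.
#' @keywords internal
number_to_words <- function(n) {
  n <- as.integer(n)
  if (n >= 0 && n <= 20) return(ONES_WORDS[n + 1L])
  digits <- strsplit(as.character(n), "")[[1]]
  ONES_WORDS[as.integer(digits) + 1L]
}

#' @rdname number_to_words
#' @param words character vector of number-word tokens.
#' @keywords internal
words_to_number <- function(words) {
  if (length(words) == 1L && words %in% ONES_WORDS)
    return(match(words, ONES_WORDS) - 1L)
  idx <- match(words, ONES_WORDS[1:10])
  if (anyNA(idx)) return(NA_integer_)
  as.integer(paste(idx - 1L, collapse = ""))
}

#' Normalize a sentence into a token stream
#'
#' Lowercases, tokenizes, drops punctuation-only tokens and single-letter
#' alphabetic tokens, and converts numbers to words: integers via
#' [number_to_words()], floating-point numbers digit-wise with `"point"`
#' (`"4.5"` becomes `four point five`). Mixed alphanumeric tokens such as
#' `"t2a"` are preserved intact because they carry staging signal.
#'
#' @param text raw sentence text.
#' @return Character vector of normalized tokens.
#' @examples
#' normalize_tokens("PSA 4.5 rising!")
#' normalize_tokens("a T2a lesion")
#' @export
normalize_tokens <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character(0))
  m <- gregexpr("[0-9]+\\.[0-9]+|[[:alnum:]]+", tolower(text), perl = TRUE)[[1]]
  toks <- if (m[1] == -1L) character(0) else regmatches(tolower(text), list(m))[[1]]
  out <- character(0)
  for (tok in toks) {
    if (grepl("^[0-9]+$", tok)) {
      out <- c(out, number_to_words(tok))
    } else if (grepl("^[0-9]+\\.[0-9]+$", tok)) {
      parts <- strsplit(tok, ".", fixed = TRUE)[[1]]
      spell <- function(p) ONES_WORDS[as.integer(strsplit(p, "")[[1]]) + 1L]
      out <- c(out, spell(parts[1]), "point", spell(parts[2]))
    } else if (grepl("^[[:alpha:]]$", tok)) {
      ## alphabetic tokens shorter than two letters are removed
    } else {
      out <- c(out, tok)
    }
  }
  out
}

#' Concatenate a patient's eligible notes into an ordered sentence list
#'
#' Takes the note subset eligible for the stage kind (see
#' [select_notes_for_stage_kind()]), in longitudinal (date) order, and
#' splits each note into sentences; note order and within-note sentence
#' order are preserved.
#'
#' @inheritParams select_notes_for_stage_kind
#' @return Data frame of sentences with note metadata columns
#'   (`note_type`, `date`) attached.
#' @export
concatenate_patient_text <- function(record, stage_kind = c("clinical", "pathological")) {
  stage_kind <- match.arg(stage_kind)
  notes <- select_notes_for_stage_kind(record, stage_kind)
  empty <- data.frame(note_id = character(0), index = integer(0),
                      text = character(0), start = integer(0), end = integer(0),
                      note_type = character(0), date = as.Date(character(0)))
  if (!nrow(notes)) return(empty)
  pieces <- lapply(seq_len(nrow(notes)), function(i) {
    s <- split_sentences(notes$text[i], notes$note_id[i])
    if (!nrow(s)) return(NULL)
    s$note_type <- notes$note_type[i]
    s$date <- notes$date[i]
    s
  })
  pieces <- Filter(Negate(is.null), pieces)
  if (!length(pieces)) return(empty)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
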