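## corpus_io: reading/writing note corpora, registry tables and gold labels,
## and assembling per-patient longitudinal records with cohort filters.

REGISTRY_COLS <- c("patient_id", "cT", "cN", "cM", "pT", "pN")

new_corpus <- function(df) {
  df$patient_id <- as.character(df$patient_id)
  df$note_id <- as.character(df$note_id)
  df$note_type <- as.character(df$note_type)
  df$note_type[!(df$note_type %in% NOTE_TYPES)] <- "other"
  df$date <- as.Date(df$date)
  df$text <- as.character(df$text)
  rownames(df) <- NULL
  structure(df[, c("patient_id", "note_id", "note_type", "date", "text")],
            class = c("tnm_corpus", "data.frame"))
}

#' Read a corpus of clinical notes
#'
#' Each record carries `patient_id`, `note_id`, `note_type`, `date` (ISO-8601,
#' may be missing) and free `text`. Rows lacking a `patient_id` or a `text`
#' field, and rows whose `note_id` duplicates an earlier row, are rejected and
#' reported with their line numbers; unknown note types map to `"other"`.
#'
#' @param path path to the corpus file.
#' @param format `"jsonl"` (one JSON object per line, the native dialect) or
#'   `"csv"` (columns `patient_id,note_id,note_type,date,text`).
#' @return A `tnm_corpus` data frame with one row per accepted note and an
#'   attribute `"rejected"` (data frame of `line`, `reason`) describing
#'   rejected rows.
#' @examples
#' f <- tempfile(fileext = ".jsonl")
#' writeLines(c(
#'   '{"patient_id":"p1","note_id":"n1","note_type":"progress",
#'    "date":"2012-03-01","text":"Staging: cT2."}'), f)
#' read_corpus(f)
#' @export
read_corpus <- function(path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("corpus file does not exist: %s", path)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    keep <- nzchar(trimws(lines))
    rows <- vector("list", length(lines))
    rejects <- list()
    for (i in seq_along(lines)) {
      if (!keep[i]) next
      rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
      if (is.null(rec) || !is.list(rec)) {
        rejects[[length(rejects) + 1L]] <- data.frame(line = i, reason = "unparseable JSON")
        next
      }
      rows[[i]] <- rec
    }
    parsed <- rows
  } else {
    df <- read.csv(path, colClasses = "character", na.strings = character(0))
    parsed <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
    ## line number = row + header line
    names(parsed) <- as.character(seq_len(nrow(df)) + 1L)
    rejects <- list()
  }
  out <- list(); seen_ids <- character(0)
  for (i in seq_along(parsed)) {
    rec <- parsed[[i]]
    if (is.null(rec)) next
    line_no <- if (format == "csv") as.integer(names(parsed)[i]) else i
    pid <- rec$patient_id
    if (is.null(pid) || length(pid) != 1L || is.na(pid) || !nzchar(pid)) {
      rejects[[length(rejects) + 1L]] <- data.frame(line = line_no, reason = "missing patient_id")
      next
    }
    if (is.null(rec$text) || length(rec$text) != 1L || is.na(rec$text)) {
      rejects[[length(rejects) + 1L]] <- data.frame(line = line_no, reason = "missing text")
      next
    }
    nid <- rec$note_id
    if (is.null(nid) || !nzchar(nid %||% "") || is.na(nid)) nid <- sprintf("line%06d", line_no)
    if (nid %in% seen_ids) {
      rejects[[length(rejects) + 1L]] <- data.frame(line = line_no, reason = "duplicate note_id")
      next
    }
    seen_ids <- c(seen_ids, nid)
    d <- rec$date %||% NA_character_
    d <- tryCatch(as.Date(d), error = function(e) as.Date(NA))
    out[[length(out) + 1L]] <- data.frame(
      patient_id = as.character(pid), note_id = as.character(nid),
      note_type = as.character(rec$note_type %||% "other"),
      date = d, text = as.character(rec$text), stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    tnm_log("corpus '", basename(path), "' produced no notes", force = TRUE)
    corpus <- new_corpus(data.frame(patient_id = character(0), note_id = character(0),
                                    note_type = character(0), date = as.Date(character(0)),
                                    text = character(0)))
  } else {
    corpus <- new_corpus(do.call(rbind, out))
  }
  rej <- if (length(rejects)) do.call(rbind, rejects) else data.frame(line = integer(0), reason = character(0))
  if (nrow(rej)) tnm_log(nrow(rej), " row(s) rejected while reading ", basename(path), force = TRUE)
  attr(corpus, "rejected") <- rej
  corpus
}

#' Write a corpus of clinical notes as JSON-lines
#'
#' Inverse of [read_corpus()]; the `text` field round-trips byte-identically.
#'
#' @param corpus a `tnm_corpus` data frame.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  write_atomic(path, function(tmp) {
    con <- file(tmp, open = "wb")
    on.exit(close(con))
    for (i in seq_len(nrow(corpus))) {
      rec <- list(patient_id = corpus$patient_id[i], note_id = corpus$note_id[i],
                  note_type = corpus$note_type[i],
                  date = if (is.na(corpus$date[i])) NULL else format(corpus$date[i]),
                  text = corpus$text[i])
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con, useBytes = TRUE)
    }
  })
}

#' Read or write a registry-style stage table
#'
#' The schema is `patient_id,cT,cN,cM,pT,pN`; an empty cell is a missing
#' stage. Gold-label tables use the same schema. Extra columns (for example
#' imputation provenance) are preserved.
#'
#' @param path CSV path.
#' @return A data frame with character stage columns, `NA` for missing.
#' @export
read_stage_table <- function(path) {
  df <- read.csv(path, colClasses = "character", na.strings = c("", "NA"))
  missing_cols <- setdiff(REGISTRY_COLS, names(df))
  if (length(missing_cols))
    stopf("stage table %s lacks column(s): %s", path, paste(missing_cols, collapse = ", "))
  df
}

#' @rdname read_stage_table
#' @param table data frame in the registry schema.
#' @export
write_stage_table <- function(table, path) {
  write_atomic(path, function(tmp) write.csv(table, tmp, row.names = FALSE, na = ""))
}

#' Assemble per-patient longitudinal records
#'
#' Groups notes by patient and orders each patient's notes by ascending date;
#' ties are broken by `note_id` and dateless notes sort last. The total note
#' count is preserved (the operation is a partition of the corpus).
#'
#' @param corpus a `tnm_corpus` data frame (or any data frame with the same
#'   columns).
#' @param ages optional named numeric vector of age at diagnosis, named by
#'   patient id.
#' @param registry optional registry stage table ([read_stage_table()]
#'   schema) attached per patient.
#' @return A list of `patient_record` objects, each a list with
#'   `patient_id`, `notes` (sorted note data frame), `age_at_diagnosis`,
#'   `registry_stage` and `flags`.
#' @export
assemble_patients <- function(corpus, ages = NULL, registry = NULL) {
  if (!nrow(corpus)) return(structure(list(), names = character(0)))
  ord <- order(corpus$patient_id, is.na(corpus$date), corpus$date,
               corpus$note_id, method = "radix")
  corpus <- corpus[ord, , drop = FALSE]
  split_notes <- split(seq_len(nrow(corpus)), corpus$patient_id)
  recs <- lapply(names(split_notes), function(pid) {
    notes <- corpus[split_notes[[pid]], , drop = FALSE]
    rownames(notes) <- NULL
    reg <- NULL
    if (!is.null(registry)) {
      hit <- registry[registry$patient_id == pid, , drop = FALSE]
      if (nrow(hit)) reg <- hit[1, , drop = FALSE]
    }
    structure(list(patient_id = pid, notes = notes,
                   age_at_diagnosis = if (!is.null(ages)) unname(ages[pid]) else NA_real_,
                   registry_stage = reg,
                   flags = list(urology_oncology_visit = NA, first_line_treatment = NA)),
              class = "patient_record")
  })
  names(recs) <- names(split_notes)
  recs
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s: %d note(s)>\n", x$patient_id, nrow(x$notes)))
  invisible(x)
}

#' Apply cohort filters to patient records
#'
#' Removes patients with fewer than `min_encounters` notes, then patients
#' older than `max_age` at diagnosis (unknown ages are retained). Rules are
#' applied in that order and an exclusion tally is attached. Notes are
#' equated with encounters.
#'
#' @param records list of `patient_record`s from [assemble_patients()].
#' @param min_encounters minimum number of notes required (default 2).
#' @param max_age maximum age at diagnosis in years (default 90).
#' @return Filtered record list with attribute `"exclusions"` — a named
#'   integer vector of counts removed per rule.
#' @export
apply_cohort_filters <- function(records, min_encounters = 2, max_age = 90) {
  stopifnot(min_encounters >= 0)
  n_notes <- vapply(records, function(r) nrow(r$notes), integer(1))
  drop1 <- n_notes < min_encounters
  kept <- records[!drop1]
  age <- vapply(kept, function(r) r$age_at_diagnosis %||% NA_real_, numeric(1))
  drop2 <- !is.na(age) & age > max_age
  out <- kept[!drop2]
  attr(out, "exclusions") <- c(too_few_encounters = sum(drop1), over_max_age = sum(drop2))
  out
}

#' Select the notes eligible for a stage kind
#'
#' Clinical stage is abstracted only from operative reports, history &
#' physical notes, discharge/transfer summaries and progress notes;
#' pathological stage only from pathology reports, history & physical notes
#' and progress notes. Relative note order is preserved. Radiology and
#' unknown note types pass neither filter.
#'
#' @param record a `patient_record` (or a bare note data frame).
#' @param stage_kind `"clinical"` or `"pathological"`.
#' @return The eligible subset of the record's note data frame.
#' @export
select_notes_for_stage_kind <- function(record, stage_kind = c("clinical", "pathological")) {
  stage_kind <- match.arg(stage_kind)
  notes <- if (inherits(record, "patient_record")) record$notes else record
  allowed <- if (stage_kind == "clinical") CLINICAL_NOTE_TYPES else PATHOLOGICAL_NOTE_TYPES
  out <- notes[notes$note_type %in% allowed, , drop = FALSE]
  rownames(out) <- NULL
  out
}
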