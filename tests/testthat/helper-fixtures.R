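# Shared fixtures: tiny in-code corpora and lexicons.

make_note <- function(patient_id, note_id, note_type = "progress",
                      date = NA, text = "") {
  data.frame(patient_id = patient_id, note_id = note_id, note_type = note_type,
              date = as.Date(date), text = text, stringsAsFactors = FALSE)
}

tiny_corpus <- function() {
  rbind(
    make_note("p1", "n1", "history_physical", "2011-06-01", "Assessment today. Staging: cT2aN0M0."),
    make_note("p1", "n2", "progress", "2012-01-02", "PSA 4.5 stable."),
    make_note("p1", "n3", "radiology", "2012-02-10", "Bone scan without lesions."),
    make_note("p2", "n4", "pathology", "2013-03-05", "Final staging pT3N1."),
    make_note("p2", "n5", "progress", "2013-04-01", "Doing well."))
}

write_jsonl_corpus <- function(lines) {
  f <- tempfile(fileext = ".jsonl")
  writeLines(lines, f, useBytes = TRUE)
  f
}

mini_targets <- function() {
  data.frame(surface = c("lymph node", "lymph node involvement", "metastasis",
                         "extracapsular extension"),
             axis = c("N", "N", "M", "T"),
             numeral = c(NA, 1L, 1L, 3L),
             kind = c("unspecified", "unspecified", "unspecified", "unspecified"),
             source = "expert", stringsAsFactors = FALSE)
}

default_lexicon <- local({
  lex <- NULL
  function() {
    if (is.null(lex)) lex <<- load_lexicon()
    lex
  }
})

noise_free_config <- function(n, seed) {
  sim_config(n_patients = n, seed = seed,
             p_negation_sentence = 0, p_historical = 0, p_hypothetical = 0,
             p_ambiguous_prefix = 0, p_missing_documentation = 0)
}
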