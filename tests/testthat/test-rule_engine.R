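# helper: hand-built mention table for resolution tests
mk_mentions <- function(axis, numeral, prefix = "clinical",
                        negated = FALSE, historical = FALSE,
                        hypothetical = FALSE, experiencer_other = FALSE,
                        note_type = "progress", date = as.Date("2012-01-01"),
                        note_id = "n1", index = 0L, start = 0L) {
  data.frame(axis = axis, numeral = as.integer(numeral), subtype = NA_character_,
             prefix = prefix, prefix_raw = "", start = start,
             end = start + 2L, source = "compact_pattern",
             pattern_id = NA_character_, ambiguous = prefix == "unspecified",
             negated = negated, historical = historical,
             hypothetical = hypothetical, experiencer_other = experiencer_other,
             note_type = note_type, date = as.Date(date), note_id = note_id,
             index = index, stringsAsFactors = FALSE)
}

test_that("compact TNM patterns parse with prefix distribution over components", {
  m <- parse_compact_tnm("pT1N2M0")
  expect_equal(m$axis, c("T", "N", "M"))
  expect_equal(m$numeral, c(1L, 2L, 0L))
  expect_equal(unique(m$prefix), "pathological")

  m <- parse_compact_tnm("cT2aN0M0")
  expect_equal(m$numeral, c(2L, 0L, 0L))
  expect_equal(m$subtype, c("a", NA, NA))
  expect_equal(unique(m$prefix), "clinical")

  expect_equal(nrow(parse_compact_tnm("no staging discussed")), 0L)
  expect_equal(nrow(parse_compact_tnm("T5 is not a stage")), 0L)

  # bare pattern: prefix unspecified and flagged ambiguous
  m <- parse_compact_tnm("he has t3a prostate cancer")
  expect_equal(m$axis, "T"); expect_equal(m$numeral, 3L)
  expect_equal(m$subtype, "a")
  expect_equal(m$prefix, "unspecified")
  expect_true(m$ambiguous)

  # 'yp' prefix and whitespace-separated components
  m <- parse_compact_tnm("ypT2 N0")
  expect_equal(unique(m$prefix), "pathological")
  expect_equal(m$axis, c("T", "N"))
})

test_that("parsing then re-rendering reproduces well-formed patterns", {
  set.seed(7)
  for (i in 1:100) {
    pre <- sample(c("", "c", "p", "yp"), 1)
    parts <- character(0)
    if (runif(1) < 0.8) parts <- c(parts, paste0("T", sample(0:4, 1),
                                   sample(c("", "a", "b", "c"), 1)))
    if (runif(1) < 0.6) parts <- c(parts, paste0("N", sample(0:3, 1)))
    if (runif(1) < 0.6) parts <- c(parts, paste0("M", sample(0:1, 1)))
    if (!length(parts)) parts <- "T2"
    pat <- paste0(pre, paste(parts, collapse = ""))
    m <- parse_compact_tnm(pat)
    expect_equal(nrow(m), length(parts), info = pat)
    expect_identical(tnmstager:::render_compact(m), pat, info = pat)
  }
})

test_that("narrative mentions map lexicon values; overall-stage stays non-TNM", {
  m <- detect_narrative_mentions("lymph node involvement identified", mini_targets())
  expect_equal(m$axis, "N"); expect_equal(m$numeral, 1L)
  expect_equal(m$prefix, "unspecified")

  expect_equal(nrow(detect_narrative_mentions("nothing relevant here", mini_targets())), 0L)

  m <- detect_narrative_mentions("known stage 2 prostate cancer", mini_targets())
  expect_equal(m$axis, "overall")
  expect_true(m$ambiguous)
  # overall-stage mentions never reach patient-level TNM fields
  full <- mk_mentions("T", 2)
  full$axis <- "overall"
  res <- resolve_patient_stage(full, "clinical")
  expect_true(is.na(res$T$category))
})

test_that("ConText scopes set and bound contextual flags", {
  lex <- default_lexicon()
  flagged <- function(s, targets = lex$targets) {
    m <- detect_narrative_mentions(s, targets)
    apply_context(s, m, lex$modifiers)
  }
  m <- flagged("no evidence of nodal metastasis")
  expect_true(m$negated)

  m <- flagged("will discuss if metastasis develops", mini_targets())
  expect_true(m$hypothetical); expect_false(m$negated)

  m <- flagged("nodal metastasis was identified")   # no trigger at all
  expect_false(any(m$negated | m$historical | m$hypothetical | m$experiencer_other))

  # termination trigger closes the scope
  m <- flagged("no evidence of nodal metastasis but extracapsular extension is seen")
  expect_true(m$negated[m$axis == "N"])
  expect_false(m$negated[m$axis == "T"])

  # backward trigger
  m <- flagged("distant metastasis was ruled out")
  expect_true(m$negated)

  # pseudo-trigger opens no scope
  m <- flagged("no increase in extracapsular extension")
  expect_false(m$negated)

  # historical and experiencer; 'family history of' outranks 'history of'
  m <- flagged("history of bone metastases")
  expect_true(m$historical); expect_false(m$experiencer_other)
  m <- flagged("family history of metastatic prostate cancer")
  expect_true(m$experiencer_other)
  expect_false(m$historical)
})

test_that("single-mention resolution matches a brute-force oracle", {
  # independent oracle for the one-mention state space
  oracle <- function(axis, numeral, neg, hyp, kind) {
    if (hyp) return(NA_character_)
    if (neg) {
      if (axis %in% c("N", "M") && numeral >= 1) return(dichotomize(kind, axis, 0))
      return(NA_character_)
    }
    dichotomize(kind, axis, numeral)
  }
  grid <- expand.grid(axis = c("T", "N", "M"), numeral = 0:4,
                      neg = c(FALSE, TRUE), hyp = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  rng <- list(T = 0:4, N = 0:3, M = 0:1)
  grid <- grid[mapply(function(a, n) n %in% rng[[a]], grid$axis, grid$numeral), ]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    m <- mk_mentions(g$axis, g$numeral, negated = g$neg, hypothetical = g$hyp)
    res <- resolve_patient_stage(m, "clinical")[[g$axis]]
    expect_identical(res$category, oracle(g$axis, g$numeral, g$neg, g$hyp, "clinical"),
                     info = paste(g, collapse = "/"))
    if (g$neg && !g$hyp && !is.na(res$category)) expect_true(res$from_negation)
  }
})

test_that("modal numeral wins; recency breaks ties; prefixes route kinds", {
  m <- rbind(mk_mentions("T", 2), mk_mentions("T", 2, note_id = "n2"),
             mk_mentions("T", 3, note_id = "n3"))
  expect_equal(resolve_patient_stage(m, "clinical")$T$category, "T1-2")

  # 1-1 tie: the more recent mention's numeral wins
  m <- rbind(mk_mentions("T", 2, date = "2012-01-01"),
             mk_mentions("T", 3, date = "2013-06-01", note_id = "n2"))
  expect_equal(resolve_patient_stage(m, "clinical")$T$numeral, 3L)

  # pathological-prefix mention is invisible to clinical resolution
  m <- mk_mentions("T", 3, prefix = "pathological")
  expect_true(is.na(resolve_patient_stage(m, "clinical")$T$category))
  # unspecified prefix routes by note type
  m <- mk_mentions("T", 3, prefix = "unspecified", note_type = "pathology")
  expect_equal(resolve_patient_stage(m, "pathological")$T$category, "T3-4")
  expect_true(is.na(resolve_patient_stage(m, "clinical")$T$category))
  # historical mentions are retained for staging
  m <- mk_mentions("T", 3, historical = TRUE)
  expect_equal(resolve_patient_stage(m, "clinical")$T$category, "T3-4")
})

test_that("resolution is permutation-invariant and monotone under negated noise", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    m <- do.call(rbind, lapply(seq_len(n), function(i)
      mk_mentions(sample(c("T", "N", "M"), 1), sample(0:1, 1),
                  prefix = sample(c("clinical", "unspecified"), 1),
                  negated = runif(1) < 0.3,
                  date = as.Date("2012-01-01") + sample(0:400, 1),
                  note_id = sprintf("n%d", i), index = i, start = i)))
    base <- resolve_patient_stage(m, "clinical")
    for (s in 1:3) {
      shuf <- m[sample(nrow(m)), ]
      expect_identical(resolve_patient_stage(shuf, "clinical"), base)
    }
    # monotonicity: a negated mention never flips an axis with positive support
    for (axis in c("N", "M")) {
      if (is.na(base[[axis]]$category) || base[[axis]]$from_negation) next
      extra <- rbind(m, mk_mentions(axis, 1, negated = TRUE, note_id = "zzz",
                                    date = as.Date("2014-01-01")))
      expect_identical(resolve_patient_stage(extra, "clinical")[[axis]]$category,
                       base[[axis]]$category)
    }
  }
})

test_that("dichotomization maps numerals onto the binary task domains", {
  expect_equal(dichotomize("clinical", "T", 1), "T1-2")
  expect_equal(dichotomize("clinical", "T", 3), "T3-4")
  expect_equal(dichotomize("pathological", "T", 4), "T3-4")
  expect_equal(dichotomize("pathological", "T", 2), "T2")
  expect_equal(dichotomize("clinical", "N", 2), "N1")   # any nodal involvement
  expect_equal(dichotomize("clinical", "M", 0), "M0")
  expect_error(dichotomize("pathological", "M", 1), "unsupported axis")
  expect_error(dichotomize("clinical", "T", 5), "out of range")
})

test_that("end-to-end extraction on a hand-built corpus", {
  st <- extract_stages(assemble_patients(tiny_corpus()))
  p1 <- st[st$patient_id == "p1", ]
  expect_equal(p1$cT, "T1-2"); expect_equal(p1$cN, "N0"); expect_equal(p1$cM, "M0")
  expect_true(is.na(p1$pT))   # no pathology-eligible stage evidence
  p2 <- st[st$patient_id == "p2", ]
  expect_equal(p2$pT, "T3-4"); expect_equal(p2$pN, "N1")
  expect_true(is.na(p2$cT))   # pathological prefix never leaks into clinical
})
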