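toy_streams <- function() {
  list(c("extracapsular", "extension", "noted", "on", "pathology"),
       c("organ", "confined", "tumor", "on", "pathology"),
       c("extracapsular", "extension", "with", "margins", "involved"),
       c("organ", "confined", "with", "margins", "clear"),
       c("psa", "stable", "on", "follow", "up"))
}

test_that("embeddings have the requested dimension and a sensible vocabulary", {
  emb <- train_embeddings(toy_streams(), dim = 100, window = 5, min_count = 2)
  expect_equal(ncol(emb$vectors), 100L)
  expect_true(all(c("extracapsular", "organ", "pathology") %in% rownames(emb$vectors)))
  expect_false("psa" %in% rownames(emb$vectors))   # below min_count

  # one repeated sentence: vocabulary is exactly its distinct tokens
  emb1 <- train_embeddings(rep(list(c("bone", "scan", "negative")), 3),
                           dim = 10, min_count = 2)
  expect_setequal(rownames(emb1$vectors), c("bone", "scan", "negative"))

  expect_error(train_embeddings(list()), "empty")
})

test_that("embedding training is deterministic", {
  a <- train_embeddings(toy_streams(), dim = 50, seed = 3)
  b <- train_embeddings(toy_streams(), dim = 50, seed = 3)
  expect_identical(a$vectors, b$vectors)
})

test_that("patient vectors are means of context-sentence vectors", {
  lex <- default_lexicon()
  notes <- rbind(
    make_note("p", "a", "progress", "2012-01-01",
              "Findings demonstrate extracapsular extension. PSA stable today."),
    make_note("p", "b", "progress", "2012-02-01",
              "There is nodal metastasis. Follow up soon."))
  rec <- assemble_patients(notes)[["p"]]
  streams <- lapply(concatenate_patient_text(rec, "clinical")$text, normalize_tokens)
  emb <- train_embeddings(c(streams, streams), dim = 20, min_count = 2)

  # task cT: single context sentence -> vector equals that sentence's mean
  pv <- build_patient_vector(rec, "cT", emb, lex)
  expect_false(pv$degenerate)
  expect_equal(pv$n_context_sentences, 1L)
  manual <- colMeans(emb$vectors[intersect(
    normalize_tokens("Findings demonstrate extracapsular extension."),
    rownames(emb$vectors)), , drop = FALSE])
  expect_equal(pv$vector, manual, tolerance = 1e-12)

  # two context sentences u, v -> (u+v)/2: duplicate the T sentence in note b
  notes2 <- notes
  notes2$text[2] <- "Findings demonstrate extracapsular extension. Follow up soon."
  rec2 <- assemble_patients(notes2)[["p"]]
  pv2 <- build_patient_vector(rec2, "cT", emb, lex)
  expect_equal(pv2$n_context_sentences, 2L)
  expect_equal(pv2$vector, manual, tolerance = 1e-12)  # mean of two equal vectors

  # no keyword match anywhere -> degenerate zero vector
  rec3 <- assemble_patients(make_note("q", "x", "progress", text = "All well."))[["q"]]
  pv3 <- build_patient_vector(rec3, "cT", emb, lex)
  expect_true(pv3$degenerate)
  expect_equal(pv3$vector, numeric(20))
})

test_that("patient vectors ignore sentence order and non-context duplicates; norms are convex", {
  lex <- default_lexicon()
  emb <- train_embeddings(toy_streams(), dim = 30, min_count = 1)
  mk <- function(texts) assemble_patients(
    make_note("p", "a", "progress", "2012-01-01", paste(texts, collapse = " ")))[["p"]]
  base <- c("There is extracapsular extension.", "PSA stable.", "Vitals fine.")
  v1 <- build_patient_vector(mk(base), "cT", emb, lex)$vector
  v2 <- build_patient_vector(mk(rev(base)), "cT", emb, lex)$vector
  v3 <- build_patient_vector(mk(c(base, "Vitals fine.")), "cT", emb, lex)$vector
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_equal(v1, v3, tolerance = 1e-12)

  max_norm <- max(sqrt(rowSums(emb$vectors^2)))
  expect_lte(sqrt(sum(v1^2)), max_norm + 1e-9)
})

test_that("classifier training is deterministic, exact on separable data, strict on degenerate labels", {
  set.seed(99)
  n <- 120
  X <- rbind(matrix(rnorm(n / 2 * 10, mean = 2), ncol = 10),
             matrix(rnorm(n / 2 * 10, mean = -2), ncol = 10))
  y <- rep(c("pos", "neg"), each = n / 2)
  cl <- train_task_classifier(X, y, task = "demo", seed = 4, n_search = 10)
  expect_equal(min(cl$heldout$f1), 1)   # separable by construction

  cl2 <- train_task_classifier(X, y, task = "demo", seed = 4, n_search = 10)
  expect_identical(cl$hyper, cl2$hyper)
  expect_identical(predict(cl, X), predict(cl2, X))

  expect_error(train_task_classifier(X, rep("pos", n), task = "cN"),
               "single class.*|cN")
})

test_that("prediction abstains on degenerate vectors and checks dimensions", {
  set.seed(1)
  X <- rbind(matrix(rnorm(200, 1), ncol = 4), matrix(rnorm(200, -1), ncol = 4))
  y <- rep(c("a", "b"), each = 50)
  cl <- train_task_classifier(X, y, seed = 1, n_search = 5)
  newX <- rbind(X[1, ], 0, X[51, ])
  pred <- predict(cl, newX, degenerate = c(FALSE, TRUE, FALSE))
  expect_true(is.na(pred[2]))
  expect_equal(unname(pred[c(1, 3)]), c("a", "b"))  # training points, separable
  expect_error(predict(cl, X[, 1:2]), "dimension")
  expect_length(predict(cl, X[0, , drop = FALSE]), 0L)
})
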