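## ml_pipeline: word embeddings, keyword-context patient vectors, and
## per-axis binary SVM classifiers with random hyperparameter search.

#' Train word embeddings on normalized token streams
#'
#' Skip-gram-style distributional embeddings computed in closed form:
#' symmetric window co-occurrence counts are transformed to positive
#' pointwise mutual information (PPMI) and factorized by truncated SVD; each
#' token's vector is its row of \eqn{U_d \sqrt{\Sigma_d}}. This count-based
#' factorization is the deterministic counterpart of sampled skip-gram
#' training and makes runs exactly reproducible. Tokens below `min_count`
#' are excluded from the vocabulary.
#'
#' @param token_streams list of character vectors (one normalized sentence
#'   each, see [normalize_tokens()]).
#' @param dim embedding dimension (default 100). If the vocabulary supports
#'   fewer informative dimensions the remaining components are zero, so all
#'   vectors always have length `dim`.
#' @param window symmetric context window width in tokens (default 5).
#' @param min_count minimum token frequency (default 2).
#' @param seed recorded for provenance; training itself is deterministic.
#' @return A `tnm_embeddings` object: list with `vectors` (matrix, one row
#'   per vocabulary token), `dim`, `window`, `min_count`, `seed`.
#' @export
train_embeddings <- function(token_streams, dim = 100, window = 5,
                             min_count = 2, seed = 1L) {
  tokens_all <- unlist(token_streams, use.names = FALSE)
  if (!length(tokens_all)) stopf("cannot train embeddings: corpus is empty")
  counts <- table(tokens_all)
  vocab <- sort(names(counts)[counts >= min_count])
  if (!length(vocab)) stopf("cannot train embeddings: no token reaches min_count = %d", min_count)
  V <- length(vocab)

  ii <- vector("list", length(token_streams)); jj <- ii
  for (s in seq_along(token_streams)) {
    ids <- match(token_streams[[s]], vocab)
    ids <- ids[!is.na(ids)]
    n <- length(ids)
    if (n < 2L) next
    pi <- list(); pj <- list()
    for (k in seq_len(min(window, n - 1L))) {
      pi[[k]] <- ids[seq_len(n - k)]
      pj[[k]] <- ids[seq_len(n - k) + k]
    }
    ii[[s]] <- unlist(pi, use.names = FALSE)
    jj[[s]] <- unlist(pj, use.names = FALSE)
  }
  i <- unlist(ii, use.names = FALSE); j <- unlist(jj, use.names = FALSE)
  if (!length(i)) stopf("cannot train embeddings: no co-occurrence pairs")
  dt <- data.table::data.table(i = c(i, j), j = c(j, i))   # symmetric
  agg <- dt[, .N, by = c("i", "j")]

  C <- matrix(0, V, V, dimnames = list(vocab, vocab))
  C[cbind(agg$i, agg$j)] <- agg$N
  total <- sum(C)
  rs <- rowSums(C)
  ppmi <- log(pmax(C * total, .Machine$double.xmin) / outer(rs, rs))
  ppmi[C == 0] <- 0
  ppmi[ppmi < 0] <- 0

  k <- min(dim, V)
  dec <- svd(ppmi, nu = k, nv = 0)
  W <- dec$u %*% diag(sqrt(dec$d[seq_len(k)]), k)
  ## deterministic sign convention: largest-magnitude loading positive
  for (c in seq_len(k)) {
    piv <- which.max(abs(W[, c]))
    if (W[piv, c] < 0) W[, c] <- -W[, c]
  }
  if (k < dim) W <- cbind(W, matrix(0, V, dim - k))
  rownames(W) <- vocab
  structure(list(vectors = W, dim = dim, window = window,
                 min_count = min_count, seed = seed,
                 algorithm = "ppmi-svd"),
            class = "tnm_embeddings")
}

#' @export
print.tnm_embeddings <- function(x, ...) {
  cat(sprintf("<tnm_embeddings: %d tokens x %d dims (window %d, min_count %d)>\n",
              nrow(x$vectors), x$dim, x$window, x$min_count))
  invisible(x)
}

## mean embedding of the in-vocabulary tokens of one token stream
stream_vector <- function(embeddings, tokens) {
  hit <- tokens[tokens %in% rownames(embeddings$vectors)]
  if (!length(hit)) return(NULL)
  colMeans(embeddings$vectors[hit, , drop = FALSE])
}

## does a sentence carry an axis keyword: a value-bearing target term of the
## axis, or a compact pattern component on the axis
axis_context_sentences <- function(sentences, axis, targets, include_anchors = FALSE) {
  if (!nrow(sentences)) return(integer(0))
  sub <- targets[targets$axis == axis, , drop = FALSE]
  if (!include_anchors) sub <- sub[!is.na(sub$numeral), , drop = FALSE]
  hits <- batch_match_phrases(sentences$text, sub)
  idx <- unique(hits$sent_idx)
  comp <- parse_compact_batch(sentences$text)
  idx <- sort(unique(c(idx, comp$sent_idx[comp$axis == axis])))
  idx
}

#' Build a patient's keyword-context vector for a stage task
#'
#' Finds the keyword-bearing sentences in the patient's task-appropriate
#' note subset (sentences containing a value-bearing target term of the
#' task's axis or a compact TNM component on that axis), represents each
#' such sentence as the mean of its in-vocabulary token embeddings, and
#' averages the sentence vectors. A patient with no keyword context is
#' degenerate: the vector is all zeros and the patient is excluded from
#' training and abstains at prediction time.
#'
#' @param record a `patient_record`.
#' @param task one of `"cT", "cN", "cM", "pT", "pN"`.
#' @param embeddings a `tnm_embeddings`.
#' @param lexicon a `tnm_lexicon`.
#' @param include_anchors also treat anchor (non-value-bearing) terms as
#'   keywords (default `FALSE`).
#' @return List with `patient_id`, `task`, `vector` (length `dim`),
#'   `n_context_sentences` and `degenerate`.
#' @export
build_patient_vector <- function(record, task, embeddings, lexicon,
                                 include_anchors = FALSE) {
  task <- match.arg(task, TASKS)
  sentences <- concatenate_patient_text(record, TASK_KIND[[task]])
  idx <- axis_context_sentences(sentences, TASK_AXIS[[task]], lexicon$targets,
                                include_anchors)
  vecs <- list()
  for (s in idx) {
    v <- stream_vector(embeddings, normalize_tokens(sentences$text[s]))
    if (!is.null(v)) vecs[[length(vecs) + 1L]] <- v
  }
  if (!length(vecs)) {
    return(list(patient_id = record$patient_id, task = task,
                vector = numeric(embeddings$dim),
                n_context_sentences = 0L, degenerate = TRUE))
  }
  list(patient_id = record$patient_id, task = task,
       vector = colMeans(do.call(rbind, vecs)),
       n_context_sentences = length(vecs), degenerate = FALSE)
}

## patient x dim matrix for one task over all records
build_task_matrix <- function(records, task, embeddings, lexicon,
                              include_anchors = FALSE) {
  pv <- lapply(records, build_patient_vector, task = task,
               embeddings = embeddings, lexicon = lexicon,
               include_anchors = include_anchors)
  X <- do.call(rbind, lapply(pv, `[[`, "vector"))
  rownames(X) <- vapply(pv, `[[`, character(1), "patient_id")
  attr(X, "degenerate") <- vapply(pv, `[[`, logical(1), "degenerate")
  attr(X, "n_context") <- vapply(pv, `[[`, integer(1), "n_context_sentences")
  X
}

f1_binary <- function(truth, pred, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  if (tp + fp == 0 || tp + fn == 0) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  if (p + r == 0) return(0)
  2 * p * r / (p + r)
}

macro_f1 <- function(truth, pred, levels) {
  mean(vapply(levels, function(l) f1_binary(truth, pred, l), numeric(1)))
}

## stratified index split: deterministic under the current RNG state
stratified_split <- function(y, fraction) {
  test <- integer(0)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    n_test <- max(1L, round(length(idx) * fraction))
    test <- c(test, sample(idx, min(n_test, length(idx) - 1L)))
  }
  sort(test)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

svm_fit <- function(X, y, cfg) {
  cw <- NULL
  if (cfg$balanced) {
    tab <- table(y)
    cw <- as.numeric(length(y) / (length(tab) * tab))
    names(cw) <- names(tab)
  }
  e1071::svm(X, y, kernel = cfg$kernel, cost = cfg$cost,
             gamma = if (cfg$kernel == "radial") cfg$gamma else 1 / ncol(X),
             class.weights = cw, scale = FALSE)
}

#' Train a binary stage classifier for one task
#'
#' Support vector machine over keyword-context patient vectors. The data
#' are split stratified 80/20 into training and held-out test sets; a
#' random hyperparameter search (kernel linear or RBF, cost log-uniform on
#' \[1e-2, 1e2\], RBF bandwidth log-uniform on \[1e-3, 1e1\], optional
#' balanced class weights) is scored by mean macro-F1 over stratified
#' 5-fold cross-validation on the training portion; the winning
#' configuration is refit on the full training portion and held-out
#' metrics are reported. Deterministic given identical data and seed.
#'
#' @param X numeric matrix of patient vectors (degenerate rows removed).
#' @param y factor or character vector of the task's two categories.
#' @param task task id, used in messages and stored on the result.
#' @param seed integer seed controlling split, folds and search.
#' @param n_search number of random configurations (default 50).
#' @param test_fraction held-out fraction (default 0.2).
#' @param folds number of CV folds (default 5).
#' @return A `tnm_classifier`: list with the fitted `model`, `hyper`,
#'   `cv_score`, `heldout` metrics data frame, `levels`, `task`, `seed`.
#' @export
train_task_classifier <- function(X, y, task = "task", seed = 1L,
                                  n_search = 50L, test_fraction = 0.2,
                                  folds = 5L) {
  y <- factor(as.character(y))
  if (nlevels(y) < 2L)
    stopf("cannot train classifier for %s: labels contain a single class", task)
  if (min(table(y)) < 2L)
    stopf("cannot train classifier for %s: fewer than 2 examples in a class", task)
  set.seed(seed)
  test_idx <- stratified_split(y, test_fraction)
  Xtr <- X[-test_idx, , drop = FALSE]; ytr <- droplevels(y[-test_idx])
  Xte <- X[test_idx, , drop = FALSE]; yte <- y[test_idx]

  cfgs <- lapply(seq_len(n_search), function(i) {
    list(kernel = sample(c("linear", "radial"), 1L),
         cost = 10^runif(1, -2, 2),
         gamma = 10^runif(1, -3, 1),
         balanced = sample(c(TRUE, FALSE), 1L))
  })
  fold <- stratified_folds(ytr, folds)
  scores <- vapply(cfgs, function(cfg) {
    fs <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      if (nlevels(droplevels(ytr[tr])) < 2L) return(NA_real_)
      fit <- svm_fit(Xtr[tr, , drop = FALSE], droplevels(ytr[tr]), cfg)
      pred <- predict(fit, Xtr[!tr, , drop = FALSE])
      macro_f1(as.character(ytr[!tr]), as.character(pred), levels(ytr))
    }, numeric(1))
    mean(fs, na.rm = TRUE)
  }, numeric(1))
  best <- cfgs[[which.max(scores)]]
  model <- svm_fit(Xtr, ytr, best)

  pred_te <- as.character(predict(model, Xte))
  heldout <- do.call(rbind, lapply(levels(y), function(lv) {
    tp <- sum(pred_te == lv & yte == lv); fp <- sum(pred_te == lv & yte != lv)
    fn <- sum(pred_te != lv & yte == lv)
    p <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    r <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f <- if (!is.na(p) && !is.na(r) && p + r > 0) 2 * p * r / (p + r) else NA_real_
    data.frame(task = task, category = lv, precision = p, recall = r, f1 = f,
               n_test = sum(yte == lv))
  }))
  structure(list(task = task, model = model, hyper = best,
                 cv_score = max(scores), heldout = heldout,
                 levels = levels(y), seed = seed, dim = ncol(X)),
            class = "tnm_classifier")
}

#' @export
print.tnm_classifier <- function(x, ...) {
  cat(sprintf("<tnm_classifier %s: %s kernel, cost %.3g, CV macro-F1 %.3f>\n",
              x$task, x$hyper$kernel, x$hyper$cost, x$cv_score))
  print(x$heldout, row.names = FALSE)
  invisible(x)
}

#' Predict task categories from patient vectors
#'
#' Degenerate patients (no keyword context) abstain: their prediction is
#' `NA` and they are never imputed.
#'
#' @param object a `tnm_classifier`.
#' @param newdata numeric matrix of patient vectors; a `"degenerate"`
#'   attribute (or the `degenerate` argument) marks abstaining rows.
#' @param degenerate optional logical vector overriding the attribute.
#' @param ... unused.
#' @return Character vector of categories (`NA` = abstain), named by row.
#' @export
predict.tnm_classifier <- function(object, newdata,
                                   degenerate = attr(newdata, "degenerate"), ...) {
  if (!nrow(newdata)) return(setNames(character(0), character(0)))
  if (ncol(newdata) != object$dim)
    stopf("vector dimension %d does not match classifier dimension %d",
          ncol(newdata), object$dim)
  if (is.null(degenerate)) degenerate <- rep(FALSE, nrow(newdata))
  out <- rep(NA_character_, nrow(newdata))
  if (any(!degenerate))
    out[!degenerate] <- as.character(predict(object$model,
                                             newdata[!degenerate, , drop = FALSE]))
  setNames(out, rownames(newdata))
}

#' Train the full ML staging arm
#'
#' Trains one shared embedding model per stage kind on the normalized
#' sentences of the kind's eligible notes, then one binary SVM per task
#' using gold labels.
#'
#' @param records list of `patient_record`s.
#' @param labels gold-label data frame in the registry schema.
#' @param lexicon a `tnm_lexicon`.
#' @param tasks which tasks to train (default all five).
#' @param dim,window embedding hyperparameters (defaults 100 and 5).
#' @param seed master seed; each task trains with a derived seed.
#' @param n_search random-search budget per task.
#' @return A `tnm_ml_model`: embeddings per stage kind plus classifiers per
#'   task.
#' @export
train_stage_models <- function(records, labels, lexicon = load_lexicon(),
                               tasks = TASKS, dim = 100, window = 5,
                               seed = 1L, n_search = 50L) {
  embeddings <- list()
  for (kind in unique(TASK_KIND[tasks])) {
    streams <- list()
    for (rec in records) {
      sents <- concatenate_patient_text(rec, kind)
      if (nrow(sents))
        streams <- c(streams, lapply(sents$text, normalize_tokens))
    }
    embeddings[[kind]] <- train_embeddings(streams, dim = dim, window = window,
                                           seed = seed)
  }
  classifiers <- list()
  vectors <- list()
  for (task in tasks) {
    emb <- embeddings[[TASK_KIND[[task]]]]
    X <- build_task_matrix(records, task, emb, lexicon)
    vectors[[task]] <- X
    lab <- labels[[task]][match(rownames(X), labels$patient_id)]
    usable <- !attr(X, "degenerate") & !is.na(lab)
    classifiers[[task]] <- train_task_classifier(
      X[usable, , drop = FALSE], lab[usable], task = task,
      seed = seed + match(task, TASKS), n_search = n_search)
  }
  structure(list(embeddings = embeddings, classifiers = classifiers,
                 tasks = tasks, seed = seed, dim = dim, window = window),
            class = "tnm_ml_model")
}

#' Predict patient-level stages with a trained ML model
#'
#' @param model a `tnm_ml_model` from [train_stage_models()].
#' @param records list of `patient_record`s.
#' @param lexicon a `tnm_lexicon`.
#' @return Data frame in the registry schema; `NA` marks abstentions.
#' @export
predict_stages <- function(model, records, lexicon = load_lexicon()) {
  out <- data.frame(patient_id = vapply(records, `[[`, character(1), "patient_id"),
                    cT = NA_character_, cN = NA_character_, cM = NA_character_,
                    pT = NA_character_, pN = NA_character_)
  for (task in model$tasks) {
    emb <- model$embeddings[[TASK_KIND[[task]]]]
    X <- build_task_matrix(records, task, emb, lexicon)
    out[[task]] <- unname(predict(model$classifiers[[task]], X))
  }
  out
}
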