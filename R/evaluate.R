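## evaluation: score predictions against gold labels and account for
## registry imputation.

#' Cohen's kappa between two label vectors
#'
#' Chance-corrected agreement from the contingency table: observed
#' agreement versus agreement expected from the marginals. Pairs where
#' either label is missing are dropped. If either labeling has fewer than
#' two distinct categories over the paired data, kappa is undefined and
#' `NA` is returned rather than an error.
#'
#' @param a,b label vectors of equal length.
#' @return Kappa in \[-1, 1\], or `NA` when undefined.
#' @examples
#' cohen_kappa(rep(c("x", "y"), 50), rep(c("x", "y"), 50))
#' @export
cohen_kappa <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  a <- as.character(a[ok]); b <- as.character(b[ok])
  if (!length(a)) return(NA_real_)
  if (length(unique(a)) < 2L || length(unique(b)) < 2L) return(NA_real_)
  levs <- sort(union(a, b))
  tab <- table(factor(a, levs), factor(b, levs))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - pe == 0) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Per-task agreement between two label tables
#'
#' @param labels_a,labels_b data frames in the registry schema.
#' @param tasks tasks to compare.
#' @return Data frame of `task`, `n_pairs`, `kappa` (`NA` when undefined).
#' @export
agreement <- function(labels_a, labels_b, tasks = TASKS) {
  m <- merge(labels_a, labels_b, by = "patient_id", suffixes = c(".a", ".b"))
  do.call(rbind, lapply(tasks, function(task) {
    a <- m[[paste0(task, ".a")]]; b <- m[[paste0(task, ".b")]]
    data.frame(task = task, n_pairs = sum(!is.na(a) & !is.na(b)),
               kappa = cohen_kappa(a, b))
  }))
}

#' Score stage predictions against gold labels
#'
#' Per task and per category, one-vs-rest TP/FP/FN/TN counts with
#' precision, recall and F1 (the harmonic mean), plus per-task Cohen's
#' kappa. Pairs where either value is missing are excluded pairwise;
#' abstentions (gold present, prediction missing) are counted so the
#' denominator is always visible. Zero-denominator metrics are marked
#' undefined (`NA`), never silently zero.
#'
#' @param predictions,gold data frames in the registry schema.
#' @param tasks tasks to score.
#' @return A `tnm_metrics` object: list with `per_category` and `per_task`
#'   data frames.
#' @examples
#' g <- data.frame(patient_id = c("a", "b"), cT = c("T1-2", "T3-4"),
#'                 cN = NA, cM = NA, pT = NA, pN = NA)
#' score(g, g, tasks = "cT")
#' @export
score <- function(predictions, gold, tasks = TASKS) {
  m <- merge(predictions, gold, by = "patient_id", suffixes = c(".pred", ".gold"))
  if (!nrow(m)) stopf("prediction and gold patient id sets do not overlap")
  per_cat <- list(); per_task <- list()
  for (task in tasks) {
    p <- m[[paste0(task, ".pred")]]; g <- m[[paste0(task, ".gold")]]
    pair <- !is.na(p) & !is.na(g)
    abst <- sum(is.na(p) & !is.na(g))
    for (cat in TASK_LEVELS[[task]]) {
      tp <- sum(pair & p == cat & g == cat)
      fp <- sum(pair & p == cat & g != cat)
      fn <- sum(pair & p != cat & g == cat)
      tn <- sum(pair & p != cat & g != cat)
      prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
        2 * prec * rec / (prec + rec) else NA_real_
      per_cat[[length(per_cat) + 1L]] <- data.frame(
        task = task, category = cat, tp = tp, fp = fp, fn = fn, tn = tn,
        precision = prec, recall = rec, f1 = f1)
    }
    per_task[[length(per_task) + 1L]] <- data.frame(
      task = task, n_pairs = sum(pair), abstentions = abst,
      kappa = cohen_kappa(p[pair], g[pair]))
  }
  structure(list(per_category = do.call(rbind, per_cat),
                 per_task = do.call(rbind, per_task)),
            class = "tnm_metrics")
}

#' @export
print.tnm_metrics <- function(x, digits = 3, ...) {
  cat("Per-category evaluation (one-vs-rest):\n")
  pc <- x$per_category
  pc$precision <- round(pc$precision, digits)
  pc$recall <- round(pc$recall, digits)
  pc$f1 <- round(pc$f1, digits)
  print(pc, row.names = FALSE)
  cat("\nPer-task agreement:\n")
  pt <- x$per_task
  pt$kappa <- round(pt$kappa, digits)
  print(pt, row.names = FALSE)
  invisible(x)
}

#' Impute missing registry stage fields from predictions
#'
#' Fills only empty registry cells with the corresponding prediction;
#' populated cells are never overwritten, and predictions disagreeing with
#' a populated cell are counted as conflicts and reported. A `<task>_source`
#' column marks each filled cell as `registry` or `imputed` (existing
#' source columns are preserved, so imputation is idempotent).
#'
#' @param registry registry data frame in the registry schema.
#' @param predictions prediction data frame in the registry schema (`NA` =
#'   abstention, never imputed).
#' @param tasks tasks to impute.
#' @return List with `table` (augmented registry) and `report`
#'   (`tnm_imputation`: per-task missing/imputed/conflict accounting and
#'   per-category imputed counts).
#' @export
impute <- function(registry, predictions, tasks = TASKS) {
  pidx <- match(registry$patient_id, predictions$patient_id)
  summary <- list(); by_cat <- list()
  for (task in tasks) {
    src_col <- paste0(task, "_source")
    if (is.null(registry[[src_col]]))
      registry[[src_col]] <- ifelse(!is.na(registry[[task]]), "registry", NA_character_)
    p <- predictions[[task]][pidx]
    missing <- is.na(registry[[task]])
    fill <- missing & !is.na(p)
    conflicts <- sum(!missing & !is.na(p) & registry[[task]] != p)
    registry[[task]][fill] <- p[fill]
    registry[[src_col]][fill] <- "imputed"
    summary[[task]] <- data.frame(
      task = task, total = nrow(registry), missing_n = sum(missing),
      missing_pct = 100 * sum(missing) / nrow(registry),
      imputed_n = sum(fill),
      imputed_pct = if (sum(missing) > 0) 100 * sum(fill) / sum(missing) else 0,
      conflicts = conflicts)
    for (cat in TASK_LEVELS[[task]]) {
      by_cat[[paste(task, cat)]] <- data.frame(
        task = task, category = cat, imputed_n = sum(fill & p == cat, na.rm = TRUE))
    }
  }
  report <- structure(list(summary = do.call(rbind, summary),
                           by_category = do.call(rbind, by_cat)),
                      class = "tnm_imputation")
  rownames(report$summary) <- rownames(report$by_category) <- NULL
  list(table = registry, report = report)
}

#' @export
print.tnm_imputation <- function(x, ...) {
  cat("Missing-data imputation accounting:\n")
  s <- x$summary
  s$missing_pct <- round(s$missing_pct, 1)
  s$imputed_pct <- round(s$imputed_pct, 1)
  print(s, row.names = FALSE)
  cat("\nImputed counts per category:\n")
  print(x$by_category, row.names = FALSE)
  invisible(x)
}

## serializable forms for the CLI JSON outputs
metrics_as_list <- function(metrics) {
  out <- list()
  for (task in unique(metrics$per_category$task)) {
    rows <- metrics$per_category[metrics$per_category$task == task, , drop = FALSE]
    cats <- list()
    for (i in seq_len(nrow(rows)))
      cats[[rows$category[i]]] <- list(precision = rows$precision[i],
                                       recall = rows$recall[i], f1 = rows$f1[i])
    pt <- metrics$per_task[metrics$per_task$task == task, ]
    out[[task]] <- list(categories = cats, kappa = pt$kappa,
                        n_pairs = pt$n_pairs, abstentions = pt$abstentions)
  }
  out
}

imputation_as_list <- function(report) {
  out <- list()
  for (i in seq_len(nrow(report$summary))) {
    row <- report$summary[i, ]
    bc <- report$by_category[report$by_category$task == row$task, , drop = FALSE]
    out[[row$task]] <- list(total = row$total, missing_n = row$missing_n,
                            missing_pct = row$missing_pct,
                            imputed_n = row$imputed_n,
                            imputed_pct = row$imputed_pct,
                            conflicts = row$conflicts,
                            imputed_by_category = setNames(as.list(bc$imputed_n),
                                                           bc$category))
  }
  out
}
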