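mk_labels <- function(pid, cT = NA, cN = NA, cM = NA, pT = NA, pN = NA) {
  data.frame(patient_id = pid, cT = cT, cN = cN, cM = cM, pT = pT, pN = pN,
             stringsAsFactors = FALSE)
}

test_that("precision, recall and F1 follow their closed forms", {
  # TP=3, FP=1, FN=1 within the cT task
  gold <- mk_labels(sprintf("p%d", 1:5),
                    cT = c("T3-4", "T3-4", "T3-4", "T1-2", "T3-4"))
  pred <- mk_labels(sprintf("p%d", 1:5),
                    cT = c("T3-4", "T3-4", "T3-4", "T3-4", "T1-2"))
  m <- score(pred, gold, tasks = "cT")
  row <- m$per_category[m$per_category$category == "T3-4", ]
  expect_equal(row[, c("tp", "fp", "fn")], data.frame(tp = 3L, fp = 1L, fn = 1L),
               ignore_attr = TRUE)
  expect_equal(row$precision, 0.75)
  expect_equal(row$recall, 0.75)
  expect_equal(row$f1, 0.75)

  # undefined metrics are NA-marked, not zero
  gold2 <- mk_labels(c("a", "b"), cM = c("M0", "M0"))
  pred2 <- mk_labels(c("a", "b"), cM = c("M0", "M0"))
  m2 <- score(pred2, gold2, tasks = "cM")
  m1row <- m2$per_category[m2$per_category$category == "M1", ]
  expect_true(is.na(m1row$precision) && is.na(m1row$recall))

  expect_error(score(mk_labels("x"), mk_labels("y")), "overlap")
})

test_that("scoring is symmetric under relabeling of the two categories", {
  set.seed(8)
  g <- sample(c("N0", "N1"), 200, TRUE, prob = c(0.8, 0.2))
  p <- ifelse(runif(200) < 0.85, g, ifelse(g == "N0", "N1", "N0"))
  m <- score(mk_labels(sprintf("p%d", 1:200), cN = p),
             mk_labels(sprintf("p%d", 1:200), cN = g), tasks = "cN")
  swap <- function(x) ifelse(x == "N0", "N1", "N0")
  m_sw <- score(mk_labels(sprintf("p%d", 1:200), cN = swap(p)),
                mk_labels(sprintf("p%d", 1:200), cN = swap(g)), tasks = "cN")
  a <- m$per_category[order(m$per_category$category), c("precision", "recall", "f1")]
  b <- m_sw$per_category[order(rev(m_sw$per_category$category)), c("precision", "recall", "f1")]
  expect_equal(a, b, ignore_attr = TRUE)
  expect_equal(m$per_task$kappa, m_sw$per_task$kappa)
})

test_that("kappa matches hand arithmetic and an independent implementation", {
  # identical vectors -> 1
  expect_equal(cohen_kappa(rep(c("x", "y"), 10), rep(c("x", "y"), 10)), 1)

  # 2x2 table [[45,5],[5,45]]: po=0.9, pe=0.5 -> 0.8
  a <- c(rep("u", 50), rep("v", 50))
  b <- c(rep("u", 45), rep("v", 5), rep("u", 5), rep("v", 45))
  expect_equal(cohen_kappa(a, b), 0.8)

  # degenerate marginal: one rater constant -> undefined-marked
  expect_true(is.na(cohen_kappa(rep("u", 20), c(rep("u", 10), rep("v", 10)))))

  # independence at chance on a large sample -> kappa near 0, and our
  # closed form agrees with e1071's contingency-table implementation
  set.seed(123)
  x <- sample(c("A", "B"), 10000, TRUE)
  y <- sample(c("A", "B"), 10000, TRUE)
  k <- cohen_kappa(x, y)
  expect_lt(abs(k), 0.05)
  k_ref <- e1071::classAgreement(table(x, y))$kappa
  expect_equal(k, k_ref, tolerance = 1e-12)
})

test_that("agreement reports per-task kappas over paired labels", {
  g <- mk_labels(sprintf("p%d", 1:100),
                 cT = rep(c("T1-2", "T3-4"), 50), cN = rep("N0", 100))
  ag <- agreement(g, g, tasks = c("cT", "cN"))
  expect_equal(ag$kappa[ag$task == "cT"], 1)
  expect_true(is.na(ag$kappa[ag$task == "cN"]))   # constant raters
})

test_that("imputation fills only missing cells, counts conflicts, and is idempotent", {
  registry <- mk_labels(sprintf("p%d", 1:6),
                        cT = c("T1-2", NA, NA, "T1-2", NA, NA))
  pred <- mk_labels(sprintf("p%d", 1:6),
                    cT = c("T1-2", "T3-4", NA, "T3-4", "T1-2", NA))
  res <- impute(registry, pred, tasks = "cT")
  s <- res$report$summary
  expect_equal(s$missing_n, 4L)
  expect_equal(s$imputed_n, 2L)
  expect_equal(s$imputed_pct, 50)
  expect_equal(s$conflicts, 1L)                       # p4 disagreed, not overwritten
  expect_equal(res$table$cT[4], "T1-2")
  expect_equal(res$table$cT_source[2], "imputed")
  expect_equal(res$table$cT_source[1], "registry")
  expect_true(is.na(res$table$cT[6]))                 # abstention never imputed

  # per-category imputed counts sum to the task's imputed count
  bc <- res$report$by_category
  expect_equal(sum(bc$imputed_n), s$imputed_n)

  # idempotence: re-imputing the augmented table changes nothing
  res2 <- impute(res$table, pred, tasks = "cT")
  expect_identical(res2$table, res$table)
  expect_equal(res2$report$summary$imputed_n, 0L)

  # zero missing -> zero imputed, 0%
  full <- mk_labels("q1", cT = "T1-2")
  r0 <- impute(full, mk_labels("q1", cT = "T1-2"), tasks = "cT")
  expect_equal(r0$report$summary$imputed_n, 0L)
  expect_equal(r0$report$summary$imputed_pct, 0)
})

test_that("imputed percentage is imputed/missing: 24 covered of 100 missing is 24%", {
  registry <- mk_labels(sprintf("p%d", 1:100), cT = NA_character_)
  pred <- mk_labels(sprintf("p%d", 1:100),
                    cT = c(rep("T1-2", 24), rep(NA, 76)))
  res <- impute(registry, pred, tasks = "cT")
  expect_equal(res$report$summary$imputed_pct, 24)
})
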