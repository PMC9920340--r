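make_subject_table <- function(n_subj = 4, per_subj = 30, sep = 2, seed = 1) {
  set.seed(seed)
  n <- n_subj * per_subj
  subj <- rep(sprintf("S%02d", seq_len(n_subj)), each = per_subj)
  y <- rep_len(c("RISK", "NON-RISK"), n)
  x <- cbind(f1 = rnorm(n) + ifelse(y == "RISK", sep, 0), f2 = rnorm(n))
  feature_table(x, y, subject_id = subj,
                env_id = rep_len(c("E1", "E2"), n))
}

test_that("LOSO folds partition rows and never leak the test subject", {
  tbl <- make_subject_table(8)
  folds <- loso_folds(tbl)
  expect_length(folds, 8)
  test_union <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(test_union, seq_len(nrow(tbl)))  # no overlap, full coverage
  for (f in folds) {
    expect_length(intersect(tbl$subject_id[f$train],
                            tbl$subject_id[f$test]), 0)
    expect_equal(sort(c(f$train, f$test)), seq_len(nrow(tbl)))
  }
  # two subjects: each fold trains on the other
  folds2 <- loso_folds(make_subject_table(2))
  expect_length(folds2, 2)
  expect_error(loso_folds(make_subject_table(1)), "at least 2")
})

test_that("classification metrics match hand arithmetic", {
  truth <- rep(c("RISK", "NON-RISK"), each = 10)
  # degenerate always-NON-RISK predictor on a 50/50 table
  m <- classification_metrics(truth, rep("NON-RISK", 20))
  expect_equal(unname(m[c("accuracy", "precision", "recall", "f1")]),
               c(0.5, 0, 0, 0))
  # hand-built confusion: tp=8, fn=2, fp=3, tn=7
  pred <- c(rep("RISK", 8), rep("NON-RISK", 2),
            rep("RISK", 3), rep("NON-RISK", 7))
  m <- classification_metrics(truth, pred)
  expect_equal(unname(m["accuracy"]), 15 / 20)
  expect_equal(unname(m["precision"]), 8 / 11)
  expect_equal(unname(m["recall"]), 8 / 10)
  expect_equal(unname(m["f1"]),
               2 * (8 / 11) * (8 / 10) / ((8 / 11) + (8 / 10)))
})

test_that("per-fold evaluation is exact on a separable table", {
  tbl <- make_subject_table(4, sep = 8)
  res <- evaluate_loso(tbl, model_spec("lda"))
  expect_s3_class(res, "loso_metrics")
  expect_equal(res$accuracy, rep(1, 4))
  expect_equal(res$n_test, rep(30, 4))
  # metric identity: accuracy recomputable from stored confusion counts
  expect_equal(res$accuracy, (res$tp + res$tn) / res$n_test)
  expect_true(all(res$train_time >= 0 & res$pred_time >= 0))
})

test_that("sensor ablation selects the documented column subsets", {
  tabs <- scaled_tables(301, "null", n_subjects = 4)
  phy <- tabs$phy
  folds <- loso_folds(phy)
  res <- sensor_ablation(phy, model_spec("knn"), folds)
  counts <- unique(res[, c("config", "n_features")])
  expect_equal(counts$n_features[match(c("I", "II", "III", "IV", "V", "VI", "VII"),
                                       counts$config)],
               c(40, 34, 22, 24, 18, 16, 6))
  # configuration I is the identity subset: equals the full evaluation
  full <- evaluate_loso(phy, model_spec("knn"), folds)
  expect_equal(res$accuracy[res$config == "I"], full$accuracy)
})

test_that("environment split flags folds with a missing environment", {
  tbl <- make_subject_table(4)
  tbl_e1 <- tbl
  tbl_e1$env_id <- "E1"
  es <- environment_split(tbl_e1, model_spec("knn"))
  expect_true(all(es$per_fold$flagged[es$per_fold$env_id == "E2"]))
  expect_true(all(is.na(es$per_fold$accuracy[es$per_fold$env_id == "E2"])))
  expect_null(es$wilcoxon)

  es2 <- environment_split(tbl, model_spec("knn"))
  expect_equal(sum(es2$per_fold$env_id == "E1" & !es2$per_fold$flagged), 4)
  expect_equal(sum(es2$per_fold$env_id == "E2" & !es2$per_fold$flagged), 4)
  expect_false(is.null(es2$wilcoxon))
})

test_that("paired signed-rank test is exact, tied-safe and Bonferroni-aware", {
  a <- c(0.7, 0.72, 0.8, 0.65, 0.77, 0.7, 0.69, 0.75)
  # identical vectors: degenerate, never significant
  w <- paired_wilcoxon(a, a)
  expect_true(w$degenerate)
  expect_equal(w$p, 1)
  expect_false(w$significant)

  # uniform +0.2 shift over 8 folds: all ranks on one side, p = 2/2^8
  w <- paired_wilcoxon(a + 0.2, a)
  expect_equal(w$p, 0.0078125)
  expect_equal(w$statistic, 36)
  expect_true(w$significant)

  # Bonferroni threshold 0.05 / 3
  w3 <- paired_wilcoxon(a + 0.2, a, n_comparisons = 3)
  expect_equal(w3$threshold, 0.05 / 3, tolerance = 1e-12)
  expect_true(w3$significant)

  # tie-free data: enumeration agrees with the exact distribution oracle
  set.seed(14)
  for (i in 1:10) {
    x <- rnorm(9)
    y <- rnorm(9)
    if (any(duplicated(abs(x - y))) || any(x == y)) next
    expect_equal(paired_wilcoxon(x, y)$p,
                 wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("reports serialise deterministically with CSV sidecars", {
  tbl <- make_subject_table(3, sep = 8)
  res <- evaluate_loso(tbl, model_spec("knn"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  payload <- list(first_analysis = as.data.frame(res),
                  wilcoxon = paired_wilcoxon(res$accuracy, res$accuracy))
  write_report(payload, d1)
  write_report(payload, d2)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
  expect_true(file.exists(file.path(d1, "first_analysis.csv")))
  js <- jsonlite::fromJSON(file.path(d1, "report.json"))
  expect_true(js$complete)
  expect_equal(nrow(js$results$first_analysis), 3)
  # partial runs are marked incomplete
  write_report(list(done = res, pending = NULL), d1)
  expect_false(jsonlite::fromJSON(file.path(d1, "report.json"))$complete)
})
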