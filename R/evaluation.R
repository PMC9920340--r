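# Leave-one-subject-out validation, classification metrics, sensor-ablation
# and environment-split analyses, the exact paired signed-rank test, and
# report serialisation.

#' Leave-one-subject-out folds
#'
#' One fold per subject: the fold's test rows are all windows of that
#' subject, its training rows everything else. Folds are ordered by
#' `subject_id` and partition the table.
#'
#' @param table A `feature_table`.
#' @return List of folds: `subject`, `train`, `test` (row indices).
#' @export
loso_folds <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  subjects <- sort(unique(table$subject_id))
  if (length(subjects) < 2) stop("LOSO requires at least 2 subjects")
  lapply(subjects, function(s) {
    test <- which(table$subject_id == s)
    list(subject = s, train = setdiff(seq_len(nrow(table)), test),
         test = test)
  })
}

#' Classification metrics for binary risk labels
#'
#' Accuracy, precision, recall and F1 with RISK as the positive class
#' (zero, not NaN, when a denominator is empty), plus the confusion counts.
#'
#' @param truth,pred Label vectors.
#' @param positive Positive class, default `"RISK"`.
#' @return Named numeric vector: `accuracy, precision, recall, f1, tp, fp,
#'   tn, fn`.
#' @export
classification_metrics <- function(truth, pred, positive = "RISK") {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred), length(truth) > 0)
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  tn <- sum(pred != positive & truth != positive)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  c(accuracy = (tp + tn) / length(truth), precision = precision,
    recall = recall, f1 = f1, tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Leave-one-subject-out evaluation of one classifier
#'
#' Trains on each fold's training rows, predicts its held-out subject and
#' reports per-fold metrics and wall-clock timings.
#'
#' @param table A `feature_table`.
#' @param spec A [model_spec()].
#' @param folds From [loso_folds()].
#' @param features Optional feature subset.
#' @return data.frame of class `loso_metrics`: one row per fold with
#'   `subject`, `n_test`, `accuracy`, `precision`, `recall`, `f1`,
#'   confusion counts and `train_time` / `pred_time` (seconds).
#' @export
evaluate_loso <- function(table, spec, folds = loso_folds(table),
                          features = NULL) {
  stopifnot(inherits(table, "feature_table"), inherits(spec, "model_spec"))
  rows <- lapply(folds, function(f) {
    if (length(intersect(table$subject_id[f$train],
                         table$subject_id[f$test])))
      stop("fold leaks its test subject into training rows")
    if (length(unique(table$label[f$train])) < 2)
      stop("fold ", f$subject, " has a single class in training rows")
    m <- train_model(spec, table[f$train, ], features = features)
    pred <- predict_model(m, table[f$test, ])
    met <- classification_metrics(table$label[f$test], pred)
    data.frame(subject = f$subject, n_test = length(f$test), t(met),
               train_time = m$train_time,
               pred_time = attr(pred, "pred_time"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("loso_metrics", "data.frame")
  out
}

# The seven sensor configurations of the ablation analysis.
.SENSOR_CONFIGS <- list(
  I = c("GSR", "CR", "ST"), II = c("GSR", "CR"), III = c("GSR", "ST"),
  IV = c("CR", "ST"), V = "CR", VI = "GSR", VII = "ST")

#' Sensor-ablation analysis
#'
#' Evaluates each classifier on the seven column subsets of the
#' physiological table defined by sensor groups: (I) GSR+CR+ST = full PHY,
#' (II) GSR+CR, (III) GSR+ST, (IV) CR+ST, (V) CR, (VI) GSR, (VII) ST.
#'
#' @param phy_table The physiological `feature_table`.
#' @param specs A [model_spec()] or list of them.
#' @param folds From [loso_folds()].
#' @return data.frame: `config`, `sensors`, `n_features`, `model`, and the
#'   per-fold metric columns of [evaluate_loso()].
#' @export
sensor_ablation <- function(phy_table, specs, folds = loso_folds(phy_table)) {
  if (inherits(specs, "model_spec")) specs <- list(specs)
  sm <- sensor_map(phy_table)
  out <- list()
  for (cfg in names(.SENSOR_CONFIGS)) {
    feats <- names(sm)[sm %in% .SENSOR_CONFIGS[[cfg]]]
    if (!length(feats)) stop("sensor configuration ", cfg,
                             " selects no features")
    for (spec in specs) {
      res <- evaluate_loso(phy_table, spec, folds, features = feats)
      res <- cbind(data.frame(
        config = cfg,
        sensors = paste(.SENSOR_CONFIGS[[cfg]], collapse = "+"),
        n_features = length(feats), model = spec$family,
        stringsAsFactors = FALSE), as.data.frame(res))
      out[[length(out) + 1]] <- res
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-environment fold accuracies
#'
#' Runs the LOSO evaluation once per fold and computes the accuracy
#' separately over the held-out subject's E1 and E2 windows, then compares
#' the paired per-fold accuracies with the exact signed-rank test. Folds
#' with no test rows in an environment are flagged and excluded from that
#' environment's summary.
#'
#' @param table A `feature_table`.
#' @param spec A [model_spec()].
#' @param folds From [loso_folds()].
#' @param features Optional feature subset.
#' @return List: `per_fold` (data.frame `subject`, `env_id`, `n_test`,
#'   `accuracy`, `flagged`), `wilcoxon` (paired E1-vs-E2 test over complete
#'   folds, `NULL` if fewer than 2).
#' @export
environment_split <- function(table, spec, folds = loso_folds(table),
                              features = NULL) {
  envs <- c("E1", "E2")
  rows <- list()
  for (f in folds) {
    m <- train_model(spec, table[f$train, ], features = features)
    pred <- predict_model(m, table[f$test, ])
    truth <- table$label[f$test]
    env <- table$env_id[f$test]
    for (e in envs) {
      sel <- env == e
      rows[[length(rows) + 1]] <- data.frame(
        subject = f$subject, env_id = e, n_test = sum(sel),
        accuracy = if (any(sel)) mean(pred[sel] == truth[sel]) else NA_real_,
        flagged = !any(sel), stringsAsFactors = FALSE)
    }
  }
  per_fold <- do.call(rbind, rows)
  wide <- merge(per_fold[per_fold$env_id == "E1" & !per_fold$flagged,
                         c("subject", "accuracy")],
                per_fold[per_fold$env_id == "E2" & !per_fold$flagged,
                         c("subject", "accuracy")],
                by = "subject", suffixes = c("_e1", "_e2"))
  wilcox <- if (nrow(wide) >= 2)
    paired_wilcoxon(wide$accuracy_e1, wide$accuracy_e2) else NULL
  list(per_fold = per_fold, wilcoxon = wilcox)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences, with the null
#' distribution computed exactly by enumerating all sign assignments of the
#' (tied-average) ranks when at most `exact_max` non-zero differences are
#' present, and by the normal approximation (with continuity correction)
#' otherwise. Exact enumeration remains valid under tied absolute
#' differences, which per-fold accuracies routinely produce. Significance is
#' declared at the Bonferroni-corrected level `0.05 / n_comparisons`.
#'
#' @param a,b Equal-length paired samples (e.g. per-fold accuracies).
#' @param n_comparisons Number of comparisons in the enclosing analysis.
#' @param exact_max Largest number of non-zero differences enumerated
#'   exactly (default 16; 2^16 sign patterns).
#' @return List: `statistic` (V, sum of positive-difference ranks), `p`,
#'   `threshold`, `significant`, `n_nonzero`, `degenerate` (all differences
#'   zero: `p = 1`), `method`.
#' @export
paired_wilcoxon <- function(a, b, n_comparisons = 1, exact_max = 16) {
  stopifnot(length(a) == length(b), length(a) > 0, n_comparisons >= 1)
  d <- a - b
  d <- d[d != 0]
  thr <- 0.05 / n_comparisons
  if (!length(d)) {
    return(list(statistic = 0, p = 1, threshold = thr, significant = FALSE,
                n_nonzero = 0L, degenerate = TRUE, method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  m <- length(d)
  if (m <= exact_max) {
    # all 2^m sign patterns of the rank vector
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    v_all <- as.vector(signs %*% r)
    p <- 2 * min(mean(v_all <= v), mean(v_all >= v))
    method <- "exact enumeration"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (v - mu - sign(v - mu) * 0.5) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  p <- min(1, p)
  list(statistic = v, p = p, threshold = thr, significant = p < thr,
       n_nonzero = m, degenerate = FALSE, method = method)
}

#' Write an evaluation report
#'
#' Serialises a named list of results to `report.json` (deterministic field
#' order) and writes each data.frame element additionally as its own CSV.
#' A report containing `NULL` elements is marked incomplete.
#'
#' @param results Named list (data.frames, test results, weight matrices...).
#' @param dir Output directory (created if missing).
#' @return Path of the JSON report, invisibly.
#' @export
write_report <- function(results, dir) {
  stopifnot(is.list(results), !is.null(names(results)),
            all(nzchar(names(results))))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  complete <- !any(vapply(results, is.null, logical(1)))
  for (nm in names(results)) {
    if (is.data.frame(results[[nm]])) {
      data.table::fwrite(as.data.frame(results[[nm]]),
                         file.path(dir, paste0(nm, ".csv")))
    }
  }
  payload <- list(complete = complete,
                  results = results[order(names(results))])
  path <- file.path(dir, "report.json")
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null", force = TRUE),
             path)
  invisible(path)
}
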