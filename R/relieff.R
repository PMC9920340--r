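# ReliefF feature weighting for binary-labeled continuous features, feature
# ranking, and the incremental optimal-feature-subset search.

.minmax_fit <- function(x) {
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  rng <- hi - lo
  rng[rng == 0] <- 1  # constant features map to 0 and carry no weight
  list(lo = lo, rng = rng)
}
.minmax_apply <- function(x, f) sweep(sweep(x, 2, f$lo), 2, f$rng, "/")

#' ReliefF feature weights
#'
#' Instance-based feature weighting for a binary classification table. All
#' features are min-max scaled to `[0, 1]`; for every instance the `k`
#' nearest same-class neighbours (hits) and `k` nearest other-class
#' neighbours (misses) are found by Euclidean distance on all scaled
#' features, and each feature's weight accumulates the miss-distance minus
#' the hit-distance along that feature, averaged over instances and
#' neighbours:
#' `W[f] = sum_i [ sum_miss |x_if - m_f| - sum_hit |x_if - h_f| ] / (n k)`.
#' Every instance is used (no subsampling), so the result is deterministic
#' up to neighbour ties, which are broken by row order.
#'
#' @param x Numeric matrix or data.frame (instances x features), or a
#'   `feature_table`.
#' @param y Binary labels (ignored when `x` is a `feature_table`, whose
#'   `label` column is used).
#' @param k Number of neighbours per class (each class must have at least
#'   `k + 1` members).
#' @return Named numeric vector of weights in `[-1, 1]`.
#' @export
relieff_weights <- function(x, y = NULL, k = 5) {
  if (inherits(x, "feature_table")) {
    y <- x$label
    x <- feature_matrix(x)
  }
  x <- as.matrix(x)
  stopifnot(is.numeric(x), !anyNA(x), k >= 1)
  y <- factor(y)
  if (nlevels(y) != 2) stop("ReliefF here requires exactly 2 classes")
  cnt <- table(y)
  short <- names(cnt)[cnt < k + 1]
  if (length(short))
    stop("class ", paste(short, collapse = ", "), " has fewer than k+1 = ",
         k + 1, " samples")
  n <- nrow(x); p <- ncol(x)
  xs <- .minmax_apply(x, .minmax_fit(x))
  d <- as.matrix(stats::dist(xs))
  w <- numeric(p)
  idx_by_class <- split(seq_len(n), y)
  for (i in seq_len(n)) {
    same <- setdiff(idx_by_class[[as.integer(y[i])]], i)
    other <- idx_by_class[[3L - as.integer(y[i])]]
    hits <- same[order(d[i, same], same)][seq_len(k)]
    misses <- other[order(d[i, other], other)][seq_len(k)]
    w <- w +
      colSums(abs(xs[misses, , drop = FALSE] -
                    matrix(xs[i, ], k, p, byrow = TRUE))) -
      colSums(abs(xs[hits, , drop = FALSE] -
                    matrix(xs[i, ], k, p, byrow = TRUE)))
  }
  stats::setNames(w / (n * k), colnames(x))
}

#' Rank features by descending weight
#'
#' Ties are broken by original column order, so the ranking is a stable
#' permutation of all feature names.
#'
#' @param weights Named numeric vector (e.g. from [relieff_weights()]).
#' @return Character vector of feature names, best first.
#' @export
rank_features <- function(weights) {
  stopifnot(is.numeric(weights), all(is.finite(weights)),
            !is.null(names(weights)))
  names(weights)[order(-weights, seq_along(weights))]
}

#' ReliefF weights across a set of neighbourhood sizes
#'
#' @param table A `feature_table`.
#' @param k_list Neighbourhood sizes, default `c(1, 3, 5, 10)`.
#' @param rank_k Which `k` to use for the ranking, default 5.
#' @return A `relieff_result`: list with `weights` (features x k matrix),
#'   `ranking`, `rank_k`.
#' @export
relieff <- function(table, k_list = c(1, 3, 5, 10), rank_k = 5) {
  stopifnot(inherits(table, "feature_table"), rank_k %in% k_list)
  w <- vapply(k_list, function(k) relieff_weights(table, k = k),
              numeric(length(feature_names(table))))
  colnames(w) <- paste0("k", k_list)
  out <- list(weights = w,
              ranking = rank_features(w[, paste0("k", rank_k)]),
              rank_k = rank_k, k_list = k_list)
  class(out) <- "relieff_result"
  out
}

#' @export
print.relieff_result <- function(x, ...) {
  cat(sprintf("<relieff_result> %d features, k in {%s}; top 3 (k=%d): %s\n",
              nrow(x$weights), paste(x$k_list, collapse = ","), x$rank_k,
              paste(x$ranking[1:min(3, length(x$ranking))], collapse = ", ")))
  invisible(x)
}

#' Incremental optimal-feature-set search
#'
#' Adds features one at a time from the heaviest to the lightest, records
#' the median leave-one-subject-out fold accuracy at each set size, and
#' selects the smallest size attaining the maximum median. In the default
#' `per_fold` mode the ranking is recomputed on each fold's training rows
#' (no selection leakage into the held-out subject); `global` mode uses one
#' ranking for all folds (supply it via `ranking` or it is computed on the
#' full table).
#'
#' @param table A `feature_table`.
#' @param spec A [model_spec()] (default 1-NN).
#' @param folds From [loso_folds()].
#' @param mode `"per_fold"` or `"global"`.
#' @param ranking Optional precomputed ranking for `global` mode.
#' @param k ReliefF neighbourhood size for the rankings.
#' @param max_features Optional cap on the search length.
#' @return List: `n_opt`, `features` (top `n_opt` by the full-table
#'   ranking), `curve` (data.frame `n`, `median_accuracy`), `mode`,
#'   `fold_rankings`.
#' @export
optimal_feature_set <- function(table, spec = model_spec("knn"),
                                folds = loso_folds(table),
                                mode = c("per_fold", "global"),
                                ranking = NULL, k = 5,
                                max_features = NULL) {
  mode <- match.arg(mode)
  feats <- feature_names(table)
  p <- if (is.null(max_features)) length(feats) else min(max_features,
                                                         length(feats))
  full_ranking <- if (is.null(ranking)) {
    rank_features(relieff_weights(table, k = k))
  } else {
    if (!setequal(ranking, feats)) stop("ranking must cover the table's features")
    ranking
  }
  fold_rankings <- lapply(folds, function(f) {
    if (mode == "global") full_ranking
    else rank_features(relieff_weights(table[f$train, ], k = k))
  })
  acc <- matrix(NA_real_, p, length(folds))
  for (fi in seq_along(folds)) {
    f <- folds[[fi]]
    rk <- fold_rankings[[fi]]
    for (ni in seq_len(p)) {
      m <- train_model(spec, table[f$train, ], features = rk[seq_len(ni)])
      pred <- predict_model(m, table[f$test, ])
      acc[ni, fi] <- mean(pred == table$label[f$test])
    }
  }
  curve <- data.frame(n = seq_len(p), median_accuracy = apply(acc, 1, stats::median))
  n_opt <- which.max(curve$median_accuracy)  # first max = smallest N
  list(n_opt = n_opt, features = full_ranking[seq_len(n_opt)],
       curve = curve, mode = mode, fold_rankings = fold_rankings)
}
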