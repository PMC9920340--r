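# The four reference classifiers behind one train/predict contract:
# 1-nearest-neighbour (Euclidean), linear discriminant analysis, Gaussian
# support vector machine (kernel scale 1, box constraint 1) and a CART
# decision tree (Gini split, min branch 10 / min leaf 1). kNN and LDA
# standardize features with training-fold statistics (unscaled kNN on
# mixed-unit features is degenerate). The SVM and the tree consume raw
# features, matching the reference stack's defaults: a fixed kernel scale
# of 1 is meant for the raw baseline-normalized feature magnitudes, and
# standardizing first would inflate distances until the Gaussian kernel
# collapses to a majority vote.

#' Classifier specification
#'
#' Families and default hyperparameters:
#' * `knn`: `n_neighbors = 1`, Euclidean distance;
#' * `lda`: linear discriminant, classes share one covariance matrix;
#' * `svm`: Gaussian (radial) kernel, `kernel_scale = 1`,
#'   `box_constraint = 1`;
#' * `tree`: Gini diversity split, standard CART,
#'   `min_branch_obs = 10`, `min_leaf_obs = 1`.
#'
#' @param family One of `"knn"`, `"lda"`, `"svm"`, `"tree"`.
#' @param ... Hyperparameter overrides (must name existing defaults).
#' @param standardize Standardize features with training statistics before
#'   fitting (`TRUE` for knn/lda; `FALSE` for svm/tree, whose reference
#'   implementations consume raw features -- see the package vignette).
#' @return A `model_spec` list with `family`, `hyper`, `standardize`,
#'   `overridden`.
#' @export
model_spec <- function(family = c("knn", "lda", "svm", "tree"), ...,
                       standardize = NULL) {
  family <- match.arg(family)
  defaults <- switch(family,
    knn  = list(n_neighbors = 1, metric = "euclidean"),
    lda  = list(),
    svm  = list(kernel_scale = 1, box_constraint = 1),
    tree = list(split = "gini", min_branch_obs = 10, min_leaf_obs = 1))
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown hyperparameter(s) for ", family, ": ",
                        paste(bad, collapse = ", "))
  hyper <- utils::modifyList(defaults, over)
  out <- list(family = family, hyper = hyper,
              standardize = if (is.null(standardize))
                family %in% c("knn", "lda") else standardize,
              overridden = names(over))
  class(out) <- "model_spec"
  out
}

#' @export
print.model_spec <- function(x, ...) {
  hp <- paste(names(x$hyper), unlist(x$hyper), sep = "=", collapse = ", ")
  cat(sprintf("<model_spec> %s {%s}%s\n", x$family, hp,
              if (length(x$overridden))
                paste0(" [overridden: ", paste(x$overridden, collapse = ","), "]")
              else ""))
  invisible(x)
}

.resolve_xy <- function(x, y, features) {
  if (inherits(x, "feature_table")) {
    y <- x$label
    x <- feature_matrix(x, features)
  } else {
    x <- as.matrix(x)
    if (!is.null(features)) x <- x[, features, drop = FALSE]
  }
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  list(x = x, y = factor(y))
}

#' Train a classifier
#'
#' @param spec A [model_spec()].
#' @param x A `feature_table` (its `label` column is the response) or a
#'   numeric matrix/data.frame.
#' @param y Labels (ignored for a `feature_table`).
#' @param features Optional subset of feature columns to train on.
#' @return A `trained_model`: `spec`, the fitted object, the training
#'   feature names and scaler parameters, class levels, dropped
#'   zero-variance columns, and the wall-clock `train_time` (seconds).
#' @export
train_model <- function(spec, x, y = NULL, features = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  xy <- .resolve_xy(x, y, features)
  if (anyNA(xy$x)) stop("training features contain missing values")
  if (nlevels(droplevels(xy$y)) < 2)
    stop("training data contains a single class")
  xm <- xy$x; yv <- droplevels(xy$y)
  t0 <- proc.time()["elapsed"]

  center <- scale_ <- NULL
  dropped <- character(0)
  if (spec$standardize) {
    center <- colMeans(xm)
    scale_ <- apply(xm, 2, stats::sd)
    dropped <- colnames(xm)[scale_ == 0]
    keep <- scale_ > 0
    xm <- sweep(sweep(xm[, keep, drop = FALSE], 2, center[keep]), 2,
                scale_[keep], "/")
    center <- center[keep]; scale_ <- scale_[keep]
    if (!ncol(xm)) stop("all features constant in training data")
  }

  fit <- switch(spec$family,
    knn = list(x = xm, y = yv),
    lda = MASS::lda(xm, grouping = yv),
    svm = e1071::svm(xm, yv, type = "C-classification", kernel = "radial",
                     gamma = 1 / spec$hyper$kernel_scale^2,
                     cost = spec$hyper$box_constraint, scale = FALSE),
    tree = {
      df <- data.frame(.y = yv, xm, check.names = TRUE)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = spec$hyper$split),
                   control = rpart::rpart.control(
                     minsplit = spec$hyper$min_branch_obs,
                     minbucket = spec$hyper$min_leaf_obs,
                     cp = 0, xval = 0, maxsurrogate = 0))
    })

  out <- list(spec = spec, fit = fit,
              features = colnames(xy$x), used = colnames(xm),
              center = center, scale = scale_, dropped = dropped,
              levels = levels(yv),
              train_time = unname(proc.time()["elapsed"] - t0))
  class(out) <- "trained_model"
  out
}

# Deterministic k-NN: distance ties and vote ties resolve to the lowest
# training-row index / its class.
.knn_predict <- function(train_x, train_y, test_x, k) {
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") -
    2 * test_x %*% t(train_x)
  pred <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    ord <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(k)]
    votes <- table(train_y[ord])
    top <- names(votes)[votes == max(votes)]
    pred[i] <- if (length(top) == 1) top else
      as.character(train_y[ord[match(TRUE, as.character(train_y[ord]) %in% top)]])
  }
  factor(pred, levels = levels(train_y))
}

#' Predict with a trained classifier
#'
#' @param model A `trained_model`.
#' @param x A `feature_table` or numeric matrix; must contain every
#'   training feature (any column order; extra columns are ignored).
#' @return Factor of predicted labels with attribute `pred_time`
#'   (wall-clock seconds; reported for information only).
#' @export
predict_model <- function(model, x) {
  stopifnot(inherits(model, "trained_model"))
  xm <- if (inherits(x, "feature_table")) feature_matrix(x) else as.matrix(x)
  if (is.null(colnames(xm))) colnames(xm) <- paste0("f", seq_len(ncol(xm)))
  miss <- setdiff(model$features, colnames(xm))
  if (length(miss))
    stop("feature mismatch; trained on features absent from input: [",
         paste(miss, collapse = ", "), "]")
  xm <- xm[, model$features, drop = FALSE]
  t0 <- proc.time()["elapsed"]
  if (model$spec$standardize) {
    xm <- sweep(sweep(xm[, model$used, drop = FALSE], 2, model$center), 2,
                model$scale, "/")
  }
  pred <- switch(model$spec$family,
    knn = .knn_predict(model$fit$x, model$fit$y, xm,
                       model$spec$hyper$n_neighbors),
    lda = stats::predict(model$fit, xm)$class,
    svm = stats::predict(model$fit, xm),
    tree = {
      df <- data.frame(xm, check.names = TRUE)
      pr <- stats::predict(model$fit, df, type = "prob")
      # deterministic argmax: first level wins exact ties
      factor(colnames(pr)[max.col(pr, ties.method = "first")],
             levels = model$levels)
    })
  pred <- factor(as.character(pred), levels = model$levels)
  attr(pred, "pred_time") <- unname(proc.time()["elapsed"] - t0)
  pred
}
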