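#' Regression configuration
#'
#' Hyperparameters for the gradient-boosted regression of pollen expression
#' on motif scan features: decision stumps (`max_depth = 1`), row
#' subsampling of 0.3 per boosting round, a minimum of 5 observations
#' behind a split, learning rate 0.1, 100 boosting rounds, and 3-fold
#' cross-validation with contiguous (unshuffled) folds.
#'
#' @param subsample Row subsampling fraction per round.
#' @param min_samples_split Minimum observations behind a split (mapped to
#'   the booster's minimum child weight).
#' @param max_depth Tree depth (1 = stumps).
#' @param n_rounds Boosting rounds.
#' @param learning_rate Shrinkage per round.
#' @param n_folds Cross-validation folds (>= 2).
#' @param seed RNG seed for the subsampling.
#' @return List of class `regression_config`.
#' @export
regression_config <- function(subsample = 0.3, min_samples_split = 5L,
                              max_depth = 1L, n_rounds = 100L,
                              learning_rate = 0.1, n_folds = 3L, seed = 1L) {
  if (subsample <= 0 || subsample > 1) stop("subsample must be in (0, 1]")
  if (n_folds < 2L) stop("need at least 2 folds")
  structure(list(subsample = subsample,
                 min_samples_split = as.integer(min_samples_split),
                 max_depth = as.integer(max_depth),
                 n_rounds = as.integer(n_rounds),
                 learning_rate = learning_rate,
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "regression_config")
}

## contiguous K-fold index blocks (classic unshuffled KFold: the first
## n %% k folds get one extra observation)
kfold_indices <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(k), function(i) starts[i]:ends[i])
}

xgb_params <- function(cfg) {
  list(objective = "reg:squarederror", max_depth = cfg$max_depth,
       eta = cfg$learning_rate, subsample = cfg$subsample,
       min_child_weight = cfg$min_samples_split, nthread = 1)
}

fit_booster <- function(X, y, cfg, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  with_isolated_rng(seed, {
    xgboost::xgb.train(params = xgb_params(cfg), data = dtrain,
                       nrounds = cfg$n_rounds, verbose = 0)
  })
}

#' Fit and cross-validate the motif-to-expression regression
#'
#' Trains gradient-boosted regression trees of pollen expression on the
#' `-log10` scan p-value features, pools out-of-fold predictions over the
#' cross-validation folds, and reports the Pearson correlation between true
#' and predicted values with its two-sided p-value. Feature importances
#' come from a full-data refit with the same hyperparameters.
#'
#' @param features Genes x motifs numeric matrix (see [feature_matrix()]).
#' @param target Named numeric vector of per-gene targets, aligned to
#'   `rownames(features)`.
#' @param cfg A [regression_config()].
#' @return List of class `regression_result`: `predictions` (data.frame
#'   gene_id, true, predicted, fold), `pearson_r`, `pearson_p`,
#'   `feature_importances` (named, sums to 1), `constant_target` flag.
#' @export
fit_evaluate <- function(features, target, cfg = regression_config()) {
  X <- as.matrix(features)
  if (!is.null(names(target))) target <- target[rownames(X)]
  y <- as.numeric(target)
  n <- nrow(X)
  if (n < cfg$n_folds * cfg$min_samples_split) {
    stop("too few genes for the requested folds")
  }
  folds <- kfold_indices(n, cfg$n_folds)
  pred <- numeric(n)
  fold_id <- integer(n)
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    fit <- fit_booster(X[train, , drop = FALSE], y[train], cfg, cfg$seed + f)
    pred[test] <- predict(fit, X[test, , drop = FALSE])
    fold_id[test] <- f
  }
  constant <- sd(y) == 0 || sd(pred) == 0
  if (constant) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- cor.test(y, pred)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  full <- fit_booster(X, y, cfg, cfg$seed)
  imp <- feature_importance(full, colnames(X))
  structure(list(
    predictions = data.frame(gene_id = rownames(X), true = y, predicted = pred,
                             fold = fold_id, stringsAsFactors = FALSE),
    pearson_r = r, pearson_p = p,
    feature_importances = imp,
    constant_target = constant
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<regression_result> %d genes, pooled CV Pearson r = %.3f (p = %.3g)\n",
              nrow(x$predictions), x$pearson_r, x$pearson_p))
  top <- head(sort(x$feature_importances, decreasing = TRUE), 5)
  cat("top features:", paste(sprintf("%s (%.2f)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Gain-based feature importances of a fitted booster
#'
#' Importances of features never used in a split are 0; the vector is
#' normalized to sum 1 (uniform if the model made no splits).
#'
#' @param model A fitted `xgb.Booster`.
#' @param feature_names Column names of the training matrix.
#' @return Named numeric vector over all features, summing to 1.
#' @export
feature_importance <- function(model, feature_names) {
  imp <- setNames(numeric(length(feature_names)), feature_names)
  tab <- tryCatch(xgboost::xgb.importance(feature_names, model = model),
                  error = function(e) NULL)
  if (!is.null(tab) && nrow(tab) > 0L) {
    imp[tab$Feature] <- tab$Gain
  }
  if (sum(imp) == 0) {
    imp[] <- 1 / length(imp)
  } else {
    imp <- imp / sum(imp)
  }
  imp
}
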