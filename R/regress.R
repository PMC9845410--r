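#' Deterministic K-fold assignment
#'
#' Shuffles indices under the seed and deals them into k folds whose sizes
#' differ by at most one. The same seed always yields the same folds.
#'
#' @param n number of samples.
#' @param k number of folds (2 <= k <= n).
#' @param seed integer seed.
#' @return Integer vector of length n with fold labels in 1..k.
#' @export
kfold_split <- function(n, k, seed) {
  if (k < 2 || k > n) stop("kfold_split: need 2 <= k <= n")
  set.seed(seed)
  fold <- integer(n)
  fold[sample.int(n)] <- rep(seq_len(k), length.out = n)
  fold
}

#' Specification of a stacked regressor
#'
#' @param base_learners named list: learner name -> hyperparameter grid (a
#'   data frame of candidate settings, or `NULL` for the learner default
#'   grid). Supported learners: `random_forest`, `gradient_boosting`,
#'   `bagging`, `extra_trees`.
#' @param n_folds K for the cross-validated grid search and the
#'   out-of-fold meta design (default 5).
#' @param seed integer seed controlling folds and learner randomness.
#' @return A list of class `stacking_spec`.
#' @export
stacking_spec <- function(base_learners = list(random_forest = NULL,
                                               gradient_boosting = NULL),
                          n_folds = 5, seed = 1L) {
  if (length(base_learners) < 2)
    stop("stacking_spec: need at least 2 base learners")
  if (n_folds < 2) stop("stacking_spec: n_folds must be >= 2")
  known <- c("random_forest", "gradient_boosting", "bagging", "extra_trees")
  bad <- setdiff(names(base_learners), known)
  if (length(bad))
    stop("stacking_spec: unknown learners: ", paste(bad, collapse = ", "))
  structure(list(base_learners = base_learners, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "stacking_spec")
}

default_grid <- function(learner) {
  switch(learner,
         random_forest = data.frame(ntree = c(100, 300)),
         bagging = data.frame(ntree = c(100, 300)),
         extra_trees = data.frame(num_trees = c(100, 300)),
         gradient_boosting = expand.grid(nrounds = c(100, 300),
                                         max_depth = 3,
                                         eta = c(0.05, 0.1)),
         stop("unknown learner: ", learner))
}

fit_base_learner <- function(learner, X, y, params, seed) {
  set.seed(seed)
  if (learner %in% c("random_forest", "bagging")) {
    mtry <- if (learner == "bagging") ncol(X)
            else max(1L, floor(ncol(X) / 3))
    model <- randomForest::randomForest(X, y, ntree = params$ntree,
                                        mtry = mtry)
  } else if (learner == "extra_trees") {
    model <- ranger::ranger(y = y, x = as.data.frame(X),
                            num.trees = params$num_trees,
                            splitrule = "extratrees", seed = seed,
                            num.threads = 1)
  } else if (learner == "gradient_boosting") {
    model <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    max_depth = params$max_depth, eta = params$eta,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y),
      nrounds = params$nrounds, verbose = 0)
  } else stop("unknown learner: ", learner)
  structure(list(learner = learner, model = model, params = params,
                 features = colnames(X)), class = "base_learner")
}

predict_base_learner <- function(fit, X) {
  X <- X[, fit$features, drop = FALSE]
  switch(fit$learner,
         random_forest = ,
         bagging = as.numeric(stats::predict(fit$model, X)),
         extra_trees = as.numeric(
           stats::predict(fit$model, data = as.data.frame(X),
                          num.threads = 1)$predictions),
         gradient_boosting = as.numeric(
           stats::predict(fit$model, xgboost::xgb.DMatrix(X))))
}

# cross-validated grid search: returns the grid row with lowest CV MSE
grid_search_cv <- function(learner, X, y, grid, fold, seed) {
  cv_mse <- vapply(seq_len(nrow(grid)), function(g) {
    pred <- numeric(length(y))
    for (f in sort(unique(fold))) {
      fit <- fit_base_learner(learner, X[fold != f, , drop = FALSE],
                              y[fold != f], grid[g, , drop = FALSE],
                              seed = seed + g)
      pred[fold == f] <- predict_base_learner(fit, X[fold == f, ,
                                                     drop = FALSE])
    }
    mean((y - pred)^2)
  }, numeric(1))
  list(best = grid[which.min(cv_mse), , drop = FALSE], cv_mse = cv_mse)
}

#' Fit a stacked ensemble regressor
#'
#' For each base learner a small grid search selects hyperparameters by
#' K-fold cross-validated MSE. With the chosen settings, out-of-fold
#' predictions (every sample predicted by a model that never saw it) form
#' the meta design matrix; the meta learner — ordinary least squares over
#' the base prediction columns — is fit on it, and the base learners are
#' then refit on the full training data. This is the standard stacking
#' construction: the meta fit sees no in-fold leakage.
#'
#' @param X numeric matrix of screened descriptors (no missing values).
#' @param y numeric pIC50 vector.
#' @param spec a [stacking_spec()].
#' @return A list of class `stacked_regressor`: fitted `base` models,
#'   `meta` coefficients, `oof` (out-of-fold prediction matrix), `fold`
#'   assignment, `feature_names`, `spec`.
#' @export
fit_stacked_regressor <- function(X, y, spec = stacking_spec()) {
  stopifnot(inherits(spec, "stacking_spec"))
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("fit_stacked_regressor: X/y mismatch")
  if (anyNA(X) || anyNA(y)) stop("fit_stacked_regressor: missing values")
  if (stats::sd(y) == 0) stop("fit_stacked_regressor: constant target")
  if (nrow(X) < 2 * spec$n_folds)
    stop("fit_stacked_regressor: need at least 2K samples")
  fold <- kfold_split(nrow(X), spec$n_folds, spec$seed)
  nm <- names(spec$base_learners)
  oof <- matrix(NA_real_, nrow(X), length(nm), dimnames = list(NULL, nm))
  base <- vector("list", length(nm))
  names(base) <- nm
  for (i in seq_along(nm)) {
    grid <- spec$base_learners[[i]]
    if (is.null(grid)) grid <- default_grid(nm[i])
    if (nrow(grid) == 0) stop("fit_stacked_regressor: empty grid for ", nm[i])
    gs <- grid_search_cv(nm[i], X, y, grid, fold, seed = spec$seed + 100 * i)
    for (f in sort(unique(fold))) {
      fit <- fit_base_learner(nm[i], X[fold != f, , drop = FALSE],
                              y[fold != f], gs$best,
                              seed = spec$seed + 100 * i + f)
      oof[fold == f, i] <- predict_base_learner(fit, X[fold == f, ,
                                                       drop = FALSE])
    }
    base[[i]] <- fit_base_learner(nm[i], X, y, gs$best,
                                  seed = spec$seed + 100 * i)
    base[[i]]$cv_mse <- gs$cv_mse
  }
  meta <- stats::lm.fit(cbind(1, oof), y)
  structure(list(base = base, meta = meta$coefficients, oof = oof,
                 fold = fold, feature_names = colnames(X), spec = spec),
            class = "stacked_regressor")
}

#' @export
predict.stacked_regressor <- function(object, newdata,
                                      type = c("response", "base"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)[, object$feature_names, drop = FALSE]
  bp <- sapply(object$base, function(b) predict_base_learner(b, X))
  if (!is.matrix(bp)) bp <- matrix(bp, nrow = 1,
                                   dimnames = list(NULL, names(object$base)))
  if (type == "base") return(bp)
  as.numeric(cbind(1, bp) %*% object$meta)
}

#' @export
print.stacked_regressor <- function(x, ...) {
  cat("stacked_regressor: bases [", paste(names(x$base), collapse = ", "),
      "], OLS meta, K =", x$spec$n_folds, "\n")
  invisible(x)
}

#' Evaluate a fitted regressor on labelled data
#'
#' @param model a `stacked_regressor` (or anything with a `predict`
#'   method returning numeric predictions).
#' @param X descriptor matrix whose columns cover the model's features.
#' @param y true pIC50 values.
#' @return [regression_metrics()] of the predictions.
#' @export
evaluate_regression <- function(model, X, y) {
  regression_metrics(y, stats::predict(model, X))
}

#' Compare regressors on identical cross-validation folds
#'
#' Each learner is evaluated by pooled out-of-fold prediction over the
#' same fold assignment, so rows are directly comparable; the fold
#' assignment is attached as an attribute together with a checksum
#' recorded per row.
#'
#' @param X descriptor matrix.
#' @param y target vector.
#' @param learners character vector of base learner names, and/or
#'   `"stacking"` for the stacked ensemble.
#' @param n_folds K.
#' @param seed integer seed (shared by every learner).
#' @param spec optional [stacking_spec()] used when `"stacking"` is
#'   requested (its folds/seed are overridden by `n_folds`/`seed`).
#' @return Data frame with columns `learner`, `mae`, `mse`, `r2`,
#'   `fold_checksum`; attribute `fold` holds the assignment.
#' @export
compare_regressors <- function(X, y, learners = c("random_forest",
                                                  "gradient_boosting",
                                                  "stacking"),
                               n_folds = 5, seed = 1L, spec = NULL) {
  X <- as.matrix(X)
  fold <- kfold_split(nrow(X), n_folds, seed)
  checksum <- sum(fold * seq_along(fold))
  rows <- lapply(learners, function(lr) {
    pred <- numeric(length(y))
    for (f in sort(unique(fold))) {
      tr <- fold != f
      if (lr == "stacking") {
        sp <- if (is.null(spec)) stacking_spec(seed = seed) else spec
        sp$seed <- as.integer(seed)
        sp$n_folds <- as.integer(n_folds)
        m <- fit_stacked_regressor(X[tr, , drop = FALSE], y[tr], sp)
        pred[!tr] <- stats::predict(m, X[!tr, , drop = FALSE])
      } else {
        grid <- default_grid(lr)
        gs <- grid_search_cv(lr, X[tr, , drop = FALSE], y[tr], grid,
                             kfold_split(sum(tr), n_folds, seed), seed)
        fit <- fit_base_learner(lr, X[tr, , drop = FALSE], y[tr], gs$best,
                                seed)
        pred[!tr] <- predict_base_learner(fit, X[!tr, , drop = FALSE])
      }
    }
    m <- regression_metrics(y, pred)
    data.frame(learner = lr, mae = m$mae, mse = m$mse, r2 = m$r2,
               fold_checksum = checksum)
  })
  out <- do.call(rbind, rows)
  attr(out, "fold") <- fold
  out
}
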