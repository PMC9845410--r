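#' Model-importance feature selection
#'
#' Fits a tree-ensemble classifier on the full training data and keeps the
#' `n_keep` features with the largest impurity-based importance (ties
#' broken by column order, so the result is deterministic under the seed).
#' The defaults mirror the dual selection sizes used for the ADMET
#' classifiers: 80 features from extremely randomized trees and 40 from
#' gradient-boosted trees.
#'
#' @param X numeric descriptor matrix.
#' @param y binary (0/1) labels; both classes must be present.
#' @param learner `"extra_trees"` or `"gradient_boosting"`.
#' @param n_keep number of features to keep.
#' @param seed integer seed.
#' @return A list of class `selection_spec`: `method`
#'   (`"model_importance"`), `learner`, `n_keep`, `selected_names`,
#'   `scores` (named importance vector over all features).
#' @export
select_by_model_importance <- function(X, y,
                                       learner = c("extra_trees",
                                                   "gradient_boosting"),
                                       n_keep = 80, seed = 1L) {
  learner <- match.arg(learner)
  X <- as.matrix(X)
  if (length(unique(y)) < 2)
    stop("select_by_model_importance: single-class labels")
  if (n_keep > ncol(X))
    stop("select_by_model_importance: n_keep exceeds feature count")
  if (learner == "extra_trees") {
    fit <- ranger::ranger(y = factor(y), x = as.data.frame(X),
                          num.trees = 300, splitrule = "extratrees",
                          importance = "impurity", seed = seed,
                          num.threads = 1)
    scores <- fit$variable.importance[colnames(X)]
  } else {
    set.seed(seed)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.1, nthread = 1),
      data = xgboost::xgb.DMatrix(X, label = y), nrounds = 200, verbose = 0)
    imp <- xgboost::xgb.importance(model = fit)
    scores <- stats::setNames(numeric(ncol(X)), colnames(X))
    scores[imp$Feature] <- imp$Gain  # unused features keep importance 0
  }
  ord <- order(-scores, seq_along(scores))
  structure(list(method = "model_importance", learner = learner,
                 n_keep = as.integer(n_keep),
                 selected_names = colnames(X)[ord[seq_len(n_keep)]],
                 scores = scores),
            class = "selection_spec")
}

#' Error-rate (FDR/FPR) univariate feature selection
#'
#' Scores every feature by a univariate two-sample ANOVA F-test of the
#' feature values between label classes (features are continuous, labels
#' binary). `fpr` mode keeps features with raw p-value below `alpha`
#' (controls the per-feature false positive rate); `fdr` mode keeps
#' features passing the Benjamini-Hochberg adjustment at level `alpha`
#' (controls the false discovery rate). A constant feature carries no
#' information and gets p = 1, so it is never selected. The FDR selection
#' is always a subset of the FPR selection at the same `alpha`.
#'
#' @param X numeric descriptor matrix.
#' @param y binary (0/1) labels; both classes must be present.
#' @param mode `"fdr"` or `"fpr"`.
#' @param alpha error-rate level (default 0.05).
#' @return A list of class `selection_spec`: `method` (the mode),
#'   `alpha`, `selected_names`, `p_values` (raw, named),
#'   `adjusted_p_values` (BH, named).
#' @export
select_by_error_rate <- function(X, y, mode = c("fdr", "fpr"),
                                 alpha = 0.05) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (length(unique(y)) < 2)
    stop("select_by_error_rate: single-class labels")
  n <- nrow(X)
  n1 <- sum(y == 1)
  n0 <- n - n1
  m1 <- colMeans(X[y == 1, , drop = FALSE])
  m0 <- colMeans(X[y == 0, , drop = FALSE])
  gm <- colMeans(X)
  ss_between <- n1 * (m1 - gm)^2 + n0 * (m0 - gm)^2
  ss_within <- pmax(colSums((X - rep(gm, each = n))^2) - ss_between, 0)
  # 0/0 (constant feature) -> NaN -> p = 1; x/0 (perfect split) -> Inf -> p = 0
  f <- ss_between / (ss_within / (n - 2))
  p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  p[is.na(p)] <- 1
  names(p) <- colnames(X)
  padj <- stats::p.adjust(p, method = "BH")
  keep <- if (mode == "fpr") p < alpha else padj < alpha
  structure(list(method = mode, alpha = alpha,
                 selected_names = colnames(X)[keep],
                 p_values = p, adjusted_p_values = padj),
            class = "selection_spec")
}

fit_member <- function(member, X, y, seed) {
  if (member == "logistic") {
    df <- data.frame(.y = y, X, check.names = FALSE)
    model <- suppressWarnings(
      stats::glm(.y ~ ., family = stats::binomial(), data = df))
  } else if (member == "extra_trees") {
    model <- ranger::ranger(y = factor(y), x = as.data.frame(X),
                            num.trees = 300, splitrule = "extratrees",
                            probability = TRUE, seed = seed,
                            num.threads = 1)
  } else if (member == "random_forest") {
    set.seed(seed)
    model <- randomForest::randomForest(X, factor(y), ntree = 300)
  } else stop("unknown member: ", member)
  structure(list(member = member, model = model, features = colnames(X)),
            class = "voting_member")
}

predict_member_prob <- function(fit, X) {
  X <- as.matrix(X)[, fit$features, drop = FALSE]
  switch(fit$member,
         logistic = as.numeric(suppressWarnings(
           stats::predict(fit$model,
                          newdata = as.data.frame(X, check.names = FALSE),
                          type = "response"))),
         extra_trees = as.numeric(
           stats::predict(fit$model, data = as.data.frame(X),
                          num.threads = 1)$predictions[, "1"]),
         random_forest = as.numeric(
           stats::predict(fit$model, X, type = "prob")[, "1"]))
}

#' Hard-majority vote over member predictions
#'
#' @param votes numeric or logical matrix, one row per sample and one
#'   column per member; entries are member class predictions (0/1).
#' @return Integer vector: 1 where more than half the members vote 1.
#' @export
majority_vote <- function(votes) {
  votes <- as.matrix(votes)
  if (ncol(votes) %% 2 == 0) stop("majority_vote: member count must be odd")
  as.integer(rowSums(votes) > ncol(votes) / 2)
}

#' Fit a hard-majority voting classifier
#'
#' Each member classifier is fit on its own selected feature subset and
#' the final prediction is the majority vote of the member class
#' predictions (member count must be odd, so no ties). The default wiring
#' pairs the logistic member with the error-rate (FDR/FPR) selection and
#' the two tree members with the two model-importance selections. The
#' ensemble's probability score — used for ROC curves — is the mean of the
#' member positive-class probabilities.
#'
#' @param X numeric descriptor matrix.
#' @param y binary (0/1) labels.
#' @param selections list of [selection_spec]s, one per member.
#' @param members character vector of member names, odd length; supported:
#'   `"logistic"`, `"extra_trees"`, `"random_forest"`.
#' @param endpoint optional endpoint name carried in the model.
#' @param seed integer seed.
#' @return A list of class `voting_model`: fitted `members`,
#'   `selections`, `endpoint`, `member_names`.
#' @export
fit_voting_classifier <- function(X, y, selections,
                                  members = c("logistic", "extra_trees",
                                              "random_forest"),
                                  endpoint = NULL, seed = 1L) {
  X <- as.matrix(X)
  if (length(members) %% 2 == 0)
    stop("fit_voting_classifier: member count must be odd")
  if (length(selections) != length(members))
    stop("fit_voting_classifier: one selection per member required")
  if (length(unique(y)) < 2)
    stop("fit_voting_classifier: single-class labels")
  fits <- lapply(seq_along(members), function(i) {
    sel <- selections[[i]]$selected_names
    if (!length(sel))
      stop("fit_voting_classifier: empty selection for member ", members[i])
    fit_member(members[i], X[, sel, drop = FALSE], y, seed + i)
  })
  structure(list(members = fits, selections = selections,
                 member_names = members, endpoint = endpoint),
            class = "voting_model")
}

#' @export
predict.voting_model <- function(object, newdata,
                                 type = c("class", "prob", "members"), ...) {
  type <- match.arg(type)
  probs <- sapply(object$members,
                  function(m) predict_member_prob(m, newdata))
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1)
  votes <- probs >= 0.5
  switch(type,
         class = majority_vote(votes),
         prob = rowMeans(probs),
         members = probs)
}

#' @export
print.voting_model <- function(x, ...) {
  cat("voting_model", if (!is.null(x$endpoint)) paste0(" [", x$endpoint, "]"),
      ": hard majority of ", paste(x$member_names, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Evaluate a voting classifier on held-out data
#'
#' @param model a `voting_model`.
#' @param X held-out descriptor matrix.
#' @param y held-out binary labels.
#' @return A list: `metrics` ([classification_metrics()] plus `kappa`,
#'   `p0`, `pe`), `roc` (a [roc_curve()], or `NULL` with
#'   `roc_defined = FALSE` when only one class is present), `counts`.
#' @export
evaluate_classifier <- function(model, X, y) {
  pred <- stats::predict(model, X, type = "class")
  prob <- stats::predict(model, X, type = "prob")
  cc <- confusion_counts(y, pred)
  cm <- classification_metrics(cc)
  kap <- cohen_kappa(y, pred)
  cm$kappa <- as.numeric(kap)
  cm$p0 <- attr(kap, "p0")
  cm$pe <- attr(kap, "pe")
  roc_ok <- length(unique(y)) == 2
  list(metrics = cm,
       roc = if (roc_ok) roc_curve(y, prob) else NULL,
       roc_defined = roc_ok, counts = cc)
}
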