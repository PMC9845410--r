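# small labelled dataset with planted signal features, built fresh per seed
clf_fixture <- function(seed, n = 300, p = 40, strong = 5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  b <- runif(strong, 1.5, 2.5) * sample(c(-1, 1), strong, replace = TRUE)
  score <- X[, 1:strong, drop = FALSE] %*% b
  y <- rbinom(n, 1, plogis(score))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  list(X = X, y = y, signal = paste0("f", 1:strong), score = score)
}

test_that("model-importance selection keeps the requested count and finds planted signal", {
  recovered <- vapply(1:5, function(seed) {
    fx <- clf_fixture(seed)
    sel <- select_by_model_importance(fx$X, fx$y, "extra_trees",
                                      n_keep = 10, seed = seed)
    expect_length(sel$selected_names, 10)
    sum(fx$signal %in% sel$selected_names)
  }, numeric(1))
  expect_gte(median(recovered), 5)
  # identity selection when n_keep equals the feature count
  fx <- clf_fixture(1)
  all_sel <- select_by_model_importance(fx$X, fx$y, "extra_trees",
                                        n_keep = ncol(fx$X), seed = 1)
  expect_setequal(all_sel$selected_names, colnames(fx$X))
  # gradient-boosting route also recovers strong planted features
  gb <- select_by_model_importance(fx$X, fx$y, "gradient_boosting",
                                   n_keep = 10, seed = 1)
  expect_length(gb$selected_names, 10)
  expect_gte(sum(fx$signal %in% gb$selected_names), 4)
  expect_error(select_by_model_importance(fx$X, rep(1, 300), "extra_trees",
                                          n_keep = 5), "single-class")
  expect_error(select_by_model_importance(fx$X, fx$y, "extra_trees",
                                          n_keep = 100), "n_keep")
})

test_that("error-rate selection keeps perfect separators and drops constants", {
  set.seed(2)
  y <- rbinom(80, 1, 0.5); y[1:2] <- c(0, 1)
  X <- cbind(perfect = as.numeric(y), const = rep(3, 80),
             noise = rnorm(80))
  for (mode in c("fdr", "fpr")) {
    sel <- select_by_error_rate(X, y, mode = mode, alpha = 0.05)
    expect_true("perfect" %in% sel$selected_names)
    expect_false("const" %in% sel$selected_names)
    expect_identical(unname(sel$p_values["const"]), 1)
  }
})

test_that("FDR selection is a subset of FPR selection at equal alpha", {
  for (seed in 1:10) {
    fx <- clf_fixture(seed, n = 150, p = 60, strong = 3)
    fdr <- select_by_error_rate(fx$X, fx$y, "fdr", alpha = 0.05)
    fpr <- select_by_error_rate(fx$X, fx$y, "fpr", alpha = 0.05)
    expect_true(all(fdr$selected_names %in% fpr$selected_names))
    expect_true(all(fdr$adjusted_p_values >= fdr$p_values - 1e-15))
  }
})

test_that("null features pass FPR at about the nominal rate and FDR at none", {
  set.seed(77)
  counts <- t(vapply(1:5, function(seed) {
    set.seed(seed)
    X <- matrix(rnorm(150 * 400), 150, 400,
                dimnames = list(NULL, paste0("n", 1:400)))
    y <- rbinom(150, 1, 0.5); y[1:2] <- c(0, 1)
    c(fpr = length(select_by_error_rate(X, y, "fpr")$selected_names),
      fdr = length(select_by_error_rate(X, y, "fdr")$selected_names))
  }, numeric(2)))
  expect_lt(abs(mean(counts[, "fpr"]) - 400 * 0.05),
            3 * sqrt(400 * 0.05 * 0.95))
  expect_identical(median(counts[, "fdr"]), 0)
})

test_that("majority vote follows the three-member truth table", {
  votes <- rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
                 c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
  expect_identical(majority_vote(votes), c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
  expect_error(majority_vote(votes[, 1:2]), "odd")
  # a unanimous outcome is stable under any single member flip: at least
  # two members must flip before the vote changes
  unanimous <- rbind(c(1, 1, 1), c(0, 0, 0))
  for (i in 1:2) for (j in 1:3) {
    flipped <- unanimous; flipped[i, j] <- 1 - flipped[i, j]
    expect_identical(majority_vote(flipped)[i], majority_vote(unanimous)[i])
    two <- unanimous; two[i, -j] <- 1 - two[i, -j]
    expect_identical(majority_vote(two)[i], 1L - majority_vote(unanimous)[i])
  }
})

test_that("voting classifier fits, predicts and beats-or-matches its members on separable data", {
  # separable endpoint: an axis-aligned threshold every member family can
  # represent, so no single member dominates the vote
  set.seed(3)
  n <- 600
  X <- matrix(rnorm(n * 30), n, 30, dimnames = list(NULL, paste0("f", 1:30)))
  y <- as.integer(X[, 1] > 0)
  fx <- list(X = X)
  tr <- 1:450; te <- 451:600
  sels <- list(
    select_by_model_importance(fx$X[tr, ], y[tr], "extra_trees", 10,
                               seed = 3),
    select_by_model_importance(fx$X[tr, ], y[tr], "gradient_boosting", 6,
                               seed = 3),
    select_by_error_rate(fx$X[tr, ], y[tr], "fpr", alpha = 0.05))
  vm <- fit_voting_classifier(fx$X[tr, ], y[tr], sels,
                              members = c("extra_trees", "random_forest",
                                          "logistic"), seed = 3)
  pred <- predict(vm, fx$X[te, ], type = "class")
  expect_true(all(pred %in% c(0L, 1L)))
  member_probs <- predict(vm, fx$X[te, ], type = "members")
  member_acc <- apply(member_probs >= 0.5, 2,
                      function(v) mean(as.integer(v) == y[te]))
  expect_gte(mean(pred == y[te]), max(member_acc) - 0.02)
  # probability score is the member mean
  expect_equal(predict(vm, fx$X[te, ], type = "prob"),
               rowMeans(member_probs), tolerance = 1e-12)
  expect_error(fit_voting_classifier(fx$X[tr, ], y[tr], sels[1:2],
                                     members = c("extra_trees",
                                                 "random_forest")),
               "odd")
})

test_that("evaluation metrics are perfect on perfectly predicted data and flag single-class sets", {
  fx <- clf_fixture(5, n = 200, p = 10, strong = 3)
  y <- as.integer(fx$score > 0)
  sels <- replicate(3, list(selected_names = colnames(fx$X)),
                    simplify = FALSE)
  vm <- fit_voting_classifier(fx$X, y, sels,
                              members = c("extra_trees", "random_forest",
                                          "logistic"), seed = 5)
  ev <- evaluate_classifier(vm, fx$X, y)  # training data: near-perfect
  expect_gte(ev$metrics$accuracy, 0.97)
  expect_gte(ev$roc$auc, 0.99)
  one_class <- evaluate_classifier(vm, fx$X[y == 1, ], y[y == 1])
  expect_false(one_class$roc_defined)
  expect_null(one_class$roc)
})

test_that("permuted labels yield chance-level AUC (no leakage through selection)", {
  aucs <- vapply(1:5, function(seed) {
    fx <- clf_fixture(seed, n = 240, p = 30, strong = 4)
    set.seed(seed + 100)
    y <- sample(fx$y)
    tr <- 1:160; te <- 161:240
    sels <- list(
      select_by_model_importance(fx$X[tr, ], y[tr], "extra_trees", 10,
                                 seed = seed),
      select_by_model_importance(fx$X[tr, ], y[tr], "gradient_boosting", 10,
                                 seed = seed),
      select_by_error_rate(fx$X[tr, ], y[tr], "fpr", alpha = 0.5))
    vm <- fit_voting_classifier(fx$X[tr, ], y[tr], sels,
                                members = c("extra_trees", "random_forest",
                                            "logistic"), seed = seed)
    if (length(unique(y[te])) < 2) return(NA_real_)
    evaluate_classifier(vm, fx$X[te, ], y[te])$roc$auc
  }, numeric(1))
  expect_gt(mean(aucs, na.rm = TRUE), 0.4)
  expect_lt(mean(aucs, na.rm = TRUE), 0.6)
})
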