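test_that("grey relational degree matches the loop oracle and the worked case", {
  # worked case: identical column has degree 1; reversed column 5/9
  g <- grey_relational_degree(
    c(0, 0.5, 1),
    make_table(cbind(x1 = c(0, 0.5, 1), x2 = c(1, 0.5, 0))))
  expect_equal(unname(g$degrees), c(1, 5 / 9), tolerance = 1e-12)
  expect_equal(unname(g$beta[, "x2"]), c(1 / 3, 1, 1 / 3),
               tolerance = 1e-12)
  expect_equal(g$delta_min, 0)
  expect_equal(g$delta_max, 1)
  # 100 random instances against the direct loop evaluation (no prescale,
  # so the oracle sees the same numbers)
  for (i in 1:100) {
    set.seed(i)
    n <- sample(3:50, 1); p <- sample(1:10, 1)
    X <- matrix(runif(n * p), n, p,
                dimnames = list(NULL, paste0("c", 1:p)))
    ref <- runif(n)
    rho <- runif(1, 0.1, 1)
    g <- grey_relational_degree(ref, X, rho = rho, prescale = "none")
    expect_equal(unname(g$degrees), oracle_grey(ref, X, rho),
                 tolerance = 1e-12)
    # closed-form coefficient bounds
    lo <- (g$delta_min + rho * g$delta_max) /
      (g$delta_max + rho * g$delta_max)
    expect_true(all(g$beta >= lo - 1e-12 & g$beta <= 1 + 1e-12))
    expect_true(all(g$degrees > 0 & g$degrees <= 1))
  }
})

test_that("a comparison column identical to the reference attains degree 1", {
  set.seed(5)
  ref <- runif(20)
  X <- cbind(same = ref, other = runif(20))
  g <- grey_relational_degree(ref, make_table(X), prescale = "none")
  expect_equal(unname(g$degrees["same"]), 1, tolerance = 1e-12)
  # degenerate: every column identical to reference
  g2 <- grey_relational_degree(ref, make_table(cbind(a = ref, b = ref)),
                               prescale = "none")
  expect_equal(unname(g2$degrees), c(1, 1))
})

test_that("grey relational degree rejects bad inputs", {
  expect_error(grey_relational_degree(1:3, make_table(cbind(a = 1:4))),
               "length")
  expect_error(grey_relational_degree(1:3, make_table(cbind(a = 1:3)),
                                      rho = 0), "rho")
})

test_that("spearman correlation: closed form, tie branch, and invariances", {
  # perfectly monotone pairs
  expect_equal(as.numeric(spearman_correlation(1:10, (1:10)^3)), 1)
  expect_equal(as.numeric(spearman_correlation(1:10, -(1:10))), -1)
  # hand case: d = (1,-1,1,-1,0) under the no-ties closed form
  s <- spearman_correlation(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(as.numeric(s), 0.8, tolerance = 1e-12)
  expect_false(attr(s, "ties_used"))
  # tie case with average ranks (1.5, 1.5, 3)
  st <- spearman_correlation(c(1, 1, 2), c(3, 5, 4))
  expect_equal(as.numeric(st), 0, tolerance = 1e-12)
  expect_true(attr(st, "ties_used"))
  # constant sequence: degenerate, reported as 0
  sc <- spearman_correlation(rep(1, 5), 1:5)
  expect_identical(as.numeric(sc), 0)
  expect_true(attr(sc, "degenerate"))
  # the two branches agree on tie-free data, and both match the
  # rank-Pearson oracle and stats::cor
  for (i in 1:100) {
    set.seed(i)
    n <- sample(3:40, 1)
    x <- sample(seq_len(1000), n)  # distinct values: tie-free
    y <- sample(seq_len(1000), n)
    closed <- 1 - 6 * sum((rank(x) - rank(y))^2) / (n * (n^2 - 1))
    got <- as.numeric(spearman_correlation(x, y))
    expect_equal(got, closed, tolerance = 1e-12)
    expect_equal(got, oracle_spearman(x, y), tolerance = 1e-12)
    expect_equal(got, cor(x, y, method = "spearman"), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(as.numeric(spearman_correlation(exp(x / 100), y)), got,
                 tolerance = 1e-12)
    expect_equal(as.numeric(spearman_correlation(x, qlogis(y / 1001))),
                 got, tolerance = 1e-12)
  }
})

test_that("equal descriptor columns receive equal scores and adjacent ranks", {
  set.seed(9)
  base <- runif(30)
  X <- cbind(twin_a = base, twin_b = base,
             noise1 = runif(30), noise2 = runif(30))
  res <- dual_screen(make_table(X, target = runif(30)), top_k = 2)
  r <- res$records
  twins <- r[r$descriptor %in% c("twin_a", "twin_b"), ]
  expect_equal(twins$grey_degree[1], twins$grey_degree[2], tolerance = 1e-12)
  expect_equal(twins$spearman[1], twins$spearman[2], tolerance = 1e-12)
  expect_equal(twins$weighted_score[1], twins$weighted_score[2],
               tolerance = 1e-12)
  expect_equal(diff(which(r$descriptor %in% c("twin_a", "twin_b"))), 1L)
})

test_that("a descriptor maximal in both scores gets Z = 1 and rank 1", {
  set.seed(14)
  y <- sort(runif(40))
  X <- cbind(best = y + rnorm(40, 0, 1e-4),  # near-copy of the target
             mid = runif(40), far = runif(40))
  res <- dual_screen(make_table(X, target = y), top_k = 1)
  r <- res$records
  expect_identical(r$descriptor[1], "best")
  expect_equal(r$weighted_score[1], 1, tolerance = 1e-12)
  expect_equal(r$norm_grey[1], 1)
  expect_equal(r$norm_spearman[1], 1)
  # normalization puts at least one descriptor at each maximum
  expect_equal(max(r$norm_grey), 1)
  expect_equal(max(r$norm_spearman), 1)
  expect_true(all(r$weighted_score >= 0 & r$weighted_score <= 1))
})

test_that("dominance in both absolute scores implies a strictly higher Z", {
  for (seed in 1:20) {
    set.seed(seed)
    X <- matrix(runif(200), 20, 10,
                dimnames = list(NULL, paste0("d", 1:10)))
    res <- dual_screen(make_table(X, target = runif(20)), top_k = 3)
    r <- res$records
    for (a in seq_len(nrow(r))) for (b in seq_len(nrow(r))) {
      dom <- r$abs_grey[a] >= r$abs_grey[b] &&
        r$abs_spearman[a] >= r$abs_spearman[b] &&
        (r$abs_grey[a] > r$abs_grey[b] ||
           r$abs_spearman[a] > r$abs_spearman[b])
      if (dom) expect_gt(r$weighted_score[a], r$weighted_score[b])
    }
  }
})

test_that("permuting descriptor columns permutes but never changes scores", {
  set.seed(31)
  X <- matrix(runif(150), 15, 10, dimnames = list(NULL, paste0("d", 1:10)))
  y <- runif(15)
  r1 <- dual_screen(make_table(X, target = y), top_k = 4)$records
  perm <- sample(10)
  r2 <- dual_screen(make_table(X[, perm], target = y), top_k = 4)$records
  m <- match(r1$descriptor, r2$descriptor)
  expect_equal(r1$weighted_score, r2$weighted_score[m], tolerance = 1e-12)
  expect_equal(r1$grey_degree, r2$grey_degree[m], tolerance = 1e-12)
})

test_that("screening recovers planted informative descriptors", {
  rec <- vapply(1:3, function(seed) {
    d <- generate_dataset(synth_config(n_compounds = 600,
                                       n_descriptors = 120,
                                       n_informative = 10, seed = seed))
    cl <- clean_descriptors(d$descriptors)
    sc <- minmax_scale(cl$table)
    s <- dual_screen(sc$table, top_k = 10)
    sum(d$truth$informative_names %in% s$top_k)
  }, numeric(1))
  expect_gte(median(rec), 8)  # >= 80% of the planted set
})

test_that("dual_screen validates its inputs", {
  tbl <- make_table(cbind(a = runif(10), b = runif(10)), target = runif(10))
  expect_error(dual_screen(tbl, top_k = 5), "top_k")
  expect_error(dual_screen(make_table(cbind(a = runif(10)),
                                      target = runif(10))), "at least 2")
  expect_error(dual_screen(tbl, weights = c(0.7, 0.4), top_k = 2),
               "sum to 1")
  expect_error(dual_screen(make_table(cbind(a = runif(10), b = runif(10))),
                           top_k = 2), "target")
})
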