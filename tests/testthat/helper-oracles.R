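# Independent oracles used across the suite. These deliberately mirror the
# written formulas with plain loops, not the vectorized implementation.

# grey relational degree by direct loop evaluation
oracle_grey <- function(reference, X, rho = 0.5) {
  n <- nrow(X); p <- ncol(X)
  delta <- matrix(0, n, p)
  for (i in seq_len(p))
    for (k in seq_len(n))
      delta[k, i] <- abs(reference[k] - X[k, i])
  dmin <- min(delta); dmax <- max(delta)
  degrees <- numeric(p)
  for (i in seq_len(p)) {
    beta <- numeric(n)
    for (k in seq_len(n))
      beta[k] <- if (dmax == 0) 1 else
        (dmin + rho * dmax) / (delta[k, i] + rho * dmax)
    degrees[i] <- mean(beta)
  }
  degrees
}

# Spearman via Pearson on average ranks (the tie-branch definition)
oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# AUC as the pairwise-comparison (Mann-Whitney) statistic
oracle_auc <- function(y, scores) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# small descriptor table from a matrix-like definition
make_table <- function(X, target = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("d", seq_len(ncol(X)))
  descriptor_table(X, target = target)
}
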