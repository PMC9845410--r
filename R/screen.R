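#' Grey relational degree of descriptors against a reference sequence
#'
#' Grey relational analysis (GRA) measures similarity between each
#' comparison sequence (descriptor column) and a reference sequence (the
#' bioactivity) from pointwise absolute differences. With
#' `delta[i, k] = |x0(k) - xi(k)|` and the two-level extremes
#' `dmin = min(delta)`, `dmax = max(delta)` taken globally over all
#' columns and points, the relational coefficient at each point is
#'
#' `beta = (dmin + rho * dmax) / (delta + rho * dmax)`
#'
#' and the relational degree of column i is the mean of its coefficients.
#' The resolution coefficient `rho` in (0, 1] damps the influence of
#' `dmax`; 0.5 is the conventional choice. Because descriptor columns
#' carry heterogeneous units, the reference and every column are min-max
#' scaled to [0, 1] before differencing by default (`prescale =
#' "minmax"`); without it, large-magnitude columns dominate the global
#' extremes.
#'
#' @param reference numeric reference sequence (length = rows of
#'   `comparisons`).
#' @param comparisons a [descriptor_table()] or numeric matrix of
#'   comparison columns.
#' @param rho resolution coefficient in (0, 1].
#' @param prescale `"minmax"` (default) or `"none"`.
#' @return A list of class `grey_computation`: `degrees` (named per-column
#'   relational degree), `beta`, `delta`, `delta_min`, `delta_max`, `rho`.
#' @export
grey_relational_degree <- function(reference, comparisons, rho = 0.5,
                                   prescale = c("minmax", "none")) {
  prescale <- match.arg(prescale)
  X <- if (inherits(comparisons, "descriptor_table")) comparisons$values
       else as.matrix(comparisons)
  if (ncol(X) == 0) stop("grey_relational_degree: empty comparisons")
  if (rho <= 0 || rho > 1)
    stop("grey_relational_degree: rho must be in (0, 1]")
  if (length(reference) != nrow(X))
    stop("grey_relational_degree: reference length must equal row count")
  if (prescale == "minmax") {
    scale01 <- function(v) {
      r <- range(v)
      if (r[1] == r[2]) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
    }
    reference <- scale01(reference)
    X <- apply(X, 2, scale01)
  }
  delta <- abs(X - reference)
  dmin <- min(delta)
  dmax <- max(delta)
  beta <- if (dmax == 0) array(1, dim(delta), dimnames = dimnames(delta))
          else (dmin + rho * dmax) / (delta + rho * dmax)
  structure(list(degrees = colMeans(beta), beta = beta, delta = delta,
                 delta_min = dmin, delta_max = dmax, rho = rho),
            class = "grey_computation")
}

#' Spearman rank correlation with explicit tie handling
#'
#' On tie-free data uses the closed form `1 - 6 * sum(d^2) / (n (n^2 -
#' 1))` over rank differences d; when either sequence has ties, falls back
#' to the Pearson correlation of average ranks (the two branches agree on
#' tie-free data). A constant sequence has no rank ordering, so the
#' correlation is reported as 0 with a `degenerate` attribute.
#'
#' @param x,y numeric sequences of equal length >= 3.
#' @return The correlation in [-1, 1], with attributes `ties_used`
#'   (logical: tie branch taken) and `degenerate` (logical).
#' @export
spearman_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("spearman_correlation: unequal lengths")
  if (n < 3) stop("spearman_correlation: need length >= 3")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(structure(0, ties_used = FALSE, degenerate = TRUE))
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  rx <- rank(x)
  ry <- rank(y)
  spc <- if (!ties) {
    1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  } else {
    stats::cor(rx, ry)
  }
  structure(spc, ties_used = ties, degenerate = FALSE)
}

#' Dual feature screening by weighted grey-relational / Spearman score
#'
#' The dual screening procedure ranks descriptors in five steps: (1)
#' compute each descriptor's grey relational degree and Spearman rank
#' correlation against the target; (2) take absolute values (correlation
#' strength acts like a distance, so sign is irrelevant); (3) min-max
#' normalize each of the two score vectors across descriptors to [0, 1];
#' (4) combine them as `Z = w1 * grey + w2 * spearman` with default
#' weights (0.6, 0.4); (5) sort descending and keep the top k (default
#' 20). Descriptors tied with the k-th score are all included, so equal
#' columns are never split arbitrarily at the boundary.
#'
#' @param table a cleaned, scaled [descriptor_table()].
#' @param target numeric target sequence; defaults to the table's target.
#' @param weights nonnegative pair summing to 1: (grey, spearman).
#' @param top_k number of descriptors to keep.
#' @param rho resolution coefficient passed to
#'   [grey_relational_degree()].
#' @param prescale GRA pre-scaling mode.
#' @return A list of class `screen_result`: `records` (data frame sorted
#'   by `weighted_score` descending, one row per descriptor with
#'   `grey_degree`, `spearman`, `ties_used`, `abs_grey`, `abs_spearman`,
#'   `norm_grey`, `norm_spearman`, `weighted_score`), `top_k` (selected
#'   names, possibly more than k under boundary ties), `k`, `weights`,
#'   `rho`, `tie_overflow`.
#' @export
dual_screen <- function(table, target = table$target,
                        weights = c(0.6, 0.4), top_k = 20, rho = 0.5,
                        prescale = c("minmax", "none")) {
  stopifnot(inherits(table, "descriptor_table"))
  if (is.null(target)) stop("dual_screen: no target sequence (pIC50)")
  p <- ncol(table$values)
  if (p < 2) stop("dual_screen: need at least 2 descriptors to normalize")
  if (top_k > p) stop("dual_screen: top_k exceeds descriptor count")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("dual_screen: weights must be nonnegative and sum to 1")
  gra <- grey_relational_degree(target, table, rho = rho,
                                prescale = match.arg(prescale))
  sp <- apply(table$values, 2, function(col) {
    s <- spearman_correlation(col, target)
    c(s, attr(s, "ties_used"))
  })
  norm01 <- function(v) {
    r <- range(v)
    if (r[1] == r[2]) rep(1, length(v)) else (v - r[1]) / (r[2] - r[1])
  }
  abs_grey <- abs(gra$degrees)
  abs_sp <- abs(sp[1, ])
  records <- data.frame(
    descriptor = descriptor_names(table),
    grey_degree = unname(gra$degrees),
    spearman = unname(sp[1, ]),
    ties_used = unname(sp[2, ]) == 1,
    abs_grey = unname(abs_grey),
    abs_spearman = unname(abs_sp),
    norm_grey = unname(norm01(abs_grey)),
    norm_spearman = unname(norm01(abs_sp)))
  records$weighted_score <- weights[1] * records$norm_grey +
    weights[2] * records$norm_spearman
  ord <- order(-records$weighted_score, records$descriptor)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  cutoff <- records$weighted_score[top_k]
  sel <- which(records$weighted_score >= cutoff - 1e-12)
  structure(list(records = records, top_k = records$descriptor[sel],
                 k = top_k, weights = weights, rho = rho,
                 tie_overflow = length(sel) - top_k),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result: ", nrow(x$records), " descriptors scored; top ",
      x$k, " selected", if (x$tie_overflow > 0)
        paste0(" (+", x$tie_overflow, " boundary ties)") else "",
      "\n", sep = "")
  print(utils::head(x$records[, c("descriptor", "grey_degree", "spearman",
                                  "weighted_score")], x$k))
  invisible(x)
}
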