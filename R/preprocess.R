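#' Drop near-null descriptor columns
#'
#' A cell counts as null when it is missing or exactly zero; large blocks
#' of exact zeros in descriptor tables usually mean the descriptor is
#' undefined for most compounds, so columns whose null fraction reaches the
#' threshold are eliminated. The target column is never touched.
#'
#' @param table a [descriptor_table()].
#' @param null_threshold proportion at or above which a column is removed
#'   (default 0.95; the comparison is `>=`).
#' @param reason label recorded for removed columns.
#' @return A list: `table` (retained columns) and `report` (a
#'   `cleaning_report` listing `removed_columns` with reasons).
#' @export
drop_null_columns <- function(table, null_threshold = 0.95,
                              reason = "null_95") {
  stopifnot(inherits(table, "descriptor_table"))
  if (ncol(table$values) == 0) stop("drop_null_columns: empty table")
  # a null cell is a missing value or an exact zero
  frac <- colMeans(is.na(table$values) | (!is.na(table$values) &
                                            table$values == 0))
  drop <- names(frac)[frac >= null_threshold]
  keep <- setdiff(descriptor_names(table), drop)
  if (!length(keep))
    stop("drop_null_columns: all descriptor columns removed")
  out <- select_descriptors(table, keep)
  report <- structure(
    list(removed_columns = if (length(drop))
      data.frame(name = drop, reason = reason)
      else data.frame(name = character(0), reason = character(0)),
      null_threshold = null_threshold),
    class = "cleaning_report")
  list(table = out, report = report)
}

#' Kolmogorov-Smirnov normality scan
#'
#' Tests each descriptor column against a normal distribution with the
#' column's own estimated mean and standard deviation (a Lilliefors-style
#' caveat applies: parameters are estimated, so the nominal p-values are
#' approximate). The scan is advisory: it documents why box-plot IQR
#' clipping rather than a z-score rule is used for outliers, and does not
#' alter the data.
#'
#' @param table a [descriptor_table()].
#' @param alpha significance level; a column is flagged normal iff the KS
#'   p-value is `>= alpha`.
#' @return Data frame with `name`, `statistic`, `p_value`, `normal`
#'   (logical) and `testable` (FALSE for constant or short columns).
#' @export
ks_normality_scan <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "descriptor_table"))
  res <- lapply(descriptor_names(table), function(nm) {
    x <- table$values[, nm]
    x <- x[!is.na(x)]
    if (length(x) < 8 || stats::sd(x) == 0)
      return(data.frame(name = nm, statistic = NA_real_, p_value = NA_real_,
                        normal = FALSE, testable = FALSE))
    kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
    data.frame(name = nm, statistic = unname(kt$statistic),
               p_value = kt$p.value, normal = kt$p.value >= alpha,
               testable = TRUE)
  })
  do.call(rbind, res)
}

#' Winsorize descriptors at box-plot fences
#'
#' Per column, quartiles are computed with the linear-interpolation
#' quantile convention; values outside
#' `[Q1 - fence_multiplier * IQR, Q3 + fence_multiplier * IQR]` are clipped
#' to the nearest fence. The operation is idempotent and never modifies the
#' target column. Constant columns pass through (their fences collapse to
#' the constant).
#'
#' @param table a [descriptor_table()].
#' @param fence_multiplier multiplier on the IQR (default 1.5, Tukey's
#'   fences).
#' @return A list: `table` (clipped values) and `fences` (data frame with
#'   per-column `lower` and `upper`).
#' @export
winsorize_iqr <- function(table, fence_multiplier = 1.5) {
  stopifnot(inherits(table, "descriptor_table"))
  X <- table$values
  q <- apply(X, 2, stats::quantile, probs = c(0.25, 0.75),
             na.rm = TRUE, names = FALSE, type = 7)
  iqr <- q[2, ] - q[1, ]
  lower <- q[1, ] - fence_multiplier * iqr
  upper <- q[2, ] + fence_multiplier * iqr
  X <- pmin(pmax(X, rep(lower, each = nrow(X))), rep(upper, each = nrow(X)))
  out <- descriptor_table(X, compound_ids = table$compound_ids,
                          target = table$target)
  list(table = out,
       fences = data.frame(name = colnames(X), lower = lower, upper = upper))
}

#' Clean a descriptor table
#'
#' Iterates near-null column elimination and box-plot winsorization until a
#' full pass removes no column, because clipping a column whose quartiles
#' sit at zero collapses it to all zeros, which the next null scan then
#' removes (recorded with reason `post_winsor_null`). Any remaining missing
#' cells are imputed to the column median after the loop. The target is
#' exempt from every step.
#'
#' @param table a raw [descriptor_table()].
#' @param null_threshold removal threshold for the null scan.
#' @param fence_multiplier IQR multiplier for the fences.
#' @param ks_alpha significance level for the advisory normality scan.
#' @return A list: `table` (cleaned) and `report` (a `cleaning_report`
#'   with `removed_columns`, final `fences`, `ks_results`, `iterations`).
#' @export
clean_descriptors <- function(table, null_threshold = 0.95,
                              fence_multiplier = 1.5, ks_alpha = 0.05) {
  stopifnot(inherits(table, "descriptor_table"))
  removed <- data.frame(name = character(0), reason = character(0))
  fences <- NULL
  iter <- 0L
  reason <- "null_95"
  repeat {
    iter <- iter + 1L
    step <- drop_null_columns(table, null_threshold, reason = reason)
    removed <- rbind(removed, step$report$removed_columns)
    w <- winsorize_iqr(step$table, fence_multiplier)
    table <- w$table
    fences <- w$fences
    if (nrow(step$report$removed_columns) == 0L && iter > 1L) break
    reason <- "post_winsor_null"
    # converged once another null scan would remove nothing
    frac <- colMeans(is.na(table$values) | (!is.na(table$values) &
                                              table$values == 0))
    if (!any(frac >= null_threshold)) break
  }
  if (anyNA(table$values)) {
    med <- apply(table$values, 2, stats::median, na.rm = TRUE)
    for (j in which(colSums(is.na(table$values)) > 0)) {
      nas <- is.na(table$values[, j])
      table$values[nas, j] <- med[j]
    }
  }
  ks <- ks_normality_scan(table, alpha = ks_alpha)
  report <- structure(
    list(removed_columns = removed, fences = fences, ks_results = ks,
         iterations = iter, null_threshold = null_threshold,
         fence_multiplier = fence_multiplier),
    class = "cleaning_report")
  list(table = table, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("cleaning_report: ", nrow(x$removed_columns), " columns removed in ",
      x$iterations, " iteration(s)\n", sep = "")
  invisible(x)
}

#' Min-max scale a descriptor table to [0, 1]
#'
#' Maps every non-constant column through `(x - min) / (max - min)`;
#' constant columns map to 0 and are flagged. The returned parameters can
#' be re-applied to new data so that train-time scaling is reused at
#' prediction time.
#'
#' @param table a cleaned [descriptor_table()].
#' @return A list: `table` (scaled) and `params` (a
#'   `normalization_params` data frame: `name`, `min`, `max`, `constant`).
#' @export
minmax_scale <- function(table) {
  stopifnot(inherits(table, "descriptor_table"))
  mins <- apply(table$values, 2, min)
  maxs <- apply(table$values, 2, max)
  params <- structure(
    data.frame(name = descriptor_names(table), min = mins, max = maxs,
               constant = maxs == mins, row.names = NULL),
    class = c("normalization_params", "data.frame"))
  list(table = apply_minmax(table, params), params = params)
}

#' Apply stored min-max parameters to a table
#'
#' @param table a [descriptor_table()] whose columns appear in `params`.
#' @param params `normalization_params` from [minmax_scale()].
#' @return The scaled `descriptor_table`.
#' @export
apply_minmax <- function(table, params) {
  stopifnot(inherits(table, "descriptor_table"))
  idx <- match(descriptor_names(table), params$name)
  if (anyNA(idx)) stop("apply_minmax: columns missing from params")
  rng <- params$max[idx] - params$min[idx]
  rng[rng == 0] <- 1  # constant columns map to 0
  X <- sweep(sweep(table$values, 2, params$min[idx], "-"), 2, rng, "/")
  descriptor_table(X, compound_ids = table$compound_ids,
                   target = table$target)
}

#' Invert min-max scaling
#'
#' @param table a scaled [descriptor_table()].
#' @param params `normalization_params` from [minmax_scale()].
#' @return The `descriptor_table` on the original scale (constant columns
#'   return to their constant).
#' @export
invert_minmax <- function(table, params) {
  stopifnot(inherits(table, "descriptor_table"))
  idx <- match(descriptor_names(table), params$name)
  if (anyNA(idx)) stop("invert_minmax: columns missing from params")
  rng <- params$max[idx] - params$min[idx]
  X <- sweep(sweep(table$values, 2, rng, "*"), 2, params$min[idx], "+")
  descriptor_table(X, compound_ids = table$compound_ids,
                   target = table$target)
}
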