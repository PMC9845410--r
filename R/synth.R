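#' Configuration for the synthetic descriptor/label generator
#'
#' Defaults emulate the structure of an anti-breast-cancer candidate
#' compound dataset: 1974 compounds by 729 descriptors, a planted
#' informative subset of 20 descriptors driving pIC50, roughly 10% of
#' columns that are at least 95% exact zeros, sparse injected outliers,
#' and five binary ADMET endpoints generated through a logistic link.
#'
#' @param n_compounds number of compounds (rows).
#' @param n_descriptors number of descriptor columns.
#' @param n_informative number of descriptors that drive pIC50.
#' @param null_col_fraction fraction of columns planted as near-null
#'   (>= 95% exact zeros); in `[0, 1)`.
#' @param outlier_rate per-cell probability of an injected extreme value.
#' @param outlier_scale multiplier on the column IQR for injected outliers.
#' @param noise_sd standard deviation of the Gaussian noise added to pIC50.
#' @param n_endpoints number of binary endpoints.
#' @param endpoint_informative number of descriptors in each endpoint's
#'   logistic model.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_compounds = 1974, n_descriptors = 729,
                         n_informative = 20, null_col_fraction = 0.1,
                         outlier_rate = 0.005, outlier_scale = 10,
                         noise_sd = 0.5, n_endpoints = 5,
                         endpoint_informative = 5, seed = 1L) {
  cfg <- list(n_compounds = as.integer(n_compounds),
              n_descriptors = as.integer(n_descriptors),
              n_informative = as.integer(n_informative),
              null_col_fraction = null_col_fraction,
              outlier_rate = outlier_rate,
              outlier_scale = outlier_scale,
              noise_sd = noise_sd,
              n_endpoints = as.integer(n_endpoints),
              endpoint_informative = as.integer(endpoint_informative),
              seed = as.integer(seed))
  counts <- c("n_compounds", "n_descriptors", "n_informative",
              "n_endpoints", "endpoint_informative")
  if (any(unlist(cfg[counts]) < 1L))
    stop("synth_config: all counts must be >= 1")
  if (cfg$null_col_fraction < 0 || cfg$null_col_fraction >= 1)
    stop("synth_config: null_col_fraction must be in [0, 1)")
  n_null <- round(cfg$null_col_fraction * cfg$n_descriptors)
  if (cfg$n_informative > cfg$n_descriptors - n_null)
    stop("synth_config: n_informative exceeds non-null descriptor count")
  if (cfg$noise_sd < 0 || cfg$outlier_rate < 0 || cfg$outlier_rate > 1 ||
      cfg$outlier_scale < 0)
    stop("synth_config: invalid noise/outlier settings")
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic descriptor table, label table and ground truth
#'
#' Informative descriptors are drawn i.i.d. standard normal, then shifted
#' and scaled per column to heterogeneous ranges (descriptor tables are not
#' standardized at source). Half of them enter pIC50 linearly and half
#' through a monotone signed-square nonlinearity, so rank-based screening
#' still detects them. Nuisance descriptors are generated in random blocks
#' with within-block correlation about 0.3, so selection is non-trivial.
#' Planted null columns carry >= 95% exact zeros. Outliers are injected by
#' replacing random cells with `median +/- outlier_scale * IQR` after the
#' target has been computed, so they act as measurement corruption that
#' cleaning can repair. Each binary endpoint is Bernoulli(logistic(linear
#' score of its feature subset)), with standardized features inside the
#' linear score.
#'
#' @param config a [synth_config()].
#' @return A list with elements `descriptors` (a [descriptor_table()] with
#'   pIC50 target), `labels` (data frame: `compound_id` plus one binary
#'   column per endpoint; the first three are named CYP3A4, hERG, MN), and
#'   `truth` (ground truth: `informative_names`,
#'   `regression_coefficients`, `nonlinear_names`, `endpoint_models`,
#'   `null_column_names`).
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_compounds
  p <- config$n_descriptors
  dnames <- sprintf("D%04d", seq_len(p))

  n_null <- round(config$null_col_fraction * p)
  null_idx <- if (n_null > 0) sample.int(p, n_null) else integer(0)
  live_idx <- setdiff(seq_len(p), null_idx)
  inf_idx <- sample(live_idx, config$n_informative)
  nuis_idx <- setdiff(live_idx, inf_idx)

  # latent standardized values; raw columns are affine transforms of these
  Z <- matrix(0, n, p)
  Z[, inf_idx] <- stats::rnorm(n * length(inf_idx))

  # correlated nuisance blocks: x = sqrt(r) * g_block + sqrt(1 - r) * e
  r <- 0.3
  if (length(nuis_idx)) {
    blocks <- split(nuis_idx, ceiling(seq_along(nuis_idx) / 5))
    for (b in blocks) {
      g <- stats::rnorm(n)
      Z[, b] <- sqrt(r) * g +
        sqrt(1 - r) * matrix(stats::rnorm(n * length(b)), n)
    }
  }

  shift <- stats::runif(p, -10, 50)
  scale <- stats::runif(p, 0.5, 20)
  X <- sweep(sweep(Z, 2, scale, "*"), 2, shift, "+")

  # near-null columns: mostly exact zeros, a thin positive tail
  for (j in null_idx) {
    col <- numeric(n)
    k <- sample.int(max(1L, floor(0.04 * n)), 1L) - 1L
    if (k > 0) col[sample.int(n, k)] <- stats::rexp(k, rate = 0.2)
    X[, j] <- col
  }

  # pIC50 from the latent (pre-outlier) informative values
  n_lin <- ceiling(config$n_informative / 2)
  lin_idx <- inf_idx[seq_len(n_lin)]
  nl_idx <- setdiff(inf_idx, lin_idx)
  # effects oriented positively: grey relational degree is a similarity
  # measure, so the screen targets positively associated descriptors
  beta <- stats::runif(config$n_informative, 0.8, 1.5)
  names(beta) <- dnames[inf_idx]
  signal <- Z[, lin_idx, drop = FALSE] %*% beta[seq_len(n_lin)]
  if (length(nl_idx)) {
    Znl <- Z[, nl_idx, drop = FALSE]
    # signed square, scaled to unit variance (E[z^4] = 3)
    signal <- signal + (Znl * abs(Znl) / sqrt(3)) %*% beta[-seq_len(n_lin)]
  }
  target <- as.numeric(5 + signal + stats::rnorm(n, 0, config$noise_sd))

  # endpoint logistic models over standardized informative-pool features
  ep_names <- c("CYP3A4", "hERG", "MN",
                paste0("endpoint_", seq_len(max(0, config$n_endpoints - 3)) + 3))
  ep_names <- ep_names[seq_len(config$n_endpoints)]
  labels <- data.frame(compound_id = paste0("cmpd_", seq_len(n)))
  endpoint_models <- list()
  for (e in ep_names) {
    feat <- sample(live_idx, config$endpoint_informative)
    b <- stats::runif(config$endpoint_informative, 1.5, 2.5) *
      sample(c(-1, 1), config$endpoint_informative, replace = TRUE)
    a <- stats::runif(1, -1, 1)
    pr <- stats::plogis(a + as.numeric(Z[, feat, drop = FALSE] %*% b))
    labels[[e]] <- stats::rbinom(n, 1, pr)
    endpoint_models[[e]] <- list(features = dnames[feat], coefficients = b,
                                 intercept = a, probabilities = pr)
  }

  # inject outliers into live descriptor cells only, after y is fixed
  if (config$outlier_rate > 0 && length(live_idx)) {
    q <- apply(X[, live_idx, drop = FALSE], 2, stats::quantile,
               probs = c(0.25, 0.5, 0.75), names = FALSE)
    for (jj in seq_along(live_idx)) {
      j <- live_idx[jj]
      hit <- which(stats::runif(n) < config$outlier_rate)
      if (length(hit)) {
        iqr <- q[3, jj] - q[1, jj]
        sgn <- sample(c(-1, 1), length(hit), replace = TRUE)
        X[hit, j] <- q[2, jj] + sgn * config$outlier_scale * iqr
      }
    }
  }

  colnames(X) <- dnames
  tbl <- descriptor_table(X, compound_ids = labels$compound_id,
                          target = target)
  truth <- list(informative_names = dnames[inf_idx],
                regression_coefficients = beta,
                nonlinear_names = dnames[nl_idx],
                endpoint_models = endpoint_models,
                null_column_names = dnames[null_idx])
  list(descriptors = tbl, labels = labels, truth = truth)
}
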