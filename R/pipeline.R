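#' Pipeline configuration
#'
#' Collects every stage's knobs: simulate (or load) a descriptor/label
#' pair, clean, screen, fit the stacked pIC50 regressor and the
#' per-endpoint voting classifiers, and write all reports to `out_dir`.
#'
#' @param out_dir output directory (created if absent).
#' @param simulate logical; when `TRUE` data come from
#'   [generate_dataset()] with `synth`; otherwise `descriptors_csv` (and
#'   optionally `labels_csv`) are read.
#' @param descriptors_csv,labels_csv input CSV paths when `simulate` is
#'   `FALSE`.
#' @param synth a [synth_config()] used when simulating.
#' @param null_threshold,fence_multiplier cleaning knobs.
#' @param weights,top_k,rho screening knobs.
#' @param stacking a [stacking_spec()] for the regression stage.
#' @param clf_mode per-endpoint error-rate mode, `"fdr"` or `"fpr"`.
#' @param clf_alpha error-rate level.
#' @param clf_keep lengths of the two model-importance selections
#'   (extremely randomized trees, gradient-boosted trees).
#' @param test_fraction held-out fraction for evaluation.
#' @param seed master seed for every stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = TRUE,
                            descriptors_csv = NULL, labels_csv = NULL,
                            synth = synth_config(),
                            null_threshold = 0.95, fence_multiplier = 1.5,
                            weights = c(0.6, 0.4), top_k = 20, rho = 0.5,
                            stacking = stacking_spec(),
                            clf_mode = "fdr", clf_alpha = 0.05,
                            clf_keep = c(80, 40), test_fraction = 0.25,
                            seed = 1L) {
  if (abs(sum(weights) - 1) > 1e-8)
    stop("pipeline_config: screening weights must sum to 1")
  if (!simulate && is.null(descriptors_csv))
    stop("pipeline_config: descriptors_csv required when simulate = FALSE")
  structure(list(out_dir = out_dir, simulate = simulate,
                 descriptors_csv = descriptors_csv, labels_csv = labels_csv,
                 synth = synth, null_threshold = null_threshold,
                 fence_multiplier = fence_multiplier, weights = weights,
                 top_k = top_k, rho = rho, stacking = stacking,
                 clf_mode = clf_mode, clf_alpha = clf_alpha,
                 clf_keep = clf_keep, test_fraction = test_fraction,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

pipeline_log <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Run the full pipeline
#'
#' Executes simulate-or-load, cleaning, min-max scaling, dual screening,
#' stacked regression and per-endpoint voting classification, and writes
#' `descriptors.csv`/`labels.csv` (when simulating), `cleaned.csv`,
#' `cleaning_report.json`, `screen.json`, `screen.csv`,
#' `regression_report.json`, one `clf_<endpoint>.json` and
#' `roc_<endpoint>.csv` per endpoint, and `manifest.json` holding the
#' seed, the configuration echo and an MD5 checksum per output file.
#' Every stage draws its randomness from the master seed, so an identical
#' configuration and seed reproduce byte-identical outputs. A failure in
#' any stage aborts with a stage-labelled error.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)

  if (config$simulate) {
    pipeline_log("simulate", "generating synthetic dataset (seed ",
                 config$synth$seed, ")")
    sim <- generate_dataset(config$synth)
    tbl <- sim$descriptors
    labels <- sim$labels
    write_descriptor_table(tbl, out("descriptors.csv"))
    utils::write.csv(labels, out("labels.csv"), row.names = FALSE,
                     quote = FALSE)
    write_report_json(sim$truth, out("ground_truth.json"))
    files <- c(files, "descriptors.csv", "labels.csv", "ground_truth.json")
  } else {
    pipeline_log("load", "reading ", config$descriptors_csv)
    tbl <- read_descriptor_table(config$descriptors_csv)
    labels <- if (!is.null(config$labels_csv))
      utils::read.csv(config$labels_csv) else NULL
  }
  if (is.null(tbl$target))
    stop("screen: target column 'pIC50' not found in descriptor table")
  if (!is.null(labels)) validate_label_table(labels, tbl)

  pipeline_log("clean", ncol(tbl$values), " descriptor columns in")
  cl <- clean_descriptors(tbl, config$null_threshold,
                          config$fence_multiplier)
  pipeline_log("clean", ncol(cl$table$values), " columns retained after ",
               cl$report$iterations, " iteration(s)")
  sc <- minmax_scale(cl$table)
  write_descriptor_table(sc$table, out("cleaned.csv"))
  write_report_json(
    list(removed_columns = cl$report$removed_columns,
         iterations = cl$report$iterations,
         n_retained = ncol(cl$table$values),
         n_not_normal = sum(!cl$report$ks_results$normal)),
    out("cleaning_report.json"))
  files <- c(files, "cleaned.csv", "cleaning_report.json")

  pipeline_log("screen", "dual screening, top ", config$top_k)
  scr <- dual_screen(sc$table, weights = config$weights,
                     top_k = config$top_k, rho = config$rho)
  write_report_json(list(top_k = scr$top_k, weights = scr$weights,
                         rho = scr$rho, records = scr$records),
                    out("screen.json"))
  utils::write.csv(
    scr$records[, c("descriptor", "grey_degree", "spearman",
                    "weighted_score")],
    out("screen.csv"), row.names = FALSE, quote = FALSE)
  files <- c(files, "screen.json", "screen.csv")

  # held-out split shared by regression and classification
  n <- nrow(sc$table$values)
  set.seed(config$seed)
  test_idx <- sort(sample.int(n, round(config$test_fraction * n)))
  train_idx <- setdiff(seq_len(n), test_idx)
  Xs <- sc$table$values[, scr$top_k, drop = FALSE]
  y <- sc$table$target

  pipeline_log("regress", "stacked regression on ", length(scr$top_k),
               " screened descriptors")
  spec <- config$stacking
  spec$seed <- config$seed
  model <- fit_stacked_regressor(Xs[train_idx, , drop = FALSE],
                                 y[train_idx], spec)
  held_out <- evaluate_regression(model, Xs[test_idx, , drop = FALSE],
                                  y[test_idx])
  base_rows <- lapply(names(model$base), function(b) {
    fit <- model$base[[b]]
    m <- regression_metrics(y[test_idx],
                            predict_base_learner(fit, Xs[test_idx, ,
                                                         drop = FALSE]))
    list(learner = b, mae = m$mae, mse = m$mse, r2 = m$r2,
         params = as.list(fit$params))
  })
  write_report_json(
    list(features = model$feature_names, n_train = length(train_idx),
         n_test = length(test_idx), folds = model$fold,
         stacked = list(mae = held_out$mae, mse = held_out$mse,
                        r2 = held_out$r2),
         base = base_rows),
    out("regression_report.json"))
  files <- c(files, "regression_report.json")

  if (!is.null(labels)) {
    Xc <- sc$table$values  # classifiers select from all retained columns
    for (ep in setdiff(names(labels), "compound_id")) {
      pipeline_log("classify", "endpoint ", ep)
      yl <- labels[[ep]]
      sels <- list(
        select_by_error_rate(Xc[train_idx, , drop = FALSE], yl[train_idx],
                             mode = config$clf_mode,
                             alpha = config$clf_alpha),
        select_by_model_importance(Xc[train_idx, , drop = FALSE],
                                   yl[train_idx], "extra_trees",
                                   n_keep = min(config$clf_keep[1],
                                                ncol(Xc)),
                                   seed = config$seed),
        select_by_model_importance(Xc[train_idx, , drop = FALSE],
                                   yl[train_idx], "gradient_boosting",
                                   n_keep = min(config$clf_keep[2],
                                                ncol(Xc)),
                                   seed = config$seed))
      if (!length(sels[[1]]$selected_names)) {
        pipeline_log("classify", ep, ": empty ", config$clf_mode,
                     " selection, falling back to fpr")
        sels[[1]] <- select_by_error_rate(Xc[train_idx, , drop = FALSE],
                                          yl[train_idx], mode = "fpr",
                                          alpha = config$clf_alpha)
      }
      vm <- fit_voting_classifier(Xc[train_idx, , drop = FALSE],
                                  yl[train_idx],
                                  selections = sels[c(2, 3, 1)],
                                  members = c("extra_trees",
                                              "random_forest", "logistic"),
                                  endpoint = ep, seed = config$seed)
      ev <- evaluate_classifier(vm, Xc[test_idx, , drop = FALSE],
                                yl[test_idx])
      write_report_json(
        list(endpoint = ep, mode = config$clf_mode,
             selected = lapply(vm$selections, function(s)
               list(method = s$method, n = length(s$selected_names),
                    names = s$selected_names)),
             members = vm$member_names,
             metrics = ev$metrics[c("accuracy", "precision", "recall",
                                    "f1", "kappa", "p0", "pe")],
             auc = if (ev$roc_defined) ev$roc$auc else NA),
        out(paste0("clf_", ep, ".json")))
      if (ev$roc_defined)
        utils::write.csv(
          data.frame(fpr = ev$roc$fpr, tpr = ev$roc$tpr,
                     threshold = ev$roc$thresholds),
          out(paste0("roc_", ep, ".csv")), row.names = FALSE, quote = FALSE)
      files <- c(files, paste0("clf_", ep, ".json"),
                 if (ev$roc_defined) paste0("roc_", ep, ".csv"))
    }
  }

  manifest <- list(
    seed = config$seed,
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = list(null_threshold = config$null_threshold,
                  fence_multiplier = config$fence_multiplier,
                  weights = config$weights, top_k = config$top_k,
                  rho = config$rho, clf_mode = config$clf_mode,
                  clf_alpha = config$clf_alpha, clf_keep = config$clf_keep,
                  test_fraction = config$test_fraction,
                  simulate = config$simulate),
    files = as.list(tools::md5sum(file.path(config$out_dir, files))))
  names(manifest$files) <- files
  write_report_json(manifest, out("manifest.json"))
  pipeline_log("done", length(files) + 1, " files written to ",
               config$out_dir)
  invisible(manifest)
}
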