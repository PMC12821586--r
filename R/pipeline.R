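# End-to-end modelling pipeline: split -> rare-attribute blocking ->
# Monte Carlo weight optimization -> endpoint regression -> statistics ->
# applicability domain -> promoter table, with artifact writing.

#' Build a full model on one split
#'
#' Runs the whole modelling chain for a single split: optimizes the
#' correlation weights, fits the endpoint regression on the active training
#' set, predicts all four subsets, computes the statistics battery per
#' subset and the applicability-domain flags.
#'
#' @param dataset A `qs_dataset`.
#' @param split A `qs_split`.
#' @param config An [optimizer_config()].
#' @param am Optional precomputed [attribute_matrix()].
#' @return A `qs_pipeline` list: `model` (`cw_model`), `fit`
#'   (`endpoint_fit`), `predictions` (data frame `record_id`, `subset`,
#'   `observed`, `predicted`), `statistics` (one row per subset), `domain`
#'   ([domain_flags()]), `split`, `config`.
#' @export
build_model <- function(dataset, split, config = optimizer_config(),
                        am = NULL) {
  if (is.null(am)) am <- attribute_matrix(dataset)
  idx <- split_indices(dataset, split)
  model <- optimize_weights(dataset, split, config, am = am)
  d <- dcw(am$counts, model$weights)
  y <- dataset$pld50
  fit <- fit_regression(d[idx$active], y[idx$active])
  pred <- predict(fit, d)
  na_attr <- length(model$weights) - length(model$blocked)
  stats_rows <- lapply(SUBSETS, function(s) {
    st <- compute_statistics(y[idx[[s]]], pred[idx[[s]]], na_attr)
    cbind(subset = s, st)
  })
  statistics <- do.call(rbind, stats_rows)
  rownames(statistics) <- NULL
  subset_of <- rep(NA_character_, nrow(dataset))
  for (s in SUBSETS) subset_of[idx[[s]]] <- s
  predictions <- data.frame(record_id = dataset$record_id,
                            subset = subset_of, observed = y,
                            predicted = pred, row.names = NULL)
  domain <- domain_flags(dataset, split, model$blocked, am = am)
  structure(list(model = model, fit = fit, predictions = predictions,
                 statistics = statistics, domain = domain, split = split,
                 config = config),
            class = "qs_pipeline")
}

#' Predictions of a fitted pipeline for new records
#'
#' @param pipeline A `qs_pipeline`.
#' @param dataset A `qs_dataset` of records to predict (unseen attributes
#'   contribute zero to the descriptor).
#' @return Data frame `record_id`, `observed`, `predicted`.
#' @export
predict_pipeline <- function(pipeline, dataset) {
  stopifnot(inherits(pipeline, "qs_pipeline"))
  d <- dcw(dataset, pipeline$model$weights)
  data.frame(record_id = dataset$record_id, observed = dataset$pld50,
             predicted = predict(pipeline$fit, d), row.names = NULL)
}

#' Run the replicate-split modelling study
#'
#' Builds an ensemble of random splits, fits one model per split (the
#' optimizer seed is derived from the run seed and the split number), and
#' optionally replicates the optimization on the first split with
#' `n_runs` different seeds to produce a promoter table. With `outdir`
#' set, all artifacts (weights, predictions, statistics, domain flags,
#' identity matrix, promoter table, config echo) are written as TSV/JSON.
#'
#' @param dataset A `qs_dataset`.
#' @param config An [optimizer_config()]; its `seed` drives every stage.
#' @param n_splits Number of replicate splits (default 5).
#' @param n_runs Replicate optimization runs on the first split for
#'   promoter classification (default 3; set below 2 to skip).
#' @param outdir Optional artifact directory.
#' @return A `qs_run`: list of per-split `pipelines`, the pooled
#'   `statistics` table (split x subset), the split `identity` matrix, the
#'   `promoters` table (or `NULL`), and the `config`.
#' @export
run_model <- function(dataset, config = optimizer_config(), n_splits = 5L,
                      n_runs = 3L, outdir = NULL) {
  stopifnot(inherits(dataset, "qs_dataset"))
  am <- attribute_matrix(dataset)
  base <- (config$seed %% 1000003L)
  ensemble <- split_ensemble(dataset, n_splits, base_seed = base * 101L + 17L)
  pipelines <- vector("list", n_splits)
  stats_all <- NULL
  for (i in seq_len(n_splits)) {
    cfg_i <- config
    cfg_i$seed <- base + 1000L * i
    pipelines[[i]] <- build_model(dataset, ensemble[[i]], cfg_i, am = am)
    stats_all <- rbind(stats_all,
                       cbind(split = i, pipelines[[i]]$statistics))
  }
  identity <- if (n_splits >= 2L) identity_matrix(ensemble) else NULL
  promoters <- NULL
  if (n_runs >= 2L) {
    runs <- lapply(seq_len(n_runs), function(r) {
      cfg_r <- config
      cfg_r$seed <- base + 500L + r
      optimize_weights(dataset, ensemble[[1]], cfg_r, am = am)
    })
    promoters <- classify_promoters(
      runs, defects = defect_table(dataset, ensemble[[1]], am = am))
  }
  out <- structure(list(pipelines = pipelines, statistics = stats_all,
                        identity = identity, promoters = promoters,
                        ensemble = ensemble, config = config),
                   class = "qs_run")
  if (!is.null(outdir)) write_run(out, outdir)
  out
}

#' Write all artifacts of a modelling run
#'
#' @param run A `qs_run`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run <- function(run, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  utils::write.table(run$statistics, file.path(outdir, "statistics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$statistics,
                       file.path(outdir, "statistics.json"),
                       dataframe = "rows", na = "null", digits = NA)
  if (!is.null(run$identity)) {
    utils::write.table(run$identity, file.path(outdir, "identity.tsv"),
                       sep = "\t", quote = FALSE)
  }
  for (i in seq_along(run$pipelines)) {
    p <- run$pipelines[[i]]
    write_weights(weight_table(p$model),
                  file.path(outdir, sprintf("weights_split%d.tsv", i)))
    write_predictions(p$predictions,
                      file.path(outdir, sprintf("predictions_split%d.tsv", i)))
    utils::write.table(as.data.frame(p$domain),
                       file.path(outdir, sprintf("domain_split%d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(p$model$trace,
                       file.path(outdir, sprintf("trace_split%d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_split(p$split, file.path(outdir, sprintf("split%d.tsv", i)))
  }
  if (!is.null(run$promoters)) {
    utils::write.table(as.data.frame(run$promoters),
                       file.path(outdir, "promoters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(unclass(run$config), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Average calibration/validation performance across splits
#'
#' Summarizes a pooled statistics table: mean determination coefficient and
#' its min-max range per subset, the usual way replicate-split studies
#' report the stability of the final model.
#'
#' @param statistics A pooled statistics table from [run_model()], or a list
#'   of them (e.g. one per target function), in which case a `label` column
#'   distinguishes them.
#' @param subsets Which subsets to summarize (default calibration and
#'   validation).
#' @return Data frame with `label` (if given), `subset`, `n_splits`,
#'   `D_mean`, `D_min`, `D_max`.
#' @export
summarize_runs <- function(statistics,
                           subsets = c("calibration", "validation")) {
  if (is.data.frame(statistics)) statistics <- list(statistics)
  labels <- names(statistics) %||% as.character(seq_along(statistics))
  out <- NULL
  for (i in seq_along(statistics)) {
    st <- statistics[[i]]
    for (s in subsets) {
      d <- st$D[st$subset == s]
      out <- rbind(out, data.frame(label = labels[i], subset = s,
                                   n_splits = length(d),
                                   D_mean = mean(d), D_min = min(d),
                                   D_max = max(d)))
    }
  }
  out
}

#' Statistics table shaped for reporting
#'
#' Formats a pooled statistics table in the conventional layout: one row per
#' split and subset. For the validation subset only the determination
#' coefficient, MAE and the attribute count are reported (the remaining
#' battery applies to the sets that took part in model building).
#'
#' @param run A `qs_run` or a pooled statistics data frame.
#' @return Data frame with columns `split`, `set`, `n`, `D`, `CCC`, `IIC`,
#'   `Q2`, `Rm2_avg`, `MAE`, `F`, `Na`.
#' @export
statistics_table <- function(run) {
  st <- if (inherits(run, "qs_run")) run$statistics else run
  out <- st[, c("split", "subset", "n", "D", "CCC", "IIC", "Q2", "Rm2_avg",
                "MAE", "F", "Na")]
  names(out)[2] <- "set"
  v <- out$set == "validation"
  out[v, c("CCC", "IIC", "Q2", "Rm2_avg", "F")] <- NA_real_
  out
}

#' Observed-versus-calculated scatter plot
#'
#' @param pipeline A `qs_pipeline`.
#' @param subsets Subsets to show (default all four).
#' @param ... Passed to [plot()].
#' @return The plotted data, invisibly.
#' @export
plot_predictions <- function(pipeline, subsets = SUBSETS, ...) {
  p <- pipeline$predictions
  p <- p[p$subset %in% subsets, ]
  cols <- stats::setNames(c("#1b9e77", "#d95f02", "#7570b3", "#e7298a"),
                          SUBSETS)
  plot(p$observed, p$predicted, col = cols[p$subset], pch = 19,
       xlab = "observed pLD50", ylab = "calculated pLD50", ...)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topleft", legend = subsets, col = cols[subsets],
                   pch = 19, bty = "n")
  invisible(p)
}

#' @export
print.qs_run <- function(x, ...) {
  cat(sprintf("quasi-SMILES modelling run: %d splits, %s\n",
              length(x$pipelines),
              if (x$config$use_iic) "TF1" else "TF0"))
  print(summarize_runs(list(run = x$statistics)))
  invisible(x)
}
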