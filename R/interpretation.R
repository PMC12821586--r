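# Mechanistic interpretation: promoters of endpoint increase/decrease.
#
# Replicate Monte Carlo runs on the same split give independent weight
# estimates per attribute. An attribute whose weight keeps one sign across
# every run is read as a promoter: all-positive weights promote endpoint
# increase, all-negative weights promote decrease; any mixed or zero weight
# leaves the attribute inconclusive.

#' Classify attributes as endpoint promoters across replicate runs
#'
#' @param models List of at least two `cw_model` objects fitted on the same
#'   split with different seeds.
#' @param defects Optional [defect_table()]; when supplied its `d_k` is
#'   reported as the per-attribute stability score `S_k`.
#' @return A `promoter_table` data frame, sorted by active-training
#'   frequency descending: `attribute`, `kind`, one `weight_run<i>` column
#'   per run, `n_active`, `n_passive`, `n_calibration`, optional `S_k`, and
#'   `classification` in `{increase, decrease, inconclusive}`. Attributes
#'   blocked in any run are excluded; attribute universes are reconciled by
#'   intersection and any dropped attributes are recorded in the
#'   `dropped` attribute.
#' @export
classify_promoters <- function(models, defects = NULL) {
  if (!is.list(models) || length(models) < 2L ||
      !all(vapply(models, inherits, TRUE, "cw_model"))) {
    stop("'models' must be a list of at least two cw_model objects",
         call. = FALSE)
  }
  universes <- lapply(models, function(m) names(m$weights))
  common <- Reduce(intersect, universes)
  dropped <- setdiff(Reduce(union, universes), common)
  blocked_any <- Reduce(union, lapply(models, function(m) m$blocked))
  keep <- setdiff(common, blocked_any)
  W <- vapply(models, function(m) m$weights[keep], numeric(length(keep)))
  if (length(keep) == 1L) W <- matrix(W, nrow = 1L)
  cls <- apply(W, 1L, function(w) {
    if (all(w > 0)) "increase"
    else if (all(w < 0)) "decrease"
    else "inconclusive"
  })
  ref <- models[[1]]
  out <- data.frame(attribute = keep,
                    kind = ref$attributes$kind[match(keep,
                      ref$attributes$attribute)],
                    row.names = NULL)
  for (i in seq_along(models)) out[[paste0("weight_run", i)]] <- W[, i]
  fr <- ref$frequencies[match(keep, ref$frequencies$attribute), ]
  out$n_active <- fr$n_active
  out$n_passive <- fr$n_passive
  out$n_calibration <- fr$n_calibration
  if (!is.null(defects)) {
    out$S_k <- defects$d_k[match(keep, defects$attribute)]
  }
  out$classification <- cls
  out <- out[order(-out$n_active, out$attribute), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  class(out) <- c("promoter_table", "data.frame")
  out
}
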