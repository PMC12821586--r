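# The one-descriptor endpoint regression and its validation battery.

#' Fit the linear endpoint model
#'
#' Ordinary least squares for `pLD50 = C0 + C1 * DCW`, fit on the active
#' training set only. The slope and intercept are the only parameters on
#' top of the attribute correlation weights.
#'
#' @param d Descriptor values (active training set).
#' @param y Observed endpoints, same length.
#' @return An `endpoint_fit`: list with `C0`, `C1`, `fitted_on`.
#' @export
fit_regression <- function(d, y) {
  if (length(d) != length(y) || length(d) < 3L) {
    stop("need at least 3 (descriptor, endpoint) pairs", call. = FALSE)
  }
  if (stats::sd(d) == 0) {
    stop("descriptor is constant; regression undefined", call. = FALSE)
  }
  fit <- stats::lm(y ~ d)
  structure(list(C0 = unname(stats::coef(fit)[1]),
                 C1 = unname(stats::coef(fit)[2]),
                 fitted_on = "active"),
            class = "endpoint_fit")
}

#' @export
#' @param object An `endpoint_fit`.
#' @param newdata Descriptor values to predict for.
#' @param ... Ignored.
#' @rdname fit_regression
predict.endpoint_fit <- function(object, newdata, ...) {
  object$C0 + object$C1 * newdata
}

# Rm^2 in one direction: y regressed on x, with and without intercept.
rm2_one <- function(y, x) {
  r2 <- safe_cor(x, y)^2
  k <- sum(x * y) / sum(x * x)
  sstot <- sum((y - mean(y))^2)
  r02 <- 1 - sum((y - k * x)^2) / sstot
  r2 * (1 - sqrt(abs(r2 - r02)))
}

#' Validation statistics battery
#'
#' Computes, for one subset, the standard battery used to judge
#' correlation-weight models:
#' * `D` — determination coefficient (squared Pearson correlation);
#' * `CCC` — Lin's concordance correlation coefficient,
#'   `2*s_xy / (s_x^2 + s_y^2 + (mean x - mean y)^2)` with `1/n` moments;
#' * `IIC` — Index of Ideality of Correlation ([iic()]);
#' * `Q2` — leave-one-out cross-validated `1 - PRESS/SS_tot` for the
#'   two-parameter regression of observed on predicted;
#' * `Rm2_avg` — Roy–Kar metric: the mean of
#'   `r^2 * (1 - sqrt(|r^2 - r0^2|))` computed with observed regressed on
#'   predicted and vice versa, `r0^2` being the through-origin
#'   determination coefficient;
#' * `MAE` — mean absolute error;
#' * `F` — Fisher ratio of the regression, `D * (n - 2) / (1 - D)`.
#'
#' @param observed,predicted Numeric vectors of length at least 3.
#' @param n_active_attributes The number of non-blocked attributes of the
#'   model (`Na`), carried through for reporting; `NA` if unknown.
#' @return A `model_statistics` one-row data frame with columns `n`, `D`,
#'   `CCC`, `IIC`, `Q2`, `Rm2_avg`, `MAE`, `F`, `Na`. When either vector has
#'   zero variance the correlation-based fields are `NA` and the reason is
#'   attached as attribute `degenerate`.
#' @export
compute_statistics <- function(observed, predicted,
                               n_active_attributes = NA_integer_) {
  n <- length(observed)
  if (length(predicted) != n || n < 3L) {
    stop("'observed' and 'predicted' must be equal-length, n >= 3",
         call. = FALSE)
  }
  mae <- mean(abs(observed - predicted))
  r <- safe_cor(observed, predicted)
  if (is.na(r)) {
    out <- data.frame(n = n, D = NA_real_, CCC = NA_real_, IIC = NA_real_,
                      Q2 = NA_real_, Rm2_avg = NA_real_, MAE = mae,
                      F = NA_real_, Na = n_active_attributes)
    attr(out, "degenerate") <- "zero variance in observed or predicted"
    class(out) <- c("model_statistics", "data.frame")
    return(out)
  }
  D <- r^2
  mx <- mean(observed); my <- mean(predicted)
  vx <- mean((observed - mx)^2); vy <- mean((predicted - my)^2)
  cxy <- mean((observed - mx) * (predicted - my))
  ccc <- 2 * cxy / (vx + vy + (mx - my)^2)
  # LOO Q2 of observed ~ predicted via the hat-matrix identity
  x <- predicted; y <- observed
  sxx <- sum((x - mean(x))^2)
  h <- 1 / n + (x - mean(x))^2 / sxx
  fit <- stats::lm(y ~ x)
  press <- sum((stats::residuals(fit) / (1 - h))^2)
  q2 <- 1 - press / sum((y - mean(y))^2)
  rm2 <- (rm2_one(observed, predicted) + rm2_one(predicted, observed)) / 2
  f <- D * (n - 2) / (1 - D)
  out <- data.frame(n = n, D = D, CCC = ccc,
                    IIC = iic(observed, predicted), Q2 = q2,
                    Rm2_avg = rm2, MAE = mae, F = f,
                    Na = n_active_attributes)
  class(out) <- c("model_statistics", "data.frame")
  out
}

#' Per-subgroup model performance
#'
#' Splits predictions by a condition feature (species `SP`, life stage `LS`
#' or observation-duration class `OB`) and reports per-group size, squared
#' Pearson correlation and root-mean-square error. Groups with fewer than
#' `min_n` records keep their metrics but are flagged `too_few`; with fewer
#' than 2 records the metrics are `NA`.
#'
#' @param dataset A `qs_dataset` (supplies the grouping feature).
#' @param predictions Named numeric vector of predicted endpoints, names
#'   being record ids, covering a subset of the dataset.
#' @param by One of `"SP"`, `"LS"`, `"OB"`.
#' @param min_n Minimum group size for reliable metrics (default 3).
#' @return Data frame with `group`, `n`, `R2`, `RMSE`, `too_few`.
#' @export
subgroup_performance <- function(dataset, predictions, by = c("SP", "LS", "OB"),
                                 min_n = 3L) {
  by <- match.arg(by)
  stopifnot(inherits(dataset, "qs_dataset"))
  ids <- names(predictions)
  if (is.null(ids) || !all(ids %in% dataset$record_id)) {
    stop("'predictions' must be named by record ids present in the dataset",
         call. = FALSE)
  }
  rows <- match(ids, dataset$record_id)
  obs <- dataset$pld50[rows]
  grp <- dataset[[by]][rows]
  res <- lapply(split(seq_along(ids), grp), function(g) {
    n <- length(g)
    if (n >= 2L) {
      r <- safe_cor(obs[g], predictions[g])
      r2 <- if (is.na(r)) NA_real_ else r^2
      rmse <- sqrt(mean((obs[g] - predictions[g])^2))
    } else {
      r2 <- NA_real_
      rmse <- if (n == 1L) abs(obs[g] - predictions[g]) else NA_real_
    }
    data.frame(n = n, R2 = r2, RMSE = rmse, too_few = n < min_n)
  })
  out <- do.call(rbind, res)
  out <- cbind(group = names(res), out)
  rownames(out) <- NULL
  out[order(-out$n, out$group), ]
}
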