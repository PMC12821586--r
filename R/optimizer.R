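# Monte Carlo optimization of attribute correlation weights.
#
# The model's only learned parameters are one real weight per non-rare
# attribute. The optimal descriptor DCW of a record is the sum of the
# weights of its attribute instances; weights are tuned by stochastic
# hill climbing of a target function built from the Pearson correlations
# between observed endpoint and DCW on the training subsets, optionally
# augmented by the Index of Ideality of Correlation on the calibration set.

# Worst-possible target value used when DCW degenerates to zero variance.
.TF_SENTINEL <- -.Machine$double.xmax

#' Attribute count matrix of a dataset
#'
#' Builds the records-by-attributes integer count matrix underlying all
#' descriptor computations, together with the attribute catalogue.
#'
#' @param dataset A `qs_dataset`.
#' @return A list with `counts` (integer matrix, rows named by `record_id`,
#'   columns by rendered attribute) and `attributes` (data frame with
#'   `attribute`, `kind`).
#' @export
attribute_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "qs_dataset"))
  feats <- qs_features()
  per_record <- lapply(seq_len(nrow(dataset)), function(i) {
    conds <- vapply(feats, function(f) dataset[[f]][i], "")
    extract_attributes(dataset$smiles[i], conds)
  })
  all_attrs <- unique(do.call(rbind, lapply(per_record, function(d) {
    d[, c("attribute", "kind")]
  })))
  all_attrs <- all_attrs[order(all_attrs$attribute), , drop = FALSE]
  rownames(all_attrs) <- NULL
  X <- matrix(0L, nrow(dataset), nrow(all_attrs),
              dimnames = list(dataset$record_id, all_attrs$attribute))
  for (i in seq_along(per_record)) {
    d <- per_record[[i]]
    X[i, d$attribute] <- as.integer(d$count)
  }
  list(counts = X, attributes = all_attrs)
}

#' Presence frequency of each attribute in a subset
#'
#' The number of records of the subset that contain the attribute at least
#' once (multiplicities within a record do not add).
#'
#' @param counts Attribute count matrix (`attribute_matrix()$counts`).
#' @param idx Integer row indices of the subset.
#' @return Named integer vector of frequencies.
#' @export
attribute_frequencies <- function(counts, idx) {
  colSums(counts[idx, , drop = FALSE] > 0L)
}

#' Identify rare (blocked) attributes
#'
#' An attribute is rare when its frequency in the active training set is
#' strictly less than the threshold `T`; rare attributes are blocked and
#' their correlation weights are fixed at zero for the whole run.
#'
#' @param frequencies Named vector of active-training frequencies.
#' @param threshold Positive integer `T`.
#' @return Character vector of blocked attribute names.
#' @export
#' @examples
#' classify_rare(c(a = 2, b = 3, c = 10), threshold = 3)
classify_rare <- function(frequencies, threshold) {
  if (length(threshold) != 1L || threshold < 1) {
    stop("'threshold' must be a positive integer", call. = FALSE)
  }
  names(frequencies)[frequencies < threshold]
}

#' Optimal descriptor of each record
#'
#' `DCW(T, N)` is the sum, over a record's attribute instances (with
#' multiplicity, condition attributes included), of the attribute
#' correlation weights. Blocked or unseen attributes contribute zero.
#'
#' @param dataset A `qs_dataset`, or an attribute count matrix.
#' @param weights Named numeric vector of correlation weights, or a
#'   `cw_model` from [optimize_weights()].
#' @return Numeric vector of descriptor values, one per record.
#' @export
dcw <- function(dataset, weights) {
  if (inherits(weights, "cw_model")) weights <- weights$weights
  X <- if (is.matrix(dataset)) dataset else attribute_matrix(dataset)$counts
  common <- intersect(colnames(X), names(weights))
  as.numeric(X[, common, drop = FALSE] %*% weights[common])
}

#' Training target function without the ideality term
#'
#' `TF0 = R_AT + R_PT - |R_AT - R_PT| * dr_weight`, where `R_AT` and `R_PT`
#' are the Pearson correlations between observed endpoint and descriptor on
#' the active and passive training sets. A zero-variance descriptor on
#' either set yields the worst-possible sentinel value.
#'
#' @param y_active,d_active Observed endpoints and descriptor values on the
#'   active training set.
#' @param y_passive,d_passive The same on the passive training set.
#' @param dr_weight Penalty weight on the correlation gap (default 0.1).
#' @return The target value.
#' @export
tf0 <- function(y_active, d_active, y_passive, d_passive, dr_weight = 0.1) {
  r_at <- safe_cor(y_active, d_active)
  r_pt <- safe_cor(y_passive, d_passive)
  if (is.na(r_at) || is.na(r_pt)) return(.TF_SENTINEL)
  r_at + r_pt - abs(r_at - r_pt) * dr_weight
}

#' Index of Ideality of Correlation
#'
#' The Pearson correlation between observed and calculated values, scaled
#' by the ratio of the smaller to the larger of the mean absolute errors of
#' the negative-residual and non-negative-residual subsets
#' (`residual = observed - calculated`; a zero residual counts as
#' non-negative). Symmetric residual spread leaves the correlation intact;
#' fully one-sided residuals drive the index to zero, so the index rewards
#' models whose errors are balanced around the identity line.
#'
#' @param observed,calculated Numeric vectors (typically the calibration
#'   set's endpoint and its predicted values).
#' @return A value in `[-1, 1]`, or `NA` if the correlation is undefined.
#' @export
iic <- function(observed, calculated) {
  if (length(observed) != length(calculated) || length(observed) < 3L) {
    stop("'observed' and 'calculated' must be equal-length, n >= 3",
         call. = FALSE)
  }
  r <- safe_cor(observed, calculated)
  if (is.na(r)) return(NA_real_)
  resid <- observed - calculated
  neg <- resid < 0
  if (!any(neg) || all(neg)) return(0)
  mae_neg <- mean(abs(resid[neg]))
  mae_pos <- mean(abs(resid[!neg]))
  hi <- max(mae_neg, mae_pos)
  if (hi == 0) return(r)  # all residuals exactly zero on both sides
  r * min(mae_neg, mae_pos) / hi
}

#' Training target function with the ideality term
#'
#' `TF1 = TF0 + IIC * iic_weight`. The ideality index is computed on the
#' calibration set from honestly predicted values: the linear endpoint map
#' (intercept and slope) is refit on the active training set at every
#' evaluation and applied to the calibration descriptors.
#'
#' @inheritParams tf0
#' @param y_calibration,d_calibration Endpoints and descriptor values on the
#'   calibration set.
#' @param iic_weight Weight of the ideality term (default 0.3).
#' @return The target value.
#' @export
tf1 <- function(y_active, d_active, y_passive, d_passive,
                y_calibration, d_calibration,
                dr_weight = 0.1, iic_weight = 0.3) {
  base <- tf0(y_active, d_active, y_passive, d_passive, dr_weight)
  if (base == .TF_SENTINEL) return(.TF_SENTINEL)
  v <- stats::var(d_active)
  c1 <- stats::cov(y_active, d_active) / v
  c0 <- mean(y_active) - c1 * mean(d_active)
  pred <- c0 + c1 * d_calibration
  ii <- iic(y_calibration, pred)
  if (is.na(ii)) return(.TF_SENTINEL)
  base + iic_weight * ii
}

#' Configuration of a correlation-weight optimization run
#'
#' @param threshold Rare-attribute threshold `T` (default 3): attributes with
#'   active-training frequency below `T` are blocked at weight zero.
#' @param n_epochs Number of Monte Carlo epochs `N` (default 15; a shorter
#'   budget such as 6 suits runs without the ideality term).
#' @param dr_weight Correlation-gap penalty in `TF0` (default 0.1).
#' @param iic_weight Weight of the ideality term in `TF1` (default 0.3).
#' @param use_iic `TRUE` (default) optimizes `TF1`, `FALSE` optimizes `TF0`.
#' @param init_range Range of the uniform positive initialization of
#'   non-blocked weights (default `c(0.5, 1.5)`).
#' @param delta Initial half-width of the uniform weight perturbation
#'   (default 0.5).
#' @param cooling Geometric per-epoch shrink factor of `delta` (default 0.9).
#' @param seed Integer seed of the run.
#' @return An `optimizer_config` list.
#' @export
optimizer_config <- function(threshold = 3L, n_epochs = 15L,
                             dr_weight = 0.1, iic_weight = 0.3,
                             use_iic = TRUE, init_range = c(0.5, 1.5),
                             delta = 0.5, cooling = 0.9, seed = 1L) {
  stopifnot(threshold >= 1, n_epochs >= 1, delta >= 0, cooling > 0,
            length(init_range) == 2L, init_range[1] <= init_range[2])
  structure(list(threshold = as.integer(threshold),
                 n_epochs = as.integer(n_epochs),
                 dr_weight = dr_weight, iic_weight = iic_weight,
                 use_iic = isTRUE(use_iic), init_range = init_range,
                 delta = delta, cooling = cooling, seed = as.integer(seed)),
            class = "optimizer_config")
}

# Internal: target-function value for a given set of per-subset descriptor
# vectors. `env` carries the fixed endpoints and config.
eval_tf <- function(da, dp, dc, env) {
  if (env$use_iic) {
    tf1(env$ya, da, env$yp, dp, env$yc, dc, env$dr_weight, env$iic_weight)
  } else {
    tf0(env$ya, da, env$yp, dp, env$dr_weight)
  }
}

#' One Monte Carlo epoch of weight refinement
#'
#' Sweeps the non-blocked attributes in a random order. For each attribute
#' the candidate steps are a signed geometric ladder `delta * ladder * u`
#' (both signs, `u` a fresh uniform draw in `[0.5, 1]`); the best candidate
#' is kept if and only if the target function does not decrease. The target
#' value after the epoch is therefore never below the value before it.
#'
#' This is the low-level step behind [optimize_weights()]; it operates on a
#' prepared optimization state and is exported mainly for inspection and
#' testing.
#'
#' @param state Internal optimization state from `optim_state()`.
#' @param delta Base perturbation magnitude for this epoch.
#' @param ladder Geometric step-magnitude multipliers (default `2^(2:-4)`,
#'   i.e. from `4 * delta` down to `delta / 16`).
#' @return The updated state.
#' @keywords internal
#' @export
monte_carlo_epoch <- function(state, delta, ladder = 2^(2:-4)) {
  free <- state$free
  if (length(free) == 0L || delta == 0) return(state)
  order <- sample(free)
  for (k in order) {
    scale <- stats::runif(1L, 0.5, 1)
    cand <- as.numeric(c(-1, 1) %o% (delta * scale * ladder))
    best_tf <- state$tf
    best_step <- 0
    xa <- state$Xa[, k]
    xp <- state$Xp[, k]
    xc <- state$Xc[, k]
    for (step in cand) {
      tf_new <- eval_tf(state$da + step * xa, state$dp + step * xp,
                        state$dc + step * xc, state$env)
      if (tf_new > best_tf) {
        best_tf <- tf_new
        best_step <- step
      }
    }
    if (best_step != 0) {
      state$w[k] <- state$w[k] + best_step
      state$da <- state$da + best_step * xa
      state$dp <- state$dp + best_step * xp
      state$dc <- state$dc + best_step * xc
      state$tf <- best_tf
    }
  }
  state
}

# Assemble the mutable optimization state for a dataset/split/config.
optim_state <- function(X, y, idx, config) {
  Xa <- X[idx$active, , drop = FALSE]
  Xp <- X[idx$passive, , drop = FALSE]
  Xc <- X[idx$calibration, , drop = FALSE]
  freq_active <- colSums(Xa > 0L)
  blocked <- classify_rare(freq_active, config$threshold)
  free <- setdiff(colnames(X), blocked)
  w <- stats::setNames(rep(0, ncol(X)), colnames(X))
  w[free] <- stats::runif(length(free), config$init_range[1],
                          config$init_range[2])
  env <- list(ya = y[idx$active], yp = y[idx$passive],
              yc = y[idx$calibration], dr_weight = config$dr_weight,
              iic_weight = config$iic_weight, use_iic = config$use_iic)
  state <- list(
    w = w, free = free, blocked = blocked,
    Xa = Xa, Xp = Xp, Xc = Xc,
    da = as.numeric(Xa %*% w), dp = as.numeric(Xp %*% w),
    dc = as.numeric(Xc %*% w),
    env = env
  )
  state$tf <- eval_tf(state$da, state$dp, state$dc, env)
  state
}

trace_row <- function(state, epoch) {
  r2 <- function(y, d) {
    r <- safe_cor(y, d)
    if (is.na(r)) NA_real_ else r^2
  }
  v <- stats::var(state$da)
  iic_c <- NA_real_
  if (is.finite(v) && v > 0) {
    c1 <- stats::cov(state$env$ya, state$da) / v
    c0 <- mean(state$env$ya) - c1 * mean(state$da)
    iic_c <- iic(state$env$yc, c0 + c1 * state$dc)
  }
  data.frame(epoch = epoch, tf = state$tf,
             r2_active = r2(state$env$ya, state$da),
             r2_passive = r2(state$env$yp, state$dp),
             r2_calibration = r2(state$env$yc, state$dc),
             iic_calibration = iic_c)
}

#' Optimize attribute correlation weights for one split
#'
#' Runs the full Monte Carlo optimization: blocks rare attributes from the
#' active-training frequencies, initializes the remaining weights uniformly
#' at random, and refines them for `n_epochs` epochs of per-attribute hill
#' climbing against `TF0` or `TF1` (see [optimizer_config()]). The
#' perturbation half-width shrinks geometrically across epochs. The whole
#' run is reproducible from `config$seed`.
#'
#' @param dataset A `qs_dataset`.
#' @param split A `qs_split` of that dataset.
#' @param config An [optimizer_config()].
#' @param am Optional precomputed [attribute_matrix()] of `dataset`.
#' @return A `cw_model` list: `weights` (named vector over all attributes;
#'   blocked attributes are exactly 0), `blocked`, `attributes` catalogue,
#'   `frequencies` (presence counts per training subset), `trace` (one row
#'   per epoch, epoch 0 being the initial state), `tf` (final target value)
#'   and `config`.
#' @export
optimize_weights <- function(dataset, split, config = optimizer_config(),
                             am = NULL) {
  stopifnot(inherits(dataset, "qs_dataset"), inherits(split, "qs_split"))
  if (is.null(am)) am <- attribute_matrix(dataset)
  X <- am$counts
  idx <- split_indices(dataset, split)
  if (any(lengths(idx) < 3L)) {
    stop("every subset needs at least 3 records", call. = FALSE)
  }
  y <- dataset$pld50
  res <- with_seed(config$seed, {
    state <- optim_state(X, y, idx, config)
    trace <- trace_row(state, 0L)
    delta <- config$delta
    for (epoch in seq_len(config$n_epochs)) {
      state <- monte_carlo_epoch(state, delta)
      trace <- rbind(trace, trace_row(state, epoch))
      delta <- delta * config$cooling
    }
    list(state = state, trace = trace)
  })
  freq <- data.frame(
    attribute = colnames(X),
    n_active = as.integer(attribute_frequencies(X, idx$active)),
    n_passive = as.integer(attribute_frequencies(X, idx$passive)),
    n_calibration = as.integer(attribute_frequencies(X, idx$calibration)),
    row.names = NULL
  )
  structure(list(weights = res$state$w, blocked = res$state$blocked,
                 attributes = am$attributes, frequencies = freq,
                 trace = res$trace, tf = res$state$tf,
                 config = config, split_seed = split$seed),
            class = "cw_model")
}

#' Attribute weight table of a fitted model
#'
#' @param model A `cw_model`.
#' @return Data frame with `attribute`, `kind`, per-subset presence
#'   frequencies, `weight` and `blocked`.
#' @export
weight_table <- function(model) {
  stopifnot(inherits(model, "cw_model"))
  out <- merge(model$attributes, model$frequencies, by = "attribute",
               sort = FALSE)
  out$weight <- unname(model$weights[out$attribute])
  out$blocked <- out$attribute %in% model$blocked
  out[order(-out$n_active, out$attribute), ]
}

#' @export
print.cw_model <- function(x, ...) {
  cat(sprintf(
    "correlation-weight model: %d attributes (%d blocked), %s, %d epochs, final TF = %.4f\n",
    length(x$weights), length(x$blocked),
    if (x$config$use_iic) "TF1" else "TF0", x$config$n_epochs, x$tf))
  invisible(x)
}
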