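# Applicability domain by statistical defects of attributes.
#
# An attribute whose relative frequency differs between the active training,
# passive training and calibration sets carries a "statistical defect": its
# distribution over the training material is unstable, so records built from
# such attributes are less reliably predicted. A record's defect is the sum
# over its non-blocked attribute instances, and the record is inside the
# applicability domain when its defect stays below twice the training mean.

#' Statistical defect of attributes
#'
#' For each attribute, with `P`, `P'`, `P''` the relative presence
#' frequencies in the active training, passive training and calibration
#' sets and `Nf`, `Nf'`, `Nf''` the absolute frequencies:
#' `d_k = |P - P'|/(Nf + Nf') + |P - P''|/(Nf + Nf'') + |P' - P''|/(Nf' + Nf'')`,
#' a pairwise term being 0 when its frequency denominator is 0. Equal
#' probabilities give `d_k = 0`.
#'
#' @param n_active,n_passive,n_calibration Absolute presence frequencies of
#'   the attributes (equal-length, possibly named, vectors).
#' @param sizes Integer vector of the three subset sizes, in the same order.
#' @return Named numeric vector of defects `d_k`.
#' @export
attribute_defect <- function(n_active, n_passive, n_calibration, sizes) {
  if (length(sizes) != 3L || any(sizes <= 0)) {
    stop("'sizes' must be the three positive subset sizes", call. = FALSE)
  }
  p <- n_active / sizes[1]
  p1 <- n_passive / sizes[2]
  p2 <- n_calibration / sizes[3]
  term <- function(pa, pb, na, nb) {
    den <- na + nb
    ifelse(den > 0, abs(pa - pb) / den, 0)
  }
  term(p, p1, n_active, n_passive) +
    term(p, p2, n_active, n_calibration) +
    term(p1, p2, n_passive, n_calibration)
}

#' Defect table of a dataset under one split
#'
#' Computes `d_k` for every attribute from its presence frequencies in the
#' three training subsets.
#'
#' @param dataset A `qs_dataset`.
#' @param split A `qs_split`.
#' @param am Optional precomputed [attribute_matrix()] of `dataset`.
#' @return Data frame with `attribute`, the three probabilities and absolute
#'   frequencies, and `d_k`.
#' @export
defect_table <- function(dataset, split, am = NULL) {
  if (is.null(am)) am <- attribute_matrix(dataset)
  X <- am$counts
  idx <- split_indices(dataset, split)
  na <- attribute_frequencies(X, idx$active)
  np <- attribute_frequencies(X, idx$passive)
  nc <- attribute_frequencies(X, idx$calibration)
  sizes <- c(length(idx$active), length(idx$passive),
             length(idx$calibration))
  data.frame(
    attribute = colnames(X),
    P_active = na / sizes[1], P_passive = np / sizes[2],
    P_calibration = nc / sizes[3],
    N_active = as.integer(na), N_passive = as.integer(np),
    N_calibration = as.integer(nc),
    d_k = as.numeric(attribute_defect(na, np, nc, sizes)),
    row.names = NULL
  )
}

#' Statistical defect of each record
#'
#' `D_j` is the sum of `d_k` over the record's non-blocked attribute
#' instances, counted with multiplicity.
#'
#' @param counts Attribute count matrix (`attribute_matrix()$counts`).
#' @param defects A [defect_table()] (or data frame with `attribute`, `d_k`)
#'   covering at least all non-blocked attributes.
#' @param blocked Character vector of blocked attributes (contribute 0).
#' @return Named numeric vector of `D_j`, one per record.
#' @export
compound_defect <- function(counts, defects, blocked = character(0)) {
  d <- stats::setNames(defects$d_k, defects$attribute)
  use <- setdiff(colnames(counts), blocked)
  missing <- setdiff(use, names(d))
  if (length(missing) > 0L) {
    stop("defect table misses non-blocked attributes: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  as.numeric(counts[, use, drop = FALSE] %*% d[use])
}

#' Applicability-domain flags for every record
#'
#' Computes each record's statistical defect `D_j`, the reference mean
#' defect over the training population, and flags a record as in-domain
#' when `D_j < 2 * Dbar`.
#'
#' @param dataset A `qs_dataset`.
#' @param split A `qs_split`.
#' @param blocked Character vector of blocked attributes, typically
#'   `model$blocked`; pass a `cw_model` to use its blocked set.
#' @param reference `"training"` (default) averages `D_j` over the active,
#'   passive and calibration records; `"active"` restricts the mean to the
#'   active training set.
#' @param am Optional precomputed [attribute_matrix()] of `dataset`.
#' @return A `domain_flags` data frame with `record_id`, `subset`, `D_j`,
#'   `in_domain`; attributes `Dbar` and `n_outliers` summarize the split.
#' @export
domain_flags <- function(dataset, split, blocked = character(0),
                         reference = c("training", "active"), am = NULL) {
  reference <- match.arg(reference)
  if (inherits(blocked, "cw_model")) blocked <- blocked$blocked
  if (is.null(am)) am <- attribute_matrix(dataset)
  X <- am$counts
  idx <- split_indices(dataset, split)
  defects <- defect_table(dataset, split, am = am)
  dj <- compound_defect(X, defects, blocked)
  ref_idx <- if (reference == "training") {
    c(idx$active, idx$passive, idx$calibration)
  } else {
    idx$active
  }
  dbar <- mean(dj[ref_idx])
  subset_of <- rep(NA_character_, nrow(dataset))
  for (s in SUBSETS) subset_of[idx[[s]]] <- s
  # a defect-free population (Dbar = 0) leaves every defect-free record in
  in_domain <- if (dbar > 0) dj < 2 * dbar else dj == 0
  out <- data.frame(record_id = dataset$record_id, subset = subset_of,
                    D_j = dj, in_domain = in_domain, row.names = NULL)
  attr(out, "Dbar") <- dbar
  attr(out, "n_outliers") <- sum(!out$in_domain)
  class(out) <- c("domain_flags", "data.frame")
  out
}
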