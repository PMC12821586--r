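# Random four-subset splits (active/passive training, calibration,
# validation) and the inter-split identity diagnostics.

SUBSETS <- c("active", "passive", "calibration", "validation")

#' Randomly split a dataset into the four modelling subsets
#'
#' Records are divided into disjoint active training, passive training,
#' calibration and validation subsets covering the whole dataset. Subset
#' sizes are `floor(n * fraction)` with the remainder distributed one record
#' at a time in the fixed order active, passive, calibration, validation.
#'
#' @param dataset A `qs_dataset`.
#' @param fractions Numeric vector of four fractions summing to 1
#'   (default equal quarters).
#' @param seed Integer seed; the split is fully reproducible given the seed.
#' @return A `qs_split`: list with character vectors `active`, `passive`,
#'   `calibration`, `validation` of record ids, plus the `seed`.
#' @export
random_split <- function(dataset, fractions = rep(0.25, 4), seed = 1L) {
  stopifnot(inherits(dataset, "qs_dataset"))
  if (length(fractions) != 4L || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("'fractions' must be four positive values summing to 1",
         call. = FALSE)
  }
  n <- nrow(dataset)
  if (n < 8L) stop("need at least 8 records to split", call. = FALSE)
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  if (rem > 0L) {
    idx <- rep_len(seq_along(sizes), rem)
    for (i in idx) sizes[i] <- sizes[i] + 1L
  }
  perm <- with_seed(seed, sample.int(n))
  ids <- dataset$record_id[perm]
  bounds <- cumsum(c(0L, sizes))
  out <- lapply(seq_along(SUBSETS), function(i) {
    ids[(bounds[i] + 1L):bounds[i + 1L]]
  })
  names(out) <- SUBSETS
  out$seed <- as.integer(seed)
  structure(out, class = "qs_split")
}

#' Build an ensemble of replicate random splits
#'
#' @param dataset A `qs_dataset`.
#' @param n_splits Number of replicate splits (default 5).
#' @param seeds Integer vector of distinct seeds, one per split; defaults to
#'   `base_seed + 0:(n_splits-1)`.
#' @param base_seed Used when `seeds` is not given.
#' @inheritParams random_split
#' @return A `qs_split_ensemble`: list of `qs_split` objects.
#' @export
split_ensemble <- function(dataset, n_splits = 5L, seeds = NULL,
                           base_seed = 1L, fractions = rep(0.25, 4)) {
  if (is.null(seeds)) seeds <- as.integer(base_seed) + seq_len(n_splits) - 1L
  if (anyDuplicated(seeds) > 0L) {
    stop("split seeds must be distinct", call. = FALSE)
  }
  splits <- lapply(seeds, function(s) random_split(dataset, fractions, s))
  structure(splits, class = "qs_split_ensemble")
}

#' Percentage of identity between two record-id sets
#'
#' Overlap normalized by the mean set size:
#' `100 * |A ∩ B| / (0.5 * (|A| + |B|))`. Equal sets give 100; disjoint sets
#' give 0. Used to check that replicate splits are genuinely different.
#'
#' @param ids_a,ids_b Non-empty character vectors of record ids.
#' @return The identity percentage in `[0, 100]`.
#' @export
#' @examples
#' identity_percentage(letters[1:10], letters[3:12])
identity_percentage <- function(ids_a, ids_b) {
  if (length(ids_a) == 0L || length(ids_b) == 0L) {
    stop("both id sets must be non-empty", call. = FALSE)
  }
  ids_a <- unique(ids_a)
  ids_b <- unique(ids_b)
  100 * length(intersect(ids_a, ids_b)) /
    (0.5 * (length(ids_a) + length(ids_b)))
}

#' Inter-split identity matrix of an ensemble
#'
#' Square matrix over the replicate splits: the lower triangle (`i > j`)
#' compares active training sets, the upper triangle (`i < j`) compares
#' validation sets, and the diagonal is 100 by construction.
#'
#' @param ensemble A `qs_split_ensemble` with at least two splits.
#' @return Numeric matrix of identity percentages.
#' @export
identity_matrix <- function(ensemble) {
  stopifnot(inherits(ensemble, "qs_split_ensemble"))
  k <- length(ensemble)
  if (k < 2L) stop("need at least two splits", call. = FALSE)
  m <- matrix(100, k, k, dimnames = list(seq_len(k), seq_len(k)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i > j) {
        m[i, j] <- identity_percentage(ensemble[[i]]$active,
                                       ensemble[[j]]$active)
      } else if (i < j) {
        m[i, j] <- identity_percentage(ensemble[[i]]$validation,
                                       ensemble[[j]]$validation)
      }
    }
  }
  m
}

split_ids <- function(split) {
  c(split$active, split$passive, split$calibration, split$validation)
}

# Integer row indices of each subset of `split` within `dataset`.
split_indices <- function(dataset, split) {
  out <- lapply(SUBSETS, function(s) {
    idx <- match(split[[s]], dataset$record_id)
    if (anyNA(idx)) {
      stop("split refers to record ids absent from the dataset",
           call. = FALSE)
    }
    idx
  })
  names(out) <- SUBSETS
  out
}

#' Write a split as a record-id/subset table
#'
#' @param split A `qs_split`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_split <- function(split, path) {
  df <- data.frame(
    record_id = split_ids(split),
    subset = rep(SUBSETS, times = lengths(split[SUBSETS]))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.qs_split <- function(x, ...) {
  cat(sprintf(
    "quasi-SMILES split (seed %d): active %d | passive %d | calibration %d | validation %d\n",
    x$seed, length(x$active), length(x$passive), length(x$calibration),
    length(x$validation)))
  invisible(x)
}
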