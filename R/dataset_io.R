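# Record tables: construction, endpoint harmonization, deduplication, I/O.

#' Convert an LD50 to the pLD50 modelling scale
#'
#' The endpoint is modelled as the negative decimal logarithm of the median
#' lethal dose in micrograms per organism; higher pLD50 means more toxic.
#'
#' @param ld50 Numeric vector of positive LD50 values (µg/organism).
#' @return `-log10(ld50)`.
#' @export
#' @examples
#' to_pld50(c(1, 0.001, 100))
to_pld50 <- function(ld50) {
  if (!is.numeric(ld50) || any(!is.finite(ld50)) || any(ld50 <= 0)) {
    stop("'ld50' must be finite and strictly positive", call. = FALSE)
  }
  -log10(ld50)
}

#' Assemble a quasi-SMILES dataset
#'
#' Validates and normalizes a table of records. Each record is one compound
#' under one full set of experimental conditions, with its endpoint.
#'
#' @param df Data frame with columns `record_id`, `smiles`, one column per
#'   condition feature (`WT`, `SS`, `SO`, `SP`, `LS`, `OB`) and `pld50`.
#'   An optional logical `qualified` column flags endpoints that carried a
#'   `>`/`<` qualifier in the source and were taken at face value.
#' @param provenance Free-text metadata attached to the dataset.
#' @param check_smiles If `TRUE` (default), every SMILES must tokenize.
#' @return A `qs_dataset`: the validated data frame with class attribute and
#'   `provenance` attribute.
#' @export
qs_dataset <- function(df, provenance = "", check_smiles = TRUE) {
  feats <- qs_features()
  needed <- c("record_id", "smiles", feats, "pld50")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$record_id <- as.character(df$record_id)
  df$smiles <- as.character(df$smiles)
  for (f in feats) df[[f]] <- as.character(df[[f]])
  df$pld50 <- as.numeric(df$pld50)
  if (anyDuplicated(df$record_id) > 0L) {
    stop("record_id values must be unique", call. = FALSE)
  }
  if (any(!is.finite(df$pld50))) {
    stop("endpoint pld50 must be finite for every record; offending rows: ",
         paste(utils::head(which(!is.finite(df$pld50)), 5L), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    validate_conditions(vapply(feats, function(f) df[[f]][i], ""))
  }
  if (check_smiles) {
    for (i in seq_len(nrow(df))) {
      tryCatch(tokenize_smiles(df$smiles[i]),
               error = function(e) stop(sprintf("row %d (%s): %s", i,
                 df$record_id[i], conditionMessage(e)), call. = FALSE))
    }
  }
  if (!"qualified" %in% names(df)) df$qualified <- FALSE
  structure(df[, c(needed, "qualified")],
            class = c("qs_dataset", "data.frame"),
            provenance = provenance)
}

#' Full quasi-SMILES identity key of each record
#'
#' The key concatenates the SMILES string with all six condition levels;
#' two records with equal keys are the same modelling object.
#'
#' @param dataset A `qs_dataset`.
#' @return Character vector, one key per record.
#' @export
quasi_smiles_key <- function(dataset) {
  feats <- qs_features()
  do.call(paste, c(list(dataset$smiles),
                   lapply(feats, function(f) paste0(f, dataset[[f]])),
                   sep = "|"))
}

#' Remove duplicated quasi-SMILES, keeping the most toxic record
#'
#' Among records sharing an identical quasi-SMILES (structure plus all six
#' conditions, or structure alone with `key = "smiles"`), the record with
#' the lowest LD50 — i.e. the highest pLD50 — is kept. The number of removed
#' records is attached as attribute `n_removed`.
#'
#' @param dataset A `qs_dataset`.
#' @param key `"quasi"` (default) to key duplicates on the full quasi-SMILES,
#'   `"smiles"` to key on the bare structure as in a pre-assembly pass.
#' @return The deduplicated `qs_dataset` (original record order preserved),
#'   with attribute `n_removed`.
#' @export
deduplicate <- function(dataset, key = c("quasi", "smiles")) {
  key <- match.arg(key)
  stopifnot(inherits(dataset, "qs_dataset"))
  k <- if (key == "quasi") quasi_smiles_key(dataset) else dataset$smiles
  keep <- rep(FALSE, nrow(dataset))
  for (g in split(seq_len(nrow(dataset)), k)) {
    # ties on pLD50 resolve to the earliest record
    keep[g[which.max(dataset$pld50[g])]] <- TRUE
  }
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "provenance") <- attr(dataset, "provenance")
  attr(out, "n_removed") <- sum(!keep)
  class(out) <- class(dataset)
  out
}

#' Read a record table from a delimited text file
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param col_map Named character vector mapping the standard column names
#'   (`record_id`, `smiles`, `WT`, `SS`, `SO`, `SP`, `LS`, `OB`, and either
#'   `pld50` or `ld50`) to the file's column names. Defaults to identity.
#' @param sep Field separator; `"\t"` for TSV (default), `","` for CSV.
#' @param ... Passed to [qs_dataset()].
#' @return A `qs_dataset`. If the endpoint column is `ld50` it is converted
#'   with [to_pld50()]; unparseable or non-positive endpoints are reported
#'   with their row number.
#' @export
read_qs_table <- function(path, col_map = NULL, sep = "\t", ...) {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "",
                           quote = "\"", check.names = FALSE)
  std <- c("record_id", "smiles", qs_features(), "pld50", "ld50", "qualified")
  if (is.null(col_map)) {
    col_map <- intersect(std, names(raw))
    names(col_map) <- col_map
  }
  missing <- setdiff(names(col_map), std)
  if (length(missing) > 0L) {
    stop("unknown standard columns in col_map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  absent <- setdiff(unname(col_map), names(raw))
  if (length(absent) > 0L) {
    stop("columns not found in ", path, ": ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  df <- raw[, unname(col_map), drop = FALSE]
  names(df) <- names(col_map)
  if ("ld50" %in% names(df) && !"pld50" %in% names(df)) {
    ld <- suppressWarnings(as.numeric(df$ld50))
    bad <- which(!is.finite(ld) | ld <= 0)
    if (length(bad) > 0L) {
      stop("unparseable or non-positive LD50 at data row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    df$pld50 <- to_pld50(ld)
    df$ld50 <- NULL
  }
  qs_dataset(df, provenance = path, ...)
}

#' Write a record table, predictions, or a weight table
#'
#' `write_qs_table()` writes a dataset back to TSV so that
#' `read_qs_table(write_qs_table(x))` round-trips. `write_predictions()` and
#' `write_weights()` write per-record predictions and the learned
#' attribute-weight table in the standard shapes.
#'
#' @param dataset A `qs_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qs_table <- function(dataset, path) {
  utils::write.table(as.data.frame(dataset), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qs_table
#' @param predictions Data frame with at least `record_id`, `observed`,
#'   `predicted` (e.g. from [predict_pipeline()]).
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_qs_table
#' @param weights A weight table as returned by [weight_table()].
#' @export
write_weights <- function(weights, path) {
  utils::write.table(weights, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.qs_dataset <- function(x, ...) {
  cat(sprintf("quasi-SMILES dataset: %d records\n", nrow(x)))
  prov <- attr(x, "provenance")
  if (!is.null(prov) && nzchar(prov)) cat("provenance:", prov, "\n")
  NextMethod()
}
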