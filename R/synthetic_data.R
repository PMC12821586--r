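# Synthetic quasi-SMILES benchmark generator with planted ground truth.
#
# Emulates the structure of a compiled pollinator-toxicity table: a few
# hundred records, each a tokenizable SMILES-like string plus six condition
# codes, with the endpoint generated as a known linear function of planted
# attribute counts plus Gaussian noise. Because the true attribute effects
# are known, descriptor optimization, validation statistics, applicability
# domain and promoter classification can all be tested end to end.

#' Specification of a synthetic quasi-SMILES dataset
#'
#' Defaults mirror a pollinator acute/chronic oral-toxicity compilation:
#' 382 records; six condition factors — quartile persistence bins in water,
#' sediment and soil, eight species levels dominated by one (honey-bee-like)
#' taxon, two life stages, and three duration classes with chronic data
#' scarce; structures of 6–25 heavy-atom tokens with branches, double bonds
#' and ring closures, drawn from a pesticide-like organic alphabet.
#'
#' @param n_records Number of records (default 382).
#' @param alphabet Named numeric vector of atom-token sampling weights.
#' @param min_len,max_len Range of the per-record atom-token count.
#' @param branch_prob,bond_prob,ring_prob Probabilities of opening a branch
#'   after an atom, of a double/triple bond before an atom, and of adding a
#'   ring-closure digit pair to a structure.
#' @param condition_levels Named list giving the number of levels of each
#'   condition feature.
#' @param condition_probs Optional named list of per-feature level sampling
#'   probabilities; features not listed are sampled uniformly.
#' @param planted Either `NULL` (default: `n_planted` attributes are chosen
#'   automatically among mid-frequency attributes) or a data frame with
#'   columns `attribute` (12-character rendering) and `effect`.
#' @param n_planted Number of auto-selected planted attributes (default 10).
#' @param effect_sizes Magnitudes cycled (with alternating sign) over the
#'   auto-selected attributes (default between 1 and 2 pLD50 units per
#'   attribute count).
#' @param intercept Baseline endpoint value (default 0.5 pLD50).
#' @param sigma Gaussian noise standard deviation (default 0.1).
#' @param outlier_fraction Fraction of records receiving an endpoint shift
#'   (default 0).
#' @param outlier_shift Magnitude of the (one-sided) endpoint shift added to
#'   outlier records (default 2).
#' @param n_alien Number of structure-alien records appended (default 0):
#'   their structures use a disjoint exotic alphabet, so they inflate the
#'   statistical defect and should fall outside the applicability domain.
#' @param seed Integer seed; generation is byte-reproducible given the seed.
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(n_records = 382L,
                           alphabet = c(C = 0.40, c = 0.20, N = 0.09,
                                        O = 0.12, Cl = 0.07, S = 0.04,
                                        n = 0.04, F = 0.03, Br = 0.01),
                           min_len = 6L, max_len = 25L,
                           branch_prob = 0.25, bond_prob = 0.15,
                           ring_prob = 0.6,
                           condition_levels = list(WT = 4L, SS = 4L,
                                                   SO = 4L, SP = 8L,
                                                   LS = 2L, OB = 3L),
                           condition_probs = list(
                             SP = c(0.55, 0.15, 0.08, 0.06, 0.05, 0.04,
                                    0.04, 0.03),
                             LS = c(0.65, 0.35),
                             OB = c(0.72, 0.23, 0.05)),
                           planted = NULL, n_planted = 10L,
                           effect_sizes = c(2, 1.8, 1.6, 1.4, 1.2),
                           intercept = 0.5, sigma = 0.1,
                           outlier_fraction = 0, outlier_shift = 2,
                           n_alien = 0L, seed = 1L) {
  stopifnot(n_records >= 8L, all(alphabet > 0), min_len >= 2L,
            max_len >= min_len, branch_prob >= 0, branch_prob <= 1,
            bond_prob >= 0, bond_prob <= 1, ring_prob >= 0, ring_prob <= 1,
            sigma >= 0, outlier_fraction >= 0, outlier_fraction <= 1,
            n_alien >= 0L)
  if (!setequal(names(condition_levels), qs_features())) {
    stop("'condition_levels' must name exactly the six features",
         call. = FALSE)
  }
  structure(list(n_records = as.integer(n_records), alphabet = alphabet,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 branch_prob = branch_prob, bond_prob = bond_prob,
                 ring_prob = ring_prob, condition_levels = condition_levels,
                 condition_probs = condition_probs, planted = planted,
                 n_planted = as.integer(n_planted),
                 effect_sizes = effect_sizes, intercept = intercept,
                 sigma = sigma, outlier_fraction = outlier_fraction,
                 outlier_shift = outlier_shift, n_alien = as.integer(n_alien),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

# One random structure: a branched chain with optional bonds and a ring
# digit pair; balanced by construction, so it always tokenizes.
gen_structure <- function(n_atoms, alphabet, branch_prob, bond_prob,
                          ring_prob) {
  atoms <- names(alphabet)
  p <- alphabet / sum(alphabet)
  chain <- function(n) {
    toks <- character(0)
    while (n > 0L) {
      if (length(toks) > 0L && !toks[length(toks)] %in% c("(") &&
          stats::runif(1) < bond_prob) {
        toks <- c(toks, sample(c("=", "#"), 1L, prob = c(0.85, 0.15)))
      }
      toks <- c(toks, sample(atoms, 1L, prob = p))
      n <- n - 1L
      if (n >= 2L && stats::runif(1) < branch_prob) {
        b <- sample.int(min(n - 1L, 4L), 1L)
        toks <- c(toks, "(", chain(b), ")")
        n <- n - b
      }
    }
    toks
  }
  toks <- chain(n_atoms)
  if (stats::runif(1) < ring_prob) {
    # a ring digit directly follows an atom at both attachment points
    at_atom <- which(toks %in% atoms)
    if (length(at_atom) >= 3L) {
      pos <- sort(sample(at_atom, 2L))
      toks <- append(toks, "1", after = pos[2])
      toks <- append(toks, "1", after = pos[1])
    }
  }
  paste(toks, collapse = "")
}

sample_conditions <- function(spec) {
  out <- lapply(qs_features(), function(f) {
    k <- spec$condition_levels[[f]]
    pr <- spec$condition_probs[[f]] %||% rep(1 / k, k)
    sample(as.character(seq_len(k)), 1L, prob = pr)
  })
  stats::setNames(unlist(out), qs_features())
}

# Mid-frequency attributes with count variation, most frequent first.
select_planted <- function(X, n_planted, effect_sizes, n_records) {
  freq <- colSums(X > 0L)
  vr <- apply(X, 2L, stats::var)
  cand <- names(freq)[freq >= 0.25 * n_records & freq <= 0.85 * n_records &
                        vr > 0]
  cand <- cand[order(-freq[cand])]
  if (length(cand) < n_planted) {
    stop("not enough mid-frequency attributes to plant effects on; ",
         "increase n_records or relax the grammar", call. = FALSE)
  }
  chosen <- cand[seq_len(n_planted)]
  effects <- rep_len(effect_sizes, n_planted) *
    rep_len(c(1, -1), n_planted)
  data.frame(attribute = chosen, effect = effects, row.names = NULL)
}

#' Generate a synthetic quasi-SMILES dataset with known ground truth
#'
#' Draws structures and condition codes per [generator_spec()], then sets
#' `pLD50 = intercept + sum(effect * attribute count) + N(0, sigma)` using
#' the planted effect table. Optional endpoint-shifted outliers exercise
#' asymmetric-residual penalties; optional structure-alien records exercise
#' the applicability domain.
#'
#' @param spec A [generator_spec()].
#' @return List with `dataset` (a `qs_dataset`; alien records have ids
#'   prefixed `ALIEN`), `truth` (data frame `attribute`, `effect`),
#'   `outlier_ids`, and the `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    n <- spec$n_records
    smiles <- vapply(seq_len(n), function(i) {
      gen_structure(sample(spec$min_len:spec$max_len, 1L), spec$alphabet,
                    spec$branch_prob, spec$bond_prob, spec$ring_prob)
    }, "")
    conds <- t(vapply(seq_len(n), function(i) sample_conditions(spec),
                      character(6L)))
    df <- data.frame(record_id = sprintf("R%04d", seq_len(n)),
                     smiles = smiles, conds, pld50 = 0,
                     stringsAsFactors = FALSE)
    colnames(df)[3:8] <- qs_features()
    if (spec$n_alien > 0L) {
      alien_alphabet <- c(`[Se]` = 0.3, `[As]` = 0.3, I = 0.2, P = 0.2)
      alien <- data.frame(
        record_id = sprintf("ALIEN%03d", seq_len(spec$n_alien)),
        smiles = vapply(seq_len(spec$n_alien), function(i) {
          gen_structure(sample(spec$min_len:spec$max_len, 1L),
                        alien_alphabet, spec$branch_prob, spec$bond_prob,
                        spec$ring_prob)
        }, ""),
        t(vapply(seq_len(spec$n_alien), function(i) sample_conditions(spec),
                 character(6L))),
        pld50 = 0, stringsAsFactors = FALSE)
      colnames(alien)[3:8] <- qs_features()
      df <- rbind(df, alien)
    }
    ds0 <- qs_dataset(df, provenance = "synthetic")
    X <- attribute_matrix(ds0)$counts
    truth <- spec$planted
    if (is.null(truth)) {
      truth <- select_planted(X[seq_len(n), , drop = FALSE], spec$n_planted,
                              spec$effect_sizes, n)
    }
    known <- intersect(truth$attribute, colnames(X))
    eff <- stats::setNames(truth$effect, truth$attribute)[known]
    y <- spec$intercept +
      as.numeric(X[, known, drop = FALSE] %*% eff) +
      stats::rnorm(nrow(ds0), 0, spec$sigma)
    outlier_ids <- character(0)
    if (spec$outlier_fraction > 0) {
      n_out <- round(spec$outlier_fraction * nrow(ds0))
      if (n_out > 0L) {
        pick <- sample.int(nrow(ds0), n_out)
        y[pick] <- y[pick] + spec$outlier_shift
        outlier_ids <- ds0$record_id[pick]
      }
    }
    ds0$pld50 <- y
    list(dataset = ds0, truth = truth, outlier_ids = outlier_ids,
         spec = spec)
  })
}

#' Write a generated dataset and its ground truth
#'
#' @param generated Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the two written paths, invisibly.
#' @export
write_generated <- function(generated, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "dataset.tsv")
  p2 <- file.path(dir, "ground_truth.tsv")
  write_qs_table(generated$dataset, p1)
  utils::write.table(generated$truth, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
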