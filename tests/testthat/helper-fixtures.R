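# Shared fixtures: tiny datasets, manual splits, fake fitted models.

# A fixed full set of condition codes.
fix_conds <- function(WT = "1", SS = "1", SO = "1", SP = "1", LS = "A",
                      OB = "1") {
  c(WT = WT, SS = SS, SO = SO, SP = SP, LS = LS, OB = OB)
}

# A small hand-written dataset; conditions constant unless supplied.
toy_dataset <- function(smiles, pld50 = seq_along(smiles),
                        conds = NULL) {
  n <- length(smiles)
  if (is.null(conds)) {
    conds <- do.call(rbind, replicate(n, fix_conds(), simplify = FALSE))
  }
  df <- data.frame(record_id = sprintf("T%02d", seq_len(n)),
                   smiles = smiles, conds, pld50 = pld50,
                   stringsAsFactors = FALSE)
  qs_dataset(df)
}

# A manually assigned split over the record ids of `dataset`.
manual_split <- function(active, passive, calibration, validation) {
  structure(list(active = active, passive = passive,
                 calibration = calibration, validation = validation,
                 seed = 0L),
            class = "qs_split")
}

# Minimal cw_model stand-in for promoter-classification rule tests.
fake_model <- function(weights, blocked = character(0)) {
  attrs <- data.frame(attribute = names(weights),
                      kind = "single", stringsAsFactors = FALSE)
  freq <- data.frame(attribute = names(weights),
                     n_active = rev(seq_along(weights)),
                     n_passive = rev(seq_along(weights)),
                     n_calibration = rev(seq_along(weights)))
  structure(list(weights = weights, blocked = blocked, attributes = attrs,
                 frequencies = freq, trace = NULL, tf = 0,
                 config = optimizer_config(), split_seed = 0L),
            class = "cw_model")
}
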