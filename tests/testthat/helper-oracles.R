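# Independent brute-force oracles for the validation metrics. These use
# explicit sums and loops only — no shared code with the implementation.

oracle_r <- function(x, y) {
  n <- length(x)
  sum((x - sum(x) / n) * (y - sum(y) / n)) /
    sqrt(sum((x - sum(x) / n)^2) * sum((y - sum(y) / n)^2))
}

oracle_D <- function(obs, pred) oracle_r(obs, pred)^2

oracle_CCC <- function(obs, pred) {
  n <- length(obs)
  mx <- sum(obs) / n
  my <- sum(pred) / n
  sxy <- sum((obs - mx) * (pred - my)) / n
  sx2 <- sum((obs - mx)^2) / n
  sy2 <- sum((pred - my)^2) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# Explicit leave-one-out loop: refit intercept+slope of obs ~ pred on the
# n-1 remaining points via the normal equations, predict the held-out one.
oracle_Q2 <- function(obs, pred) {
  n <- length(obs)
  press <- 0
  for (i in seq_len(n)) {
    x <- pred[-i]
    y <- obs[-i]
    m <- length(x)
    b <- (m * sum(x * y) - sum(x) * sum(y)) / (m * sum(x^2) - sum(x)^2)
    a <- (sum(y) - b * sum(x)) / m
    press <- press + (obs[i] - (a + b * pred[i]))^2
  }
  1 - press / sum((obs - mean(obs))^2)
}

# Explicit through-origin regression for one direction of the Roy-Kar metric.
oracle_rm2_dir <- function(y, x) {
  r2 <- oracle_r(x, y)^2
  k <- sum(x * y) / sum(x * x)
  r02 <- 1 - sum((y - k * x)^2) / sum((y - mean(y))^2)
  r2 * (1 - sqrt(abs(r2 - r02)))
}

oracle_Rm2 <- function(obs, pred) {
  (oracle_rm2_dir(obs, pred) + oracle_rm2_dir(pred, obs)) / 2
}

oracle_MAE <- function(obs, pred) sum(abs(obs - pred)) / length(obs)

# Fisher ratio from explicit regression sums of squares.
oracle_F <- function(obs, pred) {
  n <- length(obs)
  b <- (n * sum(pred * obs) - sum(pred) * sum(obs)) /
    (n * sum(pred^2) - sum(pred)^2)
  a <- (sum(obs) - b * sum(pred)) / n
  fitted <- a + b * pred
  ssreg <- sum((fitted - mean(obs))^2)
  ssres <- sum((obs - fitted)^2)
  (ssreg / 1) / (ssres / (n - 2))
}

oracle_IIC <- function(obs, calc) {
  r <- oracle_r(obs, calc)
  resid <- obs - calc
  neg <- resid[resid < 0]
  pos <- resid[resid >= 0]
  if (length(neg) == 0L || length(pos) == 0L) return(0)
  mneg <- sum(abs(neg)) / length(neg)
  mpos <- sum(abs(pos)) / length(pos)
  r * min(mneg, mpos) / max(mneg, mpos)
}

# Explicit attribute-defect computation by counting loops over a dataset.
oracle_defect_table <- function(dataset, split) {
  per_record <- lapply(seq_len(nrow(dataset)), function(i) {
    conds <- vapply(qs_features(), function(f) dataset[[f]][i], "")
    extract_attributes(dataset$smiles[i], conds)
  })
  names(per_record) <- dataset$record_id
  attrs <- sort(unique(unlist(lapply(per_record, `[[`, "attribute"))))
  count_in <- function(ids, a) {
    sum(vapply(ids, function(id) a %in% per_record[[id]]$attribute, TRUE))
  }
  sizes <- c(length(split$active), length(split$passive),
             length(split$calibration))
  out <- data.frame(attribute = attrs, d_k = NA_real_)
  for (j in seq_along(attrs)) {
    a <- attrs[j]
    nf <- count_in(split$active, a)
    nf1 <- count_in(split$passive, a)
    nf2 <- count_in(split$calibration, a)
    p <- nf / sizes[1]; p1 <- nf1 / sizes[2]; p2 <- nf2 / sizes[3]
    t1 <- if (nf + nf1 > 0) abs(p - p1) / (nf + nf1) else 0
    t2 <- if (nf + nf2 > 0) abs(p - p2) / (nf + nf2) else 0
    t3 <- if (nf1 + nf2 > 0) abs(p1 - p2) / (nf1 + nf2) else 0
    out$d_k[j] <- t1 + t2 + t3
  }
  out
}
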