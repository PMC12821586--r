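# Exact-correlation construction: returns y with cor(y, x) == rho
# (up to floating point) by mixing the standardized x with an
# orthogonal standardized residual.
vector_with_cor <- function(x, rho) {
  n <- length(x)
  sx <- (x - mean(x)) / stats::sd(x)
  set.seed(99)
  e <- stats::rnorm(n)
  e <- e - mean(e) - sx * sum((e - mean(e)) * sx) / (n - 1)
  se <- e / stats::sd(e)
  rho * sx + sqrt(1 - rho^2) * se
}

test_that("rare-attribute classification is strict at the threshold", {
  freq <- c(a = 2, b = 3, c = 10, d = 0)
  expect_setequal(classify_rare(freq, 3), c("a", "d"))
  expect_length(classify_rare(freq, 1), 1L)  # only the absent attribute
  expect_setequal(classify_rare(freq, 1), "d")
  expect_false("b" %in% classify_rare(freq, 3))  # freq == T is not rare
  expect_error(classify_rare(freq, 0), "positive")
})

test_that("the descriptor sums weights over attribute instances", {
  ds <- toy_dataset("CCO", pld50 = 1)
  out <- extract_attributes("CCO", fix_conds())
  m <- sum(out$count)
  w1 <- stats::setNames(rep(1, nrow(out)), out$attribute)
  expect_equal(dcw(ds, w1), m)
  expect_equal(dcw(ds, stats::setNames(rep(0, nrow(out)), out$attribute)), 0)
  # hand-set weights: 2*C + O + CC-pair + CO-pair + 6 conditions at 0.1
  w <- c(0.5, 1, 0.25, 0.25, rep(0.1, 6))
  names(w) <- c("C...........", "O...........", "C...C.......",
                "O...C.......",
                vapply(paste0(qs_features(), "1"), render_attribute, "",
                       kind = "condition"))
  names(w)[names(w) == "LS1........."] <- render_attribute("LSA", "condition")
  expect_equal(dcw(ds, w), 2 * 0.5 + 1 + 0.25 + 0.25 + 0.6)
})

test_that("TF0 combines the two training correlations with a gap penalty", {
  d_a <- as.numeric(1:10)
  y_a <- 2 * d_a + 1                      # R_AT = 1
  d_p <- as.numeric(1:10)
  y_p <- vector_with_cor(d_p, 0.8)        # R_PT = 0.8
  expect_equal(tf0(y_a, d_a, y_p, d_p, dr_weight = 0.1), 1.78,
               tolerance = 1e-12)
  # equal correlations: gap vanishes, TF0 = 2r
  expect_equal(tf0(y_p, d_p, y_p, d_p), 2 * stats::cor(y_p, d_p),
               tolerance = 1e-12)
  # anti-correlated on both sets
  expect_equal(tf0(-d_a, d_a, -d_p, d_p), -2, tolerance = 1e-12)
  # zero-variance descriptor yields the worst-possible sentinel
  expect_true(tf0(y_a, rep(1, 10), y_p, d_p) < -1e100)
})

test_that("TF0 is invariant under positive affine rescaling of the descriptor", {
  set.seed(31)
  d_a <- stats::rnorm(20); y_a <- stats::rnorm(20)
  d_p <- stats::rnorm(20); y_p <- stats::rnorm(20)
  expect_equal(tf0(y_a, 3 * d_a + 7, y_p, 0.2 * d_p - 1),
               tf0(y_a, d_a, y_p, d_p), tolerance = 1e-12)
})

test_that("IIC equals r for symmetric residuals and 0 for one-sided ones", {
  set.seed(7)
  calc <- stats::rnorm(12)
  obs <- calc + rep(c(-0.3, 0.3), 6)      # MAE- == MAE+ exactly
  expect_equal(iic(obs, calc), stats::cor(obs, calc), tolerance = 1e-12)
  obs2 <- calc + stats::runif(12, 0.1, 1) # every residual positive
  expect_equal(iic(obs2, calc), 0)
  expect_equal(iic(calc - stats::runif(12, 0.1, 1), calc), 0)
})

test_that("IIC matches a brute-force oracle on a toy six-point set", {
  obs <- c(1.0, 2.1, 2.9, 4.2, 5.1, 5.8)
  calc <- c(1.3, 1.8, 3.2, 4.0, 5.5, 5.6)
  expect_equal(iic(obs, calc), oracle_IIC(obs, calc), tolerance = 1e-12)
})

test_that("TF1 adds the weighted calibration IIC to TF0", {
  set.seed(13)
  d_a <- stats::rnorm(15); y_a <- d_a + 0.3 * stats::rnorm(15)
  d_p <- stats::rnorm(15); y_p <- d_p + 0.3 * stats::rnorm(15)
  d_c <- stats::rnorm(15); y_c <- d_c + 0.3 * stats::rnorm(15)
  expect_equal(tf1(y_a, d_a, y_p, d_p, y_c, d_c, iic_weight = 0),
               tf0(y_a, d_a, y_p, d_p), tolerance = 1e-12)
  # oracle composition: refit the active-set line, predict calibration
  n <- 15
  b <- (n * sum(d_a * y_a) - sum(d_a) * sum(y_a)) /
    (n * sum(d_a^2) - sum(d_a)^2)
  a <- (sum(y_a) - b * sum(d_a)) / n
  expect_equal(tf1(y_a, d_a, y_p, d_p, y_c, d_c),
               tf0(y_a, d_a, y_p, d_p) +
                 0.3 * oracle_IIC(y_c, a + b * d_c),
               tolerance = 1e-12)
})

test_that("blocked attributes keep weight zero and never reach the descriptor", {
  g <- generate_dataset(generator_spec(n_records = 80, seed = 14))
  sp <- random_split(g$dataset, seed = 2)
  m <- optimize_weights(g$dataset, sp,
                        optimizer_config(threshold = 5, n_epochs = 3,
                                         seed = 6))
  expect_true(length(m$blocked) > 0)
  expect_true(all(m$weights[m$blocked] == 0))
  X <- attribute_matrix(g$dataset)$counts
  w_free <- m$weights[setdiff(names(m$weights), m$blocked)]
  expect_equal(dcw(X, m$weights), dcw(X, w_free))
})

test_that("zero perturbation leaves the target flat across epochs", {
  g <- generate_dataset(generator_spec(n_records = 60, seed = 15))
  sp <- random_split(g$dataset, seed = 2)
  m <- optimize_weights(g$dataset, sp,
                        optimizer_config(n_epochs = 4, delta = 0, seed = 3))
  expect_equal(length(unique(m$trace$tf)), 1L)
})

test_that("the accepted-state trace is monotone non-decreasing", {
  g <- generate_dataset(generator_spec(n_records = 80, seed = 16))
  sp <- random_split(g$dataset, seed = 5)
  m <- optimize_weights(g$dataset, sp,
                        optimizer_config(n_epochs = 6, seed = 4))
  expect_true(all(diff(m$trace$tf) >= 0))
})

test_that("optimization is reproducible from the config seed", {
  g <- generate_dataset(generator_spec(n_records = 60, seed = 17))
  sp <- random_split(g$dataset, seed = 2)
  cfg <- optimizer_config(n_epochs = 3, seed = 77)
  m1 <- optimize_weights(g$dataset, sp, cfg)
  m2 <- optimize_weights(g$dataset, sp, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$trace, m2$trace)
})

test_that("a single planted linear signal is recovered within a few epochs", {
  # endpoint exactly 2 * (number of C tokens): a perfect linear optimum exists
  smiles <- vapply(1:16, function(k) strrep("C", k), "")
  ds <- toy_dataset(smiles, pld50 = 2 * (1:16))
  sp <- manual_split(ds$record_id[c(1, 5, 9, 13)],
                     ds$record_id[c(2, 6, 10, 14)],
                     ds$record_id[c(3, 7, 11, 15)],
                     ds$record_id[c(4, 8, 12, 16)])
  m <- optimize_weights(ds, sp, optimizer_config(threshold = 1,
                                                 n_epochs = 8, seed = 2))
  expect_gt(utils::tail(m$trace$r2_active, 1), 0.98)
})

test_that("the weight table orders attributes by active-training frequency", {
  g <- generate_dataset(generator_spec(n_records = 50, seed = 18))
  sp <- random_split(g$dataset, seed = 3)
  m <- optimize_weights(g$dataset, sp, optimizer_config(n_epochs = 2,
                                                        seed = 1))
  wt <- weight_table(m)
  expect_true(all(diff(wt$n_active) <= 0))
  expect_true(all(wt$weight[wt$blocked] == 0))
  expect_setequal(wt$attribute, names(m$weights))
})
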