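test_that("the endpoint regression matches the normal-equations oracle", {
  d <- c(0.5, 1.2, 1.9, 3.1, 4.0)
  y <- c(0.9, 1.8, 3.2, 4.9, 6.1)
  fit <- fit_regression(d, y)
  n <- 5
  b <- (n * sum(d * y) - sum(d) * sum(y)) / (n * sum(d^2) - sum(d)^2)
  a <- (sum(y) - b * sum(d)) / n
  expect_equal(fit$C1, b, tolerance = 1e-12)
  expect_equal(fit$C0, a, tolerance = 1e-12)
  expect_equal(predict(fit, d), a + b * d, tolerance = 1e-12)
  # exact line: zero residuals
  fit2 <- fit_regression(d, 3 * d - 1)
  expect_equal(predict(fit2, d), 3 * d - 1, tolerance = 1e-10)
  # slope sign follows the correlation sign
  fit3 <- fit_regression(d, -y)
  expect_lt(fit3$C1, 0)
  expect_error(fit_regression(rep(2, 5), y), "constant")
  expect_error(fit_regression(d[1:2], y[1:2]), "at least 3")
})

test_that("perfect and shifted predictions produce the expected battery", {
  obs <- c(0.2, 1.1, 1.9, 3.0, 4.2, 5.1)
  st <- compute_statistics(obs, obs)
  expect_equal(st$D, 1)
  expect_equal(st$CCC, 1)
  expect_equal(st$MAE, 0)
  expect_equal(st$Q2, 1)
  st2 <- compute_statistics(obs, obs + 1)
  expect_equal(st2$D, 1)
  expect_lt(st2$CCC, 1)   # concordance penalizes the location shift
  expect_equal(st2$MAE, 1)
})

test_that("all battery metrics match brute-force oracles on a toy set", {
  obs <- c(1.0, 2.1, 2.9, 4.2, 5.1, 5.8)
  pred <- c(1.3, 1.8, 3.2, 4.0, 5.5, 5.6)
  st <- compute_statistics(obs, pred, n_active_attributes = 42L)
  expect_equal(st$D, oracle_D(obs, pred), tolerance = 1e-12)
  expect_equal(st$CCC, oracle_CCC(obs, pred), tolerance = 1e-12)
  expect_equal(st$IIC, oracle_IIC(obs, pred), tolerance = 1e-12)
  expect_equal(st$Q2, oracle_Q2(obs, pred), tolerance = 1e-10)
  expect_equal(st$Rm2_avg, oracle_Rm2(obs, pred), tolerance = 1e-12)
  expect_equal(st$MAE, oracle_MAE(obs, pred), tolerance = 1e-12)
  expect_equal(st$F, oracle_F(obs, pred), tolerance = 1e-10)
  expect_equal(st$Na, 42L)
  expect_equal(st$n, 6L)
})

test_that("degenerate variance is flagged rather than propagated", {
  st <- compute_statistics(rep(1, 5), 1:5)
  expect_true(is.na(st$D))
  expect_match(attr(st, "degenerate"), "variance")
  expect_equal(st$MAE, mean(abs(rep(1, 5) - 1:5)))
})

test_that("concordance is bounded by |r| and equals r for matched moments", {
  set.seed(21)
  for (i in 1:25) {
    obs <- stats::rnorm(15)
    pred <- 0.7 * obs + 0.5 * stats::rnorm(15)
    st <- compute_statistics(obs, pred)
    r <- stats::cor(obs, pred)
    expect_lte(st$CCC, abs(r) + 1e-12)
    # matching location and scale exactly: CCC collapses to r
    pred_m <- (pred - mean(pred)) / stats::sd(pred) * stats::sd(obs) +
      mean(obs)
    expect_equal(compute_statistics(obs, pred_m)$CCC, stats::cor(obs, pred_m),
                 tolerance = 1e-12)
  }
})

test_that("LOO Q2 never exceeds D on the same set and reordering is neutral", {
  set.seed(22)
  for (i in 1:20) {
    obs <- stats::rnorm(12)
    pred <- 0.8 * obs + 0.4 * stats::rnorm(12)
    st <- compute_statistics(obs, pred)
    expect_lte(st$Q2, st$D + 1e-12)
    perm <- sample(12)
    st_p <- compute_statistics(obs[perm], pred[perm])
    expect_equal(st_p, st, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("subgroup performance reproduces global metrics for one group", {
  g <- generate_dataset(generator_spec(n_records = 60, seed = 23))
  ds <- g$dataset
  pred <- stats::setNames(ds$pld50 + stats::rnorm(60, 0, 0.2),
                          ds$record_id)
  ds$LS <- "A"
  class(ds) <- class(g$dataset)
  tab <- subgroup_performance(ds, pred, by = "LS")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$R2, stats::cor(ds$pld50, pred)^2, tolerance = 1e-12)
  expect_equal(tab$RMSE, sqrt(mean((ds$pld50 - pred)^2)), tolerance = 1e-12)
})

test_that("small subgroups are flagged but still reported", {
  conds <- rbind(fix_conds(SP = "1"), fix_conds(SP = "1"),
                 fix_conds(SP = "1"), fix_conds(SP = "1"),
                 fix_conds(SP = "2"), fix_conds(SP = "2"))
  ds <- toy_dataset(c("CC", "CO", "CN", "CS", "CCC", "COC"),
                    pld50 = c(1, 2, 3, 4, 5, 6), conds = conds)
  pred <- stats::setNames(c(1.1, 2.2, 2.8, 4.1, 5.3, 5.8), ds$record_id)
  tab <- subgroup_performance(ds, pred, by = "SP")
  expect_equal(tab$n, c(4L, 2L))
  expect_equal(tab$too_few, c(FALSE, TRUE))
  g2 <- tab[tab$group == "2", ]
  expect_equal(g2$RMSE, sqrt(mean(c(0.3, 0.2)^2)), tolerance = 1e-12)
})

test_that("per-group metrics match direct per-group computation", {
  g <- generate_dataset(generator_spec(n_records = 100, seed = 24))
  ds <- g$dataset
  pred <- stats::setNames(ds$pld50 + stats::rnorm(100, 0, 0.3),
                          ds$record_id)
  tab <- subgroup_performance(ds, pred, by = "OB")
  for (i in seq_len(nrow(tab))) {
    sel <- ds$OB == tab$group[i]
    expect_equal(tab$R2[i], stats::cor(ds$pld50[sel], pred[sel])^2,
                 tolerance = 1e-12)
    expect_equal(tab$RMSE[i], sqrt(mean((ds$pld50[sel] - pred[sel])^2)),
                 tolerance = 1e-12)
  }
})
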