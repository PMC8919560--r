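test_that("stage means honour windows and minimum-data rules", {
  dim <- seq(1, 430, length.out = 30)
  sm <- stage_means(round(dim), rep(100, 30))
  expect_equal(sm$means[["mean_complete"]], 100)

  # 27 records in the later window: missing with reason
  d2 <- c(1:20, 75:101)
  sm2 <- stage_means(d2, rep(5, length(d2)))
  expect_equal(sum(d2 >= 75 & d2 <= 450), 27)
  expect_true(is.na(sm2$means[["mean_later"]]))
  expect_equal(sm2$reasons[["mean_later"]], "min_data")

  sm3 <- stage_means(-14:-8, rep(-50, 7))
  expect_equal(sm3$means[["mean_prepartum"]], -50)
  expect_true(is.na(sm3$means[["mean_complete"]]))
})

test_that("ln_variance follows the two-point value and the scale law", {
  expect_equal(ln_variance(c(-1, 1)), log(2))
  set.seed(1)
  e <- rnorm(200, 0, 50)
  expect_equal(ln_variance(10 * e) - ln_variance(e), log(100))
  expect_equal(ln_variance(7 * e) - ln_variance(e), 2 * log(7))
  expect_true(is.na(ln_variance(rep(3, 10))))
  expect_equal(attr(ln_variance(rep(3, 10)), "reason"), "degenerate")
})

test_that("lag-1 autocorrelation matches its definitional oracle", {
  # consecutive days: direct formula vs explicit-loop oracle to 1e-12
  e <- as.numeric(1:50)
  expect_equal(lag1_autocorrelation(1:50, e), lag1_oracle(1:50, e),
               tolerance = 1e-13)
  set.seed(2)
  for (k in 1:20) {
    n <- sample(20:120, 1)
    dim <- sort(sample(1:200, n))
    e <- rnorm(n)
    r <- lag1_autocorrelation(dim, e, min_pairs = 1L)
    expect_equal(r, max(-1, min(1, lag1_oracle(dim, e))), tolerance = 1e-12)
  }
  # alternating series: exactly -(n-1)/n under this estimator
  alt <- rep(c(1, -1), 50)
  expect_equal(lag1_autocorrelation(1:100, alt), -99 / 100, tolerance = 1e-12)
  # a hole contributes no pairs
  dim <- c(1:10, 14:23)
  e2 <- rnorm(20)
  expect_equal(lag1_autocorrelation(dim, e2), lag1_oracle(dim, e2),
               tolerance = 1e-12)
  expect_true(is.na(lag1_autocorrelation(c(1, 5, 9, 13), rnorm(4))))
  expect_true(is.na(lag1_autocorrelation(1:10, rep(2, 10))))
})

test_that("mean negative residuals averages the strictly negative ones", {
  expect_equal(mean_negative_residuals(c(-2, -4, 5)), -3)
  expect_equal(mean_negative_residuals(c(-1, -1, -1, 9)), -1)
  expect_equal(mean_negative_residuals(c(-1, 0, 1)), -1)  # zero is not negative
  expect_true(is.na(mean_negative_residuals(c(0, 1, 2))))
})

test_that("drop detection matches the brute-force window scan", {
  # constructed cases
  e <- rep(1, 200); e[50:61] <- -1
  dr <- detect_step_drops(1:200, e)
  expect_equal(dr$n_drops, 1L)
  expect_equal(dr$n_drops_per_100d, 0.5)
  expect_equal(dr$mean_neg_residuals_in_drops, -1)

  e2 <- c(rep(-1, 9), 1, rep(-1, 10), rep(1, 20))
  expect_equal(detect_step_drops(seq_along(e2), e2)$n_drops, 1L)

  e3 <- c(rep(-1, 25), rep(1, 15))
  expect_equal(detect_step_drops(seq_along(e3), e3)$n_drops, 1L)

  # a missing calendar day breaks a run
  dim4 <- c(1:5, 7:12)
  e4 <- rep(-1, 11)
  expect_equal(detect_step_drops(dim4, e4)$n_drops, 0L)

  # random sign sequences against the every-window oracle
  set.seed(3)
  for (k in 1:100) {
    n <- sample(15:60, 1)
    dim <- sort(sample(1:(n + 10), n))
    e <- sample(c(-1, 1), n, TRUE, prob = c(0.75, 0.25)) * runif(n, 0.5, 2)
    got <- detect_step_drops(dim, e)
    want <- drop_scan_oracle(dim, e)
    expect_equal(got$n_drops, want$n_drops)
    if (want$n_drops > 0)
      expect_equal(got$mean_neg_residuals_in_drops, want$mean_in_drops,
                   tolerance = 1e-12)
  }
})

test_that("deeper injected events never weaken the deviation indicators", {
  set.seed(4)
  dim <- 1:300
  noise <- rnorm(300, 0, 200)
  prev_mnr <- 0
  prev_drops <- -1
  for (depth in c(0, -300, -600, -1200, -2400)) {
    y <- noise
    y[100:115] <- y[100:115] + depth
    qf <- fit_quantile_curve(dim, y)
    mnr <- mean_negative_residuals(qf$residuals)
    dr <- detect_step_drops(dim, qf$residuals)
    expect_lte(mnr, prev_mnr + 1e-9)
    expect_gte(dr$n_drops, prev_drops)
    prev_mnr <- mnr
    prev_drops <- dr$n_drops
  }
})

test_that("outlier screening is single-pass, per parity, with a kept boundary", {
  ind <- data.table::data.table(cow_id = 1:101, parity = 1L,
                                mean_complete = c(rep(0, 100), 10))
  ind$mean_complete[1:100] <- rnorm(100, 0, 1)
  s <- stats::sd(ind$mean_complete)
  m <- mean(ind$mean_complete)
  out <- remove_indicator_outliers(ind, columns = "mean_complete")
  if (abs(10 - m) > 4 * s) {
    expect_true(is.na(out$indicators$mean_complete[101]))
    expect_equal(nrow(out$log), 1L)
  }
  # all equal: nothing removed
  ind2 <- data.table::data.table(cow_id = 1:10, parity = 1L, ln_var = 5)
  expect_equal(nrow(remove_indicator_outliers(ind2, columns = "ln_var")$log), 0L)
  # exactly mean + 4 SD is kept ("more than 4 times"), just beyond is removed
  set.seed(5)
  v <- rnorm(50)
  g <- function(x) { w <- c(v, x); (x - mean(w)) - 4 * stats::sd(w) }
  x0 <- stats::uniroot(g, c(mean(v), mean(v) + 20 * stats::sd(v)),
                       tol = 1e-12)$root
  ind4 <- data.table::data.table(cow_id = 1:51, parity = 1L,
                                 ln_var = c(v, x0 - 1e-6 * stats::sd(v)))
  out4 <- remove_indicator_outliers(ind4, columns = "ln_var")
  expect_false(is.na(out4$indicators$ln_var[51]))
  ind5 <- data.table::data.table(cow_id = 1:51, parity = 1L,
                                 ln_var = c(v, x0 + 0.05 * stats::sd(v)))
  out5 <- remove_indicator_outliers(ind5, columns = "ln_var")
  expect_true(is.na(out5$indicators$ln_var[51]))
})

test_that("indicator table carries reasons and obeys invariants", {
  cfg <- tiny_config()
  sim <- simulate_herd(cfg, seed = 22)
  pipe <- run_resilience_pipeline(sim)
  ind <- pipe$indicators
  ok <- !is.na(ind$r_auto)
  expect_true(all(ind$r_auto[ok] >= -1 & ind$r_auto[ok] <= 1))
  expect_true(all(ind$n_drops_per_100d[!is.na(ind$n_drops_per_100d)] >= 0))
  expect_true(all(ind$mean_neg_residuals[!is.na(ind$mean_neg_residuals)] <= 0))
  expect_true(all(
    ind$mean_neg_residuals_in_drops[!is.na(ind$mean_neg_residuals_in_drops)] <= 0))
  # zero drops => drop-mean missing with its reason, count 0
  zero <- which(!is.na(ind$n_drops_per_100d) & ind$n_drops_per_100d == 0)
  if (length(zero)) {
    expect_true(all(is.na(ind$mean_neg_residuals_in_drops[zero])))
    expect_true(all(ind$reason_mean_neg_residuals_in_drops[zero] == "no_drops"))
  }
  # short lactations miss the fluctuation indicators with reason min_data
  short <- which(ind$n_lactation_records < 28)
  if (length(short))
    expect_true(all(ind$reason_ln_var[short] == "min_data"))
})
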