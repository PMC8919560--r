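test_that("variance ratios follow their definitions", {
  r <- derive_ratios(c(sigma2_a = 1, sigma2_pe = 1, sigma2_e = 2))
  expect_equal(r$h2, 0.25)
  expect_equal(r$repeatability, 0.5)
  r2 <- derive_ratios(c(sigma2_a = 0.3, sigma2_pe = 0, sigma2_e = 0.7))
  expect_equal(r2$h2, r2$repeatability)
  set.seed(1)
  for (k in 1:20) {
    v <- runif(3)
    r3 <- derive_ratios(c(sigma2_a = v[1], sigma2_pe = v[2], sigma2_e = v[3]))
    expect_lte(r3$h2, r3$repeatability)
    expect_lte(r3$repeatability, 1)
  }
  expect_error(derive_ratios(c(sigma2_a = 0, sigma2_pe = 0, sigma2_e = 0)),
               "zero phenotypic")
})

test_that("REML equals closed-form ANOVA on a balanced half-sib design", {
  ped <- simulate_pedigree(40, 15, seed = 3)
  dat <- simulate_repeatability_phenotypes(ped, sigma2_a = 4, sigma2_pe = 0,
                                           sigma2_e = 6, n_records = 1, seed = 11)
  fit <- fit_univariate_repeatability(dat, "y", ped, fixed = ~1,
                                      include_pe = FALSE, se = FALSE)
  dat$sire <- ped$sire[match(dat$animal, ped$animal)]
  av <- stats::anova(stats::lm(y ~ factor(sire), dat))
  k <- 15
  s2s <- (av["factor(sire)", "Mean Sq"] - av["Residuals", "Mean Sq"]) / k
  expect_gt(s2s, 0)  # interior optimum, where the identity holds
  expect_equal(unname(fit$varcomp["sigma2_a"]), 4 * s2s, tolerance = 1e-6)
  expect_equal(unname(fit$varcomp["sigma2_e"]),
               av["Residuals", "Mean Sq"] - 3 * s2s, tolerance = 1e-6)
  # sire-model heritability identity on the same data
  h2_anova <- 4 * s2s / (s2s + av["Residuals", "Mean Sq"])
  expect_equal(fit$h2, h2_anova, tolerance = 1e-5)
})

test_that("null additive variance is recovered as ~zero heritability", {
  ped <- simulate_pedigree(40, 10, seed = 4)
  dat <- simulate_repeatability_phenotypes(ped, sigma2_a = 0, sigma2_pe = 3,
                                           sigma2_e = 7, n_records = 3, seed = 5)
  fit <- fit_univariate_repeatability(dat, "y", ped, fixed = ~1, se = FALSE)
  expect_lt(fit$h2, 0.05)
  expect_equal(fit$repeatability, 0.3, tolerance = 0.08)
})

test_that("single-record designs refuse the permanent-environment term", {
  ped <- simulate_pedigree(10, 5, seed = 6)
  dat <- simulate_repeatability_phenotypes(ped, 1, 0, 1, n_records = 1, seed = 7)
  expect_error(fit_univariate_repeatability(dat, "y", ped, fixed = ~1),
               "not separable")
})

test_that("univariate REML recovers moderate-heritability truth", {
  # step-level regime: h2 = 0.45, repeatability = 0.74
  ped <- simulate_pedigree(100, 10, seed = 8)
  dat <- simulate_repeatability_phenotypes(ped, 0.45, 0.29, 0.26,
                                           n_records = 3, seed = 9)
  fit <- fit_univariate_repeatability(dat, "y", ped, fixed = ~ factor(parity))
  expect_lt(abs(fit$h2 - 0.45), 3.5 * fit$se$h2 + 0.02)
  expect_lt(abs(fit$repeatability - 0.74), 0.06)
  expect_gt(fit$se$h2, 0)
  # EBV track true breeding values
  tb <- dat[!duplicated(dat$animal), ]
  expect_gt(stats::cor(fit$ebv[as.character(tb$animal)], tb$true_bv), 0.5)
})

test_that("bivariate REML recovers genetic and PE correlations", {
  # r_g = 0.9, r_pe = 0.3 on half-sib families
  ped <- simulate_pedigree(100, 15, seed = 10)  # 1,500 cows
  G0 <- matrix(c(1, 0.9 * sqrt(0.8), 0.9 * sqrt(0.8), 0.8), 2)
  P0 <- matrix(c(0.6, 0.3 * sqrt(0.3), 0.3 * sqrt(0.3), 0.5), 2)
  R0 <- matrix(c(1.2, 0.1, 0.1, 1.0), 2)
  set.seed(12)
  n <- nrow(ped)
  s <- ifelse(is.na(match(ped$sire, ped$animal)), 0L, match(ped$sire, ped$animal))
  d <- ifelse(is.na(match(ped$dam, ped$animal)), 0L, match(ped$dam, ped$animal))
  z <- matrix(rnorm(2 * n), n, 2) %*% chol(G0)
  a <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    if (s[i] == 0L && d[i] == 0L) { a[i, ] <- z[i, ]; next }
    a[i, ] <- (a[max(s[i], 1L), ] * (s[i] > 0) + a[max(d[i], 1L), ] * (d[i] > 0)) / 2 +
      sqrt(0.5) * z[i, ]
  }
  cows <- which(ped$sex == "F" & ped$generation == 1L)
  pe <- matrix(rnorm(2 * length(cows)), ncol = 2) %*% chol(P0)
  recs <- lapply(1:3, function(k) {
    e <- matrix(rnorm(2 * length(cows)), ncol = 2) %*% chol(R0)
    data.frame(animal = ped$animal[cows], parity = k,
               t1 = a[cows, 1] + pe[, 1] + e[, 1],
               t2 = a[cows, 2] + pe[, 2] + e[, 2])
  })
  dat <- do.call(rbind, recs)
  fit <- fit_bivariate_repeatability(dat, c("t1", "t2"), ped, fixed = ~1,
                                     se = TRUE, reltol = 1e-8)
  expect_lt(abs(fit$r_g - 0.9), 3 * fit$se_r_g + 0.03)
  expect_gt(fit$r_g, 0.6)
  expect_lt(abs(fit$r_pe - 0.3), 3 * fit$se_r_pe + 0.03)
  expect_equal(fit$G[1, 1], 1, tolerance = 0.35)
  expect_equal(fit$R[1, 2], 0.1, tolerance = 0.15)

  # a trait paired with a jittered copy of itself pegs r_g at the boundary
  dat$t3 <- dat$t1 + rnorm(nrow(dat), 0, 0.05)
  fit2 <- fit_bivariate_repeatability(dat, c("t1", "t3"), ped, fixed = ~1,
                                      se = FALSE, reltol = 1e-7)
  expect_gt(fit2$r_g, 0.97)
  expect_true(fit2$boundary)
})

test_that("fixed-effect design builds full rank with pooled small cells", {
  set.seed(14)
  n <- 300
  dt <- data.table::data.table(
    parity = sample(1:3, n, TRUE),
    age_at_calving_days = sample(700:1500, n, TRUE),
    calving_date = as.Date("2017-01-01") + sample(0:900, n, TRUE),
    herd = sample(1:5, n, TRUE),
    first_dim = sample(1:30, n, TRUE))
  X <- repeatability_design(dt)
  expect_equal(Matrix::rankMatrix(as.matrix(X))[[1]], ncol(X))
  expect_equal(nrow(X), n)
})
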