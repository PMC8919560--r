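test_that("simulation is deterministic given seed and config", {
  cfg <- tiny_config()
  s1 <- simulate_herd(cfg, seed = 3)
  s2 <- simulate_herd(cfg, seed = 3)
  for (nm in c("steps", "calvings", "inseminations", "pedigree", "diseases"))
    expect_identical(as.data.frame(s1[[nm]]), as.data.frame(s2[[nm]]))
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  write_step_dataset(s1, d1)
  write_step_dataset(s2, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("conception sits one gestation before the next calving", {
  cfg <- tiny_config()
  pop <- simulate_population(simulate_pedigree(8, 4, seed = 2), cfg, seed = 5)
  lac <- pop$lactations[!is.na(pop$lactations$next_calving_date), ]
  expect_true(nrow(lac) > 0)
  expect_true(all(lac$next_calving_date - lac$conception_date == 278))
  # open lactations propagate unknown pregnancy downstream
  open <- pop$lactations[is.na(pop$lactations$next_calving_date), ]
  expect_true(nrow(open) > 0)
  expect_true(all(is.na(open$conception_date)))
})

test_that("true breeding values follow the pedigree covariance structure", {
  # zero additive variance collapses breeding values to zero
  cfg0 <- tiny_config()
  cfg0$variances$level["a"] <- 0
  cfg0$variances$variability["a"] <- 0
  cfg0$variances$droprate["a"] <- 0
  ped <- simulate_pedigree(5, 3, seed = 1)
  eff0 <- simulate_true_effects(ped, cfg0, seed = 2)
  expect_equal(max(abs(eff0$bv)), 0)

  # midparent expectation: offspring BV averages to the parent mean
  cfg <- tiny_config()
  ped1 <- simulate_pedigree(2, 400, seed = 3)
  eff <- simulate_true_effects(ped1, cfg, seed = 4)
  off <- ped1$animal[ped1$generation == 1L]
  mid <- (eff$bv[as.character(ped1$sire[match(off, ped1$animal)]), "level"] +
          eff$bv[as.character(ped1$dam[match(off, ped1$animal)]), "level"]) / 2
  dev <- eff$bv[as.character(off), "level"] - mid
  expect_lt(abs(mean(dev)) / sqrt(cfg$variances$level["a"]), 0.1)

  # diagonal G: empirical genetic correlations among founders stay near 0
  cfgd <- tiny_config(genetic_correlations = diag(3))
  pedf <- simulate_pedigree(60, 60, seed = 5)  # 3,660 founders
  efff <- simulate_true_effects(pedf, cfgd, seed = 6)
  founders <- pedf$generation == 0L
  cc <- stats::cor(efff$bv[founders, ])
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)

  # non-PSD correlation input is rejected with the eigenvalue named
  bad <- rbind(c(1, 0.99, -0.99), c(0.99, 1, 0.99), c(-0.99, 0.99, 1))
  expect_error(tiny_config(genetic_correlations = bad), "eigenvalue")
})

test_that("step series carry the configured structural effects", {
  cfg <- tiny_config()
  sim <- simulate_herd(cfg, seed = 8)
  expect_true(all(sim$steps$steps >= 0))
  expect_true(is.numeric(attr(sim$steps, "truncation_rate")))
  # grazing vs non-grazing July/January contrast in the true herd-month table
  hm <- sim$herd_month
  gz <- sim$herds$herd[sim$herds$grazing == 1L]
  ng <- sim$herds$herd[sim$herds$grazing == 0L]
  if (length(gz) && length(ng)) {
    contrast <- function(h)
      hm$effect[hm$herd == h & hm$month == 7] - hm$effect[hm$herd == h & hm$month == 1]
    expect_gt(min(sapply(gz, contrast)), max(sapply(ng, contrast)))
  }
  # disease labels only appear for registering herds
  if (nrow(sim$events)) {
    dis <- merge(sim$diseases, sim$lactations[, c("cow_id", "parity", "herd")],
                 by = c("cow_id", "parity"))
    for (dz in c("mastitis", "ketosis", "claw", "uterus")) {
      reg <- sim$herds$herd[sim$herds[[paste0("registers_", dz)]] == 1L]
      expect_true(all(dis$herd[dis[[dz]] == 1L] %in% reg))
    }
  }
})

test_that("an injected disturbance is found by the drop detector", {
  # noiseless constant series with one deep 12-day event
  dim <- 1:200
  y <- rep(0, 200)
  y[60:71] <- -800
  qf <- fit_quantile_curve(dim, y)
  dr <- detect_step_drops(dim, qf$residuals)
  expect_equal(dr$n_drops, 1L)
  expect_equal(dr$drops$start_dim, 60)
  expect_equal(dr$drops$length, 12L)
})

test_that("null drop rate matches the run-statistics oracle for iid noise", {
  # residuals from a tau-quantile fit are negative w.p. ~tau, so iid noise
  # alone produces maximal runs of >= 10 negatives at a rate near
  # (1 - tau) * tau^10 per day; detected drops should sit near that rate,
  # far below the rate once disturbances are added
  set.seed(42)
  n_days <- 0L
  n_drops <- 0L
  for (r in 1:60) {
    dim <- 1:400
    y <- rnorm(400, 0, 650)
    qf <- fit_quantile_curve(dim, y)
    dr <- detect_step_drops(dim, qf$residuals)
    n_days <- n_days + 400L
    n_drops <- n_drops + dr$n_drops
  }
  rate <- 100 * n_drops / n_days
  oracle <- 100 * 0.3 * 0.7^10
  expect_gt(rate, oracle * 0.4)
  expect_lt(rate, oracle * 1.8)
})

test_that("datasets round-trip losslessly and validate their schema", {
  cfg <- tiny_config()
  sim <- simulate_herd(cfg, seed = 9)
  sim$diseases <- sim$diseases[0, ]  # empty table still round-trips
  dir <- file.path(tempdir(), "roundtrip")
  write_step_dataset(sim, dir)
  back <- read_step_dataset(dir)
  expect_equal(as.data.frame(back$steps), as.data.frame(sim$steps),
               ignore_attr = TRUE)
  expect_equal(nrow(back$diseases), 0L)
  expect_equal(as.data.frame(back$pedigree),
               as.data.frame(sim$pedigree), ignore_attr = TRUE)

  # unknown column rejected
  utils::write.csv(cbind(as.data.frame(back$steps), rogue = 1),
                   file.path(dir, "steps.csv"), row.names = FALSE)
  expect_error(read_step_dataset(dir), "unknown column")

  # dangling cow id rejected at write time
  sim2 <- simulate_herd(cfg, seed = 10)
  sim2$steps$cow_id[1] <- 999999L
  expect_error(write_step_dataset(sim2, dir), "referential")
})
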