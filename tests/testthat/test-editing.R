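test_that("partial days rescale by 86400 over measured seconds", {
  expect_equal(rescale_partial_day(500, 43200), 1000L)
  expect_equal(rescale_partial_day(800, 86400), 800L)
  expect_equal(rescale_partial_day(333, 28800), 999L)
  expect_equal(rescale_partial_day(777, NA), 777L)
  expect_error(rescale_partial_day(100, 0), "seconds_measured")
  expect_error(rescale_partial_day(100, 90000), "seconds_measured")
  expect_error(rescale_partial_day(-5, 86400), ">= 0")

  # rescaling preserves the ordering of step rates
  set.seed(1)
  st <- sample(200:3000, 50)
  sec <- sample(20000:86400, 50)
  r <- rescale_partial_day(st, sec)
  rate <- st / sec
  expect_true(all(diff(r[order(rate)]) >= -1))  # integer rounding slack
})

test_that("lactation filters apply the age, interval, parity and breed rules", {
  lac <- data.frame(
    cow_id = 1:8, parity = c(1, 1, 2, 3, 1, 4, 1, 1),
    calving_date = as.Date("2017-01-01") + 0:7,
    age_at_calving_days = c(639, 640, 855, 1070, 700, 1200, 700, 700),
    previous_calving_interval_days = c(NA, NA, 214, 215, NA, NA, NA, NA),
    herdbook_flag = c(1, 1, 1, 1, 0, 1, 1, 1),
    holstein_fraction = c(1, 1, 1, 1, 1, 1, 0.874, 0.875))
  out <- apply_lactation_filters(lac)
  expect_setequal(out$kept$cow_id, c(2, 4, 8))
  reasons <- setNames(out$log$reason, out$log$cow_id)
  expect_equal(reasons[["1"]], "age_at_calving")   # calved before 640 d
  expect_equal(reasons[["3"]], "calving_interval") # 214 < 215
  expect_equal(reasons[["5"]], "herdbook")
  expect_equal(reasons[["6"]], "parity")
  expect_equal(reasons[["7"]], "breed_fraction")   # < 87.5% Holstein
})

test_that("gap trimming removes the neighbours of >= 7 day holes", {
  # days 1-10 then 18-30: 7 missing days, so day 10 and day 18 go
  d <- as.Date("2018-01-01") + c(0:9, 17:29)
  drop <- gap_adjacent(d, gap_days = 7)
  inner <- drop[-c(1, length(drop))]  # series ends are one-sided gaps
  expect_equal(which(inner), c(9, 10))
  # 6 missing days: nothing removed in the interior
  d6 <- as.Date("2018-01-01") + c(0:9, 16:29)
  expect_false(any(gap_adjacent(d6, 7)[-c(1, 24)]))
  # one-sided gap at the series start: only the first record after it goes
  expect_true(gap_adjacent(d6, 7)[1])
  expect_true(gap_adjacent(d6, 7)[24])
})

test_that("pregnancy status follows the reproductive calendar", {
  nxt <- as.Date("2018-06-01")
  datev <- nxt - c(10, 250, 300, 40)
  st <- assign_pregnancy_status(datev, rep(nxt, 4),
                                last_milking_date = rep(nxt - 56, 4))
  expect_equal(st, c("close_up", "pregnant", "not_pregnant", "dry"))
  expect_equal(assign_pregnancy_status(as.Date("2018-01-01"), as.Date(NA)),
               "unknown")
  # 14 days before calving is not yet close-up ("less than 14 days")
  expect_equal(assign_pregnancy_status(nxt - 14, nxt), "pregnant")
  expect_equal(assign_pregnancy_status(nxt - 13, nxt), "close_up")
})

test_that("estrus flagging applies the rolling mean + 2.5 SD rule", {
  base <- rep(c(900, 1100), 5)  # mean 1000, sample SD ~105.41
  mk <- function(day11) data.frame(
    cow_id = 1L, date = as.Date("2018-03-01") + 0:10, dim = 14:24,
    steps = c(base, day11), status = "not_pregnant")
  ins0 <- data.frame(cow_id = integer(0), date = as.Date(character(0)))
  thr <- 1000 + 2.5 * stats::sd(base)
  expect_gt(1300, thr)
  expect_lt(1200, thr)
  expect_true(flag_estrus(mk(1300), ins0)[11])
  expect_false(flag_estrus(mk(1200), ins0)[11])
  # pregnant cows are never threshold-flagged
  rec <- mk(2000)
  rec$status <- "pregnant"
  expect_false(any(flag_estrus(rec, ins0)))
  # fewer than 10 usable preceding records: no threshold flag ...
  rec2 <- mk(5000)[6:11, ]
  expect_false(any(flag_estrus(rec2, ins0)))
  # ... but an insemination day is flagged even before 14 DIM
  rec3 <- mk(900)
  rec3$dim <- 5:15
  ins <- data.frame(cow_id = 1L, date = as.Date("2018-03-01"))
  expect_true(flag_estrus(rec3, ins)[1])
})

test_that("editing reconciles, is idempotent, and respects boundaries", {
  cfg <- tiny_config()
  sim <- simulate_herd(cfg, seed = 12)
  ed <- edit_records(sim)
  # reconciliation: input records = kept + every exclusion reason
  expect_equal(sum(ed$exclusions$n_records), nrow(sim$steps))
  expect_equal(ed$exclusions$n_records[ed$exclusions$Var1 == "none"],
               nrow(ed$records))
  # kept records respect the record-level rules
  expect_true(all(ed$records$steps >= 200))
  expect_true(all(ed$records$dim >= -14 & ed$records$dim <= 450 &
                  ed$records$dim != 0))
  expect_true(all(ed$records$parity %in% 1:3))
  # 199 dropped, 200 kept at the boundary: plant the values on records that
  # survive every other rule (mid-series kept records with whole-day seconds)
  ins_key <- paste(sim$inseminations$cow_id, sim$inseminations$date)
  kept_keys <- ed$records[ed$records$seconds_measured == 86400L &
                          ed$records$dim > 50 & ed$records$dim < 200 &
                          !(paste(ed$records$cow_id, ed$records$date) %in% ins_key), ]
  kk <- kept_keys[1:2, ]
  sim2 <- sim
  sim2$steps <- data.table::copy(sim$steps)
  rows <- match(paste(kk$cow_id, kk$date),
                paste(sim2$steps$cow_id, sim2$steps$date))
  data.table::set(sim2$steps, i = rows, j = "steps", value = c(199L, 200L))
  ed2 <- edit_records(sim2)
  tagged <- ed2$all_records[match(paste(kk$cow_id, kk$date),
                                  paste(ed2$all_records$cow_id,
                                        ed2$all_records$date)), ]
  expect_equal(tagged$excluded_reason[1], "low_count")
  expect_equal(tagged$excluded_reason[2], "none")
  # estrus-flagged records are pregnant-free at flag time (unless inseminated)
  est <- ed$all_records[ed$all_records$excluded_reason == "estrus", ]
  ins_key <- paste(sim$inseminations$cow_id, sim$inseminations$date)
  not_ins <- !(paste(est$cow_id, est$date) %in% ins_key)
  expect_true(all(!est$status[not_ins] %in% c("pregnant", "dry", "close_up")))
  # filters are subsetting and idempotent: re-editing the kept records
  # (as a fresh dataset) removes nothing further except boundary gap effects
  sim3 <- sim
  sim3$steps <- ed$records[, c("cow_id", "date", "steps", "seconds_measured")]
  sim3$steps$seconds_measured <- NA_integer_  # already rescaled
  ed3 <- edit_records(sim3)
  expect_true(nrow(ed3$records) <= nrow(ed$records))
})

test_that("a zero violating-fraction yields no age-filter exclusions", {
  cfg <- tiny_config(fraction_violating_age = 0, fraction_violating_interval = 0)
  sim <- simulate_herd(cfg, seed = 13)
  ed <- edit_records(sim)
  expect_false(any(ed$lactation_log$reason == "age_at_calving"))
  expect_false(any(ed$lactation_log$reason == "calving_interval"))
})
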