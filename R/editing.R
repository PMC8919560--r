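# Record-level editing: partial-day rescaling, inclusion filters, gap
# trimming, pregnancy-status assignment and estrus flagging.

PREG_STATUSES <- c("not_pregnant", "pregnant", "dry", "close_up", "unknown")

#' Rescale partial measuring days to whole-day step counts
#'
#' Days on which the accelerometer measured for less than 86,400 seconds are
#' extrapolated to a whole day by multiplying the recorded steps by
#' `86400 / seconds_measured`, rounded to the nearest integer. Unknown
#' measuring times are assumed to cover the whole day and left unchanged.
#'
#' @param steps non-negative step counts.
#' @param seconds_measured seconds the device was measuring, in (0, 86400],
#'   or `NA` when unknown.
#' @return integer vector of whole-day step counts.
#' @export
rescale_partial_day <- function(steps, seconds_measured) {
  if (any(steps < 0, na.rm = TRUE)) stop("steps must be >= 0")
  bad <- !is.na(seconds_measured) &
    (seconds_measured <= 0 | seconds_measured > 86400)
  if (any(bad))
    stop(sprintf("invalid seconds_measured (e.g. %s): must be in (0, 86400] or NA",
                 seconds_measured[which(bad)[1]]))
  fac <- ifelse(is.na(seconds_measured), 1, 86400 / seconds_measured)
  as.integer(round(steps * fac))
}

#' Lactation-level inclusion filters
#'
#' Retains parities 1-3 of herd-book registered cows with a Holstein
#' fraction of at least 87.5% that calved at 640/855/1070 days of age or
#' later (parity 1/2/3) and whose calving interval to the previous lactation
#' was at least 215 days. Filters on missing optional fields are skipped.
#'
#' @param lactations `data.table` with columns `cow_id`, `parity`,
#'   `calving_date`, and optionally `age_at_calving_days`,
#'   `previous_calving_interval_days`, `herdbook_flag`, `holstein_fraction`.
#' @param min_interval,min_holstein,min_age_by_parity rule parameters.
#' @return list with `kept` (retained lactations) and `log` (one row per
#'   excluded lactation with the first violated rule).
#' @export
apply_lactation_filters <- function(lactations,
                                    min_interval = 215,
                                    min_holstein = 0.875,
                                    min_age_by_parity = c(640, 855, 1070)) {
  lac <- data.table::as.data.table(lactations)
  reason <- rep(NA_character_, nrow(lac))
  flag <- function(cond, why) reason[is.na(reason) & !is.na(cond) & cond] <<- why
  flag(!(lac$parity %in% seq_along(min_age_by_parity)), "parity")
  if ("herdbook_flag" %in% names(lac)) flag(lac$herdbook_flag == 0L, "herdbook")
  if ("holstein_fraction" %in% names(lac))
    flag(lac$holstein_fraction < min_holstein, "breed_fraction")
  if ("age_at_calving_days" %in% names(lac)) {
    p <- pmin(pmax(lac$parity, 1L), length(min_age_by_parity))
    flag(lac$age_at_calving_days < min_age_by_parity[p], "age_at_calving")
  }
  if ("previous_calving_interval_days" %in% names(lac))
    flag(lac$previous_calving_interval_days < min_interval, "calving_interval")
  list(kept = lac[is.na(reason), ],
       log = data.table::data.table(cow_id = lac$cow_id[!is.na(reason)],
                                    parity = lac$parity[!is.na(reason)],
                                    reason = reason[!is.na(reason)]))
}

#' Remove records adjacent to long recording gaps
#'
#' For every run of at least `gap_days` consecutive calendar days without a
#' record, the last record before and the first record after the run are
#' dropped: on those days the device was likely being attached or removed
#' and did not measure the whole day. A gap at the start or end of a series
#' has only one existing neighbour, which is removed.
#'
#' @param dates sorted record dates (`Date` or integer days) of one cow.
#' @param gap_days minimum gap length in missing days (default 7).
#' @return logical vector, `TRUE` for records to drop.
#' @export
gap_adjacent <- function(dates, gap_days = 7) {
  n <- length(dates)
  if (n == 0L) return(logical(0))
  d <- as.numeric(dates)
  if (is.unsorted(d)) stop("dates must be sorted")
  gap_after <- c(diff(d) - 1, Inf) >= gap_days   # gap following record i
  gap_before <- c(Inf, diff(d) - 1) >= gap_days  # gap preceding record i
  # Inf marks the one-sided gaps at the series boundaries: the first record
  # after device attachment and the last before removal are always suspect
  drop <- gap_after | gap_before
  drop
}

#' Assign pregnancy status to records
#'
#' Statuses follow the reproductive calendar of each lactation: `unknown`
#' when the next calving date is unknown, `close_up` less than 14 days
#' before the next calving, `dry` after the last milking, `pregnant` within
#' 278 days (gestation length) before the next calving, otherwise
#' `not_pregnant`. Precedence: close_up > dry > pregnant > not_pregnant.
#'
#' @param date record dates.
#' @param next_calving_date,last_milking_date per-record dates (`NA` when
#'   unknown).
#' @param gestation_days gestation length (default 278).
#' @return character vector of statuses.
#' @export
assign_pregnancy_status <- function(date, next_calving_date,
                                    last_milking_date = NULL,
                                    gestation_days = 278) {
  n <- length(date)
  if (is.null(last_milking_date)) last_milking_date <- as.Date(rep(NA, n))
  status <- rep("unknown", n)
  known <- !is.na(next_calving_date)
  before <- as.numeric(next_calving_date - date)
  status[known] <- "not_pregnant"
  status[known & before <= gestation_days] <- "pregnant"
  status[known & !is.na(last_milking_date) & date > last_milking_date &
         date < next_calving_date] <- "dry"
  status[known & before < 14 & before > 0] <- "close_up"
  status
}

# Threshold-based estrus scan for one cow's day-ordered kept records.
# A day is flagged when its (rescaled, uncorrected) step count exceeds the
# mean plus `k` sample standard deviations of the 10 previous kept,
# unflagged records, provided DIM >= 14 and the cow is not pregnant;
# insemination days are always flagged. Flagged days do not enter later
# baseline windows.
estrus_scan <- function(steps, dim, pregnant, inseminated,
                        k = 2.5, window = 10L) {
  n <- length(steps)
  flag <- logical(n)
  buf <- numeric(window)
  cnt <- 0L
  pos <- 0L
  s1 <- 0
  s2 <- 0
  for (i in seq_len(n)) {
    f <- inseminated[i]
    if (!f && cnt >= window && dim[i] >= 14 && !pregnant[i]) {
      m <- s1 / window
      v <- (s2 - s1 * s1 / window) / (window - 1)
      f <- steps[i] > m + k * sqrt(max(v, 0))
    }
    if (f) {
      flag[i] <- TRUE
    } else {
      pos <- pos %% window + 1L
      if (cnt == window) {
        s1 <- s1 - buf[pos]
        s2 <- s2 - buf[pos] * buf[pos]
      } else cnt <- cnt + 1L
      buf[pos] <- steps[i]
      s1 <- s1 + steps[i]
      s2 <- s2 + steps[i] * steps[i]
    }
  }
  flag
}

#' Flag estrus records
#'
#' Applies the activity-spike rule: a record is an estrus record if its step
#' count exceeds the mean plus `k` standard deviations of the `window`
#' previous kept records of that cow (possible only from 14 DIM onwards and
#' when the cow is not pregnant), or if the cow was inseminated that day.
#' Previously flagged records are excluded from later baseline windows.
#'
#' @param records day-ordered `data.table` for one or more cows with columns
#'   `cow_id`, `date`, `dim`, `steps`, `status`.
#' @param inseminations `data.table` with `cow_id`, `date`.
#' @param k threshold multiplier (default 2.5).
#' @param window number of preceding records in the baseline (default 10).
#' @return logical estrus flag aligned with `records`.
#' @export
flag_estrus <- function(records, inseminations, k = 2.5, window = 10L) {
  rec <- data.table::as.data.table(records)
  ins_key <- unique(paste(inseminations$cow_id, inseminations$date))
  insem <- paste(rec$cow_id, rec$date) %in% ins_key
  # pregnancy here means any day within gestation of a known next calving,
  # which includes the dry and close-up periods
  pregnant <- rec$status %in% c("pregnant", "dry", "close_up")
  flag <- logical(nrow(rec))
  for (idx in split(seq_len(nrow(rec)), rec$cow_id)) {
    o <- idx[order(rec$date[idx])]
    flag[o] <- estrus_scan(rec$steps[o], rec$dim[o], pregnant[o], insem[o],
                           k = k, window = window)
  }
  flag
}

#' Apply all record-editing rules to a raw dataset
#'
#' Runs the full editing chain on the tables of a (simulated or read-in)
#' dataset: assigns each step record to a lactation and a day in milk (DIM;
#' records within 14 days before a calving become the pre-partum days
#' -14..-1 of the upcoming lactation), rescales partial measuring days,
#' drops lactations failing the inclusion rules, restricts DIM to the
#' window -14..450, removes sub-200-step device-error days, trims records adjacent to
#' recording gaps of `gap_days` or more, assigns pregnancy status and flags
#' estrus records. Every removed record carries a single exclusion reason
#' and the log reconciles exactly with the input record count.
#'
#' @param dataset list with `steps`, `calvings`, `inseminations`, `dryoff`
#'   tables (see [simulate_herd()] / [read_step_dataset()]).
#' @param min_steps minimum plausible daily step count (default 200).
#' @param max_dim last retained day in milk (default 450).
#' @param gap_days recording-gap threshold in days (default 7).
#' @param estrus_k,estrus_window estrus-rule parameters (default 2.5, 10).
#' @param max_parity last retained parity (default 3).
#' @return list with `records` (kept records: cow_id, date, parity, dim,
#'   steps, seconds_measured, status, herd if available), `all_records`
#'   (including excluded ones with `excluded_reason`), `lactations` (kept),
#'   `lactation_log`, and `exclusions` (record counts by reason).
#' @export
edit_records <- function(dataset,
                         min_steps = 200,
                         max_dim = 450,
                         gap_days = 7,
                         estrus_k = 2.5,
                         estrus_window = 10L,
                         max_parity = 3L) {
  steps <- data.table::as.data.table(dataset$steps)
  calv <- data.table::as.data.table(dataset$calvings)
  data.table::setorder(calv, cow_id, parity)
  n_in <- nrow(steps)

  # lactation metadata: next calving and previous interval from the calving
  # sequence, dry-off dates where recorded
  calv[, `:=`(next_calving_date = data.table::shift(calving_date, type = "lead"),
              next_parity = data.table::shift(parity, type = "lead"),
              previous_calving_interval_days =
                as.numeric(calving_date - data.table::shift(calving_date))),
       by = "cow_id"]
  calv[!is.na(next_parity) & next_parity != parity + 1L,
       `:=`(next_calving_date = as.Date(NA))]
  if (!is.null(dataset$dryoff) && nrow(dataset$dryoff))
    calv <- merge(calv, dataset$dryoff, by = c("cow_id", "parity"),
                  all.x = TRUE, sort = FALSE)
  else calv$last_milking_date <- as.Date(NA)
  if (!is.null(dataset$lactations) && "herd" %in% names(dataset$lactations)) {
    calv <- merge(calv,
                  unique(dataset$lactations[, c("cow_id", "herd")]),
                  by = "cow_id", all.x = TRUE, sort = FALSE)
  } else if (!"herd" %in% names(calv)) calv$herd <- 1L

  # assign each record to a lactation window [calving - 14, next calving -
  # 15]: a record within 14 days before a calving becomes a pre-partum day
  # (DIM -14..-1) of the upcoming lactation, all other records belong to
  # the lactation in progress
  data.table::setorder(steps, cow_id, date)
  win <- data.table::data.table(cow_id = calv$cow_id,
                                date = calv$calving_date - 14L,
                                parity = calv$parity)
  steps$parity <- win[steps, on = c("cow_id", "date"), roll = Inf]$parity
  cal_by <- calv[, c("cow_id", "parity", "calving_date",
                     "previous_calving_interval_days", "age_at_calving_days",
                     "herdbook_flag", "holstein_fraction", "herd")]
  meta <- cal_by[steps, on = c("cow_id", "parity")]
  steps$calving_date <- meta$calving_date
  steps$herd <- meta$herd
  steps$dim <- as.numeric(steps$date - steps$calving_date)

  # reproductive calendar relative to the record date (independent of the
  # window assignment): the next calving after the date, and the dry-off of
  # the lactation in progress on that date
  nxt <- data.table::data.table(cow_id = calv$cow_id, date = calv$calving_date,
                                nxt_cal = calv$calving_date)
  steps$next_calving_date <- nxt[steps, on = c("cow_id", "date"),
                                 roll = -Inf]$nxt_cal
  same_day <- !is.na(steps$next_calving_date) &
    steps$next_calving_date == steps$date
  steps$next_calving_date[same_day] <- as.Date(NA)
  cur <- data.table::data.table(cow_id = calv$cow_id, date = calv$calving_date,
                                last_milking_date = calv$last_milking_date)
  steps$last_milking_date <- cur[steps, on = c("cow_id", "date"),
                                 roll = Inf]$last_milking_date

  steps$steps <- rescale_partial_day(steps$steps, steps$seconds_measured)

  reason <- rep(NA_character_, nrow(steps))
  flag <- function(cond, why) reason[is.na(reason) & !is.na(cond) & cond] <<- why

  # records before the first known lactation or after a cow left the data
  flag(is.na(steps$parity) | is.na(steps$calving_date), "out_of_window")

  lf <- apply_lactation_filters(calv)
  bad_lac <- paste(lf$log$cow_id, lf$log$parity)
  flag(steps$parity > max_parity, "lactation_excluded")
  flag(paste(steps$cow_id, steps$parity) %in% bad_lac, "lactation_excluded")

  flag(steps$dim > max_dim | steps$dim < -14 | steps$dim == 0, "out_of_window")

  # gap trimming on each cow's raw device series (all record dates)
  gapdrop <- logical(nrow(steps))
  for (idx in split(seq_len(nrow(steps)), steps$cow_id))
    gapdrop[idx] <- gap_adjacent(steps$date[idx], gap_days = gap_days)
  flag(gapdrop, "gap_adjacent")

  flag(steps$steps < min_steps, "low_count")

  steps$status <- assign_pregnancy_status(steps$date, steps$next_calving_date,
                                          steps$last_milking_date)

  keep <- is.na(reason)
  est <- logical(nrow(steps))
  est[keep] <- flag_estrus(steps[keep, ], dataset$inseminations,
                           k = estrus_k, window = estrus_window)
  flag(est, "estrus")
  keep <- is.na(reason)

  steps$excluded_reason <- ifelse(is.na(reason), "none", reason)
  out_cols <- c("cow_id", "date", "parity", "dim", "steps",
                "seconds_measured", "status", "herd", "excluded_reason")
  all_records <- steps[, out_cols, with = FALSE]
  records <- all_records[all_records$excluded_reason == "none", ]

  excl <- table(factor(steps$excluded_reason,
                       levels = c("none", "out_of_window", "lactation_excluded",
                                  "gap_adjacent", "low_count", "estrus")))
  stopifnot(sum(excl) == n_in)
  kept_lac <- lf$kept[lf$kept$parity <= max_parity, ]
  list(records = records,
       all_records = all_records,
       lactations = kept_lac,
       lactation_log = lf$log,
       exclusions = as.data.frame(excl, responseName = "n_records",
                                  stringsAsFactors = FALSE))
}
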