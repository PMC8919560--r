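# Synthetic herd generator.
#
# Emulates the structure of commercial leg-accelerometer step-count data:
# herd-month seasonal levels (grazing vs non-grazing herds), pregnancy-status
# effects, a lactation-stage baseline (elevated after calving, plateau from
# ~75 DIM, dip in the two weeks pre-partum), ~21-day estrus spikes until
# conception, disturbance episodes with disease labels, device artifacts
# (partial measuring days, <200-step error days, multi-day gaps), and an
# additive-genetic + permanent-environmental + residual structure on three
# latent cow traits (step level, within-cow variability, disturbance
# proneness) with a configured genetic correlation matrix.

LATENTS <- c("level", "variability", "droprate")
DISEASES <- c("mastitis", "ketosis", "claw", "uterus")

#' Simulation configuration
#'
#' Collects and validates all parameters of the synthetic herd generator.
#' Defaults define the standard study conditions used throughout the package
#' tests: 10 herds, 100 paternal half-sib families of 10 cows (1,000 cows),
#' up to 3 parities inside a three-year calendar window, daily noise of
#' ~650 steps, and a latent genetic architecture with heritability 0.45 and
#' repeatability 0.73 for the step-level trait.
#'
#' @param n_herds number of herds.
#' @param n_sires,n_dams_per_sire pedigree structure; cows with records are
#'   the `n_sires * n_dams_per_sire` offspring.
#' @param n_parities maximum parity with step records (<= 3).
#' @param start_date,end_date calendar window of the recording device
#'   (ISO-8601 strings or `Date`).
#' @param base_steps intercept of daily step count (steps/day).
#' @param herd_sd SD of static between-herd level differences (steps/day).
#' @param herd_month_amplitude seasonal amplitude (steps/day) for grazing
#'   herds; non-grazing herds get 15% of it.
#' @param grazing_fraction proportion of herds with a strong summer peak.
#' @param pregnancy_effects named vector of true level shifts (steps/day) for
#'   the physiological states `not_pregnant`, `pregnant`, `dry`, `close_up`.
#' @param stage_curve list with `early_elevation` (steps/day above plateau at
#'   DIM 1, declining linearly to 0 at DIM 75), `plateau`, and
#'   `prepartum_dip` (level shift on DIM -14..-1).
#' @param estrus list with `spike` (steps/day), `spike_sd`, `cycle_length`
#'   (days) and `first_dim` (earliest cycling day).
#' @param disturbance list with `rate_per_100d` (event onsets per 100 days at
#'   the population mean), `depth_mean` and `depth_sd` (steps/day, negative
#'   depth), `duration_min` and `duration_mean` (days), `disease_prob`
#'   (probability an event carries a disease label) and `label_probs`
#'   (named probabilities over mastitis/ketosis/claw/uterus).
#' @param artifacts list with `seconds_known_fraction`, `short_day_fraction`
#'   (partial measuring days among records with known seconds),
#'   `low_count_fraction` (<200-step device-error days), `gap_prob`
#'   (per-lactation probability of a >= 7 day hole) and `gap_len` (range).
#' @param noise_sd baseline day-to-day residual SD (steps/day).
#' @param variances list per latent trait (`level`, `variability`,
#'   `droprate`) of `c(a = , pe = , e = )` variance components. `level` is in
#'   steps^2; the other two are on the natural-log scale of multiplicative
#'   cow effects.
#' @param genetic_correlations 3x3 symmetric PSD correlation matrix of the
#'   additive-genetic effects of the latent traits.
#' @param registration_herd_fraction probability that a herd registers a
#'   given disease (disease labels are only emitted for registering herds).
#' @param fraction_no_next_calving probability that a cow's final lactation
#'   stays open (no conception, next calving unknown).
#' @param fraction_violating_age,fraction_violating_interval,
#'   fraction_nonherdbook,fraction_low_holstein small fractions of cows that
#'   violate the inclusion rules, to exercise the editing filters.
#' @param age_first_calving_mean,age_first_calving_sd days.
#' @param calving_interval_mean,calving_interval_sd,calving_interval_min days.
#' @param gestation_days gestation length used for conception dates.
#' @param dry_period_days days between last milking and next calving.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_herds = 10L,
                       n_sires = 100L,
                       n_dams_per_sire = 10L,
                       n_parities = 3L,
                       start_date = "2016-07-01",
                       end_date = "2019-07-01",
                       base_steps = 2200,
                       herd_sd = 150,
                       herd_month_amplitude = 350,
                       grazing_fraction = 0.5,
                       pregnancy_effects = c(not_pregnant = 0, pregnant = -60,
                                             dry = -180, close_up = -120),
                       stage_curve = list(early_elevation = 550, plateau = 0,
                                          prepartum_dip = -150),
                       estrus = list(spike = 2500, spike_sd = 300,
                                     cycle_length = 21, first_dim = 21),
                       disturbance = list(rate_per_100d = 1.0,
                                          depth_mean = -800, depth_sd = 200,
                                          duration_min = 4, duration_mean = 12,
                                          disease_prob = 0.6,
                                          label_probs = c(mastitis = 0.20,
                                                          ketosis = 0.25,
                                                          claw = 0.40,
                                                          uterus = 0.15)),
                       artifacts = list(seconds_known_fraction = 0.61,
                                        short_day_fraction = 0.006,
                                        low_count_fraction = 0.002,
                                        gap_prob = 0.08,
                                        gap_len = c(7L, 20L)),
                       noise_sd = 650,
                       variances = list(
                         level = c(a = 270000, pe = 170000, e = 160000),
                         variability = c(a = 0.020, pe = 0.020, e = 0.010),
                         droprate = c(a = 0.09, pe = 0.06, e = 0.05)),
                       genetic_correlations = rbind(c(1.0, 0.6, 0.0),
                                                    c(0.6, 1.0, 0.0),
                                                    c(0.0, 0.0, 1.0)),
                       registration_herd_fraction = 0.7,
                       fraction_no_next_calving = 0.15,
                       fraction_violating_age = 0.02,
                       fraction_violating_interval = 0.02,
                       fraction_nonherdbook = 0.02,
                       fraction_low_holstein = 0.02,
                       age_first_calving_mean = 740,
                       age_first_calving_sd = 35,
                       calving_interval_mean = 385,
                       calving_interval_sd = 30,
                       calving_interval_min = 330,
                       gestation_days = 278L,
                       dry_period_days = 56L) {
  cfg <- as.list(environment())
  cfg$start_date <- as.Date(start_date)
  cfg$end_date <- as.Date(end_date)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_parities < 1L || cfg$n_parities > 3L)
    stop("n_parities must be between 1 and 3")
  if (cfg$start_date >= cfg$end_date)
    stop("start_date must precede end_date")
  span <- as.numeric(cfg$end_date - cfg$start_date)
  if (span < 365 * (cfg$n_parities - 1L) + 120)
    stop("calendar window too short for the requested number of parities")
  props <- c(cfg$grazing_fraction, cfg$registration_herd_fraction,
             cfg$fraction_no_next_calving, cfg$fraction_violating_age,
             cfg$fraction_violating_interval, cfg$fraction_nonherdbook,
             cfg$fraction_low_holstein, unlist(cfg$artifacts[
               c("seconds_known_fraction", "short_day_fraction",
                 "low_count_fraction", "gap_prob")]))
  if (any(props < 0 | props > 1)) stop("proportions must lie in [0, 1]")
  v <- do.call(rbind, cfg$variances[LATENTS])
  if (any(v < 0)) stop("all variance components must be >= 0")
  R <- cfg$genetic_correlations
  if (!isTRUE(all.equal(R, t(R), tolerance = 1e-8)))
    stop("genetic correlation matrix must be symmetric")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop(sprintf("genetic correlation matrix is not positive semidefinite (eigenvalue %.4g)", min(ev)))
  invisible(cfg)
}

latent_G <- function(cfg) {
  sa <- sqrt(vapply(cfg$variances[LATENTS], `[[`, numeric(1), "a"))
  G <- diag(sa) %*% cfg$genetic_correlations %*% diag(sa)
  dimnames(G) <- list(LATENTS, LATENTS)
  G
}

#' Simulate true genetic and permanent-environmental effects
#'
#' Founder breeding values are drawn from N(0, G) with G the configured
#' additive-genetic covariance of the latent traits; non-founders receive the
#' parent average plus a Mendelian sampling deviation with covariance
#' `0.5 * (1 - (F_s + F_d)/2) * G`. Permanent-environmental effects are
#' independent across cows and latent traits.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with matrices `bv` and `pe` (animals x latent traits) and the
#'   true covariance `G`.
#' @export
simulate_true_effects <- function(ped, config, seed = 1L) {
  set.seed(seed)
  idx <- check_pedigree(ped)
  G <- latent_G(config)
  ev <- eigen(G, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values)))
    stop(sprintf("latent genetic covariance not PSD (eigenvalue %.4g)", min(ev$values)))
  Gh <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(ev$values)) %*% t(ev$vectors)
  n <- nrow(ped)
  f <- inbreeding_coefficients(ped)$f
  s <- idx$sire_idx
  d <- idx$dam_idx
  z <- matrix(stats::rnorm(n * 3L), n, 3L) %*% Gh  # N(0, G) draws
  bv <- matrix(0, n, 3L, dimnames = list(ped$animal, LATENTS))
  founders <- s == 0L & d == 0L
  bv[founders, ] <- z[founders, , drop = FALSE]
  for (i in which(!founders)) {
    pa <- 0; fbar <- 0; k <- 0L
    if (s[i] > 0L) { pa <- pa + bv[s[i], ]; fbar <- fbar + f[s[i]]; k <- k + 1L }
    if (d[i] > 0L) { pa <- pa + bv[d[i], ]; fbar <- fbar + f[d[i]]; k <- k + 1L }
    # Mendelian sampling variance relative to full G
    msv <- if (k == 2L) 0.5 * (1 - fbar / 2) else 0.75 - 0.25 * fbar
    bv[i, ] <- pa / 2 + sqrt(msv) * z[i, ]
  }
  spe <- sqrt(vapply(config$variances[LATENTS], `[[`, numeric(1), "pe"))
  pe <- matrix(stats::rnorm(n * 3L), n, 3L) %*% diag(spe)
  dimnames(pe) <- dimnames(bv)
  list(bv = bv, pe = pe, G = G)
}

#' Simulate calving, insemination and herd records
#'
#' Gives every cow of the final pedigree generation a herd, a first calving
#' (normally past the youngest admissible age), and consecutive calvings at
#' realistic intervals while they fit in the calendar window. Conception is
#' placed `gestation_days` before the next calving; inseminations consist of
#' the conceiving service plus possible earlier returns at one-cycle spacing.
#' Configurable fractions of cows violate the age, interval, herd-book and
#' breed inclusion rules so the editing filters have work to do.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list of `data.table`s: `lactations` (cow_id, parity, calving_date,
#'   next_calving_date, last_milking_date, conception_date, herd,
#'   age_at_calving_days, previous_calving_interval_days, herdbook_flag,
#'   holstein_fraction), `calvings`, `inseminations`, `dryoff`, `herds`
#'   (herd, grazing, plus per-disease registration flags).
#' @export
simulate_population <- function(ped, config, seed = 1L) {
  set.seed(seed)
  cfg <- config
  cows <- ped$animal[ped$generation == max(ped$generation) & ped$sex == "F"]
  ncow <- length(cows)
  if (ncow == 0L) stop("pedigree has no final-generation females")

  herds <- data.table::data.table(
    herd = seq_len(cfg$n_herds),
    grazing = as.integer(stats::runif(cfg$n_herds) < cfg$grazing_fraction))
  for (dz in DISEASES)
    herds[[paste0("registers_", dz)]] <-
      as.integer(stats::runif(cfg$n_herds) < cfg$registration_herd_fraction)

  herd <- sample(herds$herd, ncow, replace = TRUE)
  age1 <- round(stats::rnorm(ncow, cfg$age_first_calving_mean, cfg$age_first_calving_sd))
  bad_age <- stats::runif(ncow) < cfg$fraction_violating_age
  age1[bad_age] <- round(stats::runif(sum(bad_age), 560, 639))
  span <- as.numeric(cfg$end_date - cfg$start_date)
  # leave room for one full lactation after the last admissible first calving
  c1 <- cfg$start_date + round(stats::runif(ncow, 20, max(40, span - 400)))

  rows <- vector("list", ncow * (cfg$n_parities + 1L))
  r <- 0L
  for (i in seq_len(ncow)) {
    cal <- c1[i]
    age <- age1[i]
    prev_int <- NA_real_
    parity <- 1L
    while (parity <= cfg$n_parities + 1L && cal <= cfg$end_date) {
      int <- round(stats::rnorm(1L, cfg$calving_interval_mean, cfg$calving_interval_sd))
      int <- max(int, cfg$calving_interval_min)
      if (stats::runif(1L) < cfg$fraction_violating_interval)
        int <- round(stats::runif(1L, 180, 214))
      open <- parity >= cfg$n_parities ||
        stats::runif(1L) < 0.02  # occasional open cow in earlier parities
      open <- open && stats::runif(1L) < cfg$fraction_no_next_calving
      nxt <- if (open) as.Date(NA) else cal + int
      r <- r + 1L
      rows[[r]] <- data.table::data.table(
        cow_id = cows[i], parity = parity, calving_date = cal,
        next_calving_date = nxt, herd = herd[i],
        age_at_calving_days = age, previous_calving_interval_days = prev_int)
      if (open) break
      prev_int <- int
      age <- age + int
      cal <- nxt
      parity <- parity + 1L
    }
  }
  lac <- data.table::rbindlist(rows[seq_len(r)])
  # a next calving is only *known* if it happened inside the window
  late <- which(!is.na(lac$next_calving_date) & lac$next_calving_date > cfg$end_date)
  if (length(late))
    data.table::set(lac, i = late, j = "next_calving_date", value = as.Date(NA))
  lac$conception_date <- lac$next_calving_date - cfg$gestation_days
  lac$last_milking_date <- lac$next_calving_date - cfg$dry_period_days

  hb <- stats::runif(ncow) >= cfg$fraction_nonherdbook
  hf <- ifelse(stats::runif(ncow) < cfg$fraction_low_holstein,
               round(stats::runif(ncow, 0.3, 0.86), 2), 1)
  cowdt <- data.table::data.table(cow_id = cows, herdbook_flag = as.integer(hb),
                                  holstein_fraction = hf)
  lac <- merge(lac, cowdt, by = "cow_id", sort = FALSE)
  data.table::setorder(lac, cow_id, parity)

  # inseminations: conceiving service plus possible earlier returns
  ins <- lac[!is.na(lac$conception_date), c("cow_id", "conception_date")]
  cyc <- cfg$estrus$cycle_length
  ins_rows <- list(data.table::data.table(cow_id = ins$cow_id, date = ins$conception_date))
  back1 <- stats::runif(nrow(ins)) < 0.30
  back2 <- stats::runif(nrow(ins)) < 0.12
  ins_rows[[2]] <- data.table::data.table(cow_id = ins$cow_id[back1],
                                          date = ins$conception_date[back1] - cyc)
  ins_rows[[3]] <- data.table::data.table(cow_id = ins$cow_id[back2],
                                          date = ins$conception_date[back2] - 2L * cyc)
  inseminations <- data.table::rbindlist(ins_rows)
  data.table::setorder(inseminations, cow_id, date)

  calvings <- lac[, c("cow_id", "parity", "calving_date", "age_at_calving_days",
                      "herdbook_flag", "holstein_fraction")]
  dry <- lac[!is.na(lac$last_milking_date),
             c("cow_id", "parity", "last_milking_date")]
  list(lactations = lac[lac$parity <= cfg$n_parities, ],
       calvings = calvings, inseminations = inseminations,
       dryoff = dry, herds = herds)
}

true_herd_effects <- function(cfg, herds, seed) {
  set.seed(seed)
  lev <- stats::rnorm(nrow(herds), 0, cfg$herd_sd)
  amp <- ifelse(herds$grazing == 1L, cfg$herd_month_amplitude,
                0.15 * cfg$herd_month_amplitude)
  hm <- expand.grid(herd = herds$herd, month = 1:12)
  hm$effect <- lev[hm$herd] + amp[hm$herd] * cos(2 * pi * (hm$month - 7) / 12)
  data.table::as.data.table(hm)
}

stage_level <- function(dim, stage) {
  out <- numeric(length(dim))
  pre <- dim < 0
  out[pre] <- stage$prepartum_dip
  post <- dim >= 1
  out[post] <- stage$plateau +
    stage$early_elevation * pmax(0, 1 - (dim[post] - 1) / 74)
  out
}

#' Simulate daily step-count series
#'
#' Generates one record per cow-day. The daily mean is the sum of the herd
#' and herd-month effect, the true pregnancy-status effect, the lactation
#' stage baseline, the cow's lactation-specific level (breeding value +
#' permanent environment + lactation deviation), an active disturbance depth
#' and an estrus spike on cycle days; day-to-day noise is normal with a
#' cow-lactation-specific SD. Device artifacts (partial measuring seconds,
#' <200-step error days, multi-day gaps) are injected at the configured
#' rates and negative step counts are truncated at zero (the truncation rate
#' is returned as an attribute).
#'
#' @param population output of [simulate_population()].
#' @param effects output of [simulate_true_effects()].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return list with `steps` (cow_id, date, steps, seconds_measured),
#'   `events` (the realised disturbance episodes with disease labels) and
#'   `herd_month` (true herd-month effects). `steps` carries attribute
#'   `truncation_rate`.
#' @export
simulate_step_series <- function(population, effects, config, seed = 1L) {
  set.seed(seed)
  cfg <- config
  lac <- population$lactations
  hm <- true_herd_effects(cfg, population$herds, seed + 1L)
  set.seed(seed + 2L)
  preg_eff <- cfg$pregnancy_effects

  n_lac <- nrow(lac)
  bv <- effects$bv
  pe <- effects$pe
  an <- rownames(bv)
  ai <- match(as.character(lac$cow_id), an)
  se_lat <- sqrt(vapply(cfg$variances[LATENTS], `[[`, numeric(1), "e"))
  dev <- matrix(stats::rnorm(n_lac * 3L), n_lac, 3L) %*% diag(se_lat)
  lvl <- bv[ai, "level"] + pe[ai, "level"] + dev[, 1L]
  noise_sd <- cfg$noise_sd * exp(bv[ai, "variability"] + pe[ai, "variability"] + dev[, 2L])
  ev_rate <- cfg$disturbance$rate_per_100d / 100 *
    exp(bv[ai, "droprate"] + pe[ai, "droprate"] + dev[, 3L])

  rec <- vector("list", n_lac)
  evl <- vector("list", n_lac)
  for (l in seq_len(n_lac)) {
    cal <- lac$calving_date[l]
    nxt <- lac$next_calving_date[l]
    dim_end <- if (!is.na(nxt)) min(450, as.numeric(nxt - cal) - 15) else 450
    dim_end <- min(dim_end, as.numeric(cfg$end_date - cal))
    if (dim_end < 1) next
    dim0 <- max(-14, as.numeric(cfg$start_date - cal))
    dims <- seq.int(dim0, dim_end)
    dims <- dims[dims != 0L]  # calving day itself carries no usable record
    nd <- length(dims)
    dates <- cal + dims

    # true physiological status
    status <- rep("not_pregnant", nd)
    if (!is.na(nxt)) {
      before <- as.numeric(nxt - dates)
      status[before <= cfg$gestation_days] <- "pregnant"
      status[dates > (nxt - cfg$dry_period_days)] <- "dry"
      status[before < 14] <- "close_up"
    }
    # records before this calving: status relative to *this* calving
    pre <- dims < 0
    status[pre & dims >= -13] <- "close_up"
    status[pre & dims < -13] <- "dry"

    mu <- cfg$base_steps +
      hm$effect[match(paste(lac$herd[l], data.table::month(dates)),
                      paste(hm$herd, hm$month))] +
      preg_eff[status] + stage_level(dims, cfg$stage_curve) + lvl[l]

    # disturbance episodes (only in lactation, DIM >= 1)
    in_lact <- dims[dims >= 1]
    n_ev <- stats::rpois(1L, ev_rate[l] * length(in_lact))
    if (n_ev > 0L) {
      onset <- in_lact[sample.int(length(in_lact), n_ev, replace = TRUE)]
      dur <- cfg$disturbance$duration_min +
        stats::rpois(n_ev, max(0, cfg$disturbance$duration_mean - cfg$disturbance$duration_min))
      depth <- pmin(-100, stats::rnorm(n_ev, cfg$disturbance$depth_mean, cfg$disturbance$depth_sd))
      lab <- ifelse(stats::runif(n_ev) < cfg$disturbance$disease_prob,
                    sample(DISEASES, n_ev, replace = TRUE,
                           prob = cfg$disturbance$label_probs[DISEASES]),
                    NA_character_)
      for (e in seq_len(n_ev)) {
        act <- dims >= onset[e] & dims <= onset[e] + dur[e] - 1L
        mu[act] <- mu[act] + depth[e]
      }
      evl[[l]] <- data.table::data.table(
        cow_id = lac$cow_id[l], parity = lac$parity[l],
        onset_dim = onset, duration = dur, depth = depth, disease = lab)
    }

    # estrus spikes every cycle until conception (open cows keep cycling)
    conc_dim <- if (!is.na(nxt)) as.numeric(nxt - cal) - cfg$gestation_days else NA
    cyc <- cfg$estrus$cycle_length
    first_est <- max(cfg$estrus$first_dim, 14)
    est_dims <- if (!is.na(conc_dim)) {
      if (conc_dim >= first_est) rev(seq(conc_dim, first_est, by = -cyc)) else numeric(0)
    } else if (max(dims) >= first_est) {
      seq(first_est, max(dims), by = cyc)
    } else numeric(0)
    est <- dims %in% est_dims
    if (any(est))
      mu[est] <- mu[est] +
        pmax(0, stats::rnorm(sum(est), cfg$estrus$spike, cfg$estrus$spike_sd))

    steps <- mu + stats::rnorm(nd, 0, noise_sd[l])
    rec[[l]] <- data.table::data.table(cow_id = lac$cow_id[l], date = dates,
                                       steps = steps)
  }
  steps <- data.table::rbindlist(rec)
  events <- data.table::rbindlist(evl[!vapply(evl, is.null, logical(1))])
  n_trunc <- sum(steps$steps < 0)
  steps$steps <- pmax(0, steps$steps)

  # device artifacts
  n <- nrow(steps)
  art <- cfg$artifacts
  seconds <- rep(NA_integer_, n)
  known <- stats::runif(n) < art$seconds_known_fraction
  seconds[known] <- 86400L
  short <- known & stats::runif(n) < art$short_day_fraction
  seconds[short] <- as.integer(round(stats::runif(sum(short), 20000, 80000)))
  steps$steps[short] <- steps$steps[short] * seconds[short] / 86400
  low <- stats::runif(n) < art$low_count_fraction
  steps$steps[low] <- stats::runif(sum(low), 0, 199)
  steps$steps <- as.integer(round(steps$steps))
  steps$seconds_measured <- seconds

  # device gaps: drop a contiguous block of days within a lactation
  gap_l <- which(stats::runif(n_lac) < art$gap_prob)
  if (length(gap_l)) {
    drop <- rep(FALSE, n)
    for (l in gap_l) {
      idx <- which(steps$cow_id == lac$cow_id[l] &
                   steps$date >= lac$calving_date[l] &
                   (is.na(lac$next_calving_date[l]) |
                    steps$date < lac$next_calving_date[l]))
      if (length(idx) < 40L) next
      len <- sample(seq(art$gap_len[1], art$gap_len[2]), 1L)
      at <- sample(seq_len(length(idx) - len), 1L)
      drop[idx[seq(at, at + len - 1L)]] <- TRUE
    }
    steps <- steps[!drop, ]
  }
  data.table::setorder(steps, cow_id, date)
  attr(steps, "truncation_rate") <- n_trunc / max(1L, n)
  list(steps = steps, events = events, herd_month = hm)
}

#' Simulate a complete herd dataset
#'
#' Orchestrates [simulate_pedigree()], [simulate_population()],
#' [simulate_true_effects()] and [simulate_step_series()] and assembles the
#' per-lactation disease registry (labels are only emitted for herds that
#' register the disease in question).
#'
#' @param config a [sim_config()].
#' @param seed integer seed; identical seed and config give identical output.
#' @return list of tables: `steps`, `calvings`, `inseminations`, `pedigree`,
#'   `diseases`, `dryoff`, `truth` (true breeding values), plus `lactations`,
#'   `herds`, `events`, `herd_month` and `config` for inspection.
#' @export
simulate_herd <- function(config = sim_config(), seed = 1L) {
  validate_sim_config(config)
  set.seed(seed)
  sub <- sample.int(1e8L, 4L)
  ped <- simulate_pedigree(config$n_sires, config$n_dams_per_sire,
                           generations = 1L, seed = sub[1])
  pop <- simulate_population(ped, config, seed = sub[2])
  eff <- simulate_true_effects(ped, config, seed = sub[3])
  ser <- simulate_step_series(pop, eff, config, seed = sub[4])

  # per-lactation disease flags, emitted only for registering herds
  lac <- pop$lactations
  dis <- lac[, c("cow_id", "parity", "herd")]
  for (dz in DISEASES) dis[[dz]] <- 0L
  if (nrow(ser$events)) {
    for (dz in DISEASES) {
      ev <- ser$events[!is.na(ser$events$disease) & ser$events$disease == dz, ]
      if (!nrow(ev)) next
      hit <- paste(ev$cow_id, ev$parity)
      reg_herds <- pop$herds$herd[pop$herds[[paste0("registers_", dz)]] == 1L]
      dis[[dz]] <- as.integer(paste(dis$cow_id, dis$parity) %in% hit &
                              dis$herd %in% reg_herds)
    }
  }
  dis$herd <- NULL

  truth <- data.table::data.table(animal = ped$animal)
  for (k in LATENTS) truth[[paste0("bv_", k)]] <- eff$bv[, k]

  list(steps = ser$steps,
       calvings = pop$calvings,
       inseminations = pop$inseminations,
       pedigree = ped[, c("animal", "sire", "dam")],
       diseases = dis,
       dryoff = pop$dryoff,
       truth = truth,
       lactations = pop$lactations,
       herds = pop$herds,
       events = ser$events,
       herd_month = ser$herd_month,
       config = config)
}

DATASET_FILES <- c(steps = "steps.csv", calvings = "calvings.csv",
                   inseminations = "inseminations.csv",
                   pedigree = "pedigree.csv", diseases = "diseases.csv",
                   dryoff = "dryoff.csv", truth = "truth.csv")

DATASET_SCHEMA <- list(
  steps = c("cow_id", "date", "steps", "seconds_measured"),
  calvings = c("cow_id", "parity", "calving_date", "age_at_calving_days",
               "herdbook_flag", "holstein_fraction"),
  inseminations = c("cow_id", "date"),
  pedigree = c("animal", "sire", "dam"),
  diseases = c("cow_id", "parity", "mastitis", "ketosis", "claw", "uterus"),
  dryoff = c("cow_id", "parity", "last_milking_date"),
  truth = c("animal", "bv_level", "bv_variability", "bv_droprate"))

#' Write / read a simulated dataset as CSV files
#'
#' `write_step_dataset()` writes the seven delimited tables (`steps.csv`,
#' `calvings.csv`, `inseminations.csv`, `pedigree.csv`, `diseases.csv`,
#' `dryoff.csv`, `truth.csv`) with ISO-8601 dates after checking referential
#' integrity; `read_step_dataset()` reads them back losslessly.
#'
#' @param dataset list as returned by [simulate_herd()] (only the seven
#'   tables are written).
#' @param dir output directory, created if missing.
#' @return `write_step_dataset()` the directory invisibly;
#'   `read_step_dataset()` a named list of `data.table`s.
#' @export
write_step_dataset <- function(dataset, dir) {
  known_cows <- unique(dataset$calvings$cow_id)
  for (tb in c("steps", "inseminations", "diseases", "dryoff")) {
    bad <- setdiff(unique(dataset[[tb]]$cow_id), known_cows)
    if (length(bad))
      stop(sprintf("referential integrity: %s contains unknown cow ids (e.g. %s)",
                   tb, bad[1]))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(DATASET_FILES)) {
    tab <- data.table::as.data.table(dataset[[nm]])[, DATASET_SCHEMA[[nm]], with = FALSE]
    data.table::fwrite(tab, file.path(dir, DATASET_FILES[nm]))
  }
  invisible(dir)
}

#' @rdname write_step_dataset
#' @export
read_step_dataset <- function(dir) {
  out <- list()
  for (nm in names(DATASET_FILES)) {
    path <- file.path(dir, DATASET_FILES[nm])
    if (!file.exists(path)) stop("missing dataset file: ", path)
    tab <- data.table::fread(path)
    extra <- setdiff(names(tab), DATASET_SCHEMA[[nm]])
    if (length(extra))
      stop(sprintf("unknown column '%s' in %s", extra[1], DATASET_FILES[nm]))
    miss <- setdiff(DATASET_SCHEMA[[nm]], names(tab))
    if (length(miss))
      stop(sprintf("missing column '%s' in %s", miss[1], DATASET_FILES[nm]))
    for (cl in grep("date", names(tab), value = TRUE))
      tab[[cl]] <- as.Date(tab[[cl]])
    out[[nm]] <- tab
  }
  out
}
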