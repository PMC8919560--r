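# Per-lactation resilience indicators: stage means of corrected steps, and
# fluctuation indicators from residuals around the individual 0.7-quantile
# quartic lactation curve.

#' Pinball (check) loss of quantile regression
#'
#' `sum(tau * pmax(r, 0) + (1 - tau) * pmax(-r, 0))` over residuals `r`.
#' Used by the fitter and as an independent optimality check in tests.
#'
#' @param residuals numeric residuals (observed - fitted).
#' @param tau quantile level.
#' @export
pinball_loss <- function(residuals, tau = 0.7) {
  sum(tau * pmax(residuals, 0) + (1 - tau) * pmax(-residuals, 0))
}

#' Fit the individual quantile lactation curve
#'
#' Quantile regression of corrected step count on a quartic polynomial in
#' days in milk at quantile `tau` (default 0.7, so the curve tracks an
#' approximately unperturbed baseline above which ~30% of days lie). The
#' polynomial uses an orthogonalised basis for numerical stability; the
#' asymmetric absolute (pinball) loss is minimised by iteratively
#' reweighted least squares on a smoothed loss with a decreasing smoothing
#' parameter, which converges to the linear-programming solution.
#'
#' @param dim days in milk of the records (need not be consecutive).
#' @param y corrected step counts.
#' @param tau quantile level (default 0.7).
#' @param degree polynomial degree (default 4).
#' @param min_points minimum number of records (default 28).
#' @return object of class `quantile_curve_fit`: `fitted`, `residuals`
#'   (`y - fitted`), `coefficients` (on the orthogonal basis), `tau`,
#'   `n_points`, `converged`.
#' @export
fit_quantile_curve <- function(dim, y, tau = 0.7, degree = 4L,
                               min_points = 28L) {
  n <- length(y)
  stopifnot(length(dim) == n)
  if (n < min_points)
    stop(sprintf("need at least %d records to fit the quantile curve", min_points))
  deg <- min(degree, length(unique(dim)) - 1L)
  X <- if (deg >= 1L) cbind(1, stats::poly(dim, degree = deg)) else matrix(1, n, 1L)
  p <- ncol(X)

  scale <- stats::median(abs(y - stats::median(y)))
  if (scale == 0) scale <- max(abs(y), 1)
  beta <- stats::lm.fit(X, y)$coefficients
  beta[is.na(beta)] <- 0
  converged <- FALSE
  eps_levels <- scale * 10^seq(0, -8, by = -2)
  for (eps in eps_levels) {
    inner_tol <- if (eps == eps_levels[length(eps_levels)]) 1e-12 else 1e-8
    for (it in 1:50) {
      r <- y - drop(X %*% beta)
      w <- 0.5 / sqrt(r * r + eps * eps)
      XtW <- t(X * w)
      rhs <- XtW %*% y + (tau - 0.5) * colSums(X)
      new_beta <- tryCatch(solve(XtW %*% X, rhs),
                           error = function(e) NULL)
      if (is.null(new_beta)) break
      delta <- max(abs(new_beta - beta)) / max(max(abs(beta)), scale * 1e-8)
      beta <- drop(new_beta)
      if (delta < inner_tol) break
    }
    converged <- !is.null(new_beta)
  }
  fitted <- drop(X %*% beta)
  res <- y - fitted
  # interpolated points carry an O(eps) smoothing bias; residuals that are
  # zero in the exact solution must not count as strictly negative
  res[abs(res) < 1e-6 * scale] <- 0
  fitted <- y - res
  structure(list(fitted = fitted, residuals = res,
                 coefficients = beta, tau = tau, degree = deg,
                 zero_tol = 1e-6 * scale,
                 n_points = n, converged = converged),
            class = "quantile_curve_fit")
}

#' Stage means of corrected step count
#'
#' Arithmetic means of corrected steps over the four lactation stages:
#' complete lactation (DIM 1-450), early lactation (DIM 1-28), later
#' lactation (DIM 75-450) and pre-partum (DIM -14..-1). The complete and
#' later-lactation means require at least four weeks of data (28 records in
#' the window); the short early and pre-partum windows require one week
#' (7 records).
#'
#' @param dim days in milk.
#' @param corrected corrected step counts.
#' @param min_long,min_short minimum record counts (defaults 28 and 7).
#' @return list with numeric `mean_complete`, `mean_early`, `mean_later`,
#'   `mean_prepartum` (NA when below the minimum) and a character vector
#'   `reasons` for missing values.
#' @export
stage_means <- function(dim, corrected, min_long = 28L, min_short = 7L) {
  win <- list(mean_complete = c(1, 450, min_long),
              mean_early = c(1, 28, min_short),
              mean_later = c(75, 450, min_long),
              mean_prepartum = c(-14, -1, min_short))
  out <- numeric(0)
  reasons <- character(0)
  for (nm in names(win)) {
    w <- win[[nm]]
    v <- corrected[dim >= w[1] & dim <= w[2]]
    if (length(v) >= w[3]) {
      out[nm] <- mean(v)
    } else {
      out[nm] <- NA_real_
      reasons[nm] <- "min_data"
    }
  }
  list(means = out, reasons = reasons)
}

#' Log-variance of curve residuals
#'
#' Natural log of the sample variance (n-1 denominator) of the residuals
#' around the individual quantile curve; the fluctuation-severity indicator.
#'
#' @param residuals curve residuals.
#' @return `ln_var`, or `NA` with attribute `reason` when fewer than 2
#'   residuals or zero variance.
#' @export
ln_variance <- function(residuals) {
  if (length(residuals) < 2L)
    return(structure(NA_real_, reason = "min_data"))
  v <- stats::var(residuals)
  if (!is.finite(v) || v <= 0)
    return(structure(NA_real_, reason = "degenerate"))
  log(v)
}

#' Lag-1 autocorrelation of curve residuals
#'
#' `sum((e_t - m) * (e_{t+1} - m)) / sum((e_t - m)^2)` where the sum in the
#' numerator runs over pairs of calendar-adjacent days only (a missing day
#' contributes no pair), and `m` is the mean over all residuals. The
#' slow-recovery indicator; clipped to [-1, 1].
#'
#' @param dim day index of each residual (calendar days in milk).
#' @param residuals curve residuals.
#' @param min_pairs minimum number of adjacent pairs (default 3).
#' @return `r_auto`, or `NA` with attribute `reason`.
#' @export
lag1_autocorrelation <- function(dim, residuals, min_pairs = 3L) {
  o <- order(dim)
  dim <- dim[o]
  e <- residuals[o]
  adj <- which(diff(dim) == 1)
  if (length(adj) < min_pairs)
    return(structure(NA_real_, reason = "min_data"))
  m <- mean(e)
  denom <- sum((e - m)^2)
  if (denom == 0) return(structure(NA_real_, reason = "degenerate"))
  r <- sum((e[adj] - m) * (e[adj + 1L] - m)) / denom
  min(1, max(-1, r))
}

#' Mean of all negative residuals
#'
#' Mean of the strictly negative residuals around the individual curve; the
#' deviation-severity indicator (always <= 0).
#'
#' @param residuals curve residuals.
#' @return the mean, or `NA` with attribute `reason` when no residual is
#'   negative.
#' @export
mean_negative_residuals <- function(residuals) {
  neg <- residuals[residuals < 0]
  if (!length(neg)) return(structure(NA_real_, reason = "degenerate"))
  mean(neg)
}

#' Detect step-count drops
#'
#' A drop is a maximal run of at least `min_run` consecutive calendar days
#' that all carry a record with a strictly negative residual; a missing day
#' breaks the run. Returns the drops, the number of drops per 100 recorded
#' days, and the mean of the residuals inside drops.
#'
#' @param dim day index of each residual.
#' @param residuals curve residuals.
#' @param min_run minimum run length (default 10).
#' @return list with `drops` (data.table start_dim/length), `n_drops`,
#'   `n_drops_per_100d`, `mean_neg_residuals_in_drops` (`NA` with reason
#'   when there is no drop).
#' @export
detect_step_drops <- function(dim, residuals, min_run = 10L) {
  o <- order(dim)
  dim <- dim[o]
  e <- residuals[o]
  n <- length(e)
  if (n == 0L)
    return(list(drops = data.table::data.table(start_dim = numeric(0),
                                               length = integer(0)),
                n_drops = 0L, n_drops_per_100d = NA_real_,
                mean_neg_residuals_in_drops = structure(NA_real_,
                                                        reason = "min_data")))
  # segment label changes when a calendar day is missing or the sign flips
  neg <- e < 0
  brk <- c(TRUE, diff(dim) != 1 | diff(neg) != 0)
  seg <- cumsum(brk)
  lens <- tabulate(seg)
  seg_neg <- neg[brk]
  is_drop <- seg_neg & lens >= min_run
  starts <- dim[brk][is_drop]
  drops <- data.table::data.table(start_dim = starts,
                                  length = lens[is_drop])
  in_drop <- is_drop[seg]
  mnr <- if (any(in_drop)) mean(e[in_drop])
         else structure(NA_real_, reason = "no_drops")
  list(drops = drops, n_drops = nrow(drops),
       n_drops_per_100d = 100 * nrow(drops) / n,
       mean_neg_residuals_in_drops = mnr)
}

INDICATORS <- c("mean_complete", "mean_early", "mean_later", "mean_prepartum",
                "mean_neg_residuals", "ln_var", "r_auto", "n_drops_per_100d",
                "mean_neg_residuals_in_drops")

#' Derive the nine resilience indicators for every lactation
#'
#' For each cow-parity with corrected records: the four stage means, and --
#' for lactations with at least `min_long` records in DIM 1-450 -- the five
#' fluctuation indicators from residuals around the individual `tau`-quantile
#' quartic curve (log-variance, lag-1 autocorrelation, mean negative
#' residuals, drops per 100 days, mean residuals in drops).
#'
#' @param corrected records with `cow_id`, `parity`, `dim`, and
#'   `corrected_steps` (from [corrected_steps()]); extra columns `herd`,
#'   `date` are carried through when present.
#' @param lactations kept lactation table (for calving metadata); optional.
#' @param tau,degree quantile-curve parameters (defaults 0.7, 4).
#' @param drop_run minimum drop run length (default 10).
#' @param min_long,min_short minimum record counts (defaults 28, 7).
#' @return `data.table` with one row per cow x parity: the nine indicators,
#'   missing-reason columns (`reason_<indicator>`), record counts, and
#'   `first_dim` (first available DIM, a fixed-effect covariate downstream).
#' @export
derive_indicators <- function(corrected, lactations = NULL, tau = 0.7,
                              degree = 4L, drop_run = 10L,
                              min_long = 28L, min_short = 7L) {
  rec <- data.table::as.data.table(corrected)
  stopifnot(all(c("cow_id", "parity", "dim", "corrected_steps") %in% names(rec)))
  groups <- split(seq_len(nrow(rec)), paste(rec$cow_id, rec$parity))
  rows <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    dim <- rec$dim[idx]
    y <- rec$corrected_steps[idx]
    sm <- stage_means(dim, y, min_long = min_long, min_short = min_short)
    out <- as.list(sm$means)
    reasons <- sm$reasons
    lact <- dim >= 1 & dim <= 450
    nl <- sum(lact)
    if (nl >= min_long) {
      qf <- fit_quantile_curve(dim[lact], y[lact], tau = tau, degree = degree,
                               min_points = min_long)
      if (qf$converged) {
        e <- qf$residuals
        d <- dim[lact]
        out$ln_var <- ln_variance(e)
        out$r_auto <- lag1_autocorrelation(d, e)
        out$mean_neg_residuals <- mean_negative_residuals(e)
        dr <- detect_step_drops(d, e, min_run = drop_run)
        out$n_drops_per_100d <- dr$n_drops_per_100d
        out$mean_neg_residuals_in_drops <- dr$mean_neg_residuals_in_drops
      } else {
        for (nm in c("ln_var", "r_auto", "mean_neg_residuals",
                     "n_drops_per_100d", "mean_neg_residuals_in_drops")) {
          out[[nm]] <- NA_real_
          reasons[nm] <- "no_convergence"
        }
      }
    } else {
      for (nm in c("ln_var", "r_auto", "mean_neg_residuals",
                   "n_drops_per_100d", "mean_neg_residuals_in_drops")) {
        out[[nm]] <- NA_real_
        reasons[nm] <- "min_data"
      }
    }
    for (nm in INDICATORS) {
      rs <- attr(out[[nm]], "reason")
      if (!is.null(rs)) reasons[nm] <- rs
      out[[nm]] <- as.numeric(out[[nm]])
    }
    row <- data.table::data.table(cow_id = rec$cow_id[idx[1]],
                                  parity = rec$parity[idx[1]],
                                  n_records = length(idx),
                                  n_lactation_records = nl,
                                  first_dim = min(dim[dim >= 1], Inf))
    if ("herd" %in% names(rec)) row$herd <- rec$herd[idx[1]]
    for (nm in INDICATORS) row[[nm]] <- out[[nm]]
    for (nm in INDICATORS)
      row[[paste0("reason_", nm)]] <- unname(reasons[nm])
    rows[[g]] <- row
  }
  ind <- data.table::rbindlist(rows, fill = TRUE)
  ind$first_dim[!is.finite(ind$first_dim)] <- NA_real_
  if (!is.null(lactations)) {
    keep <- intersect(c("cow_id", "parity", "calving_date",
                        "age_at_calving_days", "herd"), names(lactations))
    ind <- merge(ind, data.table::as.data.table(lactations)[, keep, with = FALSE],
                 by = c("cow_id", "parity"), all.x = TRUE, sort = FALSE,
                 suffixes = c("", ".lac"))
    if ("herd.lac" %in% names(ind)) {
      ind$herd <- ifelse(is.na(ind$herd), ind$herd.lac, ind$herd)
      ind$herd.lac <- NULL
    }
  }
  data.table::setorder(ind, cow_id, parity)
  ind
}

#' Remove indicator outliers
#'
#' Single-pass rule per parity and indicator: values deviating more than
#' `k` sample standard deviations from the parity mean (both computed
#' before any removal) are set to missing. A value at exactly `k` SD is
#' kept.
#'
#' @param indicators table from [derive_indicators()].
#' @param k SD multiplier (default 4).
#' @param columns indicator columns to screen (default all nine).
#' @return list with `indicators` (screened table) and `log` (one row per
#'   removal: cow_id, parity, indicator, value).
#' @export
remove_indicator_outliers <- function(indicators, k = 4, columns = INDICATORS) {
  ind <- data.table::copy(data.table::as.data.table(indicators))
  logs <- list()
  for (p in sort(unique(ind$parity))) {
    sel <- which(ind$parity == p)
    for (nm in intersect(columns, names(ind))) {
      v <- ind[[nm]][sel]
      ok <- !is.na(v)
      if (sum(ok) < 2L) next
      m <- mean(v[ok])
      s <- stats::sd(v[ok])
      if (s == 0) next
      out <- ok & abs(v - m) > k * s
      if (any(out)) {
        logs[[length(logs) + 1L]] <- data.table::data.table(
          cow_id = ind$cow_id[sel[out]], parity = p, indicator = nm,
          value = v[out])
        data.table::set(ind, i = sel[out], j = nm, value = NA_real_)
        data.table::set(ind, i = sel[out], j = paste0("reason_", nm),
                        value = "outlier")
      }
    }
  }
  list(indicators = ind,
       log = if (length(logs)) data.table::rbindlist(logs)
             else data.table::data.table(cow_id = integer(0), parity = integer(0),
                                         indicator = character(0), value = numeric(0)))
}
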