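# Phenotypic exploration: disease ANOVA on the resilience indicators.
# These associations are exploratory only (registration is voluntary and
# incomplete), never genetic estimates.

#' Select herds with registrations of a disease
#'
#' A herd enters the analysis of a disease only if it has at least one
#' registration of that disease and step-count data (an indicator row) for
#' at least five lactations.
#'
#' @param diseases per-lactation registry: `cow_id`, `parity`, one 0/1
#'   column per disease.
#' @param indicators indicator table with `cow_id`, `parity`, `herd`.
#' @param disease disease column name.
#' @param min_lactations minimum lactations with step data (default 5).
#' @return integer vector of herd ids.
#' @export
select_registration_herds <- function(diseases, indicators, disease,
                                      min_lactations = 5L) {
  dz <- data.table::as.data.table(diseases)
  ind <- data.table::as.data.table(indicators)
  stopifnot(disease %in% names(dz), "herd" %in% names(ind))
  m <- merge(ind[, c("cow_id", "parity", "herd")],
             dz[, c("cow_id", "parity", disease), with = FALSE],
             by = c("cow_id", "parity"))
  agg <- m[, list(n_reg = sum(.SD[[1]], na.rm = TRUE), n_lac = .N),
           by = "herd", .SDcols = disease]
  sort(agg$herd[agg$n_reg >= 1L & agg$n_lac >= min_lactations])
}

#' Disease ANOVA on the resilience indicators
#'
#' For each disease, restricts to herds with registrations of that disease
#' (and enough step data), and fits the four-disease analysis of variance
#' `indicator ~ parity + mastitis + ketosis + claw + uterus` by least
#' squares; the reported effect of the disease is its coefficient from its
#' own herd subset, with the usual two-sided t-test p-value.
#'
#' @param indicators indicator table (one row per cow x parity) with `herd`.
#' @param diseases disease registry (`cow_id`, `parity`, four 0/1 columns).
#' @param indicator_cols indicator columns to analyse (default all nine).
#' @param alpha significance threshold reported alongside (default 0.05).
#' @param min_lactations herd-subsetting rule (default 5).
#' @return `data.table` with one row per indicator x disease: `estimate`,
#'   `se`, `p_value`, `significant`, `n`, `n_herds`, and an `exploratory`
#'   flag (always TRUE: these are phenotypic, non-genetic associations).
#' @export
disease_associations <- function(indicators, diseases,
                                 indicator_cols = INDICATORS,
                                 alpha = 0.05, min_lactations = 5L) {
  ind <- data.table::as.data.table(indicators)
  dz <- data.table::as.data.table(diseases)
  dat <- merge(ind, dz, by = c("cow_id", "parity"))
  out <- list()
  for (d in DISEASES) {
    herds <- select_registration_herds(diseases, indicators, d,
                                       min_lactations = min_lactations)
    if (!length(herds)) {
      warning("no herds with registrations of ", d, "; analysis skipped")
      next
    }
    sub <- dat[dat$herd %in% herds, ]
    for (ic in indicator_cols) {
      df <- sub[!is.na(sub[[ic]]), ]
      est <- c(estimate = NA_real_, se = NA_real_, p = NA_real_)
      n <- nrow(df)
      if (n > 10L && stats::var(df[[d]]) > 0) {
        par_term <- if (length(unique(df$parity)) > 1L) "factor(parity) +" else ""
        form <- stats::as.formula(paste(
          ic, "~", par_term, paste(DISEASES, collapse = " + ")))
        fit <- stats::lm(form, data = df)
        cf <- summary(fit)$coefficients
        if (d %in% rownames(cf))
          est <- c(cf[d, "Estimate"], cf[d, "Std. Error"], cf[d, "Pr(>|t|)"])
      }
      out[[length(out) + 1L]] <- data.table::data.table(
        indicator = ic, disease = d, estimate = est[1], se = est[2],
        p_value = est[3],
        significant = !is.na(est[3]) & est[3] < alpha,
        n = n, n_herds = length(herds), exploratory = TRUE)
    }
  }
  data.table::rbindlist(out)
}
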