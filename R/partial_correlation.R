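# Partial genetic correlations: association between a resilience indicator
# (x) and an external trait (y) among cows with the same mean step count
# (z), computed from the three pairwise genetic correlations.

#' Partial correlation of two traits given a third
#'
#' `r_xy.z = (r_xy - r_xz * r_yz) / (sqrt(1 - r_xz^2) * sqrt(1 - r_yz^2))`.
#' Used with genetic correlations to adjust indicator-trait associations
#' for mean step count level. If the implied 3x3 correlation matrix is not
#' positive semidefinite the result can fall outside [-1, 1]; it is then
#' returned as-is with attribute `non_psd = TRUE` rather than clipped.
#'
#' @param r_xy,r_xz,r_yz pairwise correlations; `|r_xz|` and `|r_yz|` must
#'   be < 1.
#' @return the partial correlation (vectorised).
#' @export
partial_genetic_correlation <- function(r_xy, r_xz, r_yz) {
  if (any(abs(c(r_xz, r_yz)) >= 1))
    stop("partial correlation undefined: |r_xz| or |r_yz| equals 1")
  out <- (r_xy - r_xz * r_yz) / (sqrt(1 - r_xz^2) * sqrt(1 - r_yz^2))
  if (any(abs(out) > 1)) attr(out, "non_psd") <- TRUE
  out
}

#' Published genetic-correlation tables
#'
#' Reads the packaged fixtures with the published genetic correlations
#' between the resilience indicators and mean step count for the whole
#' lactation (`indicator_vs_mean`, from the bivariate analyses) and between
#' indicators / mean step count and the external breeding-goal traits
#' (`vs_external`: udder health UH, hoof health HH, ketosis resistance KET,
#' longevity LON, fertility FER, body condition score BCS), together with
#' the published partial correlations (`partial_published`) used as a
#' cross-check.
#'
#' @return list of three `data.table`s.
#' @export
printed_correlation_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "resilind",
                                  mustWork = TRUE)
  list(indicator_vs_mean = data.table::fread(path("genetic_corr_indicator_vs_mean.csv")),
       vs_external = data.table::fread(path("genetic_corr_vs_external.csv")),
       partial_published = data.table::fread(path("partial_genetic_corr_published.csv")))
}

#' Published descriptive statistics of the indicators
#'
#' Mean, SD, minimum and maximum of the nine resilience indicators as
#' published for the commercial population (corrected-step scale), used as
#' sanity bands and for stage-contrast arithmetic such as the early-minus
#' pre-partum difference in mean corrected steps.
#'
#' @return a `data.table` with columns `indicator`, `mean`, `sd`, `min`,
#'   `max`.
#' @export
published_indicator_summary <- function() {
  data.table::fread(system.file("extdata", "published_indicator_summary.csv",
                                package = "resilind", mustWork = TRUE))
}

#' Partial genetic correlations with external traits
#'
#' For the indicators that are strongly genetically correlated with mean
#' step count (log-variance, mean of all negative residuals, mean of
#' negative residuals during drops), computes their genetic correlations
#' with the external traits adjusted for mean step count for the whole
#' lactation, from (i) the indicator-external correlations `r_xy`, (ii) the
#' indicator-mean correlations `r_xz` and (iii) the mean-external
#' correlations `r_yz`.
#'
#' @param indicator_vs_mean `data.table` with columns `indicator`, `r_xz`.
#' @param vs_external `data.table` with column `indicator` (including a
#'   `mean_complete` row supplying `r_yz`) and one column per external
#'   trait.
#' @return `data.table` of partial correlations, one row per indicator.
#' @export
recompute_partial_table <- function(indicator_vs_mean = NULL,
                                    vs_external = NULL) {
  if (is.null(indicator_vs_mean) || is.null(vs_external)) {
    tabs <- printed_correlation_tables()
    if (is.null(indicator_vs_mean)) indicator_vs_mean <- tabs$indicator_vs_mean
    if (is.null(vs_external)) vs_external <- tabs$vs_external
  }
  ivm <- data.table::as.data.table(indicator_vs_mean)
  vse <- data.table::as.data.table(vs_external)
  traits <- setdiff(names(vse), "indicator")
  if (!"mean_complete" %in% vse$indicator)
    stop("vs_external must contain a 'mean_complete' row (the r_yz values)")
  r_yz <- as.numeric(vse[vse$indicator == "mean_complete", traits, with = FALSE])
  out <- list()
  for (i in seq_len(nrow(ivm))) {
    x <- ivm$indicator[i]
    if (!x %in% vse$indicator)
      stop("indicator missing from vs_external table: ", x)
    r_xy <- as.numeric(vse[vse$indicator == x, traits, with = FALSE])
    r <- partial_genetic_correlation(r_xy, ivm$r_xz[i], r_yz)
    row <- data.table::as.data.table(as.list(as.numeric(r)))
    data.table::setnames(row, traits)
    out[[i]] <- cbind(data.table::data.table(indicator = x), row)
  }
  data.table::rbindlist(out)
}
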