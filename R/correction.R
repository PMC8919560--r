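# Correction of daily step counts for herd-month and pregnancy status.
# The residuals of this two-factor fixed-effects model are the "corrected
# number of steps" on which all resilience indicators are computed.

#' Fit the herd-month and pregnancy-status correction model
#'
#' Ordinary least squares of daily step count on herd-month (herd crossed
#' with calendar month 1-12, year-free) and pregnancy status, fitted
#' additively under treatment constraints with the first herd-month cell and
#' `not_pregnant` as reference levels. The model is solved through sparse
#' normal equations, so millions of records with hundreds of herd-month
#' cells are no problem.
#'
#' @param records kept records from [edit_records()]: columns `steps`,
#'   `herd`, `date` (or `month`), `status`.
#' @return object of class `step_correction_fit` with elements `intercept`,
#'   `herd_month` (data.table herd/month/effect), `pregnancy` (status ->
#'   effect, reference 0), `n_records`.
#' @export
fit_correction_model <- function(records) {
  rec <- data.table::as.data.table(records)
  if (!"month" %in% names(rec)) rec$month <- data.table::month(rec$date)
  hm <- factor(paste0("h", rec$herd, "_m", rec$month))
  status <- factor(rec$status,
                   levels = intersect(PREG_STATUSES, unique(rec$status)))
  empty <- setdiff(PREG_STATUSES, levels(status))
  y <- as.numeric(rec$steps)

  dat <- data.frame(hm = hm, status = status)
  form <- if (nlevels(status) > 1L && nlevels(hm) > 1L) ~ hm + status
          else if (nlevels(hm) > 1L) ~ hm
          else if (nlevels(status) > 1L) ~ status
          else ~ 1
  X <- Matrix::sparse.model.matrix(form, data = dat)
  XtX <- Matrix::crossprod(X)
  Xty <- Matrix::crossprod(X, y)
  ch <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(XtX), LDL = FALSE),
                 error = function(e) NULL)
  if (is.null(ch)) {  # confounded levels: drop via pivoted dense solve
    stop("correction model design is singular: ",
         "some herd-month and pregnancy levels are wholly confounded")
  }
  beta <- as.numeric(Matrix::solve(ch, Xty, system = "A"))
  names(beta) <- colnames(X)

  hm_levels <- levels(hm)
  hm_eff <- c(0, beta[paste0("hm", hm_levels[-1])])
  names(hm_eff) <- hm_levels
  parts <- do.call(rbind, strsplit(sub("^h", "", hm_levels), "_m"))
  hm_dt <- data.table::data.table(herd = as.integer(parts[, 1]),
                                  month = as.integer(parts[, 2]),
                                  effect = unname(hm_eff))
  preg <- c(0, beta[paste0("status", levels(status)[-1])])
  names(preg) <- levels(status)
  structure(list(intercept = unname(beta["(Intercept)"]),
                 herd_month = hm_dt,
                 pregnancy = preg,
                 reference = list(herd_month = hm_levels[1],
                                  pregnancy = levels(status)[1]),
                 dropped_status_levels = empty,
                 n_records = nrow(rec)),
            class = "step_correction_fit")
}

#' @export
print.step_correction_fit <- function(x, ...) {
  cat("Step-count correction model (herd-month + pregnancy status)\n")
  cat(sprintf("  records: %d, herd-month cells: %d\n", x$n_records,
              nrow(x$herd_month)))
  cat(sprintf("  intercept (reference %s, %s): %.1f steps/day\n",
              x$reference$herd_month, x$reference$pregnancy, x$intercept))
  cat("  pregnancy effects:\n")
  print(round(x$pregnancy, 1))
  invisible(x)
}

#' Corrected number of steps
#'
#' Residuals (observed minus fitted) of the herd-month + pregnancy model,
#' used as the corrected step counts on which all indicators are based.
#'
#' @param records records with `steps`, `herd`, `date`/`month`, `status`.
#' @param fit a [fit_correction_model()] object.
#' @return the records with an added numeric column `corrected_steps`.
#' @export
corrected_steps <- function(records, fit) {
  rec <- data.table::as.data.table(records)
  if (!"month" %in% names(rec)) rec$month <- data.table::month(rec$date)
  key <- paste(rec$herd, rec$month)
  i <- match(key, paste(fit$herd_month$herd, fit$herd_month$month))
  if (anyNA(i))
    stop("unseen herd-month level(s) at prediction: ",
         paste(unique(key[is.na(i)])[1:min(3, sum(is.na(i)))], collapse = ", "))
  if (any(!rec$status %in% names(fit$pregnancy)))
    stop("unseen pregnancy status at prediction: ",
         paste(setdiff(unique(rec$status), names(fit$pregnancy)), collapse = ", "))
  fitted <- fit$intercept + fit$herd_month$effect[i] +
    unname(fit$pregnancy[rec$status])
  rec$corrected_steps <- as.numeric(rec$steps) - fitted
  rec
}
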