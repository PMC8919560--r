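# REML fitting of the repeatability animal model.
#
# The restricted log-likelihood is evaluated through the mixed-model
# equations:  -2 l_R = log|R| + log|G| + log|C| + y'Py  (up to a constant),
# where C is the full MME coefficient matrix. One sparse Cholesky
# factorisation per evaluation (with a cached symbolic analysis, since the
# sparsity pattern is constant) makes each evaluation cheap, and the
# likelihood is maximised by quasi-Newton iterations on a log (univariate)
# or log-Cholesky (bivariate) parameterisation that keeps the component
# matrices positive definite, followed by a Newton polish.

logdet_chol <- function(ch) 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)

# rank-revealing column selection so the fixed-effects design has full rank
drop_aliased <- function(X) {
  Xd <- as.matrix(X)
  q <- qr(Xd)
  keep <- q$pivot[seq_len(q$rank)]
  X[, sort(keep), drop = FALSE]
}

incidence <- function(fac) {
  fac <- factor(fac)
  Matrix::sparseMatrix(i = seq_along(fac), j = as.integer(fac), x = 1,
                       dims = c(length(fac), nlevels(fac)),
                       dimnames = list(NULL, levels(fac)))
}

#' Fixed-effects design for the repeatability model
#'
#' Builds the fixed part of the repeatability animal model from whatever
#' metadata columns are present: parity, age at calving in month classes
#' nested within parity, year-season of calving (meteorological quarters)
#' nested within parity, herd-year nested within parity, and the first
#' available day in milk as a covariate nested within parity. Herd-year by
#' parity cells with fewer than `min_cell` records are pooled into one
#' within-herd class so the design stays estimable; aliased columns are
#' dropped by rank-revealing QR.
#'
#' @param data table with at least `parity`; optionally
#'   `age_at_calving_days`, `calving_date`, `herd`, `first_dim`.
#' @param min_cell minimum herd-year x parity cell size (default 3).
#' @return sparse full-rank design matrix with an intercept.
#' @export
repeatability_design <- function(data, min_cell = 3L) {
  dt <- data.table::as.data.table(data)
  parity <- factor(dt$parity)
  terms <- list(stats::model.matrix(~parity))
  if ("age_at_calving_days" %in% names(dt) && !anyNA(dt$age_at_calving_days)) {
    age_class <- floor(dt$age_at_calving_days / 30.44)
    terms <- c(terms, list(incidence(paste0("age", age_class, "_p", parity))))
  }
  if ("calving_date" %in% names(dt) && !anyNA(dt$calving_date)) {
    ys <- paste0(data.table::year(dt$calving_date), "q",
                 data.table::quarter(dt$calving_date))
    terms <- c(terms, list(incidence(paste0("ys", ys, "_p", parity))))
    if ("herd" %in% names(dt) && !anyNA(dt$herd)) {
      hy <- paste0("h", dt$herd, "_y", data.table::year(dt$calving_date),
                   "_p", parity)
      cnt <- table(hy)
      small <- names(cnt)[cnt < min_cell]
      hy[hy %in% small] <- paste0("h", dt$herd[hy %in% small], "_pooled")
      terms <- c(terms, list(incidence(hy)))
    }
  }
  if ("first_dim" %in% names(dt) && !anyNA(dt$first_dim)) {
    fd <- stats::model.matrix(~ 0 + parity)
    fd <- fd * dt$first_dim
    colnames(fd) <- paste0("first_dim_p", levels(parity))
    terms <- c(terms, list(fd))
  }
  X <- do.call(cbind, lapply(terms, Matrix::Matrix, sparse = TRUE))
  drop_aliased(X)
}

prepare_animal_terms <- function(data, pedigree) {
  ped <- data.table::as.data.table(pedigree)
  ai <- a_inverse(ped)
  an <- as.character(ped$animal)
  pos <- match(as.character(data$animal), an)
  if (anyNA(pos))
    stop("phenotyped animals missing from the pedigree: ",
         paste(utils::head(unique(data$animal[is.na(pos)]), 3), collapse = ", "))
  q <- nrow(ped)
  Z1 <- Matrix::sparseMatrix(i = seq_len(nrow(data)), j = pos, x = 1,
                             dims = c(nrow(data), q))
  cows <- sort(unique(pos))
  Z2 <- Matrix::sparseMatrix(i = seq_len(nrow(data)), j = match(pos, cows),
                             x = 1, dims = c(nrow(data), length(cows)))
  list(Z1 = Z1, Z2 = Z2, Ainv = ai$Ainv, logdet_A = ai$logdet_A,
       animals = an, cows = an[cows], pos = pos)
}

# numeric gradient and Hessian by central differences; h may be a vector
num_grad <- function(f, x, h = 1e-5) {
  h <- rep_len(h, length(x))
  vapply(seq_along(x), function(i) {
    e <- replace(numeric(length(x)), i, h[i])
    (f(x + e) - f(x - e)) / (2 * h[i])
  }, numeric(1))
}

num_hess <- function(f, x, h = 1e-4) {
  k <- length(x)
  h <- rep_len(h, k)
  H <- matrix(0, k, k)
  f0 <- f(x)
  for (i in seq_len(k)) for (j in i:k) {
    ei <- replace(numeric(k), i, h[i])
    ej <- replace(numeric(k), j, h[j])
    H[i, j] <- H[j, i] <- if (i == j)
      (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    else
      (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
  }
  H
}

newton_polish <- function(f, x, lower, upper, iter = 12L, tol = 1e-10) {
  fx <- f(x)
  for (it in seq_len(iter)) {
    g <- num_grad(f, x)
    if (max(abs(g)) < tol) break
    H <- num_hess(f, x)
    step <- tryCatch(-solve(H + diag(1e-10, length(x)), g),
                     error = function(e) -g)
    if (any(!is.finite(step))) step <- -g
    lam <- 1
    repeat {
      xn <- pmin(pmax(x + lam * step, lower), upper)
      fn <- f(xn)
      if (is.finite(fn) && fn <= fx + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8) { xn <- x; fn <- fx; break }
    }
    if (abs(fx - fn) < tol * (abs(fx) + 1)) { x <- xn; fx <- fn; break }
    x <- xn
    fx <- fn
  }
  list(par = x, objective = fx)
}

#' Univariate repeatability animal model by REML
#'
#' Fits `y = Xb + Z1 a + Z2 p + e` with `a ~ N(0, A * sigma2_a)` (A the
#' additive relationship matrix from the pedigree), `p ~ N(0, I * sigma2_pe)`
#' and `e ~ N(0, I * sigma2_e)`, maximising the restricted likelihood over
#' the log-variances. Heritability `h2 = sigma2_a / total` and repeatability
#' `r = (sigma2_a + sigma2_pe) / total` are derived with delta-method
#' standard errors from the inverse observed information.
#'
#' @param data table with columns `animal`, the response, and any
#'   fixed-effect metadata used by `fixed`.
#' @param response name of the response column.
#' @param pedigree pedigree table (`animal`, `sire`, `dam`).
#' @param fixed either a sparse design matrix, `NULL` for
#'   [repeatability_design()] on the available columns, or `~1` style
#'   one-sided formula evaluated in `data`.
#' @param include_pe fit the permanent-environmental component (default
#'   TRUE; must be FALSE when every animal has a single record, otherwise
#'   `sigma2_pe` and `sigma2_e` are not separable).
#' @param start optional starting proportions `c(a, pe, e)` of the
#'   phenotypic variance.
#' @param se compute standard errors (default TRUE).
#' @param reltol relative convergence tolerance of the optimiser.
#' @return object of class `reml_fit`.
#' @export
fit_univariate_repeatability <- function(data, response, pedigree,
                                         fixed = NULL, include_pe = TRUE,
                                         start = NULL, se = TRUE,
                                         reltol = 1e-12, polish = TRUE) {
  dt <- data.table::as.data.table(data)
  stopifnot("animal" %in% names(dt), response %in% names(dt))
  dt <- dt[!is.na(dt[[response]]), ]
  y <- as.numeric(dt[[response]])
  n <- length(y)
  if (n < 10L) stop("too few records for REML")

  X <- if (is.null(fixed)) repeatability_design(dt)
       else if (inherits(fixed, "formula")) drop_aliased(
         Matrix::sparse.model.matrix(fixed, data = as.data.frame(dt)))
       else fixed
  p <- ncol(X)
  at <- prepare_animal_terms(dt, pedigree)
  max_rec <- max(table(at$pos))
  if (include_pe && max_rec == 1L)
    stop("sigma2_pe and sigma2_e are not separable: every animal has a ",
         "single record; refit with include_pe = FALSE")

  W <- cbind(X, at$Z1, if (include_pe) at$Z2)
  WtW <- Matrix::forceSymmetric(Matrix::crossprod(W))
  Wty <- as.numeric(Matrix::crossprod(W, y))
  yty <- sum(y * y)
  q <- ncol(at$Z1)
  qc <- if (include_pe) ncol(at$Z2) else 0L
  vp <- stats::var(y)

  pad <- function(M, at_, dim_) {
    # place sparse block M at offset at_ within dim_ x dim_ zero matrix
    T_ <- Matrix::sparseMatrix(i = seq_len(nrow(M)) + at_, j = seq_len(nrow(M)),
                               x = 1, dims = c(dim_, nrow(M)))
    T_ %*% M %*% Matrix::t(T_)
  }
  dim_C <- p + q + qc
  Ablock <- pad(at$Ainv, p, dim_C)
  Iblock <- if (include_pe)
    pad(Matrix::Diagonal(qc), p + q, dim_C) else NULL

  make_C <- function(va, vpe, ve) {
    C <- WtW / ve + Ablock / va
    if (include_pe) C <- C + Iblock / vpe
    Matrix::forceSymmetric(C)
  }
  ch <- Matrix::Cholesky(make_C(vp, vp, vp), LDL = FALSE)

  m2ll <- function(th) {
    va <- exp(th[1])
    vpe <- if (include_pe) exp(th[2]) else 1
    ve <- exp(th[length(th)])
    C <- make_C(va, vpe, ve)
    chl <- tryCatch(Matrix::update(ch, C), error = function(e) NULL)
    if (is.null(chl)) return(1e10)
    rhs <- Wty / ve
    sol <- as.numeric(Matrix::solve(chl, rhs, system = "A"))
    ypy <- yty / ve - sum(sol * rhs)
    n * log(ve) + q * log(va) + at$logdet_A +
      (if (include_pe) qc * log(vpe) else 0) + logdet_chol(chl) + ypy
  }

  if (is.null(start)) start <- if (include_pe) c(0.3, 0.25, 0.45) else c(0.4, 0.6)
  th0 <- log(vp * start)
  lower <- rep(log(vp * 1e-8), length(th0))
  upper <- rep(log(vp * 1e4), length(th0))
  opt <- stats::nlminb(th0, m2ll, lower = lower, upper = upper,
                       control = list(rel.tol = reltol, iter.max = 500,
                                      eval.max = 1500))
  pol <- if (polish) newton_polish(m2ll, opt$par, lower, upper)
         else list(par = opt$par, objective = opt$objective)
  th <- pol$par

  va <- exp(th[1])
  vpe <- if (include_pe) exp(th[2]) else 0
  ve <- exp(th[length(th)])
  vc <- c(sigma2_a = va, sigma2_pe = vpe, sigma2_e = ve)

  # BLUP solutions at the optimum
  C <- make_C(va, max(vpe, vp * 1e-12), ve)
  chl <- Matrix::update(ch, C)
  sol <- as.numeric(Matrix::solve(chl, Wty / ve, system = "A"))
  ebv <- sol[p + seq_len(q)]
  names(ebv) <- at$animals

  out <- list(varcomp = vc, include_pe = include_pe,
              m2logl = pol$objective, convergence = opt$convergence,
              n_records = n, n_animals = q, n_fixed = p,
              ebv = ebv, fixed_solutions = sol[seq_len(p)],
              response = response)
  ratios <- derive_ratios_internal(vc)
  out <- c(out, ratios)

  if (se) {
    fvar <- function(v) m2ll(log(c(v[1], if (include_pe) v[2],
                                   v[length(v)])))
    v0 <- if (include_pe) vc else vc[c(1, 3)]
    H <- num_hess(fvar, v0, h = pmax(1e-5 * v0, 1e-10))
    Vcov <- tryCatch(2 * solve(H), error = function(e) matrix(NA, length(v0), length(v0)))
    out$vcov <- Vcov
    out$se <- se_from_vcov(vc, Vcov, include_pe)
  }
  class(out) <- "reml_fit"
  out
}

derive_ratios_internal <- function(vc) {
  tot <- sum(vc)
  list(h2 = unname(vc["sigma2_a"] / tot),
       repeatability = unname((vc["sigma2_a"] + vc["sigma2_pe"]) / tot),
       phenotypic_variance = tot)
}

se_from_vcov <- function(vc, Vcov, include_pe) {
  if (anyNA(Vcov)) return(NULL)
  va <- vc[["sigma2_a"]]; vpe <- vc[["sigma2_pe"]]; ve <- vc[["sigma2_e"]]
  tot <- va + vpe + ve
  if (include_pe) {
    gh2 <- c((tot - va) / tot^2, -va / tot^2, -va / tot^2)
    gr <- c(ve / tot^2, ve / tot^2, -(va + vpe) / tot^2)
  } else {
    gh2 <- c((tot - va) / tot^2, -va / tot^2)
    gr <- gh2
  }
  comp_se <- sqrt(pmax(diag(Vcov), 0))
  names(comp_se) <- if (include_pe) names(vc) else names(vc)[c(1, 3)]
  list(components = comp_se,
       h2 = sqrt(max(0, drop(gh2 %*% Vcov %*% gh2))),
       repeatability = sqrt(max(0, drop(gr %*% Vcov %*% gr))))
}

#' Heritability and repeatability from variance components
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_pe + sigma2_e)` and
#' `r = (sigma2_a + sigma2_pe) / (sigma2_a + sigma2_pe + sigma2_e)`;
#' `h2 <= r` by construction.
#'
#' @param components named vector with `sigma2_a`, `sigma2_pe`, `sigma2_e`.
#' @return list with `h2`, `repeatability`, `phenotypic_variance`.
#' @export
derive_ratios <- function(components) {
  stopifnot(all(c("sigma2_a", "sigma2_pe", "sigma2_e") %in% names(components)))
  if (sum(components) <= 0) stop("zero phenotypic variance")
  derive_ratios_internal(components)
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("Univariate repeatability animal model REML: %s\n", x$response))
  cat(sprintf("  records %d, animals %d, fixed effects %d\n",
              x$n_records, x$n_animals, x$n_fixed))
  v <- rbind(estimate = x$varcomp)
  print(signif(v, 4))
  cat(sprintf("  h2 = %.3f, repeatability = %.3f\n", x$h2, x$repeatability))
  if (!is.null(x$se))
    cat(sprintf("  SE(h2) = %.3f, SE(r) = %.3f\n", x$se$h2, x$se$repeatability))
  invisible(x)
}

#' Bivariate repeatability animal model by REML
#'
#' Stacked two-trait version of the repeatability model with unstructured
#' 2x2 additive-genetic, permanent-environmental and residual covariance
#' matrices, each parameterised through its Cholesky factor (log-scale
#' diagonal) so the estimates stay positive semidefinite. Residual
#' covariance is carried by record units (cow x parity) on which both
#' traits are observed. Genetic and permanent-environmental correlations
#' are `cov / sqrt(var1 * var2)`.
#'
#' @param data one row per cow x parity with both trait columns (NA
#'   allowed) plus `animal` and fixed-effect metadata.
#' @param traits character vector of the two trait column names.
#' @param pedigree pedigree table.
#' @param fixed as in [fit_univariate_repeatability()]; built per trait.
#' @param include_pe fit permanent-environmental components (default TRUE).
#' @param start optional list with 2x2 matrices `G`, `P`, `R`.
#' @param se compute standard errors of the correlations (default TRUE).
#' @param reltol optimiser tolerance.
#' @return object of class `reml_biv_fit` with `G`, `P`, `R` (2x2
#'   matrices), `r_g`, `r_pe` (+ SEs), `m2logl`, `boundary` flag.
#' @export
fit_bivariate_repeatability <- function(data, traits, pedigree, fixed = NULL,
                                        include_pe = TRUE, start = NULL,
                                        se = TRUE, reltol = 1e-9) {
  stopifnot(length(traits) == 2L)
  dt <- data.table::as.data.table(data)
  has <- cbind(!is.na(dt[[traits[1]]]), !is.na(dt[[traits[2]]]))
  dt <- dt[has[, 1] | has[, 2], ]
  has <- cbind(!is.na(dt[[traits[1]]]), !is.na(dt[[traits[2]]]))
  n_unit <- nrow(dt)

  Xs <- vector("list", 2L)
  ys <- vector("list", 2L)
  rows <- vector("list", 2L)
  for (t in 1:2) {
    sub <- dt[has[, t], ]
    Xs[[t]] <- if (is.null(fixed)) repeatability_design(sub)
               else if (inherits(fixed, "formula")) drop_aliased(
                 Matrix::sparse.model.matrix(fixed, data = as.data.frame(sub)))
               else fixed[has[, t], , drop = FALSE]
    ys[[t]] <- as.numeric(sub[[traits[t]]])
    rows[[t]] <- which(has[, t])
  }
  at <- prepare_animal_terms(dt, pedigree)
  q <- length(at$animals)
  qc <- length(at$cows)
  n1 <- length(ys[[1]])
  n2 <- length(ys[[2]])
  n_obs <- n1 + n2
  y <- c(ys[[1]], ys[[2]])

  bdiag2 <- function(M1, M2) Matrix::bdiag(M1, M2)
  X <- bdiag2(Xs[[1]], Xs[[2]])
  Z1 <- bdiag2(at$Z1[rows[[1]], , drop = FALSE], at$Z1[rows[[2]], , drop = FALSE])
  Z2 <- bdiag2(at$Z2[rows[[1]], , drop = FALSE], at$Z2[rows[[2]], , drop = FALSE])
  W <- cbind(X, Z1, if (include_pe) Z2)
  p <- ncol(X)
  dim_C <- p + 2L * q + (if (include_pe) 2L * qc else 0L)

  # sparse R-inverse pattern: 2x2 blocks on units with both traits
  unit_of <- c(rows[[1]], rows[[2]])
  obs_trait <- rep(1:2, c(n1, n2))
  both_units <- which(has[, 1] & has[, 2])
  o1 <- match(both_units, rows[[1]])        # obs index of trait-1 record
  o2 <- n1 + match(both_units, rows[[2]])   # obs index of trait-2 record
  ri_i <- c(seq_len(n_obs), o1)
  ri_j <- c(seq_len(n_obs), o2)

  only <- !(seq_len(n_obs) %in% c(o1, o2))
  rinv_matrix <- function(R0) {
    Ri <- solve(R0)
    dvals <- numeric(n_obs)
    dvals[o1] <- Ri[1, 1]
    dvals[o2] <- Ri[2, 2]
    dvals[only & obs_trait == 1] <- 1 / R0[1, 1]
    dvals[only & obs_trait == 2] <- 1 / R0[2, 2]
    Matrix::sparseMatrix(i = ri_i, j = ri_j, x = c(dvals, rep(Ri[1, 2], length(o1))),
                         dims = c(n_obs, n_obs), symmetric = TRUE)
  }

  chol2 <- function(v) {
    L <- matrix(0, 2, 2)
    L[1, 1] <- exp(v[1]); L[2, 1] <- v[2]; L[2, 2] <- exp(v[3])
    L %*% t(L)
  }
  par2mats <- function(th) {
    i <- 0L
    G0 <- chol2(th[1:3])
    P0 <- if (include_pe) chol2(th[4:6]) else NULL
    R0 <- chol2(th[(length(th) - 2):length(th)])
    list(G0 = G0, P0 = P0, R0 = R0)
  }

  n_both <- length(both_units)
  n_only1 <- n1 - n_both
  n_only2 <- n2 - n_both
  ch_cache <- new.env()

  m2ll <- function(th) {
    m <- par2mats(th)
    if (any(!is.finite(unlist(m[c("G0", "R0")])))) return(1e10)
    Rinv <- rinv_matrix(m$R0)
    CtW <- Matrix::crossprod(W, Rinv)
    C <- Matrix::forceSymmetric(CtW %*% W)
    Ga_inv <- kronecker(solve(m$G0), at$Ainv)
    C <- C + pad_block(Ga_inv, p, dim_C)
    if (include_pe)
      C <- C + pad_block(kronecker(solve(m$P0), Matrix::Diagonal(qc)),
                         p + 2L * q, dim_C)
    C <- Matrix::forceSymmetric(C)
    chl <- if (is.null(ch_cache$ch)) {
      ch_cache$ch <- Matrix::Cholesky(C, LDL = FALSE)
    } else tryCatch(Matrix::update(ch_cache$ch, C), error = function(e) NULL)
    if (is.null(chl)) return(1e10)
    rhs <- as.numeric(CtW %*% y)
    sol <- as.numeric(Matrix::solve(chl, rhs, system = "A"))
    ypy <- sum(y * as.numeric(Rinv %*% y)) - sum(sol * rhs)
    logR <- n_both * log(det(m$R0)) + n_only1 * log(m$R0[1, 1]) +
      n_only2 * log(m$R0[2, 2])
    logG <- q * log(det(m$G0)) + 2 * at$logdet_A +
      (if (include_pe) qc * log(det(m$P0)) else 0)
    logR + logG + logdet_chol(chl) + ypy
  }

  v1 <- stats::var(ys[[1]])
  v2 <- stats::var(ys[[2]])
  pc <- tryCatch(stats::cor(dt[[traits[1]]], dt[[traits[2]]],
                            use = "complete.obs"), error = function(e) 0)
  if (!is.finite(pc)) pc <- 0
  mk_start <- function(sh1, sh2, r) {
    cv <- r * sqrt(v1 * sh1 * v2 * sh2)
    S <- matrix(c(v1 * sh1, cv, cv, v2 * sh2), 2, 2)
    U <- chol(S + diag(1e-8 * c(v1, v2)))  # S = U'U, lower factor is t(U)
    c(log(U[1, 1]), U[1, 2], log(U[2, 2]))
  }
  th0 <- if (is.null(start)) {
    c(mk_start(0.3, 0.3, 0.5 * pc),
      if (include_pe) mk_start(0.25, 0.25, 0.5 * pc),
      mk_start(0.45, 0.45, 0.5 * pc))
  } else {
    enc <- function(M) {
      L <- t(chol(M))
      c(log(L[1, 1]), L[2, 1], log(L[2, 2]))
    }
    c(enc(start$G), if (include_pe) enc(start$P), enc(start$R))
  }
  sc <- sqrt(c(v1, v2))
  lim <- log(max(sc) * 1e3)
  lower <- rep(c(log(min(sc) * 1e-5), -max(sc)^2 * 1e6, log(min(sc) * 1e-5)),
               length(th0) / 3)
  upper <- rep(c(lim, max(sc)^2 * 1e6, lim), length(th0) / 3)
  opt <- stats::nlminb(th0, m2ll, lower = lower, upper = upper,
                       control = list(rel.tol = reltol, iter.max = 400,
                                      eval.max = 1200))
  th <- opt$par
  m <- par2mats(th)
  corr <- function(M) M[1, 2] / sqrt(M[1, 1] * M[2, 2])
  r_g <- corr(m$G0)
  r_pe <- if (include_pe) corr(m$P0) else NA_real_
  out <- list(G = m$G0, P = m$P0, R = m$R0,
              r_g = r_g, r_pe = r_pe, r_e = corr(m$R0),
              m2logl = opt$objective, convergence = opt$convergence,
              traits = traits, n_units = n_unit, n_obs = n_obs,
              boundary = abs(r_g) > 0.98 ||
                (include_pe && is.finite(r_pe) && abs(r_pe) > 0.98))
  if (se) {
    H <- num_hess(m2ll, th, h = 1e-3)
    Vth <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(Vth) && all(is.finite(Vth))) {
      g_rg <- num_grad(function(v) corr(par2mats(v)$G0), th, h = 1e-5)
      out$se_r_g <- sqrt(max(0, drop(g_rg %*% Vth %*% g_rg)))
      if (include_pe) {
        g_rpe <- num_grad(function(v) corr(par2mats(v)$P0), th, h = 1e-5)
        out$se_r_pe <- sqrt(max(0, drop(g_rpe %*% Vth %*% g_rpe)))
      }
    }
  }
  class(out) <- "reml_biv_fit"
  out
}

pad_block <- function(M, at_, dim_) {
  T_ <- Matrix::sparseMatrix(i = seq_len(nrow(M)) + at_, j = seq_len(nrow(M)),
                             x = 1, dims = c(dim_, nrow(M)))
  Matrix::forceSymmetric(T_ %*% M %*% Matrix::t(T_))
}

#' @export
print.reml_biv_fit <- function(x, ...) {
  cat(sprintf("Bivariate repeatability animal model REML: %s / %s\n",
              x$traits[1], x$traits[2]))
  cat(sprintf("  r_g = %.3f%s, r_pe = %.3f%s\n",
              x$r_g, if (!is.null(x$se_r_g)) sprintf(" (%.3f)", x$se_r_g) else "",
              x$r_pe, if (!is.null(x$se_r_pe)) sprintf(" (%.3f)", x$se_r_pe) else ""))
  if (x$boundary) cat("  note: estimate at the |r| = 1 boundary\n")
  invisible(x)
}

#' Simulate phenotypes directly under the repeatability animal model
#'
#' Draws breeding values along the pedigree (parent average + Mendelian
#' sampling), one permanent-environmental effect per cow, and iid residuals
#' for `n_records` repeated records on every final-generation female (or on
#' all animals when the pedigree carries no sex column). Useful as ground
#' truth for REML validation.
#'
#' @param ped pedigree (`animal`, `sire`, `dam`, optionally `sex`,
#'   `generation`).
#' @param sigma2_a,sigma2_pe,sigma2_e true variance components.
#' @param n_records records per animal (parities).
#' @param mu overall mean.
#' @param seed integer seed.
#' @return `data.table` with `animal`, `parity`, `y`, `true_bv`.
#' @export
simulate_repeatability_phenotypes <- function(ped, sigma2_a, sigma2_pe,
                                              sigma2_e, n_records = 3L,
                                              mu = 0, seed = 1L) {
  set.seed(seed)
  idx <- check_pedigree(ped)
  n <- nrow(ped)
  f <- inbreeding_coefficients(ped)$f
  s <- idx$sire_idx
  d <- idx$dam_idx
  a <- numeric(n)
  z <- stats::rnorm(n, 0, sqrt(sigma2_a))
  for (i in seq_len(n)) {
    if (s[i] == 0L && d[i] == 0L) { a[i] <- z[i]; next }
    pa <- 0; fbar <- 0; k <- 0L
    if (s[i] > 0L) { pa <- pa + a[s[i]]; fbar <- fbar + f[s[i]]; k <- k + 1L }
    if (d[i] > 0L) { pa <- pa + a[d[i]]; fbar <- fbar + f[d[i]]; k <- k + 1L }
    msv <- if (k == 2L) 0.5 * (1 - fbar / 2) else 0.75 - 0.25 * fbar
    a[i] <- pa / 2 + sqrt(msv) * z[i]
  }
  rec_on <- if ("sex" %in% names(ped) && "generation" %in% names(ped))
    which(ped$sex == "F" & ped$generation == max(ped$generation))
  else seq_len(n)
  pe <- stats::rnorm(length(rec_on), 0, sqrt(sigma2_pe))
  out <- data.table::data.table(
    animal = rep(ped$animal[rec_on], each = n_records),
    parity = rep(seq_len(n_records), length(rec_on)),
    true_bv = rep(a[rec_on], each = n_records))
  out$y <- mu + out$true_bv + rep(pe, each = n_records) +
    stats::rnorm(nrow(out), 0, sqrt(sigma2_e))
  out
}
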