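#' Simulate a half-sib structured pedigree
#'
#' Builds a pedigree of unrelated founder sires and dams followed by one or
#' more offspring generations. Each dam is assigned to a single sire, so the
#' offspring of one sire form a paternal half-sib family, the family
#' structure that carries most of the additive-genetic information in a
#' typical dairy population.
#'
#' @param n_sires number of founder sires per generation (>= 1).
#' @param n_dams_per_sire number of dams mated to each sire (>= 1).
#' @param generations number of offspring generations (>= 1). For
#'   `generations > 1` every female offspring of the previous generation is
#'   mated to a randomly chosen sire from a fresh set of founder sires.
#' @param seed integer seed; the same seed and counts give an identical
#'   pedigree.
#' @return a `data.table` with columns `animal`, `sire`, `dam` (0 = unknown),
#'   `sex` ("M"/"F") and `generation` (0 = founder). Parents always precede
#'   their offspring.
#' @export
simulate_pedigree <- function(n_sires, n_dams_per_sire, generations = 1L, seed = 1L) {
  if (n_sires < 1L || n_dams_per_sire < 1L || generations < 1L)
    stop("n_sires, n_dams_per_sire and generations must all be >= 1")
  set.seed(seed)
  animal <- sire <- dam <- integer(0)
  sex <- character(0)
  gen <- integer(0)
  nid <- 0L
  new_ids <- function(n) {
    ids <- nid + seq_len(n)
    nid <<- nid + n
    ids
  }
  sires0 <- new_ids(n_sires)
  dams0 <- new_ids(n_sires * n_dams_per_sire)
  animal <- c(sires0, dams0)
  sire <- c(rep(0L, length(animal)))
  dam <- rep(0L, length(animal))
  sex <- c(rep("M", n_sires), rep("F", length(dams0)))
  gen <- rep(0L, length(animal))
  mothers <- dams0
  mother_sire <- rep(sires0, each = n_dams_per_sire)
  for (g in seq_len(generations)) {
    if (g > 1L) {
      # fresh unrelated sires for later generations
      s_new <- new_ids(n_sires)
      animal <- c(animal, s_new)
      sire <- c(sire, rep(0L, n_sires))
      dam <- c(dam, rep(0L, n_sires))
      sex <- c(sex, rep("M", n_sires))
      gen <- c(gen, rep(0L, n_sires))
      mother_sire <- sample(s_new, length(mothers), replace = TRUE)
    }
    off <- new_ids(length(mothers))
    animal <- c(animal, off)
    sire <- c(sire, mother_sire)
    dam <- c(dam, mothers)
    sex <- c(sex, rep("F", length(off)))
    gen <- c(gen, rep(g, length(off)))
    mothers <- off
  }
  data.table::data.table(animal = animal, sire = sire, dam = dam,
                         sex = sex, generation = gen)
}

check_pedigree <- function(ped) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  n <- nrow(ped)
  if (anyDuplicated(ped$animal)) stop("duplicate animal ids in pedigree")
  pos <- match(ped$animal, ped$animal)
  sp <- match(ped$sire, ped$animal)
  dp <- match(ped$dam, ped$animal)
  if (any(!is.na(sp) & sp >= seq_len(n)) || any(!is.na(dp) & dp >= seq_len(n)))
    stop("pedigree not ordered: a parent appears at or after its offspring")
  if (any(ped$sire != 0L & is.na(sp)) || any(ped$dam != 0L & is.na(dp)))
    stop("pedigree refers to unknown parent ids")
  invisible(list(sire_idx = ifelse(is.na(sp), 0L, sp),
                 dam_idx = ifelse(is.na(dp), 0L, dp)))
}

#' Additive genetic relationship matrix
#'
#' Computes the numerator relationship matrix A by the tabular method:
#' `A[i,i] = 1 + A[s,d]/2` and `A[j,i] = (A[j,s] + A[j,d])/2` for `j < i`,
#' with unknown parents contributing zero.
#'
#' @param ped pedigree `data.frame` with columns `animal`, `sire`, `dam`
#'   (0 = unknown parent), parents listed before offspring.
#' @return dense symmetric matrix with dimnames equal to the animal ids.
#' @export
build_relationship_matrix <- function(ped) {
  idx <- check_pedigree(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n)
  s <- idx$sire_idx
  d <- idx$dam_idx
  for (i in seq_len(n)) {
    asd <- if (s[i] > 0L && d[i] > 0L) A[s[i], d[i]] else 0
    A[i, i] <- 1 + 0.5 * asd
    if (i > 1L) {
      j <- seq_len(i - 1L)
      v <- numeric(i - 1L)
      if (s[i] > 0L) v <- v + 0.5 * A[j, s[i]]
      if (d[i] > 0L) v <- v + 0.5 * A[j, d[i]]
      A[j, i] <- v
      A[i, j] <- v
    }
  }
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

#' Inbreeding coefficients and Mendelian sampling variances
#'
#' `F_i = A[i,i] - 1` from the tabular relationship matrix, together with the
#' Mendelian sampling variance ratio `d_i` used by Henderson's rules for the
#' inverse relationship matrix (`d_i = 1/2 - (F_s + F_d)/4` with both parents
#' known, `3/4 - F_p/4` with one, 1 with none).
#'
#' @param ped pedigree as in [build_relationship_matrix()].
#' @return list with numeric vectors `f` and `d` in pedigree order.
#' @export
inbreeding_coefficients <- function(ped) {
  idx <- check_pedigree(ped)
  s <- idx$sire_idx
  d <- idx$dam_idx
  n <- nrow(ped)
  # ancestor-traversal algorithm: A[i,i] = sum_j L[i,j]^2 d_j, visiting only
  # the ancestors of i in decreasing pedigree order so contributions merge
  f <- numeric(n)
  dv <- numeric(n)
  L <- numeric(n)
  for (i in seq_len(n)) {
    si <- s[i]; di <- d[i]
    dv[i] <- if (si > 0L && di > 0L) 0.5 - 0.25 * (f[si] + f[di])
             else if (si > 0L) 0.75 - 0.25 * f[si]
             else if (di > 0L) 0.75 - 0.25 * f[di]
             else 1
    if (si == 0L || di == 0L) next  # F = 0 with an unknown parent
    aii <- 0
    L[i] <- 1
    touched <- i
    while (length(touched)) {
      j <- max(touched)
      touched <- touched[touched != j]
      lj <- L[j]
      L[j] <- 0
      aii <- aii + lj * lj * dv[j]
      sj <- s[j]; dj <- d[j]
      if (sj > 0L) {
        if (L[sj] == 0) touched <- c(touched, sj)
        L[sj] <- L[sj] + 0.5 * lj
      }
      if (dj > 0L) {
        if (L[dj] == 0) touched <- c(touched, dj)
        L[dj] <- L[dj] + 0.5 * lj
      }
    }
    f[i] <- aii - 1
  }
  list(f = f, d = dv)
}

#' Sparse inverse of the additive relationship matrix
#'
#' Builds A-inverse directly from the pedigree by Henderson's rules,
#' accounting for inbreeding. The result is sparse (at most 9 entries per
#' animal) which keeps the mixed-model equations of the animal model sparse.
#'
#' @param ped pedigree as in [build_relationship_matrix()].
#' @return list with `Ainv` (a `dsCMatrix`), `logdet_A` (log-determinant of
#'   A, equal to the sum of log Mendelian sampling variances) and `f`
#'   (inbreeding coefficients).
#' @export
a_inverse <- function(ped) {
  idx <- check_pedigree(ped)
  n <- nrow(ped)
  fd <- inbreeding_coefficients(ped)
  alpha <- 1 / fd$d
  s <- idx$sire_idx
  d <- idx$dam_idx
  ii <- jj <- xx <- vector("list", 6L)
  add <- function(i, j, x) list(i = i, j = j, x = x)
  ent <- list(add(seq_len(n), seq_len(n), alpha))
  hs <- s > 0L
  hd <- d > 0L
  ent <- c(ent, list(
    add(which(hs), s[hs], -0.5 * alpha[hs]),
    add(which(hd), d[hd], -0.5 * alpha[hd]),
    add(s[hs], s[hs], 0.25 * alpha[hs]),
    add(d[hd], d[hd], 0.25 * alpha[hd]),
    add(s[hs & hd], d[hs & hd], 0.5 * 0.25 * alpha[hs & hd] * 2)
  ))
  i <- unlist(lapply(ent, `[[`, "i"))
  j <- unlist(lapply(ent, `[[`, "j"))
  x <- unlist(lapply(ent, `[[`, "x"))
  # symmetrise: keep lower triangle, off-diagonals added once on each side
  lo <- i >= j
  i2 <- c(i[lo], j[!lo])
  j2 <- c(j[lo], i[!lo])
  x2 <- c(x[lo], x[!lo])
  Ainv <- Matrix::sparseMatrix(i = i2, j = j2, x = x2, dims = c(n, n),
                               symmetric = TRUE)
  list(Ainv = Ainv, logdet_A = sum(log(fd$d)), f = fd$f)
}
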