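# shared fixtures built in code

tiny_config <- function(...) {
  sim_config(n_herds = 3L, n_sires = 8L, n_dams_per_sire = 4L,
             n_parities = 2L, ...)
}

# random pedigree: parents drawn from earlier animals (or unknown)
random_pedigree <- function(n = 50L, p_known = 0.7, seed = 1L) {
  set.seed(seed)
  sire <- dam <- integer(n)
  for (i in seq_len(n)) {
    if (i > 2L && stats::runif(1) < p_known) {
      pr <- sample(i - 1L, 2L)
      sire[i] <- pr[1]
      dam[i] <- pr[2]
    }
  }
  data.frame(animal = seq_len(n), sire = sire, dam = dam)
}

# brute-force additive relationship by the recursive definition, memoised
kinship_oracle <- function(ped) {
  s <- ped$sire
  d <- ped$dam
  n <- nrow(ped)
  memo <- new.env(hash = TRUE)
  a <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i < j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    v <- if (i == j) 1 + 0.5 * a(s[i], d[i])
         else 0.5 * (a(s[i], j) + a(d[i], j))
    memo[[key]] <- v
    v
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) A[i, j] <- A[j, i] <- a(i, j)
  A
}

# brute-force maximal-run drop scan over every window (prefix sums)
drop_scan_oracle <- function(dim, resid, min_run = 10L) {
  o <- order(dim)
  dim <- dim[o]
  resid <- resid[o]
  n <- length(resid)
  count <- 0L
  in_drop <- logical(n)
  for (st in seq_len(n)) {
    for (en in st:n) {
      len <- en - st + 1L
      if (len < min_run) next
      window_ok <- all(resid[st:en] < 0) &&
        all(diff(dim[st:en]) == 1)
      if (!window_ok) next
      left_ext <- st > 1L && resid[st - 1L] < 0 && dim[st] - dim[st - 1L] == 1
      right_ext <- en < n && resid[en + 1L] < 0 && dim[en + 1L] - dim[en] == 1
      if (!left_ext && !right_ext) {
        count <- count + 1L
        in_drop[st:en] <- TRUE
      }
    }
  }
  list(n_drops = count,
       mean_in_drops = if (any(in_drop)) mean(resid[in_drop]) else NA_real_)
}

# definitional lag-1 autocorrelation: explicit loop over adjacent pairs
lag1_oracle <- function(dim, e) {
  o <- order(dim)
  dim <- dim[o]
  e <- e[o]
  m <- sum(e) / length(e)
  num <- 0
  den <- 0
  for (t in seq_along(e)) {
    den <- den + (e[t] - m)^2
    if (t < length(e) && dim[t + 1L] - dim[t] == 1)
      num <- num + (e[t] - m) * (e[t + 1L] - m)
  }
  num / den
}
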