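# Independent brute-force implementations used as oracles.  These
# deliberately avoid the package's code paths: counts are accumulated
# in explicit loops and formulas written out long-hand.

oracle_confusion <- function(ref, cand) {
  st <- c("W", "N1", "N2", "N3", "R")
  m <- matrix(0, 5, 5, dimnames = list(st, st))
  for (i in seq_along(ref)) {
    m[match(ref[i], st), match(cand[i], st)] <- m[match(ref[i], st), match(cand[i], st)] + 1
  }
  m
}

oracle_kappa <- function(ref, cand) {
  m <- oracle_confusion(ref, cand)
  n <- length(ref)
  po <- 0
  for (k in 1:5) po <- po + m[k, k]
  po <- po / n
  pe <- 0
  for (k in 1:5) pe <- pe + sum(m[k, ]) * sum(m[, k])
  pe <- pe / n^2
  (po - pe) / (1 - pe)
}

oracle_pnoa <- function(ref, cand, stage) {
  a <- b <- cc <- d <- 0
  for (i in seq_along(ref)) {
    if (ref[i] == stage && cand[i] == stage) a <- a + 1
    else if (ref[i] == stage) b <- b + 1
    else if (cand[i] == stage) cc <- cc + 1
    else d <- d + 1
  }
  c(PA = if (2 * a + b + cc > 0) 100 * 2 * a / (2 * a + b + cc) else NA_real_,
    "NA" = if (2 * d + b + cc > 0) 100 * 2 * d / (2 * d + b + cc) else NA_real_,
    OA = 100 * (a + d) / length(ref))
}

# Raw periodogram band-power fraction (rectangular window), an
# independent spectral oracle for band-dominance checks.
oracle_band_fraction <- function(x, fs, lo, hi) {
  x <- x - mean(x)
  n <- length(x)
  pw <- Mod(fft(x))^2 / n
  freq <- (0:(n - 1)) * fs / n
  keep <- freq <= fs / 2
  sum(pw[keep & freq >= lo & freq < hi]) / sum(pw[keep & freq >= 0.5 & freq < fs / 2])
}

random_hypnogram_pair <- function(n, seed) {
  set.seed(seed)
  st <- c("W", "N1", "N2", "N3", "R")
  list(ref = sample(st, n, replace = TRUE),
       cand = sample(st, n, replace = TRUE))
}
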