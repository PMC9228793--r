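# Discrete prolate spheroidal (Slepian) tapers via the symmetric
# tridiagonal eigenproblem: for half-bandwidth W = nw/n the matrix with
# diagonal ((n-1-2t)/2)^2 cos(2*pi*W) and off-diagonal t(n-t)/2 has the
# DPSS sequences as eigenvectors, ordered by concentration.  Results are
# cached per (n, nw, k) for the session.

.dpss_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 2, k = 3) {
  key <- paste(n, nw, k, sep = "|")
  hit <- get0(key, envir = .dpss_cache)
  if (!is.null(hit)) return(hit)
  if (k > 2 * nw - 1) abort_config("taper count k must be <= 2*nw - 1")
  w <- nw / n
  t0 <- 0:(n - 1)
  diagv <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  offv <- (1:(n - 1)) * (n - 1:(n - 1)) / 2
  m <- matrix(0, n, n)
  m[cbind(1:n, 1:n)] <- diagv
  m[cbind(1:(n - 1), 2:n)] <- offv
  m[cbind(2:n, 1:(n - 1))] <- offv
  ev <- eigen(m, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  # unit energy; fix sign so each taper starts with a non-negative lobe
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[seq_len(max(2, n %/% 8)), j]) < 0) tap[, j] <- -tap[, j]
  }
  assign(key, tap, envir = .dpss_cache)
  tap
}

#' Multitaper power spectral density of a short window
#'
#' Averages direct spectral estimates over `k` orthogonal Slepian
#' tapers (time-bandwidth product `nw`), trading frequency resolution
#' for variance -- the standard estimator for 2-s EEG sub-epochs.  The
#' one-sided PSD is scaled so that `sum(psd) * df` approximates the
#' window's variance (Parseval).
#'
#' @param window Numeric vector of samples (length >= 8).
#' @param fs Sampling rate in Hz.
#' @param nw Time-bandwidth product (default 2).
#' @param k Number of tapers (default 3; must be <= `2*nw - 1`).
#' @param demean Subtract the window mean first (default TRUE; DC
#'   offsets are amplifier artifacts, not physiology).
#' @return List with `freq` (Hz), `psd` (uV^2/Hz), and `df` (grid step).
#' @export
#' @examples
#' w <- sin(2 * pi * 10 * seq(0, 2, by = 1 / 200))[1:400]
#' s <- multitaper_psd(w, fs = 200)
#' s$freq[which.max(s$psd)]  # ~10 Hz
multitaper_psd <- function(window, fs, nw = 2, k = 3, demean = TRUE) {
  m <- multitaper_psd_matrix(matrix(window, ncol = 1), fs, nw = nw, k = k,
                             demean = demean)
  list(freq = m$freq, psd = as.vector(m$psd), df = m$df)
}

# Vectorised form: windows in columns of `x`.  Returns psd matrix
# (frequency x window).
multitaper_psd_matrix <- function(x, fs, nw = 2, k = 3, demean = TRUE) {
  n <- nrow(x)
  if (n < 8) abort_input("window too short for spectral estimation (need >= 8 samples)")
  if (demean) x <- sweep(x, 2, colMeans(x))
  tap <- dpss_tapers(n, nw, k)
  nf <- n %/% 2 + 1
  acc <- matrix(0, nf, ncol(x))
  for (j in seq_len(k)) {
    ft <- stats::mvfft(x * tap[, j])
    acc <- acc + (Mod(ft[seq_len(nf), , drop = FALSE])^2) / fs
  }
  psd <- acc / k
  # one-sided doubling (all bins except DC and, for even n, Nyquist)
  dbl <- seq(2, nf - (1 - n %% 2))
  psd[dbl, ] <- 2 * psd[dbl, ]
  list(freq = (0:(nf - 1)) * fs / n, psd = psd, df = fs / n)
}

# Integrated band power(s) of a psd matrix over [lo, hi) Hz.
band_power_matrix <- function(psd, freq, df, lo, hi) {
  sel <- freq >= lo & freq < hi
  colSums(psd[sel, , drop = FALSE]) * df
}
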