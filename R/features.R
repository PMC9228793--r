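#' Default EEG frequency bands
#'
#' Conventional AASM band edges: delta 0.5-4, theta 4-7, alpha 8-13,
#' beta 13-30 Hz.  Bands are half-open `[lo, hi)`, non-overlapping and
#' ordered; note the conventional 7-8 Hz gap between theta and alpha.
#'
#' @return Data frame with columns `name`, `lo_hz`, `hi_hz`.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta"),
             lo_hz = c(0.5, 4, 8, 13),
             hi_hz = c(4, 7, 13, 30),
             stringsAsFactors = FALSE)
}

validate_bands <- function(bands) {
  if (any(bands$lo_hz < 0) || any(bands$lo_hz >= bands$hi_hz)) {
    abort_config("each band needs 0 <= lo_hz < hi_hz")
  }
  o <- order(bands$lo_hz)
  b <- bands[o, ]
  if (any(utils::head(b$hi_hz, -1) > utils::tail(b$lo_hz, -1) + 1e-12)) {
    abort_config("bands must be non-overlapping")
  }
  b
}

#' Feature-extraction configuration
#'
#' @param epoch_len_s Scoring epoch length (s).
#' @param window_s Sub-epoch window length (s); default 2.
#' @param step_s Sub-epoch step (s); default 1 (i.e. 1-s overlap), which
#'   tiles a 30-s epoch with 29 sub-epochs.
#' @param nw,k Multitaper time-bandwidth product and taper count.
#' @param bands EEG band table as from [default_bands()].
#' @param eog_band EOG energy band in Hz (default 0.3-5, spanning slow
#'   rolling and rapid eye movements).
#' @param total_band Band over which "total power of an epoch" is
#'   integrated (default 0.5-30 Hz, the analysed range).
#' @param eps Denominator guard for power ratios and dead channels.
#' @return List of class `feature_config`.
#' @export
feature_config <- function(epoch_len_s = 30, window_s = 2, step_s = 1,
                           nw = 2, k = 3, bands = default_bands(),
                           eog_band = c(0.3, 5), total_band = c(0.5, 30),
                           eps = 1e-12) {
  if (window_s <= 0 || step_s <= 0 || step_s > window_s) {
    abort_config("need window_s > 0 and 0 < step_s <= window_s")
  }
  structure(list(epoch_len_s = epoch_len_s, window_s = window_s,
                 step_s = step_s, nw = nw, k = k,
                 bands = validate_bands(bands), eog_band = eog_band,
                 total_band = total_band, eps = eps),
            class = "feature_config")
}

#' Slice an epoch into overlapping sub-epoch windows
#'
#' @param x Numeric vector, the epoch's samples for one channel.
#' @param fs Sampling rate (Hz).
#' @param window_s Window length (s).
#' @param step_s Step between window starts (s).
#' @return Matrix with one window per column
#'   (`floor((L - window_s)/step_s) + 1` columns for an `L`-second
#'   epoch).
#' @export
#' @examples
#' ncol(segment_subepochs(rnorm(6000), fs = 200))  # 29
segment_subepochs <- function(x, fs, window_s = 2, step_s = 1) {
  nw_s <- round(window_s * fs)
  ns_s <- round(step_s * fs)
  if (length(x) < nw_s) abort_input("epoch shorter than the sub-epoch window")
  n_win <- (length(x) - nw_s) %/% ns_s + 1L
  starts <- (seq_len(n_win) - 1L) * ns_s
  idx <- outer(seq_len(nw_s), starts, `+`)
  matrix(x[idx], nrow = nw_s)
}

#' Band-power fractions of a PSD
#'
#' Each band's integrated power divided by the epoch's total power, so
#' that fractions are invariant to overall amplitude scaling.
#'
#' @param psd A list as returned by [multitaper_psd()].
#' @param bands Band table ([default_bands()]).
#' @param total_power Total epoch power (uV^2) to normalise by.
#' @param eps Guard below which the signal is considered dead.
#' @return Named numeric vector of fractions, one per band.
#' @export
band_power_fractions <- function(psd, bands = default_bands(), total_power,
                                 eps = 1e-12) {
  if (!is.numeric(total_power) || total_power <= eps) {
    abort_input("degenerate signal: total epoch power is (near) zero")
  }
  bp <- vapply(seq_len(nrow(bands)), function(i) {
    sum(psd$psd[psd$freq >= bands$lo_hz[i] & psd$freq < bands$hi_hz[i]]) * psd$df
  }, numeric(1))
  stats::setNames(bp / total_power, bands$name)
}

#' Spectral power ratios
#'
#' Delta/theta, theta/alpha and delta/alpha ratios with an additive
#' denominator guard so the result is always finite.
#'
#' @param fractions Named vector with at least `delta`, `theta`,
#'   `alpha` entries (fractions or absolute powers; the ratio is the
#'   same).
#' @param eps Denominator guard.
#' @return Named vector `delta_theta`, `theta_alpha`, `delta_alpha`.
#' @export
power_ratios <- function(fractions, eps = 1e-12) {
  if (any(fractions < 0, na.rm = TRUE)) abort_input("band powers must be >= 0")
  c(delta_theta = unname(fractions["delta"] / (fractions["theta"] + eps)),
    theta_alpha = unname(fractions["theta"] / (fractions["alpha"] + eps)),
    delta_alpha = unname(fractions["delta"] / (fractions["alpha"] + eps)))
}

#' Line length of a window
#'
#' Sum of absolute successive differences, a cheap time-domain measure
#' of waveform complexity/amplitude.
#'
#' @param x Numeric vector, length >= 2.
#' @return Non-negative scalar (uV).
#' @export
line_length <- function(x) {
  if (length(x) < 2L) abort_input("line_length needs at least 2 samples")
  sum(abs(diff(x)))
}

#' Pearson (non-excess) kurtosis
#'
#' `m4 / m2^2` on population moments; 3 for a Gaussian.  Errors on
#' zero-variance input.
#'
#' @param x Numeric vector, length >= 4.
#' @return Dimensionless scalar.
#' @export
kurtosis_pearson <- function(x) {
  if (length(x) < 4L) abort_input("kurtosis needs at least 4 samples")
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 <= 0) abort_input("degenerate signal: zero variance")
  mean(xc^4) / m2^2
}

#' Summaries of a per-sub-epoch feature track
#'
#' @param track Numeric vector of per-sub-epoch values (length >= 2).
#' @return Named vector `p95` (95th percentile, linear interpolation
#'   between order statistics), `min`, `mean`, `sd` (sample, n-1).
#' @export
#' @examples
#' summarize_track(1:29)  # p95 = 27.6
summarize_track <- function(track) {
  if (length(track) < 2L) abort_input("track needs at least 2 values")
  c(p95 = unname(stats::quantile(track, 0.95, type = 7, names = FALSE)),
    min = min(track), mean = mean(track), sd = stats::sd(track))
}

#' Element-wise average of contralateral feature tracks
#'
#' @param left,right Numeric vectors of equal length.
#' @return Their element-wise arithmetic mean.
#' @export
contralateral_average <- function(left, right) {
  if (length(left) != length(right)) {
    abort_input("contralateral tracks have different lengths")
  }
  (left + right) / 2
}

#' EOG band energy of a window
#'
#' Integrated multitaper PSD over a fixed low-frequency band covering
#' slow rolling and rapid eye movements.
#'
#' @param x Window samples.
#' @param fs Sampling rate (Hz).
#' @param band `c(lo, hi)` in Hz.
#' @param nw,k Multitaper parameters.
#' @return Non-negative scalar (uV^2).
#' @export
eog_band_energy <- function(x, fs, band = c(0.3, 5), nw = 2, k = 3) {
  s <- multitaper_psd(x, fs, nw = nw, k = k)
  sum(s$psd[s$freq >= band[1] & s$freq < band[2]]) * s$df
}

#' EMG energy of a window
#'
#' Mean squared amplitude after mean removal (DC rejected).
#'
#' @param x Window samples (non-empty).
#' @return Non-negative scalar (uV^2).
#' @export
emg_energy <- function(x) {
  if (length(x) < 1L) abort_input("empty EMG window")
  xc <- x - mean(x)
  mean(xc^2)
}

# ---------------------------------------------------------------------
# Full per-epoch feature vector.

eeg_sites <- function() {
  list(frontal   = c("F3-M2", "F4-M1"),
       central   = c("C3-M2", "C4-M1"),
       occipital = c("O1-M2", "O2-M1"))
}

site_feature_names <- function() {
  c("delta_frac", "theta_frac", "alpha_frac", "beta_frac",
    "delta_theta_ratio", "theta_alpha_ratio", "delta_alpha_ratio",
    "line_length", "kurtosis")
}

summary_names <- function() c("p95", "min", "mean", "sd")

#' Feature-vector layout
#'
#' The fixed name/order contract of the per-epoch feature vector:
#' (site: frontal, central, occipital) x (band fractions, power ratios,
#' line length, kurtosis) x (p95, min, mean, sd), then the EOG
#' band-energy summaries, then the EMG energy summaries.
#'
#' @param config A [feature_config()] (reserved for future layout
#'   options; the default layout does not depend on it).
#' @return Character vector of feature names.
#' @export
feature_layout <- function(config = feature_config()) {
  eeg <- as.vector(vapply(names(eeg_sites()), function(site) {
    as.vector(vapply(site_feature_names(), function(f) {
      paste(site, f, summary_names(), sep = "_")
    }, character(4)))
  }, character(36)))
  c(eeg,
    paste("eog_energy", summary_names(), sep = "_"),
    paste("emg_energy", summary_names(), sep = "_"))
}

#' Extract per-epoch features from a polysomnography record
#'
#' For every whole 30-s epoch: each contralateral EEG pair is sliced
#' into 2-s sub-epochs with 1-s overlap (29 per epoch), multitaper PSDs
#' of left and right channels are averaged, band powers are normalised
#' by the epoch's total 0.5-30 Hz power, and the resulting per-sub-epoch
#' tracks (four band fractions, three power ratios, line length,
#' kurtosis) are summarised by their 95th percentile, minimum, mean and
#' standard deviation.  EOG channels contribute low-band energy
#' summaries and the chin EMG its mean-squared energy summaries.
#'
#' @param record A [psg_record()] carrying the six EEG derivations, at
#'   least one of `EOG-L`/`EOG-R`, and `chin-EMG`.
#' @param config A [feature_config()].
#' @return Numeric matrix, one row per epoch, columns named per
#'   [feature_layout()].  Attribute `flagged` marks epochs with a dead
#'   channel whose site features were zero-filled.
#' @export
extract_features <- function(record, config = feature_config()) {
  if (!inherits(record, "psg_record")) abort_input("expected a psg_record")
  sites <- eeg_sites()
  need <- unlist(sites)
  missing <- setdiff(need, names(record$channels))
  if (length(missing) > 0L) {
    abort_config(sprintf("missing required EEG channel(s): %s",
                         paste(missing, collapse = ", ")))
  }
  eogs <- intersect(c("EOG-L", "EOG-R"), names(record$channels))
  if (length(eogs) < 1L) abort_config("missing required EOG channel (EOG-L or EOG-R)")
  if (!("chin-EMG" %in% names(record$channels))) {
    abort_config("missing required channel: chin-EMG")
  }

  n_ep <- epoch_count(record, config$epoch_len_s)
  if (n_ep < 1L) abort_input("record shorter than one epoch")
  layout <- feature_layout(config)
  out <- matrix(NA_real_, n_ep, length(layout), dimnames = list(NULL, layout))
  flagged <- logical(n_ep)
  bands <- config$bands
  tb <- config$total_band

  for (e in seq_len(n_ep)) {
    vec <- numeric(0)
    for (site in names(sites)) {
      pair <- sites[[site]]
      chL <- record$channels[[pair[1]]]
      chR <- record$channels[[pair[2]]]
      wL <- segment_subepochs(epoch_samples(chL, e, config$epoch_len_s), chL$fs,
                              config$window_s, config$step_s)
      wR <- segment_subepochs(epoch_samples(chR, e, config$epoch_len_s), chR$fs,
                              config$window_s, config$step_s)
      sL <- multitaper_psd_matrix(wL, chL$fs, config$nw, config$k)
      sR <- multitaper_psd_matrix(wR, chR$fs, config$nw, config$k)
      # contralateral PSD averaging (requires matching fs, hence grids)
      if (length(sL$freq) != length(sR$freq)) {
        abort_config(sprintf("contralateral pair %s/%s sampled at different rates",
                             pair[1], pair[2]))
      }
      psd <- (sL$psd + sR$psd) / 2
      total_track <- band_power_matrix(psd, sL$freq, sL$df, tb[1], tb[2])
      epoch_total <- mean(total_track)
      if (!is.finite(epoch_total) || epoch_total <= config$eps) {
        flagged[e] <- TRUE
        vec <- c(vec, rep(0, 36))
        next
      }
      bp <- vapply(seq_len(nrow(bands)), function(i) {
        band_power_matrix(psd, sL$freq, sL$df, bands$lo_hz[i], bands$hi_hz[i])
      }, numeric(ncol(psd)))           # windows x bands
      frac <- bp / epoch_total
      colnames(frac) <- bands$name
      tracks <- list(
        delta_frac = frac[, "delta"], theta_frac = frac[, "theta"],
        alpha_frac = frac[, "alpha"], beta_frac = frac[, "beta"],
        delta_theta_ratio = frac[, "delta"] / (frac[, "theta"] + config$eps),
        theta_alpha_ratio = frac[, "theta"] / (frac[, "alpha"] + config$eps),
        delta_alpha_ratio = frac[, "delta"] / (frac[, "alpha"] + config$eps),
        line_length = contralateral_average(
          apply(wL, 2, line_length), apply(wR, 2, line_length)),
        kurtosis = contralateral_average(
          apply(wL, 2, safe_kurtosis), apply(wR, 2, safe_kurtosis)))
      if (anyNA(tracks$kurtosis)) {
        flagged[e] <- TRUE
        tracks$kurtosis[is.na(tracks$kurtosis)] <- 0
      }
      vec <- c(vec, unlist(lapply(tracks, summarize_track), use.names = FALSE))
    }
    # EOG: band energy per sub-epoch, averaged over available channels
    eog_tracks <- lapply(eogs, function(lab) {
      ch <- record$channels[[lab]]
      w <- segment_subepochs(epoch_samples(ch, e, config$epoch_len_s), ch$fs,
                             config$window_s, config$step_s)
      s <- multitaper_psd_matrix(w, ch$fs, config$nw, config$k)
      band_power_matrix(s$psd, s$freq, s$df, config$eog_band[1], config$eog_band[2])
    })
    eog_track <- Reduce(`+`, eog_tracks) / length(eog_tracks)
    chE <- record$channels[["chin-EMG"]]
    wE <- segment_subepochs(epoch_samples(chE, e, config$epoch_len_s), chE$fs,
                            config$window_s, config$step_s)
    emg_track <- apply(wE, 2, emg_energy)
    vec <- c(vec, summarize_track(eog_track), summarize_track(emg_track))
    out[e, ] <- vec
  }
  attr(out, "flagged") <- flagged
  attr(out, "layout") <- layout
  out
}

safe_kurtosis <- function(x) {
  tryCatch(kurtosis_pearson(x), error = function(e) NA_real_)
}

#' Write a feature matrix as TSV with its layout
#'
#' @param features Matrix from [extract_features()].
#' @param path Output `.tsv` path; a sidecar `<path>.layout` file lists
#'   the column contract one name per line.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  utils::write.table(as.data.frame(features), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(colnames(features), paste0(path, ".layout"))
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#'
#' @param path The `.tsv` path.
#' @return Numeric matrix with column names.
#' @export
read_features <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("feature file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  as.matrix(df)
}
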