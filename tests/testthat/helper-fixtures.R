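# Fixture builders shared across test files.  Everything is generated
# in code at test time; no data files.

make_sine_record <- function(freqs = rep(10, 9), fs = 200, dur = 60,
                             amps = rep(50, 9)) {
  labs <- c("F3-M2", "F4-M1", "C3-M2", "C4-M1", "O1-M2", "O2-M1",
            "EOG-L", "EOG-R", "chin-EMG")
  tt <- (0:(dur * fs - 1)) / fs
  chans <- lapply(seq_along(labs), function(i) {
    channel_signal(labs[i], amps[i] * sin(2 * pi * freqs[i] * tt), fs)
  })
  psg_record(chans, subject_id = "fixture")
}

# Stage-separated feature matrices directly on the real layout, so the
# stager can be exercised without signal synthesis.  Class-conditional
# Gaussians; like real extracted features, the stage signal is spread
# over whole summary blocks (p95/min/mean/sd move together) and over
# correlated neighbouring sites, not isolated single columns.
make_feature_subject <- function(n_epochs, seed, noise_sd = 0.3) {
  set.seed(seed)
  layout <- feature_layout()
  h <- generate_hypnogram(epochs = n_epochs, seed = seed + 1)
  lab <- as.character(h)
  # shifts per feature stem; applied to all four summary columns
  centers <- list(
    W  = c(occipital_alpha_frac = 3, central_alpha_frac = 1.5, emg_energy = 3),
    N1 = c(central_theta_frac = 3, frontal_theta_frac = 2),
    N2 = c(central_theta_frac = 2, frontal_delta_frac = 2,
           central_delta_frac = 1.5),
    N3 = c(frontal_delta_frac = 4, central_delta_frac = 3,
           occipital_delta_frac = 2),
    R  = c(eog_energy = 3, emg_energy = -2, central_theta_frac = 1))
  X <- matrix(rnorm(n_epochs * length(layout), sd = noise_sd),
              n_epochs, length(layout), dimnames = list(NULL, layout))
  for (s in names(centers)) {
    rows <- lab == s
    for (stem in names(centers[[s]])) {
      cols <- paste(stem, c("p95", "min", "mean", "sd"), sep = "_")
      X[rows, cols] <- X[rows, cols] + centers[[s]][stem]
    }
  }
  list(features = X, labels = h)
}

make_feature_cohort <- function(n_subjects, n_epochs, seed = 1) {
  setNames(lapply(seq_len(n_subjects), function(i) {
    make_feature_subject(n_epochs, seed = seed * 1000 + i)
  }), sprintf("S%02d", seq_len(n_subjects)))
}
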