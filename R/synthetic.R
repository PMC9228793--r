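# Synthetic polysomnography: seed-reproducible signals and hypnograms
# whose stage-conditional spectral content mimics the AASM signatures
# (occipital alpha in W, low-amplitude mixed-frequency theta in N1/R,
# spindles and K-complexes in N2, high-amplitude delta in N3, rapid eye
# movements with minimal chin tone in R).  The point is testability of
# the scoring pipeline, not physiological realism.

#' Cohort stage proportions of the reference clinical population
#'
#' Mean fractions of scored epochs per stage reported for a large
#' adult clinical sleep cohort: W 16.5%, N1 15.2%, N2 50.2%, N3 2.7%,
#' R 15.4%.
#'
#' @return Named numeric vector summing to 1.
#' @export
default_stage_proportions <- function() {
  c(W = 0.165, N1 = 0.152, N2 = 0.502, N3 = 0.027, R = 0.154)
}

#' Per-stage signal recipes of the synthetic generator
#'
#' Each stage carries sinusoidal band components (centre frequency,
#' amplitude in uV, and a frontal/central/occipital site-scaling
#' triple), broadband noise, transient-event rates (spindles, K
#' complexes), an EOG behaviour, and a chin-EMG tone.  `alpha_deficient`
#' rescales the W-stage alpha component to near zero, mimicking the
#' sizeable minority of people with little or no waking alpha rhythm.
#'
#' @param alpha_deficient Use the alpha-suppressed W recipe.
#' @return Nested list, one recipe per stage; class `stage_signal_model`.
#' @export
default_stage_model <- function(alpha_deficient = FALSE) {
  comp <- function(hz, amp, site = c(1, 1, 1)) list(hz = hz, amp = amp, site = site)
  alpha_amp <- if (alpha_deficient) 1.5 else 30
  m <- list(
    W = list(components = list(comp(10, alpha_amp, c(0.6, 1.0, 1.5)),
                               comp(20, 5, c(1, 1, 1)),
                               if (alpha_deficient) comp(6, 12, c(1, 1, 1))),
             noise_sd = 10, spindle_rate = 0, kcomplex_rate = 0,
             eog = list(kind = "blink", rate = 0.5, amp = 100),
             emg_tone = 30),
    N1 = list(components = list(comp(5, 15, c(1, 1, 0.9)),
                                comp(10, 4, c(0.6, 1, 1.2))),
              noise_sd = 10, spindle_rate = 0, kcomplex_rate = 0,
              eog = list(kind = "slow", rate = 0.3, amp = 40),
              emg_tone = 15),
    N2 = list(components = list(comp(5, 15, c(1, 1, 0.9)),
                                comp(2, 10, c(1.2, 1, 0.8))),
              noise_sd = 10, spindle_rate = 2, kcomplex_rate = 1,
              eog = list(kind = "none", rate = 0, amp = 0),
              emg_tone = 10),
    N3 = list(components = list(comp(1.5, 60, c(1.3, 1, 0.7)),
                                comp(0.8, 40, c(1.3, 1, 0.7)),
                                comp(5, 6, c(1, 1, 1))),
              noise_sd = 10, spindle_rate = 0.2, kcomplex_rate = 0,
              eog = list(kind = "none", rate = 0, amp = 0),
              emg_tone = 8),
    R = list(components = list(comp(5, 12, c(1, 1, 0.9)),
                               comp(3, 8, c(1, 1, 1)),
                               comp(22, 4, c(1, 1, 1))),
             noise_sd = 10, spindle_rate = 0, kcomplex_rate = 0,
             eog = list(kind = "rem", rate = 5, amp = 80),
             emg_tone = 4))
  m <- lapply(m, function(s) { s$components <- Filter(Negate(is.null), s$components); s })
  structure(m, class = "stage_signal_model", alpha_deficient = alpha_deficient)
}

#' Synthetic cohort configuration
#'
#' @param n_subjects Number of subjects.
#' @param epochs_per_subject Scored epochs per recording (960 = 8 h of
#'   30-s epochs).
#' @param stage_proportions Target stationary stage fractions.
#' @param alpha_deficient_fraction Fraction of subjects simulated with
#'   the alpha-suppressed W recipe (default 0.2).
#' @param dirichlet_conc Concentration of the per-subject Dirichlet
#'   jitter around `stage_proportions` (larger = less between-subject
#'   variability); 10 gives spreads broadly comparable to clinical
#'   cohort SDs.
#' @param stickiness Markov self-transition blending weight (see
#'   [generate_hypnogram()]).
#' @param fs Sampling rate in Hz for all channels.
#' @param seed Master seed; all per-subject randomness derives from it.
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 30, epochs_per_subject = 960,
                          stage_proportions = default_stage_proportions(),
                          alpha_deficient_fraction = 0.2,
                          dirichlet_conc = 10, stickiness = 0.9,
                          fs = 200, seed = 1) {
  p <- stage_proportions
  if (length(p) != 5L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort_config("stage_proportions must be 5 non-negative values summing to 1")
  }
  if (alpha_deficient_fraction < 0 || alpha_deficient_fraction > 1) {
    abort_config("alpha_deficient_fraction must be in [0, 1]")
  }
  structure(list(n_subjects = n_subjects, epochs_per_subject = epochs_per_subject,
                 stage_proportions = stats::setNames(p, stage_levels()),
                 alpha_deficient_fraction = alpha_deficient_fraction,
                 dirichlet_conc = dirichlet_conc, stickiness = stickiness,
                 fs = fs, seed = seed),
            class = "cohort_config")
}

#' Markov transition matrix with a prescribed stationary law
#'
#' `P = s*I + (1-s)*rep(pi)`: with probability `s` the stage repeats,
#' otherwise the next stage is drawn from the stationary law `pi`
#' itself, so `pi` is exactly stationary for any stickiness `s` and the
#' mean run length of stage i is `1/((1-s)(1-pi_i))`.
#'
#' @param proportions Stationary stage fractions (sum 1).
#' @param stickiness Self-transition blend in `[0, 1)`; the default 0.9
#'   gives stage bouts of a few minutes, qualitatively like human sleep.
#' @return 5x5 row-stochastic matrix.
#' @export
stage_transition_matrix <- function(proportions, stickiness = 0.9) {
  p <- as.numeric(proportions)
  if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) abort_config("invalid proportions")
  if (stickiness < 0 || stickiness >= 1) abort_config("stickiness must be in [0, 1)")
  P <- stickiness * diag(5) + (1 - stickiness) * matrix(p, 5, 5, byrow = TRUE)
  dimnames(P) <- list(stage_levels(), stage_levels())
  P
}

#' Generate a synthetic hypnogram
#'
#' First-order Markov chain whose stationary distribution equals the
#' target stage proportions (see [stage_transition_matrix()]).  The
#' chain begins in W when W has positive mass, otherwise in the first
#' stage with positive mass.
#'
#' @param proportions Target stage fractions.
#' @param epochs Number of epochs (>= 1).
#' @param seed RNG seed.
#' @param stickiness Self-transition blend.
#' @return A [hypnogram()].
#' @export
generate_hypnogram <- function(proportions = default_stage_proportions(),
                               epochs = 960, seed = 1, stickiness = 0.9) {
  if (epochs < 1) abort_input("epochs must be >= 1")
  P <- stage_transition_matrix(proportions, stickiness)
  p <- as.numeric(proportions)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  s <- integer(epochs)
  s[1] <- if (p[1] > 0) 1L else which(p > 0)[1L]
  if (epochs > 1L) {
    u <- stats::runif(epochs - 1L)
    cum <- t(apply(P, 1, cumsum))
    for (t in 2:epochs) {
      s[t] <- findInterval(u[t - 1L], cum[s[t - 1L], ], left.open = TRUE) + 1L
    }
  }
  hypnogram(stage_levels()[s])
}

# --- signal building blocks -----------------------------------------

spindle_wave <- function(t0, fs, dur = 1, hz = 13, amp = 25) {
  tt <- seq(0, dur, by = 1 / fs)
  env <- exp(-((tt - dur / 2) / (dur / 4))^2)
  amp * env * sin(2 * pi * hz * tt + stats::runif(1, 0, 2 * pi))
}

kcomplex_wave <- function(fs, dur = 0.7, amp = 75) {
  tt <- seq(0, dur, length.out = round(dur * fs))
  # biphasic slow wave: sharp negative then broad positive deflection
  amp * (-1.2 * exp(-((tt - 0.15 * dur) / (0.1 * dur))^2) +
         0.9 * exp(-((tt - 0.55 * dur) / (0.22 * dur))^2))
}

add_at <- function(x, wave, pos) {
  idx <- pos:min(length(x), pos + length(wave) - 1L)
  x[idx] <- x[idx] + wave[seq_along(idx)]
  x
}

#' Synthesise a polysomnography record for a hypnogram
#'
#' Emits the full nine-channel montage (F3-M2, F4-M1, C3-M2, C4-M1,
#' O1-M2, O2-M1, EOG-L, EOG-R, chin-EMG).  Per epoch, the stage's
#' spectral recipe drives sinusoidal band components with random phase
#' plus broadband noise; contralateral channels share the site waveform
#' and differ by independent sensor noise, so contralateral averaging
#' genuinely reduces noise.  Deterministic for a fixed seed.
#'
#' @param h A [hypnogram()].
#' @param model A [default_stage_model()].
#' @param fs Sampling rate (Hz).
#' @param seed RNG seed.
#' @param subject_id Subject id stored on the record.
#' @return A [psg_record()].
#' @export
synthesize_record <- function(h, model = default_stage_model(), fs = 200,
                              seed = 1, subject_id = "synthetic") {
  if (!inherits(model, "stage_signal_model")) abort_input("expected a stage_signal_model")
  labs <- hypnogram_labels(h)
  ep_len <- attr(h, "epoch_len_s")
  n_samp <- round(ep_len * fs)
  tt <- (0:(n_samp - 1)) / fs
  n_ep <- length(labs)
  sites <- matrix(0, n_samp * n_ep, 3)   # frontal, central, occipital base
  eogL <- numeric(n_samp * n_ep); eogR <- numeric(n_samp * n_ep)
  emg <- numeric(n_samp * n_ep)

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (e in seq_len(n_ep)) {
    rec <- model[[labs[e]]]
    idx <- (e - 1L) * n_samp + seq_len(n_samp)
    base <- matrix(0, n_samp, 3)
    for (cp in rec$components) {
      hz <- cp$hz * stats::runif(1, 0.95, 1.05)
      wave <- sin(2 * pi * hz * tt + stats::runif(1, 0, 2 * pi))
      base <- base + outer(wave, cp$site) * cp$amp
    }
    n_spin <- stats::rpois(1, rec$spindle_rate)
    for (i in seq_len(n_spin)) {
      w <- spindle_wave(fs = fs, dur = stats::runif(1, 0.5, 1.5))
      pos <- sample.int(n_samp - length(w), 1)
      base[, 2] <- add_at(base[, 2], w, pos)              # central dominant
      base[, 1] <- add_at(base[, 1], 0.6 * w, pos)
      base[, 3] <- add_at(base[, 3], 0.4 * w, pos)
    }
    n_kc <- stats::rpois(1, rec$kcomplex_rate)
    for (i in seq_len(n_kc)) {
      w <- kcomplex_wave(fs)
      pos <- sample.int(n_samp - length(w), 1)
      base[, 1] <- add_at(base[, 1], w, pos)              # frontal dominant
      base[, 2] <- add_at(base[, 2], 0.8 * w, pos)
      base[, 3] <- add_at(base[, 3], 0.5 * w, pos)
    }
    sites[idx, ] <- base

    eo <- numeric(n_samp)
    if (rec$eog$kind == "blink" || rec$eog$kind == "slow") {
      n_ev <- stats::rpois(1, rec$eog$rate)
      hz0 <- if (rec$eog$kind == "blink") 1 else 0.4
      for (i in seq_len(n_ev)) {
        dur <- 1 / hz0
        w <- rec$eog$amp * sin(pi * seq(0, 1, length.out = round(dur * fs)))
        eo <- add_at(eo, w, sample.int(max(1, n_samp - length(w)), 1))
      }
    } else if (rec$eog$kind == "rem") {
      n_ev <- stats::rpois(1, rec$eog$rate)
      for (i in seq_len(n_ev)) {
        dur <- stats::runif(1, 0.15, 0.3)
        w <- rec$eog$amp * sign(stats::runif(1) - 0.5) *
          sin(pi * seq(0, 1, length.out = round(dur * fs)))
        eo <- add_at(eo, w, sample.int(max(1, n_samp - length(w)), 1))
      }
    }
    # REM deflections are conjugate (mirrored across the eyes)
    mir <- if (rec$eog$kind == "rem") -1 else 1
    eogL[idx] <- eo + stats::rnorm(n_samp, sd = 5)
    eogR[idx] <- mir * eo + stats::rnorm(n_samp, sd = 5)
    emg[idx] <- stats::rnorm(n_samp, sd = rec$emg_tone)
  }

  nsd <- vapply(labs, function(s) model[[s]]$noise_sd, numeric(1))
  nsd <- rep(nsd, each = n_samp)
  mk <- function(site_col) sites[, site_col] + stats::rnorm(length(nsd), sd = nsd)
  chans <- list(
    channel_signal("F3-M2", mk(1), fs), channel_signal("F4-M1", mk(1), fs),
    channel_signal("C3-M2", mk(2), fs), channel_signal("C4-M1", mk(2), fs),
    channel_signal("O1-M2", mk(3), fs), channel_signal("O2-M1", mk(3), fs),
    channel_signal("EOG-L", eogL, fs), channel_signal("EOG-R", eogR, fs),
    channel_signal("chin-EMG", emg, fs))
  psg_record(chans, subject_id = subject_id)
}

# fixed sub-seed derivation: one canonical stream per subject, split by
# purpose so adding a draw in one place cannot perturb the others.
derive_seed <- function(master, index, purpose = 0L) {
  (as.numeric(master) * 48271 + index * 2654435761 + purpose * 97) %% 2147483647
}

#' Generate a synthetic cohort of recordings with ground truth
#'
#' Per subject: stage proportions are jittered around the cohort means
#' (Dirichlet), a Markov hypnogram is generated, and the nine-channel
#' record is synthesised.  A deterministic fraction of subjects
#' (rounded) uses the alpha-suppressed W recipe.
#'
#' @param config A [cohort_config()].
#' @return Named list of subjects, each
#'   `list(record, hypnogram, subject_id, alpha_deficient, seed)`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  n <- config$n_subjects
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, 0L, 3L))
  n_def <- round(config$alpha_deficient_fraction * n)
  deficient <- seq_len(n) %in% sample.int(n, n_def)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("S%03d", i)
    set.seed(derive_seed(config$seed, i, 1L))
    p <- as.numeric(config$stage_proportions)
    if (config$dirichlet_conc > 0) {
      g <- stats::rgamma(5, shape = pmax(config$dirichlet_conc * p, 1e-6))
      p <- g / sum(g)
    }
    h <- generate_hypnogram(p, config$epochs_per_subject,
                            seed = derive_seed(config$seed, i, 2L),
                            stickiness = config$stickiness)
    rec <- synthesize_record(h, default_stage_model(deficient[i]),
                             fs = config$fs,
                             seed = derive_seed(config$seed, i, 4L),
                             subject_id = sid)
    out[[i]] <- list(record = rec, hypnogram = h, subject_id = sid,
                     alpha_deficient = deficient[i],
                     seed = derive_seed(config$seed, i, 1L))
  }
  stats::setNames(out, vapply(out, `[[`, character(1), "subject_id"))
}

#' Resample a hypnogram through a scorer-noise model
#'
#' Each epoch's observed label is drawn independently from the
#' confusion row of its true stage -- a synthetic "imperfect scorer"
#' for exercising agreement statistics.
#'
#' @param truth A [hypnogram()].
#' @param noise 5x5 row-stochastic matrix in [stage_levels()] order
#'   (e.g. `clinical_reference_tables()$confusion_percent / 100`).
#' @param seed RNG seed.
#' @return A [hypnogram()] of the same length.
#' @export
corrupt_hypnogram <- function(truth, noise, seed = 1) {
  noise <- as.matrix(noise)
  if (!all(dim(noise) == c(5, 5)) || any(noise < 0) ||
      any(abs(rowSums(noise) - 1) > 1e-6)) {
    abort_config("noise must be a 5x5 row-stochastic matrix")
  }
  s <- as.integer(unclass_hypnogram(truth))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- integer(length(s))
  u <- stats::runif(length(s))
  cum <- t(apply(noise, 1, cumsum))
  cum[, 5] <- 1  # guard rounding at the top end
  for (k in 1:5) {
    sel <- s == k
    if (any(sel)) out[sel] <- findInterval(u[sel], cum[k, ], left.open = TRUE) + 1L
  }
  hypnogram(stage_levels()[out], epoch_len_s = attr(truth, "epoch_len_s"))
}
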