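test_that("sub-epoch segmentation yields the expected window counts", {
  fs <- 200
  expect_identical(ncol(segment_subepochs(rnorm(30 * fs), fs)), 29L)
  expect_identical(ncol(segment_subepochs(rnorm(30 * fs), fs, step_s = 2)), 15L)
  expect_identical(ncol(segment_subepochs(rnorm(2 * fs), fs)), 1L)
  expect_identical(nrow(segment_subepochs(rnorm(30 * fs), fs)), 400L)
  expect_error(segment_subepochs(rnorm(fs), fs), class = "somnostage_input_error")
})

test_that("band fractions isolate the constructed band for all four bands", {
  fs <- 200
  tt <- (0:(2 * fs - 1)) / fs
  probe <- c(delta = 2, theta = 5, alpha = 10, beta = 20)
  for (band in names(probe)) {
    x <- sin(2 * pi * probe[[band]] * tt)
    s <- multitaper_psd(x, fs)
    fr <- band_power_fractions(s, total_power = sum(s$psd) * s$df)
    expect_gt(fr[[band]], 0.9)
    expect_true(all(fr[names(fr) != band] < 0.05))
  }
})

test_that("zero total power is a guarded degenerate input", {
  s <- multitaper_psd(rep(0, 400), 200)
  expect_error(band_power_fractions(s, total_power = 0),
               class = "somnostage_input_error")
})

test_that("power ratios are eps-guarded and exact on clean fractions", {
  r <- power_ratios(c(delta = 0.4, theta = 0.2, alpha = 0.2))
  expect_equal(r[["delta_theta"]], 2, tolerance = 1e-9)
  expect_equal(r[["theta_alpha"]], 1, tolerance = 1e-9)
  g <- power_ratios(c(delta = 0.3, theta = 0, alpha = 0), eps = 1e-12)
  expect_true(all(is.finite(g)))
  expect_gt(g[["delta_theta"]], 1e10)
})

test_that("line length matches closed forms and scales linearly with amplitude", {
  expect_equal(line_length(rep(3, 100)), 0)
  expect_equal(line_length(c(0, 1, 0, 1)), 3)
  ramp <- seq(0, 7, length.out = 50)
  expect_equal(line_length(ramp), 7)
  set.seed(5); x <- rnorm(200)
  expect_equal(line_length(3.5 * x), 3.5 * line_length(x))
  expect_error(line_length(1), class = "somnostage_input_error")
})

test_that("kurtosis matches closed forms and is amplitude-invariant", {
  expect_equal(kurtosis_pearson(rep(c(-1, 1), 50)), 1)
  set.seed(7); g <- rnorm(1e5)
  expect_equal(kurtosis_pearson(g), 3, tolerance = 0.1)
  expect_equal(kurtosis_pearson(10 * g), kurtosis_pearson(g))
  expect_error(kurtosis_pearson(rep(2, 100)), class = "somnostage_input_error")
})

test_that("track summaries use interpolated percentiles and sample SD", {
  s <- summarize_track(rep(4, 29))
  expect_equal(unname(s[c("p95", "min", "mean", "sd")]), c(4, 4, 4, 0))
  s2 <- summarize_track(1:29)
  expect_equal(unname(s2[c("min", "mean")]), c(1, 15))
  expect_equal(s2[["p95"]], 27.6)
  expect_equal(s2[["sd"]], sd(1:29))
  expect_error(summarize_track(numeric(0)), class = "somnostage_input_error")
})

test_that("contralateral averaging is the element-wise mean, symmetric and idempotent", {
  a <- c(0, 0, 0); b <- c(1, 1, 1)
  expect_equal(contralateral_average(a, b), c(0.5, 0.5, 0.5))
  expect_equal(contralateral_average(a, a), a)
  x <- rnorm(29); y <- rnorm(29)
  expect_equal(contralateral_average(x, y), contralateral_average(y, x))
  expect_error(contralateral_average(1:3, 1:4), class = "somnostage_input_error")
})

test_that("EOG band energy captures low-frequency but not fast activity", {
  fs <- 200; tt <- (0:(2 * fs - 1)) / fs
  slow <- 50 * sin(2 * pi * 1 * tt)
  fast <- 50 * sin(2 * pi * 20 * tt)
  tot <- function(x) { s <- multitaper_psd(x, fs); sum(s$psd) * s$df }
  expect_gt(eog_band_energy(slow, fs) / tot(slow), 0.9)
  expect_lt(eog_band_energy(fast, fs) / tot(fast), 0.1)
  expect_equal(eog_band_energy(rep(0, 400), fs), 0)
})

test_that("EMG energy rejects DC and matches closed forms", {
  expect_equal(emg_energy(rep(0, 100)), 0)
  expect_equal(emg_energy(rep(42, 100)), 0)
  expect_equal(emg_energy(rep(c(-3, 3), 50)), 9)
  expect_error(emg_energy(numeric(0)), class = "somnostage_input_error")
})

test_that("extract_features obeys the shape contract and is deterministic", {
  rec <- make_sine_record(dur = 150)
  f1 <- extract_features(rec)
  expect_identical(dim(f1), c(5L, length(feature_layout())))
  expect_identical(colnames(f1), feature_layout())
  expect_true(all(is.finite(f1)))
  f2 <- extract_features(rec)
  expect_identical(f1, f2)
})

test_that("extract_features is invariant to swapping left/right channels of a pair", {
  h <- hypnogram(rep("N2", 3))
  rec <- synthesize_record(h, seed = 9)
  swapped <- rec
  swapped$channels[c("F3-M2", "F4-M1")] <- rec$channels[c("F4-M1", "F3-M2")]
  swapped$channels[["F3-M2"]]$label <- "F3-M2"
  swapped$channels[["F4-M1"]]$label <- "F4-M1"
  expect_equal(extract_features(rec), extract_features(swapped), tolerance = 1e-12)
})

test_that("band fractions are invariant to overall amplitude scaling of the epoch", {
  h <- hypnogram(rep("N2", 2))
  rec <- synthesize_record(h, seed = 11)
  scaled <- rec
  for (nm in names(scaled$channels)) {
    scaled$channels[[nm]]$samples <- 4 * scaled$channels[[nm]]$samples
  }
  f1 <- extract_features(rec); f2 <- extract_features(scaled)
  frac_cols <- grep("_frac_|_ratio_", colnames(f1), value = TRUE)
  expect_equal(f1[, frac_cols], f2[, frac_cols], tolerance = 1e-8)
  ll_cols <- grep("line_length_mean", colnames(f1), value = TRUE)
  expect_equal(unname(f2[, ll_cols]), unname(4 * f1[, ll_cols]), tolerance = 1e-8)
  kur_cols <- grep("kurtosis_mean", colnames(f1), value = TRUE)
  expect_equal(f1[, kur_cols], f2[, kur_cols], tolerance = 1e-8)
})

test_that("alpha-dominant wake and delta-dominant N3 epochs separate in the expected features", {
  recW <- synthesize_record(hypnogram(rep("W", 4)), seed = 13)
  recN3 <- synthesize_record(hypnogram(rep("N3", 4)), seed = 13)
  fW <- extract_features(recW); fN3 <- extract_features(recN3)
  expect_gt(mean(fW[, "occipital_alpha_frac_mean"]),
            mean(fN3[, "occipital_alpha_frac_mean"]))
  expect_gt(mean(fN3[, "occipital_delta_frac_mean"]),
            mean(fW[, "occipital_delta_frac_mean"]))
})

test_that("missing required channels raise a configuration error naming them", {
  rec <- make_sine_record(dur = 30)
  rec$channels[["chin-EMG"]] <- NULL
  expect_error(extract_features(rec), "chin-EMG",
               class = "somnostage_config_error")
  rec2 <- make_sine_record(dur = 30)
  rec2$channels[["O1-M2"]] <- NULL
  expect_error(extract_features(rec2), "O1-M2",
               class = "somnostage_config_error")
})

test_that("feature TSV round-trips with its layout sidecar", {
  rec <- make_sine_record(dur = 60)
  f <- extract_features(rec)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_features(f, path)
  back <- read_features(path)
  expect_equal(unname(back), unname(unclass(f)[seq_len(nrow(f)), ]), tolerance = 1e-12)
  expect_identical(colnames(back), feature_layout())
  expect_identical(readLines(paste0(path, ".layout")), feature_layout())
})
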