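#' Construct a single polysomnography channel
#'
#' @param label Montage name (e.g. `"F3-M2"`, `"EOG-L"`, `"chin-EMG"`)
#'   or raw electrode name.
#' @param samples Numeric vector of amplitudes in microvolts.
#' @param fs Sampling rate in Hz.
#' @return An object of class `channel_signal`.
#' @export
channel_signal <- function(label, samples, fs) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    abort_input("channel label must be a non-empty string")
  }
  if (length(samples) < 1L) abort_input(sprintf("channel %s has no samples", label))
  if (!is.numeric(fs) || fs <= 0) abort_input(sprintf("channel %s: fs must be > 0", label))
  structure(list(label = label, samples = as.numeric(samples), fs = fs),
            class = "channel_signal")
}

#' Construct a polysomnography record
#'
#' A multichannel signal container.  All channels must cover the same
#' duration to within one sample of the coarser rate; mixed sampling
#' rates across channels are allowed (as in EDF).
#'
#' @param channels List of [channel_signal()] objects.
#' @param subject_id Opaque subject identifier string.
#' @param start_time Optional `POSIXct` recording start.
#' @return An object of class `psg_record` with fields `subject_id`,
#'   `channels` (named by label), `start_time`, `duration_s`.
#' @export
psg_record <- function(channels, subject_id = "anonymous", start_time = NULL) {
  if (length(channels) < 1L) abort_input("a record needs at least one channel")
  channels <- lapply(channels, function(ch) {
    if (!inherits(ch, "channel_signal")) {
      ch <- channel_signal(ch$label, ch$samples, ch$fs)
    }
    ch
  })
  durs <- vapply(channels, function(ch) length(ch$samples) / ch$fs, numeric(1))
  tol <- max(vapply(channels, function(ch) 1 / ch$fs, numeric(1)))
  if (diff(range(durs)) > tol + 1e-9) {
    abort_input(sprintf(
      "channel durations disagree beyond one sample: %.3f..%.3f s",
      min(durs), max(durs)))
  }
  names(channels) <- vapply(channels, `[[`, character(1), "label")
  structure(list(subject_id = subject_id, channels = channels,
                 start_time = start_time, duration_s = min(durs)),
            class = "psg_record")
}

#' @export
print.psg_record <- function(x, ...) {
  cat(sprintf("<psg_record> subject %s, %.1f s, %d channel(s)\n",
              x$subject_id, x$duration_s, length(x$channels)))
  for (ch in x$channels) {
    cat(sprintf("  %-10s %g Hz, %d samples\n", ch$label, ch$fs, length(ch$samples)))
  }
  invisible(x)
}

#' Number of whole scoring epochs in a record
#'
#' Trailing partial epochs are discarded; the epoch grid starts at the
#' recording start with half-open intervals `[i*len, (i+1)*len)`.
#'
#' @param record A [psg_record()].
#' @param epoch_len_s Epoch length in seconds (default 30).
#' @return Integer count (0 for recordings shorter than one epoch).
#' @export
epoch_count <- function(record, epoch_len_s = 30) {
  if (!inherits(record, "psg_record")) abort_input("expected a psg_record")
  if (!is.numeric(epoch_len_s) || epoch_len_s <= 0) {
    abort_config("epoch_len_s must be > 0")
  }
  as.integer(floor(record$duration_s / epoch_len_s + 1e-9))
}

# Samples of channel `ch` in epoch e (1-based), half-open in seconds.
epoch_samples <- function(ch, e, epoch_len_s = 30) {
  i0 <- floor((e - 1) * epoch_len_s * ch$fs) + 1
  i1 <- floor(e * epoch_len_s * ch$fs)
  ch$samples[i0:i1]
}

# ---------------------------------------------------------------------
# EDF (European Data Format) I/O.  16-bit integers, little endian;
# fixed-width ASCII header of 256 bytes plus 256 per signal.  Data
# records of 1 s are used on write.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width, flag = "-")
}

#' Write a polysomnography record as EDF
#'
#' Signals are stored as 16-bit integers against a fixed physical range
#' of +/-500 microvolts (amplitudes outside the range are clipped), in
#' one-second data records.  Channel sampling rates must therefore be
#' integer Hz; the record is truncated to a whole number of seconds.
#'
#' @param record A [psg_record()].
#' @param path Output file path.
#' @param phys_range Physical range in microvolts, `c(min, max)`.
#' @return The path, invisibly.
#' @export
write_edf <- function(record, path, phys_range = c(-500, 500)) {
  if (!inherits(record, "psg_record")) abort_input("expected a psg_record")
  chs <- record$channels
  fs <- vapply(chs, `[[`, numeric(1), "fs")
  if (any(abs(fs - round(fs)) > 1e-9)) {
    abort_config("write_edf requires integer sampling rates (1-s data records)")
  }
  n_rec <- floor(min(vapply(chs, function(ch) length(ch$samples) / ch$fs, numeric(1))))
  if (n_rec < 1) abort_input("record shorter than one second; nothing to write")
  ns <- length(chs)

  con <- tryCatch(file(path, "wb"), error = function(e) NULL)
  if (is.null(con)) abort_io(sprintf("cannot open %s for writing", path))
  on.exit(close(con))

  st <- record$start_time
  dstr <- if (inherits(st, "POSIXct")) format(st, "%d.%m.%y") else "01.01.00"
  tstr <- if (inherits(st, "POSIXct")) format(st, "%H.%M.%S") else "00.00.00"
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(record$subject_id, 80),
    edf_field("somnostage", 80),
    edf_field(dstr, 8), edf_field(tstr, 8),
    edf_field(256 * (ns + 1), 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field("1", 8),
    edf_field(ns, 4))
  labels <- vapply(chs, `[[`, character(1), "label")
  spr <- as.integer(round(fs))
  sig_hdr <- paste0(
    paste(vapply(labels, edf_field, character(1), width = 16), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(rep(edf_field("uV", 8), ns), collapse = ""),
    paste(rep(edf_field(phys_range[1], 8), ns), collapse = ""),
    paste(rep(edf_field(phys_range[2], 8), ns), collapse = ""),
    paste(rep(edf_field(-32767, 8), ns), collapse = ""),
    paste(rep(edf_field(32767, 8), ns), collapse = ""),
    paste(rep(edf_field("", 80), ns), collapse = ""),
    paste(vapply(spr, edf_field, character(1), width = 8), collapse = ""),
    paste(rep(edf_field("", 32), ns), collapse = ""))
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL, useBytes = TRUE)

  # symmetric digital range so that 0 uV (for a symmetric physical
  # range) is exactly representable
  gain <- (phys_range[2] - phys_range[1]) / 65534
  dig <- lapply(chs, function(ch) {
    x <- pmin(pmax(ch$samples, phys_range[1]), phys_range[2])
    as.integer(round((x - phys_range[1]) / gain) - 32767L)
  })
  for (r in seq_len(n_rec)) {
    for (j in seq_len(ns)) {
      idx <- ((r - 1L) * spr[j] + 1L):(r * spr[j])
      writeBin(dig[[j]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF polysomnography file
#'
#' Parses the fixed-width EDF header and 16-bit signal records, mapping
#' digital values back to physical units.  When `montage_map` is given,
#' channels whose raw label appears in the map are renamed to the
#' montage name; unmapped channels are dropped with a warning, and it is
#' an error for the map to match no channel at all.
#'
#' @param path Path to an EDF/EDF+ file.
#' @param montage_map Optional named character vector or list, raw label
#'   -> montage name (e.g. `c("EEG F3-A2" = "F3-M2")`).
#' @param subject_id Optional override; defaults to the header's patient
#'   field.
#' @return A [psg_record()].
#' @export
read_edf <- function(path, montage_map = NULL, subject_id = NULL) {
  if (!file.exists(path)) abort_io(sprintf("EDF file not found: %s", path))
  con <- tryCatch(file(path, "rb"), error = function(e) NULL)
  if (is.null(con)) abort_io(sprintf("cannot open EDF file: %s", path))
  on.exit(close(con))

  hdr <- tryCatch(readChar(con, 256, useBytes = TRUE), error = function(e) "")
  if (nchar(hdr, type = "bytes") < 256) {
    abort_io(sprintf("corrupt or truncated EDF header in %s", path))
  }
  fld <- function(from, len) trimws(substr(hdr, from, from + len - 1))
  patient <- fld(9, 80)
  n_rec <- suppressWarnings(as.integer(fld(237, 8)))
  rec_dur <- suppressWarnings(as.numeric(fld(245, 8)))
  ns <- suppressWarnings(as.integer(fld(253, 4)))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || n_rec < 1 || is.na(rec_dur) || rec_dur <= 0) {
    abort_io(sprintf("corrupt EDF header fields in %s", path))
  }
  shdr <- readChar(con, 256 * ns, useBytes = TRUE)
  if (nchar(shdr, type = "bytes") < 256 * ns) {
    abort_io(sprintf("corrupt EDF signal header in %s", path))
  }
  sfld <- function(off, len, j) trimws(substr(shdr, off * ns + (j - 1) * len + 1,
                                              off * ns + j * len))
  labels <- vapply(seq_len(ns), function(j) sfld(0, 16, j), character(1))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(j) substr(shdr, 16 * ns + 80 * ns + 8 * ns + (j - 1) * 8 + 1, 16 * ns + 80 * ns + 8 * ns + j * 8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(j) substr(shdr, 16 * ns + 80 * ns + 16 * ns + (j - 1) * 8 + 1, 16 * ns + 80 * ns + 16 * ns + j * 8), character(1)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(j) substr(shdr, 16 * ns + 80 * ns + 24 * ns + (j - 1) * 8 + 1, 16 * ns + 80 * ns + 24 * ns + j * 8), character(1)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(j) substr(shdr, 16 * ns + 80 * ns + 32 * ns + (j - 1) * 8 + 1, 16 * ns + 80 * ns + 32 * ns + j * 8), character(1)))
  spr <- as.integer(vapply(seq_len(ns), function(j) substr(shdr, 16 * ns + 160 * ns + 40 * ns + (j - 1) * 8 + 1, 16 * ns + 160 * ns + 40 * ns + j * 8), character(1)))
  if (anyNA(c(pmin_, pmax_, dmin_, dmax_, spr))) {
    abort_io(sprintf("corrupt EDF signal header fields in %s", path))
  }

  per_rec <- sum(spr)
  raw <- readBin(con, "integer", n = per_rec * n_rec, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < per_rec * n_rec) {
    abort_io(sprintf("EDF data shorter than header declares in %s", path))
  }
  dat <- matrix(raw, nrow = per_rec)  # one column per data record
  offs <- c(0L, cumsum(spr))
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  chans <- lapply(seq_len(ns), function(j) {
    dig <- as.vector(dat[(offs[j] + 1L):offs[j + 1L], , drop = FALSE])
    channel_signal(labels[j], (dig - dmin_[j]) * gain[j] + pmin_[j],
                   fs = spr[j] / rec_dur)
  })

  if (!is.null(montage_map)) {
    montage_map <- unlist(montage_map)
    hit <- labels %in% names(montage_map)
    if (!any(hit)) {
      abort_config(sprintf("montage_map matches no channel in %s (channels: %s)",
                           path, paste(labels, collapse = ", ")))
    }
    if (any(!hit)) {
      warning(sprintf("dropping %d unmapped channel(s): %s",
                      sum(!hit), paste(labels[!hit], collapse = ", ")))
    }
    chans <- chans[hit]
    for (i in seq_along(chans)) {
      chans[[i]]$label <- unname(montage_map[[chans[[i]]$label]])
    }
  }
  psg_record(chans, subject_id = subject_id %||% patient)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || identical(a, "")) b else a

#' Form referential derivations from raw electrode channels
#'
#' When a record carries raw electrodes (e.g. `F3` and `M2`) instead of
#' pre-derived channels, the standard derivations are formed by sample
#' subtraction (`F3-M2 = F3 - M2`).  Channels already present under the
#' derivation name are kept as-is.
#'
#' @param record A [psg_record()].
#' @param derivations Named list mapping derivation label to the
#'   `c(active, reference)` electrode pair.
#' @return A [psg_record()] with the derivation channels available.
#' @export
compute_derivations <- function(record,
                                derivations = list(
                                  "F3-M2" = c("F3", "M2"), "F4-M1" = c("F4", "M1"),
                                  "C3-M2" = c("C3", "M2"), "C4-M1" = c("C4", "M1"),
                                  "O1-M2" = c("O1", "M2"), "O2-M1" = c("O2", "M1"))) {
  chs <- record$channels
  for (lab in names(derivations)) {
    if (lab %in% names(chs)) next
    pair <- derivations[[lab]]
    if (all(pair %in% names(chs))) {
      a <- chs[[pair[1]]]; r <- chs[[pair[2]]]
      if (abs(a$fs - r$fs) > 1e-9) {
        abort_input(sprintf("cannot derive %s: %s and %s have different fs",
                            lab, pair[1], pair[2]))
      }
      n <- min(length(a$samples), length(r$samples))
      chs[[lab]] <- channel_signal(lab, a$samples[seq_len(n)] - r$samples[seq_len(n)], a$fs)
    }
  }
  psg_record(chs, subject_id = record$subject_id, start_time = record$start_time)
}
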