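#' Sleep-stage labels
#'
#' The five AASM stages in the fixed order used for every matrix and
#' factor in the package: wake (W), the three non-REM depths (N1, N2,
#' N3), and REM sleep (R).  The order fixes confusion-matrix rows and
#' columns and the argmax tie-break of the classifiers.
#'
#' @return Character vector of length five.
#' @export
#' @examples
#' stage_levels()
stage_levels <- function() c("W", "N1", "N2", "N3", "R")

#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch sequence of sleep-stage labels across a
#' recording, one label per scoring epoch (30 s by convention).
#'
#' @param labels Character vector or factor of stage labels, each one of
#'   `stage_levels()`.
#' @param epoch_len_s Epoch length in seconds (default 30, the AASM
#'   scoring window).
#' @return An object of class `hypnogram`: a factor with levels
#'   `stage_levels()` and an `epoch_len_s` attribute.
#' @export
#' @examples
#' hypnogram(c("W", "W", "N1", "N2", "N2"))
hypnogram <- function(labels, epoch_len_s = 30) {
  labels <- as.character(labels)
  if (length(labels) < 1L) abort_input("a hypnogram needs at least one epoch")
  bad <- setdiff(unique(labels), stage_levels())
  if (length(bad) > 0L) {
    abort_input(sprintf("unknown stage label(s): %s", paste(bad, collapse = ", ")))
  }
  if (!is.numeric(epoch_len_s) || epoch_len_s <= 0) {
    abort_config("epoch_len_s must be a positive number of seconds")
  }
  structure(factor(labels, levels = stage_levels()),
            epoch_len_s = epoch_len_s,
            class = c("hypnogram", "factor"))
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs of %gs\n", length(x), attr(x, "epoch_len_s")))
  tab <- table(unclass_hypnogram(x))
  print(tab)
  invisible(x)
}

# plain factor view (drops the hypnogram class so factor methods apply)
unclass_hypnogram <- function(h) {
  factor(as.character(h), levels = stage_levels())
}

#' @export
as.character.hypnogram <- function(x, ...) {
  stage_levels()[as.integer(unclass(x))]
}

hypnogram_labels <- function(h) {
  if (!inherits(h, "hypnogram")) abort_input("expected a hypnogram object")
  stage_levels()[as.integer(unclass(h))]
}

#' Read a hypnogram from a plain-text file
#'
#' The on-disk dialect is UTF-8 with one stage token per line from
#' `stage_levels()`; lines starting with `#` and blank lines are
#' ignored.  Epoch `i` (0-based) is on data line `i + 1`.
#'
#' @param path Path to the text file.
#' @param epoch_len_s Epoch length in seconds recorded on the result.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_len_s = 30) {
  if (!file.exists(path)) abort_io(sprintf("hypnogram file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  toks <- trimws(lines[keep])
  lineno <- which(keep)
  bad <- which(!(toks %in% stage_levels()))
  if (length(bad) > 0L) {
    abort_input(sprintf("unknown stage token '%s' at line %d of %s",
                        toks[bad[1L]], lineno[bad[1L]], path))
  }
  if (length(toks) == 0L) abort_input(sprintf("no stage labels in %s", path))
  hypnogram(toks, epoch_len_s = epoch_len_s)
}

#' Write a hypnogram to a plain-text file
#'
#' @param h A [hypnogram()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_hypnogram <- function(h, path) {
  if (!inherits(h, "hypnogram")) abort_input("expected a hypnogram object")
  ok <- tryCatch({
    writeLines(hypnogram_labels(h), path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_io(sprintf("cannot write hypnogram to %s", path))
  invisible(path)
}
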