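#' Reference agreement tables from a published clinical validation
#'
#' Row-normalised confusion percentages (reference scorer in rows,
#' automated scorer in columns) and per-stage reference epoch totals as
#' printed by a large clinical validation study of automated five-stage
#' sleep scoring (72 test subjects, 69,591 epochs).  Used for worked
#' examples, as a realistic scorer-noise model, and to reconstruct the
#' pooled agreement figures those tables imply.
#'
#' @return List with `confusion_percent` (5x5, rows sum to 100) and
#'   `stage_epochs` (named vector of reference per-stage epoch counts).
#' @export
clinical_reference_tables <- function() {
  pct <- rbind(
    W  = c(94,   2.4,  2.2,  0.1, 1.3),
    N1 = c(2.8,  83.9, 10.9, 0.1, 2.3),
    N2 = c(1.1,  3.5,  89,   3.7, 2.7),
    N3 = c(0.14, 0.21, 7.1,  92,  0.55),
    R  = c(1.2,  2.1,  3.6,  0.1, 93))
  colnames(pct) <- stage_levels()
  list(confusion_percent = pct,
       stage_epochs = c(W = 14662, N1 = 6577, N2 = 33319, N3 = 4548, R = 10485))
}

#' Reconstruct pooled confusion counts from row percentages
#'
#' Multiplies each row of a row-percentage confusion table by that
#' stage's reference epoch count, yielding the pooled count matrix the
#' percentages imply (counts are fractional by construction).
#'
#' @param tables As from [clinical_reference_tables()].
#' @return A `paired_confusion` matrix.
#' @export
reconstruct_pooled_counts <- function(tables = clinical_reference_tables()) {
  cnt <- tables$confusion_percent / 100 * tables$stage_epochs
  as_paired_confusion(cnt)
}
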