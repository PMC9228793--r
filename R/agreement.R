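#' Stage-by-stage confusion matrix between two scorers
#'
#' @param reference,candidate Hypnograms of equal length; rows of the
#'   result index the reference scorer, columns the candidate.
#' @return Object of class `paired_confusion`: a 5x5 count matrix in
#'   [stage_levels()] order with attribute `n` (total epochs).
#' @export
confusion_matrix <- function(reference, candidate) {
  r <- unclass_hypnogram(reference)
  c_ <- unclass_hypnogram(candidate)
  if (length(r) != length(c_)) {
    abort_input(sprintf("hypnogram lengths differ: %d vs %d", length(r), length(c_)))
  }
  if (length(r) < 1L) abort_input("empty hypnograms")
  m <- table(reference = r, candidate = c_)
  m <- matrix(as.numeric(m), 5, 5, dimnames = list(stage_levels(), stage_levels()))
  as_paired_confusion(m)
}

as_paired_confusion <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(5, 5)) || any(m < 0)) {
    abort_input("a paired confusion matrix must be 5x5 with non-negative counts")
  }
  dimnames(m) <- list(stage_levels(), stage_levels())
  structure(m, n = sum(m), class = c("paired_confusion", "matrix"))
}

#' @export
print.paired_confusion <- function(x, ...) {
  cat(sprintf("<paired_confusion> n = %g epochs (rows = reference)\n", attr(x, "n")))
  print(unclass(x))
  invisible(x)
}

#' Row-normalised percentages of a confusion matrix
#'
#' Presentation form: each reference row as percentages summing to 100.
#' Empty rows are reported as `NA` rather than propagating 0/0.
#'
#' @param m A [confusion_matrix()].
#' @return 5x5 numeric matrix of percentages.
#' @export
row_percentages <- function(m) {
  m <- as_paired_confusion(m)
  rs <- rowSums(m)
  out <- sweep(unclass(m), 1, rs, "/") * 100
  out[rs == 0, ] <- NA_real_
  out
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = sum(diag)/n` and chance agreement
#' `p_e = sum(row_i * col_i) / n^2`.
#'
#' @param m A [confusion_matrix()] (or plain 5x5 count matrix).
#' @return Kappa in `[-1, 1]`; `NA` with a warning when both scorers use
#'   a single identical category (`p_e = 1`, kappa undefined).
#' @export
cohens_kappa <- function(m) {
  m <- as_paired_confusion(m)
  n <- attr(m, "n")
  if (n < 1) abort_input("empty confusion matrix")
  p_o <- sum(diag(m)) / n
  p_e <- sum(rowSums(m) * colSums(m)) / n^2
  if (p_e >= 1 - 1e-12) {
    warning("kappa undefined: both scorers constant on the same category")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Agreement-strength interpretation scale for kappa
#'
#' The conventional Landis-Koch breakpoints: <=0 poor, (0, 0.20]
#' slight, (0.20, 0.40] fair, (0.40, 0.60] moderate, (0.60, 0.80]
#' substantial, (0.80, 1] almost perfect.  Intervals are closed on the
#' right; custom strictly increasing breakpoints may be supplied.
#'
#' @param breakpoints Five strictly increasing upper bounds for the
#'   first five categories.
#' @param labels Six category labels.
#' @return Object of class `kappa_scale`.
#' @export
kappa_scale <- function(breakpoints = c(0, 0.20, 0.40, 0.60, 0.80),
                        labels = c("poor", "slight", "fair", "moderate",
                                   "substantial", "almost perfect")) {
  if (length(breakpoints) + 1L != length(labels)) {
    abort_config("need one more label than breakpoints")
  }
  if (any(diff(breakpoints) <= 0)) abort_config("breakpoints must be strictly increasing")
  structure(list(breakpoints = breakpoints, labels = labels), class = "kappa_scale")
}

#' Interpret a kappa value on an agreement-strength scale
#'
#' @param kappa Scalar kappa (<= 1).
#' @param scale A [kappa_scale()].
#' @return The category label.
#' @export
#' @examples
#' interpret_kappa(0.85)  # "almost perfect"
interpret_kappa <- function(kappa, scale = kappa_scale()) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa > 1 + 1e-12) abort_input("kappa cannot exceed 1")
  i <- findInterval(kappa, scale$breakpoints, left.open = FALSE) + 1L
  # right-closed intervals: a kappa exactly on a breakpoint belongs below
  if (i > 1L && kappa <= scale$breakpoints[i - 1L]) i <- i - 1L
  scale$labels[min(i, length(scale$labels))]
}

#' Collapse a confusion matrix to one stage's 2x2 table
#'
#' @param m A [confusion_matrix()].
#' @param stage One of [stage_levels()].
#' @return Named vector `a` (both scorers chose the stage), `b`
#'   (reference only), `c` (candidate only), `d` (neither), `n`.
#' @export
stage_collapse <- function(m, stage) {
  m <- as_paired_confusion(m)
  if (!(stage %in% stage_levels())) abort_input(sprintf("unknown stage: %s", stage))
  n <- attr(m, "n")
  a <- m[stage, stage]
  b <- sum(m[stage, ]) - a
  c_ <- sum(m[, stage]) - a
  c(a = unname(a), b = unname(b), c = unname(c_), d = unname(n - a - b - c_), n = unname(n))
}

#' Specific positive, negative and overall agreement
#'
#' Cicchetti-Feinstein specific agreement from a 2x2 collapse:
#' `PA = 100*2a/(2a+b+c)`, `NA = 100*2d/(2d+b+c)`, and binary overall
#' agreement `OA = 100*(a+d)/n`.  An undefined denominator yields `NA`.
#'
#' @param collapse A [stage_collapse()] result.
#' @return Named vector `PA`, `NA`, `OA` in percent.
#' @export
specific_agreement <- function(collapse) {
  a <- collapse[["a"]]; b <- collapse[["b"]]; c_ <- collapse[["c"]]
  d <- collapse[["d"]]; n <- collapse[["n"]]
  if (n < 1) abort_input("empty collapse")
  pa <- if (2 * a + b + c_ > 0) 100 * 2 * a / (2 * a + b + c_) else NA_real_
  na_ <- if (2 * d + b + c_ > 0) 100 * 2 * d / (2 * d + b + c_) else NA_real_
  c(PA = pa, "NA" = na_, OA = 100 * (a + d) / n)
}

# Per-stage + pooled metrics of one pooled confusion matrix.  The
# pooled (total) PA/NA aggregate the collapses' numerators and
# denominators across stages; total OA is the five-stage mean of the
# binary overall agreements.
agreement_metrics <- function(m) {
  cols <- lapply(stage_levels(), function(s) stage_collapse(m, s))
  per <- t(vapply(cols, specific_agreement, numeric(3)))
  rownames(per) <- stage_levels()
  num_pa <- sum(vapply(cols, function(x) 2 * x[["a"]], numeric(1)))
  den_pa <- sum(vapply(cols, function(x) 2 * x[["a"]] + x[["b"]] + x[["c"]], numeric(1)))
  num_na <- sum(vapply(cols, function(x) 2 * x[["d"]], numeric(1)))
  den_na <- sum(vapply(cols, function(x) 2 * x[["d"]] + x[["b"]] + x[["c"]], numeric(1)))
  total <- c(PA = if (den_pa > 0) 100 * num_pa / den_pa else NA_real_,
             "NA" = if (den_na > 0) 100 * num_na / den_na else NA_real_,
             OA = mean(per[, "OA"]))
  list(per_stage = per, total = total)
}

#' Bootstrapped agreement report for a set of scorer pairs
#'
#' Epochs within a subject are dependent, so the resampling unit is the
#' subject: each of `R` resamples draws subjects with replacement,
#' pools their confusion matrices, and computes per-stage and total
#' PA/NA/OA.  The report carries the per-metric median and 2.5/97.5
#' percentile bounds over the `R` resamples, the pooled Cohen's kappa
#' with its interpretation, and a per-subject kappa summary.
#'
#' @param pairs List of per-subject pairs, each a
#'   `list(reference = <hypnogram>, candidate = <hypnogram>)`.
#' @param R Number of bootstrap resamples (default 1000).
#' @param seed RNG seed for reproducibility.
#' @param scale [kappa_scale()] used for the interpretation label.
#' @return Object of class `agreement_report`.
#' @export
bootstrap_agreement <- function(pairs, R = 1000, seed = 1, scale = kappa_scale()) {
  if (length(pairs) < 1L) abort_input("need at least one subject pair")
  if (R < 1) abort_config("R must be >= 1")
  mats <- lapply(pairs, function(p) confusion_matrix(p$reference, p$candidate))
  ns <- length(mats)
  pooled <- as_paired_confusion(Reduce(`+`, lapply(mats, unclass)))

  metric_names <- c(as.vector(outer(c("PA", "NA", "OA"), stage_levels(),
                                    function(m, s) paste(s, m, sep = "."))),
                    "Total.PA", "Total.NA", "Total.OA")
  draws <- matrix(NA_real_, R, length(metric_names),
                  dimnames = list(NULL, metric_names))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  for (r in seq_len(R)) {
    idx <- sample.int(ns, ns, replace = TRUE)
    mm <- agreement_metrics(as_paired_confusion(Reduce(`+`, lapply(mats[idx], unclass))))
    draws[r, ] <- c(t(mm$per_stage), mm$total)
  }
  qs <- apply(draws, 2, function(v) {
    ok <- v[!is.na(v)]
    if (length(ok) < length(v) / 2) return(c(NA_real_, NA_real_, NA_real_))
    stats::quantile(ok, c(0.5, 0.025, 0.975), type = 7, names = FALSE)
  })
  undef <- colnames(draws)[colSums(is.na(draws)) > R / 2]
  if (length(undef) > 0L) {
    warning(sprintf("metric(s) undefined in more than half the resamples: %s",
                    paste(undef, collapse = ", ")))
  }

  shape <- function(prefix) {
    sub <- qs[, paste(prefix, c("PA", "NA", "OA"), sep = "."), drop = FALSE]
    data.frame(metric = c("PA", "NA", "OA"), median = sub[1, ],
               lo = sub[2, ], hi = sub[3, ], row.names = NULL)
  }
  per_stage <- lapply(stats::setNames(stage_levels(), stage_levels()), shape)
  kap <- cohens_kappa(pooled)
  subj_kappa <- vapply(mats, function(m) suppressWarnings(cohens_kappa(m)), numeric(1))
  structure(list(
    per_stage = per_stage, total = shape("Total"),
    kappa = kap, kappa_label = interpret_kappa(kap, scale),
    kappa_by_subject = c(median = stats::median(subj_kappa, na.rm = TRUE),
                         mean = mean(subj_kappa, na.rm = TRUE),
                         sd = stats::sd(subj_kappa),
                         min = suppressWarnings(min(subj_kappa, na.rm = TRUE)),
                         max = suppressWarnings(max(subj_kappa, na.rm = TRUE))),
    pooled_confusion = pooled, stage_epochs = rowSums(pooled),
    n_subjects = ns, n_epochs = attr(pooled, "n"), R = R, seed = seed),
    class = "agreement_report")
}

# Save/restore the global RNG state so seeded helpers do not clobber a
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d subjects, %g epochs, R = %d resamples\n",
              x$n_subjects, x$n_epochs, x$R))
  cat(sprintf("pooled kappa %.3f (%s); per-subject kappa median %.2f mean %.2f sd %.2f min %.2f max %.2f\n",
              x$kappa, x$kappa_label,
              x$kappa_by_subject[["median"]], x$kappa_by_subject[["mean"]],
              x$kappa_by_subject[["sd"]], x$kappa_by_subject[["min"]],
              x$kappa_by_subject[["max"]]))
  fmt <- function(row) sprintf("%g%% (%g-%g%%)", round_half_away(row$median),
                               round_half_away(row$lo), round_half_away(row$hi))
  cat(sprintf("%-6s %10s %22s %22s %22s\n", "", "epochs", "PA", "NA", "OA"))
  for (s in stage_levels()) {
    d <- x$per_stage[[s]]
    cat(sprintf("%-6s %10g %22s %22s %22s\n", s, x$stage_epochs[[s]],
                fmt(d[1, ]), fmt(d[2, ]), fmt(d[3, ])))
  }
  d <- x$total
  cat(sprintf("%-6s %10g %22s %22s %22s\n", "Total", x$n_epochs,
              fmt(d[1, ]), fmt(d[2, ]), fmt(d[3, ])))
  invisible(x)
}

#' Serialise an agreement report as JSON
#'
#' @param report An [bootstrap_agreement()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_agreement_report <- function(report, path) {
  obj <- list(
    n_subjects = report$n_subjects, n_epochs = report$n_epochs,
    R = report$R, seed = report$seed,
    kappa = report$kappa, kappa_label = report$kappa_label,
    kappa_by_subject = as.list(report$kappa_by_subject),
    stage_epochs = as.list(report$stage_epochs),
    per_stage = lapply(report$per_stage, function(d) {
      stats::setNames(lapply(seq_len(nrow(d)), function(i) {
        list(median = d$median[i], lo = d$lo[i], hi = d$hi[i])
      }), d$metric)
    }),
    total = stats::setNames(lapply(seq_len(nrow(report$total)), function(i) {
      list(median = report$total$median[i], lo = report$total$lo[i],
           hi = report$total$hi[i])
    }), report$total$metric),
    confusion = as.data.frame(unclass(report$pooled_confusion)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Overlay plot of two hypnograms
#'
#' Step plot with the conventional depth axis (top to bottom: W, R, N1,
#' N2, N3) and the two scorers' traces distinguishable by colour.
#'
#' @param reference,candidate Hypnograms of equal length.
#' @param path Output PNG path.
#' @param title Plot title.
#' @return `path`, invisibly.
#' @export
hypnogram_overlay <- function(reference, candidate, path,
                              title = "Hypnogram comparison") {
  r <- hypnogram_labels(reference)
  c_ <- hypnogram_labels(candidate)
  if (length(r) != length(c_)) abort_input("hypnogram lengths differ")
  depth <- c(W = 5, R = 4, N1 = 3, N2 = 2, N3 = 1)
  grDevices::png(path, width = 1200, height = 400)
  on.exit(grDevices::dev.off())
  graphics::plot(seq_along(r), depth[r], type = "s", col = "#D55E00", lwd = 2,
                 ylim = c(0.5, 5.5), yaxt = "n", xlab = "epoch (30 s)",
                 ylab = "", main = title)
  graphics::lines(seq_along(c_), depth[c_] - 0.06, type = "s",
                  col = "#0072B2", lwd = 2)
  graphics::axis(2, at = unname(depth), labels = names(depth), las = 1)
  graphics::legend("bottomright", legend = c("reference", "candidate"),
                   col = c("#D55E00", "#0072B2"), lwd = 2, bty = "n")
  invisible(path)
}
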