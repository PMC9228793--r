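#' Resolve a run configuration
#'
#' Merges package defaults, an optional YAML config file, and explicit
#' overrides (later wins).  The resolved configuration is written next
#' to every pipeline output for provenance.
#'
#' @param path Optional YAML file of settings.
#' @param overrides Named list of settings taking precedence.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    seed = 1, n_subjects = 10, epochs_per_subject = 120, fs = 200,
    alpha_deficient_fraction = 0.2, stickiness = 0.9, dirichlet_conc = 10,
    epoch_len_s = 30, variant = "all", hidden = 16, filters = 12, kernel = 5,
    train_epochs = 200, learning_rate = 0.02,
    split_fractions = c(0.8, 0.1, 0.1), bootstrap_R = 1000)
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) abort_config(sprintf("config file not found: %s", path))
    fromfile <- tryCatch(yaml::read_yaml(path), error = function(e) NULL)
    if (is.null(fromfile)) abort_config(sprintf("cannot parse config file: %s", path))
    unknown <- setdiff(names(fromfile), names(defaults))
    if (length(unknown) > 0L) {
      abort_config(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
    }
    cfg[names(fromfile)] <- fromfile
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

log_msg <- function(logfile, level, fmt, ...) {
  line <- sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

#' Run the staging pipeline end to end
#'
#' Wires the modules into five stages sharing one output directory:
#' `simulate` (synthetic cohort to EDF + hypnogram text + manifest),
#' `featurize` (EDF to per-epoch feature TSVs), `train` (subject-level
#' split, the requested classifier variant(s), best-model selection),
#' `score` (predicted hypnograms for the test subjects), `evaluate`
#' (bootstrapped agreement report of predicted vs reference).  The
#' resolved configuration and a log accompany the artifacts.
#'
#' @param config A [run_config()].
#' @param stages Subset of
#'   `c("simulate", "featurize", "train", "score", "evaluate")`, run in
#'   that order.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of artifact paths.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "featurize", "train",
                                    "score", "evaluate"),
                         out_dir) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config_resolved.yaml"))
  logfile <- file.path(out_dir, "run.log")
  artifacts <- list(config = file.path(out_dir, "config_resolved.yaml"),
                    log = logfile)

  edf_dir <- file.path(out_dir, "edf")
  ref_dir <- file.path(out_dir, "hypnograms_reference")
  feat_dir <- file.path(out_dir, "features")
  pred_dir <- file.path(out_dir, "hypnograms_predicted")
  manifest_path <- file.path(out_dir, "manifest.tsv")
  model_path <- file.path(out_dir, "model.rds")
  split_path <- file.path(out_dir, "split.yaml")

  if ("simulate" %in% stages) {
    log_msg(logfile, "INFO", "simulate: %d subjects x %d epochs, seed %d",
            config$n_subjects, config$epochs_per_subject, config$seed)
    cc <- cohort_config(n_subjects = config$n_subjects,
                        epochs_per_subject = config$epochs_per_subject,
                        alpha_deficient_fraction = config$alpha_deficient_fraction,
                        dirichlet_conc = config$dirichlet_conc,
                        stickiness = config$stickiness,
                        fs = config$fs, seed = config$seed)
    cohort <- generate_cohort(cc)
    dir.create(edf_dir, showWarnings = FALSE)
    dir.create(ref_dir, showWarnings = FALSE)
    man <- data.frame(subject_id = names(cohort),
                      seed = vapply(cohort, `[[`, numeric(1), "seed"),
                      alpha_deficient = vapply(cohort, `[[`, logical(1),
                                               "alpha_deficient"))
    for (s in cohort) {
      write_edf(s$record, file.path(edf_dir, paste0(s$subject_id, ".edf")))
      write_hypnogram(s$hypnogram, file.path(ref_dir, paste0(s$subject_id, ".txt")))
    }
    utils::write.table(man, manifest_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    artifacts$manifest <- manifest_path
  }

  subject_ids <- function() {
    if (!file.exists(manifest_path)) {
      abort_input(sprintf("missing manifest %s (run simulate first)", manifest_path))
    }
    utils::read.table(manifest_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)$subject_id
  }

  if ("featurize" %in% stages) {
    ids <- subject_ids()
    log_msg(logfile, "INFO", "featurize: %d subjects", length(ids))
    dir.create(feat_dir, showWarnings = FALSE)
    fc <- feature_config(epoch_len_s = config$epoch_len_s)
    for (sid in ids) {
      edf <- file.path(edf_dir, paste0(sid, ".edf"))
      if (!file.exists(edf)) abort_input(sprintf("missing EDF for subject %s", sid))
      feats <- extract_features(read_edf(edf), fc)
      write_features(feats, file.path(feat_dir, paste0(sid, ".tsv")))
    }
  }

  load_subject <- function(sid) {
    fp <- file.path(feat_dir, paste0(sid, ".tsv"))
    hp <- file.path(ref_dir, paste0(sid, ".txt"))
    if (!file.exists(fp)) abort_input(sprintf("missing features for subject %s", sid))
    if (!file.exists(hp)) abort_input(sprintf("missing hypnogram for subject %s", sid))
    list(features = read_features(fp), labels = read_hypnogram(hp))
  }

  if ("train" %in% stages) {
    ids <- subject_ids()
    split <- make_split(ids, config$split_fractions, seed = config$seed)
    yaml::write_yaml(split, split_path)
    log_msg(logfile, "INFO", "train: %d/%d/%d train/val/test subjects",
            length(split$train), length(split$validation), length(split$test))
    train_subj <- lapply(split$train, load_subject)
    val_subj <- lapply(split$validation, load_subject)
    variants <- if (identical(config$variant, "all")) {
      c("conv", "recurrent", "conv_recurrent")
    } else config$variant
    models <- lapply(variants, function(v) {
      sc <- stager_config(variant = v, hidden = config$hidden,
                          filters = config$filters, kernel = config$kernel,
                          train_epochs = config$train_epochs,
                          learning_rate = config$learning_rate,
                          seed = config$seed)
      m <- train_stager(train_subj, sc, val_subj)
      log_msg(logfile, "INFO", "trained %s: validation kappa %.3f, final loss %.4f",
              v, m$validation_kappa, utils::tail(m$loss_trace, 1))
      m
    })
    best <- select_best_model(models)
    log_msg(logfile, "INFO", "selected %s (kappa %.3f)", best$variant,
            best$validation_kappa)
    save_stager(best, model_path)
    artifacts$model <- model_path
  }

  if ("score" %in% stages) {
    if (!file.exists(model_path)) abort_input("missing model.rds (run train first)")
    if (!file.exists(split_path)) abort_input("missing split.yaml (run train first)")
    model <- load_stager(model_path)
    split <- yaml::read_yaml(split_path)
    dir.create(pred_dir, showWarnings = FALSE)
    for (sid in split$test) {
      s <- load_subject(sid)
      write_hypnogram(predict_hypnogram(model, s$features),
                      file.path(pred_dir, paste0(sid, ".txt")))
    }
    log_msg(logfile, "INFO", "score: wrote %d predicted hypnograms",
            length(split$test))
  }

  if ("evaluate" %in% stages) {
    if (!dir.exists(pred_dir)) abort_input("missing predicted hypnograms (run score first)")
    report_path <- file.path(out_dir, "agreement_report.json")
    preds <- list.files(pred_dir, pattern = "\\.txt$")
    if (length(preds) == 0L) abort_input("no predicted hypnograms to evaluate")
    pairs <- lapply(preds, function(f) {
      sid <- sub("\\.txt$", "", f)
      ref_f <- file.path(ref_dir, f)
      if (!file.exists(ref_f)) abort_input(sprintf("missing reference hypnogram for subject %s", sid))
      ref <- read_hypnogram(ref_f)
      cand <- read_hypnogram(file.path(pred_dir, f))
      if (length(ref) != length(cand)) {
        abort_input(sprintf("hypnogram length mismatch for subject %s: %d vs %d",
                            sid, length(ref), length(cand)))
      }
      list(reference = ref, candidate = cand)
    })
    rep <- bootstrap_agreement(pairs, R = config$bootstrap_R, seed = config$seed)
    write_agreement_report(rep, report_path)
    first <- sub("\\.txt$", "", preds[1L])
    hypnogram_overlay(pairs[[1L]]$reference, pairs[[1L]]$candidate,
                      file.path(out_dir, paste0("overlay_", first, ".png")),
                      title = sprintf("Subject %s", first))
    log_msg(logfile, "INFO", "evaluate: pooled kappa %.3f (%s), report at %s",
            rep$kappa, rep$kappa_label, report_path)
    artifacts$report <- report_path
  }

  invisible(artifacts)
}
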