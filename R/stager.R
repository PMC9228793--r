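#' Classifier configuration
#'
#' @param variant One of `"conv"`, `"recurrent"`, `"conv_recurrent"`:
#'   convolution over the feature axis within an epoch, Elman recurrence
#'   over the epoch sequence, or their composition.
#' @param hidden Recurrent hidden-state size.
#' @param filters,kernel Conv filter count and kernel width over the
#'   feature axis.
#' @param context_len Temporal context in epochs; the recurrent variants
#'   carry state across the whole sequence, and `context_len` documents
#'   the effective context the gradients are expected to exploit.
#' @param train_epochs Full-batch Adam iterations.
#' @param learning_rate Adam step size.
#' @param l2 L2 weight penalty.
#' @param seed Seed for parameter initialisation.
#' @param class_weights Optional named weights per stage; default
#'   inverse-frequency from the training labels (stage imbalance is
#'   severe in clinical cohorts -- N3 is a few percent of epochs).
#' @return List of class `stager_config`.
#' @export
stager_config <- function(variant = c("conv_recurrent", "conv", "recurrent"),
                          hidden = 16, filters = 12, kernel = 5,
                          context_len = 9, train_epochs = 200,
                          learning_rate = 0.02, l2 = 1e-4, seed = 1,
                          class_weights = NULL) {
  variant <- match.arg(variant)
  if (context_len < 1 || hidden < 1 || filters < 1 || kernel < 1) {
    abort_config("sizes and context_len must be >= 1")
  }
  structure(list(variant = variant, hidden = hidden, filters = filters,
                 kernel = kernel, context_len = context_len,
                 train_epochs = train_epochs, learning_rate = learning_rate,
                 l2 = l2, seed = seed, class_weights = class_weights),
            class = "stager_config")
}

#' Subject-level train/validation/test split
#'
#' Subjects (never epochs) are partitioned so no recording contributes
#' to two parts; reproducible for a fixed seed.
#'
#' @param subject_ids Character vector of unique subject ids.
#' @param fractions Length-3 proportions `(train, validation, test)`
#'   summing to 1.
#' @param seed RNG seed.
#' @return List with `train`, `validation`, `test` id vectors.
#' @export
make_split <- function(subject_ids, fractions = c(0.8, 0.1, 0.1), seed = 1) {
  subject_ids <- unique(as.character(subject_ids))
  n <- length(subject_ids)
  if (abs(sum(fractions) - 1) > 1e-9) abort_config("fractions must sum to 1")
  if (any(fractions < 0)) abort_config("fractions must be >= 0")
  sizes <- c(round(n * fractions[1]), round(n * fractions[2]))
  sizes <- c(sizes, n - sum(sizes))
  if (any(sizes < 0) || any(sizes == 0 & fractions > 0)) {
    abort_input(sprintf("too few subjects (%d) for fractions %s", n,
                        paste(signif(fractions, 3), collapse = "/")))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample(subject_ids)
  list(train = perm[seq_len(sizes[1])],
       validation = perm[sizes[1] + seq_len(sizes[2])],
       test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
}

subjects_to_xy <- function(subjects, layout) {
  Xs <- vector("list", length(subjects))
  ys <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    X <- s$features
    if (!identical(colnames(X), layout)) {
      abort_config(sprintf("feature layout mismatch for subject %d", i))
    }
    lab <- unclass_hypnogram(if (inherits(s$labels, "hypnogram")) s$labels
                             else hypnogram(s$labels))
    if (nrow(X) != length(lab)) {
      abort_input(sprintf("subject %d: %d feature rows but %d labels",
                          i, nrow(X), length(lab)))
    }
    Xs[[i]] <- unname(X)
    ys[[i]] <- as.integer(lab)
  }
  list(Xs = Xs, ys = ys)
}

#' Train a sleep-stage classifier
#'
#' Features are standardised with training-set statistics; the loss is
#' softmax cross-entropy with inverse-frequency class weights, minimised
#' by full-batch Adam so a fixed seed and fixed data give identical
#' models.  The pooled validation kappa (over `val_subjects`, or the
#' training subjects when none are given) is recorded for model
#' selection.
#'
#' @param subjects List of training subjects, each
#'   `list(features = <matrix from extract_features>, labels = <hypnogram>)`.
#' @param config A [stager_config()].
#' @param val_subjects Optional validation subjects, same structure.
#' @return Object of class `trained_stager` with the learned parameters,
#'   feature-layout fingerprint, loss trace and validation kappa.
#' @export
train_stager <- function(subjects, config = stager_config(), val_subjects = NULL) {
  if (length(subjects) < 1L) abort_input("no training subjects")
  layout <- colnames(subjects[[1]]$features)
  if (is.null(layout)) abort_config("training features must carry column names")
  xy <- subjects_to_xy(subjects, layout)
  all_y <- unlist(xy$ys)
  if (length(unique(all_y)) < 2L) {
    abort_input("training labels cover a single stage; nothing to separate")
  }

  allX <- do.call(rbind, xy$Xs)
  mu <- colMeans(allX)
  sdv <- apply(allX, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Xs <- lapply(xy$Xs, function(X) sweep(sweep(X, 2, mu), 2, sdv, "/"))

  cw <- config$class_weights
  if (is.null(cw)) {
    tab <- tabulate(all_y, nbins = 5)
    cw <- ifelse(tab > 0, length(all_y) / (sum(tab > 0) * tab), 0)
  } else {
    cw <- unname(cw[stage_levels()])
  }
  Ys <- lapply(xy$ys, function(y) {
    Y <- matrix(0, length(y), 5); Y[cbind(seq_along(y), y)] <- 1; Y
  })
  ws <- lapply(xy$ys, function(y) cw[y])

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  params <- net_init(config$variant, ncol(allX), config)
  state <- adam_init(params)
  loss_trace <- numeric(config$train_epochs)
  for (it in seq_len(config$train_epochs)) {
    pass <- net_pass(config$variant, params, Xs, Ys, ws, config, grad = TRUE)
    loss_trace[it] <- pass$loss
    upd <- adam_step(params, pass$grads, state, config$learning_rate,
                     l2 = config$l2)
    params <- upd$params; state <- upd$state
  }

  model <- structure(list(variant = config$variant, params = params,
                          mu = mu, sd = sdv, layout = layout,
                          config = config, n_params = n_params(params),
                          loss_trace = loss_trace,
                          validation_kappa = NA_real_),
                     class = "trained_stager")
  val <- if (length(val_subjects) > 0L) val_subjects else subjects
  model$validation_kappa <- pooled_kappa(model, val)
  model$validated_on <- if (length(val_subjects) > 0L) "validation" else "training"
  if (is.na(model$validation_kappa) && length(val_subjects) > 0L) {
    # a tiny validation pool can be single-stage (kappa undefined);
    # fall back to the training subjects so selection stays possible
    model$validation_kappa <- pooled_kappa(model, subjects)
    model$validated_on <- "training (validation pool degenerate)"
  }
  model
}

pooled_kappa <- function(model, subjects) {
  mats <- lapply(subjects, function(s) {
    pred <- predict_hypnogram(model, s$features)
    confusion_matrix(if (inherits(s$labels, "hypnogram")) s$labels
                     else hypnogram(s$labels), pred)
  })
  suppressWarnings(cohens_kappa(as_paired_confusion(Reduce(`+`, lapply(mats, unclass)))))
}

#' @export
print.trained_stager <- function(x, ...) {
  cat(sprintf("<trained_stager> variant %s, %d parameters, validation kappa %.3f (%s set)\n",
              x$variant, x$n_params, x$validation_kappa, x$validated_on))
  cat(sprintf("final training loss %.4f over %d iterations\n",
              utils::tail(x$loss_trace, 1), length(x$loss_trace)))
  invisible(x)
}

#' Predict a hypnogram from per-epoch features
#'
#' @param model A [train_stager()] result.
#' @param features Feature matrix whose columns match the model's
#'   layout fingerprint.
#' @return A [hypnogram()] with one stage per feature row (argmax;
#'   ties broken by the fixed stage order).
#' @export
predict_hypnogram <- function(model, features) {
  if (!inherits(model, "trained_stager")) abort_input("expected a trained_stager")
  if (!identical(colnames(features), model$layout)) {
    abort_config("feature layout does not match the model's layout fingerprint")
  }
  if (nrow(features) == 0L) {
    # degenerate but legal: no epochs in, no epochs out
    return(structure(factor(character(0), levels = stage_levels()),
                     epoch_len_s = 30, class = c("hypnogram", "factor")))
  }
  X <- sweep(sweep(unname(features), 2, model$mu), 2, model$sd, "/")
  pass <- net_pass(model$variant, model$params, list(X), NULL, NULL,
                   model$config, grad = FALSE)
  hypnogram(stage_levels()[pass$preds[[1]]])
}

#' Select the best model by validation kappa
#'
#' Ties are broken in favour of fewer parameters, then earlier position
#' in the candidate list.
#'
#' @param candidates List of [train_stager()] results.
#' @return The winning `trained_stager`.
#' @export
select_best_model <- function(candidates) {
  if (length(candidates) < 1L) abort_input("no candidate models")
  kap <- vapply(candidates, function(m) {
    if (!inherits(m, "trained_stager") || is.na(m$validation_kappa)) {
      abort_input("every candidate needs a recorded validation kappa")
    }
    m$validation_kappa
  }, numeric(1))
  np <- vapply(candidates, `[[`, numeric(1), "n_params")
  ord <- order(-kap, np, seq_along(candidates))
  candidates[[ord[1L]]]
}

#' Relabel isolated N1 epochs inside an N2 or R run
#'
#' Human scorers carry stage N2 (and R) across epochs of low-amplitude
#' mixed-frequency EEG; a single N1 epoch flanked on both sides by the
#' same stage S in {N2, R} is relabelled S.  Longer N1 runs and all
#' other labels are untouched; the operation is idempotent.
#'
#' @param h A [hypnogram()].
#' @return The smoothed [hypnogram()].
#' @export
apply_continuity_smoothing <- function(h) {
  lab <- hypnogram_labels(h)
  n <- length(lab)
  if (n < 3L) return(h)
  out <- lab
  for (i in 2:(n - 1L)) {
    if (lab[i] == "N1" && lab[i - 1L] == lab[i + 1L] &&
        lab[i - 1L] %in% c("N2", "R")) {
      out[i] <- lab[i - 1L]
    }
  }
  hypnogram(out, epoch_len_s = attr(h, "epoch_len_s"))
}

#' Save / load a trained model bundle
#'
#' Single-file serialised bundle carrying the parameters, layout
#' fingerprint and training metadata; reloading reproduces predictions
#' exactly.
#'
#' @param model A `trained_stager`.
#' @param path File path.
#' @return `path` / the model.
#' @export
save_stager <- function(model, path) {
  if (!inherits(model, "trained_stager")) abort_input("expected a trained_stager")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_stager
#' @export
load_stager <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("model file not found: %s", path))
  m <- readRDS(path)
  if (!inherits(m, "trained_stager")) abort_input(sprintf("%s is not a model bundle", path))
  m
}
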