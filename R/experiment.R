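#' Per-subject feature volume by name
#'
#' @param subject a cohort subject (fields `smri`, `icn_stack`, optional
#'   `ts`).
#' @param kind `"smri"`, a projection kind, `"alff"` or `"falff"`.
#' @param band [frequency_band()] for the spectral kinds.
#' @return an `nf_volume`.
#' @export
subject_feature <- function(subject, kind = c("smri", "max_icn",
                                              "abs_min_icn", "max_abs_icn",
                                              "alff", "falff"),
                            band = frequency_band()) {
  kind <- match.arg(kind)
  if (kind == "smri") return(subject$smri)
  if (kind %in% c("max_icn", "abs_min_icn", "max_abs_icn"))
    return(project_ivip(subject$icn_stack, kind))
  if (is.null(subject$ts))
    stop("subject has no time series; generate one first", call. = FALSE)
  if (kind == "alff") compute_alff(subject$ts, band)
  else compute_falff(subject$ts, band)
}

#' Build model inputs for a whole cohort
#'
#' For every subject: a mask is computed from the subject's own gray matter
#' (voxels `> mask_threshold`), the requested modality volumes are derived,
#' and the channels of the chosen experiment are assembled
#' ([build_unimodal()], [build_two_channel()] or [build_fused()]).
#'
#' @param cohort an [generate_cohort()] result, or a list of subjects.
#' @param experiment `"unimodal"`, `"two_channel"` or `"fused"`.
#' @param modality the single modality (Experiment 1) or the iVIP kind
#'   paired with sMRI (Experiments 2-3).
#' @param mask_threshold gray-matter mask threshold (default 0.03).
#' @param band spectral band for ALFF/fALFF modalities.
#' @return named list of `nf_model_input`, keyed by subject id.
#' @export
build_inputs <- function(cohort,
                         experiment = c("unimodal", "two_channel", "fused"),
                         modality = "max_abs_icn", mask_threshold = 0.03,
                         band = frequency_band()) {
  experiment <- match.arg(experiment)
  subjects <- if (inherits(cohort, "nf_cohort")) cohort$subjects else cohort
  if (experiment != "unimodal" &&
      !modality %in% c("max_icn", "abs_min_icn", "max_abs_icn"))
    stop("multimodal experiments pair sMRI with an iVIP projection",
         call. = FALSE)
  out <- lapply(subjects, function(s) {
    mask <- compute_mask(s$smri, mask_threshold)
    switch(experiment,
      unimodal = build_unimodal(subject_feature(s, modality, band), mask,
                                subject_id = s$subject_id, label = s$label),
      two_channel = build_two_channel(s$smri,
                                      subject_feature(s, modality, band),
                                      mask, subject_id = s$subject_id,
                                      label = s$label),
      fused = build_fused(s$smri, subject_feature(s, modality, band), mask,
                          subject_id = s$subject_id, label = s$label))
  })
  names(out) <- vapply(subjects, `[[`, "", "subject_id")
  out
}

experiment_channels <- c(unimodal = 1L, two_channel = 2L, fused = 3L)

#' Run a cross-validated classification experiment
#'
#' The end-to-end driver: builds per-subject channels for the chosen
#' experiment, then for every fold of the split plan trains a fresh CNN on
#' the training cohort, monitors the validation cohort, and evaluates once on
#' the held-out test cohort.  Fold metrics are aggregated to mean ± sd.
#'
#' @param cohort an [generate_cohort()] result (or a list of subjects).
#' @param plan an [make_split_plan()] over the cohort's subject ids.
#' @param experiment,modality,mask_threshold,band passed to
#'   [build_inputs()].
#' @param model_config an [cnn_config()]; its channel count must match the
#'   experiment.  Default: a compact configuration suited to small grids.
#' @param train_cfg an [train_config()].
#' @param seed master seed; fold f trains with seed `seed + f`.
#' @param folds which folds of the plan to run (default all).
#' @param verbose print per-epoch progress.
#' @return An object of class `nf_experiment`: `fold_metrics` (list of
#'   `nf_fold_metrics`), `summary` (mean ± sd data frame), `histories`,
#'   pooled `n_correct` / `n_test`, and the final fold's fit under `fit`.
#' @export
run_experiment <- function(cohort, plan,
                           experiment = c("unimodal", "two_channel",
                                          "fused"),
                           modality = "max_abs_icn",
                           model_config = NULL,
                           train_cfg = train_config(),
                           mask_threshold = 0.03, band = frequency_band(),
                           seed = 1L, folds = seq_len(plan$n_folds),
                           verbose = FALSE) {
  experiment <- match.arg(experiment)
  stopifnot(inherits(plan, "nf_split_plan"))
  inputs <- build_inputs(cohort, experiment, modality, mask_threshold, band)
  n_classes <- length(nf_class_levels(plan$labels))
  if (is.null(model_config))
    model_config <- cnn_config(experiment_channels[[experiment]], n_classes,
                               conv_filters = c(8L, 16L, 32L),
                               pool_after = 1L, fc_widths = c(32L, 16L))
  if (model_config$n_channels != experiment_channels[[experiment]])
    stop(sprintf("model_config has %d channels but experiment '%s' needs %d",
                 model_config$n_channels, experiment,
                 experiment_channels[[experiment]]), call. = FALSE)
  fold_metrics <- list()
  histories <- list()
  fit <- NULL
  for (f in folds) {
    fold <- plan$folds[[f]]
    model <- build_model(model_config, seed = seed + f)
    tc <- train_cfg
    tc$seed <- seed + 1000L + f
    fit <- train_model(model, inputs[fold$train], inputs[fold$validation],
                       tc, verbose = verbose)
    fold_metrics[[length(fold_metrics) + 1L]] <-
      evaluate(fit, inputs[fold$test], fold_id = f)
    histories[[length(histories) + 1L]] <- fit$history
  }
  summary_df <- if (length(fold_metrics) >= 2L)
    aggregate_folds(fold_metrics) else NULL
  structure(list(experiment = experiment, modality = modality,
                 fold_metrics = fold_metrics, summary = summary_df,
                 histories = histories,
                 n_correct = sum(vapply(fold_metrics, `[[`, 0, "n_correct")),
                 n_test = sum(vapply(fold_metrics, `[[`, 0, "n")),
                 model_config = model_config, train_cfg = train_cfg,
                 fit = fit),
            class = "nf_experiment")
}

#' @export
print.nf_experiment <- function(x, ...) {
  cat(sprintf("<nf_experiment> %s (%s), %d fold(s)\n",
              x$experiment, x$modality, length(x$fold_metrics)))
  if (!is.null(x$summary)) {
    print(x$summary[, c("metric", "formatted")], row.names = FALSE)
  } else if (length(x$fold_metrics) == 1L) {
    print(round(x$fold_metrics[[1L]]$metrics, 2))
  }
  invisible(x)
}

#' Write per-fold and aggregated experiment results as CSV
#'
#' @param x an `nf_experiment`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_experiment_results <- function(x, dir) {
  stopifnot(inherits(x, "nf_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  per_fold <- do.call(rbind, lapply(x$fold_metrics, function(m)
    data.frame(fold = m$fold_id, t(m$metrics))))
  utils::write.csv(per_fold, file.path(dir, "fold_metrics.csv"),
                   row.names = FALSE)
  if (!is.null(x$summary))
    utils::write.csv(x$summary, file.path(dir, "summary.csv"),
                     row.names = FALSE)
  hist <- do.call(rbind, lapply(seq_along(x$histories), function(i)
    cbind(fold = i, x$histories[[i]])))
  utils::write.csv(hist, file.path(dir, "epoch_history.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read an experiment configuration YAML
#'
#' Fields: `experiment`, `modality`, `n_folds`, `rule`, `val_size`,
#' `test_size`, `seed`, plus optional `model` and `training` blocks whose
#' entries override [cnn_config()] and [train_config()] defaults.
#'
#' @param path YAML file path.
#' @return a named list of configuration values.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(is.list(cfg))
  cfg
}
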