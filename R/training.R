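## canonical diagnostic class ordering used throughout
nf_class_levels <- function(labels) {
  canon <- c("AD", "MCI", "CN")
  u <- unique(as.character(labels))
  c(intersect(canon, u), sort(setdiff(u, canon)))
}

## largest-remainder allocation of `total` slots proportionally to counts
alloc_stratified <- function(class_counts, total) {
  share <- class_counts / sum(class_counts) * total
  base <- floor(share)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(share - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Stratified repeated-subsampling split plan
#'
#' Draws `n_folds` independent stratified train/validation/test assignments
#' (stratified Monte Carlo cross-validation: folds are repeated random
#' subsamples, not a partition).  Under the `"floor"` rule the validation and
#' test cohorts each receive `floor(n / n_folds)` subjects (e.g. 58 from
#' n = 466 with 8 folds, leaving 350 for training); `"explicit"` accepts
#' stated cohort sizes (e.g. 95/95 from n = 730, leaving 540).  Within every
#' cohort the per-class proportions match the full cohort to within one
#' subject (largest-remainder allocation).
#'
#' @param labels per-subject diagnostic labels; names, if present, are used
#'   as subject ids, otherwise ids `s1..sn` are assigned.
#' @param n_folds number of repeated subsamples (default 8).
#' @param rule `"floor"` or `"explicit"`.
#' @param val_size,test_size cohort sizes for the `"explicit"` rule.
#' @param seed integer seed; identical labels and seed reproduce the plan.
#' @return An object of class `nf_split_plan` with per-fold disjoint
#'   `train` / `validation` / `test` id vectors.
#' @examples
#' plan <- make_split_plan(rep(c("AD", "CN"), c(83, 383)), n_folds = 8,
#'                         seed = 1)
#' lengths(plan$folds[[1]])
#' @export
make_split_plan <- function(labels, n_folds = 8L,
                            rule = c("floor", "explicit"),
                            val_size = NULL, test_size = NULL, seed = 1L) {
  rule <- match.arg(rule)
  ids <- names(labels)
  labels <- as.character(labels)
  n <- length(labels)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  names(labels) <- ids
  n_folds <- as.integer(n_folds)
  stopifnot(n_folds >= 1L, n >= 2L)
  counts <- table(labels)
  if (any(counts < n_folds))
    stop(sprintf("class '%s' has fewer members (%d) than folds (%d): too small to stratify",
                 names(counts)[which.min(counts)], min(counts), n_folds),
         call. = FALSE)
  if (rule == "floor") {
    val_size <- test_size <- n %/% n_folds
  } else {
    stopifnot(!is.null(val_size), !is.null(test_size))
    val_size <- as.integer(val_size)
    test_size <- as.integer(test_size)
  }
  if (val_size + test_size >= n)
    stop("validation + test sizes leave no training subjects", call. = FALSE)
  classes <- names(counts)
  v_alloc <- stats::setNames(alloc_stratified(as.integer(counts), val_size),
                             classes)
  t_alloc <- stats::setNames(alloc_stratified(as.integer(counts), test_size),
                             classes)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  folds <- lapply(seq_len(n_folds), function(f) {
    val <- character(0); test <- character(0); train <- character(0)
    for (cl in classes) {
      pool <- sample(ids[labels == cl])
      nv <- v_alloc[[cl]]; nt <- t_alloc[[cl]]
      val <- c(val, pool[seq_len(nv)])
      test <- c(test, pool[nv + seq_len(nt)])
      train <- c(train, pool[-(seq_len(nv + nt))])
    }
    list(train = train, validation = val, test = test)
  })
  structure(list(n_folds = n_folds, folds = folds, rule = rule,
                 sizes = c(train = n - val_size - test_size,
                           validation = val_size, test = test_size),
                 seed = seed, labels = labels,
                 stratify_on = classes),
            class = "nf_split_plan")
}

#' @export
print.nf_split_plan <- function(x, ...) {
  cat(sprintf(
    "<nf_split_plan> %d repeated stratified subsamples of %d subjects\n  train %d / validation %d / test %d (rule: %s, seed %d)\n",
    x$n_folds, length(x$labels), x$sizes["train"], x$sizes["validation"],
    x$sizes["test"], x$rule, x$seed))
  invisible(x)
}

#' Training protocol configuration
#'
#' Cross-entropy loss optimized with Adam; the learning rate is halved
#' (`plateau_factor = 0.5`) when validation accuracy fails to improve by more
#' than `min_delta` for `plateau_patience` consecutive epochs, and training
#' stops after `early_stop_patience` epochs (default 20) without improvement,
#' returning the best-validation-epoch parameters.
#'
#' @param learning_rate initial Adam learning rate (searched grid:
#'   0.1, 0.01, 0.001, 1e-4, 1e-5).
#' @param batch_size mini-batch size (searched grid: 4, 8, 16, 32, 64).
#' @param max_epochs hard cap on epochs.
#' @param plateau_factor multiplicative learning-rate cut on plateau.
#' @param plateau_patience epochs without improvement defining a plateau.
#' @param early_stop_patience epochs without improvement before stopping.
#' @param min_delta minimum validation-accuracy improvement that counts.
#' @param seed integer seed for batch order, dropout, and initialization.
#' @return An object of class `nf_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 8L,
                         max_epochs = 100L, plateau_factor = 0.5,
                         plateau_patience = 5L, early_stop_patience = 20L,
                         min_delta = 1e-4, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1L, max_epochs >= 1L,
            plateau_factor > 0, plateau_factor < 1,
            plateau_patience >= 1L, early_stop_patience >= 1L,
            min_delta >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 min_delta = min_delta, seed = as.integer(seed)),
            class = "nf_train_config")
}

input_labels <- function(inputs) {
  vapply(inputs, function(i) as.character(i$label), "")
}

## accuracy of eval-mode predictions against the inputs' own labels
eval_accuracy <- function(layers, config, inputs, class_levels,
                          chunk = 32L) {
  labs <- input_labels(inputs)
  pred <- character(length(inputs))
  for (s in split(seq_along(inputs), ceiling(seq_along(inputs) / chunk))) {
    rep <- batch_to_rep(inputs[s], config$n_channels)
    lg <- net_forward(layers, rep, training = FALSE)$out
    pred[s] <- class_levels[max.col(lg, ties.method = "first")]
  }
  mean(pred == labs)
}

#' Train a CNN classifier
#'
#' Optimizes cross-entropy with Adam over mini-batches, monitoring validation
#' accuracy each epoch.  On a plateau (no improvement beyond `min_delta` for
#' `plateau_patience` epochs) the learning rate is multiplied by
#' `plateau_factor`; after `early_stop_patience` epochs without improvement
#' training halts.  The returned fit carries the parameters of the best
#' validation epoch and the per-epoch history (loss, validation accuracy,
#' learning rate).
#'
#' @param model an `nf_cnn` from [build_model()].
#' @param train,validation disjoint lists of labelled `nf_model_input`.
#' @param config an [train_config()].
#' @param verbose print a line per epoch.
#' @return An object of class `nf_cnn_fit` with elements `model` (best
#'   parameters), `history` (data frame), `best_epoch`,
#'   `best_val_accuracy`, `config`.
#' @export
train_model <- function(model, train, validation, config = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "nf_cnn"), inherits(config, "nf_train_config"))
  if (length(train) == 0L || length(validation) == 0L)
    stop("empty training or validation set", call. = FALSE)
  tr_ids <- vapply(train, `[[`, "", "subject_id")
  va_ids <- vapply(validation, `[[`, "", "subject_id")
  both <- intersect(stats::na.omit(tr_ids), stats::na.omit(va_ids))
  if (length(both) > 0L)
    stop("train and validation sets overlap: ", paste(both, collapse = ", "),
         call. = FALSE)
  class_levels <- nf_class_levels(input_labels(train))
  y_idx <- match(input_labels(train), class_levels)
  if (anyNA(y_idx)) stop("unlabelled training input", call. = FALSE)

  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(config$seed)

  layers <- model$layers
  state <- adam_init(layers)
  lr <- config$learning_rate
  n <- length(train)
  best_val <- -Inf
  best_layers <- layers
  best_epoch <- 0L
  plateau_counter <- 0L
  stop_counter <- 0L
  t_adam <- 0L
  hist <- list()

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      rep <- batch_to_rep(train[b], model$config$n_channels)
      fw <- net_forward(layers, rep, training = TRUE)
      layers <- fw$layers
      ce <- cross_entropy(fw$out, y_idx[b])
      if (!is.finite(ce$loss))
        stop(sprintf("training diverged (non-finite loss) at epoch %d",
                     epoch), call. = FALSE)
      losses[bi] <- ce$loss
      bw <- net_backward(layers, fw$caches, ce$grad, input_grad = FALSE)
      t_adam <- t_adam + 1L
      upd <- adam_step(layers, bw$grads, state, lr, t_adam)
      layers <- upd$layers
      state <- upd$state
    }
    val_acc <- eval_accuracy(layers, model$config, validation, class_levels)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_loss = mean(losses),
                                val_accuracy = val_acc, lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val acc %.3f  lr %.2g",
                      epoch, mean(losses), val_acc, lr))
    if (val_acc > best_val + config$min_delta) {
      best_val <- val_acc
      best_layers <- layers
      best_epoch <- epoch
      plateau_counter <- 0L
      stop_counter <- 0L
    } else {
      plateau_counter <- plateau_counter + 1L
      stop_counter <- stop_counter + 1L
      if (plateau_counter >= config$plateau_patience) {
        lr <- lr * config$plateau_factor
        plateau_counter <- 0L
      }
      if (stop_counter >= config$early_stop_patience) break
    }
  }
  fitted <- model
  fitted$layers <- best_layers
  attr(fitted, "class_levels") <- class_levels
  structure(list(model = fitted, history = do.call(rbind, hist),
                 best_epoch = best_epoch, best_val_accuracy = best_val,
                 class_levels = class_levels, config = config),
            class = "nf_cnn_fit")
}

#' @export
print.nf_cnn_fit <- function(x, ...) {
  cat(sprintf(
    "<nf_cnn_fit> trained %d epoch(s); best validation accuracy %.3f at epoch %d\n",
    nrow(x$history), x$best_val_accuracy, x$best_epoch))
  invisible(x)
}

#' @export
plot.nf_cnn_fit <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "Loss")
  graphics::plot(h$epoch, h$val_accuracy, type = "l", xlab = "epoch",
                 ylab = "validation accuracy", main = "Validation accuracy")
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}

## rank-based (Mann-Whitney) AUC: independent of any monotone score transform
rank_auc <- function(scores, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from predictions
#'
#' Computes the fold-level metric battery on a 0-100 scale: accuracy,
#' balanced accuracy (mean of per-class recalls), macro-averaged F1,
#' precision and recall, and AUC (binary: ROC area of the positive class,
#' `"AD"` when present; multiclass: macro one-vs-rest average), plus the
#' class-by-class confusion matrix (rows = truth).
#'
#' @param truth character vector of true labels.
#' @param predicted character vector of predicted labels.
#' @param scores optional numeric matrix (subjects x classes) of
#'   probabilities or scores with column names matching `levels`; needed for
#'   AUC.
#' @param levels class levels; defaults to the canonical ordering of the
#'   labels present in `truth`.
#' @param fold_id identifier stored with the result.
#' @return An object of class `nf_fold_metrics`.
#' @export
classification_metrics <- function(truth, predicted, scores = NULL,
                                   levels = NULL, fold_id = NA_integer_) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted), length(truth) >= 1L)
  if (is.null(levels)) levels <- nf_class_levels(truth)
  absent <- setdiff(levels, unique(truth))
  if (length(absent) > 0L)
    stop("class absent from the test set: ", paste(absent, collapse = ", "),
         " (balanced metrics undefined)", call. = FALSE)
  cm <- table(factor(truth, levels), factor(predicted, levels))
  diagc <- diag(cm)
  recalls <- diagc / rowSums(cm)
  precisions <- ifelse(colSums(cm) > 0, diagc / colSums(cm), 0)
  f1s <- ifelse(precisions + recalls > 0,
                2 * precisions * recalls / (precisions + recalls), 0)
  auc <- NA_real_
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    if (is.null(colnames(scores))) colnames(scores) <- levels
    if (length(levels) == 2L) {
      pos <- if ("AD" %in% levels) "AD" else levels[1L]
      auc <- rank_auc(scores[, pos], truth == pos)
    } else {
      auc <- mean(vapply(levels, function(cl)
        rank_auc(scores[, cl], truth == cl), 0))
    }
  }
  structure(list(
    fold_id = fold_id,
    metrics = c(test_accuracy = 100 * mean(truth == predicted),
                balanced_accuracy = 100 * mean(recalls),
                f1 = 100 * mean(f1s),
                precision = 100 * mean(precisions),
                recall = 100 * mean(recalls),
                auc = 100 * auc),
    n = length(truth),
    n_correct = sum(truth == predicted),
    confusion_matrix = cm), class = "nf_fold_metrics")
}

#' @export
print.nf_fold_metrics <- function(x, ...) {
  cat(sprintf("<nf_fold_metrics> fold %s, n = %d\n",
              as.character(x$fold_id), x$n))
  print(round(x$metrics, 2))
  invisible(x)
}

#' Evaluate a trained classifier on a held-out test set
#'
#' @param fit an `nf_cnn_fit` (or an `nf_cnn` with a `class_levels`
#'   attribute).
#' @param test nonempty list of labelled `nf_model_input`.
#' @param fold_id stored with the metrics.
#' @return An [classification_metrics()] result of class `nf_fold_metrics`.
#' @export
evaluate <- function(fit, test, fold_id = NA_integer_) {
  stopifnot(length(test) >= 1L)
  model <- as_nf_cnn(fit)
  class_levels <- attr(model, "class_levels")
  if (is.null(class_levels))
    stop("model has no class levels; train it first", call. = FALSE)
  probs <- predict(model, test, type = "prob")
  pred <- class_levels[max.col(probs, ties.method = "first")]
  classification_metrics(input_labels(test), pred, probs,
                         levels = class_levels, fold_id = fold_id)
}

#' Aggregate fold metrics to mean and standard deviation
#'
#' @param folds list of `nf_fold_metrics` (at least 2).
#' @return A data frame with one row per metric: `mean`, `sd` (sample
#'   standard deviation across folds), and `formatted` ("m ± s").
#' @export
aggregate_folds <- function(folds) {
  stopifnot(is.list(folds))
  if (length(folds) < 2L)
    stop("need at least 2 folds to aggregate", call. = FALSE)
  M <- do.call(rbind, lapply(folds, `[[`, "metrics"))
  data.frame(metric = colnames(M),
             mean = colMeans(M),
             sd = apply(M, 2L, stats::sd),
             formatted = sprintf("%.2f ± %.2f", colMeans(M),
                                 apply(M, 2L, stats::sd)),
             row.names = NULL)
}

#' Chi-squared comparison of two classifiers' accuracies
#'
#' Pools correct/incorrect counts (e.g. across folds) into a 2x2 table and
#' applies Pearson's chi-squared test with one degree of freedom and no
#' continuity correction.
#'
#' @param correct_a,n_a correct predictions and total for model A.
#' @param correct_b,n_b correct predictions and total for model B.
#' @return list with `statistic`, `p_value`, and the 2x2 `table`.
#' @export
chi_squared_compare <- function(correct_a, n_a, correct_b, n_b) {
  stopifnot(correct_a >= 0, correct_b >= 0,
            correct_a <= n_a, correct_b <= n_b)
  tab <- rbind(a = c(correct = correct_a, incorrect = n_a - correct_a),
               b = c(correct = correct_b, incorrect = n_b - correct_b))
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0))
    stop("zero marginal: expected count of 0 in the 2x2 table",
         call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       table = tab)
}

#' Hyperparameter grid search on validation accuracy
#'
#' Evaluates every (model config, train config) pair on each fold of the
#' plan and selects the pair maximizing mean validation accuracy.  Tuning
#' touches the validation sets only; held-out test sets are left for a final
#' [evaluate()] call.  `fit_eval` may be replaced (e.g. in tests) by any
#' function returning a validation accuracy for a (model config, train
#' config, fold) triple.
#'
#' @param inputs named list of `nf_model_input`, keyed by subject id.
#' @param plan an [make_split_plan()].
#' @param model_configs list of [cnn_config()] objects.
#' @param train_configs list of [train_config()] objects.
#' @param fit_eval function(model_config, train_config, fold) -> validation
#'   accuracy in `[0, 1]`; the default trains with [train_model()].
#' @param folds which folds to use (default all).
#' @return list with `model_config`, `train_config`, and a `results` data
#'   frame of mean validation accuracies.
#' @export
grid_search <- function(inputs, plan, model_configs, train_configs,
                        fit_eval = NULL, folds = seq_len(plan$n_folds)) {
  stopifnot(inherits(plan, "nf_split_plan"),
            length(model_configs) >= 1L, length(train_configs) >= 1L)
  if (is.null(fit_eval)) {
    fit_eval <- function(mc, tc, fold) {
      model <- build_model(mc, seed = tc$seed)
      fit <- train_model(model, inputs[fold$train], inputs[fold$validation],
                         tc)
      fit$best_val_accuracy
    }
  }
  res <- expand.grid(model_config = seq_along(model_configs),
                     train_config = seq_along(train_configs))
  res$mean_val_accuracy <- NA_real_
  for (i in seq_len(nrow(res))) {
    mc <- model_configs[[res$model_config[i]]]
    tc <- train_configs[[res$train_config[i]]]
    accs <- vapply(folds, function(f) fit_eval(mc, tc, plan$folds[[f]]), 0)
    res$mean_val_accuracy[i] <- mean(accs)
  }
  best <- which.max(res$mean_val_accuracy)
  list(model_config = model_configs[[res$model_config[best]]],
       train_config = train_configs[[res$train_config[best]]],
       results = res)
}

#' The default hyperparameter search grid
#'
#' Five learning rates (0.1, 0.01, 0.001, 1e-4, 1e-5), five batch sizes
#' (4, 8, 16, 32, 64) and two convolution kernel-stride-padding combinations
#' (5-2-0 and 3-2-1): 50 configurations.
#'
#' @param n_channels,n_classes passed to [cnn_config()].
#' @param ... further arguments passed to [cnn_config()].
#' @return list with `model_configs` (length 2) and `train_configs`
#'   (length 25).
#' @export
default_hyper_grid <- function(n_channels, n_classes, ...) {
  list(
    model_configs = list(
      cnn_config(n_channels, n_classes, kernel_size = 5L, stride = 2L,
                 padding = 0L, ...),
      cnn_config(n_channels, n_classes, kernel_size = 3L, stride = 2L,
                 padding = 1L, ...)),
    train_configs = unlist(lapply(c(0.1, 0.01, 0.001, 1e-4, 1e-5),
      function(lr) lapply(c(4L, 8L, 16L, 32L, 64L),
        function(bs) train_config(learning_rate = lr, batch_size = bs))),
      recursive = FALSE))
}
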