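two_way_labels <- function() rep(c("AD", "CN"), c(83, 383))
three_way_labels <- function() rep(c("AD", "MCI", "CN"), c(83, 264, 383))

test_that("the floor rule reproduces the 350/58/58 two-way cohort sizes", {
  plan <- make_split_plan(two_way_labels(), n_folds = 8, seed = 1)
  for (f in plan$folds) {
    expect_length(f$train, 350)
    expect_length(f$validation, 58)
    expect_length(f$test, 58)
  }
})

test_that("explicit 95/95 cohorts on 730 subjects leave 540 for training", {
  plan <- make_split_plan(three_way_labels(), n_folds = 8, rule = "explicit",
                          val_size = 95, test_size = 95, seed = 2)
  expect_length(plan$folds[[3]]$train, 540)
  expect_length(plan$folds[[3]]$validation, 95)
  expect_length(plan$folds[[3]]$test, 95)
})

test_that("cohorts are stratified within one subject of the class proportions", {
  labels <- rep(c("AD", "CN"), each = 40)
  plan <- make_split_plan(labels, n_folds = 8, seed = 3)
  for (f in plan$folds) {
    idx <- as.integer(sub("s", "", f$validation))  # ids s1..s40 are AD
    expect_lte(abs(sum(idx <= 40) - sum(idx > 40)), 1)
    idx <- as.integer(sub("s", "", f$test))
    expect_lte(abs(sum(idx <= 40) - sum(idx > 40)), 1)
  }
  # three-way plan: per-class proportions within 1 of proportional share
  plan3 <- make_split_plan(three_way_labels(), n_folds = 4, seed = 4)
  lab <- plan3$labels
  for (f in plan3$folds) {
    for (part in list(f$validation, f$test)) {
      got <- table(factor(lab[part], c("AD", "MCI", "CN")))
      want <- table(factor(lab, c("AD", "MCI", "CN"))) / length(lab) *
        length(part)
      expect_true(all(abs(got - want) <= 1))
    }
  }
})

test_that("splits are disjoint, exhaustive, deterministic in the seed", {
  labels <- rep(c("AD", "CN"), c(20, 28))
  p1 <- make_split_plan(labels, n_folds = 5, seed = 7)
  p2 <- make_split_plan(labels, n_folds = 5, seed = 7)
  p3 <- make_split_plan(labels, n_folds = 5, seed = 8)
  expect_identical(p1$folds, p2$folds)
  expect_false(identical(sort(p1$folds[[1]]$test), sort(p3$folds[[1]]$test)))
  for (f in p1$folds) {
    all_ids <- c(f$train, f$validation, f$test)
    expect_identical(sort(all_ids), sort(paste0("s", 1:48)))
    expect_identical(anyDuplicated(all_ids), 0L)
  }
  # repeated subsampling: folds are independent draws, not a partition
  expect_false(identical(sort(p1$folds[[1]]$test), sort(p1$folds[[2]]$test)))
})

test_that("classes smaller than the fold count refuse to stratify", {
  expect_error(make_split_plan(rep(c("AD", "CN"), c(3, 40)), n_folds = 8),
               "too small to stratify")
})

test_that("metric battery: perfect prediction, hand-computed confusion, chance AUC", {
  truth <- rep(c("AD", "CN"), each = 10)
  sc <- cbind(AD = c(rep(0.9, 10), rep(0.1, 10)),
              CN = c(rep(0.1, 10), rep(0.9, 10)))
  m <- classification_metrics(truth, truth, sc)
  expect_equal(unname(m$metrics[c("test_accuracy", "balanced_accuracy",
                                  "auc")]), c(100, 100, 100))

  # confusion [[8,2],[4,6]] (rows truth AD/CN): balanced accuracy 70
  truth2 <- rep(c("AD", "CN"), each = 10)
  pred2 <- c(rep("AD", 8), rep("CN", 2), rep("AD", 4), rep("CN", 6))
  m2 <- classification_metrics(truth2, pred2)
  expect_equal(unname(m2$metrics["balanced_accuracy"]), 70)
  expect_identical(as.vector(m2$confusion_matrix), c(8L, 4L, 2L, 6L))

  # identical scores for everyone: AUC 50
  m3 <- classification_metrics(truth, truth,
                               cbind(AD = rep(0.5, 20), CN = rep(0.5, 20)))
  expect_equal(unname(m3$metrics["auc"]), 50)

  expect_error(classification_metrics(rep("AD", 5), rep("AD", 5),
                                      levels = c("AD", "CN")),
               "absent")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(9)
  truth <- sample(rep(c("AD", "CN"), each = 15))
  s <- runif(30)
  sc1 <- cbind(AD = s, CN = 1 - s)
  sc2 <- cbind(AD = exp(3 * s), CN = -exp(3 * s))
  a1 <- classification_metrics(truth, truth, sc1)$metrics["auc"]
  a2 <- classification_metrics(truth, truth, sc2)$metrics["auc"]
  expect_equal(a1, a2)
  # cross-check the rank AUC against pROC on the same scores
  pr <- as.numeric(pROC::auc(pROC::roc(truth == "AD", s, quiet = TRUE,
                                       direction = "<")))
  expect_equal(unname(a1) / 100, pr, tolerance = 1e-12)
})

test_that("fold aggregation reports mean and sample sd as m ± s", {
  mk <- function(acc) structure(list(fold_id = 1, metrics = c(test_accuracy = acc),
                                     n = 10, n_correct = acc / 10,
                                     confusion_matrix = NULL),
                                class = "nf_fold_metrics")
  ag <- aggregate_folds(list(mk(80), mk(80)))
  expect_equal(ag$mean, 80)
  expect_equal(ag$sd, 0)
  expect_identical(ag$formatted, "80.00 ± 0.00")
  ag2 <- aggregate_folds(list(mk(80), mk(90)))
  expect_equal(ag2$mean, 85)
  expect_equal(ag2$sd, 10 / sqrt(2), tolerance = 1e-12)
  expect_error(aggregate_folds(list(mk(80))), "at least 2")
})

test_that("chi-squared comparison matches the textbook expected-count oracle", {
  # equal proportions: statistic 0, p 1
  eq <- chi_squared_compare(40, 50, 80, 100)
  expect_equal(eq$statistic, 0, tolerance = 1e-12)
  expect_equal(eq$p_value, 1, tolerance = 1e-12)

  # direct oracle on [[40,10],[25,25]]
  tab <- rbind(c(40, 10), c(25, 25))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  oracle <- sum((tab - E)^2 / E)
  got <- chi_squared_compare(40, 50, 25, 50)
  expect_equal(got$statistic, oracle, tolerance = 1e-9)
  # row swap leaves the statistic unchanged; scaling counts scales it
  expect_equal(chi_squared_compare(25, 50, 40, 50)$statistic, oracle,
               tolerance = 1e-12)
  expect_equal(chi_squared_compare(80, 100, 50, 100)$statistic, 2 * oracle,
               tolerance = 1e-9)
  expect_error(chi_squared_compare(0, 10, 0, 20), "zero marginal")
})

test_that("training halts at patience exhaustion when nothing improves", {
  g <- tiny_grid(c(8, 8, 8))
  inputs <- rand_input_set(g, 1, n_per_class = 4, seed = 1)
  m <- build_model(small_cnn_config(1, 2), seed = 1)
  # zero learning rate: validation accuracy can never improve after epoch 1
  cfg <- train_config(learning_rate = 1e-30, batch_size = 4, max_epochs = 50,
                      early_stop_patience = 6, plateau_patience = 3, seed = 2)
  fit <- train_model(m, inputs[1:6], inputs[7:8], cfg)
  expect_identical(nrow(fit$history), 1L + 6L)
  expect_identical(fit$best_epoch, 1L)
})

test_that("the scheduler halves the learning rate on a plateau", {
  g <- tiny_grid(c(8, 8, 8))
  inputs <- rand_input_set(g, 1, n_per_class = 4, seed = 3)
  m <- build_model(small_cnn_config(1, 2), seed = 1)
  cfg <- train_config(learning_rate = 1e-30, batch_size = 4, max_epochs = 50,
                      early_stop_patience = 9, plateau_patience = 3, seed = 2)
  fit <- train_model(m, inputs[1:6], inputs[7:8], cfg)
  lrs <- fit$history$lr
  # plateau windows of 3 epochs after the first: halvings at epochs 5 and 8
  expect_equal(unique(lrs), 1e-30 * c(1, 0.5, 0.25), tolerance = 1e-40)
})

test_that("training overlap between train and validation is rejected", {
  g <- tiny_grid(c(8, 8, 8))
  inputs <- rand_input_set(g, 1, n_per_class = 2, seed = 5)
  m <- build_model(small_cnn_config(1, 2), seed = 1)
  expect_error(train_model(m, inputs[1:3], inputs[3:4], train_config()),
               "overlap")
})

test_that("grid search picks the configuration dominating validation accuracy", {
  labels <- rep(c("AD", "CN"), each = 10)
  plan <- make_split_plan(labels, n_folds = 3, seed = 1)
  mc <- list(small_cnn_config(1, 2))
  tc <- list(train_config(learning_rate = 0.1),
             train_config(learning_rate = 0.001))
  stub <- function(m, t, fold) if (t$learning_rate == 0.001) 0.9 else 0.6
  gs <- grid_search(NULL, plan, mc, tc, fit_eval = stub)
  expect_identical(gs$train_config$learning_rate, 0.001)
  expect_equal(sort(unique(gs$results$mean_val_accuracy)), c(0.6, 0.9))
  # a one-point grid returns its only member
  gs1 <- grid_search(NULL, plan, mc, tc[1], fit_eval = stub)
  expect_identical(gs1$train_config$learning_rate, 0.1)
})

test_that("the default search grid enumerates 5 x 5 x 2 = 50 configurations", {
  gr <- default_hyper_grid(1, 2, conv_filters = c(4, 8), pool_after = 1,
                           fc_widths = c(8, 4))
  expect_length(gr$model_configs, 2)
  expect_length(gr$train_configs, 25)
  combos <- expand.grid(seq_along(gr$model_configs),
                        seq_along(gr$train_configs))
  expect_identical(nrow(combos), 50L)
  lrs <- unique(vapply(gr$train_configs, `[[`, 0, "learning_rate"))
  expect_setequal(lrs, c(0.1, 0.01, 0.001, 1e-4, 1e-5))
})

test_that("a separable synthetic problem trains above the majority-class rate", {
  # class signal: channel mean shifted for AD
  g <- tiny_grid(c(8, 8, 8))
  mk <- function(label, i) {
    set.seed(100 + i)
    base <- array(runif(512), g$dims)
    if (label == "AD") base <- pmin(base + 0.4, 1)
    neurofuse:::model_input(list(as_volume(base, g)),
                            subject_id = sprintf("x%02d", i), label = label,
                            experiment = "unimodal")
  }
  labs <- rep(c("AD", "CN"), each = 10)
  inputs <- lapply(seq_along(labs), function(i) mk(labs[i], i))
  m <- build_model(small_cnn_config(1, 2), seed = 2)
  cfg <- train_config(learning_rate = 1e-2, batch_size = 4, max_epochs = 25,
                      early_stop_patience = 10, seed = 3)
  fit <- train_model(m, inputs[c(1:7, 11:17)], inputs[c(8:10, 18:20)], cfg)
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  expect_gt(fit$best_val_accuracy, 0.5)
})
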