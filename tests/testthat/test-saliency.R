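## a model that is a bare linear map from the flattened input to the logits
linear_probe_model <- function(grid, n_channels, n_classes, seed = 1) {
  set.seed(seed)
  nvox <- prod(grid$dims)
  cfg <- cnn_config(n_channels, n_classes, conv_filters = 4L,
                    fc_widths = c(4L, 4L))
  lin <- neurofuse:::layer_linear(nvox * n_channels, n_classes)
  structure(list(config = cfg,
                 layers = list(neurofuse:::layer_flatten(), lin),
                 seed = seed, n_parameters = length(lin$W) + length(lin$b)),
            class = "nf_cnn")
}

test_that("on a ReLU-free linear model saliency equals the weight map", {
  g <- tiny_grid(c(5, 5, 5))
  for (nch in c(1L, 2L)) {
    m <- linear_probe_model(g, nch, 2, seed = 3)
    inp <- rand_input(g, nch, seed = 4)
    for (cl in 1:2) {
      sal <- guided_backprop(m, inp, target_class = cl)
      expect_length(sal, nch)
      W <- m$layers[[2]]$W[, cl]
      nvox <- prod(g$dims)
      for (ch in seq_len(nch)) {
        expect_equal(as.vector(sal[[ch]]$values),
                     W[((ch - 1) * nvox + 1):(ch * nvox)], tolerance = 1e-6)
      }
    }
  }
})

test_that("guided backprop equals the plain gradient when there is no ReLU", {
  g <- tiny_grid(c(5, 5, 5))
  m <- linear_probe_model(g, 1, 3, seed = 6)
  inp <- rand_input(g, 1, seed = 7)
  sal_g <- guided_backprop(m, inp, target_class = 2, guided = TRUE)
  sal_p <- guided_backprop(m, inp, target_class = 2, guided = FALSE)
  expect_equal(sal_g[[1]]$values, sal_p[[1]]$values, tolerance = 1e-12)
})

test_that("a first ReLU that kills every activation yields a zero map", {
  g <- tiny_grid(c(6, 6, 6))
  m <- build_model(small_cnn_config(1, 2), seed = 8)
  # force all pre-activations negative: large negative conv bias
  m$layers[[1]]$W[] <- 0
  m$layers[[1]]$b[] <- -5
  inp <- rand_input(g, 1, seed = 9)
  sal <- guided_backprop(m, inp, target_class = 1)
  expect_true(all(sal[[1]]$values == 0))
})

test_that("one saliency map is returned per channel, on the input grid", {
  g <- tiny_grid(c(10, 10, 10))
  m <- build_model(small_cnn_config(3, 2), seed = 10)
  inp <- rand_input(g, 3, seed = 11)
  sal <- guided_backprop(m, inp, target_class = 2)
  expect_length(sal, 3)
  for (ch in 1:3) {
    expect_identical(sal[[ch]]$channel_index, ch)
    expect_identical(dim(sal[[ch]]$values), g$dims)
    expect_true(all(is.finite(sal[[ch]]$values)))
  }
  expect_error(guided_backprop(m, inp, target_class = 7), "invalid target")
})

test_that("smoothing and averaging commute in saliency aggregation", {
  g <- tiny_grid(c(12, 12, 12))
  mask <- compute_mask(unit_volume(g, seed = 12), 0.2)
  mk <- function(seed) {
    set.seed(seed)
    structure(list(grid = g, values = array(rnorm(prod(g$dims)), g$dims),
                   channel_index = 1L, subject_id = paste0("s", seed),
                   target_class = 1L), class = "nf_saliency")
  }
  maps <- lapply(1:4, mk)
  agg <- aggregate_saliency(maps, mask, fwhm = 6, signed = TRUE)
  # oracle: mean first, then one smoothing pass
  mean_map <- Reduce(`+`, lapply(maps, function(m) {
    v <- m$values; v[!mask$included] <- 0; v
  })) / 4
  sm <- gaussian_smooth(as_volume(mean_map, g), 6)
  expect_equal(agg$mean_map, sm$values, tolerance = 1e-9)
  # permutation invariance over subjects
  agg2 <- aggregate_saliency(maps[c(3, 1, 4, 2)], mask, fwhm = 6,
                             signed = TRUE)
  expect_equal(agg2$mean_map, agg$mean_map, tolerance = 1e-12)
  # a single map aggregates to its own smoothed self
  one <- aggregate_saliency(maps[1], mask, fwhm = 6, signed = TRUE)
  v1 <- maps[[1]]$values; v1[!mask$included] <- 0
  expect_equal(one$mean_map, gaussian_smooth(as_volume(v1, g), 6)$values,
               tolerance = 1e-12)
  # magnitude mode differs from signed mode for signed inputs
  mag <- aggregate_saliency(maps, mask, fwhm = 6, signed = FALSE)
  expect_gt(mean(mag$mean_map), mean(agg$mean_map))
})

test_that("mixed channels are refused in aggregation", {
  g <- tiny_grid(c(6, 6, 6))
  mask <- compute_mask(unit_volume(g, seed = 1), 0.2)
  a <- structure(list(grid = g, values = array(0, g$dims),
                      channel_index = 1L, subject_id = "a",
                      target_class = 1L), class = "nf_saliency")
  b <- a; b$channel_index <- 2L
  expect_error(aggregate_saliency(list(a, b), mask), "mix channel")
})

test_that("montage thresholding keeps about the top quantile of in-mask voxels", {
  g <- tiny_grid(c(12, 12, 12))
  mask <- compute_mask(unit_volume(g, seed = 14), 0.2)
  set.seed(15)
  summ <- structure(list(grid = g,
                         mean_map = array(runif(prod(g$dims)), g$dims),
                         n_subjects = 2, fwhm_used = 10, fwhm_units = "mm",
                         channel_index = 1L, signed = FALSE,
                         threshold_quantile = NA_real_),
                    class = "nf_saliency_summary")
  out <- withr::local_tempfile()
  vol <- render_montage(summ, mask, threshold_quantile = 0.99, out = out)
  expect_true(file.exists(paste0(out, ".png")))
  expect_true(file.exists(paste0(out, ".nii.gz")))
  n_in <- sum(mask$included)
  expect_lte(sum(vol$values[mask$included] > 0), ceiling(0.01 * n_in) + 1)

  # quantile 0 suppresses nothing inside the mask
  vol0 <- render_montage(summ, mask, threshold_quantile = 0, out = out)
  expect_identical(vol0$values[mask$included],
                   summ$mean_map[mask$included])

  # constant map: degenerate threshold still renders, with a warning
  summ$mean_map <- array(1, g$dims)
  expect_warning(render_montage(summ, mask, 0.9, out = out), "degenerate")
})
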