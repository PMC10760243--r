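#' Guided backpropagation saliency
#'
#' Computes the gradient of the target-class logit with respect to each input
#' channel of a trained classifier, with the guided-backpropagation rule at
#' every ReLU: the backward signal is zeroed wherever the forward activation
#' was non-positive or the incoming backward signal is negative.  One signed
#' saliency volume is returned per input channel.  When the network contains
#' no ReLU, guided backpropagation coincides with the plain input gradient.
#'
#' @param model an `nf_cnn` or `nf_cnn_fit` (evaluated in eval mode).
#' @param input one `nf_model_input` with the model's channel count.
#' @param target_class class index (1-based) or class label; defaults to the
#'   input's true label when available.
#' @param guided set `FALSE` for the plain input gradient.
#' @return A list of `nf_saliency` objects (grid, values, `channel_index`,
#'   `subject_id`, `target_class`), one per channel.
#' @export
guided_backprop <- function(model, input, target_class = NULL,
                            guided = TRUE) {
  model <- as_nf_cnn(model)
  stopifnot(inherits(input, "nf_model_input"))
  class_levels <- attr(model, "class_levels")
  if (is.null(target_class)) {
    if (is.na(input$label) || is.null(class_levels))
      stop("no target class: supply `target_class` or a labelled input on a trained model",
           call. = FALSE)
    target_class <- match(input$label, class_levels)
  } else if (is.character(target_class)) {
    if (is.null(class_levels))
      stop("model has no class levels; use a numeric class index",
           call. = FALSE)
    target_class <- match(target_class, class_levels)
  }
  target_class <- as.integer(target_class)
  if (is.na(target_class) || target_class < 1L ||
      target_class > model$config$n_classes)
    stop("invalid target class index", call. = FALSE)
  rep <- batch_to_rep(list(input), model$config$n_channels)
  fw <- net_forward(model$layers, rep, training = FALSE)
  grad_out <- matrix(0, 1L, ncol(fw$out))
  grad_out[1L, target_class] <- 1
  bw <- net_backward(model$layers, fw$caches, grad_out, guided = guided)
  g <- bw$grad_input   # nvox x n_channels
  lapply(seq_len(model$config$n_channels), function(ch) {
    structure(list(grid = input$grid,
                   values = array(g[, ch], dim = input$grid$dims),
                   channel_index = ch,
                   subject_id = input$subject_id,
                   target_class = target_class),
              class = "nf_saliency")
  })
}

#' @export
print.nf_saliency <- function(x, ...) {
  cat(sprintf("<nf_saliency> channel %d, subject %s, target class %d\n",
              x$channel_index, as.character(x$subject_id), x$target_class))
  invisible(x)
}

#' Cohort-level saliency summary
#'
#' Masks each subject's saliency map, smooths it with a Gaussian kernel
#' (default FWHM 10, interpreted in mm on the grid), and averages voxel-wise
#' across subjects.  By default the absolute value is taken before smoothing
#' (`signed = FALSE`) so that positive and negative attributions do not
#' cancel in the average; set `signed = TRUE` to average the raw signed maps.
#' Because both operations are linear, smoothing and averaging commute.
#'
#' @param maps list of `nf_saliency` objects for one channel, sharing a grid.
#' @param mask an `nf_mask` applied before smoothing.
#' @param fwhm smoothing kernel FWHM (default 10).
#' @param units `"mm"` or `"voxels"`.
#' @param signed average signed values instead of magnitudes.
#' @return An object of class `nf_saliency_summary` with the mean map,
#'   `n_subjects`, `fwhm_used` and `channel_index`.
#' @export
aggregate_saliency <- function(maps, mask, fwhm = 10, units = c("mm", "voxels"),
                               signed = FALSE) {
  units <- match.arg(units)
  stopifnot(is.list(maps), length(maps) >= 1L, inherits(mask, "nf_mask"))
  ch <- unique(vapply(maps, `[[`, 0L, "channel_index"))
  if (length(ch) != 1L)
    stop("maps mix channel indices; aggregate one channel at a time",
         call. = FALSE)
  grid <- maps[[1L]]$grid
  acc <- array(0, dim = grid$dims)
  for (m in maps) {
    stopifnot(inherits(m, "nf_saliency"))
    if (!grid_equal(grid, m$grid)) stop("grid mismatch", call. = FALSE)
    v <- if (signed) m$values else abs(m$values)
    v[!mask$included] <- 0
    sm <- gaussian_smooth(as_volume(v, grid), fwhm, units = units)
    acc <- acc + sm$values
  }
  structure(list(grid = grid, mean_map = acc / length(maps),
                 n_subjects = length(maps), fwhm_used = fwhm,
                 fwhm_units = units, channel_index = ch,
                 signed = signed, threshold_quantile = NA_real_),
            class = "nf_saliency_summary")
}

#' @export
print.nf_saliency_summary <- function(x, ...) {
  cat(sprintf(
    "<nf_saliency_summary> channel %d: mean of %d subject map(s), FWHM %g %s\n",
    x$channel_index, x$n_subjects, x$fwhm_used, x$fwhm_units))
  invisible(x)
}

#' Thresholded slice montage of a saliency summary
#'
#' Suppresses voxels below the given in-mask quantile and writes a PNG slice
#' montage plus the thresholded map as NIfTI.
#'
#' @param summary an [aggregate_saliency()] result.
#' @param mask the `nf_mask` defining in-mask voxels for the quantile.
#' @param threshold_quantile quantile in `[0, 1)`; 0 suppresses nothing,
#'   default 0.9.
#' @param slice_axis 1 (sagittal), 2 (coronal) or 3 (axial).
#' @param out output path prefix; writes `<out>.png` and `<out>.nii.gz`.
#' @param n_slices number of evenly spaced slices in the montage.
#' @return invisibly, the thresholded `nf_volume`.
#' @export
render_montage <- function(summary, mask, threshold_quantile = 0.9,
                           slice_axis = 3L, out, n_slices = 9L) {
  stopifnot(inherits(summary, "nf_saliency_summary"),
            inherits(mask, "nf_mask"),
            threshold_quantile >= 0, threshold_quantile < 1,
            slice_axis %in% 1:3)
  vals <- summary$mean_map
  inm <- vals[mask$included]
  if (length(inm) == 0L) stop("empty in-mask values", call. = FALSE)
  thr <- stats::quantile(inm, threshold_quantile, names = FALSE)
  if (min(inm) == max(inm))
    warning("constant saliency map: threshold is degenerate", call. = FALSE)
  keep <- vals > thr | (threshold_quantile == 0 & vals >= thr)
  thv <- vals
  thv[!(keep & mask$included)] <- 0
  vol <- as_volume(thv, summary$grid,
                   provenance = sprintf("saliency channel %d, q=%g",
                                        summary$channel_index,
                                        threshold_quantile))
  write_volume(vol, paste0(out, ".nii.gz"))
  d <- summary$grid$dims[slice_axis]
  slices <- unique(round(seq(1, d, length.out = min(n_slices, d))))
  nc <- ceiling(sqrt(length(slices)))
  nr <- ceiling(length(slices) / nc)
  grDevices::png(paste0(out, ".png"), width = 220 * nc, height = 220 * nr)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(1, 1, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  zmax <- max(abs(thv))
  if (zmax == 0) zmax <- 1
  for (s in slices) {
    sl <- switch(slice_axis,
                 `1` = thv[s, , ],
                 `2` = thv[, s, ],
                 `3` = thv[, , s])
    graphics::image(sl, zlim = c(-zmax, zmax), axes = FALSE,
                    col = grDevices::hcl.colors(64, "Inferno"),
                    main = sprintf("slice %d", s))
  }
  invisible(vol)
}
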