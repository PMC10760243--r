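#' Multi-channel model input for one subject
#'
#' Internal constructor validating the channel contract: every channel lies in
#' `[0, 1]`, all channels share one grid, and out-of-mask voxels are zero.
#'
#' @param channels list of `nf_volume` objects.
#' @param subject_id identifier.
#' @param label diagnostic label (`"AD"`, `"MCI"`, `"CN"`) or `NA`.
#' @param experiment which construction produced the channels.
#' @return An object of class `nf_model_input`.
#' @keywords internal
model_input <- function(channels, subject_id = NA_character_,
                        label = NA_character_,
                        experiment = c("unimodal", "two_channel", "fused")) {
  experiment <- match.arg(experiment)
  stopifnot(is.list(channels), length(channels) >= 1L)
  for (ch in channels) {
    stopifnot(inherits(ch, "nf_volume"))
    check_same_grid(channels[[1L]], ch, "channels")
    if (min(ch$values) < 0 || max(ch$values) > 1)
      stop("channel values must lie in [0, 1]", call. = FALSE)
  }
  n_expected <- c(unimodal = 1L, two_channel = 2L, fused = 3L)[[experiment]]
  if (length(channels) != n_expected)
    stop(sprintf("%s inputs need %d channels, got %d",
                 experiment, n_expected, length(channels)), call. = FALSE)
  structure(list(subject_id = subject_id, label = label,
                 experiment = experiment, channels = channels,
                 grid = channels[[1L]]$grid),
            class = "nf_model_input")
}

#' @export
print.nf_model_input <- function(x, ...) {
  cat(sprintf("<nf_model_input> %s: %d channel(s), label %s\n",
              x$experiment, length(x$channels), x$label))
  invisible(x)
}

mask_volume <- function(vol, mask) {
  out <- vol$values
  out[!mask$included] <- 0
  as_volume(out, vol$grid, feature_kind = vol$feature_kind,
            provenance = vol$provenance)
}

#' Single-channel model input (Experiment 1)
#'
#' One modality at a time (gray matter, an iVIP projection, ALFF or fALFF):
#' the volume is masked with the subject's gray-matter mask and min-max
#' normalized to `[0, 1]`.
#'
#' @param vol an `nf_volume` feature map.
#' @param mask the subject's `nf_mask` (from [compute_mask()] on the
#'   subject's own sMRI).
#' @param subject_id,label carried through to the result.
#' @return An `nf_model_input` with one channel.
#' @export
build_unimodal <- function(vol, mask, subject_id = NA_character_,
                           label = NA_character_) {
  check_same_grid(vol, mask, "volume and mask")
  model_input(list(minmax_normalize(vol, mask)), subject_id, label,
              "unimodal")
}

#' Two-channel model input (Experiment 2)
#'
#' Channel 1 is the masked, normalized gray matter; channel 2 the masked,
#' normalized iVIP projection.  Channel order is semantic and fixed
#' (sMRI first).
#'
#' @param smri the subject's gray-matter `nf_volume`.
#' @param ivip the subject's iVIP `nf_volume`.
#' @inheritParams build_unimodal
#' @return An `nf_model_input` with two channels.
#' @export
build_two_channel <- function(smri, ivip, mask, subject_id = NA_character_,
                              label = NA_character_) {
  check_same_grid(smri, ivip, "sMRI and iVIP")
  check_same_grid(smri, mask, "volumes and mask")
  model_input(list(minmax_normalize(smri, mask),
                   minmax_normalize(ivip, mask)),
              subject_id, label, "two_channel")
}

#' Fused three-channel model input (Experiment 3)
#'
#' With `s` and `v` the masked, min-max normalized gray matter and iVIP, the
#' channels are the voxel-wise products `[s*s, s*v, v*v]`, each re-normalized
#' by min-max after the product; normalizing after each modality and again
#' after each product keeps the two modalities on an equal footing in the
#' fused channels.
#'
#' @inheritParams build_two_channel
#' @return An `nf_model_input` with three channels
#'   (`feature_kind = "fused_channel"`).
#' @export
build_fused <- function(smri, ivip, mask, subject_id = NA_character_,
                        label = NA_character_) {
  check_same_grid(smri, ivip, "sMRI and iVIP")
  check_same_grid(smri, mask, "volumes and mask")
  s <- minmax_normalize(smri, mask)
  v <- minmax_normalize(ivip, mask)
  prod_channel <- function(a, b, tag) {
    p <- as_volume(a$values * b$values, a$grid, feature_kind = "fused_channel",
                   provenance = tag)
    minmax_normalize(p, mask)
  }
  model_input(list(prod_channel(s, s, "smri*smri"),
                   prod_channel(s, v, "smri*ivip"),
                   prod_channel(v, v, "ivip*ivip")),
              subject_id, label, "fused")
}
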