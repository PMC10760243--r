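#' Spatial grid shared by all volumes of a subject
#'
#' A `volume_grid` records the voxel dimensions, voxel size and the affine
#' mapping voxel indices to world coordinates (mm).  Every per-subject volume
#' (gray matter, component maps, projections, channels, saliency) must live on
#' one shared grid; no resampling is performed anywhere in the package, inputs
#' are assumed pre-aligned.
#'
#' @param dims integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size_mm numeric vector of length 3, voxel edge length in mm
#'   (all > 0). Default 3 mm isotropic, the working resolution of the
#'   projection pipeline (full-size maps are 53 x 63 x 52 at 3 mm).
#' @param affine 4x4 matrix mapping 0-based voxel indices to world mm.
#'   Defaults to a diagonal scaling by `voxel_size_mm`.
#' @return An object of class `nf_grid`.
#' @examples
#' volume_grid(c(24, 24, 24))
#' @export
volume_grid <- function(dims, voxel_size_mm = c(3, 3, 3), affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("`dims` must be three integers >= 1", call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be three positive reals", call. = FALSE)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  affine <- matrix(as.numeric(affine), 4L, 4L)
  if (any(!is.finite(affine)) || abs(det(affine)) < .Machine$double.eps)
    stop("`affine` must be a finite, invertible 4x4 matrix", call. = FALSE)
  structure(list(dims = dims, voxel_size_mm = voxel_size_mm, affine = affine),
            class = "nf_grid")
}

#' @export
print.nf_grid <- function(x, ...) {
  cat(sprintf("<nf_grid> %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  invisible(x)
}

#' Compare two grids for equality
#'
#' Dimensions must match exactly; voxel sizes and affine entries within `tol`
#' (mm).
#'
#' @param a,b `nf_grid` objects.
#' @param tol numeric tolerance for voxel sizes and affine entries.
#' @return logical scalar.
#' @export
grid_equal <- function(a, b, tol = 1e-4) {
  stopifnot(inherits(a, "nf_grid"), inherits(b, "nf_grid"))
  identical(a$dims, b$dims) &&
    all(abs(a$voxel_size_mm - b$voxel_size_mm) <= tol) &&
    all(abs(a$affine - b$affine) <= tol)
}

check_same_grid <- function(a, b, what = "inputs") {
  if (!grid_equal(a$grid, b$grid))
    stop(sprintf("grid mismatch: %s must share one volume_grid", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Construct a 3D volume on a grid
#'
#' @param values numeric array whose dimensions equal `grid$dims`.
#' @param grid an [volume_grid()].
#' @param feature_kind optional character tag recording what the values are
#'   (`"smri"`, `"max_icn"`, `"abs_min_icn"`, `"max_abs_icn"`, `"alff"`,
#'   `"falff"`, `"fused_channel"`).
#' @param provenance free-text note on how the volume was produced.
#' @return An object of class `nf_volume`.
#' @export
as_volume <- function(values, grid, feature_kind = NULL, provenance = "") {
  stopifnot(inherits(grid, "nf_grid"))
  values <- as.array(values)
  if (length(dim(values)) != 3L || !all(dim(values) == grid$dims))
    stop("`values` must be a 3D array matching grid dims", call. = FALSE)
  nbad <- sum(!is.finite(values))
  if (nbad > 0L)
    stop(sprintf("volume contains %d non-finite voxels", nbad), call. = FALSE)
  storage.mode(values) <- "double"
  if (!is.null(feature_kind)) {
    feature_kind <- match.arg(feature_kind, c(
      "smri", "max_icn", "abs_min_icn", "max_abs_icn",
      "alff", "falff", "fused_channel"))
  }
  structure(list(grid = grid, values = values, feature_kind = feature_kind,
                 provenance = provenance),
            class = "nf_volume")
}

#' @export
print.nf_volume <- function(x, ...) {
  kind <- if (is.null(x$feature_kind)) "volume" else x$feature_kind
  cat(sprintf("<nf_volume> %s, %d x %d x %d, range [%.4g, %.4g]\n",
              kind, x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.array.nf_volume <- function(x, ...) x$values

grid_from_nifti <- function(img) {
  d <- dim(img)[1:3]
  pd <- RNifti::pixdim(img)[1:3]
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  volume_grid(d, abs(pd), aff)
}

#' Read a NIfTI volume or component stack
#'
#' 3D files are returned as an [as_volume()] object, 4D files as a
#' [component_stack()] whose frames share one grid.  Voxels are converted to
#' double; images with non-finite voxels or dimensionality other than 3/4 are
#' rejected.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return `nf_volume` (3D input) or `nf_stack` (4D input).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  vals <- as.array(img)
  attributes(vals) <- list(dim = dim(img))
  storage.mode(vals) <- "double"
  if (nd != 3L && nd != 4L)
    stop(sprintf("'%s' is %dD; only 3D volumes and 4D stacks are supported",
                 path, nd), call. = FALSE)
  nbad <- sum(!is.finite(vals))
  if (nbad > 0L)
    stop(sprintf("'%s' contains %d non-finite voxels", path, nbad),
         call. = FALSE)
  grid <- grid_from_nifti(img)
  if (nd == 3L) {
    as_volume(vals, grid, provenance = path)
  } else {
    component_stack(vals, grid)
  }
}

nifti_with_grid <- function(values, grid) {
  img <- RNifti::asNifti(values)
  nd <- length(dim(values))
  pd <- grid$voxel_size_mm
  if (nd == 4L) pd <- c(pd, 1)
  RNifti::pixdim(img) <- pd
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  img
}

#' Write a volume, stack, or mask as NIfTI
#'
#' Volumes and stacks are written as float64; masks as uint8.
#'
#' @param x an `nf_volume`, `nf_stack`, or `nf_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  datatype <- "auto"
  if (inherits(x, "nf_volume") || inherits(x, "nf_stack")) {
    img <- nifti_with_grid(x$values, x$grid)
  } else if (inherits(x, "nf_mask")) {
    vals <- array(as.integer(x$included), dim = x$grid$dims)
    img <- nifti_with_grid(vals, x$grid)
    datatype <- "uint8"
  } else {
    stop("`x` must be an nf_volume, nf_stack or nf_mask", call. = FALSE)
  }
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Brain mask from a gray-matter volume
#'
#' A voxel is included iff its gray-matter density is strictly greater than
#' `threshold` (default 0.03).  One mask is computed per subject from that
#' subject's own sMRI and then applied to all of the subject's channels.
#'
#' @param smri an `nf_volume` of gray-matter density.
#' @param threshold numeric scalar; voxels with value `> threshold` are kept.
#' @return An object of class `nf_mask` with fields `grid`, `included`
#'   (logical array) and `source_threshold`.
#' @export
compute_mask <- function(smri, threshold = 0.03) {
  stopifnot(inherits(smri, "nf_volume"), is.numeric(threshold),
            length(threshold) == 1L, is.finite(threshold))
  inc <- smri$values > threshold
  if (!any(inc))
    stop(sprintf("empty mask: no voxel exceeds threshold %g", threshold),
         call. = FALSE)
  structure(list(grid = smri$grid, included = inc,
                 source_threshold = threshold),
            class = "nf_mask")
}

#' @export
print.nf_mask <- function(x, ...) {
  cat(sprintf("<nf_mask> %d / %d voxels included (threshold > %g)\n",
              sum(x$included), length(x$included), x$source_threshold))
  invisible(x)
}

#' Min-max normalization within a mask
#'
#' Rescales in-mask voxels to `[0, 1]` as `(x - min) / (max - min)`, using the
#' in-mask minimum and maximum; out-of-mask voxels are set to 0.  A constant
#' in-mask volume (zero range) yields all zeros with a warning, so batch
#' pipelines keep running on degenerate inputs.
#'
#' @param vol an `nf_volume`.
#' @param mask an `nf_mask` on the same grid.
#' @return A normalized `nf_volume` (same `feature_kind`).
#' @export
minmax_normalize <- function(vol, mask) {
  stopifnot(inherits(vol, "nf_volume"), inherits(mask, "nf_mask"))
  check_same_grid(vol, mask, "volume and mask")
  out <- array(0, dim = vol$grid$dims)
  v <- vol$values[mask$included]
  rng <- range(v)
  if (rng[2] > rng[1]) {
    out[mask$included] <- (v - rng[1]) / (rng[2] - rng[1])
  } else {
    warning("constant in-mask volume: min-max range is zero, emitting zeros",
            call. = FALSE)
  }
  as_volume(out, vol$grid, feature_kind = vol$feature_kind,
            provenance = paste0(vol$provenance, " | minmax"))
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

## dense 1D Gaussian convolution operator with zero ("constant") boundary,
## kernel truncated at ceiling(4*sigma) and renormalized to sum 1
gaussian_conv_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- ceiling(4 * sigma)
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  M <- matrix(0, n, n)
  for (off in (-r):r) {
    idx <- seq_len(n)
    src <- idx + off
    ok <- src >= 1L & src <= n
    M[cbind(idx[ok], src[ok])] <- M[cbind(idx[ok], src[ok])] + k[off + r + 1L]
  }
  M
}

smooth_array_gaussian <- function(x, sigma_vox) {
  ## separable pass; aperm cycles the target axis to the front, so after
  ## three rounds the array is back in its original orientation
  for (ax in 1:3) {
    d <- dim(x)
    if (sigma_vox[ax] > 0) {
      M <- gaussian_conv_matrix(d[1], sigma_vox[ax])
      x <- array(M %*% matrix(x, d[1], d[2] * d[3]), dim = d)
    }
    x <- aperm(x, c(2, 3, 1))
  }
  x
}

#' Separable Gaussian smoothing of a volume
#'
#' Convolves each axis with a discrete Gaussian kernel of standard deviation
#' `sigma = fwhm / (2 * sqrt(2 * log(2)))`, truncated at four standard
#' deviations and renormalized to unit sum.  Boundaries are zero-padded
#' ("constant"), which is appropriate for masked volumes that are already zero
#' outside the brain.  `fwhm = 0` is the identity.
#'
#' @param vol an `nf_volume`.
#' @param fwhm full width at half maximum of the kernel, `>= 0`.
#' @param units `"mm"` (converted per axis through the grid voxel size) or
#'   `"voxels"`.
#' @return A smoothed `nf_volume`.
#' @export
gaussian_smooth <- function(vol, fwhm, units = c("mm", "voxels")) {
  stopifnot(inherits(vol, "nf_volume"), is.numeric(fwhm), length(fwhm) == 1L,
            is.finite(fwhm))
  if (fwhm < 0) stop("`fwhm` must be >= 0", call. = FALSE)
  units <- match.arg(units)
  sigma <- fwhm_to_sigma(fwhm)
  sigma_vox <- if (units == "mm") sigma / vol$grid$voxel_size_mm else
    rep(sigma, 3L)
  if (fwhm == 0) return(vol)
  out <- smooth_array_gaussian(vol$values, sigma_vox)
  as_volume(out, vol$grid, feature_kind = vol$feature_kind,
            provenance = paste0(vol$provenance,
                                sprintf(" | smooth fwhm=%g %s", fwhm, units)))
}
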