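#' Stack of component spatial maps for one subject
#'
#' Holds the K aligned intrinsic connectivity network (ICN) spatial maps of a
#' subject as a 4D array on a shared grid.  The full-size pipeline uses K = 53
#' components; any K >= 1 is accepted.
#'
#' @param values a 4D numeric array (x, y, z, K), or a list of K `nf_volume`
#'   objects sharing one grid.
#' @param grid the shared [volume_grid()]; taken from the first map when
#'   `values` is a list of volumes.
#' @return An object of class `nf_stack` with fields `grid`, `values`
#'   (4D array) and `K`.
#' @export
component_stack <- function(values, grid = NULL) {
  if (is.list(values) && all(vapply(values, inherits, TRUE, "nf_volume"))) {
    if (length(values) < 1L) stop("empty component stack", call. = FALSE)
    grid <- values[[1L]]$grid
    for (v in values) check_same_grid(values[[1L]], v, "component maps")
    values <- array(unlist(lapply(values, `[[`, "values")),
                    dim = c(grid$dims, length(values)))
  }
  stopifnot(inherits(grid, "nf_grid"))
  values <- as.array(values)
  if (length(dim(values)) != 4L || !all(dim(values)[1:3] == grid$dims))
    stop("`values` must be a 4D array matching grid dims", call. = FALSE)
  K <- dim(values)[4L]
  if (K < 1L) stop("empty component stack", call. = FALSE)
  nbad <- sum(!is.finite(values))
  if (nbad > 0L)
    stop(sprintf("component stack contains %d non-finite voxels", nbad),
         call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values, K = K), class = "nf_stack")
}

#' @export
print.nf_stack <- function(x, ...) {
  cat(sprintf("<nf_stack> K = %d component maps on %d x %d x %d\n",
              x$K, x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]))
  invisible(x)
}

## voxels-by-components matrix view of a stack
stack_matrix <- function(stack) {
  matrix(stack$values, nrow = prod(stack$grid$dims), ncol = stack$K)
}

## row-wise max and argmax (first index wins ties) of a V x K matrix
rowmax_with_arg <- function(m) {
  j <- max.col(m, ties.method = "first")
  list(values = m[cbind(seq_len(nrow(m)), j)], arg = j)
}

#' Voxel-wise intensity projections of a component stack
#'
#' The three projections summarise the K component maps into one volume per
#' subject: per voxel, `project_max` takes the maximum component value
#' (the most activating network), `project_abs_min` the absolute value of the
#' minimum (the most "absent" network), and `project_max_abs` the maximum
#' absolute value (the most extreme network regardless of sign).  Projections
#' operate on raw component values; masking and min-max normalization are
#' applied downstream.
#'
#' @param stack an [component_stack()].
#' @param return_argmax if `TRUE`, attach an `argmax` attribute (integer array
#'   of the winning component index, ties broken by the lowest index) for
#'   diagnostics.
#' @return A `FeatureVolume`-tagged `nf_volume` (`feature_kind` one of
#'   `"max_icn"`, `"abs_min_icn"`, `"max_abs_icn"`).
#' @examples
#' g <- volume_grid(c(4, 4, 4), 3)
#' st <- component_stack(array(rnorm(4^3 * 5), c(4, 4, 4, 5)), g)
#' pm <- project_max(st)
#' @export
project_max <- function(stack, return_argmax = FALSE) {
  stopifnot(inherits(stack, "nf_stack"))
  r <- rowmax_with_arg(stack_matrix(stack))
  out <- as_volume(array(r$values, dim = stack$grid$dims), stack$grid,
                   feature_kind = "max_icn",
                   provenance = sprintf("max over %d components", stack$K))
  if (return_argmax)
    attr(out, "argmax") <- array(r$arg, dim = stack$grid$dims)
  out
}

#' @rdname project_max
#' @export
project_abs_min <- function(stack, return_argmax = FALSE) {
  stopifnot(inherits(stack, "nf_stack"))
  r <- rowmax_with_arg(-stack_matrix(stack))   # max of negated = |min| if min < 0
  out <- as_volume(array(abs(-r$values), dim = stack$grid$dims), stack$grid,
                   feature_kind = "abs_min_icn",
                   provenance = sprintf("|min| over %d components", stack$K))
  if (return_argmax)
    attr(out, "argmax") <- array(r$arg, dim = stack$grid$dims)
  out
}

#' @rdname project_max
#' @export
project_max_abs <- function(stack, return_argmax = FALSE) {
  stopifnot(inherits(stack, "nf_stack"))
  r <- rowmax_with_arg(abs(stack_matrix(stack)))
  out <- as_volume(array(r$values, dim = stack$grid$dims), stack$grid,
                   feature_kind = "max_abs_icn",
                   provenance = sprintf("max|.| over %d components", stack$K))
  if (return_argmax)
    attr(out, "argmax") <- array(r$arg, dim = stack$grid$dims)
  out
}

#' Dispatch a projection by name
#'
#' @param stack an [component_stack()].
#' @param kind one of `"max_icn"`, `"abs_min_icn"`, `"max_abs_icn"`.
#' @param ... passed to the projection function.
#' @return the projected `nf_volume`.
#' @export
project_ivip <- function(stack, kind = c("max_icn", "abs_min_icn",
                                         "max_abs_icn"), ...) {
  kind <- match.arg(kind)
  switch(kind,
         max_icn = project_max(stack, ...),
         abs_min_icn = project_abs_min(stack, ...),
         max_abs_icn = project_max_abs(stack, ...))
}
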