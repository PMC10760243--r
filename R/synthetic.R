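#' Reference class composition of the emulated cohort
#'
#' The synthetic generator emulates a first-visit ADNI-style sample with 83
#' Alzheimer's disease, 264 mild cognitive impairment, and 383 cognitively
#' normal subjects; the two-way task uses the 466 AD + CN subjects, the
#' three-way task all 730.
#'
#' @return named integer vector with elements `AD`, `MCI`, `CN`.
#' @export
reference_class_counts <- function() {
  c(AD = 83L, MCI = 264L, CN = 383L)
}

#' Specification of a synthetic cohort
#'
#' The generator draws aligned gray-matter volumes and component-map stacks
#' with controllable class effects on a shared grid.  Gray matter is a fixed
#' template of smooth positive blobs inside a brain envelope; two designated
#' "atrophy" blobs are scaled by `1 - gm_effect` for AD subjects and
#' `1 - gm_effect / 2` for MCI (they play the role of hippocampus/amygdala,
#' with no anatomical claim).  Each component map has a positive and a
#' negative Gaussian lobe; in the two designated components (one positive
#' lobe, one negative lobe, both co-located with the atrophy blobs) the lobe
#' amplitude is reduced by `icn_effect / 2` for AD and `icn_effect / 4` for
#' MCI, so that both the max- and the |min|-projection carry class signal.
#' Voxel-independent Gaussian noise of standard deviation `noise_sd` is
#' added inside the brain envelope.
#'
#' @param n_per_class named counts for `AD`, `MCI`, `CN` (total >= 2).
#' @param grid_dims voxel dimensions (default 24^3 for desk-scale runs;
#'   53 x 63 x 52 for full-size runs).
#' @param voxel_size_mm voxel size (default 3 mm isotropic).
#' @param k_components number of component maps K (default 8; 53 supported).
#' @param gm_effect fractional gray-matter reduction in the designated blobs
#'   for AD (half for MCI), `>= 0`.
#' @param icn_effect amplitude shift of the designated components, `>= 0`.
#' @param noise_sd voxel noise standard deviation, `> 0`.
#' @param seed integer cohort seed; per-subject sub-seeds are drawn from it.
#' @return An object of class `nf_cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(AD = 10L, MCI = 0L, CN = 10L),
                        grid_dims = c(24L, 24L, 24L), voxel_size_mm = 3,
                        k_components = 8L, gm_effect = 0.4,
                        icn_effect = 1.0, noise_sd = 0.05, seed = 1L) {
  n_per_class <- n_per_class[c("AD", "MCI", "CN")]
  names(n_per_class) <- c("AD", "MCI", "CN")
  n_per_class[is.na(n_per_class)] <- 0L
  n_per_class <- as.integer(n_per_class)
  names(n_per_class) <- c("AD", "MCI", "CN")
  stopifnot(all(n_per_class >= 0L), sum(n_per_class) >= 2L,
            k_components >= 2L, gm_effect >= 0, icn_effect >= 0,
            is.finite(gm_effect), is.finite(icn_effect), noise_sd > 0)
  if (any(grid_dims < 8L))
    stop("grid too small for blob templates: need >= 8 voxels per axis",
         call. = FALSE)
  structure(list(n_per_class = n_per_class,
                 grid = volume_grid(grid_dims, voxel_size_mm),
                 k_components = as.integer(k_components),
                 gm_effect = gm_effect, icn_effect = icn_effect,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "nf_cohort_spec")
}

## fractional-coordinate Gaussian blob evaluated on the grid
blob_on_grid <- function(dims, center_frac, sigma_frac, amplitude = 1) {
  ax <- lapply(1:3, function(a) {
    fr <- (seq_len(dims[a]) - 0.5) / dims[a]
    (fr - center_frac[a])^2 / (2 * (sigma_frac[a])^2)
  })
  ex <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  amplitude * exp(-ex)
}

## smooth brain envelope in [0, 1]
brain_envelope <- function(dims) {
  ax <- lapply(1:3, function(a) {
    fr <- (seq_len(dims[a]) - 0.5) / dims[a]
    ((fr - 0.5) / 0.34)^2
  })
  r2 <- outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
  pmax(1 - r2, 0)
}

## fixed template geometry: everything in fractional coordinates so any
## grid >= 8 voxels per axis works
nf_templates <- function(k_components) {
  atrophy <- list(
    list(center = c(0.35, 0.35, 0.42), sigma = 0.085, amp = 0.7),
    list(center = c(0.65, 0.35, 0.42), sigma = 0.085, amp = 0.7))
  background <- list(
    list(center = c(0.38, 0.60, 0.55), sigma = 0.11, amp = 0.5),
    list(center = c(0.62, 0.60, 0.55), sigma = 0.11, amp = 0.5),
    list(center = c(0.50, 0.45, 0.62), sigma = 0.13, amp = 0.45),
    list(center = c(0.50, 0.68, 0.38), sigma = 0.10, amp = 0.4))
  ## component lobe positions: deterministic draws, independent of cohort seed
  comp <- lapply(seq_len(k_components), function(j) {
    old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
    set.seed(1000L + 17L * j)
    list(pos = stats::runif(3, 0.30, 0.70), neg = stats::runif(3, 0.30, 0.70))
  })
  ## designated components 1 and 2 have their signal lobe on the atrophy blobs
  comp[[1]]$pos <- atrophy[[1]]$center
  comp[[2]]$neg <- atrophy[[2]]$center
  list(atrophy = atrophy, background = background, components = comp,
       comp_sigma = 0.09, comp_amp = 0.8, base_gm = 0.3,
       designated = c(1L, 2L))
}

class_effect_fraction <- function(label) {
  switch(label, AD = 1, MCI = 0.5, CN = 0)
}

generate_subject <- function(spec, label, subject_id, sub_seed, templ,
                             envelope) {
  dims <- spec$grid$dims
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(sub_seed)
  f <- class_effect_fraction(label)
  gm_scale <- 1 - spec$gm_effect * f
  gm <- templ$base_gm * envelope
  for (b in templ$background)
    gm <- gm + blob_on_grid(dims, b$center, rep(b$sigma, 3), b$amp)
  for (b in templ$atrophy)
    gm <- gm + gm_scale * blob_on_grid(dims, b$center, rep(b$sigma, 3), b$amp)
  gm <- gm + spec$noise_sd * array(stats::rnorm(prod(dims)), dims) * envelope
  gm <- pmax(gm, 0)
  icn_amp <- templ$comp_amp - 0.5 * spec$icn_effect * f
  maps <- array(0, dim = c(dims, spec$k_components))
  for (j in seq_len(spec$k_components)) {
    apos <- if (j == templ$designated[1]) icn_amp else templ$comp_amp
    aneg <- if (j == templ$designated[2]) icn_amp else templ$comp_amp
    m <- blob_on_grid(dims, templ$components[[j]]$pos,
                      rep(templ$comp_sigma, 3), apos) -
      blob_on_grid(dims, templ$components[[j]]$neg,
                   rep(templ$comp_sigma, 3), aneg)
    m <- m + spec$noise_sd * array(stats::rnorm(prod(dims)), dims) * envelope
    maps[, , , j] <- m
  }
  ts_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  list(subject_id = subject_id, label = label,
       smri = as_volume(gm, spec$grid, feature_kind = "smri",
                        provenance = paste0("synthetic ", subject_id)),
       icn_stack = component_stack(maps, spec$grid),
       ts = NULL,
       ground_truth = list(label = label, gm_scale = gm_scale,
                           icn_amplitude = icn_amp,
                           designated_components = templ$designated,
                           atrophy_blobs = templ$atrophy,
                           sub_seed = sub_seed, ts_seed = ts_seed))
}

#' Generate an aligned synthetic cohort
#'
#' Draws `sum(n_per_class)` subjects with gray-matter volumes and component
#' stacks per [cohort_spec()]; deterministic given the spec seed (one cohort
#' seed fans out to per-subject sub-seeds).
#'
#' @param spec an [cohort_spec()].
#' @return An object of class `nf_cohort`: list of subjects plus a subject
#'   `table` data frame (`subject_id`, `label`).
#' @examples
#' co <- generate_cohort(cohort_spec(c(AD = 2, MCI = 0, CN = 2),
#'                                   grid_dims = c(12, 12, 12)))
#' co$table
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "nf_cohort_spec"))
  templ <- nf_templates(spec$k_components)
  envelope <- brain_envelope(spec$grid$dims)
  labels <- rep(names(spec$n_per_class), spec$n_per_class)
  n <- length(labels)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(spec$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  subjects <- vector("list", n)
  ids <- sprintf("%s%03d", labels,
                 as.integer(stats::ave(seq_len(n), labels, FUN = seq_along)))
  for (i in seq_len(n)) {
    subjects[[i]] <- generate_subject(spec, labels[i], ids[i], sub_seeds[i],
                                      templ, envelope)
  }
  names(subjects) <- ids
  structure(list(subjects = subjects,
                 table = data.frame(subject_id = ids, label = labels,
                                    stringsAsFactors = FALSE),
                 spec = spec, templates = templ),
            class = "nf_cohort")
}

#' @export
print.nf_cohort <- function(x, ...) {
  tb <- table(x$table$label)
  cat(sprintf("<nf_cohort> %d synthetic subjects (%s) on %d x %d x %d, K = %d\n",
              nrow(x$table),
              paste(sprintf("%s %d", names(tb), tb), collapse = ", "),
              x$spec$grid$dims[1], x$spec$grid$dims[2], x$spec$grid$dims[3],
              x$spec$k_components))
  invisible(x)
}

#' Synthetic BOLD-like time series for one subject
#'
#' Per voxel, an in-band sinusoid (frequency at the DFT bin nearest 0.05 Hz
#' inside 0.01-0.08 Hz) whose amplitude scales with the subject's
#' max-absolute component projection at that voxel, plus white noise;
#' reproducible from the subject's stored time-series seed.
#'
#' @param subject a subject from [generate_cohort()].
#' @param T number of time points (>= 32).
#' @param tr_seconds sampling interval in seconds.
#' @param amp_scale multiplier on the sinusoid amplitude.
#' @param noise_sd white-noise standard deviation (0 for a noise-free
#'   series).
#' @return A [time_series_volume()].
#' @export
generate_timeseries <- function(subject, T = 64L, tr_seconds = 2,
                                amp_scale = 1, noise_sd = 0.1) {
  T <- as.integer(T)
  if (T < 32L) stop("need T >= 32 time points", call. = FALSE)
  band <- frequency_band(0.01, 0.08)
  freqs <- (1:(T %/% 2)) / (T * tr_seconds)
  inband <- which(freqs >= band$lo_hz & freqs <= band$hi_hz)
  if (length(inband) == 0L)
    stop(sprintf("band %g-%g Hz infeasible for T = %d, TR = %g s",
                 band$lo_hz, band$hi_hz, T, tr_seconds), call. = FALSE)
  f0 <- freqs[inband[which.min(abs(freqs[inband] - 0.05))]]
  grid <- subject$smri$grid
  amp <- amp_scale * project_max_abs(subject$icn_stack)$values
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(subject$ground_truth$ts_seed)
  V <- prod(grid$dims)
  phase <- stats::runif(V, 0, 2 * pi)
  tsec <- (0:(T - 1L)) * tr_seconds
  S <- sin(outer(as.vector(phase), 2 * pi * f0 * tsec, "+")) *
    as.vector(amp)
  if (noise_sd > 0)
    S <- S + noise_sd * matrix(stats::rnorm(V * T), V, T)
  time_series_volume(array(S, dim = c(grid$dims, T)), grid, tr_seconds)
}

#' Write a cohort to NIfTI + CSV
#'
#' Writes one gray-matter volume and one 4D component stack per subject and a
#' `subject_table.csv` (columns `subject_id`, `label`, `smri_path`,
#' `icn_stack_path`, `ts_path`), the same layout the pipeline consumes.
#'
#' @param cohort an [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param timeseries if `TRUE`, also generate and write per-subject time
#'   series.
#' @param ... passed to [generate_timeseries()].
#' @return path of the subject table, invisibly.
#' @export
write_cohort <- function(cohort, dir, timeseries = FALSE, ...) {
  stopifnot(inherits(cohort, "nf_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- cohort$table
  tab$smri_path <- file.path(dir, paste0("smri_", tab$subject_id, ".nii.gz"))
  tab$icn_stack_path <- file.path(dir, paste0("icn_", tab$subject_id,
                                              ".nii.gz"))
  tab$ts_path <- NA_character_
  for (i in seq_len(nrow(tab))) {
    s <- cohort$subjects[[tab$subject_id[i]]]
    write_volume(s$smri, tab$smri_path[i])
    write_volume(s$icn_stack, tab$icn_stack_path[i])
    if (timeseries) {
      ts <- generate_timeseries(s, ...)
      tab$ts_path[i] <- file.path(dir, paste0("ts_", tab$subject_id,
                                              ".nii.gz"))
      write_volume(as_volume_ts(ts), tab$ts_path[i])
    }
  }
  out <- file.path(dir, "subject_table.csv")
  utils::write.csv(tab, out, row.names = FALSE)
  invisible(out)
}

as_volume_ts <- function(ts) {
  structure(list(grid = ts$grid, values = ts$values), class = "nf_stack")
}

#' Load and validate a subject table
#'
#' Reads a CSV with columns `subject_id` and `label` (and optionally
#' `smri_path`, `icn_stack_path`, `ts_path`), checks labels against
#' `{AD, MCI, CN}`, and attaches per-class counts and their total.
#'
#' @param path CSV path.
#' @return data frame with attributes `class_counts` (named table) and
#'   `n_total`.
#' @export
load_subject_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "label")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L)
    stop("subject table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(tab$label), c("AD", "MCI", "CN"))
  if (length(bad) > 0L)
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(tab$subject_id))
    stop("duplicated subject ids", call. = FALSE)
  counts <- table(tab$label)
  attr(tab, "class_counts") <- counts
  attr(tab, "n_total") <- sum(counts)
  tab
}
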