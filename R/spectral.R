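#' 4D time-series volume
#'
#' @param values 4D numeric array (x, y, z, T) of a voxel-wise BOLD series.
#' @param grid the spatial [volume_grid()].
#' @param tr_seconds sampling interval (repetition time) in seconds, > 0.
#' @return An object of class `nf_timeseries`.
#' @export
time_series_volume <- function(values, grid, tr_seconds) {
  stopifnot(inherits(grid, "nf_grid"))
  values <- as.array(values)
  if (length(dim(values)) != 4L || !all(dim(values)[1:3] == grid$dims))
    stop("`values` must be 4D (x, y, z, time) matching grid dims",
         call. = FALSE)
  T <- dim(values)[4L]
  if (T < 8L) stop("time series needs at least 8 time points", call. = FALSE)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L ||
      !is.finite(tr_seconds) || tr_seconds <= 0)
    stop("`tr_seconds` must be a positive real", call. = FALSE)
  if (any(!is.finite(values)))
    stop("time series contains non-finite values", call. = FALSE)
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values, T = T,
                 tr_seconds = tr_seconds),
            class = "nf_timeseries")
}

#' Frequency band for spectral features
#'
#' @param lo_hz,hi_hz band edges in Hz with `0 <= lo_hz < hi_hz`.  The default
#'   0.01-0.08 Hz is the standard low-frequency band of the ALFF literature.
#' @return An object of class `nf_band`.
#' @export
frequency_band <- function(lo_hz = 0.01, hi_hz = 0.08) {
  stopifnot(is.numeric(lo_hz), is.numeric(hi_hz))
  if (!(lo_hz >= 0 && lo_hz < hi_hz))
    stop("need 0 <= lo_hz < hi_hz", call. = FALSE)
  structure(list(lo_hz = lo_hz, hi_hz = hi_hz), class = "nf_band")
}

## per-voxel amplitude spectrum of the linearly detrended series:
## columns = voxels, rows = positive-frequency DFT bins (DC excluded),
## amplitude scaled 2/T so an on-bin unit sinusoid has amplitude ~1
detrended_amplitude <- function(ts) {
  T <- ts$T
  V <- prod(ts$grid$dims)
  X <- t(matrix(ts$values, nrow = V, ncol = T))      # T x V
  des <- cbind(1, seq_len(T))
  X <- stats::lm.fit(des, X)$residuals               # remove mean + trend
  amp <- (2 / T) * Mod(stats::mvfft(X))
  nyq_bin <- floor(T / 2)
  freqs <- (1:nyq_bin) / (T * ts$tr_seconds)
  list(amp = amp[2:(nyq_bin + 1L), , drop = FALSE], freqs = freqs)
}

band_bins <- function(freqs, band, tr_seconds) {
  nyquist <- 1 / (2 * tr_seconds)
  if (band$hi_hz > nyquist + 1e-12)
    stop(sprintf("band upper edge %g Hz exceeds Nyquist %g Hz",
                 band$hi_hz, nyquist), call. = FALSE)
  sel <- freqs >= band$lo_hz & freqs <= band$hi_hz   # closed interval
  if (!any(sel))
    stop("no DFT bin falls inside the band; series too short", call. = FALSE)
  sel
}

#' Amplitude of low-frequency fluctuation (ALFF)
#'
#' Per voxel: the series is linearly detrended, Fourier transformed, and the
#' mean amplitude (square root of power) over the DFT bins whose centre
#' frequency lies in the closed band `[lo_hz, hi_hz]` is returned.  ALFF is
#' positively homogeneous of degree 1 in the signal.
#'
#' @param ts a [time_series_volume()].
#' @param band a [frequency_band()]; default 0.01-0.08 Hz.
#' @return An `nf_volume` with `feature_kind = "alff"`.
#' @export
compute_alff <- function(ts, band = frequency_band()) {
  stopifnot(inherits(ts, "nf_timeseries"), inherits(band, "nf_band"))
  sp <- detrended_amplitude(ts)
  sel <- band_bins(sp$freqs, band, ts$tr_seconds)
  vals <- colMeans(sp$amp[sel, , drop = FALSE])
  as_volume(array(vals, dim = ts$grid$dims), ts$grid, feature_kind = "alff",
            provenance = sprintf("ALFF %g-%g Hz", band$lo_hz, band$hi_hz))
}

#' Fractional ALFF (fALFF)
#'
#' Per voxel: the sum of spectral amplitude over in-band bins divided by the
#' sum over all positive-frequency bins up to Nyquist (DC excluded), after
#' linear detrending.  Values lie in `[0, 1]`; a zero-variance series is
#' defined as 0 (the 0/0 convention).
#'
#' @inheritParams compute_alff
#' @return An `nf_volume` with `feature_kind = "falff"`.
#' @export
compute_falff <- function(ts, band = frequency_band()) {
  stopifnot(inherits(ts, "nf_timeseries"), inherits(band, "nf_band"))
  sp <- detrended_amplitude(ts)
  sel <- band_bins(sp$freqs, band, ts$tr_seconds)
  num <- colSums(sp$amp[sel, , drop = FALSE])
  den <- colSums(sp$amp)
  vals <- ifelse(den > 0, num / den, 0)
  vals <- pmin(pmax(vals, 0), 1)
  as_volume(array(vals, dim = ts$grid$dims), ts$grid, feature_kind = "falff",
            provenance = sprintf("fALFF %g-%g Hz", band$lo_hz, band$hi_hz))
}
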