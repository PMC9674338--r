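# Reverse-correlation temporal kernels and their biphasic indices.
#
# Bipolar-cell temporal properties are characterised by reverse
# correlation of the response against a white-noise contrast stimulus.
# Kernels live on the contrast scale used for display: 0.5 is neutral,
# values above/below 0.5 are positive/negative kernel lobes.

#' Construct a temporal kernel on the 0.5-centred contrast scale
#'
#' @param lag_s Lag axis in seconds (0 = simultaneous).
#' @param contrast Kernel values on the contrast scale (0.5 = neutral).
#' @return An object of class `temporal_kernel` with summary scalars
#'   `peak`, `trough` (each clamped to \[0, 1\]) and signed
#'   `positive_area` / `negative_area` (per-sample deviations from 0.5,
#'   clamped to \[-1, 1\], summed).
#' @export
temporal_kernel <- function(lag_s, contrast) {
  stopifnot(length(lag_s) == length(contrast))
  c0 <- contrast - 0.5
  structure(list(
    lag_s = lag_s, contrast = contrast,
    peak = max(0, min(max(c0), 1)),
    trough = max(0, min(-min(c0), 1)),
    positive_area = sum(pmax(0, pmin(c0, 1))),
    negative_area = sum(pmin(0, pmax(c0, -1)))
  ), class = "temporal_kernel")
}

#' @export
print.temporal_kernel <- function(x, ...) {
  cat(sprintf("<temporal_kernel: %d lags, peak %.3f, trough %.3f>\n",
              length(x$lag_s), x$peak, x$trough))
  invisible(x)
}

#' Response-weighted (reverse-correlation) temporal kernel
#'
#' Estimates the linear temporal filter between a white-noise contrast
#' stimulus and an ROI response by cross-correlation, normalised by the
#' stimulus variance so that for a response generated as
#' `conv(stimulus - 0.5, h)` the expected estimate equals `h`.  The
#' estimate is mapped back onto the 0.5-centred contrast scale.
#'
#' @param stimulus Numeric vector of contrast values (0.5 = neutral) on
#'   the same clock as the response.
#' @param response A [roi_trace()]; `dff` is used if present, otherwise
#'   `f_raw`.
#' @param max_lag_s Maximum lag (seconds); must not exceed the record.
#' @return A [temporal_kernel()].
#' @export
compute_sta_kernel <- function(stimulus, response, max_lag_s) {
  stopifnot(inherits(response, "roi_trace"))
  y <- if (!is.null(response$dff)) response$dff else response$f_raw
  n <- length(y)
  if (length(stimulus) != n)
    stop("stimulus and response must share a common clock")
  dt <- median(diff(response$time_s))
  n_lag <- floor(max_lag_s / dt)
  if (n_lag >= n) stop("max_lag exceeds record length")
  s0 <- stimulus - 0.5
  v <- mean(s0^2)
  if (v <= 0) stop("stimulus has zero variance")
  k <- vapply(0:n_lag, function(lag) {
    t_idx <- (1L + lag):n
    sum(y[t_idx] * s0[t_idx - lag]) / (length(t_idx) * v)
  }, numeric(1))
  temporal_kernel(lag_s = (0:n_lag) * dt, contrast = 0.5 + k)
}

#' Biphasic peak index of a temporal kernel
#'
#' `Trough / (Peak + Trough)` with `Peak` and `Trough` the kernel's
#' maximal excursions above and below neutral contrast, each clamped to
#' \[0, 1\].  0 for a kernel that never dips below neutral, 1 for one
#' that never rises above it.
#'
#' @param kernel A [temporal_kernel()].
#' @return Index in \[0, 1\].
#' @export
biphasic_peak_index <- function(kernel) {
  stopifnot(inherits(kernel, "temporal_kernel"))
  tot <- kernel$peak + kernel$trough
  if (tot <= 0) stop("flat kernel", call. = FALSE)
  kernel$trough / tot
}

#' Biphasic area index of a temporal kernel
#'
#' `-negative / (positive - negative)` where `positive` and `negative`
#' sum the per-sample deviations from neutral contrast clamped to
#' \[0, 1\] and \[-1, 0\] respectively.  0 for purely positive kernels,
#' 0.5 for antisymmetric ones.
#'
#' @inheritParams biphasic_peak_index
#' @return Index in \[0, 1\].
#' @export
biphasic_area_index <- function(kernel) {
  stopifnot(inherits(kernel, "temporal_kernel"))
  denom <- kernel$positive_area - kernel$negative_area
  if (denom <= 0) stop("zero total area", call. = FALSE)
  -kernel$negative_area / denom
}

#' Export a temporal kernel as a two-column CSV
#'
#' @inheritParams biphasic_peak_index
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kernel <- function(kernel, path) {
  write.csv(data.frame(lag_s = kernel$lag_s, contrast = kernel$contrast),
            path, row.names = FALSE)
  invisible(path)
}
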