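# Trace-kinetics metrics for ROI-level glutamate responses.
#
# All metrics operate on the dff field of a roi_trace (see compute_dff) and
# use two windows: the response window (the full stimulus window by
# default) and the plateau window (the last 1 s of the stimulus by
# default, matching a 2-s stimulus).

require_dff <- function(trace) {
  if (is.null(trace$dff)) stop("dff not computed; call compute_dff() first")
  trace
}

response_window_for <- function(trace, response_window_s = NULL) {
  if (!is.null(response_window_s)) return(response_window_s)
  if (is.na(trace$stim_onset_s) || is.na(trace$stim_offset_s))
    stop("no stimulus window: give response_window_s explicitly")
  c(trace$stim_onset_s, trace$stim_offset_s)
}

plateau_window_for <- function(trace, plateau_window_s = NULL,
                               plateau_span_s = 1) {
  if (!is.null(plateau_window_s)) return(plateau_window_s)
  if (is.na(trace$stim_offset_s))
    stop("no stimulus window: give plateau_window_s explicitly")
  c(trace$stim_offset_s - plateau_span_s, trace$stim_offset_s)
}

peak_dff <- function(trace, response_window_s = NULL) {
  trace <- require_dff(trace)
  win <- response_window_for(trace, response_window_s)
  max(trace$dff[window_idx(trace$time_s, win)])
}

#' Signal-to-noise ratio of a light response
#'
#' SNR is the peak \eqn{\Delta F/F} within the response window divided by
#' the standard deviation of \eqn{\Delta F/F} over the pre-stimulus
#' baseline window (by default the 1 s before stimulus onset).
#'
#' @inheritParams compute_dff
#' @param trace A [roi_trace()] with `dff` computed.
#' @param response_window_s Window over which the peak is taken; defaults
#'   to the stimulus window.
#' @return SNR (dimensionless scalar).
#' @export
compute_snr <- function(trace, baseline_window_s = NULL,
                        response_window_s = NULL) {
  trace <- require_dff(trace)
  bwin <- baseline_window_for(trace, baseline_window_s)
  s <- sd(trace$dff[window_idx(trace$time_s, bwin)])
  if (!is.finite(s) || s <= 0) stop("degenerate baseline", call. = FALSE)
  peak_dff(trace, response_window_s) / s
}

#' Filter a recording set by SNR
#'
#' Retains exactly the ROIs whose SNR is strictly greater than
#' `snr_threshold` (default 4, the selection criterion for further
#' analysis).  Traces without `dff` have it computed first.
#'
#' @param set A [recording_set()].
#' @param snr_threshold Strict lower bound on SNR.
#' @inheritParams compute_snr
#' @return A [recording_set()] with the surviving ROIs (possibly empty).
#' @export
filter_rois <- function(set, snr_threshold = 4, baseline_window_s = NULL,
                        response_window_s = NULL) {
  stopifnot(inherits(set, "recording_set"))
  keep <- vapply(set$traces, function(tr) {
    if (is.null(tr$dff)) tr <- compute_dff(tr, baseline_window_s)
    compute_snr(tr, baseline_window_s, response_window_s) > snr_threshold
  }, logical(1))
  set$traces <- set$traces[keep]
  set
}

#' Sustained/transient index (STi)
#'
#' STi is the mean \eqn{\Delta F/F} over the plateau window (by default
#' the last 1 s of the light response) divided by the peak \eqn{\Delta F/F}
#' within the stimulus window.  STi = 0 marks a purely transient response
#' with no plateau phase; STi = 1 a purely sustained response whose peak
#' and plateau are equal.  Negative plateau excursions are reported as-is.
#'
#' @inheritParams compute_snr
#' @param plateau_window_s Length-2 window for the plateau mean; defaults
#'   to the last 1 s of the stimulus.
#' @return STi (dimensionless scalar).
#' @export
compute_sti <- function(trace, plateau_window_s = NULL,
                        response_window_s = NULL) {
  trace <- require_dff(trace)
  pk <- peak_dff(trace, response_window_s)
  if (pk <= 0) stop("no response", call. = FALSE)
  pwin <- plateau_window_for(trace, plateau_window_s)
  mean(trace$dff[window_idx(trace$time_s, pwin)]) / pk
}

# First upward crossing of `level` at or after time `from`, linearly
# interpolated between samples.  Returns NA if never crossed.
first_crossing <- function(time_s, y, level, from = -Inf) {
  ok <- time_s >= from
  t <- time_s[ok]; v <- y[ok]
  if (!length(v)) return(NA_real_)
  if (v[1L] >= level) return(t[1L])
  up <- which(v[-1L] >= level & v[-length(v)] < level)
  if (!length(up)) return(NA_real_)
  i <- up[1L]
  t[i] + (level - v[i]) * (t[i + 1L] - t[i]) / (v[i + 1L] - v[i])
}

#' 20--80% rise time of the light response
#'
#' Time between the first upward crossings of `lo_frac` and `hi_frac`
#' times the peak \eqn{\Delta F/F} on the rising phase, with linear
#' interpolation between samples.
#'
#' @inheritParams compute_snr
#' @param lo_frac,hi_frac Fractions of the peak bounding the rising phase.
#' @return Rise time in seconds.
#' @export
compute_rise_time <- function(trace, lo_frac = 0.2, hi_frac = 0.8,
                              response_window_s = NULL) {
  stopifnot(lo_frac < hi_frac, lo_frac > 0, hi_frac < 1)
  trace <- require_dff(trace)
  win <- response_window_for(trace, response_window_s)
  pk <- peak_dff(trace, response_window_s)
  if (pk <= 0) stop("no response", call. = FALSE)
  from <- win[1L]
  t_lo <- first_crossing(trace$time_s, trace$dff, lo_frac * pk, from)
  t_hi <- first_crossing(trace$time_s, trace$dff, hi_frac * pk, from)
  if (is.na(t_lo) || is.na(t_hi))
    stop("rising phase does not reach threshold fractions", call. = FALSE)
  t_hi - t_lo
}

#' Response latency
#'
#' Time from stimulus onset to the first upward crossing of `frac` times
#' the peak \eqn{\Delta F/F}, linearly interpolated.
#'
#' @inheritParams compute_rise_time
#' @param frac Fraction of peak defining response onset (default 20%).
#' @return Latency in seconds.
#' @export
compute_latency <- function(trace, frac = 0.2, response_window_s = NULL) {
  trace <- require_dff(trace)
  if (is.na(trace$stim_onset_s)) stop("no stimulus onset defined")
  pk <- peak_dff(trace, response_window_s)
  if (pk <= 0) stop("no response", call. = FALSE)
  tc <- first_crossing(trace$time_s, trace$dff, frac * pk,
                       trace$stim_onset_s)
  if (is.na(tc)) stop("response never crosses threshold", call. = FALSE)
  tc - trace$stim_onset_s
}

#' Per-ROI kinetics table for a recording set
#'
#' Computes \eqn{\Delta F/F} where missing, then SNR, peak and plateau
#' amplitudes, STi, rise time and latency for every ROI, plus the SNR
#' filter verdict.  Metrics that error on a given trace (e.g. no positive
#' response) are reported as `NA` for that ROI.
#'
#' @inheritParams filter_rois
#' @inheritParams compute_sti
#' @return A data frame with one row per ROI.
#' @export
analyze_kinetics <- function(set, snr_threshold = 4,
                             baseline_window_s = NULL,
                             plateau_window_s = NULL,
                             response_window_s = NULL) {
  stopifnot(inherits(set, "recording_set"))
  rows <- lapply(set$traces, function(tr) {
    if (is.null(tr$dff)) tr <- compute_dff(tr, baseline_window_s)
    try_na <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    pk <- try_na(peak_dff(tr, response_window_s))
    pwin <- plateau_window_for(tr, plateau_window_s)
    snr <- try_na(compute_snr(tr, baseline_window_s, response_window_s))
    data.frame(
      roi_id = tr$roi_id, fov_id = tr$fov_id,
      radial_distance_um = tr$radial_distance_um, group = tr$group,
      peak_dff = pk,
      plateau_dff = try_na(mean(tr$dff[window_idx(tr$time_s, pwin)])),
      sti = try_na(compute_sti(tr, plateau_window_s, response_window_s)),
      snr = snr,
      rise_time_s = try_na(compute_rise_time(
        tr, response_window_s = response_window_s)),
      latency_s = try_na(compute_latency(
        tr, response_window_s = response_window_s)),
      passed_filter = is.finite(snr) && snr > snr_threshold,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cumulative STi distribution summary by ROI group
#'
#' Convenience population summary of `analyze_kinetics()` output:
#' per-group n, mean, s.d. of STi among filter-passing ROIs, optionally
#' drawn as empirical cumulative distributions.
#'
#' @param kin Data frame from [analyze_kinetics()].
#' @param plot If `TRUE`, draw per-group STi ECDFs with base graphics.
#' @return A data frame with one row per group, invisibly when plotting.
#' @export
summarize_sti <- function(kin, plot = FALSE) {
  kin <- kin[kin$passed_filter & is.finite(kin$sti), , drop = FALSE]
  groups <- split(kin$sti, kin$group)
  out <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    mean_sti = vapply(groups, mean, numeric(1)),
    sd_sti = vapply(groups, sd, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (plot && nrow(kin)) {
    cols <- grDevices::hcl.colors(max(2L, length(groups)), "Dark 3")
    graphics::plot(NULL, xlim = range(kin$sti), ylim = c(0, 1),
                   xlab = "STi", ylab = "cumulative fraction",
                   main = "STi by ROI group")
    for (i in seq_along(groups)) {
      e <- stats::ecdf(groups[[i]])
      graphics::lines(sort(groups[[i]]), e(sort(groups[[i]])),
                      type = "s", col = cols[i], lwd = 2)
    }
    graphics::legend("bottomright", legend = names(groups),
                     col = cols[seq_along(groups)], lwd = 2, bty = "n")
    return(invisible(out))
  }
  out
}
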