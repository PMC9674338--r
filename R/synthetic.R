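# Synthetic iGluSnFR data with known ground truth.
#
# Traces are built exactly the way the analysis assumes the data arise:
# an inhomogeneous Poisson vesicle train drawn from a canonical release
# profile, superposed quantal waveforms on a fine (1 kHz) clock,
# frame-integrated down to the imaging frame rate, plus additive Gaussian
# frame noise.  The generating train, profile and noiseless trace ride
# along as ground truth so every pipeline stage can be tested without any
# real recording.

#' Specification of a canonical vesicle release profile
#'
#' Sustained (proximal, BC7-like) profiles hold a ~3 vesicles/s plateau
#' for the stimulus duration; transient (distal, BC5-like) profiles decay
#' to ~1 vesicle/s after the onset peak.  During the stimulus the rate is
#' `plateau + (onset_peak - plateau) * exp(-(t - t_on)/tau)`; outside it
#' the rate sits at `baseline`.
#'
#' @param kind `"sustained"` or `"transient"`.
#' @param onset_peak_vps Instantaneous rate at stimulus onset
#'   (vesicles/s).
#' @param transient_tau_s Decay time constant of the onset transient (s).
#' @param plateau_vps Steady-state rate during the stimulus; defaults to
#'   3 (sustained) or 1 (transient) vesicles/s.
#' @param baseline_vps Spontaneous rate outside the stimulus.
#' @param stim_onset_s,stim_duration_s Stimulus timing (defaults: onset
#'   4 s after acquisition start, 2 s duration).
#' @return An object of class `release_profile_spec`.
#' @export
release_profile_spec <- function(kind = c("sustained", "transient"),
                                 onset_peak_vps = 8, transient_tau_s = 0.15,
                                 plateau_vps = NULL, baseline_vps = 0.2,
                                 stim_onset_s = 4, stim_duration_s = 2) {
  kind <- match.arg(kind)
  if (is.null(plateau_vps))
    plateau_vps <- if (kind == "sustained") 3 else 1
  stopifnot(onset_peak_vps >= 0, plateau_vps >= 0, baseline_vps >= 0,
            transient_tau_s > 0, plateau_vps <= onset_peak_vps)
  structure(list(kind = kind, onset_peak_vps = onset_peak_vps,
                 transient_tau_s = transient_tau_s,
                 plateau_vps = plateau_vps, baseline_vps = baseline_vps,
                 stim_onset_s = stim_onset_s,
                 stim_duration_s = stim_duration_s),
            class = "release_profile_spec")
}

#' Noise and acquisition specification for synthetic traces
#'
#' @param gaussian_sd Additive Gaussian frame noise, \eqn{\Delta F/F}
#'   units.
#' @param frame_rate_hz Imaging frame rate (default 58.25 Hz).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(gaussian_sd = 0.01, frame_rate_hz = 58.25) {
  stopifnot(gaussian_sd >= 0, frame_rate_hz > 0)
  structure(list(gaussian_sd = gaussian_sd, frame_rate_hz = frame_rate_hz),
            class = "noise_spec")
}

#' Build the continuous release-rate profile of a specification
#'
#' @param spec A [release_profile_spec()].
#' @param dt_s Clock step of the profile (default 1 ms).
#' @param duration_s Total profile duration.
#' @return A [release_rate()].
#' @export
make_release_profile <- function(spec, dt_s = 0.001, duration_s = 8) {
  stopifnot(inherits(spec, "release_profile_spec"))
  t <- seq(dt_s / 2, duration_s, by = dt_s)
  on <- spec$stim_onset_s
  off <- spec$stim_onset_s + spec$stim_duration_s
  rate <- rep(spec$baseline_vps, length(t))
  during <- t >= on & t < off
  rate[during] <- spec$plateau_vps +
    (spec$onset_peak_vps - spec$plateau_vps) *
    exp(-(t[during] - on) / spec$transient_tau_s)
  release_rate(t, rate, meta = list(spec = spec))
}

# Superpose frame-integrated quanta for Poisson counts on a fine clock,
# then average fine samples into imaging frames.
superpose_and_frame <- function(counts, fine_dt, quantum, frame_rate_hz,
                                duration_s) {
  qs <- sample_quantum(quantum, fine_dt)
  nf <- length(qs)
  xp <- c(rep(0, nf - 1L), counts)
  fine <- as.numeric(stats::filter(xp, qs, method = "convolution",
                                   sides = 1))[nf - 1L + seq_along(counts)]
  frame_dt <- 1 / frame_rate_hz
  n_frames <- floor(duration_s / frame_dt)
  fine_t <- (seq_along(counts) - 0.5) * fine_dt
  frame_of <- pmin(n_frames, floor(fine_t / frame_dt) + 1L)
  dff <- as.numeric(tapply(fine, frame_of, mean))[seq_len(n_frames)]
  dff[is.na(dff)] <- 0
  list(dff = dff, time_s = (seq_len(n_frames) - 0.5) * frame_dt)
}

#' Synthesise one iGluSnFR trace from a release profile
#'
#' Draws a Poisson vesicle train from the profile on its fine clock,
#' superposes one quantal waveform per vesicle, integrates into imaging
#' frames and adds Gaussian frame noise.  Raw fluorescence is
#' `f0 * (1 + dff)` so the trace exercises [compute_dff()] like real
#' data; the generating train, profile and noiseless trace are stored in
#' the `truth` field.
#'
#' @param profile A [release_rate()] (e.g. from
#'   [make_release_profile()]) carrying a `spec` in its metadata, or a
#'   [release_profile_spec()].
#' @param quantum A [quantal_waveform()]; default amplitude 0.5
#'   \eqn{\Delta F/F} per vesicle.
#' @param noise A [noise_spec()].
#' @param seed RNG seed.
#' @param roi_id,group,radial_distance_um Trace labelling.
#' @param f0 Baseline fluorescence in arbitrary units.
#' @return A [roi_trace()] (without `dff`; compute it downstream).
#' @export
synthesize_trace <- function(profile, quantum = quantal_waveform(amplitude = 0.5),
                             noise = noise_spec(), seed = NULL,
                             roi_id = "syn_roi", group = "unassigned",
                             radial_distance_um = NA_real_, f0 = 100) {
  if (inherits(profile, "release_profile_spec"))
    profile <- make_release_profile(profile)
  stopifnot(inherits(profile, "release_rate"), inherits(noise, "noise_spec"))
  fine_dt <- median(diff(profile$time_s))
  duration_s <- profile$time_s[length(profile$time_s)] + fine_dt / 2
  train <- discretize_poisson(profile, bin_s = fine_dt,
                              seed = derive_seed(seed, "train"))
  counts <- tabulate(findInterval(train$event_times_s,
                                  seq(0, duration_s, by = fine_dt),
                                  rightmost.closed = TRUE),
                     nbins = length(profile$time_s))
  sf <- superpose_and_frame(counts, fine_dt, quantum, noise$frame_rate_hz,
                            duration_s)
  dff_noisy <- sf$dff + with_seed(derive_seed(seed, "noise"),
                                  rnorm(length(sf$dff), 0, noise$gaussian_sd))
  spec <- profile$meta$spec
  roi_trace(roi_id = roi_id, time_s = sf$time_s,
            f_raw = f0 * (1 + dff_noisy),
            stim_onset_s = if (!is.null(spec)) spec$stim_onset_s else NA_real_,
            stim_offset_s = if (!is.null(spec))
              spec$stim_onset_s + spec$stim_duration_s else NA_real_,
            radial_distance_um = radial_distance_um, group = group,
            truth = list(profile = profile, train = train,
                         noiseless_dff = sf$dff, quantum = quantum,
                         seed = seed))
}

#' Synthesise a field of view mixing sustained and transient ROIs
#'
#' @param n_proximal,n_distal Number of sustained-profile (proximal) and
#'   transient-profile (distal) ROIs.
#' @param specs Named list with elements `proximal` and `distal`, each a
#'   [release_profile_spec()].
#' @param quantum,noise,seed As in [synthesize_trace()].
#' @return A [recording_set()] with per-ROI group labels and ground
#'   truth.
#' @export
synthesize_fov <- function(n_proximal, n_distal,
                           specs = list(
                             proximal = release_profile_spec("sustained"),
                             distal = release_profile_spec("transient")),
                           quantum = quantal_waveform(amplitude = 0.5),
                           noise = noise_spec(), seed = NULL) {
  stopifnot(n_proximal >= 0, n_distal >= 0)
  mk <- function(i, group) {
    spec <- specs[[if (group == "proximal") "proximal" else "distal"]]
    dist <- if (group == "proximal") runif(1, 5, 45) else runif(1, 45, 145)
    synthesize_trace(spec, quantum, noise,
                     seed = derive_seed(seed, paste0(group, i)),
                     roi_id = sprintf("%s_%03d", group, i), group = group,
                     radial_distance_um = dist)
  }
  traces <- with_seed(derive_seed(seed, "fov"), c(
    lapply(seq_len(n_proximal), mk, group = "proximal"),
    lapply(seq_len(n_distal), mk, group = "distal")))
  recording_set(traces, frame_rate_hz = noise$frame_rate_hz,
                provenance = sprintf("synthesize_fov(seed=%s)",
                                     format(seed)))
}

#' Synthesise a spontaneous-activity trace with known event times
#'
#' Sparse quantal events at a constant Poisson rate on a noisy baseline;
#' the ground-truth event times support [fit_quantum()] testing.  Warns
#' when `event_rate_vps * tau_decay > 0.2` (events no longer mostly
#' isolated).
#'
#' @param event_rate_vps Spontaneous event rate (vesicles/s).
#' @param duration_s Trace duration.
#' @inheritParams synthesize_trace
#' @return A list with elements `trace` (a [roi_trace()], `dff` set) and
#'   `event_times_s`.
#' @export
synthesize_spontaneous <- function(event_rate_vps = 0.5, duration_s = 60,
                                   quantum = quantal_waveform(amplitude = 0.5),
                                   noise = noise_spec(), seed = NULL) {
  stopifnot(event_rate_vps >= 0, duration_s > 0)
  if (event_rate_vps * quantum$tau_decay_s > 0.2)
    warning("event rate too high for mostly isolated events")
  fine_dt <- 0.001
  t <- seq(fine_dt / 2, duration_s, by = fine_dt)
  flat <- release_rate(t, rep(event_rate_vps, length(t)))
  train <- discretize_poisson(flat, bin_s = fine_dt,
                              seed = derive_seed(seed, "spont"))
  counts <- tabulate(findInterval(train$event_times_s,
                                  seq(0, duration_s, by = fine_dt),
                                  rightmost.closed = TRUE),
                     nbins = length(t))
  sf <- superpose_and_frame(counts, fine_dt, quantum, noise$frame_rate_hz,
                            duration_s)
  dff <- sf$dff + with_seed(derive_seed(seed, "spontnoise"),
                            rnorm(length(sf$dff), 0, noise$gaussian_sd))
  tr <- roi_trace(roi_id = "spontaneous", time_s = sf$time_s,
                  f_raw = 100 * (1 + dff), dff = dff,
                  truth = list(train = train, quantum = quantum))
  list(trace = tr, event_times_s = train$event_times_s)
}

#' Extract peak-aligned event snippets around known event times
#'
#' Helper for quantal fitting on synthetic (or annotated) spontaneous
#' recordings: cuts a window around each event time and aligns snippets
#' on the clock, discarding events too close to the record edges.
#'
#' @param trace A [roi_trace()] with `dff` set.
#' @param event_times_s Event times (s).
#' @param pre_s,post_s Window before and after each event.
#' @return Matrix of snippets (rows = events).
#' @export
extract_event_snippets <- function(trace, event_times_s, pre_s = 0.05,
                                   post_s = 0.2) {
  dt <- median(diff(trace$time_s))
  n_pre <- round(pre_s / dt)
  n_post <- round(post_s / dt)
  y <- if (!is.null(trace$dff)) trace$dff else trace$f_raw
  idx <- round((event_times_s - trace$time_s[1L]) / dt) + 1L
  keep <- idx - n_pre >= 1L & idx + n_post <= length(y)
  snips <- t(vapply(idx[keep],
                    function(i) y[(i - n_pre):(i + n_post)],
                    numeric(n_pre + n_post + 1L)))
  snips
}
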