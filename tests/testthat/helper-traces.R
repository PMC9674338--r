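# Shared fixture builders.  All fixtures are constructed in code; traces
# follow the default acquisition geometry (stimulus 4--6 s, ~58 Hz) unless
# a test needs otherwise.

# A deterministic trace with prescribed dff shape on a uniform clock.
make_dff_trace <- function(dff, dt = 1 / 58.25, stim_onset = 4,
                           stim_offset = 6, roi_id = "t") {
  n <- length(dff)
  roi_trace(roi_id, time_s = (seq_len(n) - 0.5) * dt,
            f_raw = 100 * (1 + dff), dff = dff,
            stim_onset_s = stim_onset, stim_offset_s = stim_offset)
}

# dff shaped by a function of time over an 8-s record.
make_shaped_trace <- function(shape, dt = 1 / 58.25, duration = 8, ...) {
  t <- seq(dt / 2, duration, by = dt)
  make_dff_trace(shape(t), dt = dt, ...)
}

# Small 3-ROI recording set with distinct constant offsets.
make_small_set <- function() {
  dt <- 0.01
  t <- seq(dt / 2, 8, by = dt)
  traces <- lapply(1:3, function(i)
    roi_trace(paste0("roi", i), t, f_raw = i * 10 + sin(t * i),
              stim_onset_s = 4, stim_offset_s = 6,
              radial_distance_um = i * 20,
              group = c("proximal", "distal", "unassigned")[i]))
  recording_set(traces, frame_rate_hz = 1 / dt, provenance = "fixture")
}
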