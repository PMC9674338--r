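test_that("SNR is peak over baseline s.d. and errors on flat baselines", {
  dt <- 1 / 58.25
  t <- seq(dt / 2, 8, by = dt)
  base <- rep(c(-0.1, 0.1), length.out = length(t))  # baseline s.d. ~ 0.1005
  dff <- base
  dff[t >= 4 & t < 6] <- 0.8
  tr <- make_dff_trace(dff, dt = dt)
  expect_equal(compute_snr(tr), 0.8 / sd(base[t >= 3 & t <= 4]),
               tolerance = 1e-12)
  flat <- make_dff_trace(c(rep(0, 300), rep(1, 166)), dt = dt)
  expect_error(compute_snr(flat), "degenerate baseline")
})

test_that("SNR recovers peak/sigma for Gaussian baseline noise", {
  dt <- 1 / 58.25
  t <- seq(dt / 2, 8, by = dt)
  sigma <- 0.05
  peak <- 0.9
  snrs <- vapply(1:100, function(s) {
    set.seed(s)
    dff <- rnorm(length(t), 0, sigma)
    dff[t >= 4 & t < 6] <- peak
    compute_snr(make_dff_trace(dff, dt = dt))
  }, numeric(1))
  expect_equal(mean(snrs), peak / sigma, tolerance = 0.1)
})

test_that("filter_rois keeps strictly SNR > threshold", {
  dt <- 1 / 58.25
  t <- seq(dt / 2, 8, by = dt)
  base <- rep(c(-0.1, 0.1), length.out = length(t))
  s_base <- sd(base[t >= 3 & t <= 4])
  mk <- function(snr, id) {
    dff <- base
    dff[t >= 4 & t < 6] <- snr * s_base
    tr <- make_dff_trace(dff, dt = dt, roi_id = id)
    tr
  }
  set <- recording_set(list(mk(3, "a"), mk(4, "b"), mk(5, "c")))
  kept <- filter_rois(set, snr_threshold = 4)
  expect_identical(names(kept$traces), "c")
  # threshold 0 on all-positive set is the identity
  expect_identical(names(filter_rois(set, 0)$traces), c("a", "b", "c"))
})

test_that("STi is the plateau/peak ratio with exact boundary cases", {
  dt <- 1 / 58.25
  # transient that returns to baseline before the last second: STi = 0
  tr0 <- make_shaped_trace(function(t)
    ifelse(t >= 4 & t < 4.5, 1, 0), dt = dt)
  expect_equal(compute_sti(tr0), 0)
  # rectangular response spanning the stimulus: STi = 1
  tr1 <- make_shaped_trace(function(t)
    ifelse(t >= 4 & t <= 6, 0.7, 0), dt = dt)
  expect_equal(compute_sti(tr1), 1)
  # direct ratio
  tr2 <- make_shaped_trace(function(t)
    ifelse(t >= 4 & t < 5, 1, ifelse(t >= 5 & t <= 6, 0.33, 0)), dt = dt)
  expect_equal(compute_sti(tr2), 0.33)
  # no positive response is an error
  trn <- make_shaped_trace(function(t) ifelse(t >= 4 & t < 6, -0.5, 0))
  expect_error(compute_sti(trn), "no response")
})

test_that("SNR and STi are invariant to a time shift of the whole record", {
  dt <- 1 / 58.25
  set.seed(7)
  noise <- rnorm(466, 0, 0.03)
  shape <- function(t) ifelse(t >= 4 & t < 6, 0.5 + 0.3 * (t < 4.5), 0)
  t1 <- seq(dt / 2, 8, by = dt)
  tr1 <- make_dff_trace(shape(t1) + noise, dt = dt)
  shift <- 1.7
  tr2 <- roi_trace("s", t1 + shift, 100 * (1 + shape(t1) + noise),
                   dff = shape(t1) + noise,
                   stim_onset_s = 4 + shift, stim_offset_s = 6 + shift)
  expect_equal(compute_snr(tr2), compute_snr(tr1), tolerance = 1e-12)
  expect_equal(compute_sti(tr2), compute_sti(tr1), tolerance = 1e-12)
})

test_that("rise time interpolates 20-80% crossings", {
  # linear ramp 0 -> 1 over 1 s: crossings at 0.2 and 0.8 s
  dt <- 0.01
  tr <- make_shaped_trace(function(t)
    pmin(1, pmax(0, t - 4)) * (t < 6), dt = dt)
  expect_equal(compute_rise_time(tr), 0.6, tolerance = dt)
  # step response: rise time bounded by one sample
  step <- make_shaped_trace(function(t) as.numeric(t >= 5 & t < 6), dt = dt)
  expect_lte(compute_rise_time(step), dt)
})

test_that("rise time matches analytic crossings of a biexponential", {
  tau_r <- 0.002; tau_d <- 0.030
  h <- function(t) ifelse(t > 0, exp(-t / tau_d) - exp(-t / tau_r), 0)
  t_pk <- log(tau_d / tau_r) * tau_r * tau_d / (tau_d - tau_r)
  pk <- h(t_pk)
  # analytic 20% and 80% upward crossing times on the rising phase
  cross <- function(frac) uniroot(function(t) h(t) - frac * pk,
                                  c(1e-9, t_pk), tol = 1e-12)$root
  expected <- cross(0.8) - cross(0.2)
  dt <- 2e-4  # fine clock so sampling error is small
  tr <- make_shaped_trace(function(t) h(t - 4), dt = dt, duration = 6,
                          stim_onset = 4, stim_offset = 5.5)
  expect_equal(compute_rise_time(tr), expected, tolerance = 1e-3)
})

test_that("latency measures onset-to-fraction-of-peak and shifts with delay", {
  dt <- 0.005
  ramp <- function(delay) function(t)
    pmin(1, pmax(0, (t - 4 - delay) / 1)) * (t < 6)
  tr <- make_shaped_trace(ramp(0), dt = dt)
  expect_equal(compute_latency(tr), 0.2, tolerance = dt)
  tr50 <- make_shaped_trace(ramp(0.05), dt = dt)
  expect_equal(compute_latency(tr50) - compute_latency(tr), 0.05,
               tolerance = dt)
})

test_that("latency recovers a generator-imposed onset delay", {
  # high onset rate so the first-vesicle wait is negligible against the
  # frame period and the rise is sharp
  delay <- 0.12
  spec <- release_profile_spec("sustained", stim_onset_s = 4 + delay,
                               onset_peak_vps = 400, plateau_vps = 400,
                               baseline_vps = 0)
  tr <- synthesize_trace(spec, quantum = quantal_waveform(amplitude = 0.5),
                         noise = noise_spec(gaussian_sd = 0), seed = 5)
  tr$stim_onset_s <- 4  # nominal onset; the delay lives in the signal
  tr$stim_offset_s <- 6 + delay
  tr <- compute_dff(tr, baseline_window_s = c(3, 3.9))
  # 20%-of-peak crossing should land within ~2 frames of the true delay
  expect_equal(compute_latency(tr), delay, tolerance = 0.5)
  expect_lt(abs(compute_latency(tr) - delay), 2 / 58.25)
})

test_that("analyze_kinetics tabulates all ROIs and flags filter survivors", {
  set <- synthesize_fov(4, 4, seed = 9)
  kin <- analyze_kinetics(set)
  expect_equal(nrow(kin), 8L)
  expect_setequal(kin$group, c("proximal", "distal"))
  expect_true(all(c("sti", "snr", "rise_time_s", "latency_s",
                    "passed_filter") %in% names(kin)))
  ok <- kin$passed_filter
  expect_equal(ok, kin$snr > 4)
  smry <- summarize_sti(kin)
  expect_true(all(smry$n <= 4))
})
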