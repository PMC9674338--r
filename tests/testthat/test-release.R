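# Quantal waveform, fluctuation analysis, deconvolution, Poisson
# discretisation and reconvolution.

test_that("frame-averaged quantum sampling conserves the waveform integral", {
  q <- quantal_waveform(amplitude = 1)
  # analytic integral of the peak-normalised biexponential
  t_pk <- log(0.030 / 0.002) * 0.002 * 0.030 / (0.030 - 0.002)
  h_pk <- exp(-t_pk / 0.030) - exp(-t_pk / 0.002)
  integral <- (0.030 - 0.002) / h_pk
  for (dt in c(1 / 1000, 1 / 58.25, 1 / 20)) {
    qs <- sample_quantum(q, dt, n = ceiling(0.6 / dt))
    expect_equal(sum(qs) * dt, integral, tolerance = 1e-3)
  }
})

test_that("fit_quantum recovers the generating time constants", {
  dt <- 1 / 1000
  t <- seq(0, 0.25, by = dt)
  qfun <- sacglu:::quantum_fun(quantal_waveform(amplitude = 0.6))
  clean <- qfun(t - 0.02)
  # single noiseless snippet: near-exact self-fit
  fit0 <- fit_quantum(clean, dt)
  expect_equal(fit0$tau_rise_s, 0.002, tolerance = 1e-3)
  expect_equal(fit0$tau_decay_s, 0.030, tolerance = 1e-3)
  expect_equal(fit0$amplitude, 0.6, tolerance = 1e-3)
  # noisy snippet collections over several seeds: within 15%
  for (s in 1:5) {
    set.seed(s)
    snips <- t(vapply(1:60, function(i) clean + rnorm(length(t), 0, 0.05),
                      numeric(length(t))))
    fit <- fit_quantum(snips, dt)
    expect_equal(fit$tau_rise_s, 0.002, tolerance = 0.15)
    expect_equal(fit$tau_decay_s, 0.030, tolerance = 0.15)
  }
  expect_error(fit_quantum(list(), dt), "empty")
})

test_that("QSE is 2 var/mean and matches Campbell shot noise", {
  # plug-in: construct a window with mean 0.5 and variance 0.01
  dt <- 1 / 58.25
  n <- round(8 / dt)
  t <- (seq_len(n) - 0.5) * dt
  y <- rep(0, n)
  win <- t >= 5 & t <= 6
  m <- sum(win)
  vals <- 0.5 + sqrt(0.01) * scale(rnorm(m))[, 1]  # exact mean/var
  y[win] <- vals
  tr <- make_dff_trace(y, dt = dt)
  expect_equal(estimate_qse(tr), 2 * 0.01 / 0.5, tolerance = 1e-10)
  # doubling the gain doubles QSE
  tr2 <- tr; tr2$dff <- 2 * tr$dff
  expect_equal(estimate_qse(tr2), 2 * estimate_qse(tr), tolerance = 1e-10)
  tr3 <- tr; tr3$dff <- -tr$dff
  expect_error(estimate_qse(tr3), "non-positive")
})

test_that("QSE recovers the quantal amplitude of an exponential-decay process", {
  # Campbell oracle: Poisson events at high rate convolved with a pure
  # exponential decay of amplitude q; QSE = 2 sigma^2/mu should equal q.
  q_amp <- 0.2
  tau <- 0.03
  dt <- 1e-3
  dur <- 40
  rate <- 50  # rate * tau >> 1, rate * dur = 2000 events
  qses <- vapply(1:8, function(s) {
    set.seed(s)
    counts <- rpois(dur / dt, rate * dt)
    kern <- q_amp * exp(-(0:(20 * tau / dt)) * dt / tau)
    y <- as.numeric(stats::filter(c(rep(0, length(kern) - 1), counts),
                                  kern, sides = 1))[
      length(kern) - 1 + seq_along(counts)]
    yss <- y[(5 / dt):(dur / dt)]
    2 * var(yss) / mean(yss)
  }, numeric(1))
  # the discrete-time correction for dt/tau is ~dt/(2 tau); well under 10%
  expect_equal(mean(qses), q_amp, tolerance = 0.1)
})

test_that("deconvolution inverts superpositions of quanta", {
  dt <- 1 / 58.25
  n <- 466
  t <- (seq_len(n) - 0.5) * dt
  q <- quantal_waveform(amplitude = 0.5)
  qs <- sample_quantum(q, dt)
  place <- function(times) {
    dff <- rep(0, n)
    for (t0 in times) {
      i0 <- round(t0 / dt)
      idx <- i0 + seq_along(qs)
      idx <- idx[idx <= n]
      dff[idx] <- dff[idx] + qs[seq_along(idx)]
    }
    make_dff_trace(dff, dt = dt)
  }
  # single quantum: rate integrates to one vesicle, concentrated at t0
  tr1 <- place(4.0)
  rr1 <- deconvolve_release_rate(tr1, q)
  expect_equal(sum(rr1$rate_raw_vps) * dt, 1, tolerance = 0.01)
  near <- abs(rr1$time_s - 4.0) < 0.1
  expect_equal(sum(rr1$rate_raw_vps[near]) * dt, 1, tolerance = 0.02)
  # superposition at known times: integral equals the event count
  tr5 <- place(c(4.1, 4.3, 4.35, 5.0, 5.5))
  rr5 <- deconvolve_release_rate(tr5, q)
  expect_equal(sum(rr5$rate_raw_vps) * dt, 5, tolerance = 0.05 * 5)
  # DC conservation: integral of rate vs integral response / integral quantum
  expect_equal(sum(rr5$rate_raw_vps) * dt,
               sum(tr5$dff) * dt / (sum(qs) * dt), tolerance = 0.01)
  # zero-DC quantum errors out
  qz <- q
  tr_err <- tr1
  expect_error(deconvolve_release_rate(
    tr1, structure(list(tau_rise_s = 1, tau_decay_s = 1, amplitude = 0,
                        form = "biexp"), class = "quantal_waveform")))
})

test_that("deconvolve then reconvolve reproduces noiseless traces", {
  set <- synthesize_fov(3, 3, noise = noise_spec(gaussian_sd = 0), seed = 4)
  set <- compute_dff(set)
  inf <- infer_release(set, amplitude = 0.5, roundtrip = TRUE)
  expect_true(all(inf$table$roundtrip_r >= 0.95))
})

test_that("discretize_poisson matches Poisson statistics", {
  # constant 3 vesicles/s over 2 s: mean count 6 over many seeds
  t <- seq(0.0005, 2, by = 0.001)
  rr <- release_rate(t, rep(3, length(t)))
  counts <- vapply(1:1000, function(s)
    length(discretize_poisson(rr, seed = s)$event_times_s), numeric(1))
  se <- sqrt(6 / 1000)
  expect_lt(abs(mean(counts) - 6), 3 * se)
  # Fano factor ~ 1
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.15)
  # zero rate: empty train; negative rate: error
  expect_length(discretize_poisson(
    release_rate(t, rep(0, length(t))), seed = 1)$event_times_s, 0L)
  expect_error(discretize_poisson(release_rate(t, rep(-1, length(t)))),
               "negative rate")
  # determinism
  expect_identical(discretize_poisson(rr, seed = 7)$event_times_s,
                   discretize_poisson(rr, seed = 7)$event_times_s)
})

test_that("time-varying Poisson trains follow the rate profile", {
  # chi-square goodness of fit of binned event counts against the profile
  t <- seq(0.0005, 4, by = 0.001)
  rate <- 5 + 4 * sin(2 * pi * t / 4)
  rr <- release_rate(t, rate)
  events <- unlist(lapply(1:200, function(s)
    discretize_poisson(rr, seed = s)$event_times_s))
  breaks <- seq(0, 4, by = 0.5)
  obs <- table(cut(events, breaks))
  expected <- vapply(seq_len(8), function(i) {
    idx <- t > breaks[i] & t <= breaks[i + 1]
    200 * sum(rate[idx]) * 0.001
  }, numeric(1))
  chi2 <- sum((as.numeric(obs) - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 7))
})

test_that("reconvolution is a linear superposition of quanta", {
  q <- quantal_waveform(amplitude = 0.5)
  t <- seq(0.0005, 1, by = 0.001)
  one <- reconvolve(vesicle_train(0.2), q, time_s = t)
  qf <- sacglu:::quantum_fun(q)
  expect_equal(max(one$dff), 0.5, tolerance = 0.02)
  expect_equal(one$dff[t > 0.21],
               qf(t[t > 0.21] - 0.2 + 0.0005), tolerance = 0.02)
  two <- reconvolve(vesicle_train(c(0.2, 0.2)), q, time_s = t)
  expect_equal(two$dff, 2 * one$dff, tolerance = 1e-12)
})

test_that("release rates and trains export to CSV", {
  t <- seq(0.0005, 1, by = 0.001)
  rr <- release_rate(t, rep(2, length(t)))
  p1 <- withr::local_tempfile(fileext = ".csv")
  write_release(rr, p1)
  expect_equal(read.csv(p1)$rate_vps, rr$rate_vps)
  tr <- discretize_poisson(rr, seed = 3)
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_release(tr, p2)
  expect_equal(read.csv(p2)$event_time_s, tr$event_times_s)
})
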