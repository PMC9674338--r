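# The unitary (quantal) iGluSnFR event waveform.
#
# A single released vesicle produces a stereotyped fluorescence transient,
# modelled as a peak-normalised double exponential (rise ~2 ms, decay
# ~30 ms) scaled by the quantal amplitude.  An alpha-function form is
# available as an alternative parameterisation; with rise << decay the two
# are numerically close.  Because imaging frames integrate fluorescence
# over the frame period, waveforms are sampled frame-averaged: each sample
# is the mean of the continuous waveform over its frame window, which
# conserves the waveform integral at any frame rate.

#' Construct a quantal event waveform
#'
#' @param tau_rise_s Rise time constant in seconds (double-exponential
#'   form only).
#' @param tau_decay_s Decay time constant in seconds.
#' @param amplitude Peak \eqn{\Delta F/F} of a single quantal event;
#'   typically set per ROI from the quantal size estimate
#'   ([estimate_qse()] / [calibrate_quantum_amplitude()]).
#' @param form `"biexp"` (default) for
#'   \eqn{A (e^{-t/\tau_d} - e^{-t/\tau_r})} peak-normalised, or
#'   `"alpha"` for \eqn{A (t/\tau_d) e^{1 - t/\tau_d}}.
#' @return An object of class `quantal_waveform`.
#' @export
quantal_waveform <- function(tau_rise_s = 0.002, tau_decay_s = 0.030,
                             amplitude = 1, form = c("biexp", "alpha")) {
  form <- match.arg(form)
  stopifnot(tau_decay_s > 0, amplitude > 0)
  if (form == "biexp") stopifnot(tau_rise_s > 0, tau_rise_s < tau_decay_s)
  structure(list(tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
                 amplitude = amplitude, form = form),
            class = "quantal_waveform")
}

#' @export
print.quantal_waveform <- function(x, ...) {
  cat(sprintf("<quantal_waveform (%s): rise %.3g ms, decay %.3g ms, amplitude %.3g dF/F>\n",
              x$form, x$tau_rise_s * 1e3, x$tau_decay_s * 1e3, x$amplitude))
  invisible(x)
}

# Continuous peak-normalised waveform as a function of time (s).
quantum_fun <- function(q) {
  if (q$form == "alpha") {
    tau <- q$tau_decay_s
    function(t) ifelse(t > 0, (t / tau) * exp(1 - t / tau), 0) * q$amplitude
  } else {
    tr <- q$tau_rise_s; td <- q$tau_decay_s
    t_pk <- log(td / tr) * tr * td / (td - tr)
    h_pk <- exp(-t_pk / td) - exp(-t_pk / tr)
    function(t) ifelse(t > 0, (exp(-t / td) - exp(-t / tr)) / h_pk, 0) *
      q$amplitude
  }
}

#' Sample a quantal waveform on a frame clock
#'
#' Each sample is the mean of the continuous waveform over its frame
#' window (frame integration), so `sum(samples) * dt_s` equals the
#' continuous integral regardless of frame rate.
#'
#' @param q A [quantal_waveform()].
#' @param dt_s Frame period in seconds.
#' @param n Number of samples; default covers 10 decay time constants.
#' @param oversample Fine subdivisions per frame used for the average.
#' @return Numeric vector of length `n` starting at the frame covering
#'   `[0, dt_s)`.
#' @export
sample_quantum <- function(q, dt_s, n = NULL,
                           oversample = max(4L, ceiling(dt_s / 2e-4))) {
  stopifnot(inherits(q, "quantal_waveform"), dt_s > 0)
  if (is.null(n)) n <- ceiling(10 * q$tau_decay_s / dt_s)
  f <- quantum_fun(q)
  fine <- (seq_len(n * oversample) - 0.5) * (dt_s / oversample)
  colMeans(matrix(f(fine), nrow = oversample))
}

#' Fit a quantal waveform to spontaneous-event snippets
#'
#' Averages peak-aligned snippets and least-squares fits a peak-normalised
#' double-exponential (or alpha-function) event with free onset time,
#' amplitude and time constants.
#'
#' @param events A numeric matrix (snippets in rows) or a list of equal
#'   clock snippet vectors, peak-aligned.
#' @param dt_s Sample period of the snippets in seconds.
#' @param form Waveform family to fit; see [quantal_waveform()].
#' @param start Optional named list of starting values
#'   (`tau_rise_s`, `tau_decay_s`).
#' @return A [quantal_waveform()] with the fitted parameters plus fields
#'   `fit_rmse` and `n_events`.
#' @export
fit_quantum <- function(events, dt_s, form = c("biexp", "alpha"),
                        start = list()) {
  form <- match.arg(form)
  if (is.list(events) && !is.data.frame(events)) {
    if (!length(events)) stop("empty event collection", call. = FALSE)
    len <- unique(vapply(events, length, integer(1)))
    if (length(len) != 1L) stop("snippets must share one clock")
    events <- do.call(rbind, events)
  }
  if (is.null(dim(events))) events <- matrix(events, nrow = 1L)
  if (!nrow(events)) stop("empty event collection", call. = FALSE)
  avg <- colMeans(events)
  n <- length(avg)
  t <- (seq_len(n) - 1) * dt_s
  i_pk <- which.max(avg)
  st <- modifyList(list(tau_rise_s = 0.002, tau_decay_s = 0.030), start)
  # onset start guess: a rise-time back from the observed peak
  st$t0 <- max(0, t[i_pk] - 3 * st$tau_rise_s)
  st$amp <- max(avg)
  model <- function(p, t) {
    q <- quantal_waveform(abs(p[["tau_rise_s"]]),
                          abs(p[["tau_rise_s"]]) + abs(p[["tau_decay_s"]]),
                          amplitude = 1, form = form)
    p[["amp"]] * quantum_fun(q)(t - p[["t0"]])
  }
  p0 <- c(tau_rise_s = st$tau_rise_s,
          tau_decay_s = st$tau_decay_s - st$tau_rise_s,
          t0 = st$t0, amp = st$amp)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = function(p) avg - model(p, t),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    res <- if (is.null(fit)) NA_real_ else sqrt(mean(fit$fvec^2))
    stop(sprintf("quantal fit did not converge (residual rmse %.4g)", res),
         call. = FALSE)
  }
  p <- fit$par
  out <- quantal_waveform(abs(p[["tau_rise_s"]]),
                          abs(p[["tau_rise_s"]]) + abs(p[["tau_decay_s"]]),
                          amplitude = abs(p[["amp"]]), form = form)
  out$fit_rmse <- sqrt(mean(fit$fvec^2))
  out$n_events <- nrow(events)
  out
}

#' Write a quantal fit report as JSON
#'
#' @param q A [quantal_waveform()] (typically from [fit_quantum()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quantum_report <- function(q, path) {
  jsonlite::write_json(unclass(q)[!vapply(unclass(q), is.null, logical(1))],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
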