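# Ball-and-stick starburst amacrine cell model.
#
# One somatic compartment plus three dendritic sections (initial, middle,
# terminal), passive membrane, driven by bipolar-cell synapses whose
# vesicle trains come from kinetically distinct release profiles.  A
# moving bar activates synapses in sequence along the dendrite; direction
# selectivity is read out from the peak terminal Ca2+ signal.  The cable
# equation is integrated by an implicit (backward-Euler) scheme in
# compiled code; the default 0.025-ms step resolves the 0.54-ms AMPA
# conductance decay, while vesicle times are drawn in 1-ms Poisson bins.

#' Starburst morphology and passive parameters
#'
#' Defaults are stand-ins consistent with published starburst models:
#' soma 8 um diameter; initial dendrite 0--40 um x 0.9 um, middle
#' 40--110 um x 0.4 um, terminal 110--150 um x 0.3 um; Cm 1 uF/cm2,
#' Rm 20 kOhm cm2, Ra 100 Ohm cm, leak reversal -60 mV.
#'
#' @param soma_diam_um Soma diameter (sphere).
#' @param sections Data frame with columns `name`, `length_um`,
#'   `diam_um` for the dendritic sections in order from the soma.
#' @param dx_um Spatial discretisation step.
#' @param cm_uF_cm2,rm_kohm_cm2,ra_ohm_cm,e_leak_mV Passive membrane
#'   parameters.
#' @return An object of class `sac_morphology`.
#' @export
sac_morphology <- function(soma_diam_um = 8,
                           sections = data.frame(
                             name = c("initial", "middle", "terminal"),
                             length_um = c(40, 70, 40),
                             diam_um = c(0.9, 0.4, 0.3)),
                           dx_um = 2, cm_uF_cm2 = 1, rm_kohm_cm2 = 20,
                           ra_ohm_cm = 100, e_leak_mV = -60) {
  stopifnot(soma_diam_um > 0, all(sections$length_um > 0),
            all(sections$diam_um > 0), dx_um > 0)
  structure(list(soma_diam_um = soma_diam_um, sections = sections,
                 dx_um = dx_um, cm_uF_cm2 = cm_uF_cm2,
                 rm_kohm_cm2 = rm_kohm_cm2, ra_ohm_cm = ra_ohm_cm,
                 e_leak_mV = e_leak_mV),
            class = "sac_morphology")
}

# Discretise the morphology into compartments.  Returns per-compartment
# capacitance (nF), leak conductance (uS), axial couplings (uS, n-1),
# and dendritic-axis positions (um; soma at 0).
build_cable <- function(morph) {
  stopifnot(inherits(morph, "sac_morphology"))
  um2_to_cm2 <- 1e-8
  um_to_cm <- 1e-4
  dx <- morph$dx_um
  seg_diam <- unlist(lapply(seq_len(nrow(morph$sections)), function(i) {
    nseg <- max(1L, round(morph$sections$length_um[i] / dx))
    rep(morph$sections$diam_um[i], nseg)
  }))
  seg_len <- unlist(lapply(seq_len(nrow(morph$sections)), function(i) {
    nseg <- max(1L, round(morph$sections$length_um[i] / dx))
    rep(morph$sections$length_um[i] / nseg, nseg)
  }))
  x_um <- cumsum(seg_len) - seg_len / 2
  # soma first, then dendritic segments
  area_cm2 <- c(pi * morph$soma_diam_um^2,
                pi * seg_diam * seg_len) * um2_to_cm2
  cm_nF <- area_cm2 * morph$cm_uF_cm2 * 1e3
  gl_uS <- area_cm2 / morph$rm_kohm_cm2 * 1e3
  # axial resistance of half-segments (Ohm); soma treated as isopotential
  cross_cm2 <- pi * (seg_diam / 2)^2 * um2_to_cm2
  r_half <- morph$ra_ohm_cm * (seg_len / 2 * um_to_cm) / cross_cm2
  n_seg <- length(seg_diam)
  r_axial <- c(r_half[1L],
               if (n_seg > 1L) r_half[-n_seg] + r_half[-1L])
  ga_uS <- 1e6 / r_axial
  sec_of <- rep(seq_len(nrow(morph$sections)),
                vapply(seq_len(nrow(morph$sections)), function(i)
                  max(1L, as.integer(round(morph$sections$length_um[i] / dx))),
                  integer(1)))
  list(n = n_seg + 1L, x_um = c(0, x_um), cm_nF = cm_nF, gl_uS = gl_uS,
       ga_uS = ga_uS, e_leak_mV = morph$e_leak_mV,
       terminal = n_seg + 1L,
       terminal_section = 1L + which(sec_of == nrow(morph$sections)))
}

#' Full model configuration
#'
#' Bundles morphology, Ca readout parameters, synapse counts and
#' placement densities, the conductance gradient, the canonical release
#' profiles, AMPA event kinetics and solver settings.
#'
#' @param morphology A [sac_morphology()].
#' @param n_proximal,n_distal Synapse counts per trial (defaults 6 and
#'   12).
#' @param densities Truncated-Gaussian placement densities: named list
#'   (`proximal`, `distal`) of lists with `mean`, `sd`, `min`, `max`
#'   (um from the soma).
#' @param conductance Linear peak-conductance gradient: list with
#'   `g_max_pS` (at `d_min_um`), `g_min_pS` (at `d_max_um`).
#' @param profiles Named list (`sustained`, `transient`) of
#'   [release_profile_spec()] objects providing onset peak, transient
#'   tau and plateau rates for model synapses.
#' @param syn_tau_rise_ms,syn_tau_decay_ms,syn_e_mV AMPA miniature-event
#'   kinetics (defaults 0.14 ms rise, 0.54 ms decay, 0 mV reversal).
#' @param ca Terminal Ca readout: Boltzmann-activated conductance
#'   (half-activation, slope), reversal, pool gain and decay time.  The
#'   Ca current is pooled over the whole terminal dendritic section
#'   (terminal Ca accumulation, not a point measurement).
#' @param dt_ms Solver step (default 0.025 ms).
#' @param record_hz Recording rate for the returned traces.
#' @return An object of class `sac_config`.
#' @export
sac_config <- function(morphology = sac_morphology(),
                       n_proximal = 6, n_distal = 12,
                       densities = list(
                         proximal = list(mean = 25, sd = 10, min = 5, max = 45),
                         distal = list(mean = 75, sd = 20, min = 45, max = 145)),
                       conductance = list(g_max_pS = 172.2, g_min_pS = 68.6,
                                          d_min_um = 5, d_max_um = 145),
                       profiles = list(
                         sustained = release_profile_spec("sustained"),
                         transient = release_profile_spec("transient")),
                       syn_tau_rise_ms = 0.14, syn_tau_decay_ms = 0.54,
                       syn_e_mV = 0,
                       ca = list(gca_uS = 1e-4, eca_mV = 60,
                                 vhalf_mV = -30, slope_mV = 6,
                                 k = 10, tau_ms = 50),
                       dt_ms = 0.025, record_hz = 1000) {
  structure(list(morphology = morphology, n_proximal = n_proximal,
                 n_distal = n_distal, densities = densities,
                 conductance = conductance, profiles = profiles,
                 syn_tau_rise_ms = syn_tau_rise_ms,
                 syn_tau_decay_ms = syn_tau_decay_ms, syn_e_mV = syn_e_mV,
                 ca = ca, dt_ms = dt_ms, record_hz = record_hz),
            class = "sac_config")
}

# draw from a truncated normal by inverse-CDF (exact, vectorised)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(mean, n))
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

#' Sample bipolar-cell synapse locations
#'
#' Draws proximal and distal synapse positions from their placement
#' densities (truncated Gaussians by default, standing in for
#' connectomic position distributions; a density with `sd = 0` is a
#' point mass).
#'
#' @inheritParams sac_config
#' @param seed RNG seed; the same seed reproduces the same roster.
#' @return Data frame with columns `position_um`, `class`
#'   (`proximal`/`distal`) and `kinetics` (`sustained` for proximal,
#'   `transient` for distal; reassign for swap experiments).
#' @export
sample_synapse_locations <- function(n_proximal = 6, n_distal = 12,
                                     densities = sac_config()$densities,
                                     seed = NULL) {
  for (d in densities)
    if (d$max <= d$min) stop("density has zero mass on the dendrite")
  with_seed(seed, {
    p <- densities$proximal
    d <- densities$distal
    pos_p <- rtruncnorm(n_proximal, p$mean, p$sd, p$min, p$max)
    pos_d <- rtruncnorm(n_distal, d$mean, d$sd, d$min, d$max)
    data.frame(
      position_um = c(pos_p, pos_d),
      class = rep(c("proximal", "distal"), c(n_proximal, n_distal)),
      kinetics = rep(c("sustained", "transient"), c(n_proximal, n_distal)),
      stringsAsFactors = FALSE)
  })
}

#' Linear peak-conductance gradient along the dendrite
#'
#' Peak AMPA conductance is scaled down linearly with distance from the
#' soma: `g_max_pS` (172.2 pS) at `d_min_um`, `g_min_pS` (68.6 pS) at
#' `d_max_um`.  Positions outside the range are clamped with a warning.
#'
#' @param position_um Synapse position(s), um from the soma.
#' @param d_min_um,d_max_um Anchoring extent of the gradient.
#' @param g_max_pS,g_min_pS Conductance at the two anchors.
#' @return Peak conductance in pS.
#' @export
conductance_scale <- function(position_um, d_min_um = 5, d_max_um = 145,
                              g_max_pS = 172.2, g_min_pS = 68.6) {
  stopifnot(d_min_um < d_max_um)
  if (any(position_um < d_min_um | position_um > d_max_um)) {
    warning("position outside conductance gradient range; clamped")
    position_um <- pmin(pmax(position_um, d_min_um), d_max_um)
  }
  g_max_pS + (g_min_pS - g_max_pS) *
    (position_um - d_min_um) / (d_max_um - d_min_um)
}

#' Moving-bar stimulus
#'
#' A 1-D bar moving along the dendritic axis (soma at 0):
#' centrifugal = soma towards tips, centripetal = tips towards soma.
#' The bar starts fully outside all receptive fields.
#'
#' @param velocity_mm_s Bar speed in mm/s (0.1--2 in the sweeps).
#' @param direction `"centrifugal"` or `"centripetal"`.
#' @param bar_width_um Bar width (default 400 um).
#' @param rf_diameter_um Bipolar-cell receptive field diameter
#'   (default 60 um).
#' @param pad_s Quiet time before the bar first touches a receptive
#'   field.
#' @return An object of class `bar_stimulus`.
#' @export
bar_stimulus <- function(velocity_mm_s,
                         direction = c("centrifugal", "centripetal"),
                         bar_width_um = 400, rf_diameter_um = 60,
                         pad_s = 0.05) {
  direction <- match.arg(direction)
  stopifnot(velocity_mm_s > 0)
  structure(list(velocity_mm_s = velocity_mm_s, direction = direction,
                 bar_width_um = bar_width_um,
                 rf_diameter_um = rf_diameter_um, pad_s = pad_s),
            class = "bar_stimulus")
}

#' Per-synapse activation schedule for a moving bar
#'
#' A synapse turns on when the bar's leading edge reaches the near edge
#' of its receptive field and off when the trailing edge clears the far
#' edge, so every synapse is active for
#' `(bar_width + rf_diameter) / velocity` seconds; centripetal motion
#' reverses the traversal order.
#'
#' @param stimulus A [bar_stimulus()].
#' @param positions_um Synapse positions along the dendrite.
#' @return Data frame with columns `onset_s` and `offset_s`.
#' @export
schedule_activation <- function(stimulus, positions_um) {
  stopifnot(inherits(stimulus, "bar_stimulus"))
  v <- stimulus$velocity_mm_s * 1000  # um/s
  rf <- stimulus$rf_diameter_um / 2
  dur <- (stimulus$bar_width_um + stimulus$rf_diameter_um) / v
  if (stimulus$direction == "centrifugal") {
    entry <- positions_um - rf
    onset <- stimulus$pad_s + (entry - min(entry)) / v
  } else {
    entry <- positions_um + rf
    onset <- stimulus$pad_s + (max(entry) - entry) / v
  }
  data.frame(onset_s = onset, offset_s = onset + dur)
}

#' Window a canonical release profile for one bar passage
#'
#' The profile's onset transient plays from `onset_s`; its plateau value
#' is held until `offset_s`; the rate is zero outside the window, so the
#' integral of the windowed rate grows linearly with window length once
#' the transient has decayed.
#'
#' @param spec A [release_profile_spec()] (its baseline applies to
#'   spontaneous imaging epochs, not to bar-driven model synapses, and
#'   is ignored here).
#' @param onset_s,offset_s Activation window from
#'   [schedule_activation()].
#' @param dt_s Clock of the windowed rate (default 1 ms, the Poisson
#'   sampling step).
#' @param duration_s Total duration of the returned rate vector.
#' @return A [release_rate()].
#' @export
build_release_for_speed <- function(spec, onset_s, offset_s, dt_s = 0.001,
                                    duration_s = offset_s + 0.2) {
  stopifnot(inherits(spec, "release_profile_spec"))
  if (offset_s <= onset_s) stop("offset must exceed onset")
  t <- seq(dt_s / 2, duration_s, by = dt_s)
  rate <- numeric(length(t))
  active <- t >= onset_s & t < offset_s
  rate[active] <- spec$plateau_vps +
    (spec$onset_peak_vps - spec$plateau_vps) *
    exp(-(t[active] - onset_s) / spec$transient_tau_s)
  release_rate(t, rate, meta = list(spec = spec, onset_s = onset_s,
                                    offset_s = offset_s))
}

#' Simulate the starburst model for one bar passage
#'
#' Draws a Poisson vesicle train per synapse from its windowed release
#' profile (1-ms bins), then integrates the passive cable with one
#' double-exponential AMPA conductance event per vesicle and records
#' somatic voltage and the terminal Ca2+ pool.
#'
#' @param config A [sac_config()].
#' @param roster Synapse roster from [sample_synapse_locations()]
#'   (columns `position_um`, `kinetics`).
#' @param stimulus A [bar_stimulus()].
#' @param seed RNG seed for the vesicle trains.
#' @param inject_nA Optional constant somatic current injection (nA)
#'   instead of synaptic drive (for calibration); the simulation then
#'   runs for `inject_dur_s`.
#' @param inject_dur_s Duration of the injection protocol.
#' @return An object of class `sac_sim_result` with fields `time_s`,
#'   `soma_vm`, `terminal_ca`, `v_terminal`, `peak_ca`, `roster`,
#'   `stimulus`, `seed`.
#' @export
simulate_sac <- function(config, roster = NULL, stimulus = NULL, seed = NULL,
                         inject_nA = NULL, inject_dur_s = 1) {
  stopifnot(inherits(config, "sac_config"))
  cable <- build_cable(config$morphology)
  dt_ms <- config$dt_ms
  if (!is.null(inject_nA)) {
    n_steps <- round(inject_dur_s * 1000 / dt_ms)
    ev_step <- ev_syn <- integer(0)
    syn_comp <- integer(0); syn_g <- numeric(0)
    inj <- rep(inject_nA, n_steps)
    roster <- data.frame(position_um = numeric(0))
  } else {
    stopifnot(!is.null(roster), inherits(stimulus, "bar_stimulus"))
    if (nrow(roster) == 0L) {
      sched <- data.frame(onset_s = numeric(0), offset_s = numeric(0))
      dur <- 0.5
    } else {
      sched <- schedule_activation(stimulus, roster$position_um)
      dur <- max(sched$offset_s) + 0.3
    }
    n_steps <- round(dur * 1000 / dt_ms)
    # Vesicle trains are drawn in each synapse's activation-locked time
    # frame and then shifted by its onset, so the same seed replays the
    # same vesicle sequence for both motion directions (paired-direction
    # comparisons then differ only through geometry and timing).
    ev_t <- vector("list", nrow(roster))
    for (j in seq_len(nrow(roster))) {
      spec <- config$profiles[[roster$kinetics[j]]]
      rr <- build_release_for_speed(spec, 0, sched$offset_s[j] - sched$onset_s[j],
                                    duration_s = sched$offset_s[j] - sched$onset_s[j])
      tr <- discretize_poisson(rr, bin_s = 0.001,
                               seed = derive_seed(seed, paste0("syn", j)))
      ev_t[[j]] <- tr$event_times_s + sched$onset_s[j]
    }
    ev_syn <- rep(seq_along(ev_t) - 1L,
                  vapply(ev_t, length, integer(1)))
    ev_step <- pmin(as.integer(round(unlist(ev_t) * 1000 / dt_ms)),
                    n_steps - 1L)
    ord <- order(ev_step)
    ev_step <- ev_step[ord]; ev_syn <- as.integer(ev_syn[ord])
    # nearest compartment per synapse (dendritic axis)
    syn_comp <- vapply(roster$position_um, function(p)
      which.min(abs(cable$x_um - p)) - 1L, integer(1))
    syn_g <- conductance_scale(roster$position_um,
                               config$conductance$d_min_um,
                               config$conductance$d_max_um,
                               config$conductance$g_max_pS,
                               config$conductance$g_min_pS) * 1e-6  # pS -> uS
    inj <- numeric(0)
  }
  rec_every <- max(1L, round(1000 / config$record_hz / dt_ms))
  res <- cable_simulate_cpp(
    cable$cm_nF, cable$gl_uS, cable$e_leak_mV, cable$ga_uS,
    dt_ms, n_steps, cable$e_leak_mV,
    as.integer(syn_comp), syn_g,
    config$syn_tau_rise_ms, config$syn_tau_decay_ms, config$syn_e_mV,
    as.integer(ev_step), as.integer(if (length(ev_step)) ev_syn else integer(0)),
    0L, inj,
    cable$terminal_section - 1L, config$ca$gca_uS, config$ca$eca_mV,
    config$ca$vhalf_mV, config$ca$slope_mV, config$ca$k, config$ca$tau_ms,
    c(0L, cable$terminal - 1L), rec_every)
  time_s <- seq_len(nrow(res$v_rec)) * rec_every * dt_ms / 1000
  structure(list(time_s = time_s, soma_vm = res$v_rec[, 1L],
                 v_terminal = res$v_rec[, 2L], terminal_ca = res$ca_rec,
                 peak_ca = max(res$ca_rec), peak_vm = max(res$v_rec[, 1L]),
                 x_um = cable$x_um, roster = roster, stimulus = stimulus,
                 seed = seed),
            class = "sac_sim_result")
}

#' @export
print.sac_sim_result <- function(x, ...) {
  cat(sprintf("<sac_sim_result: %.2f s, peak soma Vm %.2f mV, peak terminal Ca %.3g>\n",
              max(x$time_s), x$peak_vm, x$peak_ca))
  invisible(x)
}

#' Direction-selectivity index from a centrifugal/centripetal pair
#'
#' Subtraction mode (default, the literal definition): peak terminal
#' Ca2+ for centrifugal motion minus that for centripetal motion.
#' Normalised mode: `(CF - CP) / (CF + CP)`.  Positive values mean
#' centrifugal preference.
#'
#' @param result_cf,result_cp [simulate_sac()] results for the
#'   centrifugal and centripetal passes over the same roster.
#' @param mode `"subtraction"` or `"normalized"`.
#' @return DSi scalar.
#' @export
compute_dsi <- function(result_cf, result_cp,
                        mode = c("subtraction", "normalized")) {
  mode <- match.arg(mode)
  cf <- result_cf$peak_ca
  cp <- result_cp$peak_ca
  if (mode == "subtraction") return(cf - cp)
  if (cf + cp == 0) stop("CF + CP peak is zero in normalized mode")
  (cf - cp) / (cf + cp)
}
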