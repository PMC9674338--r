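# Model experiments: velocity sweeps under different kinetics
# configurations, incremental sustained-to-transient conversion, and the
# DSi-versus-synapse-distance regression.

#' Assign release kinetics to a synapse roster
#'
#' @param roster Roster from [sample_synapse_locations()].
#' @param condition `"native"` (proximal sustained, distal transient),
#'   `"swapped"` (reversed), `"all_sustained"` or `"all_transient"`.
#' @return The roster with its `kinetics` column set.
#' @export
assign_kinetics <- function(roster, condition = c("native", "swapped",
                                                  "all_sustained",
                                                  "all_transient")) {
  condition <- match.arg(condition)
  roster$kinetics <- switch(condition,
    native = ifelse(roster$class == "proximal", "sustained", "transient"),
    swapped = ifelse(roster$class == "proximal", "transient", "sustained"),
    all_sustained = "sustained",
    all_transient = "transient")
  roster
}

#' Simulate one roster in both directions and compute DSi
#'
#' @param config A [sac_config()].
#' @param roster Synapse roster with `kinetics` assigned.
#' @param velocity_mm_s Bar velocity.
#' @param seed Seed for the vesicle trains.  The same seed is used for
#'   both directions: trains are drawn in activation-locked time, so the
#'   two passes replay the identical vesicle sequences and the DSi
#'   contrast is not diluted by independent Poisson noise.
#' @param n_trials Stimulus presentations per direction; peak Ca is
#'   averaged over trials before the DSi is formed, as experimental DSi
#'   values are computed from trial-averaged responses (default 3).
#' @return List with the trial-averaged peak Ca per direction, both DSi
#'   modes, and the last trial's [simulate_sac()] results.
#' @export
simulate_bar_pair <- function(config, roster, velocity_mm_s, seed = NULL,
                              n_trials = 3) {
  last_pair <- NULL
  peaks <- vapply(seq_len(n_trials), function(k) {
    sk <- derive_seed(seed, paste0("trial", k))
    cf <- simulate_sac(config, roster,
                       bar_stimulus(velocity_mm_s, "centrifugal"),
                       seed = sk)
    cp <- simulate_sac(config, roster,
                       bar_stimulus(velocity_mm_s, "centripetal"),
                       seed = sk)
    if (k == n_trials) last_pair <<- list(cf = cf, cp = cp)
    c(cf$peak_ca, cp$peak_ca)
  }, numeric(2))
  peak_cf <- mean(peaks[1L, ])
  peak_cp <- mean(peaks[2L, ])
  list(cf = last_pair$cf, cp = last_pair$cp,
       peak_cf = peak_cf, peak_cp = peak_cp,
       dsi = peak_cf - peak_cp,
       dsi_norm = if (peak_cf + peak_cp > 0)
         (peak_cf - peak_cp) / (peak_cf + peak_cp) else NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sem <- function(x) sd(x) / sqrt(length(x))

#' DSi versus stimulus velocity
#'
#' For each velocity, `n_repeats` synapse rosters are resampled and
#' simulated in both motion directions; DSi (subtraction and normalised)
#' is aggregated as mean and s.e.m.
#'
#' @inheritParams simulate_bar_pair
#' @param velocities Bar velocities in mm/s (within (0, 2]).
#' @param n_repeats Rosters per velocity.
#' @param condition Kinetics configuration; see [assign_kinetics()].
#' @param seed Master seed.
#' @return Data frame: one row per velocity with `dsi_mean`, `dsi_sem`,
#'   `dsi_norm_mean`, `dsi_norm_sem`, `frac_positive`.
#' @export
run_velocity_sweep <- function(config, velocities = c(0.1, 0.15, 0.25, 0.5, 1, 2),
                               n_repeats = 10, condition = "native",
                               seed = NULL, n_trials = 3) {
  rows <- lapply(velocities, function(v) {
    dsis <- vapply(seq_len(n_repeats), function(r) {
      roster <- sample_synapse_locations(
        config$n_proximal, config$n_distal, config$densities,
        seed = derive_seed(seed, paste0("roster", v, "_", r)))
      roster <- assign_kinetics(roster, condition)
      pair <- simulate_bar_pair(config, roster, v,
                                seed = derive_seed(seed, paste0(v, "_", r)),
                                n_trials = n_trials)
      c(pair$dsi, pair$dsi_norm)
    }, numeric(2))
    data.frame(velocity_mm_s = v, condition = condition, n = n_repeats,
               dsi_mean = mean(dsis[1L, ]), dsi_sem = sem(dsis[1L, ]),
               dsi_norm_mean = mean(dsis[2L, ]),
               dsi_norm_sem = sem(dsis[2L, ]),
               frac_positive = mean(dsis[1L, ] > 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' DSi versus number of sustained inputs (incremental conversion)
#'
#' Fixes each repeat's synapse positions and converts proximal inputs
#' from sustained to transient one at a time, starting from the proximal
#' site furthest from the soma, at a single velocity (default
#' 0.15 mm/s).
#'
#' @inheritParams run_velocity_sweep
#' @param velocity_mm_s Bar velocity.
#' @return Data frame: one row per sustained-input count (0 to
#'   `n_proximal`) with mean and s.e.m. DSi.
#' @export
run_incremental_conversion <- function(config, velocity_mm_s = 0.15,
                                       n_repeats = 10, seed = NULL,
                                       n_trials = 3) {
  n_sus_levels <- config$n_proximal:0
  dsis <- matrix(NA_real_, nrow = length(n_sus_levels), ncol = n_repeats)
  for (r in seq_len(n_repeats)) {
    roster <- sample_synapse_locations(
      config$n_proximal, config$n_distal, config$densities,
      seed = derive_seed(seed, paste0("convroster", r)))
    prox_idx <- which(roster$class == "proximal")
    # conversion order: proximal site furthest from the soma first
    conv_order <- prox_idx[order(roster$position_um[prox_idx],
                                 decreasing = TRUE)]
    for (i in seq_along(n_sus_levels)) {
      n_sus <- n_sus_levels[i]
      roster$kinetics <- ifelse(roster$class == "proximal", "sustained",
                                "transient")
      if (n_sus < config$n_proximal)
        roster$kinetics[conv_order[seq_len(config$n_proximal - n_sus)]] <-
          "transient"
      pair <- simulate_bar_pair(config, roster, velocity_mm_s,
                                seed = derive_seed(seed, paste0("conv", r)),
                                n_trials = n_trials)
      dsis[i, r] <- pair$dsi
    }
  }
  data.frame(n_sustained = n_sus_levels,
             dsi_mean = rowMeans(dsis),
             dsi_sem = apply(dsis, 1L, sem),
             n = n_repeats)
}

#' DSi and synapse-centroid distance over resampled rosters
#'
#' Runs `n_rosters` independent rosters at one velocity and records each
#' repeat's DSi together with the distance between the mean distal
#' (transient) and mean proximal (sustained) synapse positions.
#'
#' @inheritParams run_velocity_sweep
#' @param velocity_mm_s Bar velocity (the strongest-DSi velocity is the
#'   natural choice).
#' @param n_rosters Number of resampled rosters.
#' @return Data frame with one row per roster: `dsi`, `dsi_norm`,
#'   `mean_distance_um`.
#' @export
run_dsi_distance <- function(config, velocity_mm_s = 0.15, n_rosters = 100,
                             condition = "native", seed = NULL,
                             n_trials = 3) {
  rows <- lapply(seq_len(n_rosters), function(r) {
    roster <- sample_synapse_locations(
      config$n_proximal, config$n_distal, config$densities,
      seed = derive_seed(seed, paste0("droster", r)))
    roster <- assign_kinetics(roster, condition)
    pair <- simulate_bar_pair(config, roster, velocity_mm_s,
                              seed = derive_seed(seed, paste0("dist", r)),
                              n_trials = n_trials)
    data.frame(
      dsi = pair$dsi, dsi_norm = pair$dsi_norm,
      mean_distance_um =
        mean(roster$position_um[roster$class == "distal"]) -
        mean(roster$position_um[roster$class == "proximal"]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regress DSi magnitude on mean proximal--distal synapse distance
#'
#' Ordinary least squares of `|DSi|` on the per-roster centroid distance
#' between the two synapse populations.
#'
#' @param repeats Data frame from [run_dsi_distance()] (columns `dsi`
#'   and `mean_distance_um`).
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
regress_dsi_distance <- function(repeats) {
  stopifnot(all(c("dsi", "mean_distance_um") %in% names(repeats)))
  if (var(repeats$mean_distance_um) <= 0)
    stop("degenerate distances (zero variance)", call. = FALSE)
  fit <- lm(abs(dsi) ~ mean_distance_um, data = repeats)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = summary(fit)$r.squared, n = nrow(repeats))
}
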