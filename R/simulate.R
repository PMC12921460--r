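#' Simulation parameters for a synthetic pupillometry session
#'
#' The simulator embodies the two-pathway physiological model the analysis
#' is built to dissociate: luminance steps drive the pupil toward a new
#' equilibrium through fast first-order dynamics (constriction time constant
#' of a few hundred ms, slower redilation), while cognitive load adds a slow
#' saturating dilation that builds over seconds and decays during rests.
#' On top of the deterministic signal sit hippus (a slow spontaneous
#' oscillation), white sensor noise per eye, Poisson-timed blinks recorded
#' as zero-diameter gaps in both eyes, and timestamp jitter around the
#' nominal frame rate.
#'
#' Luminance equilibria: dark shows the baseline diameter, bright shows
#' baseline minus the reflex amplitude, and the iso-luminant mid-gray sits
#' `iso_fraction` of the amplitude below baseline.
#'
#' @param baseline_dark_mm Dark-adapted pupil diameter, mm.
#' @param plr_amplitude_mm Dark-to-bright equilibrium difference, mm.
#' @param plr_latency_s Reflex latency between a luminance step and the
#'   onset of the diameter response, s.
#' @param constriction_tau_s Time constant of light-driven constriction, s.
#' @param redilation_tau_s Time constant of dark-driven redilation, s.
#' @param tepr_amplitude_mm Asymptotic task-evoked dilation under sustained
#'   high load, mm.
#' @param tepr_ramp_s Nominal rise time of the task-evoked dilation, s; the
#'   underlying first-order time constant is `tepr_ramp_s / 3` so the ramp
#'   is ~95% complete after `tepr_ramp_s`.
#' @param blink_rate_hz Mean blink rate (Poisson), blinks per second.
#' @param blink_duration_s Length-2 range (s); each blink's duration is
#'   drawn uniformly from it.
#' @param noise_sd_mm SD of independent white sensor noise per eye, mm.
#' @param hippus_amplitude_mm Amplitude of the hippus sinusoid, mm.
#' @param hippus_freq_hz Hippus frequency, Hz (must be < rate_hz / 2).
#' @param iso_fraction Position of the iso-luminant equilibrium between dark
#'   (0) and bright (1).
#' @param rate_hz Nominal sampling rate, Hz.
#' @param timestamp_jitter_s Half-width of uniform per-sample timestamp
#'   jitter, s; must stay below half the nominal frame interval so
#'   timestamps remain strictly increasing.
#' @param seed Integer RNG seed; every random element of the session is
#'   reproducible from it.
#' @return A list of class `simulation_params`.
#' @export
simulation_params <- function(baseline_dark_mm = 4.75,
                              plr_amplitude_mm = 1.5,
                              plr_latency_s = 0.25,
                              constriction_tau_s = 0.2,
                              redilation_tau_s = 0.6,
                              tepr_amplitude_mm = 0.4,
                              tepr_ramp_s = 2,
                              blink_rate_hz = 0.2,
                              blink_duration_s = c(0.1, 0.3),
                              noise_sd_mm = 0.02,
                              hippus_amplitude_mm = 0.05,
                              hippus_freq_hz = 0.15,
                              iso_fraction = 0.2,
                              rate_hz = 90,
                              timestamp_jitter_s = 0.001,
                              seed = 1L) {
  p <- list(baseline_dark_mm = baseline_dark_mm,
            plr_amplitude_mm = plr_amplitude_mm,
            plr_latency_s = plr_latency_s,
            constriction_tau_s = constriction_tau_s,
            redilation_tau_s = redilation_tau_s,
            tepr_amplitude_mm = tepr_amplitude_mm,
            tepr_ramp_s = tepr_ramp_s,
            blink_rate_hz = blink_rate_hz,
            blink_duration_s = blink_duration_s,
            noise_sd_mm = noise_sd_mm,
            hippus_amplitude_mm = hippus_amplitude_mm,
            hippus_freq_hz = hippus_freq_hz,
            iso_fraction = iso_fraction,
            rate_hz = rate_hz,
            timestamp_jitter_s = timestamp_jitter_s,
            seed = as.integer(seed))
  nonneg <- c("baseline_dark_mm", "plr_amplitude_mm", "plr_latency_s",
              "tepr_amplitude_mm", "blink_rate_hz", "noise_sd_mm",
              "hippus_amplitude_mm", "timestamp_jitter_s")
  for (nm in nonneg) {
    if (p[[nm]] < 0) stop(sprintf("%s must be >= 0", nm), call. = FALSE)
  }
  for (nm in c("constriction_tau_s", "redilation_tau_s", "tepr_ramp_s",
               "rate_hz", "hippus_freq_hz")) {
    if (p[[nm]] <= 0) stop(sprintf("%s must be > 0", nm), call. = FALSE)
  }
  if (p$rate_hz <= 2 * p$hippus_freq_hz) {
    stop("rate_hz must exceed twice the hippus frequency", call. = FALSE)
  }
  if (p$timestamp_jitter_s >= 0.5 / p$rate_hz) {
    stop("timestamp jitter must be below half the frame interval", call. = FALSE)
  }
  if (length(p$blink_duration_s) != 2L || any(p$blink_duration_s < 0) ||
      diff(p$blink_duration_s) < 0) {
    stop("blink_duration_s must be a non-decreasing length-2 range", call. = FALSE)
  }
  structure(p, class = "simulation_params")
}

# luminance-state equilibrium diameter for a given params set
.lum_target <- function(state, p) {
  switch(state,
         dark = p$baseline_dark_mm,
         bright = p$baseline_dark_mm - p$plr_amplitude_mm,
         iso = p$baseline_dark_mm - p$iso_fraction * p$plr_amplitude_mm,
         p$baseline_dark_mm)
}

#' Simulate one session with known ground truth
#'
#' Generates a binocular trace over the given protocol timeline. The
#' diameter follows first-order exponential tracking of the luminance-state
#' equilibrium (delayed by the reflex latency, with separate constriction
#' and redilation time constants), plus a task-evoked component that tracks
#' the high-load indicator with time constant `tepr_ramp_s / 3`, plus
#' hippus, per-eye Gaussian noise, and blink gaps where both eyes read
#' exactly zero. The trace is deterministic given `params$seed`.
#'
#' The returned ground truth carries the analytic targets the pipeline
#' should recover: the reflex amplitude; the peak constriction velocity of
#' the exponential model, `plr_amplitude_mm / constriction_tau_s` (its
#' value at bright onset, an upper bound for any filtered estimate); the
#' task-evoked high-minus-low mean difference computed from the noise-free
#' cognitive component; the analytic peak dilation velocity
#' `tepr_amplitude_mm / (tepr_ramp_s / 3)`; and the blink intervals drawn.
#'
#' @param params A [simulation_params()].
#' @param timeline A [build_timeline()] result.
#' @param session_id Identifier stored on the trace.
#' @return A list with elements `trace` (a [pupil_session()]) and `truth`.
#' @export
simulate_session <- function(params = simulation_params(),
                             timeline = build_timeline(),
                             session_id = sprintf("sim%04d", params$seed)) {
  stopifnot(inherits(params, "simulation_params"),
            inherits(timeline, "protocol_timeline"))
  p <- params
  set.seed(p$seed)
  total_s <- timeline$end_s[nrow(timeline)]
  n <- floor(total_s * p$rate_hz)
  t <- (seq_len(n) - 1L) / p$rate_hz
  if (p$timestamp_jitter_s > 0 && n > 1L) {
    jit <- stats::runif(n - 1L, -p$timestamp_jitter_s, p$timestamp_jitter_s)
    t[-1L] <- t[-1L] + jit
  }

  # luminance state seen by the iris: delayed by the reflex latency
  lab_delayed <- label_samples(timeline, pmax(t - p$plr_latency_s, 0))
  lum_state <- lab_delayed$luminance_state
  lum_state[is.na(lum_state)] <- "iso"
  targets <- vapply(c(dark = "dark", bright = "bright", iso = "iso"),
                    .lum_target, numeric(1), p = p)
  target <- targets[lum_state]

  lab_now <- label_samples(timeline, t)
  high_load <- !is.na(lab_now$load) & lab_now$load == "high"

  base <- numeric(n)
  s_tepr <- numeric(n)
  base[1L] <- .lum_target(lum_state[1L], p)
  tau_r <- p$tepr_ramp_s / 3
  for (i in 2:n) {
    dt <- t[i] - t[i - 1L]
    tau <- if (target[i] < base[i - 1L]) p$constriction_tau_s else p$redilation_tau_s
    base[i] <- target[i] + (base[i - 1L] - target[i]) * exp(-dt / tau)
    u <- if (high_load[i]) 1 else 0
    s_tepr[i] <- u + (s_tepr[i - 1L] - u) * exp(-dt / tau_r)
  }
  tepr <- p$tepr_amplitude_mm * s_tepr
  hippus_phase <- stats::runif(1, 0, 2 * pi)
  hippus <- p$hippus_amplitude_mm * sin(2 * pi * p$hippus_freq_hz * t + hippus_phase)
  clean <- base + tepr + hippus

  left <- clean + stats::rnorm(n, 0, p$noise_sd_mm)
  right <- clean + stats::rnorm(n, 0, p$noise_sd_mm)

  n_blinks <- stats::rpois(1, p$blink_rate_hz * total_s)
  blink_start <- sort(stats::runif(n_blinks, 0, total_s))
  blink_dur <- stats::runif(n_blinks, p$blink_duration_s[1L], p$blink_duration_s[2L])
  blink_end <- pmin(blink_start + blink_dur, total_s)
  open <- rep(1, n)
  for (b in seq_len(n_blinks)) {
    inside <- t >= blink_start[b] & t < blink_end[b]
    left[inside] <- 0
    right[inside] <- 0
    open[inside] <- 0
  }
  left <- pmin(pmax(left, 0), 11.999)
  right <- pmin(pmax(right, 0), 11.999)

  gaze <- cbind(stats::rnorm(n, 0.5, 0.02), stats::rnorm(n, 0.5, 0.02))

  trace <- pupil_session(t = t, left_mm = left, right_mm = right,
                         left_open = open, right_open = open,
                         gaze_x = gaze[, 1L], gaze_y = gaze[, 2L],
                         session_id = session_id,
                         nominal_rate_hz = p$rate_hz)

  low_mask <- !is.na(lab_now$load) & lab_now$load == "low"
  truth <- list(
    plr_amplitude_mm = p$plr_amplitude_mm,
    peak_constriction_velocity_mm_s = p$plr_amplitude_mm / p$constriction_tau_s,
    tepr_difference_mm = mean(tepr[high_load]) - mean(tepr[low_mask]),
    peak_dilation_velocity_mm_s = p$tepr_amplitude_mm / tau_r,
    blink_count = n_blinks,
    blink_intervals = if (n_blinks > 0)
      data.frame(start_s = blink_start, end_s = blink_end)
    else data.frame(start_s = numeric(0), end_s = numeric(0)),
    params = p
  )
  list(trace = trace, truth = truth)
}

#' Default cohort parameter ranges
#'
#' Uniform sampling ranges for the per-session physiological parameters,
#' calibrated so that a simulated cohort lands in the span reported for
#' healthy adults: dark baseline 3.75-6.80 mm, constriction fraction
#' 0.254-0.411 of baseline, and task-evoked dilation amplitudes of
#' 0.1-0.8 mm. Time constants default to the dissociation scenario
#' (constriction tau 0.2 s, dilation ramp 2 s).
#'
#' @return A list of length-2 numeric ranges and fixed values, consumed by
#'   [simulate_cohort()].
#' @export
cohort_ranges <- function() {
  list(baseline_dark_mm = c(3.75, 6.80),
       constriction_fraction = c(0.254, 0.411),
       tepr_amplitude_mm = c(0.1, 0.8),
       constriction_tau_s = 0.2,
       tepr_ramp_s = 2)
}

#' Simulate a cohort of sessions
#'
#' Session `i` uses seed `seed + i`; all of its parameter draws and its
#' trace derive from that seed alone, so a cohort is reproducible and
#' individual sessions can be regenerated independently of `n`.
#'
#' @param n Number of sessions (>= 1).
#' @param seed Master integer seed.
#' @param timeline A [build_timeline()] result shared by all sessions.
#' @param ranges Parameter ranges, see [cohort_ranges()].
#' @param ... Overrides passed to every session's [simulation_params()]
#'   (e.g. `noise_sd_mm = 0`).
#' @return A list of `n` elements, each a `list(trace, truth)` as returned
#'   by [simulate_session()].
#' @export
simulate_cohort <- function(n, seed = 1L, timeline = build_timeline(),
                            ranges = cohort_ranges(), ...) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  overrides <- list(...)
  lapply(seq_len(n), function(i) {
    si <- as.integer(seed) + i
    set.seed(si)
    draw <- function(r) if (length(r) == 2L) stats::runif(1, r[1L], r[2L]) else r
    baseline <- draw(ranges$baseline_dark_mm)
    frac <- draw(ranges$constriction_fraction)
    args <- list(baseline_dark_mm = baseline,
                 plr_amplitude_mm = frac * baseline,
                 tepr_amplitude_mm = draw(ranges$tepr_amplitude_mm),
                 constriction_tau_s = draw(ranges$constriction_tau_s),
                 tepr_ramp_s = draw(ranges$tepr_ramp_s),
                 seed = si)
    args[names(overrides)] <- overrides
    params <- do.call(simulation_params, args)
    simulate_session(params, timeline, session_id = sprintf("sim%04d", i))
  })
}
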