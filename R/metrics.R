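#' First derivative of a uniformly sampled trace
#'
#' Central differences at interior points, one-sided differences at the
#' edges; exact for affine signals. Units are mm/s when the input is a
#' diameter trace in mm on a grid in seconds.
#'
#' @param ft A `filtered_trace` (or any data frame `t`, `mm` on a uniform
#'   grid with >= 3 samples).
#' @return Numeric velocity series on the same grid.
#' @export
trace_velocity <- function(ft) {
  n <- nrow(ft)
  if (n < 3L) stop("need at least 3 samples for a derivative", call. = FALSE)
  dt <- ft$t[2L] - ft$t[1L]
  pracma::gradient(ft$mm, h1 = dt)
}

#' Pupillary light reflex metrics from the 4 Hz pathway
#'
#' Dark and bright means pool every Phase 1 sample labeled with the
#' respective luminance state (optionally skipping `settle_skip_s` after
#' each state onset). Amplitude is dark mean minus bright mean; constriction
#' percentage expresses it relative to the dark mean. Peak constriction
#' velocity is the largest magnitude of negative diameter velocity found
#' within `onset_window_s` after any dark-to-bright transition, reported as
#' a positive number.
#'
#' @param ft A `filtered_trace`, conventionally the 4 Hz (PLR) pathway.
#' @param timeline A [build_timeline()] result with Phase 1 intervals.
#' @param onset_window_s Velocity search window after each bright onset
#'   (default 1 s; the reflex completes within a few hundred ms).
#' @param settle_skip_s Time skipped after each state onset before samples
#'   enter the state means (default 0: whole states are pooled).
#' @return A list of class `plr_metrics`: `dark_mean_mm`, `bright_mean_mm`,
#'   `amplitude_mm`, `constriction_pct`, `peak_constriction_velocity_mm_s`.
#' @export
plr_metrics <- function(ft, timeline, onset_window_s = 1.0, settle_skip_s = 0) {
  lab <- label_samples(timeline, ft$t)
  in_plr <- lab$phase == "plr"
  if (!any(in_plr)) stop("missing-phase error: trace does not cover Phase 1", call. = FALSE)
  keep <- rep(TRUE, nrow(ft))
  if (settle_skip_s > 0) {
    starts <- timeline$start_s[timeline$phase == "plr"]
    for (s in starts) keep <- keep & !(ft$t >= s & ft$t < s + settle_skip_s)
  }
  dark <- in_plr & keep & lab$luminance_state == "dark"
  bright <- in_plr & keep & lab$luminance_state == "bright"
  if (!any(dark) || !any(bright)) {
    stop("missing-phase error: need samples in both dark and bright states", call. = FALSE)
  }
  dark_mean <- mean(ft$mm[dark])
  bright_mean <- mean(ft$mm[bright])
  amplitude <- dark_mean - bright_mean

  vel <- trace_velocity(ft)
  tr <- timeline_transitions(timeline)
  onsets <- tr$t[tr$from_lum == "dark" & tr$to_lum == "bright" &
                   tr$to_phase == "plr"]
  peak <- 0
  for (on in onsets) {
    w <- ft$t >= on & ft$t <= on + onset_window_s
    if (any(w)) peak <- max(peak, -min(vel[w]))
  }
  structure(list(dark_mean_mm = dark_mean,
                 bright_mean_mm = bright_mean,
                 amplitude_mm = amplitude,
                 constriction_pct = 100 * amplitude / dark_mean,
                 peak_constriction_velocity_mm_s = peak),
            class = "plr_metrics")
}

#' Cognitive-load metrics from the 0.5 Hz pathway
#'
#' Low- and high-load means pool every sample inside the respective task
#' blocks (rests and baseline excluded). The difference is high minus low;
#' percent change expresses it relative to the low-load mean. Peak dilation
#' velocity is the largest positive diameter velocity within
#' `onset_window_s` after any rest-to-high-load transition.
#'
#' @param ft A `filtered_trace`, conventionally the 0.5 Hz (cognitive)
#'   pathway.
#' @param timeline A [build_timeline()] result with Phase 3 intervals.
#' @param onset_window_s Velocity search window after each high-load onset
#'   (default 5 s; task-evoked dilation builds over seconds).
#' @param settle_skip_s Time skipped after each block onset before samples
#'   enter the condition means (default 0).
#' @return A list of class `cognitive_metrics`: `low_mean_mm`,
#'   `high_mean_mm`, `difference_mm`, `percent_change`,
#'   `peak_dilation_velocity_mm_s`.
#' @export
cognitive_metrics <- function(ft, timeline, onset_window_s = 5.0,
                              settle_skip_s = 0) {
  lab <- label_samples(timeline, ft$t)
  in_cog <- lab$phase == "cognitive"
  if (!any(in_cog)) stop("missing-phase error: trace does not cover Phase 3", call. = FALSE)
  keep <- rep(TRUE, nrow(ft))
  if (settle_skip_s > 0) {
    starts <- timeline$start_s[timeline$phase == "cognitive" &
                                 timeline$load %in% c("low", "high")]
    for (s in starts) keep <- keep & !(ft$t >= s & ft$t < s + settle_skip_s)
  }
  low <- in_cog & keep & lab$load == "low"
  high <- in_cog & keep & lab$load == "high"
  if (!any(low) || !any(high)) {
    stop("missing-condition error: need samples in both load conditions", call. = FALSE)
  }
  low_mean <- mean(ft$mm[low])
  high_mean <- mean(ft$mm[high])
  difference <- high_mean - low_mean

  vel <- trace_velocity(ft)
  tr <- timeline_transitions(timeline)
  onsets <- tr$t[tr$from_load == "rest" & tr$to_load == "high"]
  peak <- 0
  for (on in onsets) {
    w <- ft$t >= on & ft$t <= on + onset_window_s
    if (any(w)) peak <- max(peak, max(vel[w]))
  }
  structure(list(low_mean_mm = low_mean,
                 high_mean_mm = high_mean,
                 difference_mm = difference,
                 percent_change = 100 * difference / low_mean,
                 peak_dilation_velocity_mm_s = peak),
            class = "cognitive_metrics")
}

#' Velocity ratio: temporal dissociation statistic
#'
#' Peak PLR constriction velocity divided by peak cognitive dilation
#' velocity. The light reflex is a fast brainstem loop while task-evoked
#' dilation is a slow locus-coeruleus-mediated response, so ratios
#' substantially above 1 indicate that the cognitive signal is not a
#' residual light reflex.
#'
#' @param plr A [plr_metrics()] result.
#' @param cog A [cognitive_metrics()] result.
#' @return Dimensionless positive ratio.
#' @export
velocity_ratio <- function(plr, cog) {
  vc <- plr$peak_constriction_velocity_mm_s
  vd <- cog$peak_dilation_velocity_mm_s
  if (!is.finite(vd) || vd <= 0) {
    stop("undefined-ratio error: dilation velocity must be > 0", call. = FALSE)
  }
  if (!is.finite(vc) || vc <= 0) {
    stop("undefined-ratio error: constriction velocity must be > 0", call. = FALSE)
  }
  abs(vc) / abs(vd)
}

#' Analyze one session end to end
#'
#' Full per-session pipeline: preprocessing ([preprocess_session()]) and
#' metric extraction on the two pathway traces. Metrics are computed even
#' for sessions whose data loss exceeds the exclusion threshold; the
#' `excluded` flag records the QC decision for cohort-level filtering.
#'
#' @param trace A [pupil_session()].
#' @param timeline A [build_timeline()] result.
#' @param onset_window_plr_s,onset_window_cog_s Velocity search windows.
#' @param settle_skip_s Passed to both metric extractors.
#' @param ... Passed to [preprocess_session()].
#' @return A list of class `session_metrics`: `session_id`, `plr`,
#'   `cognitive`, `velocity_ratio`, `data_loss_fraction`, `excluded`, `qc`.
#' @export
analyze_session <- function(trace, timeline,
                            onset_window_plr_s = 1.0,
                            onset_window_cog_s = 5.0,
                            settle_skip_s = 0, ...) {
  prep <- preprocess_session(trace, ...)
  plr <- plr_metrics(prep$plr, timeline, onset_window_s = onset_window_plr_s,
                     settle_skip_s = settle_skip_s)
  cog <- cognitive_metrics(prep$cognitive, timeline,
                           onset_window_s = onset_window_cog_s,
                           settle_skip_s = settle_skip_s)
  structure(list(session_id = attr(trace, "session_id"),
                 plr = plr, cognitive = cog,
                 velocity_ratio = velocity_ratio(plr, cog),
                 data_loss_fraction = prep$data_loss_fraction,
                 excluded = prep$excluded,
                 qc = prep$qc),
            class = "session_metrics")
}

#' Write / read per-session metrics as JSON
#'
#' One flat JSON object per session, carrying all PLR and cognitive fields,
#' the velocity ratio, and the QC block.
#'
#' @param metrics A `session_metrics` object from [analyze_session()].
#' @param path File path.
#' @return `write_metrics()` returns `path` invisibly; `read_metrics()`
#'   returns a `session_metrics` object.
#' @export
write_metrics <- function(metrics, path) {
  stopifnot(inherits(metrics, "session_metrics"))
  out <- list(session_id = metrics$session_id,
              plr = unclass(metrics$plr),
              cognitive = unclass(metrics$cognitive),
              velocity_ratio = metrics$velocity_ratio,
              data_loss_fraction = metrics$data_loss_fraction,
              excluded = metrics$excluded,
              qc = metrics$qc)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(session_id = raw$session_id,
                 plr = structure(as.list(raw$plr), class = "plr_metrics"),
                 cognitive = structure(as.list(raw$cognitive),
                                       class = "cognitive_metrics"),
                 velocity_ratio = raw$velocity_ratio,
                 data_loss_fraction = raw$data_loss_fraction,
                 excluded = raw$excluded,
                 qc = raw$qc),
            class = "session_metrics")
}
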