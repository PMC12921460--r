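#' Protocol configuration for the three-phase iso-luminant paradigm
#'
#' The default configuration encodes the standard session: Phase 1 alternates
#' the whole visual field between a dark gray (RGB 20) and a bright gray
#' (RGB 180) for three 10 s + 10 s cycles to probe the pupillary light
#' reflex; Phase 2 holds an iso-luminant mid-gray (RGB 90) for a 60 s washout
#' whose final 10 s are labeled as the luminance-adapted baseline; Phase 3
#' presents four 45 s auditory task blocks in an ABBA order
#' (low, high, high, low) separated by 15 s rests, all at the unchanged
#' mid-gray.
#'
#' With `leading_rest = TRUE` (default) a 15 s rest also precedes the first
#' block, so Phase 3 totals 240 s: four blocks and three separating rests
#' alone would give 225 s, and the extra leading rest both settles the pupil
#' after the baseline and matches the 240 s phase budget.
#'
#' Gray levels are single-channel 0-255 proxies for relative luminance (the
#' stimuli are achromatic and no photometric calibration is assumed).
#'
#' @param plr_cycles Number of dark/bright cycles in Phase 1 (>= 1).
#' @param plr_state_s Duration of each luminance state in Phase 1, seconds.
#' @param washout_s Total Phase 2 duration, seconds.
#' @param baseline_s Length of the final Phase 2 window labeled `baseline`;
#'   must not exceed `washout_s`.
#' @param block_s Task block duration, seconds.
#' @param rest_s Rest interval duration, seconds.
#' @param block_order Character vector of `"low"` / `"high"` block labels.
#' @param gray_levels Named numeric vector with entries `dark`, `bright`,
#'   `iso` (0-255).
#' @param leading_rest Insert a rest before the first task block?
#' @param plr_start First Phase 1 state, `"dark"` (default) or `"bright"`.
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(plr_cycles = 3, plr_state_s = 10,
                            washout_s = 60, baseline_s = 10,
                            block_s = 45, rest_s = 15,
                            block_order = c("low", "high", "high", "low"),
                            gray_levels = c(dark = 20, bright = 180, iso = 90),
                            leading_rest = TRUE,
                            plr_start = c("dark", "bright")) {
  plr_start <- match.arg(plr_start)
  if (plr_cycles < 1) stop("config error: plr_cycles must be >= 1", call. = FALSE)
  for (nm in c("plr_state_s", "washout_s", "block_s", "rest_s")) {
    if (get(nm) <= 0) stop(sprintf("config error: %s must be > 0", nm), call. = FALSE)
  }
  if (baseline_s < 0 || baseline_s > washout_s) {
    stop("config error: baseline_s must lie in [0, washout_s]", call. = FALSE)
  }
  if (!all(c("dark", "bright", "iso") %in% names(gray_levels))) {
    stop("config error: gray_levels needs entries dark, bright, iso", call. = FALSE)
  }
  if (!all(block_order %in% c("low", "high"))) {
    stop("config error: block_order entries must be 'low' or 'high'", call. = FALSE)
  }
  structure(list(plr_cycles = as.integer(plr_cycles),
                 plr_state_s = plr_state_s,
                 washout_s = washout_s, baseline_s = baseline_s,
                 block_s = block_s, rest_s = rest_s,
                 block_order = block_order,
                 gray_levels = gray_levels,
                 leading_rest = isTRUE(leading_rest),
                 plr_start = plr_start),
            class = "protocol_config")
}

#' Build the labeled protocol timeline
#'
#' Expands a [protocol_config()] into an ordered table of contiguous,
#' non-overlapping, half-open intervals `[start_s, end_s)`, each carrying a
#' phase label (`plr`, `washout`, `baseline`, `cognitive`), a luminance state
#' (`dark`, `bright`, `iso`), a load condition (`none`, `low`, `high`,
#' `rest`) and the gray-level proxy displayed during the interval.
#'
#' @param config A [protocol_config()]; defaults to the standard session.
#' @return A data frame of class `protocol_timeline` with columns `start_s`,
#'   `end_s`, `phase`, `luminance_state`, `load`, `gray_level`.
#' @export
build_timeline <- function(config = protocol_config()) {
  stopifnot(inherits(config, "protocol_config"))
  g <- config$gray_levels
  rows <- list()
  cursor <- 0
  add <- function(dur, phase, lum, load) {
    rows[[length(rows) + 1L]] <<- data.frame(
      start_s = cursor, end_s = cursor + dur, phase = phase,
      luminance_state = lum, load = load,
      gray_level = unname(g[[lum]]), stringsAsFactors = FALSE)
    cursor <<- cursor + dur
  }
  states <- if (config$plr_start == "dark") c("dark", "bright") else c("bright", "dark")
  for (cycle in seq_len(config$plr_cycles)) {
    for (st in states) add(config$plr_state_s, "plr", st, "none")
  }
  washout_only <- config$washout_s - config$baseline_s
  if (washout_only > 0) add(washout_only, "washout", "iso", "none")
  if (config$baseline_s > 0) add(config$baseline_s, "baseline", "iso", "none")
  if (config$leading_rest) add(config$rest_s, "cognitive", "iso", "rest")
  for (i in seq_along(config$block_order)) {
    if (i > 1L) add(config$rest_s, "cognitive", "iso", "rest")
    add(config$block_s, "cognitive", "iso", config$block_order[i])
  }
  tl <- do.call(rbind, rows)
  structure(tl, config = config, class = c("protocol_timeline", "data.frame"))
}

#' @export
print.protocol_timeline <- function(x, ...) {
  cat(sprintf("<protocol_timeline: %d intervals, %.0f s total>\n",
              nrow(x), x$end_s[nrow(x)]))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Label sample times by protocol interval
#'
#' Maps each time to the half-open interval `[start_s, end_s)` containing it;
#' a time sitting exactly on a boundary belongs to the interval it starts.
#' Times outside the session (negative, or at/after the session end) get
#' phase `"outside"` with `NA` state, load, and gray level.
#'
#' @param timeline A [build_timeline()] result.
#' @param times Numeric vector of times in seconds.
#' @return A data frame with one row per time: `t`, `phase`,
#'   `luminance_state`, `load`, `gray_level`.
#' @export
label_samples <- function(timeline, times) {
  stopifnot(inherits(timeline, "protocol_timeline"))
  idx <- findInterval(times, timeline$start_s)
  total_end <- timeline$end_s[nrow(timeline)]
  outside <- idx == 0L | times >= total_end | is.na(times)
  idx[outside] <- NA_integer_
  data.frame(
    t = times,
    phase = ifelse(outside, "outside", timeline$phase[idx]),
    luminance_state = ifelse(outside, NA_character_, timeline$luminance_state[idx]),
    load = ifelse(outside, NA_character_, timeline$load[idx]),
    gray_level = ifelse(outside, NA_real_, timeline$gray_level[idx]),
    stringsAsFactors = FALSE
  )
}

#' Gray-level stimulus trace at given times
#'
#' @param timeline A [build_timeline()] result.
#' @param times Numeric vector of times in seconds.
#' @return Numeric vector of gray levels (0-255 proxy), `NA` outside the
#'   session.
#' @export
luminance_trace <- function(timeline, times) {
  label_samples(timeline, times)$gray_level
}

#' Interval-to-interval transitions in a timeline
#'
#' Returns the boundary times between consecutive intervals together with
#' the labels on both sides; used to locate luminance-step onsets (PLR
#' velocity) and rest-to-high-load onsets (cognitive dilation velocity).
#'
#' @param timeline A [build_timeline()] result.
#' @return A data frame with columns `t`, `from_phase`, `to_phase`,
#'   `from_lum`, `to_lum`, `from_load`, `to_load`.
#' @export
timeline_transitions <- function(timeline) {
  stopifnot(inherits(timeline, "protocol_timeline"))
  n <- nrow(timeline)
  if (n < 2L) {
    return(data.frame(t = numeric(0), from_phase = character(0),
                      to_phase = character(0), from_lum = character(0),
                      to_lum = character(0), from_load = character(0),
                      to_load = character(0), stringsAsFactors = FALSE))
  }
  i <- seq_len(n - 1L)
  data.frame(
    t = timeline$end_s[i],
    from_phase = timeline$phase[i],     to_phase = timeline$phase[i + 1L],
    from_lum = timeline$luminance_state[i], to_lum = timeline$luminance_state[i + 1L],
    from_load = timeline$load[i],       to_load = timeline$load[i + 1L],
    stringsAsFactors = FALSE
  )
}

#' Write / read a protocol configuration as JSON
#'
#' @param config A [protocol_config()].
#' @param path File path.
#' @return `write_protocol_config()` returns `path` invisibly;
#'   `read_protocol_config()` returns a [protocol_config()].
#' @export
write_protocol_config <- function(config, path) {
  stopifnot(inherits(config, "protocol_config"))
  out <- unclass(config)
  out$gray_levels <- as.list(out$gray_levels)  # keep names in JSON
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol_config
#' @export
read_protocol_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  protocol_config(
    plr_cycles = raw$plr_cycles, plr_state_s = raw$plr_state_s,
    washout_s = raw$washout_s, baseline_s = raw$baseline_s,
    block_s = raw$block_s, rest_s = raw$rest_s,
    block_order = raw$block_order,
    gray_levels = unlist(raw$gray_levels),
    leading_rest = raw$leading_rest, plr_start = raw$plr_start
  )
}
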