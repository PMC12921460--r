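#' Detect pupil-diameter artifacts
#'
#' Two rules, applied to the raw (unfiltered) diameter series:
#' \describe{
#'   \item{zero}{a sample whose diameter is missing or within `zero_tol` of
#'     zero (eye trackers report exact zeros during blinks and tracking
#'     dropouts);}
#'   \item{velocity}{both endpoints of any consecutive sample pair whose
#'     inter-sample rate of change exceeds `velocity_limit` in magnitude —
#'     physiologically impossible diameter jumps.}
#' }
#' Missing diameters are treated as zeros for both rules, so the edges of a
#' blink gap also trip the velocity rule. The mask records one reason per
#' sample (`zero` takes precedence over `velocity` where both apply) and the
#' per-rule flags separately.
#'
#' @param t Timestamps in seconds, strictly increasing, length >= 2.
#' @param mm Diameter series (mm), same length; `NA` = missing.
#' @param velocity_limit Maximum plausible |d(diameter)/dt| in mm/s.
#' @param zero_tol Absolute tolerance for the zero rule, mm.
#' @return An `artifact_mask`: data frame with logical `flag`, character
#'   `reason` (`"zero"`, `"velocity"`, `"dilation"`, `"none"`), and the raw
#'   per-rule flags `zero_rule`, `velocity_rule`.
#' @export
detect_artifacts <- function(t, mm, velocity_limit = 10, zero_tol = 1e-6) {
  n <- length(t)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(mm) != n) stop("t and mm must have equal length", call. = FALSE)
  if (anyNA(t) || any(diff(t) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  v <- ifelse(is.na(mm), 0, mm)
  zero_rule <- abs(v) <= zero_tol

  vel <- diff(v) / diff(t)
  hot <- abs(vel) > velocity_limit
  velocity_rule <- logical(n)
  velocity_rule[which(hot)] <- TRUE
  velocity_rule[which(hot) + 1L] <- TRUE

  flag <- zero_rule | velocity_rule
  reason <- rep("none", n)
  reason[velocity_rule] <- "velocity"
  reason[zero_rule] <- "zero"
  structure(data.frame(flag = flag, reason = reason,
                       zero_rule = zero_rule, velocity_rule = velocity_rule,
                       stringsAsFactors = FALSE),
            class = c("artifact_mask", "data.frame"))
}

#' Dilate an artifact mask in time
#'
#' Marks every unflagged sample lying within `radius_s` (inclusive) of a
#' flagged sample, tagging the additions with reason `"dilation"`. The
#' radius is measured in seconds, not samples, because acquisition jitters
#' around the nominal rate. Original reasons are preserved.
#'
#' @param mask An `artifact_mask` from [detect_artifacts()].
#' @param t Timestamps aligned with the mask.
#' @param radius_s Dilation radius in seconds (default 0.050).
#' @return The dilated `artifact_mask`.
#' @export
dilate_mask <- function(mask, t, radius_s = 0.050) {
  stopifnot(inherits(mask, "artifact_mask"))
  if (length(t) != nrow(mask)) stop("mask and t must align", call. = FALSE)
  if (radius_s < 0) stop("config error: radius_s must be >= 0", call. = FALSE)
  flagged_t <- t[mask$flag]
  if (length(flagged_t) == 0L || radius_s == 0) return(mask)
  # distance to the nearest flagged timestamp, via sorted binary search
  idx <- findInterval(t, flagged_t)
  d_left <- ifelse(idx >= 1L, t - flagged_t[pmax(idx, 1L)], Inf)
  d_right <- ifelse(idx < length(flagged_t),
                    flagged_t[pmin(idx + 1L, length(flagged_t))] - t, Inf)
  new_flag <- mask$flag | pmin(d_left, d_right) <= radius_s
  added <- new_flag & !mask$flag
  mask$flag <- new_flag
  mask$reason[added] <- "dilation"
  mask
}

#' Replace flagged samples by linear interpolation
#'
#' Flagged samples are replaced by linear interpolation in time between the
#' nearest unflagged neighbors; flagged runs at the trace edges are filled
#' with the nearest valid value. Unflagged samples are returned bit-identical.
#'
#' @param t Timestamps (seconds).
#' @param mm Diameter series (mm).
#' @param mask An `artifact_mask` aligned with the series.
#' @return The cleaned diameter series.
#' @export
interpolate_artifacts <- function(t, mm, mask) {
  stopifnot(inherits(mask, "artifact_mask"))
  n <- length(mm)
  if (length(t) != n || nrow(mask) != n) stop("series and mask must align", call. = FALSE)
  good <- !mask$flag
  if (!any(good)) {
    stop("unrecoverable trace: every sample is flagged as artifact", call. = FALSE)
  }
  if (all(good)) return(mm)
  out <- mm
  if (sum(good) == 1L) {
    out[!good] <- mm[good]
  } else {
    out[!good] <- stats::approx(t[good], mm[good], xout = t[!good],
                                method = "linear", rule = 2)$y
  }
  out
}

#' Fraction of samples lost to artifacts
#'
#' @param mask An `artifact_mask`.
#' @return Flagged count / total, in `[0, 1]`.
#' @export
data_loss_fraction <- function(mask) {
  stopifnot(inherits(mask, "artifact_mask"))
  if (nrow(mask) == 0L) stop("empty mask", call. = FALSE)
  mean(mask$flag)
}

#' Session exclusion decision
#'
#' A session is excluded when its data-loss fraction strictly exceeds the
#' threshold (default 15%), the criterion that accommodates natural blink
#' rates while guarding parameter estimation.
#'
#' @param loss_fraction Value from [data_loss_fraction()].
#' @param threshold Exclusion threshold (default 0.15).
#' @return Logical.
#' @export
session_excluded <- function(loss_fraction, threshold = 0.15) {
  loss_fraction > threshold
}

#' Resample a cleaned series onto a uniform grid
#'
#' Linear interpolation onto `t[1] + k / rate_hz`, spanning the original
#' time range. Fixed-coefficient digital filtering requires uniform
#' sampling; acquisition is only approximately uniform.
#'
#' @param t Timestamps (seconds), strictly increasing.
#' @param mm Cleaned diameter series (no missing values).
#' @param rate_hz Target rate in Hz.
#' @return A data frame `t`, `mm` with attribute `rate_hz`.
#' @export
resample_uniform <- function(t, mm, rate_hz) {
  if (rate_hz <= 0) stop("config error: rate_hz must be > 0", call. = FALSE)
  if (anyNA(mm)) stop("resample_uniform requires a cleaned series", call. = FALSE)
  grid <- t[1L] + seq(0, floor((t[length(t)] - t[1L]) * rate_hz)) / rate_hz
  y <- stats::approx(t, mm, xout = grid, method = "linear", rule = 2)$y
  structure(data.frame(t = grid, mm = y), rate_hz = rate_hz)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass forward and backward
#' (zero-phase), so filtered extrema keep their timing — a requirement for
#' comparing constriction and dilation velocities across pathways. The
#' series is extended by odd reflection at both ends before filtering to
#' suppress edge transients, then trimmed.
#'
#' The two canonical pathways are 4 Hz (`"plr"`: preserves rapid reflexive
#' dynamics) and 0.5 Hz (`"cognitive"`: isolates sustained trends from
#' saccadic noise).
#'
#' @param series Uniform series from [resample_uniform()] (or a data frame
#'   `t`, `mm` with attribute `rate_hz`).
#' @param cutoff_hz Low-pass cutoff in Hz; must be below the Nyquist rate.
#' @param order Filter order per pass (default 4).
#' @param pathway Label stored on the result, e.g. `"plr"` or `"cognitive"`.
#' @return A `filtered_trace`: data frame `t`, `mm` with attributes
#'   `rate_hz`, `cutoff_hz`, `pathway`.
#' @export
lowpass <- function(series, cutoff_hz, order = 4, pathway = NA_character_) {
  rate_hz <- attr(series, "rate_hz")
  if (is.null(rate_hz)) stop("series must carry a rate_hz attribute", call. = FALSE)
  if (cutoff_hz >= rate_hz / 2) {
    stop("config error: cutoff_hz must be below the Nyquist rate", call. = FALSE)
  }
  if (cutoff_hz <= 0 || order < 1) stop("config error: bad filter settings", call. = FALSE)
  x <- series$mm
  n <- length(x)
  if (n <= 3 * (order + 1)) {
    stop("series shorter than the filter warm-up length", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff_hz / (rate_hz / 2), type = "low")
  pad <- min(n - 1L, max(3L * (order + 1L), ceiling(3 * rate_hz / cutoff_hz)))
  front <- 2 * x[1L] - x[(pad + 1L):2L]
  back <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(front, x, back)
  # forward-backward passes; anchoring each pass at its first value keeps the
  # zero-state transient proportional to the local signal variation (and makes
  # the DC response exact), with the reflection pads absorbing what remains
  one_pass <- function(v) {
    as.numeric(signal::filter(bf, v - v[1L])) + v[1L]
  }
  y <- rev(one_pass(rev(one_pass(xp))))
  y <- y[(pad + 1L):(pad + n)]
  structure(data.frame(t = series$t, mm = y),
            rate_hz = rate_hz, cutoff_hz = cutoff_hz, pathway = pathway,
            class = c("filtered_trace", "data.frame"))
}

#' Full preprocessing of one session
#'
#' Runs the canonical chain on a binocular trace: reduce to one diameter
#' series, detect artifacts (velocity and zero rules), dilate the mask by
#' `dilate_s`, compute the post-dilation data-loss fraction and the
#' exclusion decision, interpolate flagged samples, resample to a uniform
#' grid, and produce the two pathway traces by zero-phase low-pass
#' filtering.
#'
#' @param trace A [pupil_session()].
#' @param eye Binocular reduction passed to [combine_eyes()].
#' @param velocity_limit,zero_tol Artifact rules, see [detect_artifacts()].
#' @param dilate_s Mask dilation radius in seconds.
#' @param loss_threshold Exclusion threshold on the data-loss fraction.
#' @param rate_hz Uniform resampling rate; defaults to the trace's nominal
#'   rate.
#' @param cutoffs Named numeric vector of pathway cutoffs in Hz.
#' @param order Butterworth order per pass.
#' @return A list with elements `plr` and `cognitive` (`filtered_trace`s),
#'   `uniform` (unfiltered uniform series), `mask`, `data_loss_fraction`,
#'   `excluded`, and `qc` (counts by artifact reason plus the thresholds
#'   applied).
#' @export
preprocess_session <- function(trace, eye = "mean",
                               velocity_limit = 10, zero_tol = 1e-6,
                               dilate_s = 0.050, loss_threshold = 0.15,
                               rate_hz = NULL,
                               cutoffs = c(plr = 4, cognitive = 0.5),
                               order = 4) {
  mono <- combine_eyes(trace, eye = eye)
  if (is.null(rate_hz)) rate_hz <- attr(trace, "nominal_rate_hz")
  mask <- detect_artifacts(mono$t, mono$mm, velocity_limit = velocity_limit,
                           zero_tol = zero_tol)
  mask <- dilate_mask(mask, mono$t, radius_s = dilate_s)
  loss <- data_loss_fraction(mask)
  cleaned <- interpolate_artifacts(mono$t, mono$mm, mask)
  uniform <- resample_uniform(mono$t, cleaned, rate_hz = rate_hz)
  list(
    plr = lowpass(uniform, cutoffs[["plr"]], order = order, pathway = "plr"),
    cognitive = lowpass(uniform, cutoffs[["cognitive"]], order = order,
                        pathway = "cognitive"),
    uniform = uniform,
    mask = mask,
    data_loss_fraction = loss,
    excluded = session_excluded(loss, loss_threshold),
    qc = list(
      n_samples = nrow(mask),
      n_zero = sum(mask$reason == "zero"),
      n_velocity = sum(mask$reason == "velocity"),
      n_dilation = sum(mask$reason == "dilation"),
      data_loss_fraction = loss,
      excluded = session_excluded(loss, loss_threshold),
      velocity_limit = velocity_limit, dilate_s = dilate_s,
      loss_threshold = loss_threshold, rate_hz = rate_hz,
      filter_order = order, cutoffs = as.list(cutoffs)
    )
  )
}
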