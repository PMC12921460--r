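#' Construct a pupillometry session trace
#'
#' A `pupil_session` holds one recording: timestamped binocular pupil
#' diameters with eye-openness and gaze fields, plus a session identifier and
#' the nominal sampling rate. Timestamps are seconds from session start and
#' must be strictly increasing.
#'
#' Zero diameters are legitimate values here, not missing data: eye trackers
#' emit exact zeros during blinks, and the artifact detector consumes them
#' downstream. Missingness is encoded as `NA`.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing,
#'   first value >= 0.
#' @param left_mm,right_mm Pupil diameters in mm (`NA` = missing; 0 allowed,
#'   positive values must be < 12 mm).
#' @param left_open,right_open Eye openness fractions in `[0, 1]` or `NA`.
#' @param gaze_x,gaze_y Normalized gaze coordinates or `NA`.
#' @param session_id Character identifier for the session.
#' @param nominal_rate_hz Nominal sampling rate in Hz; estimated from the
#'   median inter-sample interval when `NULL`.
#' @return An object of class `pupil_session`: a data frame with columns
#'   `t`, `left_mm`, `right_mm`, `left_open`, `right_open`, `gaze_x`,
#'   `gaze_y` and attributes `session_id`, `nominal_rate_hz`.
#' @export
pupil_session <- function(t, left_mm, right_mm,
                          left_open = NA_real_, right_open = NA_real_,
                          gaze_x = NA_real_, gaze_y = NA_real_,
                          session_id = "session", nominal_rate_hz = NULL) {
  n <- length(t)
  if (n < 2L) {
    stop("empty-trace error: a session needs at least 2 samples", call. = FALSE)
  }
  if (anyNA(t) || any(diff(t) <= 0) || t[1L] < 0) {
    stop("timestamps must be non-negative and strictly increasing", call. = FALSE)
  }
  df <- data.frame(
    t          = as.numeric(t),
    left_mm    = rep_len(as.numeric(left_mm), n),
    right_mm   = rep_len(as.numeric(right_mm), n),
    left_open  = rep_len(as.numeric(left_open), n),
    right_open = rep_len(as.numeric(right_open), n),
    gaze_x     = rep_len(as.numeric(gaze_x), n),
    gaze_y     = rep_len(as.numeric(gaze_y), n)
  )
  for (col in c("left_mm", "right_mm")) {
    v <- df[[col]]
    bad <- !is.na(v) & (v < 0 | v >= 12)
    if (any(bad)) {
      stop(sprintf("%s outside [0, 12) mm at %d sample(s)", col, sum(bad)),
           call. = FALSE)
    }
  }
  for (col in c("left_open", "right_open")) {
    v <- df[[col]]
    bad <- !is.na(v) & (v < 0 | v > 1)
    if (any(bad)) {
      stop(sprintf("%s outside [0, 1] at %d sample(s)", col, sum(bad)),
           call. = FALSE)
    }
  }
  if (is.null(nominal_rate_hz)) {
    nominal_rate_hz <- 1 / stats::median(diff(df$t))
  }
  if (!is.numeric(nominal_rate_hz) || nominal_rate_hz <= 0) {
    stop("nominal_rate_hz must be > 0", call. = FALSE)
  }
  structure(df,
            session_id = as.character(session_id),
            nominal_rate_hz = as.numeric(nominal_rate_hz),
            class = c("pupil_session", "data.frame"))
}

#' @export
print.pupil_session <- function(x, ...) {
  cat(sprintf("<pupil_session '%s': %d samples, %.1f s, ~%.1f Hz>\n",
              attr(x, "session_id"), nrow(x), x$t[nrow(x)] - x$t[1L],
              attr(x, "nominal_rate_hz")))
  invisible(x)
}

# canonical CSV header, shared by reader and writer
.session_columns <- c("t_s", "left_mm", "right_mm", "left_open", "right_open",
                      "gaze_x", "gaze_y")

#' Read a session trace from CSV
#'
#' Expects the canonical header `t_s,left_mm,right_mm,left_open,right_open,
#' gaze_x,gaze_y` (UTF-8, '.' decimal separator). Vendor exports with other
#' column names are accommodated through `column_map`. Rows whose timestamp
#' does not strictly increase are dropped, with the count reported via
#' [message()].
#'
#' @param path Path to a CSV file.
#' @param column_map Optional named character vector mapping canonical names
#'   (see above) to the file's column names, e.g.
#'   `c(t_s = "timestamp", left_mm = "pupil_L")`. Unmapped canonical columns
#'   keep their own name.
#' @param time_unit `"s"` (default) or `"ms"`; timestamps are converted to
#'   seconds and re-zeroed to the first sample.
#' @param session_id Session identifier; defaults to the file name.
#' @return A [pupil_session()].
#' @export
read_session <- function(path, column_map = NULL, time_unit = c("s", "ms"),
                         session_id = NULL) {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  wanted <- stats::setNames(.session_columns, .session_columns)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), .session_columns)
    if (length(bad)) {
      stop("unknown canonical column(s) in column_map: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    wanted[names(column_map)] <- column_map
  }
  required <- wanted[c("t_s", "left_mm", "right_mm")]
  missing_cols <- required[!required %in% names(raw)]
  if (length(missing_cols)) {
    stop("format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  get_col <- function(canon) {
    if (wanted[[canon]] %in% names(raw)) as.numeric(raw[[wanted[[canon]]]])
    else rep(NA_real_, nrow(raw))
  }
  t <- get_col("t_s")
  if (time_unit == "ms") t <- t / 1000
  t <- t - t[1L]
  # strict increase: drop any row not above the running maximum so far
  keep <- rep(TRUE, length(t))
  running <- -Inf
  for (i in seq_along(t)) {
    if (is.na(t[i]) || t[i] <= running) keep[i] <- FALSE else running <- t[i]
  }
  dropped <- sum(!keep)
  if (dropped > 0L) {
    message(sprintf("read_session: dropped %d row(s) with non-increasing timestamps",
                    dropped))
  }
  if (sum(keep) < 2L) {
    stop("empty-trace error: fewer than 2 usable rows", call. = FALSE)
  }
  if (is.null(session_id)) session_id <- sub("\\.[^.]*$", "", basename(path))
  pupil_session(
    t          = t[keep],
    left_mm    = get_col("left_mm")[keep],
    right_mm   = get_col("right_mm")[keep],
    left_open  = get_col("left_open")[keep],
    right_open = get_col("right_open")[keep],
    gaze_x     = get_col("gaze_x")[keep],
    gaze_y     = get_col("gaze_y")[keep],
    session_id = session_id
  )
}

#' Write a session trace to CSV
#'
#' Writes the canonical header; missing values are serialized as empty cells
#' so that [read_session()] inverts the operation.
#'
#' @param trace A [pupil_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(trace, path) {
  stopifnot(inherits(trace, "pupil_session"))
  out <- as.data.frame(trace)
  names(out) <- .session_columns
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) {
    stop(sprintf("I/O error writing %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(path)
}

#' Reduce binocular samples to a single diameter series
#'
#' Per sample, the diameter is the mean of the eyes that carry a value; if
#' only one eye is present that eye is used, and if both are missing the
#' result is missing. The reduction is symmetric in the two eyes. Zeros are
#' ordinary values here (blink dropouts), left for the artifact detector.
#'
#' @param trace A [pupil_session()].
#' @param eye `"mean"` (default), `"left"`, or `"right"`.
#' @return A data frame with columns `t` (s) and `mm`.
#' @export
combine_eyes <- function(trace, eye = c("mean", "left", "right")) {
  stopifnot(inherits(trace, "pupil_session"))
  eye <- match.arg(eye)
  mm <- switch(eye,
    left  = trace$left_mm,
    right = trace$right_mm,
    mean  = {
      l <- trace$left_mm
      r <- trace$right_mm
      out <- rowMeans(cbind(l, r), na.rm = TRUE)
      out[is.na(l) & is.na(r)] <- NA_real_
      out
    })
  data.frame(t = trace$t, mm = mm)
}
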