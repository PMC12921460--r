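#' One-sample t test
#'
#' Classical one-sample t statistic `t = (mean - mu0) / (sd / sqrt(n))` with
#' `df = n - 1` and a two-sided p value. The summary-input variant
#' [one_sample_t_summary()] computes the same statistic from a reported
#' mean, SD and n (useful for checking published tables).
#'
#' @param x Numeric vector of per-session values (n >= 2).
#' @param mu0 Null value.
#' @return A list `t`, `df`, `p`, `mean`, `sd`, `n`.
#' @export
one_sample_t <- function(x, mu0 = 0) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) stop("need n >= 2", call. = FALSE)
  one_sample_t_summary(mean(x), stats::sd(x), n, mu0 = mu0)
}

#' @rdname one_sample_t
#' @param m Sample mean.
#' @param s Sample standard deviation (n - 1 denominator), > 0.
#' @param n Sample size.
#' @export
one_sample_t_summary <- function(m, s, n, mu0 = 0) {
  if (!is.finite(s) || s <= 0) {
    stop("degenerate-data error: sd must be > 0", call. = FALSE)
  }
  tval <- (m - mu0) / (s / sqrt(n))
  df <- n - 1
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df = df),
       mean = m, sd = s, n = n)
}

#' One-sample Cohen's d
#'
#' Standardized mean difference `d = (mean - mu0) / sd`.
#'
#' @param x Numeric vector of values.
#' @param mu0 Null value.
#' @return Numeric d.
#' @export
cohens_d_one_sample <- function(x, mu0 = 0) {
  x <- x[!is.na(x)]
  cohens_d_summary(mean(x), stats::sd(x), mu0 = mu0)
}

#' @rdname cohens_d_one_sample
#' @param m Sample mean.
#' @param s Sample standard deviation, > 0.
#' @export
cohens_d_summary <- function(m, s, mu0 = 0) {
  if (!is.finite(s) || s <= 0) {
    stop("degenerate-data error: sd must be > 0", call. = FALSE)
  }
  (m - mu0) / s
}

#' Wilcoxon signed-rank test, normal approximation
#'
#' Ranks `|x - mu0|` (average ranks on ties, zeros dropped), sums the ranks
#' of positive differences into `W`, and standardizes against the null mean
#' `n(n+1)/4` and variance `n(n+1)(2n+1)/24`. No continuity correction by
#' default; `correct = TRUE` subtracts 0.5 from `|W - mean|`. The default
#' alternative `"greater"` suits directional hypotheses such as a velocity
#' ratio exceeding 1.
#'
#' For n up to ~12 an exact p can be obtained by enumerating all sign
#' patterns; the normal approximation here is the large-sample route and is
#' validated against that enumeration in the test suite.
#'
#' @param x Numeric vector of per-session values.
#' @param mu0 Null location (default 1, the no-dissociation value for a
#'   velocity ratio).
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`.
#' @param correct Apply the continuity correction?
#' @return A list `w` (positive-rank sum), `z`, `p`, `n` (after dropping
#'   zeros).
#' @export
wilcoxon_signed_rank <- function(x, mu0 = 1,
                                 alternative = c("greater", "less", "two.sided"),
                                 correct = FALSE) {
  alternative <- match.arg(alternative)
  d <- x[!is.na(x)] - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) stop("degenerate-data error: all values equal mu0", call. = FALSE)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu_w <- n * (n + 1) / 4
  sigma_w <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  dev <- w - mu_w
  if (correct) dev <- sign(dev) * max(abs(dev) - 0.5, 0)
  z <- dev / sigma_w
  p <- switch(alternative,
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z),
              two.sided = 2 * stats::pnorm(-abs(z)))
  list(w = w, z = z, p = p, n = n)
}

# metric extractors for cohort_summary: name, accessor, test spec
.cohort_metrics <- list(
  list(name = "plr_amplitude_mm", get = function(m) m$plr$amplitude_mm,
       test = "t", mu0 = 0),
  list(name = "constriction_pct", get = function(m) m$plr$constriction_pct,
       test = "none"),
  list(name = "peak_constriction_velocity_mm_s",
       get = function(m) m$plr$peak_constriction_velocity_mm_s, test = "none"),
  list(name = "cognitive_difference_mm",
       get = function(m) m$cognitive$difference_mm, test = "t", mu0 = 0),
  list(name = "percent_change", get = function(m) m$cognitive$percent_change,
       test = "none"),
  list(name = "peak_dilation_velocity_mm_s",
       get = function(m) m$cognitive$peak_dilation_velocity_mm_s, test = "none"),
  list(name = "velocity_ratio", get = function(m) m$velocity_ratio,
       test = "wilcoxon", mu0 = 1)
)

#' Cohort-level summary and statistical validation
#'
#' Drops sessions flagged as excluded, then tabulates per metric the n,
#' mean, SD (n - 1 denominator), and range, and runs the validation tests:
#' one-sample t against 0 (with Cohen's d) for PLR amplitude and cognitive
#' difference, and a one-sided Wilcoxon signed-rank against 1 for the
#' velocity ratio. Degenerate metrics (zero variance) get `NA` statistics
#' with `test = "degenerate"`.
#'
#' @param metrics_list A list of `session_metrics` objects.
#' @param correct Continuity correction for the Wilcoxon z.
#' @return A data frame of class `cohort_summary`, one row per metric:
#'   `metric`, `n`, `mean`, `sd`, `min`, `max`, `test`, `statistic`, `df`,
#'   `p`, `effect_size_d`.
#' @export
cohort_summary <- function(metrics_list, correct = FALSE) {
  stopifnot(is.list(metrics_list))
  usable <- Filter(function(m) !isTRUE(m$excluded), metrics_list)
  if (length(usable) < 2L) {
    stop("insufficient-data error: need >= 2 non-excluded sessions", call. = FALSE)
  }
  rows <- lapply(.cohort_metrics, function(spec) {
    vals <- vapply(usable, spec$get, numeric(1))
    vals <- vals[!is.na(vals)]
    row <- data.frame(metric = spec$name, n = length(vals),
                      mean = mean(vals), sd = stats::sd(vals),
                      min = min(vals), max = max(vals),
                      test = NA_character_, statistic = NA_real_,
                      df = NA_real_, p = NA_real_, effect_size_d = NA_real_,
                      stringsAsFactors = FALSE)
    degenerate <- !is.finite(row$sd) || row$sd <= 0
    if (spec$test == "t") {
      if (degenerate) {
        row$test <- "degenerate"
      } else {
        tt <- one_sample_t(vals, mu0 = spec$mu0)
        row$test <- "one_sample_t"
        row$statistic <- tt$t; row$df <- tt$df; row$p <- tt$p
        row$effect_size_d <- cohens_d_one_sample(vals, mu0 = spec$mu0)
      }
    } else if (spec$test == "wilcoxon") {
      if (all(vals == spec$mu0)) {
        row$test <- "degenerate"
      } else {
        ws <- wilcoxon_signed_rank(vals, mu0 = spec$mu0,
                                   alternative = "greater", correct = correct)
        row$test <- "wilcoxon_signed_rank"
        row$statistic <- ws$z; row$p <- ws$p
      }
    }
    row
  })
  structure(do.call(rbind, rows), class = c("cohort_summary", "data.frame"))
}

#' Format a cohort summary as a validation table
#'
#' Reshapes [cohort_summary()] output into the conventional publication
#' layout: Metric, Mean (SD), Range, Test Statistic, P-value, Effect Size.
#'
#' @param summary A `cohort_summary`.
#' @param digits Rounding for the formatted columns.
#' @return A character data frame.
#' @export
cohort_table <- function(summary, digits = 2) {
  stopifnot(inherits(summary, "cohort_summary"))
  fmt <- function(x) formatC(x, format = "f", digits = digits)
  stat_str <- ifelse(
    summary$test %in% "one_sample_t",
    sprintf("t(%d)=%s", as.integer(summary$df), fmt(summary$statistic)),
    ifelse(summary$test %in% "wilcoxon_signed_rank",
           sprintf("Z=%s", fmt(summary$statistic)), ""))
  data.frame(
    Metric = summary$metric,
    `Mean (SD)` = sprintf("%s (%s)", fmt(summary$mean), fmt(summary$sd)),
    Range = sprintf("%s-%s", fmt(summary$min), fmt(summary$max)),
    `Test Statistic` = stat_str,
    `P-value` = ifelse(is.na(summary$p), "",
                       formatC(summary$p, format = "g", digits = 3)),
    `Effect Size` = ifelse(is.na(summary$effect_size_d), "",
                           fmt(summary$effect_size_d)),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}
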