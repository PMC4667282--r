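#' Set the series origin to zero
#'
#' Subtracts the first sample from every sample, so the series starts at 0
#' exactly. Idempotent.
#'
#' @param s a [temperature_series()].
#' @return A [temperature_series()] with `values[1] == 0`.
#' @export
zero_origin <- function(s) {
  stopifnot(inherits(s, "temperature_series"))
  out <- s
  out$values <- s$values - s$values[1]
  out$values[1] <- 0
  out
}

#' Remove a linear trend by ordinary least squares
#'
#' Ocular-surface recordings cool steadily through evaporation; pooling raw
#' series would stitch these ramps into a spurious sawtooth
#' (pseudo-periodicity). Each series is therefore detrended separately,
#' before pooling: an ordinary least-squares line over the integer time
#' index `0 .. n-1` is removed and the residuals kept.
#'
#' @param s a [temperature_series()] of length >= 3.
#' @return An object of class `detrended_series` with fields `values`
#'   (residuals, mean zero), `slope`, `intercept`, and the parent's
#'   provenance labels (`frame_rate_hz`, `subject_id`, `region`, `group`).
#' @export
detrend_linear <- function(s) {
  stopifnot(inherits(s, "temperature_series"))
  y <- s$values
  n <- length(y)
  if (n < 3L)
    tn_stop("thermonet_insufficient_data", "detrending needs >= 3 samples, got %d", n)
  t <- seq_len(n) - 1
  # closed-form simple regression; cheap enough for the per-series hot loop
  tb <- mean(t); yb <- mean(y)
  slope <- sum((t - tb) * (y - yb)) / sum((t - tb)^2)
  intercept <- yb - slope * tb
  structure(
    list(values = y - (intercept + slope * t), slope = slope,
         intercept = intercept, frame_rate_hz = s$frame_rate_hz,
         subject_id = s$subject_id, region = s$region, group = s$group),
    class = "detrended_series"
  )
}

#' @export
print.detrended_series <- function(x, ...) {
  cat(sprintf("<detrended_series> n=%d slope=%.4g intercept=%.4g subject=%s region=%s\n",
              length(x$values), x$slope, x$intercept, x$subject_id, x$region))
  invisible(x)
}

#' Normalize residual amplitude
#'
#' Divides the residuals by their mean absolute value, bringing every series
#' to a fixed amplitude baseline (mean |residual| = 1) so subjects with
#' different fluctuation scales pool on equal footing. (Least-squares
#' residuals have mean ~0, so the signed mean is not a usable scale; the
#' mean absolute residual is the amplitude analogue.)
#'
#' @param d a `detrended_series` from [detrend_linear()].
#' @return A `detrended_series` whose residuals have mean absolute value 1.
#' @export
normalize_amplitude <- function(d) {
  stopifnot(inherits(d, "detrended_series"))
  scale <- mean(abs(d$values))
  if (scale == 0)
    tn_stop("thermonet_degenerate_input", "all-zero residuals cannot be amplitude-normalized")
  d$values <- d$values / scale
  d
}

#' Prepare one raw series for pooling
#'
#' Convenience wrapper: [zero_origin()], then [detrend_linear()], then
#' [normalize_amplitude()].
#'
#' @param s a [temperature_series()].
#' @return A normalized `detrended_series`.
#' @export
prep_series <- function(s) normalize_amplitude(detrend_linear(zero_origin(s)))

#' Pool prepared series into one cohort series
#'
#' Concatenates normalized residual series in the given order into a single
#' series — the unit that is mapped to a transition network — recording each
#' segment's 1-based start index and provenance so segments can be recovered
#' exactly and so transitions bridging unrelated subjects can be excluded
#' downstream.
#'
#' @param series_list list of normalized `detrended_series` (order is
#'   preserved; it defines segment order).
#' @param group cohort label for the pooled series.
#' @return An object of class `pooled_series` with fields `values`,
#'   `boundaries` (1-based segment starts, `boundaries[1] == 1`),
#'   `segment_meta` (data.frame: subject_id, region, length) and `group`.
#' @export
pool_series <- function(series_list, group = "") {
  if (!is.list(series_list) || length(series_list) == 0L)
    tn_stop("thermonet_parameter_error", "series_list must hold at least one detrended series")
  ok <- vapply(series_list, inherits, logical(1), "detrended_series")
  if (!all(ok))
    tn_stop("thermonet_parameter_error", "all pooled elements must be detrended series")
  lens <- vapply(series_list, function(d) length(d$values), integer(1))
  structure(
    list(
      values = unlist(lapply(series_list, `[[`, "values"), use.names = FALSE),
      boundaries = cumsum(c(1L, lens[-length(lens)])),
      segment_meta = data.frame(
        subject_id = vapply(series_list, `[[`, character(1), "subject_id"),
        region = vapply(series_list, `[[`, character(1), "region"),
        length = lens,
        stringsAsFactors = FALSE
      ),
      group = as.character(group)
    ),
    class = "pooled_series"
  )
}

#' @export
print.pooled_series <- function(x, ...) {
  cat(sprintf("<pooled_series> %d samples in %d segment(s), group=%s\n",
              length(x$values), length(x$boundaries), x$group))
  invisible(x)
}

#' Recover one segment of a pooled series
#'
#' @param p a [pool_series()] result.
#' @param i segment index.
#' @return Numeric vector of that segment's values.
#' @export
pooled_segment <- function(p, i) {
  stopifnot(inherits(p, "pooled_series"))
  if (i < 1 || i > length(p$boundaries))
    tn_stop("thermonet_parameter_error", "no segment %d", i)
  start <- p$boundaries[i]
  end <- if (i < length(p$boundaries)) p$boundaries[i + 1] - 1L else length(p$values)
  p$values[start:end]
}
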