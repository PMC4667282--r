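#' Scalar temperature series
#'
#' The instantaneous temperature of a region of interest: one scalar per
#' frame, with provenance labels carried through the whole pipeline.
#'
#' @param values numeric vector of length >= 2, finite.
#' @param frame_rate_hz sampling rate in frames per second.
#' @param subject_id,region,group provenance labels. `region` is one of
#'   `"eye_left"`, `"eye_right"`, `"cheek"`, `"other"`.
#' @return An object of class `temperature_series`.
#' @export
temperature_series <- function(values, frame_rate_hz = 9, subject_id = "",
                               region = c("other", "eye_left", "eye_right", "cheek"),
                               group = "") {
  region <- match.arg(region)
  values <- as.numeric(values)
  if (length(values) < 2L)
    tn_stop("thermonet_insufficient_data", "series needs >= 2 samples, got %d", length(values))
  if (!all(is.finite(values)))
    tn_stop("thermonet_format_error", "series values must be finite")
  structure(
    list(values = values, frame_rate_hz = as.numeric(frame_rate_hz),
         subject_id = as.character(subject_id), region = region,
         group = as.character(group)),
    class = "temperature_series"
  )
}

#' @export
print.temperature_series <- function(x, ...) {
  cat(sprintf("<temperature_series> n=%d @ %g Hz  subject=%s region=%s group=%s\n",
              length(x$values), x$frame_rate_hz, x$subject_id, x$region, x$group))
  invisible(x)
}

#' @export
length.temperature_series <- function(x) length(x$values)

#' Reduce each frame to its spatial mean intensity
#'
#' The preferred frame-to-scalar reduction: the arithmetic mean over all
#' pixels of the (cropped) frame is taken as the instantaneous temperature of
#' the region. It is cheap, hardware-friendly, and — for spatially coherent
#' signal plus independent pixel noise — carries the same temporal
#' information as the leading principal component (see
#' [compare_reduction()]).
#'
#' @param stack a [frame_stack()].
#' @param subject_id,region,group labels stored on the output series.
#' @return A [temperature_series()] of length `T`.
#' @export
mean_series <- function(stack, subject_id = "", region = "other", group = "") {
  stopifnot(inherits(stack, "frame_stack"))
  v <- apply(stack$frames, 1, mean)
  temperature_series(v, frame_rate_hz = stack$frame_rate_hz,
                     subject_id = subject_id, region = region, group = group)
}

#' Principal-component reduction of a frame stack
#'
#' Treats frames as observations and pixels as variables (the orientation
#' that yields one score per frame, i.e. a time series comparable with
#' [mean_series()]). Pixels are centered; scores of the top `k` components
#' are returned together with their explained-variance fractions. Each
#' component's sign is fixed so that its score series correlates
#' non-negatively with the mean-pixel series (PCA signs are otherwise
#' arbitrary).
#'
#' @param stack a [frame_stack()].
#' @param k number of components, `1 <= k <= min(T, H*W)`.
#' @return An object of class `pca_result` with fields `component_series`
#'   (`T x k` matrix of per-frame scores) and `explained_fraction` (length
#'   `k`, non-increasing; over all possible components the fractions sum
#'   to 1).
#' @export
pca_series <- function(stack, k = 3) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$frames)
  n <- d[1]; npix <- d[2] * d[3]
  if (k < 1 || k > min(n, npix))
    tn_stop("thermonet_parameter_error", "k must lie in 1..min(T, H*W) = %d", min(n, npix))
  x <- matrix(stack$frames, nrow = n)  # T x (H*W), pixels as columns
  x <- scale(x, center = TRUE, scale = FALSE)
  total_var <- sum(x^2) / (n - 1)
  if (total_var <= 0)
    tn_stop("thermonet_degenerate_input", "temporally constant stack has zero variance")
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  navail <- ncol(pc$x)
  if (k > navail)
    tn_stop("thermonet_parameter_error", "only %d components available for this stack", navail)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  frac <- (pc$sdev[seq_len(k)]^2) / total_var
  m <- rowMeans(matrix(stack$frames, nrow = n))
  for (j in seq_len(k)) {
    if (stats::sd(scores[, j]) > 0 && stats::sd(m) > 0 &&
        stats::cor(scores[, j], m) < 0) scores[, j] <- -scores[, j]
  }
  structure(list(component_series = scores, explained_fraction = frac,
                 n_possible = navail, total_variance = total_var),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d component(s), explained fractions: %s\n",
              ncol(x$component_series),
              paste(sprintf("%.3f", x$explained_fraction), collapse = ", ")))
  invisible(x)
}

#' Correlate the mean-pixel series with the leading principal component
#'
#' Quantifies whether the cheap spatial-mean reduction preserves the same
#' temporal signal as the leading principal component. Under the sign
#' convention of [pca_series()] a value near 1 means PCA can be safely
#' skipped.
#'
#' @param mean_s a [temperature_series()] from [mean_series()].
#' @param pca a `pca_result` from [pca_series()] on the same stack.
#' @return Pearson correlation between the mean series and the component-1
#'   score series, in `[-1, 1]`.
#' @export
compare_reduction <- function(mean_s, pca) {
  stopifnot(inherits(mean_s, "temperature_series"), inherits(pca, "pca_result"))
  a <- mean_s$values
  b <- pca$component_series[, 1]
  if (length(a) != length(b))
    tn_stop("thermonet_parameter_error", "series lengths differ: %d vs %d", length(a), length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    tn_stop("thermonet_degenerate_input", "zero variance input; correlation undefined")
  stats::cor(a, b)
}
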