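#' Fit the edge-betweenness cutoff from two labeled training networks
#'
#' Pathological cohorts produce transition networks whose betweenness
#' distributions extend to larger values than healthy ones: rare large
#' inter-quantile jumps create bridge edges that carry a disproportionate
#' share of shortest paths. Any betweenness value strictly between the two
#' training maxima therefore separates the cohorts; the midpoint is chosen
#' as it maximizes the symmetric margin. Fitting fails with a no-separation
#' error when the control maximum is not below the case maximum — the
#' cohorts are then not distinguishable by this statistic.
#'
#' @param control `ebc_table` of the pooled control (healthy) network.
#' @param case `ebc_table` of the pooled case (pathological) network.
#' @param q_used the quantile count the networks were built with (metadata).
#' @return An object of class `cutoff_model` with fields `cutoff`,
#'   `train_control_max`, `train_case_max`, `q_used`, `normalized`.
#' @export
fit_cutoff <- function(control, case, q_used = 20L) {
  stopifnot(inherits(control, "ebc_table"), inherits(case, "ebc_table"))
  if (nrow(control) == 0L || nrow(case) == 0L)
    tn_stop("thermonet_empty_table", "both training tables must be nonempty")
  if (!identical(attr(control, "normalized"), attr(case, "normalized")))
    tn_stop("thermonet_parameter_error", "training tables differ in normalization")
  lo <- max(control$bc)
  hi <- max(case$bc)
  if (lo >= hi)
    tn_stop("thermonet_no_separation",
            "control max betweenness (%.4g) is not below case max (%.4g)", lo, hi)
  structure(list(cutoff = (lo + hi) / 2, train_control_max = lo,
                 train_case_max = hi, q_used = as.integer(q_used),
                 normalized = attr(control, "normalized")),
            class = "cutoff_model")
}

#' @export
print.cutoff_model <- function(x, ...) {
  cat(sprintf("<cutoff_model> cutoff=%.4g (control max %.4g < case max %.4g), Q=%d, normalized=%s\n",
              x$cutoff, x$train_control_max, x$train_case_max, x$q_used, x$normalized))
  invisible(x)
}

#' Maximum edge betweenness over sliding length-matched windows
#'
#' Edge density of a quantile transition network grows with series length:
#' longer series populate more of the `Q * (Q - 1)` possible transitions,
#' shortening geodesics and deflating every edge's betweenness. Betweenness
#' values are therefore only comparable between networks built from
#' equal-length series. This helper slides a window of the evaluation
#' length along a pooled cohort series and returns the maximum (normalized)
#' edge betweenness of the network built from each window, respecting
#' segment boundaries within the window.
#'
#' @param p a [pool_series()] result.
#' @param window window length in samples (e.g. 540 for the pooled
#'   4 x 135-sample evaluation protocol).
#' @param stride step between window starts (default 135, one recording).
#' @param Q quantile count.
#' @param normalized see [edge_betweenness()].
#' @return Numeric vector of per-window maximum edge betweenness values.
#' @export
window_max_ebc <- function(p, window, stride = 135L, Q = 20,
                           normalized = TRUE) {
  stopifnot(inherits(p, "pooled_series"))
  n <- length(p$values)
  if (window > n)
    tn_stop("thermonet_parameter_error", "window (%d) exceeds series length (%d)", window, n)
  starts <- seq.int(1L, n - window + 1L, by = stride)
  vapply(starts, function(s) {
    idx <- s:(s + window - 1L)
    inner <- p$boundaries[p$boundaries > s & p$boundaries <= s + window - 1L]
    w <- structure(
      list(values = p$values[idx],
           boundaries = c(1L, inner - s + 1L),
           segment_meta = NULL, group = p$group),
      class = "pooled_series"
    )
    max(edge_betweenness(series_to_network(w, Q = Q), normalized = normalized)$bc)
  }, numeric(1))
}

#' Fit a length-matched cutoff from pooled training cohorts
#'
#' Variant of [fit_cutoff()] for classifying subjects whose evaluation
#' series is much shorter than the pooled training series. Each class is
#' summarized by the median of [window_max_ebc()] over windows of the
#' evaluation length, so the training statistic lives on the same
#' density scale as the held-out subjects' networks; the cutoff is the
#' midpoint of the two class medians.
#'
#' @param control_pooled,case_pooled [pool_series()] results for the two
#'   training cohorts.
#' @param window evaluation-protocol length in samples (default 540).
#' @param stride window stride (default 135).
#' @param Q quantile count.
#' @param normalized see [edge_betweenness()].
#' @return A `cutoff_model` whose `train_control_max`/`train_case_max` hold
#'   the class median window statistics.
#' @export
fit_cutoff_matched <- function(control_pooled, case_pooled, window = 540L,
                               stride = 135L, Q = 20, normalized = TRUE) {
  lo <- stats::median(window_max_ebc(control_pooled, window, stride, Q, normalized))
  hi <- stats::median(window_max_ebc(case_pooled, window, stride, Q, normalized))
  if (lo >= hi)
    tn_stop("thermonet_no_separation",
            "control median window max (%.4g) is not below case median (%.4g)", lo, hi)
  structure(list(cutoff = (lo + hi) / 2, train_control_max = lo,
                 train_case_max = hi, q_used = as.integer(Q),
                 normalized = normalized),
            class = "cutoff_model")
}

#' Classify a subject against a fitted cutoff
#'
#' A subject is labeled `case` when the maximum edge betweenness of their
#' own pooled network strictly exceeds the cutoff — equivalently, when their
#' cumulative betweenness curve has not yet reached 1 at the cutoff. A
#' subject sitting exactly on the cutoff is labeled `control` (strict
#' crossing required).
#'
#' @param subject `ebc_table` of the subject's network.
#' @param model a [fit_cutoff()] result with matching normalization.
#' @param subject_id label carried into the result.
#' @return An object of class `classification_result` with fields
#'   `subject_id`, `max_ebc`, `label` (`"case"` or `"control"`), `cutoff`
#'   and `margin = max_ebc - cutoff`.
#' @export
classify_subject <- function(subject, model, subject_id = "") {
  stopifnot(inherits(subject, "ebc_table"), inherits(model, "cutoff_model"))
  if (!identical(attr(subject, "normalized"), model$normalized))
    tn_stop("thermonet_parameter_error", "subject normalization does not match the model")
  m <- max(subject$bc)
  structure(list(subject_id = as.character(subject_id), max_ebc = m,
                 label = if (m > model$cutoff) "case" else "control",
                 cutoff = model$cutoff, margin = m - model$cutoff),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification> %s: %s (max bc %.4g vs cutoff %.4g, margin %+.4g)\n",
              x$subject_id, x$label, x$max_ebc, x$cutoff, x$margin))
  invisible(x)
}

#' Kolmogorov-Smirnov distance between cumulative betweenness curves
#'
#' The supremum over the betweenness axis of the absolute difference of the
#' two empirical cumulative distributions, evaluated over the merged step
#' grid. A distance-like separation measure in `[0, 1]`: 0 for identical
#' curves, 1 for disjoint supports.
#'
#' @param a,b [cumulative_curve()] objects.
#' @return Scalar distance in `[0, 1]`.
#' @export
curve_distance <- function(a, b) {
  stopifnot(inherits(a, "cumulative_curve"), inherits(b, "cumulative_curve"))
  grid <- sort(unique(c(a$x, b$x)))
  fa <- step_eval(a, grid)
  fb <- step_eval(b, grid)
  max(abs(fa - fb))
}

# right-continuous step evaluation: F(x) = f at the largest step <= x, 0 before
step_eval <- function(curve, x) {
  i <- findInterval(x, curve$x)
  c(0, curve$f)[i + 1]
}

#' Compare betweenness curves of two facial regions
#'
#' Named entry point for the eye-versus-cheek analysis: in healthy subjects
#' the two regions fluctuate differently and their curves separate, while
#' pathology-style coupled dynamics pull them together. Delegates to
#' [curve_distance()].
#'
#' @param eye,cheek [cumulative_curve()] objects for the two regions.
#' @return Scalar distance in `[0, 1]`.
#' @export
region_compare <- function(eye, cheek) curve_distance(eye, cheek)

#' Serialize / deserialize a cutoff model
#'
#' Flat `key=value` text format for reuse between fitting and
#' classification runs.
#'
#' @param model a `cutoff_model`.
#' @param path file path.
#' @return `path` (writer, invisibly) or a `cutoff_model` (reader).
#' @export
write_cutoff_model <- function(model, path) {
  stopifnot(inherits(model, "cutoff_model"))
  writeLines(c(
    sprintf("cutoff=%.17g", model$cutoff),
    sprintf("train_control_max=%.17g", model$train_control_max),
    sprintf("train_case_max=%.17g", model$train_case_max),
    sprintf("q_used=%d", model$q_used),
    sprintf("normalized=%s", model$normalized)
  ), path)
  invisible(path)
}

#' @rdname write_cutoff_model
#' @export
read_cutoff_model <- function(path) {
  kv <- readLines(path, warn = FALSE)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  vals <- stats::setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
  structure(list(cutoff = as.numeric(vals[["cutoff"]]),
                 train_control_max = as.numeric(vals[["train_control_max"]]),
                 train_case_max = as.numeric(vals[["train_case_max"]]),
                 q_used = as.integer(vals[["q_used"]]),
                 normalized = as.logical(vals[["normalized"]])),
            class = "cutoff_model")
}
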