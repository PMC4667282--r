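#' Write a temperature series to CSV
#'
#' Two columns `t,value` with a `#`-comment header carrying the
#' subject/region/group/frame-rate metadata, so series files are
#' self-describing and round-trip through [read_series_csv()].
#'
#' @param s a [temperature_series()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(s, path) {
  stopifnot(inherits(s, "temperature_series"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# subject_id=%s", s$subject_id),
    sprintf("# region=%s", s$region),
    sprintf("# group=%s", s$group),
    sprintf("# frame_rate_hz=%.17g", s$frame_rate_hz),
    "t,value"
  ), con)
  writeLines(sprintf("%d,%.17g", seq_along(s$values) - 1L, s$values), con)
  invisible(path)
}

#' Read a temperature series from CSV
#'
#' @param path a file written by [write_series_csv()] (or any 2-column
#'   `t,value` CSV; missing metadata default to empty labels at 9 Hz).
#' @return A [temperature_series()].
#' @export
read_series_csv <- function(path) {
  meta <- parse_comment_header(path)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("t", "value") %in% names(df)))
    tn_stop("thermonet_format_error", "series CSV needs columns t,value: %s", path)
  temperature_series(
    df$value[order(df$t)],
    frame_rate_hz = as.numeric(meta_or(meta, "frame_rate_hz", "9")),
    subject_id = meta_or(meta, "subject_id", ""),
    region = meta_or(meta, "region", "other"),
    group = meta_or(meta, "group", "")
  )
}

parse_comment_header <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[startsWith(lines, "#")]
  kv <- sub("^#\\s*", "", lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

meta_or <- function(meta, key, default) {
  if (!is.null(meta[[key]]) && nzchar(meta[[key]])) meta[[key]] else default
}

#' Write a pooled series to CSV
#'
#' Single `t,value` table with `#` headers recording the group, segment
#' boundaries and per-segment subject/region metadata.
#'
#' @param p a [pool_series()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pooled_csv <- function(p, path) {
  stopifnot(inherits(p, "pooled_series"))
  con <- file(path, "w")
  on.exit(close(con))
  segs <- apply(p$segment_meta, 1, function(r) paste(r[["subject_id"]], r[["region"]], sep = ":"))
  writeLines(c(
    sprintf("# group=%s", p$group),
    sprintf("# boundaries=%s", paste(p$boundaries, collapse = ",")),
    sprintf("# segments=%s", paste(segs, collapse = ";")),
    "t,value"
  ), con)
  writeLines(sprintf("%d,%.17g", seq_along(p$values) - 1L, p$values), con)
  invisible(path)
}

#' Read a pooled series from CSV
#'
#' @param path a file written by [write_pooled_csv()].
#' @return A `pooled_series`.
#' @export
read_pooled_csv <- function(path) {
  meta <- parse_comment_header(path)
  df <- utils::read.csv(path, comment.char = "#")
  values <- df$value[order(df$t)]
  boundaries <- as.integer(strsplit(meta_or(meta, "boundaries", "1"), ",")[[1]])
  segs <- strsplit(meta_or(meta, "segments", ":other"), ";")[[1]]
  parts <- strsplit(segs, ":", fixed = TRUE)
  lens <- diff(c(boundaries, length(values) + 1L))
  structure(
    list(values = values, boundaries = boundaries,
         segment_meta = data.frame(
           subject_id = vapply(parts, function(x) x[1], character(1)),
           region = vapply(parts, function(x) if (length(x) > 1) x[2] else "other", character(1)),
           length = lens, stringsAsFactors = FALSE),
         group = meta_or(meta, "group", "")),
    class = "pooled_series"
  )
}

#' Read a cohort manifest
#'
#' A manifest maps series files to their provenance: columns `file`,
#' `subject_id`, `region`, `group`. Relative `file` paths are resolved
#' against the manifest's own directory.
#'
#' @param path manifest CSV.
#' @return data.frame with columns file, subject_id, region, group.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("file", "subject_id", "region", "group")
  if (!all(need %in% names(df)))
    tn_stop("thermonet_format_error", "manifest needs columns %s", paste(need, collapse = ","))
  rel <- !grepl("^(/|[A-Za-z]:)", df$file)
  df$file[rel] <- file.path(dirname(path), df$file[rel])
  df[need]
}
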