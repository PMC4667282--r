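#' Equiprobable quantile partition of a pooled series
#'
#' Splits the value axis into `Q` equiprobable bins by rank: the sample with
#' 0-based rank `r` (ties broken stably by time index) is assigned bin
#' `floor(r * Q / N) + 1`, so bin occupancies differ by at most one sample
#' even in the presence of ties. Rank-based assignment also makes the
#' downstream network invariant under any strictly monotone transform of the
#' values. Interpolation-based quantile cut points were rejected as
#' tie-fragile.
#'
#' @param p a [pool_series()] result (or any object with a numeric `values`
#'   field).
#' @param Q number of bins; default 20 gives networks with a workable number
#'   of nodes and edges while keeping bins well-populated.
#' @return An object of class `quantile_partition` with fields `Q`, `n`, and
#'   `assignment` (bin index in `1..Q` per sample, in time order).
#' @export
quantile_partition <- function(p, Q = 20) {
  values <- pooled_values(p)
  n <- length(values)
  Q <- as.integer(Q)
  if (Q < 2L)
    tn_stop("thermonet_parameter_error", "Q must be >= 2")
  if (n < Q)
    tn_stop("thermonet_degenerate_partition", "need at least Q=%d samples, got %d", Q, n)
  if (length(unique(values)) < Q)
    tn_stop("thermonet_degenerate_partition",
            "need at least Q=%d distinct values, got %d", Q, length(unique(values)))
  ord <- order(values, seq_len(n))   # stable: ties broken by time index
  bins <- integer(n)
  bins[ord] <- floor((seq_len(n) - 1) * Q / n) + 1L
  structure(list(Q = Q, n = n, assignment = bins), class = "quantile_partition")
}

pooled_values <- function(p) {
  if (inherits(p, "pooled_series")) p$values
  else if (is.numeric(p)) p
  else if (is.list(p) && is.numeric(p$values)) p$values
  else tn_stop("thermonet_parameter_error", "cannot extract values from input")
}

#' Symbolize a pooled series by quantile bin
#'
#' @param p the [pool_series()] result the partition was built from.
#' @param part a [quantile_partition()] built from `p`.
#' @return An object of class `symbol_sequence` with fields `symbols` (bin
#'   index per sample), `Q`, and `boundaries` carried through from `p`.
#' @export
assign_quantiles <- function(p, part) {
  stopifnot(inherits(part, "quantile_partition"))
  values <- pooled_values(p)
  if (length(values) != part$n)
    tn_stop("thermonet_parameter_error", "partition was built from a different series (n mismatch)")
  boundaries <- if (inherits(p, "pooled_series")) p$boundaries else 1L
  group <- if (inherits(p, "pooled_series")) p$group else ""
  structure(list(symbols = part$assignment, Q = part$Q,
                 boundaries = boundaries, group = group),
            class = "symbol_sequence")
}

#' Map a symbol sequence to a directed transition network
#'
#' Nodes are occupied quantile bins (temperature ranges); a directed edge
#' `(i, j)` records that at least one consecutive sample pair moved from bin
#' `i` to bin `j`. Edges are unweighted: the diagnostic signal is which
#' transitions occur, not how often. Self-transitions are recorded
#' separately and excluded from the metric graph by default (betweenness is
#' unaffected by self-loops). Consecutive pairs spanning a pooling boundary
#' connect unrelated subjects and are excluded unless `cross_boundaries`.
#'
#' @param sym a [assign_quantiles()] result.
#' @param cross_boundaries also count transitions across segment boundaries
#'   (default `FALSE`).
#' @param keep_self_loops keep `(i, i)` transitions in the edge set rather
#'   than only in `self_loops` (default `FALSE`).
#' @return An object of class `transition_network` with fields `Q`, `nodes`
#'   (sorted occupied bins), `edges` (2-column matrix from,to; no
#'   duplicates), `self_loops` (2-column matrix), and `provenance`.
#' @export
build_transition_network <- function(sym, cross_boundaries = FALSE,
                                     keep_self_loops = FALSE) {
  stopifnot(inherits(sym, "symbol_sequence"))
  s <- sym$symbols
  n <- length(s)
  from <- s[-n]
  to <- s[-1]
  if (!cross_boundaries) {
    # pair (t, t+1) spans a boundary iff t+1 starts a new segment
    starts <- sym$boundaries[sym$boundaries > 1L]
    keep <- !((seq_len(n - 1) + 1L) %in% starts)
    from <- from[keep]; to <- to[keep]
  }
  pairs <- unique(cbind(from = from, to = to))
  loops <- pairs[pairs[, 1] == pairs[, 2], , drop = FALSE]
  if (!keep_self_loops) pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  structure(
    list(Q = sym$Q, nodes = sort(unique(s)), edges = pairs,
         self_loops = loops, provenance = sym$group),
    class = "transition_network"
  )
}

#' @export
print.transition_network <- function(x, ...) {
  cat(sprintf("<transition_network> Q=%d: %d node(s), %d edge(s), %d self-loop(s)%s\n",
              x$Q, length(x$nodes), nrow(x$edges), nrow(x$self_loops),
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' Convenience: pooled series straight to transition network
#'
#' Chains [quantile_partition()], [assign_quantiles()] and
#' [build_transition_network()].
#'
#' @inheritParams quantile_partition
#' @inheritParams build_transition_network
#' @return A `transition_network`.
#' @export
series_to_network <- function(p, Q = 20, cross_boundaries = FALSE,
                              keep_self_loops = FALSE) {
  part <- quantile_partition(p, Q)
  build_transition_network(assign_quantiles(p, part),
                           cross_boundaries = cross_boundaries,
                           keep_self_loops = keep_self_loops)
}

#' Convert a transition network to an igraph graph
#'
#' Nodes carry their quantile index as the vertex name; graph attributes
#' record `Q` and the provenance label. Self-loops are not included.
#'
#' @param net a `transition_network`.
#' @return A directed [igraph::igraph] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "transition_network"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(net$edges[, 1]),
               to = as.character(net$edges[, 2])),
    directed = TRUE,
    vertices = data.frame(name = as.character(net$nodes),
                          quantile = net$nodes)
  )
  igraph::graph_attr(g, "Q") <- net$Q
  igraph::graph_attr(g, "provenance") <- net$provenance
  g
}

#' Export a transition network
#'
#' `write_network_graphml()` writes GraphML (vertex attribute `quantile`,
#' graph attributes `Q` and `provenance`); `write_network_edgelist()` writes
#' a 2-column whitespace-separated directed edge list with `#`-comment
#' headers carrying `Q`, the provenance label and any self-loops.
#'
#' @param net a `transition_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_edgelist <- function(net, path) {
  stopifnot(inherits(net, "transition_network"))
  con <- file(path, "w")
  on.exit(close(con))
  loops <- if (nrow(net$self_loops)) paste(net$self_loops[, 1], collapse = ",") else ""
  writeLines(c(sprintf("# Q=%d", net$Q),
               sprintf("# provenance=%s", net$provenance),
               sprintf("# self_loops=%s", loops)), con)
  if (nrow(net$edges))
    writeLines(sprintf("%d %d", net$edges[, 1], net$edges[, 2]), con)
  invisible(path)
}

#' Read a transition network from an edge-list file
#'
#' @param path a file written by [write_network_edgelist()].
#' @return A `transition_network`.
#' @export
read_network_edgelist <- function(path) {
  meta <- parse_comment_header(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (length(lines)) {
    parts <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
    edges <- cbind(from = as.integer(parts[, 1]), to = as.integer(parts[, 2]))
  } else {
    edges <- cbind(from = integer(0), to = integer(0))
  }
  loops_str <- meta_or(meta, "self_loops", "")
  loops_n <- if (nzchar(loops_str)) as.integer(strsplit(loops_str, ",")[[1]]) else integer(0)
  structure(
    list(Q = as.integer(meta_or(meta, "Q", "20")),
         nodes = sort(unique(c(edges[, 1], edges[, 2], loops_n))),
         edges = edges,
         self_loops = cbind(from = loops_n, to = loops_n),
         provenance = meta_or(meta, "provenance", "")),
    class = "transition_network"
  )
}
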