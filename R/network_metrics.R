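#' Edge betweenness centrality of a transition network
#'
#' For each edge `e`, sums over ordered node pairs `(s, t)` the fraction of
#' directed shortest paths from `s` to `t` that pass through `e`, all
#' shortest paths counted with multiplicity (Brandes semantics). Pairs with
#' no directed path contribute nothing. Computation is delegated to
#' igraph's Brandes implementation; [edge_betweenness_bruteforce()] provides
#' an independent all-paths enumeration used to validate it.
#'
#' With `normalized = TRUE` (the default) values are divided by
#' `n * (n - 1)` where `n` is the number of occupied nodes, so cumulative
#' curves and the diagnostic cutoff are comparable across networks with
#' different occupied-node counts.
#'
#' @param net a `transition_network` with at least one edge (self-loops are
#'   never part of the metric graph).
#' @param normalized divide by `n * (n - 1)` (default `TRUE`).
#' @return An object of class `ebc_table`: a data.frame with columns
#'   `from`, `to`, `bc`, plus attributes `normalized` and `n_nodes`.
#' @export
edge_betweenness <- function(net, normalized = TRUE) {
  stopifnot(inherits(net, "transition_network"))
  if (nrow(net$edges) == 0L)
    tn_stop("thermonet_empty_table", "network has no edges")
  g <- as_igraph(net)
  bc <- igraph::edge_betweenness(g, directed = TRUE)
  el <- igraph::as_edgelist(g, names = TRUE)
  n <- length(net$nodes)
  if (normalized) bc <- bc / (n * (n - 1))
  ebc_table(as.integer(el[, 1]), as.integer(el[, 2]), bc,
            normalized = normalized, n_nodes = n)
}

ebc_table <- function(from, to, bc, normalized, n_nodes) {
  out <- data.frame(from = from, to = to, bc = bc)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, normalized = normalized, n_nodes = n_nodes,
            class = c("ebc_table", "data.frame"))
}

#' Brute-force edge betweenness by exhaustive shortest-path enumeration
#'
#' Independent oracle for [edge_betweenness()]: for every ordered node pair
#' it finds the geodesic distance by breadth-first search and then
#' enumerates every shortest path explicitly over the BFS layering, crediting
#' each traversed edge with `1 / sigma_st` per path. Exponential in the
#' worst case, hence restricted to small graphs.
#'
#' @param net a `transition_network` with at most 12 nodes and >= 1 edge.
#' @param normalized as in [edge_betweenness()].
#' @return An `ebc_table` with the same contract as [edge_betweenness()].
#' @export
edge_betweenness_bruteforce <- function(net, normalized = TRUE) {
  stopifnot(inherits(net, "transition_network"))
  n <- length(net$nodes)
  if (n > 12L)
    tn_stop("thermonet_size_error", "brute force limited to 12 nodes, got %d", n)
  if (nrow(net$edges) == 0L)
    tn_stop("thermonet_empty_table", "network has no edges")
  idx <- stats::setNames(seq_len(n), net$nodes)
  adj <- vector("list", n)                 # successors
  for (k in seq_len(nrow(net$edges))) {
    i <- idx[[as.character(net$edges[k, 1])]]
    j <- idx[[as.character(net$edges[k, 2])]]
    adj[[i]] <- c(adj[[i]], j)
  }
  key <- function(i, j) paste0(i, ">", j)
  acc <- new.env(parent = emptyenv())
  add <- function(i, j, w) {
    k <- key(i, j)
    acc[[k]] <- (if (is.null(acc[[k]])) 0 else acc[[k]]) + w
  }
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    frontier <- s
    while (length(frontier)) {            # BFS layering
      nxt <- integer(0)
      for (v in frontier) for (w in adj[[v]])
        if (is.na(dist[w])) { dist[w] <- dist[v] + 1L; nxt <- c(nxt, w) }
      frontier <- unique(nxt)
    }
    for (t in seq_len(n)) {
      if (t == s || is.na(dist[t])) next
      paths <- enumerate_geodesics(s, t, adj, dist)
      if (!length(paths)) next
      sigma <- length(paths)
      for (p in paths)
        for (e in seq_len(length(p) - 1)) add(p[e], p[e + 1], 1 / sigma)
    }
  }
  bc <- vapply(seq_len(nrow(net$edges)), function(k) {
    i <- idx[[as.character(net$edges[k, 1])]]
    j <- idx[[as.character(net$edges[k, 2])]]
    v <- acc[[key(i, j)]]
    if (is.null(v)) 0 else v
  }, numeric(1))
  if (normalized) bc <- bc / (n * (n - 1))
  ebc_table(net$edges[, 1], net$edges[, 2], bc,
            normalized = normalized, n_nodes = n)
}

# all shortest v->t paths as lists of node indices, walking forward along
# edges that descend the BFS distance layering rooted at the source
enumerate_geodesics <- function(v, t, adj, dist) {
  if (v == t) return(list(t))
  out <- list()
  for (w in adj[[v]]) {
    if (!is.na(dist[w]) && dist[w] == dist[v] + 1L && dist[t] >= dist[w]) {
      sub <- enumerate_geodesics(w, t, adj, dist)
      for (p in sub) out[[length(out) + 1L]] <- c(v, p)
    }
  }
  out
}

#' Summary metrics of a transition network
#'
#' In/out degree per node, node betweenness (same directed shortest-path
#' semantics as [edge_betweenness()]), graph density
#' `|E| / (n * (n - 1))`, reciprocity (fraction of edges whose reverse edge
#' is also present), and node/edge counts. Self-loops are excluded
#' throughout.
#'
#' @param net a `transition_network` with at least one node.
#' @return A list of class `metric_report` with fields `nodes`, `in_degree`,
#'   `out_degree`, `node_betweenness`, `density`, `reciprocity`, `n_nodes`,
#'   `n_edges`.
#' @export
graph_metrics <- function(net) {
  stopifnot(inherits(net, "transition_network"))
  n <- length(net$nodes)
  if (n == 0L)
    tn_stop("thermonet_empty_table", "network has no nodes")
  g <- as_igraph(net)
  m <- nrow(net$edges)
  recip <- if (m == 0L) NA_real_ else {
    fwd <- paste(net$edges[, 1], net$edges[, 2])
    rev <- paste(net$edges[, 2], net$edges[, 1])
    mean(rev %in% fwd)
  }
  structure(list(
    nodes = net$nodes,
    in_degree = stats::setNames(igraph::degree(g, mode = "in"), net$nodes),
    out_degree = stats::setNames(igraph::degree(g, mode = "out"), net$nodes),
    node_betweenness = stats::setNames(igraph::betweenness(g, directed = TRUE), net$nodes),
    density = if (n > 1) m / (n * (n - 1)) else 0,
    reciprocity = recip,
    n_nodes = n, n_edges = m
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %d node(s), %d edge(s), density=%.3f, reciprocity=%s\n",
              x$n_nodes, x$n_edges, x$density,
              if (is.na(x$reciprocity)) "NA" else sprintf("%.3f", x$reciprocity)))
  invisible(x)
}

#' Empirical cumulative distribution of edge betweenness
#'
#' The diagnostic signature: for each distinct betweenness value `x_k`, the
#' fraction of edges with betweenness `<= x_k`. The curve is a
#' right-continuous step function, non-decreasing, reaching 1 at the
#' largest value.
#'
#' @param tab an `ebc_table`.
#' @return An object of class `cumulative_curve` with fields `x` (sorted
#'   distinct betweenness values), `f` (cumulative edge fractions),
#'   `normalized`, `n_edges`.
#' @export
cumulative_curve <- function(tab) {
  stopifnot(inherits(tab, "ebc_table"))
  if (nrow(tab) == 0L)
    tn_stop("thermonet_empty_table", "empty betweenness table")
  x <- sort(unique(tab$bc))
  f <- vapply(x, function(v) mean(tab$bc <= v), numeric(1))
  structure(list(x = x, f = f, normalized = attr(tab, "normalized"),
                 n_edges = nrow(tab)),
            class = "cumulative_curve")
}

#' @export
print.cumulative_curve <- function(x, ...) {
  cat(sprintf("<cumulative_curve> %d step(s) over %d edge(s), max bc=%.4g\n",
              length(x$x), x$n_edges, max(x$x)))
  invisible(x)
}

#' Write / read an edge betweenness table as CSV
#'
#' Columns `source,target,bc`; `#` headers record the normalization flag and
#' node count.
#'
#' @param tab an `ebc_table`.
#' @param path file path.
#' @return `path` (writer, invisibly) or an `ebc_table` (reader).
#' @export
write_ebc_csv <- function(tab, path) {
  stopifnot(inherits(tab, "ebc_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# normalized=%s", attr(tab, "normalized")),
               sprintf("# n_nodes=%d", attr(tab, "n_nodes")),
               "source,target,bc"), con)
  writeLines(sprintf("%d,%d,%.17g", tab$from, tab$to, tab$bc), con)
  invisible(path)
}

#' @rdname write_ebc_csv
#' @export
read_ebc_csv <- function(path) {
  meta <- parse_comment_header(path)
  df <- utils::read.csv(path, comment.char = "#")
  ebc_table(df$source, df$target, df$bc,
            normalized = as.logical(meta_or(meta, "normalized", "TRUE")),
            n_nodes = as.integer(meta_or(meta, "n_nodes", "0")))
}

#' Write a cumulative betweenness curve as CSV
#'
#' Columns `bc,cum_fraction`.
#'
#' @param curve a [cumulative_curve()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "cumulative_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# normalized=%s", curve$normalized),
               sprintf("# n_edges=%d", curve$n_edges),
               "bc,cum_fraction"), con)
  writeLines(sprintf("%.17g,%.17g", curve$x, curve$f), con)
  invisible(path)
}
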