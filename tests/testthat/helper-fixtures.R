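# Shared fixture builders: everything is generated in code at test time.

# transition network straight from an edge matrix (2 columns: from, to)
make_net <- function(edges, Q = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2)
  colnames(edges) <- c("from", "to")
  nodes <- sort(unique(as.vector(edges)))
  if (is.null(Q)) Q <- max(nodes)
  structure(list(Q = as.integer(Q), nodes = nodes, edges = edges,
                 self_loops = cbind(from = integer(0), to = integer(0)),
                 provenance = ""),
            class = "transition_network")
}

# Erdos-Renyi style random digraph (no self-loops), at least one edge
random_digraph <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
    pairs <- pairs[pairs$from != pairs$to, ]
    keep <- runif(nrow(pairs)) < p
    if (any(keep)) return(make_net(as.matrix(pairs[keep, ]), Q = n))
  }
}

# uniform-field frame stack whose frame t sits at level[t]
uniform_stack <- function(level, h = 4, w = 5, rate = 9) {
  arr <- array(rep(level, h * w), dim = c(length(level), h, w))
  frame_stack(arr, frame_rate_hz = rate)
}

# prep + pool a simulate_cohort() result
pool_cohort <- function(cohort, group = "") {
  pool_series(lapply(unlist(cohort, recursive = FALSE), prep_series),
              group = group)
}

# one held-out subject's pooled evaluation network table (4 x 135 samples)
subject_ebc <- function(params, Q = 20) {
  coh <- simulate_cohort(1, params, segments_per_subject = 4)
  p <- pool_series(lapply(coh[[1]], prep_series))
  edge_betweenness(series_to_network(p, Q = Q))
}
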