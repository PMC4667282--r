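test_that("edge betweenness reproduces hand-enumerated micro-examples", {
  # directed 3-cycle: every edge lies on 3 geodesics (one per ordered pair
  # routed through it), so raw BC = 3, normalized 3 / (3*2) = 0.5
  cyc <- make_net(rbind(c(1, 2), c(2, 3), c(3, 1)))
  raw <- edge_betweenness(cyc, normalized = FALSE)
  expect_equal(raw$bc, rep(3, 3))
  expect_equal(edge_betweenness(cyc)$bc, rep(0.5, 3))
  # directed path 1->2->3: each edge serves its endpoint pair plus (1,3)
  path <- make_net(rbind(c(1, 2), c(2, 3)))
  expect_equal(edge_betweenness(path, normalized = FALSE)$bc, c(2, 2))
  # two nodes linked both ways
  duo <- make_net(rbind(c(1, 2), c(2, 1)))
  expect_equal(edge_betweenness(duo, normalized = FALSE)$bc, c(1, 1))
  expect_equal(edge_betweenness(duo)$bc, c(0.5, 0.5))
  # empty edge set
  empty <- make_net(rbind(c(1, 2)))
  empty$edges <- empty$edges[0, , drop = FALSE]
  expect_error(edge_betweenness(empty), class = "thermonet_empty_table")
})

test_that("brute-force oracle handles singletons, splits and unreachable pairs", {
  expect_equal(edge_betweenness_bruteforce(make_net(rbind(c(1, 2))),
                                           normalized = FALSE)$bc, 1)
  # diamond 1->2->4, 1->3->4: the two geodesics 1->4 split the credit
  dia <- make_net(rbind(c(1, 2), c(2, 4), c(1, 3), c(3, 4)))
  tab <- edge_betweenness_bruteforce(dia, normalized = FALSE)
  key <- paste(tab$from, tab$to)
  expect_equal(tab$bc[key == "1 2"], 1 + 0.5)  # pair (1,2) + half of (1,4)
  expect_equal(tab$bc[key == "3 4"], 1 + 0.5)
  # disconnected pair contributes nothing
  two <- make_net(rbind(c(1, 2), c(3, 4)))
  expect_equal(edge_betweenness_bruteforce(two, normalized = FALSE)$bc, c(1, 1))
  big <- random_digraph(13, p = 0.2, seed = 1)
  expect_error(edge_betweenness_bruteforce(big), class = "thermonet_size_error")
})

test_that("fast path agrees with the brute-force oracle on random digraphs", {
  for (i in 1:40) {
    net <- random_digraph(n = sample(3:10, 1), p = runif(1, 0.15, 0.6), seed = i)
    fast <- edge_betweenness(net, normalized = FALSE)
    slow <- edge_betweenness_bruteforce(net, normalized = FALSE)
    expect_equal(fast$from, slow$from)
    expect_equal(fast$to, slow$to)
    expect_lt(max(abs(fast$bc - slow$bc)), 1e-9)
  }
})

test_that("total edge betweenness equals total geodesic distance", {
  # every geodesic of length d spreads d edge-units of credit
  expect_equal(sum(edge_betweenness(make_net(rbind(c(1, 2), c(2, 3), c(3, 1))),
                                    normalized = FALSE)$bc), 9)
  expect_equal(sum(edge_betweenness(make_net(rbind(c(1, 2), c(2, 3))),
                                    normalized = FALSE)$bc), 4)
  for (i in 41:60) {
    net <- random_digraph(n = sample(4:9, 1), p = runif(1, 0.2, 0.5), seed = i)
    d <- igraph::distances(as_igraph(net), mode = "out")
    expect_equal(sum(edge_betweenness(net, normalized = FALSE)$bc),
                 sum(d[is.finite(d) & d > 0]), tolerance = 1e-9)
  }
})

test_that("normalized betweenness lies in [0,1] and ignores node labels", {
  net <- random_digraph(8, p = 0.3, seed = 99)
  tab <- edge_betweenness(net)
  expect_true(all(tab$bc >= 0 & tab$bc <= 1))
  # relabel nodes by an order-preserving shift
  shifted <- make_net(net$edges + 100L, Q = net$Q)
  expect_equal(sort(edge_betweenness(shifted)$bc), sort(tab$bc))
})

test_that("graph_metrics reports degrees, density, reciprocity, betweenness", {
  cyc <- make_net(rbind(c(1, 2), c(2, 3), c(3, 1)))
  m <- graph_metrics(cyc)
  expect_equal(unname(m$in_degree), rep(1, 3))
  expect_equal(unname(m$out_degree), rep(1, 3))
  expect_equal(m$density, 0.5)
  expect_equal(m$reciprocity, 0)
  full <- make_net(rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2)))
  m2 <- graph_metrics(full)
  expect_equal(m2$density, 1)
  expect_equal(m2$reciprocity, 1)
  path <- make_net(rbind(c(1, 2), c(2, 3)))
  m3 <- graph_metrics(path)
  expect_equal(unname(m3$node_betweenness[2]), 1)  # only pair (1,3) transits
  expect_equal(unname(m3$node_betweenness[c(1, 3)]), c(0, 0))
})

test_that("cumulative curves are valid ECDFs and round-trip to CSV", {
  tab <- edge_betweenness(make_net(rbind(c(1, 2), c(2, 3), c(3, 1))))
  cv <- cumulative_curve(tab)
  expect_equal(cv$x, 0.5)
  expect_equal(cv$f, 1)
  # distinct values 1..4 -> steps at 0.25, 0.5, 0.75, 1
  tab4 <- structure(data.frame(from = 1:4, to = 2:5, bc = c(1, 2, 3, 4)),
                    normalized = FALSE, n_nodes = 5,
                    class = c("ebc_table", "data.frame"))
  cv4 <- cumulative_curve(tab4)
  expect_equal(cv4$x, 1:4)
  expect_equal(cv4$f, c(0.25, 0.5, 0.75, 1))
  # any input: non-decreasing, ends at 1
  set.seed(31)
  net <- random_digraph(9, 0.4, seed = 31)
  cvr <- cumulative_curve(edge_betweenness(net))
  expect_true(all(diff(cvr$f) > 0))
  expect_equal(cvr$f[length(cvr$f)], 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_curve_csv(cvr, f)
  df <- read.csv(f, comment.char = "#")
  expect_equal(df$bc, cvr$x)
  expect_equal(df$cum_fraction, cvr$f)
})

test_that("betweenness tables round-trip through CSV", {
  tab <- edge_betweenness(random_digraph(7, 0.4, seed = 77))
  f <- withr::local_tempfile(fileext = ".csv")
  write_ebc_csv(tab, f)
  back <- read_ebc_csv(f)
  expect_equal(back$from, tab$from)
  expect_equal(back$to, tab$to)
  expect_equal(back$bc, tab$bc)
  expect_identical(attr(back, "normalized"), TRUE)
  expect_equal(attr(back, "n_nodes"), attr(tab, "n_nodes"))
})
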