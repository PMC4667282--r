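mk_tab <- function(bc, normalized = TRUE) {
  structure(data.frame(from = seq_along(bc), to = seq_along(bc) + 1, bc = bc),
            normalized = normalized, n_nodes = length(bc) + 1,
            class = c("ebc_table", "data.frame"))
}

test_that("fit_cutoff takes the midpoint of the separation gap", {
  m <- fit_cutoff(mk_tab(c(0.1, 0.2)), mk_tab(c(0.3, 0.6)))
  expect_equal(m$cutoff, 0.4)
  expect_equal(m$train_control_max, 0.2)
  expect_equal(m$train_case_max, 0.6)
  expect_error(fit_cutoff(mk_tab(0.5), mk_tab(0.5)),
               class = "thermonet_no_separation")
  expect_error(fit_cutoff(mk_tab(0.7), mk_tab(0.5)),
               class = "thermonet_no_separation")
  expect_error(fit_cutoff(mk_tab(0.1), mk_tab(0.5, normalized = FALSE)),
               class = "thermonet_parameter_error")
})

test_that("classification is a strict crossing with ties going to control", {
  m <- fit_cutoff(mk_tab(0.2), mk_tab(0.6))  # cutoff 0.4
  exact <- classify_subject(mk_tab(c(0.1, 0.4)), m, "tie")
  expect_equal(exact$label, "control")
  expect_equal(exact$margin, 0)
  above <- classify_subject(mk_tab(0.5), m, "hot")
  expect_equal(above$label, "case")
  expect_equal(above$margin, 0.1, tolerance = 1e-12)
  # monotone: raising max EBC never flips case -> control
  labels <- sapply(seq(0.05, 0.8, by = 0.05), function(b)
    classify_subject(mk_tab(b), m)$label)
  expect_true(all(diff(labels == "case") >= 0))
  expect_error(classify_subject(mk_tab(0.5, normalized = FALSE), m),
               class = "thermonet_parameter_error")
})

test_that("cutoff models round-trip through their key=value file", {
  m <- fit_cutoff(mk_tab(c(0.11, 0.23)), mk_tab(c(0.31, 0.57)), q_used = 15L)
  f <- withr::local_tempfile(fileext = ".txt")
  write_cutoff_model(m, f)
  back <- read_cutoff_model(f)
  expect_equal(back$cutoff, m$cutoff)
  expect_equal(back$train_control_max, m$train_control_max)
  expect_equal(back$train_case_max, m$train_case_max)
  expect_identical(back$q_used, 15L)
  expect_identical(back$normalized, TRUE)
})

mk_curve <- function(x, f) {
  structure(list(x = x, f = f, normalized = TRUE, n_edges = length(x)),
            class = "cumulative_curve")
}

test_that("curve_distance is the KS sup over the merged step grid", {
  a <- mk_curve(c(0.1, 0.2, 0.4), c(0.25, 0.5, 1))
  expect_equal(curve_distance(a, a), 0)
  # disjoint supports: one curve saturates before the other starts
  b <- mk_curve(c(0.6, 0.9), c(0.5, 1))
  expect_equal(curve_distance(a, b), 1)
  # brute-force oracle: evaluate both step functions on a fine grid
  set.seed(41)
  for (i in 1:20) {
    xa <- sort(runif(sample(2:6, 1))); xb <- sort(runif(sample(2:6, 1)))
    ca <- mk_curve(xa, seq_along(xa) / length(xa))
    cb <- mk_curve(xb, seq_along(xb) / length(xb))
    grid <- seq(0, 1.2, by = 1e-3)
    fa <- sapply(grid, function(g) if (any(xa <= g)) max(ca$f[xa <= g]) else 0)
    fb <- sapply(grid, function(g) if (any(xb <= g)) max(cb$f[xb <= g]) else 0)
    expect_equal(curve_distance(ca, cb), max(abs(fa - fb)), tolerance = 1e-12)
    # metric properties
    expect_equal(curve_distance(ca, cb), curve_distance(cb, ca))
    expect_gte(curve_distance(ca, cb), 0)
    expect_lte(curve_distance(ca, cb), 1)
  }
})

test_that("curve_distance satisfies the triangle inequality on random curves", {
  set.seed(42)
  rand_curve <- function() {
    x <- sort(runif(sample(2:8, 1)))
    mk_curve(x, seq_along(x) / length(x))
  }
  for (i in 1:30) {
    a <- rand_curve(); b <- rand_curve(); c3 <- rand_curve()
    expect_lte(curve_distance(a, c3),
               curve_distance(a, b) + curve_distance(b, c3) + 1e-12)
  }
})

test_that("region_compare separates coupled from uncoupled region pairs", {
  # cheeks carry regime-switching dynamics in both groups; a diseased eye
  # shares that structure (small distance), a healthy eye does not
  curve_of <- function(params, n_subj = 15, master) {
    params$seed <- master
    cohort <- simulate_cohort(n_subj, params, group = "g")
    cumulative_curve(edge_betweenness(series_to_network(pool_cohort(cohort), Q = 20)))
  }
  coupled <- generator_params(regime_delta = 0.15)
  healthy <- generator_params(regime_delta = 0)
  d_dis <- d_heal <- numeric(12)
  for (r in 1:12) {
    eye_dis <- curve_of(coupled, master = 7000 + r * 100)
    eye_heal <- curve_of(healthy, master = 8000 + r * 100)
    cheek <- curve_of(coupled, master = 9000 + r * 100)
    d_dis[r] <- region_compare(eye_dis, cheek)
    d_heal[r] <- region_compare(eye_heal, cheek)
    expect_gte(d_dis[r], 0); expect_lte(d_dis[r], 1)
  }
  expect_lt(median(d_dis), median(d_heal))
  expect_equal(region_compare(eye_dis, eye_dis), 0)
})

test_that("window statistics respect segment boundaries and lengths", {
  set.seed(55)
  cohort <- simulate_cohort(8, generator_params(seed = 1234))
  p <- pool_cohort(cohort)
  w <- window_max_ebc(p, window = 540L, stride = 135L)
  expect_length(w, (8 * 135 - 540) / 135 + 1)
  expect_true(all(w > 0 & w < 1))
  expect_error(window_max_ebc(p, window = 10000L),
               class = "thermonet_parameter_error")
})

test_that("length-matched cutoffs separate synthetic cohorts", {
  healthy <- pool_cohort(simulate_cohort(20, generator_params(seed = 310)))
  diseased <- pool_cohort(simulate_cohort(20, generator_params(seed = 311, regime_delta = 0.15)))
  m <- fit_cutoff_matched(healthy, diseased, window = 540L)
  expect_lt(m$train_control_max, m$cutoff)
  expect_gt(m$train_case_max, m$cutoff)
  # identical class dynamics: no separation or a near-zero margin
  expect_error(fit_cutoff_matched(healthy, healthy, window = 540L),
               class = "thermonet_no_separation")
})
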