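#' Parameters of the synthetic thermal-series generator
#'
#' The generator emulates the statistical structure of short ocular-surface
#' thermal recordings: a slow linear cooling trend (tear-film evaporation),
#' small autocorrelated fluctuations around it, and — in pathological
#' dynamics — occasional switching between two thermal regimes, which
#' produces the rare large inter-quantile jumps that show up downstream as
#' high-betweenness bridge edges.
#'
#' Model: `tau(t) = base_temp + trend_slope * t + mu(t) + eps(t)`, with
#' `eps` an AR(1) process (`eps_t = ar_phi * eps_{t-1} + N(0, sigma^2)`) and
#' `mu` a two-state Markov chain taking values `±regime_delta / 2` with
#' per-step switch probability `switch_prob`. `regime_delta = 0` is the
#' healthy condition; pathological dynamics use a separation of a few
#' innovation scales (e.g. `3 * sigma`).
#'
#' @param n_samples samples per recording; default 135 = 15 s at 9 Hz, the
#'   acquisition constants the defaults emulate.
#' @param frame_rate_hz sampling rate (default 9).
#' @param base_temp baseline level, arbitrary temperature-linear units
#'   (default 34, a typical ocular-surface temperature in deg C).
#' @param trend_slope cooling trend per frame (default -0.005 units/frame).
#' @param ar_phi AR(1) coefficient in `[0, 1)` (default 0.6).
#' @param sigma innovation standard deviation (default 0.05 units, the
#'   thermal-sensitivity scale of the emulated camera).
#' @param regime_delta separation between the two regime means (default 0).
#' @param switch_prob per-step regime switch probability (default 0.02).
#' @param seed integer seed; every draw is fully determined by it.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_samples = 135, frame_rate_hz = 9,
                             base_temp = 34, trend_slope = -0.005,
                             ar_phi = 0.6, sigma = 0.05,
                             regime_delta = 0, switch_prob = 0.02,
                             seed = 1L) {
  if (n_samples < 10)
    tn_stop("thermonet_parameter_error", "n_samples must be >= 10")
  if (ar_phi < 0 || ar_phi >= 1)
    tn_stop("thermonet_parameter_error", "ar_phi must lie in [0, 1)")
  if (sigma <= 0)
    tn_stop("thermonet_parameter_error", "sigma must be positive")
  if (switch_prob < 0 || switch_prob > 1)
    tn_stop("thermonet_parameter_error", "switch_prob must lie in [0, 1]")
  if (regime_delta < 0)
    tn_stop("thermonet_parameter_error", "regime_delta must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 frame_rate_hz = frame_rate_hz, base_temp = base_temp,
                 trend_slope = trend_slope, ar_phi = ar_phi, sigma = sigma,
                 regime_delta = regime_delta, switch_prob = switch_prob,
                 seed = as.integer(seed)),
            class = "generator_params")
}

# run code under a local RNG stream; the caller's RNG state is untouched
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate one synthetic thermal series
#'
#' @param params a [generator_params()].
#' @param subject_id,region,group provenance labels for the output.
#' @return A [temperature_series()] of length `n_samples`, bit-reproducible
#'   for a given `params$seed`.
#' @export
simulate_series <- function(params, subject_id = "sim", region = "other",
                            group = "") {
  stopifnot(inherits(params, "generator_params"))
  n <- params$n_samples
  with_local_seed(params$seed, {
    innov <- stats::rnorm(n, 0, params$sigma)
    eps <- as.numeric(stats::filter(innov, params$ar_phi, method = "recursive"))
    state0 <- stats::rbinom(1, 1, 0.5)
    switches <- stats::rbinom(n - 1, 1, params$switch_prob)
    state <- (state0 + cumsum(c(0L, switches))) %% 2
    mu <- (2 * state - 1) * params$regime_delta / 2
    t <- seq_len(n) - 1
    temperature_series(params$base_temp + params$trend_slope * t + mu + eps,
                       frame_rate_hz = params$frame_rate_hz,
                       subject_id = subject_id, region = region, group = group)
  })
}

#' Simulate a cohort of independent subjects
#'
#' Each subject draws from an independent stream seeded `params$seed + i`,
#' so the whole cohort is reproducible from the master seed and any subject
#' can be regenerated in isolation.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param params a [generator_params()]; `seed` acts as the master seed.
#' @param group cohort label stamped on every series.
#' @param region region label (default `"eye_left"`).
#' @param segments_per_subject recordings per subject; each subject's
#'   element is a list of that many [temperature_series()] (1 emulates a
#'   single 15 s video, 4 the pooled 60 s test-case protocol).
#' @return A list of length `n_subjects`; element `i` is the list of
#'   series for subject `i` (`subject_id` = `"<group>_<i>"`).
#' @export
simulate_cohort <- function(n_subjects, params, group = "cohort",
                            region = "eye_left", segments_per_subject = 1L) {
  if (n_subjects < 1)
    tn_stop("thermonet_parameter_error", "n_subjects must be >= 1")
  stopifnot(inherits(params, "generator_params"))
  lapply(seq_len(n_subjects), function(i) {
    lapply(seq_len(segments_per_subject), function(k) {
      p <- params
      p$seed <- params$seed + (i - 1L) * segments_per_subject + (k - 1L)
      simulate_series(p, subject_id = sprintf("%s_%d", group, i),
                      region = region, group = group)
    })
  })
}

#' Render a scalar series into a synthetic frame stack
#'
#' Frame `t` is a uniform field at `values[t]` plus independent zero-mean
#' Gaussian pixel noise, closing the loop back to the frame-reduction stage:
#' with `pixel_noise_sigma = 0`, [mean_series()] recovers the input exactly;
#' with noise, the recovery error has standard deviation
#' `pixel_noise_sigma / sqrt(H * W)`.
#'
#' @param s a [temperature_series()].
#' @param height,width frame extent in pixels (>= 1).
#' @param pixel_noise_sigma per-pixel noise standard deviation.
#' @param seed seed for the pixel noise.
#' @return A [frame_stack()] of dimension `T x height x width`.
#' @export
render_frames <- function(s, height = 8, width = 8, pixel_noise_sigma = 0,
                          seed = 1L) {
  stopifnot(inherits(s, "temperature_series"))
  if (height < 1 || width < 1)
    tn_stop("thermonet_parameter_error", "height and width must be >= 1")
  n <- length(s$values)
  arr <- with_local_seed(seed, {
    noise <- if (pixel_noise_sigma > 0)
      stats::rnorm(n * height * width, 0, pixel_noise_sigma) else 0
    array(rep(s$values, height * width) + noise, dim = c(n, height, width))
  })
  arr[arr < 0] <- 0  # intensities are counts; clip pathological noise draws
  frame_stack(arr, frame_rate_hz = s$frame_rate_hz, source_id = s$subject_id)
}
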