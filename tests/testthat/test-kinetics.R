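test_that("noiseless plateau-exponential traces are recovered to numerical precision", {
  y <- make_trace(5, 100, 10, 20, n = 60, frame_interval = 1)
  fit <- fit_pixel_trace(y, 1)
  expect_lt(abs(fit$f0 - 5) / 5, 1e-6)
  expect_lt(abs(fit$amplitude - 100) / 100, 1e-6)
  expect_lt(abs(fit$onset_t0 - 10) / 10, 1e-6)
  expect_lt(abs(fit$tau - 20) / 20, 1e-6)
  expect_gt(fit$r_squared, 1 - 1e-10)
})

test_that("the fitted curve passes through F0 + 0.632 A one tau after onset", {
  y <- make_trace(12, 300, 35, 74, n = 120, frame_interval = 5)
  fit <- fit_pixel_trace(y, 5)
  model_at <- fit$f0 + fit$amplitude * (1 - exp(-1))
  truth_at <- 12 + 300 * (1 - exp(-1))
  expect_lt(abs(model_at - truth_at) / truth_at, 1e-6)
})

test_that("noise-only traces score near-zero R-squared and are filtered out", {
  set.seed(42)
  rejected <- 0L
  for (i in 1:100) {
    y <- rnorm(60, 100, 10)
    fit <- fit_pixel_trace(y, 5)
    if (fit$r_squared < 0.8) rejected <- rejected + 1L
  }
  expect_gte(rejected, 95)
})

test_that("the R-squared filter keeps exactly the qualifying fits, in order", {
  fits <- data.frame(position = 1:3, f0 = 0, amplitude = 1, onset_t0 = 0,
                     tau = 1, r_squared = c(0.95, 0.79, 0.85), valid = TRUE)
  kept <- filter_fits(fits)
  expect_equal(kept$position, c(1L, 3L))
  expect_equal(nrow(filter_fits(fits[0, ])), 0)
  expect_equal(nrow(filter_fits(fits, r2_min = 0)), 3)
})

test_that("contiguous runs collapse to the smallest-onset event", {
  fits <- data.frame(position = c(10, 11, 12), f0 = 0, amplitude = 1,
                     onset_t0 = c(40, 42, 41), tau = c(7, 8, 9),
                     r_squared = 0.9, valid = TRUE)
  ev <- deduplicate_events(fits)
  expect_equal(ev$n_events, 1L)
  expect_equal(ev$events$onset_t0, 40)
  expect_equal(ev$events$tau, 7)

  # two runs separated by 5 rejected pixels
  fits2 <- rbind(fits, within(fits, position <- position + 8))
  ev2 <- deduplicate_events(fits2)
  expect_equal(ev2$n_events, 2L)

  # onset tie broken by higher R-squared, then lower position
  fits3 <- data.frame(position = c(5, 6), f0 = 0, amplitude = 1,
                      onset_t0 = c(30, 30), tau = c(1, 2),
                      r_squared = c(0.85, 0.95), valid = TRUE)
  expect_equal(deduplicate_events(fits3)$events$tau, 2)
})

test_that("tau summaries use the geometric mean with a log-space t interval", {
  s <- summarize_tau(c(50, 50, 50))
  expect_equal(s$geomean_s, 50)
  expect_equal(s$ci_low_s, 50)
  expect_equal(s$ci_high_s, 50)

  s2 <- summarize_tau(c(63, 86))
  expect_equal(s2$geomean_s, sqrt(63 * 86), tolerance = 1e-12)

  expect_error(summarize_tau(c(10, -1, 5)), "> 0")
  expect_error(summarize_tau(10), "at least 2")
})

test_that("a lognormal tau sample of 118 events summarizes near its geometric mean", {
  set.seed(118)
  tau <- rlnorm(118, log(74), log(1.8))
  s <- summarize_tau(tau)
  se <- sd(log(tau)) / sqrt(118)
  expect_lt(abs(log(s$geomean_s) - log(74)), 2 * se + abs(mean(log(tau)) - log(74)))
  expect_true(s$ci_low_s <= s$geomean_s && s$geomean_s <= s$ci_high_s)
})

test_that("dead time is read off the bulk arrival trace", {
  y <- make_trace(50, 400, 12, 8, n = 60, frame_interval = 1)
  expect_lt(abs(estimate_dead_time(y, 1) - 12), 1 + 1e-9)

  y0 <- make_trace(50, 400, 0, 8, n = 60, frame_interval = 1)
  expect_lt(estimate_dead_time(y0, 1), 1)

  set.seed(3)
  flat <- rnorm(60, 50, 2)
  expect_error(estimate_dead_time(flat, 1), "no arrival")
})

test_that("dead-time trimming drops pre-arrival columns and shifts onsets", {
  m <- matrix(rnorm(30 * 200), 30, 200)
  ky <- structure(list(data = m, frame_interval = 5, trace_id = 1,
                       corrected = TRUE, time_offset = 0),
                  class = "kymograph")
  expect_equal(ncol(trim_dead_time(ky, 0)$data), 200)
  tr <- trim_dead_time(ky, 50)   # 10 frames
  expect_equal(ncol(tr$data), 190)
  expect_equal(tr$time_offset, 50)
  expect_error(trim_dead_time(ky, 5 * 200), "duration")

  # trim-then-fit equals fit-then-subtract within one frame
  y <- make_trace(5, 200, 150, 40, n = 120, frame_interval = 5,
                  noise_sd = 4)
  ky2 <- structure(list(data = rbind(y), frame_interval = 5, trace_id = 1,
                        corrected = TRUE, time_offset = 0),
                   class = "kymograph")
  f_full <- fit_pixel_trace(y, 5)
  f_trim <- fit_kymograph(trim_dead_time(ky2, 50))
  expect_lt(abs((f_full$onset_t0 - 50) - f_trim$onset_t0), 5 + 1e-9)
  expect_lt(abs(f_full$tau - f_trim$tau) / f_full$tau, 0.1)
})

test_that("the production fitter matches a brute-force profiled grid search", {
  set.seed(77)
  worst <- 0
  for (i in 1:50) {
    y <- make_trace(runif(1, 0, 50), runif(1, 100, 400), runif(1, 20, 400),
                    rlnorm(1, log(74), log(1.8)), n = 120,
                    frame_interval = 5, noise_sd = 12)
    fit <- fit_pixel_trace(y, 5)
    t <- (seq_along(y) - 1) * 5
    g <- ifelse(t > fit$onset_t0,
                1 - exp(-(t - fit$onset_t0) / fit$tau), 0)
    sse_fit <- sum((y - fit$f0 - fit$amplitude * g)^2)
    sse_oracle <- oracle_plateau_sse(y, 5)
    worst <- max(worst, (sse_fit - sse_oracle) / sse_oracle)
  }
  expect_lt(worst, 0.001)
})

test_that("kymograph batch fitting agrees with the single-trace fitter", {
  set.seed(21)
  K <- rbind(
    make_trace(5, 250, 100, 60, n = 100, frame_interval = 5, noise_sd = 8),
    make_trace(0, 300, 200, 30, n = 100, frame_interval = 5, noise_sd = 8),
    rnorm(100, 0, 8)
  )
  batch <- fit_kymograph(K, 5)
  for (i in 1:2) {
    single <- fit_pixel_trace(K[i, ], 5)
    expect_lt(abs(batch$tau[i] - single$tau) / single$tau, 1e-3)
    expect_lt(abs(batch$onset_t0[i] - single$onset_t0), 0.5)
  }
  expect_lt(batch$r_squared[3], 0.5)
})
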