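test_that("a blank tube yields zero foci and zero density", {
  cfg <- sim_config(image_shape = c(40, 128), n_tubes = 1, n_frames = 2,
                    foci_rate = 0, seed = 2)
  sim <- simulate_assembly_movie(cfg)
  traces <- segment_tubes(movie_frame(sim$movie, "lipid"), cfg$pixel_size)
  foci <- detect_foci(sim$movie$channels$clathrin[, , 2], traces,
                      cfg$pixel_size)
  expect_equal(nrow(foci), 0)
  d <- compute_density(foci, traces)
  expect_equal(d$density, 0)
})

test_that("well-separated simulated foci are each detected near their position", {
  cfg <- sim_config(image_shape = c(40, 256), n_tubes = 1, n_frames = 8,
                    frame_interval = 60, dead_time = 30, n_foci = 5,
                    tau_geomean = 74, seed = 10)
  sim <- simulate_assembly_movie(cfg)
  traces <- segment_tubes(movie_frame(sim$movie, "lipid"), cfg$pixel_size)
  foci <- detect_foci(sim$movie$channels$clathrin[, , 8], traces,
                      cfg$pixel_size)
  gt <- sim$ground_truth$foci
  # ground truth for this seed is well separated; allow one merge
  expect_gte(nrow(foci), nrow(gt) - 1)
  expect_lte(nrow(foci), nrow(gt))
  for (i in seq_len(nrow(foci))) {
    expect_lt(min(abs(gt$along_um - foci$position_um[i])), 0.4)
  }
})

test_that("two foci inside one PSF width merge into a single detection", {
  img <- matrix(100, 40, 120)
  sigma_px <- 110 / 160
  p1 <- tubequant:::.psf_patch(60, 20, sigma_px, 40, 120)
  img[p1$rows, p1$cols] <- img[p1$rows, p1$cols] + 2000 * p1$patch
  p2 <- tubequant:::.psf_patch(61, 20, sigma_px, 40, 120)
  img[p2$rows, p2$cols] <- img[p2$rows, p2$cols] + 2000 * p2$patch
  tr <- structure(list(id = 1L, coords = cbind(20, 5:115),
                       length_um = 110 * 0.16),
                  class = "tube_trace")
  foci <- detect_foci(img, list(tr), 160, background = 100)
  expect_equal(nrow(foci), 1L)
})

test_that("density arithmetic: 8 foci on 20 um is 40 per 100 um", {
  tr <- structure(list(id = 1L, coords = cbind(10, 1:126), length_um = 20),
                  class = "tube_trace")
  foci <- data.frame(trace_id = 1L, position_um = seq(1, 19, length.out = 8),
                     peak_intensity = 1)
  d <- compute_density(foci, list(tr))
  expect_equal(d$density, 40)
  expect_equal(d$n_foci, 8L)
  expect_error(compute_density(foci, list()), "zero total")
})

test_that("detection is invariant to global intensity scaling", {
  cfg <- sim_config(image_shape = c(60, 256), n_tubes = 2, n_frames = 4,
                    frame_interval = 100, dead_time = 30, n_foci = 12,
                    seed = 12)
  sim <- suppressWarnings(simulate_assembly_movie(cfg))  # sparse frames by design
  traces <- segment_tubes(movie_frame(sim$movie, "lipid"), cfg$pixel_size)
  img <- sim$movie$channels$clathrin[, , 4]
  f1 <- detect_foci(img, traces, cfg$pixel_size)
  f2 <- detect_foci(img * 5, traces, cfg$pixel_size)
  expect_equal(nrow(f1), nrow(f2))
  expect_equal(f1$position_um, f2$position_um)
})

test_that("resolution-corrected density is unbiased for Poisson placement", {
  rec <- true <- numeric(12)
  for (s in seq_len(12)) {
    cfg <- sim_config(image_shape = c(150, 256), n_tubes = 8, n_frames = 4,
                      frame_interval = 110, dead_time = 30, foci_rate = 0.4,
                      tau_geomean = 74, seed = 300 + s)
    sim <- suppressWarnings(simulate_assembly_movie(cfg))  # sparse frames by design
    res <- analyze_foci_movie(sim$movie, time_s = 300)
    rec[s] <- res$density$density_corrected
    true[s] <- 100 * nrow(sim$ground_truth$foci) / sim$ground_truth$total_tube_um
  }
  expect_lt(abs(mean(rec) - mean(true)) / mean(true), 0.05)
})

test_that("condition comparisons report means and Welch p-values", {
  set.seed(5)
  d_wt <- rnorm(15, 40, 6)
  d_null <- rnorm(13, 4, 2)
  cmp <- compare_conditions(c(d_wt, d_null),
                            rep(c("WT", "CBS null"), c(15, 13)))
  expect_equal(nrow(cmp$summary), 2)
  expect_lt(cmp$tests$p_value, 1e-4)

  # identical conditions: no detectable difference
  cmp2 <- compare_conditions(c(d_wt, d_wt), rep(c("a", "b"), each = 15))
  expect_gt(cmp2$tests$p_value, 0.9)

  # a condition with n < 2 is dropped, and one condition alone errors
  expect_warning(
    expect_error(compare_conditions(c(d_wt, 4), rep(c("WT", "x"), c(15, 1))),
                 "at least 2"),
    "dropping")
})
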