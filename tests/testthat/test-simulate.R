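test_that("identical config and seed give bit-identical movies", {
  cfg <- small_template_cfg(seed = 5)
  a <- simulate_budded_template(cfg)
  b <- simulate_budded_template(cfg)
  expect_identical(a$movie$channels, b$movie$channels)
  expect_identical(a$ground_truth$buds, b$ground_truth$buds)

  mcfg <- small_movie_cfg(seed = 5, n_frames = 20)
  m1 <- simulate_assembly_movie(mcfg)
  m2 <- simulate_assembly_movie(mcfg)
  expect_identical(m1$movie$channels, m2$movie$channels)
})

test_that("unit enrichment with zero noise makes the channels identical up to scale", {
  cfg <- small_template_cfg(seed = 2, E = 1, noise = NULL)
  sim <- simulate_budded_template(cfg)
  li <- movie_frame(sim$movie, "lipid") - cfg$background
  pr <- movie_frame(sim$movie, "protein") - cfg$background
  sel <- li > max(li) * 0.01
  expect_lt(max(abs(pr[sel] / li[sel] - 1)), 1e-9)
})

test_that("integrated lipid intensity per length scales with tube diameter", {
  base <- list(image_shape = c(40, 160), n_tubes = 1, n_buds = 0,
               noise = NULL, seed = 1)
  s1 <- simulate_budded_template(do.call(sim_config, c(base, tube_diameter = 47)))
  s2 <- simulate_budded_template(do.call(sim_config, c(base, tube_diameter = 94)))
  f1 <- sum(movie_frame(s1$movie, "lipid") - 100)
  f2 <- sum(movie_frame(s2$movie, "lipid") - 100)
  expect_equal(f2 / f1, 2, tolerance = 1e-6)
})

test_that("expected intensity is linear in lipid density (pre-noise)", {
  base <- list(image_shape = c(60, 120), n_tubes = 2, n_buds = 2,
               noise = NULL, seed = 3)
  s1 <- simulate_budded_template(do.call(sim_config, c(base, lipid_density = 20000)))
  s2 <- simulate_budded_template(do.call(sim_config, c(base, lipid_density = 40000)))
  d1 <- movie_frame(s1$movie, "lipid") - 100
  d2 <- movie_frame(s2$movie, "lipid") - 100
  expect_equal(d2, 2 * d1, tolerance = 1e-9)
})

test_that("foci counts behave like a spatial Poisson process (variance/mean near 1)", {
  counts <- vapply(seq_len(150), function(s) {
    cfg <- sim_config(image_shape = c(40, 128), n_tubes = 3, n_frames = 2,
                      foci_rate = 0.4, seed = 1000 + s)
    nrow(simulate_assembly_movie(cfg)$ground_truth$foci)
  }, 0)
  vm <- stats::var(counts) / mean(counts)
  expect_gt(vm, 0.8)
  expect_lt(vm, 1.2)
})

test_that("titration identities: half-saturation at Kd, saturation at excess", {
  tit <- simulate_binding_titration(36, 1000, c(36, 3.6e7), noise_frac = 0,
                                    n_templates = 1, seed = 1)
  expect_equal(tit$fluorescence[1], 500)
  expect_equal(tit$fluorescence[2], 1000, tolerance = 1e-5)
})

test_that("zero foci rate gives a bulk-only clathrin channel, none detected", {
  cfg <- sim_config(image_shape = c(60, 128), n_tubes = 3, n_frames = 6,
                    frame_interval = 60, foci_rate = 0, dead_time = 30,
                    seed = 4)
  sim <- simulate_assembly_movie(cfg)
  expect_equal(nrow(sim$ground_truth$foci), 0)
  traces <- segment_tubes(movie_frame(sim$movie, "lipid"), cfg$pixel_size)
  foci <- detect_foci(sim$movie$channels$clathrin[, , 6], traces,
                      cfg$pixel_size)
  expect_equal(nrow(foci), 0)
})

test_that("invalid configurations are rejected, undersampling warned", {
  expect_error(sim_config(image_shape = c(0, 10)), "zero-size")
  expect_error(sim_config(tau_geosd = 0.5), "geosd")
  expect_error(sim_config(tau_geomean = -3), "tau_geomean")
  expect_error(sim_config(enrichment_E = -1), "enrichment")
  cfg <- small_movie_cfg(frame_interval = 100, tau_geomean = 74, n_frames = 10)
  expect_warning(simulate_assembly_movie(cfg), "undersampled")
})

test_that("unresolvably close buds are flagged in the ground truth", {
  cfg <- sim_config(image_shape = c(40, 60), n_tubes = 1, n_buds = 10,
                    noise = NULL, seed = 1)
  sim <- simulate_budded_template(cfg)
  expect_true(length(sim$ground_truth$warnings) > 0)
})
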