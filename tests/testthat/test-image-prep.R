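test_that("a single straight tube is traced at its true length", {
  cfg <- sim_config(image_shape = c(40, 142), n_tubes = 1, n_buds = 0,
                    seed = 1)   # 126 px span = 20.16 um
  sim <- simulate_budded_template(cfg)
  traces <- segment_tubes(movie_frame(sim$movie, "lipid"), cfg$pixel_size)
  expect_length(traces, 1)
  expect_lt(abs(traces[[1]]$length_um - sim$ground_truth$tubes$length_um), 0.5)
})

test_that("blank and noise-only images yield no traces and no buds", {
  blank <- matrix(100, 50, 80)
  expect_length(segment_tubes(blank, 160), 0)
  set.seed(7)
  noisy <- matrix(100 + rnorm(4000, 0, 10), 50, 80)
  expect_length(segment_tubes(noisy, 160), 0)
  expect_length(segment_buds(noisy, 160), 0)
})

test_that("parallel tubes get distinct traces and budded fields full bud counts", {
  cfg <- small_template_cfg(seed = 3, n_tubes = 2, n_buds = 0)
  sim <- simulate_budded_template(cfg)
  traces <- segment_tubes(movie_frame(sim$movie, "lipid"), cfg$pixel_size)
  expect_length(traces, 2)
  expect_length(unique(vapply(traces, function(t) t$id, 0L)), 2)

  cfg <- small_template_cfg(seed = 3, n_tubes = 6, n_buds = 5)
  sim <- simulate_budded_template(cfg)
  li <- movie_frame(sim$movie, "lipid")
  buds <- segment_buds(li, cfg$pixel_size)
  expect_length(buds, 5)
  # tube-only template: no buds
  cfg0 <- small_template_cfg(seed = 3, n_tubes = 6, n_buds = 0)
  sim0 <- simulate_budded_template(cfg0)
  expect_length(segment_buds(movie_frame(sim0$movie, "lipid"),
                             cfg0$pixel_size), 0)
})

test_that("bud equivalent diameter lands within one pixel of the true 408 nm", {
  cfg <- small_template_cfg(seed = 5, n_tubes = 4, n_buds = 3)
  sim <- simulate_budded_template(cfg)
  buds <- segment_buds(movie_frame(sim$movie, "lipid"), cfg$pixel_size)
  expect_length(buds, 3)
  for (b in buds) expect_lt(abs(b$diameter_nm - 408), 160)
})

test_that("segmentation recall and precision reach 0.95 on replicate fields", {
  match_hits <- total_true <- total_found <- 0
  for (s in 1:10) {
    cfg <- small_template_cfg(seed = 100 + s, n_tubes = 5, n_buds = 4)
    sim <- simulate_budded_template(cfg)
    li <- movie_frame(sim$movie, "lipid")
    traces <- segment_tubes(li, cfg$pixel_size)
    buds <- segment_buds(li, cfg$pixel_size)
    # tubes matched by centerline row, buds by centroid distance
    rows_t <- vapply(traces, function(t) stats::median(t$coords[, 1]), 0)
    hit_t <- sum(vapply(sim$ground_truth$tubes$y, function(y) {
      any(abs(rows_t - y) <= 1)
    }, TRUE))
    gt_b <- sim$ground_truth$buds
    hit_b <- sum(vapply(seq_len(nrow(gt_b)), function(i) {
      any(vapply(buds, function(b) {
        sqrt((b$centroid[1] - gt_b$y[i])^2 + (b$centroid[2] - gt_b$x[i])^2) <= 2
      }, TRUE))
    }, TRUE))
    match_hits <- match_hits + hit_t + hit_b
    total_true <- total_true + nrow(sim$ground_truth$tubes) + nrow(gt_b)
    total_found <- total_found + length(traces) + length(buds)
  }
  expect_gte(match_hits / total_true, 0.95)    # recall
  expect_gte(match_hits / total_found, 0.95)   # precision
})

test_that("background estimation recovers the camera offset", {
  expect_equal(estimate_background(matrix(7, 30, 30),
                                   matrix(FALSE, 30, 30)), 7)
  for (offset in c(100, 0)) {
    cfg <- sim_config(image_shape = c(60, 120), n_tubes = 2,
                      background = offset, seed = 9)
    sim <- simulate_budded_template(cfg)
    li <- movie_frame(sim$movie, "lipid")
    bg <- estimate_background(li)
    expect_lt(abs(bg - offset), 2)   # shot + read noise on the median
  }
  expect_error(estimate_background(matrix(1, 5, 5), matrix(TRUE, 5, 5)),
               "entire frame")
})

test_that("kymographs have L x T shape and constant movies correct to zero", {
  arr <- array(50, dim = c(30, 60, 12))
  mv <- fluor_movie(list(clathrin = arr), 160, 5)
  tr <- structure(list(id = 1L, coords = cbind(15, 5:50), length_um = 7.2),
                  class = "tube_trace")
  ky <- extract_kymograph(mv, tr, "clathrin")
  expect_equal(dim(ky$data), c(46, 12))
  expect_true(all(abs(ky$data) < 1e-12))   # value minus per-frame background
  expect_equal(ky$background, rep(50, 12))
})

test_that("kymograph extraction is linear in the image", {
  cfg <- small_movie_cfg(seed = 6, n_foci = 3, n_frames = 30)
  sim <- simulate_assembly_movie(cfg)
  mv <- sim$movie
  tr <- segment_tubes(movie_frame(mv, "lipid"), cfg$pixel_size)[[1]]
  excl <- matrix(FALSE, dim(mv$channels$clathrin)[1],
                 dim(mv$channels$clathrin)[2])
  k1 <- extract_kymograph(mv, tr, "clathrin", exclusion_mask = excl)
  mv2 <- mv
  mv2$channels$clathrin <- 3 * mv$channels$clathrin + 17
  k2 <- extract_kymograph(mv2, tr, "clathrin", exclusion_mask = excl)
  expect_equal(k2$data, 3 * k1$data, tolerance = 1e-9)
})

test_that("a single focus appears at its true position and onset", {
  cfg <- sim_config(image_shape = c(40, 128), n_tubes = 1, n_frames = 60,
                    frame_interval = 5, dead_time = 20, n_foci = 1,
                    onset_jitter_mean = 10, tau_geomean = 40, seed = 8)
  sim <- simulate_assembly_movie(cfg)
  gt <- sim$ground_truth$foci
  traces <- segment_tubes(movie_frame(sim$movie, "lipid"), cfg$pixel_size)
  ky <- extract_kymograph(sim$movie, traces[[1]], "clathrin")
  peak_row <- which.max(rowMeans(ky$data[, 40:60]))
  true_col <- round(gt$x)
  trace_cols <- traces[[1]]$coords[, 2]
  expect_lte(abs(trace_cols[peak_row] - true_col), 1)
  fit <- fit_pixel_trace(ky$data[peak_row, ], cfg$frame_interval)
  expect_lt(abs(fit$onset_t0 - gt$onset_s), cfg$frame_interval + 1e-6)
})

test_that("recovered kinetics are insensitive to the sampling band width", {
  cfg <- small_movie_cfg(seed = 17, n_foci = 8, n_frames = 100)
  sim <- simulate_assembly_movie(cfg)
  mv <- sim$movie
  tr <- segment_tubes(movie_frame(mv, "lipid"), cfg$pixel_size)
  taus <- lapply(c(1, 3), function(w) {
    ev <- list()
    for (t in tr) {
      ky <- extract_kymograph(mv, t, "clathrin", width = w)
      ky <- trim_dead_time(ky, 30)
      keep <- filter_fits(fit_kymograph(ky))
      keep <- keep[keep$amplitude > 50, , drop = FALSE]
      ev[[length(ev) + 1]] <- deduplicate_events(keep)$events$tau
    }
    unlist(ev)
  })
  expect_gt(length(taus[[1]]), 3)
  g1 <- exp(mean(log(taus[[1]])))
  g3 <- exp(mean(log(taus[[2]])))
  expect_lt(abs(g1 - g3) / g3, 0.1)
})

test_that("a trace leaving the frame is reported by id", {
  arr <- array(0, dim = c(20, 20, 5))
  mv <- fluor_movie(list(clathrin = arr), 160, 5)
  tr <- structure(list(id = "t9", coords = cbind(10, 18:25), length_um = 1),
                  class = "tube_trace")
  expect_error(extract_kymograph(mv, tr, "clathrin"), "t9")
})
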