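# Shared fixtures: small simulation configs and independent oracles.

# compact budded-template field (fast enough to replicate in properties)
small_template_cfg <- function(seed = 1, E = 13.2, n_tubes = 6, n_buds = 5,
                               noise = list(photon_scale = 1, read_sd = 3)) {
  sim_config(image_shape = c(100, 160), n_tubes = n_tubes, n_buds = n_buds,
             enrichment_E = E, noise = noise, seed = seed)
}

# compact assembly movie (a few tubes, short time series)
small_movie_cfg <- function(seed = 1, n_foci = 12, n_frames = 80,
                            frame_interval = 5, dead_time = 30,
                            tau_geomean = 74, tau_geosd = 1.8, ...) {
  sim_config(image_shape = c(80, 256), n_tubes = 4, n_frames = n_frames,
             frame_interval = frame_interval, dead_time = dead_time,
             n_foci = n_foci, tau_geomean = tau_geomean,
             tau_geosd = tau_geosd, seed = seed, ...)
}

# independent brute-force oracle for the plateau-plus-exponential fit:
# dense (t0, tau) grid with (F0, A >= 0) profiled by ordinary least squares
oracle_plateau_sse <- function(y, frame_interval, n_t0 = 160, n_tau = 80) {
  t <- (seq_along(y) - 1) * frame_interval
  d <- max(t)
  t0s <- seq(0, d, length.out = n_t0)
  taus <- exp(seq(log(frame_interval / 4), log(3 * d), length.out = n_tau))
  best <- Inf
  n <- length(y)
  sy <- sum(y)
  for (t0 in t0s) {
    g <- 1 - exp(-(t - t0) / rep(taus, each = length(t)))
    dim(g) <- c(length(t), n_tau)
    g[t <= t0, ] <- 0
    sg <- colSums(g)
    sggc <- colSums(g^2) - sg^2 / n
    cxy <- as.vector(crossprod(g, y)) - sg * sy / n
    beta <- ifelse(sggc > 1e-12, cxy / sggc, 0)
    beta[beta < 0] <- 0
    syyc <- sum(y^2) - sy^2 / n
    sse <- syyc - beta^2 * sggc
    best <- min(best, min(sse))
  }
  best
}

# one-phase trace generator used as an oracle input
make_trace <- function(f0, a, t0, tau, n = 120, frame_interval = 5,
                       noise_sd = 0) {
  t <- (seq_len(n) - 1) * frame_interval
  y <- ifelse(t <= t0, f0, f0 + a * (1 - exp(-(t - t0) / tau)))
  y + stats::rnorm(n, 0, noise_sd)
}
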