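#' Simulate a budded membrane-tube template (two channels, one frame)
#'
#' Renders a field of parallel membrane tubes carrying spherical buds
#' ("beads on a string"): narrow tubes (default 47 nm) below the diffraction
#' limit whose lipid fluorescence per unit length is proportional to
#' pi * d_tube, and buds (default 408 nm) whose integrated fluorescence is
#' proportional to pi * d_bud^2. The protein channel repeats the lipid
#' pattern scaled by the curvature enrichment `enrichment_E` on tubes and by
#' 1 on buds, emulating a curvature-sorting protein. Both channels are PSF
#' blurred; shot and read noise are applied unless `config$noise` is `NULL`.
#'
#' Buds replace the tube membrane over their footprint (the tube enters and
#' leaves the bud; there is no separate tube membrane underneath). Buds are
#' spread evenly over the first `n_buds`-capable tubes at regularly jittered
#' positions; buds closer than twice the PSF FWHM are flagged with a warning
#' recorded in the ground truth.
#'
#' @param config a [sim_config()]; `n_frames` is ignored (single frame).
#' @return list with `movie` (`fluor_movie`, channels `lipid`, `protein`) and
#'   `ground_truth` (list: `tubes`, `buds` data.frames with true geometry and
#'   densities, `warnings`).
#' @export
simulate_budded_template <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  h <- config$image_shape[1]; w <- config$image_shape[2]
  px_um <- config$pixel_size / 1000
  layout <- .default_layout(config)

  # distribute buds round-robin over tubes, jittered around even spacing
  buds <- NULL
  if (config$n_buds > 0) {
    tube_of <- rep(seq_len(config$n_tubes), length.out = config$n_buds)
    buds <- do.call(rbind, lapply(seq_len(config$n_buds), function(i) {
      tr <- layout[tube_of[i], ]
      k <- sum(tube_of[seq_len(i)] == tube_of[i])       # index on this tube
      nk <- sum(tube_of == tube_of[i])
      span <- tr$x1 - tr$x0
      x <- tr$x0 + span * (k - 0.5) / nk +
        stats::runif(1, -0.08, 0.08) * span / nk
      data.frame(bud_id = i, tube_id = tr$tube_id, x = x, y = tr$y)
    }))
    buds$diameter_nm <- config$bud_diameter
    buds$r_px <- (config$bud_diameter / 2) / config$pixel_size
  }

  sigma_px <- config$psf_sigma / config$pixel_size
  lipid <- matrix(0, h, w)
  protein <- matrix(0, h, w)
  tube_per_um <- config$lipid_density * pi * (config$tube_diameter / 1000)
  prot_per_um <- config$protein_scale * config$enrichment_E *
    pi * (config$tube_diameter / 1000)
  gaps <- if (!is.null(buds)) {
    data.frame(x = buds$x, y = buds$y, r = buds$r_px)
  } else NULL

  for (i in seq_len(nrow(layout))) {
    tr <- layout[i, ]
    g <- if (!is.null(gaps)) gaps[buds$tube_id == tr$tube_id, , drop = FALSE]
    lipid <- .deposit_segment(lipid, tr$x0, tr$y, tr$x1, tr$y,
                              tube_per_um, config$pixel_size, g)
    protein <- .deposit_segment(protein, tr$x0, tr$y, tr$x1, tr$y,
                                prot_per_um, config$pixel_size, g)
  }
  if (!is.null(buds)) {
    bud_area_um2 <- pi * (config$bud_diameter / 1000)^2
    for (i in seq_len(nrow(buds))) {
      lipid <- .deposit_sphere(lipid, buds$x[i], buds$y[i], buds$r_px[i],
                               config$lipid_density * bud_area_um2)
      protein <- .deposit_sphere(protein, buds$x[i], buds$y[i], buds$r_px[i],
                                 config$protein_scale * bud_area_um2)
    }
  }

  lipid <- .apply_psf(lipid, sigma_px) + config$background
  protein <- .apply_psf(protein, sigma_px) + config$background
  lipid <- .apply_noise(lipid, config$noise)
  protein <- .apply_noise(protein, config$noise)

  warnings <- character()
  if (!is.null(buds) && nrow(buds) > 1) {
    fwhm_px <- 2.355 * sigma_px
    d <- as.matrix(stats::dist(buds[, c("x", "y")]))
    diag(d) <- Inf
    if (any(d < 2 * (max(buds$r_px) + fwhm_px))) {
      warnings <- c(warnings, "buds closer than the resolvable separation")
    }
  }

  tubes <- layout
  tubes$length_um <- (tubes$x1 - tubes$x0) * px_um
  tubes$diameter_nm <- config$tube_diameter
  tubes$lipid_density <- config$lipid_density
  tubes$enrichment <- config$enrichment_E

  list(
    movie = fluor_movie(list(lipid = lipid, protein = protein),
                        config$pixel_size, config$frame_interval),
    ground_truth = list(tubes = tubes, buds = buds, warnings = warnings,
                        config = config)
  )
}

#' Simulate a clathrin-assembly time-lapse movie
#'
#' Renders plain (bud-free) membrane tubes in the lipid channel and a clathrin
#' channel in which: (i) uniform solution fluorescence stays flat until the
#' flow-cell dead time and then rises exponentially (amplitude
#' `bulk_amplitude`, time constant `bulk_tau`), mirroring the in-situ signal
#' used to estimate the dead time; and (ii) clathrin foci appear along the
#' tubes, placed by a spatial Poisson process at `foci_rate` per um (or
#' exactly `n_foci` uniform positions), each following
#' \eqn{F(t) = F_0} for \eqn{t \le t_0} and
#' \eqn{F_0 + A(1 - e^{-(t-t_0)/\tau})} after, with
#' \eqn{\tau} lognormal (`tau_geomean`, `tau_geosd`) and
#' \eqn{t_0 =} dead time + exponential jitter (`onset_jitter_mean`).
#' Each focus is rendered as a PSF-width spot, so its signal spans several
#' centerline pixels.
#'
#' @param config a [sim_config()] with `n_frames`, `frame_interval`,
#'   `dead_time`, and either `foci_rate` or `n_foci` set.
#' @return list with `movie` (channels `clathrin` T frames, `lipid` 1 frame)
#'   and `ground_truth` (tubes, foci with true position/onset/tau/amplitude,
#'   dead time, config).
#' @export
simulate_assembly_movie <- function(config) {
  validate_sim_config(config)
  if (config$n_frames < 2) stop("assembly movie needs n_frames >= 2")
  if (config$frame_interval > config$tau_geomean) {
    warning("frame interval exceeds tau geometric mean: kinetics undersampled")
  }
  set.seed(config$seed)
  h <- config$image_shape[1]; w <- config$image_shape[2]
  px_um <- config$pixel_size / 1000
  sigma_px <- config$psf_sigma / config$pixel_size
  layout <- .default_layout(config)
  layout$length_um <- (layout$x1 - layout$x0) * px_um
  total_um <- sum(layout$length_um)

  # lipid channel: static tubes
  lipid <- matrix(0, h, w)
  tube_per_um <- config$lipid_density * pi * (config$tube_diameter / 1000)
  for (i in seq_len(nrow(layout))) {
    lipid <- .deposit_segment(lipid, layout$x0[i], layout$y[i], layout$x1[i],
                              layout$y[i], tube_per_um, config$pixel_size)
  }
  lipid <- .apply_psf(lipid, sigma_px) + config$background
  lipid <- .apply_noise(lipid, config$noise)

  # foci: spatial Poisson along the pooled tube length
  n_foci <- if (!is.null(config$n_foci)) config$n_foci
  else stats::rpois(1, config$foci_rate * total_um)
  foci <- data.frame(focus_id = integer(), tube_id = integer(),
                     along_um = numeric(), x = numeric(), y = numeric(),
                     onset_s = numeric(), tau_s = numeric(),
                     amplitude = numeric(), baseline = numeric())
  if (n_foci > 0) {
    s_um <- stats::runif(n_foci, 0, total_um)   # position on pooled length
    cum <- cumsum(layout$length_um)
    tube_idx <- findInterval(s_um, c(0, cum), rightmost.closed = TRUE)
    along_um <- s_um - c(0, cum)[tube_idx]
    foci <- data.frame(
      focus_id = seq_len(n_foci),
      tube_id = layout$tube_id[tube_idx],
      along_um = along_um,
      x = layout$x0[tube_idx] + along_um / px_um,
      y = layout$y[tube_idx],
      onset_s = config$dead_time +
        stats::rexp(n_foci, 1 / config$onset_jitter_mean),
      tau_s = stats::rlnorm(n_foci, log(config$tau_geomean),
                            log(config$tau_geosd)),
      amplitude = config$amplitude_A,
      baseline = config$baseline_F0
    )
  }

  times <- (seq_len(config$n_frames) - 1) * config$frame_interval
  bulk <- ifelse(times <= config$dead_time, 0,
                 config$bulk_amplitude *
                   (1 - exp(-(times - config$dead_time) / config$bulk_tau)))

  clathrin <- array(0, dim = c(h, w, config$n_frames))
  patches <- if (n_foci > 0) {
    lapply(seq_len(n_foci), function(i) {
      .psf_patch(foci$x[i], foci$y[i], sigma_px, h, w)
    })
  }
  for (t in seq_len(config$n_frames)) {
    frame <- matrix(config$background + bulk[t], h, w)
    if (n_foci > 0) {
      for (i in seq_len(n_foci)) {
        tt <- times[t]
        f <- foci$baseline[i] +
          if (tt > foci$onset_s[i]) {
            foci$amplitude[i] * (1 - exp(-(tt - foci$onset_s[i]) / foci$tau_s[i]))
          } else 0
        if (f > 0) {
          p <- patches[[i]]
          frame[p$rows, p$cols] <- frame[p$rows, p$cols] + f * p$patch
        }
      }
    }
    clathrin[, , t] <- frame
  }
  clathrin <- .apply_noise(clathrin, config$noise)

  tubes <- layout
  tubes$diameter_nm <- config$tube_diameter
  list(
    movie = fluor_movie(list(lipid = lipid, clathrin = clathrin),
                        config$pixel_size, config$frame_interval),
    ground_truth = list(tubes = tubes, foci = foci,
                        dead_time = config$dead_time,
                        total_tube_um = total_um, config = config)
  )
}

#' Simulate a one-site binding titration
#'
#' Draws per-template fluorescence around the one-site isotherm
#' \eqn{F = F_{max} [P] / (K_d + [P])} with Gaussian noise of SD
#' `noise_frac * fmax`.
#'
#' @param kd dissociation constant, nM (> 0).
#' @param fmax saturation fluorescence, a.u.
#' @param concentrations protein concentrations in nM (>= 0).
#' @param noise_frac noise SD as a fraction of `fmax` (0 for noiseless).
#' @param n_templates replicates per concentration.
#' @param seed RNG seed.
#' @return data.frame (`concentration_nM`, `fluorescence`, `replicate`).
#' @export
simulate_binding_titration <- function(kd, fmax, concentrations,
                                       noise_frac = 0.05, n_templates = 3L,
                                       seed = 1L) {
  if (kd <= 0) stop("kd must be > 0")
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(n_templates),
                      concentration_nM = concentrations)
  mu <- fmax * grid$concentration_nM / (kd + grid$concentration_nM)
  data.frame(
    concentration_nM = grid$concentration_nM,
    fluorescence = mu + stats::rnorm(nrow(grid), 0, noise_frac * fmax),
    replicate = grid$replicate
  )
}
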