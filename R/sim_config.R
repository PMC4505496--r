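#' Simulation configuration for synthetic tube-template movies
#'
#' Bundles the geometry, photometry, kinetics and noise parameters of the
#' forward simulator, with defaults matching a typical supported-membrane-tube
#' (SMrT) experiment imaged on an EMCCD at 100x: 160 nm pixels, 47 nm tubes
#' carrying 408 nm buds, an isotropic Gaussian PSF of sigma 110 nm.
#'
#' Fluorescence is surface-area photometry: every membrane element deposits
#' intensity proportional to its area (`lipid_density` a.u. per um^2), tubes
#' as cylinders (area per length = pi * d) and buds as spheres (area =
#' pi * d^2), before PSF blurring and noise. The protein channel repeats the
#' lipid pattern scaled by the curvature enrichment `enrichment_E` on tubes
#' and by 1 on buds.
#'
#' @param image_shape c(H, W) in pixels.
#' @param pixel_size nm per pixel.
#' @param frame_interval s between frames.
#' @param n_frames number of frames for time-lapse channels.
#' @param tube_diameter,bud_diameter nm.
#' @param n_tubes number of parallel tube rows placed in the field.
#' @param tube_margin_px blank margin left at either end of each tube row.
#' @param n_buds total number of buds distributed over the tubes (budded
#'   template only).
#' @param lipid_density a.u. per um^2 of membrane.
#' @param protein_scale a.u. per um^2 for the protein channel at enrichment 1.
#' @param enrichment_E tube:bud protein density ratio (>= 0).
#' @param psf_sigma nm, isotropic Gaussian PSF.
#' @param noise list(photon_scale, read_sd): photons = a.u. * photon_scale are
#'   Poisson-drawn, then Gaussian read noise of SD `read_sd` a.u. is added.
#'   `NULL` disables noise entirely (noiseless ground-truth images).
#' @param background additive camera/solution offset in a.u. (Poisson-noisy
#'   like any other photon signal).
#' @param dead_time s before labeled protein reaches the field.
#' @param foci_rate clathrin foci per um of tube (spatial Poisson intensity).
#' @param n_foci optional exact focus count (overrides `foci_rate`; positions
#'   still uniform, i.e. Poisson conditioned on the count).
#' @param tau_geomean,tau_geosd lognormal assembly time-constant distribution
#'   (geometric mean in s; geometric SD unitless, >= 1).
#' @param onset_jitter_mean s; per-focus nucleation delay after the dead time,
#'   exponentially distributed.
#' @param amplitude_A a.u.; total integrated spot flux of a focus at plateau.
#' @param baseline_F0 a.u.; per-focus pre-onset plateau above background.
#' @param bulk_amplitude,bulk_tau a.u. and s; uniform solution fluorescence
#'   rising after the dead time (used for in-situ dead-time estimation).
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @return object of class `sim_config` (validated list).
#' @export
sim_config <- function(image_shape = c(128L, 256L),
                       pixel_size = 160,
                       frame_interval = 5,
                       n_frames = 1L,
                       tube_diameter = 47,
                       bud_diameter = 408,
                       n_tubes = 8L,
                       tube_margin_px = 8L,
                       n_buds = 0L,
                       lipid_density = 20000,
                       protein_scale = 20000,
                       enrichment_E = 1,
                       psf_sigma = 110,
                       noise = list(photon_scale = 1, read_sd = 3),
                       background = 100,
                       dead_time = 30,
                       foci_rate = 0.4,
                       n_foci = NULL,
                       tau_geomean = 74,
                       tau_geosd = 1.8,
                       onset_jitter_mean = 20,
                       amplitude_A = 2000,
                       baseline_F0 = 0,
                       bulk_amplitude = 200,
                       bulk_tau = 10,
                       seed = 1L) {
  cfg <- list(image_shape = as.integer(image_shape), pixel_size = pixel_size,
              frame_interval = frame_interval, n_frames = as.integer(n_frames),
              tube_diameter = tube_diameter, bud_diameter = bud_diameter,
              n_tubes = as.integer(n_tubes),
              tube_margin_px = as.integer(tube_margin_px),
              n_buds = as.integer(n_buds),
              lipid_density = lipid_density, protein_scale = protein_scale,
              enrichment_E = enrichment_E, psf_sigma = psf_sigma,
              noise = noise, background = background, dead_time = dead_time,
              foci_rate = foci_rate, n_foci = n_foci,
              tau_geomean = tau_geomean, tau_geosd = tau_geosd,
              onset_jitter_mean = onset_jitter_mean,
              amplitude_A = amplitude_A, baseline_F0 = baseline_F0,
              bulk_amplitude = bulk_amplitude, bulk_tau = bulk_tau,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @param cfg a candidate configuration list.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$image_shape) == 2)
  if (any(cfg$image_shape <= 0)) stop("zero-size field")
  pos <- c("pixel_size", "frame_interval", "tube_diameter", "bud_diameter",
           "psf_sigma", "lipid_density", "protein_scale")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop(sprintf("'%s' must be > 0", f))
    }
  }
  if (cfg$enrichment_E < 0) stop("'enrichment_E' must be >= 0")
  if (cfg$tau_geomean <= 0) stop("'tau_geomean' must be > 0")
  if (cfg$tau_geosd < 1) stop("'tau_geosd' must be >= 1 (lognormal shape)")
  if (cfg$foci_rate < 0) stop("'foci_rate' must be >= 0")
  if (cfg$dead_time < 0) stop("'dead_time' must be >= 0")
  if (!is.null(cfg$noise)) {
    stopifnot(cfg$noise$photon_scale > 0, cfg$noise$read_sd >= 0)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %dx%d px @ %g nm/px, %d frame(s) @ %g s\n",
              x$image_shape[1], x$image_shape[2], x$pixel_size, x$n_frames,
              x$frame_interval))
  cat(sprintf("  tubes: %d x d=%g nm; buds: %d x d=%g nm; E=%g\n",
              x$n_tubes, x$tube_diameter, x$n_buds, x$bud_diameter,
              x$enrichment_E))
  cat(sprintf("  kinetics: dead=%gs, rate=%g/um, tau~lognormal(%gs, gsd %g)\n",
              x$dead_time, x$foci_rate, x$tau_geomean, x$tau_geosd))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
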