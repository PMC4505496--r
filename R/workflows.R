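## End-to-end analysis workflows tying segmentation, kymograph kinetics and
## foci detection together, plus a config-driven runner with a manifest.

#' Full clathrin-assembly kinetics pipeline on a movie
#'
#' Segments tubes from the lipid channel, estimates the flow-cell dead time
#' from the mean off-tube (solution) fluorescence, extracts a
#' background-corrected kymograph per tube, removes pre-arrival frames, fits
#' the plateau-plus-exponential model to every kymograph pixel, filters fits
#' at `r2_min`, collapses contiguous retained pixels into single events
#' (smallest onset wins) and summarizes the event time constants by their
#' geometric mean with 95% CI.
#'
#' @param movie `fluor_movie` with `lipid` and `clathrin` channels.
#' @param r2_min R-squared retention threshold (default 0.8).
#' @param max_gap pixel gap bridged within an event run (default 1).
#' @param min_amplitude minimum fitted amplitude for a retained pixel, in
#'   background-noise SDs (default 5); rejects low-contrast baseline wobble
#'   that can pass the R-squared filter on trend alone.
#' @param traces optional pre-computed list of `tube_trace`.
#' @return list: `dead_time_s`, `tau_summary`, `events` (pooled data.frame),
#'   `n_raw_fits`, `n_retained`, `traces`.
#' @export
analyze_kinetics_movie <- function(movie, r2_min = 0.8, max_gap = 1,
                                   min_amplitude = 5, traces = NULL) {
  li <- movie_frame(movie, "lipid")
  cl <- movie$channels$clathrin
  if (is.null(cl)) stop("movie has no clathrin channel")
  if (is.null(traces)) traces <- segment_tubes(li, movie$pixel_size)
  if (length(traces) == 0) stop("no tubes found in the lipid channel")

  excl <- .dilate_mask(.threshold_mask(li), 5)
  off <- !excl
  if (sum(off) < 500) stop("not enough off-tube pixels for the bulk trace")
  nt <- dim(cl)[3]
  bulk <- vapply(seq_len(nt), function(t) mean(cl[, , t][off]), 0)
  dead <- estimate_dead_time(bulk, movie$frame_interval)
  noise_sd <- stats::mad(cl[, , 1][off]) / sqrt(3)

  all_events <- list()
  n_raw <- n_kept <- 0L
  for (tr in traces) {
    ky <- extract_kymograph(movie, tr, "clathrin", exclusion_mask = excl)
    ky <- trim_dead_time(ky, dead)
    fits <- fit_kymograph(ky)
    n_raw <- n_raw + nrow(fits)
    keep <- filter_fits(fits, r2_min)
    keep <- keep[keep$amplitude >= min_amplitude * noise_sd, , drop = FALSE]
    n_kept <- n_kept + nrow(keep)
    ev <- deduplicate_events(keep, max_gap)
    if (ev$n_events > 0) {
      e <- ev$events
      e$trace_id <- tr$id
      all_events[[length(all_events) + 1L]] <- e
    }
  }
  events <- do.call(rbind, all_events)
  summary <- if (!is.null(events) && nrow(events) >= 2) {
    summarize_tau(events$tau)
  } else NULL
  list(dead_time_s = dead, tau_summary = summary, events = events,
       n_raw_fits = n_raw, n_retained = n_kept, traces = traces)
}

#' Foci-density pipeline on a movie at a fixed incubation time
#'
#' Segments tubes from the lipid channel, picks the clathrin frame nearest
#' `time_s` seconds after the flow-cell dead time (the fixed-incubation
#' convention that avoids focus merging at longer times), detects foci along
#' each trace and computes the pooled density per 100 um.
#'
#' @param movie `fluor_movie` with `lipid` and `clathrin` channels.
#' @param time_s incubation time after dead time (default 300 s).
#' @param k detection prominence threshold in noise SDs (default 5).
#' @param condition label attached to the result.
#' @param dead_time_s override the estimated dead time (e.g. when the movie
#'   starts after arrival).
#' @return list: `density` (`foci_density`), `foci`, `frame_index`,
#'   `dead_time_s`, `traces`.
#' @export
analyze_foci_movie <- function(movie, time_s = 300, k = 5,
                               condition = NA_character_,
                               dead_time_s = NULL) {
  li <- movie_frame(movie, "lipid")
  cl <- movie$channels$clathrin
  if (is.null(cl)) stop("movie has no clathrin channel")
  traces <- segment_tubes(li, movie$pixel_size)
  if (length(traces) == 0) stop("no tubes found in the lipid channel")

  if (is.null(dead_time_s)) {
    excl <- .dilate_mask(.threshold_mask(li), 5)
    off <- !excl
    nt <- dim(cl)[3]
    bulk <- vapply(seq_len(nt), function(t) mean(cl[, , t][off]), 0)
    dead_time_s <- tryCatch(estimate_dead_time(bulk, movie$frame_interval),
                            error = function(e) 0)
  }
  times <- (seq_len(dim(cl)[3]) - 1) * movie$frame_interval
  frame <- which.min(abs(times - (dead_time_s + time_s)))
  img <- cl[, , frame]
  foci <- detect_foci(img, traces, movie$pixel_size, k = k)
  min_sep_um <- max(1, 2.355 * 110 / movie$pixel_size) *
    movie$pixel_size / 1000
  dens <- compute_density(foci, traces, condition = condition,
                          min_sep_um = min_sep_um)
  list(density = dens, foci = foci, frame_index = frame,
       dead_time_s = dead_time_s, traces = traces)
}

# derive reproducible per-stage seeds from one master seed
.derive_seed <- function(seed, stage) {
  (seed * 1103515245 + stage * 12345) %% 2147483647
}

#' Validate a workflow run configuration
#'
#' @param config named list; must contain `workflow` (one of
#'   `"curvature"`, `"kinetics"`, `"foci"`, `"binding"`) and `seed`; optional
#'   `out_dir`, `sim` (a named list of [sim_config()] overrides) and
#'   stage parameters (`r2_min`, `k`, `time_s`, `kd`, `fmax`,
#'   `concentrations`, `noise_frac`). Unknown keys are rejected.
#' @return the validated config, invisibly.
#' @export
validate_run_config <- function(config) {
  known <- c("workflow", "seed", "out_dir", "sim", "r2_min", "k", "time_s",
             "kd", "fmax", "concentrations", "noise_frac")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0) {
    stop(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  }
  if (is.null(config$workflow) ||
      !config$workflow %in% c("curvature", "kinetics", "foci", "binding")) {
    stop("config$workflow must be one of curvature/kinetics/foci/binding")
  }
  if (is.null(config$seed)) stop("config$seed is required")
  if (!is.null(config$sim) && length(config$sim) > 0 &&
      is.null(names(config$sim))) {
    stop("config$sim must be a named list of sim_config overrides")
  }
  invisible(config)
}

#' Simulate-and-analyze workflow runner
#'
#' Runs one of the four analysis workflows on freshly simulated data and
#' writes a deterministic bundle of artifacts (CSV/JSON plus a manifest with
#' parameters, seeds and file checksums) to `config$out_dir`.
#'
#' @param config see [validate_run_config()].
#' @return the result list of the underlying workflow, invisibly; with
#'   `manifest` added when an output directory was written.
#' @export
run_workflow <- function(config) {
  validate_run_config(config)
  seed <- .derive_seed(config$seed, 1L)
  sim_args <- config$sim %||% list()
  sim_args$seed <- seed

  res <- switch(
    config$workflow,
    curvature = {
      cfg <- do.call(sim_config, sim_args)
      sim <- simulate_budded_template(cfg)
      out <- analyze_ratio_field(sim$movie)
      out$ground_truth <- sim$ground_truth
      out
    },
    kinetics = {
      sim_args$n_frames <- sim_args$n_frames %||% 120L
      cfg <- do.call(sim_config, sim_args)
      sim <- simulate_assembly_movie(cfg)
      out <- analyze_kinetics_movie(sim$movie,
                                    r2_min = config$r2_min %||% 0.8)
      out$ground_truth <- sim$ground_truth
      out
    },
    foci = {
      sim_args$n_frames <- sim_args$n_frames %||% 12L
      sim_args$frame_interval <- sim_args$frame_interval %||% 30
      cfg <- do.call(sim_config, sim_args)
      sim <- simulate_assembly_movie(cfg)
      out <- analyze_foci_movie(sim$movie, time_s = config$time_s %||% 300,
                                k = config$k %||% 5)
      out$ground_truth <- sim$ground_truth
      out
    },
    binding = {
      tit <- simulate_binding_titration(
        kd = config$kd %||% 36, fmax = config$fmax %||% 1000,
        concentrations = config$concentrations %||%
          c(0, 1, 2, 5, 10, 20, 36, 50, 100, 200, 500, 1000),
        noise_frac = config$noise_frac %||% 0.05, seed = seed)
      fit <- fit_one_site(tit$concentration_nM, tit$fluorescence,
                          tit$replicate)
      list(titration = tit, fit = fit)
    })

  if (!is.null(config$out_dir)) {
    res$manifest <- .write_bundle(res, config)
  }
  invisible(res)
}

# write workflow artifacts + manifest (versions, seeds, params, checksums)
.write_bundle <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  wj <- function(x, name) {
    p <- file.path(config$out_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    files <<- c(files, p)
  }
  wc <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  if (config$workflow == "curvature") {
    wc(res$measurements, "measurements.csv")
    wj(list(summary = res$summary, p_value = res$p_value), "summary.json")
  } else if (config$workflow == "kinetics") {
    if (!is.null(res$events)) wc(res$events, "events.csv")
    wj(list(dead_time_s = res$dead_time_s, tau_summary = res$tau_summary,
            n_raw_fits = res$n_raw_fits, n_retained = res$n_retained),
       "summary.json")
  } else if (config$workflow == "foci") {
    wc(res$foci, "foci.csv")
    wc(res$density$per_tube, "per_tube.csv")
    wj(list(density_per_100um = res$density$density,
            n_foci = res$density$n_foci,
            total_length_um = res$density$total_length_um),
       "summary.json")
  } else {
    wc(res$titration, "titration.csv")
    f <- res$fit
    wj(list(kd_nM = f$kd_nM, fmax = f$fmax, kd_se = f$kd_se,
            fmax_se = f$fmax_se, r_squared = f$r_squared, n = f$n),
       "fit.json")
  }
  manifest <- list(
    package = "tubequant",
    version = as.character(utils::packageVersion("tubequant")),
    workflow = config$workflow,
    seed = config$seed,
    derived_seed = .derive_seed(config$seed, 1L),
    parameters = config[setdiff(names(config), c("workflow", "seed", "out_dir"))],
    files = lapply(files, function(p) {
      list(name = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  manifest
}
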