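## Plateau-plus-one-phase-exponential kinetics.
##
## The clathrin signal at a single kymograph pixel is modeled as
##   F(t) = F0                                   for t <= t0
##   F(t) = F0 + A * (1 - exp(-(t - t0) / tau))  for t >  t0
## i.e. a flat plateau (pre-nucleation baseline) followed by a one-phase
## exponential rise with onset t0 and assembly time constant tau.
##
## For fixed (t0, tau) the model is linear in (F0, A), so both fitters below
## profile the linear parameters out by ordinary least squares and search only
## over the two nonlinear ones: a coarse grid for a global start, then a
## Nelder-Mead refinement of the profiled SSE.

# rise basis g(t; t0, tau) = (1 - exp(-(t - t0)/tau)) * (t > t0)
.rise_basis <- function(t, t0, tau) {
  g <- 1 - exp(-(t - t0) / tau)
  g[t <= t0] <- 0
  g
}

# profiled SSE for one trace: F0, A solved by OLS (A clamped >= 0)
.profiled_sse <- function(y, t, t0, tau) {
  g <- .rise_basis(t, t0, tau)
  n <- length(y)
  gc <- g - mean(g)
  sgg <- sum(gc^2)
  syy <- sum((y - mean(y))^2)
  if (sgg < .Machine$double.eps) {
    return(list(sse = syy, f0 = mean(y), a = 0))
  }
  beta <- sum(gc * y) / sgg
  if (beta < 0) beta <- 0
  f0 <- mean(y) - beta * mean(g)
  sse <- sum((y - f0 - beta * g)^2)
  list(sse = sse, f0 = f0, a = beta)
}

# grid of (t0, tau) candidates for a trace of duration d sampled every dt
.kinetic_grid <- function(t, n_t0 = 60, n_tau = 24) {
  d <- max(t)
  dt <- if (length(t) > 1) t[2] - t[1] else 1
  t0s <- unique(c(0, seq(0, d * 0.95, length.out = n_t0)))
  taus <- exp(seq(log(dt / 2), log(2 * d), length.out = n_tau))
  list(t0 = t0s, tau = taus,
       grid = expand.grid(t0 = t0s, tau = taus, KEEP.OUT.ATTRS = FALSE))
}

#' Fit a plateau-plus-exponential model to one intensity trace
#'
#' Fits \eqn{F(t) = F_0} for \eqn{t \le t_0} and
#' \eqn{F_0 + A(1 - e^{-(t - t_0)/\tau})} afterwards, by least squares with
#' bounds \eqn{\tau > 0}, \eqn{A \ge 0}, \eqn{0 \le t_0 \le} duration. The
#' linear parameters are profiled out analytically at every candidate
#' \eqn{(t_0, \tau)}; a coarse grid start is refined by Nelder-Mead on
#' \eqn{(t_0, \log\tau)}.
#'
#' A trace on which the optimizer fails, or whose total sum of squares is
#' zero, is returned flagged invalid with `r_squared = 0` rather than raising
#' an error, so that noise-only kymograph pixels flow through the pipeline and
#' are removed by [filter_fits()].
#'
#' @param y intensity trace (a.u.), one value per frame; at least 10 points.
#' @param frame_interval frame interval in seconds.
#' @param position optional position index carried into the result.
#' @return A one-row data.frame (`pixel_fit`): `position`, `f0`, `amplitude`,
#'   `onset_t0` (s), `tau` (s), `r_squared`, `valid`.
#' @export
fit_pixel_trace <- function(y, frame_interval, position = NA_integer_) {
  stopifnot(is.numeric(y), frame_interval > 0)
  if (length(y) < 10) stop("need at least 10 time points")
  t <- (seq_along(y) - 1) * frame_interval

  res <- tryCatch(
    .fit_plateau_exp_core(y, t),
    error = function(e) NULL
  )
  syy <- sum((y - mean(y))^2)
  if (is.null(res) || syy <= 0) {
    return(data.frame(position = position, f0 = mean(y), amplitude = 0,
                      onset_t0 = 0, tau = frame_interval, r_squared = 0,
                      valid = FALSE))
  }
  r2 <- 1 - res$sse / syy
  data.frame(position = position, f0 = res$f0, amplitude = res$a,
             onset_t0 = res$t0, tau = res$tau,
             r_squared = max(0, min(1, r2)), valid = TRUE)
}

# shared core: coarse profiled grid + Nelder-Mead refinement on (t0, log tau)
.fit_plateau_exp_core <- function(y, t, t0_start = NULL, tau_start = NULL) {
  d <- max(t)
  if (is.null(t0_start) || is.null(tau_start)) {
    gr <- .kinetic_grid(t)
    sses <- vapply(seq_len(nrow(gr$grid)), function(i) {
      .profiled_sse(y, t, gr$grid$t0[i], gr$grid$tau[i])$sse
    }, numeric(1))
    best <- which.min(sses)
    t0_start <- gr$grid$t0[best]
    tau_start <- gr$grid$tau[best]
  }
  obj <- function(par) {
    t0 <- min(max(par[1], 0), d)
    tau <- exp(par[2])
    .profiled_sse(y, t, t0, tau)$sse
  }
  opt <- stats::optim(c(t0_start, log(tau_start)), obj, method = "Nelder-Mead",
                      control = list(maxit = 400, reltol = 1e-12))
  t0 <- min(max(opt$par[1], 0), d)
  tau <- exp(opt$par[2])
  prof <- .profiled_sse(y, t, t0, tau)
  # keep grid solution if refinement drifted upward (rare, flat landscapes)
  start_sse <- .profiled_sse(y, t, t0_start, tau_start)$sse
  if (prof$sse > start_sse) {
    t0 <- t0_start; tau <- tau_start
    prof <- .profiled_sse(y, t, t0, tau)
  }
  list(t0 = t0, tau = tau, f0 = prof$f0, a = prof$a, sse = prof$sse)
}

#' Fit every pixel trace of a kymograph
#'
#' Batch version of [fit_pixel_trace()]. The coarse (t0, tau) grid is shared
#' by all pixels, so the profiled least-squares scan over the grid reduces to
#' dense matrix products; each pixel's best grid cell is then refined
#' individually.
#'
#' @param kymo a `kymograph` (see [extract_kymograph()]) or a plain L x T
#'   matrix (rows = positions, columns = frames).
#' @param frame_interval frame interval in s (taken from `kymo` if present).
#' @return data.frame of `pixel_fit` rows, one per kymograph row.
#' @export
fit_kymograph <- function(kymo, frame_interval = NULL) {
  m <- if (inherits(kymo, "kymograph")) kymo$data else kymo
  if (inherits(kymo, "kymograph") && is.null(frame_interval)) {
    frame_interval <- kymo$frame_interval
  }
  stopifnot(is.matrix(m), !is.null(frame_interval), frame_interval > 0)
  if (ncol(m) < 10) stop("need at least 10 time points")
  t <- (seq_len(ncol(m)) - 1) * frame_interval
  n <- length(t)
  Y <- t(m)                                   # n_t x n_pixels

  gr <- .kinetic_grid(t)
  G <- mapply(function(t0, tau) .rise_basis(t, t0, tau),
              gr$grid$t0, gr$grid$tau)        # n_t x K
  sg <- colSums(G)
  sggc <- colSums(G^2) - sg^2 / n
  sy <- colSums(Y)
  syyc <- colSums(Y^2) - sy^2 / n
  Cxy <- crossprod(G, Y) - outer(sg, sy) / n  # K x P centered cross-products
  ok <- sggc > .Machine$double.eps
  beta <- Cxy / ifelse(ok, sggc, 1)
  beta[!ok, ] <- 0
  beta[beta < 0] <- 0
  SSE <- matrix(syyc, nrow = nrow(beta), ncol = ncol(beta), byrow = TRUE) -
    beta^2 * sggc
  best <- max.col(-t(SSE), ties.method = "first")

  out <- lapply(seq_len(ncol(Y)), function(p) {
    y <- Y[, p]
    syy <- syyc[p]
    if (syy <= 0) {
      return(data.frame(position = p, f0 = mean(y), amplitude = 0,
                        onset_t0 = 0, tau = frame_interval, r_squared = 0,
                        valid = FALSE))
    }
    res <- tryCatch(
      .fit_plateau_exp_core(y, t, gr$grid$t0[best[p]], gr$grid$tau[best[p]]),
      error = function(e) NULL
    )
    if (is.null(res)) {
      return(data.frame(position = p, f0 = mean(y), amplitude = 0,
                        onset_t0 = 0, tau = frame_interval, r_squared = 0,
                        valid = FALSE))
    }
    r2 <- 1 - res$sse / syy
    data.frame(position = p, f0 = res$f0, amplitude = res$a,
               onset_t0 = res$t0, tau = res$tau,
               r_squared = max(0, min(1, r2)), valid = TRUE)
  })
  do.call(rbind, out)
}

#' Estimate flow-cell dead time from the bulk fluorescence trace
#'
#' The dead time is the delay between starting the flow and labeled protein
#' reaching the imaged field. It is estimated in situ by fitting the
#' plateau-plus-exponential model to the mean solution (off-tube)
#' fluorescence and taking the fitted onset.
#'
#' @param bulk_trace mean off-tube intensity per frame (a.u.).
#' @param frame_interval frame interval in s.
#' @return onset time in seconds.
#' @export
estimate_dead_time <- function(bulk_trace, frame_interval) {
  fit <- fit_pixel_trace(bulk_trace, frame_interval)
  late <- stats::median(utils::tail(bulk_trace, max(3, length(bulk_trace) %/% 5)))
  early <- stats::median(utils::head(bulk_trace, max(3, length(bulk_trace) %/% 5)))
  noise <- stats::mad(diff(bulk_trace)) / sqrt(2)
  if (!fit$valid || fit$amplitude <= 3 * max(noise, .Machine$double.eps) ||
      fit$r_squared < 0.2 || (late - early) <= 3 * noise) {
    stop("no arrival detected")
  }
  fit$onset_t0
}

#' Remove frames acquired before the dead-time onset
#'
#' Drops kymograph columns with time < onset and re-zeroes the time axis, so
#' downstream per-pixel onsets are measured from protein arrival.
#'
#' @param kymo a `kymograph` or plain matrix.
#' @param onset dead-time onset in s (frames strictly before it are removed).
#' @return object of the same kind, with an added/updated `time_offset`.
#' @export
trim_dead_time <- function(kymo, onset) {
  m <- if (inherits(kymo, "kymograph")) kymo$data else kymo
  fi <- if (inherits(kymo, "kymograph")) kymo$frame_interval else NULL
  if (is.null(fi)) stop("trim_dead_time needs a kymograph with frame_interval")
  times <- (seq_len(ncol(m)) - 1) * fi
  if (onset >= max(times) + fi) stop("onset is at or beyond movie duration")
  keep <- times >= onset
  out <- kymo
  out$data <- m[, keep, drop = FALSE]
  out$time_offset <- (kymo$time_offset %||% 0) + min(times[keep])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter per-pixel fits by goodness of fit
#'
#' Retains fits with `r_squared >= r2_min` (default 0.8), which removes
#' noise-only pixels and artifacts such as focus drift or flow-induced
#' lateral movement of foci. Order is preserved.
#'
#' @param fits data.frame of pixel fits.
#' @param r2_min minimum R-squared (default 0.8).
#' @return the retained subset.
#' @export
filter_fits <- function(fits, r2_min = 0.8) {
  if (nrow(fits) == 0) return(fits)
  fits[fits$valid & fits$r_squared >= r2_min, , drop = FALSE]
}

#' Collapse contiguous retained pixels into single assembly events
#'
#' A clathrin focus spreads its signal across several adjacent kymograph
#' pixels, so per-pixel fits oversample events. Retained pixels are grouped
#' into runs (positions separated by at most `max_gap` missing pixels belong
#' to the same run); each run yields one event whose onset and tau are taken
#' from the member fit with the smallest onset, ties broken by higher
#' R-squared, then lower position.
#'
#' @param fits position-ordered retained pixel fits from one kymograph.
#' @param max_gap maximum number of missing pixels bridged within a run
#'   (default 1).
#' @return list of class `event_set`: `events` data.frame (position,
#'   onset_t0, tau, r_squared, run_start, run_end, run_size), plus counts
#'   `n_fits` and `n_events`.
#' @export
deduplicate_events <- function(fits, max_gap = 1) {
  if (nrow(fits) == 0) {
    ev <- data.frame(position = integer(), onset_t0 = numeric(),
                     tau = numeric(), r_squared = numeric(),
                     run_start = integer(), run_end = integer(),
                     run_size = integer())
    return(structure(list(events = ev, n_fits = 0L, n_events = 0L),
                     class = "event_set"))
  }
  fits <- fits[order(fits$position), , drop = FALSE]
  gap <- c(0, diff(fits$position) - 1)
  run <- cumsum(gap > max_gap)
  events <- do.call(rbind, lapply(split(fits, run), function(r) {
    o <- order(r$onset_t0, -r$r_squared, r$position)
    b <- r[o[1], , drop = FALSE]
    data.frame(position = b$position, onset_t0 = b$onset_t0, tau = b$tau,
               r_squared = b$r_squared,
               run_start = min(r$position), run_end = max(r$position),
               run_size = nrow(r))
  }))
  rownames(events) <- NULL
  structure(list(events = events, n_fits = nrow(fits),
                 n_events = nrow(events)),
            class = "event_set")
}

#' @export
print.event_set <- function(x, ...) {
  cat(sprintf("event_set: %d events from %d retained pixel fits\n",
              x$n_events, x$n_fits))
  invisible(x)
}

#' Summarize assembly time constants on the log scale
#'
#' Clathrin assembly time constants are long-tailed, so they are summarized
#' by the geometric mean with a t-based 95% confidence interval computed in
#' log space: \eqn{\exp(\bar{x} \pm t_{0.975, n-1} s/\sqrt{n})} where
#' \eqn{x = \ln\tau}.
#'
#' @param tau vector of time constants in s (all > 0, n >= 2), or an
#'   `event_set` from [deduplicate_events()].
#' @param conf confidence level (default 0.95).
#' @return one-row data.frame: `geomean_s`, `ci_low_s`, `ci_high_s`, `n`.
#' @export
summarize_tau <- function(tau, conf = 0.95) {
  if (inherits(tau, "event_set")) tau <- tau$events$tau
  if (length(tau) < 2) stop("need at least 2 time constants")
  if (any(!is.finite(tau)) || any(tau <= 0)) stop("all tau must be > 0")
  lt <- log(tau)
  n <- length(lt)
  m <- mean(lt)
  se <- stats::sd(lt) / sqrt(n)
  q <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  data.frame(geomean_s = exp(m), ci_low_s = exp(m - q * se),
             ci_high_s = exp(m + q * se), n = n)
}
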