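## Internal renderers: membrane objects are deposited as expected intensity
## (a.u. = photons at photon_scale 1) on the pixel grid, blurred by the PSF,
## then (optionally) noised. All photometry is surface-area-proportional:
## a tube of diameter d contributes pi*d per unit length, a bud of diameter d
## contributes pi*d^2 in total, both times the density in a.u./um^2.

# deposit a line segment (pixel coords, 1-based centers) carrying
# `per_um` a.u. per um of length; optional gaps: list of (x, y, radius_px)
# circles (bud footprints) where the tube membrane is replaced by the bud
.deposit_segment <- function(img, x0, y0, x1, y1, per_um, pixel_size,
                             gaps = NULL, step_px = 0.2) {
  len_px <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
  n <- max(2L, ceiling(len_px / step_px) + 1L)
  s <- seq(0, 1, length.out = n)
  xs <- x0 + s * (x1 - x0)
  ys <- y0 + s * (y1 - y0)
  w <- rep(len_px / (n - 1), n)          # px of tube per sample
  w[c(1, n)] <- w[1] / 2                 # trapezoid ends
  keep <- rep(TRUE, n)
  if (!is.null(gaps) && nrow(gaps) > 0) {
    for (g in seq_len(nrow(gaps))) {
      keep <- keep &
        ((xs - gaps$x[g])^2 + (ys - gaps$y[g])^2 > gaps$r[g]^2)
    }
  }
  flux <- per_um * (pixel_size / 1000) * w[keep]   # a.u. per sample
  ri <- round(ys[keep]); ci <- round(xs[keep])
  ok <- ri >= 1 & ri <= nrow(img) & ci >= 1 & ci <= ncol(img)
  if (!any(ok)) return(img)
  key <- (ci[ok] - 1) * nrow(img) + ri[ok]
  tab <- tapply(flux[ok], key, sum)
  pos <- as.integer(names(tab))
  img[pos] <- img[pos] + as.numeric(tab)
  img
}

# deposit a spherical bud: projected uniform sphere-surface profile
# (density ~ 1/sqrt(R^2 - r^2), integrable edge-bright ring), total flux a.u.
.deposit_sphere <- function(img, x, y, radius_px, total_flux, sub = 8L) {
  r_out <- radius_px + 0.5
  off <- seq(-r_out, r_out, by = 1 / sub)
  gx <- rep(off, times = length(off))
  gy <- rep(off, each = length(off))
  rr <- sqrt(gx^2 + gy^2)
  inside <- rr < radius_px * 0.999
  w <- numeric(length(rr))
  w[inside] <- 1 / sqrt(pmax(radius_px^2 - rr[inside]^2, 1e-6))
  w <- w / sum(w) * total_flux
  ri <- round(y + gy); ci <- round(x + gx)
  ok <- inside & ri >= 1 & ri <= nrow(img) & ci >= 1 & ci <= ncol(img)
  if (!any(ok)) return(img)
  key <- (ci[ok] - 1) * nrow(img) + ri[ok]
  tab <- tapply(w[ok], key, sum)
  pos <- as.integer(names(tab))
  img[pos] <- img[pos] + as.numeric(tab)
  img
}

# point source (e.g. a clathrin focus): unit-flux PSF patch centered at
# subpixel (x, y); returns list(rows, cols, patch) for repeated reuse
.psf_patch <- function(x, y, sigma_px, nr, nc, halfwidth = NULL) {
  if (is.null(halfwidth)) halfwidth <- ceiling(4 * sigma_px) + 1L
  r0 <- max(1L, round(y) - halfwidth); r1 <- min(nr, round(y) + halfwidth)
  c0 <- max(1L, round(x) - halfwidth); c1 <- min(nc, round(x) + halfwidth)
  rows <- r0:r1; cols <- c0:c1
  # integrate the Gaussian over each pixel (erf differences), exact photometry
  py <- stats::pnorm(rows + 0.5, y, sigma_px) - stats::pnorm(rows - 0.5, y, sigma_px)
  px <- stats::pnorm(cols + 0.5, x, sigma_px) - stats::pnorm(cols - 0.5, x, sigma_px)
  list(rows = rows, cols = cols, patch = outer(py, px))
}

# isotropic Gaussian PSF blur (sigma in px); pixel-integrated separable
# kernel applied by shift-and-add (exact direct convolution, replicate
# edges — avoids the numerical ripple an FFT convolution spreads over the
# background, which would corrupt noise-floor estimates downstream)
.apply_psf <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  hw <- ceiling(4 * sigma_px)
  off <- seq(-hw, hw)
  k1 <- stats::pnorm(off + 0.5, 0, sigma_px) -
    stats::pnorm(off - 0.5, 0, sigma_px)
  k1 <- k1 / sum(k1)
  conv1 <- function(m, along_rows) {
    n <- if (along_rows) nrow(m) else ncol(m)
    out <- m * 0
    for (j in seq_along(off)) {
      idx <- pmin(pmax(seq_len(n) + off[j], 1), n)
      out <- out + k1[j] * (if (along_rows) m[idx, , drop = FALSE]
                            else m[, idx, drop = FALSE])
    }
    out
  }
  conv1(conv1(img, TRUE), FALSE)
}

# photon shot noise + Gaussian read noise; `noise` = NULL leaves img exact
.apply_noise <- function(img, noise) {
  if (is.null(noise)) return(img)
  lam <- pmax(img, 0) * noise$photon_scale
  shot <- array(stats::rpois(length(lam), lam), dim = dim(img)) /
    noise$photon_scale
  shot + array(stats::rnorm(length(img), 0, noise$read_sd), dim = dim(img))
}

# default layout: n_tubes horizontal rows, evenly spaced, spanning the field
# width minus margins; returns data.frame(y, x0, x1) in pixel coords
.default_layout <- function(cfg) {
  h <- cfg$image_shape[1]; w <- cfg$image_shape[2]
  n <- cfg$n_tubes
  ys <- round(seq(h / (n + 1), h * n / (n + 1), length.out = n))
  data.frame(tube_id = seq_len(n), y = ys,
             x0 = cfg$tube_margin_px + 1, x1 = w - cfg$tube_margin_px)
}
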