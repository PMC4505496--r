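## Ratiometric curvature-sorting densitometry.
##
## For diffraction-limited membrane objects the net fluorescence is
## proportional to the underlying membrane surface area, so the
## protein:lipid fluorescence ratio of an object is proportional to the
## protein surface density. Normalizing every ratio by the mean bud ratio in
## the same field expresses tube densities as fold enrichment over the
## low-curvature buds.

#' Measure the protein:lipid fluorescence ratio of one object
#'
#' Integrates background-subtracted intensity over the ROI in both channels
#' and forms the raw ratio. `backgrounds` may be scalars or full background
#' images (e.g. a camera offset plus a modeled spill-over of neighboring
#' structures into the ROI).
#'
#' @param protein_img,lipid_img registered 2-D matrices.
#' @param pixels n x 2 matrix of ROI pixel coordinates (row, col).
#' @param backgrounds list with elements `protein` and `lipid`, each a scalar
#'   or a matrix of the image size.
#' @param id,class carried into the result.
#' @return one-row data.frame: `id`, `class`, `protein_F`, `lipid_F`,
#'   `raw_ratio`, `excluded` (TRUE when `lipid_F <= 0` after correction).
#' @export
measure_object_ratio <- function(protein_img, lipid_img, pixels, backgrounds,
                                 id = NA, class = NA_character_) {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1)
  bsub <- function(img, bg) {
    v <- img[pixels]
    b <- if (is.matrix(bg)) bg[pixels] else rep(bg, nrow(pixels))
    sum(v - b)
  }
  pF <- bsub(protein_img, backgrounds$protein)
  lF <- bsub(lipid_img, backgrounds$lipid)
  excluded <- lF <= 0
  data.frame(id = id, class = class, protein_F = pF, lipid_F = lF,
             raw_ratio = if (excluded) NA_real_ else pF / lF,
             excluded = excluded)
}

#' Normalize ratios to the bud mean and summarize per class
#'
#' Divides every raw ratio by the mean bud raw ratio of its group (field),
#' so the bud class has mean 1 by construction, then reports per-class mean,
#' SD and n plus a Welch two-sample t-test of tube versus bud.
#'
#' @param measurements data.frame from [measure_object_ratio()] rows (with
#'   `class` in `"tube"`/`"bud"`); excluded rows are dropped.
#' @param group optional grouping key (one value per row); normalization is
#'   per group.
#' @return list: `measurements` (with `norm_ratio`), `summary` (per-class
#'   mean, sd, n), `p_value` (Welch t-test, tube vs bud norm ratios).
#' @export
normalize_and_summarize <- function(measurements, group = NULL) {
  m <- measurements[!measurements$excluded, , drop = FALSE]
  if (is.null(group)) group <- rep(1L, nrow(m)) else group <- group[!measurements$excluded]
  if (!any(m$class == "bud")) stop("no buds present: nothing to normalize to")
  m$norm_ratio <- NA_real_
  for (g in unique(group)) {
    sel <- group == g
    ref <- mean(m$raw_ratio[sel & m$class == "bud"])
    if (!is.finite(ref) || ref <= 0) stop("no buds present: nothing to normalize to")
    m$norm_ratio[sel] <- m$raw_ratio[sel] / ref
  }
  sm <- do.call(rbind, lapply(split(m, m$class), function(d) {
    data.frame(class = d$class[1], mean = mean(d$norm_ratio),
               sd = stats::sd(d$norm_ratio), n = nrow(d))
  }))
  rownames(sm) <- NULL
  p <- if (sum(m$class == "tube") >= 2 && sum(m$class == "bud") >= 2) {
    tryCatch(
      stats::t.test(m$norm_ratio[m$class == "tube"],
                    m$norm_ratio[m$class == "bud"])$p.value,
      error = function(e) NA_real_)   # degenerate (constant) samples
  } else NA_real_
  list(measurements = m, summary = sm, p_value = p)
}

# per-pixel line intensity of a trace (pre-blur a.u. per centerline px),
# estimated from the 3-px band sum away from buds; `band_frac` is the PSF
# mass captured by the band
.trace_line_intensity <- function(img, coords, bg, sigma_px, keep) {
  band <- .band_pixels(coords, nrow(img), ncol(img), 3)
  sums <- rowSums(matrix(img[band$idx] - bg, ncol = 3))
  band_frac <- 2 * stats::pnorm(1.5 / sigma_px) - 1
  stats::median(sums[keep]) / band_frac
}

# band pixel coordinates: width rows normal to the trace at every position;
# returns list(idx = (width*n) index matrix stacked by offset, n = n)
.band_pixels <- function(coords, nr, nc, width = 3) {
  half <- (width - 1) / 2
  n <- nrow(coords)
  t_prev <- coords[pmax(seq_len(n) - 1, 1), , drop = FALSE]
  t_next <- coords[pmin(seq_len(n) + 1, n), , drop = FALSE]
  tang <- t_next - t_prev
  norms <- sqrt(rowSums(tang^2)); norms[norms == 0] <- 1
  normal <- cbind(-tang[, 2], tang[, 1]) / norms
  idx <- do.call(rbind, lapply(seq(-half, half), function(o) {
    rc <- round(coords + o * normal)
    rc[, 1] <- pmin(pmax(rc[, 1], 1), nr)
    rc[, 2] <- pmin(pmax(rc[, 2], 1), nc)
    rc
  }))
  list(idx = idx, n = n)
}

# model image of tube spill-over near buds: deposit the estimated per-pixel
# line intensity continuously along each (smoothed) trace, leaving sub-pixel
# accurate gaps of the bud radius, and blur with the PSF. Sub-pixel gap
# placement matters: the tube is an order of magnitude brighter per pixel
# than the bud in the protein channel, so half a pixel of mis-placed line
# mass visibly biases the bud photometry.
.tube_leak_image <- function(dim_hw, traces, line_int, buds, sigma_px,
                             pixel_size) {
  leak <- matrix(0, dim_hw[1], dim_hw[2])
  if (length(traces) == 0 || length(buds) == 0) return(leak)
  gaps <- data.frame(
    x = vapply(buds, function(b) b$centroid[2], 0),
    y = vapply(buds, function(b) b$centroid[1], 0),
    r = vapply(buds, function(b) b$radius_px, 0)
  )
  dep <- matrix(0, dim_hw[1], dim_hw[2])
  smooth5 <- function(v) as.numeric(stats::filter(v, rep(1 / 5, 5))) |>
    (\(s) ifelse(is.na(s), v, s))()
  for (i in seq_along(traces)) {
    co <- traces[[i]]$coords
    if (line_int[i] <= 0 || nrow(co) < 2) next
    ys <- smooth5(co[, 1])   # skeleton wiggle through buds is not physical
    xs <- smooth5(co[, 2])
    per_um <- line_int[i] * 1000 / pixel_size   # a.u. per um of centerline
    for (s in seq_len(length(xs) - 1)) {
      dep <- .deposit_segment(dep, xs[s], ys[s], xs[s + 1], ys[s + 1],
                              per_um, pixel_size, gaps)
    }
  }
  .apply_psf(dep, sigma_px)
}

#' Ratiometric analysis of a budded-template field
#'
#' Full curvature-sorting pipeline: segments tubes and buds from the lipid
#' channel, estimates per-channel backgrounds, measures each object's
#' protein:lipid ratio and summarizes bud-normalized enrichments.
#'
#' Two spill-over controls keep tube and bud photometry independent even
#' though buds sit on the tubes: (i) tube integration excludes positions
#' within `excl_sigma` PSF sigmas plus one bud radius of any bud centroid;
#' (ii) bud integration subtracts a modeled image of the flanking tube
#' rendered through the PSF (the tube is far brighter per pixel in the
#' protein channel than the bud, so unmodeled bleed-through would inflate the
#' bud normalizer).
#'
#' @param movie a `fluor_movie` with `lipid` and `protein` channels.
#' @param psf_sigma PSF sigma in nm (default 110).
#' @param excl_sigma exclusion half-width around buds for tube integration,
#'   in PSF sigmas beyond the bud radius (default 3.5).
#' @param k segmentation threshold (robust SDs, default 4).
#' @return as [normalize_and_summarize()], plus `traces` and `buds`.
#' @export
analyze_ratio_field <- function(movie, psf_sigma = 110, excl_sigma = 3.5,
                                k = 4) {
  li <- movie_frame(movie, "lipid")
  pr <- movie_frame(movie, "protein")
  px <- movie$pixel_size
  sigma_px <- psf_sigma / px

  traces <- segment_tubes(li, px, k = k)
  buds <- segment_buds(li, px, psf_sigma = psf_sigma, k = k)
  mask <- .dilate_mask(.threshold_mask(li, k), 5)
  bg_l <- estimate_background(li, mask)
  bg_p <- estimate_background(pr, mask)

  # tube measurements: 3-px band, bud neighborhoods excluded
  meas <- list()
  line_l <- line_p <- numeric(length(traces))
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    keep <- rep(TRUE, nrow(tr$coords))
    for (b in buds) {
      r_ex <- b$radius_px + excl_sigma * sigma_px
      keep <- keep & ((tr$coords[, 1] - b$centroid[1])^2 +
                        (tr$coords[, 2] - b$centroid[2])^2 > r_ex^2)
    }
    if (sum(keep) < 5) next
    band <- .band_pixels(tr$coords[keep, , drop = FALSE], nrow(li), ncol(li))
    meas[[length(meas) + 1L]] <- measure_object_ratio(
      pr, li, band$idx, list(protein = bg_p, lipid = bg_l),
      id = paste0("tube", tr$id), class = "tube")
    line_l[i] <- .trace_line_intensity(li, tr$coords, bg_l, sigma_px, keep)
    line_p[i] <- .trace_line_intensity(pr, tr$coords, bg_p, sigma_px, keep)
  }

  # bud measurements: blurred-tube model added to the background
  leak_l <- .tube_leak_image(dim(li), traces, line_l, buds, sigma_px, px)
  leak_p <- .tube_leak_image(dim(pr), traces, line_p, buds, sigma_px, px)
  for (b in buds) {
    meas[[length(meas) + 1L]] <- measure_object_ratio(
      pr, li, b$pixels,
      list(protein = bg_p + leak_p, lipid = bg_l + leak_l),
      id = paste0("bud", b$id), class = "bud")
  }

  res <- normalize_and_summarize(do.call(rbind, meas))
  res$traces <- traces
  res$buds <- buds
  res
}
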