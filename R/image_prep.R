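## Segmentation of the lipid channel into tube centerlines and bud ROIs,
## plus background estimation and kymograph extraction.

# robust foreground mask: background median + k * robust SD (MAD).
# On noiseless synthetic images the MAD collapses to 0; fall back to a small
# fraction of the dynamic range so the threshold still hugs the background.
.threshold_mask <- function(img, k = 4) {
  bg <- stats::median(img)
  s <- max(stats::mad(img), 0.01 * (max(img) - bg))
  if (is.na(s) || s == 0) return(img > bg)   # degenerate constant image
  img > bg + k * s
}

.dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  EBImage::dilate(mask * 1, EBImage::makeBrush(2 * floor(r) + 1, "disc")) > 0
}

# Zhang-Suen thinning; vectorized over the whole matrix
.skeletonize <- function(mask) {
  p <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  sh <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- sh(p, -1, 0); p3 <- sh(p, -1, 1); p4 <- sh(p, 0, 1)
      p5 <- sh(p, 1, 1);  p6 <- sh(p, 1, 0);  p7 <- sh(p, 1, -1)
      p8 <- sh(p, 0, -1); p9 <- sh(p, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1) {
        cond <- p == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- p == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        p[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p > 0
}

# count of 8-neighbors for each skeleton pixel
.neighbor_count <- function(skel) {
  s <- matrix(as.integer(skel), nrow(skel), ncol(skel))
  k <- matrix(1, 3, 3); k[2, 2] <- 0
  n <- EBImage::filter2(s, k, boundary = 0)
  round(n) * skel
}

# order the pixels of a simple 8-connected path; coords = n x 2 (row, col)
.order_path <- function(coords) {
  n <- nrow(coords)
  if (n <= 2) return(coords)
  key <- paste(coords[, 1], coords[, 2])
  idx <- seq_len(n)
  names(idx) <- key
  adj <- lapply(seq_len(n), function(i) {
    dr <- abs(coords[, 1] - coords[i, 1])
    dc <- abs(coords[, 2] - coords[i, 2])
    which(dr <= 1 & dc <= 1 & (dr + dc) > 0)
  })
  deg <- lengths(adj)
  start <- if (any(deg == 1)) which(deg == 1)[1] else 1L
  visited <- logical(n)
  path <- integer(n)
  cur <- start
  for (i in seq_len(n)) {
    path[i] <- cur
    visited[cur] <- TRUE
    nxt <- adj[[cur]][!visited[adj[[cur]]]]
    if (length(nxt) == 0) {
      path <- path[seq_len(i)]
      break
    }
    if (length(nxt) > 1) {   # prefer 4-connected continuation
      d <- abs(coords[nxt, 1] - coords[cur, 1]) +
        abs(coords[nxt, 2] - coords[cur, 2])
      nxt <- nxt[order(d)]
    }
    cur <- nxt[1]
  }
  coords[path, , drop = FALSE]
}

.path_length_um <- function(coords, pixel_size) {
  if (nrow(coords) < 2) return(0)
  steps <- sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2)
  sum(steps) * pixel_size / 1000
}

#' Segment tube centerlines from a lipid-channel image
#'
#' Thresholds the image at background + `k` robust SDs, fills holes,
#' skeletonizes the foreground (Zhang-Suen thinning), splits the skeleton at
#' junction pixels and orders each remaining branch into a centerline path.
#' The skeleton runs straight through buds sitting on a tube, so a budded
#' tube is returned as one continuous trace. Traces shorter than
#' `min_length_um` are discarded.
#'
#' @param lipid_image single-channel 2-D matrix.
#' @param pixel_size nm per pixel.
#' @param k threshold in robust SDs above background (default 4).
#' @param min_length_um minimum retained trace length (default 2 um).
#' @return list of `tube_trace`: `id`, `coords` (n x 2, row/col), `length_um`.
#' @export
segment_tubes <- function(lipid_image, pixel_size, k = 4, min_length_um = 2) {
  stopifnot(is.matrix(lipid_image), pixel_size > 0)
  mask <- .threshold_mask(lipid_image, k)
  if (!any(mask)) return(list())
  mask <- EBImage::fillHull(mask * 1) > 0
  skel <- .skeletonize(mask)
  nbr <- .neighbor_count(skel)
  branch <- skel & nbr <= 2                 # drop junction pixels
  if (!any(branch)) return(list())
  lab <- EBImage::bwlabel(branch * 1)
  traces <- list()
  for (id in seq_len(max(lab))) {
    coords <- which(lab == id, arr.ind = TRUE)
    coords <- .order_path(coords)
    len <- .path_length_um(coords, pixel_size)
    if (len >= min_length_um) {
      traces[[length(traces) + 1L]] <- structure(
        list(id = length(traces) + 1L, coords = unname(coords),
             length_um = len),
        class = "tube_trace")
    }
  }
  traces
}

#' Segment bud ROIs from a lipid-channel image
#'
#' Buds are thick blobs on the thin-tube mask: foreground pixels whose
#' distance-transform radius exceeds 2 px form bud cores. For each core the
#' routine estimates a centroid and a moment-based equivalent diameter: the
#' background-subtracted, tube-subtracted intensity second moment per axis is
#' \eqn{R^2/3 + \sigma_{PSF}^2} for a spherical shell of radius R convolved
#' with a Gaussian PSF, which is solved for R. The intensity of the tube
#' passing through the bud is estimated from flanking columns along the tube
#' axis and removed before taking moments.
#'
#' @param lipid_image single-channel 2-D matrix.
#' @param pixel_size nm per pixel.
#' @param psf_sigma PSF sigma in nm (default 110).
#' @param k threshold in robust SDs (default 4).
#' @param min_diameter_nm smallest retained equivalent diameter (default 250).
#' @param core_radius_px distance-transform radius separating buds from the
#'   thin tube mask (default 2).
#' @return list of `bud_roi`: `id`, `centroid` (row, col), `diameter_nm`,
#'   `radius_px`, `pixels` (n x 2 ROI pixel coords covering the blurred bud).
#' @export
segment_buds <- function(lipid_image, pixel_size, psf_sigma = 110, k = 4,
                         min_diameter_nm = 250, core_radius_px = 2) {
  stopifnot(is.matrix(lipid_image), pixel_size > 0)
  mask <- .threshold_mask(lipid_image, k)
  if (!any(mask)) return(list())
  mask <- EBImage::fillHull(mask * 1) > 0
  dm <- EBImage::distmap(mask * 1)
  core <- dm > core_radius_px
  if (!any(core)) return(list())
  lab <- EBImage::bwlabel(core * 1)
  sigma_px <- psf_sigma / pixel_size
  bg <- stats::median(lipid_image[!mask])
  rois <- list()
  for (id in seq_len(max(lab))) {
    core_px <- which(lab == id, arr.ind = TRUE)
    cy <- mean(core_px[, 1]); cx <- mean(core_px[, 2])
    est <- .bud_moment_diameter(lipid_image, cy, cx, sigma_px, bg)
    d_nm <- 2 * est$radius_px * pixel_size
    if (!is.finite(d_nm) || d_nm < min_diameter_nm) next
    r_roi <- ceiling(est$radius_px + 2.5 * sigma_px)
    rr <- round(est$cy) + seq(-r_roi, r_roi)
    cc <- round(est$cx) + seq(-r_roi, r_roi)
    grid <- expand.grid(row = rr, col = cc)
    keep <- (grid$row - est$cy)^2 + (grid$col - est$cx)^2 <= r_roi^2 &
      grid$row >= 1 & grid$row <= nrow(lipid_image) &
      grid$col >= 1 & grid$col <= ncol(lipid_image)
    rois[[length(rois) + 1L]] <- structure(
      list(id = length(rois) + 1L,
           centroid = c(est$cy, est$cx),
           diameter_nm = d_nm,
           radius_px = est$radius_px,
           pixels = as.matrix(grid[keep, , drop = FALSE])),
      class = "bud_roi")
  }
  rois
}

# moment-based bud size: refine centroid, subtract flanking-tube profile,
# average x/y second moments, remove PSF variance in quadrature
.bud_moment_diameter <- function(img, cy, cx, sigma_px, bg, win = 3L) {
  nr <- nrow(img); nc <- ncol(img)
  rr <- max(1, round(cy) - win):min(nr, round(cy) + win)
  cc <- max(1, round(cx) - win):min(nc, round(cx) + win)
  w <- img[rr, cc, drop = FALSE] - bg
  # per-row tube level from columns 5..9 px away on both sides
  fl <- c(max(1, round(cx) - win - 5):max(1, round(cx) - win - 1),
          min(nc, round(cx) + win + 1):min(nc, round(cx) + win + 5))
  fl <- unique(fl[fl >= 1 & fl <= nc])
  tube_prof <- apply(img[rr, fl, drop = FALSE] - bg, 1, stats::median)
  w <- w - tube_prof        # signed: noise cancels in the moments
  tot <- sum(w)
  if (tot <= 0) return(list(radius_px = NA_real_, cy = cy, cx = cx))
  cy2 <- sum(rr * rowSums(w)) / tot
  cx2 <- sum(cc * colSums(w)) / tot
  vy <- sum(outer(rr - cy2, rep(1, length(cc)))^2 * w) / tot
  vx <- sum(outer(rep(1, length(rr)), cc - cx2)^2 * w) / tot
  # PSF variance plus Sheppard corrections (1/12 px^2 each) for the pixel
  # binning of the photometry and the pixel-integrated PSF kernel
  v <- (vy + vx) / 2 - sigma_px^2 - 1 / 6
  list(radius_px = if (v > 0) sqrt(3 * v) else NA_real_, cy = cy2, cx = cx2)
}

#' Estimate the background level of a frame
#'
#' Median intensity over pixels outside the exclusion mask (which should
#' cover all membrane objects, dilated).
#'
#' @param image 2-D matrix.
#' @param exclusion_mask logical matrix, `TRUE` = excluded.
#' @return scalar background in a.u.
#' @export
estimate_background <- function(image, exclusion_mask = NULL) {
  if (is.null(exclusion_mask)) {
    exclusion_mask <- .dilate_mask(.threshold_mask(image), 5)
  }
  if (all(exclusion_mask)) stop("exclusion mask covers the entire frame")
  stats::median(image[!exclusion_mask])
}

#' Extract a background-corrected kymograph along a tube trace
#'
#' Row i, column t of the kymograph is the intensity at trace point i in
#' frame t, averaged over a `width`-pixel band normal to the local trace
#' direction, minus the per-frame background (median over pixels outside the
#' exclusion mask). With per-frame correction the rising bulk solution signal
#' is removed along with the camera offset, so off-focus rows sit near zero.
#'
#' @param movie a `fluor_movie`.
#' @param trace a `tube_trace` from [segment_tubes()].
#' @param channel channel name (default `"clathrin"`).
#' @param width sampling band width in pixels, odd (default 3).
#' @param exclusion_mask logical matrix of object pixels to exclude from the
#'   per-frame background; defaults to a 5-px dilation of the lipid-channel
#'   mask (or of this channel's mean-frame mask if no lipid channel exists).
#' @return object of class `kymograph`: `data` (L x T matrix), `frame_interval`,
#'   `trace_id`, `corrected = TRUE`, `time_offset = 0`,
#'   `background` (per-frame vector).
#' @export
extract_kymograph <- function(movie, trace, channel = "clathrin", width = 3,
                              exclusion_mask = NULL) {
  ch <- movie$channels[[channel]]
  if (is.null(ch)) stop(sprintf("no channel '%s'", channel))
  coords <- trace$coords
  nr <- dim(ch)[1]; nc <- dim(ch)[2]; nt <- dim(ch)[3]
  if (any(coords[, 1] < 1 | coords[, 1] > nr |
          coords[, 2] < 1 | coords[, 2] > nc)) {
    stop(sprintf("trace %s exits the frame", trace$id))
  }
  if (is.null(exclusion_mask)) {
    ref <- if (!is.null(movie$channels$lipid)) {
      movie$channels$lipid[, , 1]
    } else {
      apply(ch, c(1, 2), mean)
    }
    exclusion_mask <- .dilate_mask(.threshold_mask(ref), 5)
  }

  # band sampling offsets along the local normal
  half <- (width - 1) / 2
  n <- nrow(coords)
  t_prev <- coords[pmax(seq_len(n) - 1, 1), , drop = FALSE]
  t_next <- coords[pmin(seq_len(n) + 1, n), , drop = FALSE]
  tang <- t_next - t_prev
  norms <- sqrt(rowSums(tang^2)); norms[norms == 0] <- 1
  normal <- cbind(-tang[, 2], tang[, 1]) / norms
  samp <- lapply(seq(-half, half), function(o) {
    rc <- round(coords + o * normal)
    rc[, 1] <- pmin(pmax(rc[, 1], 1), nr)
    rc[, 2] <- pmin(pmax(rc[, 2], 1), nc)
    rc
  })

  data <- matrix(0, n, nt)
  bgv <- numeric(nt)
  off <- !exclusion_mask
  for (t in seq_len(nt)) {
    fr <- ch[, , t]
    bgv[t] <- stats::median(fr[off])
    acc <- numeric(n)
    for (s in samp) acc <- acc + fr[s]
    data[, t] <- acc / length(samp) - bgv[t]
  }
  structure(list(data = data, frame_interval = movie$frame_interval,
                 trace_id = trace$id, corrected = TRUE, time_offset = 0,
                 background = bgv),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph: %d positions x %d frames @ %g s (trace %s)\n",
              nrow(x$data), ncol(x$data), x$frame_interval, x$trace_id))
  invisible(x)
}

#' @export
print.tube_trace <- function(x, ...) {
  cat(sprintf("tube_trace %s: %d px, %.2f um\n", x$id, nrow(x$coords),
              x$length_um))
  invisible(x)
}

#' @export
print.bud_roi <- function(x, ...) {
  cat(sprintf("bud_roi %s: centroid (%.1f, %.1f), d = %.0f nm\n", x$id,
              x$centroid[1], x$centroid[2], x$diameter_nm))
  invisible(x)
}
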