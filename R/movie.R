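#' Multi-channel fluorescence movie container
#'
#' Holds named channels as H x W x T arrays sharing pixel size (nm) and frame
#' interval (s). Time-invariant channels (e.g. the lipid channel of an
#' assembly movie) may carry a single frame.
#'
#' @param channels named list of H x W matrices or H x W x T arrays (a.u.).
#' @param pixel_size nm per pixel (> 0).
#' @param frame_interval s per frame (> 0).
#' @return object of class `fluor_movie`.
#' @export
fluor_movie <- function(channels, pixel_size, frame_interval) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), pixel_size > 0, frame_interval > 0)
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, dim = c(dim(ch), 1L))
    stopifnot(length(dim(ch)) == 3)
    ch
  })
  hw <- lapply(channels, function(ch) dim(ch)[1:2])
  if (length(unique(hw)) != 1) stop("all channels must share H x W")
  structure(list(channels = channels, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "fluor_movie")
}

#' @export
print.fluor_movie <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("fluor_movie: %dx%d px @ %g nm, channels: %s\n",
              d[1], d[2], x$pixel_size,
              paste(sprintf("%s[%d]", names(x$channels),
                            vapply(x$channels, function(c) dim(c)[3], 1L)),
                    collapse = ", ")))
  invisible(x)
}

#' Extract one frame of one channel
#'
#' @param movie a `fluor_movie`.
#' @param channel channel name.
#' @param frame frame index (a single-frame channel always returns its frame).
#' @return H x W matrix.
#' @export
movie_frame <- function(movie, channel, frame = 1L) {
  ch <- movie$channels[[channel]]
  if (is.null(ch)) stop(sprintf("no channel '%s'", channel))
  if (dim(ch)[3] == 1L) frame <- 1L
  ch[, , frame]
}

#' Write a movie as multi-page TIFF plus a JSON sidecar
#'
#' Pages are ordered frame-major within channel, channels in list order;
#' 32-bit float samples. TIFF samples are stored on a 0..1 scale; the
#' per-channel scale factor (and offset, for negative-valued corrected data)
#' is recorded in the sidecar together with channel names, frame counts,
#' pixel size and frame interval, so the movie round-trips losslessly through
#' [read_movie_tiff()].
#'
#' @param movie a `fluor_movie`.
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @param extra optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, extra = NULL) {
  pages <- list()
  offsets <- scales <- numeric(length(movie$channels))
  k <- 0L
  for (nm in names(movie$channels)) {
    k <- k + 1L
    ch <- movie$channels[[nm]]
    offsets[k] <- min(ch, 0)
    scales[k] <- max(ch - offsets[k], .Machine$double.eps)
    for (t in seq_len(dim(ch)[3])) {
      pages[[length(pages) + 1L]] <- (ch[, , t] - offsets[k]) / scales[k]
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    channels = names(movie$channels),
    n_frames = vapply(movie$channels, function(c) dim(c)[3], 1L),
    scale = scales, offset = offsets,
    pixel_size_nm = movie$pixel_size,
    frame_interval_s = movie$frame_interval
  )
  if (!is.null(extra)) meta <- c(meta, extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path TIFF path with `<path>.json` sidecar alongside.
#' @return a `fluor_movie`.
#' @export
read_movie_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  channels <- list()
  i <- 1L
  for (k in seq_along(meta$channels)) {
    nf <- meta$n_frames[k]
    arr <- array(0, dim = c(dim(pages[[i]]), nf))
    for (t in seq_len(nf)) {
      arr[, , t] <- pages[[i]] * meta$scale[k] + meta$offset[k]
      i <- i + 1L
    }
    channels[[meta$channels[k]]] <- arr
  }
  fluor_movie(channels, meta$pixel_size_nm, meta$frame_interval_s)
}
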