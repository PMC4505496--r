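#' Write tube traces to CSV
#'
#' One row per centerline pixel: `trace_id`, `point`, `row`, `col`, plus the
#' trace length repeated per row for convenience.
#'
#' @param traces list of `tube_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(trace_id = tr$id, point = seq_len(nrow(tr$coords)),
               row = tr$coords[, 1], col = tr$coords[, 2],
               length_um = tr$length_um)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a kymograph to CSV
#'
#' Long format: `position`, `frame`, `time_s` (including any trim offset),
#' `intensity`.
#'
#' @param kymo a `kymograph`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_kymograph_csv <- function(kymo, path) {
  L <- nrow(kymo$data); T <- ncol(kymo$data)
  df <- data.frame(
    position = rep(seq_len(L), times = T),
    frame = rep(seq_len(T), each = L),
    time_s = rep((seq_len(T) - 1) * kymo$frame_interval +
                   (kymo$time_offset %||% 0), each = L),
    intensity = as.vector(kymo$data)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
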