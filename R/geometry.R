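#' Correct an SEM diameter for coating layers
#'
#' Scanning electron microscopy of fixed membrane templates measures the outer
#' diameter of the object plus every coating layer deposited on it (e.g.
#' streptavidin, sputtered gold). Each layer adds its thickness on both sides
#' of the object, so the membrane diameter is the measured value minus twice
#' the summed layer thicknesses.
#'
#' @param measured measured mean diameter in nm (positive scalar or vector).
#' @param layers numeric vector of coating-layer thicknesses in nm, one entry
#'   per layer (e.g. `c(streptavidin = 4.4, gold = 4.0)`). All must be >= 0.
#' @return A data.frame with columns `measured_nm`, `corrected_nm` and
#'   `corrected_round_nm` (nearest integer nm, the convention used when
#'   quoting nominal diameters).
#' @examples
#' correct_diameter(63.3, c(4.4, 4.0))   # tube: 46.5 nm, nominally 47 nm
#' correct_diameter(425.0, c(4.4, 4.0))  # bud: 408.2 nm, nominally 408 nm
#' @export
correct_diameter <- function(measured, layers) {
  stopifnot(is.numeric(measured), is.numeric(layers))
  if (any(layers < 0)) stop("layer thicknesses must be >= 0")
  offset <- 2 * sum(layers)
  if (any(measured <= offset)) {
    stop(sprintf("coating correction (%g nm) exceeds measured diameter", offset))
  }
  corrected <- measured - offset
  data.frame(
    measured_nm = measured,
    corrected_nm = corrected,
    # half-up rounding: nominal diameters are conventionally quoted with
    # 0.5 rounded away from zero (63.3 - 16.8 = 46.5 -> 47)
    corrected_round_nm = floor(corrected + 0.5)
  )
}

#' Summarize a sample of diameter measurements
#'
#' @param diameters numeric vector of diameters in nm, all > 0, length >= 2.
#' @param class optional object class label ("tube" or "bud").
#' @return A one-row data.frame with `mean_nm`, `sd_nm`, `n` and `class`.
#' @export
summarize_diameters <- function(diameters, class = NA_character_) {
  if (length(diameters) == 0) stop("empty diameter sample")
  if (length(diameters) < 2) stop("need at least 2 measurements to summarize")
  if (any(!is.finite(diameters)) || any(diameters <= 0)) {
    stop("all diameters must be finite and > 0")
  }
  data.frame(
    class = class,
    mean_nm = mean(diameters),
    sd_nm = stats::sd(diameters),
    n = length(diameters)
  )
}
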