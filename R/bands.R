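#' Frequency band specification
#'
#' A band is a named closed frequency interval in Hz. The conventional five
#' EEG rhythms used as differential-entropy feature dimensions are delta
#' (1-3 Hz), theta (4-7 Hz), alpha (8-13 Hz), beta (14-30 Hz) and gamma
#' (31-50 Hz).
#'
#' @param name band label.
#' @param low lower edge, Hz; must satisfy `0 < low < high`.
#' @param high upper edge, Hz.
#' @return An object of class `band_spec`.
#' @examples
#' band_spec("alpha", 8, 13)
#' @export
band_spec <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(is.numeric(low) && is.numeric(high) && low > 0 && low < high)) {
    stop("band edges must satisfy 0 < low < high, got [", low, ", ", high, "]")
  }
  structure(list(name = name, low = low, high = high), class = "band_spec")
}

#' Default five-band EEG rhythm set
#'
#' @return A named list of five [band_spec] objects: delta 1-3, theta 4-7,
#'   alpha 8-13, beta 14-30, gamma 31-50 Hz.
#' @export
default_bands <- function() {
  list(
    delta = band_spec("delta", 1, 3),
    theta = band_spec("theta", 4, 7),
    alpha = band_spec("alpha", 8, 13),
    beta  = band_spec("beta", 14, 30),
    gamma = band_spec("gamma", 31, 50)
  )
}

band_names <- function(bands) vapply(bands, `[[`, character(1), "name")

highest_band_edge <- function(bands) max(vapply(bands, `[[`, numeric(1), "high"))

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}
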