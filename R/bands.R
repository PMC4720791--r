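#' Canonical EEG frequency bands
#'
#' The six analysis bands used throughout the package: the near-DC MRCP band,
#' the four classical sensorimotor-rhythm subbands, and the full band covering
#' all of them.
#'
#' @return A tibble with columns `band` (name), `low` and `high` (band edges
#'   in Hz).
#' @examples
#' band_definitions()
#' @export
band_definitions <- function() {
  tibble::tibble(
    band = c("MRCP", "Theta", "Alpha", "Beta", "Gamma", "Full"),
    low  = c(0.05, 4, 8, 16, 31, 0.05),
    high = c(3, 7, 15, 30, 40, 40)
  )
}

#' Construct a band definition
#'
#' @param band Either the name of a canonical band (see [band_definitions()]),
#'   or an arbitrary name when `low`/`high` are given.
#' @param low,high Band edges in Hz; looked up from the canonical table when
#'   omitted.
#' @return A one-row tibble with columns `band`, `low`, `high`.
#' @examples
#' band_spec("Beta")
#' band_spec("custom", 6, 12)
#' @export
band_spec <- function(band, low = NULL, high = NULL) {
  if (is.null(low) || is.null(high)) {
    tab <- band_definitions()
    hit <- tab[tab$band == band, ]
    if (nrow(hit) != 1L) {
      stop("unknown band '", band, "'; give explicit low/high edges", call. = FALSE)
    }
    return(hit)
  }
  if (!(is.numeric(low) && is.numeric(high) && low > 0 && low < high)) {
    stop("band edges must satisfy 0 < low < high", call. = FALSE)
  }
  tibble::tibble(band = band, low = low, high = high)
}
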