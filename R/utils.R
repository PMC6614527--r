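#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for the published coverage
#' percentages and per-hub caseload averages. Base [round()] rounds half to
#' even, which does not reproduce the printed tables.
#'
#' @param x Numeric vector (non-negative in all package uses).
#' @param digits Number of decimal places to keep.
#' @return `x` rounded with ties going up.
#' @examples
#' round_half_up(464.5)        # 465, where round() gives 464
#' round_half_up(83.25, 1)     # 83.3
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# stop() wrapper without the call, matching the style of the readers
abort <- function(...) stop(..., call. = FALSE)

check_coords <- function(lat, lon, what = "point") {
  ok <- is.numeric(lat) && is.numeric(lon) &&
    all(is.finite(lat)) && all(is.finite(lon)) &&
    all(lat >= -90 & lat <= 90) && all(lon >= -180 & lon <= 180)
  if (!ok) {
    abort(sprintf("invalid %s coordinates: lat must lie in [-90, 90], lon in [-180, 180]",
                  what))
  }
  invisible(TRUE)
}

# deterministic uniform in [0, 1) from a character key (djb2-style modular
# hash); drives the reproducible travel-time noise without touching the
# global RNG stream
hash_unit <- function(key) {
  m <- 2147483647
  vapply(key, function(k) {
    h <- 5381
    for (b in utf8ToInt(k)) h <- (h * 33 + b) %% m
    h / m
  }, numeric(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
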