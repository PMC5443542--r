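#' @keywords internal
"_PACKAGE"

# Mean Earth radius in km, used for all great-circle and cell-area work.
EARTH_RADIUS_KM <- 6371.0088

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Round half away from zero
#'
#' Reported index values are rounded half away from zero (so 64.546 prints as
#' 64.55 and -0.025 as -0.03), unlike base [round()] which rounds half to
#' even. Computation is always carried out in full precision; this is applied
#' only when rendering reports.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_out <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Great-circle distance
#'
#' Haversine distance between points on a sphere of Earth's mean radius.
#' Inputs are recycled; degrees in, kilometres out.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distances in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
# Keeps every stochastic operation a pure function of its explicit seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

check_range <- function(x, lo, hi, what) {
  bad <- !is.na(x) & (x < lo | x > hi)
  if (any(bad)) {
    stop(sprintf("%s must be in [%g, %g]; got %s", what, lo, hi,
                 paste(format(x[bad][seq_len(min(3, sum(bad)))]), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

check_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("%s must be a single finite number", what), call. = FALSE)
  }
  invisible(x)
}
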