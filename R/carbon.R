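#' Rectangular lat/lon grid field
#'
#' A simple carrier for gridded values (bathymetric depth in metres, positive
#' downward, or ice concentration as a 0-1 fraction) on a regular
#' latitude/longitude grid. `values` is a matrix with one row per latitude
#' and one column per longitude; coordinates are cell centres.
#'
#' @param lat vector of cell-centre latitudes in \[-90, 90\], regular spacing.
#' @param lon vector of cell-centre longitudes in \[-180, 180\], regular spacing.
#' @param values numeric matrix, `length(lat)` x `length(lon)`.
#' @return an object of class `grid_field`.
#' @export
grid_field <- function(lat, lon, values) {
  check_range(lat, -90, 90, "latitude")
  check_range(lon, -180, 180, "longitude")
  values <- as.matrix(values)
  if (nrow(values) != length(lat) || ncol(values) != length(lon)) {
    stop("values must be a length(lat) x length(lon) matrix", call. = FALSE)
  }
  regular <- function(coords) {
    length(coords) < 3 ||
      max(abs(diff(diff(coords)))) <= 1e-8 * abs(mean(diff(coords)))
  }
  if (!regular(lat)) stop("latitudes must be regularly spaced", call. = FALSE)
  if (!regular(lon)) stop("longitudes must be regularly spaced", call. = FALSE)
  structure(list(lat = lat, lon = lon, values = values), class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("grid_field: %d x %d cells, lat [%g, %g], lon [%g, %g]\n",
              length(x$lat), length(x$lon), min(x$lat), max(x$lat),
              min(x$lon), max(x$lon)))
  invisible(x)
}

grid_step <- function(coords, fallback = 1) {
  if (length(coords) > 1) abs(mean(diff(coords))) else fallback
}

#' Depth/latitude habitat mask
#'
#' Marks grid cells belonging to a depth-delimited seafloor habitat: subsea
#' permafrost occupies benthic area between 0 and 120 m north of 60 deg N,
#' and methane clathrates all benthic area deeper than 300 m. Membership is
#' decided at cell centres; cells with depth <= 0 are land (or above sea
#' level) and never included.
#'
#' @param grid a [grid_field()] of depth in metres, positive downward.
#' @param depth_min,depth_max depth bounds in metres, `depth_min < depth_max`
#'   (use `Inf` for an open lower bound).
#' @param lat_min optional minimum latitude in degrees (e.g. 60 for
#'   permafrost); `NULL` for no latitude restriction.
#' @return logical matrix of the grid's shape.
#' @export
#' @examples
#' g <- grid_field(61:63, c(-70, -69), matrix(500, 3, 2))
#' habitat_mask(g, 300, Inf)          # all TRUE
#' habitat_mask(g, 0, 120, lat_min = 60) # all FALSE (too deep)
habitat_mask <- function(grid, depth_min, depth_max, lat_min = NULL) {
  stopifnot(inherits(grid, "grid_field"))
  if (depth_min >= depth_max) stop("depth_min must be < depth_max", call. = FALSE)
  d <- grid$values
  mask <- d > 0 & d >= depth_min & d <= depth_max
  if (!is.null(lat_min)) {
    mask <- mask & matrix(grid$lat >= lat_min, nrow(d), ncol(d))
  }
  mask & !is.na(d)
}

#' Per-cell areas of a grid
#'
#' Spherical cell areas `R^2 * dlat * dlon * cos(lat)` in square kilometres.
#' Summed over a full-sphere grid this reproduces the Earth's surface area
#' (~5.101e8 km^2) to within 0.1%.
#'
#' @param grid a [grid_field()].
#' @return numeric matrix of cell areas in km^2.
#' @export
cell_areas <- function(grid) {
  stopifnot(inherits(grid, "grid_field"))
  to_rad <- pi / 180
  dlat <- grid_step(grid$lat) * to_rad
  dlon <- grid_step(grid$lon) * to_rad
  if (length(grid$lat) == 0 || length(grid$lon) == 0) {
    return(matrix(numeric(0), length(grid$lat), length(grid$lon)))
  }
  area_lat <- EARTH_RADIUS_KM^2 * dlat * dlon * cos(grid$lat * to_rad)
  matrix(area_lat, length(grid$lat), length(grid$lon))
}

#' Total area of a habitat on a grid
#'
#' Convenience composition of [habitat_mask()] and [cell_areas()].
#'
#' @inheritParams habitat_mask
#' @return habitat area in km^2.
#' @export
habitat_area <- function(grid, depth_min, depth_max, lat_min = NULL) {
  sum(cell_areas(grid)[habitat_mask(grid, depth_min, depth_max, lat_min)])
}

#' Anomaly anchors for carbon-habitat health
#'
#' The health of the permafrost and clathrate 'habitats' tracks the northern
#' hemisphere sea-surface temperature anomaly above pre-industrial levels:
#' health 0 at a 3.65 deg C anomaly (a 3 deg C rise from the 2005 level of
#' 0.65 deg C, enough to destabilize most oceanic gas hydrates), declining
#' linearly so that health is 1 at the 2005 reference anomaly and 0.5 at
#' 2.15 deg C.
#'
#' @param zero_health_anomaly anomaly at which health reaches 0, default 3.65.
#' @param reference_anomaly anomaly at which health is 1, default 0.65.
#' @return an object of class `anomaly_anchors`.
#' @export
anomaly_anchors <- function(zero_health_anomaly = 3.65, reference_anomaly = 0.65) {
  check_scalar_number(zero_health_anomaly, "zero_health_anomaly")
  check_scalar_number(reference_anomaly, "reference_anomaly")
  if (zero_health_anomaly <= reference_anomaly) {
    stop("zero_health_anomaly must exceed reference_anomaly", call. = FALSE)
  }
  structure(list(zero_health_anomaly = zero_health_anomaly,
                 reference_anomaly = reference_anomaly),
            class = "anomaly_anchors")
}

#' Habitat health from a temperature anomaly
#'
#' Linear interpolation between the anchors of [anomaly_anchors()], clamped
#' to \[0, 1\].
#'
#' @param anomaly sea-surface temperature anomaly in deg C.
#' @param anchors an [anomaly_anchors()] object.
#' @return habitat health in \[0, 1\].
#' @export
#' @examples
#' habitat_health_from_anomaly(2.15) # 0.5
habitat_health_from_anomaly <- function(anomaly, anchors = anomaly_anchors()) {
  stopifnot(inherits(anchors, "anomaly_anchors"))
  h <- (anchors$zero_health_anomaly - anomaly) /
    (anchors$zero_health_anomaly - anchors$reference_anomaly)
  clamp(h, 0, 1)
}

#' Carbon-habitat trend from a CO2 series
#'
#' Trend of the permafrost/clathrate habitats, derived from the globally
#' averaged marine surface annual mean CO2 record: the negative of the
#' relative least-squares slope over the most recent `window` years,
#' multiplied by the window length (rising CO2 implies declining habitat
#' condition) and clamped to \[-1, 1\]. The relative slope divides the OLS
#' slope by the window-mean concentration.
#'
#' @param years integer years, strictly increasing.
#' @param co2 CO2 concentrations (ppm), positive.
#' @param window number of recent years, default 5.
#' @return trend in \[-1, 1\].
#' @export
carbon_trend_from_co2 <- function(years, co2, window = 5) {
  if (length(years) != length(co2)) {
    stop("years and co2 must have equal length", call. = FALSE)
  }
  if (any(diff(years) <= 0)) stop("years must be strictly increasing", call. = FALSE)
  if (length(years) < window) {
    stop(sprintf("need at least %d annual points, got %d", window, length(years)),
         call. = FALSE)
  }
  keep <- seq.int(length(years) - window + 1L, length(years))
  t <- years[keep]; v <- co2[keep]
  if (any(v <= 0)) stop("co2 values must be positive", call. = FALSE)
  slope <- stats::cov(t, v) / stats::var(t)
  clamp(-slope / mean(v) * window, -1, 1)
}

#' Combine habitats into a Carbon Storage status and trend
#'
#' Area-weighted combination of habitat records (classical coastal habitats
#' such as seagrasses and salt marshes alongside the permafrost and
#' clathrate additions): status is the area-weighted mean health times 100,
#' trend the area-weighted mean trend. Zero-area habitats are ignored.
#'
#' @param habitats data.frame with columns `habitat_id`, `area` (km^2, >= 0),
#'   `health` (0-1), `trend` (\[-1, 1\]).
#' @return list with elements `status` (0-100) and `trend`.
#' @export
#' @examples
#' combine_habitats(data.frame(habitat_id = c("a", "b"), area = c(1, 1),
#'                             health = c(0.4, 0.8), trend = c(0, 0)))
combine_habitats <- function(habitats) {
  req <- c("habitat_id", "area", "health", "trend")
  miss <- setdiff(req, names(habitats))
  if (length(miss)) stop("habitats lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(habitats) < 1) stop("need at least one habitat", call. = FALSE)
  if (any(habitats$area < 0)) stop("areas must be >= 0", call. = FALSE)
  check_range(habitats$health, 0, 1, "health")
  check_range(habitats$trend, -1, 1, "trend")
  w <- habitats$area
  if (sum(w) <= 0) stop("total habitat area must be > 0", call. = FALSE)
  list(status = 100 * sum(w * habitats$health) / sum(w),
       trend = sum(w * habitats$trend) / sum(w))
}

#' Carbon Storage status and trend from grids and series
#'
#' End-to-end helper: measures permafrost and clathrate extents on a
#' bathymetry grid, assigns both the anomaly-derived health and CO2-derived
#' trend, appends any classical habitat records, and combines by area.
#'
#' @param bathymetry a [grid_field()] of depth (m, positive down).
#' @param anomaly current sea-surface temperature anomaly, deg C.
#' @param co2_years,co2 annual CO2 series for the trend.
#' @param classical_habitats optional data.frame of extra habitat records
#'   (same columns as [combine_habitats()]).
#' @param anchors an [anomaly_anchors()] object.
#' @param permafrost_depth depth bounds (m) for subsea permafrost, default
#'   `c(0, 120)`.
#' @param permafrost_lat_min minimum latitude for permafrost, default 60.
#' @param clathrate_depth_min minimum depth (m) for methane clathrates,
#'   default 300.
#' @return list with `status`, `trend` and the assembled `habitats` table.
#' @export
carbon_storage_status <- function(bathymetry, anomaly, co2_years, co2,
                                  classical_habitats = NULL,
                                  anchors = anomaly_anchors(),
                                  permafrost_depth = c(0, 120),
                                  permafrost_lat_min = 60,
                                  clathrate_depth_min = 300) {
  health <- habitat_health_from_anomaly(anomaly, anchors)
  trend <- carbon_trend_from_co2(co2_years, co2)
  new_hab <- data.frame(
    habitat_id = c("subsea_permafrost", "methane_clathrate"),
    area = c(habitat_area(bathymetry, permafrost_depth[1], permafrost_depth[2],
                          lat_min = permafrost_lat_min),
             habitat_area(bathymetry, clathrate_depth_min, Inf)),
    health = health, trend = trend, stringsAsFactors = FALSE)
  habitats <- if (is.null(classical_habitats)) new_hab else
    rbind(classical_habitats[, names(new_hab)], new_hab)
  c(combine_habitats(habitats), list(habitats = habitats))
}
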