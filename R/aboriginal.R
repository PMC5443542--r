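#' Impute the Revised Northern Food Basket price for a community
#'
#' The Revised Northern Food Basket (RNFB) prices a nutritious diet for a
#' family of four in northern communities, but is surveyed in only a subset
#' of them. Missing prices are imputed by a group-specific linear model:
#' for Inuit communities
#' `F = a + b1*RNFB + b2*RNFB_dist + b3*ICCPI + b4*ICCPI_dist + b5*Pop`
#' (nearest surveyed basket price and its distance, the food price index of
#' the nearest major city and its distance, and population); First Nations
#' communities omit the two RNFB terms, which did not improve model fit.
#'
#' @param community data.frame (one or more rows) with columns `group`
#'   (`"Inuit"` or `"FirstNations"`), `population`, `RNFB`, `RNFB_dist`,
#'   `ICCPI`, `ICCPI_dist` (RNFB columns may be NA for First Nations rows).
#' @param coefficients named coefficient vector with attribute `group`, as
#'   returned by [cohi_rnfb_coefficients()] or [fit_rnfb_model()].
#' @return predicted basket price(s) in dollars.
#' @export
#' @examples
#' co <- data.frame(group = "Inuit", population = 0, RNFB = 0,
#'                  RNFB_dist = 0, ICCPI = 0, ICCPI_dist = 0)
#' impute_rnfb(co, cohi_rnfb_coefficients("Inuit")) # 1262, the intercept
impute_rnfb <- function(community, coefficients) {
  grp <- attr(coefficients, "group")
  if (is.null(grp)) stop("coefficients lack a 'group' attribute", call. = FALSE)
  if (!all(community$group == grp)) {
    stop(sprintf("coefficients are for group '%s' but community rows are not", grp),
         call. = FALSE)
  }
  terms <- setdiff(names(coefficients), "(Intercept)")
  cols <- sub("^Pop$", "population", terms)
  miss <- setdiff(cols, names(community))
  if (length(miss)) stop("community lacks covariates: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  X <- as.matrix(community[, cols, drop = FALSE])
  if (anyNA(X)) stop("NA covariate values for group ", grp, call. = FALSE)
  drop(coefficients["(Intercept)"] + X %*% coefficients[terms])
}

#' Fit the RNFB imputation model
#'
#' Ordinary least squares of observed basket prices on the community
#' covariates, per population group. On noiseless synthetic data this
#' recovers the generating coefficients to near machine precision.
#'
#' @param data data.frame of observed communities with columns `group`,
#'   `population`, `RNFB`, `RNFB_dist`, `ICCPI`, `ICCPI_dist` and the
#'   response `price`.
#' @param group `"Inuit"` (five covariates) or `"FirstNations"` (no RNFB
#'   terms).
#' @return named coefficient vector with attributes `group`, `se`,
#'   `adj_r_squared`, `f_statistic` and `fit` (the underlying `lm`).
#' @export
fit_rnfb_model <- function(data, group = c("Inuit", "FirstNations")) {
  group <- match.arg(group)
  data <- data[data$group == group, , drop = FALSE]
  form <- if (group == "Inuit") {
    price ~ RNFB + RNFB_dist + ICCPI + ICCPI_dist + Pop
  } else {
    price ~ ICCPI + ICCPI_dist + Pop
  }
  data$Pop <- data$population
  p <- length(attr(stats::terms(form), "term.labels")) + 1L
  if (nrow(data) <= p) {
    stop(sprintf("need more than %d observations to fit %d parameters, got %d",
                 p, p, nrow(data)), call. = FALSE)
  }
  fit <- stats::lm(form, data = data)
  if (anyNA(stats::coef(fit))) {
    stop("design matrix is rank deficient; drop collinear covariates", call. = FALSE)
  }
  s <- summary(fit)
  coefs <- stats::coef(fit)
  structure(coefs,
            group = group,
            se = s$coefficients[, "Std. Error"],
            adj_r_squared = s$adj.r.squared,
            f_statistic = unname(s$fstatistic["value"]),
            fit = fit)
}

#' Ice-cover fraction around a community
#'
#' Area-weighted mean ice concentration over all grid cells whose centres
#' lie within a great-circle radius of the community. Used to measure
#' physical access to traditional hunting and fishing grounds.
#'
#' @param ice a [grid_field()] of ice concentration (0-1), or a named list
#'   of them (one per year).
#' @param lat,lon community coordinates in degrees.
#' @param radius_km search radius, default 300.
#' @return a single fraction, or a named vector when `ice` is a list.
#' @export
ice_cover_fraction <- function(ice, lat, lon, radius_km = 300) {
  if (inherits(ice, "grid_field")) {
    d <- outer(ice$lat, ice$lon, function(la, lo) haversine_km(la, lo, lat, lon))
    inside <- d <= radius_km & !is.na(ice$values)
    if (!any(inside)) {
      stop(sprintf("no grid cells within %g km of (%g, %g)", radius_km, lat, lon),
           call. = FALSE)
    }
    check_range(ice$values[inside], 0, 1, "ice concentration")
    a <- cell_areas(ice)[inside]
    return(sum(a * ice$values[inside]) / sum(a))
  }
  vapply(ice, ice_cover_fraction, numeric(1), lat = lat, lon = lon,
         radius_km = radius_km)
}

#' Per-community access factor
#'
#' The Aboriginal Needs access factor for one community and year: the
#' food-to-fuel price ratio relative to its baseline, times the ice-cover
#' ratio, `(F/G) / (Fb/Gb) * (I/Ib)`. The factor is 1 at the baseline and
#' falls as fuel prices outpace food prices or as ice cover shrinks. When a
#' community's ice series is identically zero (no ice ever, so no access
#' lost), or the baseline ice is zero, the ice ratio is fixed at 1.
#'
#' @param food,gas current food-basket price (dollars) and gasoline price
#'   (cents/L), both > 0.
#' @param ice current ice-cover fraction, 0-1.
#' @param food_base,gas_base,ice_base 1979 baseline values.
#' @param ice_all_zero logical: the community's whole ice series is zero.
#' @return access factor >= 0.
#' @export
#' @examples
#' community_an_factor(3, 5.5, 1, 1, 1, 1) # 0.5454..., the ~54 cross-check
community_an_factor <- function(food, gas, ice, food_base, gas_base, ice_base,
                                ice_all_zero = FALSE) {
  if (any(c(food, gas, food_base, gas_base) <= 0)) {
    stop("prices must be positive", call. = FALSE)
  }
  check_range(ice, 0, 1, "ice fraction")
  if (any(ice_base < 0)) stop("baseline ice must be >= 0", call. = FALSE)
  price_ratio <- (food / gas) / (food_base / gas_base)
  ice_ratio <- ifelse(ice_all_zero | ice_base == 0, 1, ice / ice_base)
  price_ratio * ice_ratio
}

#' Aboriginal Needs score for a year
#'
#' Population-weighted mean of the per-community access factors, scaled so
#' the baseline year (1979) scores 100:
#' \deqn{AN = 100 \sum_i (P_i/P_{tot}) \frac{F_i/G_i}{Fb_i/Gb_i}
#'       \frac{I_i}{Ib_i}}
#'
#' @param panel a community panel: list with `communities` (columns
#'   `community_id`, `population`, ...) and `series` (columns
#'   `community_id`, `year`, `food_price`, `gas_price`, `ice_fraction`),
#'   as produced by [gen_communities()] or [read_community_panel()].
#' @param year evaluation year.
#' @param baseline_year baseline year, default 1979.
#' @return list with `score` (0-100 scale; can exceed 100 if access
#'   improves), and `factors`, the per-community table.
#' @export
an_index <- function(panel, year, baseline_year = 1979) {
  comm <- panel$communities
  ser <- panel$series
  if (sum(comm$population) <= 0) stop("total population must be > 0", call. = FALSE)
  cur <- ser[ser$year == year, ]
  base <- ser[ser$year == baseline_year, ]
  if (nrow(cur) == 0) stop("panel lacks year ", year, call. = FALSE)
  if (nrow(base) == 0) stop("panel lacks baseline year ", baseline_year, call. = FALSE)
  ids <- comm$community_id
  i_cur <- match(ids, cur$community_id)
  i_base <- match(ids, base$community_id)
  if (anyNA(i_cur) || anyNA(i_base)) {
    stop("every community needs rows for both the evaluation and baseline year",
         call. = FALSE)
  }
  all_zero <- vapply(ids, function(id) {
    all(ser$ice_fraction[ser$community_id == id] == 0)
  }, logical(1))
  factors <- community_an_factor(
    food = cur$food_price[i_cur], gas = cur$gas_price[i_cur],
    ice = cur$ice_fraction[i_cur],
    food_base = base$food_price[i_base], gas_base = base$gas_price[i_base],
    ice_base = base$ice_fraction[i_base], ice_all_zero = all_zero)
  w <- comm$population / sum(comm$population)
  list(score = 100 * sum(w * factors),
       factors = data.frame(community_id = ids, population = comm$population,
                            factor = factors, stringsAsFactors = FALSE))
}

#' Aboriginal Needs status series and trend
#'
#' Evaluates [an_index()] for every year of the panel and derives the recent
#' trend with the engine convention ([recent_trend()]). Scores above 100 are
#' clamped for the status layer (status cannot exceed its reference point).
#'
#' @inheritParams an_index
#' @param window trend window in years, default 5.
#' @return list with `series` (data.frame year, score, status) and `trend`.
#' @export
an_series <- function(panel, baseline_year = 1979, window = 5) {
  years <- sort(unique(panel$series$year))
  score <- vapply(years, function(y) an_index(panel, y, baseline_year)$score,
                  numeric(1))
  status <- clamp(score, 0, 100)
  trend <- recent_trend(years, status, window = window)
  list(series = data.frame(year = years, score = score, status = status),
       trend = trend)
}

#' @rdname an_series
#' @param years,status an already-computed annual status series.
#' @export
an_trend <- function(years, status, window = 5) {
  recent_trend(years, status, window = window)
}
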