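#' Configuration for the synthetic-data generators
#'
#' Collects sizes, ground-truth parameters and noise scales for the three
#' generators. Defaults describe a small but realistic world: ten goals
#' with heterogeneous true utilities; survey tasks showing five goals at a
#' time; a 1979-2013 community panel in which gasoline prices grow by a
#' factor of 5.5 and food prices by 3.0 over the horizon while ice cover is
#' flat until 1999 and then declines; and a coarse Arctic grid.
#'
#' @param seed integer RNG seed.
#' @param goals character goal ids.
#' @param true_utilities named true utilities (need not sum to zero; choice
#'   probabilities are invariant to a common shift).
#' @param n_respondents,n_tasks,set_size survey sizes (set_size >= 3).
#' @param likert_noise_sd Gaussian noise on the latent Likert scale.
#' @param likert_center centre of the latent rating map (default 4.5, so
#'   ratings cluster high and clip at 5, emulating the ceiling effect of
#'   importance ratings).
#' @param n_communities number of communities in the panel.
#' @param years panel years.
#' @param gas_growth,food_growth total price growth factors over the panel
#'   horizon (defaults 5.5 and 3.0).
#' @param ice_decline_start first year of ice decline (default 1999).
#' @param ice_decline_total total relative ice loss by the final year
#'   (default 0.15).
#' @param price_noise_sd lognormal sd of multiplicative price noise
#'   (0 for exactly geometric series).
#' @param grid_res grid spacing in degrees.
#' @param grid_lat,grid_lon latitude/longitude extents of the grid.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             goals = c("FP", "AN", "NP", "CS", "CP",
                                       "CL", "TR", "SP", "CW", "BD"),
                             true_utilities = NULL,
                             n_respondents = 200, n_tasks = 6, set_size = 5,
                             likert_noise_sd = 0.5, likert_center = 4.5,
                             n_communities = 20,
                             years = 1979:2013,
                             gas_growth = 5.5, food_growth = 3.0,
                             ice_decline_start = 1999,
                             ice_decline_total = 0.15,
                             price_noise_sd = 0,
                             grid_res = 0.5,
                             grid_lat = c(55, 75), grid_lon = c(-100, -60)) {
  if (set_size < 3) stop("set_size must be >= 3", call. = FALSE)
  if (set_size > length(goals)) stop("set_size exceeds number of goals", call. = FALSE)
  if (n_respondents < 1 || n_tasks < 1 || n_communities < 1) {
    stop("sizes must be positive", call. = FALSE)
  }
  if (is.null(true_utilities)) {
    u <- seq(-1, 1, length.out = length(goals))
    true_utilities <- stats::setNames(u - mean(u), goals)
  }
  if (!setequal(names(true_utilities), goals)) {
    stop("true_utilities must be named by the goals", call. = FALSE)
  }
  structure(list(seed = seed, goals = goals,
                 true_utilities = true_utilities[goals],
                 n_respondents = n_respondents, n_tasks = n_tasks,
                 set_size = set_size, likert_noise_sd = likert_noise_sd,
                 likert_center = likert_center,
                 n_communities = n_communities, years = years,
                 gas_growth = gas_growth, food_growth = food_growth,
                 ice_decline_start = ice_decline_start,
                 ice_decline_total = ice_decline_total,
                 price_noise_sd = price_noise_sd,
                 grid_res = grid_res, grid_lat = grid_lat,
                 grid_lon = grid_lon),
            class = "generator_config")
}

#' Generate a synthetic best-worst survey
#'
#' Draws Likert ratings and best/worst choice tasks from known true
#' utilities. Ratings are a clipped, rounded linear map of utility plus
#' Gaussian noise (a deliberately crude emulation; no data-generating
#' process for ratings is claimed). Choices follow the sequential maxdiff
#' model: the best pick is conditional-logit over the shown set, the worst
#' pick conditional-logit with sign-flipped utilities over the remainder.
#' Optionally, respondents are split into preference segments with their
#' own utilities (for group-comparison experiments).
#'
#' @param config a [generator_config()].
#' @param segments optional named list of per-segment utility vectors;
#'   respondents are assigned to segments in round-robin order and the
#'   segment is recorded in the demographics table.
#' @return list with `likert`, `tasks`, `demographics` data.frames and
#'   `truth` (the utilities used).
#' @export
gen_survey <- function(config = generator_config(), segments = NULL) {
  stopifnot(inherits(config, "generator_config"))
  goals <- config$goals
  K <- length(goals)
  with_seed(config$seed, {
    n <- config$n_respondents
    resp <- sprintf("r%04d", seq_len(n))
    seg_names <- if (is.null(segments)) "all" else names(segments)
    seg_of <- rep(seg_names, length.out = n)
    u_of <- function(s) {
      if (is.null(segments)) config$true_utilities else segments[[s]][goals]
    }

    likert <- do.call(rbind, lapply(seq_len(n), function(i) {
      u <- u_of(seg_of[i])
      scale <- if (max(abs(u - mean(u))) > 0) 1.5 / max(abs(u - mean(u))) else 0
      # centred at 4.5 so the upper tail clips at 5: importance ratings in
      # practice cluster at "important"/"very important" (nothing stops a
      # respondent rating every goal 5), which is exactly why the Likert
      # scheme discriminates less than forced best-worst trade-offs
      latent <- config$likert_center + scale * (u - mean(u)) +
        stats::rnorm(K, sd = config$likert_noise_sd)
      data.frame(respondent_id = resp[i], goal = goals,
                 rating = as.integer(clamp(round(latent), 1, 5)),
                 stringsAsFactors = FALSE)
    }))

    tasks <- do.call(rbind, lapply(seq_len(n), function(i) {
      u <- u_of(seg_of[i])
      do.call(rbind, lapply(seq_len(config$n_tasks), function(t) {
        shown <- sample(goals, config$set_size)
        us <- u[shown]
        best <- sample(shown, 1, prob = exp(us - max(us)))
        rest <- setdiff(shown, best)
        ur <- u[rest]
        worst <- sample(rest, 1, prob = exp(-(ur - min(ur))))
        data.frame(respondent_id = resp[i], task_id = t,
                   shown = paste(shown, collapse = "|"),
                   best = best, worst = worst, stringsAsFactors = FALSE)
      }))
    }))

    demographics <- data.frame(
      respondent_id = resp,
      region = sample(c("BC", "Prairies", "Ontario", "Quebec", "Atlantic"),
                      n, replace = TRUE),
      age_group = sample(c("20-24", "25-34", "35-44", "45-54", "55-64", "65+"),
                         n, replace = TRUE),
      political = sample(c("NDP/Green", "Liberal", "Conservative", "Other"),
                         n, replace = TRUE),
      ngo_member = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.2, 0.8)),
      segment = seg_of,
      stringsAsFactors = FALSE)

    list(likert = likert, tasks = tasks, demographics = demographics,
         truth = if (is.null(segments)) config$true_utilities else segments)
  })
}

#' Generate a synthetic community panel
#'
#' Communities with populations, coordinates and imputation covariates, plus
#' annual food-price, gasoline-price and ice-cover series. Prices follow
#' geometric growth to the configured total factors (gasoline x5.5, food
#' x3.0 by default), optionally with multiplicative lognormal noise; ice
#' cover is flat at its baseline until `ice_decline_start`, then declines
#' linearly to `1 - ice_decline_total` of baseline by the final year.
#' Covariates are drawn on scales consistent with the signs of the packaged
#' imputation coefficients.
#'
#' @param config a [generator_config()].
#' @return a community panel: list with `communities` and `series`
#'   data.frames (the schema consumed by [an_index()]).
#' @export
gen_communities <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    n <- config$n_communities
    years <- config$years
    ny <- length(years)
    ids <- sprintf("c%03d", seq_len(n))
    communities <- data.frame(
      community_id = ids,
      group = sample(c("Inuit", "FirstNations"), n, replace = TRUE),
      population = round(stats::rlnorm(n, meanlog = 6.5, sdlog = 0.8)),
      lat = stats::runif(n, config$grid_lat[1] + 1, config$grid_lat[2] - 1),
      lon = stats::runif(n, config$grid_lon[1] + 2, config$grid_lon[2] - 2),
      RNFB = stats::runif(n, 350, 480),
      RNFB_dist = stats::runif(n, 10, 600),
      ICCPI = stats::runif(n, 95, 135),
      ICCPI_dist = stats::runif(n, 50, 1500),
      stringsAsFactors = FALSE)
    communities$population <- pmax(communities$population, 50)

    horizon <- ny - 1
    growth_curve <- function(total) total^((seq_len(ny) - 1) / horizon)
    series <- do.call(rbind, lapply(seq_len(n), function(i) {
      food0 <- stats::runif(1, 300, 500)
      gas0 <- stats::runif(1, 20, 35)
      ice0 <- stats::runif(1, 0.5, 0.95)
      noise <- function() {
        if (config$price_noise_sd > 0) {
          exp(stats::rnorm(ny, sd = config$price_noise_sd))
        } else rep(1, ny)
      }
      decline <- ifelse(years < config$ice_decline_start, 1,
                        1 - config$ice_decline_total *
                          (years - config$ice_decline_start) /
                          max(1, max(years) - config$ice_decline_start))
      data.frame(community_id = ids[i], year = years,
                 food_price = food0 * growth_curve(config$food_growth) * noise(),
                 gas_price = gas0 * growth_curve(config$gas_growth) * noise(),
                 ice_fraction = clamp(ice0 * decline, 0, 1),
                 stringsAsFactors = FALSE)
    }))
    list(communities = communities, series = series)
  })
}

#' Generate synthetic bathymetry and ice grids
#'
#' A deterministic step-structured relief with analytically known habitat
#' areas: the western third of the grid is deep ocean (`deep_depth`, within
#' the clathrate habitat), the eastern third is a shallow shelf
#' (`shelf_depth`, within the permafrost habitat where north of 60 deg N),
#' and the middle third is land. Annual ice fields are uniform at a level
#' that declines linearly over the years.
#'
#' @param config a [generator_config()].
#' @param deep_depth,shelf_depth depths (m) of the two ocean bands.
#' @param ice_start,ice_end uniform ice concentration in the first and last
#'   year.
#' @return list with `bathymetry` (a [grid_field()]), `ice` (named list of
#'   [grid_field()]s by year) and `bands` (the longitude bands used).
#' @export
gen_grids <- function(config = generator_config(),
                      deep_depth = 500, shelf_depth = 60,
                      ice_start = 0.9, ice_end = 0.7) {
  stopifnot(inherits(config, "generator_config"))
  lat <- seq(config$grid_lat[1], config$grid_lat[2], by = config$grid_res)
  lon <- seq(config$grid_lon[1], config$grid_lon[2], by = config$grid_res)
  cuts <- stats::quantile(lon, c(1 / 3, 2 / 3), names = FALSE)
  depth_row <- ifelse(lon <= cuts[1], deep_depth,
                      ifelse(lon > cuts[2], shelf_depth, 0))
  bathy <- grid_field(lat, lon,
                      matrix(depth_row, length(lat), length(lon), byrow = TRUE))
  years <- config$years
  levels <- seq(ice_start, ice_end, length.out = length(years))
  ice <- stats::setNames(lapply(levels, function(v) {
    grid_field(lat, lon, matrix(v, length(lat), length(lon)))
  }), years)
  list(bathymetry = bathy, ice = ice,
       bands = list(deep = c(lon[1], cuts[1]), land = cuts,
                    shelf = c(cuts[2], lon[length(lon)])))
}
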