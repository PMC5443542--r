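#' Engine parameters for goal scoring
#'
#' Bundles the constants of the scoring framework. `beta` weights the recent
#' trend against the resilience-minus-pressure term when projecting the
#' likely future state; `gamma` weights ecological against social components
#' inside both the pressure and resilience combinations; `delta` is a
#' discount rate applied to the projection (zero over the short five-year
#' horizon); `x_max` is the maximum attainable status of every goal.
#'
#' @param beta trend weight in \[0, 1\]. Default 0.67.
#' @param gamma ecological/social weight in \[0, 1\]. Default 0.5.
#' @param delta discount rate, >= 0. Default 0.
#' @param x_max maximum attainable status, > 0. Default 100.
#' @return an object of class `goal_params`.
#' @export
#' @examples
#' goal_params()
goal_params <- function(beta = 0.67, gamma = 0.5, delta = 0, x_max = 100) {
  check_scalar_number(beta, "beta");  check_range(beta, 0, 1, "beta")
  check_scalar_number(gamma, "gamma"); check_range(gamma, 0, 1, "gamma")
  check_scalar_number(delta, "delta")
  if (delta < 0) stop("delta must be >= 0", call. = FALSE)
  check_scalar_number(x_max, "x_max")
  if (x_max <= 0) stop("x_max must be > 0", call. = FALSE)
  structure(list(beta = beta, gamma = gamma, delta = delta, x_max = x_max),
            class = "goal_params")
}

#' @export
print.goal_params <- function(x, ...) {
  cat(sprintf("goal scoring parameters: beta=%g gamma=%g delta=%g x_max=%g\n",
              x$beta, x$gamma, x$delta, x$x_max))
  invisible(x)
}

#' Combine resilience components
#'
#' A goal's resilience blends ecological integrity `Y_E`, the strength of
#' relevant regulations `G`, and social integrity `Y_S`, all on a 0-100
#' scale: `r = gamma * (Y_E + G)/2 + (1 - gamma) * Y_S`.
#'
#' @param ecological_integrity,regulations,social_integrity scores 0-100.
#' @param gamma weight of the ecological half, default 0.5.
#' @return resilience score 0-100.
#' @export
#' @examples
#' combine_resilience(80, 60, 40) # 55
combine_resilience <- function(ecological_integrity, regulations,
                               social_integrity, gamma = 0.5) {
  check_range(ecological_integrity, 0, 100, "ecological_integrity")
  check_range(regulations, 0, 100, "regulations")
  check_range(social_integrity, 0, 100, "social_integrity")
  check_range(gamma, 0, 1, "gamma")
  gamma * (ecological_integrity + regulations) / 2 +
    (1 - gamma) * social_integrity
}

#' Combine pressure components
#'
#' Ecological and social pressures (each 0-100) combine as the convex mix
#' `p = gamma * p_E + (1 - gamma) * p_S`.
#'
#' @param ecological,social pressure scores 0-100.
#' @param gamma weight of the ecological component, default 0.5.
#' @return pressure score 0-100.
#' @export
combine_pressure <- function(ecological, social, gamma = 0.5) {
  check_range(ecological, 0, 100, "ecological pressure")
  check_range(social, 0, 100, "social pressure")
  check_range(gamma, 0, 1, "gamma")
  gamma * ecological + (1 - gamma) * social
}

#' Likely future status of a goal
#'
#' Projects a goal's status five years ahead from its recent trend and the
#' balance of resilience over pressure:
#' \deqn{\hat x_F = (1+\delta)^{-1}\,[1 + \beta T + (1-\beta)(r - p)/100]\,x}
#' Pressure and resilience enter on the 0-100 scale and are rescaled to 0-1
#' inside the projection; the result is clamped to \[0, 100\] (a goal cannot
#' exceed its reference point).
#'
#' @param status current status `x`, 0-100.
#' @param trend recent proportional trend `T`, in \[-1, 1\].
#' @param pressure combined pressure `p`, 0-100.
#' @param resilience combined resilience `r`, 0-100.
#' @param params a [goal_params()] object.
#' @return projected future status, 0-100.
#' @export
#' @examples
#' likely_future_status(54, 0.02, 16.69, 72.81) # 64.72 after rounding
likely_future_status <- function(status, trend, pressure, resilience,
                                 params = goal_params()) {
  stopifnot(inherits(params, "goal_params"))
  check_range(status, 0, params$x_max, "status")
  check_range(trend, -1, 1, "trend")
  check_range(pressure, 0, 100, "pressure")
  check_range(resilience, 0, 100, "resilience")
  raw <- (1 + params$delta)^(-1) *
    (1 + params$beta * trend +
       (1 - params$beta) * (resilience - pressure) / 100) * status
  clamp(raw, 0, params$x_max)
}

#' Score a goal
#'
#' A goal's index score is the arithmetic mean of its current status and its
#' likely future status.
#'
#' @param status current status, 0-100.
#' @param future likely future status, 0-100.
#' @return goal score, 0-100.
#' @export
goal_score <- function(status, future) {
  check_range(status, 0, 100, "status")
  check_range(future, 0, 100, "future")
  (status + future) / 2
}

#' Weighted aggregation of subgoal values
#'
#' Applied dimension-wise (status, future, trend, score) to every
#' multi-subgoal goal. Weights are 0.5/0.5 for all two-subgoal goals except
#' Food Provision, whose subgoals are weighted by relative yield.
#'
#' @param values numeric vector of subgoal values.
#' @param weights nonnegative weights, not all zero. Default equal.
#' @return the weighted mean.
#' @export
aggregate_subgoals <- function(values, weights = rep(1, length(values))) {
  if (length(values) < 1L) stop("need at least one subgoal", call. = FALSE)
  if (length(weights) != length(values)) {
    stop("values and weights must have equal length", call. = FALSE)
  }
  if (any(weights < 0)) stop("subgoal weights must be >= 0", call. = FALSE)
  if (sum(weights) == 0) stop("subgoal weights must not all be zero", call. = FALSE)
  sum(values * weights) / sum(weights)
}

#' Aggregate goal scores into the overall index
#'
#' The overall index is \eqn{\sum_i \alpha_i I_i / \sum_i \alpha_i x^{max}
#' \times 100}: a weighted mean of goal scores expressed as a percentage of
#' the maximum attainable. The formula is invariant to rescaling all weights
#' by a positive constant, so weight vectors summing to 1 or to the number
#' of goals give identical indices.
#'
#' @param scores named numeric vector of per-goal scores (0-100).
#' @param weights named nonnegative weights; names must be a subset match of
#'   `scores`. Default equal weights over `scores`.
#' @param params a [goal_params()] object (supplies `x_max`).
#' @return overall index, 0-100.
#' @export
#' @examples
#' aggregate_index(c(a = 80, b = 60), c(a = 1, b = 1)) # 70
aggregate_index <- function(scores, weights = NULL, params = goal_params()) {
  stopifnot(inherits(params, "goal_params"))
  if (is.null(names(scores))) stop("scores must be named by goal", call. = FALSE)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(scores)), names(scores))
  if (is.null(names(weights))) stop("weights must be named by goal", call. = FALSE)
  if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
  if (sum(weights) == 0) stop("at least one weight must be > 0", call. = FALSE)
  missing_goals <- setdiff(names(weights)[weights > 0], names(scores))
  if (length(missing_goals)) {
    stop("goals in weights but missing an assessment: ",
         paste(missing_goals, collapse = ", "), call. = FALSE)
  }
  w <- weights[weights > 0]
  s <- scores[names(w)]
  check_range(s, 0, params$x_max, "goal score")
  sum(w * s) / sum(w * params$x_max) * 100
}

#' Recent trend of a status series
#'
#' The trend is the least-squares slope of status (rescaled to 0-1) against
#' year over the most recent `window` years, multiplied by the window length
#' to express total proportional change, and clamped to \[-1, 1\]. With
#' `type = "relative"` the slope is divided by the mean status in the window
#' first (relative change); the absolute convention is the default.
#'
#' @param years integer years, strictly increasing.
#' @param status status values 0-100 at those years.
#' @param window number of most recent years used, default 5.
#' @param type `"absolute"` (slope on the 0-1 scale) or `"relative"`
#'   (slope divided by mean status).
#' @return trend in \[-1, 1\].
#' @export
#' @examples
#' recent_trend(2009:2013, c(50, 52, 54, 56, 58)) # 0.10
recent_trend <- function(years, status, window = 5,
                         type = c("absolute", "relative")) {
  type <- match.arg(type)
  if (length(years) != length(status)) {
    stop("years and status must have equal length", call. = FALSE)
  }
  if (any(diff(years) <= 0)) stop("years must be strictly increasing", call. = FALSE)
  if (length(years) < window) {
    stop(sprintf("need at least %d annual points, got %d", window, length(years)),
         call. = FALSE)
  }
  keep <- seq.int(length(years) - window + 1L, length(years))
  y <- status[keep] / 100
  t <- years[keep]
  slope <- stats::cov(t, y) / stats::var(t)
  if (type == "relative") {
    m <- mean(y)
    if (m <= 0) stop("relative trend undefined for non-positive mean status", call. = FALSE)
    slope <- slope / m
  }
  clamp(slope * window, -1, 1)
}

#' Social score from the wellbeing-to-GDP ratio
#'
#' The Canadian Index of Wellbeing (CIW) relative to GDP, scaled so the base
#' year (1994) equals 100: `100 * (CIW_t / GDP_t) / (CIW_b / GDP_b)`,
#' clamped to \[0, 100\]. A value of 100 means wellbeing has kept pace with
#' economic growth since the base year; values below 100 mean GDP grew
#' without a matching gain in wellbeing. The score feeds social resilience
#' directly and social pressure as its complement (see
#' [social_layers_from_ciw()]).
#'
#' @param ciw_years,ciw years and values of the wellbeing series (values > 0).
#' @param gdp_years,gdp years and values of the GDP series (values > 0).
#' @param eval_year year to score.
#' @param base_year baseline year, default 1994.
#' @return social score, 0-100.
#' @export
ciw_gdp_index <- function(ciw_years, ciw, gdp_years, gdp, eval_year,
                          base_year = 1994) {
  pick <- function(years, values, year, what) {
    i <- match(year, years)
    if (is.na(i)) stop(sprintf("%s series lacks year %d", what, year), call. = FALSE)
    v <- values[i]
    if (!is.finite(v) || v <= 0) {
      stop(sprintf("%s value for %d must be positive", what, year), call. = FALSE)
    }
    v
  }
  ratio_t <- pick(ciw_years, ciw, eval_year, "CIW") /
    pick(gdp_years, gdp, eval_year, "GDP")
  ratio_b <- pick(ciw_years, ciw, base_year, "CIW") /
    pick(gdp_years, gdp, base_year, "GDP")
  clamp(100 * ratio_t / ratio_b, 0, 100)
}

#' Social pressure and resilience layers from the CIW:GDP score
#'
#' Maps the [ciw_gdp_index()] score onto the social components the engine
#' consumes: social resilience `Y_S` equals the score and social pressure
#' `p_S` its complement `100 - score`.
#'
#' @param score a 0-100 social score.
#' @return list with elements `social_resilience` and `social_pressure`.
#' @export
social_layers_from_ciw <- function(score) {
  check_range(score, 0, 100, "social score")
  list(social_resilience = score, social_pressure = 100 - score)
}

#' Score a full assessment table
#'
#' Runs the scoring engine over a wide assessment table: computes the likely
#' future state and score for every leaf row (subgoal rows where a goal has
#' subgoals, the goal row otherwise), aggregates subgoals dimension-wise into
#' goal rows, and computes the overall index and overall likely future under
#' the supplied goal weights.
#'
#' @param assessment data.frame with columns `goal_id`, `subgoal_id` (NA for
#'   goal-level rows), `status`, `trend`, `pressure`, `resilience`. Goal-level
#'   rows for goals that also have subgoal rows are ignored as inputs (they
#'   are recomputed by aggregation).
#' @param weights named per-goal weights; default equal.
#' @param params a [goal_params()] object.
#' @param subgoal_weights optional data.frame from [subgoal_weight_table()]
#'   with columns `goal_id`, `subgoal_id`, `weight`; default equal weights
#'   within each goal.
#' @return a data.frame with columns `goal_id`, `subgoal_id`, `status`,
#'   `trend`, `pressure`, `resilience`, `future`, `score`, with goal rows
#'   aggregated from their subgoals, plus attributes `index` (overall score)
#'   and `future_index` (overall likely future), both computed with the same
#'   weights.
#' @export
cohi_assess <- function(assessment, weights = NULL, params = goal_params(),
                        subgoal_weights = NULL) {
  req <- c("goal_id", "subgoal_id", "status", "trend", "pressure", "resilience")
  miss <- setdiff(req, names(assessment))
  if (length(miss)) stop("assessment lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  a <- assessment
  a$goal_id <- as.character(a$goal_id)
  a$subgoal_id <- as.character(a$subgoal_id)
  has_sub <- tapply(!is.na(a$subgoal_id), a$goal_id, any)
  leaf <- ifelse(has_sub[a$goal_id], !is.na(a$subgoal_id), is.na(a$subgoal_id))
  leaves <- a[leaf, , drop = FALSE]

  leaves$future <- mapply(function(x, t, p, r) {
    likely_future_status(x, t, p, r, params)
  }, leaves$status, leaves$trend, leaves$pressure, leaves$resilience)
  leaves$score <- goal_score(leaves$status, leaves$future)

  sub_w <- function(goal, subgoals) {
    if (is.null(subgoal_weights)) return(rep(1, length(subgoals)))
    w <- subgoal_weights$weight[match(
      paste(goal, subgoals), paste(subgoal_weights$goal_id, subgoal_weights$subgoal_id))]
    if (anyNA(w)) stop("missing subgoal weight for goal ", goal, call. = FALSE)
    w
  }

  goal_rows <- do.call(rbind, lapply(unique(leaves$goal_id), function(g) {
    rows <- leaves[leaves$goal_id == g, , drop = FALSE]
    if (all(is.na(rows$subgoal_id))) {
      rows$subgoal_id <- NA_character_
      return(rows[, c("goal_id", "subgoal_id", "status", "trend",
                      "pressure", "resilience", "future", "score")])
    }
    w <- sub_w(g, rows$subgoal_id)
    agg <- function(v) aggregate_subgoals(v, w)
    top <- data.frame(goal_id = g, subgoal_id = NA_character_,
                      status = agg(rows$status), trend = agg(rows$trend),
                      pressure = NA_real_, resilience = NA_real_,
                      future = agg(rows$future), score = agg(rows$score),
                      stringsAsFactors = FALSE)
    rbind(top, rows[, names(top)])
  }))
  rownames(goal_rows) <- NULL

  top <- goal_rows[is.na(goal_rows$subgoal_id), ]
  scores <- stats::setNames(top$score, top$goal_id)
  futures <- stats::setNames(top$future, top$goal_id)
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(scores)), names(scores))
  structure(goal_rows,
            index = aggregate_index(scores, weights, params),
            future_index = aggregate_index(futures, weights, params),
            weights = weights)
}
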