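#' Risk weight for a COSEWIC status category
#'
#' Maps a COSEWIC assessment category to an extinction-risk weight in
#' \[0, 1\]: unassessed, non-active, data-deficient and not-at-risk species
#' carry no risk; Special Concern 0.2; Threatened 0.4; Endangered 0.6;
#' Extinct and Extirpated 1.
#'
#' @param status character vector of COSEWIC categories.
#' @param table named numeric risk table; default [cohi_risk_table()].
#' @return risk weights in \[0, 1\].
#' @export
#' @examples
#' risk_weight("Endangered") # 0.6
risk_weight <- function(status, table = cohi_risk_table()) {
  if (any(table < 0 | table > 1)) stop("risk weights must lie in [0, 1]", call. = FALSE)
  i <- match(status, names(table))
  if (anyNA(i)) {
    stop("unknown COSEWIC status: ",
         paste(unique(status[is.na(i)]), collapse = ", "),
         "; valid categories are: ", paste(names(table), collapse = ", "),
         call. = FALSE)
  }
  unname(table[i])
}

#' Iconic Species status
#'
#' The subgoal status is the range-weighted mean of `1 - risk` across the
#' iconic species list, scaled to 0-100. Spatial range weights reflect each
#' species' COSEWIC-identified range; species with zero range weight do not
#' contribute.
#'
#' @param species data.frame with columns `cosewic_status` and
#'   `range_weight` (nonnegative, not all zero).
#' @param table named risk table, default [cohi_risk_table()].
#' @return status, 0-100.
#' @export
ico_status <- function(species, table = cohi_risk_table()) {
  req <- c("cosewic_status", "range_weight")
  miss <- setdiff(req, names(species))
  if (length(miss)) stop("species lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(species) < 1) stop("need at least one species", call. = FALSE)
  w <- species$range_weight
  if (any(w < 0)) stop("range weights must be >= 0", call. = FALSE)
  if (sum(w) <= 0) stop("all range weights are zero", call. = FALSE)
  risk <- risk_weight(species$cosewic_status, table)
  100 * sum(w * (1 - risk)) / sum(w)
}

#' Iconic Species trend
#'
#' Proportional change between two assessments under the engine's trend
#' convention: the per-year change of status on the 0-1 scale, expressed
#' over a five-year horizon and clamped to \[-1, 1\].
#'
#' @param current,previous statuses 0-100.
#' @param years_between positive number of years separating the assessments.
#' @param horizon years over which the trend is expressed, default 5.
#' @return trend in \[-1, 1\].
#' @export
#' @examples
#' ico_trend(85, 72, years_between = 5) # 0.13
ico_trend <- function(current, previous, years_between, horizon = 5) {
  check_range(current, 0, 100, "current status")
  check_range(previous, 0, 100, "previous status")
  if (years_between <= 0) stop("years_between must be > 0", call. = FALSE)
  clamp((current - previous) / 100 / years_between * horizon, -1, 1)
}
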