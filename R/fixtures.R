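cohi_extdata <- function(file) {
  path <- system.file("extdata", file, package = "cohi", mustWork = FALSE)
  if (!nzchar(path)) {
    # fall back for devtools::load_all() layouts
    path <- file.path("inst", "extdata", file)
  }
  if (!file.exists(path)) stop("packaged fixture not found: ", file, call. = FALSE)
  path
}

#' Packaged 2013 national goal assessment
#'
#' The per-(sub)goal score, status, likely future state, trend, pressure and
#' resilience values of the 2013 Canadian assessment, as packaged reference
#' data. One printed quirk is corrected here: the published table prints the
#' Sense of Place goal values on its Iconic Species subgoal row and vice
#' versa (the goal score 59.40 is exactly the mean of the subgoal scores
#' 33.89 and 84.91, and only that reading yields the overall index of
#' 64.55); the fixture stores them under the arithmetically consistent rows.
#'
#' @param include_overall keep the overall-index row (`goal_id == "OHI"`)?
#'   Default `FALSE`.
#' @return data.frame with columns `goal_id`, `goal_name`, `subgoal_id`,
#'   `subgoal_name`, `score`, `status`, `future`, `trend`, `pressure`,
#'   `resilience`.
#' @export
#' @examples
#' head(cohi_goal_assessment())
cohi_goal_assessment <- function(include_overall = FALSE) {
  d <- utils::read.csv(cohi_extdata("goal_assessment_2013.csv"),
                       stringsAsFactors = FALSE)
  if (!include_overall) d <- d[d$goal_id != "OHI", ]
  rownames(d) <- NULL
  d
}

#' Engine inputs from the packaged assessment
#'
#' The subset of [cohi_goal_assessment()] columns the scoring engine
#' consumes (status, trend, pressure, resilience of every leaf row), ready
#' for [cohi_assess()].
#'
#' @return data.frame with columns `goal_id`, `subgoal_id`, `status`,
#'   `trend`, `pressure`, `resilience`.
#' @export
cohi_assessment_inputs <- function() {
  d <- cohi_goal_assessment()
  d[, c("goal_id", "subgoal_id", "status", "trend", "pressure", "resilience")]
}

#' Packaged iconic-species list
#'
#' The 19 marine species featured on Royal Canadian Mint currency that
#' define the national Iconic Species subgoal. `salmon_added` flags the four
#' salmon species included because the coinage referenced salmon
#' non-specifically; `in_original_ohi` flags the four species shared with
#' the original global iconic list. Per-species COSEWIC statuses and range
#' weights are assessment-time inputs, not part of the published list, so
#' they are not packaged.
#'
#' @return data.frame with columns `common_name`, `scientific_name`,
#'   `salmon_added`, `in_original_ohi`.
#' @export
cohi_species <- function() {
  utils::read.csv(cohi_extdata("iconic_species_mint.csv"),
                  stringsAsFactors = FALSE)
}

#' Packaged COSEWIC risk-weight table
#'
#' @return named numeric vector mapping the nine COSEWIC categories to risk
#'   weights in \[0, 1\].
#' @export
#' @examples
#' cohi_risk_table()[["Special Concern"]] # 0.2
cohi_risk_table <- function() {
  d <- utils::read.csv(cohi_extdata("cosewic_risk_weights.csv"),
                       stringsAsFactors = FALSE)
  stats::setNames(d$risk_weight, d$cosewic_status)
}

#' Packaged RNFB imputation coefficients
#'
#' Published linear-model parameters for imputing the Revised Northern Food
#' Basket price, by population group.
#'
#' @param group `"Inuit"` or `"FirstNations"`.
#' @return named coefficient vector with attributes `group`, `se`,
#'   `adj_r_squared` and `f_statistic`, as accepted by [impute_rnfb()].
#' @export
cohi_rnfb_coefficients <- function(group = c("Inuit", "FirstNations")) {
  group <- match.arg(group)
  d <- utils::read.csv(cohi_extdata("rnfb_model_coefficients.csv"),
                       stringsAsFactors = FALSE)
  d <- d[d$group == group, ]
  stats_rows <- d$term %in% c("adj_r_squared", "f_statistic")
  coefs <- stats::setNames(d$estimate[!stats_rows], d$term[!stats_rows])
  structure(coefs,
            group = group,
            se = stats::setNames(d$se[!stats_rows], d$term[!stats_rows]),
            adj_r_squared = d$estimate[d$term == "adj_r_squared"],
            f_statistic = d$estimate[d$term == "f_statistic"])
}

#' Food Provision yield weights
#'
#' Food Provision's subgoals are weighted by relative yield. The national
#' yield split is not published directly, but it is uniquely determined by
#' the published goal and subgoal statuses: with wild-capture status 54.00,
#' mariculture status 85.77 and a combined status of 58.66, the wild-capture
#' share is `(85.77 - 58.66) / (85.77 - 54.00)` (about 0.853). The same
#' weight reproduces the published combined future and score.
#'
#' @return named numeric vector `c(FIS = ..., MAR = ...)`, summing to 1.
#' @export
cohi_fp_yield_weights <- function() {
  fis <- (85.77 - 58.66) / (85.77 - 54.00)
  c(FIS = fis, MAR = 1 - fis)
}

#' Default goal structure of the national assessment
#'
#' @return named list mapping each goal id to its subgoal ids (empty for
#'   goals without subgoals).
#' @export
cohi_goal_structure <- function() {
  list(FP = c("FIS", "MAR"), AN = character(0), NP = character(0),
       CS = character(0), CP = character(0), CL = c("LIV", "ECO"),
       TR = character(0), SP = c("ICO", "LSP"), CW = character(0),
       BD = c("HAB", "SPP"))
}

#' Default subgoal weights of the national assessment
#'
#' 0.5/0.5 everywhere except Food Provision, which uses
#' [cohi_fp_yield_weights()].
#'
#' @return data.frame as from [subgoal_weight_table()].
#' @export
cohi_subgoal_weights <- function() {
  subgoal_weight_table(cohi_goal_structure(), fp_yield = cohi_fp_yield_weights())
}
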