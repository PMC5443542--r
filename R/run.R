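#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numbers when possible. Unknown keys are kept verbatim so callers can
#' stash extra paths. Defaults (returned for missing keys) equal the
#' national assessment's constants: `beta` 0.67, `gamma` 0.5, `delta` 0,
#' `scheme` "equal", `base_year` 1979, `radius_km` 300, `seed` 1.
#'
#' @param path config file, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(beta = 0.67, gamma = 0.5, delta = 0, scheme = "equal",
              base_year = 1979, radius_km = 300,
              zero_health_anomaly = 3.65, reference_anomaly = 0.65,
              seed = 1, n_sims = 500)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    for (ln in readLines(path, warn = FALSE)) {
      ln <- sub("#.*", "", ln)
      if (!grepl("=", ln, fixed = TRUE)) next
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(num)) num else val
    }
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  if (!cfg$scheme %in% c("equal", "likert", "bw-rank", "bw-dce")) {
    stop("unknown scheme: ", cfg$scheme, call. = FALSE)
  }
  cfg$params <- goal_params(cfg$beta, cfg$gamma, cfg$delta)
  class(cfg) <- "run_config"
  cfg
}

run_log <- function(...) message(sprintf("[cohi] %s", sprintf(...)))

#' Pipeline runners
#'
#' Composition of the package's stages behind a [read_run_config()]
#' configuration; each runner logs the parameters in effect, is
#' deterministic given the config (seed included), and returns its tables
#' invisibly while optionally writing CSVs to `out_dir`.
#'
#' `run_score()` scores a layer file (or the packaged 2013 assessment when
#' `layers_path` is `NULL`) under the configured weighting scheme and writes
#' the per-goal results plus a text flower summary. `run_weights()` derives
#' the four schemes' weights from survey tables. `run_an()` computes the
#' Aboriginal Needs status series and trend from a community panel.
#' `run_carbon()` computes the Carbon Storage status/trend from a bathymetry
#' grid and CO2 series. `run_iconic()` scores the Iconic Species subgoal
#' from a species CSV. `run_simulate()` writes synthetic inputs.
#' `run_compare()` runs the bootstrap group comparison.
#'
#' @param config a `run_config` (or `NULL` for defaults).
#' @param layers_path optional layer CSV (see [read_layers()]).
#' @param likert_path,tasks_path,demographics_path survey CSVs.
#' @param out_dir optional output directory for CSV results.
#' @return the results, invisibly.
#' @name runners
NULL

ensure_out <- function(out_dir) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  out_dir
}

#' @rdname runners
#' @export
run_score <- function(config = NULL, layers_path = NULL,
                      likert_path = NULL, tasks_path = NULL,
                      out_dir = NULL) {
  if (is.null(config)) config <- read_run_config()
  run_log("scoring with scheme=%s beta=%g gamma=%g delta=%g",
          config$scheme, config$beta, config$gamma, config$delta)
  assessment <- if (is.null(layers_path)) {
    run_log("using the packaged 2013 national assessment inputs")
    cohi_assessment_inputs()
  } else {
    layers_to_assessment(read_layers(layers_path), gamma = config$gamma)
  }
  goals <- unique(assessment$goal_id)
  weights <- if (config$scheme == "equal") {
    equal_weights(goals)
  } else {
    survey <- read_survey(likert_path, tasks_path)
    goal_weights(config$scheme, likert = survey$likert, tasks = survey$tasks,
                 goals = goals)
  }
  res <- cohi_assess(assessment, weights = weights, params = config$params,
                     subgoal_weights = cohi_subgoal_weights())
  run_log("overall index %.2f (likely future %.2f)",
          round_half_out(attr(res, "index")),
          round_half_out(attr(res, "future_index")))
  if (!is.null(ensure_out(out_dir))) {
    out <- res
    out$future <- round_half_out(out$future)
    out$score <- round_half_out(out$score)
    utils::write.csv(out, file.path(out_dir, "scores.csv"), row.names = FALSE)
    writeLines(flower_text(res), file.path(out_dir, "flower.txt"))
    run_log("wrote %s", file.path(out_dir, "scores.csv"))
  }
  invisible(res)
}

#' @rdname runners
#' @export
run_weights <- function(config = NULL, likert_path, tasks_path,
                        out_dir = NULL) {
  if (is.null(config)) config <- read_run_config()
  survey <- read_survey(likert_path, tasks_path)
  goals <- sort(unique(as.character(survey$likert$goal)))
  run_log("deriving weights for %d goals from %d respondents",
          length(goals), length(unique(survey$likert$respondent_id)))
  schemes <- c("equal", "likert", "bw-rank", "bw-dce")
  tab <- do.call(rbind, lapply(schemes, function(s) {
    w <- goal_weights(s, likert = survey$likert, tasks = survey$tasks,
                      goals = goals)
    data.frame(goal = names(w), scheme = s, weight = unname(w),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(ensure_out(out_dir))) {
    utils::write.csv(tab, file.path(out_dir, "weights.csv"), row.names = FALSE)
    run_log("wrote %s", file.path(out_dir, "weights.csv"))
  }
  invisible(tab)
}

#' @rdname runners
#' @param communities_path,series_path community panel CSVs
#'   (see [read_community_panel()]).
#' @export
run_an <- function(config = NULL, communities_path, series_path,
                   out_dir = NULL) {
  if (is.null(config)) config <- read_run_config()
  panel <- read_community_panel(communities_path, series_path)
  run_log("Aboriginal Needs over %d communities, baseline %d",
          nrow(panel$communities), config$base_year)
  res <- an_series(panel, baseline_year = config$base_year)
  run_log("final-year status %.2f, trend %.3f",
          utils::tail(res$series$status, 1), res$trend)
  if (!is.null(ensure_out(out_dir))) {
    utils::write.csv(res$series, file.path(out_dir, "an_series.csv"),
                     row.names = FALSE)
    layers <- data.frame(goal_id = "AN", subgoal_id = NA,
                         dimension = c("status", "trend"),
                         year = max(res$series$year),
                         value = c(utils::tail(res$series$status, 1), res$trend))
    utils::write.csv(layers, file.path(out_dir, "an_layers.csv"),
                     row.names = FALSE)
  }
  invisible(res)
}

#' @rdname runners
#' @param bathymetry_path grid CSV of depths (see [read_grid()]).
#' @param co2_path CSV with columns `year`, `co2`.
#' @param anomaly current sea-surface temperature anomaly, deg C.
#' @export
run_carbon <- function(config = NULL, bathymetry_path, co2_path, anomaly,
                       out_dir = NULL) {
  if (is.null(config)) config <- read_run_config()
  anchors <- anomaly_anchors(config$zero_health_anomaly, config$reference_anomaly)
  co2 <- utils::read.csv(co2_path, stringsAsFactors = FALSE)
  run_log("carbon storage: anomaly %.2f degC, anchors (%g, %g)",
          anomaly, anchors$reference_anomaly, anchors$zero_health_anomaly)
  res <- carbon_storage_status(read_grid(bathymetry_path), anomaly,
                               co2$year, co2$co2, anchors = anchors)
  run_log("status %.2f, trend %.4f", res$status, res$trend)
  if (!is.null(ensure_out(out_dir))) {
    utils::write.csv(res$habitats, file.path(out_dir, "carbon_habitats.csv"),
                     row.names = FALSE)
  }
  invisible(res)
}

#' @rdname runners
#' @param species_path species CSV with `cosewic_status` and `range_weight`.
#' @export
run_iconic <- function(config = NULL, species_path, out_dir = NULL) {
  if (is.null(config)) config <- read_run_config()
  species <- utils::read.csv(species_path, stringsAsFactors = FALSE)
  status <- ico_status(species)
  run_log("iconic species status %.2f over %d species", status, nrow(species))
  if (!is.null(ensure_out(out_dir))) {
    utils::write.csv(data.frame(goal_id = "SP", subgoal_id = "ICO",
                                dimension = "status", year = NA,
                                value = status),
                     file.path(out_dir, "ico_layers.csv"), row.names = FALSE)
  }
  invisible(status)
}

#' @rdname runners
#' @export
run_simulate <- function(config = NULL, out_dir) {
  if (is.null(config)) config <- read_run_config()
  gc <- generator_config(seed = as.integer(config$seed))
  run_log("simulating survey, communities and grids with seed %d", gc$seed)
  survey <- gen_survey(gc)
  panel <- gen_communities(gc)
  grids <- gen_grids(gc)
  ensure_out(out_dir)
  utils::write.csv(survey$likert, file.path(out_dir, "likert.csv"), row.names = FALSE)
  utils::write.csv(survey$tasks, file.path(out_dir, "tasks.csv"), row.names = FALSE)
  utils::write.csv(survey$demographics, file.path(out_dir, "demographics.csv"),
                   row.names = FALSE)
  utils::write.csv(panel$communities, file.path(out_dir, "communities.csv"),
                   row.names = FALSE)
  utils::write.csv(panel$series, file.path(out_dir, "community_series.csv"),
                   row.names = FALSE)
  write_grid(grids$bathymetry, file.path(out_dir, "bathymetry.csv"))
  invisible(list(survey = survey, panel = panel, grids = grids))
}

#' @rdname runners
#' @param group_by demographics column to compare groups over.
#' @export
run_compare <- function(config = NULL, likert_path, tasks_path,
                        demographics_path, group_by = "region",
                        layers_path = NULL, out_dir = NULL) {
  if (is.null(config)) config <- read_run_config()
  survey <- read_survey(likert_path, tasks_path, demographics_path)
  assessment <- if (is.null(layers_path)) cohi_assessment_inputs() else
    layers_to_assessment(read_layers(layers_path), gamma = config$gamma)
  scored <- cohi_assess(assessment, params = config$params,
                        subgoal_weights = cohi_subgoal_weights())
  top <- scored[is.na(scored$subgoal_id), ]
  goal_scores <- stats::setNames(top$score, top$goal_id)
  run_log("comparing '%s' groups over %d simulations (seed %d)",
          group_by, config$n_sims, config$seed)
  res <- compare_groups(survey$tasks, survey$demographics, group_by,
                        goal_scores,
                        likert = survey$likert,
                        scheme = if (config$scheme == "equal") "bw-dce" else config$scheme,
                        n_sims = as.integer(config$n_sims),
                        seed = as.integer(config$seed))
  if (!is.null(ensure_out(out_dir))) {
    utils::write.csv(res$groups, file.path(out_dir, "group_comparison.csv"),
                     row.names = FALSE)
  }
  invisible(res)
}
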