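LAYER_DIMENSIONS <- c("status", "trend", "pressure", "resilience",
                      "pressure_ecological", "pressure_social",
                      "resilience_ecological", "resilience_regulation",
                      "resilience_social")

layer_range <- function(dimension) {
  if (dimension == "trend") c(-1, 1) else c(0, 100)
}

#' Read and validate a layer file
#'
#' Layers are long-format CSVs with columns `goal_id`, `subgoal_id`
#' (optional / may be empty), `dimension`, `year`, `value`. Recognized
#' dimensions are `status`, `trend`, the combined `pressure` and
#' `resilience`, and their components (`pressure_ecological`,
#' `pressure_social`, `resilience_ecological`, `resilience_regulation`,
#' `resilience_social`). Validation is strict and reports CSV line numbers:
#' unknown dimensions, out-of-range values (statuses and pressures 0-100,
#' trends -1..1) and duplicate (goal, subgoal, dimension, year) rows are
#' all errors.
#'
#' @param path CSV file path.
#' @return validated data.frame of class `cohi_layers`.
#' @export
read_layers <- function(path) {
  if (!file.exists(path)) stop("layer file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("goal_id", "dimension", "year", "value")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    stop("layer file lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"subgoal_id" %in% names(d)) d$subgoal_id <- NA_character_
  d$subgoal_id[!is.na(d$subgoal_id) & d$subgoal_id == ""] <- NA_character_
  line <- seq_len(nrow(d)) + 1L  # header is line 1

  bad_dim <- !d$dimension %in% LAYER_DIMENSIONS
  if (any(bad_dim)) {
    stop(sprintf("unknown dimension '%s' on line %d (valid: %s)",
                 d$dimension[bad_dim][1], line[bad_dim][1],
                 paste(LAYER_DIMENSIONS, collapse = ", ")), call. = FALSE)
  }
  if (any(!is.finite(d$value))) {
    stop("non-numeric value on line ", line[!is.finite(d$value)][1], call. = FALSE)
  }
  for (dim in unique(d$dimension)) {
    rng <- layer_range(dim)
    rows <- d$dimension == dim
    bad <- rows & (d$value < rng[1] | d$value > rng[2])
    if (any(bad)) {
      stop(sprintf("value %g out of range [%g, %g] for dimension '%s' on line %d",
                   d$value[bad][1], rng[1], rng[2], dim, line[bad][1]),
           call. = FALSE)
    }
  }
  key <- paste(d$goal_id, d$subgoal_id, d$dimension, d$year)
  dup <- duplicated(key)
  if (any(dup)) {
    first <- line[match(key[dup][1], key)]
    stop(sprintf("duplicate (goal, subgoal, dimension, year) rows on lines %d and %d",
                 first, line[dup][1]), call. = FALSE)
  }
  structure(d[, c("goal_id", "subgoal_id", "dimension", "year", "value")],
            class = c("cohi_layers", "data.frame"))
}

#' Collapse validated layers into an engine assessment table
#'
#' Picks one value per (goal, subgoal, dimension) — the given `year` or,
#' by default, the most recent available — and combines component pressures
#' and resiliences with [combine_pressure()] and [combine_resilience()]
#' where the combined dimensions are not supplied directly.
#'
#' @param layers a data.frame from [read_layers()].
#' @param year evaluation year; default latest per dimension.
#' @param gamma ecological/social weight for component combination.
#' @return data.frame ready for [cohi_assess()].
#' @export
layers_to_assessment <- function(layers, year = NULL, gamma = 0.5) {
  pick <- function(rows) {
    if (nrow(rows) == 0) return(NA_real_)
    if (!is.null(year)) {
      v <- rows$value[rows$year == year]
      if (length(v) == 0) return(NA_real_)
      return(v[1])
    }
    rows$value[which.max(rows$year)]
  }
  key <- unique(layers[, c("goal_id", "subgoal_id")])
  out <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    rows <- layers[layers$goal_id == key$goal_id[i] &
                     (is.na(layers$subgoal_id) == is.na(key$subgoal_id[i])) &
                     (is.na(layers$subgoal_id) |
                        layers$subgoal_id %in% key$subgoal_id[i]), ]
    val <- function(dim) pick(rows[rows$dimension == dim, ])
    p <- val("pressure")
    if (is.na(p)) {
      pe <- val("pressure_ecological"); ps <- val("pressure_social")
      if (!is.na(pe) && !is.na(ps)) p <- combine_pressure(pe, ps, gamma)
    }
    r <- val("resilience")
    if (is.na(r)) {
      ye <- val("resilience_ecological"); g <- val("resilience_regulation")
      ys <- val("resilience_social")
      if (!is.na(ye) && !is.na(g) && !is.na(ys)) {
        r <- combine_resilience(ye, g, ys, gamma)
      }
    }
    data.frame(goal_id = key$goal_id[i], subgoal_id = key$subgoal_id[i],
               status = val("status"), trend = val("trend"),
               pressure = p, resilience = r, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a community panel
#'
#' @param communities_path CSV with columns `community_id`, `group`,
#'   `population`, `lat`, `lon` and the imputation covariates.
#' @param series_path CSV with columns `community_id`, `year`,
#'   `food_price`, `gas_price`, `ice_fraction`.
#' @return a panel list as consumed by [an_index()].
#' @export
read_community_panel <- function(communities_path, series_path) {
  communities <- utils::read.csv(communities_path, stringsAsFactors = FALSE)
  series <- utils::read.csv(series_path, stringsAsFactors = FALSE)
  req_c <- c("community_id", "population")
  req_s <- c("community_id", "year", "food_price", "gas_price", "ice_fraction")
  if (length(setdiff(req_c, names(communities)))) {
    stop("communities file lacks columns: ",
         paste(setdiff(req_c, names(communities)), collapse = ", "), call. = FALSE)
  }
  if (length(setdiff(req_s, names(series)))) {
    stop("series file lacks columns: ",
         paste(setdiff(req_s, names(series)), collapse = ", "), call. = FALSE)
  }
  if (any(communities$population < 0)) stop("populations must be >= 0", call. = FALSE)
  if (any(series$food_price <= 0) || any(series$gas_price <= 0)) {
    stop("prices must be positive", call. = FALSE)
  }
  check_range(series$ice_fraction, 0, 1, "ice fraction")
  list(communities = communities, series = series)
}

#' Read a plain-text grid raster
#'
#' Long-format CSV with columns `lat`, `lon`, `value`, one row per cell of
#' a complete regular grid.
#'
#' @param path CSV file path.
#' @return a [grid_field()].
#' @export
read_grid <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("lat", "lon", "value"), names(d))
  if (length(miss)) stop("grid file lacks columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  lat <- sort(unique(d$lat)); lon <- sort(unique(d$lon))
  if (nrow(d) != length(lat) * length(lon)) {
    stop("grid file is not a complete regular grid", call. = FALSE)
  }
  m <- matrix(NA_real_, length(lat), length(lon))
  m[cbind(match(d$lat, lat), match(d$lon, lon))] <- d$value
  grid_field(lat, lon, m)
}

#' Write a grid raster to CSV
#'
#' @param grid a [grid_field()].
#' @param path output CSV path.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "grid_field"))
  d <- expand.grid(lat = grid$lat, lon = grid$lon, KEEP.OUT.ATTRS = FALSE)
  d$value <- as.vector(grid$values)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read survey tables
#'
#' @param likert_path CSV with columns `respondent_id`, `goal`, `rating`.
#' @param tasks_path CSV with columns `respondent_id`, `task_id`, `shown`
#'   (pipe-separated), `best`, `worst`.
#' @param demographics_path optional demographics CSV keyed by
#'   `respondent_id`.
#' @return list with `likert`, `tasks` and (if given) `demographics`.
#' @export
read_survey <- function(likert_path, tasks_path, demographics_path = NULL) {
  likert <- utils::read.csv(likert_path, stringsAsFactors = FALSE)
  tasks <- utils::read.csv(tasks_path, stringsAsFactors = FALSE)
  check_range(likert$rating, 1, 5, "Likert rating")
  task_index(tasks)  # validates structure
  out <- list(likert = likert, tasks = tasks)
  if (!is.null(demographics_path)) {
    out$demographics <- utils::read.csv(demographics_path, stringsAsFactors = FALSE)
  }
  out
}

#' Render a plain-text flower summary
#'
#' A terminal-friendly stand-in for the radial flower plot: one bar per
#' goal, bar length proportional to score, bar symbol density annotated
#' with the goal's weight.
#'
#' @param result a [cohi_assess()] result.
#' @param width maximum bar width in characters.
#' @return the text, invisibly; also printed with `cat()`.
#' @export
flower_text <- function(result, width = 40) {
  top <- result[is.na(result$subgoal_id), ]
  w <- attr(result, "weights")[top$goal_id]
  lines <- vapply(seq_len(nrow(top)), function(i) {
    n <- max(0, round(top$score[i] / 100 * width))
    sprintf("%-4s %6.2f  w=%.2f |%s", top$goal_id[i],
            round_half_out(top$score[i]), w[i],
            strrep("#", n))
  }, "")
  txt <- paste(c(lines,
                 sprintf("OHI  %6.2f (likely future %.2f)",
                         round_half_out(attr(result, "index")),
                         round_half_out(attr(result, "future_index")))),
               collapse = "\n")
  cat(txt, "\n")
  invisible(txt)
}
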