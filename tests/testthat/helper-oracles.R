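# Independent oracles used across test files. These reimplement operations
# by brute force or via base/stats primitives so they never share code with
# the implementation under test.

# Brute-force habitat area: explicit per-cell loop with scalar arithmetic.
brute_habitat_area <- function(grid, depth_min, depth_max, lat_min = NULL) {
  R <- 6371.0088
  dlat <- if (length(grid$lat) > 1) abs(mean(diff(grid$lat))) else 1
  dlon <- if (length(grid$lon) > 1) abs(mean(diff(grid$lon))) else 1
  total <- 0
  for (i in seq_along(grid$lat)) {
    for (j in seq_along(grid$lon)) {
      d <- grid$values[i, j]
      if (is.na(d) || d <= 0) next
      if (d < depth_min || d > depth_max) next
      if (!is.null(lat_min) && grid$lat[i] < lat_min) next
      total <- total + R^2 * (dlat * pi / 180) * (dlon * pi / 180) *
        cos(grid$lat[i] * pi / 180)
    }
  }
  total
}

# Sequential best-worst log-likelihood written independently (plain loops).
brute_maxdiff_ll <- function(u, tasks, goals) {
  ll <- 0
  for (i in seq_len(nrow(tasks))) {
    shown <- strsplit(tasks$shown[i], "|", fixed = TRUE)[[1]]
    us <- u[match(shown, goals)]
    b <- match(tasks$best[i], shown)
    w <- match(tasks$worst[i], shown)
    ll <- ll + us[b] - log(sum(exp(us)))
    rest <- setdiff(seq_along(shown), b)
    ll <- ll - us[w] - log(sum(exp(-us[rest])))
  }
  ll
}

# A tiny deterministic task table over 3 goals.
tiny_tasks <- function() {
  data.frame(
    respondent_id = rep(c("r1", "r2"), each = 4),
    task_id = rep(1:4, 2),
    shown = "A|B|C",
    best  = c("A", "A", "B", "A", "A", "C", "A", "B"),
    worst = c("C", "C", "C", "B", "B", "B", "C", "C"),
    stringsAsFactors = FALSE)
}

clamp_manual <- function(x) min(max(x, -1), 1)

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%.6g - %.6g| <= %g", actual, expected, tol))
}
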