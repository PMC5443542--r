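#' Normalize raw preference values into goal weights
#'
#' The survey schemes produce raw values on arbitrary scales (mean Likert
#' ratings, inverse ranks, logit coefficients). They are mapped to weights
#' in two steps, in this order: (1) add a constant so the smallest value
#' equals 1; (2) divide by a constant so the weights sum to the number of
#' goals (10 in the national assessment). The steps do not commute; after
#' scaling, the minimum weight is generally no longer 1.
#'
#' @param raw named numeric vector of raw per-goal values, finite.
#' @return named weights summing to `length(raw)`.
#' @export
#' @examples
#' normalize_weights(c(a = 0, b = 1)) # c(2/3, 4/3)
normalize_weights <- function(raw) {
  if (length(raw) < 1L) stop("need at least one goal", call. = FALSE)
  if (is.null(names(raw))) stop("raw values must be named by goal", call. = FALSE)
  if (any(!is.finite(raw))) stop("raw values must be finite", call. = FALSE)
  shifted <- raw + (1 - min(raw))
  shifted * length(raw) / sum(shifted)
}

#' Equal goal weights
#'
#' The status-quo scheme: every goal weighted 1 (no survey needed).
#'
#' @param goals character vector of goal ids.
#' @return named weights, all 1.
#' @export
equal_weights <- function(goals) {
  if (length(goals) < 1L) stop("need at least one goal", call. = FALSE)
  stats::setNames(rep(1, length(goals)), goals)
}

#' Likert-derived goal weights
#'
#' Averages each goal's importance rating (1 "Not Important" to 5 "Very
#' Important") across respondents, then applies [normalize_weights()].
#'
#' @param likert data.frame with columns `respondent_id`, `goal`, `rating`
#'   (integers 1-5).
#' @param goals optional goal ids; defaults to the goals present. Every goal
#'   must be rated by at least one respondent.
#' @return named weights summing to the number of goals.
#' @export
likert_weights <- function(likert, goals = NULL) {
  check_range(likert$rating, 1, 5, "Likert rating")
  if (is.null(goals)) goals <- sort(unique(as.character(likert$goal)))
  means <- tapply(likert$rating, factor(likert$goal, levels = goals), mean)
  if (anyNA(means)) {
    stop("goals with no ratings: ",
         paste(goals[is.na(means)], collapse = ", "), call. = FALSE)
  }
  normalize_weights(stats::setNames(as.numeric(means), goals))
}

# Convert a tasks data.frame (shown as pipe-separated ids) to index form.
task_index <- function(tasks, goals = NULL) {
  shown <- strsplit(as.character(tasks$shown), "|", fixed = TRUE)
  k <- lengths(shown)
  if (any(k < 3)) stop("every task must show at least 3 goals", call. = FALSE)
  if (length(unique(k)) != 1L) {
    stop("all tasks must show the same number of goals", call. = FALSE)
  }
  if (is.null(goals)) goals <- sort(unique(unlist(shown)))
  idx <- matrix(match(unlist(shown), goals), nrow(tasks), k[1], byrow = TRUE)
  if (anyNA(idx)) stop("task shows a goal missing from the goal set", call. = FALSE)
  bpos <- mapply(function(s, b) match(b, s), shown, as.character(tasks$best))
  wpos <- mapply(function(s, w) match(w, s), shown, as.character(tasks$worst))
  if (anyNA(bpos) || anyNA(wpos)) {
    stop("best/worst choices must belong to the shown set", call. = FALSE)
  }
  if (any(bpos == wpos)) stop("best and worst must differ", call. = FALSE)
  if (!all(seq_along(goals) %in% idx)) {
    stop("goals never shown in any task: ",
         paste(goals[!seq_along(goals) %in% idx], collapse = ", "), call. = FALSE)
  }
  list(goals = goals, idx = idx, bpos = bpos, wpos = wpos,
       respondent = as.character(tasks$respondent_id))
}

#' Best-worst rank goal weights
#'
#' Counts, for each goal, how often it was chosen best minus how often it
#' was chosen worst across all tasks, ranks goals by this net score
#' (rank 1 = most preferred), uses the inverse rank
#' `n_goals + 1 - rank` as the raw weight, and applies
#' [normalize_weights()]. Ties in the net score are broken by goal-id order
#' (with a message), so results are deterministic.
#'
#' @param tasks data.frame with columns `respondent_id`, `task_id`, `shown`
#'   (pipe-separated goal ids), `best`, `worst`.
#' @param goals optional goal ids.
#' @return named weights summing to the number of goals.
#' @export
bw_rank_weights <- function(tasks, goals = NULL) {
  ti <- task_index(tasks, goals)
  n_best <- tabulate(ti$idx[cbind(seq_len(nrow(ti$idx)), ti$bpos)],
                     nbins = length(ti$goals))
  n_worst <- tabulate(ti$idx[cbind(seq_len(nrow(ti$idx)), ti$wpos)],
                      nbins = length(ti$goals))
  net <- n_best - n_worst
  if (anyDuplicated(net)) {
    message("bw_rank_weights: ties in net best-worst counts broken by goal-id order")
  }
  # rank 1 = largest net count; ties broken by position (goal-id order)
  rk <- rank(-net, ties.method = "first")
  raw <- length(ti$goals) + 1 - rk
  normalize_weights(stats::setNames(as.numeric(raw), ti$goals))
}

# Sequential best-worst log-likelihood, gradient and Hessian in utility
# space. The best choice is a conditional logit over the shown set; the
# worst choice a conditional logit with sign-flipped utilities over the
# shown set minus the best.
maxdiff_ll_parts <- function(u, ti, hessian = FALSE) {
  n <- nrow(ti$idx); k <- ncol(ti$idx); K <- length(ti$goals)
  U <- matrix(u[ti$idx], n, k)
  bi <- cbind(seq_len(n), ti$bpos)
  wi <- cbind(seq_len(n), ti$wpos)
  eb <- exp(U)
  denb <- rowSums(eb)
  pb <- eb / denb
  ew <- exp(-U)
  ew[bi] <- 0
  denw <- rowSums(ew)
  pw <- ew / denw
  ll <- sum(U[bi] - log(denb)) + sum(-U[wi] - log(denw))

  cb <- -pb; cb[bi] <- cb[bi] + 1      # d ll / d u at shown positions (best)
  cw <- pw; cw[wi] <- cw[wi] - 1       # (worst stage)
  grad <- numeric(K)
  contrib <- c(cb + cw)
  gidx <- c(ti$idx)
  sums <- rowsum(contrib, gidx)
  grad[as.integer(rownames(sums))] <- sums

  H <- NULL
  if (hessian) {
    scatter <- function(p) {
      P <- matrix(0, n, K)
      P[cbind(rep(seq_len(n), k), gidx)] <- c(p)
      P
    }
    Pb <- scatter(pb)
    Pw <- scatter(pw)
    H <- crossprod(Pb) - diag(colSums(Pb)) +
      crossprod(Pw) - diag(colSums(Pw))
  }
  list(ll = ll, grad = grad, hessian = H)
}

#' Fit a best-worst (maxdiff) conditional logit
#'
#' Maximum-likelihood estimation of per-goal utilities from best/worst
#' choice tasks, with a single preference class. Each task is modelled
#' sequentially: the best choice follows a conditional logit over the shown
#' set, \eqn{P(b|S) = e^{u_b}/\sum_{j \in S} e^{u_j}}, and the worst choice
#' a conditional logit with sign-flipped utilities over the remaining goals.
#' Utilities are identified by a sum-to-zero constraint. The likelihood is
#' concave; estimation uses Newton-Raphson with analytic gradient and
#' Hessian, initialized at zero, and is deterministic given the data.
#' Standard errors come from the observed information.
#'
#' @param tasks data.frame with columns `respondent_id`, `task_id`, `shown`
#'   (pipe-separated goal ids), `best`, `worst`.
#' @param goals optional goal ids (all must appear in at least one task).
#' @param tol convergence tolerance on the gradient max-norm, default 1e-8.
#' @param max_iter maximum Newton iterations, default 100.
#' @return object of class `maxdiff_fit`: list with `utilities` (named,
#'   summing to 0), `se`, `loglik`, `n_tasks`, `iterations`, `converged`.
#' @export
fit_maxdiff_logit <- function(tasks, goals = NULL, tol = 1e-8, max_iter = 100) {
  ti <- task_index(tasks, goals)
  K <- length(ti$goals)
  # free parameters: u[1..K-1]; u[K] = -sum (sum-to-zero identification)
  A <- rbind(diag(K - 1), rep(-1, K - 1))
  theta <- numeric(K - 1)
  parts <- maxdiff_ll_parts(A %*% theta, ti, hessian = TRUE)
  it <- 0
  while (it < max_iter) {
    g <- crossprod(A, parts$grad)
    if (max(abs(g)) < tol) break
    it <- it + 1
    H <- crossprod(A, parts$hessian %*% A)
    step <- tryCatch(solve(H, g), error = function(e) {
      solve(H - diag(1e-8, K - 1), g)
    })
    # Newton ascent with step halving; the likelihood is concave so the
    # full step almost always succeeds.
    lambda <- 1
    repeat {
      cand <- theta - lambda * step
      new_parts <- maxdiff_ll_parts(A %*% cand, ti, hessian = TRUE)
      if (new_parts$ll >= parts$ll - 1e-12 || lambda < 1e-10) break
      lambda <- lambda / 2
    }
    if (new_parts$ll < parts$ll) break  # stuck at numerical precision
    theta <- cand
    parts <- new_parts
  }
  g <- crossprod(A, parts$grad)
  # the gradient tolerance is capped by what double precision can deliver
  # at this log-likelihood scale
  tol_eff <- max(tol, 1e7 * .Machine$double.eps * (1 + abs(parts$ll)))
  if (max(abs(g)) >= tol_eff) {
    stop(sprintf(paste0("maxdiff logit did not converge in %d iterations ",
                        "(gradient max-norm %.3g, loglik %.6f); the data may ",
                        "be separable (a goal always/never chosen)"),
                 it, max(abs(g)), parts$ll), call. = FALSE)
  }
  u <- drop(A %*% theta)
  H_theta <- crossprod(A, parts$hessian %*% A)
  vcov_theta <- solve(-H_theta)
  vcov_u <- A %*% vcov_theta %*% t(A)
  structure(list(utilities = stats::setNames(u, ti$goals),
                 se = stats::setNames(sqrt(diag(vcov_u)), ti$goals),
                 vcov = vcov_u,
                 loglik = parts$ll,
                 n_tasks = nrow(ti$idx),
                 iterations = it,
                 converged = TRUE),
            class = "maxdiff_fit")
}

#' @export
print.maxdiff_fit <- function(x, ...) {
  cat(sprintf("best-worst conditional logit: %d tasks, loglik %.3f, %d iterations\n",
              x$n_tasks, x$loglik, x$iterations))
  print(data.frame(utility = round(x$utilities, 4), se = round(x$se, 4)))
  invisible(x)
}

#' Goal weights from discrete-choice coefficients
#'
#' The BW-DCE scheme: the fitted maxdiff utilities (which measure the
#' probability of choosing one goal over another) passed through
#' [normalize_weights()].
#'
#' @param fit a `maxdiff_fit` object, or a named utility vector.
#' @return named weights summing to the number of goals.
#' @export
dce_weights <- function(fit) {
  u <- if (inherits(fit, "maxdiff_fit")) fit$utilities else fit
  normalize_weights(u)
}

#' Subgoal weight table
#'
#' Subgoal weights are 0.5/0.5 within every goal except Food Provision,
#' whose wild-capture and mariculture subgoals are weighted by relative
#' yield.
#'
#' @param goal_structure named list: goal id -> character vector of subgoal
#'   ids (goals without subgoals may be omitted or map to `character(0)`).
#' @param fp_yield named nonnegative yields for the Food Provision subgoals
#'   (required if `"FP"` has subgoals); proportions are taken.
#' @param fp_goal id of the Food Provision goal, default `"FP"`.
#' @return data.frame with columns `goal_id`, `subgoal_id`, `weight`.
#' @export
#' @examples
#' subgoal_weight_table(list(BD = c("HAB", "SPP"), FP = c("FIS", "MAR")),
#'                      fp_yield = c(FIS = 85, MAR = 15))
subgoal_weight_table <- function(goal_structure, fp_yield = NULL,
                                 fp_goal = "FP") {
  rows <- lapply(names(goal_structure), function(g) {
    subs <- goal_structure[[g]]
    if (length(subs) == 0) return(NULL)
    if (g == fp_goal) {
      if (is.null(fp_yield)) {
        stop("Food Provision subgoals need yield weights", call. = FALSE)
      }
      y <- fp_yield[subs]
      if (anyNA(y) || any(y < 0) || sum(y) <= 0) {
        stop("invalid Food Provision yields", call. = FALSE)
      }
      w <- as.numeric(y) / sum(y)
    } else {
      w <- rep(0.5, length(subs))
    }
    data.frame(goal_id = g, subgoal_id = subs, weight = w,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compute goal weights under a named scheme
#'
#' Dispatch helper for the four schemes: `"equal"`, `"likert"`,
#' `"bw-rank"`, `"bw-dce"`.
#'
#' @param scheme scheme name.
#' @param likert,tasks survey tables as in [likert_weights()] and
#'   [fit_maxdiff_logit()] (only the ones the scheme needs are required).
#' @param goals goal ids.
#' @return named weights.
#' @export
goal_weights <- function(scheme = c("equal", "likert", "bw-rank", "bw-dce"),
                         likert = NULL, tasks = NULL, goals = NULL) {
  scheme <- match.arg(scheme)
  switch(scheme,
         "equal" = {
           if (is.null(goals)) stop("equal scheme needs the goal list", call. = FALSE)
           equal_weights(goals)
         },
         "likert" = likert_weights(likert, goals),
         "bw-rank" = bw_rank_weights(tasks, goals),
         "bw-dce" = dce_weights(fit_maxdiff_logit(tasks, goals)))
}

# Maximal cliques of a small undirected graph given as a logical adjacency
# matrix (diagonal TRUE). Groups here number at most a handful, so a plain
# Bron-Kerbosch recursion is ample.
maximal_cliques <- function(adj) {
  n <- nrow(adj)
  cliques <- list()
  bk <- function(r, p, x) {
    if (length(p) == 0 && length(x) == 0) {
      cliques[[length(cliques) + 1L]] <<- sort(r)
      return()
    }
    for (v in p) {
      nb <- setdiff(which(adj[v, ]), v)
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  unique(cliques)
}

# Compact letter display: groups ordered by decreasing index; each maximal
# clique of the "not different" graph gets a letter; a group's label is the
# sorted concatenation of the letters of cliques containing it.
letters_from_similarity <- function(adj, order_by) {
  ord <- order(order_by, decreasing = TRUE)
  cl <- maximal_cliques(adj)
  # order cliques by their best-ranked member for stable letter assignment
  cl <- cl[order(vapply(cl, function(m) min(match(m, ord)), numeric(1)))]
  lab <- rep("", nrow(adj))
  for (i in seq_along(cl)) {
    lab[cl[[i]]] <- paste0(lab[cl[[i]]], letters[i])
  }
  vapply(lab, function(s) paste(sort(strsplit(s, "")[[1]]), collapse = ""), "")
}

#' Bootstrap comparison of group-specific indices
#'
#' Compares the overall index between respondent groups (regions, age
#' groups, political affiliations, NGO membership) under a survey-derived
#' weighting scheme. For each simulation, respondents are resampled with
#' replacement within each group, the scheme's weights are refit, and the
#' overall index recomputed from the fixed per-goal scores. Two groups
#' share a letter when their indices are statistically indistinguishable;
#' with `share_rule = "interval"` (default) that means the central 95%
#' interval of the bootstrapped index difference contains 0, and with
#' `share_rule = "proportion"` that the indices differed beyond the
#' reporting precision in fewer than 95% of simulations.
#'
#' @param tasks best/worst tasks table (see [fit_maxdiff_logit()]).
#' @param demographics data.frame with `respondent_id` and the grouping
#'   column.
#' @param group_by name of the grouping column.
#' @param goal_scores named per-goal scores from the engine (these do not
#'   depend on the weights).
#' @param likert optional Likert table (needed for `scheme = "likert"`).
#' @param scheme weighting scheme, default `"bw-dce"`.
#' @param n_sims number of bootstrap simulations, default 500.
#' @param seed RNG seed.
#' @param share_rule `"interval"` or `"proportion"`.
#' @param precision reporting precision for the proportion rule, default 0.01.
#' @param goals optional goal ids.
#' @return list with `groups` (group, n respondents, index, letter),
#'   `similar` (logical matrix), and `sims` (n_sims x n_groups index draws).
#' @export
compare_groups <- function(tasks, demographics, group_by, goal_scores,
                           likert = NULL,
                           scheme = c("bw-dce", "bw-rank", "likert"),
                           n_sims = 500, seed = 1,
                           share_rule = c("interval", "proportion"),
                           precision = 0.01, goals = NULL) {
  scheme <- match.arg(scheme)
  share_rule <- match.arg(share_rule)
  if (n_sims < 1) stop("n_sims must be >= 1", call. = FALSE)
  if (is.null(goals)) goals <- sort(names(goal_scores))
  grp <- as.character(demographics[[group_by]])
  if (is.null(grp)) stop("demographics lacks column ", group_by, call. = FALSE)
  groups <- sort(unique(grp))
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  by_group <- split(as.character(demographics$respondent_id), grp)
  n_resp <- lengths(by_group)
  if (any(n_resp < 2)) {
    stop("groups with fewer than 2 respondents: ",
         paste(groups[n_resp < 2], collapse = ", "), call. = FALSE)
  }

  weights_for <- function(ids) {
    # resampled ids can repeat; replicate task (and likert) rows per draw
    t_sub <- do.call(rbind, lapply(ids, function(id) {
      tasks[tasks$respondent_id == id, , drop = FALSE]
    }))
    l_sub <- if (!is.null(likert)) {
      do.call(rbind, lapply(ids, function(id) {
        likert[likert$respondent_id == id, , drop = FALSE]
      }))
    }
    goal_weights(scheme, likert = l_sub, tasks = t_sub, goals = goals)
  }
  index_for <- function(ids) {
    aggregate_index(goal_scores, weights_for(ids))
  }

  point <- vapply(by_group, index_for, numeric(1))
  sims <- with_seed(seed, {
    vapply(seq_len(n_sims), function(s) {
      vapply(by_group, function(ids) {
        index_for(sample(ids, length(ids), replace = TRUE))
      }, numeric(1))
    }, numeric(length(groups)))
  })
  sims <- t(matrix(sims, nrow = length(groups)))
  colnames(sims) <- groups

  ng <- length(groups)
  similar <- diag(TRUE, ng)
  dimnames(similar) <- list(groups, groups)
  for (i in seq_len(ng - 1)) {
    for (j in seq.int(i + 1, ng)) {
      d <- sims[, i] - sims[, j]
      same <- if (share_rule == "interval") {
        q <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
        q[1] <= 0 && 0 <= q[2]
      } else {
        mean(abs(d) > precision) < 0.95
      }
      similar[i, j] <- similar[j, i] <- same
    }
  }
  lab <- letters_from_similarity(similar, point)
  list(groups = data.frame(group = groups, n = as.integer(n_resp),
                           index = unname(point), letter = lab,
                           stringsAsFactors = FALSE),
       similar = similar, sims = sims)
}
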