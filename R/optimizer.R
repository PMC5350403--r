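# Two-level Taguchi orthogonal-array optimization with variance-weighted
# farthest-point (VVP) probabilistic restarts.
#
# A vertex is a full 20-variable stem configuration (15 continuous semiaxes
# + 5 integer exponents). Each restart picks the stored vertex farthest
# from the rest, builds two levels per variable (x -/+ 0.2 * domain width
# for continuous variables, p -/+ 1 for exponents, box-projected into
# bounds), runs the smallest two-level orthogonal array covering all
# factors, and steps to the main-effects optimum until no further
# improvement; the local optimum joins the vertex store.

#' Two-level orthogonal array
#'
#' Smallest standard two-level orthogonal array (Sylvester-Hadamard
#' construction: L4, L8, L16, L32, L64) accommodating `n_factors` columns.
#' Every column is balanced and every column pair contains each level
#' combination equally often; 20 factors yield the 32-run array.
#'
#' @param n_factors number of two-level factors (>= 1)
#' @return runs x n_factors integer matrix with entries 1/2
#' @export
orthogonal_array <- function(n_factors) {
  if (!is_number(n_factors) || n_factors < 1)
    stop_stemopt("n_factors must be a positive integer", "invalid_parameter")
  n_factors <- as.integer(n_factors)
  runs <- 2L
  while (runs - 1L < n_factors && runs <= 64L) runs <- runs * 2L
  if (runs > 64L)
    stop_stemopt("orthogonal arrays supported up to 63 factors (64 runs)",
                 "capacity_error")
  h <- matrix(1, 1, 1)
  while (nrow(h) < runs) h <- rbind(cbind(h, h), cbind(h, -h))
  oa <- (3L - h[, 2L:(n_factors + 1L), drop = FALSE]) / 2L
  storage.mode(oa) <- "integer"
  oa
}

#' Box projection into variable bounds
#'
#' Clamps each value to its `[lower, upper]` interval; idempotent.
#'
#' @param x values
#' @param lower,upper bounds (recycled)
#' @return projected values
#' @export
box_project <- function(x, lower, upper) clamp(x, lower, upper)

#' Two-level design around a vertex
#'
#' Continuous variables get the levels `x -/+ offset * (upper - lower)`;
#' integer exponent variables get `p -/+ 1`. All levels are box-projected
#' into their bounds.
#'
#' @param values current vertex values
#' @param lower,upper per-variable bounds
#' @param integer logical: which variables are integer exponents
#' @param offset level offset as a fraction of the domain width (default
#'   0.2)
#' @return 2 x n matrix of levels (row k = level k)
#' @export
make_levels <- function(values, lower, upper, integer = NULL, offset = 0.2) {
  n <- length(values)
  if (is.null(integer)) integer <- rep(FALSE, n)
  delta <- ifelse(integer, 1, offset * (upper - lower))
  lv <- rbind(values - delta, values + delta)
  lv[1, ] <- box_project(lv[1, ], lower, upper)
  lv[2, ] <- box_project(lv[2, ], lower, upper)
  lv[, integer] <- round(lv[, integer])
  rownames(lv) <- c("level1", "level2")
  lv
}

#' Farthest stored vertex (variable variance probability selection)
#'
#' Selects the stored vertex that is farthest from the rest: vertices are
#' normalized to the unit box, each coordinate is weighted by the store's
#' per-coordinate variance (so directions along which the store already
#' spreads count more), and the vertex maximizing the minimum weighted
#' Euclidean distance to all other vertices wins. Ties break toward the
#' lowest index; `weighting = "uniform"` gives the plain max-min distance.
#'
#' @param store matrix of stored vertices (rows)
#' @param lower,upper per-variable bounds used for normalization
#' @param weighting `"variance"` (default) or `"uniform"`
#' @param eligible optional logical vector: vertices selectable as the next
#'   restart start (all by default). Ineligible vertices still shape the
#'   distances, so a start is never reused while the store keeps repelling
#'   new selections away from it.
#' @return list with `index` and `values`
#' @export
vvp_select <- function(store, lower, upper,
                       weighting = c("variance", "uniform"),
                       eligible = NULL) {
  weighting <- match.arg(weighting)
  if (is.null(dim(store)) || nrow(store) < 2L)
    stop_stemopt("vertex store must contain at least two vertices",
                 "insufficient_vertices")
  n <- nrow(store)
  if (is.null(eligible)) eligible <- rep(TRUE, n)
  if (!any(eligible))
    stop_stemopt("no eligible vertices left in the store",
                 "insufficient_vertices")
  u <- sweep(sweep(store, 2L, lower), 2L, pmax(upper - lower, 1e-300), "/")
  w <- if (weighting == "variance") apply(u, 2L, stats::var) else
    rep(1, ncol(u))
  if (all(w <= 0)) w <- rep(1, ncol(u))
  score <- vapply(seq_len(n), function(i) {
    if (!eligible[i]) return(-Inf)
    d2 <- colSums(w * (t(u[-i, , drop = FALSE]) - u[i, ])^2)
    sqrt(min(d2))
  }, numeric(1))
  idx <- which.max(score)   # which.max already breaks ties at lowest index
  list(index = idx, values = store[idx, ])
}

#' One Taguchi orthogonal-array step
#'
#' Evaluates every run of the orthogonal array over the two-level design
#' around `values`, estimates per-factor main effects (mean response per
#' level, smaller-is-better; optionally the Taguchi signal-to-noise ratio
#' `-10 log10(y^2)`, larger-is-better), evaluates the predicted optimal
#' level combination, and returns the better of the predicted optimum and
#' the best evaluated run (the fallback covers factor interactions that
#' invalidate the main-effects prediction).
#'
#' @param evaluator function(values) -> finite objective (smaller is
#'   better)
#' @param values current vertex
#' @param lower,upper,integer,offset as in [make_levels()]
#' @param sn_ratio use the signal-to-noise transform for main effects?
#' @return list: `values` (proposed vertex), `objective`, `predicted_used`
#'   (FALSE when the best run replaced an underperforming prediction),
#'   `runs` (data.frame log: one row per array run plus the prediction)
#' @export
taguchi_step <- function(evaluator, values, lower, upper, integer = NULL,
                         offset = 0.2, sn_ratio = FALSE) {
  n <- length(values)
  if (is.null(integer)) integer <- rep(FALSE, n)
  lv <- make_levels(values, lower, upper, integer, offset)
  oa <- orthogonal_array(n)
  runs <- nrow(oa)
  x_runs <- matrix(NA_real_, runs, n)
  for (i in seq_len(n)) x_runs[, i] <- lv[oa[, i], i]
  y <- vapply(seq_len(runs), function(r) evaluator(x_runs[r, ]), numeric(1))
  if (any(!is.finite(y)))
    stop_stemopt("evaluator returned a non-finite objective for an array run",
                 "infeasible_region")
  resp <- if (sn_ratio) -(-10 * log10(pmax(y, 1e-300)^2)) else y
  # per-factor level choice: smaller mean response is better
  best_level <- vapply(seq_len(n), function(i) {
    m1 <- mean(resp[oa[, i] == 1L])
    m2 <- mean(resp[oa[, i] == 2L])
    if (m1 <= m2) 1L else 2L
  }, integer(1))
  pred <- vapply(seq_len(n), function(i) lv[best_level[i], i], numeric(1))
  y_pred <- evaluator(pred)
  log_df <- data.frame(run = c(seq_len(runs), NA),
                       objective = c(y, y_pred),
                       kind = c(rep("array", runs), "predicted"))
  best_run <- which.min(y)
  if (is.finite(y_pred) && y_pred <= y[best_run])
    list(values = pred, objective = y_pred, predicted_used = TRUE,
         runs = log_df)
  else
    list(values = x_runs[best_run, ], objective = y[best_run],
         predicted_used = FALSE, runs = log_df)
}

#' Taguchi orthogonal-array global optimization with probabilistic restarts
#'
#' Seeds a vertex store with `n_init` random configurations, then repeats
#' up to `max_restarts` times: select the farthest stored vertex
#' ([vvp_select()]), descend from it by repeated [taguchi_step()]s until the
#' suggested optimum stops improving, and add the resulting local optimum
#' to the store (an optimum already stored within tolerance is skipped).
#' Stops when the restart budget is exhausted and returns all distinct
#' local optima ranked by objective plus the full evaluation log.
#'
#' @param evaluator function(values) -> finite objective (smaller is
#'   better)
#' @param lower,upper per-variable bounds
#' @param integer logical vector marking integer variables (default none)
#' @param n_init number of random initial vertices (default 10)
#' @param max_restarts maximum number of restarts (default 30)
#' @param seed RNG seed (single seeded generator drives the whole run)
#' @param offset level offset fraction (default 0.2)
#' @param sn_ratio use the signal-to-noise main-effects transform?
#' @param weighting restart selection weighting, see [vvp_select()]
#' @param max_local_iter cap on Taguchi steps per restart
#' @param dup_tol duplicate-vertex tolerance in the unit box
#' @return object of class `opt_result`: `best` (list: values, objective),
#'   `optima` (ranked data.frame of distinct local optima), `store`
#'   (vertex matrix), `log` (per-evaluation data.frame), `n_evals`,
#'   `restarts` (per-restart outcome codes: "optimum", "duplicate")
#' @export
taguchi_optimize <- function(evaluator, lower, upper, integer = NULL,
                             n_init = 10, max_restarts = 30, seed = 1,
                             offset = 0.2, sn_ratio = FALSE,
                             weighting = "variance", max_local_iter = 25,
                             dup_tol = 1e-6) {
  n <- length(lower)
  if (length(upper) != n || any(upper < lower))
    stop_stemopt("invalid bounds", "invalid_parameter")
  if (is.null(integer)) integer <- rep(FALSE, n)
  if (n_init < 2) stop_stemopt("need n_init >= 2", "invalid_parameter")
  set.seed(seed)

  n_evals <- 0L
  log_rows <- list()
  ev <- function(x, context) {
    y <- evaluator(x)
    if (!is.finite(y))
      stop_stemopt("evaluator returned non-finite objective",
                   "infeasible_region")
    n_evals <<- n_evals + 1L
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      eval = n_evals, context = context, objective = y,
      t(stats::setNames(x, paste0("x", seq_along(x)))))
    y
  }

  random_vertex <- function() {
    v <- lower + stats::runif(n) * (upper - lower)
    v[integer] <- floor(lower[integer] +
      stats::runif(sum(integer)) * (upper[integer] - lower[integer] + 1))
    v[integer] <- clamp(v[integer], lower[integer], upper[integer])
    v
  }

  store <- t(vapply(seq_len(n_init), function(i) random_vertex(),
                    numeric(n)))
  f_store <- vapply(seq_len(n_init),
                    function(i) ev(store[i, ], "init"), numeric(1))
  is_optimum <- rep(FALSE, n_init)
  eligible <- rep(TRUE, n_init)   # a vertex starts one restart at most

  unit <- function(x) (x - lower) / pmax(upper - lower, 1e-300)
  duplicated_in_store <- function(x) {
    ux <- unit(x)
    any(apply(store, 1L, function(s) sqrt(sum((unit(s) - ux)^2)) < dup_tol))
  }

  restarts <- character(0)
  if (max_restarts > 0) for (r in seq_len(max_restarts)) {
    if (!any(eligible)) break           # every stored vertex already used
    sel <- vvp_select(store, lower, upper, weighting, eligible)
    eligible[sel$index] <- FALSE
    cur <- sel$values
    f_cur <- f_store[sel$index]
    for (it in seq_len(max_local_iter)) {
      stp <- taguchi_step(function(x) ev(x, sprintf("restart%d", r)),
                          cur, lower, upper, integer, offset, sn_ratio)
      if (stp$objective < f_cur - 1e-12) {
        cur <- stp$values
        f_cur <- stp$objective
      } else break                      # suggested optimum no longer better
    }
    if (duplicated_in_store(cur)) {     # optimum already known: skip
      restarts <- c(restarts, "duplicate")
      next
    }
    store <- rbind(store, cur)
    f_store <- c(f_store, f_cur)
    is_optimum <- c(is_optimum, TRUE)
    eligible <- c(eligible, TRUE)       # new optima may seed later restarts
    restarts <- c(restarts, "optimum")
  }

  ord <- order(f_store)
  opt_idx <- ord[is_optimum[ord] | ord == ord[1]]
  optima <- data.frame(rank = seq_along(opt_idx),
                       objective = f_store[opt_idx],
                       store[opt_idx, , drop = FALSE])
  names(optima)[-(1:2)] <- paste0("x", seq_len(n))
  rownames(store) <- NULL
  structure(list(
    best = list(values = store[ord[1], ], objective = f_store[ord[1]]),
    optima = optima, store = store, objectives = f_store,
    log = do.call(rbind, log_rows), n_evals = n_evals,
    restarts = restarts, seed = seed,
    config = list(n_init = n_init, max_restarts = max_restarts,
                  offset = offset, weighting = weighting)),
    class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf(
    "opt_result: best objective %.6g after %d evaluations, %d restart(s) (%d distinct optima)\n",
    x$best$objective, x$n_evals, length(x$restarts),
    sum(x$restarts == "optimum")))
  invisible(x)
}
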