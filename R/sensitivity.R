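# One-way sensitivity analysis: grid sweep of a single parameter with
# bisection refinement of the cost-effectiveness threshold.

#' One-way sensitivity analysis with threshold search
#'
#' Sweeps a single parameter over `[low, high]` holding everything else at
#' base case. At each grid value `outcome_fn(value)` must rebuild and solve
#' every strategy, returning outcomes accepted by [rank_strategies()]. The
#' predicate tracked is "`target` is the cost-effective choice at `wtp`";
#' wherever it changes sign between adjacent grid points the crossing is
#' refined by bisection to `tol` times the parameter range.
#'
#' @param outcome_fn Function of one numeric parameter value returning a
#'   list of [strategy_outcome()]s or an outcome data frame for all
#'   strategies.
#' @param parameter Name of the swept parameter (for labelling).
#' @param low,high Sweep bounds, `low < high`.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @param target Strategy name whose cost-effectiveness is tracked.
#' @param n_grid Number of grid points (default 41).
#' @param comparator Optional strategy name; when given, `icer_curve` is the
#'   pairwise ICER of `target` vs `comparator` at each grid value, otherwise
#'   the target's frontier ICER (or `NA` when off the frontier).
#' @param tol Bisection tolerance as a fraction of `high - low`.
#' @return A `sensitivity_result` list: `parameter`, `grid`, `icer_curve`,
#'   `choice` (cost-effective strategy per grid value), `target_ce` (logical
#'   predicate per grid value), and `threshold` (the refined crossing, or
#'   `NA` when the predicate is constant over the grid). When several
#'   crossings exist all are refined; `threshold` is the first and
#'   `thresholds` lists every crossing.
#' @export
one_way_sensitivity <- function(outcome_fn, parameter, low, high, wtp, target,
                                n_grid = 41L, comparator = NULL, tol = 1e-6) {
  if (!(low < high)) stop("low must be < high", call. = FALSE)
  if (n_grid < 2L) stop("n_grid must be >= 2", call. = FALSE)
  grid <- seq(low, high, length.out = n_grid)

  eval_point <- function(v) {
    res <- rank_strategies(outcome_fn(v))
    if (!target %in% res$name) {
      stop(sprintf("target strategy '%s' not produced by outcome_fn", target),
           call. = FALSE)
    }
    ce <- identical(cost_effective_choice(res, wtp), target)
    ic <- if (!is.null(comparator)) {
      ti <- match(target, res$name); ci <- match(comparator, res$name)
      icer(list(cost = res$cost[ti], effect = res$effect[ti]),
           list(cost = res$cost[ci], effect = res$effect[ci]))$icer
    } else {
      res$icer[match(target, res$name)]
    }
    list(ce = ce, icer = ic, choice = cost_effective_choice(res, wtp))
  }

  pts <- lapply(grid, eval_point)
  target_ce <- vapply(pts, `[[`, logical(1), "ce")
  icer_curve <- vapply(pts, `[[`, numeric(1), "icer")
  choice <- vapply(pts, `[[`, character(1), "choice")

  thresholds <- numeric(0)
  flips <- which(target_ce[-1] != target_ce[-n_grid])
  abs_tol <- tol * (high - low)
  for (k in flips) {
    lo <- grid[k]; hi <- grid[k + 1L]
    ce_lo <- target_ce[k]
    while (hi - lo > abs_tol) {
      mid <- (lo + hi) / 2
      if (eval_point(mid)$ce == ce_lo) lo <- mid else hi <- mid
    }
    thresholds <- c(thresholds, (lo + hi) / 2)
  }
  structure(list(parameter = parameter, grid = grid,
                 icer_curve = icer_curve, choice = choice,
                 target_ce = target_ce, target = target, wtp = wtp,
                 threshold = if (length(thresholds)) thresholds[1] else NA_real_,
                 thresholds = thresholds),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("One-way sensitivity on '%s' over [%g, %g] (%d points)\n",
              x$parameter, min(x$grid), max(x$grid), length(x$grid)))
  cat(sprintf("Target '%s' cost-effective at WTP %g on %d/%d grid points\n",
              x$target, x$wtp, sum(x$target_ce), length(x$grid)))
  if (is.na(x$threshold)) {
    cat("No threshold crossing inside the sweep range\n")
  } else {
    cat(sprintf("Threshold: %s = %.6g\n", x$parameter, x$threshold))
  }
  invisible(x)
}

#' Tornado table over several one-way sweeps
#'
#' @param sweeps Named list: parameter name -> list(low =, high =).
#' @param outcome_fn_factory Function of (parameter name) returning the
#'   single-parameter `outcome_fn` used by [one_way_sensitivity()].
#' @param wtp,target,comparator,n_grid Passed through.
#' @return Data frame with one row per parameter: ICER at low, at high, and
#'   the threshold if one was found.
#' @export
tornado_table <- function(sweeps, outcome_fn_factory, wtp, target,
                          comparator = NULL, n_grid = 11L) {
  rows <- lapply(names(sweeps), function(p) {
    sw <- one_way_sensitivity(outcome_fn_factory(p), p,
                              sweeps[[p]]$low, sweeps[[p]]$high,
                              wtp, target, n_grid = n_grid,
                              comparator = comparator)
    data.frame(parameter = p,
               low = sweeps[[p]]$low, high = sweeps[[p]]$high,
               icer_at_low = sw$icer_curve[1],
               icer_at_high = sw$icer_curve[length(sw$icer_curve)],
               threshold = sw$threshold,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
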