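# Cost-effectiveness analytics: ICERs, strict and extended dominance,
# efficiency frontier, willingness-to-pay decision rule.

#' A strategy outcome (discounted cost and effect)
#'
#' @param name Strategy label.
#' @param cost Discounted total cost (USD), `>= 0`.
#' @param effect Discounted total effect (QALYs), `>= 0`.
#' @return An object of class `strategy_outcome`.
#' @export
strategy_outcome <- function(name, cost, effect) {
  if (cost < 0 || effect < 0) {
    stop("cost and effect must be non-negative", call. = FALSE)
  }
  structure(list(name = as.character(name), cost = as.numeric(cost),
                 effect = as.numeric(effect)),
            class = "strategy_outcome")
}

#' Incremental cost-effectiveness ratio between two strategies
#'
#' Computes `(cost_ref - cost_comp) / (effect_ref - effect_comp)` in
#' USD/QALY. The ratio is positive when the reference strategy is both more
#' costly and more effective than the comparator. A negative ratio with the
#' reference cheaper and more effective is classified `"dominant"`; cheaper
#' and less effective or costlier and less effective cases are classified
#' accordingly. When the effect difference is exactly zero no ratio exists
#' and `icer` is `NA` with classification `"equal-effect"`.
#'
#' @param reference,comparator [strategy_outcome()] objects (or lists with
#'   `cost` and `effect`).
#' @return A list with `icer` (USD/QALY or `NA`), `delta_cost`,
#'   `delta_effect` and a `classification` string.
#' @export
icer <- function(reference, comparator) {
  dc <- reference$cost - comparator$cost
  de <- reference$effect - comparator$effect
  if (de == 0) {
    cls <- if (dc == 0) "equivalent" else "equal-effect"
    return(list(icer = NA_real_, delta_cost = dc, delta_effect = de,
                classification = cls))
  }
  r <- dc / de
  cls <- if (dc <= 0 && de > 0) {
    "dominant (cheaper and better)"
  } else if (dc > 0 && de > 0) {
    "trade-off (more costly, more effective)"
  } else if (dc >= 0 && de < 0) {
    "dominated (costlier and worse)"
  } else {
    "trade-off (cheaper, less effective)"
  }
  list(icer = r, delta_cost = dc, delta_effect = de, classification = cls)
}

#' Rank strategies: dominance, extended dominance and frontier ICERs
#'
#' Strategies are sorted by increasing effect. A strategy is strictly
#' dominated when another strategy has no higher cost and no lower effect,
#' with at least one strict inequality. Extended dominance is then removed
#' iteratively: a strategy whose incremental ICER exceeds that of the next
#' more effective remaining strategy is excluded from the frontier. The
#' surviving frontier has strictly increasing cost, effect and ICERs.
#' Exact cost-and-effect ties are both kept on the frontier and flagged
#' `"equivalent"`.
#'
#' @param outcomes A list of [strategy_outcome()] objects or a data frame
#'   with columns `name`, `cost`, `effect`.
#' @return A `cea_result`: a data frame sorted by increasing effect with
#'   columns `name`, `cost`, `effect`, `status`
#'   (`"on-frontier"`, `"dominated"`, `"extended-dominated"`,
#'   `"equivalent"`) and `icer` (frontier ICER vs the previous frontier
#'   strategy; `NA` for the least effective frontier strategy).
#' @export
rank_strategies <- function(outcomes) {
  df <- as_outcome_df(outcomes)
  if (nrow(df) < 2L) stop("at least 2 strategies are required", call. = FALSE)
  if (anyDuplicated(df$name)) {
    stop("duplicate strategy names", call. = FALSE)
  }
  # stable sort: effect, then cost, then name for reproducible ordering
  df <- df[order(df$effect, df$cost, df$name), , drop = FALSE]
  rownames(df) <- NULL
  n <- nrow(df)
  status <- rep("on-frontier", n)

  # exact ties in both coordinates: equivalent, kept
  key <- paste(df$cost, df$effect)
  tied <- key %in% key[duplicated(key)]

  # strict dominance
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$cost[j] <= df$cost[i] && df$effect[j] >= df$effect[i] &&
          (df$cost[j] < df$cost[i] || df$effect[j] > df$effect[i])) {
        status[i] <- "dominated"
        break
      }
    }
  }

  # extended dominance: drop frontier candidates whose incremental ICER
  # exceeds that of the next more effective candidate, repeating to fixpoint
  repeat {
    idx <- which(status == "on-frontier")
    if (length(idx) < 3L) break
    removed <- FALSE
    for (k in 2:(length(idx) - 1L)) {
      a <- idx[k - 1L]; b <- idx[k]; c <- idx[k + 1L]
      de_ab <- df$effect[b] - df$effect[a]
      de_bc <- df$effect[c] - df$effect[b]
      if (de_ab == 0 || de_bc == 0) next  # exact ties carry no ICER
      icer_ab <- (df$cost[b] - df$cost[a]) / de_ab
      icer_bc <- (df$cost[c] - df$cost[b]) / de_bc
      if (icer_ab > icer_bc) {
        status[b] <- "extended-dominated"
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  status[tied & status == "on-frontier"] <- "equivalent"

  icers <- rep(NA_real_, n)
  idx <- which(status %in% c("on-frontier", "equivalent"))
  if (length(idx) > 1L) {
    for (k in 2:length(idx)) {
      a <- idx[k - 1L]; b <- idx[k]
      de <- df$effect[b] - df$effect[a]
      if (de > 0) icers[b] <- (df$cost[b] - df$cost[a]) / de
    }
  }
  df$status <- status
  df$icer <- icers
  class(df) <- c("cea_result", "data.frame")
  df
}

as_outcome_df <- function(outcomes) {
  if (is.data.frame(outcomes)) {
    stopifnot(all(c("name", "cost", "effect") %in% names(outcomes)))
    df <- outcomes[, c("name", "cost", "effect")]
  } else {
    df <- do.call(rbind, lapply(outcomes, function(o) {
      data.frame(name = o$name, cost = o$cost, effect = o$effect,
                 stringsAsFactors = FALSE)
    }))
  }
  if (any(df$cost < 0) || any(df$effect < 0)) {
    stop("costs and effects must be non-negative", call. = FALSE)
  }
  df
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness ranking (sorted by increasing effect):\n")
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' Cost-effective strategy at a willingness-to-pay threshold
#'
#' Returns the most effective frontier strategy whose frontier ICER does not
#' exceed `wtp`; when no frontier ICER qualifies, the least costly strategy
#' is returned.
#'
#' @param result A `cea_result` from [rank_strategies()].
#' @param wtp Willingness-to-pay threshold (USD/QALY, `>= 0`).
#' @return The chosen strategy name.
#' @export
cost_effective_choice <- function(result, wtp) {
  stopifnot(inherits(result, "cea_result"))
  if (wtp < 0) stop("willingness-to-pay must be >= 0", call. = FALSE)
  idx <- which(result$status %in% c("on-frontier", "equivalent"))
  choice <- idx[1L]   # least effective (and least costly) frontier point
  if (length(idx) > 1L) {
    for (k in 2:length(idx)) {
      i <- idx[k]
      if (!is.na(result$icer[i]) && result$icer[i] <= wtp) choice <- i
      else if (is.na(result$icer[i]) && result$status[i] == "equivalent") next
      else break
    }
  }
  result$name[choice]
}
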