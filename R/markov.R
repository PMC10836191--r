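# Discrete-time Markov cohort engine: state spaces, models, traces,
# reward accumulation and discounting.

ROW_SUM_TOL <- 1e-9     # maximum tolerated deviation of a row sum from 1
RENORM_TOL  <- 1e-12    # deviations below this are silently renormalized

#' Define a Markov state space
#'
#' @param names Character vector of unique state labels.
#' @param absorbing Character vector naming the absorbing states; must be a
#'   subset of `names` and non-empty (every cohort model here has at least a
#'   "Dead" state).
#' @return An object of class `state_space`.
#' @export
state_space <- function(names, absorbing = "Dead") {
  if (anyDuplicated(names)) stop("state names must be unique", call. = FALSE)
  if (!all(absorbing %in% names)) {
    stop("absorbing states must be a subset of state names", call. = FALSE)
  }
  if (length(absorbing) < 1L) {
    stop("at least one absorbing state is required", call. = FALSE)
  }
  structure(list(names = as.character(names),
                 absorbing = as.character(absorbing)),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space:", paste(x$names, collapse = ", "), "\n")
  cat("Absorbing:  ", paste(x$absorbing, collapse = ", "), "\n")
  invisible(x)
}

# Validate one transition matrix against a state space; `cycle` only
# used for error messages. Renormalizes floating-point dust in place.
validate_transition <- function(P, states, cycle = NA) {
  n <- length(states$names)
  if (!is.matrix(P) || nrow(P) != n || ncol(P) != n) {
    stop("transition matrix must be ", n, " x ", n, call. = FALSE)
  }
  if (any(P < -RENORM_TOL) || any(P > 1 + RENORM_TOL)) {
    bad <- which(P < -RENORM_TOL | P > 1 + RENORM_TOL, arr.ind = TRUE)[1, ]
    stop(sprintf("transition probability out of [0,1] from state '%s'",
                 states$names[bad[1]]), call. = FALSE)
  }
  rs <- rowSums(P)
  dev <- abs(rs - 1)
  if (any(dev > ROW_SUM_TOL)) {
    i <- which.max(dev)
    stop(sprintf(
      "transition row for state '%s'%s sums to %.12g, not 1",
      states$names[i],
      if (is.na(cycle)) "" else sprintf(" (cycle %d)", cycle),
      rs[i]), call. = FALSE)
  }
  fix <- dev > 0 & dev <= RENORM_TOL
  if (any(fix)) P[fix, ] <- P[fix, , drop = FALSE] / rs[fix]
  for (a in states$absorbing) {
    i <- match(a, states$names)
    row <- numeric(n); row[i] <- 1
    if (max(abs(P[i, ] - row)) > ROW_SUM_TOL) {
      stop(sprintf("absorbing state '%s' must map to itself with probability 1", a),
           call. = FALSE)
    }
  }
  dimnames(P) <- list(states$names, states$names)
  P
}

#' Construct a Markov cohort model
#'
#' Transitions may be a single row-stochastic matrix (applied every cycle)
#' or a list of `n_cycles` matrices for time-varying transitions such as
#' age-indexed background mortality.
#'
#' @param states A [state_space()].
#' @param transition A single `n x n` matrix or a list of `n_cycles` matrices;
#'   rows must sum to 1 within `1e-9` and absorbing rows must be unit vectors.
#' @param initial Probability vector over states (sums to 1).
#' @param n_cycles Positive integer number of annual cycles.
#' @param costs Per-state annual cost (USD/year), non-negative.
#' @param utilities Per-state annual utility weight in `[0, 1]`.
#' @param discount_rate Annual discount rate (fraction, `>= 0`), applied to
#'   costs; QALYs use `discount_rate_qaly` which defaults to the same value.
#' @param discount_rate_qaly Annual discount rate for QALYs.
#' @param one_time_costs Optional `n x n` matrix of one-time transition costs
#'   (USD) credited when the corresponding transition is made.
#' @param cycle_length Cycle duration in years (fixed at 1 for this model
#'   family; kept explicit for transparency).
#' @return An object of class `markov_model`.
#' @export
markov_model <- function(states, transition, initial, n_cycles,
                         costs = NULL, utilities = NULL,
                         discount_rate = 0.03,
                         discount_rate_qaly = discount_rate,
                         one_time_costs = NULL,
                         cycle_length = 1) {
  stopifnot(inherits(states, "state_space"))
  n <- length(states$names)
  if (!is.numeric(n_cycles) || length(n_cycles) != 1L || n_cycles < 1 ||
      n_cycles != round(n_cycles)) {
    stop("n_cycles must be a positive integer", call. = FALSE)
  }
  n_cycles <- as.integer(n_cycles)
  if (is.matrix(transition)) {
    transition <- validate_transition(transition, states)
    time_varying <- FALSE
  } else if (is.list(transition)) {
    if (length(transition) != n_cycles) {
      stop("a transition list must supply one matrix per cycle", call. = FALSE)
    }
    transition <- lapply(seq_along(transition), function(t) {
      validate_transition(transition[[t]], states, cycle = t)
    })
    time_varying <- TRUE
  } else {
    stop("transition must be a matrix or a list of matrices", call. = FALSE)
  }
  if (length(initial) != n || abs(sum(initial) - 1) > ROW_SUM_TOL ||
      any(initial < 0)) {
    stop("initial distribution must be a non-negative vector summing to 1",
         call. = FALSE)
  }
  if (is.null(costs)) costs <- numeric(n)
  if (is.null(utilities)) utilities <- numeric(n)
  if (length(costs) != n || any(costs < 0)) {
    stop("costs must be non-negative, one per state", call. = FALSE)
  }
  if (length(utilities) != n || any(utilities < 0) || any(utilities > 1)) {
    stop("utilities must lie in [0, 1], one per state", call. = FALSE)
  }
  if (discount_rate < 0 || discount_rate_qaly < 0) {
    stop("discount rates must be >= 0", call. = FALSE)
  }
  if (!is.null(one_time_costs)) {
    if (!is.matrix(one_time_costs) || any(dim(one_time_costs) != n) ||
        any(one_time_costs < 0)) {
      stop("one_time_costs must be a non-negative n x n matrix", call. = FALSE)
    }
    dimnames(one_time_costs) <- list(states$names, states$names)
  }
  structure(list(states = states, transition = transition,
                 time_varying = time_varying,
                 initial = as.numeric(initial) / sum(initial),
                 n_cycles = n_cycles,
                 costs = stats::setNames(as.numeric(costs), states$names),
                 utilities = stats::setNames(as.numeric(utilities), states$names),
                 discount_rate = discount_rate,
                 discount_rate_qaly = discount_rate_qaly,
                 one_time_costs = one_time_costs,
                 cycle_length = cycle_length),
            class = "markov_model")
}

# Transition matrix in force during cycle t (1-based).
transition_at <- function(model, t) {
  if (model$time_varying) model$transition[[t]] else model$transition
}

#' Run the cohort trace of a Markov model
#'
#' Propagates the initial distribution through the cycle-indexed transition
#' matrices: row `t + 1` of the trace is row `t` times the cycle-`t` matrix.
#'
#' @param model A [markov_model()].
#' @return A `cohort_trace`: a `(n_cycles + 1) x n_states` matrix whose row
#'   `t` is the state distribution at the start of cycle `t` (row 1 is the
#'   initial distribution).
#' @export
run_trace <- function(model) {
  stopifnot(inherits(model, "markov_model"))
  n <- length(model$states$names)
  occ <- matrix(0, nrow = model$n_cycles + 1L, ncol = n,
                dimnames = list(cycle = 0:model$n_cycles, model$states$names))
  occ[1L, ] <- model$initial
  for (t in seq_len(model$n_cycles)) {
    occ[t + 1L, ] <- occ[t, ] %*% transition_at(model, t)
  }
  structure(occ, class = c("cohort_trace", "matrix"))
}

#' Discounted total cost and QALYs of a cohort trace
#'
#' Cycle-`t` rewards (t = 0, ..., n_cycles - 1) are discounted by
#' `(1 + r)^-t`. By default rewards are credited to the state occupied at
#' the start of each cycle; with `half_cycle = TRUE` the mean of the
#' start-of-cycle and end-of-cycle occupancies is used instead. One-time
#' transition costs are accrued in the cycle in which the transition occurs.
#'
#' @param trace A `cohort_trace` from [run_trace()].
#' @param costs Per-state annual cost vector.
#' @param utilities Per-state annual utility vector.
#' @param discount_rate Annual discount rate for costs.
#' @param discount_rate_qaly Annual discount rate for QALYs (defaults to
#'   `discount_rate`).
#' @param one_time_costs Optional `n x n` per-transition cost matrix; requires
#'   `model` to evaluate expected transition counts.
#' @param model The model that produced the trace; required when
#'   `one_time_costs` is given.
#' @param half_cycle Apply the half-cycle correction (default `FALSE`).
#' @return A list with elements `cost` (USD) and `qaly`.
#' @export
discounted_totals <- function(trace, costs, utilities, discount_rate,
                              discount_rate_qaly = discount_rate,
                              one_time_costs = NULL, model = NULL,
                              half_cycle = FALSE) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (any(costs < 0) || any(utilities < 0)) {
    stop("costs and utilities must be non-negative", call. = FALSE)
  }
  if (discount_rate < 0 || discount_rate_qaly < 0) {
    stop("discount rates must be >= 0", call. = FALSE)
  }
  n_cycles <- nrow(trace) - 1L
  t_idx <- 0:(n_cycles - 1L)
  dfc <- (1 + discount_rate)^(-t_idx)
  dfq <- (1 + discount_rate_qaly)^(-t_idx)
  occ <- if (half_cycle) {
    (trace[seq_len(n_cycles), , drop = FALSE] +
       trace[seq_len(n_cycles) + 1L, , drop = FALSE]) / 2
  } else {
    trace[seq_len(n_cycles), , drop = FALSE]
  }
  cost <- sum(dfc * as.numeric(occ %*% costs))
  qaly <- sum(dfq * as.numeric(occ %*% utilities))
  if (!is.null(one_time_costs)) {
    if (is.null(model)) {
      stop("one_time_costs requires the model to evaluate transition flows",
           call. = FALSE)
    }
    for (t in seq_len(n_cycles)) {
      P <- transition_at(model, t)
      flows <- trace[t, ] * P          # expected transition counts in cycle t
      cost <- cost + dfc[t] * sum(flows * one_time_costs)
    }
  }
  list(cost = cost, qaly = qaly)
}

#' Run a model and return its discounted totals
#'
#' Convenience wrapper: [run_trace()] followed by [discounted_totals()] using
#' the rewards and rates stored in the model.
#'
#' @inheritParams run_trace
#' @param half_cycle Apply the half-cycle correction.
#' @return A list with `cost`, `qaly` and the `trace`.
#' @export
evaluate_model <- function(model, half_cycle = FALSE) {
  trace <- run_trace(model)
  tot <- discounted_totals(trace, model$costs, model$utilities,
                           model$discount_rate, model$discount_rate_qaly,
                           one_time_costs = model$one_time_costs,
                           model = model, half_cycle = half_cycle)
  list(cost = tot$cost, qaly = tot$qaly, trace = trace)
}
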