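# Independent oracles and fixture builders shared across test files.

# Random valid Markov cohort model: dense random rows (Dirichlet via
# normalized gammas), one absorbing Dead state reachable from every state.
random_markov_model <- function(seed, n_states = 5, n_cycles = 10,
                                discount_rate = 0.03) {
  set.seed(seed)
  states <- c(paste0("S", seq_len(n_states - 1)), "Dead")
  P <- matrix(rgamma(n_states^2, shape = 1), n_states, n_states)
  P[, n_states] <- P[, n_states] + 0.2   # keep death reachable everywhere
  P <- P / rowSums(P)
  P[n_states, ] <- c(rep(0, n_states - 1), 1)
  init <- rgamma(n_states, 1); init[n_states] <- 0; init <- init / sum(init)
  markov_model(state_space(states, absorbing = "Dead"), P, init, n_cycles,
               costs = runif(n_states, 0, 5000) * c(rep(1, n_states - 1), 0),
               utilities = c(runif(n_states - 1, 0.3, 1), 0),
               discount_rate = discount_rate)
}

# Exhaustive change-making: smallest unit count achieving `target` exactly,
# enumerating every count vector with at most `max_units` units.
brute_force_min_units <- function(target, strengths, max_units = 90) {
  strengths <- sort(unique(strengths), decreasing = TRUE)
  best <- Inf
  recurse <- function(i, remaining, used) {
    if (used >= best) return()
    if (abs(remaining) < 1e-9) { best <<- min(best, used); return() }
    if (i > length(strengths) || remaining < -1e-9) return()
    max_i <- floor(remaining / strengths[i] + 1e-9)
    for (cnt in max_i:0) {
      if (used + cnt < best) {
        recurse(i + 1, remaining - cnt * strengths[i], used + cnt)
      }
    }
  }
  recurse(1, target, 0)
  if (is.finite(best)) best else NA_integer_
}

# Frontier oracle by willingness-to-pay sweep: a strategy belongs to the
# cost-effectiveness frontier iff it minimizes (cost - lambda * effect) for
# some lambda >= 0. Candidate lambdas: 0, all non-negative pairwise slopes,
# and midpoints between consecutive distinct slopes.
frontier_oracle <- function(df) {
  n <- nrow(df)
  slopes <- c(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    de <- df$effect[j] - df$effect[i]
    if (de > 0) slopes <- c(slopes, (df$cost[j] - df$cost[i]) / de)
  }
  slopes <- sort(unique(pmax(0, slopes)))
  cand <- sort(unique(c(slopes, slopes + 1e-6,
                        (head(slopes, -1) + tail(slopes, -1)) / 2,
                        max(slopes) + 1)))
  on <- rep(FALSE, n)
  for (lam in cand) {
    score <- df$cost - lam * df$effect
    # every minimizer belongs to the frontier: boundary-ICER ties are kept
    # (strict-inequality extended-dominance convention); callers exclude
    # strictly dominated points beforehand
    on[score <= min(score) + 1e-9] <- TRUE
  }
  on
}

# Strict dominance by definition (used to split non-frontier strategies
# into dominated vs extended-dominated in oracle comparisons).
strictly_dominated <- function(df) {
  n <- nrow(df)
  vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      j != i && df$cost[j] <= df$cost[i] && df$effect[j] >= df$effect[i] &&
        (df$cost[j] < df$cost[i] || df$effect[j] > df$effect[i])
    }, logical(1)))
  }, logical(1))
}

# Small, fast shared parameter set for arm-model tests.
test_shared <- function(...) {
  args <- list(start_age = 60, p_mi_fatal = 0.2, p_death_post_mi = 0.05,
               mi_event_cost = 30000, post_mi_annual_cost = 3000,
               post_mi_treatment_cost = 50,
               utilities = list(on_tx = 0.9, off_tx = 0.9, post_mi = 0.7),
               n_cycles = 40L)
  override <- list(...)
  args[names(override)] <- override
  do.call(shared_parameters, args)
}

# n = 10 contents with an exact mean and sample sd: a symmetric pair of
# deviations leaves the mean unchanged and sets the sd precisely
contents_with <- function(mean, sd) {
  base <- rep(mean, 10)
  if (sd > 0) {
    delta <- sd * sqrt(9 / 2)
    base[1] <- mean + delta
    base[2] <- mean - delta
  }
  base
}

test_arm <- function(name = "FDC", ...) {
  args <- list(name = name, p_side_effect = 0.1,
               p_discontinue_given_side_effect = 0.5,
               p_nonadherence = 0.08,
               p_mi_on_treatment_no_se = 0.011,
               p_mi_on_treatment_after_se = 0.014,
               p_mi_off_treatment = 0.03,
               monthly_drug_cost = 40, side_effect_cost = 300,
               side_effect_disutility = 0.05)
  override <- list(...)
  args[names(override)] <- override
  do.call(arm_parameters, args)
}
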