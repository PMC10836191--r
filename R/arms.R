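# Three-arm cardiovascular polypill model: standard care, fixed-dose
# combination (FDC) polypill, variable-dose (VD) modular polypill.
#
# Health states: OnTx_NoSE (on treatment, no side effects), OnTx_PostSE
# (continued treatment after side effects), OffTx (discontinued, via side
# effects or non/low adherence), PostMI (survived a myocardial infarction;
# fully adherent thereafter), Dead. Structural assumptions: discontinuation
# happens only through side effects or non-adherence; the myocardial
# infarction (MI) probability off treatment does not depend on the reason
# for discontinuation; post-MI patients never discontinue; side-effect
# status affects MI risk only through the arm's per-state MI parameters.
# Patients who continue after a side effect remain exposed to recurrent
# side-effect events (and the discontinuation they may trigger), which makes
# the two on-treatment states exactly lumpable when side effects carry no
# cost, no disutility and no MI-risk change.

ARM_NAMES <- c("standard_care", "FDC", "VD")

#' Treatment-arm parameters
#'
#' All probabilities are annual. Costs are in 2019 USD.
#'
#' @param name Arm label.
#' @param p_side_effect Annual probability of a side-effect event while on
#'   treatment without prior side effects.
#' @param p_discontinue_given_side_effect Probability that a side-effect
#'   event leads to discontinuation (otherwise the patient continues on
#'   treatment in the post-side-effect state).
#' @param p_nonadherence Annual probability of discontinuation through
#'   non/low adherence.
#' @param p_mi_on_treatment_no_se Annual MI probability on treatment, no
#'   prior side effects.
#' @param p_mi_on_treatment_after_se Annual MI probability on treatment
#'   after side effects.
#' @param p_mi_off_treatment Annual MI probability off treatment (same for
#'   side-effect discontinuers and non-adherers).
#' @param monthly_drug_cost Drug cost, USD/month (annualized internally).
#' @param side_effect_cost Annual cost of managing side effects while in the
#'   post-side-effect state (USD/year).
#' @param side_effect_disutility Utility decrement applied in the
#'   post-side-effect state (QALY weight, in `[0, 1]`).
#' @return An object of class `arm_parameters`.
#' @export
arm_parameters <- function(name,
                           p_side_effect,
                           p_discontinue_given_side_effect,
                           p_nonadherence,
                           p_mi_on_treatment_no_se,
                           p_mi_on_treatment_after_se,
                           p_mi_off_treatment,
                           monthly_drug_cost,
                           side_effect_cost = 0,
                           side_effect_disutility = 0) {
  p <- c(p_side_effect, p_discontinue_given_side_effect, p_nonadherence,
         p_mi_on_treatment_no_se, p_mi_on_treatment_after_se,
         p_mi_off_treatment)
  if (any(p < 0) || any(p > 1)) {
    stop("all arm probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (monthly_drug_cost < 0 || side_effect_cost < 0) {
    stop("arm costs must be >= 0", call. = FALSE)
  }
  if (side_effect_disutility < 0 || side_effect_disutility > 1) {
    stop("side_effect_disutility must lie in [0, 1]", call. = FALSE)
  }
  structure(list(name = name,
                 p_side_effect = p_side_effect,
                 p_discontinue_given_side_effect = p_discontinue_given_side_effect,
                 p_nonadherence = p_nonadherence,
                 p_mi_on_treatment_no_se = p_mi_on_treatment_no_se,
                 p_mi_on_treatment_after_se = p_mi_on_treatment_after_se,
                 p_mi_off_treatment = p_mi_off_treatment,
                 monthly_drug_cost = monthly_drug_cost,
                 side_effect_cost = side_effect_cost,
                 side_effect_disutility = side_effect_disutility),
            class = "arm_parameters")
}

#' Gompertz-like background mortality
#'
#' Parametric stand-in for a life-table: annual death probability
#' `q(a) = min(1, A * exp(B * a))` at age `a`. Defaults give `q(60) ~ 0.008`
#' and `q(90) ~ 0.1`, a plausible all-cause schedule for a general adult
#' population.
#'
#' @param A Level parameter (default `5e-5`).
#' @param B Log-slope per year of age (default `0.085`).
#' @return A function mapping age (years) to annual death probability.
#' @export
gompertz_mortality <- function(A = 5e-5, B = 0.085) {
  force(A); force(B)
  function(age) pmin(1, A * exp(B * age))
}

#' Shared (arm-independent) model parameters
#'
#' @param start_age Cohort age at model start (years; base case 60).
#' @param p_mi_fatal Probability that an MI is immediately fatal.
#' @param p_death_post_mi Annual excess death probability after a survived
#'   MI (combined with background mortality as competing risks).
#' @param background_mortality Either a function of age returning an annual
#'   death probability, or a data frame with columns `age` and `q` covering
#'   `[start_age, start_age + n_cycles]`.
#' @param mi_event_cost One-time cost of a non-fatal MI event (USD).
#' @param post_mi_annual_cost Annual care cost in the post-MI state
#'   (USD/year).
#' @param post_mi_treatment_cost Post-MI medication cost (USD/month).
#' @param utilities Named list with QALY weights `on_tx`, `off_tx`,
#'   `post_mi`, each in `[0, 1]` (Dead is 0).
#' @param discount_rate Annual discount rate (default 0.03), applied to both
#'   costs and QALYs.
#' @param wtp Willingness-to-pay threshold (default 100000 USD/QALY).
#' @param n_cycles Number of annual cycles; default runs to age 100
#'   ("lifetime" horizon).
#' @return An object of class `shared_parameters`.
#' @export
shared_parameters <- function(start_age = 60,
                              p_mi_fatal,
                              p_death_post_mi,
                              background_mortality = gompertz_mortality(),
                              mi_event_cost,
                              post_mi_annual_cost,
                              post_mi_treatment_cost = 0,
                              utilities = list(on_tx = 0.9, off_tx = 0.9,
                                               post_mi = 0.7),
                              discount_rate = 0.03,
                              wtp = 1e5,
                              n_cycles = NULL) {
  if (is.null(n_cycles)) n_cycles <- max(1L, as.integer(100 - start_age))
  if (p_mi_fatal < 0 || p_mi_fatal > 1 || p_death_post_mi < 0 ||
      p_death_post_mi > 1) {
    stop("shared probabilities must lie in [0, 1]", call. = FALSE)
  }
  u <- unlist(utilities[c("on_tx", "off_tx", "post_mi")])
  if (length(u) != 3L || any(u < 0) || any(u > 1)) {
    stop("utilities must provide on_tx, off_tx, post_mi in [0, 1]",
         call. = FALSE)
  }
  if (mi_event_cost < 0 || post_mi_annual_cost < 0 ||
      post_mi_treatment_cost < 0) {
    stop("costs must be >= 0", call. = FALSE)
  }
  if (is.data.frame(background_mortality)) {
    tab <- background_mortality
    stopifnot(all(c("age", "q") %in% names(tab)))
    need <- start_age:(start_age + n_cycles)
    if (!all(need %in% tab$age)) {
      stop("background mortality table must cover ages ",
           min(need), " to ", max(need), call. = FALSE)
    }
    background_mortality <- function(age) tab$q[match(age, tab$age)]
  }
  structure(list(start_age = start_age, p_mi_fatal = p_mi_fatal,
                 p_death_post_mi = p_death_post_mi,
                 background_mortality = background_mortality,
                 mi_event_cost = mi_event_cost,
                 post_mi_annual_cost = post_mi_annual_cost,
                 post_mi_treatment_cost = post_mi_treatment_cost,
                 utilities = utilities, discount_rate = discount_rate,
                 wtp = wtp, n_cycles = as.integer(n_cycles)),
            class = "shared_parameters")
}

#' Combine independent annual risks into per-row transition probabilities
#'
#' Converts each annual probability to a rate `r_i = -log(1 - p_i)`,
#' computes the total probability of leaving the state,
#' `1 - exp(-sum(r_i))`, and allocates it across causes proportionally to
#' their rates. A probability of exactly 1 makes that cause certain: all
#' exit mass goes to the certain cause(s) (split equally if several) and a
#' warning is emitted when other causes carry positive probability.
#'
#' @param p Numeric vector of independent annual probabilities in `[0, 1]`.
#' @return A list with `exit` (per-cause exit probabilities, same order as
#'   `p`) and `stay` (probability of remaining); `sum(exit) + stay == 1`.
#' @export
combine_competing_risks <- function(p) {
  if (any(p < 0) || any(p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  n <- length(p)
  if (any(p == 1)) {
    if (any(p > 0 & p < 1)) {
      warning("a certain event absorbs all exit probability; ",
              "other competing risks are ignored")
    }
    exit <- numeric(n)
    certain <- which(p == 1)
    exit[certain] <- 1 / length(certain)
    return(list(exit = exit, stay = 0))
  }
  r <- -log1p(-p)
  total <- sum(r)
  if (total == 0) return(list(exit = numeric(n), stay = 1))
  p_exit <- -expm1(-total)
  exit <- p_exit * r / total
  list(exit = exit, stay = 1 - p_exit)
}

# Assemble one cycle's transition row set for the arm model.
# q_bg is the background death probability at the cohort's current age.
arm_transition_matrix <- function(arm, shared, q_bg, states,
                                  split_offtx = FALSE) {
  n <- length(states)
  P <- matrix(0, n, n, dimnames = list(states, states))
  to <- function(s) match(s, states)
  off_se  <- if (split_offtx) "OffTx_SE" else "OffTx"
  off_na  <- if (split_offtx) "OffTx_NonAdh" else "OffTx"

  place_mi <- function(row, from, mass) {
    row[to("Dead")]   <- row[to("Dead")] + mass * shared$p_mi_fatal
    row[to("PostMI")] <- row[to("PostMI")] + mass * (1 - shared$p_mi_fatal)
    row
  }

  # OnTx_NoSE: side effect / non-adherence / MI / background death
  cr <- combine_competing_risks(c(arm$p_side_effect, arm$p_nonadherence,
                                  arm$p_mi_on_treatment_no_se, q_bg))
  row <- numeric(n)
  pd <- arm$p_discontinue_given_side_effect
  row[to(off_se)] <- row[to(off_se)] + cr$exit[1] * pd
  row[to("OnTx_PostSE")] <- row[to("OnTx_PostSE")] + cr$exit[1] * (1 - pd)
  row[to(off_na)] <- row[to(off_na)] + cr$exit[2]
  row <- place_mi(row, "OnTx_NoSE", cr$exit[3])
  row[to("Dead")] <- row[to("Dead")] + cr$exit[4]
  row[to("OnTx_NoSE")] <- row[to("OnTx_NoSE")] + cr$stay
  P["OnTx_NoSE", ] <- row

  # OnTx_PostSE: recurrent side effects (may still trigger discontinuation)
  # / non-adherence / MI (post-SE rate) / background death
  cr <- combine_competing_risks(c(arm$p_side_effect, arm$p_nonadherence,
                                  arm$p_mi_on_treatment_after_se, q_bg))
  row <- numeric(n)
  row[to(off_se)] <- row[to(off_se)] + cr$exit[1] * pd
  row[to("OnTx_PostSE")] <- row[to("OnTx_PostSE")] + cr$exit[1] * (1 - pd)
  row[to(off_na)] <- row[to(off_na)] + cr$exit[2]
  row <- place_mi(row, "OnTx_PostSE", cr$exit[3])
  row[to("Dead")] <- row[to("Dead")] + cr$exit[4]
  row[to("OnTx_PostSE")] <- row[to("OnTx_PostSE")] + cr$stay
  P["OnTx_PostSE", ] <- row

  # OffTx (single MI probability regardless of discontinuation reason)
  off_states <- if (split_offtx) c("OffTx_SE", "OffTx_NonAdh") else "OffTx"
  for (s in off_states) {
    cr <- combine_competing_risks(c(arm$p_mi_off_treatment, q_bg))
    row <- numeric(n)
    row <- place_mi(row, s, cr$exit[1])
    row[to("Dead")] <- row[to("Dead")] + cr$exit[2]
    row[to(s)] <- row[to(s)] + cr$stay
    P[s, ] <- row
  }

  # PostMI: excess post-MI mortality competing with background death
  cr <- combine_competing_risks(c(shared$p_death_post_mi, q_bg))
  P["PostMI", to("Dead")] <- sum(cr$exit)
  P["PostMI", to("PostMI")] <- cr$stay

  P["Dead", to("Dead")] <- 1
  P
}

#' Build the Markov model for one treatment arm
#'
#' Produces a time-varying [markov_model()] over the five polypill health
#' states (six with `split_offtx = TRUE`, which tracks side-effect and
#' non-adherence discontinuers separately; with a single off-treatment MI
#' probability the two representations are equivalent). Competing annual
#' risks within a state are combined on the rate scale
#' (see [combine_competing_risks()]), MI events are split into fatal and
#' non-fatal by `p_mi_fatal`, and the non-fatal MI transition carries the
#' one-time `mi_event_cost`. Background mortality is age-indexed from
#' `shared$start_age`.
#'
#' @param arm An [arm_parameters()] object.
#' @param shared A [shared_parameters()] object.
#' @param n_cycles Horizon override; defaults to `shared$n_cycles`.
#' @param split_offtx Track the two discontinuation reasons as separate
#'   states (used for lumping-equivalence checks).
#' @return A [markov_model()] starting with the whole cohort on treatment
#'   without side effects.
#' @export
build_arm_model <- function(arm, shared, n_cycles = shared$n_cycles,
                            split_offtx = FALSE) {
  stopifnot(inherits(arm, "arm_parameters"),
            inherits(shared, "shared_parameters"))
  states <- if (split_offtx) {
    c("OnTx_NoSE", "OnTx_PostSE", "OffTx_SE", "OffTx_NonAdh", "PostMI", "Dead")
  } else {
    c("OnTx_NoSE", "OnTx_PostSE", "OffTx", "PostMI", "Dead")
  }
  ss <- state_space(states, absorbing = "Dead")
  n <- length(states)

  mats <- lapply(seq_len(n_cycles), function(t) {
    age <- shared$start_age + t - 1L
    q <- shared$background_mortality(age)
    if (is.na(q) || q < 0 || q > 1) {
      stop(sprintf("invalid background mortality at age %d", age),
           call. = FALSE)
    }
    arm_transition_matrix(arm, shared, q, states, split_offtx)
  })

  u <- shared$utilities
  utilities <- stats::setNames(numeric(n), states)
  utilities["OnTx_NoSE"] <- u$on_tx
  utilities["OnTx_PostSE"] <- max(0, u$on_tx - arm$side_effect_disutility)
  utilities[grep("^OffTx", states)] <- u$off_tx
  utilities["PostMI"] <- u$post_mi

  costs <- stats::setNames(numeric(n), states)
  costs["OnTx_NoSE"] <- 12 * arm$monthly_drug_cost
  costs["OnTx_PostSE"] <- 12 * arm$monthly_drug_cost + arm$side_effect_cost
  costs["PostMI"] <- shared$post_mi_annual_cost +
    12 * shared$post_mi_treatment_cost

  otc <- matrix(0, n, n, dimnames = list(states, states))
  otc[setdiff(states, c("PostMI", "Dead")), "PostMI"] <- shared$mi_event_cost

  init <- numeric(n); init[1] <- 1
  markov_model(ss, mats, init, n_cycles,
               costs = costs, utilities = utilities,
               discount_rate = shared$discount_rate,
               one_time_costs = otc)
}

#' Run the three-arm base case
#'
#' Builds and evaluates the standard-care, FDC and VD arms over the lifetime
#' horizon, then ranks the strategies (dominance, extended dominance,
#' frontier ICERs).
#'
#' @param arms Named list of three [arm_parameters()] with names
#'   `standard_care`, `FDC`, `VD`.
#' @param shared A [shared_parameters()] object.
#' @param n_cycles Horizon override.
#' @param half_cycle Apply the half-cycle correction.
#' @return A list with `result` (the [rank_strategies()] `cea_result`),
#'   `outcomes` (per-arm discounted cost and QALY data frame), and `choice`
#'   (the cost-effective strategy at `shared$wtp`).
#' @export
run_three_arm_base_case <- function(arms, shared,
                                    n_cycles = shared$n_cycles,
                                    half_cycle = FALSE) {
  if (!setequal(names(arms), ARM_NAMES) || length(arms) != 3L) {
    stop("arms must be a named list: standard_care, FDC, VD", call. = FALSE)
  }
  outcomes <- lapply(ARM_NAMES, function(a) {
    ev <- evaluate_model(build_arm_model(arms[[a]], shared, n_cycles),
                         half_cycle = half_cycle)
    strategy_outcome(a, ev$cost, ev$qaly)
  })
  res <- rank_strategies(outcomes)
  list(result = res,
       outcomes = as_outcome_df(outcomes),
       choice = cost_effective_choice(res, shared$wtp))
}
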