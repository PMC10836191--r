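# Seeded synthetic-data generators: cost-effectiveness parameter sets shaped
# like the model's input tables, tablet-batch measurements, and a
# micro-simulation oracle for the cohort engine. All draws use R's default
# Mersenne-Twister stream; each output block consumes its own sub-seed so
# adding a field to one block never perturbs the others.

sub_seed <- function(seed, block) {
  (as.integer(seed) * 1009L + block * 7919L) %% 2147483587L
}

#' Default parameter ranges for the CEA generator
#'
#' Uniform draw bounds per parameter. The ranges are deliberately wide:
#' the VD monthly cost range spans $129, the FDC side-effect range spans
#' 0.68, and the on-treatment MI ranges span 0.011 and 0.014 per year, so
#' threshold-search machinery is exercised near the decision boundaries.
#' These are stand-ins for literature-derived inputs, not estimates.
#'
#' @return Nested list of `c(low, high)` bounds.
#' @export
default_cea_ranges <- function() {
  list(
    shared = list(
      u_healthy = c(0.85, 0.95),
      u_post_mi = c(0.60, 0.80),
      p_mi_fatal = c(0.10, 0.30),
      p_death_post_mi = c(0.03, 0.08),
      mi_event_cost = c(20000, 50000),
      post_mi_annual_cost = c(2000, 5000),
      post_mi_treatment_cost = c(20, 100)
    ),
    standard_care = list(
      p_side_effect = c(0.10, 0.50),
      p_discontinue_given_side_effect = c(0.30, 0.80),
      p_nonadherence = c(0.15, 0.40),
      p_mi_on_treatment_no_se = c(0.005, 0.020),
      p_mi_on_treatment_after_se = c(0.007, 0.025),
      p_mi_off_treatment = c(0.025, 0.050),
      monthly_drug_cost = c(5, 19),
      side_effect_cost = c(100, 600),
      side_effect_disutility = c(0.02, 0.10)
    ),
    FDC = list(
      p_side_effect = c(0.10, 0.80),
      p_discontinue_given_side_effect = c(0.30, 0.80),
      p_nonadherence = c(0.03, 0.14),
      p_mi_on_treatment_no_se = c(0.005, 0.020),
      p_mi_on_treatment_after_se = c(0.007, 0.025),
      p_mi_off_treatment = c(0.025, 0.050),
      monthly_drug_cost = c(20, 60),
      side_effect_cost = c(100, 600),
      side_effect_disutility = c(0.02, 0.10)
    ),
    VD = list(
      p_side_effect = c(0.02, 0.60),
      p_discontinue_given_side_effect = c(0.30, 0.80),
      p_nonadherence = c(0.03, 0.12),
      p_mi_on_treatment_no_se = c(0.005, 0.020),
      p_mi_on_treatment_after_se = c(0.007, 0.025),
      p_mi_off_treatment = c(0.025, 0.050),
      monthly_drug_cost = c(40, 160),
      side_effect_cost = c(100, 600),
      side_effect_disutility = c(0.02, 0.10)
    )
  )
}

#' Default tablet-batch generator settings
#'
#' Nominal values emulate an immediate-release 137 mg tablet batch that
#' comfortably meets every compendial limit: 2% weight and content CVs, a
#' two-minute mean disintegration, ~0.4% friability loss and a Weibull
#' dissolution profile saturating near 95%.
#'
#' @return List of batch generator settings.
#' @export
default_batch_spec <- function() {
  list(label_claim = 5, target_weight = 137, weight_cv = 2,
       content_mean = 100, content_cv = 2,
       disintegration_mean = 120, disintegration_cv = 20,
       dissolution_fmax = 95, dissolution_scale = 10, dissolution_shape = 1.2,
       dissolution_noise_sd = 1,
       friability_initial = 6.5, friability_loss_mean = 0.4,
       friability_loss_sd = 0.15,
       hardness_mean = 4, hardness_cv = 10)
}

#' Generator specification
#'
#' @param seed Base RNG seed (integer).
#' @param oracle_n Cohort size for the micro-simulation oracle.
#' @param ranges CEA parameter draw bounds; see [default_cea_ranges()].
#' @param batch Tablet-batch settings; see [default_batch_spec()].
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(seed = 1L, oracle_n = 1e5,
                           ranges = default_cea_ranges(),
                           batch = default_batch_spec()) {
  check_range <- function(r, name, lo = -Inf, hi = Inf) {
    if (length(r) != 2L || r[1] > r[2] || r[1] < lo || r[2] > hi) {
      stop("invalid range for ", name, call. = FALSE)
    }
  }
  for (blk in names(ranges)) {
    for (p in names(ranges[[blk]])) {
      bounds <- if (grepl("^(p_|u_)", p)) c(0, 1) else c(0, Inf)
      check_range(ranges[[blk]][[p]], paste(blk, p, sep = "$"),
                  bounds[1], bounds[2])
    }
  }
  cvs <- unlist(batch[grep("_cv$", names(batch))])
  if (any(cvs < 0)) stop("batch CVs must be >= 0", call. = FALSE)
  structure(list(seed = as.integer(seed), oracle_n = oracle_n,
                 ranges = ranges, batch = batch),
            class = "generator_spec")
}

runif_range <- function(r) stats::runif(1, r[1], r[2])

#' Generate a synthetic CEA parameter set
#'
#' Draws every probability, utility and cost uniformly within its range
#' (independent sub-stream from `spec$seed`), then enforces the arm-ordering
#' constraints expected of the three strategies: standard care has the
#' lowest drug cost and the highest non-adherence, and the personalized VD
#' polypill's side-effect probability never exceeds the FDC's. The output
#' always passes [build_arm_model()] validation.
#'
#' @param spec A [generator_spec()].
#' @return List with `shared` ([shared_parameters()]) and `arms` (named list
#'   of three [arm_parameters()]).
#' @export
gen_cea_params <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sub_seed(spec$seed, 1L))

  rg <- spec$ranges
  sh <- lapply(rg$shared, runif_range)
  draw_arm <- function(name) {
    v <- lapply(rg[[name]], runif_range)
    c(list(name = name), v)
  }
  arms_raw <- lapply(stats::setNames(ARM_NAMES, ARM_NAMES), draw_arm)

  # ordering constraints across arms
  costs <- vapply(arms_raw, `[[`, numeric(1), "monthly_drug_cost")
  arms_raw$standard_care$monthly_drug_cost <- min(costs)
  nonadh <- vapply(arms_raw, `[[`, numeric(1), "p_nonadherence")
  arms_raw$standard_care$p_nonadherence <- max(nonadh)
  arms_raw$VD$p_side_effect <- min(arms_raw$VD$p_side_effect,
                                   arms_raw$FDC$p_side_effect)

  shared <- shared_parameters(
    start_age = 60,
    p_mi_fatal = sh$p_mi_fatal,
    p_death_post_mi = sh$p_death_post_mi,
    mi_event_cost = sh$mi_event_cost,
    post_mi_annual_cost = sh$post_mi_annual_cost,
    post_mi_treatment_cost = sh$post_mi_treatment_cost,
    utilities = list(on_tx = sh$u_healthy, off_tx = sh$u_healthy,
                     post_mi = sh$u_post_mi))
  arms <- lapply(arms_raw, function(a) do.call(arm_parameters, a))
  list(shared = shared, arms = arms)
}

#' Micro-simulation oracle for a Markov cohort model
#'
#' Simulates `n` independent individual trajectories by per-cycle
#' categorical sampling from the model's transition rows, and accumulates
#' per-individual discounted costs and QALYs under the same reward
#' conventions as [discounted_totals()] (rewards credited to the
#' start-of-cycle state; one-time transition costs in the cycle they occur).
#' Used as an independent check of [run_trace()] / [discounted_totals()]:
#' the empirical occupancy is a binomial proportion, so it should sit within
#' a few `sqrt(p (1 - p) / n)` of the cohort trace.
#'
#' @param model A [markov_model()].
#' @param n Number of individuals (`>= 1`).
#' @param seed RNG seed.
#' @return List: `occupancy` (empirical trace, `(n_cycles + 1) x n_states`),
#'   `cost`/`qaly` (means), `cost_se`/`qaly_se` (standard errors), `n`.
#' @export
simulate_individuals <- function(model, n, seed = 1L) {
  stopifnot(inherits(model, "markov_model"), n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  k <- length(model$states$names)
  cur <- sample.int(k, n, replace = TRUE, prob = model$initial)
  occ <- matrix(0, model$n_cycles + 1L, k,
                dimnames = list(cycle = 0:model$n_cycles, model$states$names))
  occ[1L, ] <- tabulate(cur, k) / n
  cost_i <- numeric(n)
  qaly_i <- numeric(n)
  otc <- model$one_time_costs
  for (t in seq_len(model$n_cycles)) {
    dfc <- (1 + model$discount_rate)^(-(t - 1L))
    dfq <- (1 + model$discount_rate_qaly)^(-(t - 1L))
    cost_i <- cost_i + dfc * model$costs[cur]
    qaly_i <- qaly_i + dfq * model$utilities[cur]
    P <- transition_at(model, t)
    cum <- t(apply(P, 1L, cumsum))
    u <- stats::runif(n)
    nxt <- integer(n)
    for (s in unique(cur)) {
      idx <- cur == s
      nxt[idx] <- findInterval(u[idx], cum[s, ]) + 1L
    }
    nxt[nxt > k] <- k  # guard against u landing on the closed upper bound
    if (!is.null(otc)) cost_i <- cost_i + dfc * otc[cbind(cur, nxt)]
    cur <- nxt
    occ[t + 1L, ] <- tabulate(cur, k) / n
  }
  list(occupancy = occ,
       cost = mean(cost_i), cost_se = stats::sd(cost_i) / sqrt(n),
       qaly = mean(qaly_i), qaly_se = stats::sd(qaly_i) / sqrt(n),
       n = n)
}

rnorm_pos <- function(n, mean, cv_pct) {
  if (cv_pct == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, mean * cv_pct / 100)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), mean, mean * cv_pct / 100)
  }
  x
}

#' Generate a synthetic tablet batch
#'
#' Emulates one formulation's compendial measurements: 20 unit weights and
#' 10 assayed contents (normal around their targets with the specified CVs),
#' 6 disintegration times, a friability run, 10 hardness readings, and a
#' 4-vessel dissolution profile following a Weibull release curve
#' `F(t) = F_max (1 - exp(-(t / scale)^shape))` sampled at 5, 10, 15, 20,
#' 30, 45 and 60 min with additive observation noise. Fully deterministic
#' under a fixed spec.
#'
#' @param spec A [generator_spec()]; the `batch` element controls the draw.
#' @param drug Optional drug label (used to look up dissolution criteria).
#' @return A `tablet_batch` list.
#' @export
gen_tablet_batch <- function(spec, drug = NULL) {
  stopifnot(inherits(spec, "generator_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sub_seed(spec$seed, 2L))
  b <- spec$batch

  weights <- rnorm_pos(20L, b$target_weight, b$weight_cv)
  contents <- if (b$content_cv == 0) rep(b$content_mean, 10L) else
    stats::rnorm(10L, b$content_mean, b$content_mean * b$content_cv / 100)
  disint <- rnorm_pos(6L, b$disintegration_mean, b$disintegration_cv)
  loss <- if (b$friability_loss_sd == 0) b$friability_loss_mean else
    abs(stats::rnorm(1L, b$friability_loss_mean, b$friability_loss_sd))
  hardness <- rnorm_pos(10L, b$hardness_mean, b$hardness_cv)

  times <- c(5, 10, 15, 20, 30, 45, 60)
  curve <- b$dissolution_fmax *
    (1 - exp(-(times / b$dissolution_scale)^b$dissolution_shape))
  dissolution <- lapply(seq_len(4L), function(v) {
    noise <- if (b$dissolution_noise_sd == 0) 0 else
      stats::rnorm(length(times), 0, b$dissolution_noise_sd)
    data.frame(time = times,
               dissolved = pmin(110, pmax(0, curve + noise)))
  })

  structure(list(
    drug = drug,
    label_claim = b$label_claim,
    target_weight = b$target_weight,
    weights = weights,
    contents = contents,
    disintegration_times = disint,
    friability = list(initial_g = b$friability_initial,
                      final_g = b$friability_initial * (1 - loss / 100),
                      breakage = FALSE),
    hardness = hardness,
    dissolution = dissolution
  ), class = "tablet_batch")
}
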