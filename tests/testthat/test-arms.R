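# Three-arm polypill model structure and competing-risk composition.

test_that("competing risks: closed forms and edge cases", {
  # single risk passes through unchanged
  cr <- combine_competing_risks(0.3)
  expect_equal(cr$exit, 0.3, tolerance = 1e-12)
  expect_equal(cr$stay, 0.7, tolerance = 1e-12)
  # two 0.5 risks: exit 1 - exp(-ln 4) = 0.75 split equally
  cr <- combine_competing_risks(c(0.5, 0.5))
  expect_equal(cr$exit, c(0.375, 0.375), tolerance = 1e-12)
  expect_equal(cr$stay, 0.25, tolerance = 1e-12)
  # no risk: stay with certainty
  cr <- combine_competing_risks(c(0, 0, 0))
  expect_equal(cr$stay, 1)
  expect_equal(cr$exit, c(0, 0, 0))
  # a certain event absorbs everything, with a warning if others compete
  expect_warning(cr <- combine_competing_risks(c(1, 0.2)), "certain")
  expect_equal(cr$exit, c(1, 0))
  expect_equal(cr$stay, 0)
  expect_silent(combine_competing_risks(c(1, 0)))
  expect_error(combine_competing_risks(c(0.5, 1.2)), "0, 1")
  # exit probabilities always sum with stay to 1
  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(1:5, 1))
    cr <- combine_competing_risks(p)
    expect_equal(sum(cr$exit) + cr$stay, 1, tolerance = 1e-12)
  }
})

test_that("zero side-effect probability makes OnTx_PostSE unreachable", {
  m <- build_arm_model(test_arm(p_side_effect = 0), test_shared())
  tr <- run_trace(m)
  expect_true(all(tr[, "OnTx_PostSE"] == 0))
})

test_that("with all hazards off the cohort never leaves OnTx_NoSE", {
  arm <- test_arm(p_side_effect = 0, p_nonadherence = 0,
                  p_mi_on_treatment_no_se = 0, p_mi_on_treatment_after_se = 0,
                  p_mi_off_treatment = 0)
  sh <- test_shared(background_mortality = function(age) 0,
                    p_death_post_mi = 0)
  tr <- run_trace(build_arm_model(arm, sh))
  expect_true(all(tr[, "OnTx_NoSE"] == 1))
})

test_that("split off-treatment states lump exactly onto the 5-state model", {
  arm <- test_arm()
  sh <- test_shared()
  tr5 <- run_trace(build_arm_model(arm, sh))
  tr6 <- run_trace(build_arm_model(arm, sh, split_offtx = TRUE))
  expect_equal(unname(tr6[, "OffTx_SE"] + tr6[, "OffTx_NonAdh"]),
               unname(tr5[, "OffTx"]), tolerance = 1e-12)
  for (s in c("OnTx_NoSE", "OnTx_PostSE", "PostMI", "Dead")) {
    expect_equal(unname(tr6[, s]), unname(tr5[, s]), tolerance = 1e-12)
  }
  ev5 <- evaluate_model(build_arm_model(arm, sh))
  ev6 <- evaluate_model(build_arm_model(arm, sh, split_offtx = TRUE))
  expect_equal(ev5$cost, ev6$cost, tolerance = 1e-9)
  expect_equal(ev5$qaly, ev6$qaly, tolerance = 1e-9)
})

test_that("clinically neutral side effects lump the on-treatment states", {
  # equal MI risk, no SE cost/disutility: the 5-state model must match a
  # 4-state reduction where the on-treatment states are merged
  arm <- test_arm(p_mi_on_treatment_after_se = 0.011,
                  side_effect_cost = 0, side_effect_disutility = 0)
  sh <- test_shared()
  ev5 <- evaluate_model(build_arm_model(arm, sh))

  states <- c("OnTx", "OffTx", "PostMI", "Dead")
  mats <- lapply(seq_len(sh$n_cycles), function(t) {
    q <- sh$background_mortality(sh$start_age + t - 1)
    P <- matrix(0, 4, 4, dimnames = list(states, states))
    cr <- combine_competing_risks(c(arm$p_side_effect, arm$p_nonadherence,
                                    arm$p_mi_on_treatment_no_se, q))
    P["OnTx", "OffTx"] <- cr$exit[1] * arm$p_discontinue_given_side_effect +
      cr$exit[2]
    P["OnTx", "Dead"] <- cr$exit[3] * sh$p_mi_fatal + cr$exit[4]
    P["OnTx", "PostMI"] <- cr$exit[3] * (1 - sh$p_mi_fatal)
    P["OnTx", "OnTx"] <- 1 - sum(P["OnTx", ])
    cr <- combine_competing_risks(c(arm$p_mi_off_treatment, q))
    P["OffTx", "Dead"] <- cr$exit[1] * sh$p_mi_fatal + cr$exit[2]
    P["OffTx", "PostMI"] <- cr$exit[1] * (1 - sh$p_mi_fatal)
    P["OffTx", "OffTx"] <- cr$stay
    cr <- combine_competing_risks(c(sh$p_death_post_mi, q))
    P["PostMI", "Dead"] <- sum(cr$exit)
    P["PostMI", "PostMI"] <- cr$stay
    P["Dead", "Dead"] <- 1
    P
  })
  otc <- matrix(0, 4, 4, dimnames = list(states, states))
  otc[c("OnTx", "OffTx"), "PostMI"] <- sh$mi_event_cost
  m4 <- markov_model(state_space(states, "Dead"), mats, c(1, 0, 0, 0),
                     sh$n_cycles,
                     costs = c(12 * arm$monthly_drug_cost, 0,
                               sh$post_mi_annual_cost +
                                 12 * sh$post_mi_treatment_cost, 0),
                     utilities = c(0.9, 0.9, 0.7, 0),
                     discount_rate = sh$discount_rate, one_time_costs = otc)
  ev4 <- evaluate_model(m4)
  expect_equal(ev5$cost, ev4$cost, tolerance = 1e-9)
  expect_equal(ev5$qaly, ev4$qaly, tolerance = 1e-9)
})

test_that("raising any MI probability never increases QALYs (monotone sweep)", {
  sh <- test_shared()
  for (param in c("p_mi_on_treatment_no_se", "p_mi_on_treatment_after_se",
                  "p_mi_off_treatment")) {
    grid <- seq(0.001, 0.2, length.out = 10)
    qalys <- vapply(grid, function(p) {
      arm <- do.call(test_arm, stats::setNames(list(p), param))
      ev <- evaluate_model(build_arm_model(arm, sh))
      ev$qaly
    }, numeric(1))
    expect_true(all(diff(qalys) <= 1e-12), info = param)
    # cumulative MI incidence rises; entries into PostMI are proportional
    # to total MI events (constant non-fatal share), so they carry the test
    mi_inc <- vapply(grid, function(p) {
      arm <- do.call(test_arm, stats::setNames(list(p), param))
      m <- build_arm_model(arm, sh)
      tr <- run_trace(m)
      inc <- 0
      for (t in seq_len(m$n_cycles)) {
        flows <- tr[t, ] * m$transition[[t]]
        inc <- inc + sum(flows[, "PostMI"])
      }
      inc
    }, numeric(1))
    expect_true(all(diff(mi_inc) >= -1e-12), info = param)
  }
})

test_that("identical arms with zero drug cost tie exactly", {
  arm <- test_arm(monthly_drug_cost = 0)
  arms <- list(standard_care = arm_parameters("standard_care",
                                              arm$p_side_effect,
                                              arm$p_discontinue_given_side_effect,
                                              arm$p_nonadherence,
                                              arm$p_mi_on_treatment_no_se,
                                              arm$p_mi_on_treatment_after_se,
                                              arm$p_mi_off_treatment,
                                              0, arm$side_effect_cost,
                                              arm$side_effect_disutility),
               FDC = test_arm("FDC", monthly_drug_cost = 0),
               VD = test_arm("VD", monthly_drug_cost = 0))
  bc <- run_three_arm_base_case(arms, test_shared())
  expect_equal(length(unique(round(bc$outcomes$cost, 9))), 1L)
  expect_equal(length(unique(round(bc$outcomes$effect, 9))), 1L)
  expect_true(all(bc$result$status == "equivalent"))
  expect_true(all(is.na(bc$result$icer)))
})

test_that("three-arm runner validates arm names and produces a ranking", {
  p <- gen_cea_params(generator_spec(seed = 21))
  bc <- run_three_arm_base_case(p$arms, p$shared)
  expect_s3_class(bc$result, "cea_result")
  expect_setequal(bc$outcomes$name, c("standard_care", "FDC", "VD"))
  expect_true(bc$choice %in% bc$outcomes$name)
  expect_error(run_three_arm_base_case(p$arms[1:2], p$shared), "named list")
  bad <- p$arms; names(bad) <- c("a", "b", "c")
  expect_error(run_three_arm_base_case(bad, p$shared), "named list")
})

test_that("a VD arm with lower MI risk but higher cost lands on the frontier", {
  sh <- test_shared()
  arms <- list(
    standard_care = test_arm("standard_care", monthly_drug_cost = 10,
                             p_nonadherence = 0.3,
                             p_mi_on_treatment_no_se = 0.015),
    FDC = test_arm("FDC", monthly_drug_cost = 30,
                   p_mi_on_treatment_no_se = 0.012),
    VD = test_arm("VD", monthly_drug_cost = 60,
                  p_mi_on_treatment_no_se = 0.008,
                  p_side_effect = 0.05))
  bc <- run_three_arm_base_case(arms, sh)
  vd <- bc$result[bc$result$name == "VD", ]
  expect_equal(vd$status, "on-frontier")
  expect_true(is.finite(vd$icer) && vd$icer > 0)
})

test_that("parameter constructors reject out-of-domain values", {
  expect_error(test_arm(p_side_effect = 1.2), "\\[0, 1\\]")
  expect_error(test_arm(monthly_drug_cost = -5), ">= 0")
  expect_error(test_shared(p_mi_fatal = -0.1), "\\[0, 1\\]")
  expect_error(test_shared(utilities = list(on_tx = 1.5, off_tx = 0.9,
                                            post_mi = 0.7)), "utilities")
  tab <- data.frame(age = 60:70, q = rep(0.01, 11))
  expect_error(test_shared(background_mortality = tab), "cover ages")
})
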