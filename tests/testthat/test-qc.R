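# Pharmacopeial QC calculators: acceptance value, weight variation,
# friability, disintegration, dissolution, hardness.

test_that("acceptance value reproduces hand-computed cases", {
  r <- acceptance_value(rep(100, 10))
  expect_equal(r$av, 0)
  expect_true(r$pass)

  x <- contents_with(97, 1)
  expect_equal(mean(x), 97, tolerance = 1e-12)
  expect_equal(sd(x), 1, tolerance = 1e-12)
  r <- acceptance_value(x)
  expect_equal(r$M, 98.5)
  expect_equal(r$av, 1.5 + 2.4 * 1.0, tolerance = 1e-12)
  expect_true(r$pass)

  r <- acceptance_value(contents_with(102, 6))
  expect_equal(r$M, 101.5)
  expect_equal(r$av, 0.5 + 2.4 * 6, tolerance = 1e-12)
  expect_true(r$pass)                 # 14.9 < 15.0, boundary pass

  r <- acceptance_value(contents_with(102, 6.1))
  expect_equal(r$av, 0.5 + 2.4 * 6.1, tolerance = 1e-12)
  expect_false(r$pass)                # 15.14 fails

  # AV = 15.0 exactly must fail (strictly-less-than limit)
  r <- acceptance_value(contents_with(100, 6.25))
  expect_equal(r$av, 15.0, tolerance = 1e-12)
  expect_false(r$pass)
})

test_that("acceptance value needs n = 10 unless k is supplied", {
  expect_error(acceptance_value(rep(100, 8)), "k")
  r <- acceptance_value(rep(100, 30), k = 2.0)
  expect_equal(r$av, 0)
})

test_that("AV is permutation-invariant and non-decreasing in s", {
  x <- contents_with(99, 2)
  expect_equal(acceptance_value(sample(x))$av, acceptance_value(x)$av)
  avs <- vapply(c(0.5, 1, 2, 4, 6), function(s) {
    acceptance_value(contents_with(99, s))$av
  }, numeric(1))
  expect_true(all(diff(avs) > 0))
})

test_that("weight variation: limits, boundaries and scale invariance", {
  w <- rep(200, 20)
  r <- weight_variation(w)
  expect_equal(r$max_deviation, 0)
  expect_true(r$pass)

  # one tablet at +8% of a 200 mg mean fails strict mode
  w <- rep(200, 20); w[1] <- 216
  m <- mean(w)
  expect_false(weight_variation(w)$pass)
  expect_gt(abs(216 - m) / m * 100, 7.5)

  # exactly +7.5% passes (inclusive limit); a symmetric pair keeps the mean
  w <- rep(200, 20); w[1] <- 215; w[2] <- 185
  expect_equal(mean(w), 200)
  r <- weight_variation(w)
  expect_equal(r$max_deviation, 7.5, tolerance = 1e-12)
  expect_true(r$pass)

  # scaling all weights leaves percent deviations unchanged (limit needs to
  # be explicit outside the 130-324 mg band)
  r2 <- weight_variation(w * 2, limit = 7.5)
  expect_equal(r2$deviations, r$deviations, tolerance = 1e-12)

  expect_error(weight_variation(rep(500, 20)), "supply the limit")
  expect_error(weight_variation(rep(200, 10)), "n = 20")

  # classic mode tolerates up to 2 units beyond the limit, none beyond 2x
  w <- rep(200, 20); w[1] <- 218; w[2] <- 182
  expect_false(weight_variation(w)$pass)
  expect_true(weight_variation(w, mode = "usp_classic")$pass)
  w[3] <- 231; w[4] <- 169  # third unit beyond the limit
  expect_false(weight_variation(w, mode = "usp_classic")$pass)
})

test_that("friability boundaries and breakage rule", {
  r <- friability_loss(6.5, 6.5)
  expect_equal(r$loss_pct, 0)
  expect_true(r$pass)
  r <- friability_loss(6.5, 6.435)
  expect_equal(r$loss_pct, 1.0, tolerance = 1e-12)
  expect_true(r$pass)                  # boundary: 1.00% passes
  expect_false(friability_loss(6.5, 6.43)$pass)
  expect_false(friability_loss(6.5, 6.49, breakage = TRUE)$pass)
  expect_error(friability_loss(6.5, 6.6), "measurement error")
})

test_that("disintegration: 15-minute rule with the printed worst case", {
  expect_true(disintegration_pass(rep(60, 6))$pass)
  expect_true(disintegration_pass(c(100, 120, 150, 200, 240, 256))$pass)
  expect_true(disintegration_pass(rep(900, 6))$pass)
  expect_false(disintegration_pass(c(rep(100, 5), 901))$pass)
  expect_error(disintegration_pass(rep(60, 5)), "n = 6")
})

test_that("dissolution: exact points, interpolation and boundaries", {
  prof <- function(vals, times = c(5, 10, 15, 20, 30, 45, 60)) {
    data.frame(time = times, dissolved = vals)
  }
  # exact sample point at the criterion time
  vessels <- replicate(4, prof(c(20, 45, 62, 75, 96.8, 99, 100)),
                       simplify = FALSE)
  r <- dissolution_pass(vessels, Q = 75, time = 30)
  expect_equal(r$mean_dissolved, 96.8)
  expect_true(r$pass)
  # mean below Q fails
  vessels <- replicate(4, prof(c(10, 20, 30, 40, 74.9, 80, 85)),
                       simplify = FALSE)
  expect_false(dissolution_pass(vessels, Q = 75, time = 30)$pass)
  # linear interpolation between bracketing points
  vessels <- list(data.frame(time = c(20, 40), dissolved = c(60, 90)))
  r <- dissolution_pass(vessels, Q = 75, time = 30)
  expect_equal(r$mean_dissolved, 75)
  expect_true(r$pass)
  # criterion time outside the sampled range
  expect_error(dissolution_pass(vessels, Q = 75, time = 45), "outside")
  expect_error(dissolution_pass(vessels, Q = 0, time = 30), "Q must")
})

test_that("interpolated dissolution is monotone for monotone profiles", {
  f <- function(t) 95 * (1 - exp(-(t / 12)^1.3))
  vessel <- list(data.frame(time = c(5, 10, 20, 30, 45), dissolved = f(c(5, 10, 20, 30, 45))))
  at <- vapply(seq(6, 44, by = 2), function(tt) {
    dissolution_pass(vessel, Q = 1, time = tt)$mean_dissolved
  }, numeric(1))
  expect_true(all(diff(at) > 0))
})

test_that("bundled criteria table carries every monograph limit", {
  tab <- dissolution_criteria()
  expect_equal(tab$Q[tab$drug == "rosuvastatin"], 75)
  expect_equal(tab$time_min[tab$drug == "rosuvastatin"], 30)
  expect_equal(tab$Q[tab$drug == "hydrochlorothiazide"], 60)
  expect_equal(tab$time_min[tab$drug == "hydrochlorothiazide"], 60)
  expect_equal(tab$Q[tab$drug == "isoniazid"], 80)
  expect_equal(tab$Q[tab$drug == "ethambutol"], 75)
  expect_match(tab$note[tab$drug == "ethambutol"], "presumed")
  expect_equal(nrow(tab), 9L)
})

test_that("hardness summary matches direct computation and rejects n < 2", {
  r <- hardness_summary(c(2, 2, 2))
  expect_equal(r$mean, 2)
  expect_equal(r$sd, 0)
  x <- c(1.75, 2.1, 1.9, 2.3, 1.6, 2.0, 1.85, 2.2, 1.95, 2.05)
  r <- hardness_summary(x)
  expect_equal(r$mean, sum(x) / 10, tolerance = 1e-12)
  expect_equal(r$sd, sqrt(sum((x - mean(x))^2) / 9), tolerance = 1e-12)
  expect_error(hardness_summary(5), "at least 2")
})

test_that("qc_report aggregates all checks and finds bundled criteria", {
  spec <- generator_spec(seed = 5)
  batch <- gen_tablet_batch(spec, drug = "rosuvastatin")
  rep <- qc_report(batch)
  expect_true(all(c("content_uniformity", "weight_variation", "friability",
                    "disintegration", "dissolution") %in% names(rep)))
  expect_true(is.logical(rep$all_pass))
  # dissolution criterion picked up from the bundled table (Q = 75 at 30)
  expect_true(rep$dissolution$pass)
})
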