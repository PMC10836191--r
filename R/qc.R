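# Pharmacopeial quality-control calculators: content-uniformity acceptance
# value, weight variation, friability, disintegration, dissolution
# Q-criteria and a hardness summary.
#
# Boundary conventions (made explicit because the compendial text rarely
# says open or closed): AV passes strictly below 15.0; weight deviation
# <= 7.5% passes; friability loss <= 1.0% passes (but any breakage fails);
# disintegration <= 900 s passes; dissolution batch mean >= Q passes.
# Comparisons at a limit use a 1e-9 guard so a measurement that equals the
# limit exactly is classified by the convention, not by rounding noise.

AV_LIMIT <- 15.0
AV_M_LOW <- 98.5
AV_M_HIGH <- 101.5
QC_EPS <- 1e-9   # absorbs float representation noise exactly at a limit

#' Content-uniformity acceptance value (AV)
#'
#' `AV = |M - X̄| + k * s` with `X̄` the mean assayed content (% of label
#' claim), `s` the sample standard deviation (n - 1 denominator), and the
#' reference value `M` equal to `X̄` clipped to `[98.5, 101.5]`. The batch
#' passes when `AV < 15.0` (strict).
#'
#' @param contents Assayed unit contents as % of label claim; the standard
#'   first-stage test uses n = 10 with `k = 2.4`.
#' @param k Acceptability constant; defaults to 2.4 and is required
#'   explicitly for any n other than 10.
#' @return List with `av`, `pass`, `mean`, `sd`, `M`.
#' @export
acceptance_value <- function(contents, k = NULL) {
  n <- length(contents)
  if (is.null(k)) {
    if (n != 10L) {
      stop("n = ", n, " units: supply the acceptability constant k ",
           "explicitly (k = 2.4 applies to n = 10)", call. = FALSE)
    }
    k <- 2.4
  }
  if (n < 2L) stop("at least 2 content values required", call. = FALSE)
  xbar <- mean(contents)
  s <- stats::sd(contents)
  M <- min(max(xbar, AV_M_LOW), AV_M_HIGH)
  av <- abs(M - xbar) + k * s
  list(av = av, pass = av < AV_LIMIT - QC_EPS, mean = xbar, sd = s, M = M)
}

#' Weight variation of a tablet batch
#'
#' Per-unit percentage deviation from the batch mean weight. In `"strict"`
#' mode (the default) the batch passes when the maximum deviation does not
#' exceed the limit; `"usp_classic"` mode allows up to 2 units beyond the
#' limit provided none exceeds twice the limit. The 7.5% limit applies to
#' uncoated tablets with mean weight between 130 and 324 mg; other mean
#' weights require an explicit `limit`.
#'
#' @param weights Measured unit weights (mg); the compendial test uses
#'   n = 20.
#' @param limit Percentage limit; defaults to 7.5 when the mean weight lies
#'   in `[130, 324]` mg and must be supplied otherwise.
#' @param mode `"strict"` or `"usp_classic"`.
#' @return List with `max_deviation` (%), `pass`, `mean`, `deviations`.
#' @export
weight_variation <- function(weights, limit = NULL,
                             mode = c("strict", "usp_classic")) {
  mode <- match.arg(mode)
  if (length(weights) != 20L) {
    stop("weight variation requires n = 20 units", call. = FALSE)
  }
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  m <- mean(weights)
  if (is.null(limit)) {
    if (m < 130 || m > 324) {
      stop(sprintf(
        "mean weight %.1f mg outside [130, 324]; supply the limit explicitly",
        m), call. = FALSE)
    }
    limit <- 7.5
  }
  dev <- abs(weights - m) / m * 100
  pass <- if (mode == "strict") {
    max(dev) <= limit + QC_EPS
  } else {
    sum(dev > limit + QC_EPS) <= 2L && all(dev <= 2 * limit + QC_EPS)
  }
  list(max_deviation = max(dev), pass = pass, mean = m, deviations = dev,
       limit = limit)
}

#' Friability mass loss
#'
#' @param initial_g,final_g Sample mass before/after tumbling (g).
#' @param breakage Any tablet broke, capped or cracked during the test; a
#'   broken sample fails regardless of mass loss.
#' @return List with `loss_pct`, `pass`.
#' @export
friability_loss <- function(initial_g, final_g, breakage = FALSE) {
  if (initial_g <= 0 || final_g <= 0) {
    stop("masses must be positive", call. = FALSE)
  }
  if (final_g > initial_g) {
    stop("final mass exceeds initial mass: measurement error", call. = FALSE)
  }
  loss <- (initial_g - final_g) / initial_g * 100
  list(loss_pct = loss, pass = loss <= 1.0 + QC_EPS && !isTRUE(breakage))
}

#' Disintegration pass/fail
#'
#' Uncoated tablets must fully disintegrate within 15 min (900 s).
#'
#' @param times Disintegration times (s) for the n = 6 tested units.
#' @return List with `max_time`, `pass`.
#' @export
disintegration_pass <- function(times) {
  if (length(times) != 6L) {
    stop("disintegration requires n = 6 units", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  list(max_time = max(times), pass = max(times) <= 900)
}

#' Dissolution acceptance against a Q criterion
#'
#' Evaluates the percent dissolved at the criterion time in each vessel —
#' from the exact sample point when one exists, otherwise by linear
#' interpolation between the bracketing points — and compares the batch mean
#' to Q (single-stage test on the tested vessels; pass when mean `>= Q`).
#'
#' @param profiles List of per-vessel data frames with columns `time`
#'   (minutes) and `dissolved` (% of label claim).
#' @param Q Minimum mean percent dissolved.
#' @param time Criterion time (minutes); must lie within every vessel's
#'   sampled range.
#' @return List with `mean_dissolved`, `pass`, `per_vessel`.
#' @export
dissolution_pass <- function(profiles, Q, time) {
  if (Q <= 0 || Q > 100) stop("Q must lie in (0, 100]", call. = FALSE)
  per <- vapply(profiles, function(p) {
    if (time < min(p$time) || time > max(p$time)) {
      stop(sprintf("criterion time %g min outside sampled range [%g, %g]",
                   time, min(p$time), max(p$time)), call. = FALSE)
    }
    o <- order(p$time)
    stats::approx(p$time[o], p$dissolved[o], xout = time, ties = mean)$y
  }, numeric(1))
  m <- mean(per)
  list(mean_dissolved = m, pass = m >= Q - QC_EPS, per_vessel = per)
}

#' Bundled dissolution Q-criteria table
#'
#' Per-drug monograph acceptance limits: not less than Q percent dissolved
#' at the stated time. The source text prints the 75%/45-min row a second
#' time under the name isoniazid; that row is transcribed here as ethambutol
#' (the only drug in the set otherwise missing a limit) and flagged in the
#' `note` column — callers must name the drug explicitly.
#'
#' @return Data frame with columns `drug`, `Q`, `time_min`, `note`.
#' @export
dissolution_criteria <- function() {
  utils::read.csv(system.file("extdata", "dissolution_criteria.csv",
                              package = "modpolypill", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Hardness summary
#'
#' Crushing-force mean and sample standard deviation. Hardness has no
#' compendial acceptance limit, so no pass/fail flag is produced.
#'
#' @param forces Breaking forces (kp), `n >= 2`.
#' @return List with `mean`, `sd`, `n`.
#' @export
hardness_summary <- function(forces) {
  if (length(forces) < 2L) {
    stop("hardness summary requires at least 2 measurements", call. = FALSE)
  }
  list(mean = mean(forces), sd = stats::sd(forces), n = length(forces))
}

#' Full QC report for a tablet batch
#'
#' Runs every applicable pharmacopeial check on a `tablet_batch` (see
#' [gen_tablet_batch()] or [read_tablet_batch()]).
#'
#' @param batch A `tablet_batch` list.
#' @param criterion Optional list/row with `Q` and `time_min` for the
#'   dissolution check; when `drug` is set on the batch and `criterion` is
#'   missing, the bundled criteria table is consulted.
#' @return A named list of per-test results plus `all_pass`.
#' @export
qc_report <- function(batch, criterion = NULL) {
  if (is.null(criterion) && !is.null(batch$drug)) {
    tab <- dissolution_criteria()
    row <- tab[tab$drug == batch$drug, ]
    if (nrow(row) == 1L) criterion <- list(Q = row$Q, time_min = row$time_min)
  }
  out <- list(
    content_uniformity = acceptance_value(batch$contents),
    weight_variation = weight_variation(batch$weights),
    friability = friability_loss(batch$friability$initial_g,
                                 batch$friability$final_g,
                                 batch$friability$breakage),
    disintegration = disintegration_pass(batch$disintegration_times),
    hardness = if (!is.null(batch$hardness)) hardness_summary(batch$hardness)
  )
  if (!is.null(criterion)) {
    out$dissolution <- dissolution_pass(batch$dissolution,
                                        criterion$Q, criterion$time_min)
  }
  flags <- vapply(out, function(x) {
    if (is.null(x$pass)) NA else x$pass
  }, logical(1))
  out$all_pass <- all(flags, na.rm = TRUE)
  out
}
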