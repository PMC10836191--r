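# File interfaces: Markov model definitions and CEA parameter sets as JSON,
# cohort traces as CSV, tablet-batch measurements as a directory of CSVs.

#' Read a Markov model definition from JSON
#'
#' Expected document: `states` (array), `absorbing` (array), `transitions`
#' (array of objects `from`, `to`, `probability`; unlisted pairs are 0 and
#' each state's diagonal absorbs any remainder when `complete_rows` is
#' true), `initial` (object state -> probability), `n_cycles`, optional
#' `costs`, `utilities` (objects state -> value), `discount_rate`.
#'
#' @param path JSON file path.
#' @return A [markov_model()].
#' @export
read_markov_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  ss <- state_space(doc$states,
                    absorbing = if (!is.null(doc$absorbing)) doc$absorbing else "Dead")
  n <- length(doc$states)
  P <- matrix(0, n, n, dimnames = list(doc$states, doc$states))
  tr <- doc$transitions
  for (i in seq_len(nrow(tr))) {
    P[tr$from[i], tr$to[i]] <- tr$probability[i]
  }
  if (isTRUE(doc$complete_rows)) {
    for (s in doc$states) {
      off <- sum(P[s, ]) - P[s, s]
      P[s, s] <- 1 - off
    }
  }
  init <- numeric(n)
  init[match(names(doc$initial), doc$states)] <- unlist(doc$initial)
  pick <- function(field) {
    v <- stats::setNames(numeric(n), doc$states)
    if (!is.null(doc[[field]])) {
      v[match(names(doc[[field]]), doc$states)] <- unlist(doc[[field]])
    }
    v
  }
  markov_model(ss, P, init, doc$n_cycles,
               costs = pick("costs"), utilities = pick("utilities"),
               discount_rate = if (!is.null(doc$discount_rate)) doc$discount_rate else 0.03)
}

#' Write a cohort trace as CSV
#'
#' One row per cycle, one column per state, first column `cycle`.
#'
#' @param trace A `cohort_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(cycle = 0:(nrow(trace) - 1L), unclass(trace),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a three-arm CEA parameter set as JSON
#'
#' The document mirrors the [shared_parameters()] and [arm_parameters()]
#' fields one-for-one, so externally estimated inputs (e.g. a transcribed
#' probability/cost table) can be dropped in without code changes.
#' Background mortality is stored as an explicit age table.
#'
#' @param params List with `shared` and `arms` (as from [gen_cea_params()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cea_params <- function(params, path) {
  sh <- params$shared
  ages <- sh$start_age:(sh$start_age + sh$n_cycles)
  doc <- list(
    shared = list(
      start_age = sh$start_age, p_mi_fatal = sh$p_mi_fatal,
      p_death_post_mi = sh$p_death_post_mi,
      background_mortality = data.frame(age = ages,
                                        q = sh$background_mortality(ages)),
      mi_event_cost = sh$mi_event_cost,
      post_mi_annual_cost = sh$post_mi_annual_cost,
      post_mi_treatment_cost = sh$post_mi_treatment_cost,
      utilities = sh$utilities, discount_rate = sh$discount_rate,
      wtp = sh$wtp, n_cycles = sh$n_cycles),
    arms = lapply(params$arms, unclass))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a three-arm CEA parameter set from JSON
#'
#' @param path JSON file written by [write_cea_params()] or hand-authored to
#'   the same schema.
#' @return List with `shared` and `arms`.
#' @export
read_cea_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sh <- doc$shared
  shared <- shared_parameters(
    start_age = sh$start_age, p_mi_fatal = sh$p_mi_fatal,
    p_death_post_mi = sh$p_death_post_mi,
    background_mortality = as.data.frame(sh$background_mortality),
    mi_event_cost = sh$mi_event_cost,
    post_mi_annual_cost = sh$post_mi_annual_cost,
    post_mi_treatment_cost = sh$post_mi_treatment_cost,
    utilities = as.list(sh$utilities), discount_rate = sh$discount_rate,
    wtp = sh$wtp, n_cycles = sh$n_cycles)
  arms <- lapply(doc$arms, function(a) do.call(arm_parameters, as.list(a)))
  list(shared = shared, arms = arms)
}

#' Read tablet-batch measurements from a directory of CSV files
#'
#' Expected files (headers in parentheses): `weights.csv` (`weight_mg`),
#' `contents.csv` (`content_pct`), `disintegration.csv` (`time_s`),
#' `friability.csv` (`initial_g`, `final_g`, `breakage`), optional
#' `hardness.csv` (`force_kp`) and `dissolution.csv`
#' (`vessel`, `time_min`, `dissolved_pct`), plus optional `batch.csv`
#' (`drug`, `label_claim_mg`, `target_weight_mg`).
#'
#' @param dir Directory path.
#' @return A `tablet_batch` list.
#' @export
read_tablet_batch <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  meta <- if (file.exists(file.path(dir, "batch.csv"))) rd("batch.csv") else NULL
  fr <- rd("friability.csv")
  batch <- list(
    drug = meta$drug, label_claim = meta$label_claim_mg,
    target_weight = meta$target_weight_mg,
    weights = rd("weights.csv")$weight_mg,
    contents = rd("contents.csv")$content_pct,
    disintegration_times = rd("disintegration.csv")$time_s,
    friability = list(initial_g = fr$initial_g[1], final_g = fr$final_g[1],
                      breakage = isTRUE(as.logical(fr$breakage[1]))))
  if (file.exists(file.path(dir, "hardness.csv"))) {
    batch$hardness <- rd("hardness.csv")$force_kp
  }
  if (file.exists(file.path(dir, "dissolution.csv"))) {
    d <- rd("dissolution.csv")
    batch$dissolution <- lapply(split(d, d$vessel), function(v) {
      data.frame(time = v$time_min, dissolved = v$dissolved_pct)
    })
  }
  structure(batch, class = "tablet_batch")
}

#' Write tablet-batch measurements as a directory of CSV files
#'
#' Inverse of [read_tablet_batch()].
#'
#' @param batch A `tablet_batch`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_tablet_batch <- function(batch, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f), row.names = FALSE)
  wr(data.frame(drug = if (is.null(batch$drug)) NA else batch$drug,
                label_claim_mg = batch$label_claim,
                target_weight_mg = batch$target_weight), "batch.csv")
  wr(data.frame(weight_mg = batch$weights), "weights.csv")
  wr(data.frame(content_pct = batch$contents), "contents.csv")
  wr(data.frame(time_s = batch$disintegration_times), "disintegration.csv")
  wr(data.frame(initial_g = batch$friability$initial_g,
                final_g = batch$friability$final_g,
                breakage = batch$friability$breakage), "friability.csv")
  if (!is.null(batch$hardness)) {
    wr(data.frame(force_kp = batch$hardness), "hardness.csv")
  }
  if (!is.null(batch$dissolution)) {
    d <- do.call(rbind, lapply(seq_along(batch$dissolution), function(v) {
      data.frame(vessel = v, time_min = batch$dissolution[[v]]$time,
                 dissolved_pct = batch$dissolution[[v]]$dissolved)
    }))
    wr(d, "dissolution.csv")
  }
  invisible(dir)
}
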