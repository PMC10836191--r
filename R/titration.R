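# Integer dose titration: pick modular tablet units whose strengths sum
# exactly to the target dose, with as few units as possible, then check the
# assembled polypill against the capsule/rod capacity limits.
#
# Doses are compared exactly: milligram values are scaled to integers by a
# common power of ten (2.5 and 12.5 mg steps need one decimal digit), so no
# floating-point equality is ever tested.

# Capacity limits per design/container: design 1 tablets interlock and fit
# an AA capsule (<= 5 units) or a 000 capsule (<= 8); design 2 annular disks
# stack on a dissolvable rod (<= 10).
CAPACITY <- list(`1` = c(AA = 5L, `000` = 8L), `2` = c(rod = 10L))

# Scale a set of mg values to exact integers. Uses up to 6 decimal digits;
# values are rounded at 1e-9 to absorb representation noise first.
mg_scale <- function(x) {
  x <- round(x, 9)
  for (d in 0:6) {
    scaled <- x * 10^d
    if (max(abs(scaled - round(scaled))) < 1e-6) {
      return(list(ints = as.numeric(round(scaled)), scale = 10^d))
    }
  }
  stop("doses must be expressible with at most 6 decimal digits of mg",
       call. = FALSE)
}

# Lexicographic comparison of candidate solutions:
# fewer units, then fewer distinct strengths, then larger strengths first
# (counts compared in decreasing-strength order). `a`, `b` are count vectors
# aligned to strengths sorted decreasing. Returns TRUE when a is better.
better_solution <- function(a, b) {
  if (is.null(b)) return(TRUE)
  ta <- sum(a); tb <- sum(b)
  if (ta != tb) return(ta < tb)
  da <- sum(a > 0); db <- sum(b > 0)
  if (da != db) return(da < db)
  d <- a - b
  nz <- which(d != 0)
  if (!length(nz)) return(FALSE)
  d[nz[1]] > 0
}

#' Solve one drug's dose from modular unit strengths
#'
#' Finds unit counts with `sum(count * strength) == target` exactly,
#' minimizing the total number of units; ties prefer fewer distinct
#' strengths, then combinations using larger strengths first. A target of 0
#' returns an empty selection.
#'
#' @param target Target dose (mg, `>= 0`).
#' @param strengths Available unit strengths (mg, positive, non-empty).
#' @return A `dose_solution` list: `counts` (named numeric, strength ->
#'   count, decreasing strength, zero counts dropped), `n_units`, `target`.
#' @section Infeasibility: when no exact combination exists an error of
#'   class `dose_infeasible` is thrown whose `data` lists the nearest
#'   achievable doses below and above the target.
#' @export
solve_drug_dose <- function(target, strengths) {
  if (length(strengths) < 1L || any(strengths <= 0)) {
    stop("strengths must be a non-empty vector of positive doses",
         call. = FALSE)
  }
  if (target < 0) stop("target dose must be >= 0", call. = FALSE)
  strengths <- sort(unique(strengths), decreasing = TRUE)
  sc <- mg_scale(c(target, strengths))
  ti <- sc$ints[1]
  si <- sc$ints[-1]
  if (ti == 0) {
    return(structure(list(counts = stats::setNames(numeric(0), character(0)),
                          n_units = 0L, target = target),
                     class = "dose_solution"))
  }

  # dynamic program over achievable integer doses up to target + min strength
  # (the smallest achievable dose above the target is at most one minimal
  # unit beyond it, since multiples of the smallest strength are achievable)
  lim <- ti + min(si)
  k <- length(si)
  best <- vector("list", lim + 1L)       # best[a + 1] = count vector for dose a
  best[[1L]] <- numeric(k)
  for (a in seq_len(lim)) {
    for (j in seq_len(k)) {
      prev <- a - si[j]
      if (prev >= 0 && !is.null(best[[prev + 1L]])) {
        cand <- best[[prev + 1L]]
        cand[j] <- cand[j] + 1
        if (better_solution(cand, best[[a + 1L]])) best[[a + 1L]] <- cand
      }
    }
  }
  sol <- best[[ti + 1L]]
  if (is.null(sol)) {
    feas <- which(!vapply(best, is.null, logical(1))) - 1L
    below <- suppressWarnings(max(feas[feas < ti & feas > 0]))
    above <- suppressWarnings(min(feas[feas > ti]))
    msg <- sprintf(
      "target %g mg is not an exact combination of strengths {%s}; nearest achievable: %s below, %s above",
      target, paste(strengths, collapse = ", "),
      if (is.finite(below)) sprintf("%g mg", below / sc$scale) else "none",
      if (is.finite(above)) sprintf("%g mg", above / sc$scale) else "none")
    cond <- structure(
      class = c("dose_infeasible", "error", "condition"),
      list(message = msg, call = sys.call(-1),
           data = list(target = target,
                       below = if (is.finite(below)) below / sc$scale else NA_real_,
                       above = if (is.finite(above)) above / sc$scale else NA_real_)))
    stop(cond)
  }
  keep <- sol > 0
  structure(list(counts = stats::setNames(sol[keep], format(strengths[keep])),
                 n_units = as.integer(sum(sol)), target = target),
            class = "dose_solution")
}

#' @export
print.dose_solution <- function(x, ...) {
  if (x$n_units == 0L) {
    cat(sprintf("%g mg: no units\n", x$target))
  } else {
    cat(sprintf("%g mg = %s (%d unit%s)\n", x$target,
                paste(sprintf("%s x %g mg", x$counts, as.numeric(names(x$counts))),
                      collapse = " + "),
                x$n_units, if (x$n_units == 1L) "" else "s"))
  }
  invisible(x)
}

#' Read a modular-unit catalogue
#'
#' @param path CSV file with columns `drug`, `strength_mg`, `design`.
#' @return Data frame catalogue.
#' @export
read_catalogue <- function(path) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("drug", "strength_mg", "design")
  if (!all(need %in% names(cat))) {
    stop("catalogue must have columns drug, strength_mg, design",
         call. = FALSE)
  }
  if (any(cat$strength_mg <= 0) || !all(cat$design %in% c(1, 2))) {
    stop("catalogue strengths must be positive and design 1 or 2",
         call. = FALSE)
  }
  cat
}

#' Bundled modular-unit catalogue
#'
#' The strengths manufactured for the cardiovascular drugs (design 1:
#' interlocking dome/dimple tablets), the first-line antituberculosis drugs
#' and prednisone (design 2: annular disks on a rod).
#'
#' @return Data frame with columns `drug`, `strength_mg`, `design`.
#' @export
default_catalogue <- function() {
  read_catalogue(system.file("extdata", "catalogue.csv",
                             package = "modpolypill", mustWork = TRUE))
}

# smallest container admitting `total` units of `design`, or NULL
select_container <- function(total, design) {
  caps <- CAPACITY[[as.character(design)]]
  ok <- which(total <= caps)
  if (!length(ok)) return(NULL)
  names(caps)[ok[1]]
}

#' Assemble a polypill from per-drug dose targets
#'
#' Solves each drug independently with [solve_drug_dose()] against the
#' catalogue strengths for the requested design, sums the units, and selects
#' the smallest container that holds them: design 1 fits an AA capsule up to
#' 5 units or a 000 capsule up to 8; design 2 fits a rod up to 10 units.
#' Mixed designs in one polypill are not allowed.
#'
#' @param targets Named numeric vector or list: drug -> target dose (mg).
#' @param catalogue Catalogue data frame (see [read_catalogue()]); defaults
#'   to the bundled one.
#' @param design Tablet design, 1 or 2.
#' @return A `polypill_config` list: `counts` (drug -> dose_solution),
#'   `design`, `container`, `total_units`.
#' @export
assemble_polypill <- function(targets, catalogue = default_catalogue(),
                              design) {
  if (!design %in% c(1, 2)) stop("design must be 1 or 2", call. = FALSE)
  targets <- unlist(targets)
  counts <- list()
  for (drug in names(targets)) {
    rows <- catalogue[catalogue$drug == drug & catalogue$design == design, ]
    if (!nrow(rows)) {
      stop(sprintf("drug '%s' not in catalogue for design %d", drug, design),
           call. = FALSE)
    }
    counts[[drug]] <- solve_drug_dose(targets[[drug]], rows$strength_mg)
  }
  total <- sum(vapply(counts, `[[`, integer(1), "n_units"))
  container <- select_container(total, design)
  if (is.null(container)) {
    lim <- max(CAPACITY[[as.character(design)]])
    stop(sprintf(
      "polypill needs %d units but design %d holds at most %d",
      total, design, lim), call. = FALSE)
  }
  structure(list(counts = counts, design = design, container = container,
                 total_units = as.integer(total)),
            class = "polypill_config")
}

#' @export
print.polypill_config <- function(x, ...) {
  cat(sprintf("Polypill (design %d, container %s, %d units):\n",
              x$design, x$container, x$total_units))
  for (drug in names(x$counts)) {
    cat(" ", drug, ": ", sep = "")
    print(x$counts[[drug]])
  }
  invisible(x)
}

#' Titration schedule across a dose sequence
#'
#' Solves each period of a taper (or any dose sequence) independently.
#' Increasing doses within a labelled taper are legal but warned about.
#'
#' @param dose_sequence Numeric vector of per-period target doses (mg,
#'   `>= 0`).
#' @param strengths Available unit strengths (mg).
#' @param design Tablet design, 1 or 2 (recorded in the output).
#' @return List of `dose_solution` objects, one per period.
#' @export
taper_schedule <- function(dose_sequence, strengths, design = 2) {
  if (any(dose_sequence < 0)) {
    stop("doses must be >= 0", call. = FALSE)
  }
  if (any(diff(dose_sequence) > 0)) {
    warning("dose sequence is not non-increasing; tapering usually decreases")
  }
  out <- vector("list", length(dose_sequence))
  for (i in seq_along(dose_sequence)) {
    out[[i]] <- tryCatch(
      solve_drug_dose(dose_sequence[i], strengths),
      dose_infeasible = function(e) {
        stop(sprintf("period %d (dose %g mg): %s",
                     i, dose_sequence[i], conditionMessage(e)), call. = FALSE)
      })
  }
  out
}
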