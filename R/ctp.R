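# CTP: Content and Timing of care in Pregnancy classifier.
#
# Decision sequence (one category per woman):
#   1. initiation of care after the cutoff (default: after 14 completed
#      weeks) -> Inadequate, regardless of content;
#   2. some whole-pregnancy intervention count below its lower range and
#      no count above its upper range -> Inadequate;
#   3. some count below its lower range and some count above its upper
#      range -> Intermediate (over-provision of one element alongside
#      under-provision of another);
#   4. all counts at or above their lower ranges -> Appropriate when
#      every per-trimester timing minimum is met, else Sufficient.

#' CTP tool configuration
#'
#' All thresholds of the CTP decision algorithm. The lower ranges and
#' trimester minima follow the NICE and Belgian low-risk guidelines: at
#' least 2 US, 6 BP and 2 BS over the whole pregnancy, timed as T1 >= 1
#' US + 1 BP + 1 BS, T2 >= 1 US + 2 BP, T3 >= 3 BP + 1 BS. Upper ranges
#' mark over-provision ("exceeds the range" means strictly above the
#' upper value); the shipped defaults (US 7, BP 10, BS 10) are
#' implementation defaults in the neighbourhood of observed 75th
#' percentiles of national use, not guideline values, and should be set
#' explicitly for substantive work.
#'
#' @param initiation_cutoff_weeks last completed week at which initiation
#'   still counts as timely (default 14; initiation *after* this week is
#'   late).
#' @param lower_range named integer vector `c(US=, BP=, BS=)` of minimum
#'   whole-pregnancy counts.
#' @param upper_range named integer vector; a count strictly above the
#'   upper value "exceeds the range".
#' @param trimester_minima named list `T1`/`T2`/`T3`, each a named
#'   integer vector of per-trimester minimum counts. The per-intervention
#'   sums across trimesters must equal `lower_range`.
#' @param boundaries a [trimester_boundaries()] list.
#' @return a `ctp_config` list.
#' @seealso [classify_ctp()], [write_ctp_config()]
#' @export
ctp_config <- function(initiation_cutoff_weeks = 14,
                       lower_range = c(US = 2, BP = 6, BS = 2),
                       upper_range = c(US = 7, BP = 10, BS = 10),
                       trimester_minima = list(
                         T1 = c(US = 1, BP = 1, BS = 1),
                         T2 = c(US = 1, BP = 2, BS = 0),
                         T3 = c(US = 0, BP = 3, BS = 1)
                       ),
                       boundaries = trimester_boundaries()) {
  codes <- intervention_codes()
  fill <- function(x) {
    out <- stats::setNames(rep(0L, length(codes)), codes)
    if (!all(names(x) %in% codes)) {
      stop_validation(sprintf("unknown intervention code(s): %s",
                              paste(setdiff(names(x), codes), collapse = ", ")))
    }
    out[names(x)] <- as.integer(x)
    out
  }
  lower_range <- fill(lower_range)
  upper_range <- fill(upper_range)
  trimester_minima <- lapply(trimester_minima, fill)
  if (!identical(sort(names(trimester_minima)), c("T1", "T2", "T3"))) {
    stop_validation("trimester_minima must have elements T1, T2, T3")
  }
  trimester_minima <- trimester_minima[c("T1", "T2", "T3")]
  if (any(lower_range > upper_range)) {
    stop_validation("lower_range must not exceed upper_range for any intervention")
  }
  sums <- Reduce(`+`, trimester_minima)
  if (!all(sums == lower_range)) {
    stop_validation(sprintf(
      "trimester minima must sum to the lower range per intervention (got %s, lower %s)",
      paste(sums, collapse = "/"), paste(lower_range, collapse = "/")))
  }
  structure(list(
    initiation_cutoff_weeks = as.integer(initiation_cutoff_weeks),
    lower_range = lower_range,
    upper_range = upper_range,
    trimester_minima = trimester_minima,
    boundaries = boundaries
  ), class = "ctp_config")
}

# Whole-pregnancy and per-trimester counts as a 3x3 matrix
# (rows T1/T2/T3, columns US/BP/BS).
trimester_counts <- function(trajectory, boundaries = trimester_boundaries()) {
  tri <- trimester_of(trajectory$gestational_week, boundaries)
  m <- matrix(0L, nrow = 3, ncol = 3,
              dimnames = list(c("T1", "T2", "T3"), intervention_codes()))
  for (t in c("T1", "T2", "T3")) {
    rows <- tri == t
    m[t, ] <- c(sum(trajectory$us[rows]), sum(trajectory$bp[rows]), sum(trajectory$bs[rows]))
  }
  m
}

#' Classify one trajectory with the CTP tool
#'
#' Applies the four-step CTP decision sequence (see [ctp_config()] and
#' the package vignette) to a single woman's trajectory and returns the
#' category together with an auditable rule trace.
#'
#' @param trajectory a one-woman `care_cohort` with at least one visit;
#'   an empty trajectory raises an undefined-initiation error (no-care
#'   women are out of scope and must be handled upstream).
#' @param config a [ctp_config()].
#' @return a `ctp_result` list: `woman_id`, `category` (one of
#'   [ctp_levels()]), `initiation_week`, `counts` (named whole-pregnancy
#'   US/BP/BS totals), `trimester_counts` (3x3 matrix), and `rule_trace`,
#'   a character vector recording each decision node in order.
#' @export
#' @examples
#' # over-provision of ultrasound alongside under-provision -> Intermediate
#' t <- care_trajectory("w", weeks = rep(8, 8), us = 1, ga_at_delivery = 40)
#' t$bp[1] <- 1; t$bs[1] <- 1
#' classify_ctp(t)$category
classify_ctp <- function(trajectory, config = ctp_config()) {
  assert_single_woman(trajectory)
  init <- initiation_week(trajectory)
  tri <- trimester_counts(trajectory, config$boundaries)
  totals <- colSums(tri)
  trace <- sprintf("initiation at week %d (cutoff %d): %s", init,
                   config$initiation_cutoff_weeks,
                   if (init > config$initiation_cutoff_weeks) "late" else "timely")

  if (init > config$initiation_cutoff_weeks) {
    category <- "Inadequate"
    trace <- c(trace, "late initiation -> Inadequate")
  } else {
    below <- totals < config$lower_range
    above <- totals > config$upper_range
    trace <- c(trace, sprintf(
      "counts US=%d BP=%d BS=%d vs lower %s, upper %s",
      totals["US"], totals["BP"], totals["BS"],
      paste(config$lower_range, collapse = "/"), paste(config$upper_range, collapse = "/")))
    if (any(below) && !any(above)) {
      category <- "Inadequate"
      trace <- c(trace, sprintf("below lower range (%s), none above upper -> Inadequate",
                                paste(names(totals)[below], collapse = ",")))
    } else if (any(below) && any(above)) {
      category <- "Intermediate"
      trace <- c(trace, sprintf("below lower range (%s) but above upper range (%s) -> Intermediate",
                                paste(names(totals)[below], collapse = ","),
                                paste(names(totals)[above], collapse = ",")))
    } else {
      minima <- do.call(rbind, config$trimester_minima)
      met <- tri >= minima
      if (all(met)) {
        category <- "Appropriate"
        trace <- c(trace, "all lower ranges met; all trimester timing minima met -> Appropriate")
      } else {
        fails <- which(!met, arr.ind = TRUE)
        category <- "Sufficient"
        trace <- c(trace, sprintf(
          "all lower ranges met; timing minima failed at %s -> Sufficient",
          paste(sprintf("%s:%s", rownames(met)[fails[, 1]],
                        colnames(met)[fails[, 2]]), collapse = ", ")))
      }
    }
  }
  structure(list(
    woman_id = trajectory$woman_id[1],
    category = category,
    initiation_week = init,
    counts = totals,
    trimester_counts = tri,
    rule_trace = trace
  ), class = "ctp_result")
}

#' @export
print.ctp_result <- function(x, ...) {
  cat(sprintf("CTP: %s (woman %s)\n", x$category, x$woman_id))
  cat(paste0("  ", x$rule_trace, collapse = "\n"), "\n")
  invisible(x)
}

#' Classify every woman in a cohort with the CTP tool
#'
#' @param cohort a `care_cohort`.
#' @param config a [ctp_config()].
#' @param strict if `TRUE`, the first per-woman classification error
#'   aborts the batch; if `FALSE` (default) failing women are collected
#'   in the `"errors"` attribute and the remainder are classified.
#' @return data frame with one row per classified woman: `woman_id`,
#'   `category` (ordered factor over [ctp_levels()]), `initiation_week`,
#'   `n_us`, `n_bp`, `n_bs`, `rule` (final trace line). Attribute
#'   `"errors"` is a named character vector of per-woman error messages
#'   (empty when all women classified).
#' @export
classify_cohort_ctp <- function(cohort, config = ctp_config(), strict = FALSE) {
  trajs <- cohort_trajectories(cohort)
  errors <- character()
  rows <- lapply(names(trajs), function(id) {
    res <- tryCatch(classify_ctp(trajs[[id]], config), carescore_error = function(e) e)
    if (inherits(res, "error")) {
      if (strict) stop(res)
      errors[[id]] <<- conditionMessage(res)
      return(NULL)
    }
    data.frame(woman_id = id, category = res$category,
               initiation_week = res$initiation_week,
               n_us = res$counts[["US"]], n_bp = res$counts[["BP"]],
               n_bs = res$counts[["BS"]],
               rule = res$rule_trace[length(res$rule_trace)])
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows) > 0) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(woman_id = character(), category = character(),
               initiation_week = integer(), n_us = integer(),
               n_bp = integer(), n_bs = integer(), rule = character())
  }
  out$category <- factor(out$category, levels = ctp_levels(), ordered = TRUE)
  attr(out, "errors") <- errors
  out
}
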