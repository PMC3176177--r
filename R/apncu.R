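# APNCU (Kotelchuck) index: initiation timing plus the ratio of observed
# to expected visits, with pluggable recommended-visit schedules.
#
# Ratio bands (timely initiation): < 0.50 Inadequate, [0.50, 0.80)
# Intermediate, [0.80, 1.10) Adequate, >= 1.10 AdequatePlus. The original
# verbal bands ("80-109%", "more than 110%") leave exactly 110%
# unassigned; the standard convention >= 110% -> AdequatePlus is used, so
# the four bands partition [0, Inf). Initiation after the 4th month is
# Inadequate regardless of the ratio.

#' Recommended-visit schedule for the APNCU index
#'
#' A schedule is a strictly increasing template of recommended visit
#' weeks plus the initiation cutoff. Expected visits for a woman are the
#' template weeks falling between her initiation and delivery (floored
#' at 1, since the initiation visit itself is always expected).
#'
#' Two named templates ship with the package:
#'
#' * `"acog"` -- the ACOG low-risk rhythm (every 4 weeks to 28, every
#'   2-3 weeks to 36, weekly to 42): weeks
#'   8, 12, 16, 20, 24, 28, 30, 32, 34, 36, 37, 38, 39, 40, 41, 42;
#' * `"belgian"` -- a 10-visit template to week 40 emulating the Belgian
#'   low-risk guideline: weeks 8, 12, 16, 20, 24, 28, 31, 34, 37, 40.
#'   The guideline's authoritative week list is not published in machine
#'   form; replications should pass their own `visit_weeks`.
#'
#' The month cutoff follows the index definition -- initiation after the
#' 4th month is late. Months are not printed in week units anywhere in
#' the index definition; with an average month of ~4.35 weeks, "within
#' the 4th month" is encoded as initiation at or before 17 completed
#' weeks (4 x 4.35 ~ 17.4), configurable via `initiation_week_cutoff`.
#'
#' @param name `"acog"`, `"belgian"`, or any label for a custom
#'   template.
#' @param visit_weeks strictly increasing integer vector of recommended
#'   visit weeks (<= 45); required when `name` is not a shipped
#'   template.
#' @param initiation_month_cutoff month number; initiation after this
#'   month is late (default 4).
#' @param initiation_week_cutoff last timely initiation week; default
#'   `ceiling(4.345 * initiation_month_cutoff) - 1 = 17` for month 4.
#' @param expected_basis `"week"` (default) counts template weeks from
#'   the exact initiation week; `"month"` counts from the first week of
#'   the initiation month, the convention of the original
#'   month-resolution index.
#' @return an `apncu_schedule` list.
#' @seealso [expected_visits()], [classify_apncu()]
#' @export
#' @examples
#' apncu_schedule("belgian")
#' apncu_schedule("custom4", visit_weeks = c(12, 20, 30, 38))
apncu_schedule <- function(name = c("belgian", "acog"),
                           visit_weeks = NULL,
                           initiation_month_cutoff = 4,
                           initiation_week_cutoff = NULL,
                           expected_basis = c("week", "month")) {
  templates <- list(
    acog    = c(8, 12, 16, 20, 24, 28, 30, 32, 34, 36, 37, 38, 39, 40, 41, 42),
    belgian = c(8, 12, 16, 20, 24, 28, 31, 34, 37, 40)
  )
  if (is.null(visit_weeks)) {
    name <- match.arg(name)
    visit_weeks <- templates[[name]]
  } else {
    name <- as.character(name)[1]
  }
  visit_weeks <- as.integer(visit_weeks)
  if (length(visit_weeks) == 0 || any(diff(visit_weeks) <= 0) ||
      any(visit_weeks < 0) || any(visit_weeks > 45)) {
    stop_validation("visit_weeks must be a nonempty strictly increasing vector of weeks in [0, 45]")
  }
  if (is.null(initiation_week_cutoff)) {
    initiation_week_cutoff <- ceiling(4.345 * initiation_month_cutoff) - 1
  }
  structure(list(
    name = name,
    visit_weeks = visit_weeks,
    initiation_month_cutoff = as.integer(initiation_month_cutoff),
    initiation_week_cutoff = as.integer(initiation_week_cutoff),
    expected_basis = match.arg(expected_basis)
  ), class = "apncu_schedule")
}

month_start_week <- function(week) {
  # first completed week of the (1-based) month containing `week`
  m <- floor(week / 4.345) + 1
  as.integer(ceiling(4.345 * (m - 1)))
}

#' Expected number of antenatal visits under a schedule
#'
#' Counts the schedule's recommended visit weeks falling in
#' `[initiation_week, ga_at_delivery]`, adjusting the expectation both
#' for late entry into care and for gestational age at delivery. The
#' count is floored at 1: the initiation visit itself is always
#' expected, which also keeps the observed/expected ratio defined for
#' very early deliveries.
#'
#' @param schedule an [apncu_schedule()].
#' @param initiation_week completed weeks at first visit.
#' @param ga_at_delivery completed weeks at delivery; must be >=
#'   `initiation_week`.
#' @return integer >= 1.
#' @export
#' @examples
#' expected_visits(apncu_schedule("acog"), 8, 40)    # 14
#' expected_visits(apncu_schedule("belgian"), 6, 40) # 10
expected_visits <- function(schedule, initiation_week, ga_at_delivery) {
  if (initiation_week > ga_at_delivery) {
    stop_validation("initiation_week must not exceed ga_at_delivery")
  }
  from <- if (schedule$expected_basis == "month") {
    month_start_week(initiation_week)
  } else {
    initiation_week
  }
  n <- sum(schedule$visit_weeks >= from & schedule$visit_weeks <= ga_at_delivery)
  max(1L, as.integer(n))
}

apncu_band <- function(ratio) {
  if (ratio < 0.50) "Inadequate"
  else if (ratio < 0.80) "Intermediate"
  else if (ratio < 1.10) "Adequate"
  else "AdequatePlus"
}

#' Classify one trajectory with the APNCU index
#'
#' Computes initiation timing and the observed/expected visit ratio and
#' assigns one of the four APNCU categories. Every visit row counts as
#' one observed visit regardless of its content; the index is blind to
#' which interventions were delivered.
#'
#' Category rule: initiation after the 4th month (i.e. after
#' `schedule$initiation_week_cutoff` completed weeks) *or* a ratio below
#' 0.50 gives Inadequate; with timely initiation, ratios in
#' `[0.50, 0.80)` give Intermediate, `[0.80, 1.10)` Adequate, and
#' `>= 1.10` AdequatePlus.
#'
#' @param trajectory a one-woman `care_cohort` with at least one visit.
#' @param schedule an [apncu_schedule()].
#' @return an `apncu_result` list: `woman_id`, `category` (one of
#'   [apncu_levels()]), `initiation_week`, `observed`, `expected`,
#'   `ratio`, `rule_trace`.
#' @export
#' @examples
#' t <- care_trajectory("w", weeks = seq(8, 40, by = 4), ga_at_delivery = 40)
#' classify_apncu(t, apncu_schedule("belgian"))$category
classify_apncu <- function(trajectory, schedule = apncu_schedule("belgian")) {
  assert_single_woman(trajectory)
  init <- initiation_week(trajectory)
  observed <- nrow(trajectory)
  expected <- expected_visits(schedule, init, trajectory$ga_at_delivery[1])
  ratio <- observed / expected
  late <- init > schedule$initiation_week_cutoff
  trace <- c(
    sprintf("initiation at week %d (timely through week %d): %s", init,
            schedule$initiation_week_cutoff, if (late) "late" else "timely"),
    sprintf("observed %d / expected %d visits = ratio %.3f [schedule %s]",
            observed, expected, ratio, schedule$name)
  )
  category <- if (late) {
    trace <- c(trace, "late initiation -> Inadequate")
    "Inadequate"
  } else {
    band <- apncu_band(ratio)
    trace <- c(trace, sprintf("ratio band -> %s", band))
    band
  }
  structure(list(
    woman_id = trajectory$woman_id[1],
    category = category,
    initiation_week = init,
    observed = observed,
    expected = expected,
    ratio = ratio,
    rule_trace = trace
  ), class = "apncu_result")
}

#' @export
print.apncu_result <- function(x, ...) {
  cat(sprintf("APNCU: %s (woman %s, %d/%d visits)\n",
              x$category, x$woman_id, x$observed, x$expected))
  cat(paste0("  ", x$rule_trace, collapse = "\n"), "\n")
  invisible(x)
}

#' Classify every woman in a cohort with the APNCU index
#'
#' @inheritParams classify_cohort_ctp
#' @param schedule an [apncu_schedule()].
#' @return data frame with `woman_id`, `category` (ordered factor over
#'   [apncu_levels()]), `initiation_week`, `observed`, `expected`,
#'   `ratio`; attribute `"errors"` as in [classify_cohort_ctp()].
#' @export
classify_cohort_apncu <- function(cohort, schedule = apncu_schedule("belgian"),
                                  strict = FALSE) {
  trajs <- cohort_trajectories(cohort)
  errors <- character()
  rows <- lapply(names(trajs), function(id) {
    res <- tryCatch(classify_apncu(trajs[[id]], schedule), carescore_error = function(e) e)
    if (inherits(res, "error")) {
      if (strict) stop(res)
      errors[[id]] <<- conditionMessage(res)
      return(NULL)
    }
    data.frame(woman_id = id, category = res$category,
               initiation_week = res$initiation_week,
               observed = res$observed, expected = res$expected,
               ratio = res$ratio)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows) > 0) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(woman_id = character(), category = character(),
               initiation_week = integer(), observed = integer(),
               expected = integer(), ratio = numeric())
  }
  out$category <- factor(out$category, levels = apncu_levels(), ordered = TRUE)
  attr(out, "errors") <- errors
  out
}
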