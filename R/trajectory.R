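# Domain model: visit-level antenatal care trajectories.
#
# A cohort is stored in long format, one row per antenatal visit:
#   woman_id, gestational_week, us, bp, bs, ga_at_delivery, scheduled
# where us/bp/bs are non-negative intervention counts at that visit
# (multiplicity is preserved: two blood-pressure measurements in one
# visit count twice), ga_at_delivery is repeated per row for a woman and
# must be consistent, and scheduled is an optional carried flag.

#' Intervention codes tracked by the CTP tool
#'
#' The three content indicators: `US` (ultrasound scan), `BP`
#' (blood-pressure measurement), `BS` (blood screening). All range and
#' timing configuration is keyed by these codes; unknown codes are
#' rejected wherever they can enter.
#'
#' @return character vector `c("US", "BP", "BS")`.
#' @export
intervention_codes <- function() c("US", "BP", "BS")

#' CTP category levels, lowest to highest
#' @return character vector of the four ordinal CTP labels.
#' @export
ctp_levels <- function() c("Inadequate", "Intermediate", "Sufficient", "Appropriate")

#' APNCU category levels, lowest to highest
#' @return character vector of the four ordinal APNCU labels.
#' @export
apncu_levels <- function() c("Inadequate", "Intermediate", "Adequate", "AdequatePlus")

cohort_columns <- function() {
  c("woman_id", "gestational_week", "us", "bp", "bs", "ga_at_delivery", "scheduled")
}

# column holding the per-visit count for an intervention code
code_column <- function(code) {
  code <- match.arg(code, intervention_codes())
  c(US = "us", BP = "bp", BS = "bs")[[code]]
}

#' Construct a validated care cohort
#'
#' Builds the canonical long-format cohort object from a data frame of
#' visit rows. Rows are sorted by `(woman_id, gestational_week)` and all
#' trajectory invariants are enforced:
#'
#' * `gestational_week` is an integer in `[0, 45]`;
#' * `us`, `bp`, `bs` are non-negative integer counts;
#' * `ga_at_delivery` is a single consistent integer per woman, at least
#'   as large as her latest visit week.
#'
#' @param visits data frame with columns `woman_id`, `gestational_week`,
#'   `us`, `bp`, `bs`, `ga_at_delivery` and optionally `scheduled`
#'   (logical or 0/1/NA).
#' @return a `care_cohort` object (a sorted data frame with the columns
#'   above, `scheduled` as logical).
#' @seealso [care_trajectory()] for a one-woman shorthand,
#'   [read_cohort_csv()] for file ingestion.
#' @export
#' @examples
#' care_cohort(data.frame(
#'   woman_id = "w1", gestational_week = c(8, 20, 32),
#'   us = 1, bp = 1, bs = c(1, 0, 1), ga_at_delivery = 40
#' ))
care_cohort <- function(visits) {
  visits <- as.data.frame(visits)
  if (!"scheduled" %in% names(visits)) visits$scheduled <- rep(NA, nrow(visits))
  required <- setdiff(cohort_columns(), "scheduled")
  missing <- setdiff(required, names(visits))
  if (length(missing) > 0) {
    stop_format(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  visits <- visits[, cohort_columns()]
  visits$woman_id <- as.character(visits$woman_id)

  check_int <- function(x, what, min = 0, max = Inf) {
    bad <- which(is.na(x) | x != as.integer(x) | x < min | x > max)
    if (length(bad) > 0) {
      stop_validation(sprintf("invalid %s in visit row(s) %s", what,
                              paste(utils::head(bad, 5), collapse = ", ")),
                      rows = bad)
    }
    as.integer(x)
  }
  visits$gestational_week <- check_int(suppressWarnings(as.numeric(visits$gestational_week)),
                                       "gestational_week (integer 0-45 required)", 0, 45)
  for (col in c("us", "bp", "bs")) {
    visits[[col]] <- check_int(suppressWarnings(as.numeric(visits[[col]])),
                               sprintf("intervention count '%s' (non-negative integer required)", col))
  }
  visits$ga_at_delivery <- check_int(suppressWarnings(as.numeric(visits$ga_at_delivery)),
                                     "ga_at_delivery (integer week required)", 0, 45)
  if (is.numeric(visits$scheduled)) visits$scheduled <- visits$scheduled != 0
  visits$scheduled <- as.logical(visits$scheduled)

  visits <- visits[order(visits$woman_id, visits$gestational_week), , drop = FALSE]
  rownames(visits) <- NULL

  ga <- tapply(visits$ga_at_delivery, visits$woman_id, function(x) length(unique(x)))
  if (any(ga > 1)) {
    stop_validation(sprintf("inconsistent ga_at_delivery for woman_id: %s",
                            paste(names(ga)[ga > 1], collapse = ", ")))
  }
  late <- tapply(seq_len(nrow(visits)), visits$woman_id, function(i) {
    any(visits$gestational_week[i] > visits$ga_at_delivery[i])
  })
  if (any(late)) {
    stop_validation(sprintf("visit after delivery for woman_id: %s",
                            paste(names(late)[late], collapse = ", ")))
  }
  class(visits) <- c("care_cohort", "data.frame")
  visits
}

#' Construct a single-woman care trajectory
#'
#' Convenience constructor used throughout examples and tests.
#'
#' @param woman_id identifier.
#' @param weeks integer vector of gestational weeks, one per visit.
#' @param us,bp,bs per-visit intervention counts, recycled to
#'   `length(weeks)`.
#' @param ga_at_delivery completed weeks of gestation at delivery.
#' @return a one-woman `care_cohort`.
#' @export
#' @examples
#' care_trajectory("w1", weeks = c(8, 20, 32), bp = 2, ga_at_delivery = 40)
care_trajectory <- function(woman_id, weeks, us = 0, bp = 0, bs = 0, ga_at_delivery) {
  n <- length(weeks)
  care_cohort(data.frame(
    woman_id = woman_id,
    gestational_week = weeks,
    us = rep_len(us, n), bp = rep_len(bp, n), bs = rep_len(bs, n),
    ga_at_delivery = ga_at_delivery
  ))
}

#' Number of women in a cohort
#' @param cohort a `care_cohort`.
#' @return integer count of distinct `woman_id` values.
#' @export
n_women <- function(cohort) length(unique(cohort$woman_id))

#' Split a cohort into per-woman trajectories
#' @param cohort a `care_cohort`.
#' @return named list of one-woman `care_cohort` objects, keyed by
#'   `woman_id`.
#' @export
cohort_trajectories <- function(cohort) {
  out <- split(as.data.frame(cohort), cohort$woman_id)
  lapply(out, function(d) {
    rownames(d) <- NULL
    class(d) <- c("care_cohort", "data.frame")
    d
  })
}

assert_single_woman <- function(trajectory) {
  if (nrow(trajectory) == 0) {
    stop_empty_trajectory("trajectory has no visits: initiation of care is undefined")
  }
  ids <- unique(trajectory$woman_id)
  if (length(ids) != 1) {
    stop_validation(sprintf("expected a single-woman trajectory, got %d woman_id values", length(ids)))
  }
  invisible(trajectory)
}

#' Gestational week of initiation of care
#'
#' Initiation of care is the gestational week of the first antenatal
#' visit (the minimum visit week). It is the first branch of both the
#' CTP tool and the APNCU index.
#'
#' @param trajectory a one-woman `care_cohort` with at least one visit.
#' @return integer completed weeks at first visit.
#' @export
#' @examples
#' initiation_week(care_trajectory("w", c(8, 12, 20), ga_at_delivery = 40)) # 8
initiation_week <- function(trajectory) {
  assert_single_woman(trajectory)
  min(trajectory$gestational_week)
}

#' Count intervention occurrences in a gestational window
#'
#' Sums the recorded multiplicity of one intervention across visits
#' whose gestational week falls in an inclusive window. With the default
#' window the count covers the whole pregnancy.
#'
#' @param trajectory a one-woman `care_cohort`.
#' @param code one of `"US"`, `"BP"`, `"BS"`.
#' @param window inclusive `c(low, high)` week interval, or `NULL` for
#'   the whole pregnancy.
#' @return non-negative integer count.
#' @export
#' @examples
#' t <- care_trajectory("w", c(8, 20, 24, 30, 34, 38), bp = 1, ga_at_delivery = 40)
#' count_interventions(t, "BP")               # 6
#' count_interventions(t, "BP", c(15, 28))    # 2
count_interventions <- function(trajectory, code, window = NULL) {
  col <- code_column(code)
  wk <- trajectory$gestational_week
  keep <- if (is.null(window)) {
    rep(TRUE, length(wk))
  } else {
    if (length(window) != 2 || any(window < 0) || window[1] > window[2]) {
      stop_validation("window must be c(low, high) with 0 <= low <= high")
    }
    wk >= window[1] & wk <= window[2]
  }
  sum(trajectory[[col]][keep])
}

#' Trimester boundary configuration
#'
#' The classifiers take trimester boundaries as configuration. The
#' defaults place the end of the first trimester at 14 completed weeks
#' (aligned with the CTP initiation cutoff) and the end of the second at
#' 28 completed weeks, so T1 = weeks 0-14, T2 = 15-28, T3 = 29 to
#' delivery.
#'
#' @param t1_end last completed week counted in the first trimester.
#' @param t2_end last completed week counted in the second trimester.
#' @return list with elements `t1_end`, `t2_end`.
#' @export
trimester_boundaries <- function(t1_end = 14, t2_end = 28) {
  stopifnot(t1_end >= 0, t2_end > t1_end)
  list(t1_end = t1_end, t2_end = t2_end)
}

#' Map gestational weeks to trimesters
#'
#' Total mapping: every non-negative week belongs to exactly one of
#' `"T1"`, `"T2"`, `"T3"` under the configured boundaries.
#'
#' @param gestational_week integer vector of completed weeks.
#' @param boundaries a [trimester_boundaries()] list.
#' @return character vector of `"T1"`, `"T2"`, `"T3"`.
#' @export
#' @examples
#' trimester_of(c(14, 15, 29)) # "T1" "T2" "T3"
trimester_of <- function(gestational_week, boundaries = trimester_boundaries()) {
  stopifnot(all(gestational_week >= 0))
  ifelse(gestational_week <= boundaries$t1_end, "T1",
         ifelse(gestational_week <= boundaries$t2_end, "T2", "T3"))
}

trimester_window <- function(trimester, boundaries = trimester_boundaries()) {
  switch(trimester,
         T1 = c(0, boundaries$t1_end),
         T2 = c(boundaries$t1_end + 1, boundaries$t2_end),
         T3 = c(boundaries$t2_end + 1, 45),
         stop_validation(sprintf("unknown trimester '%s'", trimester)))
}

# CSV ingestion / emission -----------------------------------------------

#' Read a visit-level cohort CSV
#'
#' Reads the canonical comma-delimited, UTF-8 visit file with header
#' `woman_id,gestational_week,us,bp,bs,ga_at_delivery,scheduled`. Rows
#' for the same woman are grouped and sorted by gestational week; all
#' trajectory invariants are enforced (see [care_cohort()]).
#'
#' Structural problems raise classed conditions: a missing required
#' column raises a format error naming the column; an inconsistent or
#' missing `ga_at_delivery`, or a delivery before the last visit, raises
#' a validation error naming the `woman_id`; a malformed intervention
#' count raises a validation error citing the offending row number.
#'
#' @param path file to read.
#' @param sep field separator (default comma).
#' @return a `care_cohort`. The attribute `"parse_report"` carries a
#'   character vector of notes (currently empty unless rows were
#'   whitespace-padded or the optional `scheduled` column was absent).
#' @seealso [write_cohort_csv()]
#' @export
read_cohort_csv <- function(path, sep = ",") {
  if (!file.exists(path)) stop_io(sprintf("input file not found: %s", path))
  raw <- utils::read.csv(path, sep = sep, colClasses = "character",
                         strip.white = TRUE, fileEncoding = "UTF-8")
  report <- character()
  required <- setdiff(cohort_columns(), "scheduled")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_format(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  }
  if (!"scheduled" %in% names(raw)) {
    report <- c(report, "optional column 'scheduled' absent; filled with NA")
    raw$scheduled <- NA
  }
  blank <- apply(raw[, required, drop = FALSE] == "" |
                   is.na(raw[, required, drop = FALSE]), 1, any)
  for (col in c("gestational_week", "us", "bp", "bs", "ga_at_delivery")) {
    x <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!blank & (is.na(x) | x != floor(x) | x < 0))
    if (length(bad) > 0) {
      stop_validation(sprintf("column '%s': non-integer or negative value in data row(s) %s",
                              col, paste(utils::head(bad, 5), collapse = ", ")),
                      rows = bad)
    }
    raw[[col]] <- x
  }
  if (any(blank)) {
    miss_ids <- unique(raw$woman_id[blank & (is.na(raw$ga_at_delivery) | raw$ga_at_delivery == "")])
    if (length(miss_ids) > 0) {
      stop_validation(sprintf("missing ga_at_delivery for woman_id: %s",
                              paste(miss_ids, collapse = ", ")))
    }
    stop_validation(sprintf("blank required field(s) in data row(s) %s",
                            paste(utils::head(which(blank), 5), collapse = ", ")))
  }
  sched <- trimws(raw$scheduled)
  raw$scheduled <- ifelse(sched %in% c("", "NA", NA), NA,
                          ifelse(sched %in% c("1", "TRUE", "true"), TRUE, FALSE))
  cohort <- care_cohort(raw)
  attr(cohort, "parse_report") <- report
  cohort
}

#' Write a cohort to the canonical CSV layout
#'
#' Emits one row per visit, ordered by `(woman_id, gestational_week)`,
#' with the same header [read_cohort_csv()] expects, so that
#' `read_cohort_csv(write_cohort_csv(cohort, f))` round-trips exactly.
#' `scheduled` is written as `1`/`0`/`NA`.
#'
#' @param cohort a `care_cohort`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- as.data.frame(cohort)[, cohort_columns()]
  out <- out[order(out$woman_id, out$gestational_week), , drop = FALSE]
  out$scheduled <- ifelse(is.na(out$scheduled), NA_integer_, as.integer(out$scheduled))
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA",
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop_io(sprintf("cannot write cohort CSV to '%s': %s",
                                   path, conditionMessage(ok)))
  invisible(path)
}
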