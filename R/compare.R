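# Comparison of the two classifications over one cohort: 4x4
# cross-tabulation, marginal percentages, per-row agreement shares, and
# Pearson's chi-square test of independence.

as_label_vector <- function(x, levels, what) {
  if (is.data.frame(x)) {
    if (!all(c("woman_id", "category") %in% names(x))) {
      stop_validation(sprintf("%s data frame needs columns woman_id and category", what))
    }
    x <- stats::setNames(as.character(x$category), x$woman_id)
  }
  if (is.null(names(x)) && length(x) > 0) {
    stop_validation(sprintf("%s labels must be named by woman_id", what))
  }
  x <- stats::setNames(as.character(x), names(x))
  bad <- setdiff(unique(x), levels)
  if (length(bad) > 0) {
    stop_validation(sprintf("unknown %s category label(s): %s", what,
                            paste(bad, collapse = ", ")))
  }
  x
}

#' Cross-tabulate APNCU against CTP assignments
#'
#' Builds the 4x4 contingency table of APNCU categories (rows) by CTP
#' categories (columns) over a common set of women. All sixteen cells
#' are always present, zero-filled, in the canonical ordinal order.
#'
#' @param apncu_labels named character vector (names = `woman_id`,
#'   values in [apncu_levels()]) or the data frame returned by
#'   [classify_cohort_apncu()].
#' @param ctp_labels named character vector with values in
#'   [ctp_levels()] or the data frame from [classify_cohort_ctp()]. Must
#'   cover exactly the same women as `apncu_labels`.
#' @return a `care_crosstab`: list with `counts` (4x4 integer matrix)
#'   and `n_total`.
#' @export
#' @examples
#' a <- c(w1 = "Adequate", w2 = "AdequatePlus")
#' c <- c(w1 = "Sufficient", w2 = "Appropriate")
#' cross_tabulate(a, c)$counts
cross_tabulate <- function(apncu_labels, ctp_labels) {
  a <- as_label_vector(apncu_labels, apncu_levels(), "APNCU")
  c_ <- as_label_vector(ctp_labels, ctp_levels(), "CTP")
  only_a <- setdiff(names(a), names(c_))
  only_c <- setdiff(names(c_), names(a))
  if (length(only_a) > 0 || length(only_c) > 0) {
    stop_validation(sprintf(
      "label key sets differ; only in APNCU: {%s}; only in CTP: {%s}",
      paste(only_a, collapse = ", "), paste(only_c, collapse = ", ")))
  }
  c_ <- c_[names(a)]
  counts <- table(factor(a, levels = apncu_levels()),
                  factor(c_, levels = ctp_levels()))
  counts <- matrix(as.integer(counts), nrow = 4,
                   dimnames = list(APNCU = apncu_levels(), CTP = ctp_levels()))
  structure(list(counts = counts, n_total = length(a)), class = "care_crosstab")
}

#' @export
print.care_crosstab <- function(x, ...) {
  cat(sprintf("APNCU x CTP cross-tabulation (N = %d)\n", x$n_total))
  print(x$counts)
  invisible(x)
}

#' Marginal category percentages of a cross-tabulation
#'
#' Per-category share of women on one axis, as percentages of the grand
#' total, rounded half-up.
#'
#' @param tab a `care_crosstab`.
#' @param axis `"rows"` (APNCU marginals) or `"columns"` (CTP
#'   marginals).
#' @param decimals decimal places for half-up rounding (default 1, the
#'   usual reporting convention).
#' @return named numeric vector of percentages.
#' @export
marginal_proportions <- function(tab, axis = c("rows", "columns"), decimals = 1) {
  axis <- match.arg(axis)
  if (tab$n_total < 1) stop_validation("proportions undefined for an empty table")
  m <- if (axis == "rows") rowSums(tab$counts) else colSums(tab$counts)
  round_half_up(100 * m / tab$n_total, decimals)
}

#' Per-row agreement between APNCU and CTP
#'
#' For each APNCU category, the share of its women whom CTP places in
#' the upper half of its scale (Sufficient or Appropriate) and the
#' complementary share in the lower half (Inadequate or Intermediate).
#' This is the discordance summary used when the two tools are compared:
#' APNCU-high rows with a substantial low-CTP share mark women whose
#' many visits lacked the recommended content.
#'
#' @param tab a `care_crosstab`.
#' @param decimals decimal places for the percentage columns.
#' @return data frame with one row per APNCU category: `apncu`, `n_row`,
#'   `n_ctp_high`, `pct_ctp_high`, `n_ctp_low`, `pct_ctp_low`.
#'   Percentages are `NA` for empty rows.
#' @export
agreement_summary <- function(tab, decimals = 1) {
  high_cols <- c("Sufficient", "Appropriate")
  low_cols <- c("Inadequate", "Intermediate")
  n_row <- rowSums(tab$counts)
  n_high <- rowSums(tab$counts[, high_cols, drop = FALSE])
  n_low <- rowSums(tab$counts[, low_cols, drop = FALSE])
  pct <- function(x) ifelse(n_row > 0, round_half_up(100 * x / n_row, decimals), NA_real_)
  data.frame(
    apncu = rownames(tab$counts),
    n_row = as.integer(n_row),
    n_ctp_high = as.integer(n_high),
    pct_ctp_high = pct(n_high),
    n_ctp_low = as.integer(n_low),
    pct_ctp_low = pct(n_low),
    row.names = NULL
  )
}

#' Pearson chi-square test of independence on a cross-tabulation
#'
#' Classical Pearson X-squared = sum (obs - exp)^2 / exp with
#' exp = row_total x col_total / n, no continuity correction. All-zero
#' rows and columns are dropped before testing; degrees of freedom are
#' (rows - 1)(cols - 1) after pruning. Sparse category tables routinely
#' contain expected cells below 5, where the asymptotic p-value is
#' approximate; `small_expected_flag` reports this.
#'
#' @param tab a `care_crosstab`.
#' @return a `chi_square_result` list: `statistic`, `dof`, `p_value`,
#'   `expected` (matrix on the pruned table), `small_expected_flag`.
#' @export
chi_square <- function(tab) {
  m <- tab$counts
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop_validation("degenerate table: need at least 2 non-empty rows and columns")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(list(
    statistic = unname(ht$statistic),
    dof = unname(ht$parameter),
    p_value = unname(ht$p.value),
    expected = ht$expected,
    small_expected_flag = any(ht$expected < 5)
  ), class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X2 = %.3f, df = %d, p = %.3g%s\n",
              x$statistic, x$dof, x$p_value,
              if (x$small_expected_flag) " (expected cell < 5: asymptotic p approximate)" else ""))
  invisible(x)
}

#' The CTP development-cohort cross-tabulation
#'
#' The 4x4 APNCU-by-CTP table observed in the tool's development cohort
#' of 333 Brussels women, reconstructed cell by cell through
#' [cross_tabulate()] from engineered per-woman labels. Used as the
#' worked example for the comparison arithmetic (marginals, agreement
#' shares, chi-square); the underlying diary data are not public, so
#' only quantities that are arithmetic consequences of the printed table
#' can be reproduced.
#'
#' @return a `care_crosstab` with row totals (8, 23, 107, 195) and
#'   column totals (34, 28, 120, 151), N = 333.
#' @export
#' @examples
#' tab <- development_crosstab()
#' marginal_proportions(tab, "columns") # 10.2 8.4 36.0 45.3
development_crosstab <- function() {
  counts <- matrix(c(
    8, 0, 0, 0,
    9, 5, 3, 6,
    9, 12, 51, 35,
    8, 11, 66, 110
  ), nrow = 4, byrow = TRUE,
  dimnames = list(APNCU = apncu_levels(), CTP = ctp_levels()))
  labs <- expand_crosstab_labels(counts)
  cross_tabulate(labs$apncu, labs$ctp)
}

# one woman per unit count, ids w001.., row-major over the table
expand_crosstab_labels <- function(counts) {
  apncu <- rep(rownames(counts)[row(counts)], counts)
  ctp <- rep(colnames(counts)[col(counts)], counts)
  ids <- sprintf("w%03d", seq_along(apncu))
  list(apncu = stats::setNames(apncu, ids), ctp = stats::setNames(ctp, ids))
}

#' Full comparison report for one cohort
#'
#' Runs both classifiers, cross-tabulates, and assembles marginals,
#' agreement shares and the chi-square test into one list (the payload
#' of the CLI `compare` subcommand).
#'
#' @param cohort a `care_cohort`.
#' @param config a [ctp_config()].
#' @param schedule an [apncu_schedule()].
#' @return list with elements `crosstab`, `ctp_marginals_pct`,
#'   `apncu_marginals_pct`, `agreement`, `chi_square`.
#' @export
compare_classifications <- function(cohort, config = ctp_config(),
                                    schedule = apncu_schedule("belgian")) {
  ctp <- classify_cohort_ctp(cohort, config)
  apncu <- classify_cohort_apncu(cohort, schedule)
  tab <- cross_tabulate(apncu, ctp)
  list(
    crosstab = tab,
    ctp_marginals_pct = marginal_proportions(tab, "columns"),
    apncu_marginals_pct = marginal_proportions(tab, "rows"),
    agreement = agreement_summary(tab),
    chi_square = chi_square(tab)
  )
}
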