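test_that("configuration invariants are enforced", {
  expect_s3_class(ctp_config(), "ctp_config")
  expect_error(ctp_config(lower_range = c(US = 8, BP = 6, BS = 2)),
               "lower_range", class = "carescore_validation_error")
  expect_error(ctp_config(trimester_minima = list(T1 = c(US = 1), T2 = c(BP = 2),
                                                  T3 = c(BP = 3, BS = 1))),
               "sum", class = "carescore_validation_error")
  expect_error(ctp_config(lower_range = c(ZZ = 2)), class = "carescore_validation_error")
})

test_that("the four decision branches classify the worked patterns as defined", {
  # late initiation dominates everything else
  late <- care_trajectory("a", c(16, 20, 30), us = 1, bp = 2, bs = 1, ga_at_delivery = 40)
  expect_equal(classify_ctp(late)$category, "Inadequate")

  # under-provision without over-provision: 2 US, 1 BP, 1 BS
  under <- care_trajectory("b", c(8, 12), us = 1, bp = c(1, 0), bs = c(1, 0),
                           ga_at_delivery = 40)
  expect_equal(classify_ctp(under)$category, "Inadequate")

  # under-provision of BP/BS with over-provision of US: 8 US, 1 BP, 1 BS
  over <- care_trajectory("c", seq(6, 34, by = 4), us = 1,
                          bp = c(1, rep(0, 7)), bs = c(1, rep(0, 7)),
                          ga_at_delivery = 40)
  expect_equal(classify_ctp(over)$category, "Intermediate")

  # counts and timing both met
  expect_equal(classify_ctp(textbook_trajectory())$category, "Appropriate")

  # counts met but both ultrasounds in the third trimester
  mistimed <- care_cohort(data.frame(
    woman_id = "e", gestational_week = c(8, 20, 24, 30, 30, 34, 38),
    us = c(0, 0, 0, 1, 1, 0, 0), bp = c(1, 1, 1, 1, 1, 1, 0),
    bs = c(1, 0, 0, 1, 0, 0, 0), ga_at_delivery = 40))
  expect_equal(classify_ctp(mistimed)$category, "Sufficient")
  expect_equal(oracle_ctp(8, rbind(c(0, 1, 1), c(0, 3, 0), c(2, 2, 1))), "Sufficient")
})

test_that("boundary conventions: week 14 is timely, a count equal to the upper range does not exceed it", {
  at_cutoff <- care_trajectory("w", c(14, 20), us = 1, bp = 1, bs = 1, ga_at_delivery = 40)
  res <- classify_ctp(at_cutoff)
  expect_match(res$rule_trace[1], "timely")

  # US exactly at the upper range (7) with BP/BS deficient: no exceedance -> Inadequate
  at_upper <- care_trajectory("w", rep(8, 7), us = 1, ga_at_delivery = 40)
  expect_equal(classify_ctp(at_upper)$category, "Inadequate")
  # one more ultrasound crosses the range -> Intermediate
  above <- care_trajectory("w", rep(8, 8), us = 1, ga_at_delivery = 40)
  expect_equal(classify_ctp(above)$category, "Intermediate")
})

test_that("late initiation dominates any intervention profile", {
  set.seed(101)
  for (i in 1:30) {
    m <- matrix(c(0, 0, 0, sample(0:8, 6, replace = TRUE)), nrow = 3, byrow = TRUE)
    t <- traj_from_counts(sample(15:28, 1), m)
    expect_equal(classify_ctp(t)$category, "Inadequate")
  }
})

test_that("adding interventions to an Appropriate trajectory never demotes it", {
  set.seed(202)
  base <- textbook_trajectory()
  expect_equal(classify_ctp(base)$category, "Appropriate")
  for (i in 1:30) {
    t <- base
    row <- sample(nrow(t), 1)
    col <- sample(c("us", "bp", "bs"), 1)
    t[[col]][row] <- t[[col]][row] + sample(1:10, 1)
    expect_equal(classify_ctp(t)$category, "Appropriate")
  }
})

test_that("the label ignores how counts are spread across visit rows", {
  set.seed(303)
  for (i in 1:15) {
    m <- matrix(sample(0:4, 9, replace = TRUE), nrow = 3)
    merged <- traj_from_counts(6, m)
    # split every visit row into per-unit rows at the same week
    rows <- as.data.frame(merged)
    split_rows <- do.call(rbind, lapply(seq_len(nrow(rows)), function(j) {
      r <- rows[j, ]
      n <- max(1, r$us + r$bp + r$bs)
      out <- r[rep(1, n), ]
      out[c("us", "bp", "bs")] <- 0
      units <- rep(c("us", "bp", "bs"), times = c(r$us, r$bp, r$bs))
      for (k in seq_along(units)) out[[units[k]]][k] <- 1
      out
    }))
    expect_equal(classify_ctp(care_cohort(split_rows))$category,
                 classify_ctp(merged)$category)
  }
})

test_that("rule traces are consistent with the assigned category", {
  set.seed(404)
  for (i in 1:20) {
    m <- matrix(sample(c(0:3, 12), 9, replace = TRUE), nrow = 3)
    init <- sample(c(6, 16), 1)
    if (init > 14) m[1, ] <- 0
    res <- classify_ctp(traj_from_counts(init, m))
    expect_match(res$rule_trace[length(res$rule_trace)], res$category)
  }
})

test_that("cohort classification composes per-woman results and handles failures leniently", {
  cohort <- care_cohort(rbind(
    data.frame(woman_id = "late", gestational_week = 16, us = 1, bp = 1, bs = 1,
               ga_at_delivery = 40),
    data.frame(woman_id = "tb", gestational_week = c(8, 20, 24, 30, 34, 38),
               us = c(1, 1, 0, 0, 0, 0), bp = 1, bs = c(1, 0, 0, 1, 0, 0),
               ga_at_delivery = 40)
  ))
  res <- classify_cohort_ctp(cohort)
  expect_setequal(as.character(res$category), c("Inadequate", "Appropriate"))
  expect_length(attr(res, "errors"), 0)

  empty <- cohort[0, ]
  expect_equal(nrow(classify_cohort_ctp(empty)), 0)
  expect_error(classify_ctp(empty), class = "carescore_empty_trajectory_error")
})
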