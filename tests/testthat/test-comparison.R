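test_that("cross-tabulation counts label pairs and checks key sets", {
  a <- c(w1 = "Adequate", w2 = "Adequate", w3 = "Inadequate")
  c_ <- c(w3 = "Inadequate", w1 = "Sufficient", w2 = "Appropriate")
  tab <- cross_tabulate(a, c_)
  expect_equal(tab$n_total, 3)
  expect_equal(tab$counts["Adequate", "Sufficient"], 1)
  expect_equal(tab$counts["Adequate", "Appropriate"], 1)
  expect_equal(tab$counts["Inadequate", "Inadequate"], 1)
  expect_equal(sum(tab$counts), 3)

  # identical labels for all women -> one nonzero cell
  same <- cross_tabulate(setNames(rep("AdequatePlus", 10), paste0("w", 1:10)),
                         setNames(rep("Appropriate", 10), paste0("w", 1:10)))
  expect_equal(sum(same$counts), 10)
  expect_equal(same$counts["AdequatePlus", "Appropriate"], 10)

  # empty input -> all-zero table
  empty <- cross_tabulate(character(), character())
  expect_equal(empty$n_total, 0)
  expect_true(all(empty$counts == 0))

  err <- expect_error(cross_tabulate(c(w1 = "Adequate"), c(w2 = "Sufficient")),
                      class = "carescore_validation_error")
  expect_match(conditionMessage(err), "w1")
  expect_match(conditionMessage(err), "w2")
  expect_error(cross_tabulate(c(w1 = "Fine"), c(w1 = "Sufficient")),
               class = "carescore_validation_error")
})

test_that("marginals match direct label frequencies and sum to ~100%", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(20:80, 1)
    ids <- sprintf("w%03d", seq_len(n))
    a <- setNames(sample(apncu_levels(), n, replace = TRUE), ids)
    c_ <- setNames(sample(ctp_levels(), n, replace = TRUE), ids)
    tab <- cross_tabulate(a, c_)
    expect_equal(unname(rowSums(tab$counts)),
                 unname(table(factor(a, apncu_levels()))[apncu_levels()]),
                 ignore_attr = TRUE)
    expect_equal(unname(colSums(tab$counts)),
                 unname(table(factor(c_, ctp_levels()))[ctp_levels()]),
                 ignore_attr = TRUE)
    expect_lte(abs(sum(marginal_proportions(tab, "rows")) - 100), 0.2)
    expect_lte(abs(sum(marginal_proportions(tab, "columns")) - 100), 0.2)
  }
  single <- cross_tabulate(c(w1 = "Inadequate"), c(w1 = "Inadequate"))
  expect_equal(unname(marginal_proportions(single, "rows")), c(100, 0, 0, 0))
  expect_error(marginal_proportions(cross_tabulate(character(), character()), "rows"),
               class = "carescore_validation_error")
})

test_that("half-up rounding follows the reporting convention", {
  expect_equal(round_half_up(c(45.345, 2.45, 2.35, -2.45) * 1, 1),
               c(45.3, 2.5, 2.4, -2.5))
  expect_equal(round_half_up(0.5, 0), 1)
})

test_that("agreement summary splits each APNCU row at the CTP Sufficient boundary", {
  tab <- development_crosstab()
  ag <- agreement_summary(tab)
  expect_equal(ag$n_ctp_high[ag$apncu == "Inadequate"], 0)
  expect_equal(ag$pct_ctp_low[ag$apncu == "Inadequate"], 100)
  expect_equal(ag$n_ctp_high + ag$n_ctp_low, ag$n_row)

  # empty rows are flagged undefined, not divided by zero
  a <- c(w1 = "Adequate"); c_ <- c(w1 = "Sufficient")
  ag2 <- agreement_summary(cross_tabulate(a, c_))
  expect_true(is.na(ag2$pct_ctp_high[ag2$apncu == "Inadequate"]))
})

test_that("chi-square matches hand and brute-force evaluations", {
  mk_tab <- function(m) {
    labs <- list(apncu = rep(apncu_levels()[row(m)], m), ctp = rep(ctp_levels()[col(m)], m))
    ids <- sprintf("x%04d", seq_along(labs$apncu))
    cross_tabulate(setNames(labs$apncu, ids), setNames(labs$ctp, ids))
  }
  # perfect independence
  M <- matrix(0, 4, 4); M[1:2, 1:2] <- 5
  r <- chi_square(mk_tab(M))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$dof, 1) # zero rows/columns pruned first

  # perfect association on the diagonal: X2 = n with all expected = 5
  diag2 <- mk_tab({M <- matrix(0, 4, 4); M[1, 1] <- 10; M[2, 2] <- 10; M})
  r2 <- chi_square(diag2)
  expect_equal(r2$statistic, 20)
  expect_equal(r2$dof, 1)

  # brute-force double loop on random tables
  set.seed(66)
  for (i in 1:10) {
    M <- matrix(rpois(16, 8) + 1, 4, 4)
    tab <- mk_tab(M)
    r3 <- chi_square(tab)
    n <- sum(M)
    stat <- 0
    for (a in 1:4) for (b in 1:4) {
      e <- sum(M[a, ]) * sum(M[, b]) / n
      stat <- stat + (M[a, b] - e)^2 / e
    }
    expect_equal(r3$statistic, stat, tolerance = 1e-9)
    expect_equal(r3$p_value, pchisq(stat, 9, lower.tail = FALSE), tolerance = 1e-9)
  }

  # invariance under simultaneous relabeling of rows and columns
  M <- matrix(rpois(16, 6) + 1, 4, 4)
  perm <- sample(4)
  expect_equal(chi_square(mk_tab(M))$statistic,
               chi_square(mk_tab(M[perm, perm]))$statistic, tolerance = 1e-12)

  # degenerate table
  one_row <- mk_tab({M <- matrix(0, 4, 4); M[2, ] <- c(3, 4, 5, 6); M})
  expect_error(chi_square(one_row), class = "carescore_validation_error")
})

test_that("the full comparison report assembles consistently on a simulated cohort", {
  params <- cohort_sim_params(n_women = 120, seed = 21)
  rep <- compare_classifications(simulate_cohort(params))
  expect_equal(rep$crosstab$n_total, 120)
  expect_equal(sum(rep$crosstab$counts), 120)
  expect_equal(rep$agreement$n_row, unname(rowSums(rep$crosstab$counts)))
  expect_true(rep$chi_square$p_value >= 0 && rep$chi_square$p_value <= 1)
})
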