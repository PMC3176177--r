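# Test helpers: trajectory builders and independently coded rule-table
# oracles for both classifiers. The oracles are written straight from
# the verbal rule definitions, against count matrices rather than
# trajectories, so they share no code path with the implementation.

# Build a trajectory realizing a 3x3 per-trimester count matrix
# (rows T1/T2/T3, columns US/BP/BS): one visit row per trimester at a
# representative week, carrying that trimester's counts with
# multiplicity. `init` must be the earliest visit week; with late
# initiation (week 15-28) no first-trimester visit is possible, so the
# T1 row of `m` must be zero and the T2 visit sits at `init`.
traj_from_counts <- function(init, m, ga = 40, id = "w") {
  if (init <= 14) {
    df <- data.frame(woman_id = id, gestational_week = c(init, 20, 32),
                     us = m[, 1], bp = m[, 2], bs = m[, 3], ga_at_delivery = ga)
  } else {
    stopifnot(init <= 28, all(m[1, ] == 0))
    df <- data.frame(woman_id = id, gestational_week = c(init, 32),
                     us = m[2:3, 1], bp = m[2:3, 2], bs = m[2:3, 3],
                     ga_at_delivery = ga)
  }
  care_cohort(df)
}

# CTP rule table, coded independently from the category definitions.
oracle_ctp <- function(init, m) {
  totals <- colSums(m)
  if (init > 14) return("Inadequate")
  lower <- c(2, 6, 2)
  upper <- c(7, 10, 10)
  below <- totals < lower
  above <- totals > upper
  if (any(below) && !any(above)) return("Inadequate")
  if (any(below) && any(above)) return("Intermediate")
  minima <- rbind(c(1, 1, 1), c(1, 2, 0), c(0, 3, 1))
  if (all(m >= minima)) "Appropriate" else "Sufficient"
}

# APNCU rule table, independently coded: expected = template weeks in
# [init, delivery] floored at 1; bands on observed/expected.
oracle_apncu <- function(init, delivery, observed, template, timely_through = 17) {
  expected <- max(1, sum(template >= init & template <= delivery))
  ratio <- observed / expected
  if (init > timely_through || ratio < 0.5) return("Inadequate")
  if (ratio < 0.8) return("Intermediate")
  if (ratio < 1.1) return("Adequate")
  "AdequatePlus"
}

# Trajectory with a given visit count: first visit at init, the rest at
# delivery (ties allowed; APNCU only counts rows).
traj_with_n_visits <- function(init, delivery, n, id = "w") {
  weeks <- c(init, rep(delivery, n - 1))
  care_trajectory(id, weeks, ga_at_delivery = delivery)
}

# Small random cohort for round-trip and property tests.
random_cohort <- function(n = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    delivery <- sample(30:43, 1)
    k <- sample(1:12, 1)
    weeks <- sort(sample(0:delivery, k, replace = TRUE))
    data.frame(woman_id = sprintf("r%03d", i), gestational_week = weeks,
               us = rbinom(k, 2, 0.3), bp = rbinom(k, 2, 0.5),
               bs = rbinom(k, 2, 0.3), ga_at_delivery = delivery,
               scheduled = sample(c(TRUE, FALSE, NA), k, replace = TRUE))
  })
  care_cohort(do.call(rbind, rows))
}

# The textbook trajectory meeting every CTP criterion exactly.
textbook_trajectory <- function(id = "tb", ga = 40) {
  care_cohort(data.frame(
    woman_id = id, gestational_week = c(8, 20, 24, 30, 34, 38),
    us = c(1, 1, 0, 0, 0, 0), bp = c(1, 1, 1, 1, 1, 1),
    bs = c(1, 0, 0, 1, 0, 0), ga_at_delivery = ga
  ))
}
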