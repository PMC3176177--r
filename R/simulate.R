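# Synthetic antenatal-care cohort simulator.
#
# The generator emulates the care-use structure reported for the
# development cohort: median initiation at 7 completed weeks (IQR 6-10),
# median 11 consultations (IQR 10-14), median delivery at 40 weeks
# (IQR 38-40). Distribution families are simulator choices -- only
# medians and quartiles are published: initiation and visit counts are
# discretized log-normals fitted to the quartiles, delivery a
# discretized truncated normal. Visit weeks follow a schedule-with-jitter
# process between initiation and delivery; interventions are Bernoulli
# per visit with per-trimester probabilities.

default_intervention_probs <- function() {
  matrix(c(
    0.80, 0.80, 0.80,   # T1: US, BP, BS
    0.50, 0.80, 0.55,   # T2
    0.25, 0.85, 0.60    # T3
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("T1", "T2", "T3"), intervention_codes()))
}

#' Simulation parameters for a synthetic antenatal-care cohort
#'
#' Each marginal distribution is either a fitted family (the default) or
#' degenerate (`list(fixed = k)`), which the presets use to force
#' particular care patterns. Defaults are calibrated to the development
#' cohort's summary statistics (see the package vignette): initiation
#' log-normal with quartiles 6 and 10 weeks (median ~7 after
#' discretization), visit count log-normal with quartiles 10 and 14
#' (median ~11), delivery normal truncated to `[22, 43]` weeks with
#' median 40.
#'
#' @param n_women number of trajectories to generate.
#' @param initiation `list(meanlog, sdlog, min, max)` for a floored
#'   log-normal over completed weeks, or `list(fixed = week)`.
#' @param delivery `list(mean, sd, min, max)` for a floored truncated
#'   normal, or `list(fixed = week)`.
#' @param visits `list(meanlog, sdlog, min, max)` for a floored
#'   log-normal visit count, or `list(fixed = n)`.
#' @param intervention_probs 3x3 matrix (rows T1/T2/T3, columns
#'   US/BP/BS) of per-visit Bernoulli probabilities.
#' @param template optional fixed visit plan: a data frame with columns
#'   `week`, `us`, `bp`, `bs` plus attribute-free `ga_at_delivery`
#'   passed as the `template_ga` argument; when set, every woman
#'   receives exactly this plan and the stochastic components are
#'   ignored.
#' @param template_ga delivery week used with `template`.
#' @param boundaries a [trimester_boundaries()] list (used to look up
#'   intervention probabilities).
#' @param seed integer seed consumed by [simulate_cohort()]; `NA` leaves
#'   the RNG state untouched.
#' @return a `cohort_sim_params` list.
#' @export
cohort_sim_params <- function(n_women = 333,
                              initiation = list(meanlog = 2.0472, sdlog = 0.3787,
                                                min = 0, max = 20),
                              delivery = list(mean = 40.2, sd = 1.5,
                                              min = 22, max = 43),
                              visits = list(meanlog = 2.4709, sdlog = 0.2494,
                                            min = 1, max = 30),
                              intervention_probs = default_intervention_probs(),
                              template = NULL,
                              template_ga = 40,
                              boundaries = trimester_boundaries(),
                              seed = NA) {
  stopifnot(n_women >= 1)
  p <- as.numeric(intervention_probs)
  if (any(p < 0 | p > 1)) stop_validation("intervention probabilities must lie in [0, 1]")
  init_min <- if (!is.null(initiation$fixed)) initiation$fixed else initiation$min
  del_max <- if (!is.null(delivery$fixed)) delivery$fixed else delivery$max
  if (is.null(template) && init_min > del_max) {
    stop_validation("infeasible parameters: earliest possible initiation after latest possible delivery")
  }
  structure(list(
    n_women = as.integer(n_women), initiation = initiation, delivery = delivery,
    visits = visits, intervention_probs = intervention_probs,
    template = template, template_ga = template_ga,
    boundaries = boundaries, seed = seed
  ), class = "cohort_sim_params")
}

# floored draw from a (possibly degenerate) marginal, rejection-truncated
draw_weeks <- function(n, spec, lo_override = NULL, hi_override = NULL, family) {
  if (!is.null(spec$fixed)) return(rep(as.integer(spec$fixed), n))
  lo <- if (is.null(lo_override)) spec$min else pmax(spec$min, lo_override)
  hi <- if (is.null(hi_override)) spec$max else pmin(spec$max, hi_override)
  out <- integer(n)
  todo <- seq_len(n)
  for (iter in 1:1000) {
    m <- length(todo)
    if (m == 0) break
    x <- floor(switch(family,
      lognormal = stats::rlnorm(m, spec$meanlog, spec$sdlog),
      normal = stats::rnorm(m, spec$mean, spec$sd)
    ))
    lo_t <- if (length(lo) == 1) rep(lo, n) else lo
    hi_t <- if (length(hi) == 1) rep(hi, n) else hi
    ok <- x >= lo_t[todo] & x <= hi_t[todo]
    out[todo[ok]] <- as.integer(x[ok])
    todo <- todo[!ok]
  }
  if (length(todo) > 0) stop_validation("simulation truncation bounds admit (almost) no mass")
  out
}

#' Simulate a synthetic antenatal-care cohort
#'
#' Generates `params$n_women` valid trajectories. Per woman: a delivery
#' week, an initiation week no later than delivery, a visit count, visit
#' weeks placed on an even grid between initiation and delivery with
#' +/- 1 week jitter (ties allowed; the first visit is the initiation
#' week), and per-visit intervention indicators drawn with the
#' per-trimester probabilities. Identical seeds give identical cohorts.
#'
#' @param params a [cohort_sim_params()].
#' @return a `care_cohort` of `params$n_women` women with ids
#'   `"w00001"`, ...
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_sim_params(n_women = 20, seed = 1))
#' n_women(cohort)
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  if (!is.na(params$seed)) set.seed(as.integer(params$seed))
  n <- params$n_women
  ids <- sprintf("w%05d", seq_len(n))

  if (!is.null(params$template)) {
    tpl <- params$template
    k <- nrow(tpl)
    visits <- data.frame(
      woman_id = rep(ids, each = k),
      gestational_week = rep(tpl$week, n),
      us = rep(tpl$us, n), bp = rep(tpl$bp, n), bs = rep(tpl$bs, n),
      ga_at_delivery = params$template_ga
    )
    return(care_cohort(visits))
  }

  delivery <- draw_weeks(n, params$delivery, family = "normal")
  initiation <- draw_weeks(n, params$initiation, hi_override = delivery, family = "lognormal")
  n_visits <- draw_weeks(n, params$visits, family = "lognormal")
  n_visits <- pmax(1L, n_visits)

  probs <- params$intervention_probs
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_visits[i]
    if (k == 1) {
      weeks <- initiation[i]
    } else {
      base <- round(seq(initiation[i], delivery[i], length.out = k))
      jit <- sample(-1:1, k, replace = TRUE)
      weeks <- pmin(pmax(base + jit, initiation[i]), delivery[i])
      weeks[1] <- initiation[i]
      weeks <- sort(weeks)
    }
    tri <- trimester_of(weeks, params$boundaries)
    rows[[i]] <- data.frame(
      woman_id = ids[i],
      gestational_week = weeks,
      us = stats::rbinom(k, 1, probs[tri, "US"]),
      bp = stats::rbinom(k, 1, probs[tri, "BP"]),
      bs = stats::rbinom(k, 1, probs[tri, "BS"]),
      ga_at_delivery = delivery[i]
    )
  }
  care_cohort(do.call(rbind, rows))
}

#' Named preset simulation scenarios
#'
#' Four ready-made parameter sets:
#'
#' * `"study_like"` -- the calibrated defaults emulating the development
#'   cohort's care characteristics;
#' * `"all_appropriate"` -- a deterministic textbook plan (initiation at
#'   week 8; 2 US, 6 BP, 2 BS timed to satisfy every trimester minimum)
#'   so every woman classifies CTP Appropriate;
#' * `"late_initiators"` -- initiation fixed at week 20, past both the
#'   CTP first-trimester cutoff and the APNCU 4th-month cutoff, so every
#'   woman is Inadequate under both tools;
#' * `"high_visits_low_content"` -- timely initiation and 11-20 visits
#'   but a low probability (0.08) of any tracked intervention at each
#'   visit: the discordance pattern in which APNCU scores care adequate
#'   or better on visit numbers while CTP flags the missing content.
#'
#' @param n_women women per cohort (applied to every preset).
#' @return named list of [cohort_sim_params()].
#' @export
#' @examples
#' names(preset_scenarios())
preset_scenarios <- function(n_women = 333) {
  textbook <- data.frame(
    week = c(8, 20, 24, 30, 34, 38),
    us = c(1, 1, 0, 0, 0, 0),
    bp = c(1, 1, 1, 1, 1, 1),
    bs = c(1, 0, 0, 1, 0, 0)
  )
  list(
    study_like = cohort_sim_params(n_women = n_women),
    all_appropriate = cohort_sim_params(
      n_women = n_women, template = textbook, template_ga = 40),
    late_initiators = cohort_sim_params(
      n_women = n_women, initiation = list(fixed = 20)),
    high_visits_low_content = cohort_sim_params(
      n_women = n_women,
      initiation = list(fixed = 7),
      visits = list(meanlog = log(14), sdlog = 0.12, min = 11, max = 20),
      intervention_probs = matrix(0.08, 3, 3,
        dimnames = list(c("T1", "T2", "T3"), intervention_codes()))
    )
  )
}
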