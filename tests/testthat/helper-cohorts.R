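# Fixtures are built in code: small hand-made cohorts plus a tie-free random
# generator that is deliberately independent of the package's own simulator.

make_cohort <- function(arm, followup, event_time = rep(NA_real_, length(arm)),
                        death = rep(FALSE, length(arm)),
                        id = sprintf("s%02d", seq_along(arm))) {
  as_cohort(data.frame(
    subject_id = id, arm = arm, event_time = event_time,
    event_observed = !is.na(event_time), followup_time = followup,
    death_observed = death, stringsAsFactors = FALSE))
}

# continuous times, so risk-set tie conventions never matter
random_cohort <- function(n = 60, seed = 1) {
  set.seed(seed)
  arm <- rep(0:1, length.out = n)
  tev <- rexp(n, rate = ifelse(arm == 1, 0.6, 1.1))
  tdeath <- rexp(n, rate = 0.4)
  tcens <- runif(n, 0.3, 3)
  fu <- pmin(tdeath, tcens)
  ev <- tev <= fu
  make_cohort(arm, followup = fu,
              event_time = ifelse(ev, tev, NA_real_),
              death = tdeath <= tcens)
}

# a valid weight table with arbitrary weights, for likelihood-calculus checks
random_table <- function(n = 50, seed = 2) {
  tab <- unit_weight_table(random_cohort(n, seed))
  set.seed(seed + 1000)
  tab$p <- runif(length(tab$j), 0.2, 1)
  tab
}

cox_beta <- function(time, status, z) {
  f <- suppressWarnings(survival::coxph(
    survival::Surv(time, status) ~ z, ties = "breslow",
    control = survival::coxph.control(eps = 1e-14, iter.max = 100)))
  unname(stats::coef(f))
}

cs_cox_beta <- function(cohort) {
  cox_beta(ifelse(cohort$event_observed, cohort$event_time,
                  cohort$followup_time),
           cohort$event_observed, cohort$arm)
}
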