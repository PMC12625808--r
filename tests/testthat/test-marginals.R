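test_that("death model matches a grid-search maximization of the explicit partial likelihood", {
  # deaths at t=1 (arm 1) and t=2 (arm 0), one censored subject per arm:
  # PL(b) = [e^b/(2e^b + 2)] * [1/(e^b + 2)], maximized directly on a grid
  coh <- make_cohort(arm = c(1, 0, 1, 0), followup = c(1, 2, 3, 3),
                     death = c(TRUE, TRUE, FALSE, FALSE))
  grid <- seq(-4, 4, by = 1e-5)
  logpl <- grid - log(2 * exp(grid) + 2) - log(exp(grid) + 2)
  dm <- fit_death_model(coh)
  expect_lt(abs(dm$beta - grid[which.max(logpl)]), 1e-4)
  expect_equal(dm$beta, cox_beta(coh$followup_time, coh$death_observed,
                                 coh$arm), tolerance = 1e-8)
})

test_that("death fit agrees with an established Cox implementation on random cohorts", {
  for (seed in c(11, 12, 13)) {
    coh <- random_cohort(70, seed)
    dm <- fit_death_model(coh)
    expect_lt(abs(dm$beta - cox_beta(coh$followup_time, coh$death_observed,
                                     coh$arm)), 1e-8)
    # Breslow baseline agrees with survival's estimator
    f <- suppressWarnings(survival::coxph(
      survival::Surv(followup_time, death_observed) ~ arm, data = coh,
      ties = "breslow", control = survival::coxph.control(eps = 1e-14)))
    bh <- survival::basehaz(f, centered = FALSE)
    expect_equal(dm$cumhaz, bh$hazard[match(dm$times, bh$time)],
                 tolerance = 1e-6)
  }
})

test_that("death and cause-specific fits share one partial-likelihood machinery", {
  coh <- random_cohort(50, seed = 21)
  relabelled <- make_cohort(coh$arm, followup = coh$followup_time,
                            event_time = coh$followup_time *
                              ifelse(coh$death_observed, 1, NA),
                            death = rep(FALSE, nrow(coh)))
  expect_identical(fit_death_model(coh)$beta,
                   fit_cause_specific(relabelled)$beta)
})

test_that("degenerate death patterns are flagged, not fatal", {
  nodeath <- make_cohort(arm = 0:1, followup = c(2, 3),
                         event_time = c(1, NA))
  dm <- fit_death_model(nodeath)
  expect_true(dm$degenerate)
  expect_identical(survival_death(dm, c(0, 1, 5), z = 1), c(1, 1, 1))

  onearm <- make_cohort(arm = c(1, 1, 0, 0), followup = c(1, 2, 3, 3),
                        death = c(TRUE, TRUE, FALSE, FALSE))
  dm <- fit_death_model(onearm)
  expect_false(dm$converged)
  expect_true(dm$capped)
  expect_equal(abs(dm$beta), 20)
})

test_that("survival_death evaluates exp(-Lambda0 e^(beta z)) with left limits", {
  coh <- make_cohort(arm = c(0, 0, 1, 1), followup = c(1, 2, 1.5, 2),
                     death = c(TRUE, FALSE, TRUE, FALSE))
  dm <- fit_death_model(coh)
  expect_identical(survival_death(dm, 0, 0), 1)
  # manual Breslow reconstruction
  eb <- exp(dm$beta)
  jumps <- c(1 / (2 + 2 * eb), 1 / (1 + 2 * eb))
  expect_equal(dm$cumhaz, cumsum(jumps), tolerance = 1e-12)
  expect_equal(survival_death(dm, 1.7, 1), exp(-sum(jumps) * eb),
               tolerance = 1e-12)
  # at a death time the left limit excludes that jump
  expect_equal(survival_death(dm, 1.5, 0, left = TRUE), exp(-jumps[1]),
               tolerance = 1e-12)
  expect_equal(survival_death(dm, 1.5, 0), exp(-sum(jumps)),
               tolerance = 1e-12)
  t <- sort(runif(20, 0, 3))
  expect_true(all(diff(survival_death(dm, t, 1)) <= 0))
  expect_error(survival_death(dm, -1, 0), "nonnegative")
})

test_that("conditional event survival counts subjects under observation", {
  expect_identical(
    conditional_event_survival(random_cohort(30, 5), 0, z = 0), 1)
  # 4 subjects followed past t, one with an event before t
  coh <- make_cohort(arm = rep(0, 4), followup = rep(3, 4),
                     event_time = c(0.5, NA, NA, NA))
  expect_identical(conditional_event_survival(coh, 1, z = 0), 0.75)
  expect_error(conditional_event_survival(coh, 4, z = 0), "empty risk set")

  # enumeration oracle on a 10-subject fixture
  coh <- random_cohort(10, seed = 9)
  for (t in c(0.2, 0.7, 1.1)) {
    for (z in 0:1) {
      under <- which(coh$arm == z & coh$followup_time > t)
      if (!length(under)) next
      ok <- 0
      for (i in under) {
        if (!(coh$event_observed[i] && coh$event_time[i] <= t)) ok <- ok + 1
      }
      expect_identical(conditional_event_survival(coh, t, z),
                       ok / length(under))
    }
  }
})

test_that("marginal evaluators start at 1, are nonincreasing, and respect the floor", {
  coh <- random_cohort(50, seed = 31)
  marg <- marginal_estimates(coh)
  grid <- seq(0, max(coh$followup_time) + 1, length.out = 60)
  for (z in 0:1) {
    st <- marg$event_conditional_survival(grid, z)
    sy <- marg$death_survival(grid, z)
    expect_identical(st[1], 1)
    expect_identical(sy[1], 1)
    expect_true(all(diff(st) <= 0))
    expect_true(all(diff(sy) <= 0))
    expect_true(all(st >= marg$eps) && all(sy >= marg$eps))
  }
})
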