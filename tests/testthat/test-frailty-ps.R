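test_that("frailty inversions reproduce closed-form values and limits", {
  expect_identical(eta_from_death_survival(1, 0.3), 0)
  expect_equal(eta_from_death_survival(0.8, 2), 2 * (0.8^(-1 / 2) - 1),
               tolerance = 1e-12)
  # homogeneous limit: gamma (s^(-1/gamma) - 1) -> -log s
  expect_equal(eta_from_death_survival(0.5, 1e6), log(2), tolerance = 1e-6)
  expect_error(eta_from_death_survival(0, 1), "\\(0, 1\\]")
  expect_error(eta_from_death_survival(1.2, 1), "\\(0, 1\\]")
  expect_error(eta_from_death_survival(0.5, -1), "positive")

  expect_identical(eta_from_event_survival(1, 3, 2), 0)
  expect_equal(eta_from_event_survival(0.8, 0, 2),
               eta_from_death_survival(0.8, 2), tolerance = 1e-14)
  expect_equal(eta_from_event_survival(0.9, 0.5, 1), 1.5 * (1 / 0.9 - 1),
               tolerance = 1e-12)
  expect_error(eta_from_event_survival(0.9, -0.1, 1), ">= 0")

  # increasing hazard as survival drops
  s <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(eta_from_death_survival(s, 0.7)) < 0))
})

test_that("principal-stratum probabilities follow the gamma closed forms", {
  expect_identical(ps_probability(2.3, 0, 0.8), 1)
  expect_identical(ps_probability(2.3, 0, 0.8, case = "event_at_tj"), 1)
  # gamma=1, eta_T=1, eta_Ycf=2: A = 1/2
  expect_equal(ps_probability(1, 2, 1), 0.5, tolerance = 1e-14)
  expect_equal(ps_probability(1, 2, 1, case = "event_at_tj"), 0.25,
               tolerance = 1e-14)
  # homogeneous limit A^gamma -> exp(-eta_Ycf), both cases
  expect_equal(ps_probability(0.7, 0.3, 1e6), exp(-0.3), tolerance = 1e-6)
  expect_equal(ps_probability(0.7, 0.3, 1e6, case = "event_at_tj"),
               exp(-0.3), tolerance = 1e-6)
  expect_error(ps_probability(-1, 0.3, 1), ">= 0")
  # event-time case is the at-risk case times one extra factor of A
  a <- (2 + 0.4) / (2 + 0.9 + 0.4)
  expect_equal(ps_probability(0.4, 0.9, 2, case = "event_at_tj"),
               ps_probability(0.4, 0.9, 2) * a, tolerance = 1e-14)
})

test_that("weight table reduces to unit Cox risk sets without mortality", {
  coh <- make_cohort(arm = rep(0:1, 5), followup = rep(4, 10),
                     event_time = c(0.3, 0.9, 1.4, NA, 2.2, NA, 0.7, 1.9,
                                    NA, 3.1))
  tab <- build_weight_table(coh, gamma = 0.5)
  expect_identical(unique(tab$p), 1)
  unit <- unit_weight_table(coh)
  expect_identical(tab$j, unit$j)
  expect_identical(tab$z, unit$z)
  expect_identical(tab$is_event, unit$is_event)
})

test_that("every event subject belongs to its own risk set with weights in (0,1]", {
  coh <- random_cohort(60, seed = 17)
  tab <- build_weight_table(coh, gamma = 1)
  expect_true(all(tab$p > 0 & tab$p <= 1))
  m <- length(tab$times)
  expect_identical(sort(unique(tab$j[tab$is_event])), seq_len(m))
  # case-1 entries never exceed the case-2 weight of the same stratum
  df <- as.data.frame(tab)
  for (j in which(tabulate(tab$j) > 1)) {
    rows <- df[df$time == tab$times[j], ]
    for (z in unique(rows$arm)) {
      sub <- rows[rows$arm == z, ]
      if (any(sub$case == "event_at_tj") && any(sub$case == "at_risk")) {
        expect_lte(max(sub$weight[sub$case == "event_at_tj"]),
                   min(sub$weight[sub$case == "at_risk"]) + 1e-14)
      }
    }
  }
})

test_that("weights match an independent straight-line recomputation on a hand-made cohort", {
  # 6 subjects, 2 deaths, 3 events; everything recomputed from first
  # principles below with survival::coxph supplying the death model
  coh <- make_cohort(arm = c(0, 0, 0, 1, 1, 1),
                     followup = c(1.0, 2.5, 3.0, 1.8, 3.0, 2.2),
                     event_time = c(0.6, 1.2, NA, NA, 2.0, NA),
                     death = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  gam <- 0.8
  n <- 6
  eps <- 1 / (2 * n)
  tab <- as.data.frame(build_weight_table(coh, gamma = gam))

  f <- suppressWarnings(survival::coxph(
    survival::Surv(followup_time, death_observed) ~ arm, data = coh,
    ties = "breslow", control = survival::coxph.control(eps = 1e-14)))
  bh <- survival::basehaz(f, centered = FALSE)
  lam0_left <- function(t) {
    keep <- bh$time < t
    if (any(keep)) max(bh$hazard[keep]) else 0
  }
  s_y <- function(t, z) max(eps, exp(-lam0_left(t) * exp(coef(f) * z)))
  s_t_raw <- function(t, z) { # right-continuous raw ratio
    sel <- coh$arm == z
    den <- sum(sel & coh$followup_time > t)
    num <- sum(sel & coh$followup_time > t &
                 !(coh$event_observed & !is.na(coh$event_time) &
                     coh$event_time <= t))
    if (den > 0) num / den else 1
  }
  # the ratio jumps only where a follow-up ends or an event occurs
  jump_pts <- sort(unique(c(coh$followup_time,
                            coh$event_time[coh$event_observed])))
  s_grid <- sort(unique(coh$event_time[coh$event_observed]))
  for (j in seq_along(s_grid)) {
    tj <- s_grid[j]
    for (i in seq_len(n)) {
      at_risk_time <- if (coh$event_observed[i]) coh$event_time[i] else
        coh$followup_time[i]
      if (at_risk_time < tj) next
      z <- coh$arm[i]
      # left limit at tj of the running minimum of the raw ratio
      before <- jump_pts[jump_pts < tj]
      st <- max(eps, min(1, vapply(before, s_t_raw, numeric(1), z = z)))
      ey_own <- gam * (s_y(tj, z)^(-1 / gam) - 1)
      ey_cf <- gam * (s_y(tj, 1 - z)^(-1 / gam) - 1)
      et <- (gam + ey_own) * (st^(-1 / gam) - 1)
      a <- (gam + et) / (gam + ey_cf + et)
      expected <- a^(gam + (coh$event_observed[i] &&
                              coh$event_time[i] == tj))
      got <- tab$weight[tab$time == tj &
                          tab$subject_id == coh$subject_id[i]]
      # tolerance bounded by coxph's own convergence precision on beta
      expect_equal(got, expected, tolerance = 1e-7,
                   label = sprintf("p(subject %d, t=%.1f)", i, tj))
    }
  }
})

test_that("weights approach the counterfactual death survival as gamma grows", {
  coh <- random_cohort(80, seed = 23)
  dm <- fit_death_model(coh)
  tab <- build_weight_table(coh, gamma = 1e6)
  target <- survival_death(dm, tab$times[tab$j], 1 - tab$z, left = TRUE)
  expect_lt(max(abs(tab$p - target)), 1e-4)
})

test_that("weights are invariant to row order and subject relabeling", {
  coh <- random_cohort(40, seed = 29)
  tab1 <- as.data.frame(build_weight_table(coh, gamma = 0.7))
  set.seed(1)
  perm <- sample(nrow(coh))
  shuffled <- coh[perm, ]
  shuffled$subject_id <- sprintf("relabel%02d", seq_len(nrow(coh)))
  rownames(shuffled) <- NULL
  tab2 <- as.data.frame(build_weight_table(shuffled, gamma = 0.7))
  key1 <- order(tab1$time, coh$subject_id[match(tab1$subject_id,
                                                coh$subject_id)])
  tab2$orig <- coh$subject_id[perm][match(tab2$subject_id,
                                          shuffled$subject_id)]
  key2 <- order(tab2$time, tab2$orig)
  expect_equal(tab1$weight[key1], tab2$weight[key2], tolerance = 1e-14)
  expect_identical(tab1$time[key1], tab2$time[key2])
})
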