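## Semi-competing-risks simulator. Conditional on a subject-level frailty
## theta (mean 1, variance 1/gamma; gamma or inverse-Gaussian family), death
## is exponential with arm rate theta * nu_z, loss to follow-up is
## exponential with rate nu_c, follow-up is capped at tau, and the first
## nonfatal event is drawn by inverting theta * eta_Tz(t) = -log U. The
## placebo event hazard is linear, eta_T0(t) = phi t; the treated-arm
## eta_T1 is constructed so the marginal principal-stratum hazard ratio is
## exactly r under the gamma frailty.

#' Simulation configuration
#'
#' Bundles and validates the generator parameters. The defaults are the
#' common operating conditions of the validation study: placebo conditional
#' death rate `nu0 = 0.25`, active `nu1 = 0.2`, loss to follow-up
#' `nu_c = 0.03`, administrative cap `tau = 2`, placebo event-hazard slope
#' `phi = 2`, target principal-stratum hazard ratio `r = 0.5`, frailty
#' dispersion `gamma = 2`, `n = 300` subjects with 1:1 allocation. Times are
#' in the same (arbitrary) unit throughout, e.g. years.
#'
#' @param nu0,nu1 Arm-specific conditional death rates (`>= 0`; 0 disables
#'   death in that arm).
#' @param nu_c Loss-to-follow-up rate (`>= 0`).
#' @param tau Administrative follow-up cap (`> 0`).
#' @param phi Placebo-arm event-hazard slope (`> 0`).
#' @param r Target marginal principal-stratum hazard ratio (`> 0`).
#' @param gamma Frailty dispersion (`> 0`); frailty variance is `1/gamma`.
#' @param frailty_family `"gamma"` or `"inverse_gaussian"`.
#' @param n Cohort size (`>= 2`).
#' @param allocation Length-2 arm ratio, default `c(1, 1)`; allocation is
#'   deterministic (exact counts), not Bernoulli.
#' @param seed Optional default seed used by [simulate_cohort()].
#' @return A `ppsh_sim_config` list.
#' @export
simulation_config <- function(nu0 = 0.25, nu1 = 0.2, nu_c = 0.03, tau = 2,
                              phi = 2, r = 0.5, gamma = 2,
                              frailty_family = c("gamma", "inverse_gaussian"),
                              n = 300L, allocation = c(1, 1), seed = NULL) {
  frailty_family <- match.arg(frailty_family)
  stopifnot(nu0 >= 0, nu1 >= 0, nu_c >= 0, tau > 0, phi > 0, r > 0,
            gamma > 0, n >= 2, length(allocation) == 2,
            all(allocation > 0))
  if (nu0 + nu1 > 0 && abs(nu0 + nu1 + phi * (1 - r)) < 1e-12) {
    stop("r must differ from 1 + (nu0 + nu1) / phi")
  }
  structure(
    list(nu0 = nu0, nu1 = nu1, nu_c = nu_c, tau = tau, phi = phi, r = r,
         gamma = gamma, frailty_family = frailty_family, n = as.integer(n),
         allocation = allocation, seed = seed),
    class = "ppsh_sim_config")
}

#' Draw frailties with mean 1 and variance 1/gamma
#'
#' Gamma family: shape = rate = `gamma`. Inverse-Gaussian family: mean 1 and
#' shape `gamma` (variance `mean^3 / shape = 1/gamma`), sampled with the
#' Michael-Schucany-Haas transformation.
#'
#' @param n Number of draws.
#' @param gamma Dispersion (`> 0`).
#' @param family `"gamma"` or `"inverse_gaussian"`.
#' @param seed Optional seed.
#' @return Vector of `n` positive frailties.
#' @export
draw_frailty <- function(n, gamma, family = c("gamma", "inverse_gaussian"),
                         seed = NULL) {
  family <- match.arg(family)
  .check_gamma(gamma)
  if (!is.null(seed)) set.seed(seed)
  if (family == "gamma") {
    stats::rgamma(n, shape = gamma, rate = gamma)
  } else {
    .rinvgauss(n, mean = 1, shape = gamma)
  }
}

.rinvgauss <- function(n, mean, shape) {
  w <- stats::rnorm(n)^2
  x <- mean + mean^2 * w / (2 * shape) -
    mean / (2 * shape) * sqrt(4 * mean * shape * w + mean^2 * w^2)
  ifelse(stats::runif(n) <= mean / (mean + x), x, mean^2 / x)
}

#' Treated-arm conditional cumulative event hazard targeting ratio r
#'
#' With placebo event hazard `eta_T0(t) = phi t`, conditional death hazards
#' `nu_z t` and gamma frailty with dispersion `gamma`, the marginal
#' principal-stratum hazard of arm z is
#' `eta_Tz'(t) * gamma / (gamma + eta_Tz(t) + nu_Y t)` with
#' `nu_Y = nu0 + nu1`. This function returns the closed-form `eta_T1` that
#' makes the treated-to-placebo ratio of these hazards exactly `r` at every
#' `t`:
#' \deqn{\eta_{T1}(t) = \frac{\phi}{\nu_Y + \phi(1-r)}\left[(1-r)\,
#'   \gamma^{1-k} \{\gamma + (\phi+\nu_Y)t\}^{k} + \gamma(r-1) +
#'   \nu_Y r t\right], \quad k = \frac{r\phi}{\phi+\nu_Y}.}
#' Special cases: `phi t` when `r = 1`, and
#' `gamma^(1-r) (gamma + phi t)^r - gamma` when `nu_Y = 0`.
#'
#' @param t Nonnegative time(s).
#' @param phi Placebo event-hazard slope (`> 0`).
#' @param nu_y Total conditional death rate `nu0 + nu1` (`>= 0`).
#' @param gamma Frailty dispersion (`> 0`).
#' @param r Target hazard ratio (`> 0`, with `r != 1 + nu_y/phi`).
#' @return Nondecreasing cumulative hazard, 0 at `t = 0`.
#' @export
eta_event_treated <- function(t, phi, nu_y, gamma, r) {
  stopifnot(all(t >= 0), phi > 0, nu_y >= 0, gamma > 0, r > 0)
  if (r == 1) return(phi * t)
  den <- nu_y + phi * (1 - r)
  if (abs(den) < 1e-12) stop("r must differ from 1 + nu_y/phi")
  k <- r * phi / (phi + nu_y)
  (phi / den) * ((1 - r) * gamma^(1 - k) * (gamma + (phi + nu_y) * t)^k +
                   gamma * (r - 1) + nu_y * r * t)
}

#' Invert a cumulative hazard to draw an event time
#'
#' Solves `theta * eta(t) = -log(u)` for `t` by bracketed root-finding on
#' `[0, horizon]`. When even `theta * eta(horizon)` falls short of
#' `-log(u)`, the event does not occur within follow-up and `NA` is
#' returned. Monotonicity of `eta` is spot-checked on the bracket.
#'
#' @param theta Positive frailty.
#' @param u Uniform(0,1) draw.
#' @param eta Vectorized nondecreasing function with `eta(0) = 0`.
#' @param horizon Follow-up bound (`> 0`).
#' @param tol Absolute root tolerance, default `1e-12`.
#' @return The event time in `(0, horizon]`, or `NA` if none.
#' @export
invert_event_time <- function(theta, u, eta, horizon, tol = 1e-12) {
  stopifnot(theta > 0, u > 0, u < 1, horizon > 0)
  probe <- eta(seq(0, horizon, length.out = 5))
  if (any(diff(probe) < -1e-12) || abs(probe[1]) > 1e-12) {
    stop("eta must be nondecreasing with eta(0) = 0")
  }
  target <- -log(u) / theta
  if (probe[5] < target) return(NA_real_)
  stats::uniroot(function(t) eta(t) - target, lower = 0, upper = horizon,
                 tol = tol)$root
}

#' Simulate a semi-competing-risks cohort
#'
#' Allocates arms deterministically, draws per-subject frailties, death times
#' (exponential with rate `theta * nu_z`; no death when `nu_z = 0`),
#' loss-to-follow-up times, caps follow-up at `tau`, and inverts the
#' arm-specific conditional cumulative event hazard to obtain the first
#' nonfatal event, observed only if it falls within follow-up. The shared
#' frailty is the sole source of dependence between the processes. Setting
#' `nu0 = nu1 = 0` produces the hypothetical no-mortality cohort with
#' follow-up `min(C, tau)`.
#'
#' @param config A [simulation_config()].
#' @param seed Seed for this cohort; defaults to `config$seed`.
#' @param latent Attach the latent draws (`theta`, `latent_death`,
#'   `latent_censor`, `latent_event`) as extra columns? `latent_event` is
#'   recorded when the generated event fell within follow-up, `NA` otherwise.
#' @return A `ppsh_cohort` with attribute `"sim_config"`.
#' @export
simulate_cohort <- function(config, seed = config$seed, latent = TRUE) {
  stopifnot(inherits(config, "ppsh_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  n0 <- round(n * config$allocation[1] / sum(config$allocation))
  z <- rep(c(0L, 1L), c(n0, n - n0))
  theta <- draw_frailty(n, config$gamma, config$frailty_family)
  nu_z <- ifelse(z == 0, config$nu0, config$nu1)
  death <- rep(Inf, n)
  pos <- nu_z > 0
  death[pos] <- stats::rexp(sum(pos)) / (theta[pos] * nu_z[pos])
  censor <- if (config$nu_c > 0) stats::rexp(n) / config$nu_c else
    rep(Inf, n)
  fu <- pmin(death, censor, config$tau)
  u <- stats::runif(n)
  target <- -log(u) / theta
  nu_y <- config$nu0 + config$nu1
  tev <- rep(NA_real_, n)
  tev[z == 0] <- target[z == 0] / config$phi
  trt <- which(z == 1)
  if (config$r == 1 || nu_y == 0) {
    # closed-form inversion of eta_event_treated
    tev[trt] <- if (config$r == 1) target[trt] / config$phi else
      config$gamma *
        ((1 + target[trt] / config$gamma)^(1 / config$r) - 1) / config$phi
  } else {
    for (i in trt) {
      if (eta_event_treated(fu[i], config$phi, nu_y, config$gamma,
                            config$r) >= target[i]) {
        tev[i] <- stats::uniroot(
          function(t) eta_event_treated(t, config$phi, nu_y, config$gamma,
                                        config$r) - target[i],
          lower = 0, upper = fu[i], tol = 1e-12)$root
      }
    }
  }
  observed <- !is.na(tev) & tev <= fu
  df <- data.frame(
    subject_id = sprintf("s%05d", seq_len(n)), arm = z,
    event_time = ifelse(observed, tev, NA_real_),
    event_observed = observed, followup_time = fu,
    death_observed = is.finite(death) & death <= censor &
      death <= config$tau,
    stringsAsFactors = FALSE)
  if (latent) {
    df$theta <- theta
    df$latent_death <- death
    df$latent_censor <- censor
    df$latent_event <- tev
  }
  out <- as_cohort(df)
  attr(out, "sim_config") <- config
  out
}

#' Descriptive summary of simulated cohorts
#'
#' Per arm and averaged over replicates: the proportions dead
#' (follow-up ended in death), administratively censored (follow-up reached
#' the cap alive and uncensored), and lost to follow-up -- a partition of
#' every subject -- plus mean and median follow-up and the proportion with an
#' observed nonfatal event.
#'
#' @param cohorts A `ppsh_cohort` or list of them (replicates).
#' @param tau Administrative cap; taken from the first cohort's
#'   `"sim_config"` attribute when `NULL`.
#' @return Data frame with one row per arm.
#' @export
summarize_cohorts <- function(cohorts, tau = NULL) {
  if (inherits(cohorts, "ppsh_cohort")) cohorts <- list(cohorts)
  stopifnot(length(cohorts) >= 1)
  if (is.null(tau)) {
    cfg <- attr(cohorts[[1]], "sim_config")
    if (is.null(cfg)) stop("tau must be supplied for non-simulated cohorts")
    tau <- cfg$tau
  }
  per <- lapply(cohorts, function(coh) {
    do.call(rbind, lapply(0:1, function(zz) {
      s <- coh[coh$arm == zz, ]
      dead <- s$death_observed
      admin <- !dead & s$followup_time >= tau
      data.frame(arm = zz, dead = mean(dead), censored = mean(admin),
                 lof = mean(!dead & !admin),
                 mean_followup = mean(s$followup_time),
                 median_followup = stats::median(s$followup_time),
                 event = mean(s$event_observed))
    }))
  })
  arr <- Reduce(`+`, per) / length(per)
  arr$arm <- per[[1]]$arm
  arr
}

#' Run the simulation study
#'
#' For each replicate, generates the semi-competing-risks cohort and
#' (optionally) an independent hypothetical no-mortality cohort
#' (`nu0 = nu1 = 0`, follow-up `min(C, tau)`), then fits the hypothetical
#' Cox model, the cause-specific Cox model, and the PS model at each value of
#' `gamma_tilde`. Reports, per estimator, the Monte-Carlo mean of `beta`,
#' its bias, the Monte-Carlo standard error (SD of the estimates divided by
#' the square root of the replicate count) and `HR = exp(mean beta)`. Under
#' the gamma frailty family the reference value is `log(r)`; under the
#' inverse-Gaussian family the generator is not exactly proportional on the
#' PS scale, so bias is measured against the hypothetical-cohort mean
#' instead. Non-converged replicates are dropped and counted.
#'
#' @param config A [simulation_config()].
#' @param reps Number of replicates (`>= 1`).
#' @param gamma_tilde Grid of dispersions for the PS fits.
#' @param seed Master seed; every cohort gets its own derived sub-seed.
#' @param hypothetical,cause_specific Toggle the reference fits.
#' @return A `ppsh_sim_study`: `estimates` (one row per estimator),
#'   `descriptives` (per-arm averages for the mortality cohorts), `reps`,
#'   `config`.
#' @export
run_simulation_study <- function(config, reps = 1000L,
                                 gamma_tilde = c(0.5, 2, 5), seed = NULL,
                                 hypothetical = TRUE, cause_specific = TRUE) {
  stopifnot(inherits(config, "ppsh_sim_config"), reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  seeds <- matrix(sample.int(2147483646L, 2L * reps), nrow = 2L)
  hyp_config <- config
  hyp_config$nu0 <- hyp_config$nu1 <- 0
  gl <- length(gamma_tilde)
  ps_b <- matrix(NA_real_, reps, gl)
  cs_b <- hyp_b <- rep(NA_real_, reps)
  desc <- vector("list", reps)
  grab <- function(fit) if (!is.null(fit) && fit$converged) fit$beta else
    NA_real_
  for (k in seq_len(reps)) {
    coh <- simulate_cohort(config, seed = seeds[1L, k])
    desc[[k]] <- summarize_cohorts(coh)
    if (hypothetical) {
      hyp <- simulate_cohort(hyp_config, seed = seeds[2L, k])
      hyp_b[k] <- grab(tryCatch(fit_cause_specific(hyp),
                                error = function(e) NULL))
    }
    if (cause_specific) {
      cs_b[k] <- grab(tryCatch(fit_cause_specific(coh),
                               error = function(e) NULL))
    }
    if (gl) {
      marg <- tryCatch(marginal_estimates(coh), error = function(e) NULL)
      if (!is.null(marg)) {
        for (g in seq_len(gl)) {
          ps_b[k, g] <- grab(tryCatch(
            fit_ppsh(build_weight_table(coh, gamma_tilde[g], marg)),
            error = function(e) NULL))
        }
      }
    }
  }
  truth <- if (config$frailty_family == "gamma") log(config$r) else
    mean(hyp_b, na.rm = TRUE)
  row <- function(label, gt, b, ref) {
    ok <- b[!is.na(b)]
    data.frame(
      estimator = label, gamma_tilde = gt, mean_beta = mean(ok),
      bias = mean(ok) - ref,
      se = if (length(ok) > 1) stats::sd(ok) / sqrt(length(ok)) else
        NA_real_,
      hr = exp(mean(ok)), n_converged = length(ok),
      n_failed = sum(is.na(b)), stringsAsFactors = FALSE)
  }
  est <- list()
  if (hypothetical) est <- c(est, list(row("hypothetical", NA, hyp_b,
                                           log(config$r))))
  if (cause_specific) est <- c(est, list(row("cause_specific", Inf, cs_b,
                                             truth)))
  for (g in seq_len(gl)) {
    est <- c(est, list(row("principal_stratum", gamma_tilde[g], ps_b[, g],
                           truth)))
  }
  estimates <- do.call(rbind, est)
  rownames(estimates) <- NULL
  descriptives <- Reduce(`+`, lapply(desc, as.matrix)) / reps
  descriptives <- as.data.frame(descriptives)
  descriptives$arm <- c(0, 1)
  structure(
    list(estimates = estimates, descriptives = descriptives,
         reps = as.integer(reps), gamma_tilde = gamma_tilde,
         config = config, seed = seed),
    class = "ppsh_sim_study")
}

#' @export
print.ppsh_sim_study <- function(x, digits = 3, ...) {
  cat(sprintf(
    "Simulation study: %d replicates, n = %d, %s frailty (gamma = %g)\n",
    x$reps, x$config$n, x$config$frailty_family, x$config$gamma))
  cat(sprintf("  nu0 = %g, nu1 = %g, nu_c = %g, tau = %g, phi = %g, r = %g\n",
              x$config$nu0, x$config$nu1, x$config$nu_c, x$config$tau,
              x$config$phi, x$config$r))
  cat("\nPer-arm descriptives (averaged over replicates):\n")
  print(cbind(arm = x$descriptives$arm,
              round(x$descriptives[setdiff(names(x$descriptives), "arm")],
                    digits)))
  cat("\nEstimators:\n")
  est <- x$estimates
  est$mean_beta <- round(est$mean_beta, digits)
  est$bias <- round(est$bias, digits)
  est$se <- round(est$se, digits + 1)
  est$hr <- round(est$hr, digits)
  print(est)
  invisible(x)
}

#' @export
print.ppsh_sim_config <- function(x, ...) {
  cat("Semi-competing-risks simulation configuration\n")
  cat(sprintf(
    "  n = %d (%g:%g), %s frailty gamma = %g (variance %g)\n",
    x$n, x$allocation[1], x$allocation[2], x$frailty_family, x$gamma,
    1 / x$gamma))
  cat(sprintf(
    "  death rates nu0 = %g, nu1 = %g; censoring nu_c = %g, cap tau = %g\n",
    x$nu0, x$nu1, x$nu_c, x$tau))
  cat(sprintf("  event hazard slope phi = %g, target PS hazard ratio r = %g\n",
              x$phi, x$r))
  invisible(x)
}
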