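## Stage-one marginal building blocks: a Cox (Breslow) fit for death giving
## S_Y(t|z) = exp(-Lambda0(t) e^{beta z}), and the nonparametric conditional
## event survival S_T(t | alive at t, z) as a ratio of counts among subjects
## still under observation.

#' Fit the proportional hazards model for death
#'
#' Fits time-to-death (outcome `followup_time`, event flag `death_observed`)
#' on the treatment arm with the package's Newton-Raphson partial-likelihood
#' fitter (Breslow ties) and computes the Breslow baseline cumulative hazard.
#' This is the same machinery used for the weighted principal-stratum fit, so
#' unit-weight behaviour is shared across the package.
#'
#' Degenerate inputs are handled rather than refused: a cohort with no deaths
#' returns a flagged model with `beta = 0` and a flat baseline (so death
#' survival is identically 1), and a cohort with all deaths in a single arm
#' returns a non-converged model with `beta` capped.
#'
#' @param cohort A validated `ppsh_cohort` with at least one subject per arm.
#' @return A `ppsh_death_model`: list with `beta` (log hazard ratio of arm on
#'   death), `times`/`cumhaz` (Breslow baseline step function), `n_deaths`,
#'   and flags `degenerate`, `converged`, `capped`.
#' @export
fit_death_model <- function(cohort) {
  .check_two_arms(cohort)
  time <- cohort$followup_time
  status <- cohort$death_observed
  z <- cohort$arm
  n_deaths <- sum(status)
  if (n_deaths == 0) {
    return(structure(
      list(beta = 0, times = numeric(), cumhaz = numeric(),
           n_deaths = 0L, degenerate = TRUE, converged = TRUE,
           capped = FALSE),
      class = "ppsh_death_model"))
  }
  fit <- fit_ppsh(.risk_table(time, status, z, cohort$subject_id))
  beta <- fit$beta
  yk <- sort(unique(time[status]))
  dk <- vapply(yk, function(t) sum(status & time == t), numeric(1))
  denom <- vapply(yk, function(t) sum(exp(beta * z[time >= t])), numeric(1))
  structure(
    list(beta = beta, times = yk, cumhaz = cumsum(dk / denom),
         n_deaths = as.integer(n_deaths), degenerate = FALSE,
         converged = fit$converged, capped = fit$capped),
    class = "ppsh_death_model")
}

.check_two_arms <- function(cohort) {
  if (!any(cohort$arm == 0) || !any(cohort$arm == 1)) {
    stop("fit requires at least one subject in each arm")
  }
  invisible(TRUE)
}

#' Death survival function from a fitted death model
#'
#' Evaluates `S_Y(t|z) = exp(-Lambda0(t) exp(beta z))`. With `left = TRUE`
#' the baseline is evaluated at `t-` (jumps strictly before `t`), the variant
#' used at event times so that deaths at an event time do not enter its own
#' risk weights.
#'
#' @param model A `ppsh_death_model` from [fit_death_model()].
#' @param t Nonnegative time(s).
#' @param z Arm code, 0 or 1 (scalar or vector matching `t`).
#' @param left Evaluate the left limit `S_Y(t-|z)`?
#' @return Survival probabilities in `(0, 1]`; 1 at `t = 0`.
#' @export
survival_death <- function(model, t, z, left = FALSE) {
  stopifnot(inherits(model, "ppsh_death_model"))
  if (any(t < 0)) stop("t must be nonnegative")
  idx <- findInterval(t, model$times, left.open = left)
  lam <- c(0, model$cumhaz)[idx + 1L]
  exp(-lam * exp(model$beta * z))
}

#' Nonparametric conditional survival of the nonfatal event
#'
#' Estimates `S_T(t | Y > t, z)` as the fraction, among arm-`z` subjects
#' still under observation at `t` (follow-up beyond `t`), of those with no
#' nonfatal event by `t`. Follow-up continues past a nonfatal event in this
#' data model, so "under observation" tracks survival-and-uncensored status
#' regardless of the event.
#'
#' This is the raw ratio; the monotone-clamped, floored version used in the
#' weight chain lives in [marginal_estimates()].
#'
#' @param cohort A validated `ppsh_cohort`.
#' @param t Nonnegative time(s).
#' @param z Arm code, 0 or 1.
#' @param left Use the left-limit convention (subjects with follow-up or
#'   event exactly at `t` still count as at risk / event-free)?
#' @return Proportions in `[0, 1]`; errors when no arm-`z` subject remains
#'   under observation at some `t`.
#' @export
conditional_event_survival <- function(cohort, t, z, left = FALSE) {
  if (any(t < 0)) stop("t must be nonnegative")
  sel <- cohort$arm == z
  fu <- cohort$followup_time[sel]
  ev <- cohort$event_observed[sel]
  et <- cohort$event_time[sel]
  vapply(t, function(s) {
    under <- if (left) fu >= s else fu > s
    if (!any(under)) {
      stop("empty risk set: no arm-", z, " subject under observation at t = ",
           s)
    }
    had_event <- if (left) ev & !is.na(et) & et < s else ev & !is.na(et) & et <= s
    sum(under & !had_event) / sum(under)
  }, numeric(1))
}

#' Marginal survival estimates for the weight chain
#'
#' Bundles the two stage-one marginal estimators: the Cox-based death
#' survival and the nonparametric conditional event survival, the latter
#' precomputed on each arm's jump grid, clamped to be nonincreasing (running
#' minimum) and floored at `eps` so the downstream frailty transforms stay
#' finite.
#'
#' @param cohort A validated `ppsh_cohort`.
#' @param eps Floor applied to both survival curves; defaults to `1/(2n)`.
#' @return A `ppsh_marginals` object with evaluator functions
#'   `death_survival(t, z, left)` and `event_conditional_survival(t, z,
#'   left)`, the fitted `death_model`, and the per-arm step curves.
#' @export
marginal_estimates <- function(cohort, eps = 1 / (2 * nrow(cohort))) {
  .check_two_arms(cohort)
  dm <- fit_death_model(cohort)
  curves <- lapply(0:1, function(zz) {
    sel <- cohort$arm == zz
    fu <- cohort$followup_time[sel]
    ev <- cohort$event_observed[sel]
    et <- cohort$event_time[sel]
    knots <- sort(unique(c(fu, et[ev])))
    den <- vapply(knots, function(s) sum(fu > s), numeric(1))
    num <- vapply(knots, function(s) sum(fu > s & !(ev & !is.na(et) & et <= s)),
                  numeric(1))
    val <- ifelse(den > 0, num / den, NA_real_)
    # beyond the last follow-up the ratio is undefined; carry the last value
    for (k in seq_along(val)) {
      if (is.na(val[k])) val[k] <- if (k > 1) val[k - 1] else 1
    }
    list(knots = knots, values = pmax(cummin(val), eps))
  })
  obj <- list(death_model = dm, curves = curves, eps = eps, n = nrow(cohort))
  obj$death_survival <- function(t, z, left = FALSE) {
    pmax(survival_death(dm, t, z, left = left), eps)
  }
  obj$event_conditional_survival <- function(t, z, left = FALSE) {
    cv <- curves[[z + 1L]]
    idx <- findInterval(t, cv$knots, left.open = left)
    c(1, cv$values)[idx + 1L]
  }
  structure(obj, class = "ppsh_marginals")
}

#' @export
as.data.frame.ppsh_marginals <- function(x, ...) {
  do.call(rbind, lapply(0:1, function(z) {
    cv <- x$curves[[z + 1L]]
    data.frame(arm = z, time = cv$knots,
               death_survival = x$death_survival(cv$knots, z),
               event_conditional_survival = cv$values)
  }))
}

#' @export
print.ppsh_death_model <- function(x, ...) {
  cat("Cox model for death (Breslow ties)\n")
  if (x$degenerate) {
    cat("  no deaths observed: S_Y(t|z) = 1 for all t\n")
  } else {
    cat(sprintf("  deaths: %d   log HR (arm): %.4f   HR: %.4f%s\n",
                x$n_deaths, x$beta, exp(x$beta),
                if (!x$converged) "  [not converged]" else ""))
  }
  invisible(x)
}
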