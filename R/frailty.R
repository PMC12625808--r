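## Shared-gamma-frailty identification of principal-stratum ("always
## survivor") membership probabilities. With frailty theta ~ Gamma(gamma,
## gamma) (mean 1, variance 1/gamma), marginal survival S relates to the
## conditional (theta = 1) cumulative hazard eta by S = {gamma/(gamma+eta)}^gamma,
## which inverts in closed form; membership probabilities then follow from
## the gamma Laplace transform.

#' Conditional cumulative hazard of death from marginal survival
#'
#' Inverts the gamma-frailty relation for death:
#' `eta = gamma * (s^(-1/gamma) - 1)`, the cumulative hazard of death given
#' frailty 1 that reproduces marginal survival `s`. As `gamma` grows this
#' tends to `-log(s)` (homogeneous population).
#'
#' @param s Marginal death survival probability in `(0, 1]`.
#' @param gamma Frailty dispersion `gamma > 0` (frailty variance `1/gamma`).
#' @return Nonnegative cumulative hazard, 0 iff `s = 1`.
#' @export
eta_from_death_survival <- function(s, gamma) {
  .check_gamma(gamma)
  if (any(s <= 0 | s > 1)) stop("s must lie in (0, 1]")
  gamma * expm1(-log(s) / gamma)
}

#' Conditional cumulative hazard of the nonfatal event
#'
#' Same inversion for the nonfatal event, accounting for the competing risk
#' of death: conditioning on survival tilts the frailty distribution, so the
#' scale becomes `gamma + eta_death`:
#' `eta = (gamma + eta_death) * (s^(-1/gamma) - 1)`, with `s` the conditional
#' event survival `S_T(t | Y > t, z)` and `eta_death` the same-arm death
#' hazard from [eta_from_death_survival()]. Reduces to the death form when
#' `eta_death = 0`.
#'
#' @param s Conditional event survival in `(0, 1]`.
#' @param eta_death_same_arm Nonnegative conditional cumulative death hazard
#'   of the same arm at the same time.
#' @param gamma Frailty dispersion.
#' @return Nonnegative cumulative hazard, 0 iff `s = 1`.
#' @export
eta_from_event_survival <- function(s, eta_death_same_arm, gamma) {
  .check_gamma(gamma)
  if (any(s <= 0 | s > 1)) stop("s must lie in (0, 1]")
  if (any(eta_death_same_arm < 0)) stop("eta_death_same_arm must be >= 0")
  (gamma + eta_death_same_arm) * expm1(-log(s) / gamma)
}

#' Principal-stratum membership probability
#'
#' Probability that a subject at risk at an event time would also be alive
#' under the counterfactual arm, under the shared gamma frailty. With
#' `A = (gamma + eta_T) / (gamma + eta_Y_cf + eta_T)` the closed forms are
#' `A^(gamma+1)` for the subject whose event occurs at that time
#' (`case = "event_at_tj"`; conditioning on the event tilts the frailty once
#' more) and `A^gamma` for other at-risk subjects (`case = "at_risk"`).
#' As `gamma` grows both tend to `exp(-eta_Y_cf)`.
#'
#' @param eta_event_own_arm Conditional cumulative event hazard of the
#'   subject's own arm at the event time (left limit).
#' @param eta_death_counterfactual_arm Conditional cumulative death hazard of
#'   the opposite arm at the event time.
#' @param gamma Frailty dispersion.
#' @param case `"at_risk"` (default) or `"event_at_tj"`.
#' @return Probability in `(0, 1]`; equals 1 iff the counterfactual death
#'   hazard is 0.
#' @export
ps_probability <- function(eta_event_own_arm, eta_death_counterfactual_arm,
                           gamma, case = c("at_risk", "event_at_tj")) {
  case <- match.arg(case)
  .check_gamma(gamma)
  if (any(eta_event_own_arm < 0) || any(eta_death_counterfactual_arm < 0)) {
    stop("cumulative hazards must be >= 0")
  }
  log_a <- log1p(-eta_death_counterfactual_arm /
                   (gamma + eta_death_counterfactual_arm + eta_event_own_arm))
  exp((gamma + (case == "event_at_tj")) * log_a)
}

.check_gamma <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1 || !is.finite(gamma) ||
      gamma <= 0) {
    stop("gamma must be a single positive number")
  }
  invisible(TRUE)
}

#' Build the principal-stratum weight table
#'
#' For every distinct nonfatal event time `t_j` and every subject in the
#' at-risk set (alive, uncensored, and event-free just before `t_j`),
#' computes the membership probability `p_ij` by chaining the marginal
#' estimates through [eta_from_death_survival()], [eta_from_event_survival()]
#' and [ps_probability()]. All marginal curves are evaluated at the left
#' limit `t_j-`, so a subject's own event does not enter its weight. Subjects
#' whose event occurs at `t_j` get the `"event_at_tj"` closed form; all other
#' members get `"at_risk"`. Tied events share the same risk set (Breslow
#' convention).
#'
#' @param cohort A validated `ppsh_cohort` with at least one observed event.
#' @param gamma Prespecified frailty dispersion `gamma > 0` (the sensitivity
#'   parameter; variance of the frailty is `1/gamma`).
#' @param marginals Optional precomputed [marginal_estimates()] for the same
#'   cohort (they do not depend on `gamma`, so reuse them across a grid).
#' @return A `ppsh_weight_table`; use [as.data.frame()] for the long-format
#'   audit view `(time, subject_id, arm, case, weight)`.
#' @export
build_weight_table <- function(cohort, gamma, marginals = NULL) {
  .check_gamma(gamma)
  .check_two_arms(cohort)
  if (is.null(marginals)) marginals <- marginal_estimates(cohort)
  s_times <- event_times(cohort)
  if (!length(s_times)) stop("cohort contains no observed nonfatal events")

  s_y <- vapply(0:1, function(z)
    marginals$death_survival(s_times, z, left = TRUE), numeric(length(s_times)))
  s_t <- vapply(0:1, function(z)
    marginals$event_conditional_survival(s_times, z, left = TRUE),
    numeric(length(s_times)))
  dim(s_y) <- dim(s_t) <- c(length(s_times), 2L)
  eta_y <- apply(s_y, 2, eta_from_death_survival, gamma = gamma)
  eta_t <- vapply(1:2, function(k)
    eta_from_event_survival(s_t[, k], eta_y[, k], gamma),
    numeric(length(s_times)))
  dim(eta_y) <- dim(eta_t) <- c(length(s_times), 2L)

  str <- .risk_sets(cohort)
  zi <- cohort$arm[str$idx]
  own <- eta_t[cbind(str$j, zi + 1L)]
  cf <- eta_y[cbind(str$j, 2L - zi)]
  p <- ps_probability(own, cf, gamma)
  p[str$is_event] <- ps_probability(own[str$is_event], cf[str$is_event],
                                    gamma, case = "event_at_tj")
  structure(
    list(times = s_times, j = str$j, subject = cohort$subject_id[str$idx],
         z = as.numeric(zi), p = p, is_event = str$is_event,
         gamma = gamma, n = nrow(cohort)),
    class = "ppsh_weight_table")
}

## Risk-set structure shared by the weighted and unit-weight tables: a
## subject is at risk at t_j while its first-event-or-follow-up time is
## >= t_j (ties between censoring and an event resolved as
## censoring-after-event, the standard Cox convention).
.risk_sets <- function(cohort) {
  time_at_risk <- ifelse(cohort$event_observed, cohort$event_time,
                         cohort$followup_time)
  s_times <- event_times(cohort)
  m <- length(s_times)
  js <- idxs <- evs <- vector("list", m)
  for (j in seq_len(m)) {
    at <- which(time_at_risk >= s_times[j])
    js[[j]] <- rep.int(j, length(at))
    idxs[[j]] <- at
    evs[[j]] <- cohort$event_observed[at] &
      cohort$event_time[at] == s_times[j]
  }
  list(j = unlist(js), idx = unlist(idxs),
       is_event = unlist(evs) %in% TRUE)
}

#' Unit-weight risk table for a cause-specific fit
#'
#' The same risk-set structure as [build_weight_table()] with every weight
#' set to 1: the ordinary Cox (Breslow) partial likelihood for the nonfatal
#' event with death relabelled as censoring. Feeding it to [fit_ppsh()]
#' reproduces a standard Cox fit; it is also the input for the
#' proportionality test of a cause-specific model.
#'
#' @param cohort A validated `ppsh_cohort` with at least one observed event.
#' @return A `ppsh_weight_table` with all weights 1 (`gamma = Inf`).
#' @export
unit_weight_table <- function(cohort) {
  if (!length(event_times(cohort))) {
    stop("cohort contains no observed nonfatal events")
  }
  str <- .risk_sets(cohort)
  structure(
    list(times = event_times(cohort), j = str$j,
         subject = cohort$subject_id[str$idx],
         z = as.numeric(cohort$arm[str$idx]),
         p = rep(1, length(str$j)), is_event = str$is_event,
         gamma = Inf, n = nrow(cohort)),
    class = "ppsh_weight_table")
}

## Generic single-binary-covariate Cox risk table (used for the death fit),
## sharing .risk_sets via a minimal synthetic cohort.
.risk_table <- function(time, status, z, subject) {
  coh <- data.frame(subject_id = subject, arm = z,
                    event_time = ifelse(status, time, NA_real_),
                    event_observed = status, followup_time = time,
                    death_observed = FALSE)
  class(coh) <- c("ppsh_cohort", "data.frame")
  unit_weight_table(coh)
}

#' @export
as.data.frame.ppsh_weight_table <- function(x, ...) {
  data.frame(time = x$times[x$j], subject_id = x$subject, arm = x$z,
             case = ifelse(x$is_event, "event_at_tj", "at_risk"),
             weight = x$p, stringsAsFactors = FALSE)
}

#' @export
print.ppsh_weight_table <- function(x, ...) {
  cat(sprintf(
    "Principal-stratum weight table: %d event times, %d at-risk entries\n",
    length(x$times), length(x$j)))
  cat(sprintf("  gamma = %g   weight range: [%.4f, %.4f]\n",
              x$gamma, min(x$p), max(x$p)))
  invisible(x)
}
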