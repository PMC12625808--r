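## The PPSH estimator: a Cox-type partial likelihood over all event times,
## with each risk-set member weighted by its always-survivor membership
## probability and each event term weighted by the event subject's own
## probability. Breslow handling of ties throughout. The constant
## sum(log p_(j)j) term is dropped from the reported log partial likelihood;
## it does not involve beta.

.pl_quantities <- function(table, beta) {
  w <- table$p * exp(beta * table$z)
  s0 <- rowsum(w, table$j, reorder = TRUE)[, 1]
  s1 <- rowsum(w * table$z, table$j, reorder = TRUE)[, 1]
  zbar <- s1 / s0
  ev <- table$is_event
  pe <- table$p[ev]
  ze <- table$z[ev]
  je <- table$j[ev]
  list(
    logpl = sum(pe * (beta * ze - log(s0[je]))),
    score = sum(pe * (ze - zbar[je])),
    # z is binary so sum p z^2 e^{bz} = s1 and V_j = zbar (1 - zbar)
    info = sum(pe * zbar[je] * (1 - zbar[je]))
  )
}

.check_table <- function(table) {
  if (!inherits(table, "ppsh_weight_table") || !length(table$j)) {
    stop("a nonempty ppsh_weight_table is required")
  }
  invisible(TRUE)
}

#' Weighted log partial likelihood of the PPSH model
#'
#' `sum_j p_(j)j [beta Z_(j) - log sum_{i in R_j} p_ij exp(beta Z_i)]`, the
#' membership-weighted Breslow log partial likelihood. The beta-free constant
#' `sum_j log p_(j)j` is omitted. With all weights 1 this is the standard Cox
#' log partial likelihood. Strictly concave in `beta` whenever some risk set
#' mixes arms.
#'
#' @param beta Log hazard-ratio value at which to evaluate.
#' @param table A `ppsh_weight_table`.
#' @return Scalar log partial likelihood (up to the stated constant).
#' @export
weighted_log_pl <- function(beta, table) {
  .check_table(table)
  .pl_quantities(table, beta)$logpl
}

#' Modified score function of the PPSH model
#'
#' `U*(beta) = sum_j p_(j)j W_j` with
#' `W_j = Z_(j) - sum p_ij Z_i e^{beta Z_i} / sum p_ij e^{beta Z_i}`;
#' the derivative of [weighted_log_pl()] in `beta`.
#'
#' @inheritParams weighted_log_pl
#' @return Scalar score value.
#' @export
ppsh_score <- function(beta, table) {
  .check_table(table)
  .pl_quantities(table, beta)$score
}

#' Information of the PPSH model
#'
#' Minus the second derivative of [weighted_log_pl()]:
#' `sum_j p_(j)j V_j` where `V_j` is the weighted variance of the arm
#' indicator over the risk set. Nonnegative; strictly positive when some risk
#' set contains both arms.
#'
#' @inheritParams weighted_log_pl
#' @return Scalar information.
#' @export
ppsh_information <- function(beta, table) {
  .check_table(table)
  .pl_quantities(table, beta)$info
}

#' Fit the proportional principal stratum hazards model
#'
#' Solves `U*(beta) = 0` by Newton-Raphson,
#' `beta <- beta + U*(beta) / information(beta)`, starting from `init`
#' (default 0). Convergence when `|U*| < tol` or the step falls below 1e-8.
#' Monotone-likelihood degeneracies (all events effectively in one arm, as
#' can happen in small bootstrap resamples) are caught by capping `|beta|`
#' at `beta_cap` and flagging non-convergence.
#'
#' @param table A `ppsh_weight_table` from [build_weight_table()] (or
#'   [unit_weight_table()] for an unweighted Cox fit).
#' @param init Starting value for `beta`.
#' @param tol Score tolerance, default `1e-9`.
#' @param max_iter Iteration cap, default 50.
#' @param beta_cap Bound on `|beta|` guarding monotone likelihoods.
#' @return A `ppsh_fit`: `beta`, `hr = exp(beta)`, `score` and `information`
#'   at the optimum, `loglik`, `iterations`, `converged`, `capped`,
#'   `gamma_used`.
#' @export
fit_ppsh <- function(table, init = 0, tol = 1e-9, max_iter = 50L,
                     beta_cap = 20) {
  .check_table(table)
  beta <- init
  converged <- FALSE
  capped <- FALSE
  iter <- 0L
  repeat {
    q <- .pl_quantities(table, beta)
    if (abs(q$score) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    if (q$info <= .Machine$double.eps) {
      # flat likelihood but nonzero score: monotone direction
      beta <- sign(q$score) * beta_cap
      capped <- TRUE
      break
    }
    iter <- iter + 1L
    step <- q$score / q$info
    beta_new <- beta + step
    if (abs(beta_new) >= beta_cap) {
      beta_new <- sign(beta_new) * beta_cap
      if (capped) { # pinned to the cap twice: monotone likelihood
        beta <- beta_new
        break
      }
      capped <- TRUE
    }
    if (abs(beta_new - beta) < 1e-8) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  if (capped) converged <- FALSE
  q <- .pl_quantities(table, beta)
  structure(
    list(beta = beta, hr = exp(beta), score = q$score,
         information = q$info, loglik = q$logpl, iterations = iter,
         converged = converged, capped = capped, gamma_used = table$gamma,
         n_event_times = length(table$times),
         n_events = sum(table$is_event), type = "principal_stratum"),
    class = "ppsh_fit")
}

#' Cause-specific Cox fit for the nonfatal event
#'
#' The conventional comparator: a Cox (Breslow) fit of time to first nonfatal
#' event on arm, treating both death and loss to follow-up as censoring.
#' Implemented as [fit_ppsh()] on the [unit_weight_table()], so it shares the
#' partial-likelihood machinery of the weighted fit exactly.
#'
#' @param cohort A validated `ppsh_cohort` with events and both arms.
#' @return A `ppsh_fit` with `gamma_used = Inf` and `type =
#'   "cause_specific"`.
#' @export
fit_cause_specific <- function(cohort) {
  .check_two_arms(cohort)
  fit <- fit_ppsh(unit_weight_table(cohort))
  fit$type <- "cause_specific"
  fit
}

#' Score test of proportional (principal-stratum) hazards
#'
#' One-degree-of-freedom score test of `H0: phi = 0` in the extended linear
#' predictor `beta * Z + phi * Z * g(t)`, evaluated at the fitted `beta` with
#' the same membership weights as the fit (Grambsch-Therneau-style; with unit
#' weights and `g` the identity it coincides with the identity-transform
#' `cox.zph` test). The default transform is `g(t) = t`.
#'
#' @param table The `ppsh_weight_table` the model was fitted on.
#' @param fit The corresponding converged [fit_ppsh()] result.
#' @param g Time transform applied to the event times; must not be constant.
#' @return An object of class `htest` with the chi-square statistic (1 df)
#'   and p-value.
#' @export
proportionality_test <- function(table, fit, g = function(t) t) {
  .check_table(table)
  stopifnot(inherits(fit, "ppsh_fit"))
  gt <- g(table$times)
  if (!is.numeric(gt) || length(gt) != length(table$times)) {
    stop("g must map the event times to a numeric vector of the same length")
  }
  if (diff(range(gt)) <= 0) stop("degenerate time transform: g is constant")
  w <- table$p * exp(fit$beta * table$z)
  s0 <- rowsum(w, table$j, reorder = TRUE)[, 1]
  s1 <- rowsum(w * table$z, table$j, reorder = TRUE)[, 1]
  zbar <- s1 / s0
  vj <- zbar * (1 - zbar)
  ev <- table$is_event
  pe <- table$p[ev]
  ze <- table$z[ev]
  je <- table$j[ev]
  u_phi <- sum(pe * gt[je] * (ze - zbar[je]))
  i_bb <- sum(pe * vj[je])
  i_bp <- sum(pe * gt[je] * vj[je])
  i_pp <- sum(pe * gt[je]^2 * vj[je])
  v <- i_pp - i_bp^2 / i_bb
  if (!is.finite(v) || v <= 0) {
    stop("singular information for the time-varying term")
  }
  stat <- u_phi^2 / v
  structure(
    list(statistic = c(chisq = stat), parameter = c(df = 1),
         p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         method = paste("Weighted partial-likelihood score test of",
                        "proportional principal stratum hazards"),
         data.name = deparse(substitute(table))),
    class = "htest")
}

#' @export
print.ppsh_fit <- function(x, digits = 4, ...) {
  lab <- switch(x$type,
                cause_specific = "Cause-specific Cox fit (Breslow)",
                "Proportional principal stratum hazards fit")
  cat(lab, "\n")
  if (is.finite(x$gamma_used)) {
    cat(sprintf("  gamma-tilde = %g (frailty variance %g)\n",
                x$gamma_used, 1 / x$gamma_used))
  }
  cat(sprintf("  beta = %.*f   HR = %.*f\n", digits, x$beta, digits, x$hr))
  cat(sprintf("  events: %d at %d distinct times; %d iterations; %s\n",
              x$n_events, x$n_event_times, x$iterations,
              if (x$converged) "converged" else
                if (x$capped) "NOT converged (beta capped)" else
                  "NOT converged"))
  invisible(x)
}

#' @export
as.data.frame.ppsh_fit <- function(x, ...) {
  data.frame(type = x$type, gamma_used = x$gamma_used, beta = x$beta,
             hr = x$hr,
             se_proxy = if (x$information > 0) 1 / sqrt(x$information)
             else NA_real_,
             iterations = x$iterations, converged = x$converged,
             stringsAsFactors = FALSE)
}
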