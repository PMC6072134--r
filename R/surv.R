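## Kaplan-Meier estimation and the one-sided log-rank comparison used in the
## killing and longevity assays.  Estimation and the chi-square statistic are
## delegated to the survival package; the one-sided convention is applied on
## top of the observed direction.

#' Kaplan-Meier survival curve for one group
#'
#' Product-limit estimate; censored records reduce the risk set without a
#' survival drop.  Deaths sharing a time are handled in one risk-set update.
#'
#' @param cohort `data.frame` with columns `group`, `time`, `event`
#'   ([read_survival_cohort()] / [gen_survival()]).
#' @param group Group label to estimate.
#' @return `data.frame` with columns `time`, `n_risk`, `n_event`,
#'   `survival` (non-increasing, starting below 1 only after the first
#'   death).
#' @export
km_estimate <- function(cohort, group) {
  rows <- cohort[cohort$group == group, , drop = FALSE]
  if (nrow(rows) == 0L) stop("group ", sQuote(group), " not found")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = rows)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             survival = fit$surv)
}

#' One-sided log-rank comparison of two survival cohorts
#'
#' Standard log-rank test (observed minus expected deaths summed over
#' distinct event times, hypergeometric variance, chi-square with 1 df for
#' the two-sided p).  The one-sided p is half the two-sided p when the group
#' observed to fare worse (more deaths than expected) is the hypothesized
#' one, and one minus that half otherwise.
#'
#' @param cohort `data.frame` with columns `group`, `time`, `event`.
#' @param group_a,group_b The two group labels to compare.
#' @param hypothesized_worse The group hypothesized a priori to have worse
#'   survival (defaults to `group_b`).
#' @return A list with `chi2`, `p_two_sided`, `p_one_sided`, `direction`
#'   (label of the group with worse observed survival) and the per-group
#'   observed and expected death counts.
#' @export
logrank_onesided <- function(cohort, group_a, group_b,
                             hypothesized_worse = group_b) {
  rows <- cohort[cohort$group %in% c(group_a, group_b), , drop = FALSE]
  if (!all(c(group_a, group_b) %in% rows$group))
    stop("both groups must be present in the cohort")
  if (!hypothesized_worse %in% c(group_a, group_b))
    stop("hypothesized_worse must be one of the two groups")
  if (sum(rows$event) == 0L)
    stop("log-rank statistic undefined: no events in either group")
  rows$group <- factor(rows$group, levels = c(group_a, group_b))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = rows)
  if (!is.finite(sd$chisq) || all(abs(sd$obs - sd$exp) < .Machine$double.eps) &&
      sd$var[1, 1] == 0)
    stop("log-rank statistic undefined: zero variance")
  chi2 <- unname(sd$chisq)
  p_two <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  obs <- as.numeric(sd$obs); expd <- as.numeric(sd$exp)
  direction <- if (obs[1] > expd[1]) group_a else group_b
  p_one <- if (direction == hypothesized_worse) p_two / 2 else 1 - p_two / 2
  list(chi2 = chi2, p_two_sided = p_two, p_one_sided = p_one,
       direction = direction,
       observed = stats::setNames(obs, c(group_a, group_b)),
       expected = stats::setNames(expd, c(group_a, group_b)))
}
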