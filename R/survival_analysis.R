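#' Median split into expression cohorts
#'
#' Subjects with expression strictly above the median go to the "high"
#' cohort; the rest (ties included) to "low".
#'
#' @param table survival data.frame with one expression column per gene.
#' @param gene name of the expression column to split on.
#' @return factor with levels `c("low", "high")`, one per subject.
#' @export
median_split <- function(table, gene) {
  if (!gene %in% names(table)) stop("gene '", gene, "' not found in the table")
  x <- table[[gene]]
  if (sum(!is.na(x)) < 4) stop("at least 4 subjects with expression are required")
  if (length(unique(x[!is.na(x)])) == 1)
    stop("all expression values are equal; no median split possible")
  med <- stats::median(x, na.rm = TRUE)
  factor(ifelse(x > med, "high", "low"), levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' Step function of the survival probability, with deaths processed before
#' censorings at tied times. The median survival is the smallest time at
#' which S(t) <= 0.5, and is `NA` (flagged) when the curve never reaches
#' 0.5 -- in particular when there are no events.
#'
#' @param times positive follow-up times.
#' @param events event indicators (1 = death, 0 = censored).
#' @return list of class `km_fit` with `steps` (time, n_risk, n_event,
#'   n_censor, surv), `median`, `has_median`, `n` and `n_events`.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  if (sum(events) == 0)
    message("no events observed; survival stays at 1 and the median is undefined")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  steps <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  reach <- steps$time[steps$surv <= 0.5]
  med <- if (length(reach) > 0) min(reach) else NA_real_
  structure(list(steps = steps, median = med, has_median = !is.na(med),
                 n = length(times), n_events = sum(events)),
            class = "km_fit")
}

check_two_cohorts <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(group) != 2 || any(table(group) == 0))
    stop("exactly two nonempty cohorts are required")
  if (sum(events) == 0) stop("at least one event is required")
  droplevels(group)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-squared statistic on 1 degree of freedom.
#'
#' @param times positive follow-up times.
#' @param events event indicators (1 = death, 0 = censored).
#' @param group two-level cohort factor.
#' @return list with `chisq`, `p`, and the observed/expected event counts
#'   per cohort.
#' @export
logrank_test <- function(times, events, group) {
  group <- check_two_cohorts(times, events, group)
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Mantel-Haenszel hazard ratio with 95 percent confidence interval
#'
#' HR (second level vs first level of `group`) =
#' (O2/E2) / (O1/E1) from the log-rank observed/expected event counts, with
#' var(log HR) = 1/E1 + 1/E2 and CI = exp(log HR +/- 1.96 SE). This is the
#' univariate estimator reported by median-split survival tools, not a
#' fitted Cox model.
#'
#' @param times positive follow-up times.
#' @param events event indicators (1 = death, 0 = censored).
#' @param group two-level cohort factor; HR compares the second level
#'   against the first (e.g. high vs low).
#' @return list with `hr`, `ci_low`, `ci_high`, `se_log_hr`, `observed`,
#'   `expected`.
#' @export
hazard_ratio <- function(times, events, group) {
  group <- check_two_cohorts(times, events, group)
  if (any(tapply(events, group, sum) == 0))
    stop("both cohorts need at least one event")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  O <- unname(sd$obs)
  E <- unname(sd$exp)
  if (any(E == 0)) stop("zero expected events in a cohort")
  hr <- (O[2] / E[2]) / (O[1] / E[1])
  se <- sqrt(1 / E[1] + 1 / E[2])
  list(hr = hr, ci_low = hr * exp(-1.96 * se), ci_high = hr * exp(1.96 * se),
       se_log_hr = se, observed = O, expected = E)
}

#' Median-split Kaplan-Meier analysis for one gene
#'
#' Splits the cohort at the median expression of `gene`, estimates the
#' Kaplan-Meier curve and median survival per cohort, and reports the
#' log-rank test and the Mantel-Haenszel hazard ratio (high vs low).
#'
#' @param table survival data.frame with columns `time_months` and `event`
#'   plus one expression column per gene.
#' @param gene gene column to analyse.
#' @param time_col,event_col column names (defaults `time_months`, `event`).
#' @return list of class `km_result` with `gene`, `cohorts` (per-cohort
#'   `km_fit`), `logrank` and `hr`.
#' @export
km_analysis <- function(table, gene, time_col = "time_months",
                        event_col = "event") {
  stopifnot(all(c(time_col, event_col) %in% names(table)))
  grp <- median_split(table, gene)
  times <- table[[time_col]]
  events <- table[[event_col]]
  cohorts <- lapply(stats::setNames(levels(grp), levels(grp)), function(l)
    km_estimate(times[grp == l], events[grp == l]))
  structure(list(gene = gene, cohorts = cohorts,
                 n = stats::setNames(as.integer(table(grp)), levels(grp)),
                 logrank = logrank_test(times, events, grp),
                 hr = hazard_ratio(times, events, grp)),
            class = "km_result")
}
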