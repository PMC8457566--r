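# Kaplan-Meier estimation, lifespan summaries, log-rank comparisons with
# Benjamini-Hochberg correction, and percent-effect arithmetic. Estimation
# delegates to the survival package; this file owns the bookkeeping and the
# published-lifespan-table reporting conventions.

#' Kaplan-Meier product-limit curve
#'
#' Fits the product-limit estimate and returns it with full event/at-risk
#' bookkeeping. Ties are grouped at identical scored days; censorings at a
#' death time leave the risk set after the deaths.
#'
#' @param durations Per-worm event/censor days (> 0).
#' @param event_observed Logical per worm: `TRUE` = death, `FALSE` =
#'   censored.
#' @return An object of class `km_curve` with fields `time`, `surv`,
#'   `n_risk`, `n_event`, `n_censor`, `n_total`, `n_events_total`.
#' @export
km_curve <- function(durations, event_observed) {
  if (length(durations) != length(event_observed))
    stop("durations and event_observed must have equal length")
  if (length(durations) == 0) stop("empty input")
  if (any(durations <= 0)) stop("durations must be positive")
  event_observed <- as.logical(event_observed)
  fit <- survival::survfit(
    survival::Surv(durations, event_observed) ~ 1,
    conf.type = "none")
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n_censor = fit$n.censor,
                 n_total = length(durations),
                 n_events_total = sum(event_observed)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("<km_curve> n =", x$n_total, ", events =", x$n_events_total, "\n")
  print(data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
                   n_censor = x$n_censor, surv = round(x$surv, 4)))
  invisible(x)
}

#' Area under a Kaplan-Meier curve (restricted mean)
#'
#' Integrates the KM step function from 0 to `horizon`. The curve equals 1
#' before the first observed time and is right-continuous. With no censoring
#' and `horizon` at or beyond the last death, this equals the arithmetic
#' mean of the death days.
#'
#' @param curve A [km_curve()].
#' @param horizon Upper limit of integration; default the last observed
#'   event time (see `to_last_event`).
#' @param to_last_event If `TRUE` (default) and `horizon` is `NULL`,
#'   integrate to the last *death* time; otherwise to the last observed time.
#' @return Restricted mean (days).
#' @export
km_mean <- function(curve, horizon = NULL, to_last_event = TRUE) {
  if (is.null(horizon)) {
    horizon <- if (to_last_event && curve$n_events_total > 0)
      max(curve$time[curve$n_event > 0]) else max(curve$time)
  }
  tt <- c(0, curve$time[curve$time <= horizon], horizon)
  ss <- c(1, curve$surv[curve$time <= horizon])
  sum(diff(tt) * ss)
}

#' Per-strain lifespan summary
#'
#' The default mean-lifespan estimator is the arithmetic mean of observed
#' death days with censored worms excluded (the convention under which the
#' printed effect percentages of a standard lifespan table recompute
#' exactly); the KM restricted mean (RMST) is reported alongside, and the
#' two are flagged when they differ by more than 5%. The standard error is
#' sd/sqrt(n_events). "Maximum lifespan" defaults to the mean of the top
#' decile of death days; `"max"` (single longest-lived worm) and `"p90"`
#' (90th percentile) are selectable.
#'
#' @param cohort A [worm_cohort()].
#' @param strain Strain label.
#' @param horizon Horizon for the RMST; default last observed time.
#' @param max_estimator One of `"top_decile"` (default), `"max"`, `"p90"`.
#' @return An object of class `survival_summary`: list with `strain`, `n`,
#'   `n_events`, `n_censored`, `mean_lifespan`, `sd`, `sem`, `max_lifespan`,
#'   `rmst`, `rmst_divergent`.
#' @export
summarize_survival <- function(cohort, strain, horizon = NULL,
                               max_estimator = c("top_decile", "max",
                                                 "p90")) {
  max_estimator <- match.arg(max_estimator)
  d <- cohort_durations(cohort, strain)
  deaths <- d$duration[d$event]
  if (length(deaths) == 0) stop("strain ", strain, " has zero death events")
  curve <- km_curve(d$duration, d$event)
  rmst <- km_mean(curve, horizon = horizon, to_last_event = FALSE)
  m <- mean(deaths)
  s <- stats::sd(deaths)
  maxl <- switch(max_estimator,
    top_decile = mean(sort(deaths, decreasing = TRUE)[
      seq_len(max(1L, ceiling(length(deaths) / 10)))]),
    max = max(deaths),
    p90 = unname(stats::quantile(deaths, 0.9, type = 7)))
  structure(list(strain = strain, n = nrow(d), n_events = length(deaths),
                 n_censored = sum(!d$event), mean_lifespan = m, sd = s,
                 sem = s / sqrt(length(deaths)), max_lifespan = maxl,
                 rmst = rmst,
                 rmst_divergent = abs(rmst - m) > 0.05 * m),
            class = "survival_summary")
}

#' @export
print.survival_summary <- function(x, ...) {
  cat(sprintf(
    "<survival_summary> %s: n=%d (%d deaths, %d censored)\n  mean %.1f +/- %.2f (SEM) d, sd %.2f, max %.1f, RMST %.1f%s\n",
    x$strain, x$n, x$n_events, x$n_censored, x$mean_lifespan, x$sem, x$sd,
    x$max_lifespan, x$rmst,
    if (isTRUE(x$rmst_divergent)) "  [RMST and naive mean differ >5%]" else ""))
  invisible(x)
}

#' Mantel-Cox log-rank test
#'
#' One-degree-of-freedom log-rank comparison of two survival samples.
#'
#' @param durations_a,events_a Durations and event flags of group A.
#' @param durations_b,events_b Durations and event flags of group B.
#' @return list with `chi_square`, `p_value`, `df`.
#' @export
logrank_test <- function(durations_a, events_a, durations_b, events_b) {
  if (length(durations_a) == 0 || length(durations_b) == 0)
    stop("both groups must be non-empty")
  if (sum(events_a) + sum(events_b) == 0)
    stop("no events in either group")
  if (identical(sort(durations_a), sort(durations_b)) &&
      sum(events_a) == sum(events_b) &&
      identical(sort(durations_a[as.logical(events_a)]),
                sort(durations_b[as.logical(events_b)]))) {
    # identical samples: the statistic is exactly zero
    return(list(chi_square = 0, p_value = 1, df = 1L))
  }
  time <- c(durations_a, durations_b)
  ev <- c(as.logical(events_a), as.logical(events_b))
  grp <- rep(c("a", "b"), c(length(durations_a), length(durations_b)))
  sd_ <- survival::survdiff(survival::Surv(time, ev) ~ grp)
  chi <- unname(sd_$chisq)
  list(chi_square = chi,
       p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE), df = 1L)
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Standard step-up false-discovery-rate control.
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @param alpha FDR level for the significance flags, default 0.05.
#' @return list with `p_adjusted` and logical `significant`.
#' @export
bh_adjust <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, significant = !is.na(adj) & adj < alpha)
}

#' Percent change of an endpoint versus control
#'
#' `100 * (value_strain - value_control) / value_control`, the "Effect vs
#' control" arithmetic of a standard lifespan table.
#'
#' @param value_strain,value_control Scalar endpoint values;
#'   `value_control > 0`.
#' @return Signed percent change (not rounded; reports round to 0.1).
#' @examples
#' effect_percent(26.0, 20.6)  # 26.21...
#' @export
effect_percent <- function(value_strain, value_control) {
  if (any(value_control <= 0)) stop("control value must be positive")
  100 * (value_strain - value_control) / value_control
}

#' Format a p-value the way lifespan tables print it
#'
#' Values below double precision are printed as `"<2.0E-16"`.
#'
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 2e-16, "<2.0E-16", sprintf("%.1E", p))
}

#' Strain-table survival report for a cohort
#'
#' Per strain: n, deaths, censored, mean lifespan +/- SEM, sd, RMST, maximum
#' lifespan, percent effect vs the control strain, log-rank p vs control and
#' its Benjamini-Hochberg adjustment.
#'
#' @param cohort A [worm_cohort()].
#' @param control Label of the control strain.
#' @param alpha FDR level, default 0.05.
#' @inheritParams summarize_survival
#' @return data.frame, one row per strain (control first).
#' @export
survival_table <- function(cohort, control, alpha = 0.05,
                           max_estimator = "top_decile") {
  strains <- unique(cohort$records$strain)
  if (!control %in% strains)
    stop("control strain '", control, "' not present in cohort")
  strains <- c(control, sort(setdiff(strains, control)))
  sums <- lapply(strains, function(s)
    summarize_survival(cohort, s, max_estimator = max_estimator))
  dc <- cohort_durations(cohort, control)
  ctrl_mean <- sums[[1]]$mean_lifespan
  eff <- p <- rep(NA_real_, length(strains))
  for (i in seq_along(strains)[-1]) {
    ds <- cohort_durations(cohort, strains[i])
    eff[i] <- effect_percent(sums[[i]]$mean_lifespan, ctrl_mean)
    p[i] <- logrank_test(ds$duration, ds$event, dc$duration, dc$event)$p_value
  }
  adj <- bh_adjust(p[-1], alpha = alpha)
  data.frame(
    strain = strains,
    n = vapply(sums, `[[`, 0, "n"),
    n_events = vapply(sums, `[[`, 0, "n_events"),
    n_censored = vapply(sums, `[[`, 0, "n_censored"),
    mean_lifespan = round(vapply(sums, `[[`, 0, "mean_lifespan"), 1),
    sem = round(vapply(sums, `[[`, 0, "sem"), 2),
    sd = round(vapply(sums, `[[`, 0, "sd"), 2),
    max_lifespan = round(vapply(sums, `[[`, 0, "max_lifespan"), 1),
    rmst = round(vapply(sums, `[[`, 0, "rmst"), 1),
    effect_percent = round(eff, 1),
    p_value = c(NA, format_p(p[-1])),
    p_adjusted = c(NA, format_p(adj$p_adjusted)),
    significant = c(NA, adj$significant),
    stringsAsFactors = FALSE, row.names = NULL)
}
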