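# Motility-based healthspan: transition events out of the mobile (A) and
# mobile-or-impaired (A,B) state sets, KM state occupancy, mean-duration
# decomposition (mobile + impaired + frail = lifespan) and lifespan
# fractions.

#' Per-worm times of leaving a motility state set
#'
#' For each worm of a strain, the duration is the first day the worm is
#' observed outside `from_states` -- by motility transition OR by death, a
#' composite endpoint (death while still mobile ends the mobile period as an
#' event; only this convention makes the mean-duration decomposition sum to
#' mean lifespan). Worms censored while still inside `from_states` are
#' censored at their censoring day (`censor_policy = "censor"`, default) or
#' dropped (`"exclude"`, the convention of daily bar-chart tallies).
#'
#' @param cohort A [worm_cohort()].
#' @param strain Strain label.
#' @param from_states `c("A")` (exit from full mobility) or `c("A", "B")`
#'   (entry into frailty or death).
#' @param censor_policy `"censor"` or `"exclude"`.
#' @return data.frame with columns `worm_id`, `duration`, `event`.
#' @export
extract_transition_times <- function(cohort, strain,
                                     from_states = c("A"),
                                     censor_policy = c("censor", "exclude")) {
  censor_policy <- match.arg(censor_policy)
  if (!all(from_states %in% c("A", "B")) || length(from_states) == 0)
    stop("from_states must be 'A' or c('A','B')")
  r <- cohort$records
  r <- r[r$strain == strain, , drop = FALSE]
  if (nrow(r) == 0) stop("no records for strain ", strain)
  if (any(r$status == "alive" & r$motility == "not_scored"))
    stop("strain ", strain,
         " has unscored motility on days worms were alive")
  r <- r[order(r$worm_id, r$day), , drop = FALSE]
  out <- lapply(split(r, r$worm_id), function(w) {
    outside <- (w$status == "alive" & !w$motility %in% from_states) |
      w$status == "dead"
    if (any(outside)) {
      data.frame(worm_id = w$worm_id[1], duration = w$day[which(outside)[1]],
                 event = TRUE, stringsAsFactors = FALSE)
    } else {
      # censored while still inside from_states
      if (censor_policy == "exclude") return(NULL)
      data.frame(worm_id = w$worm_id[1], duration = max(w$day),
                 event = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Mean days spent mobile, impaired and frail
#'
#' KM-based decomposition of mean lifespan into state-occupancy durations:
#' the mean mobile time is the KM mean of the exit-from-A durations; the mean
#' impaired time is the difference between the KM mean time spent mobile or
#' impaired and the mean mobile time; the mean frail time is the difference
#' between mean lifespan and the mean time spent mobile or impaired.
#' Fractions are percentages of mean lifespan. On censoring-free cohorts the
#' decomposition is exact.
#'
#' @inheritParams extract_transition_times
#' @return An object of class `state_occupancy`: list with `strain`,
#'   `mean_mobile`, `mean_impaired`, `mean_frail`, `mean_lifespan`,
#'   `frac_mobile`, `frac_impaired`, `frac_frail` (percent), `n`.
#' @export
state_mean_durations <- function(cohort, strain,
                                 censor_policy = "censor") {
  ta <- extract_transition_times(cohort, strain, "A", censor_policy)
  tab <- extract_transition_times(cohort, strain, c("A", "B"), censor_policy)
  d <- cohort_durations(cohort, strain)
  if (sum(ta$event) == 0 || sum(tab$event) == 0 || sum(d$event) == 0)
    stop("strain ", strain, " has zero events in a transition analysis")
  horizon <- max(d$duration)
  mean_a <- km_mean(km_curve(ta$duration, ta$event), horizon = horizon)
  mean_ab <- km_mean(km_curve(tab$duration, tab$event), horizon = horizon)
  mean_ls <- km_mean(km_curve(d$duration, d$event), horizon = horizon)
  state_occupancy(strain, mean_a, mean_ab - mean_a, mean_ls - mean_ab,
                  mean_ls, n = nrow(d))
}

#' Assemble a state-occupancy summary from mean durations
#'
#' Used both by [state_mean_durations()] and to replay printed occupancy
#' tables (mean days per state plus mean lifespan).
#'
#' @param strain Strain label.
#' @param mean_mobile,mean_impaired,mean_frail Mean days per state.
#' @param mean_lifespan Mean lifespan (days); defaults to the sum of the
#'   three state durations.
#' @param n Number of worms (optional).
#' @return An object of class `state_occupancy`.
#' @export
state_occupancy <- function(strain, mean_mobile, mean_impaired, mean_frail,
                            mean_lifespan = NULL, n = NA_integer_) {
  if (is.null(mean_lifespan))
    mean_lifespan <- mean_mobile + mean_impaired + mean_frail
  structure(list(strain = strain, mean_mobile = mean_mobile,
                 mean_impaired = mean_impaired, mean_frail = mean_frail,
                 mean_lifespan = mean_lifespan,
                 frac_mobile = 100 * mean_mobile / mean_lifespan,
                 frac_impaired = 100 * mean_impaired / mean_lifespan,
                 frac_frail = 100 * mean_frail / mean_lifespan,
                 n = n),
            class = "state_occupancy")
}

#' @export
print.state_occupancy <- function(x, ...) {
  cat(sprintf(
    "<state_occupancy> %s: lifespan %.1f d\n  mobile %.1f d (%.1f%%), impaired %.1f d (%.1f%%), frail %.1f d (%.1f%%)\n",
    x$strain, x$mean_lifespan, x$mean_mobile, x$frac_mobile,
    x$mean_impaired, x$frac_impaired, x$mean_frail, x$frac_frail))
  invisible(x)
}

#' Percent change of a state's lifespan fraction versus control
#'
#' `100 * (f_strain - f_control) / f_control` on the lifespan fractions of
#' the named state. Fractions are rounded to `digits` decimals first
#' (default 1, the occupancy-report convention); pass `digits = NULL` to
#' compare unrounded fractions.
#'
#' @param strain_summary,control_summary [state_occupancy()] objects.
#' @param state One of `"mobile"`, `"impaired"`, `"frail"`.
#' @param digits Rounding applied to the fractions before comparison.
#' @return Signed percent change of the fraction.
#' @export
fraction_change <- function(strain_summary, control_summary,
                            state = c("mobile", "impaired", "frail"),
                            digits = 1) {
  state <- match.arg(state)
  field <- paste0("frac_", state)
  fs <- strain_summary[[field]]
  fc <- control_summary[[field]]
  if (!is.null(digits)) {
    fs <- round(fs, digits)
    fc <- round(fc, digits)
  }
  if (fc == 0) stop("control fraction for state ", state, " is zero")
  100 * (fs - fc) / fc
}

#' Daily distribution of motility states among live worms
#'
#' Per observation day, the fractions of worms in states A, B and C among
#' worms alive that day (dead and censored animals are excluded from the
#' tallies). Days with no live worms are omitted.
#'
#' @inheritParams extract_transition_times
#' @return data.frame with columns `day`, `n_alive`, `frac_A`, `frac_B`,
#'   `frac_C` (fractions summing to 1 per row).
#' @export
daily_state_distribution <- function(cohort, strain) {
  r <- cohort$records
  r <- r[r$strain == strain & r$status == "alive", , drop = FALSE]
  if (nrow(r) == 0) stop("no live records for strain ", strain)
  tab <- table(factor(r$day, levels = sort(unique(r$day))),
               factor(r$motility, levels = c("A", "B", "C")))
  n <- rowSums(tab)
  keep <- n > 0
  data.frame(day = as.integer(rownames(tab))[keep], n_alive = n[keep],
             frac_A = (tab[, "A"] / n)[keep],
             frac_B = (tab[, "B"] / n)[keep],
             frac_C = (tab[, "C"] / n)[keep],
             row.names = NULL)
}

#' Log-rank comparison of motility-transition curves between strains
#'
#' Delegates to [logrank_test()] on the composite transition endpoints of
#' [extract_transition_times()].
#'
#' @inheritParams extract_transition_times
#' @param strain_a,strain_b Strain labels.
#' @return list with `chi_square`, `p_value`, `df`.
#' @export
motility_logrank <- function(cohort, strain_a, strain_b,
                             from_states = c("A"),
                             censor_policy = "censor") {
  ta <- extract_transition_times(cohort, strain_a, from_states,
                                 censor_policy)
  tb <- extract_transition_times(cohort, strain_b, from_states,
                                 censor_policy)
  logrank_test(ta$duration, ta$event, tb$duration, tb$event)
}

#' Occupancy report for all strains of a cohort
#'
#' @param cohort A [worm_cohort()].
#' @param control Optional control strain label; when given, fraction-change
#'   columns versus the control are added.
#' @inheritParams extract_transition_times
#' @return data.frame, one row per strain; days rounded to 0.1, fractions to
#'   0.1 percent.
#' @export
occupancy_table <- function(cohort, control = NULL,
                            censor_policy = "censor") {
  strains <- sort(unique(cohort$records$strain))
  if (!is.null(control)) strains <- c(control, setdiff(strains, control))
  occ <- lapply(strains, function(s)
    state_mean_durations(cohort, s, censor_policy))
  out <- data.frame(
    strain = strains,
    n = vapply(occ, `[[`, 0, "n"),
    mean_mobile = round(vapply(occ, `[[`, 0, "mean_mobile"), 1),
    mean_impaired = round(vapply(occ, `[[`, 0, "mean_impaired"), 1),
    mean_frail = round(vapply(occ, `[[`, 0, "mean_frail"), 1),
    mean_lifespan = round(vapply(occ, `[[`, 0, "mean_lifespan"), 1),
    frac_mobile = round(vapply(occ, `[[`, 0, "frac_mobile"), 1),
    frac_impaired = round(vapply(occ, `[[`, 0, "frac_impaired"), 1),
    frac_frail = round(vapply(occ, `[[`, 0, "frac_frail"), 1),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(control)) {
    ctrl <- occ[[1]]
    for (st in c("mobile", "impaired", "frail")) {
      out[[paste0("change_", st)]] <- round(vapply(occ, function(o)
        fraction_change(o, ctrl, st), 0), 1)
    }
  }
  out
}
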