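# Synthetic cohorts: Gompertz mortality with additive log-hazard intervention
# effects and optional pairwise interactions, a progressive A->B->C motility
# process with its own Gompertz transition hazards coupled to mortality via a
# frailty multiplier, daily discretization and FUdR-era censoring.

#' Gompertz survival function
#'
#' Survival under the Gompertz hazard h(t) = a e^{bt}:
#' S(t) = exp(-(a/b)(e^{bt} - 1)), reducing to the exponential exp(-a t)
#' when b = 0.
#'
#' @param t Days (vectorised), `t >= 0`.
#' @param a Scale (baseline hazard per day), `a > 0`.
#' @param b Shape (log-hazard slope per day), `b >= 0`.
#' @return Survival probabilities in (0, 1], non-increasing in `t`.
#' @examples
#' gompertz_survival(0, 0.001, 0.25)        # 1
#' gompertz_survival(10, 0.1, 0)            # exp(-1)
#' @export
gompertz_survival <- function(t, a, b) {
  if (any(t < 0)) stop("t must be non-negative")
  if (a <= 0) stop("a must be positive")
  if (b < 0) stop("b must be non-negative")
  if (b == 0) exp(-a * t) else exp(-(a / b) * (exp(b * t) - 1))
}

# Expected recorded death day under daily scoring (death recorded on the
# first day scored dead): E[ceil(T)] = sum_{k>=0} S(k). `hr` multiplies the
# hazard. Serves as the closed-form oracle for parameter-recovery checks.
#' Expected recorded death day of a Gompertz cohort under daily scoring
#'
#' With continuous Gompertz death times discretized to the first scoring day
#' at which the worm is found dead, the expected recorded day is
#' `sum_{k>=0} S(k)`. Used as the analytic ground truth when checking that
#' simulated cohorts recover their configured mean lifespans.
#'
#' @inheritParams gompertz_survival
#' @param hr Proportional-hazards multiplier applied to the hazard.
#' @param kmax Upper summation limit (days).
#' @return Expected recorded death day (days).
#' @export
gompertz_mean_day <- function(a, b, hr = 1, kmax = 500) {
  k <- 0:kmax
  if (b == 0) sum(exp(-hr * a * k)) else
    sum(exp(-hr * (a / b) * (exp(b * k) - 1)))
}

#' Configuration for the cohort simulator
#'
#' Mortality follows a Gompertz hazard `a e^{bt}` with strain log-hazard
#' `log a_strain = log a + sum(beta) + sum(gamma)`: each intervention
#' contributes an additive log-hazard effect beta (negative = pro-longevity;
#' diluted RNAi contributes `dilution_factor * beta`), and intervention pairs
#' may carry an interaction gamma (negative = synergistic on the hazard
#' scale). Motility declines through states A (mobile), B (impaired),
#' C (frail) with age-based Gompertz transition hazards; while impaired or
#' frail, the death hazard is multiplied by `frailty_mortality_multiplier`.
#' Worms are censored with a per-day probability, with causes drawn from the
#' classic FUdR-era list (bagging, wall-crawling, organ extrusion).
#'
#' Defaults emulate the observational design of a standard 20 C daily-scored
#' lifespan assay: 85 worms per strain per experiment, 3 replicates, wild-type
#' mean lifespan near 20.6 days and intervention effects in the 4-26% range.
#'
#' @param baseline_a,baseline_b Gompertz scale/shape of the control strain.
#' @param intervention_effects Named numeric: log-hazard effect per
#'   intervention.
#' @param interaction_terms Named numeric: log-hazard interaction per
#'   intervention pair, names as canonical keys `"geneA+geneB"` (sorted).
#' @param motility_hazards Numeric vector `c(a_AB, b_AB, a_BC, b_BC)`:
#'   Gompertz parameters of the A->B and B->C transitions.
#' @param motility_effects Named numeric: log-hazard effect of each
#'   intervention on both motility transitions (negative = stays mobile
#'   longer). Default none.
#' @param frailty_mortality_multiplier Hazard ratio (>= 1) applied to the
#'   death hazard while in states B or C.
#' @param censor_daily_prob Per-day probability that a live worm is censored.
#' @param censor_cause_probs Named probabilities over censoring causes.
#' @param dilution_factor Attenuation of beta for `rnai_diluted`
#'   interventions (1:1 RNAi/EV mixes), default 0.5.
#' @param n_worms Worms per strain per replicate.
#' @param n_replicates Number of independent experiments.
#' @param horizon_days Administrative horizon; survivors are censored there.
#' @param seed Master seed; every strain x replicate draws from its own
#'   stream derived from it, so adding a strain does not perturb others.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(baseline_a = 0.00095, baseline_b = 0.25,
                              intervention_effects = c("odr-3" = -1.37,
                                                       "ife-2" = -0.94,
                                                       "cku-70" = -0.24),
                              interaction_terms = numeric(),
                              motility_hazards = c(a_AB = 5e-4, b_AB = 0.30,
                                                   a_BC = 4e-3, b_BC = 0.28),
                              motility_effects = numeric(),
                              frailty_mortality_multiplier = 1.5,
                              censor_daily_prob = 0.01,
                              censor_cause_probs = c(bagging = 0.4,
                                                     wall = 0.4,
                                                     extrusion = 0.15,
                                                     other = 0.05),
                              dilution_factor = 0.5,
                              n_worms = 85, n_replicates = 3,
                              horizon_days = 60, seed = 1L) {
  stopifnot(baseline_a > 0, baseline_b >= 0, n_worms >= 1, n_replicates >= 1,
            horizon_days >= 1, frailty_mortality_multiplier >= 1,
            censor_daily_prob >= 0, censor_daily_prob <= 1,
            dilution_factor >= 0, dilution_factor <= 1)
  mh <- motility_hazards
  if (length(mh) != 4 || any(mh[c(1, 3)] <= 0) || any(mh[c(2, 4)] < 0))
    stop("motility_hazards must be c(a_AB, b_AB, a_BC, b_BC) with positive ",
         "scales and non-negative shapes")
  names(mh) <- c("a_AB", "b_AB", "a_BC", "b_BC")
  ccp <- censor_cause_probs / sum(censor_cause_probs)
  structure(list(baseline_a = baseline_a, baseline_b = baseline_b,
                 intervention_effects = intervention_effects,
                 interaction_terms = interaction_terms,
                 motility_hazards = mh, motility_effects = motility_effects,
                 frailty_mortality_multiplier = frailty_mortality_multiplier,
                 censor_daily_prob = censor_daily_prob,
                 censor_cause_probs = ccp,
                 dilution_factor = dilution_factor,
                 n_worms = as.integer(n_worms),
                 n_replicates = as.integer(n_replicates),
                 horizon_days = as.integer(horizon_days),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Deterministic 31-bit sub-seed for a named RNG stream.
derive_seed <- function(master, label) {
  h <- 0
  for (v in utf8ToInt(label)) h <- (h * 131 + v) %% 2147483647
  as.integer((h + as.numeric(master) * 48271) %% 2147483647)
}

# Next event time after t0 under hazard mult * a * exp(b t), by inversion of
# the cumulative hazard against an Exp(1) draw.
rgompertz_after <- function(t0, a, b, mult = 1) {
  e <- stats::rexp(1)
  if (b == 0) return(t0 + e / (a * mult))
  arg <- exp(b * t0) + b * e / (a * mult)
  log(arg) / b
}

# Strain-level hazard multipliers from its intervention set.
strain_multipliers <- function(set, config) {
  iv <- set$interventions
  unknown <- setdiff(iv, names(config$intervention_effects))
  if (length(unknown))
    stop("no intervention_effects entry for: ",
         paste(unknown, collapse = ", "))
  beta <- config$intervention_effects[iv]
  dil <- ifelse(set$modes[iv] == "rnai_diluted", config$dilution_factor, 1)
  lh <- sum(beta * dil)
  if (length(iv) >= 2 && length(config$interaction_terms)) {
    prs <- utils::combn(sort(iv), 2,
                        FUN = function(p) paste(p, collapse = "+"))
    lh <- lh + sum(config$interaction_terms[intersect(prs,
                                    names(config$interaction_terms))])
  }
  me <- config$motility_effects[intersect(iv, names(config$motility_effects))]
  list(death = exp(lh), motility = exp(sum(me)))
}

simulate_worm <- function(config, hr_death, hr_mot) {
  mh <- config$motility_hazards
  a <- config$baseline_a; b <- config$baseline_b
  fm <- config$frailty_mortality_multiplier
  # state A from t = 0
  t_death <- rgompertz_after(0, a, b, hr_death)
  t_ab <- rgompertz_after(0, mh["a_AB"], mh["b_AB"], hr_mot)
  t_bc <- Inf
  if (t_ab < t_death) {
    # entered B: death hazard picks up the frailty multiplier from t_ab on
    t_death <- rgompertz_after(t_ab, a, b, hr_death * fm)
    t_bc <- rgompertz_after(t_ab, mh["a_BC"], mh["b_BC"], hr_mot)
    if (t_bc < t_death)
      t_death <- rgompertz_after(t_bc, a, b, hr_death * fm)
    else
      t_bc <- Inf
  } else {
    t_ab <- Inf
  }
  list(t_death = t_death, t_ab = t_ab, t_bc = t_bc)
}

#' Simulate a daily-scored lifespan/healthspan cohort
#'
#' Draws continuous death and motility-transition times per worm from the
#' hazards in `config`, discretizes them to daily records (death recorded on
#' the first day scored dead), and applies per-day censoring with causes.
#' Identical config and seed give identical output; each strain x replicate
#' has its own RNG stream derived from the master seed.
#'
#' @param config A [simulation_config()].
#' @param strains List of [intervention_set()] objects (include the empty set
#'   for the control strain).
#' @return A [worm_cohort()].
#' @export
simulate_cohort <- function(config, strains) {
  stopifnot(inherits(config, "simulation_config"))
  if (inherits(strains, "intervention_set")) strains <- list(strains)
  labels <- vapply(strains, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate strain labels")
  horizon <- config$horizon_days
  causes <- names(config$censor_cause_probs)
  out <- vector("list", length(strains) * config$n_replicates)
  k <- 0
  for (si in seq_along(strains)) {
    set <- strains[[si]]
    mult <- strain_multipliers(set, config)
    for (rep_i in seq_len(config$n_replicates)) {
      set.seed(derive_seed(config$seed, paste0(set$label, "#", rep_i)))
      recs <- vector("list", config$n_worms)
      for (wi in seq_len(config$n_worms)) {
        w <- simulate_worm(config, mult$death, mult$motility)
        death_day <- max(1L, as.integer(ceiling(w$t_death)))
        # daily censoring: first day k >= 1 with a positive draw
        cens_day <- Inf
        if (config$censor_daily_prob > 0) {
          g <- stats::rgeom(1, config$censor_daily_prob) + 1L
          cens_day <- g
        }
        cause <- "none"
        if (cens_day < death_day) {
          end_day <- as.integer(cens_day)
          status_end <- "censored"
          cause <- sample(causes, 1, prob = config$censor_cause_probs)
        } else if (death_day > horizon) {
          end_day <- horizon
          status_end <- "censored"
          cause <- "other"
        } else {
          end_day <- death_day
          status_end <- "dead"
        }
        days <- 0:end_day
        alive_days <- days[-length(days)]
        motility <- ifelse(alive_days < w$t_ab, "A",
                           ifelse(alive_days < w$t_bc, "B", "C"))
        recs[[wi]] <- data.frame(
          worm_id = sprintf("%s_r%d_w%03d", iv_key_or_bg(set), rep_i, wi),
          strain = set$label, replicate = rep_i, day = days,
          status = c(rep("alive", length(alive_days)), status_end),
          censor_cause = c(rep("none", length(alive_days)), cause),
          motility = c(motility, "not_scored"),
          stringsAsFactors = FALSE)
      }
      k <- k + 1
      out[[k]] <- do.call(rbind, recs)
    }
  }
  records <- do.call(rbind, out)
  meta <- data.frame(strain = sort(unique(labels)), diet = "HT115(DE3)",
                     temperature = 20, fudr = 15, stringsAsFactors = FALSE)
  strains_map <- stats::setNames(strains, labels)
  worm_cohort(records, metadata = meta, strains = strains_map,
              validate = FALSE)
}

iv_key_or_bg <- function(set) {
  key <- iv_key(set)
  if (key == "") set$background else gsub("[^A-Za-z0-9.+-]", "", key)
}

#' Configuration for the pharyngeal-pumping simulator
#'
#' Pumping rate (contractions/min) declines exponentially with age:
#' `rate(day) = rate_day1 * exp(-decline_rate * (day - 1))`, with Gaussian
#' counting noise, truncation at zero and rounding to integer counts.
#' Interventions multiply the decline rate (values < 1 slow the decline).
#' Defaults emulate a wild-type-like decline from ~250/min at day 1 toward
#' ~15/min at day 15, sampled at days 1, 5, 10 and 15 on 14 filmed worms.
#'
#' @param rate_day1 Mean contractions/min at day 1 post-L4.
#' @param decline_rate Exponential decay per day.
#' @param intervention_rate_effects Named numeric: multiplicative slowdown of
#'   the decline per intervention.
#' @param noise_sd Gaussian noise SD (counts/min).
#' @param sample_days Observation days post-L4.
#' @param n_sampled Worms filmed per strain per time point.
#' @param seed Master seed.
#' @return An object of class `pumping_config`.
#' @export
pumping_config <- function(rate_day1 = 250, decline_rate = 0.20,
                           intervention_rate_effects = numeric(),
                           noise_sd = 25, sample_days = c(1, 5, 10, 15),
                           n_sampled = 14, seed = 1L) {
  stopifnot(rate_day1 > 0, decline_rate >= 0, n_sampled >= 1, noise_sd >= 0)
  structure(list(rate_day1 = rate_day1, decline_rate = decline_rate,
                 intervention_rate_effects = intervention_rate_effects,
                 noise_sd = noise_sd, sample_days = sample_days,
                 n_sampled = as.integer(n_sampled), seed = as.integer(seed)),
            class = "pumping_config")
}

#' Simulate a pharyngeal-pumping endpoint table
#'
#' @param config A [pumping_config()].
#' @param strains List of [intervention_set()] objects.
#' @return An endpoint table: data.frame with columns `assay`, `worm_id`,
#'   `strain`, `replicate`, `day`, `value` (non-negative integer
#'   contractions/min).
#' @export
simulate_pumping <- function(config, strains) {
  stopifnot(inherits(config, "pumping_config"))
  if (inherits(strains, "intervention_set")) strains <- list(strains)
  out <- list()
  for (set in strains) {
    iv <- set$interventions
    unknown <- setdiff(iv, names(config$intervention_rate_effects))
    if (length(iv) && length(unknown) &&
        length(config$intervention_rate_effects))
      stop("no intervention_rate_effects entry for: ",
           paste(unknown, collapse = ", "))
    eff <- config$intervention_rate_effects[iv]
    slow <- if (length(eff)) prod(eff) else 1
    d <- config$decline_rate * slow
    set.seed(derive_seed(config$seed, paste0("pump:", set$label)))
    for (day in config$sample_days) {
      mu <- config$rate_day1 * exp(-d * (day - 1))
      vals <- round(pmax(0, stats::rnorm(config$n_sampled, mu,
                                         config$noise_sd)))
      out[[length(out) + 1]] <- data.frame(
        assay = "pumping",
        worm_id = sprintf("%s_d%d_w%02d", iv_key_or_bg(set), day,
                          seq_len(config$n_sampled)),
        strain = set$label, replicate = 1L, day = day, value = vals,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate a stress-survival assay
#'
#' A seeded binomial draw of survivors out of `n` exposed animals, emulating
#' scoring the fraction alive after an acute heat or oxidative insult.
#'
#' @param n Number of animals exposed (`n >= 1`).
#' @param survival_prob True per-animal survival probability.
#' @param seed Seed.
#' @return list with `survivors` and `total`.
#' @export
simulate_stress_assay <- function(n, survival_prob, seed = 1L) {
  if (n < 1) stop("n must be at least 1")
  if (survival_prob < 0 || survival_prob > 1)
    stop("survival_prob must be in [0, 1]")
  set.seed(as.integer(seed))
  list(survivors = stats::rbinom(1, n, survival_prob), total = as.integer(n))
}
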