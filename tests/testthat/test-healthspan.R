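test_that("transition times use the composite exit-or-death endpoint", {
  co <- worm_cohort(rbind(
    worm_records("w1", c("A", "A", "B", "B")),          # exits A on day 2
    worm_records("w2", c("A", "A")),                    # dies day 2 in A
    worm_records("w3", c("A", "A", "A"), terminal = "censored",
                 cause = "wall")))                      # censored day 3 in A
  tt <- extract_transition_times(co, "WT", "A")
  tt <- tt[order(tt$worm_id), ]
  expect_equal(tt$duration, c(2, 2, 3))
  expect_equal(tt$event, c(TRUE, TRUE, FALSE))

  # exit from {A, B}: w1 dies on day 4 having never reached C
  tab <- extract_transition_times(co, "WT", c("A", "B"))
  expect_equal(tab$duration[tab$worm_id == "w1"], 4)
  expect_true(tab$event[tab$worm_id == "w1"])

  excl <- extract_transition_times(co, "WT", "A", censor_policy = "exclude")
  expect_false("w3" %in% excl$worm_id)
})

test_that("worms mobile until death give mobile time = lifespan", {
  co <- worm_cohort(rbind(worm_records("a", rep("A", 10)),
                          worm_records("b", rep("A", 14))))
  occ <- state_mean_durations(co, "WT")
  expect_equal(occ$mean_mobile, occ$mean_lifespan)
  expect_equal(occ$mean_impaired, 0)
  expect_equal(occ$mean_frail, 0)
  expect_equal(occ$frac_mobile, 100)
})

test_that("decomposition identity is exact on censoring-free cohorts", {
  cfg <- test_sim_config(n_worms = 120, censor_daily_prob = 0)
  co <- simulate_cohort(cfg, list(wt_set(), intervention_set("odr-3")))
  for (s in c("WT", "odr-3")) {
    occ <- state_mean_durations(co, s)
    expect_equal(occ$mean_mobile + occ$mean_impaired + occ$mean_frail,
                 occ$mean_lifespan, tolerance = 1e-10)
    d <- cohort_durations(co, s)
    expect_equal(occ$mean_lifespan, mean(d$duration), tolerance = 1e-10)
    expect_gte(occ$mean_impaired, 0)
    expect_gte(occ$mean_frail, 0)
    expect_equal(occ$frac_mobile + occ$frac_impaired + occ$frac_frail, 100,
                 tolerance = 0.2)
  }
})

test_that("occupancy ordering holds under censoring", {
  cfg <- test_sim_config(n_worms = 150, censor_daily_prob = 0.03)
  co <- simulate_cohort(cfg, list(wt_set()))
  occ <- state_mean_durations(co, "WT")
  ta <- extract_transition_times(co, "WT", "A")
  tab <- extract_transition_times(co, "WT", c("A", "B"))
  d <- cohort_durations(co, "WT")
  h <- max(d$duration)
  m_a <- km_mean(km_curve(ta$duration, ta$event), horizon = h)
  m_ab <- km_mean(km_curve(tab$duration, tab$event), horizon = h)
  m_l <- km_mean(km_curve(d$duration, d$event), horizon = h)
  expect_lte(m_a, m_ab + 1e-12)
  expect_lte(m_ab, m_l + 1e-12)
  expect_equal(occ$mean_mobile, m_a)
})

test_that("published occupancy rows replay to the printed fractions", {
  rep_ <- published_replay()
  fr <- rep_$fractions
  expect_equal(fr$frac_mobile[fr$strain == "WT(EV)"], 84.0)
  expect_equal(fr$frac_mobile[fr$strain == "odr-3"], 80.0)
  expect_equal(fr$frac_mobile[fr$strain == "odr-3; ife-2"], 86.5)
  expect_equal(fr$frac_impaired[fr$strain == "WT(EV)"], 7.3)
  expect_equal(fr$frac_frail[fr$strain == "WT(EV)"], 8.7)
  # mean durations sum exactly to the printed mean lifespans
  occ <- published_occupancy()
  expect_equal(occ$mean_mobile + occ$mean_impaired + occ$mean_frail,
               occ$mean_lifespan)
})

test_that("fraction changes match the published comparisons", {
  a <- state_occupancy("odr-3", 80, 10, 10, 100)
  b <- state_occupancy("WT", 84, 7.3, 8.7, 100)
  expect_equal(round(fraction_change(a, b, "mobile"), 1), -4.8)
  ife <- state_occupancy("ife-2", 86.4, 6.6, 7.0, 100)
  expect_equal(round(fraction_change(ife, b, "frail"), 1), -19.5)
  expect_equal(fraction_change(b, b, "mobile"), 0)
  zero <- state_occupancy("z", 100, 0, 0, 100)
  expect_error(fraction_change(b, zero, "frail"), "zero")
})

test_that("daily state distribution tallies live worms only", {
  co <- tiny_cohort()
  d <- daily_state_distribution(co, "WT")
  expect_equal(d$frac_A[d$day == 0], 1)
  two <- worm_cohort(rbind(worm_records("x", c("A", "B")),
                           worm_records("y", c("A", "C"))))
  dd <- daily_state_distribution(two, "WT")
  expect_equal(unlist(dd[dd$day == 1, c("frac_A", "frac_B", "frac_C")],
                      use.names = FALSE), c(0, 0.5, 0.5))
  expect_true(all(abs(rowSums(dd[c("frac_A", "frac_B", "frac_C")]) - 1)
                  < 1e-12))

  # brute-force tally oracle on a simulated cohort
  cfg <- test_sim_config(n_worms = 50)
  sim <- simulate_cohort(cfg, list(wt_set()))
  ds <- daily_state_distribution(sim, "WT")
  r <- sim$records[sim$records$status == "alive", ]
  for (day in sample(ds$day, 5)) {
    rows <- r[r$day == day, ]
    expect_equal(ds$frac_B[ds$day == day], mean(rows$motility == "B"))
    expect_equal(ds$n_alive[ds$day == day], nrow(rows))
  }
})

test_that("motility log-rank detects slower mobility decline", {
  co <- tiny_cohort()
  self <- motility_logrank(co, "WT", "WT")
  expect_equal(self$p_value, 1)

  cfg <- test_sim_config(n_worms = 250, censor_daily_prob = 0,
                         intervention_effects = c(slowmo = 0),
                         motility_effects = c(slowmo = -1.5))
  sim <- simulate_cohort(cfg, list(wt_set(), intervention_set("slowmo")))
  r <- motility_logrank(sim, "WT", "slowmo", "A")
  expect_lt(r$p_value, 1e-6)
  occ_wt <- state_mean_durations(sim, "WT")
  occ_slow <- state_mean_durations(sim, "slowmo")
  expect_gt(occ_slow$mean_mobile, occ_wt$mean_mobile)
})

test_that("occupancy table reports all strains with control-relative changes", {
  cfg <- test_sim_config(n_worms = 60)
  co <- simulate_cohort(cfg, list(wt_set(), intervention_set("odr-3")))
  tab <- occupancy_table(co, control = "WT")
  expect_equal(tab$strain[1], "WT")
  expect_equal(tab$change_mobile[1], 0)
  expect_true(all(c("mean_mobile", "frac_frail", "change_frail") %in%
                  names(tab)))
})
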