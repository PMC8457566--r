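# Fixture builders: hand-made observation records and small simulation
# configs, all constructed in code.

# One worm's records: `motility` is the per-day stage sequence while alive;
# the terminal record follows on the next day.
worm_records <- function(id, motility, terminal = "dead", cause = "none",
                         strain = "WT", replicate = 1L) {
  n <- length(motility)
  data.frame(worm_id = id, strain = strain, replicate = replicate,
             day = 0:n,
             status = c(rep("alive", n), terminal),
             censor_cause = c(rep("none", n),
                              if (terminal == "censored") cause else "none"),
             motility = c(motility, "not_scored"),
             stringsAsFactors = FALSE)
}

# A small hand-made two-strain cohort.
tiny_cohort <- function() {
  recs <- rbind(
    worm_records("w1", c("A", "A", "B")),
    worm_records("w2", c("A", "B", "B", "C")),
    worm_records("w3", c("A", "A"), terminal = "censored", cause = "wall"),
    worm_records("w4", c("A", "A", "A", "B", "C"), strain = "mut"),
    worm_records("w5", c("A", "A", "A", "A"), strain = "mut"))
  worm_cohort(recs)
}

# Fast simulation config for tests: small cohorts, no interactions.
test_sim_config <- function(...) {
  args <- list(n_worms = 40, n_replicates = 1, seed = 7L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simulation_config, args)
}

wt_set <- function() intervention_set()

# Independent product-limit oracle: direct hand computation of the KM
# steps, never via the package or the survival package.
km_oracle <- function(durations, events) {
  ts <- sort(unique(durations[events]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    t <- ts[i]
    n_risk <- sum(durations >= t)
    d <- sum(durations == t & events)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}

# Independent log-rank oracle: O-E and hypergeometric variance summed over
# event times, two groups.
logrank_oracle <- function(d1, e1, d2, e2) {
  times <- sort(unique(c(d1[e1], d2[e2])))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    n1 <- sum(d1 >= t); n2 <- sum(d2 >= t); n <- n1 + n2
    dd1 <- sum(d1 == t & e1); dd2 <- sum(d2 == t & e2); dd <- dd1 + dd2
    o_minus_e <- o_minus_e + dd1 - dd * n1 / n
    if (n > 1) v <- v + dd * (n1 / n) * (n2 / n) * (n - dd) / (n - 1)
  }
  (o_minus_e)^2 / v
}
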