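# Replay of the published summary statistics: the per-strain means shipped
# with the package (lifespan table, state-occupancy durations, day-15
# pumping effects) are treated as inputs and pushed through the effect
# arithmetic, the occupancy fractions and the synergy classifier -- a full
# desk check of the analysis chain that involves no simulation.

replay_file <- function(name) {
  system.file("extdata", name, package = "nemaspan", mustWork = TRUE)
}

parse_set <- function(interventions, modes = NULL, label = NULL,
                      background = "WT") {
  iv <- if (interventions %in% c("", ".")) character() else
    strsplit(interventions, ",", fixed = TRUE)[[1]]
  md <- if (is.null(modes) || modes %in% c("", ".")) NULL else
    strsplit(modes, ",", fixed = TRUE)[[1]]
  intervention_set(iv, modes = md, background = background, label = label)
}

#' Published per-strain mean lifespans shipped with the package
#'
#' The mean lifespan table of the combined odr-3 / ife-2 / cku-70
#' intervention experiments (WT background, 20 C, pooled replicates):
#' strain label, intervention set, comparability arm (`full` = full-dose
#' RNAi, `ev` = half-dose 1:1 RNAi/EV mixes, `both` = identical in either
#' arm), mean lifespan (days), SEM and the reported log-rank p-value versus
#' control (upper bounds stored at their bound).
#'
#' @return data.frame with a list-column `set` of [intervention_set()]s.
#' @export
published_lifespans <- function() {
  x <- utils::read.delim(replay_file("published_lifespans.tsv"),
                         stringsAsFactors = FALSE)
  x$set <- Map(parse_set, x$interventions, x$modes, x$label)
  x
}

#' Published state-occupancy durations shipped with the package
#'
#' Mean days spent mobile, impaired and frail, plus mean lifespan, for the
#' WT(EV), odr-3, ife-2 and odr-3; ife-2 strains.
#'
#' @return data.frame.
#' @export
published_occupancy <- function() {
  utils::read.delim(replay_file("published_occupancy.tsv"),
                    stringsAsFactors = FALSE)
}

#' Replay the published summary statistics through the analysis chain
#'
#' Recomputes, from the printed per-strain means only (no simulation):
#' every "effect vs control" percentage of the lifespan table; the
#' state-occupancy lifespan fractions and their changes versus control; the
#' synergy classification of the odr-3 + ife-2 combination on mean lifespan
#' (full-dose arm), of the triple combination on the half-dose arm, and of
#' the day-15 pharyngeal-pumping combination.
#'
#' @param tol_rel Relative additivity tolerance for the classifier,
#'   default 0.10.
#' @return list with `effects` (data.frame: strain, mean, effect_percent),
#'   `occupancy` (list of [state_occupancy()]), `fractions` (data.frame),
#'   `fraction_changes` (data.frame), `lifespan_classification`,
#'   `triple_classification`, `pumping_classification`.
#' @export
published_replay <- function(tol_rel = 0.10) {
  t1 <- published_lifespans()
  ctrl_mean <- t1$mean_lifespan[t1$label == "WT(EV)"]
  effects <- data.frame(
    strain = t1$label,
    mean_lifespan = t1$mean_lifespan,
    effect_percent = round(effect_percent(t1$mean_lifespan, ctrl_mean), 1),
    stringsAsFactors = FALSE)

  lat <- function(arm) {
    rows <- which(t1$arm %in% c(arm, "both"))
    build_lattice(lapply(rows, function(i)
      list(set = t1$set[[i]], value = t1$mean_lifespan[i], sem = t1$sem[i],
           p_adjusted = t1$p_value[i])))
  }
  lifespan_cls <- classify_combination(lat("full"), c("odr-3", "ife-2"),
                                       tol_rel = tol_rel)
  triple_cls <- classify_combination(lat("ev"),
                                     c("odr-3", "ife-2", "cku-70"),
                                     tol_rel = tol_rel)

  occ_tab <- published_occupancy()
  occupancy <- lapply(seq_len(nrow(occ_tab)), function(i)
    state_occupancy(occ_tab$strain[i], occ_tab$mean_mobile[i],
                    occ_tab$mean_impaired[i], occ_tab$mean_frail[i],
                    occ_tab$mean_lifespan[i]))
  names(occupancy) <- occ_tab$strain
  fractions <- data.frame(
    strain = occ_tab$strain,
    frac_mobile = round(vapply(occupancy, `[[`, 0, "frac_mobile"), 1),
    frac_impaired = round(vapply(occupancy, `[[`, 0, "frac_impaired"), 1),
    frac_frail = round(vapply(occupancy, `[[`, 0, "frac_frail"), 1),
    stringsAsFactors = FALSE, row.names = NULL)
  ctrl <- occupancy[["WT(EV)"]]
  chg <- expand.grid(strain = setdiff(occ_tab$strain, "WT(EV)"),
                     state = c("mobile", "impaired", "frail"),
                     stringsAsFactors = FALSE)
  chg$change_percent <- round(mapply(function(s, st)
    fraction_change(occupancy[[s]], ctrl, st), chg$strain, chg$state), 1)

  pump <- utils::read.delim(replay_file("pumping_day15_effects.tsv"),
                            stringsAsFactors = FALSE)
  # reconstruct node values on an arbitrary positive control scale (100),
  # so that effect_percent() reproduces the printed effects exactly
  pump_lat <- build_lattice(lapply(seq_len(nrow(pump)), function(i)
    list(set = parse_set(pump$interventions[i], label = pump$label[i]),
         value = 100 + pump$effect_percent[i])),
    endpoint = "pumping_day15")
  pumping_cls <- classify_combination(pump_lat, c("odr-3", "ife-2"),
                                      tol_rel = tol_rel)

  list(effects = effects, occupancy = occupancy, fractions = fractions,
       fraction_changes = chg, lifespan_classification = lifespan_cls,
       triple_classification = triple_cls,
       pumping_classification = pumping_cls,
       lattice_full = lat("full"), lattice_ev = lat("ev"))
}
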