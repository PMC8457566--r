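# End-to-end orchestration: simulate (or load) a cohort, run the survival
# and occupancy analyses, build the strain network, classify every measured
# combination, and write a deterministic report bundle with a
# machine-readable manifest.

#' Configuration of a report run
#'
#' Exactly one of `cohort` (a [worm_cohort()] or path to an observation
#' file) or `sim_config` + `strains` must be supplied.
#'
#' @param cohort A [worm_cohort()] or file path, or `NULL`.
#' @param sim_config A [simulation_config()], or `NULL`.
#' @param strains List of [intervention_set()]s (required with
#'   `sim_config`; used to map strain labels to sets when classifying).
#' @param control Label of the control strain.
#' @param alpha Significance level, default 0.05.
#' @param tol_rel Additivity tolerance for the classifier, default 0.10.
#' @param out_dir Output directory for the bundle.
#' @param seed Master seed recorded in the manifest (overrides the one in
#'   `sim_config` when given).
#' @param quiet Suppress progress messages.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = NULL, sim_config = NULL, strains = NULL,
                       control, alpha = 0.05, tol_rel = 0.10,
                       out_dir = tempfile("nemaspan_report_"), seed = NULL,
                       quiet = FALSE) {
  if (is.null(cohort) == is.null(sim_config))
    stop("supply exactly one of 'cohort' or 'sim_config'")
  if (!is.null(sim_config) && is.null(strains))
    stop("'strains' is required with a simulation config")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(cohort = cohort, sim_config = sim_config,
                 strains = strains, control = control, alpha = alpha,
                 tol_rel = tol_rel, out_dir = out_dir, seed = seed,
                 quiet = quiet),
            class = "run_config")
}

report_log <- function(quiet, stage, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Stages: obtain the cohort (simulation or file), validate, survival table
#' with log-rank tests and BH correction, state-occupancy table, effect
#' lattice + strain network (GraphML), synergy classification of every
#' strain carrying >= 2 interventions, and a JSON manifest listing package
#' version, seed, and the MD5 digest of every artifact. Identical
#' configuration and seed produce a byte-identical bundle (the manifest
#' contains no timestamps).
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory tables, classifications and
#'   the manifest.
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  quiet <- isTRUE(config$quiet)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()

  if (!is.null(config$sim_config)) {
    sc <- config$sim_config
    if (!is.null(config$seed)) sc$seed <- as.integer(config$seed)
    report_log(quiet, "simulate", length(config$strains), " strains, ",
               sc$n_worms, " worms x ", sc$n_replicates,
               " replicates, seed ", sc$seed)
    cohort <- simulate_cohort(sc, config$strains)
    cohort_path <- file.path(config$out_dir, "cohort.tsv")
    write_cohort(cohort, cohort_path)
    artifacts["cohort"] <- cohort_path
    seed_used <- sc$seed
  } else {
    cohort <- config$cohort
    if (is.character(cohort)) cohort <- read_cohort(cohort)
    if (!is.null(config$strains))
      cohort$strains <- stats::setNames(
        config$strains, vapply(config$strains, `[[`, "", "label"))
    seed_used <- if (is.null(config$seed)) NA_integer_ else config$seed
  }
  validate_cohort(cohort)
  strains_present <- unique(cohort$records$strain)
  if (!config$control %in% strains_present)
    stop("control strain '", config$control,
         "' missing from cohort (background has no control)")

  report_log(quiet, "survival", length(strains_present), " strains vs ",
             config$control)
  surv <- survival_table(cohort, config$control, alpha = config$alpha)
  surv_path <- file.path(config$out_dir, "survival.tsv")
  utils::write.table(surv, surv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  artifacts["survival"] <- surv_path

  report_log(quiet, "healthspan", "state occupancy per strain")
  occ <- occupancy_table(cohort, control = config$control)
  occ_path <- file.path(config$out_dir, "occupancy.tsv")
  utils::write.table(occ, occ_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  artifacts["occupancy"] <- occ_path

  classifications <- list()
  lattice <- NULL
  if (!is.null(cohort$strains)) {
    report_log(quiet, "lattice", "building effect lattice and network")
    sums <- lapply(seq_len(nrow(surv)), function(i) {
      set <- cohort$strains[[surv$strain[i]]]
      if (is.null(set)) return(NULL)
      list(set = set, value = surv$mean_lifespan[i], sem = surv$sem[i],
           p_adjusted = suppressWarnings(
             as.numeric(gsub("<", "", surv$p_adjusted[i]))))
    })
    sums <- Filter(Negate(is.null), sums)
    lattice <- build_lattice(sums)
    graph <- annotate_edges(lattice, alpha = config$alpha)
    graph_path <- file.path(config$out_dir, "network.graphml")
    export_graph(graph, graph_path, "graphml")
    artifacts["network"] <- graph_path
    multi <- Filter(function(s) length(s$interventions) >= 2,
                    cohort$strains)
    for (set in multi) {
      cls <- tryCatch(
        classify_combination(lattice, set, tol_rel = config$tol_rel),
        error = function(e) list(target = iv_key(set),
                                 category = "unclassifiable",
                                 reason = conditionMessage(e)))
      classifications[[iv_key(set)]] <- cls
      report_log(quiet, "classify", iv_key(set), " -> ", cls$category)
    }
    cls_path <- file.path(config$out_dir, "classifications.json")
    jsonlite::write_json(
      lapply(classifications, function(cls)
        list(target = cls$target, category = cls$category,
             tolerance = cls$tolerance_used,
             evidence = cls$evidence)),
      cls_path, digits = NA, auto_unbox = TRUE, null = "null")
    artifacts["classifications"] <- cls_path
  }

  manifest <- list(
    package = "nemaspan",
    version = as.character(utils::packageVersion("nemaspan")),
    seed = seed_used,
    control = config$control,
    alpha = config$alpha,
    tol_rel = config$tol_rel,
    n_worms = length(unique(cohort$records$worm_id)),
    n_strains = length(strains_present),
    artifacts = lapply(stats::setNames(nm = names(artifacts)), function(a)
      list(file = basename(artifacts[[a]]),
           md5 = unname(tools::md5sum(artifacts[[a]])))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, digits = NA,
                       auto_unbox = TRUE, null = "null")
  report_log(quiet, "done", "bundle written to ", config$out_dir)
  invisible(list(cohort = cohort, survival = surv, occupancy = occ,
                 lattice = lattice, classifications = classifications,
                 manifest = manifest, out_dir = config$out_dir))
}
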