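# Observation-table data model: one row per worm per day, daily scoring at
# 20 C, death/censoring as terminal records, A/B/C motility staging.

COHORT_COLUMNS <- c("worm_id", "strain", "replicate", "day",
                    "status", "censor_cause", "motility")
STATUS_LEVELS <- c("alive", "dead", "censored")
CENSOR_CAUSES <- c("none", "bagging", "wall", "extrusion", "other")
MOTILITY_LEVELS <- c("A", "B", "C", "not_scored")

#' Construct a worm cohort from per-worm-day observation records
#'
#' A cohort couples an observation table (one row per worm per day: status
#' alive/dead/censored, censoring cause, motility stage A/B/C) with per-strain
#' culture metadata. The recorded death day is the first day a worm was scored
#' dead (last day alive + 1); day 0 is the L4 moult.
#'
#' @param records data.frame with columns `worm_id`, `strain`, `replicate`,
#'   `day`, `status`, `censor_cause`, `motility`.
#' @param metadata data.frame with columns `strain`, `diet`, `temperature`,
#'   `fudr`; defaults to one placeholder row per strain present in `records`
#'   (HT115 diet, 20 C, 15 uM FUdR -- the standard conditions).
#' @param strains Optional named list of [intervention_set()] objects keyed by
#'   strain label, mapping labels in `records` to intervention sets.
#' @param validate Run [validate_cohort()] (default `TRUE`).
#' @return An object of class `worm_cohort`.
#' @seealso [read_cohort()], [simulate_cohort()]
#' @export
worm_cohort <- function(records, metadata = NULL, strains = NULL,
                        validate = TRUE) {
  records <- as.data.frame(records)
  missing_cols <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing_cols))
    stop("observation table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  records <- records[COHORT_COLUMNS]
  records$worm_id <- as.character(records$worm_id)
  records$strain <- as.character(records$strain)
  records$replicate <- as.integer(records$replicate)
  records$day <- as.integer(records$day)
  records$status <- as.character(records$status)
  records$censor_cause <- as.character(records$censor_cause)
  records$motility <- as.character(records$motility)
  rownames(records) <- NULL
  if (is.null(metadata)) {
    labs <- sort(unique(records$strain))
    metadata <- data.frame(strain = labs,
                           diet = rep("HT115(DE3)", length(labs)),
                           temperature = rep(20, length(labs)),
                           fudr = rep(15, length(labs)),
                           stringsAsFactors = FALSE)
  }
  metadata <- as.data.frame(metadata)
  x <- structure(list(records = records, metadata = metadata,
                      strains = strains),
                 class = "worm_cohort")
  if (validate) validate_cohort(x)
  x
}

#' @export
print.worm_cohort <- function(x, ...) {
  r <- x$records
  term <- r[r$status != "alive", , drop = FALSE]
  cat("<worm_cohort> ", length(unique(r$worm_id)), " worms, ",
      length(unique(r$strain)), " strain(s), ",
      length(unique(r$replicate)), " replicate(s), ",
      nrow(r), " worm-day records\n", sep = "")
  cat("  deaths: ", sum(term$status == "dead"),
      "  censored: ", sum(term$status == "censored"), "\n", sep = "")
  invisible(x)
}

#' Validate the per-worm invariants of an observation table
#'
#' Checks, per worm: exactly one terminal (dead/censored) record and nothing
#' after it; strictly increasing consecutive days; motility scored iff alive;
#' monotone non-improving A->B->C motility (the progressive staging of the
#' locomotion assay); censoring causes drawn from the recognised list
#' (bagging, wall-crawling, organ extrusion, other). Every strain referenced
#' must appear in the metadata.
#'
#' @param cohort A [worm_cohort()].
#' @param permissive_motility Allow `not_scored` motility on days a worm is
#'   alive (default `FALSE`: daily motility scoring is required, as in the
#'   locomotion assay run alongside the lifespan assay).
#' @return Invisibly `TRUE`; otherwise an error naming the offending worm and
#'   rule.
#' @export
validate_cohort <- function(cohort, permissive_motility = FALSE) {
  r <- cohort$records
  bad_status <- !r$status %in% STATUS_LEVELS
  if (any(bad_status))
    stop("unknown status value(s): ",
         paste(unique(r$status[bad_status]), collapse = ", "))
  bad_cause <- !r$censor_cause %in% CENSOR_CAUSES
  if (any(bad_cause))
    stop("unknown censor_cause value(s): ",
         paste(unique(r$censor_cause[bad_cause]), collapse = ", "),
         " (recognised: ", paste(CENSOR_CAUSES, collapse = ", "), ")")
  bad_mot <- !r$motility %in% MOTILITY_LEVELS
  if (any(bad_mot))
    stop("unknown motility value(s): ",
         paste(unique(r$motility[bad_mot]), collapse = ", "))
  if (any(r$day < 0)) stop("negative day values")
  if (any(r$censor_cause != "none" & r$status != "censored"))
    stop("censor_cause given on a non-censored record: worm ",
         r$worm_id[which(r$censor_cause != "none" & r$status != "censored")[1]])
  if (any(r$status == "censored" & r$censor_cause == "none"))
    stop("censored record without a censor_cause: worm ",
         r$worm_id[which(r$status == "censored" & r$censor_cause == "none")[1]])

  fail <- function(id, rule) stop("worm ", id, ": ", rule, call. = FALSE)
  for (id in unique(r$worm_id)) {
    w <- r[r$worm_id == id, , drop = FALSE]
    w <- w[order(w$day), , drop = FALSE]
    term <- which(w$status != "alive")
    if (length(term) == 0)
      fail(id, "no terminal (dead/censored) record")
    if (length(term) > 1 || term != nrow(w))
      fail(id, "records present after the terminal (dead/censored) record")
    if (nrow(w) > 1 && any(diff(w$day) != 1L))
      fail(id, "days are not strictly increasing consecutive integers")
    alive <- w$status == "alive"
    if (any(w$motility[!alive] != "not_scored"))
      fail(id, "motility scored on a dead/censored record")
    if (!permissive_motility && any(w$motility[alive] == "not_scored"))
      fail(id, "motility not scored on a day the worm was alive")
    stages <- match(w$motility[alive & w$motility != "not_scored"],
                    c("A", "B", "C"))
    if (length(stages) > 1 && any(diff(stages) < 0))
      fail(id, "motility improves over days (non-monotone A->B->C trajectory)")
    if (length(unique(w$strain)) > 1)
      fail(id, "worm assigned to more than one strain")
  }
  missing_meta <- setdiff(unique(r$strain), cohort$metadata$strain)
  if (length(missing_meta))
    stop("strain(s) missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  invisible(TRUE)
}

detect_delimiter <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a cohort observation table from delimited text
#'
#' The file must be UTF-8 delimited text (comma or tab, auto-detected from
#' the header line) with one row per worm per day and columns `worm_id`,
#' `strain`, `replicate`, `day`, `status`, `censor_cause`, `motility`.
#' The table is validated on read.
#'
#' @param path Path to the observation file.
#' @param dialect Field delimiter; `NULL` (default) auto-detects tab vs comma.
#' @inheritParams worm_cohort
#' @return A [worm_cohort()].
#' @export
read_cohort <- function(path, dialect = NULL, metadata = NULL,
                        strains = NULL, permissive_motility = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (is.null(dialect)) detect_delimiter(path) else dialect
  records <- utils::read.table(path, header = TRUE, sep = sep,
                               colClasses = "character",
                               stringsAsFactors = FALSE, quote = "",
                               comment.char = "", na.strings = NULL,
                               fileEncoding = "UTF-8")
  missing_cols <- setdiff(COHORT_COLUMNS, names(records))
  if (length(missing_cols))
    stop("observation file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  x <- worm_cohort(records, metadata = metadata, strains = strains,
                   validate = FALSE)
  validate_cohort(x, permissive_motility = permissive_motility)
  x
}

#' Write a cohort observation table as tab-delimited text
#'
#' Output is deterministic: rows sorted by (strain, worm_id, day), fixed
#' column order, no quoting. The file round-trips through [read_cohort()].
#'
#' @param cohort A [worm_cohort()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  r <- cohort$records
  r <- r[order(r$strain, r$worm_id, r$day), COHORT_COLUMNS, drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(COHORT_COLUMNS, collapse = "\t"), con)
  if (nrow(r))
    writeLines(do.call(paste, c(unname(as.list(r)), sep = "\t")), con)
  invisible(path)
}

#' Pool replicate cohorts into one
#'
#' Union of the observation records of several independently run experiments,
#' with replicate indices kept distinct across sources and worm identifiers
#' disambiguated (prefixed by experiment index). Pooling a single cohort is
#' the identity. Metadata for a strain appearing in several sources must
#' agree.
#'
#' @param cohorts List of [worm_cohort()] objects.
#' @return A pooled [worm_cohort()].
#' @export
pool_replicates <- function(cohorts) {
  stopifnot(length(cohorts) >= 1)
  if (length(cohorts) == 1) return(cohorts[[1]])
  meta_all <- unique(do.call(rbind, lapply(cohorts, `[[`, "metadata")))
  if (anyDuplicated(meta_all$strain))
    stop("conflicting metadata for strain(s): ",
         paste(unique(meta_all$strain[duplicated(meta_all$strain)]),
               collapse = ", "))
  offset <- 0L
  recs <- vector("list", length(cohorts))
  for (i in seq_along(cohorts)) {
    r <- cohorts[[i]]$records
    r$worm_id <- paste0("e", i, ".", r$worm_id)
    r$replicate <- r$replicate + offset
    offset <- max(r$replicate)
    recs[[i]] <- r
  }
  strains <- do.call(c, lapply(cohorts, `[[`, "strains"))
  strains <- strains[!duplicated(names(strains))]
  worm_cohort(do.call(rbind, recs), metadata = meta_all, strains = strains)
}

#' Per-worm durations and event indicators
#'
#' Collapses the daily records to one row per worm: the terminal day
#' (recorded death day, or censoring day), whether the terminal record is a
#' death, and the censoring cause.
#'
#' @param cohort A [worm_cohort()].
#' @param strain Optional strain label to filter on.
#' @return data.frame with columns `worm_id`, `strain`, `replicate`,
#'   `duration`, `event`, `censor_cause`.
#' @export
cohort_durations <- function(cohort, strain = NULL) {
  r <- cohort$records
  if (!is.null(strain)) {
    r <- r[r$strain == strain, , drop = FALSE]
    if (nrow(r) == 0) stop("no records for strain ", strain)
  }
  term <- r[r$status != "alive", , drop = FALSE]
  data.frame(worm_id = term$worm_id, strain = term$strain,
             replicate = term$replicate, duration = term$day,
             event = term$status == "dead",
             censor_cause = term$censor_cause,
             stringsAsFactors = FALSE, row.names = NULL)
}
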