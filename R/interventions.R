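#' Define a set of longevity interventions carried by a strain
#'
#' An intervention set identifies a worm strain by the genetic interventions
#' it carries (e.g. a mutation in `odr-3`, RNAi knock-down of `ife-2`) on top
#' of a genetic background (wild type, or e.g. a `daf-16` mutant). The empty
#' set denotes the control strain for its background. Equality is
#' order-insensitive: interventions are stored sorted by gene symbol.
#'
#' @param interventions Character vector of intervention identifiers
#'   (gene symbols). May be empty (the control strain).
#' @param modes Delivery mode per intervention, each one of `"mutation"`,
#'   `"rnai"` or `"rnai_diluted"` (RNAi bacteria mixed 1:1 with empty-vector
#'   bacteria, i.e. half-dose dsRNA). Recycled from length 1; default
#'   `"mutation"`.
#' @param background Background genotype identifier, default `"WT"`.
#' @param label Display label; defaults to the background for the empty set,
#'   otherwise the sorted gene symbols joined by `"; "` (diluted knock-downs
#'   are suffixed `";EV"`).
#' @return An object of class `intervention_set`.
#' @examples
#' intervention_set("odr-3")
#' intervention_set(c("odr-3", "ife-2"), modes = c("mutation", "rnai"))
#' intervention_set()  # control
#' @export
intervention_set <- function(interventions = character(), modes = NULL,
                             background = "WT", label = NULL) {
  interventions <- as.character(interventions)
  if (anyDuplicated(interventions))
    stop("intervention identifiers must be unique within a set")
  if (is.null(modes)) modes <- "mutation"
  modes <- rep_len(as.character(modes), length(interventions))
  ok <- modes %in% c("mutation", "rnai", "rnai_diluted")
  if (length(interventions) > 0 && !all(ok))
    stop("modes must be one of 'mutation', 'rnai', 'rnai_diluted'")
  ord <- order(interventions)
  interventions <- interventions[ord]
  modes <- modes[ord]
  names(modes) <- interventions
  if (is.null(label)) {
    label <- if (length(interventions) == 0) background else
      paste(ifelse(modes == "rnai_diluted",
                   paste0(interventions, ";EV"), interventions),
            collapse = "; ")
  }
  structure(
    list(interventions = interventions, modes = modes,
         background = as.character(background), label = as.character(label)),
    class = "intervention_set")
}

#' @export
print.intervention_set <- function(x, ...) {
  cat("<intervention_set> ", x$label,
      " [background ", x$background, "]\n", sep = "")
  if (length(x$interventions))
    cat("  ", paste0(x$interventions, " (", x$modes, ")", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Canonical key of an intervention set
#'
#' Order-insensitive identifier used to index lattice nodes: sorted gene
#' symbols joined by `"+"`; the empty set maps to `""`.
#'
#' @param x An `intervention_set` or a character vector of gene symbols.
#' @return A length-1 character key.
#' @export
iv_key <- function(x) {
  iv <- if (inherits(x, "intervention_set")) x$interventions else
    as.character(x)
  paste(sort(iv), collapse = "+")
}

#' @export
`==.intervention_set` <- function(e1, e2) {
  iv_key(e1) == iv_key(e2) && e1$background == e2$background
}

is_subset_of <- function(a, b) all(a %in% b)
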