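# Classification of intervention combinations over the subset lattice of
# measured strains (full/simple/partially-known synergism, additive,
# intermediate, antagonistic, deleterious), and the strain-network graph
# with percent-change edges.

#' Build an effect lattice from per-strain endpoint summaries
#'
#' Indexes strain summaries by the (order-insensitive) set of interventions
#' each carries and computes every strain's percent effect versus the empty
#' set (the control of the shared background). All strains must share one
#' background; mixed-background summaries must be split into separate
#' lattices.
#'
#' @param summaries List of lists/rows, each with fields `set` (an
#'   [intervention_set()]), `value` (mean endpoint), and optionally `sem` and
#'   `p_adjusted`.
#' @param background Background identifier; default taken from the control.
#' @param endpoint Endpoint name, e.g. `"mean_lifespan"`.
#' @return An object of class `effect_lattice`: list with `background`,
#'   `endpoint` and `nodes` (data.frame keyed by canonical set key).
#' @export
build_lattice <- function(summaries, background = NULL,
                          endpoint = "mean_lifespan") {
  keys <- vapply(summaries, function(s) iv_key(s$set), "")
  if (anyDuplicated(keys))
    stop("duplicate strain(s) in lattice: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  bgs <- unique(vapply(summaries, function(s) s$set$background, ""))
  if (length(bgs) > 1)
    stop("summaries mix backgrounds (", paste(bgs, collapse = ", "),
         "); build one lattice per background")
  if (is.null(background)) background <- bgs
  if (!"" %in% keys)
    stop("missing control strain (empty intervention set) for background ",
         background)
  value <- vapply(summaries, function(s) as.numeric(s$value), 0)
  ctrl_value <- value[keys == ""]
  nodes <- data.frame(
    key = keys,
    label = vapply(summaries, function(s) s$set$label, ""),
    n_interventions = vapply(summaries,
                             function(s) length(s$set$interventions), 0L),
    value = value,
    sem = vapply(summaries, function(s)
      if (is.null(s$sem)) NA_real_ else as.numeric(s$sem), 0),
    p_adjusted = vapply(summaries, function(s)
      if (is.null(s$p_adjusted)) NA_real_ else as.numeric(s$p_adjusted), 0),
    effect = effect_percent(value, ctrl_value),
    stringsAsFactors = FALSE, row.names = NULL)
  nodes <- nodes[order(nodes$n_interventions, nodes$key), , drop = FALSE]
  rownames(nodes) <- NULL
  sets <- stats::setNames(lapply(summaries, `[[`, "set"), keys)
  structure(list(background = background, endpoint = endpoint,
                 nodes = nodes, sets = sets),
            class = "effect_lattice")
}

split_key <- function(k) {
  if (identical(k, "")) character(0) else strsplit(k, "+", fixed = TRUE)[[1]]
}

lattice_effect <- function(lattice, key) {
  i <- match(key, lattice$nodes$key)
  if (is.na(i)) NA_real_ else lattice$nodes$effect[i]
}

proper_subsets <- function(iv) {
  n <- length(iv)
  out <- list()
  for (k in seq_len(n - 1))
    out <- c(out, utils::combn(iv, k, simplify = FALSE))
  out
}

#' Classify an intervention combination on the effect lattice
#'
#' Decision procedure over the percent effects (vs the background control)
#' of a target combination of N >= 2 interventions and its measured subsets:
#'
#' 1. *Full synergism* -- all 2^N - 2 proper non-empty subsets measured and,
#'    for every bipartition (S1, S2) of the target, the target effect
#'    exceeds the summed effects of S1 and S2 by more than the relative
#'    tolerance.
#' 2. *Simple synergism* -- all singletons measured and the target effect
#'    exceeds the sum of all single-intervention effects by more than the
#'    relative tolerance.
#' 3. *Partially known synergism* -- subset coverage is incomplete, but one
#'    incremental chain from the control to the target is fully measured
#'    with a strict endpoint increase at every extension.
#' 4. *Additive* -- the target effect is within `tol_rel` (relative, default
#'    10%) of the summed singleton effects.
#' 5. *Intermediate* -- between the largest singleton effect and the
#'    singleton sum (outside tolerance).
#' 6. *Antagonistic* -- positive but no larger than the largest singleton
#'    effect.
#' 7. *Deleterious* -- non-positive.
#'
#' Synergism calls must clear the same relative tolerance that defines the
#' additive band, so a combination lands in exactly one category: effects
#' inside the band are additive, beyond it synergistic, below it
#' intermediate/antagonistic (ties are never synergism). The chain rule only
#' applies when subset coverage is incomplete (with all subsets measured a
#' monotone chain is not evidence of synergy beyond rules 1-2). The category is point-estimate-based; every
#' margin evaluated is recorded in `evidence` so uncertainty can be judged
#' downstream.
#'
#' @param lattice An [effect_lattice()].
#' @param target An [intervention_set()] (or character vector of gene
#'   symbols) with at least 2 interventions.
#' @param tol_rel Relative additivity tolerance, default 0.10.
#' @return An object of class `synergy_classification`: list with `target`,
#'   `category`, `evidence` (data.frame of comparisons and margins),
#'   `tolerance_used`.
#' @export
classify_combination <- function(lattice, target, tol_rel = 0.10) {
  iv <- if (inherits(target, "intervention_set")) target$interventions else
    sort(as.character(target))
  if (length(iv) < 2) stop("target must combine at least 2 interventions")
  tkey <- iv_key(iv)
  d_target <- lattice_effect(lattice, tkey)
  if (is.na(d_target))
    stop("target combination ", tkey, " is not present in the lattice")
  subs <- proper_subsets(iv)
  sub_keys <- vapply(subs, iv_key, "")
  sub_eff <- vapply(sub_keys, function(k) lattice_effect(lattice, k), 0)
  full_cov <- !anyNA(sub_eff)
  singles_keys <- iv
  singles <- vapply(singles_keys, function(k) lattice_effect(lattice, k), 0)
  singles_cov <- !anyNA(singles)
  evidence <- list()

  # (1) full synergism: every bipartition, exceeded beyond the tolerance
  if (full_cov) {
    halves <- subs[vapply(subs, length, 0L) <= length(iv) / 2]
    seen <- character()
    all_exceed <- TRUE
    for (s1 in halves) {
      s2 <- setdiff(iv, s1)
      pair_id <- paste(iv_key(s1), "|", iv_key(s2))
      rev_id <- paste(iv_key(s2), "|", iv_key(s1))
      if (pair_id %in% seen || rev_id %in% seen) next
      seen <- c(seen, pair_id)
      ssum <- lattice_effect(lattice, iv_key(s1)) +
        lattice_effect(lattice, iv_key(s2))
      evidence[[length(evidence) + 1]] <- data.frame(
        rule = "bipartition", comparison = pair_id, reference = ssum,
        threshold = tol_rel * abs(ssum), target_effect = d_target,
        margin = d_target - ssum, stringsAsFactors = FALSE)
      if (!(d_target > ssum + tol_rel * abs(ssum))) all_exceed <- FALSE
    }
    if (all_exceed)
      return(synergy_classification(iv, "full_synergism", evidence, tol_rel))
  }
  # (2) simple synergism: beyond the tolerance on the singleton sum
  if (singles_cov) {
    ssum <- sum(singles)
    evidence[[length(evidence) + 1]] <- data.frame(
      rule = "singleton_sum", comparison = paste(singles_keys, collapse = "+"),
      reference = ssum, threshold = tol_rel * abs(ssum),
      target_effect = d_target, margin = d_target - ssum,
      stringsAsFactors = FALSE)
    if (d_target > ssum + tol_rel * abs(ssum))
      return(synergy_classification(iv, "simple_synergism", evidence,
                                    tol_rel))
  }
  # (3) partially known synergism: only with incomplete coverage
  if (!full_cov) {
    chain <- find_increasing_chain(lattice, iv)
    if (!is.null(chain)) {
      evidence[[length(evidence) + 1]] <- data.frame(
        rule = "incremental_chain", comparison = paste(chain, collapse = " < "),
        reference = NA_real_, threshold = NA_real_,
        target_effect = d_target, margin = NA_real_,
        stringsAsFactors = FALSE)
      return(synergy_classification(iv, "partially_known_synergism",
                                    evidence, tol_rel))
    }
  }
  if (!singles_cov) {
    missing <- c(singles_keys[is.na(singles)],
                 if (!full_cov) sub_keys[is.na(sub_eff)])
    stop("insufficient lattice coverage to classify ", tkey,
         "; missing subset strain(s): ",
         paste(unique(missing), collapse = ", "))
  }
  ssum <- sum(singles)
  tol_abs <- tol_rel * abs(ssum)
  evidence[[length(evidence) + 1]] <- data.frame(
    rule = "additivity_band", comparison = paste0("|", round(d_target, 3),
                                                  " - ", round(ssum, 3), "|"),
    reference = ssum, threshold = tol_abs, target_effect = d_target,
    margin = abs(d_target - ssum), stringsAsFactors = FALSE)
  category <- if (abs(d_target - ssum) <= tol_abs) "additive"
  else if (d_target <= 0) "deleterious"
  else if (d_target <= max(singles)) "antagonistic"
  else "intermediate"
  synergy_classification(iv, category, evidence, tol_rel)
}

# Depth-first search for a fully measured incremental chain control ->
# target, adding one intervention per step, with strictly increasing
# endpoint value at every extension.
find_increasing_chain <- function(lattice, iv) {
  extend <- function(current) {
    ckey <- iv_key(current)
    if (length(current) == length(iv)) return(ckey)
    for (nxt in setdiff(iv, current)) {
      cand <- c(current, nxt)
      e_now <- if (length(current) == 0) 0 else lattice_effect(lattice, ckey)
      e_next <- lattice_effect(lattice, iv_key(cand))
      if (!is.na(e_next) && e_next > e_now) {
        rest <- extend(cand)
        if (!is.null(rest))
          return(c(if (ckey == "") lattice$background else ckey, rest))
      }
    }
    NULL
  }
  extend(character())
}

synergy_classification <- function(iv, category, evidence, tol_rel) {
  structure(list(target = iv_key(iv), interventions = iv,
                 category = category,
                 evidence = if (length(evidence))
                   do.call(rbind, evidence) else
                   data.frame(rule = character(), comparison = character(),
                              reference = numeric(), threshold = numeric(),
                              target_effect = numeric(), margin = numeric()),
                 tolerance_used = tol_rel),
            class = "synergy_classification")
}

#' @export
print.synergy_classification <- function(x, ...) {
  cat("<synergy_classification> ", x$target, ": ", x$category,
      " (tol_rel = ", x$tolerance_used, ")\n", sep = "")
  print(x$evidence)
  invisible(x)
}

#' Build the strain-network graph with percent-change edges
#'
#' Nodes are the lattice strains (vertical coordinate = mean endpoint value;
#' shape class by number of interventions). Edges connect strains differing
#' by exactly one intervention (origin a subset of destination) and carry
#' the signed percent change between origin and destination node means,
#' a significance flag and a colour class: `"neutral"` (grey) when the
#' adjusted p is at or above `alpha` or the absolute change is below
#' `neutral_threshold`, otherwise `"increase"` (green) or `"decrease"`
#' (red) by sign.
#'
#' @param lattice An [effect_lattice()].
#' @param pairwise_tests Optional named numeric of adjusted p-values per
#'   edge, names `"<origin key>-><destination key>"`; defaults to the
#'   destination node's `p_adjusted`.
#' @param neutral_threshold Percent change below which an edge is grey,
#'   default 5.
#' @param alpha Significance level for edge colouring, default 0.05.
#' @return An object of class `lattice_graph`: list with `nodes` and
#'   `edges` data.frames.
#' @export
annotate_edges <- function(lattice, pairwise_tests = NULL,
                           neutral_threshold = 5, alpha = 0.05) {
  nd <- lattice$nodes
  shape_classes <- c("diamond", "circle", "square", "hexagon", "octagon")
  nd$shape_class <- shape_classes[pmin(nd$n_interventions + 1,
                                       length(shape_classes))]
  edges <- list()
  for (i in seq_len(nrow(nd))) {
    for (j in seq_len(nrow(nd))) {
      si <- split_key(nd$key[i])
      sj <- split_key(nd$key[j])
      if (length(sj) != length(si) + 1 || !is_subset_of(si, sj)) next
      change <- 100 * (nd$value[j] - nd$value[i]) / nd$value[i]
      id <- paste0(nd$key[i], "->", nd$key[j])
      p <- if (!is.null(pairwise_tests) && id %in% names(pairwise_tests))
        unname(pairwise_tests[[id]]) else nd$p_adjusted[j]
      signif <- !is.na(p) && p < alpha
      color <- if (!signif || abs(change) < neutral_threshold) "neutral"
      else if (change > 0) "increase" else "decrease"
      edges[[length(edges) + 1]] <- data.frame(
        from = nd$key[i], to = nd$key[j], change_percent = change,
        p_adjusted = if (is.null(p)) NA_real_ else p,
        significant = signif, color_class = color,
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(),
               change_percent = numeric(), p_adjusted = numeric(),
               significant = logical(), color_class = character())
  structure(list(nodes = nd, edges = edges, endpoint = lattice$endpoint,
                 background = lattice$background),
            class = "lattice_graph")
}

#' Export a strain-network graph to GraphML or JSON
#'
#' Lossless attribute export; [import_graph()] round-trips the node and edge
#' tables.
#'
#' @param graph A [annotate_edges()] result.
#' @param path Output path.
#' @param format `"graphml"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(graph, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(list(endpoint = graph$endpoint,
                              background = graph$background,
                              nodes = graph$nodes, edges = graph$edges),
                         path, digits = NA, auto_unbox = TRUE, null = "null")
    return(invisible(path))
  }
  nd <- graph$nodes
  nd$name <- ifelse(nd$key == "", "(control)", nd$key)
  ed <- graph$edges
  if (nrow(ed)) {
    ed$from <- ifelse(ed$from == "", "(control)", ed$from)
    ed$to <- ifelse(ed$to == "", "(control)", ed$to)
  } else {
    ed <- data.frame(from = character(), to = character())
  }
  g <- igraph::graph_from_data_frame(
    d = ed, directed = TRUE,
    vertices = nd[, c("name", setdiff(names(nd), "name"))])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Re-import an exported strain-network graph
#'
#' @param path File written by [export_graph()].
#' @param format `"graphml"` or `"json"`.
#' @return A `lattice_graph` (node/edge tables; attribute types restored).
#' @export
import_graph <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- as.data.frame(x$nodes)
    edges <- as.data.frame(x$edges)
    if (nrow(edges) == 0)
      edges <- data.frame(from = character(), to = character(),
                          change_percent = numeric(), p_adjusted = numeric(),
                          significant = logical(),
                          color_class = character())
    return(structure(list(nodes = nodes, edges = edges,
                          endpoint = x$endpoint, background = x$background),
                     class = "lattice_graph"))
  }
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::as_data_frame(g, what = "vertices")
  edges <- igraph::as_data_frame(g, what = "edges")
  nodes$name <- NULL
  nodes$id <- NULL
  rownames(nodes) <- NULL
  if (nrow(edges)) {
    edges$from <- ifelse(edges$from == "(control)", "", edges$from)
    edges$to <- ifelse(edges$to == "(control)", "", edges$to)
  }
  structure(list(nodes = nodes, edges = edges), class = "lattice_graph")
}
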