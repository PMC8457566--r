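# Endpoint statistics for pumping, stress-survival and fecundity assays:
# group summaries, one-way ANOVA, and Dunnett many-to-one comparisons with
# a seeded Monte Carlo family-wise adjustment.

#' Group summaries (mean, SD, SEM) of an endpoint table
#'
#' @param table Endpoint data.frame with a `value` column (e.g. from
#'   [simulate_pumping()]).
#' @param stratify_by Grouping columns, default `c("strain", "day")`.
#' @return data.frame with the grouping columns plus `n`, `mean`, `sd`,
#'   `sem` (`sd`/`sem` are `NA` for n = 1).
#' @export
summarize_groups <- function(table, stratify_by = c("strain", "day")) {
  stratify_by <- intersect(stratify_by, names(table))
  if (length(stratify_by) == 0) stop("no valid stratification columns")
  if (!"value" %in% names(table)) stop("endpoint table needs a value column")
  key <- interaction(table[stratify_by], drop = TRUE, lex.order = TRUE)
  parts <- split(table, key)
  out <- lapply(parts, function(p) {
    v <- p$value
    cbind(p[1, stratify_by, drop = FALSE],
          data.frame(n = length(v), mean = mean(v), sd = stats::sd(v),
                     sem = stats::sd(v) / sqrt(length(v))))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[do.call(order, out[stratify_by]), , drop = FALSE]
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition via [stats::aov()].
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `F`, `p_value`, `df_between`, `df_within`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2))
    stop("each group needs at least 2 values")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (stats::var(value) == 0)
    stop("degenerate input: zero variance within and between groups")
  fit <- stats::aov(value ~ grp)
  tab <- summary(fit)[[1]]
  list(F = tab[1, "F value"], p_value = tab[1, "Pr(>F)"],
       df_between = tab[1, "Df"], df_within = tab[2, "Df"])
}

#' Dunnett many-to-one comparisons with Monte Carlo adjustment
#'
#' Two-sided comparisons of every treatment group against the control using
#' pooled-variance t statistics. The family-wise adjusted p-value of each
#' comparison is the probability, under the joint null of the maximum
#' absolute statistic, that max |t*| exceeds the observed |t|; the joint
#' null is approximated by a seeded Monte Carlo draw of group means and the
#' pooled variance (multivariate t with the equal-correlation structure
#' implied by the group sizes), which keeps the procedure reproducible and
#' honours unbalanced designs.
#'
#' @param groups List of numeric vectors.
#' @param control_index Index of the control group, default 1.
#' @param n_draws Monte Carlo draws, default 1e5.
#' @param seed Seed for the draw.
#' @return data.frame with one row per non-control group: `group`, `n`,
#'   `mean`, `estimate` (difference vs control), `t`, `p_raw`, `p_adjusted`.
#' @export
dunnett_test <- function(groups, control_index = 1, n_draws = 1e5,
                         seed = 1L) {
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (length(groups[[control_index]]) == 0) stop("control group is empty")
  ns <- vapply(groups, length, 0L)
  if (any(ns < 2)) stop("each group needs at least 2 values")
  means <- vapply(groups, mean, 0)
  df <- sum(ns) - k
  s2 <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / df
  idx <- setdiff(seq_len(k), control_index)
  se <- sqrt(s2 * (1 / ns[idx] + 1 / ns[control_index]))
  tstat <- (means[idx] - means[control_index]) / se
  p_raw <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)

  set.seed(as.integer(seed))
  z0 <- stats::rnorm(n_draws, sd = 1 / sqrt(ns[control_index]))
  w <- sqrt(stats::rchisq(n_draws, df) / df)
  maxt <- rep(0, n_draws)
  for (j in seq_along(idx)) {
    zj <- stats::rnorm(n_draws, sd = 1 / sqrt(ns[idx[j]]))
    tj <- abs(zj - z0) / (w * sqrt(1 / ns[idx[j]] + 1 / ns[control_index]))
    maxt <- pmax(maxt, tj)
  }
  p_adj <- vapply(abs(tstat), function(t0) mean(maxt >= t0), 0)
  p_adj <- pmax(p_adj, p_raw)  # family-wise p can never undercut the raw p
  data.frame(group = idx, n = ns[idx], mean = means[idx],
             estimate = means[idx] - means[control_index], t = tstat,
             p_raw = p_raw, p_adjusted = p_adj, row.names = NULL)
}

#' Stress-assay summary and comparison against control
#'
#' Survival fractions analysed per replicate plate as the unit of
#' observation: per-strain mean fraction +/- SEM, one-way ANOVA across
#' strains and Dunnett comparisons against the control strain.
#'
#' @param table data.frame with columns `strain`, `replicate`, `value`
#'   (survival fraction per plate in \[0, 1\]).
#' @param control Control strain label.
#' @param seed Seed for the Dunnett adjustment.
#' @return list with `summary` (per-strain), `anova`, `dunnett`.
#' @export
stress_stats <- function(table, control, seed = 1L) {
  if (any(table$value < 0 | table$value > 1))
    stop("survival fractions must be in [0, 1]")
  strains <- c(control, sort(setdiff(unique(table$strain), control)))
  if (!control %in% table$strain)
    stop("control strain '", control, "' not present")
  groups <- lapply(strains, function(s) table$value[table$strain == s])
  dt <- dunnett_test(groups, control_index = 1, seed = seed)
  dt$strain <- strains[dt$group]
  list(summary = summarize_groups(table, "strain"),
       anova = one_way_anova(groups), dunnett = dt)
}
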