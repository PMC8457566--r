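make_lattice <- function(effects, control_value = 100, background = "WT") {
  # effects: named percent effects vs control; names are "+"-joined keys
  sums <- list(list(set = intervention_set(background = background),
                    value = control_value))
  for (k in names(effects)) {
    iv <- strsplit(k, "+", fixed = TRUE)[[1]]
    sums[[length(sums) + 1]] <- list(
      set = intervention_set(iv, background = background),
      value = control_value * (1 + effects[[k]] / 100))
  }
  build_lattice(sums)
}

test_that("lattices index strains by order-insensitive intervention sets", {
  t1 <- published_lifespans()
  rows <- which(t1$arm %in% c("full", "both"))
  lat <- build_lattice(lapply(rows, function(i)
    list(set = t1$set[[i]], value = t1$mean_lifespan[i], sem = t1$sem[i],
         p_adjusted = t1$p_value[i])))
  expect_equal(nrow(lat$nodes), 6)
  expect_equal(lat$nodes$effect[lat$nodes$key == "odr-3"], 26.2,
               tolerance = 0.05)
  expect_equal(lat$nodes$effect[lat$nodes$key == ""], 0)

  # permuted input order gives the identical lattice
  lat2 <- build_lattice(lapply(rev(rows), function(i)
    list(set = t1$set[[i]], value = t1$mean_lifespan[i], sem = t1$sem[i],
         p_adjusted = t1$p_value[i])))
  expect_identical(lat$nodes, lat2$nodes)

  two <- build_lattice(list(
    list(set = intervention_set(), value = 20),
    list(set = intervention_set("g"), value = 25)))
  expect_equal(nrow(two$nodes), 2)

  expect_error(build_lattice(list(
    list(set = intervention_set("g"), value = 25),
    list(set = intervention_set("g"), value = 26),
    list(set = intervention_set(), value = 20))), "duplicate")
  expect_error(build_lattice(list(
    list(set = intervention_set("g"), value = 25))), "control")
  expect_error(build_lattice(list(
    list(set = intervention_set(), value = 20),
    list(set = intervention_set("g", background = "daf-16"), value = 25))),
    "background")
})

test_that("the published worked examples classify as reported", {
  # lifespan: 40.3 vs 26.2 + 18.0 at 10% tolerance -> additive
  lat <- make_lattice(c("odr-3" = 26.2, "ife-2" = 18.0,
                        "ife-2+odr-3" = 40.3))
  cls <- classify_combination(lat, c("odr-3", "ife-2"))
  expect_equal(cls$category, "additive")
  band <- cls$evidence[cls$evidence$rule == "additivity_band", ]
  expect_equal(band$margin, 3.9, tolerance = 0.05)
  expect_equal(band$threshold, 4.42, tolerance = 0.05)

  # day-15 pumping: 187 vs 66 + 55, all subsets measured -> full synergism
  pump <- make_lattice(c("odr-3" = 66, "ife-2" = 55, "ife-2+odr-3" = 187))
  cls2 <- classify_combination(pump, c("odr-3", "ife-2"))
  expect_equal(cls2$category, "full_synergism")
  expect_true(all(cls2$evidence$margin[cls2$evidence$rule ==
                                       "bipartition"] > 0))
  # full synergism implies the simple-synergism condition
  singles <- vapply(c("odr-3", "ife-2"), function(k)
    pump$nodes$effect[pump$nodes$key == k], 0)
  expect_gt(pump$nodes$effect[pump$nodes$key == "ife-2+odr-3"],
            sum(singles))
})

test_that("boundary and degenerate combinations fall through correctly", {
  # exact bipartition equality is not synergism (strict >): additive
  lat <- make_lattice(c(a = 10, b = 20, "a+b" = 30))
  expect_equal(classify_combination(lat, c("a", "b"))$category, "additive")

  # below the largest singleton but positive: antagonistic
  lat2 <- make_lattice(c(a = 10, b = 20, "a+b" = 8))
  expect_equal(classify_combination(lat2, c("a", "b"))$category,
               "antagonistic")

  # non-positive combined effect: deleterious
  lat3 <- make_lattice(c(a = 10, b = 20, "a+b" = -5))
  expect_equal(classify_combination(lat3, c("a", "b"))$category,
               "deleterious")

  # between max singleton and the sum, outside tolerance: intermediate
  lat4 <- make_lattice(c(a = 30, b = 30, "a+b" = 40))
  expect_equal(classify_combination(lat4, c("a", "b"))$category,
               "intermediate")

  # incomplete coverage with an increasing chain: partially known synergism
  lat5 <- make_lattice(c(a = 10, "a+b" = 25, "a+b+c" = 45))
  cls5 <- classify_combination(lat5, c("a", "b", "c"))
  expect_equal(cls5$category, "partially_known_synergism")

  # no singleton coverage and no chain: explicit unclassifiable error
  lat6 <- make_lattice(c(a = 10, "a+b+c" = 5))
  expect_error(classify_combination(lat6, c("a", "b", "c")),
               "missing subset")

  expect_error(classify_combination(lat, "a"), "at least 2")
  expect_error(classify_combination(lat, c("x", "y")), "not present")
})

test_that("the half-dose arm triple classifies between max single and sum", {
  rep_ <- published_replay()
  expect_equal(rep_$triple_classification$category, "intermediate")
  expect_equal(rep_$lifespan_classification$category, "additive")
  expect_equal(rep_$pumping_classification$category, "full_synergism")
})

test_that("classifier recovers the generating interaction structure", {
  strains <- list(intervention_set(), intervention_set("g1"),
                  intervention_set("g2"),
                  intervention_set(c("g1", "g2")))
  # additive-on-effect construction: with mortality uncoupled from the
  # motility process (frailty multiplier 1), additive log-hazard effects are
  # additive on the percent-effect scale to within 0.1% analytically, so
  # gamma = 0 is the additive ground truth and a strong negative gamma the
  # synergistic one. Effects are at the odr-3 scale (~26% each) so that the
  # 10% additivity band (~5 points) stands clear of the ~2-point sampling
  # noise of the margin at 500 worms per strain.
  run_case <- function(gamma, seed) {
    cfg <- simulation_config(
      intervention_effects = c(g1 = -1.37, g2 = -1.37),
      interaction_terms = c("g1+g2" = gamma),
      frailty_mortality_multiplier = 1,
      censor_daily_prob = 0, n_worms = 500, n_replicates = 1, seed = seed)
    co <- simulate_cohort(cfg, strains)
    sums <- lapply(strains, function(s) list(
      set = s, value = summarize_survival(co, s$label)$mean_lifespan))
    classify_combination(build_lattice(sums), c("g1", "g2"))$category
  }
  seeds <- 1:10
  additive <- vapply(seeds, function(s) run_case(0, s), "")
  synergy <- vapply(seeds, function(s) run_case(-0.9, s), "")
  expect_gte(mean(additive == "additive"), 0.9)
  expect_gte(mean(synergy == "full_synergism"), 0.9)
})

test_that("edge annotations are consistent with node means", {
  rep_ <- published_replay()
  g <- annotate_edges(rep_$lattice_full)
  e <- g$edges
  wt_odr <- e[e$from == "" & e$to == "odr-3", ]
  expect_equal(wt_odr$change_percent, 26.2, tolerance = 0.05)
  expect_equal(wt_odr$color_class, "increase")
  # brute-force recomputation of every edge from the node means
  for (i in seq_len(nrow(e))) {
    vo <- g$nodes$value[g$nodes$key == e$from[i]]
    vd <- g$nodes$value[g$nodes$key == e$to[i]]
    expect_equal(e$change_percent[i], 100 * (vd - vo) / vo)
    si <- if (e$from[i] == "") character() else
      strsplit(e$from[i], "+", fixed = TRUE)[[1]]
    sj <- strsplit(e$to[i], "+", fixed = TRUE)[[1]]
    expect_equal(length(sj), length(si) + 1)
    expect_true(all(si %in% sj))
  }
  # compounded edge ratios along a path equal the endpoint value ratio
  path_ratio <- prod(1 + e$change_percent[c(
    which(e$from == "" & e$to == "odr-3"),
    which(e$from == "odr-3" & e$to == "ife-2+odr-3"))] / 100)
  v <- g$nodes$value
  k <- g$nodes$key
  expect_equal(path_ratio, v[k == "ife-2+odr-3"] / v[k == ""],
               tolerance = 1e-12)

  flat <- make_lattice(c(a = 0), control_value = 50)
  gf <- annotate_edges(flat)
  expect_equal(gf$edges$change_percent, 0)
  expect_equal(gf$edges$color_class, "neutral")
})

test_that("graph export round-trips through GraphML and JSON", {
  # a two-gene-plus-extensions lattice of 13 nodes
  effs <- c(a = 10, b = 18, c = 4, "a+b" = 30, "a+c" = 12, "b+c" = 20,
            "a+b+c" = 33, d = -8, "a+d" = 2, "b+d" = 9, "c+d" = -3,
            "a+b+d" = 25)
  lat <- make_lattice(effs)
  g <- annotate_edges(lat)
  expect_gte(nrow(g$edges), 12)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_graph(g, gml, "graphml")
  back <- import_graph(gml, "graphml")
  expect_equal(nrow(back$nodes), 13)
  expect_equal(sort(back$nodes$key), sort(g$nodes$key))
  m <- merge(g$edges, back$edges, by = c("from", "to"))
  expect_equal(nrow(m), nrow(g$edges))
  expect_equal(m$change_percent.x, m$change_percent.y, tolerance = 1e-9)
  expect_identical(sort(unique(back$edges$color_class)),
                   sort(unique(g$edges$color_class)))

  js <- withr::local_tempfile(fileext = ".json")
  export_graph(g, js, "json")
  back2 <- import_graph(js, "json")
  expect_equal(back2$nodes$value, g$nodes$value)
  expect_equal(back2$edges$change_percent, g$edges$change_percent)

  empty <- annotate_edges(make_lattice(setNames(numeric(), character())))
  export_graph(empty, js, "json")
  expect_equal(nrow(import_graph(js, "json")$edges), 0)
  expect_error(export_graph(g, js, "dot"), "should be one of")
})
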