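test_that("a minimal well-formed observation file reads into a cohort", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("worm_id,strain,replicate,day,status,censor_cause,motility",
               "w1,WT,1,0,alive,none,A",
               "w1,WT,1,1,alive,none,A",
               "w1,WT,1,2,alive,none,B",
               "w1,WT,1,3,dead,none,not_scored"), path)
  co <- read_cohort(path)
  expect_s3_class(co, "worm_cohort")
  expect_equal(nrow(co$records), 4)
  d <- cohort_durations(co)
  expect_equal(d$duration, 3)
  expect_true(d$event)
})

test_that("schema and invariant violations are rejected with named causes", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("worm_id,strain,replicate,day,status,censor_cause",
               "w1,WT,1,0,alive,none"), path)
  expect_error(read_cohort(path), "motility")

  # record after a terminal death record
  bad <- rbind(worm_records("w9", c("A", "A")),
               data.frame(worm_id = "w9", strain = "WT", replicate = 1L,
                          day = 3, status = "alive", censor_cause = "none",
                          motility = "A"))
  expect_error(worm_cohort(bad), "w9.*terminal")

  # unknown censoring cause is an error, not a silent coercion
  oops <- worm_records("w2", c("A", "A"), terminal = "censored",
                       cause = "lost")
  expect_error(worm_cohort(oops), "censor_cause")

  # motility reversal B -> A
  expect_error(worm_cohort(worm_records("w3", c("A", "B", "A"))),
               "w3.*monotone|w3.*improv")

  # day gap
  gap <- worm_records("w4", c("A", "A", "A"))
  gap$day <- c(0, 1, 3, 4)
  expect_error(worm_cohort(gap), "w4.*consecutive")

  # unscored motility while alive requires the permissive flag
  ns <- worm_records("w5", c("A", "not_scored", "A"))
  expect_error(worm_cohort(ns), "w5.*not scored")
  expect_silent(validate_cohort(worm_cohort(ns, validate = FALSE),
                                permissive_motility = TRUE))
})

test_that("randomly corrupted cohorts are always rejected", {
  set.seed(11)
  co <- simulate_cohort(test_sim_config(), list(wt_set()))
  alive_rows <- which(co$records$status == "alive" & co$records$day > 0)
  for (i in 1:20) {
    bad <- co
    row <- sample(alive_rows, 1)
    if (i %% 2 == 0) {
      bad$records$motility[row] <- "C"
      bad$records$motility[bad$records$worm_id ==
          bad$records$worm_id[row] &
          bad$records$day > bad$records$day[row] &
          bad$records$status == "alive"] <- "A"
      # only a genuine downgrade-then-improve violates monotonicity
      if (!any(bad$records$worm_id == bad$records$worm_id[row] &
               bad$records$day > bad$records$day[row] &
               bad$records$status == "alive")) next
    } else {
      bad$records$status[row] <- "dead"
      bad$records$motility[row] <- "not_scored"
    }
    expect_error(validate_cohort(bad))
  }
})

test_that("serialization round-trips losslessly and deterministically", {
  co <- simulate_cohort(test_sim_config(n_worms = 100, n_replicates = 2),
                        list(wt_set(), intervention_set("odr-3")))
  expect_equal(length(unique(co$records$worm_id)), 400)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, p1)
  back <- read_cohort(p1, metadata = co$metadata)
  write_cohort(back, p2)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  ord <- function(r) {
    r <- r[order(r$strain, r$worm_id, r$day), ]
    rownames(r) <- NULL
    r
  }
  expect_identical(ord(back$records), ord(co$records))
})

test_that("writing preserves censor causes and handles the empty cohort", {
  co <- worm_cohort(worm_records("w1", c("A", "A"), terminal = "censored",
                                 cause = "wall"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, path)
  expect_true(any(grepl("censored\twall", readLines(path))))

  empty <- worm_cohort(worm_records("w1", "A")[0, ], validate = FALSE)
  write_cohort(empty, path)
  expect_equal(readLines(path),
               "worm_id\tstrain\treplicate\tday\tstatus\tcensor_cause\tmotility")
})

test_that("pooling replicates unions records and preserves means", {
  co <- tiny_cohort()
  expect_identical(pool_replicates(list(co)), co)

  cfg <- test_sim_config(n_worms = 85, censor_daily_prob = 0)
  c1 <- simulate_cohort(cfg, list(wt_set()))
  cfg2 <- cfg; cfg2$seed <- 8L
  c2 <- simulate_cohort(cfg2, list(wt_set()))
  pooled <- pool_replicates(list(c1, c2))
  expect_equal(length(unique(pooled$records$worm_id)), 170)
  expect_equal(length(unique(pooled$records$replicate)), 2)

  m1 <- summarize_survival(c1, "WT")$mean_lifespan
  m2 <- summarize_survival(c2, "WT")$mean_lifespan
  mp <- summarize_survival(pooled, "WT")$mean_lifespan
  expect_equal(mp, (85 * m1 + 85 * m2) / 170, tolerance = 1e-12)

  c2bad <- c2
  c2bad$metadata$fudr <- 0
  expect_error(pool_replicates(list(c1, c2bad)), "conflicting metadata")
})

test_that("delimiter is auto-detected from the header line", {
  co <- tiny_cohort()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, tsv)
  csv <- withr::local_tempfile(fileext = ".csv")
  r <- co$records[order(co$records$strain, co$records$worm_id,
                        co$records$day), ]
  write.csv(r, csv, row.names = FALSE, quote = FALSE)
  a <- read_cohort(tsv)
  b <- read_cohort(csv)
  expect_identical(a$records, b$records)
})
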