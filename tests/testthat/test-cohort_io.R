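full <- build_full_schema()

test_that("cohort CSV round-trips and serializes canonically", {
  co <- random_cohort(full, n_patients = 2, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path, full)
  back <- read_cohort(path, full)
  key <- function(d) paste(d$patient_id, d$timepoint, d$rater_id,
                           d$joint, d$site, d$feature)
  expect_setequal(paste(key(back), back$value), paste(key(co), co$value))
  # write -> read -> write is the identity on bytes
  path_rt <- withr::local_tempfile(fileext = ".csv")
  write_cohort(back, path_rt, full)
  expect_identical(readLines(path_rt), readLines(path))

  # shuffled input writes the same bytes as sorted input
  path2 <- withr::local_tempfile(fileext = ".csv")
  set.seed(1)
  write_cohort(co[sample.int(nrow(co)), ], path2, full)
  expect_identical(readLines(path), readLines(path2))

  # empty cohort -> header-only file; 1 record -> 2 lines
  write_cohort(co[0, ], path, full)
  expect_length(readLines(path), 1L)
  write_cohort(co[1, ], path, full)
  expect_length(readLines(path), 2L)
})

test_that("reading rejects out-of-range values, duplicates and bad tokens", {
  co <- make_cohort(full, "P1")
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- co
  bad$value[bad$feature == "synovitis"][1] <- 4L
  utils::write.csv(bad, path, row.names = FALSE)
  expect_error(read_cohort(path, full), "0-3")

  dup <- rbind(co, co[1, ])
  utils::write.csv(dup, path, row.names = FALSE)
  expect_error(read_cohort(path, full), "duplicate")

  tok <- co
  tok$joint[1] <- "MCP9"
  utils::write.csv(tok, path, row.names = FALSE)
  expect_error(read_cohort(path, full), "MCP9")

  # follow-up-only patients violate the longitudinal design
  t1only <- make_cohort(full, "P2", timepoints = "t1")
  expect_error(validate_cohort(t1only, full), "no baseline")

  # site display aliases are canonicalized on read
  al <- co
  al$site <- ifelse(al$site == "site_A", "proximal", "palmar")
  utils::write.csv(al, path, row.names = FALSE)
  expect_equal(sort(unique(read_cohort(path, full)$site)),
               c("site_A", "site_B"))
})

test_that("rater resolution honours consensus, mean and single policies", {
  co2 <- make_cohort(full, "P1", raters = c("A", "B"),
                     value_fun = function(p, tp, j, s, f, mx) 1L)
  same <- resolve_raters(co2, "consensus_required")
  expect_true(all(same$value == 1L))
  expect_equal(nrow(same), 288L) # one record per key, two timepoints

  # disagreement without a consensus rater errors, with one resolves
  dis <- co2
  dis$value[dis$rater_id == "B" & dis$joint == "MCP3" &
              dis$feature == "synovitis"] <- 2L
  expect_error(resolve_raters(dis, "consensus_required"), "disagreement")
  cons <- make_cohort(full, "P1", raters = "consensus",
                      value_fun = function(p, tp, j, s, f, mx) 3L)
  cons$value <- pmin(cons$value, 1L)
  resolved <- resolve_raters(rbind(dis, cons), "consensus_required")
  expect_equal(nrow(resolved), 288L)

  # mean rounds half away from zero: (1 + 2)/2 -> 2
  expect_true(all(resolve_raters(dis, "mean")$value %in% c(1L, 2L)))
  expect_equal(
    sum(resolve_raters(dis, "mean")$value == 2L),
    sum(dis$value[dis$rater_id == "B"] == 2L))
  # fractional means available behind the flag
  frac <- resolve_raters(dis, "mean", round_mean = FALSE)
  expect_true(any(frac$value == 1.5))

  # mean is idempotent
  m1 <- resolve_raters(co2, "mean")
  expect_equal(resolve_raters(m1, "mean")$value, m1$value)

  expect_equal(unique(resolve_raters(co2, "single:B")$rater_id), "B")
  expect_error(resolve_raters(co2, "single:C"), "unknown rater")
})

test_that("aggregation sums at all four granularities and respects bounds", {
  zeroes <- make_cohort(full, "P1")
  agg <- aggregate_scores(zeroes, full)
  expect_true(all(agg$score == 0))

  one <- make_cohort(full, "P1",
                     value_fun = function(p, tp, j, s, f, mx)
                       if (j == "MCP3" && s == "site_A" && f == "bone_erosion") 7L else 0L)
  agg <- aggregate_scores(one, full)
  expect_equal(agg$score[agg$level == "overall"], c(7, 7))
  expect_equal(unique(agg$score[agg$level == "joint" & agg$joint == "MCP3"]), 7)
  expect_equal(unique(agg$score[agg$level == "feature" &
                                  agg$feature == "bone_erosion"]), 7)
  expect_equal(unique(agg$score[agg$level == "joint_feature" &
                                  agg$joint == "MCP3" &
                                  agg$feature == "bone_erosion"]), 7)

  # reduced-schema aggregation equals full aggregation restricted to joints
  co <- random_cohort(full, n_patients = 3, seed = 9)
  s <- build_reduced_schema(full, c("MCP3", "MCP4", "PIP4"), "sPsAMRIS")
  agg_s <- aggregate_scores(co, s)
  agg_f <- aggregate_scores(co, full)
  oracle <- tapply(
    co$value[co$joint %in% s$joints],
    paste(co$patient_id, co$timepoint)[co$joint %in% s$joints], sum)
  got <- agg_s$score[agg_s$level == "overall"]
  names(got) <- paste(agg_s$patient_id, agg_s$timepoint)[agg_s$level == "overall"]
  expect_equal(got[names(oracle)], oracle, ignore_attr = TRUE)

  # overall bounded by the schema maximum
  expect_true(all(agg_f$score[agg_f$level == "overall"] <= max_total_score(full)))

  # missing items error by default and are named
  expect_error(aggregate_scores(one[-1, ], full), "missing")
  expect_message(aggregate_scores(one[-1, ], full, on_missing = "zero"),
                 "imputing")
})

test_that("aggregation is linear in the record values", {
  co1 <- random_cohort(full, n_patients = 2, seed = 21)
  a1 <- aggregate_scores(co1, full)
  co2 <- co1
  co2$value <- co1$value * 2L
  # summed cohorts aggregate to summed aggregates
  co3 <- co1
  co3$value <- co1$value + co2$value
  a3 <- aggregate_scores(co3, full)
  expect_equal(a3$score, a1$score * 3)
})

test_that("descriptive summaries use sample SD and midpoint medians", {
  s <- summarize_scores(c(2, 4, 4, 4, 5, 5, 7, 9))
  expect_equal(s$mean, 5.0)
  expect_equal(s$median, 4.5) # midpoint of the two central order statistics
  expect_equal(summarize_scores(rep(3, 5))$sd, 0)
  single <- summarize_scores(7)
  expect_true(is.nan(single$sd))
  expect_equal(single[c("mean", "min", "max", "median")],
               list(mean = 7, min = 7, max = 7, median = 7))
  expect_error(summarize_scores(numeric(0)), "empty")
})
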