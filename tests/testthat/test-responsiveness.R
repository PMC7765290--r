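full <- build_full_schema()

test_that("change scores use the t0 - t1 sign convention and complete cases", {
  co <- make_change_cohort(change = c(-2L, 1L), base = c(10L, 10L))
  agg <- aggregate_scores(co, full)
  ch <- change_scores(agg, "overall")
  # patient 1: overall 10 at t0, 12 at t1 -> change -2
  expect_equal(ch$change[ch$patient_id == "Q01"], -2)
  expect_equal(ch$change[ch$patient_id == "Q02"], 1)

  # 17 patients at baseline, 13 with follow-up -> 13 records, 4 excluded
  co17 <- simulate_cohort(sim_config(raters = 1, seed = 6))
  ch17 <- change_scores(aggregate_scores(co17, full), "overall")
  expect_equal(nrow(ch17), 13L)
  expect_equal(attr(ch17, "n_excluded"), 4L)

  # identical timepoints -> all changes zero
  same <- make_change_cohort(change = c(0L, 0L, 0L), base = c(3L, 5L, 7L))
  expect_true(all(change_scores(aggregate_scores(same, full), "overall")$change == 0))

  expect_error(change_scores(aggregate_scores(make_change_cohort(1L, 5L), full)),
               "fewer than 2")
})

test_that("srm divides mean change by sample SD with degenerate-case rules", {
  r <- srm(c(1, 2, 3))
  expect_equal(r$mean_change, 2)
  expect_equal(r$sd_change, 1)
  expect_equal(r$srm, 2)
  expect_equal(r$label, "large")

  # static nonzero scores: sd = 0, mean = 0 -> srm 0
  r0 <- srm(c(0, 0, 0), all_zero = FALSE)
  expect_equal(r0$srm, 0)
  expect_equal(r0$label, "trivial")

  # feature absent from the cohort -> NaN, not_available
  rna <- srm(c(0, 0, 0), all_zero = TRUE)
  expect_true(is.nan(rna$srm))
  expect_equal(rna$label, "not_available")

  # zero variance with nonzero mean is flagged as degenerate
  expect_warning(rdeg <- srm(c(2, 2, 2)), "degenerate")
  expect_true(is.nan(rdeg$srm))

  expect_error(srm(1), "at least 2")
})

test_that("responsiveness strata classify |SRM| with the 0.2/0.5/0.8 cuts", {
  expect_equal(classify_srm(0.8), "large")
  expect_equal(classify_srm(0.79), "moderate")
  expect_equal(classify_srm(0.5), "moderate")
  expect_equal(classify_srm(0.2), "small")
  expect_equal(classify_srm(-0.13), "trivial")
  expect_equal(classify_srm(-0.95), "large")
  expect_equal(classify_srm(NaN), "not_available")
  expect_equal(classify_srm(c(0.1, 0.3, 0.6, 0.9)),
               c("trivial", "small", "moderate", "large"))
})

test_that("the SRM grid covers 12 x 7 joint cells plus instrument rows", {
  co <- simulate_cohort(sim_config(raters = 1, seed = 8))
  g <- srm_grid(co, full)
  expect_s3_class(g, "srm_grid")
  expect_equal(sum(!is.na(g$joint)), 12L * 7L)
  expect_equal(sum(is.na(g$joint)), 7L)
  expect_true(all(g$n == 13L))
})

test_that("sub-score SRMs are local: changes in one joint stay in its column", {
  co <- make_cohort(full, sprintf("Q%02d", 1:4),
                    value_fun = function(p, tp, j, s, f, mx) {
                      if (j == "MCP3" && f == "bone_erosion" && s == "site_A")
                        (if (tp == "t1") match(p, sprintf("Q%02d", 1:4)) else 1L)
                      else 1L # static elsewhere: zero change everywhere
                    })
  g <- srm_grid(co, full)
  per_joint <- g[!is.na(g$joint) & g$feature == "overall", ]
  expect_true(per_joint$srm[per_joint$joint == "MCP3"] != 0)
  expect_true(all(per_joint$srm[per_joint$joint != "MCP3"] == 0))
})

test_that("a proliferation-free cohort yields a NaN row labelled not_available", {
  prev <- sim_config()$feature_prevalence
  prev["bone_proliferation"] <- 0
  co <- simulate_cohort(sim_config(raters = 1, feature_prevalence = prev, seed = 3))
  g <- srm_grid(co, full)
  row <- g$srm[g$feature == "bone_proliferation"]
  expect_true(all(is.nan(row)))
  expect_true(all(g$label[g$feature == "bone_proliferation"] == "not_available"))
})

test_that("SRM is scale invariant and antisymmetric under timepoint swap", {
  for (seed in 1:3) {
    set.seed(seed)
    ch <- rnorm(11)
    base <- srm(ch)$srm
    for (c_scale in c(0.5, 3, 117)) {
      expect_equal(srm(ch * c_scale)$srm, base)
    }
    expect_equal(srm(-ch)$srm, -base)
    # independent one-line oracle
    expect_equal(base, mean(ch) / sd(ch))
  }
})

test_that("grid SRMs match a direct mean/SD oracle on a random cohort", {
  co <- random_cohort(full, n_patients = 5, seed = 14)
  g <- srm_grid(co, full)
  # oracle: per-patient overall sums by hand
  tot <- tapply(co$value, list(co$patient_id, co$timepoint), sum)
  d <- tot[, "t0"] - tot[, "t1"]
  expect_equal(g$srm[is.na(g$joint) & g$feature == "overall"],
               mean(d) / sd(d))
  # and one joint_feature cell
  sel <- co$joint == "PIP2" & co$feature == "synovitis"
  cell <- tapply(co$value[sel], list(co$patient_id[sel], co$timepoint[sel]), sum)
  dc <- cell[, "t0"] - cell[, "t1"]
  oracle <- if (sd(dc) > 0) mean(dc) / sd(dc) else if (mean(dc) == 0) 0 else NaN
  expect_equal(g$srm[!is.na(g$joint) & g$joint == "PIP2" &
                       g$feature == "synovitis"], oracle)
})
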