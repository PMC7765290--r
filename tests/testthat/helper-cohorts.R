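# Fixture builders: complete in-memory cohorts constructed from a schema and
# a value rule, so tests never ship data files.

# complete cohort: every schema item for every patient x timepoint x rater,
# values from value_fun(patient_id, timepoint, joint, site, feature, score_max)
make_cohort <- function(schema, patients, timepoints = c("t0", "t1"),
                        raters = "R1",
                        value_fun = function(p, tp, j, s, f, mx) 0L) {
  items <- enumerate_items(schema)
  blocks <- list()
  for (p in patients) for (tp in timepoints) for (r in raters) {
    v <- mapply(value_fun, p, tp, items$joint, items$site, items$feature,
                items$score_max)
    blocks[[length(blocks) + 1L]] <- data.frame(
      patient_id = p, timepoint = tp, rater_id = r,
      joint = items$joint, site = items$site, feature = items$feature,
      value = as.integer(v), stringsAsFactors = FALSE
    )
  }
  do.call(rbind, blocks)
}

# cohort whose per-patient overall changes are controlled: patient i scores
# `base[i]` at t0 and `base[i] - change[i]` at t1, spread over bone_erosion
# items of MCP2 (range 0-10 x 2 sites x n joints leaves plenty of headroom)
make_change_cohort <- function(change, base = NULL, schema = build_full_schema()) {
  n <- length(change)
  if (is.null(base)) base <- rep(max(abs(change)) + 2L, n)
  pats <- sprintf("Q%02d", seq_len(n))
  spread <- function(total, j, s) {
    # place `total` across the two bone_erosion sites of MCP2 (0-10 each)
    if (j == "MCP2" && s == "site_A") min(total, 10L)
    else if (j == "MCP2" && s == "site_B") max(total - 10L, 0L)
    else 0L
  }
  make_cohort(schema, pats,
              value_fun = function(p, tp, j, s, f, mx) {
                if (f != "bone_erosion") return(0L)
                i <- match(p, pats)
                tot <- if (tp == "t0") base[i] else base[i] - change[i]
                spread(tot, j, s)
              })
}

# random valid single-rater cohort over a schema (complete cases only)
random_cohort <- function(schema, n_patients = 6, seed = 1) {
  set.seed(seed)
  items <- enumerate_items(schema)
  make_cohort(schema, sprintf("R%02d", seq_len(n_patients)),
              value_fun = function(p, tp, j, s, f, mx)
                sample.int(mx + 1L, 1L) - 1L)
}

expect_cohort_valid <- function(cohort, schema) {
  expect_silent(validate_cohort(cohort, schema))
}
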