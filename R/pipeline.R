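# End-to-end orchestration: cohort (simulated or read) -> rater resolution ->
# SRM grid -> joint selection -> simplified schema -> relative-efficacy
# bootstrap -> agreement report, written as a deterministic bundle of
# artifacts. Display rounding (2 decimals) happens only at serialization;
# every computation runs at full precision and the long-format artifacts
# retain the full-precision values.

round2 <- function(x) round(x, 2)

grid_wide <- function(grid, schema) {
  joints <- schema$joints
  feats <- c("overall", schema$features$feature)
  w <- sapply(joints, function(j)
    sapply(feats, function(f) grid$srm[!is.na(grid$joint) &
                                         grid$joint == j & grid$feature == f]))
  data.frame(sub_score = feats, round2(w), check.names = FALSE,
             row.names = NULL)
}

instrument_column <- function(grid, feats) {
  sapply(c("overall", feats),
         function(f) grid$srm[is.na(grid$joint) & grid$feature == f])
}

#' Run the full score-simplification pipeline
#'
#' Simulates (or reads) a cohort, resolves raters, computes the full-schema
#' SRM grid, ranks and selects the most responsive joints, derives the
#' simplified instrument, bootstraps the relative efficacy of simplified vs
#' full score, and computes full-vs-simplified correlations per scope and
#' timepoint plus inter-rater ICCs. Writes a deterministic artifact bundle:
#' `srm_grid.csv` (wide, 2 decimals) and `srm_grid_long.csv` (full
#' precision), `selection.json`, `schema_simplified.json`,
#' `srm_comparison.csv`, `efficacy.json`, `correlation.csv`, `icc.json`,
#' `manifest.json`. Identical inputs give byte-identical bundles.
#'
#' @param outdir Output directory (created if needed).
#' @param sim A `sim_config` used when `cohort_csv` is NULL.
#' @param cohort_csv Optional path to a cohort CSV instead of simulating.
#' @param k Number of joints to select (default 3).
#' @param B Bootstrap replicates (default 5000).
#' @param seed Seed for the bootstrap resampling.
#' @param rater_policy Policy for [resolve_raters()].
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `grid_full`, `grid_simplified`, `selection`, `schema_simplified`,
#'   `efficacy`, `correlations`, `icc`).
#' @export
run_pipeline <- function(outdir, sim = adam_config(1L), cohort_csv = NULL,
                         k = 3L, B = 5000L, seed = 1L,
                         rater_policy = "mean") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  schema_full <- build_full_schema()
  cohort <- if (is.null(cohort_csv)) simulate_cohort(sim)
            else read_cohort(cohort_csv, schema_full)
  one <- if (length(unique(cohort$rater_id)) > 1L)
    resolve_raters(cohort, rater_policy) else cohort

  grid_full <- srm_grid(one, schema_full)
  ranked <- rank_joints(grid_full)
  selection <- select_joints(ranked, k = k)
  schema_s <- derive_simplified(schema_full, selection)
  grid_s <- srm_grid(one, schema_s)
  eff <- bootstrap_re(one, schema_s, schema_full, B = B, seed = seed)

  # full-vs-simplified correlations per scope and timepoint
  agg_f <- aggregate_scores(one, schema_full)
  agg_s <- aggregate_scores(one, schema_s)
  feats <- schema_full$features$feature
  cor_rows <- list()
  for (f in c("overall", feats)) {
    for (tp in c("t0", "t1")) {
      sf <- aggregate_slice(agg_f, if (f == "overall") "overall" else "feature",
                            feature = if (f == "overall") NULL else f)
      ss <- aggregate_slice(agg_s, if (f == "overall") "overall" else "feature",
                            feature = if (f == "overall") NULL else f)
      xf <- sf$score[sf$timepoint == tp]
      xs <- ss$score[ss$timepoint == tp][match(sf$patient_id[sf$timepoint == tp],
                                               ss$patient_id[ss$timepoint == tp])]
      res <- tryCatch(pearson_cor(xf, xs), error = function(e) NULL)
      cor_rows[[length(cor_rows) + 1L]] <- data.frame(
        sub_score = f, timepoint = tp,
        n = length(xf),
        r = if (is.null(res)) NA_real_ else res$r,
        ci_lower = if (is.null(res)) NA_real_ else res$ci95[["lower"]],
        ci_upper = if (is.null(res)) NA_real_ else res$ci95[["upper"]],
        p = if (is.null(res)) NA_real_ else res$p,
        strength = if (is.null(res)) "undefined" else res$strength,
        stringsAsFactors = FALSE
      )
    }
  }
  correlations <- do.call(rbind, cor_rows)

  # inter-rater ICCs on overall scores (patient x timepoint targets), per schema
  raters <- sort(setdiff(unique(cohort$rater_id), "consensus"))
  icc <- NULL
  if (length(raters) >= 2L) {
    icc <- lapply(list(full = schema_full, simplified = schema_s), function(sch) {
      grids <- lapply(raters, function(r) {
        a <- aggregate_scores(cohort[cohort$rater_id == r, , drop = FALSE], sch)
        s <- aggregate_slice(a, "overall")
        s$score[order(s$patient_id, s$timepoint)]
      })
      icc_two_way(do.call(cbind, grids))
    })
  }

  # ---- artifact bundle -------------------------------------------------
  p <- function(f) file.path(outdir, f)
  utils::write.csv(grid_wide(grid_full, schema_full), p("srm_grid.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(grid_full), p("srm_grid_long.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(ranked = selection$ranked, selected = selection$selected,
         k_requested = selection$k_requested,
         tie_expanded = selection$tie_expanded, notes = selection$notes),
    p("selection.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_schema(schema_s, p("schema_simplified.json"))

  comp <- data.frame(
    sub_score = c("overall", feats),
    full = round2(instrument_column(grid_full, feats)),
    simplified = round2(instrument_column(grid_s, feats)),
    full_precision_full = instrument_column(grid_full, feats),
    full_precision_simplified = instrument_column(grid_s, feats),
    row.names = NULL
  )
  utils::write.csv(comp, p("srm_comparison.csv"), row.names = FALSE,
                   quote = FALSE)

  jsonlite::write_json(
    list(srm_simplified = eff$srm_simplified,
         srm_reference = eff$srm_reference,
         re_point = eff$re_point,
         bounds = as.list(eff$bounds), B = eff$B,
         n_degenerate_replicates = eff$n_degenerate_replicates,
         n_patients = eff$n_patients, seed = eff$seed),
    p("efficacy.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  utils::write.csv(correlations, p("correlation.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    if (is.null(icc)) list(note = "fewer than two raters; ICC skipped")
    else lapply(icc, function(x) x[c("sicc", "aicc", "k_raters", "n_targets",
                                     "ms_rows", "ms_error", "type")]),
    p("icc.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "spsamris",
    version = as.character(utils::packageVersion("spsamris")),
    seed = seed, k = k, B = B, rater_policy = rater_policy,
    input = if (is.null(cohort_csv)) "simulated" else cohort_csv,
    sim_seed = if (is.null(cohort_csv)) sim$seed else NA,
    selected_joints = selection$selected,
    flags = list(srm_sd = "sample (n-1)", ranking = "absolute SRM",
                 change_sign = "t0 - t1", percentile = "nearest rank",
                 icc_type = "consistency",
                 mean_rounding = "half away from zero")
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, grid_full = grid_full,
                 grid_simplified = grid_s, selection = selection,
                 schema_simplified = schema_s, efficacy = eff,
                 correlations = correlations, icc = icc))
}
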