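# Change scores and standardized response means (SRMs).
#
# SRM = mean(within-patient change) / sample SD(within-patient change), with
# change defined as score(t0) - score(t1): scores that rise under therapy
# give negative SRMs. Responsiveness strata: |SRM| >= 0.8 large,
# [0.5, 0.8) moderate, [0.2, 0.5) small, < 0.2 trivial.

#' Within-patient change scores for one scope
#'
#' Only complete-case patients (present at both timepoints) contribute;
#' baseline-only patients are excluded and counted in the `"n_excluded"`
#' attribute.
#'
#' @param aggregates A `score_aggregates` data frame from
#'   [aggregate_scores()].
#' @param level One of `"overall"`, `"feature"`, `"joint"`,
#'   `"joint_feature"`.
#' @param joint,feature Scope coordinates where the level requires them.
#' @return Data frame with `patient_id` and `change` (= t0 - t1).
#' @export
change_scores <- function(aggregates, level = "overall",
                          joint = NULL, feature = NULL) {
  s <- aggregate_slice(aggregates, level, joint, feature)
  if (nrow(s) == 0L) stop("no aggregates match the requested scope")
  t0 <- s[s$timepoint == "t0", ]
  t1 <- s[s$timepoint == "t1", ]
  i <- match(t1$patient_id, t0$patient_id)
  if (anyNA(i)) stop("follow-up-only patient in aggregates")
  out <- data.frame(patient_id = t1$patient_id,
                    change = t0$score[i] - t1$score,
                    stringsAsFactors = FALSE)
  if (nrow(out) < 2L)
    stop("fewer than 2 complete-case patients")
  attr(out, "n_excluded") <- nrow(t0) - nrow(out)
  out
}

#' Standardized response mean of a set of change scores
#'
#' `srm = mean(change) / sd(change)` with the sample SD (n-1 denominator).
#' Degenerate cases: if the underlying scores are all zero at both timepoints
#' (feature absent from the cohort) the SRM is `NaN` and labelled
#' `not_available`; zero variance with zero mean (scores present but static)
#' gives SRM 0; zero variance with nonzero mean gives `NaN` with a
#' degenerate-variance warning.
#'
#' @param changes Numeric vector of change scores, or a data frame from
#'   [change_scores()].
#' @param all_zero Were the underlying scores all zero at both timepoints?
#' @return List of class `srm_result`: `n`, `mean_change`, `sd_change`,
#'   `srm`, `label`.
#' @export
srm <- function(changes, all_zero = FALSE) {
  ch <- if (is.data.frame(changes)) changes$change else as.numeric(changes)
  n <- length(ch)
  if (n < 2L) stop("SRM requires at least 2 complete cases")
  m <- mean(ch)
  s <- stats::sd(ch)
  v <- if (all_zero) {
    NaN
  } else if (s > 0) {
    m / s
  } else if (m == 0) {
    0
  } else {
    warning("degenerate variance: nonzero mean change with zero SD")
    NaN
  }
  structure(list(n = n, mean_change = m, sd_change = s,
                 srm = v, label = classify_srm(v)),
            class = "srm_result")
}

#' Classify SRM magnitude into responsiveness strata
#'
#' Strata on |SRM|: >= 0.8 large, [0.5, 0.8) moderate, [0.2, 0.5) small,
#' < 0.2 trivial, `NaN`/`NA` not_available. Classification uses the
#' magnitude so that, e.g., an SRM of -0.13 is trivial.
#'
#' @param value Numeric vector of SRMs.
#' @return Character vector of labels.
#' @export
classify_srm <- function(value) {
  vapply(value, function(v) {
    if (is.na(v)) return("not_available")
    a <- abs(v)
    if (a >= 0.8) "large"
    else if (a >= 0.5) "moderate"
    else if (a >= 0.2) "small"
    else "trivial"
  }, character(1L))
}

#' SRM grid over every joint and feature of an instrument
#'
#' Computes an `srm_result` for each joint x (overall + feature) cell, plus
#' instrument-level rows (joint `NA`) for the overall score and each feature
#' sub-score.
#'
#' @param cohort Single-effective-rater cohort data frame.
#' @param schema A `score_schema`.
#' @return Data frame of class `srm_grid` with columns `joint` (NA for
#'   instrument-level rows), `feature` (`"overall"` or a feature name), `n`,
#'   `mean_change`, `sd_change`, `srm`, `label`.
#' @export
srm_grid <- function(cohort, schema) {
  agg <- aggregate_scores(cohort, schema)
  sub <- cohort[cohort$joint %in% schema$joints, , drop = FALSE]
  feats <- schema$features$feature

  cell <- function(level, joint, feature) {
    ch <- change_scores(agg, level, joint = joint, feature = feature)
    keep <- rep(TRUE, nrow(sub))
    if (!is.null(joint)) keep <- keep & sub$joint == joint
    if (!is.null(feature)) keep <- keep & sub$feature == feature
    r <- srm(ch, all_zero = all(sub$value[keep] == 0))
    data.frame(joint = if (is.null(joint)) NA_character_ else joint,
               feature = if (is.null(feature)) "overall" else feature,
               n = r$n, mean_change = r$mean_change, sd_change = r$sd_change,
               srm = r$srm, label = r$label, stringsAsFactors = FALSE)
  }

  rows <- list(cell("overall", NULL, NULL))
  for (f in feats) rows[[length(rows) + 1L]] <- cell("feature", NULL, f)
  for (j in schema$joints) {
    rows[[length(rows) + 1L]] <- cell("joint", j, NULL)
    for (f in feats) rows[[length(rows) + 1L]] <- cell("joint_feature", j, f)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "schema_name") <- schema$name
  class(out) <- c("srm_grid", "data.frame")
  out
}
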