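# Long-format item-level cohorts: reading, validation, rater resolution and
# aggregation into overall and sub-scores.
#
# A cohort is a plain data frame with columns
#   patient_id, timepoint (t0/t1), rater_id, joint, site, feature, value
# validated against a score_schema.

.cohort_cols <- c("patient_id", "timepoint", "rater_id",
                  "joint", "site", "feature", "value")

cohort_key <- function(cohort, with_rater = TRUE) {
  if (with_rater)
    paste(cohort$patient_id, cohort$timepoint, cohort$rater_id,
          cohort$joint, cohort$site, cohort$feature, sep = "\r")
  else
    paste(cohort$patient_id, cohort$timepoint,
          cohort$joint, cohort$site, cohort$feature, sep = "\r")
}

canonical_site <- function(site) unname(.site_aliases[as.character(site)])

#' Validate a long-format cohort against a schema
#'
#' Checks tokens, score ranges, key uniqueness and the longitudinal design
#' constraint that no patient has follow-up records without baseline records.
#' All violations are collected and reported together with row numbers.
#'
#' @param cohort Data frame with the cohort columns.
#' @param schema A `score_schema`.
#' @return The cohort, invisibly, if valid; otherwise an error listing the
#'   violations.
#' @export
validate_cohort <- function(cohort, schema) {
  missing_cols <- setdiff(.cohort_cols, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "))
  probs <- character(0)
  note <- function(rows, what) {
    if (any(rows))
      probs <<- c(probs, sprintf("row %d: %s", which(rows)[seq_len(min(sum(rows), 10L))],
                                 what[rows][seq_len(min(sum(rows), 10L))]))
  }

  bad_tp <- !cohort$timepoint %in% c("t0", "t1")
  note(bad_tp, sprintf("unknown timepoint '%s' (expected t0/t1)", cohort$timepoint))
  bad_joint <- !cohort$joint %in% schema$joints
  note(bad_joint, sprintf("unknown joint '%s'", cohort$joint))
  bad_site <- is.na(canonical_site(cohort$site))
  note(bad_site, sprintf("unknown site '%s'", cohort$site))
  fi <- match(cohort$feature, schema$features$feature)
  note(is.na(fi), sprintf("unknown feature '%s'", cohort$feature))
  lo <- schema$features$score_min[fi]
  hi <- schema$features$score_max[fi]
  v <- cohort$value
  bad_val <- !is.na(fi) & (!is.finite(v) | v != round(v) | v < lo | v > hi)
  note(bad_val, sprintf("value %s out of range %d-%d for %s",
                        format(v), lo, hi, cohort$feature))

  ok_rows <- !(bad_tp | bad_joint | bad_site | is.na(fi) | bad_val)
  if (any(ok_rows)) {
    cc <- cohort[ok_rows, , drop = FALSE]
    cc$site <- canonical_site(cc$site)
    dup <- duplicated(cohort_key(cc))
    if (any(dup)) {
      rows <- which(ok_rows)[dup]
      probs <- c(probs, sprintf("row %d: duplicate key (%s %s %s %s %s %s)",
                                rows, cc$patient_id[dup], cc$timepoint[dup],
                                cc$rater_id[dup], cc$joint[dup], cc$site[dup],
                                cc$feature[dup]))
    }
    t1_only <- setdiff(cc$patient_id[cc$timepoint == "t1"],
                       cc$patient_id[cc$timepoint == "t0"])
    if (length(t1_only))
      probs <- c(probs, sprintf("patient %s has follow-up (t1) but no baseline (t0) records",
                                t1_only))
  }
  if (length(probs))
    stop("invalid cohort:\n  ", paste(utils::head(probs, 25L), collapse = "\n  "))
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Expects a header `patient_id,timepoint,rater_id,joint,site,feature,value`.
#' Site display aliases (`proximal`/`dorsal` for site_A, `distal`/`palmar`
#' for site_B) are accepted on read and canonicalized.
#'
#' @param path CSV path.
#' @param schema A `score_schema` the records must validate against.
#' @return Validated cohort data frame.
#' @export
read_cohort <- function(path, schema) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "numeric"))
  missing_cols <- setdiff(.cohort_cols, names(df))
  if (length(missing_cols))
    stop("cohort CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, .cohort_cols]
  for (col in setdiff(.cohort_cols, "value")) df[[col]] <- as.character(df[[col]])
  validate_cohort(df, schema)
  df$site <- canonical_site(df$site)
  df$value <- as.integer(df$value)
  df
}

# canonical record order: patient, timepoint, rater, anatomical item order
cohort_canonical_order <- function(cohort, schema) {
  feats <- schema$features$feature
  order(cohort$patient_id, cohort$timepoint, cohort$rater_id,
        joint_order(cohort$joint), cohort$site,
        match(cohort$feature, feats))
}

#' Write a cohort CSV in canonical order
#'
#' Rows are sorted by patient, timepoint, rater and anatomical item order so
#' that read/write round trips and re-serializations are byte-identical.
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @param schema A `score_schema` (used for the canonical item order).
#' @export
write_cohort <- function(cohort, path, schema = build_full_schema()) {
  out <- cohort[cohort_canonical_order(cohort, schema), .cohort_cols]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Collapse multiple raters into one effective rater
#'
#' Policies:
#' \describe{
#'   \item{`"consensus_required"`}{Where the raters disagree, a record from a
#'     rater literally named `"consensus"` must exist and is used; agreement
#'     passes through. Disagreement without a consensus record is an error
#'     listing the offending keys.}
#'   \item{`"mean"`}{Averages the raters; by default rounds half away from
#'     zero so values stay on the ordinal grid (`round_mean = FALSE` keeps
#'     fractional means).}
#'   \item{`"single:<rater_id>"`}{Keeps one rater's records.}
#' }
#'
#' @param cohort Cohort data frame (validated).
#' @param policy One of the policies above.
#' @param round_mean Round mean values half away from zero (default TRUE).
#' @return Cohort data frame with a single effective rater.
#' @export
resolve_raters <- function(cohort, policy = "consensus_required",
                           round_mean = TRUE) {
  raters <- sort(unique(cohort$rater_id))
  if (startsWith(policy, "single:")) {
    id <- sub("^single:", "", policy)
    if (!id %in% raters) stop("unknown rater '", id, "'")
    out <- cohort[cohort$rater_id == id, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  scoring <- setdiff(raters, "consensus")
  if (length(scoring) == 0L) stop("no scoring raters in cohort")

  key <- cohort_key(cohort, with_rater = FALSE)
  keys <- unique(key[cohort$rater_id == scoring[1]])
  vals <- matrix(NA_real_, length(keys), length(scoring),
                 dimnames = list(keys, scoring))
  for (r in scoring) {
    sel <- cohort$rater_id == r
    i <- match(key[sel], keys)
    if (anyNA(i) || sum(sel) != length(keys))
      stop("rater '", r, "' does not cover the same keys as rater '",
           scoring[1], "'")
    vals[i, r] <- cohort$value[sel]
  }
  if (anyNA(vals)) stop("missing rater cells")

  template <- cohort[cohort$rater_id == scoring[1], , drop = FALSE]
  template <- template[match(keys, key[cohort$rater_id == scoring[1]]), ]

  if (policy == "mean") {
    m <- rowMeans(vals)
    template$value <- if (round_mean) sign(m) * floor(abs(m) + 0.5) else m
    template$rater_id <- "mean"
  } else if (policy == "consensus_required") {
    agree <- apply(vals, 1L, function(x) all(x == x[1]))
    eff <- vals[, 1L]
    if (any(!agree)) {
      cons_sel <- cohort$rater_id == "consensus"
      cons_i <- match(keys[!agree], key[cons_sel])
      if (anyNA(cons_i))
        stop("rater disagreement without consensus record for key(s): ",
             paste(utils::head(gsub("\r", "/", keys[!agree][is.na(cons_i)]), 10L),
                   collapse = ", "))
      eff[!agree] <- cohort$value[cons_sel][cons_i]
    }
    template$value <- eff
    template$rater_id <- "consensus"
  } else {
    stop("unknown rater policy '", policy, "'")
  }
  rownames(template) <- NULL
  template
}

#' Aggregate item scores into overall and sub-scores
#'
#' For each patient and timepoint, sums the item values at four
#' granularities: overall, per feature, per joint, and per (joint, feature) —
#' the sub-scores of the instrument. Aggregating under a reduced schema
#' (records outside the schema's joints are ignored) yields the simplified
#' score directly.
#'
#' @param cohort Single-effective-rater cohort data frame.
#' @param schema A `score_schema`.
#' @param on_missing `"error"` (default; the study scored every item) or
#'   `"zero"`, which imputes 0 for absent items and emits a loud message —
#'   silent zero-imputation would bias SRMs toward 0.
#' @return Data frame of class `score_aggregates` with columns `patient_id`,
#'   `timepoint`, `level` (overall/feature/joint/joint_feature), `joint`,
#'   `feature`, `score`.
#' @export
aggregate_scores <- function(cohort, schema, on_missing = c("error", "zero")) {
  on_missing <- match.arg(on_missing)
  if (length(unique(cohort$rater_id)) > 1L)
    stop("cohort has multiple raters; run resolve_raters() first")
  sub <- cohort[cohort$joint %in% schema$joints &
                  cohort$feature %in% schema$features$feature, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no records match the schema")

  pt <- paste(sub$patient_id, sub$timepoint, sep = "\r")
  upt <- unique(pt)
  cnt <- table(pt)
  if (any(cnt != item_count(schema))) {
    if (on_missing == "error") {
      bad <- names(cnt)[cnt != item_count(schema)][1]
      sel <- pt == bad
      have <- paste(sub$joint[sel], sub$site[sel], sub$feature[sel], sep = "/")
      items <- enumerate_items(schema)
      want <- paste(items$joint, items$site, items$feature, sep = "/")
      miss <- setdiff(want, have)
      stop("incomplete item grid for ", gsub("\r", " at ", bad),
           ": missing ", if (length(miss)) miss[1] else "nothing",
           " (", length(miss), " item(s) in total)")
    }
    message("aggregate_scores: imputing 0 for missing items (on_missing = \"zero\")")
  }

  jf <- tapply(sub$value,
               list(pt = factor(pt, levels = upt),
                    joint = factor(sub$joint, levels = schema$joints),
                    feature = factor(sub$feature, levels = schema$features$feature)),
               sum)
  jf[is.na(jf)] <- 0

  split_pt <- do.call(rbind, strsplit(upt, "\r", fixed = TRUE))
  nj <- length(schema$joints)
  nf <- nrow(schema$features)

  rows <- vector("list", length(upt))
  for (i in seq_along(upt)) {
    m <- jf[i, , , drop = TRUE]                       # joints x features
    m <- matrix(m, nj, nf, dimnames = list(schema$joints, schema$features$feature))
    rows[[i]] <- data.frame(
      patient_id = split_pt[i, 1], timepoint = split_pt[i, 2],
      level = c("overall", rep("feature", nf), rep("joint", nj),
                rep("joint_feature", nj * nf)),
      joint = c(NA, rep(NA, nf), schema$joints, rep(schema$joints, nf)),
      feature = c(NA, schema$features$feature, rep(NA, nj),
                  rep(schema$features$feature, each = nj)),
      score = c(sum(m), colSums(m), rowSums(m), as.vector(m)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("score_aggregates", "data.frame")
  out
}

# pull one aggregate series (patient_id, timepoint, score) for a scope
aggregate_slice <- function(aggregates, level = "overall",
                            joint = NULL, feature = NULL) {
  sel <- aggregates$level == level
  if (!is.null(joint)) sel <- sel & !is.na(aggregates$joint) & aggregates$joint == joint
  if (!is.null(feature)) sel <- sel & !is.na(aggregates$feature) & aggregates$feature == feature
  aggregates[sel, c("patient_id", "timepoint", "score"), drop = FALSE]
}

#' Descriptive summary of a set of scores
#'
#' @param x Non-empty numeric vector.
#' @return List with `mean`, `sd` (sample SD, n-1 denominator; `NaN` for a
#'   single observation), `min`, `max`, `median`.
#' @export
summarize_scores <- function(x) {
  if (length(x) == 0L) stop("empty input")
  list(mean = mean(x),
       sd = if (length(x) < 2L) NaN else stats::sd(x),
       min = min(x), max = max(x),
       median = stats::median(x))
}
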