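# Relative efficacy of the simplified versus the reference instrument:
# RE = (SRM_simplified / SRM_reference)^2, with percentile bootstrap
# confidence bounds from resampling complete-case patients with replacement.

#' Relative efficacy of two SRMs
#'
#' `RE = (srm_s / srm_ref)^2`. Values above 1 mean the simplified score
#' detects change more efficiently than the reference; below 1 the opposite.
#' A zero reference SRM with nonzero simplified SRM gives `Inf` (flagged);
#' 0/0 and `NaN` inputs give `NaN` with a warning.
#'
#' @param srm_s SRM of the simplified instrument.
#' @param srm_ref SRM of the reference instrument.
#' @return Squared SRM ratio.
#' @export
relative_efficacy <- function(srm_s, srm_ref) {
  if (is.na(srm_s) || is.na(srm_ref)) {
    warning("NaN SRM input; relative efficacy undefined")
    return(NaN)
  }
  if (srm_ref == 0) {
    if (srm_s == 0) {
      warning("both SRMs zero; relative efficacy undefined")
      return(NaN)
    }
    warning("reference SRM is zero; relative efficacy infinite")
    return(Inf)
  }
  (srm_s / srm_ref)^2
}

# nearest-rank empirical quantile: sorted[ceiling(p * m)], so bounds are
# reproducible bit-for-bit given a seed
nearest_rank <- function(sorted, p) {
  m <- length(sorted)
  sorted[max(1L, ceiling(p * m))]
}

#' Bootstrap percentile bounds for relative efficacy
#'
#' Complete-case patients are resampled with replacement `B` times (the
#' patient is the only exchangeable unit in a paired pre/post design). For
#' each replicate both overall SRMs and their RE are recomputed; the 2.5% and
#' 97.5% nearest-rank percentiles of the replicate REs are the confidence
#' bounds. Replicates with undefined RE (zero-variance resamples, 0/0) are
#' dropped from the percentile ranking and counted; infinite REs are retained
#' and rank last.
#'
#' @param cohort Single-effective-rater cohort data frame.
#' @param schema_s Simplified `score_schema` (RE numerator).
#' @param schema_ref Reference `score_schema` (RE denominator).
#' @param B Number of bootstrap replicates (default 5000).
#' @param seed Integer seed for the resampling.
#' @param exhaustive Enumerate all n^n with-replacement resamples instead of
#'   sampling (only for tiny n; makes the percentile bounds exact).
#' @return List of class `efficacy_result`: `srm_simplified`,
#'   `srm_reference`, `re_point`, `B`, `bounds` (lower, upper),
#'   `n_degenerate_replicates`, `seed`, `n_patients`.
#' @export
bootstrap_re <- function(cohort, schema_s, schema_ref, B = 5000L,
                         seed = 1L, exhaustive = FALSE) {
  agg_s <- aggregate_scores(cohort, schema_s)
  agg_r <- aggregate_scores(cohort, schema_ref)
  ch_s <- change_scores(agg_s, "overall")
  ch_r <- change_scores(agg_r, "overall")
  i <- match(ch_s$patient_id, ch_r$patient_id)
  stopifnot(!anyNA(i))
  xs <- ch_s$change
  xr <- ch_r$change[i]
  n <- length(xs)
  if (n < 2L) stop("need at least 2 complete-case patients")

  zero_s <- all(cohort$value[cohort$joint %in% schema_s$joints] == 0)
  zero_r <- all(cohort$value[cohort$joint %in% schema_ref$joints] == 0)
  srm_s <- srm(xs, all_zero = zero_s)$srm
  srm_r <- srm(xr, all_zero = zero_r)$srm
  point <- relative_efficacy(srm_s, srm_r)

  if (exhaustive) {
    if (n^n > 2e5)
      stop("exhaustive enumeration infeasible for n = ", n)
    idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  } else {
    set.seed(seed)
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  }

  rep_srm <- function(x) {
    M <- matrix(x[idx], nrow = nrow(idx))
    m <- rowMeans(M)
    s2 <- (rowSums(M^2) - n * m^2) / (n - 1)
    s <- sqrt(pmax(s2, 0))
    ifelse(s > 0, m / s, ifelse(m == 0, 0, NaN))
  }
  rs <- rep_srm(xs)
  rr <- rep_srm(xr)
  re <- (rs / rr)^2  # x/0 -> Inf, 0/0 -> NaN, NaN propagates

  valid <- !is.nan(re)
  n_degenerate <- sum(!valid)
  kept <- re[valid]
  if (length(kept) == 0L) stop("every bootstrap replicate was degenerate")
  kept <- sort(kept)  # Inf sorts last
  bounds <- c(lower = nearest_rank(kept, 0.025),
              upper = nearest_rank(kept, 0.975))

  structure(
    list(srm_simplified = srm_s, srm_reference = srm_r, re_point = point,
         B = nrow(idx), bounds = bounds,
         n_degenerate_replicates = n_degenerate,
         seed = if (exhaustive) NA_integer_ else as.integer(seed),
         n_patients = n),
    class = "efficacy_result"
  )
}

#' @export
print.efficacy_result <- function(x, ...) {
  cat(sprintf("<efficacy_result> RE = %.4g (2.5/97.5%% bounds %.4g / %.4g), B = %d\n",
              x$re_point, x$bounds[["lower"]], x$bounds[["upper"]], x$B))
  cat(sprintf("  SRM simplified %.4g vs reference %.4g; %d patient(s), %d degenerate replicate(s)\n",
              x$srm_simplified, x$srm_reference, x$n_patients,
              x$n_degenerate_replicates))
  invisible(x)
}
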