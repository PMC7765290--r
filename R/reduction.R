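# Joint selection: rank joints by the magnitude of their overall-score SRM
# and keep the top k, expanding over ties, to define the simplified
# instrument.

#' Rank joints by overall-SRM magnitude
#'
#' Sorts by |SRM| descending; `NaN` SRMs rank last; ties are broken by
#' anatomical order (MCP before PIP before DIP, digit ascending), so the
#' ranking is deterministic.
#'
#' @param x An `srm_grid` (its per-joint overall rows are used) or a named
#'   numeric vector of per-joint overall SRMs.
#' @return Data frame with columns `joint`, `srm`, `abs_srm`, `rank`.
#' @export
rank_joints <- function(x) {
  if (inherits(x, "srm_grid")) {
    d <- x[!is.na(x$joint) & x$feature == "overall", c("joint", "srm")]
  } else if (is.numeric(x) && !is.null(names(x))) {
    d <- data.frame(joint = names(x), srm = unname(x), stringsAsFactors = FALSE)
  } else {
    stop("x must be an srm_grid or a named numeric vector")
  }
  if (nrow(d) == 0L) stop("no per-joint overall SRMs found")
  if (all(is.nan(d$srm))) stop("all per-joint SRMs are NaN")
  d$abs_srm <- abs(d$srm)
  sortkey <- ifelse(is.nan(d$srm), -Inf, d$abs_srm)
  d <- d[order(-sortkey, joint_order(d$joint)), , drop = FALSE]
  d$rank <- seq_len(nrow(d))
  rownames(d) <- NULL
  d
}

#' Select the top-k most responsive joints
#'
#' Takes the first `k` ranked joints. If the |SRM| at rank `k` equals the
#' |SRM| at rank `k + 1` the whole tie block is included and `tie_expanded`
#' is set, so the selection never depends on an arbitrary cut through a tie.
#'
#' @param ranked Ranking from [rank_joints()].
#' @param k Number of joints requested (default 3).
#' @param tol Numeric tolerance for tie detection.
#' @return List of class `joint_selection`: `ranked`, `selected` (joint
#'   tokens in anatomical order), `k_requested`, `tie_expanded`, `notes`.
#' @export
select_joints <- function(ranked, k = 3L, tol = 1e-12) {
  n <- nrow(ranked)
  if (k < 1L) stop("k must be at least 1")
  if (k > n) stop("k = ", k, " exceeds the ", n, " ranked joints")
  tied <- function(a, b) {
    (is.nan(a) && is.nan(b)) ||
      (is.finite(a) && is.finite(b) && abs(a - b) <= tol)
  }
  n_sel <- k
  tie_expanded <- FALSE
  while (n_sel < n && tied(ranked$abs_srm[k], ranked$abs_srm[n_sel + 1L])) {
    n_sel <- n_sel + 1L
    tie_expanded <- TRUE
  }
  sel <- ranked$joint[seq_len(n_sel)]
  sel <- sel[order(joint_order(sel))]
  structure(
    list(ranked = ranked, selected = sel, k_requested = as.integer(k),
         tie_expanded = tie_expanded,
         notes = if (tie_expanded)
           sprintf("tie at rank %d expanded selection to %d joints", k, n_sel)
         else sprintf("clean cut after rank %d", k)),
    class = "joint_selection"
  )
}

#' Derive the simplified instrument from a joint selection
#'
#' @param full The full `score_schema`.
#' @param selection A `joint_selection` or a character vector of joints.
#' @param name Name of the simplified instrument.
#' @return A reduced `score_schema`.
#' @examples
#' sel <- select_joints(rank_joints(spsamris_reference_srms()), k = 3)
#' item_count(derive_simplified(build_full_schema(), sel)) # 36
#' @export
derive_simplified <- function(full, selection, name = "sPsAMRIS") {
  joints <- if (inherits(selection, "joint_selection")) selection$selected
            else as.character(selection)
  build_reduced_schema(full, joints, name = name)
}

#' @export
print.joint_selection <- function(x, ...) {
  cat(sprintf("<joint_selection> k = %d -> %d joint(s): %s%s\n",
              x$k_requested, length(x$selected),
              paste(x$selected, collapse = ", "),
              if (x$tie_expanded) " [tie expanded]" else ""))
  invisible(x)
}
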