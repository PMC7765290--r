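# Instrument definition: which joints, joint sites and ordinal features make
# up a hand MRI score. Both the full PsAMRIS and any reduced variant
# (e.g. sPsAMRIS) are values of the same "score_schema" class.

.joint_rows <- c("MCP", "PIP", "DIP")
.joint_digits <- 2:5
.sites <- c("site_A", "site_B")

# accepted site spellings -> canonical token; display aliases depend on the
# feature (proximal/distal for bone features, dorsal/palmar for inflammation)
.site_aliases <- c(
  site_A = "site_A", proximal = "site_A", dorsal = "site_A",
  site_B = "site_B", distal = "site_B", palmar = "site_B"
)

#' All twelve hand joints of the full instrument, in anatomical order
#'
#' The anatomical ordering (MCP before PIP before DIP, digit ascending within
#' each row) is the package-wide convention for serialization and for
#' deterministic tie-breaking during joint selection.
#'
#' @return Character vector of joint tokens `"MCP2"` ... `"DIP5"`.
#' @export
psamris_joints <- function() {
  as.vector(vapply(.joint_rows, function(r) paste0(r, .joint_digits),
                   character(length(.joint_digits))))
}

# rank of a joint token in the anatomical order; NA for unknown tokens
joint_order <- function(joints) match(joints, psamris_joints())

#' The six PsAMRIS features and their ordinal score ranges
#'
#' Synovitis 0-3, flexor tenosynovitis 0-3, periarticular inflammation 0-1,
#' bone edema 0-3, bone erosion 0-10, bone proliferation 0-1. All features
#' start at 0 (feature absent).
#'
#' @return A data frame with columns `feature`, `score_min`, `score_max`.
#' @export
psamris_features <- function() {
  data.frame(
    feature = c("synovitis", "flexor_tenosynovitis",
                "periarticular_inflammation", "bone_edema",
                "bone_erosion", "bone_proliferation"),
    score_min = 0L,
    score_max = c(3L, 3L, 1L, 3L, 10L, 1L),
    stringsAsFactors = FALSE
  )
}

new_score_schema <- function(name, joints, features, sites_per_joint = 2L) {
  structure(
    list(name = as.character(name),
         joints = as.character(joints),
         features = features,
         sites_per_joint = as.integer(sites_per_joint)),
    class = "score_schema"
  )
}

#' Build the full 144-item PsAMRIS instrument
#'
#' 12 joints (MCP/PIP/DIP of digits 2-5) x 2 joint sites x 6 features.
#'
#' @return A `score_schema` object.
#' @examples
#' sch <- build_full_schema()
#' item_count(sch)     # 144
#' max_total_score(sch) # 504
#' @export
build_full_schema <- function() {
  new_score_schema("PsAMRIS", psamris_joints(), psamris_features())
}

#' Restrict a schema to a subset of joints
#'
#' Features and sites are unchanged; joints are kept in anatomical order
#' regardless of the order they are requested in.
#'
#' @param base A `score_schema`.
#' @param joints Character vector of joint tokens, a non-empty subset of
#'   `base$joints`.
#' @param name Name for the reduced instrument.
#' @return A `score_schema` restricted to `joints`.
#' @examples
#' s <- build_reduced_schema(build_full_schema(), c("MCP3", "MCP4", "PIP4"),
#'                           name = "sPsAMRIS")
#' item_count(s) # 36
#' @export
build_reduced_schema <- function(base, joints, name = "reduced") {
  stopifnot(inherits(base, "score_schema"))
  joints <- unique(as.character(joints))
  if (length(joints) == 0L)
    stop("joint set must be non-empty")
  unknown <- setdiff(joints, base$joints)
  if (length(unknown))
    stop("unknown joint(s): ", paste(unknown, collapse = ", "))
  new_score_schema(name, base$joints[base$joints %in% joints],
                   base$features, base$sites_per_joint)
}

#' Enumerate every scored item of a schema
#'
#' Deterministic order: anatomical joint order, then site_A before site_B,
#' then features in schema order.
#'
#' @param schema A `score_schema`.
#' @return Data frame with columns `joint`, `site`, `feature`, `score_min`,
#'   `score_max`; one row per item.
#' @export
enumerate_items <- function(schema) {
  stopifnot(inherits(schema, "score_schema"))
  grid <- expand.grid(
    feature = schema$features$feature,
    site = .sites[seq_len(schema$sites_per_joint)],
    joint = schema$joints,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("joint", "site", "feature")]
  m <- match(grid$feature, schema$features$feature)
  grid$score_min <- schema$features$score_min[m]
  grid$score_max <- schema$features$score_max[m]
  rownames(grid) <- NULL
  grid
}

#' Number of items in a schema
#' @param schema A `score_schema`.
#' @return Integer: joints x sites x features.
#' @export
item_count <- function(schema) {
  length(schema$joints) * schema$sites_per_joint * nrow(schema$features)
}

#' Maximum attainable total score of a schema
#' @param schema A `score_schema`.
#' @return Integer sum of `score_max` over all items.
#' @export
max_total_score <- function(schema) sum(enumerate_items(schema)$score_max)

#' Validate a single item score against a schema
#'
#' Never raises for a bad score; returns a violation record instead, so bulk
#' validation can report every offending row.
#'
#' @param schema A `score_schema`.
#' @param joint,site,feature Item coordinates; site accepts the display
#'   aliases `"proximal"`/`"dorsal"` (site_A) and `"distal"`/`"palmar"`
#'   (site_B).
#' @param value Integer score.
#' @return List with `ok` (logical) and, when not ok, `reason`.
#' @export
validate_item <- function(schema, joint, site, feature, value) {
  if (!joint %in% schema$joints)
    return(list(ok = FALSE, reason = sprintf("unknown joint '%s'", joint)))
  canon <- unname(.site_aliases[as.character(site)])
  if (is.na(canon) || !canon %in% .sites[seq_len(schema$sites_per_joint)])
    return(list(ok = FALSE, reason = sprintf("unknown site '%s'", site)))
  i <- match(feature, schema$features$feature)
  if (is.na(i))
    return(list(ok = FALSE, reason = sprintf("unknown feature '%s'", feature)))
  lo <- schema$features$score_min[i]
  hi <- schema$features$score_max[i]
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value) ||
      value != round(value))
    return(list(ok = FALSE,
                reason = sprintf("value '%s' is not an integer", format(value))))
  if (value < lo || value > hi)
    return(list(ok = FALSE,
                reason = sprintf("value %d out of range %d-%d for %s",
                                 as.integer(value), lo, hi, feature)))
  list(ok = TRUE, reason = NULL)
}

#' Write a schema to a JSON document
#' @param schema A `score_schema`.
#' @param path Output path.
#' @export
write_schema <- function(schema, path) {
  jsonlite::write_json(
    list(name = schema$name,
         joints = schema$joints,
         sites_per_joint = schema$sites_per_joint,
         features = schema$features),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Read a schema from a JSON document
#' @param path Path to a JSON file written by [write_schema()].
#' @return A `score_schema`.
#' @export
read_schema <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- as.data.frame(x$features, stringsAsFactors = FALSE)
  feats$score_min <- as.integer(feats$score_min)
  feats$score_max <- as.integer(feats$score_max)
  new_score_schema(x$name, x$joints, feats, x$sites_per_joint)
}

#' @export
print.score_schema <- function(x, ...) {
  cat(sprintf("<score_schema> %s: %d joints x %d sites x %d features = %d items (max total %d)\n",
              x$name, length(x$joints), x$sites_per_joint,
              nrow(x$features), item_count(x), max_total_score(x)))
  cat("  joints: ", paste(x$joints, collapse = " "), "\n", sep = "")
  invisible(x)
}
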