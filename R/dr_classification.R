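#' Default DR area cut-offs
#'
#' The cut-off table distinguishing immature from other desmoplastic
#' reaction for each area feature and margin. ACP (automatic cut-off point)
#' entries are the values derived by maximally selected rank statistics on
#' the original 396-patient training cohort; MCP (manual cut-off point) is
#' the area of one 40x microscope field, 0.196 mm^2, the criterion used in
#' manual DR grading. These defaults are cohort-derived reference values,
#' not universal constants: [maxstat_cutpoint()] recomputes ACPs on any new
#' cohort.
#'
#' @return A `cutoff_set` data frame with columns `feature` (`"total"`,
#'   `"average"`, `"largest"`), `margin` (`"Margin1"`, `"Margin2"`),
#'   `regime` (`"ACP"`, `"MCP"`) and `threshold_mm2`.
#' @export
default_cutoffs <- function() {
  out <- data.frame(
    feature = c("total", "average", "largest", "largest",
                "total", "average", "largest", "largest"),
    margin = rep(c("Margin1", "Margin2"), each = 4L),
    regime = c("ACP", "ACP", "ACP", "MCP", "ACP", "ACP", "ACP", "MCP"),
    threshold_mm2 = c(0.27392, 0.00622, 1.04863, 0.19600,
                      0.31949, 0.15859, 0.17410, 0.19600),
    stringsAsFactors = FALSE)
  class(out) <- c("cutoff_set", class(out))
  out
}

lookup_cutoff <- function(cutoffs, feature, margin, regime = "ACP") {
  hit <- cutoffs$feature == feature & cutoffs$margin == margin &
    cutoffs$regime == regime
  if (sum(hit) != 1L) {
    stop(sprintf("no cut-off defined for (%s, %s, %s)", feature, margin, regime),
         call. = FALSE)
  }
  cutoffs$threshold_mm2[hit]
}

#' Classify desmoplastic reaction from margin features
#'
#' A patient is called `immature` when the chosen area feature strictly
#' exceeds the cut-off for that (feature, margin, regime) combination, and
#' `other` otherwise (ties go to `other`). A patient with no myxoid stroma
#' in the margin therefore always receives `other`.
#'
#' @param features A [compute_margin_features()] row (or any data frame with
#'   `margin`, `total_mm2`, `average_mm2`, `largest_mm2` and optionally
#'   `patient_id`).
#' @param cutoffs A [default_cutoffs()]-style cut-off set.
#' @param feature `"total"`, `"average"` or `"largest"`.
#' @param regime `"ACP"` or `"MCP"`.
#' @param strict Use strict `>` at the threshold (default; set `FALSE` for
#'   `>=`).
#' @return A `dr_call` data frame: `patient_id`, `feature`, `margin`,
#'   `regime`, `value_mm2`, `threshold_mm2`, `category`.
#' @export
classify_dr <- function(features, cutoffs = default_cutoffs(),
                        feature = c("largest", "total", "average"),
                        regime = c("ACP", "MCP"), strict = TRUE) {
  feature <- match.arg(feature)
  regime <- match.arg(regime)
  col <- paste0(feature, "_mm2")
  if (!col %in% names(features) || !"margin" %in% names(features)) {
    stop("features must carry columns 'margin' and '", col, "'", call. = FALSE)
  }
  value <- features[[col]]
  thr <- vapply(features$margin, function(m)
    lookup_cutoff(cutoffs, feature, m, regime), 0)
  immature <- if (strict) value > thr else value >= thr
  out <- data.frame(
    patient_id = if ("patient_id" %in% names(features)) features$patient_id
                 else NA_character_,
    feature = feature,
    margin = features$margin,
    regime = regime,
    value_mm2 = value,
    threshold_mm2 = unname(thr),
    category = ifelse(immature, "immature", "other"),
    stringsAsFactors = FALSE)
  class(out) <- c("dr_call", class(out))
  out
}
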