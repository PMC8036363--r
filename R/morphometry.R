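#' Decompose a tissue mask into stroma objects
#'
#' Partitions mask foreground into maximal 8-connected components
#' ("objects"), each carrying its physical area. Object-level decomposition
#' is what makes the "largest single myxoid stroma area" feature possible.
#'
#' @param mask Binary myxoid-stroma mask.
#' @param res A [resolution()].
#' @return A `stroma_objects` object: the label raster plus a data frame of
#'   per-object pixel counts and areas in mm^2 (ids in raster order).
#' @export
extract_objects <- function(mask, res = resolution()) {
  res <- as_resolution(res)
  mask <- as_binary_mask(mask)
  lab <- cpp_label8(array(as.integer(mask), dim = dim(mask)))
  n <- max(lab)
  px <- if (n > 0L) tabulate(lab[lab > 0L], nbins = n) else integer(0)
  structure(list(labels = lab,
                 objects = data.frame(id = seq_len(n),
                                      n_px = px,
                                      area_mm2 = px * res$um_per_px^2 / 1e6),
                 um_per_px = res$um_per_px),
            class = "stroma_objects")
}

#' Margin-restricted myxoid stroma area features
#'
#' For each stroma object, measures the area of its intersection with the
#' margin band (objects that do not touch the band are excluded) and
#' summarises the three DR features: total area, average (mean per-object)
#' area and largest single area within the margin. The full (unclipped)
#' object areas are carried alongside for transparency.
#'
#' @param objects A [extract_objects()] result.
#' @param band A [build_margin_band()] result.
#' @param patient_id Optional identifier copied into the output.
#' @return A `margin_features` object (also a one-row data frame) with
#'   columns `patient_id`, `margin`, `total_mm2`, `average_mm2`,
#'   `largest_mm2`, `n_objects`.
#' @export
compute_margin_features <- function(objects, band, patient_id = NA_character_) {
  stopifnot(inherits(objects, "stroma_objects"), inherits(band, "margin_band"))
  if (objects$um_per_px != band$um_per_px) {
    stop("mask and margin band were rasterised at different resolutions",
         call. = FALSE)
  }
  if (!all(dim(objects$labels) == dim(band$mask))) {
    stop("mask and margin band dimensions differ", call. = FALSE)
  }
  n <- nrow(objects$objects)
  px_in <- if (n > 0L) {
    labs_in <- objects$labels[band$mask]
    tabulate(labs_in[labs_in > 0L], nbins = n)
  } else integer(0)
  in_mm2 <- px_in * objects$um_per_px^2 / 1e6
  hit <- in_mm2 > 0
  out <- data.frame(patient_id = patient_id,
                    margin = band$label,
                    total_mm2 = sum(in_mm2[hit]),
                    average_mm2 = if (any(hit)) mean(in_mm2[hit]) else 0,
                    largest_mm2 = if (any(hit)) max(in_mm2[hit]) else 0,
                    n_objects = sum(hit),
                    stringsAsFactors = FALSE)
  attr(out, "per_object") <- data.frame(
    id = objects$objects$id[hit],
    area_mm2 = objects$objects$area_mm2[hit],
    area_in_margin_mm2 = in_mm2[hit])
  class(out) <- c("margin_features", class(out))
  out
}

#' Dice overlap between a ground-truth and a predicted mask
#'
#' `dice = 2 TP / (2 TP + FP + FN)` on physical areas, where TP, FP and FN
#' are the areas of the intersection, prediction-only and truth-only pixel
#' sets. Symmetric in its two arguments. When both masks are empty the score
#' is defined as 1 (a slide with no myxoid stroma that is predicted empty is
#' a perfect segmentation).
#'
#' @param gt,pred Binary masks of equal dimensions.
#' @param res A [resolution()].
#' @return A `dice_report` list: `tp_area_mm2`, `fp_area_mm2`, `fn_area_mm2`,
#'   `dice`.
#' @export
dice_score <- function(gt, pred, res = resolution()) {
  res <- as_resolution(res)
  gt <- as_binary_mask(gt)
  pred <- as_binary_mask(pred)
  if (!all(dim(gt) == dim(pred))) {
    stop("ground-truth and prediction dimensions differ", call. = FALSE)
  }
  px2mm2 <- res$um_per_px^2 / 1e6
  tp <- sum(gt & pred) * px2mm2
  fp <- sum(pred & !gt) * px2mm2
  fn <- sum(gt & !pred) * px2mm2
  dice <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  structure(list(tp_area_mm2 = tp, fp_area_mm2 = fp, fn_area_mm2 = fn,
                 dice = dice),
            class = "dice_report")
}

#' Pool Dice reports over several images
#'
#' @param reports List of [dice_score()] results.
#' @param method `"pooled"` (default; sums TP/FP/FN areas across images and
#'   applies the Dice formula once) or `"mean"` (average of per-image Dice).
#' @return A `dice_report` (pooled) or a single number (mean).
#' @export
aggregate_dice <- function(reports, method = c("pooled", "mean")) {
  method <- match.arg(method)
  stopifnot(length(reports) > 0L,
            all(vapply(reports, inherits, TRUE, "dice_report")))
  if (method == "mean") {
    return(mean(vapply(reports, `[[`, 0, "dice")))
  }
  tp <- sum(vapply(reports, `[[`, 0, "tp_area_mm2"))
  fp <- sum(vapply(reports, `[[`, 0, "fp_area_mm2"))
  fn <- sum(vapply(reports, `[[`, 0, "fn_area_mm2"))
  structure(list(tp_area_mm2 = tp, fp_area_mm2 = fp, fn_area_mm2 = fn,
                 dice = if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)),
            class = "dice_report")
}
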