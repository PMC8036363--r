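#' Pipeline run configuration
#'
#' Collects every setting of an end-to-end DR quantification run. Stages
#' whose inputs are absent are skipped by design: with a precomputed mask
#' the segmentation stage is bypassed; without a cohort table the survival
#' stage is skipped.
#'
#' @param mask_png Path to a precomputed myxoid mask (PNG). Either this or
#'   (`image_png` + `segmenter`) must be given.
#' @param image_png Path to an RGB image to segment.
#' @param segmenter A trained `dr_segmenter` (or path to one saved with
#'   [save_segmenter()]).
#' @param annotations_geojson Path to the GeoJSON holding the
#'   invasive-front LineString and tumour-region Polygon.
#' @param cohort_csv Optional cohort CSV for the survival stage.
#' @param out_dir Output directory (created if missing).
#' @param um_per_px Working resolution.
#' @param margins_um Margin widths, microns, strictly positive and sorted
#'   (default `c(500, 1000)`).
#' @param feature,regime DR classification settings (see [classify_dr()]).
#' @param probability_threshold,min_object_mm2 Segmentation operating point.
#' @param minprop,n_perm Cut-point discovery settings (see
#'   [maxstat_cutpoint()]).
#' @param patient_id Identifier attached to the slide-level outputs.
#' @param seed Seed for all stochastic stages.
#' @return A `run_config` object.
#' @export
run_config <- function(mask_png = NULL, image_png = NULL, segmenter = NULL,
                       annotations_geojson, cohort_csv = NULL, out_dir,
                       um_per_px = 1.0, margins_um = c(500, 1000),
                       feature = "largest", regime = "ACP",
                       probability_threshold = 0.80, min_object_mm2 = 0.1,
                       minprop = 0.1, n_perm = 1000L,
                       patient_id = "slide", seed = 1L) {
  if (any(margins_um <= 0) || is.unsorted(margins_um)) {
    stop("margins_um must be positive and sorted increasing", call. = FALSE)
  }
  if (is.null(mask_png) && (is.null(image_png) || is.null(segmenter))) {
    stop("provide either mask_png or both image_png and a segmenter", call. = FALSE)
  }
  structure(list(mask_png = mask_png, image_png = image_png,
                 segmenter = segmenter,
                 annotations_geojson = annotations_geojson,
                 cohort_csv = cohort_csv, out_dir = out_dir,
                 um_per_px = um_per_px, margins_um = margins_um,
                 feature = feature, regime = regime,
                 probability_threshold = probability_threshold,
                 min_object_mm2 = min_object_mm2,
                 minprop = minprop, n_perm = as.integer(n_perm),
                 patient_id = patient_id, seed = as.integer(seed)),
            class = "run_config")
}

#' Save / load a trained segmenter
#'
#' The reference segmenter is fully described by its coefficient vector and
#' configuration, so it serialises to a small JSON artefact.
#'
#' @param segmenter A trained `dr_segmenter`.
#' @param path File path (JSON).
#' @return `load_segmenter` returns the handle; `save_segmenter` the path
#'   invisibly.
#' @export
save_segmenter <- function(segmenter, path) {
  stopifnot(inherits(segmenter, "dr_segmenter"))
  cfg <- segmenter$cfg
  jsonlite::write_json(list(
    coef = as.list(segmenter$coef),
    feature_names = segmenter$feature_names,
    cfg = list(probability_threshold = cfg$probability_threshold,
               min_object_mm2 = cfg$min_object_mm2,
               um_per_px = cfg$res$um_per_px,
               augmentation = cfg$augmentation,
               n_augment = cfg$n_augment,
               samples_per_image = cfg$samples_per_image,
               texture_window = cfg$texture_window,
               seed = cfg$seed)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  j <- jsonlite::read_json(path)
  cfg <- segmenter_config(
    probability_threshold = j$cfg$probability_threshold,
    min_object_mm2 = j$cfg$min_object_mm2,
    res = resolution(j$cfg$um_per_px),
    augmentation = j$cfg$augmentation,
    n_augment = j$cfg$n_augment,
    samples_per_image = j$cfg$samples_per_image,
    texture_window = j$cfg$texture_window,
    seed = j$cfg$seed)
  structure(list(coef = unlist(j$coef), feature_names = unlist(j$feature_names),
                 cfg = cfg),
            class = "dr_segmenter")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the end-to-end DR quantification pipeline
#'
#' Executes segment (optional) -> margin bands -> quantify -> classify ->
#' cut-point discovery and survival statistics (optional), writing
#' `mask.png` (when segmenting), `features.csv`, `calls.csv`,
#' `cutpoints.csv`, `cox_univariate.csv`, `km_rates.csv` and
#' `manifest.json` into `out_dir`. Deterministic stages are bit-reproducible
#' given identical inputs; stochastic stages reproduce under the configured
#' seed. No stage mutates its inputs.
#'
#' @param config A [run_config()].
#' @return A `run_manifest` list (also written as JSON): configuration
#'   echo, input checksums, package version, per-stage outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- resolution(cfg$um_per_px)
  outputs <- list()
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  # --- segmentation (skipped when a mask is supplied) ---
  if (!is.null(cfg$mask_png)) {
    mask <- stage("segment", read_mask_png(cfg$mask_png))
    note("segment: skipped, using precomputed mask %s", cfg$mask_png)
  } else {
    seg <- cfg$segmenter
    if (is.character(seg)) seg <- stage("segment", load_segmenter(seg))
    img <- stage("segment", read_image_png(cfg$image_png))
    pm <- stage("segment", predict_probability(seg, img))
    mask <- threshold_mask(pm, cfg$probability_threshold)
    mask <- filter_min_size(mask, cfg$min_object_mm2, res)
    outputs$mask <- file.path(cfg$out_dir, "mask.png")
    write_mask_png(mask, outputs$mask)
    note("segment: image %s -> %d foreground px", cfg$image_png, sum(mask))
  }

  # --- margin bands (requires both annotations to orient 'outward') ---
  front <- stage("band", read_front_geojson(cfg$annotations_geojson))
  tumour <- stage("band", read_tumour_geojson(cfg$annotations_geojson))
  bands <- stage("band", lapply(seq_along(cfg$margins_um), function(i)
    build_margin_band(front, tumour, cfg$margins_um[i], res, dim(mask),
                      label = paste0("Margin", i))))
  note("band: built %d margin band(s) at widths %s um",
       length(bands), paste(cfg$margins_um, collapse = ", "))

  # --- morphometry ---
  objects <- stage("quantify", extract_objects(mask, res))
  feats <- stage("quantify", do.call(rbind, lapply(bands, function(b)
    compute_margin_features(objects, b, patient_id = cfg$patient_id))))
  outputs$features <- file.path(cfg$out_dir, "features.csv")
  write_table_csv(feats, outputs$features)
  note("quantify: %d object(s), %d margin row(s)", nrow(objects$objects),
       nrow(feats))

  # --- DR classification ---
  calls <- stage("classify",
                 classify_dr(feats, default_cutoffs(), feature = cfg$feature,
                             regime = cfg$regime))
  outputs$calls <- file.path(cfg$out_dir, "calls.csv")
  write_table_csv(calls, outputs$calls)
  note("classify: %s", paste(calls$category, collapse = ", "))

  # --- survival statistics (optional) ---
  if (!is.null(cfg$cohort_csv)) {
    cohort <- stage("survival", read_cohort_csv(cfg$cohort_csv))
    feat_cols <- intersect(c("total_m1", "average_m1", "largest_m1",
                             "total_m2", "average_m2", "largest_m2"),
                           names(cohort))
    cuts <- stage("survival", do.call(rbind, lapply(feat_cols, function(fc) {
      ms <- maxstat_cutpoint(cohort[[fc]], cohort$time_months, cohort$event,
                             minprop = cfg$minprop, n_perm = cfg$n_perm,
                             seed = cfg$seed)
      data.frame(feature = fc, cutpoint_mm2 = ms$best_cutpoint,
                 statistic = ms$statistic, p_value = ms$p_value)
    })))
    outputs$cutpoints <- file.path(cfg$out_dir, "cutpoints.csv")
    write_table_csv(cuts, outputs$cutpoints)

    uni <- stage("survival", do.call(rbind, lapply(feat_cols, function(fc) {
      thr <- cuts$cutpoint_mm2[cuts$feature == fc]
      grp <- as.integer(cohort[[fc]] > thr)
      cf <- cox_fit(cbind(cohort, .high = grp), ".high")
      lr <- logrank_test(cohort$time_months, cohort$event, grp)
      data.frame(feature = fc, hr = cf$table$hr, lower = cf$table$lower,
                 upper = cf$table$upper, cox_p = cf$table$p,
                 logrank_p = lr$p_value)
    })))
    uni$logrank_p_bh <- bh_adjust(uni$logrank_p)
    outputs$cox <- file.path(cfg$out_dir, "cox_univariate.csv")
    write_table_csv(uni, outputs$cox)

    km <- stage("survival", do.call(rbind, lapply(feat_cols, function(fc) {
      thr <- cuts$cutpoint_mm2[cuts$feature == fc]
      grp <- ifelse(cohort[[fc]] > thr, "high", "low")
      kc <- km_estimate(cohort$time_months, cohort$event, grp)
      data.frame(feature = fc, group = names(kc),
                 surv_at_horizon = vapply(kc, `[[`, 0, "surv_at_horizon"),
                 surv_at_last_event = vapply(kc, `[[`, 0, "surv_at_last_event"))
    })))
    outputs$km <- file.path(cfg$out_dir, "km_rates.csv")
    write_table_csv(km, outputs$km)
    note("survival: %d feature(s) analysed", length(feat_cols))
  }

  inputs <- Filter(Negate(is.null),
                   list(mask = cfg$mask_png, image = cfg$image_png,
                        annotations = cfg$annotations_geojson,
                        cohort = cfg$cohort_csv))
  manifest <- list(
    tool = "drquant",
    version = as.character(utils::packageVersion("drquant")),
    config = cfg[setdiff(names(cfg), "segmenter")],
    input_md5 = lapply(inputs, function(p) unname(tools::md5sum(p))),
    outputs = outputs,
    log = log)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  class(manifest) <- "run_manifest"
  manifest
}
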