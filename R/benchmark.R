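#' Segmentation accuracy benchmark on synthetic slides
#'
#' Trains the reference segmenter on a set of generated slides and evaluates
#' it on held-out generated slides, applying the full operating point
#' (probability threshold, then minimum-object filter) before scoring
#' against the ground-truth masks. Dice is pooled over the held-out slides
#' (TP/FP/FN areas summed before applying the formula); the per-image mean
#' is reported alongside.
#'
#' @param n_train,n_test Numbers of training and held-out slides.
#' @param train_seed,test_seed Base seeds for the two slide sets (slide `i`
#'   uses `base * 1000 + i`, keeping the sets disjoint and reproducible).
#' @param params Slide generator settings ([slide_gen_params()]; the seed
#'   field is overridden per slide).
#' @param cfg Segmenter settings ([segmenter_config()]).
#' @return List: `pooled` ([aggregate_dice()] report), `mean_dice`,
#'   `per_image` (data frame of per-slide TP/FP/FN/Dice), `n_train`,
#'   `n_test`.
#' @export
dice_benchmark <- function(n_train = 20L, n_test = 10L,
                           train_seed = 1L, test_seed = 2L,
                           params = slide_gen_params(),
                           cfg = segmenter_config()) {
  gen <- function(base, i) {
    p <- params
    p$seed <- as.integer(base * 1000L + i)
    generate_slide(p)
  }
  train <- lapply(seq_len(n_train), function(i) gen(train_seed, i))
  seg <- train_reference_segmenter(lapply(train, `[[`, "image"),
                                   lapply(train, `[[`, "mask"), cfg)
  reports <- lapply(seq_len(n_test), function(i) {
    s <- gen(test_seed, i)
    pm <- predict_probability(seg, s$image)
    m <- threshold_mask(pm, cfg)
    m <- filter_min_size(m, cfg, cfg$res)
    dice_score(s$mask, m, cfg$res)
  })
  per_image <- do.call(rbind, lapply(seq_along(reports), function(i)
    data.frame(slide = i,
               tp_area_mm2 = reports[[i]]$tp_area_mm2,
               fp_area_mm2 = reports[[i]]$fp_area_mm2,
               fn_area_mm2 = reports[[i]]$fn_area_mm2,
               dice = reports[[i]]$dice)))
  list(pooled = aggregate_dice(reports),
       mean_dice = aggregate_dice(reports, "mean"),
       per_image = per_image,
       n_train = n_train, n_test = n_test)
}
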