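#' Segmenter configuration
#'
#' Settings shared by the segmentation stage: the probability threshold
#' applied to the per-pixel myxoid-class probability map (default 0.80), the
#' minimum connected-object size kept after thresholding (default 0.1 mm^2),
#' the working resolution (default 1 um/px) and the colour-augmentation
#' ranges used during training to simulate stain variation.
#'
#' @param probability_threshold Fraction in \[0, 1\]; pixels with probability
#'   `>=` this value become mask foreground.
#' @param min_object_mm2 Connected components smaller than this (mm^2) are
#'   discarded; components of exactly this area are retained.
#' @param res Working [resolution()].
#' @param augmentation List with elements `hue`, `sat`, `bright`: half-widths
#'   of the uniform per-image jitter applied in HSV space (hue as a fraction
#'   of the full hue circle, saturation and brightness as relative scale
#'   half-widths).
#' @param n_augment Number of colour-augmented copies of each training image
#'   added during training (0 = train on originals only).
#' @param samples_per_image Pixels sampled per (possibly augmented) training
#'   image, split between the two classes.
#' @param texture_window Side (pixels, odd) of the local window used for the
#'   texture features (local mean / standard deviation of intensity).
#' @param seed Integer seed making training and augmentation reproducible.
#' @return A `segmenter_config` object.
#' @export
segmenter_config <- function(probability_threshold = 0.80,
                             min_object_mm2 = 0.1,
                             res = resolution(1.0),
                             augmentation = list(hue = 0.02, sat = 0.10, bright = 0.10),
                             n_augment = 1L,
                             samples_per_image = 3000L,
                             texture_window = 7L,
                             seed = 1L) {
  if (!is.numeric(probability_threshold) || probability_threshold < 0 ||
      probability_threshold > 1) {
    stop("probability_threshold must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(min_object_mm2) || min_object_mm2 < 0) {
    stop("min_object_mm2 must be >= 0", call. = FALSE)
  }
  aug <- modifyList(list(hue = 0, sat = 0, bright = 0), as.list(augmentation))
  if (any(unlist(aug) < 0)) stop("augmentation ranges must be >= 0", call. = FALSE)
  structure(list(probability_threshold = probability_threshold,
                 min_object_mm2 = min_object_mm2,
                 res = as_resolution(res),
                 augmentation = aug,
                 n_augment = as.integer(n_augment),
                 samples_per_image = as.integer(samples_per_image),
                 texture_window = as.integer(texture_window),
                 seed = as.integer(seed)),
            class = "segmenter_config")
}

# run code under a temporary RNG state so package routines never disturb the
# caller's random stream
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

check_rgb <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3L] != 3L ||
      !is.numeric(image)) {
    stop("image must be an H x W x 3 numeric RGB array", call. = FALSE)
  }
  if (min(image) < 0 || max(image) > 1) {
    stop("RGB values must lie in [0, 1]", call. = FALSE)
  }
  image
}

rgb_to_hsv_arr <- function(image) {
  d <- dim(image)
  m <- grDevices::rgb2hsv(r = as.vector(image[, , 1L]),
                          g = as.vector(image[, , 2L]),
                          b = as.vector(image[, , 3L]), maxColorValue = 1)
  array(c(m[1L, ], m[2L, ], m[3L, ]), dim = d)
}

hsv_to_rgb_arr <- function(hsv) {
  h <- as.vector(hsv[, , 1L]) * 6
  s <- as.vector(hsv[, , 2L])
  v <- as.vector(hsv[, , 3L])
  i <- floor(h) %% 6
  f <- h - floor(h)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  array(c(r, g, b), dim = dim(hsv))
}

#' Colour-augment an RGB image
#'
#' Applies one uniform per-image jitter in HSV space: a hue rotation, a
#' saturation scaling and a brightness scaling, each drawn uniformly within
#' the configured half-widths. Training on such perturbed copies makes the
#' pixel classifier tolerant to haematoxylin/eosin stain variation between
#' slides. With all ranges zero the image is returned unchanged; for a fixed
#' seed the output is reproducible.
#'
#' @param image H x W x 3 numeric RGB array with values in \[0, 1\].
#' @param cfg A [segmenter_config()] supplying the ranges.
#' @param seed Integer seed for the jitter draw.
#' @return A colour-perturbed copy of `image`.
#' @export
augment_colour <- function(image, cfg = segmenter_config(), seed = cfg$seed) {
  check_rgb(image)
  a <- cfg$augmentation
  if (a$hue == 0 && a$sat == 0 && a$bright == 0) return(image)
  jit <- with_seed(seed, runif(3, -1, 1))
  hsv <- rgb_to_hsv_arr(image)
  hsv[, , 1L] <- (hsv[, , 1L] + jit[1L] * a$hue) %% 1
  hsv[, , 2L] <- pmin(1, pmax(0, hsv[, , 2L] * (1 + jit[2L] * a$sat)))
  hsv[, , 3L] <- pmin(1, pmax(0, hsv[, , 3L] * (1 + jit[3L] * a$bright)))
  hsv_to_rgb_arr(hsv)
}

# local mean and sd over a w x w box (truncated at borders) via integral images
box_stats <- function(m, w) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  pad_cum <- function(x) {
    s <- apply(x, 2L, cumsum)
    t(apply(s, 1L, cumsum))
  }
  S <- pad_cum(m)
  S2 <- pad_cum(m * m)
  # window sums via padded cumulative matrices (vectorised over the grid)
  Sp <- rbind(0, cbind(0, S))
  S2p <- rbind(0, cbind(0, S2))
  r0 <- pmax(seq_len(nr) - h, 1L); r1 <- pmin(seq_len(nr) + h, nr)
  c0 <- pmax(seq_len(nc) - h, 1L); c1 <- pmin(seq_len(nc) + h, nc)
  win_sum <- function(P) {
    P[r1 + 1L, c1 + 1L, drop = FALSE] - P[r0, c1 + 1L, drop = FALSE] -
      P[r1 + 1L, c0, drop = FALSE] + P[r0, c0, drop = FALSE]
  }
  n <- outer(r1 - r0 + 1L, c1 - c0 + 1L)
  mu <- win_sum(Sp) / n
  v <- pmax(win_sum(S2p) / n - mu^2, 0)
  list(mean = mu, sd = sqrt(v))
}

pixel_features <- function(image, cfg) {
  check_rgb(image)
  hsv <- rgb_to_hsv_arr(image)
  intensity <- (image[, , 1L] + image[, , 2L] + image[, , 3L]) / 3
  bs <- box_stats(intensity, cfg$texture_window)
  cbind(r = as.vector(image[, , 1L]),
        g = as.vector(image[, , 2L]),
        b = as.vector(image[, , 3L]),
        s = as.vector(hsv[, , 2L]),
        v = as.vector(hsv[, , 3L]),
        loc_mean = as.vector(bs$mean),
        loc_sd = as.vector(bs$sd))
}

#' Train the reference myxoid-stroma pixel classifier
#'
#' The reference segmenter is a logistic-regression pixel classifier on
#' colour (RGB, saturation, value) and local-texture (windowed mean and
#' standard deviation of intensity) features, trained on pixels sampled from
#' annotated images and their colour-augmented copies. It implements the
#' same contract as any heavier segmentation model plugged into the
#' pipeline: it produces a per-pixel probability map that is then
#' thresholded and size-filtered.
#'
#' @param images List of H x W x 3 RGB arrays.
#' @param gt_masks List of binary ground-truth masks (foreground = myxoid
#'   stroma), aligned with `images`.
#' @param cfg A [segmenter_config()].
#' @return A `dr_segmenter` handle usable with [predict_probability()].
#' @export
train_reference_segmenter <- function(images, gt_masks, cfg = segmenter_config()) {
  stopifnot(is.list(images), is.list(gt_masks))
  if (length(images) < 1L || length(images) != length(gt_masks)) {
    stop("need >= 1 aligned image/mask pair", call. = FALSE)
  }
  gt_masks <- lapply(gt_masks, as_binary_mask)
  for (i in seq_along(images)) {
    check_rgb(images[[i]])
    if (!all(dim(images[[i]])[1:2] == dim(gt_masks[[i]]))) {
      stop("image and mask dimensions differ at pair ", i, call. = FALSE)
    }
  }
  n_fg <- sum(vapply(gt_masks, sum, 0))
  n_px <- sum(vapply(gt_masks, length, 0L))
  if (n_fg == 0L || n_fg == n_px) {
    stop("ground truth must contain both myxoid and non-myxoid pixels",
         call. = FALSE)
  }
  with_seed(cfg$seed, {
    xs <- list(); ys <- list()
    k <- 0L
    for (i in seq_along(images)) {
      copies <- c(list(images[[i]]),
                  lapply(seq_len(cfg$n_augment), function(j)
                    augment_colour(images[[i]], cfg,
                                   seed = cfg$seed + 1000L * i + j)))
      for (img in copies) {
        feat <- pixel_features(img, cfg)
        y <- as.vector(gt_masks[[i]])
        per_class <- cfg$samples_per_image %/% 2L
        pick <- c(sample(which(y), min(per_class, sum(y))),
                  sample(which(!y), min(per_class, sum(!y))))
        k <- k + 1L
        xs[[k]] <- feat[pick, , drop = FALSE]
        ys[[k]] <- y[pick]
      }
    }
    X <- do.call(rbind, xs)
    y <- unlist(ys)
    df <- data.frame(y = y, X)
    fit <- suppressWarnings(glm(y ~ ., family = binomial(), data = df))
    structure(list(coef = stats::coef(fit),
                   feature_names = colnames(X),
                   cfg = cfg),
              class = "dr_segmenter")
  })
}

#' Predict the per-pixel myxoid-stroma probability map
#'
#' @param segmenter A trained `dr_segmenter` handle.
#' @param image H x W x 3 RGB array.
#' @return Numeric matrix of probabilities in \[0, 1\] with the image's
#'   spatial dimensions.
#' @export
predict_probability <- function(segmenter, image) {
  if (!inherits(segmenter, "dr_segmenter") || is.null(segmenter$coef)) {
    stop("segmenter is not a trained dr_segmenter handle", call. = FALSE)
  }
  check_rgb(image)
  feat <- pixel_features(image, segmenter$cfg)
  eta <- drop(cbind(1, feat) %*% segmenter$coef)
  matrix(stats::plogis(eta), nrow = dim(image)[1L], ncol = dim(image)[2L])
}

#' Threshold a probability map into a binary tissue mask
#'
#' Foreground where probability is greater than or equal to the configured
#' threshold (boundary-inclusive; the standard operating point is 80%).
#'
#' @param p Numeric matrix of probabilities in \[0, 1\].
#' @param cfg A [segmenter_config()], or a bare threshold value.
#' @return Logical mask of the same dimensions.
#' @export
threshold_mask <- function(p, cfg = segmenter_config()) {
  thr <- if (inherits(cfg, "segmenter_config")) cfg$probability_threshold else cfg
  if (!is.numeric(thr) || length(thr) != 1L || thr < 0 || thr > 1) {
    stop("probability threshold must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(p) || min(p) < 0 || max(p) > 1) {
    stop("probability map values must lie in [0, 1]", call. = FALSE)
  }
  p >= thr
}

#' Remove connected objects below the minimum size
#'
#' Drops 8-connected foreground components whose area is strictly below the
#' configured minimum (default 0.1 mm^2); components of exactly the minimum
#' area are retained. Retained components are unchanged, so the operation is
#' idempotent and never adds foreground.
#'
#' @param mask Binary mask.
#' @param cfg A [segmenter_config()], or a bare minimum area in mm^2.
#' @param res A [resolution()].
#' @return Filtered logical mask.
#' @export
filter_min_size <- function(mask, cfg = segmenter_config(), res = resolution()) {
  min_mm2 <- if (inherits(cfg, "segmenter_config")) cfg$min_object_mm2 else cfg
  res <- as_resolution(res)
  mask <- as_binary_mask(mask)
  if (!any(mask)) return(mask)
  lab <- cpp_label8(array(as.integer(mask), dim = dim(mask)))
  px_areas <- tabulate(lab[lab > 0L])
  keep <- which(px_areas * res$um_per_px^2 / 1e6 >= min_mm2)
  out <- array(lab %in% keep & mask, dim = dim(mask))
  out
}
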