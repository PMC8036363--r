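#' Parameters for the synthetic slide generator
#'
#' The generator emulates the visual situation DR quantification faces at
#' the invasive front: a tumour mass bounded by a wavy invasive front, a
#' collagenous (fibrillar, eosin-pink) extramural stroma, and pale
#' blue-grey, smooth-textured myxoid blobs scattered in a band outward of
#' the front. Ground-truth myxoid masks match the rendered blob pixels
#' exactly. The colours and textures are a rendering convention — chosen so
#' that colour-plus-texture classification is the right tool, as it is on
#' real H&E — not a histologically validated appearance model.
#'
#' @param canvas_px Canvas `c(nrow, ncol)` in pixels (default 1500 x 1500,
#'   i.e. 1.5 x 1.5 mm at 1 um/px).
#' @param res A [resolution()] (default 1 um/px, the working resolution of
#'   the whole pipeline).
#' @param n_blobs Number of myxoid blobs (default 3).
#' @param area_meanlog,area_sdlog Log-normal blob-area distribution in mm^2
#'   (defaults `log(0.25)` and 0.4, keeping essentially all blobs above the
#'   0.1 mm^2 minimum-object filter, as in annotated immature-DR material).
#' @param blob_area_mm2 Optional fixed per-blob area (overrides the
#'   log-normal draw; recycled to `n_blobs`).
#' @param offset_um Range `c(lo, hi)` of blob-centre offsets outward from
#'   the front, microns (default 150-900, inside Margin 2).
#' @param front_x_um Mean x-position of the front (default 500).
#' @param front_amp_um,front_period_um Amplitude and period of the front's
#'   sinusoidal waviness (defaults 60 and 700 um).
#' @param colours List of mean RGB triplets for `myxoid`, `stroma`,
#'   `tumour`.
#' @param stroma_texture_amp Amplitude of the fibrillar intensity modulation
#'   in the collagenous stroma (drives the local-sd texture contrast).
#' @param noise_sd Per-pixel Gaussian colour noise.
#' @param seed Integer seed; the generator is a pure function of
#'   (params, seed).
#' @return A `slide_gen_params` object.
#' @export
slide_gen_params <- function(canvas_px = c(1500L, 1500L),
                             res = resolution(1.0),
                             n_blobs = 3L,
                             area_meanlog = log(0.25),
                             area_sdlog = 0.4,
                             blob_area_mm2 = NULL,
                             offset_um = c(150, 900),
                             front_x_um = 500,
                             front_amp_um = 60,
                             front_period_um = 700,
                             colours = list(myxoid = c(0.72, 0.76, 0.88),
                                            stroma = c(0.93, 0.70, 0.77),
                                            tumour = c(0.58, 0.42, 0.66)),
                             stroma_texture_amp = 0.10,
                             noise_sd = 0.02,
                             seed = 1L) {
  stopifnot(length(canvas_px) == 2L, all(canvas_px > 0),
            n_blobs >= 0, length(offset_um) == 2L, all(is.finite(offset_um)),
            offset_um[1] <= offset_um[2])
  if (!is.null(blob_area_mm2) && any(blob_area_mm2 <= 0)) {
    stop("blob areas must be positive", call. = FALSE)
  }
  structure(list(canvas_px = as.integer(canvas_px), res = as_resolution(res),
                 n_blobs = as.integer(n_blobs),
                 area_meanlog = area_meanlog, area_sdlog = area_sdlog,
                 blob_area_mm2 = blob_area_mm2,
                 offset_um = offset_um, front_x_um = front_x_um,
                 front_amp_um = front_amp_um, front_period_um = front_period_um,
                 colours = colours, stroma_texture_amp = stroma_texture_amp,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "slide_gen_params")
}

# Fourier-perturbed ellipse outline (closed polygon, microns)
blob_polygon <- function(area_um2, cx, cy, n_pts = 72L) {
  aspect <- runif(1, 0.55, 1)
  theta0 <- runif(1, 0, pi)
  # ellipse with the requested area: pi * a * b = area, b = aspect * a
  a <- sqrt(area_um2 / (pi * aspect))
  b <- aspect * a
  th <- seq(0, 2 * pi, length.out = n_pts + 1L)[-(n_pts + 1L)]
  r_base <- a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  pert <- rep(0, n_pts)
  for (k in 2:5) pert <- pert + rnorm(1, 0, 0.04) * cos(k * th + runif(1, 0, 2 * pi))
  r <- r_base * pmax(1 + pert, 0.3)
  ct <- cos(theta0); st <- sin(theta0)
  x <- r * cos(th); y <- r * sin(th)
  cbind(cx + ct * x - st * y, cy + st * x + ct * y)
}

# rasterise a polygon into an existing logical canvas (TRUE inside),
# restricted to the polygon's bounding box for speed
fill_polygon <- function(mask, poly, res) {
  nr <- nrow(mask); nc <- ncol(mask)
  c0 <- max(1L, floor(min(poly[, 1L]) / res))
  c1 <- min(nc, ceiling(max(poly[, 1L]) / res) + 1L)
  r0 <- max(1L, floor(min(poly[, 2L]) / res))
  r1 <- min(nr, ceiling(max(poly[, 2L]) / res) + 1L)
  if (c0 > c1 || r0 > r1) return(mask)
  sub <- cpp_polygon_mask(r1 - r0 + 1L, c1 - c0 + 1L, res,
                          (c0 - 1L) * res, (r0 - 1L) * res,
                          poly[, 1L], poly[, 2L], TRUE)
  mask[r0:r1, c0:c1] <- mask[r0:r1, c0:c1] | sub
  mask
}

#' Generate a synthetic invasive-front slide
#'
#' Renders an H&E-like RGB image together with its exact ground-truth
#' myxoid mask, the tumour region polygon and the invasive-front polyline.
#' All randomness is governed by `params$seed`.
#'
#' @param params A [slide_gen_params()].
#' @return List with `image` (H x W x 3 array in \[0, 1\]), `mask` (logical
#'   ground-truth myxoid mask), `tumour` ([tumour_region()]), `front`
#'   ([invasive_front()]), `params`.
#' @export
generate_slide <- function(params = slide_gen_params()) {
  stopifnot(inherits(params, "slide_gen_params"))
  p <- params
  res <- p$res$um_per_px
  nr <- p$canvas_px[1L]; nc <- p$canvas_px[2L]
  h_um <- nr * res; w_um <- nc * res
  with_seed(p$seed, {
    # wavy invasive front, running top to bottom; tumour occupies its left
    ys <- seq(0, h_um, by = 50)
    phase <- runif(1, 0, 2 * pi)
    xs <- p$front_x_um + p$front_amp_um * sin(2 * pi * ys / p$front_period_um + phase)
    front <- invasive_front(cbind(xs, ys), closed = FALSE)
    tum_poly <- rbind(cbind(xs, ys), c(0, h_um), c(0, 0))
    tumour <- tumour_region(tum_poly)

    # myxoid blobs outward of the front
    explicit <- !is.null(p$blob_area_mm2)
    areas_mm2 <- if (explicit) {
      rep_len(p$blob_area_mm2, p$n_blobs)
    } else if (p$n_blobs > 0L) {
      # cap random draws so every blob can fit the canvas (documented
      # truncation of the log-normal tail; explicit areas are never capped)
      a_cap <- pi * (min(w_um - p$front_x_um, h_um) / 3.4)^2 / 1e6
      pmin(rlnorm(p$n_blobs, p$area_meanlog, p$area_sdlog), a_cap)
    } else numeric(0)
    mask <- matrix(FALSE, nr, nc)
    for (i in seq_len(p$n_blobs)) {
      area_um2 <- areas_mm2[i] * 1e6
      poly0 <- blob_polygon(area_um2, 0, 0)
      xr <- range(poly0[, 1L]); yr <- range(poly0[, 2L])
      # feasible centre positions keeping the whole outline on the canvas
      cx_lo <- -xr[1L] + res; cx_hi <- w_um - xr[2L] - res
      cy_lo <- -yr[1L] + res; cy_hi <- h_um - yr[2L] - res
      if (cx_lo > cx_hi || cy_lo > cy_hi) {
        stop(sprintf("blob of %.2f mm^2 cannot fit the %.1f x %.1f mm canvas",
                     areas_mm2[i], w_um / 1e3, h_um / 1e3), call. = FALSE)
      }
      cy <- runif(1, cy_lo, cy_hi)
      off <- runif(1, p$offset_um[1L], p$offset_um[2L])
      fx <- p$front_x_um + p$front_amp_um *
        sin(2 * pi * cy / p$front_period_um + phase)
      cx <- min(max(fx + off, cx_lo), cx_hi)
      poly <- cbind(poly0[, 1L] + cx, poly0[, 2L] + cy)
      mask <- fill_polygon(mask, poly, res)
    }

    # render: tumour / collagenous stroma / myxoid layers, then noise
    inside_tum <- cpp_polygon_mask(nr, nc, res, 0, 0,
                                   tumour$polygon[, 1L], tumour$polygon[, 2L],
                                   TRUE)
    img <- array(0, dim = c(nr, nc, 3L))
    # fibrillar texture: oriented sinusoidal intensity modulation
    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    ang <- runif(1, 0, pi)
    freq <- runif(1, 0.15, 0.35)
    fib <- p$stroma_texture_amp *
      sin(freq * (cos(ang) * rows + sin(ang) * cols)) +
      rnorm(nr * nc, 0, p$stroma_texture_amp / 2)
    for (ch in 1:3) {
      base <- matrix(p$colours$stroma[ch], nr, nc) + fib
      base[inside_tum] <- p$colours$tumour[ch] +
        rnorm(sum(inside_tum), 0, p$stroma_texture_amp / 3)
      base[mask] <- p$colours$myxoid[ch] + rnorm(sum(mask), 0, 0.01)
      img[, , ch] <- pmin(1, pmax(0, base + rnorm(nr * nc, 0, p$noise_sd)))
    }
    list(image = img, mask = mask, tumour = tumour, front = front,
         params = p)
  })
}

#' Parameters for the synthetic cohort generator
#'
#' Emulates the statistical structure of a stage II/III colorectal cancer
#' cohort scored for DR: a configurable immature fraction (default 0.237),
#' a planted disease-specific hazard ratio for immature DR (default 3.5),
#' an exponential baseline hazard, administrative censoring at the end of
#' follow-up (default 134 months ~ 11.2 years) plus uniform dropout, and
#' per-patient area features that straddle the corresponding cut-offs by
#' class.
#'
#' @param n_patients Cohort size (default 528).
#' @param immature_frac Probability of immature DR (default 0.237).
#' @param hr True hazard ratio of immature vs other (default 3.5).
#' @param baseline_rate Exponential baseline hazard per month (default
#'   0.0018, i.e. ~79% survival at the administrative cap for the
#'   other-DR class).
#' @param admin_cap_months Administrative censoring time (default 134).
#' @param dropout_max_months Uniform dropout horizon (default 360; dropout
#'   before the cap is uncommon).
#' @param cutoffs Cut-off set whose thresholds the simulated feature values
#'   straddle (default [default_cutoffs()]).
#' @param manual_agreement Probability that the manual DR call agrees with
#'   the true class (default 0.9; manual grading is imperfect).
#' @param seed Integer seed.
#' @return A `cohort_gen_params` object.
#' @export
cohort_gen_params <- function(n_patients = 528L,
                              immature_frac = 0.237,
                              hr = 3.5,
                              baseline_rate = 0.0018,
                              admin_cap_months = 134,
                              dropout_max_months = 360,
                              cutoffs = default_cutoffs(),
                              manual_agreement = 0.9,
                              seed = 1L) {
  stopifnot(n_patients >= 1, immature_frac >= 0, immature_frac <= 1)
  if (hr <= 0 || baseline_rate <= 0 || admin_cap_months <= 0 ||
      dropout_max_months <= 0) {
    stop("hazard ratio, rates and censoring horizons must be positive",
         call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 immature_frac = immature_frac, hr = hr,
                 baseline_rate = baseline_rate,
                 admin_cap_months = admin_cap_months,
                 dropout_max_months = dropout_max_months,
                 cutoffs = cutoffs,
                 manual_agreement = manual_agreement,
                 seed = as.integer(seed)),
            class = "cohort_gen_params")
}

# feature value above (immature) or below (other) a threshold, log-normal
# multiplicative distance from it
straddle <- function(n, thr, above, spread = 0.45) {
  gap <- abs(rnorm(n, 0.55, spread))
  thr * exp(ifelse(above, gap, -gap))
}

#' Generate a synthetic survival cohort with planted DR effect
#'
#' Draws DR class, clinicopathological covariates, per-margin area features
#' straddling the class cut-offs, and exponential survival times whose
#' hazard is multiplied by the planted hazard ratio for immature patients;
#' censoring is administrative-plus-dropout. Pure function of
#' (params, seed).
#'
#' @param params A [cohort_gen_params()].
#' @return Data frame with one row per patient: `patient_id`,
#'   `time_months`, `event`, `dr_true`, `manual_DR`, `pT`, `pN`,
#'   `differentiation`, `tumour_type`, and feature columns `total_m1`,
#'   `average_m1`, `largest_m1`, `total_m2`, `average_m2`, `largest_m2`
#'   (mm^2).
#' @export
generate_cohort <- function(params = cohort_gen_params()) {
  stopifnot(inherits(params, "cohort_gen_params"))
  p <- params
  n <- p$n_patients
  cut <- function(f, m) lookup_cutoff(p$cutoffs, f, m, "ACP")
  with_seed(p$seed, {
    immature <- runif(n) < p$immature_frac
    rate <- p$baseline_rate * ifelse(immature, p$hr, 1)
    t_event <- rexp(n, rate)
    t_cens <- pmin(p$admin_cap_months, runif(n, 0, p$dropout_max_months))
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    manual <- ifelse(runif(n) < p$manual_agreement, immature, !immature)
    total_m1 <- straddle(n, cut("total", "Margin1"), immature)
    largest_m1 <- straddle(n, cut("largest", "Margin1"), immature)
    total_m2 <- straddle(n, cut("total", "Margin2"), immature)
    largest_m2 <- straddle(n, cut("largest", "Margin2"), immature)
    n_obj <- 1L + stats::rpois(n, 2)
    data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      time_months = time,
      event = event,
      dr_true = ifelse(immature, "immature", "other"),
      manual_DR = ifelse(manual, "immature", "other"),
      pT = sample(c(3L, 4L), n, replace = TRUE, prob = c(0.765, 0.235)),
      pN = sample(0:2, n, replace = TRUE, prob = c(0.52, 0.333, 0.147)),
      differentiation = sample(c("well", "moderate", "poor"), n, TRUE,
                               prob = c(0.417, 0.52, 0.063)),
      tumour_type = sample(c("adenocarcinoma", "mucinous"), n, TRUE,
                           prob = c(0.955, 0.045)),
      total_m1 = total_m1,
      average_m1 = total_m1 / n_obj,
      largest_m1 = largest_m1,
      total_m2 = total_m2,
      average_m2 = total_m2 / n_obj,
      largest_m2 = largest_m2,
      stringsAsFactors = FALSE)
  })
}
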