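#' Pixel resolution of a raster
#'
#' @param um_per_px Physical size of one pixel side, in microns. The
#'   morphometry in this package was designed around 1 um/px rasters, the
#'   resolution at which whole-slide myxoid-stroma classification is run.
#' @return A `resolution` object.
#' @export
resolution <- function(um_per_px = 1.0) {
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L ||
      !is.finite(um_per_px) || um_per_px <= 0) {
    stop("um_per_px must be a single finite positive number", call. = FALSE)
  }
  structure(list(um_per_px = as.numeric(um_per_px)), class = "resolution")
}

as_resolution <- function(res) {
  if (inherits(res, "resolution")) return(res)
  resolution(res)
}

check_vertices <- function(xy, what, min_n = 2L) {
  if (!is.matrix(xy) || ncol(xy) != 2L) {
    stop(what, " vertices must be a two-column matrix of (x, y) in microns",
         call. = FALSE)
  }
  if (nrow(xy) < min_n) {
    stop(what, " needs at least ", min_n, " vertices", call. = FALSE)
  }
  if (!all(is.finite(xy))) {
    stop(what, " contains non-finite coordinates", call. = FALSE)
  }
  d <- rowSums((xy[-1L, , drop = FALSE] - xy[-nrow(xy), , drop = FALSE])^2)
  if (any(d == 0)) {
    stop(what, " has consecutive duplicate vertices", call. = FALSE)
  }
  xy
}

#' Invasive tumour front annotation
#'
#' The invasive front is the tumour periphery adjacent to non-cancerous
#' tissue; it is the reference contour from which margin bands extend
#' outward.
#'
#' @param vertices Two-column matrix of (x, y) vertex coordinates in microns.
#' @param closed Whether the annotation is a closed contour (`TRUE`) or an
#'   open polyline (`FALSE`, the default).
#' @return An `invasive_front` object.
#' @export
invasive_front <- function(vertices, closed = FALSE) {
  vertices <- check_vertices(vertices, "invasive front")
  structure(list(vertices = vertices, closed = isTRUE(closed)),
            class = "invasive_front")
}

#' Tumour region annotation
#'
#' A simple closed polygon covering the tumour mass. It orients "outward":
#' margin-band pixels must lie outside this polygon, so the band extends into
#' the extramural tissue only.
#'
#' @param polygon Two-column matrix of polygon vertices in microns; the
#'   closing edge back to the first vertex is implicit.
#' @return A `tumour_region` object.
#' @export
tumour_region <- function(polygon) {
  polygon <- check_vertices(polygon, "tumour region", min_n = 3L)
  # drop an explicitly repeated closing vertex
  n <- nrow(polygon)
  if (all(polygon[1L, ] == polygon[n, ])) polygon <- polygon[-n, , drop = FALSE]
  if (nrow(polygon) < 3L) stop("tumour region needs >= 3 distinct vertices", call. = FALSE)
  a <- polygon_area(polygon)
  if (a <= 0) stop("tumour region polygon must have positive area", call. = FALSE)
  structure(list(polygon = polygon), class = "tumour_region")
}

polygon_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

front_segments <- function(front) {
  v <- front$vertices
  n <- nrow(v)
  i0 <- seq_len(n - 1L)
  i1 <- i0 + 1L
  if (front$closed && n > 2L) {
    i0 <- c(i0, n)
    i1 <- c(i1, 1L)
  }
  list(x0 = v[i0, 1L], y0 = v[i0, 2L], x1 = v[i1, 1L], y1 = v[i1, 2L])
}

#' Build an outward margin band around the invasive front
#'
#' Constructs the region of interest in which myxoid stroma is quantified: a
#' binary raster whose foreground pixels have their centre within `width_um`
#' (Euclidean distance to the front polyline, rounded end-caps) of the
#' invasive front and outside the tumour polygon. The defaults used in DR
#' assessment are 500 um ("Margin1") and 1000 um ("Margin2"). Pixel (r, c)
#' of the raster (1-based) has its centre at
#' ((c - 0.5) * um_per_px, (r - 0.5) * um_per_px) microns; pixel centres
#' lying exactly on the tumour polygon boundary count as tumour and are
#' excluded.
#'
#' @param front An [invasive_front()].
#' @param tumour A [tumour_region()] orienting which side is extramural.
#' @param width_um Band width in microns (>= 0).
#' @param res A [resolution()] (or a bare um/px number).
#' @param canvas_shape Integer vector `c(nrow, ncol)` of the output raster in
#'   pixels.
#' @param label Band label; defaults to `"Margin1"` for 500 um, `"Margin2"`
#'   for 1000 um, otherwise `"Margin<width>"`.
#' @param tissue_mask Optional binary raster; when given, the band is
#'   additionally intersected with it (e.g. to exclude glass background).
#'   Default `NULL`: no clipping.
#' @return A `margin_band` object with fields `mask` (logical matrix),
#'   `width_um`, `label`, and `um_per_px`.
#' @export
build_margin_band <- function(front, tumour, width_um, res = resolution(),
                              canvas_shape, label = NULL, tissue_mask = NULL) {
  stopifnot(inherits(front, "invasive_front"), inherits(tumour, "tumour_region"))
  res <- as_resolution(res)
  if (!is.numeric(width_um) || length(width_um) != 1L || !is.finite(width_um) ||
      width_um < 0) {
    stop("width_um must be a single finite number >= 0", call. = FALSE)
  }
  canvas_shape <- as.integer(canvas_shape)
  if (length(canvas_shape) != 2L || any(canvas_shape < 1L)) {
    stop("canvas_shape must be c(nrow, ncol) with positive entries", call. = FALSE)
  }
  w_um <- canvas_shape[2L] * res$um_per_px
  h_um <- canvas_shape[1L] * res$um_per_px
  v <- front$vertices
  if (all(v[, 1L] < 0 | v[, 1L] > w_um | v[, 2L] < 0 | v[, 2L] > h_um)) {
    stop(sprintf(
      "invasive front lies entirely outside the %.0f x %.0f um canvas", w_um, h_um),
      call. = FALSE)
  }
  if (is.null(label)) {
    label <- if (width_um == 500) "Margin1" else if (width_um == 1000) "Margin2"
             else paste0("Margin", format(width_um))
  }
  if (width_um == 0) {
    band <- matrix(FALSE, canvas_shape[1L], canvas_shape[2L])
  } else {
    seg <- front_segments(front)
    near <- cpp_distance_band(canvas_shape[1L], canvas_shape[2L], res$um_per_px,
                              seg$x0, seg$y0, seg$x1, seg$y1, width_um)
    inside <- cpp_polygon_mask(canvas_shape[1L], canvas_shape[2L], res$um_per_px,
                               0, 0, tumour$polygon[, 1L], tumour$polygon[, 2L],
                               TRUE)
    band <- near & !inside
  }
  if (!is.null(tissue_mask)) {
    tissue_mask <- as_binary_mask(tissue_mask)
    if (!all(dim(tissue_mask) == dim(band))) {
      stop("tissue_mask dimensions do not match the canvas", call. = FALSE)
    }
    band <- band & tissue_mask
  }
  structure(list(mask = band, width_um = width_um, label = label,
                 um_per_px = res$um_per_px),
            class = "margin_band")
}

as_binary_mask <- function(m) {
  if (inherits(m, "margin_band")) m <- m$mask
  if (is.logical(m)) {
    if (anyNA(m)) stop("mask contains NA", call. = FALSE)
    return(m)
  }
  if (!is.numeric(m) && !is.integer(m)) stop("mask must be numeric or logical", call. = FALSE)
  u <- unique(as.vector(m))
  if (anyNA(u) || !all(u %in% c(0, 1, 255))) {
    stop("mask is not binary (values must be 0/1 or 0/255)", call. = FALSE)
  }
  array(m > 0, dim = dim(m))
}

#' Convert a binary mask to physical area
#'
#' `area = foreground pixels * (um_per_px)^2 / 1e6` square millimetres, the
#' unit in which all DR area features and cut-offs are expressed.
#'
#' @param mask Binary matrix (logical, or 0/1, or 0/255).
#' @param res A [resolution()] (or a bare um/px number).
#' @return Area in mm^2.
#' @export
area_mm2 <- function(mask, res = resolution()) {
  res <- as_resolution(res)
  mask <- as_binary_mask(mask)
  sum(mask) * res$um_per_px^2 / 1e6
}

#' Area of a circular microscope field
#'
#' The manual criterion for immature DR compares the largest myxoid stroma
#' area against the area of one 40x objective field of view, a circle of
#' diameter 0.5 mm: pi * (0.25 mm)^2 = 0.196 mm^2 (3 d.p.).
#'
#' @param diameter_mm Field-of-view diameter in millimetres (default 0.5,
#'   a standard 40x objective).
#' @return Field area in mm^2.
#' @export
field_area_mm2 <- function(diameter_mm = 0.5) {
  stopifnot(is.numeric(diameter_mm), diameter_mm > 0)
  pi * (diameter_mm / 2)^2
}
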