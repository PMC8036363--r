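#' Read / write binary masks and RGB images as PNG
#'
#' Masks are written as single-channel 8-bit PNG with background 0 and
#' foreground 255; RGB images as 8-bit colour PNG. Resolution is never
#' stored in the image: it is supplied in configuration wherever physical
#' areas are computed. Round trips are lossless for binary masks; RGB
#' images round-trip at 8-bit precision.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param path File path.
#' @return `read_mask_png` returns a logical matrix; writers return the
#'   path invisibly.
#' @export
write_mask_png <- function(mask, path) {
  mask <- as_binary_mask(mask)
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  m > 0.5
}

#' @rdname write_mask_png
#' @param image H x W x 3 RGB array in \[0, 1\].
#' @export
write_image_png <- function(image, path) {
  check_rgb(image)
  png::writePNG(image, path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3L] == 4L) img <- img[, , 1:3]  # drop alpha
  img
}

#' Read / write invasive-front and tumour annotations as GeoJSON
#'
#' Annotations use CRS-free planar coordinates in microns, y increasing
#' downward (raster row direction): the invasive front is a `LineString`,
#' the tumour region a `Polygon`. A file holding the wrong geometry type
#' for the requested annotation is rejected with the offending type named.
#'
#' @param front An [invasive_front()].
#' @param tumour A [tumour_region()].
#' @param path File path.
#' @return Readers return the corresponding annotation object; writers the
#'   path invisibly.
#' @export
write_annotations_geojson <- function(front, tumour, path) {
  stopifnot(inherits(front, "invasive_front"), inherits(tumour, "tumour_region"))
  poly <- rbind(tumour$polygon, tumour$polygon[1L, ])  # GeoJSON rings close
  fc <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature",
           properties = list(name = "invasive_front"),
           geometry = list(type = "LineString",
                           coordinates = unname(split(front$vertices,
                                                      row(front$vertices)[, 1L])))),
      list(type = "Feature",
           properties = list(name = "tumour_region"),
           geometry = list(type = "Polygon",
                           coordinates = list(unname(split(poly,
                                                           row(poly)[, 1L])))))))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_geojson_feature <- function(path, name, expect_type) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  for (f in gj$features) {
    if (identical(f$properties$name, name)) {
      g <- f$geometry
      if (!identical(g$type, expect_type)) {
        stop(sprintf("annotation '%s' has geometry type %s, expected %s",
                     name, g$type, expect_type), call. = FALSE)
      }
      return(g)
    }
  }
  stop(sprintf("annotation '%s' not found in %s", name, path), call. = FALSE)
}

coords_to_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(pt) c(pt[[1]], pt[[2]])))
}

#' @rdname write_annotations_geojson
#' @export
read_front_geojson <- function(path) {
  g <- read_geojson_feature(path, "invasive_front", "LineString")
  invasive_front(coords_to_matrix(g$coordinates))
}

#' @rdname write_annotations_geojson
#' @export
read_tumour_geojson <- function(path) {
  g <- read_geojson_feature(path, "tumour_region", "Polygon")
  tumour_region(coords_to_matrix(g$coordinates[[1]]))
}

#' Read / write feature and call tables as CSV
#'
#' @param x Data frame.
#' @param path File path.
#' @return Readers return a data frame; writers the path invisibly.
#' @export
write_table_csv <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read a cohort survival table
#'
#' Validates the survival columns of a cohort CSV: `patient_id`,
#' `time_months` (finite, >= 0) and `event` (0/1) are required; covariate
#' and feature columns pass through unchanged.
#'
#' @param path CSV path.
#' @return Validated data frame.
#' @export
read_cohort_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_months", "event")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L) {
    stop("cohort table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(d$time_months)) || any(d$time_months < 0)) {
    stop("cohort column 'time_months' must be finite and >= 0", call. = FALSE)
  }
  if (!all(d$event %in% c(0L, 1L))) {
    stop("cohort column 'event' must be 0/1", call. = FALSE)
  }
  d
}
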