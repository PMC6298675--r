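# File formats.
#
# Images and sinograms travel as TIFF (32-bit samples with an affine scale
# recorded in a JSON sidecar, giving ~1e-10 relative round-trip error), PNG
# (display only, 8-bit grayscale, rescaled) or CSV (exact full-precision
# text, for small cases).  Sinograms always carry a JSON sidecar with their
# angles and geometry.

.sidecar_path <- function(path) paste0(path, ".json")

.ext_of <- function(path) tolower(tools::file_ext(path))

# 32-bit TIFF with affine rescale to [0,1]; scale recorded in sidecar
.write_tiff_scaled <- function(m, path, extra = list()) {
  lo <- min(m); hi <- max(m)
  scaled <- if (hi > lo) (m - lo) / (hi - lo) else m * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L, compression = "none")
  meta <- c(list(scale_min = lo, scale_max = hi), extra)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.read_tiff_scaled <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  sc <- .sidecar_path(path)
  meta <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
  if (!is.null(meta) && !is.null(meta$scale_min)) {
    m <- m * (meta$scale_max - meta$scale_min) + meta$scale_min
  }
  list(values = m, meta = meta)
}

#' Write an image to disk
#'
#' TIFF (`.tif`/`.tiff`): 32-bit samples plus a JSON sidecar recording the
#' affine scale (near-lossless).  PNG: 8-bit grayscale, rescaled to the full
#' range, scale recorded in the sidecar (display only).  CSV: exact
#' full-precision text.
#'
#' @param image a `ct_image` or matrix.
#' @param path output path; format chosen by extension.
#' @return the path, invisibly.
#' @export
write_image <- function(image, path) {
  m <- as.matrix(image)
  if (!dir.exists(dirname(path))) {
    .stop_typed("tomowiener_io_error",
                sprintf("directory does not exist: %s", dirname(path)))
  }
  ext <- .ext_of(path)
  if (ext %in% c("tif", "tiff")) {
    .write_tiff_scaled(m, path)
  } else if (ext == "png") {
    lo <- min(m); hi <- max(m)
    scaled <- if (hi > lo) (m - lo) / (hi - lo) else m * 0
    png::writePNG(scaled, path, dpi = NULL)
    jsonlite::write_json(list(scale_min = lo, scale_max = hi),
                         .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                       path, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    .stop_typed("tomowiener_io_error", sprintf("unknown image format: .%s", ext))
  }
  invisible(path)
}

#' Read an image from disk
#'
#' @param path TIFF, PNG or CSV file written by [write_image()] (or any
#'   grayscale TIFF/PNG).
#' @return a `ct_image`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    .stop_typed("tomowiener_io_error", sprintf("file not found: %s", path))
  }
  ext <- .ext_of(path)
  m <- if (ext %in% c("tif", "tiff")) {
    .read_tiff_scaled(path)$values
  } else if (ext == "png") {
    v <- png::readPNG(path)
    if (length(dim(v)) == 3) v <- v[, , 1]
    sc <- .sidecar_path(path)
    if (file.exists(sc)) {
      meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
      v <- v * (meta$scale_max - meta$scale_min) + meta$scale_min
    }
    v
  } else if (ext == "csv") {
    as.matrix(utils::read.csv(path, header = FALSE))
  } else {
    .stop_typed("tomowiener_io_error", sprintf("unknown image format: .%s", ext))
  }
  dimnames(m) <- NULL
  ct_image(m)
}

#' Write a sinogram (with JSON sidecar)
#'
#' The sinogram matrix (rows = views) goes to TIFF or CSV; the sidecar
#' `<path>.json` records `angles_deg`, `bin_spacing`, `image_size` and, for
#' TIFF, the value scale.
#'
#' @param sino a `ct_sinogram`.
#' @param path output path (`.tif`/`.tiff` or `.csv`).
#' @return the path, invisibly.
#' @export
write_sinogram <- function(sino, path) {
  if (!inherits(sino, "ct_sinogram")) {
    .stop_typed("tomowiener_type_error", "sino must be a ct_sinogram")
  }
  meta <- list(angles_deg = attr(sino, "angles") * 180 / pi,
               # full-precision strings: JSON doubles do not round-trip exactly
               angles_rad = sprintf("%.17g", attr(sino, "angles")),
               bin_spacing = attr(sino, "bin_spacing"),
               image_size = attr(sino, "image_size"))
  ext <- .ext_of(path)
  if (ext %in% c("tif", "tiff")) {
    .write_tiff_scaled(unclass(sino), path, extra = meta)
  } else if (ext == "csv") {
    utils::write.table(format(unclass(sino), digits = 17, scientific = TRUE,
                              trim = TRUE),
                       path, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else {
    .stop_typed("tomowiener_io_error", sprintf("unknown sinogram format: .%s", ext))
  }
  invisible(path)
}

#' Read a sinogram written by [write_sinogram()]
#'
#' @param path TIFF or CSV sinogram with its JSON sidecar.
#' @return a `ct_sinogram`.
#' @export
read_sinogram <- function(path) {
  if (!file.exists(path)) {
    .stop_typed("tomowiener_io_error", sprintf("file not found: %s", path))
  }
  ext <- .ext_of(path)
  if (ext %in% c("tif", "tiff")) {
    r <- .read_tiff_scaled(path)
    values <- r$values
    meta <- r$meta
  } else if (ext == "csv") {
    values <- as.matrix(utils::read.csv(path, header = FALSE))
    sc <- .sidecar_path(path)
    meta <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else NULL
  } else {
    .stop_typed("tomowiener_io_error", sprintf("unknown sinogram format: .%s", ext))
  }
  if (is.null(meta) || is.null(meta$angles_deg)) {
    .stop_typed("tomowiener_io_error",
                sprintf("missing or incomplete sidecar: %s", .sidecar_path(path)))
  }
  dimnames(values) <- NULL
  angles <- if (!is.null(meta$angles_rad)) {
    as.numeric(meta$angles_rad)
  } else {
    meta$angles_deg * pi / 180
  }
  ct_sinogram(values, angles,
              bin_spacing = if (is.null(meta$bin_spacing)) 1 else meta$bin_spacing,
              image_size = meta$image_size)
}
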