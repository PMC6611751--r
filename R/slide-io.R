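#' Construct a slide image object
#'
#' A slide is an H x W x 3 array of RGB intensities in `[0, 1]` (8-bit
#' precision on disk) with an identifier and a pixel size in microns. The
#' 0.5 um/pixel default matches the 20x scan convention.
#'
#' @param pixels numeric H x W x 3 array with values in `[0, 1]`
#' @param slide_id character identifier
#' @param microns_per_pixel positive pixel size in microns
#' @return an object of class `slide_image`
#' @export
slide_image <- function(pixels, slide_id = "slide", microns_per_pixel = 0.5) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop("pixels must be an H x W x 3 RGB array")
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("pixel intensities must lie in [0, 1]")
  }
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0) {
    stop("microns_per_pixel must be positive")
  }
  structure(
    list(slide_id = as.character(slide_id), pixels = pixels,
         microns_per_pixel = microns_per_pixel),
    class = "slide_image"
  )
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image> %s: %d x %d px, %.3g um/px\n",
              x$slide_id, d[1], d[2], x$microns_per_pixel))
  invisible(x)
}

#' Dimensions of a slide
#' @param slide a `slide_image`
#' @return integer vector `(height, width)`
#' @export
slide_dim <- function(slide) {
  dim(slide$pixels)[1:2]
}

meta_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.json")
}

#' Read a slide image from PNG or TIFF
#'
#' The image must be 8-bit RGB (an alpha channel, if present, is dropped).
#' The pixel size is taken from an optional `<name>.meta.json` sidecar
#' (`{"microns_per_pixel": ...}`) next to the image, falling back to
#' `default_mpp`.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file
#' @param default_mpp pixel size used when no sidecar is present
#' @return a [slide_image()]
#' @export
load_slide <- function(path, default_mpp = 0.5) {
  if (!file.exists(path)) stop("slide file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported slide format '.", ext, "': expected PNG or TIFF")
  )
  if (length(dim(px)) != 3 || dim(px)[3] < 3) {
    stop("slide is not an RGB image: ", path,
         " (", paste(dim(px), collapse = " x "), ")")
  }
  px <- px[, , 1:3, drop = FALSE]
  mpp <- default_mpp
  mp <- meta_path(path)
  if (file.exists(mp)) {
    meta <- jsonlite::read_json(mp)
    if (!is.null(meta$microns_per_pixel)) mpp <- as.numeric(meta$microns_per_pixel)
  }
  slide_image(px, slide_id = tools::file_path_sans_ext(basename(path)),
              microns_per_pixel = mpp)
}

#' Write a slide image to PNG or TIFF
#'
#' Writes 8-bit RGB plus a `.meta.json` sidecar recording the pixel size.
#' PNG round-trips pixel-identically at 8-bit precision.
#'
#' @param slide a [slide_image()]
#' @param path output path (`.png`, `.tif`, `.tiff`)
#' @return `path`, invisibly
#' @export
save_slide <- function(slide, path) {
  stopifnot(inherits(slide, "slide_image"))
  ext <- tolower(tools::file_ext(path))
  # quantize to the 8-bit grid so that a reload is bit-identical
  px <- round(slide$pixels * 255) / 255
  switch(ext,
    png = png::writePNG(px, target = path),
    tif = ,
    tiff = tiff::writeTIFF(px, where = path, bits.per.sample = 8L,
                           compression = "deflate"),
    stop("unsupported slide format '.", ext, "'")
  )
  jsonlite::write_json(
    list(slide_id = slide$slide_id, microns_per_pixel = slide$microns_per_pixel),
    meta_path(path), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
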