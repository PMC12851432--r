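#' Construct a calibrated micrograph
#'
#' A micrograph couples a grayscale intensity raster with its physical
#' calibration (micrometres per pixel) and the fixed brightness/contrast
#' transform (`gain`, `offset`) of the analysis run. The transform must be
#' identical across all fields of view of one run; [binarize()] applies it
#' before thresholding.
#'
#' @param pixels Integer matrix of grayscale intensities (rows x cols).
#' @param pixel_size Pixel edge length in micrometres; must be positive.
#' @param fov_id Identifier of the field of view.
#' @param magnification Nominal magnification (metadata only).
#' @param gain,offset Linear intensity transform applied before
#'   thresholding: `gain * I + offset`, clipped to `[0, max_intensity]`.
#' @param max_intensity Maximum representable intensity of the raster's
#'   bit depth (255 for 8-bit, 65535 for 16-bit).
#' @return An object of class `"micrograph"`.
#' @seealso [read_micrograph()], [binarize()]
#' @export
micrograph <- function(pixels, pixel_size, fov_id = "fov1",
                       magnification = NA_real_, gain = 1, offset = 0,
                       max_intensity = 255) {
  if (!is.matrix(pixels) || length(pixels) == 0L)
    stop("'pixels' must be a non-empty matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (um per pixel)")
  if (!is.finite(gain) || !is.finite(offset))
    stop("'gain' and 'offset' must be finite")
  if (!is.finite(max_intensity) || max_intensity <= 0)
    stop("'max_intensity' must be positive")
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, pixel_size = pixel_size, fov_id = fov_id,
         magnification = magnification, gain = gain, offset = offset,
         max_intensity = max_intensity),
    class = "micrograph"
  )
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("micrograph '%s': %d x %d px, %.5f um/px (%.1f x %.1f um)\n",
              x$fov_id, nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              ncol(x$pixels) * x$pixel_size, nrow(x$pixels) * x$pixel_size))
  cat(sprintf("  intensity range %d..%d of 0..%d; gain %.3g, offset %.3g\n",
              min(x$pixels), max(x$pixels), as.integer(x$max_intensity),
              x$gain, x$offset))
  invisible(x)
}

#' Read a grayscale micrograph from TIFF or PNG
#'
#' Pixel size is mandatory external metadata: SEM export conventions vary and
#' the calibration is never guessed from the image file. Multi-channel images
#' are rejected. TIFF is read at native bit depth (8- or 16-bit); PNG is
#' treated as 8-bit.
#'
#' @param path Path to a single-channel TIFF or PNG file.
#' @inheritParams micrograph
#' @return A [micrograph()] object.
#' @export
read_micrograph <- function(path, pixel_size, fov_id = NULL,
                            magnification = NA_real_, gain = 1, offset = 0) {
  if (missing(pixel_size) || is.null(pixel_size))
    stop("'pixel_size' metadata is required and is never guessed from the image")
  if (!file.exists(path)) stop("image file not found: ", path)
  if (is.null(fov_id))
    fov_id <- tools::file_path_sans_ext(basename(path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) != 2L)
      stop("multi-channel image not supported: ", path)
    maxi <- if (max(img) > 255L) 65535 else 255
  } else if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) != 2L)
      stop("multi-channel image not supported: ", path)
    img <- round(img * 255)
    maxi <- 255
  } else {
    stop("unsupported image format '", ext, "' (use TIFF or PNG)")
  }
  micrograph(img, pixel_size = pixel_size, fov_id = fov_id,
             magnification = magnification, gain = gain, offset = offset,
             max_intensity = maxi)
}

#' Write a micrograph to an 8-bit grayscale PNG
#'
#' @param image A [micrograph()] object.
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
write_micrograph <- function(image, path) {
  stopifnot(inherits(image, "micrograph"))
  px <- pmin(pmax(image$pixels, 0L), 255L)
  png::writePNG(px / 255, target = path)
  invisible(path)
}

#' Binarize a micrograph at a fixed intensity threshold
#'
#' Applies the run's fixed linear brightness/contrast transform
#' (`gain * I + offset`, clipped to the representable range) and marks as
#' foreground every pixel whose transformed intensity is at least
#' `threshold`. The same settings must be applied to every field of view of
#' an analysis run; the transform lives on the [micrograph()] so this holds
#' by construction.
#'
#' @param image A [micrograph()] object, or a plain integer matrix (then
#'   `gain = 1`, `offset = 0`).
#' @param threshold Intensity level; pixels with transformed intensity
#'   `>= threshold` become foreground. A threshold above the maximum
#'   representable intensity yields an empty mask.
#' @return A logical matrix the same shape as the raster (`TRUE` =
#'   candidate particle material).
#' @export
binarize <- function(image, threshold) {
  if (is.matrix(image)) image <- micrograph(image, pixel_size = 1)
  stopifnot(inherits(image, "micrograph"))
  if (length(image$pixels) == 0L) stop("empty raster")
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("'threshold' must be a single finite number")
  tr <- image$gain * image$pixels + image$offset
  tr <- pmin(pmax(tr, 0), image$max_intensity)
  mask <- tr >= threshold
  dim(mask) <- dim(image$pixels)
  mask
}

#' Automatic threshold from intensity bimodality (Otsu)
#'
#' Convenience fallback that maximises between-class variance of the
#' intensity histogram. The analysis-faithful mode is a manually chosen,
#' fixed threshold; this helper is provided for exploratory work only.
#'
#' @param image A [micrograph()] object or integer matrix.
#' @return A single intensity threshold on the raster's native scale.
#' @export
auto_threshold <- function(image) {
  px <- if (inherits(image, "micrograph")) image$pixels else image
  v <- as.integer(px)
  lev <- sort(unique(v))
  if (length(lev) < 2L) return(lev[1] + 1)
  h <- tabulate(match(v, lev))
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[length(mu)]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)
  # threshold sits just above the last background level
  (lev[k] + lev[min(k + 1L, length(lev))]) / 2
}
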