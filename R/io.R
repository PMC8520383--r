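#' Load a color fundus photograph
#'
#' Reads a PNG/TIFF/PPM/JPEG raster and returns an H x W x 3 numeric array of
#' intensities in `[0, 1]` (8/16-bit inputs are normalized by their full
#' range), indexed `[row, col, channel]` with row 1 at the top and channels
#' ordered R, G, B. Grayscale files are replicated across the three channels;
#' an alpha channel, if present, is dropped.
#'
#' @param path path to an image file.
#' @return numeric array `H x W x 3` with values in `[0, 1]`.
#' @examples
#' \dontrun{img <- load_image("fundus_01.png")}
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stopf("cannot read image: file not found: %s", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) stopf("cannot decode image %s: %s",
                                            path, conditionMessage(e)))
  x <- EBImage::imageData(img)  # EBImage stores [x = col, y = row]
  if (length(dim(x)) == 2L) {
    g <- t(x)
    arr <- array(g, c(dim(g), 3L))
  } else {
    nch <- dim(x)[3L]
    if (nch == 2L) {            # gray + alpha
      g <- t(x[, , 1L])
      arr <- array(g, c(dim(g), 3L))
    } else {
      arr <- aperm(x[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
    }
  }
  if (nrow(arr) < 32L || ncol(arr) < 32L)
    stopf("image %s is %dx%d; at least 32x32 is required to host a 15x15 detection window",
          path, nrow(arr), ncol(arr))
  clip01(arr)
}

#' Inverted green channel
#'
#' The green channel has the highest vessel/background contrast in fundus
#' photographs; inverting it (`1 - G`) makes vessels bright on a dark
#' background, the orientation the line detector expects.
#'
#' @param img `H x W x 3` RGB array in `[0, 1]` (see [load_image()]), or an
#'   `H x W` matrix already holding the green channel.
#' @return numeric matrix `H x W` in `[0, 1]`.
#' @export
inverted_green <- function(img) {
  g <- if (is.matrix(img)) img else {
    if (length(dim(img)) != 3L || dim(img)[3L] < 2L)
      stopf("expected an H x W x 3 RGB array")
    img[, , 2L]
  }
  check_image(g, "green channel")
  1 - g
}

#' Field-of-view mask
#'
#' Fundus photographs carry retinal content only inside a roughly circular
#' aperture; detection responses and evaluation metrics are restricted to it.
#' Three ways to obtain the mask:
#' \describe{
#'   \item{`file`}{read a binary mask image (pixels > 0.5 are inside), the
#'     DRIVE convention of one mask file per photograph.}
#'   \item{`threshold`}{mark pixels whose red channel is at least `tau`
#'     (the aperture is bright in red even where the retina is dark), keep
#'     the largest 8-connected component and fill its holes. The default when
#'     no mask file exists, as for STARE.}
#'   \item{`full`}{the whole frame.}
#' }
#'
#' @param img `H x W x 3` RGB array; required for `threshold` and `full`.
#' @param mode one of `"threshold"`, `"file"`, `"full"`.
#' @param path mask image path (mode `file`).
#' @param tau red-channel threshold in `[0, 1]`, default 0.1.
#' @return logical matrix, `TRUE` = inside the field of view.
#' @export
fov_mask <- function(img = NULL, mode = c("threshold", "file", "full"),
                     path = NULL, tau = 0.1) {
  mode <- match.arg(mode)
  if (mode == "file") {
    if (is.null(path)) stopf("mode 'file' requires a mask path")
    if (!file.exists(path)) stopf("cannot read FOV mask: %s", path)
    m <- EBImage::readImage(path)
    x <- EBImage::imageData(m)
    if (length(dim(x)) == 3L) x <- x[, , 1L]
    inside <- t(x) > 0.5
    if (!is.null(img)) check_same_shape(inside, img, "FOV mask vs image")
    if (!any(inside)) stopf("FOV mask %s is empty", path)
    return(inside)
  }
  if (is.null(img)) stopf("mode '%s' requires an image", mode)
  h <- dim(img)[1L]; w <- dim(img)[2L]
  if (mode == "full") return(matrix(TRUE, h, w))
  red <- if (is.matrix(img)) img else img[, , 1L]
  inside <- red >= tau
  if (!any(inside))
    stopf("no pixel reaches red-channel threshold %g; use mode = 'full'", tau)
  lab <- label_components(inside, connectivity = 8)
  sizes <- tabulate(lab[lab > 0L])
  inside <- lab == which.max(sizes)
  filled <- EBImage::fillHull(t(inside * 1)) # EBImage works column-major
  t(EBImage::imageData(filled)) > 0.5
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask logical matrix.
#' @param path output path ending in `.png`.
#' @export
save_mask <- function(mask, path) {
  check_mask(mask)
  EBImage::writeImage(EBImage::Image(t(mask * 1)), path)
  invisible(path)
}

#' Write a response map as a 32-bit float TIFF with a min/max sidecar
#'
#' Real-valued response maps are affinely rescaled to `[0, 1]` and written as
#' 32-bit float TIFF; the original range is stored in a plain-text sidecar
#' `<path>.range.txt` so [load_response()] can undo the scaling.
#'
#' @param map numeric matrix.
#' @param path output path ending in `.tif`/`.tiff`.
#' @export
save_response <- function(map, path) {
  check_image(map, "response map")
  lo <- min(map); hi <- max(map)
  scaled <- if (hi > lo) (map - lo) / (hi - lo) else map * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 32L)
  writeLines(sprintf("%.17g %.17g", lo, hi), paste0(path, ".range.txt"))
  invisible(path)
}

#' Read back a response map written by [save_response()]
#' @param path TIFF path; the `<path>.range.txt` sidecar must sit next to it.
#' @return numeric matrix on the original scale.
#' @export
load_response <- function(path) {
  rng <- scan(paste0(path, ".range.txt"), what = double(), quiet = TRUE)
  x <- tiff::readTIFF(path)
  rng[1L] + x * (rng[2L] - rng[1L])
}
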