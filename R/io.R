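#' Save and load pipeline objects
#'
#' Forward models (`truncated_operator`, with geometry attached),
#' datasets, regularizers and reconstructions are stored as RDS
#' containers.  Thin wrappers are provided so scripts read naturally.
#'
#' @param object Object to store.
#' @param path File path.
#' @return `load_object()` returns the stored object.
#' @export
save_object <- function(object, path) {
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_object
#' @export
load_object <- function(path) readRDS(path)

#' Export an image as PNG
#'
#' Writes a coefficient vector or image matrix as an 8-bit grayscale PNG
#' for visual inspection, mapping `[lo, hi]` to black..white.  Requires
#' the `png` package.
#'
#' @param x Coefficient vector (length `N^2`) or image matrix.
#' @param path Output file.
#' @param lo,hi Intensity window (defaults to the data range).
#' @return Invisibly, the path.
#' @export
write_image_png <- function(x, path, lo = NULL, hi = NULL) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the png package is required for PNG export", call. = FALSE)
  }
  img <- coef_to_image(x)
  if (is.null(lo)) lo <- min(img)
  if (is.null(hi)) hi <- max(img)
  if (hi <= lo) hi <- lo + 1
  scaled <- pmin(1, pmax(0, (img - lo) / (hi - lo)))
  # row 1 at the top: flip the x2 axis into raster convention
  png::writePNG(t(scaled)[ncol(scaled):1, , drop = FALSE], target = path)
  invisible(path)
}
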