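#' Calibrated image
#'
#' A pixel grid with one (grayscale) or three (RGB) channels and a physical
#' per-pixel area calibration. Channels are stored as an `h x w` matrix or an
#' `h x w x 3` array of intensities in `[0, 1]`; rows run top to bottom.
#'
#' @param channels numeric matrix (`h x w`) or array (`h x w x 3`), values in
#'   `[0, 1]`.
#' @param pixel_area_um2 physical area of one pixel in square micrometres
#'   (default 17.43).
#' @return An object of class `calibrated_image`.
#' @examples
#' img <- calibrated_image(array(0.5, c(10, 12, 3)))
#' pixel_edge_um(img)
#' @export
calibrated_image <- function(channels, pixel_area_um2 = 17.43) {
  stopifnot_scalar_number(pixel_area_um2, "pixel_area_um2", min = 1e-12)
  d <- dim(channels)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop("`channels` must be an h x w matrix or an h x w x 3 array",
         call. = FALSE)
  if (length(d) == 3L && d[3] != 3L)
    stop("3-channel images must have exactly 3 planes", call. = FALSE)
  structure(list(channels = channels, pixel_area_um2 = pixel_area_um2),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<calibrated_image> %d x %d px, %d channel(s), %.4g um2/px\n",
              d[1], d[2], if (length(d) == 3L) d[3] else 1L,
              x$pixel_area_um2))
  invisible(x)
}

#' @rdname calibrated_image
#' @param img a `calibrated_image`.
#' @export
pixel_edge_um <- function(img) {
  pa <- if (inherits(img, "calibrated_image")) img$pixel_area_um2 else img
  sqrt(pa)
}

n_channels <- function(img) {
  d <- dim(img$channels)
  if (length(d) == 3L) d[3] else 1L
}

image_dim <- function(img) dim(img$channels)[1:2]

#' Co-registered mask set
#'
#' Binary implant, trephine-defect and bone masks sharing one pixel grid and
#' one area calibration. The defect mask is the full drilled cavity
#' (including the implant footprint where the disc sits inside it); bone is
#' always disjoint from the implant.
#'
#' @param implant,defect,bone logical matrices of identical dimension.
#' @param pixel_area_um2 per-pixel area in um2.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(implant, defect, bone = NULL, pixel_area_um2 = 17.43) {
  stopifnot(is.logical(implant), is.logical(defect))
  if (!identical(dim(implant), dim(defect)))
    stop("masks must share one grid", call. = FALSE)
  if (is.null(bone)) bone <- array(FALSE, dim(implant))
  if (!identical(dim(bone), dim(implant)))
    stop("masks must share one grid", call. = FALSE)
  if (any(bone & implant))
    stop("bone mask overlaps the implant mask", call. = FALSE)
  structure(list(implant = implant, defect = defect, bone = bone,
                 pixel_area_um2 = pixel_area_um2),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf(
    "<mask_set> %d x %d px | implant %d px, defect %d px, bone %d px\n",
    nrow(x$implant), ncol(x$implant),
    sum(x$implant), sum(x$defect), sum(x$bone)))
  invisible(x)
}

#' Read / write calibrated images
#'
#' Thin wrappers around [EBImage::readImage()] / [EBImage::writeImage()]
#' converting between EBImage's `(x, y)` layout and the row-major `(h, w)`
#' matrices used throughout this package. TIFF and PNG are supported.
#'
#' @param path file path (`.png` or `.tif`/`.tiff`).
#' @param pixel_area_um2 calibration to attach on read.
#' @return `read_image` returns a `calibrated_image`; `write_image` returns
#'   `path` invisibly.
#' @export
read_image <- function(path, pixel_area_um2 = 17.43) {
  x <- EBImage::imageData(EBImage::readImage(path))
  d <- dim(x)
  ch <- if (length(d) == 2L) t(x) else {
    if (d[3] > 3L) x <- x[, , 1:3, drop = FALSE]  # drop alpha
    aperm(x[, , 1:min(3L, dim(x)[3]), drop = FALSE], c(2L, 1L, 3L))
  }
  calibrated_image(ch, pixel_area_um2)
}

#' @rdname read_image
#' @param img a `calibrated_image` or a logical mask matrix.
#' @export
write_image <- function(img, path) {
  ch <- if (inherits(img, "calibrated_image")) img$channels else img
  if (is.logical(ch)) ch <- ch * 1
  d <- dim(ch)
  x <- if (length(d) == 2L) t(ch) else aperm(ch, c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(x,
    colormode = if (length(d) == 3L) "Color" else "Grayscale"), path)
  invisible(path)
}
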