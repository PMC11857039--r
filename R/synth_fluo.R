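#' Generate a synthetic CD31 immunofluorescence field
#'
#' Renders a fluorescence field of physical size `field_um` (default
#' 725 x 543 um, the implant surface at the lower border): the red channel
#' carries CD31-positive blobs whose centres are concentrated towards the
#' lower border (vascularization is densest near the implant surface), the
#' blue channel carries nuclei unrelated to the red measurement, and the
#' green channel is empty. The ground-truth CD31 area is the rendered
#' red-positive pixel count times the pixel area.
#'
#' @param field_um field width and height in um (default `c(725, 543)`).
#' @param n_blobs number of CD31-positive blobs (>= 0).
#' @param blob_area_um2 nominal area of one blob, um2.
#' @param pixel_area_um2 per-pixel area, um2 (default 17.43).
#' @param overlap allow blobs to overlap (default `FALSE`: centres are
#'   rejection-sampled to keep disks disjoint).
#' @param n_nuclei number of blue nuclei.
#' @param seed RNG seed.
#' @return List with `field` (3-channel `calibrated_image`) and `truth`
#'   (list: `cd31_area_um2`, `red_mask`).
#' @export
gen_fluorescence <- function(field_um = c(725, 543), n_blobs = 10,
                             blob_area_um2 = 500, pixel_area_um2 = 17.43,
                             overlap = FALSE, n_nuclei = 40, seed = 1L) {
  if (any(field_um <= 0)) stop("field dimensions must be positive",
                               call. = FALSE)
  stopifnot_scalar_number(n_blobs, "n_blobs", min = 0)
  stopifnot_scalar_number(blob_area_um2, "blob_area_um2", min = 0)
  e <- sqrt(pixel_area_um2)
  w <- max(4L, round(field_um[1] / e))
  h <- max(4L, round(field_um[2] / e))
  if (n_blobs * blob_area_um2 > 0.5 * w * h * pixel_area_um2)
    stop("requested blob area exceeds half the field area", call. = FALSE)
  r_px <- sqrt(blob_area_um2 / pi) / e
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)
  with_seed(seed, {
    red_mask <- matrix(FALSE, h, w)
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < n_blobs && tries < 2000L * max(1, n_blobs)) {
      tries <- tries + 1L
      cx <- runif(1, r_px + 1, w - r_px)
      cy <- h - abs(rnorm(1, 0, h / 3))       # concentrated near lower border
      if (cy < r_px + 1 || cy > h - r_px) next
      if (!overlap && nrow(centers) &&
          any((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 <
                (2 * r_px + 1)^2)) next
      centers <- rbind(centers, c(cx, cy))
      red_mask <- red_mask | ((col - cx)^2 + (row - cy)^2 <= r_px^2)
    }
    if (nrow(centers) < n_blobs)
      warning(sprintf("placed %d of %d blobs without overlap",
                      nrow(centers), n_blobs))
    red <- matrix(0.03, h, w)
    red[red_mask] <- 0.85
    blue <- matrix(0.02, h, w)
    if (n_nuclei > 0) {
      nr <- max(1, round(3 / e))              # ~3 um nuclei radius
      for (i in seq_len(n_nuclei)) {
        cx <- runif(1, 1, w); cy <- runif(1, 1, h)
        blue <- pmax(blue,
                     0.7 * ((col - cx)^2 + (row - cy)^2 <= nr^2))
      }
    }
    field <- calibrated_image(array(c(red, matrix(0, h, w), blue),
                                    c(h, w, 3)), pixel_area_um2)
    list(field = field,
         truth = list(cd31_area_um2 = sum(red_mask) * pixel_area_um2,
                      red_mask = red_mask))
  })
}
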