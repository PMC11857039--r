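#' Euclidean distance to the implant surface
#'
#' Exact Euclidean distance (in um, centre-to-centre) from every pixel to the
#' nearest implant pixel, computed with the distance transform of
#' [EBImage::distmap()]. Implant pixels have distance 0.
#'
#' @param implant_mask logical matrix, non-empty.
#' @param pixel_area_um2 per-pixel area in um2 (edge = sqrt of this).
#' @return A numeric matrix of distances in um.
#' @export
implant_distance_um <- function(implant_mask, pixel_area_um2) {
  if (!any(implant_mask))
    stop("empty implant mask: cannot build a peri-implant geometry",
         call. = FALSE)
  d <- EBImage::imageData(EBImage::distmap(
    EBImage::Image(1 - (implant_mask * 1))))
  d * sqrt(pixel_area_um2)
}

#' Peri-implant band
#'
#' The peri-implant zone: all pixels outside the implant whose Euclidean
#' distance to the implant is strictly below `thickness_um` (default 300 um),
#' intersected with the trephine defect.
#'
#' @param implant_mask,defect_mask co-registered logical masks; the implant
#'   must be non-empty. `defect_mask = NULL` skips the defect clip.
#' @param pixel_area_um2 per-pixel area, um2.
#' @param thickness_um band thickness in um (default 300).
#' @param dist_um optional precomputed [implant_distance_um()] matrix.
#' @return Logical band mask.
#' @export
build_band <- function(implant_mask, defect_mask, pixel_area_um2,
                       thickness_um = 300, dist_um = NULL) {
  stopifnot_scalar_number(thickness_um, "thickness_um", min = 0)
  if (is.null(dist_um))
    dist_um <- implant_distance_um(implant_mask, pixel_area_um2)
  band <- !implant_mask & dist_um < thickness_um
  if (!is.null(defect_mask)) band <- band & defect_mask
  band
}

#' 1-pixel implant surface band
#'
#' Enlarges the implant mask by one pixel (8-connectivity), removes the
#' implant itself, and limits the result to the trephine defect. This band —
#' one pixel, about 4.18 um at the default calibration — is the surface set
#' against which bone-implant contact is scored.
#'
#' @inheritParams build_band
#' @return Logical mask of the 1-px surface band; always disjoint from the
#'   implant.
#' @export
surface_band <- function(implant_mask, defect_mask = NULL) {
  if (!any(implant_mask))
    stop("empty implant mask: no surface to enlarge", call. = FALSE)
  band <- dilate8(implant_mask) & !implant_mask
  if (!is.null(defect_mask)) band <- band & defect_mask
  band
}

zone_layers <- c("immediate", "intermediate", "remote")
zone_sides <- c("upper", "lower")
zone_sections <- c("peripheral-left", "central", "peripheral-right")

#' The 18-region peri-implant zone partition
#'
#' Partitions the 300 um peri-implant band (clipped to the trephine defect)
#' into 18 regions: 3 distance layers of 100 um each (immediate
#' `[0, 100)`, intermediate `[100, 200)`, remote `[200, 300)` um), on both
#' sides (upper/lower) of the implant cross-section, each split into a
#' central third and two peripheral thirds along the implant's long axis.
#'
#' Sides are determined by the sign of a pixel's perpendicular offset from
#' the implant's principal axis (PCA of implant pixel coordinates; ties go
#' to "upper"); section thirds by the pixel's normalized projection onto
#' that axis, scaled to the implant's own extent and clamped to `[0, 1]`
#' (bins `[0,1/3)`, `[1/3,2/3)`, `[2/3,1]`). All 18 region ids are always
#' defined, possibly with zero pixels.
#'
#' @inheritParams build_band
#' @param layer_um layer thickness in um (default 100; three layers).
#' @return An object of class `zone_partition`: list with `labels` (integer
#'   matrix, 0 outside the band, 1-18 inside) and `regions` (data frame:
#'   `region`, `side`, `layer`, `section`, `pixels`, `area_mm2`).
#' @examples
#' m <- section_masks(section_spec(scale = 12))
#' zp <- partition_zones(m$implant, m$defect, m$pixel_area_um2)
#' nrow(zp$regions)  # 18
#' @export
partition_zones <- function(implant_mask, defect_mask, pixel_area_um2,
                            thickness_um = 300, layer_um = 100,
                            dist_um = NULL) {
  if (sum(implant_mask) < 2L)
    stop("degenerate implant mask: need at least 2 pixels for an axis",
         call. = FALSE)
  if (is.null(dist_um))
    dist_um <- implant_distance_um(implant_mask, pixel_area_um2)
  band <- build_band(implant_mask, defect_mask, pixel_area_um2,
                     thickness_um, dist_um = dist_um)

  # principal axis of the implant cross-section
  ij <- which(implant_mask, arr.ind = TRUE)
  pts <- cbind(x = ij[, 2], y = ij[, 1])
  ctr <- colMeans(pts)
  ev <- eigen(stats::cov(pts), symmetric = TRUE)$vectors
  a <- ev[, 1]
  if (a[1] < 0 || (a[1] == 0 && a[2] < 0)) a <- -a
  nrm <- c(-a[2], a[1])
  if (nrm[2] > 0) nrm <- -nrm            # positive offset = towards top rows
  proj_rng <- range(pts %*% a - sum(ctr * a))

  bidx <- which(band, arr.ind = TRUE)
  labels <- matrix(0L, nrow(implant_mask), ncol(implant_mask))
  if (nrow(bidx)) {
    dx <- bidx[, 2] - ctr["x"]; dy <- bidx[, 1] - ctr["y"]
    s <- dx * nrm[1] + dy * nrm[2]
    side <- ifelse(s >= 0, 1L, 2L)       # 1 upper, 2 lower
    layer <- pmin(length(zone_layers),
                  1L + (dist_um[band] %/% layer_um))
    tn <- (dx * a[1] + dy * a[2] - proj_rng[1]) / diff(proj_rng)
    tn <- clamp01(tn)
    sect <- ifelse(tn < 1 / 3, 1L, ifelse(tn < 2 / 3, 2L, 3L))
    labels[band] <- (side - 1L) * 9L + (layer - 1L) * 3L + sect
  }
  regions <- expand.grid(section = zone_sections, layer = zone_layers,
                         side = zone_sides, stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)[, c("side", "layer", "section")]
  regions$region <- seq_len(18L)
  counts <- tabulate(labels[labels > 0L], nbins = 18L)
  regions$pixels <- counts
  regions$area_mm2 <- counts * pixel_area_um2 * 1e-6
  structure(list(labels = labels, regions = regions[, c(
    "region", "side", "layer", "section", "pixels", "area_mm2")],
    pixel_area_um2 = pixel_area_um2,
    thickness_um = thickness_um, layer_um = layer_um),
    class = "zone_partition")
}

#' @export
print.zone_partition <- function(x, ...) {
  cat(sprintf("<zone_partition> %d regions, %d band pixels (%.3f mm2)\n",
              nrow(x$regions), sum(x$regions$pixels),
              sum(x$regions$area_mm2)))
  invisible(x)
}
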