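#' Bone formation (BF): absolute bone area in a region
#'
#' Pixel count of `bone & region`, converted to mm2 via the pixel
#' calibration (um2/pixel x 1e-6).
#'
#' @param bone_mask,region_mask co-registered logical masks.
#' @param pixel_area_um2 per-pixel area in um2.
#' @return Area in mm2.
#' @examples
#' bone_area(matrix(TRUE, 10, 100), matrix(TRUE, 10, 100), 17.43)  # 0.01743
#' @export
bone_area <- function(bone_mask, region_mask, pixel_area_um2) {
  stopifnot(identical(dim(bone_mask), dim(region_mask)))
  sum(bone_mask & region_mask) * pixel_area_um2 * 1e-6
}

#' Bone density (BD): bone area relative to region area
#'
#' @inheritParams bone_area
#' @return Percentage in `[0, 100]`; `NA` for an empty region.
#' @export
bone_density <- function(bone_mask, region_mask) {
  stopifnot(identical(dim(bone_mask), dim(region_mask)))
  n <- sum(region_mask)
  if (n == 0L) return(NA_real_)
  100 * sum(bone_mask & region_mask) / n
}

#' Bone-implant contact (BIC)
#'
#' Enlarges the implant by one pixel (8-connectivity), limits the resulting
#' surface band to the trephine defect, and scores the percentage of band
#' pixels occupied by bone. The defect-clipped band is used for both
#' numerator and denominator, so BIC is bounded by 100 by construction; set
#' `clip_to_defect = FALSE` for the unclipped whole-perimeter variant.
#'
#' @param implant_mask,bone_mask,defect_mask co-registered logical masks.
#' @param clip_to_defect clip the surface band to the defect (default TRUE).
#' @return Percentage in `[0, 100]`; `NA` when the surface band is empty.
#' @export
compute_bic <- function(implant_mask, bone_mask, defect_mask = NULL,
                        clip_to_defect = TRUE) {
  band <- surface_band(implant_mask,
                       if (clip_to_defect) defect_mask else NULL)
  n <- sum(band)
  if (n == 0L) return(NA_real_)
  100 * sum(band & bone_mask) / n
}

#' Place fluorescence fields along the implant edges
#'
#' Positions `n_upper` field boxes evenly along the upper implant edge and
#' `n_lower` along the lower edge, each box one field high with the implant
#' surface at its lower border (i.e. upper-edge boxes sit on top of the
#' implant, lower-edge boxes hang below it, mirroring a field acquired
#' looking onto that surface). Boxes are clipped to the image; when the
#' available edge is shorter than the total field width, the boxes overlap
#' and a warning is issued, but the requested count is preserved.
#'
#' @param implant_mask logical implant mask.
#' @param pixel_area_um2 per-pixel area, um2.
#' @param field_um field width and height in um (default `c(725, 543)`).
#' @param n_upper,n_lower number of fields per edge (defaults 7 and 6).
#' @param defect_mask optional; restricts the usable edge to the implant's
#'   extent inside the defect.
#' @return Data frame with one row per field: `side`, `index`, and pixel
#'   bounds `row0`, `row1`, `col0`, `col1`.
#' @export
place_fields <- function(implant_mask, pixel_area_um2,
                         field_um = c(725, 543), n_upper = 7, n_lower = 6,
                         defect_mask = NULL) {
  if (!any(implant_mask)) stop("empty implant mask", call. = FALSE)
  e <- sqrt(pixel_area_um2)
  fw <- max(1L, round(field_um[1] / e))
  fh <- max(1L, round(field_um[2] / e))
  h <- nrow(implant_mask); w <- ncol(implant_mask)
  usable <- implant_mask
  if (!is.null(defect_mask)) usable <- usable & defect_mask
  if (!any(usable)) usable <- implant_mask
  cols <- which(colSums(usable) > 0)
  extent <- range(cols)
  if (diff(extent) + 1 < fw)
    warning("implant edge shorter than one field width; fields are clipped")
  out <- list()
  for (side in c("upper", "lower")) {
    nf <- if (side == "upper") n_upper else n_lower
    if (nf <= 0) next
    if (nf * fw > diff(extent) + 1)
      warning(sprintf("%s edge shorter than %d non-overlapping fields; %s",
                      side, nf, "boxes overlap"))
    centers <- extent[1] + (seq_len(nf) - 0.5) / nf * diff(extent)
    for (i in seq_len(nf)) {
      cc <- round(centers[i])
      cc <- min(max(cc, extent[1]), extent[2])
      rows <- which(usable[, cc])
      if (!length(rows)) {
        cand <- which(colSums(usable) > 0)
        cc <- cand[which.min(abs(cand - cc))]
        rows <- which(usable[, cc])
      }
      if (side == "upper") {
        r1 <- min(rows) - 1L; r0 <- r1 - fh + 1L
      } else {
        r0 <- max(rows) + 1L; r1 <- r0 + fh - 1L
      }
      c0 <- round(cc - fw / 2); c1 <- c0 + fw - 1L
      out[[length(out) + 1L]] <- data.frame(
        side = side, index = i,
        row0 = max(1L, r0), row1 = min(h, r1),
        col0 = max(1L, c0), col1 = min(w, c1))
    }
  }
  if (!length(out))
    return(data.frame(side = character(), index = integer(),
                      row0 = integer(), row1 = integer(),
                      col0 = integer(), col1 = integer()))
  do.call(rbind, out)
}

#' Morphometry of one cross-section
#'
#' Runs the full per-section quantification: BF and BD for each of the 18
#' peri-implant regions and for the whole defect (defect minus implant), and
#' whole-section BIC.
#'
#' @param masks a `mask_set` (implant, defect, bone).
#' @param zones optional precomputed [partition_zones()] result for the same
#'   geometry (computed on the fly otherwise).
#' @return Long data frame: `region` (`"whole_defect"` or
#'   `"<side>.<layer>.<section>"`), `metric` (`"BF"`, `"BD"`, `"BIC"`),
#'   `value`. BIC is reported once, for the whole section.
#' @export
section_morphometry <- function(masks, zones = NULL) {
  stopifnot(inherits(masks, "mask_set"))
  if (is.null(zones))
    zones <- partition_zones(masks$implant, masks$defect,
                             masks$pixel_area_um2)
  pa <- masks$pixel_area_um2
  lab <- zones$labels
  bone_counts <- tabulate(lab[masks$bone & lab > 0L], nbins = 18L)
  reg <- zones$regions
  rid <- paste(reg$side, reg$layer, reg$section, sep = ".")
  bf <- bone_counts * pa * 1e-6
  bd <- ifelse(reg$pixels > 0, 100 * bone_counts / reg$pixels, NA_real_)
  whole <- masks$defect & !masks$implant
  out <- rbind(
    data.frame(region = "whole_defect", metric = "BF",
               value = bone_area(masks$bone, whole, pa)),
    data.frame(region = "whole_defect", metric = "BD",
               value = bone_density(masks$bone, whole)),
    data.frame(region = rid, metric = "BF", value = bf),
    data.frame(region = rid, metric = "BD", value = bd),
    data.frame(region = "whole_defect", metric = "BIC",
               value = compute_bic(masks$implant, masks$bone, masks$defect)))
  rownames(out) <- NULL
  out
}

#' Per-disc aggregation over serial cross-sections
#'
#' Arithmetic mean of each metric in each region across the 3-4 cross
#' sections of one disc, excluding missing values pairwise. Fewer than 3
#' contributing sections triggers a low-count warning; zero records flag the
#' disc as missing.
#'
#' @param records long data frame with columns `cross_section`, `region`,
#'   `metric`, `value` (one disc's sections).
#' @return Data frame `region`, `metric`, `value` (mean), `n_sections`; with
#'   attribute `n_sections` = number of distinct sections seen.
#' @export
aggregate_disc <- function(records) {
  need <- c("cross_section", "region", "metric", "value")
  if (!all(need %in% names(records)))
    stop("records need columns ", paste(need, collapse = ", "), call. = FALSE)
  ns <- length(unique(records$cross_section))
  if (ns == 0L || nrow(records) == 0L) {
    warning("no cross-section records: disc flagged missing")
    out <- data.frame(region = character(), metric = character(),
                      value = numeric(), n_sections = integer())
    attr(out, "n_sections") <- 0L
    return(out)
  }
  if (ns < 3L)
    warning(sprintf("only %d cross-section(s) for this disc", ns))
  agg <- aggregate(value ~ region + metric, data = records,
                   FUN = function(v) c(m = mean(v, na.rm = TRUE),
                                       n = sum(!is.na(v))),
                   na.action = stats::na.pass)
  out <- data.frame(region = agg$region, metric = agg$metric,
                    value = agg$value[, "m"],
                    n_sections = as.integer(agg$value[, "n"]))
  out$value[is.nan(out$value)] <- NA_real_
  attr(out, "n_sections") <- ns
  out
}
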