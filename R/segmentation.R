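#' Stain-colour segmentation configuration
#'
#' Threshold windows used to pick Alizarin-red-stained bone out of a colour
#' section and to find the dark implant cross-section. The default windows
#' are expressed in HSV (hue is robust to illumination scaling); a simple
#' RGB red-dominance rule is available as a fallback. Per-image manual
#' overrides mirror the manually adjusted thresholds of routine
#' histomorphometry: a named list mapping an image id to a list of
#' replacement values for any of the threshold fields.
#'
#' @param color_space `"HSV"` (default) or `"RGB"`.
#' @param bone_hue_range hue window `[lo, hi]` in `[0, 1]`; if `lo > hi` the
#'   window wraps around 1 (red hues).
#' @param bone_saturation_min minimum saturation of stained bone.
#' @param bone_value_range value (brightness) window of stained bone.
#' @param implant_value_max maximum brightness of implant metal.
#' @param min_object_px minimum connected-component size kept by
#'   [segment_bone()] (speck removal; 0 disables).
#' @param rgb_red_min,rgb_red_excess RGB-fallback rule: red channel at least
#'   `rgb_red_min` and exceeding both green and blue by `rgb_red_excess`.
#' @param manual_overrides named list of per-image threshold replacements.
#' @return An object of class `color_config`.
#' @export
color_config <- function(color_space = c("HSV", "RGB"),
                         bone_hue_range = c(0.88, 1.00),
                         bone_saturation_min = 0.40,
                         bone_value_range = c(0.35, 0.95),
                         implant_value_max = 0.20,
                         min_object_px = 5,
                         rgb_red_min = 0.35, rgb_red_excess = 0.12,
                         manual_overrides = list()) {
  color_space <- match.arg(color_space)
  stopifnot(length(bone_hue_range) == 2L, length(bone_value_range) == 2L,
            bone_value_range[1] <= bone_value_range[2],
            all(bone_hue_range >= 0 & bone_hue_range <= 1))
  structure(list(color_space = color_space,
                 bone_hue_range = bone_hue_range,
                 bone_saturation_min = bone_saturation_min,
                 bone_value_range = bone_value_range,
                 implant_value_max = implant_value_max,
                 min_object_px = min_object_px,
                 rgb_red_min = rgb_red_min, rgb_red_excess = rgb_red_excess,
                 manual_overrides = manual_overrides),
            class = "color_config")
}

# Apply per-image manual overrides, if any are registered for `image_id`.
apply_overrides <- function(cfg, image_id) {
  if (is.null(image_id) || !length(cfg$manual_overrides)) return(cfg)
  ov <- cfg$manual_overrides[[image_id]]
  if (is.null(ov)) return(cfg)
  for (k in names(ov)) cfg[[k]] <- ov[[k]]
  cfg
}

image_hsv <- function(img) {
  ch <- img$channels
  m <- rbind(as.vector(ch[, , 1]), as.vector(ch[, , 2]), as.vector(ch[, , 3]))
  grDevices::rgb2hsv(m, maxColorValue = 1)
}

#' Segment Alizarin-red-stained bone
#'
#' Thresholds a colour section image in HSV (or with the RGB fallback rule)
#' to the bone-stain windows of a [color_config()], optionally removes
#' connected components smaller than `min_object_px`, and excludes implant
#' pixels when an implant mask is supplied.
#'
#' @param image a 3-channel `calibrated_image`.
#' @param cfg a [color_config()].
#' @param implant_mask optional logical mask excluded from the result.
#' @param image_id optional id used to look up manual threshold overrides.
#' @return Logical bone mask.
#' @export
segment_bone <- function(image, cfg = color_config(), implant_mask = NULL,
                         image_id = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  if (n_channels(image) != 3L)
    stop("segment_bone needs a 3-channel colour image", call. = FALSE)
  cfg <- apply_overrides(cfg, image_id)
  d <- image_dim(image)
  if (cfg$color_space == "HSV") {
    hsv <- image_hsv(image)
    hr <- cfg$bone_hue_range
    in_hue <- if (hr[1] <= hr[2]) hsv[1, ] >= hr[1] & hsv[1, ] <= hr[2]
              else hsv[1, ] >= hr[1] | hsv[1, ] <= hr[2]
    keep <- in_hue & hsv[2, ] >= cfg$bone_saturation_min &
      hsv[3, ] >= cfg$bone_value_range[1] &
      hsv[3, ] <= cfg$bone_value_range[2]
  } else {
    r <- as.vector(image$channels[, , 1])
    g <- as.vector(image$channels[, , 2])
    b <- as.vector(image$channels[, , 3])
    keep <- r >= cfg$rgb_red_min & (r - g) >= cfg$rgb_red_excess &
      (r - b) >= cfg$rgb_red_excess
  }
  mask <- matrix(keep, d[1], d[2])
  if (!is.null(implant_mask)) mask <- mask & !implant_mask
  if (cfg$min_object_px > 0 && any(mask)) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask) * 1)))
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < cfg$min_object_px)
    if (length(drop)) mask[t(lab) %in% drop] <- FALSE
  }
  mask
}

#' Detect the implant cross-section
#'
#' Thresholds dark pixels (`value < implant_value_max`), labels connected
#' components, keeps the largest, and fills its holes. Sections where no
#' dark component exists raise a detection error — the cue to supply a
#' manual implant mask instead.
#'
#' @inheritParams segment_bone
#' @return Logical implant mask.
#' @export
segment_implant <- function(image, cfg = color_config(), image_id = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  if (n_channels(image) != 3L)
    stop("segment_implant needs a 3-channel colour image", call. = FALSE)
  cfg <- apply_overrides(cfg, image_id)
  v <- apply(image$channels, c(1, 2), max)
  dark <- v < cfg$implant_value_max
  if (!any(dark))
    stop("no dark component found: supply a manual implant mask",
         call. = FALSE)
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(dark) * 1)))
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  comp <- lab == big
  comp <- EBImage::imageData(EBImage::fillHull(EBImage::Image(comp * 1))) > 0
  t(comp)
}

#' CD31-positive area of a fluorescence field
#'
#' Counts red-channel pixels at or above `intensity_threshold` and converts
#' the count to um2 via the field's pixel calibration.
#'
#' @param field a `calibrated_image`; the red channel is plane 1 of a
#'   3-channel image, or the single plane of a 1-channel image.
#' @param intensity_threshold threshold in `[0, 1]` (default 0.5).
#' @return Positive area in um2.
#' @export
measure_cd31 <- function(field, intensity_threshold = 0.5) {
  stopifnot(inherits(field, "calibrated_image"))
  stopifnot_scalar_number(intensity_threshold, "intensity_threshold",
                          min = 0, max = 1)
  red <- if (n_channels(field) == 1L) field$channels else
    field$channels[, , 1]
  sum(red >= intensity_threshold) * field$pixel_area_um2
}
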