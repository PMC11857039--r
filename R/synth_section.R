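#' Synthetic cross-section specification
#'
#' Parameters of the synthetic stained cross-section: a dark trapezoidal
#' implant (disc cross-section, long axis horizontal) sitting inside a
#' trephine defect (vertical rectangle with a semicircular bottom), with
#' mineralized bone growing in from the defect walls and creeping along the
#' implant surface (osteoconduction). The disc is longer (7 mm) than the
#' 5 mm trephine diameter, so its ends are press-fit into the native bone
#' beyond the cavity walls.
#'
#' Image size is derived from the physical geometry and the pixel
#' calibration unless given explicitly; `scale` multiplies the pixel edge
#' (scale 1 is the native 17.43 um2/px calibration, larger values give
#' coarser, faster grids with identical physical geometry).
#'
#' @param pixel_area_um2 per-pixel area, um2 (default 17.43).
#' @param scale pixel-edge multiplier applied to `pixel_area_um2`.
#' @param implant_length_mm,implant_thickness_mm disc cross-section size
#'   (defaults 7.0 and 1.0 mm).
#' @param defect_diameter_mm,defect_depth_mm trephine diameter and depth
#'   (defaults 5.0 and 5.0 mm).
#' @param margin_mm blank margin around the drawn geometry.
#' @param image_width_px,image_height_px optional explicit grid size; must be
#'   large enough for the geometry.
#' @param growth_steps number of stochastic growth iterations.
#' @param conduction_bias relative growth speed inside the 100 um band along
#'   the implant surface (>= 1; default 4).
#' @param accept_prob baseline per-candidate-pixel acceptance probability of
#'   one growth step (bulk rate, default 0.2).
#' @param noise_level rendering noise in `[0, 1]` (0 = clean colours).
#' @param seed integer RNG seed.
#' @return An object of class `section_spec`.
#' @export
section_spec <- function(pixel_area_um2 = 17.43, scale = 1,
                         implant_length_mm = 7, implant_thickness_mm = 1,
                         defect_diameter_mm = 5, defect_depth_mm = 5,
                         margin_mm = 0.3,
                         image_width_px = NULL, image_height_px = NULL,
                         growth_steps = 60, conduction_bias = 4,
                         accept_prob = 0.2,
                         noise_level = 0, seed = 1L) {
  stopifnot_scalar_number(pixel_area_um2, "pixel_area_um2", min = 1e-9)
  stopifnot_scalar_number(scale, "scale", min = 1e-9)
  stopifnot_scalar_number(implant_length_mm, "implant_length_mm", min = 1e-9)
  stopifnot_scalar_number(implant_thickness_mm, "implant_thickness_mm",
                          min = 1e-9)
  stopifnot_scalar_number(defect_diameter_mm, "defect_diameter_mm",
                          min = 1e-9)
  stopifnot_scalar_number(growth_steps, "growth_steps", min = 0)
  stopifnot_scalar_number(conduction_bias, "conduction_bias", min = 1)
  stopifnot_scalar_number(noise_level, "noise_level", min = 0, max = 1)
  stopifnot_scalar_number(accept_prob, "accept_prob", min = 1e-9, max = 1)
  pa <- pixel_area_um2 * scale^2
  e <- sqrt(pa)
  need_w <- ceiling(mm_to_px(implant_length_mm + 2 * margin_mm, e))
  need_h <- ceiling(mm_to_px(defect_depth_mm + 2 * margin_mm, e))
  w <- as.integer(if (is.null(image_width_px)) need_w else image_width_px)
  h <- as.integer(if (is.null(image_height_px)) need_h else image_height_px)
  if (w < need_w || h < need_h)
    stop(sprintf(
      "geometry infeasible: image %d x %d px cannot hold %g x %g mm at %g um2/px",
      h, w, implant_length_mm + 2 * margin_mm,
      defect_depth_mm + 2 * margin_mm, pa), call. = FALSE)
  structure(list(
    pixel_area_um2 = pa, pixel_edge_um = e,
    image_width_px = w, image_height_px = h,
    implant_length_mm = implant_length_mm,
    implant_thickness_mm = implant_thickness_mm,
    defect_diameter_mm = defect_diameter_mm,
    defect_depth_mm = defect_depth_mm, margin_mm = margin_mm,
    growth_steps = as.integer(growth_steps),
    conduction_bias = conduction_bias, accept_prob = accept_prob,
    noise_level = noise_level, seed = as.integer(seed)),
    class = "section_spec")
}

#' @export
print.section_spec <- function(x, ...) {
  cat(sprintf(
    "<section_spec> %d x %d px @ %.4g um2/px | implant %g x %g mm, defect d=%g mm\n",
    x$image_height_px, x$image_width_px, x$pixel_area_um2,
    x$implant_length_mm, x$implant_thickness_mm, x$defect_diameter_mm))
  invisible(x)
}

#' Deterministic section geometry (implant + defect masks)
#'
#' Draws the implant and defect masks implied by a [section_spec()]: the
#' defect is a vertical slot of the trephine diameter with a semicircular
#' bottom, opening at the top bone surface; the implant is a symmetric
#' horizontal trapezoid centred in the defect, its ends crossing the cavity
#' walls into native bone.
#'
#' @param spec a [section_spec()].
#' @return A `mask_set` with empty bone.
#' @export
section_masks <- function(spec) {
  stopifnot(inherits(spec, "section_spec"))
  h <- spec$image_height_px; w <- spec$image_width_px
  e <- spec$pixel_edge_um
  margin <- max(2, round(mm_to_px(spec$margin_mm, e)))
  cx <- (w + 1) / 2
  row <- matrix(seq_len(h), h, w)
  col <- matrix(seq_len(w), h, w, byrow = TRUE)

  # trephine defect: slot + semicircular bottom
  R <- mm_to_px(spec$defect_diameter_mm, e) / 2
  D <- mm_to_px(spec$defect_depth_mm, e)
  r0 <- margin + 1                       # bone surface / defect opening
  rc <- r0 + D - R                       # centre row of the bottom arc
  defect <- (abs(col - cx) <= R & row >= r0 & row <= rc) |
    ((row - rc)^2 + (col - cx)^2 <= R^2 & row > rc)

  # implant trapezoid: long axis horizontal, slight taper towards the bottom
  L2 <- mm_to_px(spec$implant_length_mm, e) / 2
  T_ <- mm_to_px(spec$implant_thickness_mm, e)
  ri_c <- r0 + 0.45 * D                  # implant mid-depth in the defect
  top <- ri_c - T_ / 2
  frac <- clamp01((row - top) / T_)      # 0 at top edge, 1 at bottom edge
  halfw <- L2 * (1 - 0.08 * frac)        # 8% taper
  implant <- row >= top & row <= top + T_ & abs(col - cx) <= halfw

  if (!any(implant) || !any(defect & !implant))
    stop("geometry infeasible: empty implant or defect region", call. = FALSE)
  mask_set(implant, defect, pixel_area_um2 = spec$pixel_area_um2)
}

# Precomputed growth scaffold: linear-index domain, wall seeds, conduction
# band, zone labels. Shared by grow_bone() and gen_study().
section_geometry <- function(spec) {
  masks <- section_masks(spec)
  h <- nrow(masks$implant)
  e <- spec$pixel_edge_um
  margin <- max(2, round(mm_to_px(spec$margin_mm, e)))
  r0 <- margin + 1
  domain <- masks$defect & !masks$implant
  row <- matrix(seq_len(h), h, ncol(masks$implant))
  # native bone: outside the cavity, at or below the bone surface, not implant
  native <- !masks$defect & !masks$implant & row >= r0
  seeds <- which(dilate8(native) & domain)          # wall-adjacent candidates
  dist_um <- implant_distance_um(masks$implant, spec$pixel_area_um2)
  band <- !masks$implant & dist_um < 100            # conduction band, 100 um
  list(spec = spec, masks = masks, domain = domain,
       domain_idx = which(domain), seeds = seeds,
       band = band, dist_um = dist_um, h = h)
}

# Index-based stochastic cellular growth. Runs until `steps` iterations or
# until the bone fraction of `until_mask` reaches `until_fraction`.
grow_engine <- function(geom, steps, accept_prob, conduction_bias,
                        until_mask = NULL, until_fraction = NULL,
                        keep_series = FALSE) {
  h <- geom$h
  n <- length(geom$domain)
  bone <- logical(n)
  in_cand <- logical(n)
  cand <- geom$seeds
  in_cand[cand] <- TRUE
  p_bulk <- accept_prob
  p_band <- min(0.95, accept_prob * conduction_bias)
  band <- as.vector(geom$band)
  domain <- as.vector(geom$domain)
  series <- if (keep_series) vector("list", steps) else NULL
  until_idx <- if (!is.null(until_mask)) which(as.vector(until_mask)) else NULL
  until_n <- if (!is.null(until_idx)) length(until_idx) else NULL
  counts <- integer(0)
  step <- 0L
  while (step < steps && length(cand)) {
    step <- step + 1L
    p <- ifelse(band[cand], p_band, p_bulk)
    acc <- cand[runif(length(cand)) < p]
    if (length(acc)) {
      bone[acc] <- TRUE
      in_cand[acc] <- FALSE
      nb <- neighbor_idx8(acc, h)
      nb <- nb[nb >= 1L & nb <= n]
      nb <- nb[domain[nb] & !bone[nb] & !in_cand[nb]]
      nb <- unique(nb)
      in_cand[nb] <- TRUE
      cand <- c(cand[!bone[cand]], nb)
    }
    counts <- c(counts, sum(bone))
    if (keep_series)
      series[[step]] <- matrix(bone, h)
    if (!is.null(until_idx) &&
        sum(bone[until_idx]) / until_n >= until_fraction) break
  }
  list(bone = matrix(bone, h), series = if (keep_series) series[seq_len(step)],
       counts = counts, steps_run = step)
}

#' Simulate osteoconductive bone growth in a synthetic section
#'
#' Stochastic cellular growth of mineralized bone: growth is seeded
#' exclusively at the trephine-defect walls and advances by 8-connected
#' dilation, each frontier pixel being mineralized with probability
#' `accept_prob` per step — multiplied by `conduction_bias` (capped at 0.95)
#' inside the 100 um band along the implant surface, which reproduces the
#' preferential propagation of new bone along the implant observed
#' histologically. Bone never invades the implant, and the mask sequence is
#' monotone increasing.
#'
#' @param spec a [section_spec()]; `growth_steps`, `conduction_bias`,
#'   `accept_prob` and `seed` control the run.
#' @param keep_series if `TRUE`, return the full list of per-step bone masks
#'   (memory-heavy on large grids).
#' @return A list with `masks` (a `mask_set` whose `bone` is the final mask),
#'   `counts` (bone pixel count after each step), and — when requested —
#'   `series`, the per-step masks.
#' @examples
#' g <- grow_bone(section_spec(scale = 12, growth_steps = 15, seed = 7))
#' g$masks
#' @export
grow_bone <- function(spec, keep_series = FALSE) {
  stopifnot(inherits(spec, "section_spec"))
  geom <- section_geometry(spec)
  res <- with_seed(spec$seed,
    grow_engine(geom, spec$growth_steps, spec$accept_prob,
                spec$conduction_bias, keep_series = keep_series))
  masks <- geom$masks
  masks$bone <- res$bone
  list(masks = masks, counts = res$counts, series = res$series,
       steps_run = res$steps_run)
}

# Default stain-colour book used by render_stain() and, as the matching
# acceptance windows, by color_config(). Hue/sat/value in [0,1].
stain_palette <- function() {
  list(
    bone       = c(h = 0.94, s = 0.70, v = 0.70),  # Alizarin red/magenta
    soft       = c(h = 0.62, s = 0.50, v = 0.80),  # toluidine-blue tissue
    native     = c(h = 0.10, s = 0.25, v = 0.90),  # pale native bone matrix
    background = c(h = 0.60, s = 0.05, v = 0.97),  # mounting medium
    implant    = c(h = 0.00, s = 0.00, v = 0.07))  # titanium, near-black
}

#' Render a stained-section colour image from masks
#'
#' Paints each compartment of a `mask_set` with its stain colour (Alizarin
#' red/magenta bone, blue-ish soft tissue, near-black implant, near-white
#' background, pale native bone outside the cavity) and applies an optional
#' noise model: per-pixel hue/saturation/value jitter, Gaussian blur, and
#' additive sensor noise, all scaled by `noise_level`. At `noise_level = 0`
#' every bone pixel's colour lies strictly inside the default segmentation
#' windows of [color_config()] and every non-bone pixel strictly outside, so
#' segmentation recovers the ground-truth mask exactly.
#'
#' @param masks a `mask_set`.
#' @param noise_level noise amplitude in `[0, 1]`.
#' @param seed RNG seed (rendering is bit-reproducible for a fixed seed).
#' @return A 3-channel `calibrated_image`.
#' @export
render_stain <- function(masks, noise_level = 0, seed = 1L) {
  stopifnot(inherits(masks, "mask_set"))
  stopifnot_scalar_number(noise_level, "noise_level", min = 0, max = 1)
  pal <- stain_palette()
  h <- nrow(masks$implant); w <- ncol(masks$implant)
  n <- h * w
  cls <- matrix("background", h, w)
  row <- matrix(seq_len(h), h, w)
  # native bone occupies everything beside/below the cavity mouth
  r0 <- min(row[masks$defect])
  cls[!masks$defect & row >= r0] <- "native"
  cls[masks$defect] <- "soft"
  cls[masks$bone] <- "bone"
  cls[masks$implant] <- "implant"
  H <- S <- V <- numeric(n)
  for (k in names(pal)) {
    i <- which(cls == k)
    H[i] <- pal[[k]]["h"]; S[i] <- pal[[k]]["s"]; V[i] <- pal[[k]]["v"]
  }
  img <- with_seed(seed, {
    if (noise_level > 0) {
      H <- H + rnorm(n, 0, 0.02 * noise_level)
      S <- clamp01(S + rnorm(n, 0, 0.08 * noise_level))
      V <- clamp01(V + rnorm(n, 0, 0.08 * noise_level))
    }
    rgb <- hsv_to_rgb(H %% 1, S, V)
    ch <- array(c(rgb$r, rgb$g, rgb$b), c(h, w, 3))
    if (noise_level > 0) {
      sigma <- 1.2 * noise_level
      eb <- EBImage::gblur(EBImage::Image(aperm(ch, c(2, 1, 3)),
                                          colormode = "Color"), sigma = sigma)
      ch <- aperm(EBImage::imageData(eb), c(2, 1, 3))
      ch <- clamp01(ch + rnorm(length(ch), 0, 0.04 * noise_level))
    }
    ch
  })
  calibrated_image(img, masks$pixel_area_um2)
}
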