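#' Study design for the synthetic in vivo experiment
#'
#' Describes the surface conditions, animals, healing timepoints, planted
#' effects, and lost discs of a synthetic study. The default conditions are
#' the ten evaluated surface designs (2-zone PEM films in both loading
#' orders, co-loaded and single-loaded PEM films, unloaded PEM, and bare-Ti
#' controls).
#'
#' @param conditions unique non-empty character vector of surface-condition
#'   labels.
#' @param n_animals number of animals (>= 2; default 12).
#' @param timepoints healing times in weeks (default `c(4, 13)`).
#' @param planted_effects `NULL`, or a data frame with columns `condition`,
#'   `timepoint`, `shift`: additive shift on the disc-level immediate-layer
#'   bone fraction for that condition at that timepoint.
#' @param lost_discs `NULL`, or a data frame with columns `animal`,
#'   `condition`, `timepoint` listing discs lost during preparation.
#' @param baseline_immediate named numeric: mean immediate-layer bone
#'   fraction per timepoint (defaults: 0.10 at 4 weeks, 0.30 at 13 weeks,
#'   matching the low early zone densities and substantially filled defects
#'   at the late timepoint).
#' @param sigma_animal,sigma_disc SDs of the animal and disc random effects
#'   on the logit scale (defaults 0.25 and 0.35; together about a 0.10 SD
#'   on the fraction scale near a 0.3 baseline — the design-stage sigma of
#'   10%).
#' @return An object of class `study_design`.
#' @export
study_design <- function(conditions = default_conditions(),
                         n_animals = 12, timepoints = c(4, 13),
                         planted_effects = NULL, lost_discs = NULL,
                         baseline_immediate = c("4" = 0.10, "13" = 0.30),
                         sigma_animal = 0.25, sigma_disc = 0.35) {
  if (!length(conditions) || anyDuplicated(conditions))
    stop("`conditions` must be non-empty and unique", call. = FALSE)
  stopifnot_scalar_number(n_animals, "n_animals", min = 2)
  if (!length(timepoints)) stop("need at least one timepoint", call. = FALSE)
  miss <- setdiff(as.character(timepoints), names(baseline_immediate))
  if (length(miss))
    stop("`baseline_immediate` lacks timepoint(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  structure(list(conditions = conditions, n_animals = as.integer(n_animals),
                 timepoints = timepoints, planted_effects = planted_effects,
                 lost_discs = lost_discs,
                 baseline_immediate = baseline_immediate,
                 sigma_animal = sigma_animal, sigma_disc = sigma_disc),
            class = "study_design")
}

#' @rdname study_design
#' @export
default_conditions <- function() c(
  "PEM10_BMP2+PEM10_VEGF",  # BMP2 below, VEGF on top
  "PEM10_VEGF+PEM10_BMP2",  # VEGF below, BMP2 on top
  "PEM20_VEGF_BMP2", "PEM20_VEGF", "PEM20_BMP2", "PEM20_unloaded",
  "Ti_VEGF_BMP2", "Ti_VEGF", "Ti_BMP2", "Ti_control")

#' Disc accounting for a study design
#'
#' Number of discs scheduled (conditions x animals x timepoints-per-animal)
#' and surviving (minus lost discs). With the full set of 14 implanted
#' surface groups over 12 animals (one timepoint each) and a single lost
#' disc, 167 discs survive preparation.
#'
#' @param n_conditions number of surface conditions.
#' @param n_animals number of animals.
#' @param n_lost number of discs lost during preparation.
#' @param timepoints_per_animal how many timepoints each animal contributes
#'   (1 in a parallel-group sacrifice design; default 1).
#' @return List with `scheduled` and `surviving` counts.
#' @examples
#' count_discs(14, 12, n_lost = 1)$surviving  # 167
#' @export
count_discs <- function(n_conditions, n_animals, n_lost = 0,
                        timepoints_per_animal = 1) {
  scheduled <- n_conditions * n_animals * timepoints_per_animal
  list(scheduled = scheduled, surviving = scheduled - n_lost)
}

# disc-level target immediate-layer fractions implied by a design
draw_disc_targets <- function(design) {
  grid <- expand.grid(animal = seq_len(design$n_animals),
                      condition = design$conditions,
                      timepoint = design$timepoints,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  a_eff <- rnorm(design$n_animals, 0, design$sigma_animal)
  base <- design$baseline_immediate[as.character(grid$timepoint)]
  shift <- numeric(nrow(grid))
  pe <- design$planted_effects
  if (!is.null(pe) && nrow(pe)) {
    for (i in seq_len(nrow(pe))) {
      hit <- grid$condition == pe$condition[i] &
        grid$timepoint == pe$timepoint[i]
      shift[hit] <- shift[hit] + pe$shift[i]
    }
  }
  mu <- qlogis(pmin(0.95, pmax(0.02, base + shift)))
  grid$target_immediate <- plogis(mu + a_eff[grid$animal] +
                                    rnorm(nrow(grid), 0, design$sigma_disc))
  grid$target_immediate <- pmin(0.95, pmax(0.01, grid$target_immediate))
  grid
}

#' Generate a full synthetic study
#'
#' Simulates one disc per (animal, condition, timepoint) minus lost discs.
#' Each disc gets a target immediate-layer bone fraction drawn from a
#' logit-normal model (timepoint baseline + planted condition effects +
#' animal and disc random effects); each of its 3-4 cross-sections is an
#' independent osteoconductive growth realization run until the immediate
#' layer reaches the disc's target fraction, then quantified through the
#' zone partition ([section_morphometry()]). The zone geometry is computed
#' once per study (implant and defect are identical across discs).
#'
#' @param design a [study_design()].
#' @param spec a [section_spec()] defining the section geometry and growth
#'   parameters (use a coarse `scale` for large simulations).
#' @param seed RNG seed for the whole study.
#' @param keep_masks keep each section's bone mask (memory-heavy).
#' @param max_steps growth-step cap per section.
#' @return List of class `synthetic_study`: `discs` (one row per surviving
#'   disc: ids, condition, timepoint, `target_immediate`, `n_sections`,
#'   `complete_block`), `records` (long per-section morphometry:
#'   disc ids + `cross_section`, `region`, `metric`, `value`), `design`,
#'   `spec`, and optionally `masks`.
#' @export
gen_study <- function(design, spec, seed = 1L, keep_masks = FALSE,
                      max_steps = 2000L) {
  stopifnot(inherits(design, "study_design"), inherits(spec, "section_spec"))
  geom <- section_geometry(spec)
  zones <- partition_zones(geom$masks$implant, geom$masks$defect,
                           spec$pixel_area_um2, dist_um = geom$dist_um)
  imm_ids <- zones$regions$region[zones$regions$layer == "immediate"]
  imm <- matrix(zones$labels %in% imm_ids, nrow(zones$labels))
  with_seed(seed, {
    discs <- draw_disc_targets(design)
    lost <- design$lost_discs
    if (!is.null(lost) && nrow(lost)) {
      key <- paste(discs$animal, discs$condition, discs$timepoint)
      drop <- key %in% paste(lost$animal, lost$condition, lost$timepoint)
      lost_blocks <- unique(paste(discs$animal[drop], discs$timepoint[drop]))
      discs <- discs[!drop, , drop = FALSE]
    } else lost_blocks <- character(0)
    discs$disc_id <- sprintf("A%02d_%s_w%s", discs$animal, discs$condition,
                             discs$timepoint)
    discs$n_sections <- sample(3:4, nrow(discs), replace = TRUE)
    discs$complete_block <-
      !(paste(discs$animal, discs$timepoint) %in% lost_blocks)
    rec <- vector("list", nrow(discs))
    masks_out <- if (keep_masks) vector("list", nrow(discs)) else NULL
    for (d in seq_len(nrow(discs))) {
      secs <- vector("list", discs$n_sections[d])
      for (s in seq_len(discs$n_sections[d])) {
        g <- grow_engine(geom, steps = max_steps,
                         accept_prob = spec$accept_prob,
                         conduction_bias = spec$conduction_bias,
                         until_mask = imm,
                         until_fraction = discs$target_immediate[d])
        m <- geom$masks
        m$bone <- g$bone
        sm <- section_morphometry(m, zones)
        sm$cross_section <- s
        secs[[s]] <- sm
        if (keep_masks)
          masks_out[[d]] <- c(masks_out[[d]], list(g$bone))
      }
      r <- do.call(rbind, secs)
      r$disc_id <- discs$disc_id[d]
      r$animal <- discs$animal[d]
      r$condition <- discs$condition[d]
      r$timepoint <- discs$timepoint[d]
      rec[[d]] <- r
    }
    records <- do.call(rbind, rec)
    structure(list(discs = discs, records = records[, c(
      "disc_id", "animal", "condition", "timepoint", "cross_section",
      "region", "metric", "value")],
      design = design, spec = spec, masks = masks_out),
      class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d discs (%d conditions x %d animals x %d timepoints)\n",
              nrow(x$discs), length(x$design$conditions),
              x$design$n_animals, length(x$design$timepoints)))
  invisible(x)
}

#' Per-disc means of a synthetic study
#'
#' Applies [aggregate_disc()] to every disc of a study and binds the result
#' into one long table.
#'
#' @param study a `synthetic_study` (or any long records table with disc
#'   ids).
#' @return Data frame: `disc_id`, `animal`, `condition`, `timepoint`,
#'   `region`, `metric`, `value`, `n_sections`.
#' @export
study_disc_means <- function(study) {
  rec <- if (inherits(study, "synthetic_study")) study$records else study
  out <- lapply(split(rec, rec$disc_id), function(r) {
    agg <- suppressWarnings(aggregate_disc(
      r[, c("cross_section", "region", "metric", "value")]))
    agg$disc_id <- r$disc_id[1]; agg$animal <- r$animal[1]
    agg$condition <- r$condition[1]; agg$timepoint <- r$timepoint[1]
    agg
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("disc_id", "animal", "condition", "timepoint", "region",
          "metric", "value", "n_sections")]
}

#' Blocks-by-conditions matrix for one metric/region/timepoint
#'
#' Pivot of per-disc means into the animal x condition matrix consumed by
#' [friedman_bonferroni()].
#'
#' @param disc_means output of [study_disc_means()].
#' @param metric,region,timepoint selectors.
#' @return Numeric matrix, rows = animals, columns = conditions (`NA` where
#'   a disc is missing).
#' @export
study_matrix <- function(disc_means, metric, region, timepoint) {
  sub <- disc_means[disc_means$metric == metric &
                      disc_means$region == region &
                      disc_means$timepoint == timepoint, , drop = FALSE]
  animals <- sort(unique(sub$animal))
  conds <- unique(sub$condition)
  m <- matrix(NA_real_, length(animals), length(conds),
              dimnames = list(animals, conds))
  m[cbind(match(sub$animal, animals), match(sub$condition, conds))] <-
    sub$value
  m
}
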