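test_that("section geometry is consistent and scale-invariant in mm", {
  sp <- test_spec()
  m <- section_masks(sp)
  expect_false(any(m$bone))
  expect_equal(dim(m$implant), dim(m$defect))
  # physical implant area ~ length x thickness (trapezoid, 8% taper)
  area_mm2 <- sum(m$implant) * sp$pixel_area_um2 * 1e-6
  expect_lt(abs(area_mm2 - 7 * 1 * 0.96), 0.35)
  # defect width ~ 5 mm
  wd_px <- diff(range(which(colSums(m$defect) > 0))) + 1
  expect_lt(abs(wd_px * sp$pixel_edge_um / 1000 - 5), 0.2)
  # implant crosses the defect walls (disc longer than trephine diameter)
  expect_gt(sum(m$implant & !m$defect), 0)
  expect_error(section_spec(image_width_px = 10, image_height_px = 10),
               "infeasible")
})

test_that("bone growth is monotone, wall-seeded and implant-avoiding", {
  sp <- test_spec(growth_steps = 25, seed = 5)
  g <- grow_bone(sp, keep_series = TRUE)
  expect_equal(g$steps_run, 25)
  expect_true(all(diff(g$counts) >= 0))
  for (i in seq_along(g$series)[-1])
    expect_true(all(g$series[[i - 1]] <= g$series[[i]]))
  expect_false(any(g$masks$bone & g$masks$implant))
  expect_true(all(g$masks$bone <= (g$masks$defect & !g$masks$implant)))
  # first-step bone is seeded at the defect walls only
  first <- g$series[[1]]
  adj_out <- brute_adjacent8(!g$masks$defect)
  expect_true(all(adj_out[first]))
})

test_that("zero growth steps produce an empty bone mask", {
  g <- grow_bone(test_spec(growth_steps = 0))
  expect_equal(sum(g$masks$bone), 0)
})

test_that("unbiased growth fills layers evenly; conduction bias favours the immediate layer", {
  # bias 1, saturating growth: immediate and remote layer fractions converge
  sp1 <- test_spec(conduction_bias = 1, growth_steps = 500, accept_prob = 0.5,
                   seed = 3)
  g1 <- grow_bone(sp1)
  zp <- partition_zones(g1$masks$implant, g1$masks$defect,
                        sp1$pixel_area_um2)
  frac_layer <- function(g, layer) {
    ids <- zp$regions$region[zp$regions$layer == layer]
    sum(g$masks$bone & matrix(zp$labels %in% ids, nrow(zp$labels))) /
      sum(zp$regions$pixels[zp$regions$region %in% ids])
  }
  expect_lt(abs(frac_layer(g1, "immediate") - frac_layer(g1, "remote")), 0.05)
  # bias 4, moderate steps: immediate strictly exceeds remote
  sp4 <- test_spec(conduction_bias = 4, growth_steps = 30, seed = 3)
  g4 <- grow_bone(sp4)
  expect_gt(frac_layer(g4, "immediate"), frac_layer(g4, "remote"))
})

test_that("rendering is seed-reproducible and noiseless rendering is exactly invertible", {
  sp <- test_spec(growth_steps = 30, seed = 9)
  g <- grow_bone(sp)
  a <- render_stain(g$masks, noise_level = 0.2, seed = 17)
  b <- render_stain(g$masks, noise_level = 0.2, seed = 17)
  expect_identical(a$channels, b$channels)
  c0 <- render_stain(g$masks, noise_level = 0)
  got <- segment_bone(c0, color_config(min_object_px = 0))
  expect_identical(got, g$masks$bone)
})

test_that("fluorescence fields have exact ground truth and seeded determinism", {
  f0 <- gen_fluorescence(n_blobs = 0, seed = 1)
  expect_equal(f0$truth$cd31_area_um2, 0)
  f <- gen_fluorescence(n_blobs = 10, blob_area_um2 = 500, seed = 4)
  expect_equal(measure_cd31(f$field), f$truth$cd31_area_um2)
  # nominal 10 x 500 um2 within pixel-quantization slack
  expect_lt(abs(f$truth$cd31_area_um2 - 5000) / 5000, 0.05)
  f2 <- gen_fluorescence(n_blobs = 10, blob_area_um2 = 500, seed = 4)
  expect_identical(f$field$channels, f2$field$channels)
  expect_error(gen_fluorescence(n_blobs = 100, blob_area_um2 = 1e5),
               "exceeds")
})

test_that("release series follow the closed-form law and stay nondecreasing", {
  r0 <- gen_release_series(0)
  expect_true(all(r0$interval_ug == 0))
  rd <- gen_release_series(2.59, delay_days = 30, noise_sd = 0)
  expect_equal(max(rd$cumulative_ug), 0)
  r <- gen_release_series(2.59, 0.3, 0.2, 0, noise_sd = 0)
  expect_equal(tail(r$cumulative_ug, 1), 2.59 * (0.3 + 0.7 * (1 - exp(-4.2))))
  rn <- gen_release_series(2.59, 0.3, 0.2, 0, noise_sd = 0.5, seed = 8)
  expect_true(all(diff(rn$cumulative_ug) >= 0))
  expect_true(all(rn$interval_ug >= 0))
  expect_identical(rn, gen_release_series(2.59, 0.3, 0.2, 0, noise_sd = 0.5,
                                          seed = 8))
  expect_error(gen_release_series(-1), "must be")
})

test_that("gen_study emits one disc per cell, honours losses, and is reproducible", {
  des <- study_design(n_animals = 4,
                      conditions = default_conditions()[1:3],
                      baseline_immediate = c("4" = 0.1, "13" = 0.3))
  sp <- test_spec(scale = 16, growth_steps = 2000)
  st <- gen_study(des, sp, seed = 21)
  expect_equal(nrow(st$discs), 3 * 4 * 2)
  expect_true(all(st$discs$n_sections %in% 3:4))
  st2 <- gen_study(des, sp, seed = 21)
  expect_identical(st$records, st2$records)
  lost <- data.frame(animal = 2, condition = des$conditions[1],
                     timepoint = 13)
  stl <- gen_study(study_design(n_animals = 4,
                                conditions = default_conditions()[1:3],
                                lost_discs = lost,
                                baseline_immediate = c("4" = 0.1, "13" = 0.3)),
                   sp, seed = 21)
  expect_equal(nrow(stl$discs), 23)
  flagged <- stl$discs[stl$discs$animal == 2 & stl$discs$timepoint == 13, ]
  expect_true(all(!flagged$complete_block))
  expect_true(all(stl$discs$complete_block[stl$discs$timepoint == 4]))
})

test_that("planted effects shift the realized immediate-layer density", {
  pe <- data.frame(condition = "B", timepoint = 13, shift = 0.3)
  des <- study_design(conditions = c("A", "B"), n_animals = 6,
                      timepoints = 13, planted_effects = pe,
                      baseline_immediate = c("13" = 0.3))
  st <- gen_study(des, test_spec(scale = 16, growth_steps = 2000), seed = 2)
  dm <- study_disc_means(st)
  imm <- dm[dm$metric == "BD" & grepl("immediate", dm$region), ]
  means <- tapply(imm$value, imm$condition, mean)
  expect_gt(means["B"] - means["A"], 10)  # +0.3 fraction = +30 pp density
})

test_that("section specs round-trip through YAML", {
  skip_if_not_installed("yaml")
  sp <- test_spec(scale = 10, growth_steps = 7, seed = 3)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_section_spec(sp, p)
  sp2 <- read_section_spec(p)
  expect_identical(sp[order(names(sp))], sp2[order(names(sp2))])
})
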