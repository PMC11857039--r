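test_that("bone area converts pixel counts at the calibrated pixel size", {
  region <- matrix(TRUE, 20, 50)
  expect_equal(bone_area(matrix(FALSE, 20, 50), region, 17.43), 0)
  expect_equal(bone_area(region, region, 17.43), 20 * 50 * 17.43 * 1e-6)
  bone <- matrix(FALSE, 20, 50); bone[seq_len(1000)] <- TRUE
  expect_equal(bone_area(bone, region, 17.43), 0.01743)
})

test_that("bone density is the in-region bone percentage", {
  region <- matrix(TRUE, 10, 10)
  expect_equal(bone_density(region, region), 100)
  expect_equal(bone_density(matrix(FALSE, 10, 10), region), 0)
  half <- matrix(FALSE, 10, 10); half[1:5, ] <- TRUE
  expect_equal(bone_density(half, region), 50)
  expect_true(is.na(bone_density(half, matrix(FALSE, 10, 10))))
})

test_that("BIC matches the exhaustive adjacency oracle on random mask triples", {
  implant <- matrix(FALSE, 30, 30); implant[10:20, 5:25] <- TRUE
  defect <- matrix(TRUE, 30, 30)
  band <- surface_band(implant, defect)
  expect_equal(compute_bic(implant, band, defect), 100)   # bone everywhere
  expect_equal(compute_bic(implant, matrix(FALSE, 30, 30), defect), 0)
  set.seed(123)
  for (i in 1:100) {
    h <- sample(15:50, 1); w <- sample(15:50, 1)
    implant <- random_blob(h, w)
    defect <- random_rect(h, w, min_side = 8)
    bone <- matrix(runif(h * w) < 0.4, h, w) & !implant
    adj <- brute_adjacent8(implant) & defect
    got <- compute_bic(implant, bone, defect)
    if (sum(adj) == 0) expect_true(is.na(got))
    else expect_equal(got, 100 * sum(adj & bone) / sum(adj))
  }
})

test_that("BIC is monotone under addition of bone pixels", {
  sp <- test_spec(growth_steps = 30, seed = 4)
  g <- grow_bone(sp, keep_series = TRUE)
  bics <- vapply(g$series, function(b)
    compute_bic(g$masks$implant, b, g$masks$defect), numeric(1))
  expect_true(all(diff(bics) >= 0))
})

test_that("zone BF sums exactly to the 300-um band BF", {
  sp <- test_spec(growth_steps = 35, seed = 6)
  g <- grow_bone(sp)
  zp <- partition_zones(g$masks$implant, g$masks$defect, sp$pixel_area_um2)
  sm <- section_morphometry(g$masks, zp)
  zone_bf <- sum(sm$value[sm$metric == "BF" & sm$region != "whole_defect"])
  band <- build_band(g$masks$implant, g$masks$defect, sp$pixel_area_um2)
  expect_equal(zone_bf, bone_area(g$masks$bone, band, sp$pixel_area_um2))
})

test_that("morphometry equals generator ground truth on noiseless renders and within tolerance at noise 0.2", {
  sp <- test_spec(scale = 6, growth_steps = 50, seed = 31)
  g <- grow_bone(sp)
  zp <- partition_zones(g$masks$implant, g$masks$defect, sp$pixel_area_um2)
  truth <- section_morphometry(g$masks, zp)
  # noiseless pipeline: render -> segment -> quantify, exactly equal
  img <- render_stain(g$masks, 0)
  imp <- segment_implant(img)
  bone <- segment_bone(img, color_config(min_object_px = 0),
                       implant_mask = imp)
  est <- section_morphometry(
    mask_set(imp, g$masks$defect, bone, sp$pixel_area_um2), zp)
  expect_equal(est, truth)
  # noisy pipeline: whole-defect BD within 2 percentage points
  imgn <- render_stain(g$masks, 0.2, seed = 12)
  bn <- segment_bone(imgn, implant_mask = segment_implant(imgn))
  wd <- g$masks$defect & !g$masks$implant
  expect_lt(abs(bone_density(bn, wd) - bone_density(g$masks$bone, wd)), 2)
})

test_that("field placement yields 7 upper + 6 lower boxes on the implant surface", {
  sp <- test_spec(scale = 4)
  m <- section_masks(sp)
  fl <- place_fields(m$implant, sp$pixel_area_um2)
  expect_equal(nrow(fl), 13)
  expect_equal(sum(fl$side == "upper"), 7)
  expect_equal(sum(fl$side == "lower"), 6)
  top <- min(which(rowSums(m$implant) > 0))
  bot <- max(which(rowSums(m$implant) > 0))
  expect_true(all(fl$row1[fl$side == "upper"] < top))
  expect_true(all(fl$row0[fl$side == "lower"] > bot))
  expect_equal(nrow(place_fields(m$implant, sp$pixel_area_um2,
                                 n_upper = 0, n_lower = 0)), 0)
  # edge too short for non-overlap: count preserved, warning logged
  expect_warning(
    fl2 <- place_fields(m$implant, sp$pixel_area_um2,
                        defect_mask = m$defect, n_upper = 9),
    "overlap")
  expect_equal(sum(fl2$side == "upper"), 9)
})

test_that("per-disc aggregation averages sections and flags degraded input", {
  rec <- data.frame(cross_section = rep(1:3, each = 2),
                    region = rep(c("whole_defect", "r1"), 3),
                    metric = "BD", value = c(1, 10, 2, 20, 3, 30))
  agg <- aggregate_disc(rec)
  expect_equal(agg$value[agg$region == "whole_defect"], 2)
  expect_equal(agg$value[agg$region == "r1"], 20)
  expect_equal(attr(agg, "n_sections"), 3)
  # identical sections: mean equals each value
  rec2 <- rec; rec2$value <- rep(c(5, 7), 3)
  agg2 <- aggregate_disc(rec2)
  expect_equal(sort(agg2$value), c(5, 7))
  # missing values excluded pairwise
  rec$value[1] <- NA
  expect_equal(aggregate_disc(rec)$value[agg$region == "whole_defect"], 2.5)
  expect_warning(aggregate_disc(rec[rec$cross_section < 3, ]), "2 cross")
  expect_warning(out <- aggregate_disc(rec[0, ]), "missing")
  expect_equal(nrow(out), 0)
})
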