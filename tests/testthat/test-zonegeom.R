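test_that("band construction matches the brute-force distance oracle", {
  set.seed(41)
  for (i in 1:5) {
    h <- sample(40:80, 1); w <- sample(40:80, 1)
    implant <- random_rect(h, w)
    defect <- matrix(TRUE, h, w)
    pa <- 17.43 * sample(4:20, 1)^2
    for (th in c(0, 100, 300)) {
      band <- build_band(implant, defect, pa, thickness_um = th)
      d_oracle <- brute_distance_px(implant) * sqrt(pa)
      expect_identical(band, !implant & d_oracle < th)
    }
  }
})

test_that("band edge cases: zero thickness, no defect clip", {
  implant <- matrix(FALSE, 30, 30); implant[10:20, 10:20] <- TRUE
  expect_equal(sum(build_band(implant, matrix(TRUE, 30, 30), 17.43, 0)), 0)
  full <- build_band(implant, NULL, 17.43, 300)
  clipped <- build_band(implant, matrix(TRUE, 30, 30), 17.43, 300)
  expect_identical(full, clipped)
  expect_error(build_band(matrix(FALSE, 5, 5), NULL, 17.43), "empty")
})

test_that("surface band equals the exhaustive adjacency oracle", {
  # solid rectangle, unclipped: 2(w+h)+4 pixels under 8-connectivity
  implant <- matrix(FALSE, 30, 40)
  implant[10:19, 5:24] <- TRUE  # 10 x 20
  expect_equal(sum(surface_band(implant)), 2 * (10 + 20) + 4)
  # implant fully outside the defect: empty band
  defect <- matrix(FALSE, 30, 40); defect[25:29, 30:39] <- TRUE
  expect_equal(sum(surface_band(implant, defect)), 0)
  # random blobs vs enumeration
  set.seed(7)
  for (i in 1:20) {
    h <- sample(20:50, 1); w <- sample(20:50, 1)
    blob <- random_blob(h, w)
    defect <- random_rect(h, w, min_side = 8)
    got <- surface_band(blob, defect)
    expect_identical(got, brute_adjacent8(blob) & defect)
    expect_false(any(got & blob))
  }
})

test_that("zone partition defines 18 disjoint regions that tile the clipped band", {
  sp <- test_spec()
  m <- section_masks(sp)
  zp <- partition_zones(m$implant, m$defect, m$pixel_area_um2)
  expect_equal(nrow(zp$regions), 18)
  expect_equal(sort(zp$regions$region), 1:18)
  expect_true(all(zp$regions$pixels > 0))
  band <- build_band(m$implant, m$defect, m$pixel_area_um2)
  expect_equal(sum(zp$regions$pixels), sum(band))
  expect_identical(zp$labels > 0, band)
  # layer bins are half-open on the distance transform
  d <- implant_distance_um(m$implant, m$pixel_area_um2)
  for (li in seq_along(c("immediate", "intermediate", "remote"))) {
    ids <- zp$regions$region[zp$regions$layer ==
                               c("immediate", "intermediate", "remote")[li]]
    in_layer <- matrix(zp$labels %in% ids, nrow(zp$labels))
    expect_true(all(d[in_layer] >= (li - 1) * 100 & d[in_layer] < li * 100))
  }
})

test_that("region areas sum to band-and-defect area on random geometries", {
  set.seed(99)
  for (i in 1:50) {
    h <- sample(50:90, 1); w <- sample(60:110, 1)
    implant <- random_rect(h, w, min_side = 3)
    defect <- random_rect(h, w, min_side = 15)
    pa <- (17.43) * sample(3:12, 1)^2
    zp <- partition_zones(implant, defect, pa)
    band <- build_band(implant, defect, pa)
    expect_equal(sum(zp$regions$pixels), sum(band))
    expect_equal(sum(zp$regions$area_mm2), sum(band) * pa * 1e-6)
  }
})

test_that("an implant flush against a wall leaves regions defined but empty", {
  sp <- test_spec()
  m <- section_masks(sp)
  # clip the defect to the left half: right-end regions lose their pixels
  defect <- m$defect
  defect[, (ncol(defect) %/% 2):ncol(defect)] <- FALSE
  zp <- partition_zones(m$implant, defect, m$pixel_area_um2)
  expect_equal(nrow(zp$regions), 18)
  expect_true(any(zp$regions$pixels == 0))
  expect_error(partition_zones(matrix(FALSE, 9, 9), NULL, 17.43),
               "degenerate|empty")
})

test_that("the 1-px surface band lies inside the immediate layer", {
  sp <- test_spec()
  m <- section_masks(sp)
  sb <- surface_band(m$implant, m$defect)
  imm <- build_band(m$implant, m$defect, m$pixel_area_um2,
                    thickness_um = 100)
  expect_true(all(sb <= imm))
})
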