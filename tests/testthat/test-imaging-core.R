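# Morphology, PBR, BUM, BEI: contracts, frozen examples, and properties.

test_that("se_disk builds the closed discrete ball", {
  se0 <- se_disk(0)
  expect_equal(nrow(se0$offsets), 1L)
  expect_true(all(se0$offsets == 0L))
  se <- se_disk(3)
  expect_true(all(se$offsets[, 1]^2 + se$offsets[, 2]^2 <= 9))
  # symmetric under negation, contains origin
  key <- paste(se$offsets[, 1], se$offsets[, 2])
  neg <- paste(-se$offsets[, 1], -se$offsets[, 2])
  expect_setequal(key, neg)
  expect_true("0 0" %in% key)
  expect_error(se_disk(-1), "non-negative")
})

test_that("dilate/erode edge cases: empty mask, r = 0 identity, thin mask", {
  empty <- binary_mask(matrix(0L, 8, 8))
  expect_true(all(mask_dilate(empty, se_disk(3)) == 0L))
  m <- random_mask(12, 12)
  expect_true(all(mask_dilate(m, se_disk(0)) == m))
  expect_true(all(mask_erode(m, se_disk(0)) == m))
  # a 1-px-thin line has no translate of a radius-2 disk inside it
  thin <- binary_mask(rbind(matrix(0L, 5, 12), matrix(1L, 1, 12),
                            matrix(0L, 6, 12)))
  expect_true(all(mask_erode(thin, se_disk(2)) == 0L))
})

test_that("dilate/erode of a filled disk match the enumeration oracle", {
  m <- disk_mask(64, 10)
  se <- se_disk(3)
  expect_equal(unclass(mask_dilate(m, se)), oracle_dilate(unclass(m), se$offsets),
               ignore_attr = TRUE)
  expect_equal(unclass(mask_erode(m, se)), oracle_erode(unclass(m), se$offsets),
               ignore_attr = TRUE)
})

test_that("dilate/erode monotonicity and border-aware duality", {
  set.seed(11)
  for (case in 1:20) {
    r <- sample(1:3, 1)
    se <- se_disk(r)
    m2 <- random_mask()
    m1 <- binary_mask(unclass(m2) * matrix(as.integer(runif(256) < 0.7), 16))
    expect_true(all(mask_dilate(m1, se) <= mask_dilate(m2, se)))
    expect_true(all(mask_erode(m1, se) <= mask_erode(m2, se)))
    # erosion = complement of dilation of complement, away from borders
    comp <- binary_mask(1L - unclass(m2))
    dual <- 1L - unclass(mask_dilate(comp, se))
    er <- unclass(mask_erode(m2, se))
    interior <- (r + 1):(16 - r)
    expect_equal(er[interior, interior], dual[interior, interior])
  }
})

test_that("PBR is dilation minus erosion and covers the coarse boundary", {
  m <- disk_mask(40, 10)
  pbr <- potential_boundary_region(m, 3)
  se <- se_disk(3)
  d <- mask_dilate(m, se); e <- mask_erode(m, se)
  expect_equal(sum(pbr), sum(d) - sum(e))
  expect_true(all(unclass(pbr) == unclass(d) * (1L - unclass(e))))
  # every pixel with an opposite-valued 4-neighbour lies in the band
  mm <- unclass(m)
  for (i in 2:39) for (j in 2:39) {
    if (mm[i, j] == 1L &&
        min(mm[i - 1, j], mm[i + 1, j], mm[i, j - 1], mm[i, j + 1]) == 0L)
      expect_equal(pbr[i, j], 1L)
  }
})

test_that("PBR of a full-frame mask is the border band; empty mask warns", {
  full <- binary_mask(matrix(1L, 20, 20))
  pbr <- potential_boundary_region(full, 3)
  se <- se_disk(3)
  expect_equal(unclass(pbr),
               oracle_dilate(unclass(full), se$offsets) *
                 (1L - oracle_erode(unclass(full), se$offsets)),
               ignore_attr = TRUE)
  expect_true(all(pbr[4:17, 4:17] == 0L))  # deep interior survives erosion
  expect_true(all(pbr[1, ] == 1L))
  expect_warning(p0 <- potential_boundary_region(binary_mask(matrix(0L, 8, 8)), 2),
                 "empty")
  expect_true(all(p0 == 0L))
})

test_that("Gaussian kernel: odd window, unit sum, SD = r", {
  k4 <- uglseg:::gaussian_kernel(4)
  expect_equal(dim(k4), c(5, 5))  # even window widened to odd
  expect_equal(sum(k4), 1)
  k3 <- uglseg:::gaussian_kernel(3)
  expect_equal(dim(k3), c(3, 3))
  expect_equal(k3[1, 1] / k3[2, 2], exp(-2 / (2 * 9)))
})

test_that("BUM: normalization, single-pixel stamp, annulus symmetry", {
  # all-ones PBR stays 1 everywhere under reflect borders
  ones <- binary_mask(matrix(1L, 16, 16))
  expect_equal(boundary_uncertainty_map(ones, 5), matrix(1, 16, 16))
  # single pixel at the centre reproduces the kernel
  single <- points_mask(17, cbind(9, 9))
  bum <- boundary_uncertainty_map(single, 3)
  expect_equal(bum[8:10, 8:10], uglseg:::gaussian_kernel(3))
  expect_equal(sum(bum), 1)
  # annular PBR from a centred disk: radially symmetric up to the grid,
  # maximum attained on the band
  pbr <- potential_boundary_region(disk_mask(41, 10), 3)
  b2 <- boundary_uncertainty_map(pbr, 3)
  expect_equal(b2, b2[41:1, ], ignore_attr = TRUE)        # mirror symmetry
  expect_equal(b2, t(b2), ignore_attr = TRUE)             # transpose symmetry
  expect_equal(max(b2), max(b2[pbr == 1L]))
})

test_that("BUM equals the dense convolution oracle on random PBRs", {
  set.seed(7)
  for (case in 1:25) {
    r <- sample(1:4, 1)
    pbr <- random_mask(16, 16, p = 0.3)
    got <- boundary_uncertainty_map(pbr, r)
    want <- oracle_conv2_reflect(matrix(as.numeric(pbr), 16),
                                 uglseg:::gaussian_kernel(r))
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1))
  }
  # kernel mass is conserved for PBRs that stay clear of the borders
  for (case in 1:10) {
    r <- sample(1:4, 1)
    inner <- matrix(0L, 16, 16)
    inner[4:13, 4:13] <- matrix(as.integer(runif(100) < 0.3), 10)
    pbr <- binary_mask(inner)
    expect_equal(sum(boundary_uncertainty_map(pbr, r)), sum(pbr),
                 tolerance = 1e-9)
  }
})

test_that("BEI is the elementwise product, broadcasting over channels", {
  set.seed(3)
  img <- matrix(runif(256), 16)
  ones <- binary_mask(matrix(1L, 16, 16))
  expect_equal(background_excluded_image(ones, img), img)
  zero <- binary_mask(matrix(0L, 16, 16))
  expect_true(all(background_excluded_image(zero, img) == 0))
  pbr <- random_mask(16, 16)
  expect_equal(background_excluded_image(pbr, img),
               img * as.numeric(unclass(pbr)))
  rgb <- array(runif(16 * 16 * 3), c(16, 16, 3))
  bei <- background_excluded_image(pbr, rgb)
  for (ch in 1:3)
    expect_equal(bei[, , ch], rgb[, , ch] * matrix(as.numeric(pbr), 16))
  expect_error(background_excluded_image(pbr, matrix(0, 8, 8)), "shape")
})

test_that("build_uncertainty_bundle composes the three operations", {
  set.seed(5)
  img <- matrix(runif(64 * 64), 64)
  coarse <- disk_mask(64, 12)
  b <- build_uncertainty_bundle(coarse, img, r_m = 3)
  expect_s3_class(b, "uncertainty_bundle")
  expect_equal(unclass(b$pbr),
               unclass(potential_boundary_region(coarse, 3)), ignore_attr = TRUE)
  expect_equal(b$bum, boundary_uncertainty_map(b$pbr, 3))
  expect_equal(b$bei, background_excluded_image(b$pbr, img))
  expect_true(all(b$bei[b$pbr == 0L] == 0))
  # large radius as used for real optic-cup patches: structural checks only
  big <- build_uncertainty_bundle(disk_mask(64, 12), img, r_m = 25)
  expect_true(sum(big$pbr) > sum(b$pbr))
  expect_true(all(big$bum >= 0 & big$bum <= 1))
  expect_warning(empty <- build_uncertainty_bundle(
    binary_mask(matrix(0L, 16, 16)), matrix(0.5, 16, 16), 2), "empty")
  expect_true(all(empty$pbr == 0L) && all(empty$bum == 0) && all(empty$bei == 0))
})
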