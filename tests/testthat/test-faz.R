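test_that("circularity is near 1 for disks and near pi/4 for squares", {
  disk <- roi_mask(make_disk(121, 40))
  fm <- faz_metrics(disk, 3 / 245)
  expect_gte(fm$circularity, 0.95)
  expect_lte(fm$circularity, 1.02)
  for (side in c(60, 80)) {
    sq <- roi_mask(make_square(side + 40, side))
    fs <- faz_metrics(sq, 3 / 245)
    expect_lt(abs(fs$circularity - pi / 4), 0.03)
  }
})

test_that("disk area matches the closed form and circularity is recomputable", {
  s <- 3 / 245
  disk <- roi_mask(make_disk(121, 40))
  fm <- faz_metrics(disk, s)
  expect_lt(abs(fm$area_mm2 - pi * 40^2 * s^2) / (pi * 40^2 * s^2), 0.02)
  expect_equal(fm$circularity,
               4 * pi * fm$area_mm2 / fm$perimeter_mm^2)
})

test_that("the disk attains the maximal circularity among equal-area shapes", {
  s <- 3 / 245
  shapes <- list(
    disk = make_disk(131, 40),
    square = make_square(131, 71),            # 71^2 ~ pi*40^2
    ellipse = make_ellipse(131, 57, 28.5),    # 2:1, ~same area
    cross = make_cross(131, 45, 29))
  circ <- vapply(shapes, function(m)
    faz_metrics(roi_mask(m), s)$circularity, numeric(1))
  areas <- vapply(shapes, sum, numeric(1))
  expect_true(all(abs(areas / areas["disk"] - 1) < 0.15))  # comparable areas
  expect_true(all(circ["disk"] >= circ[-1]))
})

test_that("multi-component masks are rejected", {
  m <- matrix(0, 50, 50); m[5:10, 5:10] <- 1; m[30:35, 30:35] <- 1
  expect_error(faz_metrics(roi_mask(m)), "components")
})

test_that("FAZ detection recovers the generated avascular zone", {
  gen <- generate_angiogram(angiogram_params(rng_seed = 42))
  slab <- binarize_angiogram(gen$image, "otsu")
  fz <- detect_faz(slab)
  s <- slab$pixel_spacing_mm
  truth_area <- sum(gen$truth$faz_mask$pixels) * s^2
  det_area <- sum(fz$pixels) * s^2
  expect_lt(abs(det_area - truth_area) / truth_area, 0.10)
})

test_that("degenerate slabs behave as specified in FAZ detection", {
  empty <- binary_slab(matrix(0, 64, 64))
  fz <- detect_faz(empty)
  expect_equal(sum(fz$pixels), 64 * 64)  # whole image is one background zone
  full <- binary_slab(matrix(1, 64, 64))
  expect_error(detect_faz(full), "no avascular zone")
})

test_that("an off-center foreground pocket still finds a nearby seed", {
  m <- matrix(1, 64, 64)
  m[30:40, 36:45] <- 0  # background pocket near but not at the center
  fz <- detect_faz(binary_slab(m), closing_radius_px = 0)
  expect_gte(sum(fz$pixels), 100)
})
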