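test_that("perfusion density is the slab mean over the region of interest", {
  ones <- binary_slab(matrix(1, 64, 64))
  expect_equal(perfusion_density(ones), 1)
  checker <- binary_slab(outer(1:64, 1:64, function(i, j) (i + j) %% 2))
  expect_equal(perfusion_density(checker), 0.5)
  right <- binary_slab(cbind(matrix(0, 64, 32), matrix(1, 64, 32)))
  left_roi <- roi_mask(cbind(matrix(1, 64, 32), matrix(0, 64, 32)))
  expect_equal(perfusion_density(right, left_roi), 0)
})

test_that("roi geometry mismatches and empty rois are rejected", {
  slab <- binary_slab(matrix(0, 20, 20))
  expect_error(perfusion_density(slab, roi_mask(matrix(1, 10, 10))), "geometry")
  expect_error(roi_mask(matrix(0, 20, 20)), "at least one")
})

test_that("vessel density follows the skeleton-mean scaling definition", {
  empty <- skeleton_slab(matrix(0, 245, 245))
  expect_equal(vessel_density(empty), 0)
  # one full-width 1-px trace: 3 mm of vessel in 9 mm^2
  line <- matrix(0, 245, 245); line[123, ] <- 1
  expect_equal(vessel_density(skeleton_slab(line)), 1 / 3)
  # alternating full rows: identity VD = mean / spacing, exactly
  alt <- matrix(0, 245, 245); alt[seq(1, 245, by = 2), ] <- 1
  sk <- skeleton_slab(alt)
  expect_identical(vessel_density(sk) * sk$pixel_spacing_mm, mean(sk$pixels))
})

test_that("density invariants hold on generated skeletons", {
  gen <- generate_angiogram(angiogram_params(rng_seed = 77), n_px = 171)
  slab <- gen$truth$mask
  sk <- skeletonize_slab(slab)
  # scaling identity, exact
  expect_identical(vessel_density(sk) * sk$pixel_spacing_mm, mean(sk$pixels))
  # bounds
  expect_lte(perfusion_density(slab), 1)
  expect_lte(vessel_density(sk), 1 / sk$pixel_spacing_mm)
  # skeleton subset: VD <= PD / spacing
  expect_lte(vessel_density(sk), perfusion_density(slab) / slab$pixel_spacing_mm)
})

test_that("full-roi densities are invariant to 90-degree rotation and flips", {
  gen <- generate_angiogram(angiogram_params(rng_seed = 78), n_px = 145)
  slab <- gen$truth$mask
  sk <- skeletonize_slab(slab)
  rot <- function(m) t(m)[, nrow(m):1]
  expect_equal(perfusion_density(binary_slab(rot(slab$pixels), slab$pixel_spacing_mm)),
               perfusion_density(slab))
  expect_equal(vessel_density(skeleton_slab(rot(sk$pixels), sk$pixel_spacing_mm)),
               vessel_density(sk))
})

test_that("the same network rasterized at 245 and 490 px gives VD within 10%", {
  gen <- generate_angiogram(angiogram_params(rng_seed = 5))
  net <- gen$truth$network
  vds <- sapply(c(245, 490), function(n) {
    ras <- rasterize_network(net, n)
    vessel_density(skeletonize_slab(binary_slab(ras$mask, 3 / n)))
  })
  expect_lt(abs(vds[1] - vds[2]) / vds[1], 0.10)
})
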