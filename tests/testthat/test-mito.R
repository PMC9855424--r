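# Mitochondrial morphometry: generator truth, segmentation,
# skeletonization, branch statistics.

test_that("single straight segment: 1 individual, 0 networks", {
  img <- make_mito_image(list(c(5, 10, 34, 10)), thickness_px = 3)
  th <- synthetic_truth(img)$truth
  expect_equal(th$n_individuals, 1L)
  expect_equal(th$n_networks, 0L)
  expect_equal(th$total_branch_length, 29)
  st <- skeleton_stats(segment_mitochondria(img))
  expect_equal(st$n_individuals, 1L)
  expect_equal(st$n_networks, 0L)
  # thinning erodes the dilated bar's rounded caps by about a pixel per
  # end, so the measured centerline is slightly shorter than the layout
  expect_gte(st$mean_branch_length, 26)
  expect_lte(st$mean_branch_length, 30)
})

test_that("H layout: one network with five branches and two junctions", {
  img <- make_mito_image(list(c(5, 5, 5, 25), c(15, 5, 15, 25),
                              c(5, 15, 15, 15)), thickness_px = 3)
  th <- synthetic_truth(img)$truth
  expect_equal(th$n_networks, 1L)
  expect_equal(th$n_individuals, 0L)
  expect_equal(th$n_branches, 5L)
  st <- skeleton_stats(segment_mitochondria(img))
  expect_equal(st$n_networks, 1L)
  expect_gte(st$mean_branches_per_network, 4)   # +-1: junction clustering
  expect_lte(st$mean_branches_per_network, 6)
  expect_gte(st$n_junctions, 2)
})

test_that("two disjoint bars count as two individuals", {
  img <- make_mito_image(list(c(2, 2, 20, 2), c(2, 10, 20, 10)),
                         thickness_px = 3)
  st <- skeleton_stats(segment_mitochondria(img))
  expect_equal(st$n_individuals, 2L)
  expect_equal(st$n_networks, 0L)
})

test_that("layout validation rejects degenerate inputs", {
  expect_error(make_mito_image(list()), "empty layout")
  # X crossing: interior-to-interior intersection
  expect_error(make_mito_image(list(c(0, 0, 20, 20), c(0, 20, 20, 0))),
               "ambiguous")
  # collinear overlap
  expect_error(make_mito_image(list(c(0, 5, 20, 5), c(10, 5, 30, 5))),
               "ambiguous")
})

test_that("segmentation recovers a two-level image and flags empties", {
  img <- matrix(0, 30, 30)
  img[10:20, 5:25] <- 100
  mask <- segment_mitochondria(img)
  # the 3x3 median pre-filter clips the four single-pixel corners of the
  # rectangle; everything else must match exactly, with no false positives
  expect_length(setdiff(which(mask), which(img == 100)), 0)
  missing <- setdiff(which(img == 100), which(mask))
  corner_idx <- vapply(list(c(10, 5), c(20, 5), c(10, 25), c(20, 25)),
                       function(rc) (rc[2] - 1) * nrow(img) + rc[1],
                       numeric(1))
  expect_true(all(missing %in% corner_idx))
  flat <- matrix(0, 10, 10)
  m0 <- segment_mitochondria(flat)
  expect_true(isTRUE(attr(m0, "no_signal")))
  expect_false(any(m0))
})

test_that("mask footprint tracks the dilated-skeleton truth area", {
  img <- make_mito_image(list(c(5, 5, 5, 25), c(15, 5, 15, 25),
                              c(5, 15, 15, 15)), thickness_px = 3,
                         blur_sigma_px = 0.8, noise_sigma = 3, seed = 5)
  th <- synthetic_truth(img)$truth
  mask <- segment_mitochondria(img)
  expect_lt(abs(sum(mask) - th$tube_area_px) / th$tube_area_px, 0.15)
})

test_that("skeleton classification matches the exhaustive oracle", {
  shapes <- list(
    {m <- matrix(FALSE, 12, 12); m[6, 2:11] <- TRUE; m},          # line
    {m <- matrix(FALSE, 15, 15); m[8, 2:14] <- TRUE; m[2:14, 8] <- TRUE; m},
    {m <- matrix(FALSE, 14, 14); for (i in 2:12) m[i, i] <- TRUE; m},
    {m <- matrix(FALSE, 16, 20); m[4, 3:17] <- TRUE; m[4:12, 10] <- TRUE
     m[12, 5:15] <- TRUE; m},
    {m <- matrix(FALSE, 10, 10); m[5, 5] <- TRUE; m})             # point
  for (skel in shapes) {
    expect_identical(myoquant:::classify_skeleton(skel),
                     classify_oracle(skel))
  }
})

test_that("skeleton stats are invariant to 90-degree rotation and flips", {
  img <- make_mito_image(list(c(5, 5, 5, 25), c(15, 5, 15, 25),
                              c(5, 15, 15, 15)), thickness_px = 3)
  mask <- segment_mitochondria(img)
  st0 <- skeleton_stats(mask)
  variants <- list(t(mask),
                   mask[rev(seq_len(nrow(mask))), ],
                   mask[, rev(seq_len(ncol(mask)))])
  for (m in variants) {
    st <- skeleton_stats(m)
    expect_equal(st$n_individuals, st0$n_individuals)
    expect_equal(st$n_networks, st0$n_networks)
    expect_equal(st$n_branches, st0$n_branches)
    expect_equal(st$total_branch_length, st0$total_branch_length)
    expect_equal(st$footprint, st0$footprint)
  }
})

test_that("empty mask yields zeroed flagged stats", {
  st <- skeleton_stats(matrix(FALSE, 10, 10))
  expect_true(st$empty)
  expect_equal(st$n_individuals, 0L)
  expect_equal(st$total_branch_length, 0)
})

test_that("pixel calibration scales lengths and footprint", {
  img <- make_mito_image(list(c(5, 10, 34, 10)), thickness_px = 3)
  mask <- segment_mitochondria(img)
  st_px <- skeleton_stats(mask)
  st_um <- skeleton_stats(mask, pixel_um = 0.2)
  expect_equal(st_um$total_branch_length, 0.2 * st_px$total_branch_length)
  expect_equal(st_um$footprint, 0.04 * st_px$footprint)
  expect_equal(st_um$units, "um")
})
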