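test_that("mask_volume converts voxel counts through anisotropic spacing", {
  expect_equal(mask_volume(block_mask(1000, dim = c(10, 10, 10))), 1.0)
  expect_equal(mask_volume(block_mask(0)), 0.0)
  # 54 voxels at 0.86 x 0.86 x 2.5 mm: voxel volume 1.849 mm^3
  m <- block_mask(54, dim = c(10, 10, 10), spacing = c(0.86, 0.86, 2.5))
  expect_equal(mask_volume(m), 54 * 0.86 * 0.86 * 2.5 / 1000)
  expect_equal(mask_volume(m), 0.099846)
})

test_that("dice and non-overlap match hand-computed set arithmetic", {
  # |A| = 100, |B| = 60, |A n B| = 40 (B = voxels 61..120 of A's order)
  a <- block_mask(100, dim = c(10, 10, 2))
  b <- block_mask(60, dim = c(10, 10, 2), offset = 60)
  expect_equal(dice_coefficient(a, b), 2 * 40 / 160)
  expect_equal(non_overlap_volume(a, b), 80 * 1 / 1000)

  # same counts at spacing (1, 1, 2.5): dice unchanged, volume scales
  a2 <- block_mask(100, dim = c(10, 10, 2), spacing = c(1, 1, 2.5))
  b2 <- block_mask(60, dim = c(10, 10, 2), spacing = c(1, 1, 2.5), offset = 60)
  expect_equal(dice_coefficient(a2, b2), 0.5)
  expect_equal(non_overlap_volume(a2, b2), 80 * 2.5 / 1000)

  cmp <- compare_pair(a, b)
  expect_equal(cmp$dice, 0.5)
  expect_equal(cmp$non_overlap_volume, 0.08)
  expect_equal(cmp$mean_volume, (0.1 + 0.06) / 2)
  expect_equal(cmp$volume_intersection, 0.04)
})

test_that("identical, disjoint and one-empty pairs hit the boundary values", {
  a <- ball_mask(4)
  expect_equal(dice_coefficient(a, a), 1.0)
  expect_equal(non_overlap_volume(a, a), 0.0)
  b <- ball_mask(3, centre = c(18, 18, 18))
  expect_equal(dice_coefficient(a, b), 0.0)
  expect_equal(non_overlap_volume(a, b), mask_volume(a) + mask_volume(b))
  empty <- block_mask(0, dim = c(24, 24, 24))
  expect_equal(dice_coefficient(a, empty), 0.0)
  expect_error(dice_coefficient(empty, empty), "two empty")
  expect_equal(non_overlap_volume(empty, empty), 0.0)
  expect_error(compare_pair(empty, empty), "two empty")
})

test_that("pair metrics satisfy symmetry, bounds and the algebraic identity", {
  withr::local_seed(42)
  for (i in 1:25) {
    a <- random_mask(p = runif(1, 0.05, 0.6), spacing = c(0.98, 0.98, 3))
    b <- random_mask(p = runif(1, 0.05, 0.6), spacing = c(0.98, 0.98, 3))
    if (sum(a$voxels) + sum(b$voxels) == 0) next
    d <- dice_coefficient(a, b)
    expect_identical(d, dice_coefficient(b, a))
    expect_identical(non_overlap_volume(a, b), non_overlap_volume(b, a))
    expect_gte(d, 0); expect_lte(d, 1)
    cmp <- compare_pair(a, b)
    # non_overlap = (|A| + |B|) (1 - dice); mean volume; intersection bound
    expect_equal(cmp$non_overlap_volume,
                 (cmp$volume_a + cmp$volume_b) * (1 - cmp$dice))
    expect_equal(cmp$mean_volume, (cmp$volume_a + cmp$volume_b) / 2)
    expect_lte(cmp$volume_intersection,
               min(cmp$volume_a, cmp$volume_b) + 1e-12)
    # spacing invariance of dice
    a5 <- label_mask(a$voxels, a$spacing * 2)
    b5 <- label_mask(b$voxels, b$spacing * 2)
    expect_equal(dice_coefficient(a5, b5), d)
    expect_equal(non_overlap_volume(a5, b5), 8 * cmp$non_overlap_volume)
  }
})

test_that("count_components follows 26-connectivity", {
  expect_identical(count_components(block_mask(0)), 0L)
  expect_identical(count_components(ball_mask(5)), 1L)

  two <- array(FALSE, c(12, 12, 12))
  two[2:4, 2:4, 2:4] <- TRUE
  two[8:10, 8:10, 8:10] <- TRUE  # separated by >= 2 empty voxels
  expect_identical(count_components(label_mask(two, c(1, 1, 1))), 2L)

  # corner contact counts as connected under 26-connectivity
  diag2 <- array(FALSE, c(4, 4, 4))
  diag2[1, 1, 1] <- TRUE
  diag2[2, 2, 2] <- TRUE
  expect_identical(count_components(label_mask(diag2, c(1, 1, 1))), 1L)

  # scattered singletons: each isolated voxel is its own component
  sparse <- array(FALSE, c(9, 9, 9))
  sparse[c(1, 365, 729)] <- TRUE
  expect_identical(count_components(label_mask(sparse, c(1, 1, 1))), 3L)
})

test_that("merge_lesions_per_femur takes the voxelwise union", {
  a <- ball_mask(3, centre = c(6, 6, 6))
  expect_identical(merge_lesions_per_femur(list(a))$voxels, a$voxels)
  b <- ball_mask(2, centre = c(18, 18, 18))
  u <- merge_lesions_per_femur(list(a, b))
  expect_identical(u$voxels, a$voxels | b$voxels)
  expect_identical(sum(u$voxels), sum(a$voxels) + sum(b$voxels))
  bad <- ball_mask(2, dim = c(20, 20, 20))
  expect_error(merge_lesions_per_femur(list(a, bad)), "axis")
})
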