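test_that("dice handles the canonical cases", {
  a <- array(FALSE, c(4, 4, 4)); b <- a
  expect_equal(dice(a, b), 1.0)            # both empty: no disagreement
  a[1:2, 1:2, 1:2] <- TRUE
  expect_equal(dice(a, a), 1.0)
  b[3:4, 3:4, 3:4] <- TRUE
  expect_equal(dice(a, b), 0.0)
  # |a| = |b| = 8, overlap 4
  b <- array(FALSE, c(4, 4, 4)); b[1:2, 1:2, 2:3] <- TRUE
  expect_equal(dice(a, b), 0.5)
  expect_equal(dice(a, b), dice(b, a))
  expect_error(dice(a, array(FALSE, c(3, 3, 3))), "match")
})

test_that("hausdorff95 matches simple analytic cases", {
  a <- array(FALSE, c(8, 8, 8)); a[4, 4, 4] <- TRUE
  b <- array(FALSE, c(8, 8, 8)); b[5, 4, 4] <- TRUE
  expect_equal(hausdorff95(a, a, 0.6), 0)
  expect_equal(hausdorff95(a, b, 0.6), 0.6, tolerance = 1e-12)
  expect_warning(h <- hausdorff95(a, array(FALSE, c(8, 8, 8)), 1), "empty")
  expect_true(is.na(h))
})

test_that("dice and hausdorff95 agree with brute-force oracles", {
  set.seed(101)
  n_pairs <- 100
  for (i in seq_len(n_pairs)) {
    a <- random_mask(); b <- random_mask()
    if (!any(a) || !any(b)) next
    expect_identical(dice(a, b), oracle_dice(a, b))
    h <- hausdorff95(a, b, 0.7)
    expect_equal(h, oracle_h95(a, b, 0.7), tolerance = 1e-9)
    expect_lte(h, oracle_hmax(a, b, 0.7) + 1e-9)
  }
})

test_that("largest_component keeps the biggest component, ties by coordinate", {
  m <- array(FALSE, c(10, 10, 10))
  m[1:2, 1:5, 1] <- TRUE              # 10 voxels
  m[8:10, 9, 9] <- TRUE               # 3 voxels
  out <- largest_component(m)
  expect_equal(sum(out), 10)
  expect_true(all(which(out) %in% which(m)))
  expect_identical(largest_component(array(FALSE, c(3, 3, 3))),
                   array(FALSE, c(3, 3, 3)))
  # two 5-voxel components: the one containing (1,1,1) wins
  t2 <- array(FALSE, c(12, 12, 12))
  t2[1:5, 1, 1] <- TRUE
  t2[8:12, 8, 8] <- TRUE
  kept <- largest_component(t2)
  expect_true(kept[1, 1, 1])
  expect_false(kept[8, 8, 8])
  # connectivity matters: a diagonal touch is connected at 26 but not 6
  dg <- array(FALSE, c(4, 4, 4))
  dg[1, 1, 1] <- TRUE; dg[2, 2, 2] <- TRUE; dg[4, 4, 4] <- TRUE
  expect_equal(sum(largest_component(dg, 26)), 2)
  expect_equal(sum(largest_component(dg, 6)), 1)
})

test_that("volume differences are signed toward over-segmentation", {
  gt <- array(FALSE, c(6, 6, 6)); gt[2:4, 2:4, 2:4] <- TRUE  # 27 voxels
  expect_equal(unname(volume_differences(gt, gt)), c(0, 0))
  pred <- gt; pred[5, 2:4, 2:4] <- TRUE  # 36 voxels: overshoot by 1/3
  vd <- volume_differences(pred, gt)
  expect_equal(unname(vd), c(1 / 3, 1 / 3), tolerance = 1e-12)
  vd0 <- volume_differences(array(FALSE, c(6, 6, 6)), gt)
  expect_equal(unname(vd0), c(-1, 1))
  expect_error(volume_differences(pred, array(FALSE, c(6, 6, 6))), "empty")
})

test_that("largest-component post-processing cannot hurt dice and tames h95", {
  set.seed(7)
  for (rep in 1:5) {
    gt <- array(FALSE, c(16, 16, 16)); gt[4:8, 4:8, 4:8] <- TRUE
    pred <- gt
    # inject small spurious blobs far from the structure
    pred[14:15, 14, 14] <- TRUE
    pred[15, 2, 15] <- TRUE
    post <- largest_component(pred)
    expect_gte(dice(post, gt), dice(pred, gt))
    expect_lte(hausdorff95(post, gt, 1), hausdorff95(pred, gt, 1))
  }
})

test_that("dice is invariant under a shared axis permutation", {
  set.seed(11)
  a <- random_mask(); b <- random_mask()
  expect_equal(dice(a, b), dice(aperm(a, c(3, 1, 2)), aperm(b, c(3, 1, 2))))
})
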