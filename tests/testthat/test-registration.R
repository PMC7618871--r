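test_that("rigid_align identity is exact and round trips within tolerance", {
  s <- make_phantom(22, seed = 42, config = test_phantom_config(speckle_sd = 0.05))
  v0 <- rigid_align(s$image, rigid_transform())
  expect_equal(v0$data, s$image$data, tolerance = 1e-12)
  t <- rigid_transform(c(8, -6, 12), c(2.5, -1.5, 2))
  fwd <- rigid_align(s$image, t)
  back <- rigid_align(fwd, rt_invert(t))
  # interior round-trip error below 2% of the intensity range
  rng <- diff(range(s$image$data))
  interior <- s$brain_mask
  expect_lt(mean(abs(back$data[interior] - s$image$data[interior])) / rng,
            0.02)
})

test_that("a 90-degree rotation maps an axis-aligned box exactly", {
  d <- c(21, 21, 21)
  lab <- array(0L, d)
  lab[9:13, 7:15, 10:12] <- 1L   # 5 x 9 x 3 box about the centre
  lm <- labelmap(lab, spacing = 1)
  rot <- rigid_align(lm, rigid_transform(c(0, 0, 90)))
  # rotating about z by 90 degrees swaps the x/y extents
  w <- which(rot$data == 1L, arr.ind = TRUE)
  expect_equal(diff(range(w[, 1])) + 1, 9)
  expect_equal(diff(range(w[, 2])) + 1, 5)
  expect_equal(sum(rot$data == 1L), sum(lab == 1L))
})

test_that("demons recovers a pure translation", {
  s <- make_phantom(22, seed = 15, config = test_phantom_config(speckle_sd = 0.1))
  a <- s$image$data
  b <- array(0, dim(a))
  b[1:(dim(a)[1] - 4), , ] <- a[5:dim(a)[1], , ]  # content shifted by -4 in x
  reg <- demons_register(a, b, iters = c(40, 30, 15))
  # warped(v) = b(v + d(v)) and b(v) = a(v + 4), so d should be about -4 in x
  core <- s$brain_mask
  core[c(1:8, (dim(a)[1] - 8):dim(a)[1]), , ] <- FALSE
  med_dx <- median(reg$disp[, , , 1][core])
  expect_lt(abs(med_dx + 4), 1)
  expect_lt(abs(median(reg$disp[, , , 2][core])), 1)
})

test_that("field inversion composes to identity on the brain mask", {
  s <- fixture_phantom()
  d <- dim(s$image$data)
  disp <- array(0, c(d, 3))
  cg <- fetalsubcort:::coord_grids(d[1], 1)
  disp[, , , 1] <- 2.5 * exp(-(array(rep(cg$x, d[2] * d[3]), d))^2 / 200)
  inv <- invert_field(disp, mask = s$brain_mask)
  expect_lt(attr(inv, "fail_frac"), 0.01)
  comp <- fetalsubcort:::.compose_disp(disp, inv, d)
  expect_lt(max(abs(array(comp, c(d, 3))[, , , 1][s$brain_mask])), 0.1)
})

test_that("groupwise templates satisfy their contracts", {
  s <- fixture_phantom()
  # single input: template equals the input with a zero field
  gw1 <- groupwise_template(list(s$image))
  expect_identical(gw1$template$intensity, s$image$data)
  expect_true(all(gw1$fields[[1]]$forward == 0))
  # two identical inputs: template equals the input, fields ~ zero
  gw2 <- groupwise_template(list(s$image, s$image))
  expect_equal(gw2$template$intensity, s$image$data, tolerance = 1e-6)
  expect_lt(max(abs(gw2$fields[[1]]$forward)), 1e-6)
  expect_error(groupwise_template(list(
    s$image, volume3d(array(0, c(8, 8, 8))))), "grid")
})

test_that("groupwise recovers a translation between two members", {
  s <- make_phantom(22, seed = 21, config = test_phantom_config(speckle_sd = 0.05))
  a <- s$image$data
  b <- array(0, dim(a)); b[1:(dim(a)[1] - 4), , ] <- a[5:dim(a)[1], , ]
  gw <- groupwise_template(list(volume3d(a, 1.8), volume3d(b, 1.8)),
                           iters = 2, demons_iters = c(40, 30, 15))
  core <- s$brain_mask
  core[c(1:8, (dim(a)[1] - 8):dim(a)[1]), , ] <- FALSE
  d1 <- median(gw$fields[[1]]$forward[, , , 1][core])
  d2 <- median(gw$fields[[2]]$forward[, , , 1][core])
  # the two recovered x-displacements should differ by about 4 voxels
  expect_lt(abs(abs(d2 - d1) - 4), 1)
})

test_that("template intensity stays within the member intensity envelope", {
  set.seed(30)
  cfg <- test_phantom_config()
  vols <- lapply(1:3, function(i)
    make_phantom(21.5 + 0.2 * i, seed = 30 + i, config = cfg)$image)
  gw <- groupwise_template(vols, iters = 1, demons_iters = c(20, 10, 5))
  lo <- min(vapply(vols, function(v) min(v$data), 0))
  hi <- max(vapply(vols, function(v) max(v$data), 0))
  expect_gte(min(gw$template$intensity), lo - 1e-9)
  expect_lte(max(gw$template$intensity), hi + 1e-9)
})
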