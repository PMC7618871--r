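test_that("structure_volume converts voxel counts to cm^3", {
  lab <- array(0L, c(12, 12, 12))
  lab[1:10, 1:10, 1:10] <- 1L          # 1000 voxels
  expect_equal(structure_volume(lab, 1, spacing_mm = 1), 1.0)
  lab2 <- array(0L, c(10, 10, 10)); lab2[1:4, 1:5, 1:5] <- 4L  # 100 voxels
  expect_equal(structure_volume(lab2, 4, spacing_mm = 0.6), 0.0216)
  expect_warning(v0 <- structure_volume(lab2, 2, spacing_mm = 1), "absent")
  expect_equal(v0, 0)
  # post-processing removes spurious satellites before measuring
  lab3 <- lab2; lab3[10, 10, 10] <- 4L
  expect_equal(structure_volume(lab3, 4, spacing_mm = 1, post = TRUE), 0.1)
})

test_that("relative volume is a guarded ratio", {
  expect_equal(relative_volume(2, 100), 0.02)
  expect_equal(relative_volume(0, 100), 0)
  expect_equal(relative_volume(5, 5), 1)
  expect_error(relative_volume(1, 0), "positive")
})

test_that("whole-brain volume is recovered by affine mask registration", {
  s <- fixture_phantom()
  truth <- sum(s$brain_mask) * prod(s$image$spacing) / 1000
  v <- whole_brain_volume(s$image, s$brain_mask, ga = s$ga_weeks)
  expect_lt(abs(v / truth - 1), 0.05)
  # a voxelized sphere template recovers the analytic volume
  d <- c(24, 24, 24)
  cg <- fetalsubcort:::coord_grids(24, 1)
  X <- array(rep(cg$x, 576), d)
  Y <- array(rep(rep(cg$y, each = 24), 24), d)
  Z <- array(rep(cg$z, each = 576), d)
  r <- 7
  sph <- (X^2 + Y^2 + Z^2) <= r^2
  analytic <- 4 / 3 * pi * r^3 / 1000
  surface_layer <- 4 * pi * r^2 * 1 / 1000
  expect_lt(abs(sum(sph) / 1000 - analytic), surface_layer)
})

test_that("brain template selection uses a floor week below range", {
  tpl <- list(`21` = "w21", `22` = "w22", `25` = "w25")
  expect_identical(select_brain_template(18, tpl), "w21")
  expect_identical(select_brain_template(22.3, tpl), "w22")
  expect_identical(select_brain_template(26.9, tpl), "w25")
})

test_that("growth fits recover exact linear laws and gate the quadratic", {
  ga <- rep(seq(18, 26, length.out = 10), 2)
  v <- 0.1 + 0.025 * (ga - 18)
  rec <- data.frame(ga_weeks = ga, volume_cm3 = v,
                    model = rep(c("expert", "atlas"), each = 10),
                    structure = "LPVH")
  # summary() warns about the essentially perfect fit; that is the point
  fits <- suppressWarnings(fit_growth_curve(rec))
  for (f in fits) {
    expect_equal(f$degree, 1L)   # degenerate quadratic gate: not significant
    expect_equal(unname(f$coefficients), c(-0.35, 0.025), tolerance = 1e-9)
  }
  expect_error(fit_growth_curve(rec[rec$ga_weeks < 20, ]), "records|spread")
})

test_that("a strong quadratic is retained and recovered", {
  set.seed(31)
  ga <- rep(seq(18, 26, by = 0.5), 4)
  truth <- 0.5 + 0.1 * (ga - 18) + 0.05 * (ga - 18)^2
  rec <- data.frame(
    ga_weeks = c(ga, ga),
    volume_cm3 = c(truth + rnorm(length(ga), 0, 0.05),
                   1.1 * truth + rnorm(length(ga), 0, 0.05)),
    model = rep(c("expert", "atlas"), each = length(ga)), structure = "CB")
  fits <- fit_growth_curve(rec)
  expect_equal(fits$expert$degree, 2L)
  ct <- tidy.growth_fit(fits$expert)
  b2 <- ct[ct$term == "I(ga_weeks^2)", ]
  expect_lt(abs(b2$estimate - 0.05), 2.5 * b2$std.error)
})

test_that("the quadratic gate requires significance in both model tags", {
  set.seed(33)
  ga <- rep(seq(18, 26, by = 0.5), 3)
  quad <- 0.5 + 0.1 * (ga - 18) + 0.05 * (ga - 18)^2
  lin <- 0.5 + 0.5 * (ga - 18)
  rec <- data.frame(
    ga_weeks = c(ga, ga),
    volume_cm3 = c(quad + rnorm(length(ga), 0, 0.05),
                   lin + rnorm(length(ga), 0, 0.05)),
    model = rep(c("expert", "atlas"), each = length(ga)))
  fits <- fit_growth_curve(rec)
  expect_equal(fits$expert$degree, 1L)
  expect_equal(fits$atlas$degree, 1L)
})

test_that("prediction intervals have near-nominal coverage", {
  set.seed(35)
  cover <- 0
  n_draws <- 40
  for (i in seq_len(n_draws)) {
    ga <- runif(30, 18, 26)
    v <- 1 + 0.2 * (ga - 18) + rnorm(30, 0, 0.15)
    rec <- data.frame(ga_weeks = ga[-1], volume_cm3 = v[-1], model = "expert")
    f <- fit_growth_curve(rec)$expert
    pr <- predict(f, ga[1])
    cover <- cover + (v[1] >= pr$lwr && v[1] <= pr$upr)
  }
  expect_gte(cover / n_draws, 0.85)
})

test_that("proportionally biased model tags preserve residual signs", {
  # one network over-segmenting every volume by the same factor yields the
  # same above/below-the-curve pattern as the other
  set.seed(37)
  ga <- runif(30, 18, 26)
  v <- 0.5 + 0.1 * (ga - 18) + rnorm(30, 0, 0.08)
  rec <- data.frame(ga_weeks = rep(ga, 2), volume_cm3 = c(v, 1.25 * v),
                    model = rep(c("expert", "atlas"), each = 30))
  fits <- fit_growth_curve(rec)
  r_exp <- unname(residuals(fits$expert$fit))
  r_atl <- unname(residuals(fits$atlas$fit))
  expect_identical(sign(r_exp), sign(r_atl))
  expect_equal(unname(r_atl), unname(1.25 * r_exp), tolerance = 1e-9)
})

test_that("volume records are well-formed and relative volumes sum below 1", {
  s <- fixture_phantom()
  vb <- sum(s$brain_mask) * prod(s$image$spacing) / 1000
  rec <- suppressWarnings(
    volume_records(list(s$labels), s$ga_weeks, vb, "expert"))
  expect_equal(nrow(rec), 4)
  expect_true(all(rec$v_rel_brain >= 0 & rec$v_rel_brain < 1))
  expect_lt(sum(rec$v_rel_brain), 1)
  expect_identical(unique(rec$model), "expert")
})
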