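test_that("growth laws reproduce the calibrated endpoints", {
  laws <- default_growth_laws()
  expect_equal(growth_model(26, laws$LPVH), 0.3, tolerance = 1e-12)
  expect_equal(growth_model(18, laws$LPVH), 0.1, tolerance = 1e-12)
  expect_equal(growth_model(18, laws$CSPV), 0.01, tolerance = 1e-12)
  expect_equal(growth_model(26, laws$CSPV), 0.6, tolerance = 1e-12)
  # linear midpoint of a custom law
  lin <- growth_law("LPVH", "linear", c(0.1, 0.025))
  expect_equal(growth_model(22, lin), 0.2, tolerance = 1e-12)
  expect_error(growth_model(17, lin), "within")
  expect_error(growth_model(27.5, lin), "within")
})

test_that("default laws are positive and non-decreasing over 18-26 weeks", {
  laws <- default_growth_laws()
  gas <- seq(18, 26, by = 0.25)
  for (nm in names(laws)) {
    v <- vapply(gas, function(g) growth_model(g, laws[[nm]]), 0)
    expect_true(all(v > 0), info = nm)
    expect_true(all(diff(v) >= -1e-12), info = nm)
  }
  # brain-relative fractions match the calibration targets
  frac_cb <- vapply(gas, function(g)
    growth_model(g, laws$CB) / brain_reference_volume(g), 0)
  expect_true(all(frac_cb >= 0.015 & frac_cb <= 0.025))
  expect_gt(growth_model(18, laws$CP) / brain_reference_volume(18), 0.115)
  expect_lt(growth_model(27, laws$CP) / brain_reference_volume(27), 0.035)
})

test_that("phantom generation is deterministic and respects its invariants", {
  cfg <- test_phantom_config()
  a <- make_phantom(22, seed = 9, config = cfg)
  b <- make_phantom(22, seed = 9, config = cfg)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$labels$data, b$labels$data)
  # labels inside the brain mask; exactly the four structures present
  expect_true(all(a$labels$data[!a$brain_mask] == 0L))
  expect_setequal(sort(unique(as.integer(a$labels$data))), 0:4)
  # CP and LPVH only in the visible hemisphere (left = first-axis half)
  d <- dim(a$labels$data)
  occl <- a$labels$data[(d[1] %/% 2 + 1):d[1], , ]
  expect_false(any(occl %in% c(STRUCTURES[["CP"]], STRUCTURES[["LPVH"]])))
})

test_that("voxelized structure volumes match the growth laws", {
  s <- make_phantom(22, seed = 1)  # 64^3 desk default
  vox <- prod(s$image$spacing) / 1000
  brain_cm3 <- brain_reference_volume(22) * s$config$brain_scale
  for (nm in names(STRUCTURES)) {
    v <- sum(s$labels$data == STRUCTURES[[nm]]) * vox
    expect_lt(abs(v / growth_model(22, s$config$laws[[nm]], brain_cm3) - 1),
              0.1)
  }
})

test_that("shadow darkens the occluded hemisphere; strength 0 equalizes", {
  cfg <- test_phantom_config(speckle_sd = 0)
  s <- make_phantom(22, seed = 3, config = cfg, visible_hemisphere = "left")
  d <- dim(s$image$data)
  left <- s$image$data[seq_len(d[1] %/% 2), , ]
  right <- s$image$data[(d[1] %/% 2 + 1):d[1], , ]
  expect_gt(mean(left), mean(right))
  cfg0 <- test_phantom_config(speckle_sd = 0, shadow_strength = 0)
  s0 <- make_phantom(22, seed = 3, config = cfg0)
  l0 <- s0$image$data[seq_len(d[1] %/% 2), , ]
  r0 <- s0$image$data[(d[1] %/% 2 + 1):d[1], , ]
  expect_lt(abs(mean(l0) - mean(r0)) / mean(l0), 0.02)
})

test_that("with all corruptions off the level sets equal the label regions", {
  s <- fixture_clean_phantom()
  iv <- c(CP = 0.85, LPVH = 0.10, CSPV = 0.15, CB = 0.75)
  expect_lte(length(unique(as.numeric(s$image$data))), 6)
  for (nm in names(iv))
    expect_identical(abs(s$image$data - iv[[nm]]) < 1e-12,
                     array(s$labels$data == STRUCTURES[[nm]],
                           dim(s$labels$data)))
})

test_that("speckle is multiplicative with unit mean", {
  cfg <- test_phantom_config(shadow_strength = 0, psf_sigma_vox = 0,
                             mirror_structures = FALSE)
  clean <- make_phantom(22, seed = 5, config = test_phantom_config(
    speckle_sd = 0, shadow_strength = 0, psf_sigma_vox = 0,
    mirror_structures = FALSE))
  noisy <- make_phantom(22, seed = 5, config = cfg)
  ratio <- noisy$image$data / clean$image$data
  expect_lt(abs(mean(ratio) - 1), 0.01)
  expect_gt(sd(ratio), 0.2)
})

test_that("cohorts cover the GA range with balanced hemispheres", {
  cfg <- test_phantom_config()
  co <- make_cohort(9, c(18, 26), seed = 2, config = cfg)
  expect_equal(vapply(co, function(s) s$ga_weeks, 0), 18:26)
  co2 <- make_cohort(9, c(18, 26), seed = 2, config = cfg)
  expect_identical(cohort_manifest(co), cohort_manifest(co2))
  # binomial bound at p = 0.5 for n = 100 (check hemisphere draws only)
  set.seed(2)
  hemi <- ifelse(runif(100) < 0.5, "left", "right")
  frac <- mean(hemi == "right")
  expect_gte(frac, 0.35)
  expect_lte(frac, 0.65)
  expect_error(make_cohort(3, c(26, 18), seed = 1), "range")
})

test_that("rigid transforms compose with their inverse to identity", {
  t <- rigid_transform(c(10, -5, 20), c(3, -2, 1))
  m <- fetalsubcort:::rt_as_matrix(t)
  inv <- rt_invert(t)
  expect_equal(inv$R %*% m$R, diag(3), tolerance = 1e-12)
  expect_equal(as.numeric(inv$R %*% m$trans + inv$trans), c(0, 0, 0),
               tolerance = 1e-12)
})
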