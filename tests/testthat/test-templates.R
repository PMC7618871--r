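make_labelled_template <- function() {
  s <- fixture_clean_phantom()
  brain_template(s$image$data, labels = s$labels$data, ga_bin = 22,
                 hemisphere = "fused", spacing = s$image$spacing)
}

zero_df <- function(d, id = 1) {
  structure(list(forward = fetalsubcort:::zero_field(d),
                 inverse = fetalsubcort:::zero_field(d), source_id = id),
            class = "deformation_field")
}

test_that("fuse_hemispheres cuts at the central sagittal plane", {
  d <- c(16L, 16L, 16L)
  left <- brain_template(array(1, d), hemisphere = "left")
  right <- brain_template(array(2, d), hemisphere = "right")
  fused <- fuse_hemispheres(left, right)
  expect_equal(fused$hemisphere, "fused")
  expect_identical(dim(fused$intensity), d)
  expect_setequal(unique(as.numeric(fused$intensity)), c(1, 2))
  expect_true(all(fused$intensity[1:8, , ] == 1))
  expect_true(all(fused$intensity[9:16, , ] == 2))
  # a mirror pair fuses to a mirror-symmetric template
  s <- fixture_phantom()
  l <- brain_template(s$image$data, hemisphere = "left")
  r <- mirror_template(l, "right")
  f <- fuse_hemispheres(l, r)
  expect_equal(f$intensity, f$intensity[dim(f$intensity)[1]:1, , ],
               tolerance = 1e-12)
  expect_error(fuse_hemispheres(l, brain_template(array(0, c(8, 8, 8)))),
               "grid")
})

test_that("propagate_labels through identity and translation fields", {
  tpl <- make_labelled_template()
  d <- dim(tpl$intensity)
  out <- propagate_labels(tpl, list(zero_df(d)))[[1]]
  expect_identical(out$data, tpl$labels)
  expect_equal(out$provenance, "atlas")
  # a +2-voxel inverse displacement along x shifts labels by -2 in x
  f <- zero_df(d)
  f$inverse[, , , 1] <- 2
  shifted <- propagate_labels(tpl, list(f))[[1]]
  expect_identical(shifted$data[1:(d[1] - 2), , ], tpl$labels[3:d[1], , ])
  # voxels sampling outside the grid become background
  expect_true(all(shifted$data[(d[1] - 1):d[1], , ] == 0L))
  f$inverse <- NULL
  expect_error(propagate_labels(tpl, list(f)), "inverse")
  expect_error(propagate_labels(brain_template(tpl$intensity),
                                list(zero_df(d))), "labels")
})

test_that("propagated label classes are a subset of the template's", {
  tpl <- make_labelled_template()
  d <- dim(tpl$intensity)
  set.seed(4)
  f <- zero_df(d)
  f$inverse <- f$inverse + array(rnorm(prod(d) * 3, sd = 1.5), c(d, 3))
  out <- propagate_labels(tpl, list(f))[[1]]
  expect_true(all(unique(as.integer(out$data)) %in%
                    unique(as.integer(tpl$labels))))
})

test_that("annotate_template majority vote is exact for identity fields", {
  s <- fixture_clean_phantom()
  d <- dim(s$labels$data)
  tpl <- brain_template(s$image$data, spacing = s$image$spacing)
  # two identical voters and one dissenting empty labelmap
  empty <- labelmap(array(0L, d), spacing = s$image$spacing)
  tpl <- annotate_template(tpl, list(zero_df(d), zero_df(d), zero_df(d)),
                           list(s$labels, s$labels, empty))
  expect_identical(tpl$labels, array(as.integer(s$labels$data), d))
})

test_that("ga_week_bin rounds halves down", {
  expect_identical(ga_week_bin(c(20.4, 20.5, 20.6, 21.5)),
                   c(20L, 20L, 21L, 21L))
})
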