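test_that("histogram equalization flattens intensities and fixes degeneracy", {
  const <- array(3.7, c(8, 8, 8))
  eq <- hist_equalize(const)
  expect_equal(length(unique(as.numeric(eq))), 1)   # single level remains
  s <- fixture_phantom()
  eq2 <- hist_equalize(s$image$data)
  expect_gte(min(eq2), 0); expect_lte(max(eq2), 1)
  # Kolmogorov distance to uniform below 0.05
  ks <- suppressWarnings(ks.test(as.numeric(eq2), "punif"))$statistic
  expect_lt(unname(ks), 0.05)
})

test_that("prepare_crops mirrors right-hemisphere samples and crops to bbox", {
  cfg <- test_phantom_config()
  sl <- make_phantom(22, seed = 61, config = cfg, visible_hemisphere = "left",
                     lpvh_mode = 1)
  sr <- make_phantom(22, seed = 61, config = cfg, visible_hemisphere = "right",
                     lpvh_mode = 1)
  bbox <- lpvh_bbox(list(sl, sr))
  crops <- prepare_crops(list(sl, sr), bbox)
  expect_equal(dim(crops[[1]]), unname(bbox$hi - bbox$lo + 1),
               ignore_attr = TRUE)
  expect_identical(dim(crops[[1]]), dim(crops[[2]]))
  # after mirroring, both LPVH masks land in the same region
  expect_gt(dice(attr(crops[[1]], "lpvh"), attr(crops[[2]], "lpvh")), 0.3)
  expect_error(prepare_crops(list(sl), list(lo = c(0, 1, 1), hi = c(5, 5, 5))),
               "bbox")
})

test_that("pairwise SSD is symmetric with a zero diagonal and exact", {
  a <- array(runif(6^3), c(6, 6, 6))
  roi <- array(TRUE, c(6, 6, 6))
  D0 <- pairwise_ssd(list(a, a, a), roi, register = FALSE)
  expect_true(all(D0 == 0))
  # constant offset c on an ROI of m voxels, registration disabled
  b <- a + 0.3
  roi2 <- array(FALSE, c(6, 6, 6)); roi2[2:4, 2:4, 2:4] <- TRUE
  D <- pairwise_ssd(list(a, b), roi2, register = FALSE)
  expect_equal(D[1, 2], 27 * 0.3^2, tolerance = 1e-12)
  expect_identical(unclass(D), t(unclass(D)))
  expect_error(pairwise_ssd(list(a, b), array(FALSE, c(6, 6, 6))), "region")
})

test_that("k_medoids recovers planted blocks and matches brute force", {
  # two blocks of 3 with tight within- and loose between-distances
  D <- matrix(10, 6, 6)
  D[1:3, 1:3] <- 1; D[4:6, 4:6] <- 1
  diag(D) <- 0
  cl <- k_medoids(D, k = 2, restarts = 20, min_size = 3, seed = 7)
  grp <- split(seq_len(6), cl$assignments)
  expect_setequal(lapply(grp, sort), list(1:3, 4:6))
  expect_equal(cl$cost, oracle_kmedoids_cost(D, 2))
  # k = 1 on a matrix with unique row sums: medoid = argmin of row sums
  set.seed(40)
  Du <- as.matrix(dist(matrix(rnorm(14), 7)))
  cl1 <- k_medoids(Du, k = 1, restarts = 10, min_size = 1, seed = 1)
  expect_equal(cl1$medoids, unname(which.min(rowSums(Du))))
})

test_that("k_medoids equals exhaustive search on random instances", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(4:8, 1)
    k <- sample(2:3, 1)
    X <- matrix(rnorm(2 * n), n)
    D <- as.matrix(dist(X))
    cl <- k_medoids(D, k, restarts = 30, min_size = 1, seed = i)
    expect_equal(cl$cost, oracle_kmedoids_cost(D, k), tolerance = 1e-9)
  }
})

test_that("k_medoids is deterministic and honours min_size", {
  set.seed(5)
  D <- as.matrix(dist(matrix(rnorm(16), 8)))
  a <- k_medoids(D, 2, restarts = 25, min_size = 1, seed = 3)
  b <- k_medoids(D, 2, restarts = 25, min_size = 1, seed = 3)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$medoids, b$medoids)
  # an isolated point forms a singleton cluster; min_size = 2 must refuse k=3
  D2 <- matrix(1, 5, 5); diag(D2) <- 0
  D2[5, ] <- D2[, 5] <- 50; D2[5, 5] <- 0
  expect_error(k_medoids(D2, 3, restarts = 10, min_size = 2, seed = 1),
               "min_size|smaller k")
})

test_that("best-of-restarts cost is non-increasing in the restart budget", {
  set.seed(17)
  D <- as.matrix(dist(matrix(rnorm(20), 10)))
  costs <- vapply(c(1, 3, 10, 30), function(r)
    k_medoids(D, 3, restarts = r, min_size = 1, seed = 2)$cost, 0)
  expect_true(all(diff(costs) <= 1e-12))
})

test_that("outlier handling flags planted outliers and reassigns them", {
  set.seed(23)
  X <- rbind(matrix(rnorm(10, 0, 0.2), 5), matrix(rnorm(10, 5, 0.2), 5), c(50, 50))
  D <- as.matrix(dist(X))
  o <- handle_outliers(D)
  expect_identical(o$outliers, 11L)
  cl <- k_medoids(D[o$core, o$core], 2, restarts = 20, min_size = 1, seed = 1)
  glob <- cl; glob$medoids <- o$core[cl$medoids]
  asg <- assign_outliers(D, glob, o$outliers)
  expect_true(asg %in% glob$medoids)
  # no outliers in a homogeneous cloud
  Dh <- as.matrix(dist(matrix(rnorm(20), 10)))
  expect_length(handle_outliers(Dh)$outliers, 0)
})

test_that("cluster templates of identical members equal the member", {
  a <- array(runif(8^3), c(8, 8, 8))
  lp <- array(FALSE, c(8, 8, 8)); lp[4:5, 4:5, 4:5] <- TRUE
  attr(a, "lpvh") <- lp
  tpls <- build_cluster_templates(list(a, a), c(1L, 1L))
  expect_length(tpls, 1)
  expect_equal(tpls[[1]]$intensity, unclass(a), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(tpls[[1]]$labels == STRUCTURES[["LPVH"]], lp,
                   ignore_attr = TRUE)
  expect_error(build_cluster_templates(list(a, a), c(1L, 2L), min_size = 2),
               "min_size")
})
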