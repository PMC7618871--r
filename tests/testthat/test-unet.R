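tiny_cfg <- function(...) seg_config(depth = 2, init_features = 4, seed = 7, ...)

test_that("forward pass returns a per-voxel probability simplex", {
  set.seed(7)
  p <- unet_init(tiny_cfg())
  x <- array(rnorm(16^3), c(16, 16, 16))
  fw <- unet_forward(p, x)
  expect_identical(dim(fw$logits), c(16L, 16L, 16L, 5L))
  probs <- fetalsubcort:::.unet_pass(p, x, dim(x), NULL, 1, FALSE)$probs
  expect_identical(dim(probs), c(16L, 16L, 16L, 5L))
  sums <- apply(probs, c(1, 2, 3), sum)
  expect_equal(range(sums), c(1, 1), tolerance = 1e-5)
  expect_gte(min(probs), 0)
})

test_that("single-precision pass agrees with the double-precision reference", {
  set.seed(8)
  p <- unet_init(tiny_cfg())
  x <- array(rnorm(16^3), c(16, 16, 16))
  lab <- array(sample(0:4, 16^3, TRUE, prob = c(.9, rep(.025, 4))),
               c(16, 16, 16))
  fw <- unet_forward(p, x, train = TRUE)
  lg <- fetalsubcort:::loss_grad_from_logits(fw$logits, lab)
  gr <- unet_backward(p, lg$dlogits, fw$cache)
  ps <- fetalsubcort:::.unet_pass(p, x, dim(x), as.integer(lab), 1, TRUE)
  expect_equal(ps$loss, lg$loss, tolerance = 1e-4)
  expect_equal(ps$grads$head$w, gr$head$w, tolerance = 1e-3)
  rel <- max(abs(ps$grads$enc[[1]]$conv1$w - gr$enc[[1]]$conv1$w)) /
    max(abs(gr$enc[[1]]$conv1$w))
  expect_lt(rel, 0.05)
})

test_that("combined loss matches its analytic anchor points", {
  n <- 4^3
  target <- array(sample(0:4, n, TRUE), c(4, 4, 4))
  onehot <- matrix(0, n, 5); onehot[cbind(seq_len(n), target + 1)] <- 1
  # perfect prediction with epsilon -> 0: both terms vanish
  l <- combined_loss(onehot, target, lambda = 1, epsilon = 1e-12)
  expect_equal(as.numeric(l), 0, tolerance = 1e-6)
  # uniform probabilities: cross-entropy is log(5) per voxel
  unif <- matrix(0.2, n, 5)
  lu <- combined_loss(unif, target, lambda = 1)
  expect_equal(attr(lu, "L_CE"), log(5), tolerance = 1e-12)
  expect_equal(seg_config()$lambda_ce, 1)
})

test_that("combined loss is permutation-equivariant in foreground classes", {
  set.seed(9)
  n <- 5^3
  p <- matrix(rexp(n * 5), n); p <- p / rowSums(p)
  target <- sample(0:4, n, TRUE)
  l0 <- as.numeric(combined_loss(p, target))
  sigma <- c(0, 3, 1, 4, 2)  # permutes foreground classes, fixes background
  p2 <- p
  for (cls in 0:4) p2[, sigma[cls + 1] + 1] <- p[, cls + 1]
  lp <- as.numeric(combined_loss(p2, sigma[target + 1]))
  expect_equal(lp, l0, tolerance = 1e-12)
})

test_that("loss decreases monotonically toward the target one-hot", {
  set.seed(10)
  n <- 6^3
  target <- sample(0:4, n, TRUE)
  onehot <- matrix(0, n, 5); onehot[cbind(seq_len(n), target + 1)] <- 1
  unif <- matrix(0.2, n, 5)
  ts <- seq(0, 1, by = 0.1)
  ls <- vapply(ts, function(t)
    as.numeric(combined_loss((1 - t) * unif + t * onehot, target,
                             epsilon = 1e-9)), 0)
  expect_true(all(diff(ls) < 0))
})

test_that("scaling_range reproduces the analytic bounds and clips", {
  expect_equal(scaling_range(18)[["s_min"]], 0.9^(1 / 3), tolerance = 1e-12)
  expect_equal(scaling_range(26)[["s_max"]], 1.1^(1 / 3), tolerance = 1e-12)
  # V(26)/V(w) = 8 forces the upper clip: (8.8)^(1/3) > 1.5
  vbar <- data.frame(ga_weeks = c(18, 20, 26),
                     volume_cm3 = c(10, 15, 120))
  expect_equal(scaling_range(20, vbar)[["s_max"]], 1.5)
  # lower clip engages when the target shrink exceeds 1/1.5
  vbar2 <- data.frame(ga_weeks = c(18, 25, 26), volume_cm3 = c(10, 80, 90))
  expect_equal(scaling_range(25, vbar2)[["s_min"]], 1 / 1.5)
  # exhaustive over the default table: always inside [1/1.5, 1.5]
  for (w in 18:27) {
    s <- scaling_range(w)
    expect_gte(s[["s_min"]], 1 / 1.5)
    expect_lte(s[["s_max"]], 1.5)
    expect_lte(s[["s_min"]], s[["s_max"]])
  }
})

test_that("augmentation honours its bounds and degenerate draws", {
  s <- fixture_phantom()
  # all magnitudes zero, flip off: exact identity
  spec0 <- augmentation_spec(flip_prob = 0, rotation_max_deg = 0,
                             translation_max_vox = 0,
                             vbar = data.frame(ga_weeks = c(18, 22, 26),
                                               volume_cm3 = c(1, 1, 1) * 50))
  # force the scale draw to 1 by a degenerate table
  spec0$vbar$volume_cm3 <- c(50 / 0.9, 50, 50 / 1.1)
  sm <- scaling_range(22, spec0$vbar)
  skip_if_not(abs(sm[["s_min"]] - 1) < 1e-9 && abs(sm[["s_max"]] - 1) < 1e-9)
  out <- augment(s$image$data, s$labels$data, 22, spec0)
  expect_identical(out$image, s$image$data)
  expect_identical(out$labels, s$labels$data)
})

test_that("augmentation cannot invent label classes and respects scale range", {
  s <- fixture_phantom()
  spec <- augmentation_spec(translation_max_vox = 4)
  set.seed(2)
  scales <- replicate(200, {
    out <- augment(s$image$data, s$labels$data, 18, spec)
    expect_true(all(unique(as.integer(out$labels)) %in%
                      unique(as.integer(s$labels$data))))
    out$draws$scale
  })
  sr <- scaling_range(18)
  expect_gte(min(scales), sr[["s_min"]])
  expect_lte(max(scales), sr[["s_max"]])
})

test_that("training runs the exact budget, logs losses and is seeded", {
  s <- fixture_phantom()
  ds <- list(list(image = s$image, labels = s$labels, ga_weeks = s$ga_weeks))
  cfg <- tiny_cfg(batch_size = 1, iteration_budget = 6, learning_rate = 0.01)
  spec <- augmentation_spec(translation_max_vox = 3)
  m1 <- train_segmenter(ds, cfg, spec)
  m2 <- train_segmenter(ds, cfg, spec)
  expect_equal(nrow(m1$log), 6)
  expect_true(all(is.finite(m1$log$loss)))
  expect_identical(m1$log$loss, m2$log$loss)
  expect_equal(m1$params$head$w, m2$params$head$w, tolerance = 1e-12)
  expect_error(train_segmenter(list(), cfg), "empty")
})

test_that("prediction uses argmax with low-index tie-breaking", {
  s <- fixture_phantom()
  ds <- list(list(image = s$image, labels = s$labels, ga_weeks = s$ga_weeks))
  cfg <- tiny_cfg(batch_size = 1, iteration_budget = 2)
  m <- train_segmenter(ds, cfg, augment_data = FALSE)
  pred <- predict_labels(m, s$image)
  expect_identical(dim(pred$data), dim(s$image$data))
  expect_equal(pred$provenance, "predicted")
  expect_equal(pred$spacing, s$image$spacing)
  expect_error(predict_labels(m, array(0, c(8, 8, 8))), "grid")
  # tie rule: equal probabilities resolve to the lowest class index
  pm <- matrix(0.2, 3, 5)
  expect_identical(max.col(pm, ties.method = "first") - 1L, rep(0L, 3))
})
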