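# Shared small fixtures, built once per test run.

.fix <- new.env(parent = emptyenv())

# small, fast phantom configuration used throughout the unit tests
test_phantom_config <- function(...) {
  phantom_config(size = 32, spacing = 1.8, brain_scale = 0.35, ...)
}

fixture_phantom <- function() {
  if (is.null(.fix$phantom))
    .fix$phantom <- make_phantom(22, seed = 42, config = test_phantom_config())
  .fix$phantom
}

fixture_clean_phantom <- function() {
  if (is.null(.fix$clean))
    .fix$clean <- make_phantom(
      22, seed = 42,
      config = test_phantom_config(speckle_sd = 0, shadow_strength = 0,
                                   psf_sigma_vox = 0,
                                   mirror_structures = FALSE))
  .fix$clean
}

# brute-force oracles for the metric tests
oracle_dice <- function(a, b) {
  ia <- which(a); ib <- which(b)
  if (!length(ia) && !length(ib)) return(1)
  2 * length(intersect(ia, ib)) / (length(ia) + length(ib))
}

oracle_boundary <- function(m) {
  d <- dim(m)
  out <- array(FALSE, d)
  for (i in which(m)) {
    co <- arrayInd(i, d)
    nb <- expand.grid(x = co[1] + (-1:1), y = co[2] + (-1:1), z = co[3] + (-1:1))
    nb <- nb[!(nb$x == co[1] & nb$y == co[2] & nb$z == co[3]), ]
    edge <- any(nb$x < 1 | nb$y < 1 | nb$z < 1 | nb$x > d[1] | nb$y > d[2] |
                  nb$z > d[3])
    inb <- nb[nb$x >= 1 & nb$y >= 1 & nb$z >= 1 & nb$x <= d[1] &
                nb$y <= d[2] & nb$z <= d[3], ]
    if (edge || any(!m[cbind(inb$x, inb$y, inb$z)])) out[i] <- TRUE
  }
  out
}

oracle_h95 <- function(a, b, spacing) {
  ba <- which(oracle_boundary(a), arr.ind = TRUE) * spacing
  bb <- which(oracle_boundary(b), arr.ind = TRUE) * spacing
  dmat <- as.matrix(dist(rbind(ba, bb)))[seq_len(nrow(ba)),
                                         nrow(ba) + seq_len(nrow(bb)),
                                         drop = FALSE]
  dab <- apply(dmat, 1, min)
  dba <- apply(dmat, 2, min)
  max(quantile(dab, 0.95, names = FALSE), quantile(dba, 0.95, names = FALSE))
}

oracle_hmax <- function(a, b, spacing) {
  ba <- which(oracle_boundary(a), arr.ind = TRUE) * spacing
  bb <- which(oracle_boundary(b), arr.ind = TRUE) * spacing
  dmat <- as.matrix(dist(rbind(ba, bb)))[seq_len(nrow(ba)),
                                         nrow(ba) + seq_len(nrow(bb)),
                                         drop = FALSE]
  max(apply(dmat, 1, min), apply(dmat, 2, min))
}

random_mask <- function(d = c(12, 12, 12), p = 0.15) {
  m <- array(runif(prod(d)) < p, d)
  m
}

# exhaustive k-medoids oracle: best medoid subset with nearest assignment
oracle_kmedoids_cost <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(D[, med, drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}
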