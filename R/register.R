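## Rigid resampling and diffeomorphic demons non-rigid registration.
## Displacement fields use the pull-back convention: warped(v) = img(v + d(v))
## with d in voxel units on the fixed grid.

#' Rigidly resample a volume
#'
#' Applies a rigid transform (active, in mm, about the volume centre) to a
#' volume or labelmap by resampling on the same grid. Labelmaps are always
#' resampled nearest-neighbour.
#'
#' @param vol a [volume3d()] or [labelmap()].
#' @param t a [rigid_transform()] (or its inverse from [rt_invert()]).
#' @param interp `"trilinear"` or `"nearest"`; forced to nearest for labels.
#' @param aligned orientation state recorded on the result (volumes only).
#' @return Resampled object of the same class.
#' @export
rigid_align <- function(vol, t, interp = c("trilinear", "nearest"),
                        aligned = TRUE) {
  interp <- match.arg(interp)
  m <- rt_as_matrix(t)
  if (abs(det(m$R)) < 1e-8) stop("transform is not invertible")
  is_lab <- inherits(vol, "labelmap")
  if (is_lab) interp <- "nearest"
  d <- dim(vol$data)
  sp <- vol$spacing
  c0 <- (d - 1) / 2
  ## pull-back: src_vox = diag(1/sp) R^T (diag(sp)(y - c0) - trans) + c0
  Rinv <- t(m$R)
  A <- diag(1 / sp) %*% Rinv %*% diag(sp)
  b <- as.numeric(diag(1 / sp) %*% Rinv %*% (-m$trans)) - A %*% c0 + c0
  M <- cbind(A, b)
  out <- .affine_resample(vol$data, M, dim(vol$data), interp == "nearest")
  out <- array(out, d)
  if (is_lab) labelmap(array(as.integer(round(out)), d), spacing = sp,
                       provenance = vol$provenance)
  else volume3d(out, spacing = sp, ga_weeks = vol$ga_weeks, aligned = aligned)
}

#' Rigidly align a phantom sample to the reference space
#'
#' Applies the inverse of the sample's stored pose to its image (trilinear),
#' labels and brain mask (nearest).
#'
#' @param sample a `cohort_sample`.
#' @return The aligned sample (pose becomes the identity).
#' @export
align_sample <- function(sample) {
  if (is_identity_rt(sample$pose)) return(sample)
  inv <- rt_invert(sample$pose)
  sample$image <- rigid_align(sample$image, inv, "trilinear", aligned = TRUE)
  sample$labels <- rigid_align(sample$labels, inv)
  bm <- labelmap(array(as.integer(sample$brain_mask), dim(sample$brain_mask)),
                 spacing = sample$image$spacing)
  sample$brain_mask <- rigid_align(bm, inv)$data > 0
  sample$pose <- rigid_transform()
  sample
}

gauss_arr <- function(a, sigma) {
  if (sigma <= 0) return(a)
  array(.gauss3(a, dim(a), sigma), dim(a))
}

downsample2 <- function(a) {
  d <- dim(a)
  nd <- pmax(1L, d %/% 2L)
  M <- cbind(diag(3) * 2, c(0.5, 0.5, 0.5))
  array(.affine_resample(gauss_arr(a, 1), M, nd, FALSE, d), nd)
}

upsample_field <- function(field, newdim) {
  d <- dim(field)[1:3]
  sc <- d / newdim
  M <- cbind(diag(sc), (sc - 1) / 2)
  out <- array(0, c(newdim, 3))
  for (k in 1:3)
    out[, , , k] <- array(.affine_resample(field[, , , k], M, newdim, FALSE,
                                           d), newdim) / sc[k]
  out
}

zero_field <- function(d) array(0, c(d, 3))

#' Diffeomorphic demons registration
#'
#' Multi-resolution compositive demons with fluid (update) and diffusion
#' (total field) Gaussian regularisation. Returns the displacement field on
#' the fixed grid, pull-back convention, in voxel units.
#'
#' @param fixed,moving 3D arrays on a common grid.
#' @param iters iterations per pyramid level, coarse to fine.
#' @param sigma_fluid,sigma_diff Gaussian sigmas (voxels) for the update and
#'   total field.
#' @param sigma_img pre-smoothing of both images at each level.
#' @return List with `disp` (nx,ny,nz,3) and the final `ssd`.
#' @export
demons_register <- function(fixed, moving, iters = c(30, 20, 8),
                            sigma_fluid = 1, sigma_diff = 1, sigma_img = 1) {
  stopifnot(identical(dim(fixed), dim(moving)))
  nlev <- length(iters)
  fl <- list(fixed); ml <- list(moving)
  for (l in seq_len(nlev - 1)) {
    fl <- c(list(downsample2(fl[[1]])), fl)
    ml <- c(list(downsample2(ml[[1]])), ml)
  }
  d <- NULL
  for (l in seq_len(nlev)) {
    f <- gauss_arr(fl[[l]], sigma_img)
    m <- gauss_arr(ml[[l]], sigma_img)
    dm <- dim(f)
    d <- if (is.null(d)) zero_field(dm) else upsample_field(d, dm)
    gf <- .grad3(f, dm)
    best <- d
    w <- array(.warp_disp(m, d, dm, FALSE), dm)
    best_ssd <- mean((w - f)^2)
    for (it in seq_len(iters[l])) {
      u <- -array(.demons_force(f, w, gf, dm), c(dm, 3))
      for (k in 1:3) u[, , , k] <- gauss_arr(u[, , , k], sigma_fluid)
      d <- array(.compose_disp(d, u, dm), c(dm, 3))
      for (k in 1:3) d[, , , k] <- gauss_arr(d[, , , k], sigma_diff)
      w <- array(.warp_disp(m, d, dm, FALSE), dm)
      ssd <- mean((w - f)^2)
      if (ssd < best_ssd) { best_ssd <- ssd; best <- d } else { d <- best; break }
    }
    d <- best
  }
  list(disp = d, ssd = best_ssd)
}

#' Invert a displacement field
#'
#' Fixed-point inversion of the forward displacement; accuracy is checked on
#' an optional mask and failures (residual above `tol` voxels) are reported.
#'
#' @param disp (nx,ny,nz,3) displacement, voxel units.
#' @param iters fixed-point iterations.
#' @param tol residual tolerance in voxels.
#' @param mask optional logical array restricting the accuracy check.
#' @param max_fail_frac error if more than this fraction of checked voxels
#'   exceeds `tol`.
#' @return The inverse displacement field, with attribute `fail_frac`.
#' @export
invert_field <- function(disp, iters = 20, tol = 0.1, mask = NULL,
                         max_fail_frac = 0.01) {
  dm <- dim(disp)[1:3]
  inv <- array(.invert_disp(disp, dm, iters), c(dm, 3))
  comp <- array(.compose_disp(disp, inv, dm), c(dm, 3))
  resid <- sqrt(comp[, , , 1]^2 + comp[, , , 2]^2 + comp[, , , 3]^2)
  frac <- if (is.null(mask)) mean(resid > tol) else mean(resid[mask] > tol)
  if (is.finite(frac) && frac > max_fail_frac)
    warning(sprintf("field inversion residual > %.2f vox on %.1f%% of voxels",
                    tol, 100 * frac))
  attr(inv, "fail_frac") <- frac
  inv
}

#' Warp a volume or label array by a displacement field
#'
#' @param a 3D array.
#' @param disp displacement field, pull-back convention, voxel units.
#' @param nearest use nearest-neighbour sampling (mandatory for labels).
#' @return Warped array; voxels sampling outside the grid become 0.
#' @export
warp_array <- function(a, disp, nearest = FALSE) {
  dm <- dim(a)
  out <- array(.warp_disp(a, disp, dm, nearest), dm)
  if (is.integer(a)) storage.mode(out) <- "integer"
  out
}
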