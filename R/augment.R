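## Gestational-age-aware geometric augmentation: random midline flips,
## rotations, voxel translations and isotropic scaling restricted to brain
## sizes that exist in the dataset.

#' Mean whole-brain volume table
#'
#' Per-week average brain volume used to bound the augmentation scaling,
#' by default from [brain_reference_volume()]. Scaling bounds only depend
#' on volume ratios, so any proportional rescaling of the table leaves
#' them unchanged.
#'
#' @param weeks gestational weeks covered by the table.
#' @return data.frame with columns `ga_weeks`, `volume_cm3`.
#' @export
default_vbar <- function(weeks = 18:27) {
  data.frame(ga_weeks = weeks, volume_cm3 = brain_reference_volume(weeks))
}

vbar_lookup <- function(vbar, w) {
  if (w < min(vbar$ga_weeks) || w > max(vbar$ga_weeks))
    stop("gestational age outside the brain-volume table")
  v <- approx(vbar$ga_weeks, vbar$volume_cm3, xout = w)$y
  if (!is.finite(v) || v <= 0) stop("non-positive brain volume in table")
  v
}

#' Per-week augmentation scaling range
#'
#' Linear scale bounds derived from the brain-volume ratios so that scaled
#' images stay within the brain sizes present between 18 and 26 weeks:
#' `s_min = max((0.9 V(18)/V(w))^(1/3), 1/1.5)` and
#' `s_max = min((1.1 V(26)/V(w))^(1/3), 1.5)` (cube roots convert volume
#' ratios to linear scale).
#'
#' @param w gestational age in weeks.
#' @param vbar brain-volume table, see [default_vbar()].
#' @return Named vector `c(s_min, s_max)`.
#' @export
scaling_range <- function(w, vbar = default_vbar()) {
  v18 <- vbar_lookup(vbar, 18)
  v26 <- vbar_lookup(vbar, 26)
  vw <- vbar_lookup(vbar, w)
  s_min <- max((0.9 * v18 / vw)^(1 / 3), 1 / 1.5)
  s_max <- min((1.1 * v26 / vw)^(1 / 3), 1.5)
  c(s_min = s_min, s_max = s_max)
}

#' Augmentation settings
#'
#' @param flip_prob probability of a flip across the midline.
#' @param rotation_max_deg rotation bound in degrees (each axis).
#' @param translation_max_vox translation bound in voxels (each axis).
#' @param vbar brain-volume table for [scaling_range()].
#' @return Object of class `augmentation_spec`.
#' @export
augmentation_spec <- function(flip_prob = 0.5, rotation_max_deg = 30,
                              translation_max_vox = 10,
                              vbar = default_vbar()) {
  for (w in vbar$ga_weeks) {
    s <- scaling_range(w, vbar)
    stopifnot(1 / 1.5 <= s[1], s[1] <= s[2], s[2] <= 1.5)
  }
  structure(list(flip_prob = flip_prob, rotation_max_deg = rotation_max_deg,
                 translation_max_vox = translation_max_vox, vbar = vbar),
            class = "augmentation_spec")
}

#' Randomly augment an image/label pair
#'
#' One random draw each of: midline flip, rotation in
#' `[-rotation_max_deg, +rotation_max_deg]` per axis, translation in
#' `[-translation_max_vox, +translation_max_vox]` per axis, and isotropic
#' scale in `[s_min(ga), s_max(ga)]`. The identical geometric transform is
#' applied to image (trilinear) and labels (nearest neighbour). Uses the
#' current RNG state.
#'
#' @param image 3D array.
#' @param labels integer 3D array on the same grid.
#' @param ga gestational age in weeks.
#' @param spec an [augmentation_spec()].
#' @return List with `image`, `labels` and the realized `draws`.
#' @export
augment <- function(image, labels, ga, spec = augmentation_spec()) {
  stopifnot(identical(dim(image), dim(labels)))
  d <- dim(image)
  flip <- runif(1) < spec$flip_prob
  rot <- runif(3, -spec$rotation_max_deg, spec$rotation_max_deg)
  trans <- runif(3, -spec$translation_max_vox, spec$translation_max_vox)
  sr <- scaling_range(ga, spec$vbar)
  s <- runif(1, sr[1], sr[2])

  R <- rot_matrix(rot)
  Fd <- diag(c(if (flip) -1 else 1, 1, 1))
  A <- R %*% (s * Fd)
  c0 <- (d - 1) / 2
  Ainv <- solve(A)
  b <- as.numeric(c0 - Ainv %*% (c0 + trans))
  M <- cbind(Ainv, b)
  img_out <- array(.affine_resample(image, M, d, FALSE), d)
  lab_out <- array(as.integer(.affine_resample(labels + 0.0, M, d, TRUE)), d)
  list(image = img_out, labels = lab_out,
       draws = list(flip = flip, rotation_deg = rot, translation_vox = trans,
                    scale = s))
}
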