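## Synthetic ultrasound phantom: GA-dependent growth laws, ellipsoid
## anatomy clipped into a brain ellipsoid, speckle (multiplicative gamma
## noise), acoustic shadowing of the hemisphere proximal to the virtual
## transducer, and random rigid pose.

#' Reference whole-brain volume law
#'
#' Quadratic reference law for healthy whole-brain volume over the second
#' trimester, in cm^3 at acquisition scale: 30 cm^3 at 18 weeks rising to
#' 120 cm^3 at 26 weeks, consistent with fetal imaging literature. Phantom
#' configurations may scale the realised brain by a volume factor
#' (`brain_scale`) to fit a smaller field of view; structures whose growth
#' laws are brain-relative scale along with it.
#'
#' @param ga_weeks gestational age in weeks.
#' @return brain volume in cm^3.
#' @export
brain_reference_volume <- function(ga_weeks) {
  t <- ga_weeks - 18
  30 + 6.25 * t + 0.625 * t^2
}

#' Construct a growth law
#'
#' A growth law maps gestational age to an expected structure volume in
#' cm^3. Coefficients are for a polynomial in `t = ga - 18`. When
#' `relative_to_brain` is `TRUE` the polynomial is calibrated at the
#' reference brain size ([brain_reference_volume()]) and the predicted
#' volume scales proportionally with the actual brain volume, so that
#' brain-proportional structures (CP, CB) keep their relative size in
#' smaller phantoms.
#'
#' @param structure one of `"CP"`, `"LPVH"`, `"CSPV"`, `"CB"`.
#' @param form `"linear"` or `"quadratic"` in gestational age.
#' @param coefficients numeric; `c(a, b)` for linear `a + b*t`, `c(a, b, c)`
#'   for quadratic.
#' @param relative_to_brain logical, see Details.
#' @return An object of class `growth_law`.
#' @export
growth_law <- function(structure, form = c("linear", "quadratic"),
                       coefficients, relative_to_brain = FALSE) {
  form <- match.arg(form)
  stopifnot(all(is.finite(coefficients)),
            length(coefficients) == if (form == "linear") 2L else 3L)
  structure(list(structure = structure, form = form,
                 coefficients = as.numeric(coefficients),
                 relative_to_brain = isTRUE(relative_to_brain)),
            class = "growth_law")
}

#' Default growth laws for the four subcortical structures
#'
#' LPVH grows linearly from 0.1 cm^3 at 18 weeks to 0.3 cm^3 at 26 weeks and
#' the CSPV from 0.01 cm^3 to 0.6 cm^3 over the same range. The CP shows
#' only a very small absolute increase, which makes its brain-relative
#' volume fall from about 12% at 18 weeks to about 3% at 27 weeks; the CB
#' grows quadratically with a brain-relative volume held between 1.5% and
#' 2.5%. CP and CB laws are brain-relative (they scale with the phantom
#' brain), LPVH and CSPV are absolute.
#'
#' @return Named list of [growth_law()] objects.
#' @export
default_growth_laws <- function() {
  list(
    CP   = growth_law("CP", "linear", c(3.6, 0.075), relative_to_brain = TRUE),
    LPVH = growth_law("LPVH", "linear", c(0.1, 0.025)),
    CSPV = growth_law("CSPV", "linear", c(0.01, 0.59 / 8)),
    CB   = growth_law("CB", "quadratic", c(0.57, 0.156, 0.0147),
                      relative_to_brain = TRUE)
  )
}

#' Expected structure volume at a gestational age
#'
#' @param ga_weeks gestational age in weeks, in `[18, 27]`.
#' @param law a [growth_law()].
#' @param brain_volume_cm3 actual whole-brain volume; used only for
#'   brain-relative laws. Defaults to the reference brain volume.
#' @return Expected volume in cm^3.
#' @export
growth_model <- function(ga_weeks, law,
                         brain_volume_cm3 = brain_reference_volume(ga_weeks)) {
  if (ga_weeks < 18 || ga_weeks > 27)
    stop("ga_weeks must be within [18, 27]")
  stopifnot(inherits(law, "growth_law"))
  t <- ga_weeks - 18
  co <- law$coefficients
  v <- co[1] + co[2] * t + if (length(co) > 2) co[3] * t^2 else 0
  if (law$relative_to_brain)
    v <- v * brain_volume_cm3 / brain_reference_volume(ga_weeks)
  if (v <= 0) stop("growth law predicts non-positive volume")
  v
}

## ---- rigid transforms ------------------------------------------------

#' Create a rigid transform
#'
#' Rotation as three Euler angles in degrees (applied as Rz Ry Rx) and a
#' translation in mm. Transforms act about the volume centre.
#'
#' @param rotation_deg length-3 angles in degrees.
#' @param translation_mm length-3 translation in mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0)) {
  stopifnot(length(rotation_deg) == 3, length(translation_mm) == 3)
  structure(list(rotation_deg = as.numeric(rotation_deg),
                 translation_mm = as.numeric(translation_mm)),
            class = "rigid_transform")
}

rot_matrix <- function(rotation_deg) {
  a <- rotation_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @return A list with the inverse rotation matrix and translation; applying
#'   it after `t` yields the identity map.
#' @export
rt_invert <- function(t) {
  R <- rot_matrix(t$rotation_deg)
  structure(list(R = t(R), trans = -crossprod(R, t$translation_mm)[, 1]),
            class = "rigid_matrix")
}

rt_as_matrix <- function(t) {
  if (inherits(t, "rigid_matrix")) return(t)
  structure(list(R = rot_matrix(t$rotation_deg), trans = t$translation_mm),
            class = "rigid_matrix")
}

is_identity_rt <- function(t) {
  m <- rt_as_matrix(t)
  isTRUE(all.equal(m$R, diag(3), tolerance = 1e-12)) &&
    isTRUE(all.equal(unname(m$trans), c(0, 0, 0), tolerance = 1e-12))
}

## ---- phantom configuration -------------------------------------------

#' Phantom generator settings
#'
#' @param size grid size (cubic), default 64 (desk scale); full acquisition
#'   scale is 160.
#' @param spacing isotropic voxel spacing in mm, default 1.2 (acquisition scale:
#'   0.6).
#' @param brain_scale volume factor applied to the reference brain law so
#'   the brain fits the field of view; default 0.5 at desk scale.
#' @param speckle_sd standard deviation of the unit-mean multiplicative
#'   gamma speckle; 0 disables speckle.
#' @param shadow_strength peak attenuation of the hemisphere proximal to
#'   the virtual transducer, in `[0, 1)`; 0 disables shadowing.
#' @param shadow_width_mm width of the smooth attenuation ramp across the
#'   midline.
#' @param psf_sigma_vox Gaussian point-spread blur (voxels) applied to the
#'   clean piecewise-constant scene; 0 disables it.
#' @param mirror_structures paint the CP/LPVH intensity pattern in both
#'   hemispheres (the anatomy exists bilaterally; only the visible side is
#'   labelled). Disable for strictly label-matched piecewise-constant scenes.
#' @param laws growth laws, see [default_growth_laws()].
#' @param n_lpvh_modes number of discrete LPVH shape modes (2--4).
#' @return A list of settings of class `phantom_config`.
#' @export
phantom_config <- function(size = 64L, spacing = 1.2, brain_scale = 0.5,
                           speckle_sd = 0.25, shadow_strength = 0.5,
                           shadow_width_mm = 6, psf_sigma_vox = 0.8,
                           mirror_structures = TRUE,
                           laws = default_growth_laws(),
                           n_lpvh_modes = 3L) {
  stopifnot(size > 7, spacing > 0, brain_scale > 0, speckle_sd >= 0,
            shadow_strength >= 0, shadow_strength < 1,
            n_lpvh_modes >= 2, n_lpvh_modes <= 4)
  structure(list(size = as.integer(size), spacing = spacing,
                 brain_scale = brain_scale, speckle_sd = speckle_sd,
                 shadow_strength = shadow_strength,
                 shadow_width_mm = shadow_width_mm,
                 psf_sigma_vox = psf_sigma_vox,
                 mirror_structures = isTRUE(mirror_structures),
                 laws = laws, n_lpvh_modes = as.integer(n_lpvh_modes)),
            class = "phantom_config")
}

## tissue intensities of the clean scene
PHANTOM_INTENSITY <- c(background = 0.02, brain = 0.35,
                       CP = 0.85, LPVH = 0.10, CSPV = 0.15, CB = 0.75)

## anatomical placement: centres as fractions of the brain semi-axes, axis
## ratios of each ellipsoid; shapes may have several components (the scale
## solver grows them jointly). h = hemisphere sign. LPVH shape modes are
## deliberately distinct (compact blob, bent two-lobe horn, flat plate,
## vertical horn) so that cluster-based templates have variation to recover
## that smooth registration cannot fully absorb.
structure_geometry <- function(lpvh_mode) {
  lpvh_modes <- list(
    list(list(dc = c(0, 0, 0), ratio = c(0.9, 1.1, 0.8))),
    list(list(dc = c(0, 0.25, 0), ratio = c(0.55, 1.30, 0.55)),
         list(dc = c(0.40, -0.80, 0), ratio = c(1.20, 1.00, 0.50))),
    list(list(dc = c(0, 0, 0), ratio = c(1.35, 1.15, 0.42))),
    list(list(dc = c(0, 0, 0), ratio = c(0.60, 0.75, 1.55)))
  )
  list(
    CB   = list(centre = c(0, -0.60, -0.42),
                parts = list(list(dc = c(0, 0, 0),
                                  ratio = c(1.70, 0.75, 0.50))),
                hemisphere = FALSE),
    CSPV = list(centre = c(0, 0.30, 0.08),
                parts = list(list(dc = c(0, 0, 0),
                                  ratio = c(0.45, 1.70, 0.60))),
                hemisphere = FALSE),
    CP   = list(centre = c(0.45, 0.05, 0.02),
                parts = list(list(dc = c(0, 0, 0),
                                  ratio = c(0.62, 1.50, 0.80))),
                hemisphere = TRUE),
    LPVH = list(centre = c(0.40, -0.62, 0.05), parts = lpvh_modes[[lpvh_mode]],
                hemisphere = TRUE)
  )
}

## voxel-centre coordinate grids in mm, centred on the volume centre
coord_grids <- function(n, spacing) {
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  list(x = ax, y = ax, z = ax)
}

## posed ellipsoid indicator over precomputed coordinate arrays X, Y, Z
## (mm, any shape). centre and semi-axes in mm, R a rotation matrix.
ellipsoid_mask <- function(X, Y, Z, centre, semi, R = diag(3)) {
  dx <- X - centre[1]; dy <- Y - centre[2]; dz <- Z - centre[3]
  u <- R[1, 1] * dx + R[2, 1] * dy + R[3, 1] * dz
  v <- R[1, 2] * dx + R[2, 2] * dy + R[3, 2] * dz
  w <- R[1, 3] * dx + R[2, 3] * dy + R[3, 3] * dz
  (u / semi[1])^2 + (v / semi[2])^2 + (w / semi[3])^2 <= 1
}

## Size a (possibly multi-component) ellipsoid shape so its voxelized
## region, clipped to `allowed`, matches the target volume. Each component
## is an ellipsoid with axis ratios `ratio` and a centre offset `dc * s` in
## the local frame; component offsets are kept small enough relative to the
## axes that voxel membership is monotone in the scale `s`, so a binary
## search on the voxel count converges to within one voxel.
solve_structure_mask <- function(xs, ys, zs, centre, parts, R,
                                 target_mm3, vox_mm3) {
  dx <- xs - centre[1]; dy <- ys - centre[2]; dz <- zs - centre[3]
  u <- R[1, 1] * dx + R[2, 1] * dy + R[3, 1] * dz
  v <- R[1, 2] * dx + R[2, 2] * dy + R[3, 2] * dz
  w <- R[1, 3] * dx + R[2, 3] * dy + R[3, 3] * dz
  if (length(parts) == 1 && all(parts[[1]]$dc == 0)) {
    ratio <- parts[[1]]$ratio
    ratio <- ratio / prod(ratio)^(1 / 3)
    q <- (u / ratio[1])^2 + (v / ratio[2])^2 + (w / ratio[3])^2
    k <- max(1L, min(length(q), as.integer(round(target_mm3 / vox_mm3))))
    thr <- sort(q, partial = k)[k]
    return(q <= thr)
  }
  inside_at <- function(s) {
    m <- rep(FALSE, length(u))
    for (p in parts) {
      m <- m | (((u - s * p$dc[1]) / p$ratio[1])^2 +
                  ((v - s * p$dc[2]) / p$ratio[2])^2 +
                  ((w - s * p$dc[3]) / p$ratio[3])^2 <= s^2)
    }
    m
  }
  target_vox <- max(1, round(target_mm3 / vox_mm3))
  s0 <- (target_mm3 / (4 / 3 * pi))^(1 / 3)
  lo <- 0.1 * s0; hi <- 4 * s0
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (sum(inside_at(mid)) < target_vox) lo <- mid else hi <- mid
  }
  inside_at(hi)
}

#' Generate a synthetic fetal-brain ultrasound phantom
#'
#' Builds a speckled, shadowed 3D scene containing a brain ellipsoid with
#' four subcortical structures whose volumes follow the configured growth
#' laws, at a random or given rigid pose. The CP and LPVH are labelled only
#' in the visible hemisphere (the one distal to the virtual transducer);
#' CSPV and CB sit at the midline and are labelled in full. Deterministic
#' for fixed `(ga_weeks, seed, config)` and pose arguments.
#'
#' @param ga_weeks gestational age in weeks, in `[18, 27]`.
#' @param seed integer RNG seed.
#' @param config a [phantom_config()].
#' @param visible_hemisphere `"left"` or `"right"`.
#' @param pose a [rigid_transform()]; the identity by default.
#' @param lpvh_mode LPVH shape mode (1..`n_lpvh_modes`); sampled if `NULL`.
#' @return A `cohort_sample`: list with `image` ([volume3d()]), `labels`
#'   ([labelmap()], provenance expert), `ga_weeks`, `visible_hemisphere`,
#'   `brain_mask`, `pose`, `lpvh_mode`, `seed`, `config`.
#' @export
make_phantom <- function(ga_weeks, seed, config = phantom_config(),
                         visible_hemisphere = "left",
                         pose = rigid_transform(), lpvh_mode = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (ga_weeks < 18 || ga_weeks > 27) stop("ga_weeks must be within [18, 27]")
  visible_hemisphere <- match.arg(visible_hemisphere, c("left", "right"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  n <- config$size
  sp <- config$spacing
  grids <- coord_grids(n, sp)
  vox_mm3 <- sp^3
  if (is.null(lpvh_mode)) lpvh_mode <- sample.int(config$n_lpvh_modes, 1)

  pm <- rt_as_matrix(pose)
  Rp <- pm$R
  brain_cm3 <- brain_reference_volume(ga_weeks) * config$brain_scale
  sb <- (brain_cm3 * 1000 / (4 / 3 * pi))^(1 / 3)
  br_ratio <- c(0.95, 1.25, 0.85)
  br_ratio <- br_ratio / prod(br_ratio)^(1 / 3)
  brain_semi <- sb * br_ratio
  brain_centre <- pm$trans

  nvox <- n^3
  X <- array(rep(grids$x, times = n * n), c(n, n, n))
  Y <- array(rep(rep(grids$y, each = n), times = n), c(n, n, n))
  Z <- array(rep(grids$z, each = n * n), c(n, n, n))
  brain_mask <- ellipsoid_mask(X, Y, Z, brain_centre, brain_semi, Rp)

  ## hemisphere indicator in *brain* coordinates (the midsagittal plane
  ## moves with the pose): left is local x < 0
  localx <- Rp[1, 1] * (X - brain_centre[1]) + Rp[2, 1] * (Y - brain_centre[2]) +
    Rp[3, 1] * (Z - brain_centre[3])
  h_sign <- if (visible_hemisphere == "left") -1 else 1
  visible_half <- (localx * h_sign) >= 0

  geo <- structure_geometry(lpvh_mode)
  labels <- array(0L, dim = c(n, n, n))
  place_structure <- function(nm, flip_hemi = FALSE, exclude = labels != 0L) {
    g <- geo[[nm]]
    centre_local <- g$centre * brain_semi
    hs <- if (flip_hemi) -h_sign else h_sign
    if (g$hemisphere) centre_local[1] <- centre_local[1] * hs
    centre <- as.numeric(Rp %*% centre_local) + brain_centre
    target <- growth_model(ga_weeks, config$laws[[nm]], brain_cm3) * 1000
    allowed <- brain_mask & !exclude
    if (g$hemisphere) allowed <- allowed & (if (flip_hemi) !visible_half else visible_half)
    idx <- which(allowed)
    inside <- solve_structure_mask(X[idx], Y[idx], Z[idx], centre, g$parts,
                                   Rp, target, vox_mm3)
    idx[inside]
  }
  struct_vox <- list()
  for (nm in c("CB", "CSPV", "CP", "LPVH")) {
    vx <- place_structure(nm)
    if (length(vx) * vox_mm3 > brain_cm3 * 1000)
      stop("structure volume exceeds brain volume; check config")
    labels[vx] <- STRUCTURES[[nm]]
    struct_vox[[nm]] <- vx
  }

  img <- array(PHANTOM_INTENSITY[["background"]], dim = c(n, n, n))
  img[brain_mask] <- PHANTOM_INTENSITY[["brain"]]
  for (nm in c("CB", "CSPV", "CP", "LPVH"))
    img[struct_vox[[nm]]] <- PHANTOM_INTENSITY[[nm]]
  if (config$mirror_structures) {
    ## paint the bilateral anatomy on the occluded side (unlabelled)
    occluded <- labels != 0L
    for (nm in c("CP", "LPVH")) {
      vx <- place_structure(nm, flip_hemi = TRUE, exclude = occluded)
      img[vx] <- PHANTOM_INTENSITY[[nm]]
      occluded[vx] <- TRUE
    }
  }

  if (config$psf_sigma_vox > 0)
    img <- array(.gauss3(img, dim(img), config$psf_sigma_vox), dim(img))
  if (config$shadow_strength > 0) {
    ## attenuation ramp toward the hemisphere proximal to the transducer
    ramp <- 1 - config$shadow_strength /
      (1 + exp(-(-h_sign) * grids$x / config$shadow_width_mm))
    img <- img * array(rep(ramp, times = n * n), c(n, n, n))
  }
  if (config$speckle_sd > 0) {
    shape <- 1 / config$speckle_sd^2
    img <- img * array(rgamma(nvox, shape = shape, rate = shape), dim(img))
  }

  structure(list(
    image = volume3d(img, spacing = sp, ga_weeks = ga_weeks,
                     aligned = is_identity_rt(pose)),
    labels = labelmap(labels, spacing = sp, provenance = "expert"),
    ga_weeks = ga_weeks, visible_hemisphere = visible_hemisphere,
    brain_mask = brain_mask, pose = pose, lpvh_mode = lpvh_mode,
    seed = seed, config = config), class = "cohort_sample")
}

#' Generate a phantom cohort
#'
#' Gestational ages uniformly cover `ga_range`; the visible hemisphere is
#' assigned left/right with equal probability; when `aligned = FALSE` each
#' sample receives a random rigid pose (rotations up to
#' `pose_max_rot_deg`, translations up to `pose_max_trans_mm`).
#'
#' @param n number of samples (>= 1).
#' @param ga_range length-2 gestational-age interval in weeks.
#' @param seed integer RNG seed.
#' @param config a [phantom_config()].
#' @param aligned if `TRUE` all poses are the identity.
#' @param pose_max_rot_deg,pose_max_trans_mm pose sampling bounds.
#' @return List of `cohort_sample` objects (class `phantom_cohort`), with a
#'   manifest available through [cohort_manifest()].
#' @export
make_cohort <- function(n, ga_range = c(18, 26), seed = 1,
                        config = phantom_config(), aligned = TRUE,
                        pose_max_rot_deg = 10, pose_max_trans_mm = 3) {
  stopifnot(n >= 1)
  if (diff(range(ga_range)) < 0 || length(ga_range) != 2 ||
      ga_range[2] < ga_range[1])
    stop("empty gestational-age range")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  gas <- if (n == 1) mean(ga_range) else seq(ga_range[1], ga_range[2], length.out = n)
  hemi <- ifelse(runif(n) < 0.5, "left", "right")
  seeds <- sample.int(2^30, n)
  poses <- lapply(seq_len(n), function(i) {
    if (aligned) rigid_transform()
    else rigid_transform(runif(3, -pose_max_rot_deg, pose_max_rot_deg),
                         runif(3, -pose_max_trans_mm, pose_max_trans_mm))
  })
  modes <- sample.int(config$n_lpvh_modes, n, replace = TRUE)
  out <- lapply(seq_len(n), function(i)
    make_phantom(gas[i], seeds[i], config, visible_hemisphere = hemi[i],
                 pose = poses[[i]], lpvh_mode = modes[i]))
  class(out) <- "phantom_cohort"
  out
}

#' Cohort manifest
#'
#' @param cohort a list of `cohort_sample` objects.
#' @return data.frame with columns id, ga_weeks, hemisphere, lpvh_mode, seed.
#' @export
cohort_manifest <- function(cohort) {
  data.frame(
    id = seq_along(cohort),
    ga_weeks = vapply(cohort, function(s) s$ga_weeks, 0),
    hemisphere = vapply(cohort, function(s) s$visible_hemisphere, ""),
    lpvh_mode = vapply(cohort, function(s) s$lpvh_mode, 0L),
    seed = vapply(cohort, function(s) s$seed, 0L)
  )
}

#' Write a cohort to disk
#'
#' Image and labels as NIfTI-1, gestational age and pose in a sidecar JSON,
#' manifest as CSV.
#'
#' @param cohort list of `cohort_sample`s.
#' @param outdir output directory (created if needed).
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    id <- sprintf("sample%03d", i)
    write_volume(s$image, file.path(outdir, paste0(id, "_image.nii.gz")))
    write_volume(s$labels, file.path(outdir, paste0(id, "_labels.nii.gz")))
    jsonlite::write_json(
      list(ga_weeks = s$ga_weeks, hemisphere = s$visible_hemisphere,
           rotation_deg = s$pose$rotation_deg,
           translation_mm = s$pose$translation_mm, seed = s$seed),
      file.path(outdir, paste0(id, ".json")), auto_unbox = TRUE, digits = NA)
  }
  write.csv(cohort_manifest(cohort), file.path(outdir, "manifest.csv"),
            row.names = FALSE)
  invisible(outdir)
}
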