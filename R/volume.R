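#' Structure classes segmented by the package
#'
#' Integer labels used in all labelmaps: 0 background, 1 choroid plexus (CP),
#' 2 lateral posterior ventricle horn (LPVH), 3 cavum septum pellucidum et
#' vergae (CSPV), 4 cerebellum (CB).
#'
#' @export
STRUCTURES <- c(CP = 1L, LPVH = 2L, CSPV = 3L, CB = 4L)

#' Create a 3D image volume
#'
#' A `volume3d` is a 3D numeric array with isotropic (or anisotropic) voxel
#' spacing in mm, an optional gestational age in weeks and an orientation
#' state recording whether the volume has been rigidly aligned to the
#' reference coordinate system.
#'
#' @param data 3D numeric array.
#' @param spacing voxel spacing in mm, length 1 (isotropic) or 3.
#' @param ga_weeks gestational age in weeks, or `NA`.
#' @param aligned logical; `TRUE` if in the reference space.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = 1, ga_weeks = NA_real_, aligned = TRUE) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  stopifnot(length(spacing) == 3, all(spacing > 0))
  structure(list(data = data, spacing = as.numeric(spacing),
                 ga_weeks = as.numeric(ga_weeks), aligned = isTRUE(aligned)),
            class = "volume3d")
}

#' Create a labelmap
#'
#' Integer class grid on the same lattice as its image, with label
#' provenance: `"expert"` (ground truth), `"atlas"` (propagated from a
#' template) or `"predicted"` (network output).
#'
#' @param data 3D integer array with values in 0..4.
#' @param spacing voxel spacing in mm.
#' @param provenance one of `"expert"`, `"atlas"`, `"predicted"`.
#' @return An object of class `labelmap`.
#' @export
labelmap <- function(data, spacing = 1,
                     provenance = c("expert", "atlas", "predicted")) {
  provenance <- match.arg(provenance)
  stopifnot(is.array(data), length(dim(data)) == 3)
  storage.mode(data) <- "integer"
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  structure(list(data = data, spacing = as.numeric(spacing),
                 provenance = provenance),
            class = "labelmap")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d> %dx%dx%d @ %.2f mm, GA %.1f wk, %s\n",
              d[1], d[2], d[3], x$spacing[1],
              x$ga_weeks, if (x$aligned) "aligned" else "unaligned"))
  invisible(x)
}

#' @export
print.labelmap <- function(x, ...) {
  d <- dim(x$data)
  tab <- table(factor(x$data, levels = 0:4))
  cat(sprintf("<labelmap> %dx%dx%d @ %.2f mm, provenance %s\n",
              d[1], d[2], d[3], x$spacing[1], x$provenance))
  cat("  voxels per class:", paste(names(tab), as.integer(tab),
                                   sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Voxel volume in cubic millimetres
#' @param spacing length-3 spacing in mm.
#' @return scalar mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(spacing) prod(spacing)

same_grid <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing))
}

#' Write a volume or labelmap to NIfTI-1
#'
#' @param x a `volume3d` or `labelmap`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(x$data, reference = NULL)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 file as a volume or labelmap
#'
#' @param path NIfTI path.
#' @param labels if `TRUE` return a `labelmap` (integer) else a `volume3d`.
#' @param ... passed to [volume3d()] or [labelmap()].
#' @export
read_volume <- function(path, labels = FALSE, ...) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  if (labels) labelmap(array(as.integer(round(arr)), dim(arr)), spacing = sp, ...)
  else volume3d(arr, spacing = sp, ...)
}
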