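## Post-processing and evaluation: largest-connected-component filtering,
## Dice overlap, 95th-percentile Hausdorff distance, relative volume
## differences.

as_mask <- function(x) {
  if (inherits(x, "labelmap")) x <- x$data
  if (inherits(x, "volume3d")) x <- x$data
  stopifnot(is.array(x), length(dim(x)) == 3)
  storage.mode(x) <- "logical"
  x
}

#' Keep the largest connected component of a binary mask
#'
#' Size ties are broken in favour of the component containing the
#' lexicographically smallest `(x, y, z)` voxel coordinate. An empty mask
#' is returned unchanged.
#'
#' @param mask logical 3D array (or labelmap treated as non-zero).
#' @param connectivity 6, 18 or 26.
#' @return Logical array with only the largest component retained.
#' @export
largest_component <- function(mask, connectivity = 26) {
  m <- as_mask(mask)
  if (!any(m)) return(m)
  stopifnot(connectivity %in% c(6, 18, 26))
  lab <- .label_components(m, dim(m), as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  winners <- which(sizes == max(sizes))
  if (length(winners) > 1) {
    ## compare lexicographically smallest member coordinates
    key <- lapply(winners, function(w) {
      ci <- which(lab == w, arr.ind = TRUE)
      ci[order(ci[, 1], ci[, 2], ci[, 3])[1], ]
    })
    ord <- order(vapply(key, `[`, 0, 1), vapply(key, `[`, 0, 2),
                 vapply(key, `[`, 0, 3))
    winners <- winners[ord[1]]
  }
  array(lab == winners, dim(m))
}

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks score 1 (no disagreement).
#'
#' @param a,b logical 3D arrays on the same grid.
#' @return Dice overlap in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!identical(dim(a), dim(b))) stop("mask grids do not match")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a & b) / (sa + sb)
}

#' 95th-percentile Hausdorff distance
#'
#' Symmetric-max convention: the larger of the two directed 95th-percentile
#' distances between the boundary voxel sets (voxels with a background
#' neighbour under `connectivity`; the grid edge counts as background), in
#' mm via the voxel spacing, with linear-interpolated percentiles.
#'
#' @param a,b logical 3D arrays on the same grid.
#' @param spacing_mm voxel spacing (length 1 or 3).
#' @param connectivity boundary-neighbour connectivity.
#' @return Distance in mm, or `NA` with a warning if either mask is empty
#'   (the comparison is undefined, not zero).
#' @export
hausdorff95 <- function(a, b, spacing_mm = 1, connectivity = 26) {
  a <- as_mask(a); b <- as_mask(b)
  if (!identical(dim(a), dim(b))) stop("mask grids do not match")
  if (!any(a) || !any(b)) {
    warning("hausdorff95 undefined for an empty mask")
    return(NA_real_)
  }
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  ba <- which(.boundary_mask(a, dim(a), as.integer(connectivity)), arr.ind = TRUE)
  bb <- which(.boundary_mask(b, dim(b), as.integer(connectivity)), arr.ind = TRUE)
  A <- sweep(ba, 2, spacing_mm, `*`)
  B <- sweep(bb, 2, spacing_mm, `*`)
  dab <- .min_dists(A, B)
  dba <- .min_dists(B, A)
  max(quantile(dab, 0.95, names = FALSE, type = 7),
      quantile(dba, 0.95, names = FALSE, type = 7))
}

#' Signed and unsigned relative volume differences
#'
#' Positive signed values indicate over-segmentation.
#'
#' @param pred,gt logical 3D arrays; `gt` must be non-empty.
#' @param spacing voxel spacing (unused by the ratio but kept for interface
#'   symmetry).
#' @return Named vector `c(signed_rvd, unsigned_rvd)`.
#' @export
volume_differences <- function(pred, gt, spacing = 1) {
  pred <- as_mask(pred); gt <- as_mask(gt)
  if (!any(gt)) stop("ground-truth mask is empty")
  s <- (sum(pred) - sum(gt)) / sum(gt)
  c(signed_rvd = s, unsigned_rvd = abs(s))
}

#' Per-class segmentation evaluation report
#'
#' @param pred,gt [labelmap()]s on the same grid.
#' @param spacing voxel spacing in mm (defaults to the prediction's).
#' @param post apply largest-connected-component post-processing to each
#'   predicted class first.
#' @param classes classes to evaluate.
#' @param connectivity passed to [largest_component()] and [hausdorff95()].
#' @return data.frame with columns class, structure, dsc, h95_mm,
#'   signed_rvd, unsigned_rvd, post_processed.
#' @export
evaluate_segmentation <- function(pred, gt, spacing = NULL, post = TRUE,
                                  classes = STRUCTURES, connectivity = 26) {
  if (is.null(spacing)) spacing <- pred$spacing
  rows <- lapply(seq_along(classes), function(i) {
    cls <- classes[[i]]
    pm <- pred$data == cls
    gm <- gt$data == cls
    if (post) pm <- largest_component(pm, connectivity)
    rvd <- if (any(gm)) volume_differences(pm, gm)
           else c(signed_rvd = NA_real_, unsigned_rvd = NA_real_)
    h95 <- if (any(pm) && any(gm)) hausdorff95(pm, gm, spacing, connectivity)
           else NA_real_
    data.frame(class = cls, structure = names(classes)[i],
               dsc = dice(pm, gm), h95_mm = h95,
               signed_rvd = rvd[["signed_rvd"]],
               unsigned_rvd = rvd[["unsigned_rvd"]],
               post_processed = post)
  })
  do.call(rbind, rows)
}
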