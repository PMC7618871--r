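## Per-gestational-week template construction by groupwise registration,
## hemisphere fusion at the midsagittal plane, and propagation of template
## labels back to individuals as weak "atlas" labels.

#' Create a template object
#'
#' @param intensity 3D array on the reference grid.
#' @param labels optional integer label array on the same grid.
#' @param ga_bin gestational week (or window label for clustered templates).
#' @param hemisphere `"left"`, `"right"`, `"fused"` or `"n/a"`.
#' @param member_ids ids of the images averaged into the template.
#' @param spacing voxel spacing in mm.
#' @return Object of class `brain_template`.
#' @export
brain_template <- function(intensity, labels = NULL, ga_bin = NA,
                           hemisphere = "n/a", member_ids = integer(),
                           spacing = 1) {
  if (!is.null(labels)) stopifnot(identical(dim(labels), dim(intensity)))
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  structure(list(intensity = intensity, labels = labels, ga_bin = ga_bin,
                 hemisphere = hemisphere, member_ids = member_ids,
                 spacing = spacing), class = "brain_template")
}

#' @export
print.brain_template <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<brain_template> %dx%dx%d, GA bin %s, %s, %d member(s), %s\n",
              d[1], d[2], d[3], paste(x$ga_bin, collapse = "-"),
              x$hemisphere, length(x$member_ids),
              if (is.null(x$labels)) "unlabelled" else "labelled"))
  invisible(x)
}

#' Round gestational age to its week bin (ties round down)
#' @param ga gestational age in weeks.
#' @return Integer week.
#' @export
ga_week_bin <- function(ga) as.integer(ceiling(ga - 0.5))

## extract plain arrays from volume3d / arrays
as_arr <- function(x) if (inherits(x, c("volume3d", "labelmap"))) x$data else x

#' Groupwise template construction
#'
#' Iteratively registers every member to the current voxelwise-mean template
#' with diffeomorphic demons and re-averages the deformed members. Iteration
#' stops early if the mean pairwise SSD between deformed members stops
#' decreasing. A single input returns itself with a zero field.
#'
#' @param samples list of [volume3d()]s (or arrays) on a common grid,
#'   rigidly aligned.
#' @param iters number of template refinement passes.
#' @param member_ids ids recorded on the template.
#' @param ga_bin,hemisphere metadata recorded on the template.
#' @param demons_iters per-level iterations for [demons_register()].
#' @param ... further arguments to [demons_register()].
#' @return List with `template` ([brain_template()]) and `fields`: one
#'   `deformation_field` per member (forward pull-back displacement from the
#'   member, plus its inverse).
#' @export
groupwise_template <- function(samples, iters = 2, member_ids = seq_along(samples),
                               ga_bin = NA, hemisphere = "n/a",
                               demons_iters = c(30, 20, 8), ...) {
  stopifnot(length(samples) >= 1)
  arrs <- lapply(samples, as_arr)
  dm <- dim(arrs[[1]])
  if (!all(vapply(arrs, function(a) identical(dim(a), dm), TRUE)))
    stop("all member volumes must share one grid")
  sp <- if (inherits(samples[[1]], "volume3d")) samples[[1]]$spacing else rep(1, 3)

  if (length(arrs) == 1) {
    fld <- structure(list(forward = zero_field(dm), inverse = zero_field(dm),
                          source_id = member_ids[1]), class = "deformation_field")
    return(list(template = brain_template(arrs[[1]], ga_bin = ga_bin,
                                          hemisphere = hemisphere,
                                          member_ids = member_ids,
                                          spacing = sp),
                fields = list(fld)))
  }

  tpl <- Reduce(`+`, arrs) / length(arrs)
  fields <- lapply(arrs, function(a) zero_field(dm))
  warped <- arrs
  pair_ssd <- function(ws) {
    s <- 0; np <- 0
    for (i in seq_along(ws)) for (j in seq_along(ws)) if (i < j) {
      s <- s + mean((ws[[i]] - ws[[j]])^2); np <- np + 1
    }
    s / np
  }
  best_ssd <- pair_ssd(warped)
  best_tpl <- tpl; best_fields <- fields
  for (it in seq_len(iters)) {
    ## residual refinement: register the current warped member to the
    ## template and compose, so displacement accumulates across passes
    ## instead of restarting against a ghosted mean image
    for (i in seq_along(arrs)) {
      r <- demons_register(tpl, warped[[i]], iters = demons_iters, ...)$disp
      fields[[i]] <- array(.compose_disp(fields[[i]], r, dm), c(dm, 3))
      warped[[i]] <- warp_array(arrs[[i]], fields[[i]])
    }
    tpl <- Reduce(`+`, warped) / length(warped)
    ssd <- pair_ssd(warped)
    if (ssd < best_ssd) {
      best_ssd <- ssd; best_tpl <- tpl; best_fields <- fields
    } else break
  }
  flds <- lapply(seq_along(best_fields), function(i)
    structure(list(forward = best_fields[[i]],
                   inverse = invert_field(best_fields[[i]]),
                   source_id = member_ids[i]), class = "deformation_field"))
  list(template = brain_template(best_tpl, ga_bin = ga_bin,
                                 hemisphere = hemisphere,
                                 member_ids = member_ids, spacing = sp),
       fields = flds)
}

#' Fuse left- and right-hemisphere templates at the midsagittal plane
#'
#' The fused template takes the left template's voxels on the left
#' half-lattice (first-axis index up to the central sagittal plane) and the
#' right template's voxels on the remaining half.
#'
#' @param left,right [brain_template()]s on the same grid with hemisphere
#'   tags `"left"` and `"right"`.
#' @return Fused [brain_template()] (hemisphere `"fused"`).
#' @export
fuse_hemispheres <- function(left, right) {
  if (!identical(dim(left$intensity), dim(right$intensity)))
    stop("template grids do not match")
  d <- dim(left$intensity)
  cut <- d[1] %/% 2
  intens <- right$intensity
  intens[seq_len(cut), , ] <- left$intensity[seq_len(cut), , ]
  labs <- NULL
  if (!is.null(left$labels) && !is.null(right$labels)) {
    labs <- right$labels
    labs[seq_len(cut), , ] <- left$labels[seq_len(cut), , ]
  }
  brain_template(intens, labs, ga_bin = left$ga_bin, hemisphere = "fused",
                 member_ids = c(left$member_ids, right$member_ids),
                 spacing = left$spacing)
}

#' Mirror a template across the midsagittal plane
#' @param tpl a [brain_template()].
#' @param hemisphere hemisphere tag of the mirrored result.
#' @return Mirrored template.
#' @export
mirror_template <- function(tpl, hemisphere) {
  n <- dim(tpl$intensity)[1]
  tpl$intensity <- tpl$intensity[n:1, , ]
  if (!is.null(tpl$labels)) tpl$labels <- tpl$labels[n:1, , ]
  tpl$hemisphere <- hemisphere
  tpl
}

#' Annotate a template by consensus of its members
#'
#' Forward-warps each member's labelmap into template space through its
#' deformation field and takes the per-voxel majority class (ties favour the
#' lower class index, background included). This plays the role of the
#' manual template annotation step when ground-truth member labels exist.
#'
#' @param tpl a [brain_template()].
#' @param fields list of `deformation_field`s from [groupwise_template()].
#' @param member_labels list of [labelmap()]s (or integer arrays), one per
#'   field.
#' @return The template with a `labels` array.
#' @export
annotate_template <- function(tpl, fields, member_labels) {
  stopifnot(length(fields) == length(member_labels))
  dm <- dim(tpl$intensity)
  counts <- array(0L, c(dm, 5))
  for (i in seq_along(fields)) {
    wl <- warp_array(as_arr(member_labels[[i]]), fields[[i]]$forward,
                     nearest = TRUE)
    for (cls in 0:4)
      counts[, , , cls + 1] <- counts[, , , cls + 1] + (wl == cls)
  }
  cm <- matrix(counts, ncol = 5)
  tpl$labels <- array(max.col(cm, ties.method = "first") - 1L, dm)
  tpl
}

#' Propagate template labels to individual images
#'
#' Resamples the template's labels through the inverse of each member's
#' deformation field (nearest neighbour); voxels mapping outside the grid
#' become background. Provenance of the outputs is `"atlas"`.
#'
#' @param tpl labelled [brain_template()].
#' @param fields list of `deformation_field`s with inverses.
#' @return List of [labelmap()]s, one per field.
#' @export
propagate_labels <- function(tpl, fields) {
  if (is.null(tpl$labels)) stop("template has no labels")
  lapply(fields, function(f) {
    if (is.null(f$inverse)) stop("deformation field has no inverse")
    labelmap(warp_array(tpl$labels, f$inverse, nearest = TRUE),
             spacing = tpl$spacing, provenance = "atlas")
  })
}

## restrict CP/LPVH labels to the member's visible half-lattice
restrict_to_hemisphere <- function(lab, hemisphere) {
  d <- dim(lab$data)
  cut <- d[1] %/% 2
  occluded <- if (hemisphere == "left") (cut + 1):d[1] else seq_len(cut)
  sub <- lab$data[occluded, , ]
  sub[sub %in% c(STRUCTURES[["CP"]], STRUCTURES[["LPVH"]])] <- 0L
  lab$data[occluded, , ] <- sub
  lab
}

#' Build per-week templates and propagate weak atlas labels for a cohort
#'
#' The full atlas-label pipeline at phantom scale: samples are rigidly
#' aligned, binned by gestational week, per-hemisphere templates are built
#' by groupwise registration from the members whose visible hemisphere
#' matches, annotated by member consensus, fused at the midsagittal plane,
#' and each member is then registered to its fused weekly template so the
#' template labels can be propagated back through the inverse field. CP and
#' LPVH labels are kept only in each member's visible hemisphere, matching
#' the annotation convention of the ground truth.
#'
#' @param cohort list of `cohort_sample`s.
#' @param iters groupwise refinement passes.
#' @param demons_iters per-level demons iterations.
#' @return List with `templates` (per week, fused + per-hemisphere),
#'   `atlas_labels` (one [labelmap()] per cohort member, provenance atlas)
#'   and `fields` (member registration to its weekly fused template).
#' @export
build_atlas_labels <- function(cohort, iters = 1, demons_iters = c(30, 20, 8)) {
  aligned <- lapply(cohort, align_sample)
  weeks <- vapply(aligned, function(s) ga_week_bin(s$ga_weeks), 0L)
  sp <- aligned[[1]]$image$spacing
  out_templates <- list()
  atlas_labels <- vector("list", length(cohort))
  fields_out <- vector("list", length(cohort))
  for (w in sort(unique(weeks))) {
    ids <- which(weeks == w)
    hemi_tpl <- list()
    for (h in c("left", "right")) {
      hid <- ids[vapply(aligned[ids], function(s) s$visible_hemisphere, "") == h]
      if (!length(hid)) next
      gw <- groupwise_template(lapply(aligned[hid], `[[`, "image"),
                               iters = iters, member_ids = hid, ga_bin = w,
                               hemisphere = h, demons_iters = demons_iters)
      hemi_tpl[[h]] <- annotate_template(gw$template, gw$fields,
                                         lapply(aligned[hid], `[[`, "labels"))
    }
    if (is.null(hemi_tpl$left) && is.null(hemi_tpl$right))
      stop("empty gestational-week bin")
    if (is.null(hemi_tpl$left))
      hemi_tpl$left <- mirror_template(hemi_tpl$right, "left")
    if (is.null(hemi_tpl$right))
      hemi_tpl$right <- mirror_template(hemi_tpl$left, "right")
    fused <- fuse_hemispheres(hemi_tpl$left, hemi_tpl$right)
    out_templates[[as.character(w)]] <-
      list(fused = fused, left = hemi_tpl$left, right = hemi_tpl$right)
    for (i in ids) {
      reg <- demons_register(fused$intensity, as_arr(aligned[[i]]$image),
                             iters = demons_iters)
      fld <- structure(list(forward = reg$disp,
                            inverse = invert_field(reg$disp),
                            source_id = i), class = "deformation_field")
      fields_out[[i]] <- fld
      lab <- propagate_labels(fused, list(fld))[[1]]
      atlas_labels[[i]] <-
        restrict_to_hemisphere(lab, aligned[[i]]$visible_hemisphere)
    }
  }
  list(templates = out_templates, atlas_labels = atlas_labels,
       fields = fields_out)
}
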