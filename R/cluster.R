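## Cluster-based LPVH template construction: crop around the LPVH,
## histogram-equalize, pairwise demons registration + SSD distance matrix,
## k-medoids with seeded restarts, outlier handling, per-cluster templates.

#' Histogram-equalize intensities to [0, 1]
#'
#' Rank-based equalization; a constant image stays at a single level.
#'
#' @param a numeric array.
#' @return Array of the same shape with near-uniform intensity distribution.
#' @export
hist_equalize <- function(a) {
  r <- rank(a, ties.method = "average")
  array((r - 0.5) / length(a), dim(a))
}

## binary dilation by `r` steps of the 26-neighbourhood
dilate_mask <- function(mask, r = 1) {
  d <- dim(mask)
  for (step in seq_len(r)) {
    out <- mask
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      xs <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
      ys <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
      zs <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
      out <- out | mask[xs, ys, zs]
    }
    mask <- out
  }
  mask
}

#' Crop and normalize volumes around the LPVH
#'
#' Right-hemisphere samples are mirrored across the midline first so that
#' all LPVHs sit in the same hemisphere, then a fixed bounding box is
#' extracted and histogram-equalized to `[0, 1]`.
#'
#' @param samples list of `cohort_sample`s (rigidly aligned).
#' @param bbox list with `lo` and `hi`, 1-based inclusive voxel corners,
#'   identical for all members of the window.
#' @return List of equalized crop arrays; mirrored ground-truth LPVH crop
#'   masks are attached as attribute `"lpvh"` on each element.
#' @export
prepare_crops <- function(samples, bbox) {
  d <- dim(samples[[1]]$image$data)
  if (any(bbox$lo < 1) || any(bbox$hi > d)) stop("bbox exceeds the image grid")
  lapply(samples, function(s) {
    img <- s$image$data
    lab <- s$labels$data
    if (s$visible_hemisphere == "right") {
      img <- img[d[1]:1, , ]
      lab <- lab[d[1]:1, , ]
    }
    cr <- img[bbox$lo[1]:bbox$hi[1], bbox$lo[2]:bbox$hi[2],
              bbox$lo[3]:bbox$hi[3]]
    lp <- lab[bbox$lo[1]:bbox$hi[1], bbox$lo[2]:bbox$hi[2],
              bbox$lo[3]:bbox$hi[3]] == STRUCTURES[["LPVH"]]
    out <- hist_equalize(cr)
    attr(out, "lpvh") <- lp
    out
  })
}

#' Fixed LPVH bounding box for a set of aligned samples
#'
#' Union of the (mirrored-to-left) ground-truth LPVH extents over the
#' members, dilated by a margin; identical box for every member.
#'
#' @param samples list of `cohort_sample`s.
#' @param margin dilation margin in voxels.
#' @return List with `lo` and `hi` voxel corners.
#' @export
lpvh_bbox <- function(samples, margin = 4) {
  d <- dim(samples[[1]]$labels$data)
  lo <- d; hi <- c(1, 1, 1)
  for (s in samples) {
    lab <- s$labels$data
    if (s$visible_hemisphere == "right") lab <- lab[d[1]:1, , ]
    w <- which(lab == STRUCTURES[["LPVH"]], arr.ind = TRUE)
    if (!nrow(w)) next
    lo <- pmin(lo, apply(w, 2, min))
    hi <- pmax(hi, apply(w, 2, max))
  }
  list(lo = pmax(1, lo - margin), hi = pmin(d, hi + margin))
}

#' Pairwise SSD distance matrix between registered crops
#'
#' `D[i, j]` is the sum of squared differences over the region of interest
#' between crop `j` deformed onto crop `i` (demons registration) and crop
#' `i`. The matrix is symmetrized as `(D + t(D)) / 2` with a zero diagonal.
#'
#' @param crops list of arrays on a common grid.
#' @param roi_mask logical array within the crop.
#' @param register if `FALSE`, skip registration (plain SSD).
#' @param demons_iters per-level demons iterations.
#' @return Object of class `distance_matrix` (a symmetric matrix).
#' @export
pairwise_ssd <- function(crops, roi_mask, register = TRUE,
                         demons_iters = c(20, 10)) {
  n <- length(crops)
  stopifnot(n >= 2)
  if (!any(roi_mask)) stop("empty region of interest")
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    mj <- if (register)
      warp_array(crops[[j]],
                 demons_register(crops[[i]], crops[[j]],
                                 iters = demons_iters)$disp)
    else crops[[j]]
    D[i, j] <- sum((mj[roi_mask] - crops[[i]][roi_mask])^2)
  }
  D <- (D + t(D)) / 2
  diag(D) <- 0
  structure(D, class = c("distance_matrix", "matrix"))
}

pam_assign <- function(D, medoids) {
  medoids[apply(D[, medoids, drop = FALSE], 1, which.min)]
}

pam_cost <- function(D, medoids) {
  sum(apply(D[, medoids, drop = FALSE], 1, min))
}

## one PAM run: random medoid init, best-improvement swap until convergence
pam_once <- function(D, k) {
  n <- nrow(D)
  medoids <- sort(sample.int(n, k))
  cost <- pam_cost(D, medoids)
  repeat {
    best_delta <- 0; best_sw <- NULL
    for (m in medoids) for (h in setdiff(seq_len(n), medoids)) {
      cand <- sort(c(setdiff(medoids, m), h))
      delta <- pam_cost(D, cand) - cost
      if (delta < best_delta - 1e-12) { best_delta <- delta; best_sw <- cand }
    }
    if (is.null(best_sw)) break
    medoids <- best_sw
    cost <- cost + best_delta
  }
  list(medoids = medoids, cost = cost)
}

#' K-medoids clustering with seeded restarts and minimum cluster size
#'
#' PAM-style swap optimization from random medoid initializations. Restart
#' `r` uses seed `seed + r`; restarts whose solution contains a cluster with
#' fewer than `min_size` members are discarded. Among valid restarts the
#' lowest cost wins; exact cost ties are broken by the lexicographically
#' smallest medoid index set.
#'
#' @param D distance matrix (symmetric, zero diagonal).
#' @param k number of clusters (`k <= n`).
#' @param restarts number of seeded restarts (>= 1).
#' @param min_size minimum members per cluster.
#' @param seed base seed of the restart chain.
#' @return Object of class `clustering`: assignments (medoid id per member),
#'   medoids, cost, n_c, n_restarts, and the restart that won.
#' @export
k_medoids <- function(D, k, restarts = 500, min_size = 3, seed = 1) {
  D <- unclass(D)
  n <- nrow(D)
  stopifnot(k >= 1, k <= n, restarts >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + r)
    sol <- pam_once(D, k)
    assign_m <- pam_assign(D, sol$medoids)
    sizes <- table(factor(assign_m, levels = sol$medoids))
    if (any(sizes < min_size)) next
    better <- is.null(best) || sol$cost < best$cost - 1e-12 ||
      (abs(sol$cost - best$cost) <= 1e-12 &&
         isTRUE(vec_less(sol$medoids, best$medoids)))
    if (better)
      best <- list(medoids = sol$medoids, cost = sol$cost,
                   assignments = assign_m, winning_restart = r)
  }
  if (is.null(best))
    stop("no restart produced clusters of at least min_size members; ",
         "consider a smaller k")
  structure(list(assignments = best$assignments, medoids = best$medoids,
                 cost = best$cost, n_c = k, n_restarts = restarts,
                 winning_restart = best$winning_restart, seed = seed),
            class = "clustering")
}

## lexicographic strictly-less for equal-length integer vectors
vec_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Flag distance-matrix outliers
#'
#' A member is an outlier when its median distance to all others exceeds
#' the cohort mean of those medians by `z` standard deviations. Outliers
#' are meant to be excluded before clustering and assigned to the nearest
#' medoid afterwards ([assign_outliers()]); templates are built including
#' them.
#'
#' @param D distance matrix.
#' @param z threshold in standard deviations.
#' @param max_frac warn (and proceed) if more than this fraction is flagged.
#' @return List with `core` and `outliers` (member indices).
#' @export
handle_outliers <- function(D, z = 2, max_frac = 0.2) {
  D <- unclass(D)
  n <- nrow(D)
  med <- vapply(seq_len(n), function(i) median(D[i, -i]), 0)
  thr <- mean(med) + z * sd(med)
  out <- which(med > thr)
  if (length(out) > max_frac * n)
    warning(sprintf("outlier rule excluded %d/%d members; proceeding", length(out), n))
  list(core = setdiff(seq_len(n), out), outliers = out)
}

#' Assign outliers to the cluster of their nearest medoid
#'
#' @param D distance matrix over all members.
#' @param clustering a `clustering` over the core members (indices into `D`).
#' @param outliers outlier member indices.
#' @return Named integer vector: medoid id for each outlier.
#' @export
assign_outliers <- function(D, clustering, outliers) {
  D <- unclass(D)
  vapply(outliers, function(i)
    clustering$medoids[which.min(D[i, clustering$medoids])], 0L)
}

#' Build one template per cluster
#'
#' Groupwise registration of each cluster's member crops (outliers that were
#' assigned post hoc are included) and consensus annotation of the LPVH.
#'
#' @param crops list of crop arrays (with `"lpvh"` attribute masks, as
#'   produced by [prepare_crops()]).
#' @param assignments medoid id per member (over all members).
#' @param min_size error if any cluster has fewer members.
#' @param ga_bin window label recorded on the templates.
#' @param demons_iters per-level demons iterations.
#' @return List of labelled [brain_template()]s (one per cluster, named by
#'   medoid), each with `fields` attribute holding member fields.
#' @export
build_cluster_templates <- function(crops, assignments, min_size = 1,
                                    ga_bin = NA, demons_iters = c(20, 10)) {
  meds <- sort(unique(assignments))
  out <- list()
  for (m in meds) {
    ids <- which(assignments == m)
    if (length(ids) < min_size)
      stop("cluster below min_size after outlier reassignment")
    gw <- groupwise_template(crops[ids], iters = 1, member_ids = ids,
                             ga_bin = ga_bin, demons_iters = demons_iters)
    member_labs <- lapply(crops[ids], function(cr)
      array(as.integer(attr(cr, "lpvh")) * STRUCTURES[["LPVH"]],
            dim(cr)))
    tpl <- annotate_template(gw$template, gw$fields, member_labs)
    attr(tpl, "fields") <- gw$fields
    out[[as.character(m)]] <- tpl
  }
  out
}

#' Two-week gestational windows tiling [18, 26]
#' @return List of `c(lo, hi)` integer week windows.
#' @export
ga_windows <- function() list(c(18, 19), c(20, 21), c(22, 23), c(24, 25), c(26, 26))

#' Clustered LPVH atlas labels for a cohort
#'
#' For each two-week gestational window: crop the (mirrored, equalized)
#' LPVH region, compute the pairwise registered SSD matrix over the dilated
#' LPVH region of interest, exclude outliers, k-medoids cluster the rest,
#' reassign outliers to their nearest medoid, build one template per
#' cluster (outliers included) and propagate each cluster template's LPVH
#' annotation back to its members through the inverse fields.
#'
#' @param cohort list of `cohort_sample`s.
#' @param k clusters per window (capped at the window size).
#' @param restarts,min_size,seed passed to [k_medoids()].
#' @param demons_iters per-level demons iterations at crop scale.
#' @return List with per-window results and `atlas_labels`: full-grid LPVH
#'   [labelmap()]s (provenance atlas), one per cohort member.
#' @export
cluster_atlas_lpvh <- function(cohort, k = 4, restarts = 50, min_size = 1,
                               seed = 1, demons_iters = c(30, 20)) {
  aligned <- lapply(cohort, align_sample)
  weeks <- vapply(aligned, function(s) ga_week_bin(s$ga_weeks), 0L)
  d <- dim(aligned[[1]]$image$data)
  atlas <- vector("list", length(cohort))
  windows_out <- list()
  for (wi in seq_along(ga_windows())) {
    w <- ga_windows()[[wi]]
    ids <- which(weeks >= w[1] & weeks <= w[2])
    if (!length(ids)) next
    samples <- aligned[ids]
    bbox <- lpvh_bbox(samples)
    crops <- prepare_crops(samples, bbox)
    roi <- Reduce(`|`, lapply(crops, attr, "lpvh"))
    roi <- dilate_mask(roi, 2)
    if (length(ids) == 1) {
      assignments <- 1L
      clust <- NULL
    } else {
      D <- pairwise_ssd(crops, roi, demons_iters = demons_iters)
      o <- handle_outliers(D)
      kk <- min(k, length(o$core))
      clust <- k_medoids(unclass(D)[o$core, o$core, drop = FALSE], kk,
                         restarts = restarts, min_size = min_size,
                         seed = seed + wi)
      assignments <- integer(length(ids))
      assignments[o$core] <- o$core[match(clust$assignments,
                                          seq_along(o$core))]
      if (length(o$outliers)) {
        glob <- clust
        glob$medoids <- o$core[clust$medoids]
        assignments[o$outliers] <- assign_outliers(D, glob, o$outliers)
      }
    }
    tpls <- build_cluster_templates(crops, assignments, min_size = 1,
                                    ga_bin = w, demons_iters = demons_iters)
    for (m in names(tpls)) {
      tpl <- tpls[[m]]
      flds <- attr(tpl, "fields")
      labs <- propagate_labels(tpl, flds)
      for (j in seq_along(flds)) {
        local_id <- flds[[j]]$source_id
        gid <- ids[local_id]
        full <- array(0L, d)
        s <- samples[[local_id]]
        bb <- bbox
        cr_lab <- labs[[j]]$data
        full[bb$lo[1]:bb$hi[1], bb$lo[2]:bb$hi[2], bb$lo[3]:bb$hi[3]] <- cr_lab
        if (s$visible_hemisphere == "right") full <- full[d[1]:1, , ]
        atlas[[gid]] <- labelmap(full, spacing = s$image$spacing,
                                 provenance = "atlas")
      }
    }
    windows_out[[wi]] <- list(window = w, ids = ids, clustering = clust,
                              assignments = assignments, templates = tpls)
  }
  list(windows = windows_out, atlas_labels = atlas)
}
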