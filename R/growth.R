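## Volumetric growth curves: structure volumes from predicted labelmaps,
## whole-brain volume by affine mask registration, relative volumes, and
## per-structure polynomial fits with a significance-gated quadratic term
## and 95% prediction intervals.

#' Volume of one labelled structure
#'
#' Voxel count of the class times the voxel volume, in cm^3, computed after
#' largest-connected-component post-processing by default.
#'
#' @param labels a [labelmap()] or integer array.
#' @param class class id (1..4).
#' @param spacing_mm voxel spacing (default from the labelmap).
#' @param post apply [largest_component()] first.
#' @return Volume in cm^3 (0 with a warning if the class is absent).
#' @export
structure_volume <- function(labels, class, spacing_mm = NULL, post = TRUE) {
  if (inherits(labels, "labelmap")) {
    if (is.null(spacing_mm)) spacing_mm <- labels$spacing
    labels <- labels$data
  }
  if (is.null(spacing_mm)) spacing_mm <- 1
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  stopifnot(class %in% 1:4)
  m <- labels == class
  if (!any(m)) {
    warning(sprintf("class %d absent from labelmap", class))
    return(0)
  }
  if (post) m <- largest_component(m)
  sum(m) * prod(spacing_mm) / 1000
}

#' Whole-brain volume by affine mask registration
#'
#' Registers a binary whole-brain template mask to the image with an affine
#' transform (rigid + isotropic scale; Nelder-Mead over translation,
#' rotation and log-scale, initialized from intensity moments) and reports
#' the warped mask volume. The image is binarized with an iterative
#' two-means (Ridler-Calvard) threshold to define the registration target.
#'
#' @param image a [volume3d()].
#' @param brain_template_mask logical 3D array on the same grid.
#' @param ga gestational age (recorded; template selection is the caller's
#'   via [select_brain_template()]).
#' @param maxit optimizer iterations.
#' @return Volume in cm^3, with the fitted parameters as attribute `fit`.
#' @export
whole_brain_volume <- function(image, brain_template_mask, ga = NA,
                               maxit = 150) {
  img <- as_arr(image)
  sp <- if (inherits(image, "volume3d")) image$spacing else rep(1, 3)
  d <- dim(img)
  stopifnot(identical(dim(brain_template_mask), d))
  ## Ridler-Calvard two-means threshold, relaxed to 60% so that
  ## shadow-attenuated brain tissue stays inside the target mask
  th <- mean(range(img))
  for (i in 1:8) th <- (mean(img[img <= th]) + mean(img[img > th])) / 2
  target <- img > 0.6 * th
  tm <- brain_template_mask + 0.0

  sub <- function(a) a[seq(1, d[1], 2), seq(1, d[2], 2), seq(1, d[3], 2)]
  tgt_s <- sub(target) + 0.0
  ds <- dim(tgt_s)

  ci <- function(m) {
    w <- which(m > 0.5, arr.ind = TRUE)
    colMeans(w)
  }
  t0 <- ci(target) - ci(brain_template_mask)
  s0 <- (sum(target) / max(sum(brain_template_mask), 1))^(1 / 3)
  p0 <- c(t0 / 2, 0, 0, 0, log(s0))

  cost <- function(p) {
    R <- rot_matrix(p[4:6])
    s <- exp(p[7])
    c0 <- (ds - 1) / 2
    Ainv <- t(R) / s
    b <- as.numeric(c0 - Ainv %*% (c0 + p[1:3]))
    w <- .affine_resample(sub(tm), cbind(Ainv, b), ds, FALSE)
    mean((w - tgt_s)^2)
  }
  cost_full <- function(p) {
    R <- rot_matrix(p[4:6])
    s <- exp(p[7])
    c0 <- (d - 1) / 2
    Ainv <- t(R) / s
    b <- as.numeric(c0 - Ainv %*% (c0 + p[1:3]))
    w <- .affine_resample(tm, cbind(Ainv, b), d, FALSE)
    mean((w - (target + 0.0))^2)
  }
  c_init <- cost(p0)
  opt <- optim(p0, cost, method = "Nelder-Mead", control = list(maxit = maxit))
  ## refine at full resolution (translations were in half-resolution voxels)
  p1 <- c(2 * opt$par[1:3], opt$par[4:7])
  opt2 <- optim(p1, cost_full, method = "Nelder-Mead",
                control = list(maxit = maxit))
  if (opt$value > c_init + 1e-12)
    stop("affine registration failed to improve the alignment cost")
  ## warp at full resolution and count
  R <- rot_matrix(opt2$par[4:6])
  s <- exp(opt2$par[7])
  c0 <- (d - 1) / 2
  Ainv <- t(R) / s
  b <- as.numeric(c0 - Ainv %*% (c0 + opt2$par[1:3]))
  w <- .affine_resample(tm, cbind(Ainv, b), d, TRUE)
  v <- sum(w > 0.5) * prod(sp) / 1000
  attr(v, "fit") <- list(par = opt$par, cost = opt$value, init_cost = c_init)
  v
}

#' Select the brain-mask template for a gestational week
#'
#' Rounded-week lookup; ages below the youngest available template use the
#' youngest one (configurable floor), ages above use the oldest.
#'
#' @param ga gestational age in weeks.
#' @param templates named list of masks, names are integer weeks.
#' @param floor_week youngest week to use (default: youngest available).
#' @return The selected template mask.
#' @export
select_brain_template <- function(ga, templates, floor_week = NULL) {
  weeks <- sort(as.integer(names(templates)))
  floor_week <- floor_week %||% min(weeks)
  w <- max(ga_week_bin(ga), floor_week)
  w <- min(max(w, min(weeks)), max(weeks))
  templates[[as.character(w)]]
}

#' Brain-relative structure volume
#'
#' @param v structure volume in cm^3.
#' @param v_brain whole-brain volume in cm^3 (> 0).
#' @return `v / v_brain`.
#' @export
relative_volume <- function(v, v_brain) {
  if (v_brain <= 0) stop("v_brain must be positive")
  v / v_brain
}

#' Per-sample volume records for growth-curve fitting
#'
#' @param labelmaps list of predicted [labelmap()]s.
#' @param ga_weeks gestational ages, one per labelmap.
#' @param v_brain whole-brain volumes in cm^3, one per labelmap.
#' @param model_tag `"expert"` or `"atlas"` model provenance.
#' @param post post-process before measuring volumes.
#' @return data.frame: id, ga_weeks, structure, volume_cm3, v_brain_cm3,
#'   v_rel_brain, model.
#' @export
volume_records <- function(labelmaps, ga_weeks, v_brain, model_tag, post = TRUE) {
  rows <- list()
  for (i in seq_along(labelmaps)) {
    for (nm in names(STRUCTURES)) {
      v <- suppressWarnings(
        structure_volume(labelmaps[[i]], STRUCTURES[[nm]], post = post))
      rows[[length(rows) + 1]] <- data.frame(
        id = i, ga_weeks = ga_weeks[i], structure = nm, volume_cm3 = v,
        v_brain_cm3 = v_brain[i],
        v_rel_brain = relative_volume(v, v_brain[i]), model = model_tag)
    }
  }
  do.call(rbind, rows)
}

#' Fit a growth curve with a significance-gated quadratic term
#'
#' Ordinary least squares of volume on gestational age, per model tag. The
#' quadratic term is retained only when its two-sided t-test is significant
#' at `alpha` for every model tag present (the underlying growth must be
#' the same regardless of which network produced the volumes). 95%
#' prediction intervals come from the retained model. Works identically for
#' absolute (`volume_cm3`) and relative (`v_rel_brain`) responses.
#'
#' @param records data.frame with columns `ga_weeks`, `model` and the
#'   response; typically one structure's subset of [volume_records()].
#' @param response column to fit, `"volume_cm3"` or `"v_rel_brain"`.
#' @param alpha significance level of the quadratic gate.
#' @param min_n,min_span minimum records and gestational-age span per tag.
#' @return Named list (one `growth_fit` per model tag). Each carries the
#'   fitted `lm`, degree, coefficients, residual variance and the
#'   quadratic p-values of all tags.
#' @export
fit_growth_curve <- function(records, response = "volume_cm3", alpha = 0.05,
                             min_n = 10, min_span = 4) {
  stopifnot(response %in% names(records))
  tags <- unique(records$model)
  qp <- setNames(numeric(length(tags)), tags)
  for (tg in tags) {
    r <- records[records$model == tg, ]
    if (nrow(r) < min_n)
      stop("need at least ", min_n, " records per model tag")
    if (diff(range(r$ga_weeks)) < min_span)
      stop("insufficient gestational-age spread")
    fq <- lm(r[[response]] ~ ga_weeks + I(ga_weeks^2), data = r)
    ct <- summary(fq)$coefficients
    p <- if ("I(ga_weeks^2)" %in% rownames(ct)) ct["I(ga_weeks^2)", 4] else NA
    ## degenerate zero-residual fits report the quadratic as non-significant
    qp[tg] <- if (is.finite(p)) p else 1
  }
  degree <- if (all(qp < alpha)) 2L else 1L
  out <- list()
  for (tg in tags) {
    r <- records[records$model == tg, ]
    fit <- if (degree == 2)
      lm(r[[response]] ~ ga_weeks + I(ga_weeks^2), data = r)
    else lm(r[[response]] ~ ga_weeks, data = r)
    out[[tg]] <- structure(
      list(structure = if ("structure" %in% names(r))
             as.character(r$structure[1]) else NA_character_,
           model_tag = tg, response = response, degree = degree,
           coefficients = coef(fit), sigma2 = summary(fit)$sigma^2,
           quadratic_p_values = qp, alpha = alpha, fit = fit,
           n = nrow(r), ga_range = range(r$ga_weeks)),
      class = "growth_fit")
  }
  out
}

#' Predict from a growth fit with 95% prediction intervals
#'
#' @param object a `growth_fit`.
#' @param ga_weeks ages to predict at.
#' @param level interval level.
#' @param ... unused.
#' @return data.frame: ga_weeks, fit, lwr, upr.
#' @export
predict.growth_fit <- function(object, ga_weeks, level = 0.95, ...) {
  nd <- data.frame(ga_weeks = ga_weeks)
  p <- predict(object$fit, newdata = nd, interval = "prediction",
               level = level)
  data.frame(ga_weeks = ga_weeks, fit = p[, "fit"], lwr = p[, "lwr"],
             upr = p[, "upr"])
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> %s (%s, %s): degree %d, n = %d\n",
              x$structure %||% "?", x$model_tag, x$response, x$degree, x$n))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Tidy coefficient table of a growth fit
#' @param x a `growth_fit`.
#' @param ... unused.
#' @return data.frame of terms, estimates, standard errors and p-values.
#' @export
tidy.growth_fit <- function(x, ...) {
  ct <- summary(x$fit)$coefficients
  data.frame(term = rownames(ct), estimate = ct[, 1], std.error = ct[, 2],
             statistic = ct[, 3], p.value = ct[, 4], row.names = NULL)
}

#' One-row summary of a growth fit
#' @param x a `growth_fit`.
#' @param ... unused.
#' @return data.frame with degree, sigma, r.squared, n and the quadratic
#'   gate outcome.
#' @export
glance.growth_fit <- function(x, ...) {
  s <- summary(x$fit)
  data.frame(structure = x$structure, model = x$model_tag, degree = x$degree,
             sigma = s$sigma, r.squared = s$r.squared, n = x$n,
             quadratic_retained = x$degree == 2L)
}

#' Plot a growth fit with its 95% prediction band
#'
#' @param x a `growth_fit`.
#' @param records optional data.frame of the underlying records to overlay.
#' @param n_grid curve resolution.
#' @param ... passed to `plot`.
#' @export
plot.growth_fit <- function(x, records = NULL, n_grid = 100, ...) {
  ga <- seq(x$ga_range[1], x$ga_range[2], length.out = n_grid)
  pr <- predict(x, ga)
  ylim <- range(pr$lwr, pr$upr,
                if (!is.null(records)) records[[x$response]])
  plot(ga, pr$fit, type = "n", xlab = "gestational age (weeks)",
       ylab = x$response, ylim = ylim,
       main = sprintf("%s (%s)", x$structure %||% "", x$model_tag), ...)
  polygon(c(ga, rev(ga)), c(pr$lwr, rev(pr$upr)),
          col = rgb(0.85, 0.3, 0.3, 0.2), border = NA)
  lines(ga, pr$fit, lwd = 2)
  lines(ga, pr$lwr, lty = 2, col = "red3")
  lines(ga, pr$upr, lty = 2, col = "red3")
  if (!is.null(records))
    points(records$ga_weeks, records[[x$response]], pch = 19, cex = 0.6,
           col = rgb(0.2, 0.2, 0.6, 0.6))
  invisible(x)
}
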