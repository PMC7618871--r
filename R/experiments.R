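## Desk-scale study runners: canned experiments that reproduce the study's
## comparative findings on phantom cohorts. Both the test suite and
## scripts/acceptance.R drive these.

#' Weak atlas-label fidelity study
#'
#' Generates an unaligned phantom cohort, builds per-week fused templates
#' and propagates weak atlas labels, then measures their per-structure Dice
#' against the phantom ground truth; additionally builds cluster-based LPVH
#' templates and compares single-template versus clustered LPVH label
#' fidelity.
#'
#' @param seed base seed.
#' @param n cohort size.
#' @param config phantom configuration (desk default 64^3).
#' @param k,restarts clustering settings per two-week window.
#' @return List: `dsc` (4 x n matrix, rows CP/LPVH/CSPV/CB), `mean_dsc`
#'   (named per structure), `lpvh_single`, `lpvh_clustered` (per-member
#'   Dice vectors), and `single_component_fraction` (per class, the share
#'   of members whose propagated label is one connected component).
#' @export
run_atlas_label_study <- function(seed = 1, n = 20, config = phantom_config(),
                                  k = 4, restarts = 50) {
  cohort <- make_cohort(n, c(18, 26), seed = seed, config = config,
                        aligned = FALSE)
  atl <- build_atlas_labels(cohort)
  aligned <- lapply(cohort, align_sample)
  dsc <- vapply(seq_len(n), function(i)
    evaluate_segmentation(atl$atlas_labels[[i]], aligned[[i]]$labels,
                          post = FALSE)$dsc, numeric(4))
  rownames(dsc) <- names(STRUCTURES)
  cl <- cluster_atlas_lpvh(cohort, k = k, restarts = restarts,
                           seed = seed + 1)
  lp <- STRUCTURES[["LPVH"]]
  lpvh_single <- vapply(seq_len(n), function(i)
    dice(atl$atlas_labels[[i]]$data == lp, aligned[[i]]$labels$data == lp), 0)
  lpvh_clustered <- vapply(seq_len(n), function(i)
    dice(cl$atlas_labels[[i]]$data == lp, aligned[[i]]$labels$data == lp), 0)
  ## topology sanity: fraction of members whose propagated class stays one
  ## connected component (26-connectivity)
  single_component <- vapply(seq_along(STRUCTURES), function(cls) {
    mean(vapply(atl$atlas_labels, function(l) {
      m <- l$data == cls
      if (!any(m)) return(NA)
      max(.label_components(m, dim(m), 26L)) == 1
    }, NA), na.rm = TRUE)
  }, 0)
  names(single_component) <- names(STRUCTURES)
  list(dsc = dsc, mean_dsc = rowMeans(dsc), lpvh_single = lpvh_single,
       lpvh_clustered = lpvh_clustered,
       single_component_fraction = single_component)
}

## training phantom configuration at a given grid size
training_phantom_config <- function(size = 48) {
  phantom_config(size = size, spacing = 1.2,
                 brain_scale = if (size >= 64) 0.5 else 0.35)
}

## desk-scale augmentation: translations capped so the brain stays in view
desk_augmentation_spec <- function() augmentation_spec(translation_max_vox = 6)

#' Scaled-down training study
#'
#' Trains a reduced U-Net on an aligned phantom cohort and reports held-out
#' per-structure Dice.
#'
#' @param seed base seed (phantom cohort and network).
#' @param n_train,n_test cohort sizes.
#' @param size grid size.
#' @param iterations optimizer steps.
#' @param depth,features reduced network size.
#' @param batch_size,learning_rate desk-scale optimizer settings.
#' @return List: `model`, `dsc` (4 x n_test), `mean_fg_dsc`, `h95`
#'   (4 x n_test, mm).
#' @export
run_training_study <- function(seed = 1, n_train = 16, n_test = 6, size = 48,
                               iterations = 200, depth = 3, features = 8,
                               batch_size = 2, learning_rate = 0.01) {
  cfgp <- training_phantom_config(size)
  train <- make_cohort(n_train, c(18, 26), seed = seed, config = cfgp)
  test <- make_cohort(n_test, c(18, 26), seed = seed + 1000, config = cfgp)
  cfg <- seg_config(depth = depth, init_features = features,
                    batch_size = batch_size, iteration_budget = iterations,
                    learning_rate = learning_rate, seed = seed)
  model <- train_segmenter(train, cfg, desk_augmentation_spec())
  ev <- lapply(test, function(s)
    evaluate_segmentation(predict_labels(model, s$image), s$labels))
  dsc <- vapply(ev, `[[`, numeric(4), "dsc")
  h95 <- vapply(ev, `[[`, numeric(4), "h95_mm")
  rownames(dsc) <- rownames(h95) <- names(STRUCTURES)
  list(model = model, dsc = dsc, mean_fg_dsc = mean(dsc), h95 = h95)
}

#' Two-sample overfit check
#'
#' Trains on two phantoms only and reports the training-loss reduction and
#' the Dice of re-predicting a training sample — a functional test that the
#' optimizer and loss can drive the network to memorize its inputs.
#'
#' @param seed base seed.
#' @param size grid size (32 keeps the check fast).
#' @param iterations optimizer steps.
#' @param learning_rate desk-scale learning rate.
#' @return List: `loss_initial`, `loss_final`, `reduction` (fraction of the
#'   initial loss removed), `reduction_at_300` (same, at the 300-iteration
#'   mark of the log), `train_dsc` (4-vector).
#' @export
run_overfit_study <- function(seed = 1, size = 32, iterations = 500,
                              learning_rate = 0.01) {
  cfgp <- training_phantom_config(size)
  s1 <- make_phantom(20, seed = seed, config = cfgp)
  s2 <- make_phantom(25, seed = seed + 1, config = cfgp)
  cfg <- seg_config(depth = 3, init_features = 8, batch_size = 2,
                    iteration_budget = iterations,
                    learning_rate = learning_rate, seed = seed)
  m <- train_segmenter(list(s1, s2), cfg, augment_data = FALSE)
  dsc <- evaluate_segmentation(predict_labels(m, s1$image), s1$labels)$dsc
  at300 <- min(300, iterations)
  list(loss_initial = m$log$loss[1], loss_final = tail(m$log$loss, 1),
       reduction = 1 - tail(m$log$loss, 1) / m$log$loss[1],
       reduction_at_300 = 1 - m$log$loss[at300] / m$log$loss[1],
       train_dsc = setNames(dsc, names(STRUCTURES)))
}

## mean H95 with missing comparisons (empty predictions) charged half the
## grid diagonal -- dropping them would reward predicting nothing
mean_h95_penalized <- function(h95, size, spacing) {
  pen <- sqrt(3) * size * spacing / 2
  mean(ifelse(is.na(h95), pen, h95))
}

#' Expert- versus atlas-label experiment
#'
#' The study's central comparison at phantom scale: networks trained from a
#' few expert-labelled volumes versus many weakly atlas-labelled volumes,
#' in the rigidly aligned and the unaligned setting, with metrics averaged
#' over replicate training seeds.
#'
#' @param seed base seed.
#' @param n_seeds replicate training runs per arm.
#' @param n_train cohort size for atlas labels; `n_expert` of them keep
#'   their expert labels in the expert arm.
#' @param n_expert number of expert-labelled volumes (few-shot budget).
#' @param n_test held-out cohort size.
#' @param size grid size.
#' @param iterations,depth,features,batch_size,learning_rate reduced
#'   training settings.
#' @return List of per-arm results (`expert_aligned`, `atlas_aligned`,
#'   `expert_unaligned`, `atlas_unaligned`), each with seed-mean `dsc` and
#'   `h95`, plus `h95_advantage_aligned` / `h95_advantage_unaligned`
#'   (expert minus atlas mean H95; positive favours atlas labels).
#' @export
run_alignment_study <- function(seed = 1, n_seeds = 3, n_train = 18,
                                n_expert = 9, n_test = 4, size = 32,
                                iterations = 60, depth = 2, features = 8,
                                batch_size = 2, learning_rate = 0.01) {
  cfgp <- training_phantom_config(size)
  cohort <- make_cohort(n_train, c(18, 26), seed = seed, config = cfgp,
                        aligned = FALSE)
  test <- make_cohort(n_test, c(18, 26), seed = seed + 1000, config = cfgp,
                      aligned = FALSE)
  atl <- build_atlas_labels(cohort, demons_iters = c(25, 15, 6))
  aligned_cohort <- lapply(cohort, align_sample)
  aligned_test <- lapply(test, align_sample)

  ## expert arm: evenly GA-spaced subset with ground-truth labels
  exp_ids <- unique(round(seq(1, n_train, length.out = n_expert)))
  datasets <- list(
    expert_aligned = lapply(aligned_cohort[exp_ids], identity),
    atlas_aligned = lapply(seq_len(n_train), function(i) {
      s <- aligned_cohort[[i]]; s$labels <- atl$atlas_labels[[i]]; s
    }),
    expert_unaligned = lapply(cohort[exp_ids], identity),
    atlas_unaligned = lapply(seq_len(n_train), function(i) {
      s <- cohort[[i]]
      ## atlas labels live in the aligned space; carry them back through
      ## the rigid pose as the annotation convention prescribes
      s$labels <- rigid_align(atl$atlas_labels[[i]], s$pose)
      s
    }))

  res <- list()
  for (arm in names(datasets)) {
    is_aligned <- grepl("aligned$", arm) && !grepl("unaligned", arm)
    src <- if (grepl("expert", arm)) "expert" else "atlas"
    tst <- if (is_aligned) aligned_test else test
    dscs <- c(); h95s <- c()
    for (k in seq_len(n_seeds)) {
      cfg <- seg_config(depth = depth, init_features = features,
                        batch_size = batch_size,
                        iteration_budget = iterations,
                        learning_rate = learning_rate, label_source = src,
                        aligned = is_aligned, seed = seed + 10 * k)
      m <- train_segmenter(datasets[[arm]], cfg, desk_augmentation_spec())
      ev <- lapply(tst, function(s)
        evaluate_segmentation(predict_labels(m, s$image), s$labels))
      dscs <- c(dscs, mean(vapply(ev, function(e) mean(e$dsc), 0)))
      h95s <- c(h95s, mean(vapply(ev, function(e)
        mean_h95_penalized(e$h95_mm, size, cfgp$spacing), 0)))
    }
    res[[arm]] <- list(dsc = mean(dscs), h95 = mean(h95s),
                       dsc_by_seed = dscs, h95_by_seed = h95s)
  }
  res$h95_advantage_aligned <- res$expert_aligned$h95 - res$atlas_aligned$h95
  res$h95_advantage_unaligned <-
    res$expert_unaligned$h95 - res$atlas_unaligned$h95
  res
}

#' Growth-curve recovery study
#'
#' Simulates volume measurements from the default LPVH growth law with
#' Gaussian noise and checks (a) how often the true slope falls inside the
#' fitted 95% confidence interval over seeded cohorts, and (b) the
#' false-positive rate of the quadratic gate on linear-law data.
#'
#' @param seed base seed.
#' @param n_cohorts cohorts for slope coverage.
#' @param n_replicates replicates for the quadratic gate.
#' @param n_per_cohort measurements per cohort.
#' @param noise_sd measurement noise (cm^3).
#' @param alpha gate level.
#' @return List: `slope_covered` (logical vector), `coverage`,
#'   `quad_retained` (logical vector), `false_positive_rate`.
#' @export
run_growth_recovery_study <- function(seed = 1, n_cohorts = 20,
                                      n_replicates = 50, n_per_cohort = 50,
                                      noise_sd = 0.03, alpha = 0.05) {
  law <- default_growth_laws()$LPVH
  slope <- law$coefficients[2]
  covered <- logical(n_cohorts)
  for (i in seq_len(n_cohorts)) {
    set.seed(seed + i)
    ga <- runif(n_per_cohort, 18, 26)
    v <- vapply(ga, function(g) growth_model(g, law), 0) +
      rnorm(n_per_cohort, 0, noise_sd)
    fit <- lm(v ~ ga)
    ci <- stats::confint(fit, "ga", level = 0.95)
    covered[i] <- slope >= ci[1] && slope <= ci[2]
  }
  quad <- logical(n_replicates)
  for (i in seq_len(n_replicates)) {
    set.seed(seed + 1000 + i)
    ga <- rep(runif(n_per_cohort, 18, 26), 2)
    v <- vapply(ga, function(g) growth_model(g, law), 0) +
      rnorm(2 * n_per_cohort, 0, noise_sd)
    rec <- data.frame(ga_weeks = ga, volume_cm3 = v,
                      model = rep(c("expert", "atlas"), each = n_per_cohort))
    fits <- fit_growth_curve(rec, alpha = alpha)
    quad[i] <- fits[[1]]$degree == 2L
  }
  list(slope_covered = covered, coverage = mean(covered),
       quad_retained = quad, false_positive_rate = mean(quad))
}
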