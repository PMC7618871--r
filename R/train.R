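## Training and inference for the multi-label segmentation network.

#' Segmentation training configuration
#'
#' Defaults follow the study settings: network depth 5 with 16 initial
#' feature maps, loss weight lambda = 1, ADAM at learning rate 0.001,
#' batch size 4, and an iteration budget equivalent to 100 epochs over the
#' full atlas-labelled training set so that expert- and atlas-label modes
#' receive equal optimization effort. Desk-scale experiments override
#' depth/features/budget explicitly.
#'
#' @param depth U-Net depth (number of resolution levels).
#' @param init_features feature maps in the first encoder block.
#' @param num_classes output classes (background + 4 structures).
#' @param lambda_ce cross-entropy weight in the combined loss.
#' @param learning_rate ADAM learning rate.
#' @param batch_size samples per iteration.
#' @param iteration_budget optimizer steps; `NULL` means
#'   `100 * ceiling(n_train / batch_size)` computed at fit time.
#' @param dice_squared use squared-denominator soft Dice (V-Net style)
#'   instead of the plain sum denominator.
#' @param label_smooth cross-entropy label smoothing in `[0, 1)`; 0 (the
#'   default) disables it.
#' @param label_source `"expert"` or `"atlas"` (recorded in artifacts).
#' @param aligned whether training images are rigidly aligned (recorded).
#' @param validation_frac held-out fraction for atlas-mode monitoring
#'   (expert mode uses none).
#' @param seed RNG seed for weight init, batching and augmentation.
#' @return Object of class `seg_config`.
#' @export
seg_config <- function(depth = 5, init_features = 16, num_classes = 5,
                       lambda_ce = 1, learning_rate = 0.001, batch_size = 4,
                       iteration_budget = NULL, dice_squared = FALSE,
                       label_smooth = 0,
                       label_source = c("expert", "atlas"), aligned = TRUE,
                       validation_frac = 0.1, seed = 1) {
  label_source <- match.arg(label_source)
  stopifnot(depth >= 1, init_features >= 1, num_classes >= 2,
            lambda_ce >= 0, learning_rate > 0, batch_size >= 1,
            label_smooth >= 0, label_smooth < 1)
  structure(list(depth = as.integer(depth),
                 init_features = as.integer(init_features),
                 num_classes = as.integer(num_classes),
                 lambda_ce = lambda_ce, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 iteration_budget = iteration_budget,
                 dice_squared = isTRUE(dice_squared),
                 label_smooth = label_smooth,
                 label_source = label_source, aligned = isTRUE(aligned),
                 validation_frac = validation_frac, seed = as.integer(seed)),
            class = "seg_config")
}

dataset_entry <- function(x) {
  img <- as_arr(x$image)
  lab <- as_arr(x$labels)
  stopifnot(identical(dim(img), dim(lab)))
  list(image = img, labels = lab, ga = x$ga_weeks %||% x$ga)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the segmentation network
#'
#' Runs exactly the configured number of iterations (one batch per
#' iteration) regardless of dataset size, with random geometric
#' augmentation per sample, the combined Dice/cross-entropy loss and ADAM.
#' In atlas mode a fraction of the data is held out for monitoring; the
#' deliverable is always the last-iteration weights.
#'
#' @param dataset list of samples, each with `image`, `labels` and
#'   `ga_weeks` (cohort samples work directly; atlas labels can be
#'   substituted beforehand).
#' @param config a [seg_config()].
#' @param spec an [augmentation_spec()].
#' @param augment_data apply random augmentation (disable for debugging).
#' @param verbose print loss every 25 iterations.
#' @return Object of class `trained_model`: parameters, config snapshot,
#'   per-iteration training log, and mode tags.
#' @export
train_segmenter <- function(dataset, config = seg_config(),
                            spec = augmentation_spec(), augment_data = TRUE,
                            verbose = FALSE) {
  if (!length(dataset)) stop("empty training dataset")
  data <- lapply(dataset, dataset_entry)
  dm <- dim(data[[1]]$image)
  if (!all(vapply(data, function(s) identical(dim(s$image), dm), TRUE)))
    stop("all training images must share one grid")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n <- length(data)
  val_ids <- integer()
  if (config$label_source == "atlas" && config$validation_frac > 0 && n >= 10)
    val_ids <- sample.int(n, max(1, round(config$validation_frac * n)))
  train_ids <- setdiff(seq_len(n), val_ids)

  budget <- config$iteration_budget %||%
    (100L * as.integer(ceiling(length(train_ids) / config$batch_size)))
  params <- unet_init(config)
  ## start the softmax at the training-set class priors so early iterations
  ## refine structure boundaries instead of re-learning the class imbalance
  freq <- rep(1e-6, config$num_classes)
  for (id in train_ids) {
    tb <- tabulate(data[[id]]$labels + 1L, nbins = config$num_classes)
    freq <- freq + tb / sum(tb)
  }
  params$head$b <- log(freq / sum(freq))
  tt <- trainable_tree(params)
  state <- list(m = tree_zero(tt), v = tree_zero(tt), t = 0)
  log <- data.frame(iteration = seq_len(budget), loss = NA_real_,
                    l_md = NA_real_, l_ce = NA_real_)

  for (it in seq_len(budget)) {
    idx <- sample(train_ids, config$batch_size, replace = TRUE)
    grads <- NULL
    loss_acc <- md_acc <- ce_acc <- 0
    for (id in idx) {
      s <- data[[id]]
      if (augment_data) {
        a <- augment(s$image, s$labels, s$ga, spec)
        img <- a$image; lab <- a$labels
      } else { img <- s$image; lab <- s$labels }
      ps <- .unet_pass(params, img, dim(img), as.integer(lab),
                       config$lambda_ce, TRUE, config$dice_squared,
                       config$label_smooth)
      params <- update_bn_stats(params, ps$stats)
      g <- ps$grads
      grads <- if (is.null(grads)) g else tree_map2(`+`, grads, g)
      loss_acc <- loss_acc + ps$loss
      md_acc <- md_acc + ps$l_md
      ce_acc <- ce_acc + ps$l_ce
    }
    grads <- tree_map2(function(a, b) a / config$batch_size, grads, grads)
    upd <- adam_step(params, grads, state, config$learning_rate)
    params <- upd$params
    state <- upd$state
    log$loss[it] <- loss_acc / config$batch_size
    log$l_md[it] <- md_acc / config$batch_size
    log$l_ce[it] <- ce_acc / config$batch_size
    if (verbose && it %% 25 == 0)
      message(sprintf("iter %d/%d loss %.4f", it, budget, log$loss[it]))
  }

  structure(list(params = params, config = config, aug_spec = spec,
                 log = log, grid = dm, val_ids = val_ids,
                 label_source = config$label_source,
                 aligned = config$aligned), class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> theta^%s (%s), depth %d, %d features, %d iterations, final loss %.4f\n",
              substr(x$label_source, 1, 3),
              if (x$aligned) "aligned" else "unaligned",
              x$config$depth, x$config$init_features, nrow(x$log),
              tail(x$log$loss, 1)))
  invisible(x)
}

#' Per-voxel class probabilities for an image
#'
#' @param model a `trained_model`.
#' @param image [volume3d()] or 3D array on the model's grid.
#' @return Array `(nx, ny, nz, num_classes)`; channels sum to 1 per voxel.
#' @export
predict_probs <- function(model, image) {
  img <- as_arr(image)
  if (!identical(dim(img), model$grid))
    stop("image grid does not match the model's training grid")
  .unet_pass(model$params, img, dim(img), NULL, 1, FALSE)$probs
}

#' Predict a labelmap
#'
#' Per-voxel argmax over the softmax channels; probability ties resolve to
#' the lowest class index.
#'
#' @param model a `trained_model`.
#' @param image [volume3d()] or 3D array on the model's grid.
#' @return [labelmap()] with provenance `"predicted"`.
#' @export
predict_labels <- function(model, image) {
  p <- predict_probs(model, image)
  d <- dim(p)
  cls <- max.col(matrix(p, ncol = d[4]), ties.method = "first") - 1L
  sp <- if (inherits(image, "volume3d")) image$spacing else 1
  labelmap(array(cls, d[1:3]), spacing = sp, provenance = "predicted")
}
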