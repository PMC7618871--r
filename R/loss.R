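## Combined multi-class soft-Dice + cross-entropy segmentation loss.
## The Dice term averages soft Dice over the four foreground classes only
## (background excluded: the Dice term exists to counter the extreme
## foreground/background imbalance); the cross-entropy term is the
## voxel-mean over all five classes.

#' Combined Dice / cross-entropy loss
#'
#' `L_total = L_MD + lambda * L_CE`, with
#' `L_MD = 1 - mean_c (2*sum(p_c t_c) + eps) / (sum(p_c) + sum(t_c) + eps)`
#' over the foreground classes and `L_CE` the voxel-mean cross-entropy.
#'
#' @param probs per-voxel class probabilities: array `(nx, ny, nz, C)` or
#'   matrix `(nvox, C)`, rows on the probability simplex.
#' @param target one-hot array/matrix of the same shape, or an integer
#'   class array.
#' @param lambda relative weight of the cross-entropy term (default 1).
#' @param epsilon Dice smoothing constant.
#' @return Scalar loss with attributes `L_MD` and `L_CE`.
#' @export
combined_loss <- function(probs, target, lambda = 1, epsilon = 1e-5) {
  C <- tail(dim(probs), 1)
  if (is.matrix(probs)) C <- ncol(probs)
  pm <- matrix(probs, ncol = C)
  tm <- to_onehot(target, C, nrow(pm))
  if (!identical(dim(pm), dim(tm))) stop("probs/target shapes do not match")
  dsc <- vapply(2:C, function(c)
    (2 * sum(pm[, c] * tm[, c]) + epsilon) /
      (sum(pm[, c]) + sum(tm[, c]) + epsilon), 0)
  l_md <- 1 - mean(dsc)
  l_ce <- -mean(log(pmax(rowSums(pm * tm), 1e-12)))
  out <- l_md + lambda * l_ce
  attr(out, "L_MD") <- l_md
  attr(out, "L_CE") <- l_ce
  out
}

to_onehot <- function(target, C, nvox) {
  if (length(target) == nvox) {
    ti <- as.integer(target)
    tm <- matrix(0, nvox, C)
    tm[cbind(seq_len(nvox), ti + 1L)] <- 1
    tm
  } else if (length(target) == nvox * C) {
    matrix(target, ncol = C)
  } else stop("probs/target shapes do not match")
}

## loss and gradient w.r.t. logits, for training
loss_grad_from_logits <- function(logits, target_int, lambda = 1,
                                  epsilon = 1e-5) {
  d <- dim(logits)
  C <- d[4]
  lm <- matrix(logits, ncol = C)
  mx <- lm[, 1]
  for (c in 2:C) mx <- pmax(mx, lm[, c])
  e <- exp(lm - mx)
  pm <- e / rowSums(e)
  n <- nrow(pm)
  ti <- as.integer(target_int)
  tm <- matrix(0, n, C)
  tm[cbind(seq_len(n), ti + 1L)] <- 1

  inter <- colSums(pm * tm)
  sums <- colSums(pm) + colSums(tm)
  dsc <- (2 * inter[2:C] + epsilon) / (sums[2:C] + epsilon)
  l_md <- 1 - mean(dsc)
  l_ce <- -mean(log(pmax(pm[cbind(seq_len(n), ti + 1L)], 1e-12)))

  ## d L_MD / d p_c(v) for foreground classes
  gp <- matrix(0, n, C)
  for (c in 2:C) {
    num <- 2 * inter[c] + epsilon
    den <- sums[c] + epsilon
    gp[, c] <- -(2 * tm[, c] * den - num) / den^2 / (C - 1)
  }
  ## chain through softmax: dL/dz_j = p_j (g_j - sum_c g_c p_c)
  dot <- rowSums(gp * pm)
  dz_md <- pm * (gp - dot)
  dz_ce <- (pm - tm) / n
  list(loss = l_md + lambda * l_ce, l_md = l_md, l_ce = l_ce,
       dlogits = array(dz_md + lambda * dz_ce, d))
}
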