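## Multi-label 3D U-Net implemented directly on top of the package's
## convolution kernels: two conv+BN+ReLU blocks per level, 2x max pooling,
## nearest-neighbour upsampling followed by a halving convolution, skip
## concatenation, channel doubling per level and a 1x1x1 classification
## head. Arrays are (nx, ny, nz, channels); weights for a 3x3x3 convolution
## are a (27*cin) x cout matrix.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

conv_params <- function(cin, cout) {
  list(w = matrix(rnorm(27 * cin * cout, sd = sqrt(2 / (27 * cin))),
                  27 * cin, cout),
       b = numeric(cout))
}

bn_params <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c), rm = numeric(c), rv = rep(1, c))
}

#' Initialize U-Net weights
#'
#' He-initialized convolution weights; batch-normalization scale/shift at
#' 1/0. Uses the current RNG state (seed it for reproducibility).
#'
#' @param config a [seg_config()].
#' @param in_channels input image channels.
#' @return Nested parameter list.
#' @export
unet_init <- function(config, in_channels = 1) {
  d <- config$depth; f <- config$init_features
  ch <- f * 2^(seq_len(d) - 1)
  enc <- list()
  cin <- in_channels
  for (i in seq_len(d)) {
    enc[[i]] <- list(conv1 = conv_params(cin, ch[i]), bn1 = bn_params(ch[i]),
                     conv2 = conv_params(ch[i], ch[i]), bn2 = bn_params(ch[i]))
    cin <- ch[i]
  }
  dec <- list()
  for (i in seq_len(d - 1)) {
    dec[[i]] <- list(upconv = conv_params(ch[i + 1], ch[i]),
                     bnup = bn_params(ch[i]),
                     conv1 = conv_params(2 * ch[i], ch[i]),
                     bn1 = bn_params(ch[i]),
                     conv2 = conv_params(ch[i], ch[i]),
                     bn2 = bn_params(ch[i]))
  }
  head <- list(w = matrix(rnorm(ch[1] * config$num_classes,
                                sd = sqrt(2 / ch[1])),
                          ch[1], config$num_classes),
               b = numeric(config$num_classes))
  list(enc = enc, dec = dec, head = head, depth = d, channels = ch)
}

conv_f <- function(x, p) .conv3d_fwd(x, p$w, p$b, dim(x))

bn_f <- function(x, p, train) {
  d <- dim(x)
  C <- d[4]
  xm <- matrix(x, ncol = C)
  if (train) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
  } else {
    mu <- p$rm; v <- p$rv
  }
  istd <- 1 / sqrt(v + BN_EPS)
  xhat <- xm
  y <- xm
  for (c in seq_len(C)) {
    xhat[, c] <- (xm[, c] - mu[c]) * istd[c]
    y[, c] <- xhat[, c] * p$gamma[c] + p$beta[c]
  }
  list(y = array(y, d), cache = list(xhat = xhat, istd = istd,
                                     mu = mu, v = v))
}

bn_b <- function(dy, p, cache) {
  d <- dim(dy)
  C <- d[4]
  dym <- matrix(dy, ncol = C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dx <- dym
  for (c in seq_len(C)) {
    dxh <- dym[, c] * p$gamma[c]
    dx[, c] <- (dxh - mean(dxh) - cache$xhat[, c] * mean(dxh * cache$xhat[, c])) *
      cache$istd[c]
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

cbr_f <- function(x, conv, bn, train) {
  c1 <- conv_f(x, conv)
  b1 <- bn_f(c1, bn, train)
  mask <- b1$y > 0
  list(y = b1$y * mask, cache = list(x = x, bn = b1$cache, mask = mask))
}

cbr_b <- function(dy, conv, bn, cache) {
  dy <- dy * cache$mask
  bb <- bn_b(dy, bn, cache$bn)
  cb <- .conv3d_bwd(cache$x, conv$w, bb$dx, dim(cache$x))
  list(dx = cb$dx,
       gconv = list(w = cb$dw, b = cb$db),
       gbn = list(gamma = bb$dgamma, beta = bb$dbeta))
}

block_f <- function(x, bp, train) {
  a <- cbr_f(x, bp$conv1, bp$bn1, train)
  b <- cbr_f(a$y, bp$conv2, bp$bn2, train)
  list(y = b$y, cache = list(a = a$cache, b = b$cache))
}

block_b <- function(dy, bp, cache) {
  g2 <- cbr_b(dy, bp$conv2, bp$bn2, cache$b)
  g1 <- cbr_b(g2$dx, bp$conv1, bp$bn1, cache$a)
  list(dx = g1$dx,
       g = list(conv1 = g1$gconv, bn1 = g1$gbn,
                conv2 = g2$gconv, bn2 = g2$gbn))
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1:3], da[4] + db[4]))
}

#' U-Net forward pass
#'
#' @param params from [unet_init()].
#' @param x input array `(nx, ny, nz)` or `(nx, ny, nz, 1)`.
#' @param train batch-statistics mode (also returns caches for backprop).
#' @return List with `logits` (nx, ny, nz, num_classes) and, when
#'   `train = TRUE`, the `cache` for [unet_backward()].
#' @export
unet_forward <- function(params, x, train = FALSE) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  d <- params$depth
  skips <- list(); cache <- list(enc = list(), pool = list(), dec = list())
  h <- x
  for (i in seq_len(d)) {
    r <- block_f(h, params$enc[[i]], train)
    cache$enc[[i]] <- r$cache
    h <- r$y
    if (i < d) {
      skips[[i]] <- h
      mp <- .maxpool2_fwd(h, dim(h))
      cache$pool[[i]] <- list(arg = mp$arg, indim = dim(h))
      h <- mp$y
    }
  }
  for (i in rev(seq_len(d - 1))) {
    updim <- dim(h)
    up <- .upsample2_fwd(h, updim)
    u <- cbr_f(up, params$dec[[i]]$upconv, params$dec[[i]]$bnup, train)
    cat_in <- concat_ch(skips[[i]], u$y)
    r <- block_f(cat_in, params$dec[[i]],
                 train)
    cache$dec[[i]] <- list(updim = updim, up = u$cache, blk = r$cache,
                           nskip = dim(skips[[i]])[4])
    h <- r$y
  }
  dm <- dim(h)
  hm <- matrix(h, ncol = dm[4])
  logits <- sweep(hm %*% params$head$w, 2, params$head$b, `+`)
  cache$head_in <- if (train) hm else NULL
  cache$head_dim <- dm
  list(logits = array(logits, c(dm[1:3], ncol(logits))), cache = cache)
}

#' U-Net backward pass
#'
#' @param params network parameters.
#' @param dlogits gradient of the loss w.r.t. the logits.
#' @param cache from [unet_forward()] with `train = TRUE`.
#' @return Gradient tree mirroring the trainable parameters.
#' @export
unet_backward <- function(params, dlogits, cache) {
  d <- params$depth
  dm <- cache$head_dim
  dLm <- matrix(dlogits, ncol = dim(dlogits)[4])
  ghead <- list(w = crossprod(cache$head_in, dLm), b = colSums(dLm))
  dh <- array(dLm %*% t(params$head$w), dm)
  gdec <- list(); genc <- list()
  for (i in seq_len(d - 1)) {
    cc <- cache$dec[[i]]
    r <- block_b(dh, params$dec[[i]], cc$blk)
    nsk <- cc$nskip
    dcat <- r$dx
    dskip <- dcat[, , , seq_len(nsk), drop = FALSE]
    dup_out <- dcat[, , , nsk + seq_len(dim(dcat)[4] - nsk), drop = FALSE]
    u <- cbr_b(dup_out, params$dec[[i]]$upconv, params$dec[[i]]$bnup, cc$up)
    dh <- .upsample2_bwd(u$dx, cc$updim)
    gdec[[i]] <- c(r$g, list(upconv = u$gconv, bnup = u$gbn))
    ## stash the skip gradient to merge with the encoder path
    gdec[[i]]$dskip <- dskip
    dh_next <- dh
    dh <- dh_next
  }
  ## encoder backward, merging pooled and skip gradients
  for (i in rev(seq_len(d))) {
    if (i < d) {
      dh <- .maxpool2_bwd(dh, cache$pool[[i]]$arg, cache$pool[[i]]$indim)
      dh <- dh + gdec[[i]]$dskip
      gdec[[i]]$dskip <- NULL
    }
    r <- block_b(dh, params$enc[[i]], cache$enc[[i]])
    genc[[i]] <- r$g
    dh <- r$dx
  }
  list(enc = genc, dec = gdec, head = ghead)
}

## update batch-norm running statistics from a training forward cache
update_bn_stats <- function(params, cache) {
  upd <- function(p, cc) {
    p$rm <- (1 - BN_MOMENTUM) * p$rm + BN_MOMENTUM * cc$mu
    p$rv <- (1 - BN_MOMENTUM) * p$rv + BN_MOMENTUM * cc$v
    p
  }
  for (i in seq_along(params$enc)) {
    params$enc[[i]]$bn1 <- upd(params$enc[[i]]$bn1, cache$enc[[i]]$a$bn)
    params$enc[[i]]$bn2 <- upd(params$enc[[i]]$bn2, cache$enc[[i]]$b$bn)
  }
  for (i in seq_along(cache$dec)) {
    if (is.null(cache$dec[[i]])) next
    params$dec[[i]]$bnup <- upd(params$dec[[i]]$bnup, cache$dec[[i]]$up$bn)
    params$dec[[i]]$bn1 <- upd(params$dec[[i]]$bn1, cache$dec[[i]]$blk$a$bn)
    params$dec[[i]]$bn2 <- upd(params$dec[[i]]$bn2, cache$dec[[i]]$blk$b$bn)
  }
  params
}

## elementwise binary operation over parallel numeric trees (lists may be
## named or positional)
tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- a
    for (i in seq_along(a))
      if (!is.null(a[[i]])) out[[i]] <- tree_map2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

## Adam step over the gradient tree; `state` carries (m, v) trees and the
## step counter. Only leaves present in `grads` are updated; decoupled
## weight decay (AdamW-style) applies to convolution weight matrices only.
adam_step <- function(params, grads, state, lr, weight_decay = 0) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1
  walk <- function(p, g, m, v, leaf = "") {
    if (is.list(g)) {
      nms <- names(g)
      for (i in seq_along(g)) {
        if (is.null(g[[i]])) next
        key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
        r <- walk(p[[key]], g[[i]], m[[key]], v[[key]],
                  if (is.character(key)) key else leaf)
        p[[key]] <- r$p; m[[key]] <- r$m; v[[key]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^state$t)
    vhat <- v / (1 - b2^state$t)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    if (weight_decay > 0 && leaf == "w") p <- p - lr * weight_decay * p
    list(p = p, m = m, v = v)
  }
  for (part in c("enc", "dec", "head")) {
    r <- walk(params[[part]], grads[[part]], state$m[[part]], state$v[[part]])
    params[[part]] <- r$p
    state$m[[part]] <- r$m
    state$v[[part]] <- r$v
  }
  list(params = params, state = state)
}

## trainable-parameter tree with the same shape as a gradient tree
trainable_tree <- function(params) {
  strip_bn <- function(p) list(gamma = p$gamma, beta = p$beta)
  enc <- lapply(params$enc, function(b)
    list(conv1 = b$conv1, bn1 = strip_bn(b$bn1),
         conv2 = b$conv2, bn2 = strip_bn(b$bn2)))
  dec <- lapply(params$dec, function(b)
    list(conv1 = b$conv1, bn1 = strip_bn(b$bn1),
         conv2 = b$conv2, bn2 = strip_bn(b$bn2),
         upconv = b$upconv, bnup = strip_bn(b$bnup)))
  list(enc = enc, dec = dec, head = params$head)
}
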