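#' Intensity preprocessing for segmentation
#'
#' Clips the volume to the [-30, 800] HU window (calcium saturates near
#' the top, air/fat below the bottom) and standardizes to zero mean and
#' unit SD over the clipped volume.
#'
#' @param vol an `image_volume`.
#' @param window clipping window (HU), default c(-30, 800).
#' @return preprocessed `image_volume`.
#' @export
preprocess_volume <- function(vol, window = c(-30, 800)) {
  x <- pmin(pmax(vol$data, window[1]), window[2])
  s <- stats::sd(as.vector(x))
  if (s < 1e-12) stop("constant image: cannot standardize")
  vol$data <- (x - mean(x)) / s
  vol
}

#' Random augmentation of an image/label pair
#'
#' Seeded pipeline applied jointly to an image and its label map:
#' Gaussian smoothing (probability `p_blur`, sigma drawn in
#' [0.25, 0.75] mm) and a random affine transform (probability
#' `p_affine`; rotation up to 10 degrees about a random axis, isotropic
#' scale in [0.9, 1.1]) about the volume center. The image is resampled
#' with trilinear interpolation, the labels with nearest neighbor, so
#' label values stay binary.
#'
#' @param vol `image_volume`.
#' @param labels `label_map` on the same grid.
#' @param seed integer seed; the same seed reproduces the same pair.
#' @param p_blur,p_affine application probabilities.
#' @return list of `image` and `labels`.
#' @export
augment_pair <- function(vol, labels, seed, p_blur = 0.2, p_affine = 0.3) {
  check_same_grid(vol, labels)
  with_seed(seed, {
    img <- vol$data
    lab <- labels$data
    if (runif(1) < p_blur) {
      sig <- runif(1, 0.25, 0.75)
      img <- gaussian_blur3d(img, sig, vol$spacing)
    }
    if (runif(1) < p_affine) {
      axis <- rnorm(3)
      axis <- axis / sqrt(sum(axis^2))
      theta <- runif(1, -10, 10) * pi / 180
      scale <- runif(1, 0.9, 1.1)
      R <- rotation_about(axis, theta) * scale
      img <- affine_resample(img, vol$spacing, R, "linear")
      lab <- affine_resample(lab, vol$spacing, R, "nearest")
    }
    vol$data <- img
    out_lab <- label_map(lab, labels$spacing, labels$origin,
                         labels$direction)
    list(image = vol, labels = out_lab)
  })
}

# Resample arr under x -> R (x - c) + c in mm about the volume center.
affine_resample <- function(arr, spacing, R, interpolation = "linear") {
  d <- dim(arr)
  ctr <- (d - 1) / 2 * spacing
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  mm <- sweep(sweep(idx - 1, 2, spacing, "*"), 2, ctr, "-")
  src <- sweep(mm %*% t(solve(R)), 2, ctr, "+")
  src_idx <- sweep(src, 2, spacing, "/") + 1
  if (interpolation == "nearest") {
    ijk <- round(src_idx)
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 &
      ijk[, 2] <= d[2] & ijk[, 3] >= 1 & ijk[, 3] <= d[3]
    out <- numeric(nrow(ijk))
    out[ok] <- arr[ijk[ok, , drop = FALSE]]
    return(array(out, d))
  }
  f <- floor(src_idx)
  w <- src_idx - f
  out <- numeric(nrow(f))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ijk <- f + matrix(rep(c(dx, dy, dz), each = nrow(f)), ncol = 3)
    wt <- (ifelse(dx == 1, w[, 1], 1 - w[, 1])) *
      (ifelse(dy == 1, w[, 2], 1 - w[, 2])) *
      (ifelse(dz == 1, w[, 3], 1 - w[, 3]))
    ok <- ijk[, 1] >= 1 & ijk[, 1] <= d[1] & ijk[, 2] >= 1 &
      ijk[, 2] <= d[2] & ijk[, 3] >= 1 & ijk[, 3] <= d[3]
    vals <- numeric(nrow(ijk))
    vals[ok] <- arr[ijk[ok, , drop = FALSE]]
    out <- out + wt * vals
  }
  array(out, d)
}

#' Dice-Focal loss parameters
#'
#' alpha balances foreground/background in the focal term, gamma focuses
#' training on hard voxels, and lambda_f / lambda_d weight the focal and
#' Dice components. Stage presets: stage 1 (2.5D multi-view) uses
#' lambda_f = 1.1, lambda_d = 0.4; stage 2 (3D refinement) uses
#' lambda_f = 0.5, lambda_d = 1.
#'
#' @param alpha focal class balance in (0, 1), default 0.6.
#' @param gamma focal exponent >= 0, default 2.
#' @param lambda_f,lambda_d component weights >= 0.
#' @param stage optional 1 or 2; applies the stage presets for the
#'   lambdas.
#' @export
loss_params <- function(alpha = 0.6, gamma = 2, lambda_f = 1.1,
                        lambda_d = 0.4, stage = NULL) {
  if (!is.null(stage)) {
    stopifnot(stage %in% c(1, 2))
    if (stage == 2) { lambda_f <- 0.5; lambda_d <- 1.0 }
    else { lambda_f <- 1.1; lambda_d <- 0.4 }
  }
  stopifnot(alpha > 0, alpha < 1, gamma >= 0, lambda_f >= 0, lambda_d >= 0)
  list(alpha = alpha, gamma = gamma, lambda_f = lambda_f,
       lambda_d = lambda_d)
}

#' Dice-Focal loss
#'
#' `DFL = lambda_f * mean_i[-alpha (1-p_i)^gamma y_i log p_i
#' - (1-alpha) p_i^gamma (1-y_i) log(1-p_i)]
#' + lambda_d * [1 - 2 sum(y p) / (sum y + sum p)]`,
#' with predictions clamped to [1e-7, 1-1e-7]. The focal term is
#' averaged over voxels so the loss scale is independent of patch size.
#'
#' @param pred predicted foreground probabilities (array or vector).
#' @param ref binary reference of the same shape.
#' @param params a [loss_params()] list.
#' @return scalar loss >= 0.
#' @export
dice_focal_loss <- function(pred, ref, params = loss_params()) {
  if (length(pred) != length(ref))
    stop("prediction/reference shape mismatch")
  dfl_terms(as.numeric(pred), as.numeric(ref), params)$loss
}

dfl_terms <- function(p, y, params, want_grad = FALSE) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  a <- params$alpha
  g <- params$gamma
  n <- length(p)
  focal <- -a * (1 - p)^g * y * log(p) -
    (1 - a) * p^g * (1 - y) * log(1 - p)
  sy <- sum(y)
  sp <- sum(p)
  syp <- sum(y * p)
  dice <- 1 - 2 * syp / (sy + sp + eps)
  loss <- params$lambda_f * mean(focal) + params$lambda_d * dice
  if (!want_grad) return(list(loss = loss))
  dfoc <- -a * y * (-g * (1 - p)^(g - 1) * log(p) + (1 - p)^g / p) -
    (1 - a) * (1 - y) * (g * p^(g - 1) * log(1 - p) - p^g / (1 - p))
  ddice <- -(2 * y * (sy + sp + eps) - 2 * syp) / (sy + sp + eps)^2
  list(loss = loss,
       grad = params$lambda_f * dfoc / n + params$lambda_d * ddice)
}

#' Fuse multi-view posterior probabilities
#'
#' Element-wise maximum of the foreground probabilities predicted from
#' axial, coronal and sagittal slicing, thresholded into a binary label
#' map. The fusion is invariant under permutation of the views.
#'
#' @param y_ax,y_cor,y_sag `image_volume`s of probabilities in [0, 1] on
#'   one grid.
#' @param threshold foreground threshold, default 0.5.
#' @return a `label_map`.
#' @export
fuse_multiview <- function(y_ax, y_cor, y_sag, threshold = 0.5) {
  check_same_grid(y_ax, y_cor)
  check_same_grid(y_ax, y_sag)
  rng <- range(y_ax$data, y_cor$data, y_sag$data)
  if (rng[1] < 0 || rng[2] > 1)
    stop("posterior probabilities must lie in [0, 1]")
  fused <- pmax(y_ax$data, pmax(y_cor$data, y_sag$data))
  label_map((fused >= threshold) * 1, y_ax$spacing, y_ax$origin,
            y_ax$direction)
}

#' Assemble a U-Net description
#'
#' Builds the encoder/decoder layer plan of the segmentation networks:
#' the 2D variant uses 3x3 kernels, instance normalization and PReLU
#' over 5 resolution levels; the 3D variant uses 5x5x5 kernels, batch
#' normalization and a 2-channel input (image plus first-stage mask).
#' Decoder levels upsample and concatenate the matching encoder skip.
#' The returned object carries the layer table, the trainable parameter
#' count, and the input-divisibility constraint.
#'
#' @param dim 2 or 3.
#' @param config list of overrides: `levels` (default 5), `base_filters`
#'   (default 8), `in_channels`, `kernel`.
#' @return object of class `unet_config`.
#' @export
build_unet <- function(dim = 2, config = list()) {
  stopifnot(dim %in% c(2, 3))
  cfg <- modify_defaults(list(
    levels = 5L,
    base_filters = 8L,
    in_channels = if (dim == 2) 1L else 2L,
    kernel = if (dim == 2) 3L else 5L,
    norm = if (dim == 2) "instance" else "batch",
    activation = "prelu"), config)
  if (cfg$levels < 1 || cfg$levels > 8) stop("invalid depth")
  if (cfg$base_filters < 1) stop("invalid width")
  ch <- cfg$base_filters * 2^(seq_len(cfg$levels) - 1)
  layers <- data.frame(
    stage = c(rep("encoder", cfg$levels), rep("decoder", cfg$levels - 1),
              "head"),
    level = c(seq_len(cfg$levels), rev(seq_len(cfg$levels - 1)), 1),
    in_ch = NA_integer_, out_ch = NA_integer_, kernel = cfg$kernel)
  enc_in <- c(cfg$in_channels, ch[-cfg$levels])
  layers$in_ch[seq_len(cfg$levels)] <- enc_in
  layers$out_ch[seq_len(cfg$levels)] <- ch
  dec_rows <- cfg$levels + seq_len(cfg$levels - 1)
  dec_lv <- rev(seq_len(cfg$levels - 1))
  layers$in_ch[dec_rows] <- ch[dec_lv + 1] + ch[dec_lv]  # upsampled + skip
  layers$out_ch[dec_rows] <- ch[dec_lv]
  layers$in_ch[nrow(layers)] <- ch[1]
  layers$out_ch[nrow(layers)] <- 1L
  layers$kernel[nrow(layers)] <- 1L
  kvol <- ifelse(layers$kernel == 1, 1, layers$kernel^dim)
  layers$n_params <- kvol * layers$in_ch * layers$out_ch + layers$out_ch
  structure(list(dim = dim, config = cfg, layers = layers,
                 n_params = sum(layers$n_params) + nrow(layers),  # + PReLU
                 divisor = 2^(cfg$levels - 1)),
            class = "unet_config")
}

#' @export
print.unet_config <- function(x, ...) {
  cat(sprintf("<unet_config> %dD, %d levels, base %d, kernel %d, %s norm, %d params\n",
              x$dim, x$config$levels, x$config$base_filters,
              x$config$kernel, x$config$norm, x$n_params))
  invisible(x)
}

#' Run a U-Net forward pass with seeded random weights
#'
#' Executes the assembled encoder/decoder on an input tensor to verify
#' the shape contract (output spatial size equals input spatial size,
#' one foreground-probability channel). Weights are He-initialized from
#' the seed; normalization layers standardize per channel.
#'
#' @param model a [build_unet()] object.
#' @param x input array: spatial dims, or spatial dims plus a channel
#'   dimension matching the model's `in_channels`.
#' @param seed weight-initialization seed.
#' @return array of foreground probabilities with the input's spatial
#'   dimensions.
#' @export
unet_forward <- function(model, x, seed = 1) {
  nd <- model$dim
  cfg <- model$config
  if (length(dim(x)) == nd) dim(x) <- c(dim(x), 1)
  if (dim(x)[nd + 1] != cfg$in_channels)
    stop("input has ", dim(x)[nd + 1], " channels; model expects ",
         cfg$in_channels)
  sp <- dim(x)[seq_len(nd)]
  if (any(sp %% model$divisor != 0))
    stop("spatial dimensions must be divisible by ", model$divisor)
  k <- cfg$kernel
  L <- cfg$levels
  ch <- cfg$base_filters * 2^(seq_len(L) - 1)
  he <- function(kv, ci, co) array(rnorm(kv * ci * co, 0, sqrt(2 / (kv * ci))),
                                   c(kv, ci, co))
  norm_act <- function(z) {
    spn <- dim(z)[seq_len(nd)]
    zm <- matrix(z, prod(spn))
    zm <- scale(zm)
    zm[is.nan(zm)] <- 0
    prelu(array(zm, dim(z)))
  }
  with_seed(seed, {
    enc_in <- c(cfg$in_channels, ch[-L])
    Wenc <- lapply(seq_len(L), function(l) he(k^nd, enc_in[l], ch[l]))
    Wdec <- lapply(seq_len(L - 1), function(l) he(k^nd, ch[l + 1] + ch[l], ch[l]))
    Whead <- he(1, ch[1], 1)
    feats <- vector("list", L - 1)
    for (l in seq_len(L)) {
      x <- norm_act(conv_nd(x, Wenc[[l]], NULL, k, nd))
      if (l < L) {
        feats[[l]] <- x
        x <- pool_nd(x, nd)
      }
    }
    for (l in rev(seq_len(L - 1))) {
      x <- upsample_nd(x, nd)
      x <- abind_channels(x, feats[[l]])
      x <- norm_act(conv_nd(x, Wdec[[l]], NULL, k, nd))
    }
    p <- sigmoid(conv_nd(x, Whead, NULL, 1, nd))
    array(p, dim(p)[seq_len(nd)])
  })
}

pool_nd <- function(x, nd) {
  sp <- dim(x)[seq_len(nd)]
  ch <- dim(x)[nd + 1]
  offs <- as.matrix(do.call(expand.grid, rep(list(0:1), nd)))
  out <- NULL
  for (o in seq_len(nrow(offs))) {
    idx <- lapply(seq_len(nd), function(a) seq(1 + offs[o, a], sp[a], by = 2))
    slab <- do.call(`[`, c(list(x), idx, list(TRUE), list(drop = FALSE)))
    out <- if (is.null(out)) slab else pmax(out, slab)
  }
  out
}

upsample_nd <- function(x, nd) {
  sp <- dim(x)[seq_len(nd)]
  idx <- lapply(seq_len(nd), function(a) rep(seq_len(sp[a]), each = 2))
  do.call(`[`, c(list(x), idx, list(TRUE), list(drop = FALSE)))
}

abind_channels <- function(a, b) {
  da <- dim(a)
  nd <- length(da) - 1
  out <- array(0, c(da[seq_len(nd)], da[nd + 1] + dim(b)[nd + 1]))
  idx <- lapply(seq_len(nd), function(x2) seq_len(da[x2]))
  out <- do.call(`[<-`, c(list(out), idx, list(seq_len(da[nd + 1])), list(a)))
  do.call(`[<-`, c(list(out), idx,
                   list(da[nd + 1] + seq_len(dim(b)[nd + 1])), list(b)))
}

# ---- minimal native conv nets (no deep-learning framework used) ------------

# N-d "same" convolution via shifted-slab accumulation.
# x: spatial dims + channel dim; w: array (k^nd, in_ch, out_ch); b: out_ch.
conv_nd <- function(x, w, b, k, nd) {
  sp <- dim(x)[seq_len(nd)]
  in_ch <- dim(x)[nd + 1]
  out_ch <- dim(w)[3]
  X <- im2col_nd(x, k, nd)                 # (prod(sp)) x (k^nd * in_ch)
  out <- X %*% matrix(w, ncol = out_ch)
  if (!is.null(b)) out <- sweep(out, 2, b, "+")
  array(out, c(sp, out_ch))
}

im2col_nd <- function(x, k, nd) {
  sp <- dim(x)[seq_len(nd)]
  in_ch <- dim(x)[nd + 1]
  h <- (k - 1) %/% 2
  offs <- as.matrix(do.call(expand.grid, rep(list(seq(-h, h)), nd)))
  n <- prod(sp)
  X <- matrix(0, n, nrow(offs) * in_ch)
  pad_lo <- rep(h, nd)
  padded_dims <- sp + 2 * h
  padded <- array(0, c(padded_dims, in_ch))
  idx_core <- lapply(seq_len(nd), function(a) seq_len(sp[a]) + h)
  padded <- do.call(`[<-`, c(list(padded), idx_core, list(TRUE), list(x)))
  col <- 0
  for (o in seq_len(nrow(offs))) {
    idx <- lapply(seq_len(nd), function(a) seq_len(sp[a]) + h + offs[o, a])
    slab <- do.call(`[`, c(list(padded), idx, list(TRUE), list(drop = FALSE)))
    X[, col + seq_len(in_ch)] <- matrix(slab, n)
    col <- col + in_ch
  }
  X
}

prelu <- function(x, a = 0.1) ifelse(x > 0, x, a * x)
prelu_grad <- function(x, a = 0.1) ifelse(x > 0, 1, a)
sigmoid <- function(x) 1 / (1 + exp(-x))

# Shallow convolutional segmenter used for smoke training:
# conv(k, in->w) PReLU -> conv(k, w->w) PReLU -> conv(1x1, w->1) sigmoid.
init_smoke_net <- function(nd, in_ch, width, k, seed) {
  with_seed(seed, {
    kv <- k^nd
    list(W1 = array(rnorm(kv * in_ch * width, 0, sqrt(2 / (kv * in_ch))),
                    c(kv, in_ch, width)),
         b1 = rep(0, width),
         W2 = array(rnorm(kv * width * width, 0, sqrt(2 / (kv * width))),
                    c(kv, width, width)),
         b2 = rep(0, width),
         W3 = array(rnorm(width, 0, sqrt(2 / width)), c(1, width, 1)),
         b3 = 0, k = k, nd = nd)
  })
}

smoke_forward <- function(net, x) {
  z1 <- conv_nd(x, net$W1, net$b1, net$k, net$nd)
  a1 <- prelu(z1)
  z2 <- conv_nd(a1, net$W2, net$b2, net$k, net$nd)
  a2 <- prelu(z2)
  z3 <- conv_nd(a2, net$W3, net$b3, 1, net$nd)
  list(p = sigmoid(z3), z1 = z1, a1 = a1, z2 = z2, a2 = a2, z3 = z3, x = x)
}

smoke_backward <- function(net, fw, y, params) {
  nd <- net$nd
  sp <- dim(fw$p)[seq_len(nd)]
  n <- prod(sp)
  terms <- dfl_terms(as.numeric(fw$p), as.numeric(y), params,
                     want_grad = TRUE)
  dz3 <- terms$grad * as.numeric(fw$p) * (1 - as.numeric(fw$p))
  dz3m <- matrix(dz3, n, 1)
  A2 <- im2col_nd(fw$a2, 1, nd)
  gW3 <- array(crossprod(A2, dz3m), dim(net$W3))
  gb3 <- sum(dz3m)
  # 1x1 conv backward: da2 = dz3 * W3 per channel
  w3 <- as.numeric(net$W3)
  da2 <- array(as.numeric(dz3m) %o% w3, c(sp, length(w3)))
  dz2 <- da2 * prelu_grad(fw$z2)
  A1 <- im2col_nd(fw$a1, net$k, nd)
  gW2 <- array(crossprod(A1, matrix(dz2, n)), dim(net$W2))
  gb2 <- colSums(matrix(dz2, n))
  da1 <- conv_nd(dz2, flip_kernel(net$W2), NULL, net$k, nd)
  dz1 <- da1 * prelu_grad(fw$z1)
  X <- im2col_nd(fw$x, net$k, nd)
  gW1 <- array(crossprod(X, matrix(dz1, n)), dim(net$W1))
  gb1 <- colSums(matrix(dz1, n))
  list(loss = terms$loss, gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2,
       gW3 = gW3, gb3 = gb3)
}

# Gradient w.r.t. the input of a same-padded conv: convolve with the
# spatially flipped kernel and swapped in/out channels.
flip_kernel <- function(w) {
  kv <- dim(w)[1]
  aperm(w[kv:1, , , drop = FALSE], c(1, 3, 2))
}

#' Desk-scale smoke training of the segmentation stage
#'
#' Trains a small-width shallow convolutional segmenter (two k x k
#' convolution + PReLU layers and a 1x1 sigmoid head) with the
#' Dice-Focal loss of the requested stage, on synthetic phantoms.
#' Stage 1 trains on 2D axial slices (3x3 kernels); stage 2 trains on
#' 3D patches with a 2-channel input (image + prior mask). This
#' verifies the training loop, loss gradients and data plumbing at desk
#' scale; it does not reproduce cohort-scale training.
#'
#' @param phantoms list of lists with `image` (`image_volume`) and
#'   `labels` (`label_map`); at least 4. The last `n_val` phantoms are
#'   held out for validation.
#' @param stage 1 or 2 (selects loss preset and dimensionality).
#' @param epochs training epochs, default 5.
#' @param seed RNG seed controlling initialization and shuffling.
#' @param width filters per layer, default 8.
#' @param lr learning rate, default 0.2.
#' @param n_val number of held-out phantoms, default 2.
#' @return list with `net`, `epoch_loss` (mean loss per epoch),
#'   `val_dsc`, `stage`.
#' @export
smoke_train <- function(phantoms, stage = 1, epochs = 5, seed = 1,
                        width = 8, lr = 0.2, n_val = 2) {
  stopifnot(length(phantoms) >= 4, stage %in% c(1, 2))
  params <- loss_params(stage = stage)
  nd <- if (stage == 1) 2L else 3L
  in_ch <- if (stage == 1) 1L else 2L
  k <- 3L
  n <- length(phantoms)
  train_set <- phantoms[seq_len(n - n_val)]
  val_set <- phantoms[seq(n - n_val + 1, n)]

  samples <- unlist(lapply(train_set, function(ph) {
    img <- preprocess_volume(ph$image)$data
    lab <- ph$labels$data
    if (nd == 2) {
      lapply(seq_len(dim(img)[3]), function(kz)
        list(x = array(img[, , kz], c(dim(img)[1:2], 1)),
             y = lab[, , kz]))
    } else {
      list(list(x = array(c(img, lab), c(dim(img), 2)), y = lab))
    }
  }), recursive = FALSE)

  net <- init_smoke_net(nd, in_ch, width, k, seed)
  epoch_loss <- numeric(epochs)
  ord_seeds <- with_seed(seed, sample.int(1e6, epochs))
  for (ep in seq_len(epochs)) {
    ord <- with_seed(ord_seeds[ep], sample(seq_along(samples)))
    losses <- numeric(length(ord))
    for (m in seq_along(ord)) {
      smp <- samples[[ord[m]]]
      fw <- smoke_forward(net, smp$x)
      bw <- smoke_backward(net, fw, smp$y, params)
      if (!is.finite(bw$loss)) stop("training diverged (seed ", seed, ")")
      net$W1 <- net$W1 - lr * bw$gW1
      net$b1 <- net$b1 - lr * bw$gb1
      net$W2 <- net$W2 - lr * bw$gW2
      net$b2 <- net$b2 - lr * bw$gb2
      net$W3 <- net$W3 - lr * bw$gW3
      net$b3 <- net$b3 - lr * bw$gb3
      losses[m] <- bw$loss
    }
    epoch_loss[ep] <- mean(losses)
  }

  dscs <- vapply(val_set, function(ph) {
    pred <- smoke_predict(net, ph, nd)
    overlap_metrics(label_map(pred, ph$labels$spacing, ph$labels$origin,
                              ph$labels$direction), ph$labels)$dsc
  }, numeric(1))
  list(net = net, epoch_loss = epoch_loss, val_dsc = mean(dscs),
       stage = stage)
}

smoke_predict <- function(net, ph, nd) {
  img <- preprocess_volume(ph$image)$data
  if (nd == 2) {
    pred <- array(0, dim(img))
    for (kz in seq_len(dim(img)[3])) {
      x <- array(img[, , kz], c(dim(img)[1:2], 1))
      pred[, , kz] <- smoke_forward(net, x)$p
    }
  } else {
    x <- array(c(img, ph$labels$data * 0), c(dim(img), 2))
    pred <- array(smoke_forward(net, x)$p, dim(img))
  }
  (pred >= 0.5) * 1
}
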