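#' Residual U-Net configuration
#'
#' Architecture hyper-parameters for the 2-D residual U-Net used for
#' three-class root segmentation. The default configuration is a 5-level
#' encoder/decoder starting at 32 channels and doubling per level, with
#' residual blocks of two subunits (batch norm, ReLU, 3x3 convolution),
#' stride-2 resampling between levels, and a final 1x1 classification
#' convolution, for roughly 6.6 million trainable parameters.
#'
#' @param levels Number of resolution levels (encoder depth). Inputs must
#'   have sides divisible by `2^(levels - 1)`.
#' @param base_channels Channels at the first (full-resolution) level.
#' @param channel_multiplier Channel growth factor per level.
#' @param in_channels Input channels (3 for RGB scans).
#' @param n_classes Output classes (background, noise, root).
#' @param dropout Spatial dropout rate inside each residual block,
#'   active during training only.
#' @param seed Seed for weight initialization.
#' @return A `resunet_config` list.
#' @export
model_config <- function(levels = 5L, base_channels = 32L,
                         channel_multiplier = 2L, in_channels = 3L,
                         n_classes = 3L, dropout = 0.2, seed = 42L) {
  stopifnot(levels >= 2L, n_classes >= 2L, base_channels >= 1L,
            dropout >= 0, dropout < 1)
  structure(list(levels = as.integer(levels),
                 base_channels = as.integer(base_channels),
                 channel_multiplier = as.integer(channel_multiplier),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 dropout = dropout, seed = as.integer(seed)),
            class = "resunet_config")
}

resunet_channels <- function(config) {
  config$base_channels * config$channel_multiplier^(seq_len(config$levels) - 1L)
}

#' Build a residual U-Net
#'
#' Instantiates the network: an encoder of `levels` residual blocks with
#' stride-2 downsampling and channel doubling, a symmetric decoder with
#' nearest-neighbour upsampling, 1x1 channel reduction and additive skip
#' connections from each encoder level, each block being two subunits of
#' (batch norm, ReLU, 3x3 convolution) with an identity shortcut (1x1
#' projection where shape changes), and a final 1x1 convolution to class
#' logits.
#'
#' @param config A [model_config()].
#' @return A `resunet` model object holding the parameter tree.
#' @export
build_resunet <- function(config = model_config()) {
  stopifnot(inherits(config, "resunet_config"))
  ch <- resunet_channels(config)
  L <- config$levels
  params <- with_seed(config$seed, {
    p <- list(enc = vector("list", L), dec = vector("list", L - 1L))
    cin <- config$in_channels
    for (l in seq_len(L)) {
      p$enc[[l]] <- resblock_init(cin, ch[l], if (l == 1L) 1L else 2L)
      cin <- ch[l]
    }
    for (l in seq_len(L - 1L)) {
      p$dec[[l]] <- list(up = conv_init(ch[l + 1L], ch[l], 1L),
                         block = resblock_init(ch[l], ch[l], 1L))
    }
    p$final <- conv_init(ch[1L], config$n_classes, 1L)
    p
  })
  structure(list(config = config, params = params), class = "resunet")
}

#' Count trainable parameters
#'
#' @param model A `resunet` model.
#' @return Integer count of trainable weights (convolution kernels and
#'   biases, batch-norm scales and shifts; running statistics excluded).
#' @export
count_parameters <- function(model) {
  paths <- tree_walk_names(model$params)
  sum(vapply(paths, function(p) length(tree_get(model$params, p)), numeric(1)))
}

#' @export
print.resunet <- function(x, ...) {
  ch <- resunet_channels(x$config)
  cat("Residual U-Net: ", x$config$levels, " levels, channels ",
      paste(ch, collapse = "-"), ", ", x$config$in_channels, " in / ",
      x$config$n_classes, " classes, ",
      format(count_parameters(x), big.mark = ","),
      " trainable parameters\n", sep = "")
  invisible(x)
}

check_input_divisibility <- function(model, h, w) {
  div <- 2L^(model$config$levels - 1L)
  if (h %% div != 0L || w %% div != 0L) {
    stop("input size ", h, "x", w, " not divisible by ", div,
         " (required for a ", model$config$levels, "-level network)")
  }
}

resunet_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (length(d) == 3L) {
    dim(x) <- c(d, 1L)
    d <- dim(x)
  }
  check_input_divisibility(model, d[1], d[2])
  p <- model$params
  L <- model$config$levels
  dr <- model$config$dropout
  enc_out <- vector("list", L)
  enc_cache <- vector("list", L)
  moments <- list()
  h <- x
  for (l in seq_len(L)) {
    fb <- resblock_fwd(h, p$enc[[l]], if (l == 1L) 1L else 2L, training, dr)
    enc_out[[l]] <- fb$out
    enc_cache[[l]] <- fb$cache
    moments[[paste0("enc", l)]] <- fb$moments
    h <- fb$out
  }
  dec_cache <- vector("list", L - 1L)
  d_cur <- enc_out[[L]]
  for (l in rev(seq_len(L - 1L))) {
    up <- upsample2_fwd(d_cur)
    uc <- conv_fwd(up$out, p$dec[[l]]$up, 1L)
    fused <- uc$out + enc_out[[l]]
    fb <- resblock_fwd(fused, p$dec[[l]]$block, 1L, training, dr)
    dec_cache[[l]] <- list(up = up$cache, uc = uc$cache, block = fb$cache)
    moments[[paste0("dec", l)]] <- fb$moments
    d_cur <- fb$out
  }
  fin <- conv_fwd(d_cur, p$final, 1L)
  list(logits = fin$out,
       cache = list(enc = enc_cache, dec = dec_cache, fin = fin$cache),
       moments = moments)
}

resunet_backward <- function(model, cache, dlogits) {
  p <- model$params
  L <- model$config$levels
  g <- list(enc = vector("list", L), dec = vector("list", L - 1L))
  fb <- conv_bwd(cache$fin, p$final, dlogits)
  g$final <- fb$grads
  dd <- fb$dx
  denc <- vector("list", L)  # gradient flowing into each encoder output
  for (l in seq_len(L - 1L)) {
    bb <- resblock_bwd(cache$dec[[l]]$block, p$dec[[l]]$block, dd)
    g$dec[[l]]$block <- bb$grads
    denc[[l]] <- bb$dx  # skip-add: same gradient reaches encoder level l
    ub <- conv_bwd(cache$dec[[l]]$uc, p$dec[[l]]$up, bb$dx)
    g$dec[[l]]$up <- ub$grads
    dd <- upsample2_bwd(cache$dec[[l]]$up, ub$dx)
  }
  dcur <- dd
  for (l in rev(seq_len(L))) {
    bb <- resblock_bwd(cache$enc[[l]], p$enc[[l]], dcur)
    g$enc[[l]] <- bb$grads
    dcur <- bb$dx
    # each encoder output below the bottleneck also feeds a decoder skip-add
    if (l > 1L && !is.null(denc[[l - 1L]])) dcur <- dcur + denc[[l - 1L]]
  }
  list(grads = g, dx = dcur)
}

update_running_stats <- function(model, moments, momentum = 0.1) {
  p <- model$params
  for (key in names(moments)) {
    mo <- moments[[key]]
    if (is.null(mo$bn1$batch_mean)) next
    if (startsWith(key, "enc")) {
      l <- as.integer(sub("enc", "", key))
      for (bn in c("bn1", "bn2")) {
        p$enc[[l]][[bn]]$rmean <- (1 - momentum) * p$enc[[l]][[bn]]$rmean +
          momentum * mo[[bn]]$batch_mean
        p$enc[[l]][[bn]]$rvar <- (1 - momentum) * p$enc[[l]][[bn]]$rvar +
          momentum * mo[[bn]]$batch_var
      }
    } else {
      l <- as.integer(sub("dec", "", key))
      for (bn in c("bn1", "bn2")) {
        p$dec[[l]]$block[[bn]]$rmean <-
          (1 - momentum) * p$dec[[l]]$block[[bn]]$rmean +
          momentum * mo[[bn]]$batch_mean
        p$dec[[l]]$block[[bn]]$rvar <-
          (1 - momentum) * p$dec[[l]]$block[[bn]]$rvar +
          momentum * mo[[bn]]$batch_var
      }
    }
  }
  model$params <- p
  model
}

# Weighted cross-entropy loss and its logit gradient for a batch.
# labels: (H, W, N) integer array in 0..K-1; logits: (H, W, K, N).
wce_loss_grad <- function(logits, labels, beta) {
  d <- dim(logits)
  K <- d[3]
  zm <- matrix(aperm(logits, c(1, 2, 4, 3)), ncol = K)
  zm <- zm - apply(zm, 1, max)
  ez <- exp(zm)
  pm <- ez / rowSums(ez)
  lab <- as.integer(labels) + 1L
  npix <- nrow(pm)
  idx <- cbind(seq_len(npix), lab)
  w <- beta[lab]
  loss <- mean(-w * log(pmax(pm[idx], 1e-12)))
  dl <- pm * w
  dl[idx] <- dl[idx] - w
  dl <- dl / npix
  dim(dl) <- c(d[1], d[2], d[4], K)
  list(loss = loss, dlogits = aperm(dl, c(1, 2, 4, 3)))
}

patches_to_batch <- function(patchset, idx) {
  s <- patchset$patch_size
  n <- length(idx)
  x <- array(0, c(s, s, 3L, n))
  y <- array(0L, c(s, s, n))
  for (i in seq_len(n)) {
    p <- patchset$patches[[idx[i]]]
    x[, , , i] <- p$image
    y[, , i] <- p$labels
  }
  list(x = x, y = y)
}

#' Train a residual U-Net on a patch set
#'
#' Optimizes the class-weighted cross-entropy with Adam on the training
#' split, with optional run-time augmentation, tracking validation loss
#' each epoch and keeping the best-validation weights. All randomness
#' (shuffling, dropout, augmentation draws) derives from `seed`.
#'
#' @param model A `resunet` from [build_resunet()].
#' @param patchset A split [extract_patches()] patch set.
#' @param epochs,batch_size,lr Optimization hyper-parameters.
#' @param seed Integer seed for the training RNG stream.
#' @param class_weights Optional [compute_class_weights()] vector; computed
#'   from the training-split labels when `NULL`.
#' @param augment Optional [augmentation_config()] applied to each training
#'   patch at batch-assembly time.
#' @param verbose Print per-epoch losses.
#' @return The model with trained parameters (`$params` at best validation
#'   loss when a validation split exists) and `$history`, a data frame with
#'   one row per epoch (train and validation loss).
#' @export
train_resunet <- function(model, patchset, epochs = 10L, batch_size = 8L,
                          lr = 1e-3, seed = 1L, class_weights = NULL,
                          augment = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "resunet"))
  if (is.null(patchset$split)) stop("patchset has no split; call split_dataset() first")
  tr_idx <- which(patchset$split == "train")
  va_idx <- which(patchset$split == "val")
  if (length(tr_idx) == 0L) stop("empty training split")
  if (is.null(class_weights)) {
    class_weights <- compute_class_weights(
      lapply(tr_idx, function(i) patchset$patches[[i]]$labels),
      n_classes = model$config$n_classes)
  }
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(val = Inf, params = model$params)
  state <- adam_init(model$params)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(tr_idx)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- 0
      for (bi in seq_along(batches)) {
        b <- patches_to_batch(patchset, batches[[bi]])
        if (!is.null(augment)) {
          for (i in seq_len(dim(b$x)[4])) {
            aug <- augment_patch(list(image = array(b$x[, , , i], dim(b$x)[1:3]),
                                      labels = b$y[, , i]),
                                 augment,
                                 draw_seed = sample.int(.Machine$integer.max, 1L))
            b$x[, , , i] <- aug$image
            b$y[, , i] <- aug$labels
          }
        }
        fw <- resunet_forward(model, b$x, training = TRUE)
        model <- update_running_stats(model, fw$moments)
        lg <- wce_loss_grad(fw$logits, b$y, class_weights)
        bw <- resunet_backward(model, fw$cache, lg$dlogits)
        st <- adam_step(model$params, bw$grads, state, lr)
        model$params <- st$params
        state <- st$state
        ep_loss <- ep_loss + lg$loss
      }
      ep_loss <- ep_loss / length(batches)
      val_loss <- NA_real_
      if (length(va_idx) > 0L) {
        vb <- patches_to_batch(patchset, va_idx)
        vf <- resunet_forward(model, vb$x, training = FALSE)
        val_loss <- wce_loss_grad(vf$logits, vb$y, class_weights)$loss
        if (val_loss < best$val) {
          best$val <- val_loss
          best$params <- model$params
        }
      }
      history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss,
                                           val_loss = val_loss))
      if (verbose) {
        message(sprintf("epoch %d: train %.4f val %.4f", ep, ep_loss, val_loss))
      }
    }
  })
  if (is.finite(best$val)) model$params <- best$params
  model$history <- history
  model$class_weights <- class_weights
  model
}

#' Predict class probabilities for a single patch
#'
#' @param model Trained `resunet`.
#' @param image (H, W, 3) array in `[0, 1]`; sides must satisfy the model's
#'   divisibility requirement.
#' @return A `prediction_tensor`: list with `probs` (H, W, K) and
#'   `class_map` (H, W, values `0..K-1`).
#' @export
predict_patch <- function(model, image) {
  fw <- resunet_forward(model, image, training = FALSE)
  logits <- array(fw$logits, dim(fw$logits)[1:3])
  probs <- softmax(logits)
  structure(list(probs = probs,
                 class_map = array(max.col(matrix(probs, ncol = dim(probs)[3])) - 1L,
                                   dim(probs)[1:2]),
                 logits = logits),
            class = "prediction_tensor")
}

reflect_pad_hw <- function(x, bottom, right) {
  d <- dim(x)
  if (bottom > 0L) {
    ri <- c(seq_len(d[1]), rev(seq_len(d[1]))[seq_len(bottom)])
    x <- if (length(d) == 3L) x[ri, , , drop = FALSE] else x[ri, , drop = FALSE]
  }
  d <- dim(x)
  if (right > 0L) {
    ci <- c(seq_len(d[2]), rev(seq_len(d[2]))[seq_len(right)])
    x <- if (length(d) == 3L) x[, ci, , drop = FALSE] else x[, ci, drop = FALSE]
  }
  x
}

#' Tiled full-image inference
#'
#' Tiles the scan with the given overlap, averages per-class softmax
#' probabilities where tiles overlap, and argmaxes to a full-size class
#' map. Images smaller than the tile are reflection-padded, predicted as a
#' single tile, and cropped back.
#'
#' @param model Trained `resunet`.
#' @param pixels (H, W, 3) RGB array in `[0, 1]`, or a `root_scan`.
#' @param tile Tile side in px; must satisfy the model's divisibility.
#' @param overlap Fractional overlap between neighbouring tiles in `[0, 1)`.
#' @return A `prediction_tensor` (full-size `probs` and `class_map`).
#' @export
predict_full_image <- function(model, pixels, tile = 64L, overlap = 0.25) {
  if (inherits(pixels, "root_scan")) pixels <- pixels$pixels
  tile <- as.integer(tile)
  check_input_divisibility(model, tile, tile)
  d <- dim(pixels)
  h <- d[1]; w <- d[2]
  xp <- reflect_pad_hw(pixels, max(0L, tile - h), max(0L, tile - w))
  dp <- dim(xp)
  stride <- max(1L, as.integer(round(tile * (1 - overlap))))
  rpos <- unique(c(seq(1L, dp[1] - tile + 1L, by = stride), dp[1] - tile + 1L))
  cpos <- unique(c(seq(1L, dp[2] - tile + 1L, by = stride), dp[2] - tile + 1L))
  K <- model$config$n_classes
  acc <- array(0, c(dp[1], dp[2], K))
  cnt <- matrix(0, dp[1], dp[2])
  for (r in rpos) {
    for (cc in cpos) {
      sub <- xp[r:(r + tile - 1L), cc:(cc + tile - 1L), , drop = FALSE]
      pr <- predict_patch(model, array(sub, c(tile, tile, d[3])))$probs
      acc[r:(r + tile - 1L), cc:(cc + tile - 1L), ] <-
        acc[r:(r + tile - 1L), cc:(cc + tile - 1L), , drop = FALSE] + pr
      cnt[r:(r + tile - 1L), cc:(cc + tile - 1L)] <-
        cnt[r:(r + tile - 1L), cc:(cc + tile - 1L)] + 1
    }
  }
  probs <- acc / array(cnt, c(dp[1], dp[2], K))
  probs <- probs[seq_len(h), seq_len(w), , drop = FALSE]
  structure(list(probs = probs,
                 class_map = array(max.col(matrix(probs, ncol = K)) - 1L, c(h, w))),
            class = "prediction_tensor")
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single serialized file holding the parameter tree,
#' the architecture config and the training history.
#'
#' @param model A `resunet`.
#' @param path Checkpoint file path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "resunet"))
  m
}
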