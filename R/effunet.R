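#' Configuration of the U-shaped segmentation network
#'
#' The encoder follows the mobile inverted-bottleneck (MBConv) design with
#' squeeze-and-excitation: seven stages, each a repeated MBConv block with
#' an expansion 1x1 convolution, a depthwise convolution (stride 2 where
#' the stage downsamples), channel reweighting and a linear 1x1 projection,
#' preceded by a full-resolution convolution stem.  The decoder mirrors the
#' five downsampling steps: each block is a 2x2 stride-2 upsampling
#' convolution, concatenation of the encoder feature map at that
#' resolution, and two 3x3 convolutions with batch normalization and ReLU.
#' The head is a 1x1 convolution with per-pixel softmax.  `width` scales
#' all channel counts, allowing desk-scale instantiations of the same
#' topology.
#'
#' @param input_size nominal square input size (default 512; the network is
#'   fully convolutional, so any size divisible by the downsampling factor
#'   works and other sizes are padded).
#' @param n_classes output classes (default 3: background/disc/cup).
#' @param width channel multiplier applied to the default widths.
#' @param stages optional data.frame overriding the encoder plan, with
#'   columns `expand`, `kernel`, `stride` (1 or 2), `repeats`, `channels`.
#' @param stem_channels channels of the full-resolution stem.
#' @param decoder_channels optional per-block decoder widths; default
#'   halves at each block from the deepest encoder width.
#' @param se_ratio squeeze-and-excitation reduction ratio (of the block
#'   input channels).
#' @return An object of class `effunet_config`.
#' @export
effunet_config <- function(input_size = 512L, n_classes = 3L, width = 1,
                           stages = NULL, stem_channels = NULL,
                           decoder_channels = NULL, se_ratio = 0.25) {
  if (is.null(stages)) {
    stages <- data.frame(
      expand = c(1, 6, 6, 6, 6, 6, 6),
      kernel = c(3, 3, 5, 3, 5, 5, 3),
      stride = c(2, 2, 2, 2, 1, 2, 1),
      repeats = c(1, 2, 2, 3, 3, 4, 1),
      channels = pmax(4L, round(width * c(16, 24, 40, 80, 112, 192, 320))))
  }
  if (!all(stages$stride %in% 1:2)) abort_input("stage strides must be 1 or 2")
  if (any(stages$repeats < 1)) abort_input("stage repeats must be >= 1")
  factor <- prod(stages$stride)
  if (log2(factor) != round(log2(factor))) {
    abort_input("total downsampling must be a power of two")
  }
  n_up <- as.integer(log2(factor))
  if (is.null(stem_channels)) stem_channels <- pmax(4L, round(width * 32))
  if (is.null(decoder_channels)) {
    deepest <- stages$channels[nrow(stages)]
    decoder_channels <- pmax(4L, round(deepest / 2^seq_len(n_up)))
  }
  if (length(decoder_channels) != n_up) {
    abort_input(sprintf("decoder needs %d blocks (one per downsampling step)", n_up))
  }
  structure(list(input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes),
                 stages = stages, stem_channels = as.integer(stem_channels),
                 decoder_channels = as.integer(decoder_channels),
                 se_ratio = se_ratio, factor = as.integer(factor)),
            class = "effunet_config")
}

#' @export
print.effunet_config <- function(x, ...) {
  cat(sprintf("<effunet_config: %d stages, stem %d ch, decoder %s, /%d downsampling, %d classes>\n",
              nrow(x$stages), x$stem_channels,
              paste(x$decoder_channels, collapse = "-"), x$factor, x$n_classes))
  invisible(x)
}

new_bn <- function(ch) {
  list(params = list(gamma = rep(1, ch), beta = rep(0, ch)),
       running = list(mean = rep(0, ch), var = rep(1, ch)))
}

#' Build the segmentation network
#'
#' Initializes all weights (He initialization) under the given seed; two
#' builds with the same seed produce identical networks.
#'
#' @param config an [effunet_config()].
#' @param seed RNG seed for weight initialization.
#' @return An object of class `effunet`.
#' @export
build_effunet <- function(config, seed = 1L) {
  set.seed(seed)
  st <- config$stages
  params <- list()
  running <- list()
  meta <- list(stages = list(), skip_channels = integer(0))

  conv_init <- function(k, cin, cout) {
    list(W = he_init(c(k, k, cin, cout), k * k * cin), b = rep(0, cout))
  }

  sc <- config$stem_channels
  bn <- new_bn(sc)
  params$stem <- list(conv = conv_init(3L, 3L, sc), bn = bn$params)
  running$stem <- list(bn = bn$running)

  cur <- sc
  params$stages <- list()
  running$stages <- list()
  for (s in seq_len(nrow(st))) {
    blocks_p <- list(); blocks_r <- list(); blocks_m <- list()
    if (st$stride[s] == 2L) {
      meta$skip_channels <- c(meta$skip_channels, cur)
    }
    for (r in seq_len(st$repeats[s])) {
      cin <- if (r == 1L) cur else st$channels[s]
      cout <- st$channels[s]
      stride <- if (r == 1L) st$stride[s] else 1L
      expand <- st$expand[s]
      ce <- if (expand > 1) as.integer(expand * cin) else cin
      cr <- max(1L, round(config$se_ratio * cin))
      p <- list()
      rn <- list()
      if (expand > 1) {
        p$expand <- conv_init(1L, cin, ce)
        bn <- new_bn(ce); p$bn1 <- bn$params; rn$bn1 <- bn$running
      }
      p$dw <- list(W = he_init(c(st$kernel[s], st$kernel[s], ce),
                               st$kernel[s]^2),
                   b = rep(0, ce))
      bn <- new_bn(ce); p$bn2 <- bn$params; rn$bn2 <- bn$running
      p$se <- list(W1 = he_init(c(ce, cr), ce), b1 = rep(0, cr),
                   W2 = he_init(c(cr, ce), cr), b2 = rep(0, ce))
      p$proj <- conv_init(1L, ce, cout)
      bn <- new_bn(cout); p$bn3 <- bn$params; rn$bn3 <- bn$running
      blocks_p[[r]] <- p
      blocks_r[[r]] <- rn
      blocks_m[[r]] <- list(stride = stride, kernel = st$kernel[s],
                            expand = expand, cin = cin, cout = cout,
                            use_res = stride == 1L && cin == cout)
    }
    params$stages[[s]] <- blocks_p
    running$stages[[s]] <- blocks_r
    meta$stages[[s]] <- blocks_m
    cur <- st$channels[s]
  }

  n_up <- length(config$decoder_channels)
  params$decoder <- list()
  running$decoder <- list()
  prev <- cur
  for (k in seq_len(n_up)) {
    dc <- config$decoder_channels[k]
    skc <- meta$skip_channels[n_up - k + 1L]
    p <- list(up = list(W = he_init(c(2L, 2L, prev, dc), 4L * prev),
                        b = rep(0, dc)),
              conv1 = conv_init(3L, dc + skc, dc),
              conv2 = conv_init(3L, dc, dc))
    bn <- new_bn(dc); p$bnc1 <- bn$params; rn <- list(bnc1 = bn$running)
    bn <- new_bn(dc); p$bnc2 <- bn$params; rn$bnc2 <- bn$running
    params$decoder[[k]] <- p
    running$decoder[[k]] <- rn
    prev <- dc
  }
  params$head <- conv_init(1L, prev, config$n_classes)

  net <- structure(list(config = config, params = params, running = running,
                        meta = meta), class = "effunet")
  net
}

#' @export
print.effunet <- function(x, ...) {
  np <- effunet_n_params(x)
  cat(sprintf("<effunet: %s total parameters (encoder %s, decoder+head %s), /%d downsampling>\n",
              format(np$total, big.mark = ","), format(np$encoder, big.mark = ","),
              format(np$decoder, big.mark = ","), x$config$factor))
  invisible(x)
}

#' Parameter counts of a network
#'
#' Model-summary utility reporting the trainable parameter counts of the
#' encoder (stem + MBConv stages) and of the decoder plus head.
#'
#' @param net an [build_effunet()] network.
#' @return List with `encoder`, `decoder`, `total`.
#' @export
effunet_n_params <- function(net) {
  count <- function(p) tree_sum(length, p)
  enc <- count(net$params$stem) + count(net$params$stages)
  dec <- count(net$params$decoder) + count(net$params$head)
  list(encoder = enc, decoder = dec, total = enc + dec)
}

# --- forward / backward ---------------------------------------------------

mbconv_fwd <- function(x, p, run, meta, training) {
  cache <- list(x = x)
  h <- x
  if (meta$expand > 1) {
    cv <- conv2d_fwd(h, p$expand$W, p$expand$b, 1L)
    bn <- bn_fwd(cv$out, p$bn1$gamma, p$bn1$beta, run$bn1, training)
    run$bn1 <- bn$running
    rl <- relu_fwd(bn$out)
    cache$expand <- cv$cache; cache$bn1 <- bn$cache; cache$relu1 <- rl$cache
    h <- rl$out
  }
  dw <- dwconv_fwd(h, p$dw$W, p$dw$b, meta$stride)
  bn <- bn_fwd(dw$out, p$bn2$gamma, p$bn2$beta, run$bn2, training)
  run$bn2 <- bn$running
  rl <- relu_fwd(bn$out)
  cache$dw <- dw$cache; cache$bn2 <- bn$cache; cache$relu2 <- rl$cache
  se <- se_fwd(rl$out, p$se$W1, p$se$b1, p$se$W2, p$se$b2)
  cache$se <- se$cache
  pj <- conv2d_fwd(se$out, p$proj$W, p$proj$b, 1L)
  bn3 <- bn_fwd(pj$out, p$bn3$gamma, p$bn3$beta, run$bn3, training)
  run$bn3 <- bn3$running
  cache$proj <- pj$cache; cache$bn3 <- bn3$cache
  out <- bn3$out
  if (meta$use_res) out <- out + x
  list(out = out, cache = cache, run = run)
}

mbconv_bwd <- function(dout, p, cache, meta) {
  g <- list()
  bn3 <- bn_bwd(dout, cache$bn3, p$bn3$gamma)
  g$bn3 <- list(gamma = bn3$dgamma, beta = bn3$dbeta)
  pj <- conv2d_bwd(bn3$dx, cache$proj, p$proj$W)
  g$proj <- list(W = pj$dW, b = pj$db)
  se <- se_bwd(pj$dx, cache$se, p$se$W1, p$se$W2)
  g$se <- list(W1 = se$dW1, b1 = se$db1, W2 = se$dW2, b2 = se$db2)
  dh <- relu_bwd(se$dx, cache$relu2)
  bn2 <- bn_bwd(dh, cache$bn2, p$bn2$gamma)
  g$bn2 <- list(gamma = bn2$dgamma, beta = bn2$dbeta)
  dw <- dwconv_bwd(bn2$dx, cache$dw, p$dw$W)
  g$dw <- list(W = dw$dW, b = dw$db)
  dx <- dw$dx
  if (meta$expand > 1) {
    dh <- relu_bwd(dx, cache$relu1)
    bn1 <- bn_bwd(dh, cache$bn1, p$bn1$gamma)
    g$bn1 <- list(gamma = bn1$dgamma, beta = bn1$dbeta)
    ex <- conv2d_bwd(bn1$dx, cache$expand, p$expand$W)
    g$expand <- list(W = ex$dW, b = ex$db)
    dx <- ex$dx
  }
  if (meta$use_res) dx <- dx + dout
  # reorder gradients to match the parameter list order
  list(dx = dx, grads = g[names(p)])
}

effunet_forward <- function(net, x, training = FALSE) {
  p <- net$params; run <- net$running; meta <- net$meta
  cache <- list()

  cv <- conv2d_fwd(x, p$stem$conv$W, p$stem$conv$b, 1L)
  bn <- bn_fwd(cv$out, p$stem$bn$gamma, p$stem$bn$beta, run$stem$bn, training)
  run$stem$bn <- bn$running
  rl <- relu_fwd(bn$out)
  cache$stem <- list(conv = cv$cache, bn = bn$cache, relu = rl$cache)
  cur <- rl$out

  skips <- list()
  cache$stages <- list()
  for (s in seq_along(p$stages)) {
    cache$stages[[s]] <- list()
    for (r in seq_along(p$stages[[s]])) {
      m <- meta$stages[[s]][[r]]
      if (r == 1L && m$stride == 2L) skips[[length(skips) + 1L]] <- cur
      fw <- mbconv_fwd(cur, p$stages[[s]][[r]], run$stages[[s]][[r]], m, training)
      cache$stages[[s]][[r]] <- fw$cache
      run$stages[[s]][[r]] <- fw$run
      cur <- fw$out
    }
  }

  n_up <- length(p$decoder)
  cache$decoder <- list()
  for (k in seq_len(n_up)) {
    dp <- p$decoder[[k]]
    up <- tconv_fwd(cur, dp$up$W, dp$up$b)
    skip <- skips[[n_up - k + 1L]]
    cat_in <- array(c(up$out, skip),
                    c(dim(up$out)[1], dim(up$out)[2],
                      dim(up$out)[3] + dim(skip)[3]))
    c1 <- conv2d_fwd(cat_in, dp$conv1$W, dp$conv1$b, 1L)
    b1 <- bn_fwd(c1$out, dp$bnc1$gamma, dp$bnc1$beta,
                 run$decoder[[k]]$bnc1, training)
    run$decoder[[k]]$bnc1 <- b1$running
    r1 <- relu_fwd(b1$out)
    c2 <- conv2d_fwd(r1$out, dp$conv2$W, dp$conv2$b, 1L)
    b2 <- bn_fwd(c2$out, dp$bnc2$gamma, dp$bnc2$beta,
                 run$decoder[[k]]$bnc2, training)
    run$decoder[[k]]$bnc2 <- b2$running
    r2 <- relu_fwd(b2$out)
    cache$decoder[[k]] <- list(up = up$cache, up_ch = dim(up$out)[3],
                               conv1 = c1$cache, bnc1 = b1$cache,
                               relu1 = r1$cache, conv2 = c2$cache,
                               bnc2 = b2$cache, relu2 = r2$cache)
    cur <- r2$out
  }

  hd <- conv2d_fwd(cur, p$head$W, p$head$b, 1L)
  cache$head <- hd$cache
  list(logits = hd$out, cache = cache, running = run)
}

effunet_backward <- function(net, cache, dlogits) {
  p <- net$params; meta <- net$meta
  g <- list()

  hd <- conv2d_bwd(dlogits, cache$head, p$head$W)
  g$head <- list(W = hd$dW, b = hd$db)
  dcur <- hd$dx

  n_up <- length(p$decoder)
  g$decoder <- vector("list", n_up)
  dskips <- vector("list", n_up)
  for (k in rev(seq_len(n_up))) {
    dp <- p$decoder[[k]]
    ck <- cache$decoder[[k]]
    dr2 <- relu_bwd(dcur, ck$relu2)
    b2 <- bn_bwd(dr2, ck$bnc2, dp$bnc2$gamma)
    c2 <- conv2d_bwd(b2$dx, ck$conv2, dp$conv2$W)
    dr1 <- relu_bwd(c2$dx, ck$relu1)
    b1 <- bn_bwd(dr1, ck$bnc1, dp$bnc1$gamma)
    c1 <- conv2d_bwd(b1$dx, ck$conv1, dp$conv1$W)
    uc <- ck$up_ch
    dcat <- c1$dx
    dup <- dcat[, , seq_len(uc), drop = FALSE]
    dskips[[n_up - k + 1L]] <- dcat[, , uc + seq_len(dim(dcat)[3] - uc),
                                    drop = FALSE]
    up <- tconv_bwd(dup, ck$up, dp$up$W)
    g$decoder[[k]] <- list(up = list(W = up$dW, b = up$db),
                           conv1 = list(W = c1$dW, b = c1$db),
                           conv2 = list(W = c2$dW, b = c2$db),
                           bnc1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                           bnc2 = list(gamma = b2$dgamma, beta = b2$dbeta))
    g$decoder[[k]] <- g$decoder[[k]][names(dp)]
    dcur <- up$dx
  }

  g$stages <- vector("list", length(p$stages))
  skip_i <- length(dskips)
  for (s in rev(seq_along(p$stages))) {
    g$stages[[s]] <- vector("list", length(p$stages[[s]]))
    for (r in rev(seq_along(p$stages[[s]]))) {
      m <- meta$stages[[s]][[r]]
      bw <- mbconv_bwd(dcur, p$stages[[s]][[r]], cache$stages[[s]][[r]], m)
      g$stages[[s]][[r]] <- bw$grads
      dcur <- bw$dx
      if (r == 1L && m$stride == 2L) {
        dcur <- dcur + dskips[[skip_i]]
        skip_i <- skip_i - 1L
      }
    }
  }

  dr <- relu_bwd(dcur, cache$stem$relu)
  bn <- bn_bwd(dr, cache$stem$bn, p$stem$bn$gamma)
  cv <- conv2d_bwd(bn$dx, cache$stem$conv, p$stem$conv$W)
  g$stem <- list(conv = list(W = cv$dW, b = cv$db),
                 bn = list(gamma = bn$dgamma, beta = bn$dbeta))
  g[names(p)]
}

# Soft multi-class Dice loss on softmax probabilities; returns the gradient
# with respect to the logits.
dice_loss <- function(logits, labels) {
  d <- dim(logits)
  K <- d[3]
  p <- as_mat(softmax_probs(logits))
  n <- nrow(p)
  yh <- matrix(0, n, K)
  yh[cbind(seq_len(n), as.integer(labels) + 1L)] <- 1
  eps <- 1e-6
  num <- 2 * colSums(p * yh) + eps
  den <- colSums(p) + colSums(yh) + eps
  loss <- 1 - mean(num / den)
  # dL/dp then through the softmax Jacobian
  dp <- -(2 * yh * matrix(den, n, K, byrow = TRUE) -
            matrix(num, n, K, byrow = TRUE)) /
    matrix(den^2, n, K, byrow = TRUE) / K
  dot <- rowSums(dp * p)
  dlog <- p * (dp - dot)
  list(loss = loss, dlogits = as_arr(dlog, d[1], d[2], d[3]))
}

#' Training specification
#'
#' @param epochs passes over the image set (>= 1; the headline experiments
#'   in the field use around 200).
#' @param lr Adam learning rate.
#' @param loss `"ce"` (per-pixel cross-entropy, default) or `"dice"`.
#' @param seed RNG seed (image order shuffling).
#' @param shuffle shuffle image order each epoch.
#' @return Object of class `train_spec`.
#' @export
train_spec <- function(epochs = 200L, lr = 1e-3, loss = c("ce", "dice"),
                       seed = 1L, shuffle = TRUE) {
  if (epochs < 1L) abort_input("epochs must be >= 1")
  structure(list(epochs = as.integer(epochs), lr = lr,
                 loss = match.arg(loss), seed = as.integer(seed),
                 shuffle = isTRUE(shuffle)), class = "train_spec")
}

#' Train the segmentation network
#'
#' Minimizes the per-pixel loss with Adam, one image per step.  After each
#' epoch, pixel accuracy is evaluated on the held-out pairs (the training
#' pairs when no holdout is given) and the best-scoring parameters are
#' retained as the returned checkpoint.
#'
#' @param net a [build_effunet()] network.
#' @param images list of `H x W x 3` arrays in `[0, 1]`.
#' @param masks list of matching [label_mask()] (or integer matrices with
#'   classes `0..n_classes-1`).
#' @param spec a [train_spec()].
#' @param holdout optional list(images, masks) used for checkpoint
#'   selection.
#' @return The trained network, with `history` (per-step loss trace),
#'   `best_accuracy` and `best_epoch` attached.
#' @export
train_effunet <- function(net, images, masks, spec = train_spec(),
                          holdout = NULL) {
  if (!inherits(spec, "train_spec")) abort_input("spec must be a train_spec")
  if (inherits(images, "array")) images <- list(images)
  if (!is.list(masks)) masks <- list(masks)
  if (length(images) != length(masks)) abort_input("images and masks differ in length")
  for (i in seq_along(images)) {
    if (!identical(dim(images[[i]])[1:2], dim(masks[[i]])[1:2])) {
      abort_input(sprintf("image/mask %d shapes differ", i))
    }
  }
  labels <- lapply(masks, function(m) matrix(as.integer(unclass(m)),
                                             nrow(m), ncol(m)))
  ev_img <- if (is.null(holdout)) images else holdout$images
  ev_lab <- if (is.null(holdout)) labels else
    lapply(holdout$masks, function(m) matrix(as.integer(unclass(m)),
                                             nrow(m), ncol(m)))

  set.seed(spec$seed)
  state <- adam_init(net$params)
  trace <- numeric(0)
  best <- list(acc = -Inf, params = net$params, running = net$running,
               epoch = 0L)
  loss_fun <- if (spec$loss == "ce") softmax_ce else dice_loss

  for (epoch in seq_len(spec$epochs)) {
    ord <- if (spec$shuffle) sample(seq_along(images)) else seq_along(images)
    for (i in ord) {
      fw <- effunet_forward(net, images[[i]], training = TRUE)
      net$running <- fw$running
      ls <- loss_fun(fw$logits, labels[[i]])
      trace <- c(trace, ls$loss)
      grads <- effunet_backward(net, fw$cache, ls$dlogits)
      st <- adam_step(net$params, grads, state, spec$lr)
      net$params <- st$params
      state <- st$state
    }
    acc <- mean(vapply(seq_along(ev_img), function(i) {
      pr <- effunet_forward(net, ev_img[[i]], training = FALSE)
      lab <- apply(pr$logits, c(1, 2), which.max) - 1L
      mean(lab == ev_lab[[i]])
    }, 0))
    if (acc > best$acc) {
      best <- list(acc = acc, params = net$params, running = net$running,
                   epoch = epoch)
    }
  }
  net$params <- best$params
  net$running <- best$running
  net$history <- trace
  net$best_accuracy <- best$acc
  net$best_epoch <- best$epoch
  net
}

#' Predict a label mask for an image
#'
#' Runs the network in inference mode and takes the per-pixel argmax class.
#' Inputs whose size is not divisible by the downsampling factor are
#' zero-padded and the prediction cropped back.  The result is normalized
#' by the usual containment rule (cup clipped inside disc).
#'
#' @param net a (typically trained) [build_effunet()] network.
#' @param image `H x W x 3` array in `[0, 1]`.
#' @return A [label_mask()]; the disc may be empty for an untrained
#'   network.
#' @export
predict_masks <- function(net, image) {
  d <- dim(image)
  f <- net$config$factor
  ph <- (f - d[1] %% f) %% f
  pw <- (f - d[2] %% f) %% f
  x <- if (ph > 0 || pw > 0) zero_pad(image, c(0L, ph), c(0L, pw)) else image
  fw <- effunet_forward(net, x, training = FALSE)
  probs <- softmax_probs(fw$logits)
  lab <- apply(probs, c(1, 2), which.max) - 1L
  lab <- lab[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  suppressWarnings(label_mask_raw(lab))
}

# label_mask that tolerates an empty disc (network may predict none).
label_mask_raw <- function(lab) {
  m <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  structure(m, class = c("label_mask", "matrix", "array"))
}

#' Forward pass returning per-pixel class probabilities
#'
#' @param net a [build_effunet()] network.
#' @param image `H x W x 3` array.
#' @return `H x W x n_classes` array of softmax probabilities.
#' @export
predict_probs <- function(net, image) {
  softmax_probs(effunet_forward(net, image, training = FALSE)$logits)
}

# --- preprocessing --------------------------------------------------------

#' Preprocess a fundus image: remove black borders and resize
#'
#' Crops the bounding box of pixels whose maximum channel intensity exceeds
#' the darkness threshold, then resizes to `size x size` with bilinear
#' interpolation.  The crop box is attached as attribute `crop_box`
#' (`c(r1, r2, c1, c2)`) so the matching mask can be cropped identically
#' with [preprocess_mask()].
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param size output side length (default 512).
#' @param dark_threshold maximum-channel intensity below which a pixel
#'   counts as border (default 10/255).
#' @return Resized `size x size x 3` array with attribute `crop_box`.
#' @export
preprocess_image <- function(image, size = 512L, dark_threshold = 10 / 255) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    abort_input("image must be an H x W x 3 array")
  }
  mx <- pmax(image[, , 1], image[, , 2], image[, , 3])
  keep_r <- which(apply(mx >= dark_threshold, 1, any))
  keep_c <- which(apply(mx >= dark_threshold, 2, any))
  if (!length(keep_r)) abort_degenerate("image is entirely black")
  box <- c(min(keep_r), max(keep_r), min(keep_c), max(keep_c))
  crop <- image[box[1]:box[2], box[3]:box[4], , drop = FALSE]
  out <- array(0, c(size, size, 3))
  for (ch in 1:3) out[, , ch] <- resize_bilinear(crop[, , ch], size, size)
  attr(out, "crop_box") <- box
  out
}

#' @rdname preprocess_image
#' @param mask a [label_mask()].
#' @param crop_box optional `c(r1, r2, c1, c2)` from a preprocessed image.
#' @return `preprocess_mask()`: a resized [label_mask()] (nearest
#'   neighbour).
#' @export
preprocess_mask <- function(mask, size = 512L, crop_box = NULL) {
  m <- unclass(mask)
  if (!is.null(crop_box)) {
    m <- m[crop_box[1]:crop_box[2], crop_box[3]:crop_box[4], drop = FALSE]
  }
  label_mask_raw(resize_nearest(m, size, size))
}

resize_bilinear <- function(plane, h2, w2) {
  h <- nrow(plane); w <- ncol(plane)
  sy <- pmin(pmax((seq_len(h2) - 0.5) * h / h2 + 0.5, 1), h)
  sx <- pmin(pmax((seq_len(w2) - 0.5) * w / w2 + 0.5, 1), w)
  y0 <- pmin(floor(sy), h - 1); y1 <- y0 + 1; wy <- sy - y0
  x0 <- pmin(floor(sx), w - 1); x1 <- x0 + 1; wx <- sx - x0
  if (h == 1L) { y0 <- y1 <- rep(1L, h2); wy <- rep(0, h2) }
  if (w == 1L) { x0 <- x1 <- rep(1L, w2); wx <- rep(0, w2) }
  WY <- matrix(wy, h2, w2); WX <- matrix(wx, h2, w2, byrow = TRUE)
  plane[y0, x0, drop = FALSE] * (1 - WY) * (1 - WX) +
    plane[y1, x0, drop = FALSE] * WY * (1 - WX) +
    plane[y0, x1, drop = FALSE] * (1 - WY) * WX +
    plane[y1, x1, drop = FALSE] * WY * WX
}

resize_nearest <- function(plane, h2, w2) {
  h <- nrow(plane); w <- ncol(plane)
  sy <- pmin(pmax(round((seq_len(h2) - 0.5) * h / h2 + 0.5), 1), h)
  sx <- pmin(pmax(round((seq_len(w2) - 0.5) * w / w2 + 0.5), 1), w)
  plane[sy, sx, drop = FALSE]
}
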