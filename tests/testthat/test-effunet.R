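test_that("the network is fully convolutional with a softmax head", {
  net <- build_effunet(tiny_net_config(32), seed = 2)
  for (sz in c(32L, 48L)) {
    x <- array(runif(sz * sz * 3), c(sz, sz, 3))
    pr <- predict_probs(net, x)
    expect_identical(dim(pr), c(sz, sz, 3L))
    expect_true(all(abs(apply(pr, c(1, 2), sum) - 1) < 1e-5))
  }
  # sizes not divisible by the downsampling factor are padded and cropped
  x2 <- array(runif(50 * 46 * 3), c(50, 46, 3))
  m <- predict_masks(net, x2)
  expect_identical(dim(unclass(m)), c(50L, 46L))
  expect_s3_class(m, "label_mask")
})

test_that("initialization and forward passes are deterministic in the seed", {
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  n1 <- build_effunet(tiny_net_config(32), seed = 5)
  n2 <- build_effunet(tiny_net_config(32), seed = 5)
  expect_identical(predict_probs(n1, x), predict_probs(n2, x))
  n3 <- build_effunet(tiny_net_config(32), seed = 6)
  expect_false(identical(predict_probs(n1, x), predict_probs(n3, x)))
})

test_that("backpropagation matches numerical gradients", {
  cfg <- effunet_config(
    input_size = 16, width = 0.25,
    stages = data.frame(expand = c(1, 4), kernel = c(3, 3), stride = c(2, 2),
                        repeats = c(1, 1), channels = c(4, 6)),
    stem_channels = 4, decoder_channels = c(6, 4))
  net <- build_effunet(cfg, seed = 3)
  set.seed(9)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  lab <- matrix(sample(0:2, 256, TRUE), 16, 16)
  fw <- spagen:::effunet_forward(net, x, training = TRUE)
  ls <- spagen:::softmax_ce(fw$logits, lab)
  gr <- spagen:::effunet_backward(net, fw$cache, ls$dlogits)

  getg <- function(p, ks) { for (k in ks) p <- p[[k]]; p }
  modp <- function(p, ks, f) {
    if (!length(ks)) return(f(p))
    p[[ks[[1]]]] <- modp(p[[ks[[1]]]], ks[-1], f)
    p
  }
  num_grad <- function(path, idx, eps = 1e-5) {
    lossat <- function(v) {
      nn <- net
      nn$params <- modp(net$params, path, function(a) { a[idx] <- v; a })
      f <- spagen:::effunet_forward(nn, x, training = TRUE)
      spagen:::softmax_ce(f$logits, lab)$loss
    }
    v0 <- getg(net$params, path)[idx]
    (lossat(v0 + eps) - lossat(v0 - eps)) / (2 * eps)
  }
  checks <- list(list(list("stem", "conv", "W"), 5),
                 list(list("stages", 1L, 1L, "dw", "W"), 3),
                 list(list("stages", 2L, 1L, "expand", "W"), 2),
                 list(list("stages", 2L, 1L, "bn2", "gamma"), 2),
                 list(list("stages", 2L, 1L, "proj", "W"), 2),
                 list(list("decoder", 1L, "up", "W"), 4),
                 list(list("decoder", 2L, "conv1", "W"), 7),
                 list(list("head", "W"), 2))
  for (ch in checks) {
    ng <- num_grad(ch[[1]], ch[[2]])
    ag <- getg(gr, ch[[1]])[ch[[2]]]
    expect_equal(ag, ng, tolerance = 1e-5,
                 label = paste(unlist(ch[[1]]), collapse = "$"))
  }
})

test_that("training is deterministic and rejects malformed inputs", {
  sc <- toy_scene(32, seed = 11)
  spec <- train_spec(epochs = 3, lr = 1e-2, seed = 4)
  n1 <- train_effunet(build_effunet(tiny_net_config(32), seed = 1),
                      list(sc$image), list(sc$mask), spec)
  n2 <- train_effunet(build_effunet(tiny_net_config(32), seed = 1),
                      list(sc$image), list(sc$mask), spec)
  expect_identical(n1$history, n2$history)
  expect_length(n1$history, 3)
  expect_gte(n1$best_accuracy, 0)

  expect_error(train_spec(epochs = 0), class = "spagen_input_error")
  bad_mask <- label_mask(matrix(1L, 16, 16))
  expect_error(train_effunet(build_effunet(tiny_net_config(32), seed = 1),
                             list(sc$image), list(bad_mask), spec),
               class = "spagen_input_error")
})

test_that("the Dice loss option trains and reports sane losses", {
  sc <- toy_scene(32, seed = 12)
  net <- train_effunet(build_effunet(tiny_net_config(32), seed = 1),
                       list(sc$image), list(sc$mask),
                       train_spec(epochs = 5, lr = 1e-2, loss = "dice", seed = 1))
  expect_true(all(net$history >= 0 & net$history <= 1))
  expect_lt(net$history[5], net$history[1])
})

test_that("an untrained network still yields a valid label mask", {
  net <- build_effunet(tiny_net_config(32), seed = 8)
  sc <- toy_scene(32, seed = 13)
  m <- predict_masks(net, sc$image)
  expect_s3_class(m, "label_mask")
  expect_true(all(unclass(m) %in% 0:2))
  # constant input gives deterministic output
  x <- array(0.5, c(32, 32, 3))
  expect_identical(unclass(predict_masks(net, x)), unclass(predict_masks(net, x)))
})

test_that("the model-summary utility reports encoder and decoder parameters", {
  net <- build_effunet(tiny_net_config(32), seed = 1)
  np <- effunet_n_params(net)
  expect_gt(np$encoder, 0)
  expect_gt(np$decoder, 0)
  expect_identical(np$total, np$encoder + np$decoder)
  hand <- spagen:::tree_sum(length, net$params)
  expect_identical(np$total, hand)
  # the default full-scale topology downsamples by 32
  full <- effunet_config()
  expect_identical(full$factor, 32L)
  expect_length(full$decoder_channels, 5)
})

test_that("preprocessing crops dark borders and resizes", {
  set.seed(17)
  img <- array(0, c(90, 80, 3))
  img[21:70, 21:60, ] <- runif(50 * 40 * 3, 0.3, 1)
  pre <- preprocess_image(img, size = 64)
  expect_identical(dim(pre), c(64L, 64L, 3L))
  expect_identical(attr(pre, "crop_box"), c(21L, 70L, 21L, 60L))
  expect_gt(mean(pre), 0.3)  # border gone

  clean <- array(runif(64 * 64 * 3, 0.2, 1), c(64, 64, 3))
  pre2 <- preprocess_image(clean, size = 64)
  expect_identical(attr(pre2, "crop_box"), c(1L, 64L, 1L, 64L))
  expect_equal(pre2[30, 30, ], clean[30, 30, ], tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(preprocess_image(array(0, c(32, 32, 3))),
               class = "spagen_degenerate_mask_error")

  # nearest-neighbour mask resize preserves the label set
  m <- toy_scene(64)$mask
  m2 <- preprocess_mask(m, size = 32)
  expect_identical(sort(unique(as.vector(unclass(m2)))), c(0L, 1L, 2L))
})
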