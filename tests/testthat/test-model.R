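tiny_model <- function(seed = 7L) {
  build_resunet(model_config(levels = 2L, base_channels = 4L, dropout = 0,
                             seed = seed))
}

test_that("softmax matches its closed form and is overflow-safe", {
  expect_equal(softmax(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(softmax(c(1000, 0, 0)), c(1, 0, 0))
  expect_equal(softmax(c(1, 2, 3)),
               c(0.09003057, 0.24472847, 0.66524096), tolerance = 1e-7)
  set.seed(4)
  z <- matrix(rnorm(50 * 3, sd = 5), 50, 3)
  p <- softmax(z)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0))
  expect_error(softmax(c(1, NA, 2)), "finite")
})

test_that("balanced cross-entropy reproduces hand-evaluated cases", {
  # perfect prediction
  expect_equal(balanced_cross_entropy(c(0L, 1L, 2L), diag(3)[c(1, 2, 3), ],
                                      rep(1 / 3, 3)), 0, tolerance = 1e-9)
  # single pixel, uniform p and beta: (1/3) log 3
  expect_equal(balanced_cross_entropy(2L, matrix(1 / 3, 1, 3), rep(1 / 3, 3)),
               log(3) / 3, tolerance = 1e-12)
  # beta_c = 0 silences class c
  set.seed(8)
  p <- softmax(matrix(rnorm(30), 10, 3))
  lab <- rep(2L, 10)
  expect_equal(balanced_cross_entropy(lab, p, c(0.5, 0.5, 0)), 0)
})

test_that("uniform weights reduce to plain cross-entropy / M", {
  set.seed(9)
  for (rep in 1:20) {
    p <- softmax(matrix(rnorm(60), 20, 3))
    lab <- sample(0:2, 20, TRUE)
    plain <- mean(-log(p[cbind(1:20, lab + 1L)]))
    expect_equal(balanced_cross_entropy(lab, p, rep(1 / 3, 3)), plain / 3,
                 tolerance = 1e-12)
  }
})

test_that("class weights are normalized inverse frequencies", {
  expect_equal(compute_class_weights(matrix(c(0L, 1L, 2L), 3, 2)),
               rep(1 / 3, 3))
  # frequencies (0.8, 0.1, 0.1): oracle = normalize (1/0.8, 1/0.1, 1/0.1)
  m <- matrix(0L, 10, 10)
  m[1:10] <- 1L
  m[11:20] <- 2L
  w <- compute_class_weights(m)
  oracle <- c(1 / 0.8, 1 / 0.1, 1 / 0.1)
  expect_equal(w, oracle / sum(oracle), tolerance = 1e-12)
  expect_equal(w, c(0.0588235, 0.4705882, 0.4705882), tolerance = 1e-6)
  expect_warning(w0 <- compute_class_weights(matrix(0L, 5, 5)), "absent")
  expect_true(all(is.finite(w0)))
})

test_that("segmentation metrics reproduce confusion-count arithmetic", {
  perfect <- matrix(sample(0:2, 100, TRUE), 10, 10)
  sm <- segmentation_metrics(perfect, perfect)
  expect_equal(sm[c("accuracy", "precision", "recall", "iou")],
               list(accuracy = 1, precision = 1, recall = 1, iou = 1))
  # truth root 100 px, pred root 150 px, overlap 90
  truth <- matrix(0L, 20, 20)
  pred <- matrix(0L, 20, 20)
  truth[1:100] <- 2L
  pred[11:160] <- 2L
  sm <- segmentation_metrics(truth, pred)
  expect_equal(sm$precision, 90 / 150)
  expect_equal(sm$recall, 90 / 100)
  expect_equal(sm$iou, 90 / 160)
  # disjoint roots
  t2 <- matrix(0L, 4, 4); p2 <- matrix(0L, 4, 4)
  t2[1:4] <- 2L; p2[13:16] <- 2L
  expect_equal(segmentation_metrics(t2, p2)$iou, 0)
  # both empty
  expect_warning(sm0 <- segmentation_metrics(matrix(0L, 3, 3), matrix(0L, 3, 3)),
                 "empty")
  expect_equal(sm0$iou, 1)
  expect_true(is.na(sm0$precision))
})

test_that("IOU <= min(precision, recall) and the harmonic identity hold", {
  set.seed(10)
  for (i in 1:10000) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp + fp == 0 || tp + fn == 0 || tp + fp + fn == 0) next
    prec <- tp / (tp + fp); rec <- tp / (tp + fn)
    iou <- tp / (tp + fp + fn)
    expect_lte(iou, min(prec, rec) + 1e-12)
    if (prec + rec > 0) {
      expect_equal(iou, prec * rec / (prec + rec - prec * rec),
                   tolerance = 1e-12)
    }
  }
})

test_that("the reported AUC matches the rank-statistic oracle", {
  set.seed(11)
  truth <- matrix(sample(c(0L, 2L), 400, TRUE), 20, 20)
  probs <- array(runif(400 * 3), c(20, 20, 3))
  probs[, , 3] <- probs[, , 3] + (truth == 2L)  # informative score
  probs <- probs / array(rowSums(matrix(probs, ncol = 3)), c(20, 20, 3))
  sm <- segmentation_metrics(truth, truth, probs)
  expect_equal(sm$auc,
               rank_auc(as.integer(truth == 2L), as.numeric(probs[, , 3])),
               tolerance = 1e-9)
})

test_that("the default architecture has about 6.5 million parameters", {
  n <- count_parameters(build_resunet(model_config()))
  expect_lt(abs(n / 1e6 - 6.5) / 6.5, 0.10)
})

test_that("forward pass honours the shape contract and eval determinism", {
  m <- tiny_model()
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p1 <- predict_patch(m, x)
  expect_equal(dim(p1$probs), c(64L, 64L, 3L))
  expect_equal(dim(p1$class_map), c(64L, 64L))
  expect_true(all(abs(apply(p1$probs, c(1, 2), sum) - 1) < 1e-6))
  p2 <- predict_patch(m, x)
  expect_identical(p1$logits, p2$logits)
  expect_error(predict_patch(m, array(0.5, c(63, 64, 3))), "divisible")
})

test_that("analytic gradients match finite differences", {
  m <- build_resunet(model_config(levels = 3L, base_channels = 2L,
                                  dropout = 0, seed = 7L))
  # temper the classifier scale so no pixel sits at the loss clip, where
  # the clipped finite-difference oracle and the softmax gradient differ
  m$params$final$W <- m$params$final$W * 0.1
  set.seed(21)
  x <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  y <- array(sample(0:2, 8 * 8 * 2, TRUE), c(8, 8, 2))
  beta <- c(0.2, 0.3, 0.5)
  fw <- rootseg:::resunet_forward(m, x, training = TRUE)
  probs <- softmax(matrix(aperm(fw$logits, c(1, 2, 4, 3)), ncol = 3))
  expect_gt(min(probs[cbind(seq_len(nrow(probs)), as.integer(y) + 1L)]),
            1e-8)
  lg <- rootseg:::wce_loss_grad(fw$logits, y, beta)
  bw <- rootseg:::resunet_backward(m, fw$cache, lg$dlogits)
  lossfn <- function(model) {
    f <- rootseg:::resunet_forward(model, x, training = TRUE)
    rootseg:::wce_loss_grad(f$logits, y, beta)$loss
  }
  paths <- rootseg:::tree_walk_names(m$params)
  for (pi in sample(length(paths), 8)) {
    path <- paths[[pi]]
    par <- rootseg:::tree_get(m$params, path)
    j <- sample(length(par), 1)
    eps <- 1e-5
    for (sgn in c(1, -1)) {
      par2 <- par
      par2[j] <- par[j] + sgn * eps
      m2 <- m
      m2$params <- rootseg:::tree_set(m$params, path, par2)
      if (sgn > 0) lp <- lossfn(m2) else lm_ <- lossfn(m2)
    }
    num <- (lp - lm_) / (2 * eps)
    ana <- rootseg:::tree_get(bw$grads, path)[j]
    expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-4)
  }
})

test_that("training runs, learns a separable phantom, and is seed-stable", {
  s <- render_phantom(small_phantom(seed = 31, artifact_density = 40))
  sets <- lapply(1:3, function(i)
    extract_patches(s$scans[[i]], s$masks[[i]], 32L))
  ps <- filter_sparse_patches(combine_patch_sets(sets))
  ps <- split_dataset(ps, fractions = c(0.8, 0.2, 0), seed = 2)
  m <- build_resunet(model_config(levels = 2L, base_channels = 4L, seed = 6))
  # one-epoch smoke: finite loss in history
  m1 <- train_resunet(m, ps, epochs = 1L, batch_size = 4L, seed = 3)
  expect_equal(nrow(m1$history), 1L)
  expect_true(is.finite(m1$history$train_loss))
  # longer run learns
  m2 <- train_resunet(m, ps, epochs = 8L, batch_size = 4L, seed = 3)
  expect_lt(m2$history$train_loss[8], m2$history$train_loss[1])
  # same seed, same result
  m3 <- train_resunet(m, ps, epochs = 2L, batch_size = 4L, seed = 5)
  m4 <- train_resunet(m, ps, epochs = 2L, batch_size = 4L, seed = 5)
  expect_identical(m3$history$val_loss, m4$history$val_loss)
  expect_error(train_resunet(m, structure(list(patches = list(), split = character()),
                                          class = "patch_set")),
               "empty|split")
})

test_that("stitched single-tile prediction equals the direct patch prediction", {
  m <- tiny_model(seed = 9L)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  direct <- predict_patch(m, x)
  stitched <- predict_full_image(m, x, tile = 64L, overlap = 0)
  expect_equal(stitched$probs, direct$probs, tolerance = 1e-12)
  expect_identical(stitched$class_map, direct$class_map)
})

test_that("tiled inference covers every pixel for any overlap", {
  m <- tiny_model(seed = 9L)
  x <- array(runif(96 * 80 * 3), c(96, 80, 3))
  for (ov in c(0, 0.5)) {
    pred <- predict_full_image(m, x, tile = 32L, overlap = ov)
    expect_equal(dim(pred$class_map), c(96L, 80L))
    expect_true(all(pred$class_map %in% 0:2))
  }
  # image smaller than the tile: single padded tile, cropped back
  small <- predict_full_image(m, array(runif(20 * 24 * 3), c(20, 24, 3)),
                              tile = 32L)
  expect_equal(dim(small$class_map), c(20L, 24L))
})

test_that("checkpoints round-trip through save and load", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(predict_patch(m, x)$logits, predict_patch(m2, x)$logits)
})
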