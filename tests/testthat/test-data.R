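make_scan <- function(rows, cols, seed = 1) {
  set.seed(seed)
  array(runif(rows * cols * 3), c(rows, cols, 3))
}

test_that("patch grids follow floor-division arithmetic", {
  cases <- list(list(r = 3000, c = 2039, s = 64, n = 46L * 31L),
                list(r = 512, c = 384, s = 128, n = 4L * 3L),
                list(r = 96, c = 96, s = 96, n = 1L))
  for (cs in cases) {
    img <- array(0.5, c(cs$r, cs$c, 3))
    msk <- matrix(0L, cs$r, cs$c)
    ps <- extract_patches(img, msk, cs$s)
    expect_equal(length(ps$patches), cs$n)
    expect_true(all(vapply(ps$patches, function(p) all(dim(p$labels) == cs$s),
                           logical(1))))
  }
})

test_that("a patch equal to the whole image is the identity tiling", {
  img <- make_scan(32, 32)
  msk <- matrix(0L, 32, 32)
  ps <- extract_patches(img, msk, 32L)
  expect_equal(length(ps$patches), 1L)
  expect_equal(ps$patches[[1]]$image, img)
})

test_that("oversized patch sizes raise an error naming both shapes", {
  img <- make_scan(32, 48)
  expect_error(extract_patches(img, matrix(0L, 32, 48), 64L), "64.*32x48")
})

test_that("provenance reconstructs each patch from its source scan", {
  scan <- root_scan(make_scan(96, 64), chamber_id = "C3", timepoint = 2L)
  msk <- matrix(sample(0:2, 96 * 64, TRUE), 96, 64)
  ps <- extract_patches(scan, msk, 32L)
  for (k in sample(length(ps$patches), 3)) {
    r0 <- ps$provenance$row[k]; c0 <- ps$provenance$col[k]
    expect_equal(ps$patches[[k]]$image,
                 scan$pixels[r0 + 1:32, c0 + 1:32, , drop = FALSE])
    expect_equal(ps$provenance$chamber_id[k], "C3")
  }
})

test_that("the sparse-label filter cuts exactly at the threshold", {
  mk <- function(n_fg) {
    lab <- matrix(0L, 64, 64)
    if (n_fg > 0) lab[seq_len(n_fg)] <- 2L
    lab
  }
  img <- make_scan(64, 64)
  ps <- structure(list(patches = list(list(image = img, labels = mk(819)),
                                      list(image = img, labels = mk(820)),
                                      list(image = img, labels = mk(0)),
                                      list(image = img, labels = mk(4096))),
                       provenance = data.frame(chamber_id = rep("C", 4),
                                               timepoint = 0L,
                                               row = 0L, col = 0L),
                       patch_size = 64L, split = NULL),
                  class = "patch_set")
  # 819/4096 = 0.19995 < 0.20 removed; 820/4096 = 0.20019 retained
  fp <- filter_sparse_patches(ps, 0.20)
  expect_equal(length(fp$patches), 2L)
  expect_equal(sum(fp$patches[[1]]$labels != 0L), 820L)
  expect_equal(sum(fp$patches[[2]]$labels != 0L), 4096L)
})

test_that("filtering raises the mean foreground fraction on phantoms", {
  s <- render_phantom(small_phantom(seed = 13))
  sets <- lapply(1:3, function(i)
    extract_patches(s$scans[[i]], s$masks[[i]], 32L))
  ps <- combine_patch_sets(sets)
  fg <- function(x) mean(vapply(x$patches, function(p) mean(p$labels != 0L),
                                numeric(1)))
  fp <- filter_sparse_patches(ps, 0.20)
  expect_gt(length(fp$patches), 0L)
  expect_gt(fg(fp), fg(ps))
})

test_that("smaller patch sizes retain more patches after filtering", {
  s <- render_phantom(phantom_config(seed = 17))
  counts <- vapply(c(32L, 64L, 128L), function(sz) {
    sets <- lapply(seq_along(s$scans), function(i)
      extract_patches(s$scans[[i]], s$masks[[i]], sz))
    length(suppressWarnings(
      filter_sparse_patches(combine_patch_sets(sets)))$patches)
  }, numeric(1))
  expect_true(all(diff(counts) < 0))
})

test_that("splits hit the requested fractions within one patch", {
  img <- make_scan(32, 32)
  mk_ps <- function(n) {
    structure(list(patches = rep(list(list(image = img,
                                           labels = matrix(2L, 32, 32))), n),
                   provenance = data.frame(chamber_id = rep("C", n),
                                           timepoint = 0L, row = 0L, col = 0L),
                   patch_size = 32L, split = NULL),
              class = "patch_set")
  }
  sp <- split_dataset(mk_ps(10L), seed = 4)
  expect_equal(unname(table(sp$split)[c("train", "val", "test")]),
               c(8L, 1L, 1L), ignore_attr = TRUE)
  sp2 <- split_dataset(mk_ps(10L), seed = 4)
  expect_identical(sp$split, sp2$split)
  all_train <- split_dataset(mk_ps(7L), fractions = c(1, 0, 0), seed = 1)
  expect_true(all(all_train$split == "train"))
  # larger n stays within one patch of exact fractions
  sp3 <- split_dataset(mk_ps(123L), seed = 9)
  tab <- table(sp3$split)
  expect_lte(abs(tab[["train"]] - 0.8 * 123), 1)
  expect_lte(abs(tab[["val"]] - 0.1 * 123), 1)
})

test_that("disabled augmentation is the identity", {
  cfg <- augmentation_config(rotation = FALSE, flips = FALSE,
                             crop_fraction = 0, shift = FALSE,
                             zoom_range = c(1, 1),
                             brightness_contrast_range = 0)
  p <- list(image = make_scan(32, 32), labels = matrix(sample(0:2, 1024, TRUE), 32, 32))
  a <- augment_patch(p, cfg, draw_seed = 99)
  expect_identical(a$image, p$image)
  expect_identical(a$labels, p$labels)
})

test_that("a horizontal flip applied twice with the same draw is the identity", {
  cfg <- augmentation_config(rotation = FALSE, flips = TRUE,
                             crop_fraction = 0, shift = FALSE,
                             zoom_range = c(1, 1),
                             brightness_contrast_range = 0)
  p <- list(image = make_scan(16, 16), labels = matrix(sample(0:2, 256, TRUE), 16, 16))
  once <- augment_patch(p, cfg, draw_seed = 3)
  twice <- augment_patch(once, cfg, draw_seed = 3)
  expect_equal(twice$image, p$image)
  expect_identical(twice$labels, p$labels)
})

test_that("augmented labels never leave {0, 1, 2} and never interpolate", {
  cfg <- augmentation_config()
  set.seed(1)
  p <- list(image = make_scan(32, 32),
            labels = matrix(sample(0:2, 1024, TRUE, prob = c(0.7, 0.1, 0.2)),
                            32, 32))
  for (ds in 1:1000) {
    a <- augment_patch(p, cfg, draw_seed = ds)
    expect_true(all(a$labels %in% 0:2))
    expect_true(all(a$labels == as.integer(a$labels)))
    expect_equal(dim(a$image), c(32L, 32L, 3L))
  }
})
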