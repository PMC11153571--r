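test_that("max projection is the union of root occupancy", {
  a <- matrix(0L, 6, 6); a[2, 2] <- 2L
  b <- matrix(0L, 6, 6); b[5, 5] <- 2L; b[2, 2] <- 1L
  expect_equal(max_projection(list(a)), a == 2L)
  proj <- max_projection(list(a, b))
  expect_equal(sum(proj), 2L)
  expect_true(proj[2, 2] && proj[5, 5])
  # oracle: explicit set union of root coordinates
  set.seed(2)
  maps <- lapply(1:4, function(i) matrix(sample(0:2, 64, TRUE), 8, 8))
  proj <- max_projection(maps)
  union_px <- unique(do.call(rbind, lapply(maps, function(m)
    which(m == 2L, arr.ind = TRUE))))
  expect_equal(sum(proj), nrow(union_px))
})

test_that("graham_scan handles canonical small cases", {
  tri <- rbind(c(1, 1), c(1, 11), c(11, 1))
  h <- graham_scan(tri)
  expect_false(h$degenerate)
  expect_equal(point_set_key(h$vertices), point_set_key(tri))
  sq <- rbind(c(1, 1), c(1, 5), c(5, 1), c(5, 5), c(3, 3))
  h2 <- graham_scan(sq)
  expect_equal(nrow(h2$vertices), 4L)
  expect_equal(point_set_key(h2$vertices), point_set_key(sq[1:4, ]))
  # pivot convention flag leaves the vertex set unchanged
  h3 <- graham_scan(sq, pivot = "top")
  expect_equal(point_set_key(h3$vertices), point_set_key(h2$vertices))
})

test_that("degenerate point sets return flagged hulls, not errors", {
  expect_true(graham_scan(rbind(c(2, 2)))$degenerate)
  expect_true(graham_scan(rbind(c(1, 1), c(4, 4)))$degenerate)
  col3 <- graham_scan(rbind(c(1, 1), c(2, 2), c(3, 3), c(5, 5)))
  expect_true(col3$degenerate)
  expect_equal(point_set_key(col3$vertices),
               point_set_key(rbind(c(1, 1), c(5, 5))))
})

test_that("graham_scan matches the brute-force hull on random point sets", {
  set.seed(33)
  for (i in 1:200) {
    n <- sample(3:60, 1)
    pts <- cbind(sample.int(40, n, TRUE), sample.int(40, n, TRUE))
    if (i %% 4 == 0) pts <- rbind(pts, pts[sample(n, 3, TRUE), ])  # duplicates
    if (i %% 5 == 0) {
      k <- sample(3:6, 1)  # collinear run
      pts <- rbind(pts, cbind(seq_len(k) * 2, seq_len(k) * 3))
    }
    h <- graham_scan(pts)
    oracle <- brute_force_hull(pts)
    if (h$degenerate) {
      expect_lte(nrow(unique(pts)), max(2L, nrow(oracle)))
    } else {
      expect_equal(point_set_key(h$vertices), point_set_key(oracle))
    }
  }
})

test_that("hull vertices are counterclockwise starting at the pivot", {
  set.seed(5)
  pts <- cbind(sample.int(50, 30, TRUE), sample.int(50, 30, TRUE))
  h <- graham_scan(pts)
  v <- h$vertices
  # pivot = bottom-most (largest row), leftmost on ties
  expect_equal(v[1, 1], max(pts[, 1]))
  # CCW in (x = col, y = -row): signed area positive
  x <- v[, 2]; y <- -v[, 1]
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  expect_gt(area2, 0)
})

test_that("hull_mask rasterizes inclusively and covers the generators", {
  tri <- graham_scan(rbind(c(1, 1), c(1, 11), c(11, 1)))
  m <- hull_mask(tri, c(11, 11))
  expect_equal(sum(m), 66L)  # lattice points with (r-1) + (c-1) <= 10
  frame <- graham_scan(rbind(c(1, 1), c(1, 8), c(8, 1), c(8, 8)))
  expect_true(all(hull_mask(frame, c(8, 8))))
  set.seed(6)
  pts <- cbind(sample.int(30, 40, TRUE), sample.int(30, 40, TRUE))
  hm <- hull_mask(graham_scan(pts), c(30, 30))
  expect_true(all(hm[pts]))
})

test_that("clean_prediction removes out-of-hull blobs and respects identity", {
  map <- matrix(0L, 60, 60)
  map[20:40, 20:40] <- 2L            # root block
  map[5:8, 50:53] <- 2L              # artifact far outside the hull
  hull <- graham_scan(map[, ] == 2L & row(map) >= 20)  # hull of the root block
  params0 <- morpho_params(erosion_radius = 0, area_opening_min = 0,
                           area_closing_min = 0)
  cleaned <- clean_prediction(map, hull, params0)
  expect_false(any(cleaned[5:8, 50:53]))
  expect_true(all(cleaned[20:40, 20:40]))
  # identity configuration: no hull, all-zero params
  expect_equal(clean_prediction(map, NULL, params0), map == 2L)
  # containment in the hull mask always
  expect_true(all(!cleaned | hull_mask(hull, dim(map))))
})

test_that("area opening honours the component-size threshold", {
  map <- matrix(0L, 40, 40)
  map[10:20, 10:20] <- 2L
  map[30, 30] <- 2L; map[30, 31] <- 2L; map[31, 30] <- 2L   # 3-px speck
  map[2:6, 2:5] <- 2L                                       # 20-px blob
  params <- morpho_params(erosion_radius = 0, area_opening_min = 10,
                          area_closing_min = 0)
  cleaned <- clean_prediction(map, NULL, params)
  expect_false(any(cleaned[30:31, 30:31]))
  expect_true(all(cleaned[2:6, 2:5]))
})

test_that("thickness matches bar geometry and dilation arithmetic", {
  bar <- matrix(FALSE, 40, 120)
  bar[18:22, 11:110] <- TRUE       # 100 x 5 bar
  th <- mean_thickness(bar)
  expect_equal(th, 5, tolerance = 0.3)
  dil <- rootseg:::binary_dilate(bar, 2)
  expect_equal(mean_thickness(dil) - th, 4, tolerance = 1)
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(mean_thickness(single), 1)
  expect_warning(z <- mean_thickness(matrix(FALSE, 4, 4)), "empty")
  expect_equal(z, 0)
})

test_that("erosion search recovers the dilation radius and breaks ties low", {
  bar <- matrix(FALSE, 50, 150)
  bar[23:27, 16:135] <- TRUE
  grid <- lapply(0:5, function(r)
    morpho_params(erosion_radius = r, area_opening_min = 0,
                  area_closing_min = 0))
  # identical pairs: zero erosion wins with objective 0
  same <- optimize_erosion(list(bar), list(bar), grid)
  expect_equal(same$best$erosion_radius, 0L)
  expect_equal(same$objective, 0)
  # single-element grid returns that element
  one <- optimize_erosion(list(bar), list(bar), grid[2])
  expect_equal(one$best$erosion_radius, 1L)
  # preds dilated by r: erosion_radius r is selected
  for (r in 1:3) {
    preds <- list(rootseg:::binary_dilate(bar, r))
    res <- optimize_erosion(preds, list(bar), grid)
    expect_equal(res$best$erosion_radius, r)
    expect_lt(res$objective, 0.5)
    expect_gte(mean(res$iou_after), mean(res$iou_before))
  }
})

test_that("opening never enlarges the root (anti-extensivity)", {
  set.seed(12)
  for (i in 1:5) {
    x <- matrix(runif(900) < 0.4, 30, 30)
    x <- rootseg:::binary_dilate(x, 1)
    opened <- rootseg:::binary_dilate(rootseg:::binary_erode(x, 2), 2)
    expect_true(all(!opened | x))
  }
})

test_that("prediction stacks validate shapes and timepoint order", {
  a <- matrix(0L, 5, 5)
  expect_error(prediction_stack(list(a, matrix(0L, 4, 4))))
  expect_error(prediction_stack(list(a, a), timepoints = c(3, 1)))
  st <- prediction_stack(list(a, a), chamber_id = "C9")
  expect_equal(st$timepoints, c(0L, 1L))
})
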