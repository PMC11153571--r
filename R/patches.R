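#' Extract a non-overlapping patch grid
#'
#' Tiles the scan and its label mask into non-overlapping `patch_size`
#' squares from the origin (top-left); incomplete edge tiles are
#' discarded, so the count is `floor(rows/s) * floor(cols/s)`. Provenance
#' (chamber, timepoint, top-left row/col) is recorded per patch.
#'
#' @param scan A `root_scan` or (rows, cols, 3) array.
#' @param mask Integer label raster (values in `{0, 1, 2}`) aligned to the
#'   scan.
#' @param patch_size Patch side `s` in px.
#' @return A `patch_set`: list with `patches` (each `list(image, labels)`),
#'   `provenance` data frame, `patch_size`, and `split` (`NULL` until
#'   [split_dataset()]).
#' @export
extract_patches <- function(scan, mask, patch_size = 64L) {
  if (inherits(scan, "root_scan")) {
    meta <- scan[c("chamber_id", "timepoint")]
    pixels <- scan$pixels
  } else {
    meta <- list(chamber_id = "NA", timepoint = NA_integer_)
    pixels <- scan
  }
  s <- as.integer(patch_size)
  d <- dim(pixels)
  stopifnot(all(dim(mask) == d[1:2]))
  check_label_mask(mask)
  if (s > min(d[1], d[2])) {
    stop("patch_size ", s, " exceeds image size ", d[1], "x", d[2])
  }
  nr <- d[1] %/% s
  nc <- d[2] %/% s
  patches <- vector("list", nr * nc)
  prov <- data.frame(chamber_id = character(nr * nc),
                     timepoint = integer(nr * nc),
                     row = integer(nr * nc), col = integer(nr * nc),
                     stringsAsFactors = FALSE)
  k <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      k <- k + 1L
      r0 <- (i - 1L) * s
      c0 <- (j - 1L) * s
      patches[[k]] <- list(image = pixels[r0 + seq_len(s), c0 + seq_len(s), ,
                                          drop = FALSE],
                           labels = mask[r0 + seq_len(s), c0 + seq_len(s)])
      prov$chamber_id[k] <- meta$chamber_id
      prov$timepoint[k] <- meta$timepoint
      prov$row[k] <- r0
      prov$col[k] <- c0
    }
  }
  structure(list(patches = patches, provenance = prov, patch_size = s,
                 split = NULL),
            class = "patch_set")
}

#' Combine patch sets
#'
#' @param ... `patch_set` objects with equal `patch_size`.
#' @return One combined `patch_set` (split dropped).
#' @export
combine_patch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "patch_set")) sets <- sets[[1L]]
  stopifnot(length(sets) > 0L,
            length(unique(vapply(sets, function(s) s$patch_size, integer(1)))) == 1L)
  structure(list(patches = do.call(c, lapply(sets, function(s) s$patches)),
                 provenance = do.call(rbind, lapply(sets, function(s) s$provenance)),
                 patch_size = sets[[1L]]$patch_size, split = NULL),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat("patch_set: ", length(x$patches), " patches of ", x$patch_size, "x",
      x$patch_size, sep = "")
  if (!is.null(x$split)) {
    cat(" (", paste(names(table(x$split)), table(x$split),
                    sep = "=", collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Remove sparsely annotated patches
#'
#' Retains exactly the patches whose fraction of non-background pixels
#' (label != 0, i.e. noise or root) is at least `min_annotated_fraction`,
#' preserving order. This is the class-imbalance filter: scans are
#' dominated by background (>80% of pixels), and dropping mostly-black
#' patches rebalances the training corpus.
#'
#' @param patchset A `patch_set`.
#' @param min_annotated_fraction Retention threshold (default 0.20).
#' @return The filtered `patch_set`; empty results are permitted, with a
#'   warning.
#' @export
filter_sparse_patches <- function(patchset, min_annotated_fraction = 0.20) {
  stopifnot(inherits(patchset, "patch_set"))
  frac <- vapply(patchset$patches,
                 function(p) mean(p$labels != 0L), numeric(1))
  keep <- frac >= min_annotated_fraction
  if (!any(keep)) {
    warning("no patches meet min_annotated_fraction = ", min_annotated_fraction)
  }
  structure(list(patches = patchset$patches[keep],
                 provenance = patchset$provenance[keep, , drop = FALSE],
                 patch_size = patchset$patch_size,
                 split = patchset$split[keep]),
            class = "patch_set")
}

#' Split a patch set into train/val/test
#'
#' Uniform random assignment at the patch level, deterministic for a fixed
#' seed; split sizes are within one patch of the exact fractions.
#'
#' @param patchset A `patch_set`.
#' @param fractions Train/val/test fractions summing to 1.
#' @param seed Integer seed.
#' @param by_chamber Assign whole chambers to a split instead of single
#'   patches (avoids leakage between splits in real studies).
#' @return The `patch_set` with `$split` filled with
#'   `"train"/"val"/"test"`.
#' @export
split_dataset <- function(patchset, fractions = c(0.8, 0.1, 0.1), seed = 1L,
                          by_chamber = FALSE) {
  stopifnot(inherits(patchset, "patch_set"), length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-8)
  n <- length(patchset$patches)
  labels <- c("train", "val", "test")
  split <- character(n)
  with_seed(seed, {
    if (by_chamber) {
      chambers <- unique(patchset$provenance$chamber_id)
      nch <- length(chambers)
      counts <- diff(c(0L, round(cumsum(fractions) * nch)))
      perm <- sample(chambers)
      ch_assign <- stats::setNames(rep(labels, counts), perm)
      split <- ch_assign[patchset$provenance$chamber_id]
    } else {
      counts <- diff(c(0L, round(cumsum(fractions) * n)))
      split <- rep(labels, counts)[sample(n)]
    }
  })
  patchset$split <- unname(split)
  patchset
}

#' Augmentation configuration
#'
#' The run-time augmentation suite applied to training patches: random
#' rotations (any direction), random horizontal/vertical flips, random
#' cropping (2%), random integer shifts, random zoom in `[0.8, 1]`, and
#' brightness/contrast variation within +/-5%. Geometric transforms are
#' applied identically to the label patch with nearest-neighbour
#' resampling and reflection padding; photometric jitter touches the RGB
#' patch only.
#'
#' @param rotation,flips,shift Enable flags.
#' @param crop_fraction Fraction of the side cropped before resizing back.
#' @param zoom_range Zoom interval within `(0, 1]`.
#' @param brightness_contrast_range Half-width of the brightness shift and
#'   contrast scale jitter.
#' @param seed Base seed (informational; per-draw seeds are passed to
#'   [augment_patch()]).
#' @return An `augmentation_config` list.
#' @export
augmentation_config <- function(rotation = TRUE, flips = TRUE,
                                crop_fraction = 0.02, shift = TRUE,
                                zoom_range = c(0.8, 1.0),
                                brightness_contrast_range = 0.05,
                                seed = 1L) {
  stopifnot(length(zoom_range) == 2L, all(zoom_range > 0), all(zoom_range <= 1),
            zoom_range[1] <= zoom_range[2],
            crop_fraction >= 0, crop_fraction < 0.5)
  structure(list(rotation = rotation, flips = flips,
                 crop_fraction = crop_fraction, shift = shift,
                 zoom_range = zoom_range,
                 brightness_contrast_range = brightness_contrast_range,
                 seed = as.integer(seed)),
            class = "augmentation_config")
}

# Reflect a (possibly fractional) coordinate into [1, n].
reflect_coord <- function(v, n) {
  if (n == 1L) return(rep(1, length(v)))
  period <- 2 * (n - 1)
  v <- abs(v - 1) %% period
  ifelse(v > n - 1, period - v, v) + 1
}

# Affine resample: target (rows_out x cols_out) pulled from src at
# src = A %*% (target - ctr_t) + ctr_s. Reflection boundary; bilinear for
# images, nearest-neighbour for label rasters.
warp_affine <- function(src, A, rows_out, cols_out, interp = "bilinear") {
  d <- dim(src)
  is_img <- length(d) == 3L
  ctr_t <- c((rows_out + 1) / 2, (cols_out + 1) / 2)
  ctr_s <- c((d[1] + 1) / 2, (d[2] + 1) / 2)
  tg <- cbind(rep(seq_len(rows_out), times = cols_out) - ctr_t[1],
              rep(seq_len(cols_out), each = rows_out) - ctr_t[2])
  sc <- tg %*% t(A)
  sr <- reflect_coord(sc[, 1] + ctr_s[1], d[1])
  scc <- reflect_coord(sc[, 2] + ctr_s[2], d[2])
  if (interp == "nearest") {
    idx <- cbind(pmin(pmax(round(sr), 1), d[1]), pmin(pmax(round(scc), 1), d[2]))
    out <- matrix(src[idx], rows_out, cols_out)
    return(out)
  }
  r0 <- pmin(floor(sr), d[1] - 1); c0 <- pmin(floor(scc), d[2] - 1)
  fr <- sr - r0; fc <- scc - c0
  out <- array(0, c(rows_out, cols_out, if (is_img) d[3] else 1L))
  for (ch in seq_len(dim(out)[3])) {
    m <- if (is_img) src[, , ch] else src
    v <- m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
      m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
      m[cbind(r0 + 1, c0 + 1)] * fr * fc
    out[, , ch] <- matrix(v, rows_out, cols_out)
  }
  if (!is_img) out <- out[, , 1L]
  out
}

rot90k <- function(x, k) {
  k <- k %% 4L
  if (k == 0L) return(x)
  is_img <- length(dim(x)) == 3L
  rot1 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  for (i in seq_len(k)) {
    if (is_img) {
      x <- array(apply(x, 3, rot1), c(dim(x)[2], dim(x)[1], dim(x)[3]))
    } else {
      x <- rot1(x)
    }
  }
  x
}

apply_geom <- function(image, labels, fn_img, fn_lab) {
  list(image = fn_img(image), labels = fn_lab(labels))
}

#' Augment one training patch
#'
#' Applies the enabled transforms of an [augmentation_config()], each with
#' an independent coin flip drawn from `draw_seed`. The identical
#' geometric transform is applied to the label patch with
#' nearest-neighbour resampling, so labels remain in `{0, 1, 2}` with no
#' interpolated values; brightness/contrast jitter affects the RGB patch
#' only.
#'
#' @param patch `list(image, labels)` with a square image.
#' @param config An [augmentation_config()].
#' @param draw_seed Integer seed for this draw.
#' @return The transformed `list(image, labels)`.
#' @export
augment_patch <- function(patch, config, draw_seed = 1L) {
  stopifnot(inherits(config, "augmentation_config"))
  img <- patch$image
  lab <- patch$labels
  s <- dim(lab)[1]
  stopifnot(dim(lab)[2] == s)
  with_seed(draw_seed, {
    if (config$flips) {
      if (stats::runif(1) < 0.5) {  # horizontal flip (reverse columns)
        img <- img[, s:1, , drop = FALSE]
        lab <- lab[, s:1, drop = FALSE]
      }
      if (stats::runif(1) < 0.5) {  # vertical flip
        img <- img[s:1, , , drop = FALSE]
        lab <- lab[s:1, , drop = FALSE]
      }
    }
    if (config$rotation && stats::runif(1) < 0.5) {
      k <- sample(0:3, 1L)
      img <- rot90k(img, k)
      lab <- rot90k(lab, k)
      theta <- stats::runif(1, -45, 45) * pi / 180
      if (abs(theta) > 1e-8) {
        A <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2L, 2L)
        img <- warp_affine(img, A, s, s, "bilinear")
        lab <- warp_affine(lab, A, s, s, "nearest")
      }
    }
    if (config$crop_fraction > 0 && stats::runif(1) < 0.5) {
      m <- max(1L, round(config$crop_fraction * s))
      r0 <- sample.int(m + 1L, 1L) - 1L
      c0 <- sample.int(m + 1L, 1L) - 1L
      keep_r <- (r0 + 1L):(s - (m - r0))
      keep_c <- (c0 + 1L):(s - (m - c0))
      sub_img <- img[keep_r, keep_c, , drop = FALSE]
      sub_lab <- lab[keep_r, keep_c, drop = FALSE]
      z <- length(keep_r) / s
      A <- diag(c(z, z))
      img <- warp_affine(sub_img, A, s, s, "bilinear")
      lab <- warp_affine(sub_lab, A, s, s, "nearest")
    }
    if (config$shift && stats::runif(1) < 0.5) {
      mx <- max(1L, round(0.05 * s))
      dr <- sample(-mx:mx, 1L)
      dc <- sample(-mx:mx, 1L)
      ri <- round(reflect_coord(seq_len(s) + dr, s))
      ci <- round(reflect_coord(seq_len(s) + dc, s))
      img <- img[ri, ci, , drop = FALSE]
      lab <- lab[ri, ci, drop = FALSE]
    }
    if ((config$zoom_range[1] < 1 || config$zoom_range[2] < 1) &&
        stats::runif(1) < 0.5) {
      z <- stats::runif(1, config$zoom_range[1], config$zoom_range[2])
      if (z < 1) {
        A <- diag(c(z, z))
        img <- warp_affine(img, A, s, s, "bilinear")
        lab <- warp_affine(lab, A, s, s, "nearest")
      }
    }
    if (config$brightness_contrast_range > 0 && stats::runif(1) < 0.5) {
      bc <- config$brightness_contrast_range
      ctr <- stats::runif(1, 1 - bc, 1 + bc)
      br <- stats::runif(1, -bc, bc)
      img <- pmin(pmax((img - 0.5) * ctr + 0.5 + br, 0), 1)
    }
  })
  list(image = img, labels = lab)
}
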