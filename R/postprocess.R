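#' Prediction stack for one chamber
#'
#' Ordered per-timepoint class maps for a single chamber; binary root
#' maps are derived as `label == 2`.
#'
#' @param class_maps List of integer label rasters (equal shapes).
#' @param chamber_id Chamber identifier.
#' @param timepoints Strictly increasing integer timepoints (defaults to
#'   `0 .. n-1`).
#' @return A `prediction_stack`.
#' @export
prediction_stack <- function(class_maps, chamber_id = "C1",
                             timepoints = NULL) {
  stopifnot(length(class_maps) >= 1L)
  d <- dim(class_maps[[1L]])
  for (m in class_maps) stopifnot(all(dim(m) == d))
  if (is.null(timepoints)) timepoints <- seq_along(class_maps) - 1L
  stopifnot(length(timepoints) == length(class_maps),
            all(diff(timepoints) > 0))
  structure(list(class_maps = class_maps, chamber_id = chamber_id,
                 timepoints = as.integer(timepoints)),
            class = "prediction_stack")
}

#' Maximum-intensity projection of a time series
#'
#' A pixel is foreground in the projection iff it is root (class 2, or
#' `TRUE` for binary rasters) in at least one timepoint: the union of root
#' occupancy over the series.
#'
#' @param stack A `prediction_stack`, or a list of class maps / binary
#'   rasters.
#' @return Logical raster.
#' @export
max_projection <- function(stack) {
  maps <- if (inherits(stack, "prediction_stack")) stack$class_maps else stack
  stopifnot(length(maps) >= 1L)
  as_root <- function(m) if (is.logical(m)) m else m == 2L
  Reduce(`|`, lapply(maps, as_root))
}

cross2 <- function(o, a, b) {
  (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
}

#' Convex hull by Graham's scan
#'
#' Implements the classic scan: pick the pivot (bottom-most point on
#' screen, i.e. largest row, leftmost on ties — or top-most with
#' `pivot = "top"`; the hull is identical either way), sort the remaining
#' points by polar angle around the pivot, then sweep a stack keeping only
#' counterclockwise turns. Collinear points interior to hull edges are
#' dropped. Orientation is counterclockwise in standard axes (x = col,
#' y increasing upward).
#'
#' @param points Two-column matrix or data frame of (row, col) points, or
#'   a logical raster whose `TRUE` pixels are used.
#' @param pivot `"bottom"` (default) or `"top"` pivot convention.
#' @return A `convex_hull`: list with `vertices` (matrix of (row, col),
#'   counterclockwise, starting at the pivot) and `degenerate` flag
#'   (`TRUE` for < 3 distinct points or an all-collinear set, in which
#'   case the vertices are the extreme point(s) of the set).
#' @export
graham_scan <- function(points, pivot = c("bottom", "top")) {
  pivot <- match.arg(pivot)
  if (is.logical(points) && is.matrix(points)) points <- which(points, arr.ind = TRUE)
  pts <- unique(as.matrix(points)[, 1:2, drop = FALSE])
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n == 0L) stop("no points")
  # math coordinates: x = col, y = -row (y up); "top" pivot flips y
  ysign <- if (pivot == "bottom") -1 else 1
  xy <- cbind(pts[, 2L], ysign * pts[, 1L])
  if (n <= 2L) {
    return(structure(list(vertices = pts, degenerate = TRUE),
                     class = "convex_hull"))
  }
  # pivot: lowest y, leftmost x on ties
  pi_ <- order(xy[, 2L], xy[, 1L])[1L]
  p0 <- xy[pi_, ]
  rest <- xy[-pi_, , drop = FALSE]
  ang <- atan2(rest[, 2L] - p0[2L], rest[, 1L] - p0[1L])
  d2 <- (rest[, 1L] - p0[1L])^2 + (rest[, 2L] - p0[2L])^2
  ord <- order(ang, d2)
  rest <- rest[ord, , drop = FALSE]
  ang <- ang[ord]
  if (abs(max(ang) - min(ang)) < 1e-12) {
    # all points collinear through the pivot: degenerate segment
    far <- which.max((rest[, 1L] - p0[1L])^2 + (rest[, 2L] - p0[2L])^2)
    seg <- rbind(p0, rest[far, ])
    verts <- cbind(ysign * seg[, 2L], seg[, 1L])
    return(structure(list(vertices = verts, degenerate = TRUE),
                     class = "convex_hull"))
  }
  # of points sharing a polar angle, only the farthest can be a vertex
  if (nrow(rest) > 1L) {
    keep <- rep(TRUE, nrow(rest))
    for (i in seq_len(nrow(rest) - 1L)) {
      cr <- cross2(p0, rest[i, ], rest[i + 1L, ])
      if (abs(cr) <= 1e-9) keep[i] <- FALSE  # sorted near-to-far within runs
    }
    rest <- rest[keep, , drop = FALSE]
    ang <- ang[keep]
  }
  stack <- matrix(0, nrow(rest) + 1L, 2L)
  stack[1L, ] <- p0
  top <- 1L
  for (i in seq_len(nrow(rest))) {
    p <- rest[i, ]
    while (top >= 2L && cross2(stack[top - 1L, ], stack[top, ], p) <= 1e-12) {
      top <- top - 1L
    }
    top <- top + 1L
    stack[top, ] <- p
  }
  hull_xy <- stack[seq_len(top), , drop = FALSE]
  verts <- cbind(ysign * hull_xy[, 2L], hull_xy[, 1L])
  structure(list(vertices = verts, degenerate = FALSE),
            class = "convex_hull")
}

#' @export
print.convex_hull <- function(x, ...) {
  cat("convex_hull: ", nrow(x$vertices), " vertices",
      if (x$degenerate) " (degenerate)", "\n", sep = "")
  invisible(x)
}

#' Rasterize a convex hull
#'
#' Marks every pixel whose centre lies inside or on the hull polygon
#' (boundary inclusive). Degenerate hulls rasterize to their point or
#' segment.
#'
#' @param hull A `convex_hull`.
#' @param shape `(rows, cols)` of the output raster.
#' @return Logical raster.
#' @export
hull_mask <- function(hull, shape) {
  stopifnot(inherits(hull, "convex_hull"), length(shape) == 2L)
  out <- matrix(FALSE, shape[1L], shape[2L])
  v <- hull$vertices
  if (hull$degenerate) {
    if (nrow(v) == 1L) {
      out[round(v[1L, 1L]), round(v[1L, 2L])] <- TRUE
    } else {
      nstep <- max(abs(v[2L, ] - v[1L, ])) + 1L
      t <- seq(0, 1, length.out = max(2L, ceiling(nstep) * 2L))
      rr <- round(v[1L, 1L] + t * (v[2L, 1L] - v[1L, 1L]))
      cc <- round(v[1L, 2L] + t * (v[2L, 2L] - v[1L, 2L]))
      out[cbind(rr, cc)] <- TRUE
    }
    return(out)
  }
  # CCW polygon in (x = col, y = -row): inside iff left-of-or-on all edges
  px <- rep(seq_len(shape[2L]), each = shape[1L])     # x = col
  py <- -rep(seq_len(shape[1L]), times = shape[2L])   # y = -row
  inside <- rep(TRUE, length(px))
  nv <- nrow(v)
  for (i in seq_len(nv)) {
    a <- c(v[i, 2L], -v[i, 1L])
    b_ <- v[if (i == nv) 1L else i + 1L, ]
    b <- c(b_[2L], -b_[1L])
    cr <- (b[1L] - a[1L]) * (py - a[2L]) - (b[2L] - a[2L]) * (px - a[1L])
    inside <- inside & (cr >= -1e-9)
    if (!any(inside)) break
  }
  out[] <- inside
  out
}

#' Morphological post-processing parameters
#'
#' @param dilation_radius Disk radius (px) applied to the max-projection
#'   before hull extraction.
#' @param erosion_radius Disk radius (px) of the final erosion (0 skips).
#' @param area_opening_min Minimum connected foreground component area
#'   (px^2) retained.
#' @param area_closing_min Maximum background hole area (px^2) filled.
#' @param structuring_element `"disc"` or `"box"` for erosion/dilation.
#' @return A `morpho_params` list.
#' @export
morpho_params <- function(dilation_radius = 2L, erosion_radius = 0L,
                          area_opening_min = 64L, area_closing_min = 64L,
                          structuring_element = c("disc", "box")) {
  structuring_element <- match.arg(structuring_element)
  stopifnot(dilation_radius >= 0L, erosion_radius >= 0L,
            area_opening_min >= 0L, area_closing_min >= 0L)
  structure(list(dilation_radius = as.integer(dilation_radius),
                 erosion_radius = as.integer(erosion_radius),
                 area_opening_min = as.integer(area_opening_min),
                 area_closing_min = as.integer(area_closing_min),
                 structuring_element = structuring_element),
            class = "morpho_params")
}

se_brush <- function(radius, shape = "disc") {
  EBImage::makeBrush(2L * radius + 1L, shape = shape)
}

binary_dilate <- function(x, radius, shape = "disc") {
  if (radius <= 0L) return(x)
  EBImage::dilate(x * 1, se_brush(radius, shape)) > 0.5
}

binary_erode <- function(x, radius, shape = "disc") {
  if (radius <= 0L) return(x)
  EBImage::erode(x * 1, se_brush(radius, shape)) > 0.5
}

# Remove foreground components smaller than min_area.
area_opening <- function(x, min_area) {
  if (min_area <= 0L || !any(x)) return(x)
  lab <- EBImage::bwlabel(x * 1)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_area)
  if (length(small) > 0L) x[lab %in% small] <- FALSE
  x
}

# Fill background holes smaller than min_area.
area_closing <- function(x, min_area) {
  if (min_area <= 0L) return(x)
  lab <- EBImage::bwlabel((!x) * 1)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes < min_area)
  if (length(small) > 0L) x[lab %in% small] <- TRUE
  x
}

#' Hull of the dilated time-stacked root
#'
#' Convenience wrapper: max-projects the stack, dilates by
#' `params$dilation_radius`, and returns the Graham-scan hull of the
#' resulting foreground. The hull is computed once per chamber and then
#' applied to every timepoint.
#'
#' @param stack A `prediction_stack` (or list of class maps).
#' @param params A [morpho_params()].
#' @return A `convex_hull`.
#' @export
stack_hull <- function(stack, params = morpho_params()) {
  proj <- max_projection(stack)
  if (!any(proj)) stop("empty projection: no root pixels in any timepoint")
  dil <- binary_dilate(proj, params$dilation_radius, params$structuring_element)
  graham_scan(dil)
}

#' Clean one timepoint's prediction
#'
#' Pipeline order: take the root class of the per-timepoint map, zero all
#' pixels outside the chamber hull, fill small background holes (area
#' closing), remove small isolated components (area opening), then apply
#' the final erosion (radius 0 skips it).
#'
#' @param class_map Integer label raster (root = 2) or logical root
#'   raster.
#' @param hull A `convex_hull` from [stack_hull()] (or `NULL` to skip hull
#'   masking).
#' @param params A [morpho_params()].
#' @return Logical cleaned root raster.
#' @export
clean_prediction <- function(class_map, hull, params = morpho_params()) {
  root <- if (is.logical(class_map)) class_map else class_map == 2L
  if (!is.null(hull)) {
    root <- root & hull_mask(hull, dim(root))
  }
  root <- area_closing(root, params$area_closing_min)
  root <- area_opening(root, params$area_opening_min)
  root <- binary_erode(root, params$erosion_radius, params$structuring_element)
  root
}

#' Skeletonize a binary raster
#'
#' Morphological thinning (Zhang-Suen) to a 1-px-wide medial skeleton.
#'
#' @param x Logical raster.
#' @return Logical skeleton raster.
#' @export
skeletonize <- function(x) {
  img <- matrix(0L, nrow(x) + 2L, ncol(x) + 2L)
  img[2:(nrow(x) + 1L), 2:(ncol(x) + 1L)] <- as.integer(x)
  sh <- function(m, dr, dc) {
    r <- seq_len(nrow(m) - 2L) + 1L + dr
    c <- seq_len(ncol(m) - 2L) + 1L + dc
    m[r, c]
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- sh(img, -1L, 0L); p3 <- sh(img, -1L, 1L); p4 <- sh(img, 0L, 1L)
      p5 <- sh(img, 1L, 1L); p6 <- sh(img, 1L, 0L); p7 <- sh(img, 1L, -1L)
      p8 <- sh(img, 0L, -1L); p9 <- sh(img, -1L, -1L)
      ctr <- sh(img, 0L, 0L)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- cbind(as.vector(p2), as.vector(p3), as.vector(p4),
                    as.vector(p5), as.vector(p6), as.vector(p7),
                    as.vector(p8), as.vector(p9), as.vector(p2))
      a <- matrix(rowSums(seqs[, 1:8, drop = FALSE] == 0 &
                            seqs[, 2:9, drop = FALSE] == 1),
                  nrow(ctr), ncol(ctr))
      if (sub == 1L) {
        cond <- ctr == 1L & bsum >= 2L & bsum <= 6L & a == 1L &
          (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        cond <- ctr == 1L & bsum >= 2L & bsum <= 6L & a == 1L &
          (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      if (any(cond)) {
        changed <- TRUE
        inner <- img[2:(nrow(img) - 1L), 2:(ncol(img) - 1L)]
        inner[cond] <- 0L
        img[2:(nrow(img) - 1L), 2:(ncol(img) - 1L)] <- inner
      }
    }
    if (!changed) break
  }
  img[2:(nrow(x) + 1L), 2:(ncol(x) + 1L)] == 1L
}

#' Mean root thickness
#'
#' Thickness estimated as foreground area divided by medial-skeleton
#' length (thinning skeleton pixel count), in px.
#'
#' @param root Logical root raster.
#' @return Mean thickness in px; 0 with a warning for an empty raster.
#' @export
mean_thickness <- function(root) {
  if (!any(root)) {
    warning("empty root raster; thickness 0")
    return(0)
  }
  sk <- skeletonize(root)
  len <- sum(sk)
  if (len == 0L) len <- 1L
  sum(root) / len
}

#' Erosion hyper-parameter search
#'
#' Exhaustive grid search over morphological parameter sets. The
#' objective is the mean absolute error between the cleaned predictions'
#' thickness and the ground-truth thickness, pooled over pairs; ties are
#' broken toward the smaller erosion radius. Per-pair root IOU before and
#' after cleaning is reported alongside.
#'
#' @param preds,truths Paired lists of binary root rasters.
#' @param grid List of [morpho_params()] to evaluate.
#' @param hulls Optional list of hulls (defaults to each prediction's own
#'   dilated hull).
#' @return List: `best` ([morpho_params()]), `objective` (px MAE),
#'   `results` data frame (one row per grid point), `iou_before`,
#'   `iou_after` (per-pair, at the optimum).
#' @export
optimize_erosion <- function(preds, truths, grid, hulls = NULL) {
  stopifnot(length(preds) == length(truths), length(grid) >= 1L)
  n <- length(preds)
  if (is.null(hulls)) {
    hulls <- lapply(seq_len(n), function(i) {
      p <- preds[[i]]
      if (!any(p)) return(NULL)
      graham_scan(binary_dilate(p, grid[[1L]]$dilation_radius))
    })
  }
  truth_thick <- vapply(truths, mean_thickness, numeric(1))
  res <- data.frame(grid_index = seq_along(grid),
                    erosion_radius = vapply(grid, function(g) g$erosion_radius,
                                            integer(1)),
                    objective = NA_real_)
  cleaned_at <- vector("list", length(grid))
  for (gi in seq_along(grid)) {
    cleaned <- lapply(seq_len(n), function(i)
      clean_prediction(preds[[i]], hulls[[i]], grid[[gi]]))
    th <- vapply(cleaned, function(x) {
      if (!any(x)) 0 else mean_thickness(x)
    }, numeric(1))
    res$objective[gi] <- mean(abs(th - truth_thick))
    cleaned_at[[gi]] <- cleaned
  }
  ord <- order(res$objective, res$erosion_radius)
  best_i <- ord[1L]
  iou_pair <- function(a, b) {
    u <- sum(a | b)
    if (u == 0) 1 else sum(a & b) / u
  }
  list(best = grid[[best_i]],
       objective = res$objective[best_i],
       results = res,
       iou_before = vapply(seq_len(n), function(i)
         iou_pair(preds[[i]], truths[[i]]), numeric(1)),
       iou_after = vapply(seq_len(n), function(i)
         iou_pair(cleaned_at[[best_i]][[i]], truths[[i]]), numeric(1)))
}
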