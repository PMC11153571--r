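#' Phantom generator configuration
#'
#' Parameters for the synthetic root-phantom generator, which emulates the
#' statistical structure of hydroponic-chamber (EcoFAB) root scans: a
#' single root system per chamber growing monotonically over timepoints as
#' a downward-biased branching walk rendered in green-brown hues on a
#' near-black background, plus class-1 "noise" artifacts (droplets,
#' bubbles, condensation blotches, shadow bands), under a dominant
#' background fraction.
#'
#' @param seed Integer RNG seed; the same seed and config produce
#'   bit-identical output.
#' @param image_size `(rows, cols)` in px.
#' @param n_timepoints Number of acquisition timepoints (>= 1).
#' @param branch_prob Per-growth-step probability that an active root tip
#'   spawns a branch, in `[0, 1]`.
#' @param root_thickness_px Rendered root caliper in px (skeleton dilated
#'   by a disk of radius `floor(thickness / 2)`).
#' @param growth_steps_per_timepoint Skeleton growth steps added per
#'   timepoint.
#' @param artifact_density Expected artifacts per megapixel per timepoint
#'   (Poisson); 0 means no class-1 pixels anywhere.
#' @param background_fraction_target Minimum fraction of class-0 pixels
#'   enforced in every rendered mask (the ~80/20 imbalance of real scans).
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(seed = 1L, image_size = c(512L, 384L),
                           n_timepoints = 5L, branch_prob = 0.3,
                           root_thickness_px = 5L,
                           growth_steps_per_timepoint = 80L,
                           artifact_density = 40,
                           background_fraction_target = 0.8) {
  stopifnot(length(image_size) == 2L, all(image_size >= 16L),
            n_timepoints >= 1L, branch_prob >= 0, branch_prob <= 1,
            root_thickness_px >= 1L, growth_steps_per_timepoint >= 0L,
            artifact_density >= 0, background_fraction_target >= 0,
            background_fraction_target <= 1)
  structure(list(seed = as.integer(seed),
                 image_size = as.integer(image_size),
                 n_timepoints = as.integer(n_timepoints),
                 branch_prob = branch_prob,
                 root_thickness_px = as.integer(root_thickness_px),
                 growth_steps_per_timepoint = as.integer(growth_steps_per_timepoint),
                 artifact_density = artifact_density,
                 background_fraction_target = background_fraction_target),
            class = "phantom_config")
}

# One growth step: every active tip descends one row with a lateral drift
# step in {-1, 0, 1}; tips strictly descend, so each tip path holds at most
# one pixel per row (hence <= 2 skeleton neighbours when branch_prob = 0)
# and the skeleton at timepoint t is always a prefix-superset of t - 1.
grow_skeleton_steps <- function(config, n_steps) {
  h <- config$image_size[1]; w <- config$image_size[2]
  max_tips <- 32L
  tips <- list(list(r = max(2L, h %/% 16L), c = w %/% 2L,
                    drift = 0L))
  px <- matrix(NA_integer_, nrow = n_steps * max_tips + 1L, ncol = 2L)
  px[1L, ] <- c(tips[[1L]]$r, tips[[1L]]$c)
  np <- 1L
  if (n_steps > 0L) {
    for (step in seq_len(n_steps)) {
      new_tips <- list()
      for (ti in seq_along(tips)) {
        tip <- tips[[ti]]
        if (is.null(tip)) next
        # lateral drift persists with occasional re-draws
        if (stats::runif(1) < 0.2) {
          tip$drift <- sample(c(-1L, 0L, 1L), 1L, prob = c(0.3, 0.4, 0.3))
        }
        dc <- sample(c(tip$drift, -1L, 0L, 1L), 1L,
                     prob = c(0.55, 0.15, 0.15, 0.15))
        tip$r <- tip$r + 1L
        tip$c <- min(max(tip$c + dc, 2L), w - 1L)
        if (tip$r >= h - 1L) {
          tips[[ti]] <- NULL  # reached the chamber bottom
          next
        }
        np <- np + 1L
        px[np, ] <- c(tip$r, tip$c)
        tips[[ti]] <- tip
        if (length(tips) + length(new_tips) < max_tips &&
            stats::runif(1) < config$branch_prob) {
          new_tips[[length(new_tips) + 1L]] <-
            list(r = tip$r, c = tip$c,
                 drift = sample(c(-1L, 1L), 1L))
        }
      }
      tips <- c(Filter(Negate(is.null), tips), new_tips)
      if (length(tips) == 0L) break
    }
  }
  px[seq_len(np), , drop = FALSE]
}

#' Grow a root skeleton up to a timepoint
#'
#' Simulates the branching downward random walk from the fixed seed point
#' for `(timepoint + 1) * growth_steps_per_timepoint` steps. Because the
#' walk consumes its RNG stream step by step, the skeleton at timepoint
#' `t` is always a superset of the skeleton at `t - 1`.
#'
#' @param config A [phantom_config()].
#' @param timepoint 0-based timepoint, `0 <= timepoint < n_timepoints`.
#' @return Integer matrix of skeleton pixel `(row, col)` coordinates
#'   (1-based within the raster), in growth order, duplicates possible at
#'   branch points.
#' @export
grow_root_skeleton <- function(config, timepoint) {
  stopifnot(inherits(config, "phantom_config"),
            timepoint >= 0L, timepoint < config$n_timepoints)
  with_seed(config$seed,
            grow_skeleton_steps(config,
                                (timepoint + 1L) * config$growth_steps_per_timepoint))
}

disk_offsets <- function(radius) {
  if (radius <= 0L) return(matrix(c(0L, 0L), 1L, 2L))
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  g <- g[g$dr^2 + g$dc^2 <= radius^2, ]
  as.matrix(g)
}

# Stamp disk-shaped neighbourhoods of the given pixels onto a logical mask.
stamp_disk <- function(mask, px, radius) {
  h <- nrow(mask); w <- ncol(mask)
  off <- disk_offsets(radius)
  for (k in seq_len(nrow(off))) {
    r <- px[, 1L] + off[k, 1L]
    c <- px[, 2L] + off[k, 2L]
    ok <- r >= 1L & r <= h & c >= 1L & c <= w
    mask[cbind(r[ok], c[ok])] <- TRUE
  }
  mask
}

draw_disc_px <- function(h, w, r0, c0, radius, annulus = FALSE) {
  off <- disk_offsets(radius)
  if (annulus) {
    inner <- off[, 1L]^2 + off[, 2L]^2 >= (max(1L, radius - 2L))^2
    off <- off[inner, , drop = FALSE]
  }
  r <- r0 + off[, 1L]; c <- c0 + off[, 2L]
  ok <- r >= 1L & r <= h & c >= 1L & c <= w
  cbind(r[ok], c[ok])
}

# Draw one artifact; returns list(px, color_fn) where color_fn(n) gives an
# n x 3 RGB matrix. Types follow the noise classes seen on real chambers.
draw_artifact <- function(h, w, near = NULL) {
  type <- sample(c("droplet", "bubble", "condensation", "shadow"), 1L,
                 prob = c(0.3, 0.3, 0.25, 0.15))
  if (!is.null(near) && stats::runif(1) < 0.4) {
    r0 <- near[1L] + sample(-20:20, 1L)
    c0 <- near[2L] + sample(-20:20, 1L)
  } else {
    r0 <- sample.int(h, 1L)
    c0 <- sample.int(w, 1L)
  }
  r0 <- min(max(r0, 1L), h); c0 <- min(max(c0, 1L), w)
  if (type == "droplet") {
    rad <- sample(4:12, 1L)
    px <- draw_disc_px(h, w, r0, c0, rad, annulus = TRUE)
    col <- function(n) cbind(stats::runif(n, 0.55, 0.75),
                             stats::runif(n, 0.6, 0.8),
                             stats::runif(n, 0.65, 0.85))
  } else if (type == "bubble") {
    rad <- sample(3:10, 1L)
    px <- draw_disc_px(h, w, r0, c0, rad)
    col <- function(n) cbind(stats::runif(n, 0.5, 0.7),
                             stats::runif(n, 0.5, 0.7),
                             stats::runif(n, 0.55, 0.75))
  } else if (type == "condensation") {
    n_blobs <- sample(3:8, 1L)
    px <- NULL
    for (b in seq_len(n_blobs)) {
      px <- rbind(px, draw_disc_px(h, w,
                                   min(max(r0 + sample(-15:15, 1L), 1L), h),
                                   min(max(c0 + sample(-15:15, 1L), 1L), w),
                                   sample(2:5, 1L)))
    }
    col <- function(n) cbind(stats::runif(n, 0.2, 0.3),
                             stats::runif(n, 0.2, 0.3),
                             stats::runif(n, 0.22, 0.32))
  } else {
    band_h <- sample(6:15, 1L)
    band_w <- sample(30:80, 1L)
    rr <- r0:min(h, r0 + band_h)
    cc <- c0:min(w, c0 + band_w)
    px <- as.matrix(expand.grid(rr, cc))
    col <- function(n) cbind(stats::runif(n, 0.01, 0.03),
                             stats::runif(n, 0.01, 0.03),
                             stats::runif(n, 0.01, 0.03))
  }
  list(px = px, col = col)
}

#' Render a phantom chamber time series
#'
#' Renders, for each timepoint, the dilated root skeleton in green-brown
#' hues on a dark noisy background, draws Poisson-count artifacts as
#' class-1 regions (some adjacent to the root), and emits aligned RGB
#' scans and 3-class masks. The class-0 (background) fraction of every
#' mask is enforced to stay at or above `background_fraction_target`: root
#' growth is truncated and artifacts are skipped once the foreground
#' budget is exhausted.
#'
#' @param config A [phantom_config()].
#' @param chamber_id Chamber identifier stored in the scans.
#' @param treatment Treatment tag stored in the scans (e.g. "Full", "N").
#' @return A `phantom_series`: list with `scans` (list of `root_scan`),
#'   `masks` (list of integer rasters), `true_root_pixel_counts`, and the
#'   config.
#' @export
render_phantom <- function(config, chamber_id = "C1", treatment = "Full") {
  stopifnot(inherits(config, "phantom_config"))
  h <- config$image_size[1]; w <- config$image_size[2]
  if (any(config$image_size < 2L * config$root_thickness_px)) {
    stop("image_size ", h, "x", w, " smaller than 2 * root_thickness_px (",
         2L * config$root_thickness_px, ")")
  }
  rad <- config$root_thickness_px %/% 2L
  max_fg <- (1 - config$background_fraction_target) * h * w
  with_seed(config$seed, {
    skel_all <- grow_skeleton_steps(config,
                                    config$n_timepoints *
                                      config$growth_steps_per_timepoint)
    # per-pixel step index at which each skeleton pixel appeared
    n_per_tp <- integer(config$n_timepoints)
    scans <- vector("list", config$n_timepoints)
    masks <- vector("list", config$n_timepoints)
    counts <- integer(config$n_timepoints)
    # root pixel budget: reserve ~70% of the allowed foreground for root
    root_budget <- 0.7 * max_fg
    # skeleton prefix lengths per timepoint
    tp_len <- integer(config$n_timepoints)
    # recompute prefix length per timepoint by re-simulating step counts:
    # pixels were emitted in growth order, so prefixes correspond to
    # step-count cutoffs; approximate by equal pixel fractions per step.
    # Exact per-step bookkeeping:
    # (grow_skeleton_steps does not return step ids; re-run per timepoint)
    for (tp in seq_len(config$n_timepoints)) {
      tp_len[tp] <- nrow(with_seed(config$seed,
        grow_skeleton_steps(config, tp * config$growth_steps_per_timepoint)))
    }
    for (tp in seq_len(config$n_timepoints)) {
      skel <- skel_all[seq_len(tp_len[tp]), , drop = FALSE]
      root <- matrix(FALSE, h, w)
      root <- stamp_disk(root, skel, rad)
      if (sum(root) > root_budget) {
        lo <- 1L; hi <- nrow(skel)
        while (lo < hi) {
          mid <- (lo + hi + 1L) %/% 2L
          rm_ <- stamp_disk(matrix(FALSE, h, w),
                            skel[seq_len(mid), , drop = FALSE], rad)
          if (sum(rm_) <= root_budget) lo <- mid else hi <- mid - 1L
        }
        root <- stamp_disk(matrix(FALSE, h, w),
                           skel[seq_len(lo), , drop = FALSE], rad)
      }
      # background with sensor noise
      npx <- h * w
      img <- array(0, c(h, w, 3L))
      img[, , 1L] <- 0.08 + stats::rnorm(npx, sd = 0.02)
      img[, , 2L] <- 0.07 + stats::rnorm(npx, sd = 0.02)
      img[, , 3L] <- 0.06 + stats::rnorm(npx, sd = 0.02)
      mask <- matrix(0L, h, w)
      # artifacts first (root occludes them)
      n_art <- stats::rpois(1L, config$artifact_density * npx / 1e6)
      fg_used <- sum(root)
      if (n_art > 0L) {
        near_pt <- skel[sample.int(nrow(skel), 1L), ]
        for (a in seq_len(n_art)) {
          art <- draw_artifact(h, w, near = near_pt)
          if (is.null(art$px) || nrow(art$px) == 0L) next
          new_px <- art$px[!mask[art$px] & !root[art$px], , drop = FALSE]
          if (fg_used + nrow(new_px) > max_fg) next
          fg_used <- fg_used + nrow(new_px)
          mask[art$px] <- 1L
          img[cbind(art$px, 1L)] <- art$col(nrow(art$px))[, 1L]
          img[cbind(art$px, 2L)] <- art$col(nrow(art$px))[, 2L]
          img[cbind(art$px, 3L)] <- art$col(nrow(art$px))[, 3L]
        }
      }
      # root rendering: green-brown hue with per-pixel jitter
      rp <- which(root)
      hue_mix <- stats::runif(1, 0.3, 0.7)  # per-timepoint brown/green blend
      nr <- length(rp)
      img[, , 1L][rp] <- 0.35 + 0.2 * hue_mix + stats::rnorm(nr, sd = 0.03)
      img[, , 2L][rp] <- 0.45 + 0.1 * (1 - hue_mix) + stats::rnorm(nr, sd = 0.03)
      img[, , 3L][rp] <- 0.18 + stats::rnorm(nr, sd = 0.02)
      mask[root] <- 2L
      img <- pmin(pmax(img, 0), 1)
      counts[tp] <- sum(mask == 2L)
      scans[[tp]] <- root_scan(img, chamber_id = chamber_id,
                               timepoint = tp - 1L, treatment = treatment)
      masks[[tp]] <- mask
    }
    structure(list(scans = scans, masks = masks,
                   true_root_pixel_counts = counts,
                   chamber_id = chamber_id, treatment = treatment,
                   config = config),
              class = "phantom_series")
  })
}

#' Write a phantom series to disk
#'
#' Writes scans as RGB PNG, masks as single-channel PNG with values
#' `{0, 1, 2}`, and a CSV manifest with columns
#' `chamber_id,timepoint,treatment,scan_path,mask_path,root_pixels`.
#' When `manifest_path` already exists and `append = TRUE`, rows are
#' appended (multi-chamber datasets).
#'
#' @param series A `phantom_series` from [render_phantom()].
#' @param directory Output directory (created if needed).
#' @param append Append to an existing manifest instead of overwriting.
#' @return The manifest data frame, invisibly.
#' @export
write_phantom_dataset <- function(series, directory, append = FALSE) {
  stopifnot(inherits(series, "phantom_series"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  n <- length(series$scans)
  rows <- vector("list", n)
  for (tp in seq_len(n)) {
    scan_path <- file.path(directory,
                           sprintf("%s_t%02d_scan.png", series$chamber_id, tp - 1L))
    mask_path <- file.path(directory,
                           sprintf("%s_t%02d_mask.png", series$chamber_id, tp - 1L))
    write_scan_png(series$scans[[tp]]$pixels, scan_path)
    write_mask_png(series$masks[[tp]], mask_path)
    rows[[tp]] <- data.frame(chamber_id = series$chamber_id,
                             timepoint = tp - 1L,
                             treatment = series$treatment,
                             scan_path = scan_path,
                             mask_path = mask_path,
                             root_pixels = series$true_root_pixel_counts[tp],
                             stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(directory, "manifest.csv")
  if (append && file.exists(mpath)) {
    old <- utils::read.csv(mpath, stringsAsFactors = FALSE)
    manifest_out <- rbind(old, manifest)
  } else {
    manifest_out <- manifest
  }
  utils::write.csv(manifest_out, mpath, row.names = FALSE)
  invisible(manifest)
}
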