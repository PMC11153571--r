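# Independent oracles used to cross-check package implementations.

# Brute-force convex hull: point p is a hull vertex iff it is an endpoint
# of a maximal edge (i, j) such that every other point lies on or to the
# left of the directed line i -> j, and every collinear point projects
# inside the segment. O(n^3) overall, independent of the scan algorithm.
brute_force_hull <- function(pts) {
  pts <- unique(as.matrix(pts)[, 1:2, drop = FALSE])
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  xy <- cbind(pts[, 2L], -pts[, 1L])
  eps <- 1e-9
  is_vertex <- rep(FALSE, n)
  for (i in seq_len(n)) {
    ax <- xy[, 1L] - xy[i, 1L]
    ay <- xy[, 2L] - xy[i, 2L]
    # cross[j, k] = cross(p_j - p_i, p_k - p_i)
    cr <- outer(ax, ay) - outer(ay, ax)
    valid_j <- apply(cr, 1L, min) >= -eps
    valid_j[i] <- FALSE
    for (j in which(valid_j)) {
      if (ax[j] == 0 && ay[j] == 0) next  # duplicate of pivot handled by unique()
      col_k <- which(abs(cr[j, ]) <= eps)
      tproj <- (ax[col_k] * ax[j] + ay[col_k] * ay[j]) / (ax[j]^2 + ay[j]^2)
      if (any(tproj < -1e-12 | tproj > 1 + 1e-12)) next
      is_vertex[i] <- TRUE
      is_vertex[j] <- TRUE
    }
  }
  pts[is_vertex, , drop = FALSE]
}

point_set_key <- function(pts) {
  pts <- unique(round(as.matrix(pts), 9))
  paste(sort(paste(pts[, 1L], pts[, 2L], sep = ",")), collapse = ";")
}

# Rank-statistic AUC (Mann-Whitney with midranks), independent of pROC.
rank_auc <- function(response, score) {
  r <- rank(score)
  n1 <- sum(response == 1)
  n0 <- sum(response == 0)
  (sum(r[response == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Small phantom used across unit tests (desk-scale but quick).
small_phantom <- function(seed = 1L, artifact_density = 80,
                          n_timepoints = 3L, ...) {
  phantom_config(seed = seed, image_size = c(128L, 96L),
                 n_timepoints = n_timepoints,
                 growth_steps_per_timepoint = 24L,
                 artifact_density = artifact_density, ...)
}
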