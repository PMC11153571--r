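#' Root pixel count
#'
#' Image-derived biomass proxy: the number of pixels assigned to the root
#' class.
#'
#' @param root Logical root raster, or an integer class map (root = 2).
#' @return Integer count of foreground pixels.
#' @export
root_pixel_count <- function(root) {
  if (!is.logical(root)) root <- root == 2L
  sum(root)
}

#' L2 normalization
#'
#' Divides each value by the Euclidean norm of the vector, so the output
#' has unit L2 norm. Mirrors the normalization applied across all
#' chambers at the final acquisition date before comparison with
#' scale-measured weights.
#'
#' @param values Numeric vector of non-negative values.
#' @return Normalized vector; an all-zero vector is returned unchanged
#'   with a warning.
#' @export
l2_normalize <- function(values) {
  stopifnot(is.numeric(values), all(values >= 0))
  nrm <- sqrt(sum(values^2))
  if (nrm == 0) {
    warning("all-zero vector; returned unchanged")
    return(values)
  }
  values / nrm
}

#' Biomass time series for one chamber
#'
#' @param chamber_id,treatment Metadata.
#' @param timepoints Integer acquisition indices.
#' @param root_pixels Per-timepoint root pixel counts.
#' @return A `biomass_series`.
#' @export
biomass_series <- function(chamber_id, treatment, timepoints, root_pixels) {
  stopifnot(length(timepoints) == length(root_pixels), all(root_pixels >= 0))
  structure(list(chamber_id = chamber_id, treatment = treatment,
                 timepoints = as.integer(timepoints),
                 root_pixels = as.numeric(root_pixels)),
            class = "biomass_series")
}

#' Regression of measured weight on predicted biomass
#'
#' Ordinary least squares of the scale-measured (normalized) weights on
#' the image-derived (normalized) biomass, reporting slope, intercept,
#' Pearson correlation r, coefficient of determination R^2, and the RMSE
#' of the residuals. The reverse direction (biomass on weight) is
#' reported alongside.
#'
#' @param predicted Numeric predicted biomass per chamber (typically
#'   [l2_normalize()]d pixel counts at the final acquisition date).
#' @param measured Numeric measured weights per chamber, same order and
#'   normalization.
#' @return A `regression_result`: list with `slope`, `intercept`, `r`,
#'   `r_squared`, `rmse`, `n`, and `reverse` (same fields for the
#'   swapped regression).
#' @export
compare_to_scale <- function(predicted, measured) {
  stopifnot(length(predicted) == length(measured), length(predicted) >= 3L)
  if (stats::sd(predicted) == 0) stop("zero-variance predictor")
  fit_dir <- function(x, y) {
    fit <- stats::lm(y ~ x)
    r <- stats::cor(x, y)
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r = r, r_squared = r^2,
         rmse = sqrt(mean(stats::residuals(fit)^2)))
  }
  fwd <- fit_dir(predicted, measured)
  rev_ <- fit_dir(measured, predicted)
  structure(c(fwd, list(n = length(predicted), reverse = rev_)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(paste0("regression (measured ~ predicted, n = %d):\n",
                     "  slope %.4f  intercept %.4f\n",
                     "  r %.4f  R^2 %.4f  RMSE %.4f\n"),
              x$n, x$slope, x$intercept, x$r, x$r_squared, x$rmse))
  invisible(x)
}

#' Long-format growth table
#'
#' Combines per-chamber biomass series into a tidy table (one row per
#' chamber-timepoint) for per-treatment growth curves. Missing timepoints
#' (e.g. chambers whose plants died early) are absent, not imputed.
#'
#' @param series List of [biomass_series()].
#' @return Data frame with columns `treatment`, `timepoint`, `chamber_id`,
#'   `biomass` (root pixel count).
#' @export
growth_table <- function(series) {
  stopifnot(length(series) >= 1L)
  do.call(rbind, lapply(series, function(s) {
    data.frame(treatment = s$treatment, timepoint = s$timepoints,
               chamber_id = s$chamber_id, biomass = s$root_pixels,
               stringsAsFactors = FALSE)
  }))
}
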