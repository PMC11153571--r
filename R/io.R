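#' Root scan container
#'
#' One RGB scan of one chamber at one timepoint, with acquisition
#' metadata. Coordinates are (row, col), 0-based timepoints, origin top
#' left.
#'
#' @param pixels (rows, cols, 3) numeric array in `[0, 1]`.
#' @param chamber_id Chamber identifier.
#' @param timepoint Integer acquisition date index (0-based).
#' @param treatment Treatment tag (e.g. "Full", "N", "K", "Ca").
#' @return A `root_scan` object.
#' @export
root_scan <- function(pixels, chamber_id = "C1", timepoint = 0L,
                      treatment = "Full") {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  structure(list(pixels = pixels, chamber_id = as.character(chamber_id),
                 timepoint = as.integer(timepoint),
                 treatment = as.character(treatment)),
            class = "root_scan")
}

#' @export
print.root_scan <- function(x, ...) {
  d <- dim(x$pixels)
  cat("root_scan ", x$chamber_id, " t=", x$timepoint, " (", x$treatment,
      "), ", d[1], "x", d[2], " px\n", sep = "")
  invisible(x)
}

check_label_mask <- function(labels) {
  vals <- unique(as.integer(labels))
  if (!all(vals %in% 0:2)) {
    stop("label mask contains values outside {0, 1, 2}: ",
         paste(setdiff(vals, 0:2), collapse = ", "))
  }
  invisible(labels)
}

#' Read and write scans and masks as PNG
#'
#' Scans are RGB PNG; masks are 8-bit single-channel PNG storing the raw
#' class values `{0, 1, 2}`.
#'
#' @param path File path.
#' @return `read_scan_png`: (rows, cols, 3) array in `[0, 1]`;
#'   `read_mask_png`: integer matrix with values in `{0, 1, 2}`.
#' @export
read_scan_png <- function(path) {
  if (!file.exists(path)) stop("scan file not found: ", path)
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  px[, , 1:3, drop = FALSE]
}

#' @rdname read_scan_png
#' @param pixels (rows, cols, 3) array in `[0, 1]`.
#' @export
write_scan_png <- function(pixels, path) {
  ok <- try(png::writePNG(pmin(pmax(pixels, 0), 1), path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write scan: ", path)
  invisible(path)
}

#' @rdname read_scan_png
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  labels <- matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  check_label_mask(labels)
  labels
}

#' @rdname read_scan_png
#' @param labels Integer matrix with values in `{0, 1, 2}`.
#' @export
write_mask_png <- function(labels, path) {
  check_label_mask(labels)
  ok <- try(png::writePNG(labels / 255, path), silent = TRUE)
  if (inherits(ok, "try-error")) stop("failed to write mask: ", path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' The manifest CSV (as written by [write_phantom_dataset()], or hand-made
#' for real data) has columns
#' `chamber_id,timepoint,treatment,scan_path,mask_path,root_pixels`; only
#' the first four are required.
#'
#' @param path Manifest CSV path.
#' @param base_dir Optional directory against which relative scan/mask
#'   paths are resolved.
#' @return Data frame of the manifest.
#' @export
read_manifest <- function(path, base_dir = NULL) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("chamber_id", "timepoint", "scan_path")
  missing_cols <- setdiff(req, names(m))
  if (length(missing_cols) > 0L) {
    stop("manifest ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.null(base_dir)) {
    for (col in intersect(c("scan_path", "mask_path"), names(m))) {
      rel <- !file.exists(m[[col]])
      m[[col]][rel] <- file.path(base_dir, m[[col]][rel])
    }
  }
  m
}
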