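#' FLIM image stack and ROI mask containers
#'
#' A `flim_image` is a `rows x cols x n_bins` integer array of per-pixel,
#' per-time-bin photon counts, carrying its `bin_grid` as an attribute.
#' An `roi_mask` is an integer matrix with the convention: 0 = background,
#' positive k = pixel belongs to ROI k, negative -k = pixel belongs to ROI k
#' but is excluded from analysis (nucleolus or low-lifetime carve-out).
#'
#' @param counts 3D non-negative integer array `(rows, cols, n_bins)`.
#' @param grid A `bin_grid` with `n_bins` matching `dim(counts)[3]`.
#' @param labels Integer matrix of ROI labels.
#' @return `flim_image()` returns a `flim_image`; `roi_mask()` an `roi_mask`.
#' @export
flim_image <- function(counts, grid = bin_grid(n_bins = dim(counts)[3])) {
  if (length(dim(counts)) != 3L) abort_input("counts must be a 3D array")
  if (dim(counts)[3] != grid$n_bins) {
    abort_input("third dimension of counts must equal grid$n_bins")
  }
  if (any(counts < 0)) abort_input("counts must be non-negative")
  structure(counts, grid = grid, class = "flim_image")
}

#' @rdname flim_image
#' @export
roi_mask <- function(labels) {
  if (length(dim(labels)) != 2L) abort_input("labels must be a matrix")
  if (any(labels != round(labels))) abort_input("labels must be integers")
  structure(matrix(as.integer(labels), nrow(labels), ncol(labels)),
            class = "roi_mask")
}

image_grid <- function(image) attr(image, "grid")

#' @export
print.flim_image <- function(x, ...) {
  d <- dim(x)
  cat("<flim_image> ", d[1], "x", d[2], " pixels, ", d[3], " time bins, ",
      sum(x), " photons\n", sep = "")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  labs <- sort(unique(x[x > 0]))
  cat("<roi_mask> ", nrow(x), "x", ncol(x), ", ", length(labs),
      " ROI label(s)\n", sep = "")
  invisible(x)
}

# 16-bit TIFF payload limit for the tiff writer used here
.TIFF_MAX <- 65535L
.MASK_OFFSET <- 32768L

#' Read / write a FLIM time stack as multi-page TIFF
#'
#' One TIFF page per time bin, 16-bit unsigned pixels holding photon counts
#' (values above 65535 are rejected). The time axis (`bin_width_ns`,
#' `origin_ns`) travels in a JSON sidecar `<path>.json`; when the sidecar is
#' absent the reader requires an explicit `bin_width_ns`.
#'
#' @param image A `flim_image`.
#' @param path TIFF file path.
#' @param bin_width_ns Bin width override/fallback (ns).
#' @param origin_ns Time origin fallback (ns), default 0.
#' @return `write_time_stack_tiff()` returns `path` invisibly;
#'   `read_time_stack_tiff()` returns a `flim_image`.
#' @export
write_time_stack_tiff <- function(image, path) {
  if (!inherits(image, "flim_image")) abort_input("`image` must be a flim_image")
  if (max(image) > .TIFF_MAX) {
    abort_input("pixel count exceeds 65535; 16-bit TIFF cannot store it")
  }
  g <- image_grid(image)
  pages <- lapply(seq_len(dim(image)[3]),
                  function(k) unclass(image)[, , k] / .TIFF_MAX)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(bin_width_ns = g$bin_width_ns, origin_ns = g$origin_ns,
         n_bins = g$n_bins),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_time_stack_tiff
#' @export
read_time_stack_tiff <- function(path, bin_width_ns = NULL, origin_ns = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 1L) {
    warning("single-page stack: treating as a one-bin image", call. = FALSE)
  }
  if (any(vapply(pages, function(p) any(p != round(p)), logical(1)))) {
    abort_input(paste0(path, ": float pixels; photon-count stacks must be integer"))
  }
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    bin_width_ns <- bin_width_ns %||% meta$bin_width_ns
    origin_ns <- origin_ns %||% meta$origin_ns
  }
  if (is.null(bin_width_ns)) {
    abort_input(paste0(path, ": no bin width in sidecar metadata; ",
                       "pass bin_width_ns explicitly"))
  }
  origin_ns <- origin_ns %||% 0
  d <- dim(pages[[1]])
  counts <- array(0L, dim = c(d[1], d[2], length(pages)))
  for (k in seq_along(pages)) counts[, , k] <- as.integer(pages[[k]])
  flim_image(counts, bin_grid(bin_width_ns, length(pages), origin_ns))
}

#' Read / write an ROI mask as TIFF
#'
#' Signed labels are stored offset-binary in 16-bit samples
#' (`stored = label + 32768`), so negative (excluded) labels round-trip
#' losslessly through an unsigned-integer TIFF.
#'
#' @param mask An `roi_mask`.
#' @param path TIFF file path.
#' @return `write_roi_mask_tiff()` returns `path` invisibly;
#'   `read_roi_mask_tiff()` returns an `roi_mask`.
#' @export
write_roi_mask_tiff <- function(mask, path) {
  if (!inherits(mask, "roi_mask")) abort_input("`mask` must be an roi_mask")
  if (any(mask < -.MASK_OFFSET) || any(mask > .TIFF_MAX - .MASK_OFFSET)) {
    abort_input("labels outside the storable range [-32768, 32767]")
  }
  tiff::writeTIFF((unclass(mask) + .MASK_OFFSET) / .TIFF_MAX, path,
                  bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' @rdname write_roi_mask_tiff
#' @export
read_roi_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (any(m != round(m))) abort_input(paste0(path, ": float pixels in mask"))
  roi_mask(matrix(as.integer(m) - .MASK_OFFSET, nrow(m), ncol(m)))
}

#' Fast-lifetime map
#'
#' The fit-free per-pixel lifetime estimate used for display and pixel
#' filtering: the photon-weighted mean arrival time (bin centres) minus an
#' origin. No truncation correction is applied, so values are biased low when
#' the window does not capture the full decay. Pixels with zero photons are
#' `NA`.
#'
#' @param image A `flim_image`.
#' @param origin_ns Time origin (ns). Default: the bin-centre time of the
#'   maximum of the image's pooled histogram (a proxy for the IRF peak).
#' @return Numeric matrix (ns) with `NA` at zero-photon pixels.
#' @export
fast_lifetime_map <- function(image, origin_ns = NULL) {
  g <- image_grid(image)
  centers <- grid_centers(g)
  if (is.null(origin_ns)) {
    pooled <- apply(unclass(image), 3, sum)
    origin_ns <- centers[which.max(pooled)]
  }
  if (origin_ns < g$origin_ns || origin_ns > g$origin_ns + grid_window_ns(g)) {
    abort_input("origin_ns must lie within the time window")
  }
  d <- dim(image)
  flat <- matrix(unclass(image), d[1] * d[2], d[3])
  tot <- rowSums(flat)
  val <- as.vector(flat %*% centers) / tot - origin_ns
  val[tot == 0] <- NA_real_
  matrix(val, d[1], d[2])
}

#' Exclude low-lifetime pixels from ROIs
#'
#' Pixels inside positive ROIs whose fast-lifetime value falls below
#' `threshold_ns` (e.g. plastid autofluorescence with very short lifetimes)
#' are flipped to the negative of their label, excluding them from pooling.
#'
#' @param image A `flim_image`.
#' @param mask An `roi_mask`.
#' @param threshold_ns Positive lifetime threshold (ns).
#' @param origin_ns Passed to [fast_lifetime_map()].
#' @return A new `roi_mask`; the number of flipped pixels is reported via
#'   `message()`.
#' @export
exclude_low_lifetime_pixels <- function(image, mask, threshold_ns,
                                        origin_ns = NULL) {
  if (!is.finite(threshold_ns) || threshold_ns <= 0) {
    abort_input("threshold_ns must be > 0")
  }
  if (!all(dim(mask) == dim(image)[1:2])) {
    abort_input("mask shape must match the image")
  }
  flm <- fast_lifetime_map(image, origin_ns)
  flip <- mask > 0 & !is.na(flm) & flm < threshold_ns
  out <- unclass(mask)
  out[flip] <- -out[flip]
  message(sum(flip), " pixel(s) excluded below ", threshold_ns, " ns")
  roi_mask(out)
}

#' Pool an ROI into a single TCSPC histogram
#'
#' Bin-wise sum of photon counts over all pixels carrying the given positive
#' label; excluded pixels (negative labels) are omitted.
#'
#' @param image A `flim_image`.
#' @param mask An `roi_mask`.
#' @param label Positive integer ROI label present in the mask.
#' @return A `tcspc_histogram`.
#' @export
pool_roi <- function(image, mask, label) {
  if (!is.finite(label) || label <= 0) abort_input("label must be positive")
  if (!all(dim(mask) == dim(image)[1:2])) {
    abort_input("mask shape must match the image")
  }
  if (!any(abs(mask) == label)) {
    abort_input(paste0("label ", label, " not present in mask"))
  }
  d <- dim(image)
  flat <- matrix(unclass(image), d[1] * d[2], d[3])
  sel <- as.vector(mask == label)
  counts <- if (any(sel)) colSums(flat[sel, , drop = FALSE]) else
    rep(0L, d[3])
  tcspc_histogram(counts, image_grid(image),
                  source = paste0("pooled ROI label ", label))
}
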