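#' TCSPC histogram
#'
#' Binned photon arrival counts for one ROI or one fit: a tibble with columns
#' `time_ns` (left edge of each bin, uniformly spaced) and `counts`
#' (non-negative integers).
#'
#' @param counts Non-negative integer counts per bin.
#' @param grid A `bin_grid` describing the time axis.
#' @param source Provenance string.
#' @return A tibble of class `tcspc_histogram`.
#' @export
tcspc_histogram <- function(counts, grid = bin_grid(), source = "") {
  if (length(counts) != grid$n_bins) {
    abort_input("length(counts) must equal grid$n_bins")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort_input("counts must be non-negative")
  }
  if (any(counts != round(counts))) abort_input("counts must be integers")
  out <- tibble(time_ns = grid_edges(grid)[seq_len(grid$n_bins)],
                counts = as.integer(round(counts)))
  class(out) <- c("tcspc_histogram", class(out))
  attr(out, "source") <- source
  out
}

is_tcspc_histogram <- function(x) inherits(x, "tcspc_histogram")

#' @export
print.tcspc_histogram <- function(x, ...) {
  g <- hist_grid(x)
  cat("<tcspc_histogram> ", sum(x$counts), " photons in ", g$n_bins,
      " bins of ", g$bin_width_ns * 1000, " ps\n", sep = "")
  NextMethod()
}

#' Total photons in a histogram
#' @param hist A `tcspc_histogram`.
#' @return Integer photon total.
#' @export
total_photons <- function(hist) sum(hist$counts)

# Reconstruct the bin grid from the (uniform) time column.
hist_grid <- function(hist, rel_tol = 1e-6) {
  t <- hist$time_ns
  if (length(t) < 1L) abort_input("empty histogram")
  if (length(t) == 1L) return(bin_grid(1, 1L, origin_ns = t))
  d <- diff(t)
  w <- mean(d)
  if (w <= 0 || any(abs(d - w) > rel_tol * abs(w))) {
    bad <- which(abs(d - w) > rel_tol * abs(w))[1]
    abort_input(paste0("time bins are not uniform (first offending row: ",
                       bad + 1L, ")"))
  }
  bin_grid(w, length(t), origin_ns = t[1])
}

#' Read / write a TCSPC histogram as CSV
#'
#' The on-disk format is a two-column CSV with header `time_ns,counts`; the
#' time column holds uniformly spaced bin left edges and the counts column
#' non-negative integers. The bin width is inferred from the time column
#' (relative non-uniformity above 1e-6 is an error).
#'
#' @param path CSV file path.
#' @param hist A `tcspc_histogram`.
#' @return `read_histogram_csv()` returns a `tcspc_histogram`;
#'   `write_histogram_csv()` returns `path` invisibly.
#' @export
read_histogram_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!identical(names(df), c("time_ns", "counts"))) {
    abort_input(paste0(path, ": header must be exactly 'time_ns,counts' (line 1)"))
  }
  if (nrow(df) == 0L) abort_input(paste0(path, ": no data rows"))
  if (any(!is.finite(df$counts)) || any(df$counts < 0)) {
    bad <- which(!is.finite(df$counts) | df$counts < 0)[1]
    abort_input(paste0(path, ": negative or non-finite count (line ", bad + 1L, ")"))
  }
  if (any(df$counts != round(df$counts))) {
    bad <- which(df$counts != round(df$counts))[1]
    abort_input(paste0(path, ": non-integer count (line ", bad + 1L, ")"))
  }
  h <- tibble(time_ns = df$time_ns, counts = as.integer(df$counts))
  class(h) <- c("tcspc_histogram", class(h))
  attr(h, "source") <- path
  hist_grid(h)  # validates uniform spacing
  h
}

#' @rdname read_histogram_csv
#' @export
write_histogram_csv <- function(hist, path) {
  if (!is_tcspc_histogram(hist)) abort_input("`hist` must be a tcspc_histogram")
  write.csv(data.frame(time_ns = hist$time_ns, counts = hist$counts),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
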