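#' Donor decay pattern
#'
#' A donor pattern is the fixed set of donor-only decay components (lifetimes
#' and relative pre-exponential amplitudes) that constrains every OPA fit.
#' Amplitudes are normalised to sum to one; components are ordered by
#' decreasing lifetime.
#'
#' @param lifetimes_ns Numeric vector of 1-3 component lifetimes in
#'   nanoseconds, all positive and pairwise distinct.
#' @param amplitudes Numeric vector of pre-exponential amplitudes, same
#'   length, all non-negative with a positive sum. Normalised internally.
#' @param source_note Free-text provenance note (e.g. which donor-only fits
#'   produced the pattern).
#'
#' @return A tibble of class `donor_pattern` with columns `lifetime_ns` and
#'   `amplitude` (normalised), ordered by decreasing lifetime.
#' @examples
#' donor_pattern(c(3.0, 1.2), c(0.9, 0.1))
#' @export
donor_pattern <- function(lifetimes_ns, amplitudes, source_note = "") {
  if (length(lifetimes_ns) < 1L || length(lifetimes_ns) > 3L) {
    abort_input("a donor pattern has 1-3 components")
  }
  if (length(amplitudes) != length(lifetimes_ns)) {
    abort_input("lifetimes_ns and amplitudes must have the same length")
  }
  if (any(!is.finite(lifetimes_ns)) || any(lifetimes_ns <= 0)) {
    abort_input("all lifetimes must be positive and finite")
  }
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0) || sum(amplitudes) <= 0) {
    abort_input("amplitudes must be non-negative with a positive sum")
  }
  ord <- order(lifetimes_ns, decreasing = TRUE)
  lt <- lifetimes_ns[ord]
  am <- amplitudes[ord] / sum(amplitudes)
  if (length(lt) > 1L && any(diff(lt) >= 0)) {
    abort_input("lifetimes must be pairwise distinct (ties forbidden)")
  }
  out <- tibble(lifetime_ns = as.double(lt), amplitude = as.double(am))
  class(out) <- c("donor_pattern", class(out))
  attr(out, "source_note") <- source_note
  out
}

is_donor_pattern <- function(x) inherits(x, "donor_pattern")

validate_pattern <- function(pattern) {
  if (!is_donor_pattern(pattern)) {
    abort_input("`pattern` must be a donor_pattern (see donor_pattern())")
  }
  if (abs(sum(pattern$amplitude) - 1) > 1e-9) {
    abort_input("pattern amplitudes must sum to 1")
  }
  invisible(pattern)
}

#' @export
print.donor_pattern <- function(x, ...) {
  cat("<donor_pattern> ", nrow(x), " component(s); tau_m = ",
      format(amplitude_weighted_lifetime(x), digits = 4), " ns\n", sep = "")
  note <- attr(x, "source_note")
  if (!is.null(note) && nzchar(note)) cat("  source: ", note, "\n", sep = "")
  print(tibble::as_tibble(unclass_pattern(x)), ...)
  invisible(x)
}

unclass_pattern <- function(x) {
  class(x) <- setdiff(class(x), "donor_pattern")
  x
}

#' Amplitude-weighted mean lifetime
#'
#' The conventional single-number FLIM readout: the mean of the component
#' lifetimes weighted by their pre-exponential amplitudes,
#' \eqn{\tau_m = \sum_i \alpha_i \tau_i / \sum_i \alpha_i}.
#'
#' @param components A `donor_pattern` or any data frame with columns
#'   `lifetime_ns` and `amplitude`.
#' @return The amplitude-weighted mean lifetime in nanoseconds.
#' @examples
#' amplitude_weighted_lifetime(donor_pattern(c(3, 1.2), c(0.9, 0.1)))
#' @export
amplitude_weighted_lifetime <- function(components) {
  if (is.null(dim(components)) || nrow(components) == 0L) {
    abort_input("`components` must be a nonempty data frame of decay components")
  }
  tau <- components$lifetime_ns
  a <- components$amplitude
  if (any(tau <= 0)) abort_input("all lifetimes must be positive")
  if (sum(a) <= 0) abort_input("amplitude sum must be positive")
  sum(a * tau) / sum(a)
}

#' Reference lifetime of a donor pattern
#'
#' The lifetime against which the FRET component is compared when converting
#' between FRET efficiency and FRET lifetime. The default is the
#' amplitude-weighted mean of the pattern; `"longest"` uses the slowest
#' component instead.
#'
#' @param pattern A `donor_pattern`.
#' @param tau_ref `"weighted"` (default) or `"longest"`.
#' @return Reference lifetime in nanoseconds.
#' @export
pattern_tau_ref <- function(pattern, tau_ref = c("weighted", "longest")) {
  validate_pattern(pattern)
  tau_ref <- match.arg(tau_ref)
  if (tau_ref == "weighted") amplitude_weighted_lifetime(pattern)
  else max(pattern$lifetime_ns)
}

#' Serialise / read a donor pattern as JSON
#'
#' @param pattern A `donor_pattern`.
#' @param path File path.
#' @return `write_pattern_json()` returns `path` invisibly;
#'   `read_pattern_json()` returns a `donor_pattern`.
#' @export
write_pattern_json <- function(pattern, path) {
  validate_pattern(pattern)
  obj <- list(
    lifetimes_ns = pattern$lifetime_ns,
    amplitudes = pattern$amplitude,
    source = attr(pattern, "source_note") %||% "",
    n_fits = attr(pattern, "n_fits") %||% NA_integer_,
    created_by = paste0("opaflim ", as.character(packageVersion("opaflim")))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pattern_json
#' @export
read_pattern_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$lifetimes_ns) || is.null(obj$amplitudes)) {
    abort_input(paste0("not a pattern file: ", path))
  }
  p <- donor_pattern(obj$lifetimes_ns, obj$amplitudes,
                     source_note = obj$source %||% "")
  if (!is.null(obj$n_fits)) attr(p, "n_fits") <- obj$n_fits
  p
}
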