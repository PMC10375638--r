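#' Instrument response functions
#'
#' TCSPC decays are convolved with the temporal response of the
#' excitation/detection system. Three kinds are supported: `irf_none()` (ideal
#' delta excitation at the time origin; fits then run in tail mode from the
#' histogram peak), `irf_gaussian()` (analytic Gaussian response with a given
#' centre and FWHM), and `irf_empirical()` (a measured response histogram on
#' the analysis grid, normalised to sum one).
#'
#' @param center_ns Centre of the response peak on the absolute time axis (ns).
#' @param fwhm_ns Full width at half maximum of the Gaussian response (ns).
#' @param histogram Non-negative counts (or densities) per bin of the analysis
#'   grid; normalised internally.
#' @return An object of class `irf`.
#' @export
irf_none <- function() {
  structure(list(kind = "none", center_ns = 0), class = "irf")
}

#' @rdname irf_none
#' @export
irf_gaussian <- function(center_ns = 0, fwhm_ns = 0.2) {
  if (!is.finite(fwhm_ns) || fwhm_ns <= 0) abort_input("fwhm_ns must be > 0")
  structure(list(kind = "gaussian", center_ns = center_ns, fwhm_ns = fwhm_ns,
                 sigma_ns = fwhm_ns / (2 * sqrt(2 * log(2)))),
            class = "irf")
}

#' @rdname irf_none
#' @export
irf_empirical <- function(histogram, center_ns = NULL) {
  h <- as.double(histogram)
  if (any(!is.finite(h)) || any(h < 0) || sum(h) <= 0) {
    abort_input("empirical IRF histogram must be non-negative with positive sum")
  }
  structure(list(kind = "empirical", histogram = h / sum(h),
                 center_ns = center_ns %||% NA_real_),
            class = "irf")
}

#' @export
print.irf <- function(x, ...) {
  cat("<irf kind=", x$kind, ">\n", sep = "")
  invisible(x)
}

#' Time-bin grid
#'
#' Uniform half-open time bins `[t0, t1)` for TCSPC histograms. The default
#' matches a typical 80 MHz TCSPC configuration: a 12.5 ns window of 250 bins
#' of 50 ps.
#'
#' @param bin_width_ns Bin width (ns), positive.
#' @param n_bins Number of bins, positive integer.
#' @param origin_ns Left edge of bin 0 on the absolute time axis (ns).
#' @return An object of class `bin_grid`.
#' @export
bin_grid <- function(bin_width_ns = 0.05, n_bins = 250L, origin_ns = 0) {
  if (!is.finite(bin_width_ns) || bin_width_ns <= 0) {
    abort_input("bin_width_ns must be > 0")
  }
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) abort_input("n_bins must be a positive integer")
  structure(list(bin_width_ns = as.double(bin_width_ns), n_bins = n_bins,
                 origin_ns = as.double(origin_ns)),
            class = "bin_grid")
}

grid_edges <- function(grid) grid$origin_ns + grid$bin_width_ns * (0:grid$n_bins)
grid_centers <- function(grid) {
  grid$origin_ns + grid$bin_width_ns * (seq_len(grid$n_bins) - 0.5)
}
grid_window_ns <- function(grid) grid$bin_width_ns * grid$n_bins

#' @export
print.bin_grid <- function(x, ...) {
  cat("<bin_grid> ", x$n_bins, " bins x ", x$bin_width_ns * 1000, " ps, origin ",
      x$origin_ns, " ns\n", sep = "")
  invisible(x)
}

#' FRET efficiency / FRET lifetime conversions
#'
#' FRET quenches the donor: the FRET component's lifetime is reduced relative
#' to the unquenched donor reference lifetime, `E = 1 - tau_fret / tau_ref`,
#' and conversely `tau_fret = (1 - E) * tau_ref`.
#'
#' @param tau_fret_ns,tau_ref_ns Lifetimes in ns, positive.
#' @param efficiency FRET efficiency fraction in `[0, 1)`.
#' @return `fret_efficiency()` returns the efficiency (may be negative when
#'   `tau_fret_ns > tau_ref_ns`; the caller decides validity);
#'   `fret_lifetime()` returns the quenched lifetime in ns.
#' @examples
#' fret_efficiency(1.8, 3.0)  # 0.4
#' fret_lifetime(3.0, 0.4)    # 1.8
#' @export
fret_efficiency <- function(tau_fret_ns, tau_ref_ns) {
  if (any(!is.finite(tau_fret_ns)) || any(tau_fret_ns <= 0) ||
      any(!is.finite(tau_ref_ns)) || any(tau_ref_ns <= 0)) {
    abort_input("lifetimes must be positive")
  }
  1 - tau_fret_ns / tau_ref_ns
}

#' @rdname fret_efficiency
#' @export
fret_lifetime <- function(tau_ref_ns, efficiency) {
  if (any(!is.finite(tau_ref_ns)) || any(tau_ref_ns <= 0)) {
    abort_input("tau_ref_ns must be positive")
  }
  if (any(!is.finite(efficiency)) || any(efficiency < 0) || any(efficiency >= 1)) {
    abort_input("efficiency must lie in [0, 1)")
  }
  (1 - efficiency) * tau_ref_ns
}

#' Convert a BINDING amplitude fraction to a photon (intensity) fraction
#'
#' BINDING is the relative pre-exponential amplitude of the FRET component: a
#' molecule-fraction proxy. The fraction of detected photons contributed by
#' the FRET component differs, because each component's integrated intensity
#' is amplitude times lifetime:
#' `B * tau_fret / (B * tau_fret + (1 - B) * tau_m)` with `tau_m` the
#' amplitude-weighted pattern lifetime.
#'
#' @param binding BINDING fraction in `[0, 1]`.
#' @param pattern A `donor_pattern`.
#' @param tau_fret_ns FRET-component lifetime (ns), positive.
#' @return Photon fraction in `[0, 1]`.
#' @export
amplitude_to_photon_fraction <- function(binding, pattern, tau_fret_ns) {
  if (any(!is.finite(binding)) || any(binding < 0) || any(binding > 1)) {
    abort_input("binding must lie in [0, 1]")
  }
  if (any(tau_fret_ns <= 0)) abort_input("tau_fret_ns must be positive")
  validate_pattern(pattern)
  tau_m <- amplitude_weighted_lifetime(pattern)
  binding * tau_fret_ns / (binding * tau_fret_ns + (1 - binding) * tau_m)
}

# Scaled complementary error function, stable over the whole real line.
# pracma::erfcx overflows to NaN above ~26; switch to the asymptotic series.
erfcx_stable <- function(x) {
  out <- numeric(length(x))
  lo <- x <= 25
  if (any(lo)) out[lo] <- pracma::erfcx(x[lo])
  if (any(!lo)) {
    z <- x[!lo]
    # erfcx(z) ~ 1/(z sqrt(pi)) (1 - 1/(2z^2) + 3/(4z^4) - 15/(8 z^6))
    iz2 <- 1 / z^2
    out[!lo] <- (1 - 0.5 * iz2 + 0.75 * iz2^2 - 1.875 * iz2^3) / (z * sqrt(pi))
  }
  out
}

# CDF of an exponential decay (rate 1/tau, onset mu) convolved with a
# Gaussian of sd sigma: the exponentially-modified-Gaussian CDF.
# F(t) = Phi(z) - 0.5 * erfcx((sigma/tau - z)/sqrt(2)) * exp(-z^2/2), z=(t-mu)/sigma
emg_cdf <- function(t, mu, sigma, tau) {
  z <- (t - mu) / sigma
  x <- (sigma / tau - z) / sqrt(2)
  term2 <- numeric(length(t))
  far <- x < -4  # erfc(x) ~ 2: exponential tail, evaluate directly
  if (any(far)) {
    term2[far] <- exp(sigma^2 / (2 * tau^2) - (t[far] - mu) / tau)
  }
  if (any(!far)) {
    term2[!far] <- 0.5 * erfcx_stable(x[!far]) * exp(-z[!far]^2 / 2)
  }
  pnorm(z) - term2
}

# Per-bin photon mass of one decay component (unit amplitude density
# alpha=1), on the grid, under the given IRF. Returns a vector proportional
# to the *photon count* contribution, i.e. integrated intensity ~ tau.
component_bin_mass <- function(tau, irf, grid) {
  edges <- grid_edges(grid)
  if (irf$kind == "none") {
    t0 <- pmax(edges[-length(edges)], 0)
    t1 <- pmax(edges[-1], 0)
    tau * (exp(-t0 / tau) - exp(-t1 / tau))
  } else if (irf$kind == "gaussian") {
    f <- emg_cdf(edges, irf$center_ns, irf$sigma_ns, tau)
    tau * diff(f)
  } else { # empirical: discrete convolution on a 4x oversampled grid
    os <- 4L
    fine_w <- grid$bin_width_ns / os
    nf <- grid$n_bins * os
    tf <- (seq_len(nf) - 0.5) * fine_w  # decay time since excitation
    dec <- exp(-tf / tau) * fine_w     # ~ integral of e^(-t/tau) per fine bin
    irf_fine <- rep(irf$histogram / os, each = os)
    conv <- convolve_causal(irf_fine, dec, nf)
    colSums(matrix(conv, nrow = os))   # photon mass per coarse bin (~ tau overall)
  }
}

# causal discrete convolution, truncated to n bins
convolve_causal <- function(a, b, n) {
  full <- stats::convolve(a, rev(b), type = "open")
  full[seq_len(n)]
}

#' Expected TCSPC counts under the pattern-constrained three-component model
#'
#' The per-photon decay density is
#' `(1 - B) * sum_j alpha_j exp(-t / tau_j) + B * exp(-t / tau_fret)` with
#' `tau_fret = (1 - E) * tau_ref(pattern)`, convolved with the instrument
#' response, integrated over each bin, mixed with a uniform background at
#' `background_fraction`, and scaled to `total_photons`.
#'
#' Negative BINDING (a fit artefact on donor-only data) can drive the density
#' negative; entries are then clipped at a floor of 1e-12 and the returned
#' vector carries `attr(, "model_valid") = FALSE`.
#'
#' @param pattern A `donor_pattern`.
#' @param binding BINDING amplitude fraction `B` (may be negative during
#'   fitting; must be `<= 1`).
#' @param efficiency FRET efficiency `E` in `[0, 1)`.
#' @param background_fraction Fraction of photons from a time-uniform
#'   background, in `[0, 1)`.
#' @param irf An `irf` object.
#' @param grid A `bin_grid`.
#' @param total_photons Positive scale: the vector sums to this value.
#' @param tau_ref `"weighted"` or `"longest"` reference-lifetime convention.
#' @return Numeric vector of length `grid$n_bins`, summing to `total_photons`,
#'   with attribute `model_valid`.
#' @export
expected_counts <- function(pattern, binding = 0, efficiency = 0,
                            background_fraction = 0, irf = irf_none(),
                            grid = bin_grid(), total_photons = 1,
                            tau_ref = "weighted") {
  validate_pattern(pattern)
  if (!is.finite(total_photons) || total_photons <= 0) {
    abort_input("total_photons must be > 0")
  }
  if (!is.finite(efficiency) || efficiency < 0 || efficiency >= 1) {
    abort_input("efficiency must lie in [0, 1)")
  }
  if (!is.finite(background_fraction) || background_fraction < 0 ||
      background_fraction >= 1) {
    abort_input("background_fraction must lie in [0, 1)")
  }
  if (binding > 1) abort_input("binding must be <= 1")
  if (grid$bin_width_ns > min(pattern$lifetime_ns)) {
    warning("bin width exceeds the smallest pattern lifetime; ",
            "the grid is too coarse to resolve it", call. = FALSE)
  }
  if (grid_window_ns(grid) < 3 * max(pattern$lifetime_ns)) {
    warning("time window is shorter than 3x the longest pattern lifetime; ",
            "the decay is substantially truncated", call. = FALSE)
  }

  donor <- rowSums(vapply(
    seq_len(nrow(pattern)),
    function(j) pattern$amplitude[j] *
      component_bin_mass(pattern$lifetime_ns[j], irf, grid),
    numeric(grid$n_bins)
  ))
  mass <- (1 - binding) * donor
  if (binding != 0) {
    t_ref <- pattern_tau_ref(pattern, tau_ref)
    t_fret <- fret_lifetime(t_ref, efficiency)
    mass <- mass + binding * component_bin_mass(t_fret, irf, grid)
  }

  model_valid <- TRUE
  if (any(mass < 0)) {
    mass <- pmax(mass, 1e-12)
    model_valid <- FALSE
  }
  p <- (1 - background_fraction) * mass / sum(mass) +
    background_fraction / grid$n_bins
  out <- p * total_photons
  attr(out, "model_valid") <- model_valid
  out
}

# Mean arrival time (ns, absolute axis) of a per-bin expectation vector.
mean_arrival_time <- function(counts, grid) {
  sum(counts * grid_centers(grid)) / sum(counts)
}
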