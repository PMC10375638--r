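#' Free multi-exponential decay fit
#'
#' Maximum-likelihood fit of a 1-3 component exponential decay (plus uniform
#' background) to a TCSPC histogram, assuming Poisson counting noise. Used to
#' calibrate the donor-only pattern and for the legacy average-lifetime
#' analysis. Lifetimes are bounded in `options$tau_bounds` (default
#' 0.05-10 ns); amplitudes are fitted on the simplex and reported normalised
#' to sum 1, sorted by descending lifetime.
#'
#' @param hist A `tcspc_histogram` with at least `options$min_photons` photons.
#' @param n_components 1, 2 or 3.
#' @param irf An `irf`, or `NULL` for tail fitting from the histogram peak.
#' @param options An [opa_options()] list.
#' @return An object of class `calibration_fit` with elements `components`
#'   (tibble `lifetime_ns`, `amplitude`), `background`, `fit_statistic`
#'   (reduced Poisson deviance), `n_photons`, `converged`, `hit_bound`.
#' @export
fit_multiexp <- function(hist, n_components = 2, irf = NULL,
                         options = opa_options()) {
  if (!n_components %in% c(1, 2, 3)) abort_input("n_components must be 1, 2 or 3")
  k <- as.integer(n_components)
  n_ph <- total_photons(hist)
  check_photons(n_ph, options)
  fd <- prepare_fit_data(hist, irf)
  y <- fd$y
  grid <- fd$grid

  comp_mass <- function(tau) component_bin_mass(tau, fd$irf, grid)
  sticks_to_amp <- function(s) {
    if (k == 1L) return(1)
    if (k == 2L) return(c(s[1], 1 - s[1]))
    c(s[1], (1 - s[1]) * s[2], (1 - s[1]) * (1 - s[2]))
  }
  model <- function(par) {
    tau <- par[seq_len(k)]
    amp <- sticks_to_amp(par[k + seq_len(max(k - 1L, 0L))])
    bg <- par[2L * k]
    mass <- rowSums(vapply(seq_len(k),
                           function(j) amp[j] * comp_mass(tau[j]),
                           numeric(grid$n_bins)))
    ((1 - bg) * mass / sum(mass) + bg / grid$n_bins) * sum(y)
  }
  obj <- function(par) fit_loss(y, model(par), options$loss)

  # method-of-moments start: mean arrival time anchors the lifetime scale
  tau_hat <- max(sum(y * grid_centers(grid)) / sum(y) - grid$origin_ns, 0.2)
  tau0 <- switch(k, tau_hat, tau_hat * c(1.4, 0.45), tau_hat * c(1.8, 0.8, 0.3))
  tau0 <- pmin(pmax(tau0, options$tau_bounds[1] * 1.5),
               options$tau_bounds[2] * 0.8)
  s0 <- switch(k, numeric(0), 0.7, c(0.6, 0.6))
  par0 <- c(tau0, s0, 0.01)
  lower <- c(rep(options$tau_bounds[1], k), rep(1e-3, k - 1L), 0)
  upper <- c(rep(options$tau_bounds[2], k), rep(1 - 1e-3, k - 1L),
             options$bg_max)

  opt <- optim_restart(par0, obj, lower = lower, upper = upper,
                       maxit = options$maxit)
  if (is.null(opt)) {
    return(structure(list(components = tibble(lifetime_ns = rep(NA_real_, k),
                                              amplitude = rep(NA_real_, k)),
                          background = NA_real_, fit_statistic = NA_real_,
                          n_photons = n_ph, converged = FALSE,
                          hit_bound = character(0), n_components = k,
                          observed = y, fitted = NULL, grid = grid,
                          fit_mode = fd$mode),
                     class = "calibration_fit"))
  }

  tau <- opt$par[seq_len(k)]
  amp <- sticks_to_amp(opt$par[k + seq_len(max(k - 1L, 0L))])
  bg <- opt$par[2L * k]
  ord <- order(tau, decreasing = TRUE)
  tau <- tau[ord]; amp <- amp[ord] / sum(amp)
  if (k > 1L && any(abs(diff(tau)) / tau[-k] < 0.05)) {
    abort_input(paste0("degenerate fit: two fitted lifetimes within 5% of ",
                       "each other; refit with fewer components"))
  }
  tau_at_bound <- any(near_bound(tau, options$tau_bounds[1],
                                 options$tau_bounds[2]))
  hb <- if (tau_at_bound) "lifetime" else character(0)
  mu <- model(opt$par)
  n_par <- 2L * k + 1L  # k lifetimes, k-1 simplex, background, scale
  structure(list(components = tibble(lifetime_ns = tau, amplitude = amp),
                 background = bg,
                 fit_statistic = poisson_deviance(y, mu) /
                   max(length(y) - n_par, 1L),
                 n_photons = n_ph,
                 converged = opt$convergence == 0 && !tau_at_bound,
                 hit_bound = hb, n_components = k, observed = y, fitted = mu,
                 grid = grid, fit_mode = fd$mode),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("<calibration_fit> ", x$n_components, " component(s), ",
      x$n_photons, " photons, reduced deviance ",
      format(x$fit_statistic, digits = 4), ", converged: ", x$converged,
      "\n", sep = "")
  print(x$components, ...)
  invisible(x)
}

#' Freeze a calibration fit into a donor pattern
#'
#' @param fit A converged `calibration_fit`.
#' @return A `donor_pattern` with normalised amplitudes and a provenance note.
#' @export
make_pattern <- function(fit) {
  if (!inherits(fit, "calibration_fit")) {
    abort_input("`fit` must be a calibration_fit")
  }
  if (!isTRUE(fit$converged)) {
    abort_input("refusing to build a pattern from a non-converged fit")
  }
  donor_pattern(fit$components$lifetime_ns, fit$components$amplitude,
                source_note = sprintf(
                  "calibrated from %d photons (%d components, reduced deviance %.3f)",
                  fit$n_photons, fit$n_components, fit$fit_statistic))
}

#' Aggregate several donor-only calibration fits into one pattern
#'
#' Component-wise photon-weighted mean of lifetimes and amplitudes, matched by
#' rank order (components are sorted by descending lifetime), renormalised.
#' One aggregated pattern per donor construct is the intended calibration
#' unit.
#'
#' @param fits List of converged `calibration_fit`s, all with the same number
#'   of components.
#' @return A `donor_pattern`; `attr(, "n_fits")` records the number pooled.
#' @export
aggregate_patterns <- function(fits) {
  if (length(fits) < 1L) abort_input("need at least one fit")
  if (!all(vapply(fits, inherits, logical(1), "calibration_fit"))) {
    abort_input("all elements must be calibration_fits")
  }
  if (!all(vapply(fits, function(f) isTRUE(f$converged), logical(1)))) {
    abort_input("all fits must be converged")
  }
  ks <- vapply(fits, function(f) f$n_components, integer(1))
  if (length(unique(ks)) != 1L) {
    abort_input("all fits must have the same number of components")
  }
  w <- vapply(fits, function(f) as.double(f$n_photons), numeric(1))
  w <- w / sum(w)
  tau <- Reduce(`+`, Map(function(f, wi) wi * f$components$lifetime_ns,
                         fits, w))
  amp <- Reduce(`+`, Map(function(f, wi) wi * f$components$amplitude,
                         fits, w))
  p <- donor_pattern(tau, amp,
                     source_note = sprintf(
                       "photon-weighted aggregate of %d calibration fits",
                       length(fits)))
  attr(p, "n_fits") <- length(fits)
  p
}
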