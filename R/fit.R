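#' Fit options
#'
#' Tuning knobs shared by the OPA and calibration fits.
#'
#' @param min_photons Minimum photons required in a histogram (default 1e4).
#'   Can be lowered (e.g. to 1e3 for low-count acquisitions); histograms below
#'   1e4 photons then trigger a low-photon warning instead of an error.
#' @param cutoff BINDING cut-off below which the fitted FRET efficiency is
#'   flagged invalid (default 0.10; strictly-below exclusion).
#' @param b_min Lower BINDING bound during fitting (default -0.5: negative
#'   apparent BINDING on donor-only data is an expected fit artefact).
#' @param e_limits FRET-efficiency fit limits (default `c(0.10, 0.80)`).
#' @param bg_max Upper bound on the background fraction (default 0.5).
#' @param tau_ref Reference-lifetime convention, `"weighted"` or `"longest"`.
#' @param loss `"poisson"` (maximum likelihood on binned counts; correct for
#'   TCSPC shot noise) or `"wls"` (weighted least squares, variance
#'   `max(counts, 1)`), kept for cross-checks.
#' @param maxit Optimiser iteration cap (default 2000).
#' @param n_starts Coarse-grid starts per axis for the (B, E) multi-start
#'   (default 5, i.e. a 5x5 grid).
#' @param tau_bounds Lifetime bounds for free multi-exponential fits (ns).
#' @return A list of class `opa_options`.
#' @export
opa_options <- function(min_photons = 1e4, cutoff = 0.10, b_min = -0.5,
                        e_limits = c(0.10, 0.80), bg_max = 0.5,
                        tau_ref = c("weighted", "longest"),
                        loss = c("poisson", "wls"), maxit = 2000L,
                        n_starts = 5L, tau_bounds = c(0.05, 10)) {
  structure(list(min_photons = min_photons, cutoff = cutoff, b_min = b_min,
                 e_limits = e_limits, bg_max = bg_max,
                 tau_ref = match.arg(tau_ref), loss = match.arg(loss),
                 maxit = as.integer(maxit), n_starts = as.integer(n_starts),
                 tau_bounds = tau_bounds),
            class = "opa_options")
}

check_photons <- function(n, options) {
  if (n < options$min_photons) {
    abort_input(paste0("histogram has ", n, " photons, below the required ",
                       "minimum of ", options$min_photons,
                       " (lower min_photons in opa_options() to override)"))
  }
  if (n < 1e4) {
    warning("low photon count (", n, "); estimates will be noisy",
            call. = FALSE)
  }
  invisible(n)
}

# Reconvolution when an IRF is supplied; otherwise tail-fit from the
# histogram peak with an ideal (delta) response at the peak bin's left edge.
prepare_fit_data <- function(hist, irf) {
  g <- hist_grid(hist)
  y <- hist$counts
  if (is.null(irf) || irf$kind == "none") {
    peak <- which.max(y)
    used <- peak:length(y)
    grid_used <- bin_grid(g$bin_width_ns, length(used),
                          origin_ns = g$origin_ns + (peak - 1) * g$bin_width_ns)
    list(y = y[used], grid = grid_used, irf = irf_none(), mode = "tail",
         first_bin = peak)
  } else {
    list(y = y, grid = g, irf = irf, mode = "reconvolution", first_bin = 1L)
  }
}

poisson_deviance <- function(y, mu) {
  mu <- pmax(mu, 1e-300)
  2 * sum(mu - y + ifelse(y > 0, y * log(y / mu), 0))
}

wls_loss <- function(y, mu) sum((y - mu)^2 / pmax(y, 1))

fit_loss <- function(y, mu, loss) {
  if (loss == "poisson") poisson_deviance(y, mu) else wls_loss(y, mu)
}

# Precompute the donor mass once; return mu(B, E, bg) on the fit grid.
make_opa_model <- function(pattern, irf, grid, tau_ref, total) {
  donor <- rowSums(vapply(
    seq_len(nrow(pattern)),
    function(j) pattern$amplitude[j] *
      component_bin_mass(pattern$lifetime_ns[j], irf, grid),
    numeric(grid$n_bins)))
  t_ref <- pattern_tau_ref(pattern, tau_ref)
  n <- grid$n_bins
  function(B, E, bg) {
    mass <- (1 - B) * donor
    if (B != 0) {
      mass <- mass + B * component_bin_mass((1 - E) * t_ref, irf, grid)
    }
    mass <- pmax(mass, 1e-12)
    ((1 - bg) * mass / sum(mass) + bg / n) * total
  }
}

near_bound <- function(x, lo, hi, tol = 1e-6) {
  span <- max(hi - lo, 1e-12)
  c(lo = (x - lo) <= tol * span, hi = (hi - x) <= tol * span)
}

# Bounded optimisation with one restart: L-BFGS-B occasionally aborts its
# line search when started at (or reaching) a stationary point; a restart
# that cannot improve the objective is accepted as converged.
optim_restart <- function(par0, obj, lower, upper, maxit) {
  run <- function(par) {
    tryCatch(
      optim(par, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = maxit, factr = 1e5)),
      error = function(e) NULL)
  }
  o1 <- run(par0)
  if (is.null(o1)) return(NULL)
  if (o1$convergence == 0) return(o1)
  o2 <- run(o1$par)
  if (is.null(o2)) return(o1)
  best <- if (o2$value <= o1$value) o2 else o1
  if (abs(o1$value - o2$value) <= 1e-6 * (abs(o1$value) + 1)) {
    best$convergence <- 0  # stationary: no further improvement possible
  }
  best
}

#' Pattern-constrained OPA fit of one histogram
#'
#' The core one-pattern analysis: the donor components' lifetimes and
#' amplitude ratio are frozen to the calibrated pattern, and a third
#' FRET-quenched component is fitted. Free parameters are BINDING `B`
#' (relative amplitude of the FRET component, bounded in `[b_min, 1]`),
#' FRET efficiency `E` (bounded in the model limits, default 10-80%), and the
#' background fraction; the overall scale is profiled out by the Poisson
#' maximum-likelihood normalisation. Optimisation is bounded local search
#' (L-BFGS-B) from the best point of a coarse (B, E) start grid.
#'
#' When the fitted BINDING falls below the cut-off (default 10%), the FRET
#' efficiency is still reported numerically but flagged
#' `valid_efficiency = FALSE`: in that regime fitted efficiencies are
#' unreliable and accumulate at the fit limits, so downstream summaries
#' suppress them.
#'
#' @param hist A `tcspc_histogram`.
#' @param pattern The fixed `donor_pattern`.
#' @param irf An `irf`, or `NULL`/`irf_none()` for tail fitting from the
#'   histogram peak.
#' @param options An [opa_options()] list.
#' @param roi_id Opaque ROI identifier carried into the result.
#' @param acceptor_photons Optional acceptor-channel photon count (metadata
#'   for concentration correlation; no acceptor decay is modelled).
#' @return An object of class `opa_fit`; see [tidy.opa_fit()].
#' @examples
#' h <- simulate_histogram(default_donor_pattern(), binding = 0.3,
#'                         efficiency = 0.4, n_photons = 2e5, seed = 1)
#' fit <- fit_opa(h, default_donor_pattern())
#' tidy(fit)
#' @export
fit_opa <- function(hist, pattern, irf = NULL, options = opa_options(),
                    roi_id = NA_character_, acceptor_photons = NA_integer_) {
  validate_pattern(pattern)
  n_ph <- total_photons(hist)
  check_photons(n_ph, options)
  fd <- prepare_fit_data(hist, irf)
  model <- make_opa_model(pattern, fd$irf, fd$grid, options$tau_ref,
                          total = sum(fd$y))
  e_lo <- options$e_limits[1]; e_hi <- options$e_limits[2]

  obj <- function(par) fit_loss(fd$y, model(par[1], par[2], par[3]),
                                options$loss)

  ns <- options$n_starts
  b_starts <- seq(max(options$b_min, -0.25), 0.9, length.out = ns)
  e_starts <- seq(e_lo, e_hi, length.out = ns)
  starts <- expand.grid(B = b_starts, E = e_starts)
  start_loss <- vapply(seq_len(nrow(starts)),
                       function(i) obj(c(starts$B[i], starts$E[i], 0.02)),
                       numeric(1))
  best <- as.numeric(starts[which.min(start_loss), ])

  opt <- optim_restart(c(best[1], best[2], 0.02), obj,
                       lower = c(options$b_min, e_lo, 0),
                       upper = c(1, e_hi, options$bg_max),
                       maxit = options$maxit)

  t_ref <- pattern_tau_ref(pattern, options$tau_ref)
  model_tag <- if (nrow(pattern) == 1L) "mono-donor" else "opa"
  if (is.null(opt)) {
    return(new_opa_fit(model_tag, roi_id, NA_real_, NA_real_, NA_real_, t_ref,
                       NA_real_, NA_real_, n_ph, length(fd$y), FALSE,
                       character(0), NA, options$cutoff, acceptor_photons,
                       fd$y, rep(NA_real_, length(fd$y)), fd$grid, fd$mode))
  }
  B <- opt$par[1]; E <- opt$par[2]; bg <- opt$par[3]
  hb <- character(0)
  nb <- near_bound(B, options$b_min, 1)
  if (nb["lo"] || nb["hi"]) hb <- c(hb, "binding")
  ne <- near_bound(E, e_lo, e_hi)
  if (ne["lo"] || ne["hi"]) hb <- c(hb, "efficiency")
  nbg <- near_bound(bg, 0, options$bg_max)
  if (nbg["hi"]) hb <- c(hb, "background")
  mu <- model(B, E, bg)
  dev <- poisson_deviance(fd$y, mu)
  new_opa_fit(model_tag, roi_id, B, E, (1 - E) * t_ref, t_ref, bg,
              dev / max(length(fd$y) - 4L, 1L), n_ph, length(fd$y),
              opt$convergence == 0, hb, B >= options$cutoff, options$cutoff,
              acceptor_photons, fd$y, mu, fd$grid, fd$mode)
}

new_opa_fit <- function(model, roi_id, binding, efficiency, tau_fret_ns,
                        tau_ref_ns, background, fit_statistic, n_photons,
                        n_bins_used, converged, hit_bound, valid_efficiency,
                        cutoff, acceptor_photons, observed, fitted, grid,
                        fit_mode) {
  structure(list(model = model, roi_id = roi_id, binding = binding,
                 efficiency = efficiency, tau_fret_ns = tau_fret_ns,
                 tau_ref_ns = tau_ref_ns, background = background,
                 fit_statistic = fit_statistic, n_photons = n_photons,
                 n_bins_used = n_bins_used, converged = converged,
                 hit_bound = hit_bound, valid_efficiency = valid_efficiency,
                 cutoff = cutoff, acceptor_photons = acceptor_photons,
                 observed = observed, fitted = fitted, grid = grid,
                 fit_mode = fit_mode),
            class = "opa_fit")
}

#' @export
print.opa_fit <- function(x, ...) {
  cat("<opa_fit model=", x$model, ">\n", sep = "")
  cat(sprintf("  BINDING %.3f  E %.3f%s  tau_FRET %.3f ns  bg %.3f\n",
              x$binding, x$efficiency,
              if (isTRUE(x$valid_efficiency)) "" else " (below cut-off)",
              x$tau_fret_ns, x$background))
  cat(sprintf("  %d photons, reduced deviance %.3f, converged: %s%s\n",
              x$n_photons, x$fit_statistic, x$converged,
              if (length(x$hit_bound)) paste0(", at bound: ",
                                              paste(x$hit_bound, collapse = ","))
              else ""))
  invisible(x)
}

#' Apply the BINDING cut-off to a fit result
#'
#' Below the cut-off (default 10% BINDING), fitted FRET efficiencies are
#' unreliable and are flagged invalid. The exclusion is strictly below:
#' a BINDING of exactly the cut-off counts as valid.
#'
#' @param result An `opa_fit`, or a data frame with a `binding` column (e.g.
#'   from [batch_fit()]).
#' @param cutoff Cut-off fraction in `[0, 1]` (default 0.10).
#' @return The input with `valid_efficiency` recomputed.
#' @export
apply_fret_cutoff <- function(result, cutoff = 0.10) {
  if (!is.finite(cutoff) || cutoff < 0 || cutoff > 1) {
    abort_input("cutoff must lie in [0, 1]")
  }
  if (inherits(result, "opa_fit")) {
    result$valid_efficiency <- isTRUE(result$binding >= cutoff)
    result$cutoff <- cutoff
    result
  } else if (is.data.frame(result)) {
    dplyr::mutate(result, valid_efficiency = .data$binding >= cutoff)
  } else {
    abort_input("`result` must be an opa_fit or a data frame")
  }
}

#' Comparison fit assuming a mono-exponential donor
#'
#' The donor is collapsed to a single fixed component and the FRET component
#' is fitted as usual. An analyst who assumes a mono-exponential donor
#' describes it by its principal (long) lifetime, so the default collapse is
#' the pattern's longest component; on a genuinely bi-exponential donor the
#' short donor component then has nowhere to go but the FRET term, inflating
#' apparent BINDING towards the short component's amplitude. The fit is
#' provided to demonstrate (and test) that failure mode;
#' `collapse = "weighted"` uses the amplitude-weighted mean lifetime instead.
#'
#' @inheritParams fit_opa
#' @param collapse `"longest"` (default) or `"weighted"`: which single
#'   lifetime represents the donor.
#' @return An `opa_fit` with `model = "mono-donor"`.
#' @export
fit_mono_donor <- function(hist, pattern, irf = NULL, options = opa_options(),
                           roi_id = NA_character_,
                           acceptor_photons = NA_integer_,
                           collapse = c("longest", "weighted")) {
  validate_pattern(pattern)
  collapse <- match.arg(collapse)
  tau <- if (collapse == "longest") max(pattern$lifetime_ns)
         else amplitude_weighted_lifetime(pattern)
  mono <- donor_pattern(tau, 1,
                        source_note = paste0("mono-donor collapse (",
                                             collapse, ") of pattern"))
  fit_opa(hist, mono, irf, options, roi_id, acceptor_photons)
}

#' Legacy average-lifetime analysis
#'
#' The conventional FLIM readout: a free multi-exponential fit (no pattern
#' constraint) summarised by the amplitude-weighted mean lifetime. FRET shows
#' up only as a reduction in the mean lifetime; affinity and proximity are
#' confounded.
#'
#' @inheritParams fit_opa
#' @param n_components 1 or 2 free components.
#' @return A list with `tau_m_ns` (amplitude-weighted mean lifetime) and
#'   `fit` (the underlying `calibration_fit`).
#' @export
fit_average_lifetime <- function(hist, irf = NULL, n_components = 2,
                                 options = opa_options()) {
  if (!n_components %in% c(1, 2)) abort_input("n_components must be 1 or 2")
  fit <- fit_multiexp(hist, n_components, irf, options)
  list(tau_m_ns = amplitude_weighted_lifetime(fit$components), fit = fit)
}

#' Fit many ROIs with one pattern
#'
#' @param histograms Either a list of `tcspc_histogram` objects (names become
#'   `roi_id`s) or a data frame with columns `roi_id`, `hist` (list column of
#'   histograms) and optionally `acceptor_photons`.
#' @inheritParams fit_opa
#' @return A tibble with one row per ROI (the [tidy.opa_fit()] columns).
#'   Per-ROI failures (e.g. too few photons) are recorded as non-converged
#'   rows; the remaining ROIs are unaffected.
#' @export
batch_fit <- function(histograms, pattern, irf = NULL,
                      options = opa_options()) {
  if (is.data.frame(histograms)) {
    if (!all(c("roi_id", "hist") %in% names(histograms))) {
      abort_input("data-frame input needs columns roi_id and hist")
    }
    ids <- histograms$roi_id
    hs <- histograms$hist
    acc <- histograms$acceptor_photons %||% rep(NA_integer_, length(hs))
  } else if (is.list(histograms) && length(histograms) > 0) {
    hs <- histograms
    ids <- names(histograms) %||% as.character(seq_along(histograms))
    if (is.null(names(histograms))) ids <- as.character(seq_along(histograms))
    acc <- rep(NA_integer_, length(hs))
  } else {
    abort_input("`histograms` must be a nonempty list or data frame")
  }
  if (length(hs) == 0) abort_input("`histograms` is empty")
  rows <- purrr::map(seq_along(hs), function(i) {
    res <- tryCatch(
      fit_opa(hs[[i]], pattern, irf, options, roi_id = ids[i],
              acceptor_photons = acc[i]),
      error = function(e) NULL)
    if (is.null(res)) {
      tibble(roi_id = ids[i], model = "opa", binding = NA_real_,
             efficiency = NA_real_, valid_efficiency = NA,
             tau_fret_ns = NA_real_, background = NA_real_,
             n_photons = total_photons(hs[[i]]), fit_statistic = NA_real_,
             converged = FALSE, hit_bound = "",
             acceptor_photons = acc[i])
    } else {
      tidy(res)
    }
  })
  dplyr::bind_rows(rows)
}

#' Exhaustive grid-search OPA estimate
#'
#' Brute-force maximisation of the same Poisson likelihood over a regular
#' (B, E) grid with the background fixed; used to cross-check the bounded
#' optimiser.
#'
#' @inheritParams fit_opa
#' @param background Fixed background fraction.
#' @param step Grid step for both B and E (default 0.005).
#' @return A list with `binding`, `efficiency` and `deviance` at the grid
#'   optimum.
#' @export
opa_grid_search <- function(hist, pattern, irf = NULL, background = 0,
                            step = 0.005, options = opa_options()) {
  validate_pattern(pattern)
  fd <- prepare_fit_data(hist, irf)
  model <- make_opa_model(pattern, fd$irf, fd$grid, options$tau_ref,
                          total = sum(fd$y))
  b_grid <- seq(options$b_min, 1, by = step)
  e_grid <- seq(options$e_limits[1], options$e_limits[2], by = step)
  best <- c(NA_real_, NA_real_, Inf)
  for (E in e_grid) {
    # the model is linear in B given E: evaluate all B cheaply
    for (B in b_grid) {
      d <- fit_loss(fd$y, model(B, E, background), options$loss)
      if (d < best[3]) best <- c(B, E, d)
    }
  }
  list(binding = best[1], efficiency = best[2], deviance = best[3])
}
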