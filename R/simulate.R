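#' Default donor pattern used by the simulator fixtures
#'
#' A bi-exponential donor with a long ~3 ns component carrying most of the
#' amplitude and a short 1.2 ns component, the typical behaviour of
#' yellow-fluorescent-protein donors.
#'
#' @return A `donor_pattern` (3.0 ns at amplitude 0.9, 1.2 ns at 0.1).
#' @export
default_donor_pattern <- function() {
  donor_pattern(c(3.0, 1.2), c(0.9, 0.1), source_note = "simulator default")
}

validate_sim_params <- function(binding, efficiency) {
  if (!is.finite(binding) || binding < 0 || binding > 1) {
    abort_input("simulated binding must lie in [0, 1]")
  }
  if (binding > 0 && (efficiency < 0.10 || efficiency > 0.80)) {
    abort_input("simulated efficiency must lie in [0.10, 0.80] when binding > 0")
  }
  # with binding = 0 the efficiency has no effect on the model
  invisible(TRUE)
}

#' Simulate a TCSPC histogram
#'
#' Draws photon counts from the pattern-constrained three-component decay
#' model with shot noise. `sampling = "multinomial"` distributes exactly
#' `n_photons` over the bins; `sampling = "poisson"` draws each bin
#' independently with the model expectation (total varies).
#'
#' @param pattern A `donor_pattern`.
#' @param binding True BINDING fraction in `[0, 1]`.
#' @param efficiency True FRET efficiency; must lie in `[0.10, 0.80]` when
#'   `binding > 0` (the fit model's limits), ignored when `binding = 0`.
#' @param background_fraction Uniform-background photon fraction in `[0, 1)`.
#' @param irf An `irf`.
#' @param grid A `bin_grid`.
#' @param n_photons Expected (poisson) or exact (multinomial) photon total.
#' @param seed Integer seed; the caller's RNG state is preserved.
#' @param sampling `"multinomial"` or `"poisson"`.
#' @return A `tcspc_histogram`.
#' @examples
#' h <- simulate_histogram(default_donor_pattern(), binding = 0.3,
#'                         efficiency = 0.4, n_photons = 1e5, seed = 1)
#' @export
simulate_histogram <- function(pattern = default_donor_pattern(), binding = 0,
                               efficiency = 0, background_fraction = 0,
                               irf = irf_none(), grid = bin_grid(),
                               n_photons = 1e6, seed = NULL,
                               sampling = c("multinomial", "poisson")) {
  sampling <- match.arg(sampling)
  validate_sim_params(binding, efficiency)
  if (!is.finite(n_photons) || n_photons < 1) abort_input("n_photons must be >= 1")
  if (binding == 0) efficiency <- 0
  mu <- expected_counts(pattern, binding, efficiency, background_fraction,
                        irf, grid, total_photons = 1)
  counts <- with_seed(seed, {
    if (sampling == "multinomial") {
      as.integer(rmultinom(1, size = as.integer(n_photons), prob = mu))
    } else {
      rpois(length(mu), lambda = mu * n_photons)
    }
  })
  tcspc_histogram(counts, grid,
                  source = sprintf("simulated B=%.3g E=%.3g bg=%.3g seed=%s",
                                   binding, efficiency, background_fraction,
                                   seed %||% NA))
}

#' Simulate an acceptor-photobleaching pair
#'
#' Acceptor photobleaching abolishes FRET: the post-bleach member of the pair
#' is re-simulated from the same donor pattern and photon budget with
#' `binding = 0`, using a fresh seed derived from the pair seed.
#'
#' @inheritParams simulate_histogram
#' @return A list with elements `before` and `after` (both `tcspc_histogram`).
#' @export
simulate_bleach_pair <- function(pattern = default_donor_pattern(),
                                 binding, efficiency = 0.4,
                                 background_fraction = 0, irf = irf_none(),
                                 grid = bin_grid(), n_photons = 1e6,
                                 seed = NULL,
                                 sampling = c("multinomial", "poisson")) {
  sampling <- match.arg(sampling)
  if (!is.finite(binding) || binding <= 0) {
    abort_input("a bleach pair requires binding > 0 before bleaching")
  }
  before <- simulate_histogram(pattern, binding, efficiency,
                               background_fraction, irf, grid, n_photons,
                               seed = seed, sampling = sampling)
  after <- simulate_histogram(pattern, binding = 0, efficiency = 0,
                              background_fraction = background_fraction,
                              irf = irf, grid = grid, n_photons = n_photons,
                              seed = derive_seed(seed %||% 0, 104729),
                              sampling = sampling)
  list(before = before, after = after)
}

#' Describe a synthetic FLIM scene
#'
#' A scene places elliptical nuclei (each with its own BINDING, efficiency and
#' photon density), optional nucleolus carve-outs (a concentric ellipse
#' excluded from analysis, mirroring the convention that nucleoli are excluded
#' from FLIM analysis), optional small plastid-like spots with a short
#' mono-exponential lifetime, and a uniform background photon density.
#'
#' @param image_shape `(rows, cols)` of the image.
#' @param nuclei Data frame with columns `row`, `col` (centre, 1-based),
#'   `r_row`, `r_col` (ellipse radii in pixels), `binding`, `efficiency`,
#'   `density` (expected photons per pixel).
#' @param nucleolus_fraction Fraction of each nucleus radius carved out and
#'   labelled excluded (0 disables carve-outs).
#' @param plastids Optional data frame with columns `row`, `col`, `radius`,
#'   `lifetime_ns`, `density`: short-lifetime spots added on top.
#' @param background_density Expected background photons per pixel (uniform in
#'   time).
#' @return A list of class `flim_scene`.
#' @export
flim_scene <- function(image_shape = c(32L, 32L), nuclei,
                       nucleolus_fraction = 0.25, plastids = NULL,
                       background_density = 0) {
  nuclei <- as_tibble(nuclei)
  need <- c("row", "col", "r_row", "r_col", "binding", "efficiency", "density")
  if (!all(need %in% names(nuclei))) {
    abort_input(paste0("nuclei must have columns: ", paste(need, collapse = ", ")))
  }
  if (nucleolus_fraction < 0 || nucleolus_fraction >= 1) {
    abort_input("nucleolus_fraction must lie in [0, 1)")
  }
  for (i in seq_len(nrow(nuclei))) {
    validate_sim_params(nuclei$binding[i], nuclei$efficiency[i])
    if (nuclei$row[i] - nuclei$r_row[i] < 1 ||
        nuclei$row[i] + nuclei$r_row[i] > image_shape[1] ||
        nuclei$col[i] - nuclei$r_col[i] < 1 ||
        nuclei$col[i] + nuclei$r_col[i] > image_shape[2]) {
      abort_input(paste0("nucleus ", i, " extends outside the image"))
    }
  }
  structure(list(image_shape = as.integer(image_shape), nuclei = nuclei,
                 nucleolus_fraction = nucleolus_fraction,
                 plastids = if (!is.null(plastids)) as_tibble(plastids),
                 background_density = background_density),
            class = "flim_scene")
}

ellipse_pixels <- function(shape, row0, col0, r_row, r_col) {
  rows <- pmax(1L, floor(row0 - r_row)):pmin(shape[1], ceiling(row0 + r_row))
  cols <- pmax(1L, floor(col0 - r_col)):pmin(shape[2], ceiling(col0 + r_col))
  px <- expand.grid(row = rows, col = cols)
  inside <- ((px$row - row0) / r_row)^2 + ((px$col - col0) / r_col)^2 <= 1
  px[inside, , drop = FALSE]
}

#' Simulate a FLIM image stack with ROI mask and ground truth
#'
#' Generates per-pixel time-binned photon counts for a `flim_scene`. The ROI
#' mask labels each nucleus with a distinct positive integer; nucleolus pixels
#' carry the negative of their nucleus label (excluded); background is 0.
#' Per-nucleus seeds are derived from the master seed and the label, so each
#' ROI is independently reproducible.
#'
#' @param scene A `flim_scene`.
#' @param pattern Donor pattern shared by all nuclei.
#' @param irf,grid Acquisition model, as in [simulate_histogram()].
#' @param seed Master seed.
#' @return A list with `image` (a `flim_image`), `mask` (integer matrix,
#'   `roi_mask`), and `truth` (tibble: label, binding, efficiency,
#'   n_photons_total, n_photons_included).
#' @export
simulate_flim_image <- function(scene, pattern = default_donor_pattern(),
                                irf = irf_none(), grid = bin_grid(),
                                seed = NULL) {
  if (!inherits(scene, "flim_scene")) abort_input("`scene` must be a flim_scene")
  shape <- scene$image_shape
  nb <- grid$n_bins
  counts <- array(0L, dim = c(shape[1], shape[2], nb))
  mask <- matrix(0L, shape[1], shape[2])

  # nucleus labels + nucleolus carve-outs, with overlap detection
  for (k in seq_len(nrow(scene$nuclei))) {
    nk <- scene$nuclei[k, ]
    px <- ellipse_pixels(shape, nk$row, nk$col, nk$r_row, nk$r_col)
    idx <- cbind(px$row, px$col)
    if (any(mask[idx] != 0L)) abort_input("nuclei overlap")
    mask[idx] <- k
    if (scene$nucleolus_fraction > 0) {
      nucleolus <- ellipse_pixels(shape, nk$row, nk$col,
                                  nk$r_row * scene$nucleolus_fraction,
                                  nk$r_col * scene$nucleolus_fraction)
      mask[cbind(nucleolus$row, nucleolus$col)] <- -k
    }
  }

  truth <- vector("list", nrow(scene$nuclei))
  for (k in seq_len(nrow(scene$nuclei))) {
    nk <- scene$nuclei[k, ]
    eff <- if (nk$binding > 0) nk$efficiency else 0
    mu <- expected_counts(pattern, nk$binding, eff, 0, irf, grid,
                          total_photons = 1)
    sel <- which(abs(mask) == k, arr.ind = TRUE)
    with_seed(derive_seed(seed %||% 0, k), {
      for (i in seq_len(nrow(sel))) {
        n_i <- rpois(1, nk$density)
        if (n_i > 0) {
          counts[sel[i, 1], sel[i, 2], ] <-
            counts[sel[i, 1], sel[i, 2], ] + as.integer(rmultinom(1, n_i, mu))
        }
      }
    })
    tot_px <- apply(counts, c(1, 2), sum)
    total_k <- sum(tot_px[abs(mask) == k])
    included_k <- sum(tot_px[mask == k])
    truth[[k]] <- tibble(label = k, binding = nk$binding, efficiency = eff,
                         n_photons_total = total_k,
                         n_photons_included = included_k)
  }

  # plastid-like short-lifetime spots (added on top; mask untouched)
  if (!is.null(scene$plastids) && nrow(scene$plastids) > 0) {
    for (j in seq_len(nrow(scene$plastids))) {
      pj <- scene$plastids[j, ]
      spot <- donor_pattern(pj$lifetime_ns, 1)
      mu <- expected_counts(spot, 0, 0, 0, irf, grid, total_photons = 1)
      px <- ellipse_pixels(shape, pj$row, pj$col, pj$radius, pj$radius)
      with_seed(derive_seed(seed %||% 0, 1000L + j), {
        for (i in seq_len(nrow(px))) {
          n_i <- rpois(1, pj$density)
          if (n_i > 0) {
            counts[px$row[i], px$col[i], ] <-
              counts[px$row[i], px$col[i], ] + as.integer(rmultinom(1, n_i, mu))
          }
        }
      })
    }
  }

  # uniform background photons, uniform in time
  if (scene$background_density > 0) {
    with_seed(derive_seed(seed %||% 0, 999983L), {
      n_px <- shape[1] * shape[2]
      bg_tot <- rpois(n_px, scene$background_density)
      for (i in which(bg_tot > 0)) {
        r <- ((i - 1) %% shape[1]) + 1
        c <- ((i - 1) %/% shape[1]) + 1
        counts[r, c, ] <- counts[r, c, ] +
          as.integer(rmultinom(1, bg_tot[i], rep(1, nb)))
      }
    })
  }

  img <- flim_image(counts, grid)
  list(image = img, mask = roi_mask(mask), truth = dplyr::bind_rows(truth))
}
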