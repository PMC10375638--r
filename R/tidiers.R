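#' Tidy an OPA fit into a one-row tibble
#'
#' @param x An `opa_fit`.
#' @param ... Unused.
#' @return One row with `roi_id`, `model`, `binding`, `efficiency`,
#'   `valid_efficiency`, `tau_fret_ns`, `background`, `n_photons`,
#'   `fit_statistic`, `converged`, `hit_bound` (comma-separated),
#'   `acceptor_photons`.
#' @export
tidy.opa_fit <- function(x, ...) {
  tibble(roi_id = x$roi_id, model = x$model, binding = x$binding,
         efficiency = x$efficiency, valid_efficiency = x$valid_efficiency,
         tau_fret_ns = x$tau_fret_ns, background = x$background,
         n_photons = x$n_photons, fit_statistic = x$fit_statistic,
         converged = x$converged,
         hit_bound = paste(x$hit_bound, collapse = ","),
         acceptor_photons = x$acceptor_photons)
}

#' Fit-level diagnostics of an OPA fit
#'
#' @param x An `opa_fit`.
#' @param ... Unused.
#' @return One row with the deviance-based fit statistic, bins used, fit mode
#'   and reference lifetime.
#' @export
glance.opa_fit <- function(x, ...) {
  tibble(fit_statistic = x$fit_statistic, n_bins_used = x$n_bins_used,
         n_photons = x$n_photons, fit_mode = x$fit_mode,
         tau_ref_ns = x$tau_ref_ns, converged = x$converged)
}

#' Tidy a free multi-exponential calibration fit
#'
#' @param x A `calibration_fit`.
#' @param ... Unused.
#' @return One row per component: `term`, `lifetime_ns`, `amplitude`.
#' @export
tidy.calibration_fit <- function(x, ...) {
  dplyr::mutate(x$components,
                term = paste0("component_", dplyr::row_number()),
                .before = 1)
}

#' @rdname tidy.calibration_fit
#' @export
glance.calibration_fit <- function(x, ...) {
  tibble(n_components = x$n_components, background = x$background,
         fit_statistic = x$fit_statistic, n_photons = x$n_photons,
         tau_m_ns = if (all(is.finite(x$components$lifetime_ns)))
           amplitude_weighted_lifetime(x$components) else NA_real_,
         converged = x$converged, fit_mode = x$fit_mode)
}

#' Plot a TCSPC histogram with an optional fitted curve
#'
#' @param hist A `tcspc_histogram`.
#' @param fit Optional `opa_fit` or `calibration_fit` whose fitted expectation
#'   is overlaid (on the bins the fit used).
#' @param log_y Log-scale the count axis (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_decay <- function(hist, fit = NULL, log_y = TRUE) {
  df <- tibble(time_ns = hist$time_ns, counts = hist$counts)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ns, y = .data$counts)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "time (ns)", y = "photon counts")
  if (!is.null(fit) && !is.null(fit$fitted)) {
    fdf <- tibble(time_ns = grid_edges(fit$grid)[seq_len(fit$grid$n_bins)],
                  mu = fit$fitted)
    p <- p + ggplot2::geom_line(data = fdf,
                                ggplot2::aes(x = .data$time_ns, y = .data$mu),
                                colour = "firebrick", linewidth = 0.5)
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p + ggplot2::theme_minimal()
}

#' @export
autoplot.opa_fit <- function(object, ...) {
  df <- tibble(time_ns = grid_edges(object$grid)[seq_len(object$grid$n_bins)],
               counts = object$observed, mu = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ns)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$counts), size = 0.6,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mu), colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ns)", y = "photon counts",
                  title = sprintf("BINDING %.1f%%, E %.1f%%",
                                  100 * object$binding,
                                  100 * object$efficiency)) +
    ggplot2::theme_minimal()
}

#' Strip plot of BINDING and FRET efficiency per sample group
#'
#' Per-ROI BINDING (all results) and FRET efficiency (valid results only) as
#' jittered points per group, with the BINDING cut-off marked by a dashed
#' line.
#'
#' @param data Results data frame with columns `binding`, `efficiency`,
#'   `valid_efficiency` and the grouping column.
#' @param group Grouping column (unquoted).
#' @param cutoff BINDING cut-off to draw (fraction).
#' @return A ggplot object (percent scales, faceted BINDING / efficiency).
#' @export
plot_binding_strip <- function(data, group, cutoff = 0.10) {
  g_quo <- rlang::enquo(group)
  long <- dplyr::bind_rows(
    dplyr::transmute(data, group = as.character(!!g_quo),
                     what = "BINDING [%]", value = 100 * .data$binding),
    data |>
      dplyr::filter(.data$valid_efficiency) |>
      dplyr::transmute(group = as.character(!!g_quo),
                       what = "FRET efficiency [%]",
                       value = 100 * .data$efficiency))
  cut_df <- tibble(what = "BINDING [%]", y = 100 * cutoff)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7, size = 1) +
    ggplot2::geom_hline(data = cut_df, ggplot2::aes(yintercept = .data$y),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::facet_wrap(~what, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Render a fast-lifetime map
#'
#' @param map Matrix from [fast_lifetime_map()].
#' @return A ggplot raster of per-pixel fast lifetimes (ns).
#' @export
plot_fast_lifetime <- function(map) {
  df <- tidyr::expand_grid(row = seq_len(nrow(map)), col = seq_len(ncol(map)))
  df$lifetime_ns <- map[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$lifetime_ns)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20",
                                  name = "fast lifetime (ns)") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
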