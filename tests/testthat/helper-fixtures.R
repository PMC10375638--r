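# Shared fixtures: the reference bi-exponential donor and small helpers.

ref_pattern <- function() donor_pattern(c(3.0, 1.2), c(0.9, 0.1))

ref_grid <- function() bin_grid(0.05, 250L, 0)

# Independent quadrature oracle for the per-bin photon mass of the decay
# density under a Gaussian IRF: direct numerical integration of the
# convolution integral, no shared code with component_bin_mass().
quad_bin_mass_gaussian <- function(tau, center, sigma, grid, n_quad = 2001) {
  edges <- opaflim:::grid_edges(grid)
  conv_density <- function(t) {
    # int_0^Inf exp(-s/tau) * dnorm(t - s, 0, sigma) ds, IRF centred at `center`
    vapply(t, function(ti) {
      integrate(function(s) exp(-s / tau) * dnorm(ti - center - s, 0, sigma),
                lower = 0, upper = ti - center + 8 * sigma + 12 * tau,
                rel.tol = 1e-10, abs.tol = 0)$value
    }, numeric(1))
  }
  vapply(seq_len(grid$n_bins), function(k) {
    integrate(conv_density, edges[k], edges[k + 1], rel.tol = 1e-8,
              abs.tol = 0)$value
  }, numeric(1))
}

# Analytic mean arrival time of the truncated-window mixture model, by
# quadrature over the continuous density (independent of expected_counts).
quad_mean_arrival <- function(pattern, binding, efficiency, bg, grid) {
  t_ref <- sum(pattern$amplitude * pattern$lifetime_ns)
  t_f <- (1 - efficiency) * t_ref
  dens <- function(t) {
    d <- (1 - binding) * colSums(pattern$amplitude *
                                   exp(-outer(1 / pattern$lifetime_ns, t)))
    if (binding != 0) d <- d + binding * exp(-t / t_f)
    d
  }
  t0 <- grid$origin_ns
  t1 <- grid$origin_ns + opaflim:::grid_window_ns(grid)
  z <- integrate(dens, t0, t1, rel.tol = 1e-12)$value
  m_dec <- integrate(function(t) t * dens(t), t0, t1, rel.tol = 1e-12)$value / z
  m_bg <- (t0 + t1) / 2
  (1 - bg) * m_dec + bg * m_bg
}
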