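# The pattern-constrained OPA fit, comparison fits and batching.

test_that("BINDING and efficiency are recovered on a FRET simulation", {
  p <- ref_pattern()
  res <- vapply(1:10, function(s) {
    h <- simulate_histogram(p, 0.30, 0.40, 0.02, n_photons = 1e6, seed = s)
    f <- fit_opa(h, p)
    c(f$binding, f$efficiency)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - 0.30), 0.03)
  expect_lt(abs(mean(res[2, ]) - 0.40), 0.05)
})

test_that("donor-only data yield near-zero BINDING and an invalid efficiency", {
  p <- ref_pattern()
  f <- fit_opa(simulate_histogram(p, 0, background_fraction = 0.02,
                                  n_photons = 5e5, seed = 3), p)
  expect_lt(abs(f$binding), 0.10)
  expect_false(f$valid_efficiency)
  # efficiency is still reported numerically, pinned inside the fit limits
  expect_true(f$efficiency >= 0.10 && f$efficiency <= 0.80)
})

test_that("tau_fret is tied to the fitted efficiency and the pattern reference", {
  p <- ref_pattern()
  h <- simulate_histogram(p, 0.3, 0.4, 0, n_photons = 2e5, seed = 4)
  f <- fit_opa(h, p)
  expect_equal(f$tau_fret_ns, (1 - f$efficiency) * f$tau_ref_ns,
               tolerance = 1e-9)
  expect_equal(f$tau_ref_ns, 2.82)
  f_long <- fit_opa(h, p, options = opa_options(tau_ref = "longest"))
  expect_equal(f_long$tau_ref_ns, 3.0)
})

test_that("cut-off semantics: strictly below excludes, at the boundary is valid", {
  p <- ref_pattern()
  h <- simulate_histogram(p, 0.3, 0.4, 0, n_photons = 1e5, seed = 5)
  f <- fit_opa(h, p)
  f05 <- f; f05$binding <- 0.05
  expect_false(apply_fret_cutoff(f05)$valid_efficiency)
  f10 <- f; f10$binding <- 0.10
  expect_true(apply_fret_cutoff(f10)$valid_efficiency)
  f30 <- f; f30$binding <- 0.30
  expect_true(apply_fret_cutoff(f30)$valid_efficiency)
  expect_error(apply_fret_cutoff(f, cutoff = 1.5), "\\[0, 1\\]")
  # data-frame method
  df <- tibble::tibble(binding = c(0.05, 0.10, 0.30))
  expect_equal(apply_fret_cutoff(df)$valid_efficiency, c(FALSE, TRUE, TRUE))
})

test_that("a true efficiency outside the fit limits pins to the nearest bound", {
  p <- ref_pattern(); g <- ref_grid()
  draw <- function(E, seed) {
    mu <- expected_counts(p, 0.3, E, 0.01, irf_none(), g, 1)
    counts <- opaflim:::with_seed(seed,
                                  as.integer(rmultinom(1, 5e5,
                                                       as.numeric(mu))))
    tcspc_histogram(counts, g)
  }
  f_lo <- fit_opa(draw(0.05, 201), p)
  expect_equal(f_lo$efficiency, 0.10, tolerance = 1e-6)
  expect_true("efficiency" %in% f_lo$hit_bound)
  f_hi <- fit_opa(draw(0.90, 202), p)
  expect_equal(f_hi$efficiency, 0.80, tolerance = 1e-6)
  expect_true("efficiency" %in% f_hi$hit_bound)
})

test_that("the optimiser matches an exhaustive grid search", {
  p <- ref_pattern()
  for (s in 1:3) {
    h <- simulate_histogram(p, 0.25, 0.5, 0, n_photons = 2e5, seed = 300 + s)
    gs <- opa_grid_search(h, p, background = 0, step = 0.005)
    f <- fit_opa(h, p, options = opa_options(bg_max = 1e-9))
    expect_lt(abs(f$binding - gs$binding), 0.01)
    expect_lt(abs(f$efficiency - gs$efficiency), 0.01)
  }
})

test_that("deviance at the fit is no worse than at the generating truth", {
  p <- ref_pattern()
  h <- simulate_histogram(p, 0.3, 0.4, 0.02, n_photons = 5e5, seed = 6)
  f <- fit_opa(h, p)
  fd <- opaflim:::prepare_fit_data(h, NULL)
  model <- opaflim:::make_opa_model(p, fd$irf, fd$grid, "weighted",
                                    total = sum(fd$y))
  dev_truth <- opaflim:::poisson_deviance(fd$y, model(0.3, 0.4, 0.02))
  dev_fit <- f$fit_statistic * max(length(fd$y) - 4L, 1L)
  expect_lte(dev_fit, dev_truth + 1e-6)
})

test_that("mono-donor fits inflate BINDING on bi-exponential donors", {
  p <- ref_pattern()
  deltas <- vapply(1:20, function(s) {
    h <- simulate_histogram(p, 0, background_fraction = 0.02,
                            n_photons = 5e5, seed = 400 + s)
    fit_mono_donor(h, p)$binding - fit_opa(h, p)$binding
  }, numeric(1))
  # the short donor component is misattributed to FRET: inflation towards
  # its amplitude (0.1), essentially always above the OPA estimate
  expect_gt(mean(deltas > 0), 0.9)
  expect_gt(mean(deltas), 0.05)
  # on a truly mono-exponential donor the mono model is unbiased
  mono <- donor_pattern(2.82, 1.0)
  b_mono <- vapply(1:10, function(s) {
    fit_mono_donor(simulate_histogram(mono, 0, n_photons = 5e5,
                                      seed = 500 + s), mono)$binding
  }, numeric(1))
  expect_gt(mean(abs(b_mono) < 0.10), 0.85)
})

test_that("fit_opa with a one-component pattern equals fit_mono_donor", {
  p <- ref_pattern()
  mono <- donor_pattern(max(p$lifetime_ns), 1)
  h <- simulate_histogram(p, 0.2, 0.4, 0, n_photons = 2e5, seed = 8)
  a <- fit_opa(h, mono)
  b <- fit_mono_donor(h, p)
  expect_identical(a$binding, b$binding)
  expect_identical(a$efficiency, b$efficiency)
  expect_identical(a$model, "mono-donor")
  expect_identical(b$model, "mono-donor")
})

test_that("average-lifetime mode recovers tau_m and orders FRET below donor-only", {
  p <- ref_pattern()
  h0 <- simulate_histogram(p, 0, n_photons = 1e6, seed = 9)
  al0 <- fit_average_lifetime(h0, n_components = 2)
  expect_lt(abs(al0$tau_m_ns - 2.82) / 2.82, 0.02)
  taus <- vapply(1:5, function(s) {
    hf <- simulate_histogram(p, 0.3, 0.4, 0, n_photons = 1e6, seed = 600 + s)
    fit_average_lifetime(hf, n_components = 2)$tau_m_ns
  }, numeric(1))
  expect_true(all(taus < al0$tau_m_ns))
  # closed form: amplitude-weighted mean of the generating components
  t_f <- (1 - 0.4) * 2.82
  tau_m_true <- 0.7 * (0.9 * 3.0 + 0.1 * 1.2) + 0.3 * t_f
  expect_lt(abs(mean(taus) - tau_m_true) / tau_m_true, 0.05)
})

test_that("bias and RMSE of the OPA estimates shrink with photon count", {
  p <- ref_pattern()
  levels <- c(1e4, 1e5, 1e6)
  stats <- vapply(seq_along(levels), function(li) {
    est <- vapply(1:12, function(s) {
      h <- simulate_histogram(p, 0.3, 0.4, 0, n_photons = levels[li],
                              seed = 700 + 20 * li + s)
      f <- fit_opa(h, p)
      c(f$binding, f$efficiency)
    }, numeric(2))
    c(rmse_b = sqrt(mean((est[1, ] - 0.3)^2)),
      rmse_e = sqrt(mean((est[2, ] - 0.4)^2)))
  }, numeric(2))
  expect_true(all(diff(stats["rmse_b", ]) < 0))
  expect_true(all(diff(stats["rmse_e", ]) < 0))
})

test_that("batch fitting preserves order and isolates per-ROI failures", {
  p <- ref_pattern()
  hs <- list(
    a = simulate_histogram(p, 0, n_photons = 1e5, seed = 21),
    b = simulate_histogram(p, 0, n_photons = 50, seed = 22),  # too few
    c = simulate_histogram(p, 0.3, 0.4, n_photons = 1e5, seed = 23))
  res <- batch_fit(hs, p)
  expect_equal(res$roi_id, c("a", "b", "c"))
  expect_false(res$converged[2])
  expect_true(all(res$converged[c(1, 3)]))
  expect_true(is.na(res$binding[2]))
  expect_gt(res$binding[3], 0.2)
  expect_error(batch_fit(list(), p), "empty")
})

test_that("tidy and glance expose the fit as tibble rows", {
  p <- ref_pattern()
  f <- fit_opa(simulate_histogram(p, 0.3, 0.4, n_photons = 1e5, seed = 31), p,
               roi_id = "n1", acceptor_photons = 1234L)
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1L)
  expect_equal(td$roi_id, "n1")
  expect_equal(td$acceptor_photons, 1234L)
  gl <- glance(f)
  expect_equal(gl$fit_mode, "tail")
})
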