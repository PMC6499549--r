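test_that("radial average reproduces constant and analytic inputs", {
  g <- tiny_geometry()
  qm <- build_qmap(g, tiny_beam())
  f <- matrix(3.5, g$n_rows, g$n_cols); f[qm$gap] <- NA
  prof <- radial_average(f, qm, n_bins = 32)
  expect_true(all(abs(prof$mean - 3.5) < 1e-12))
  expect_true(all(diff(prof$q) > 0))
  # noiseless sphere pattern: profile equals the model within discretization
  g2 <- detector_geometry(259, 3.3, panel_rows = 256, panel_cols = 512)
  qm2 <- build_qmap(g2, tiny_beam())
  truth <- sphere_intensity(qm2$q, 30, 5)
  truth[qm2$gap] <- NA
  prof2 <- radial_average(truth, qm2, n_bins = 256)
  model <- sphere_intensity(prof2$q, 30, 5)
  keep <- model > 1e-3 * max(model)
  expect_lt(max(abs(prof2$mean[keep] - model[keep]) / model[keep]), 0.01)
  # all-masked input errors
  fa <- matrix(NA_real_, g$n_rows, g$n_cols)
  expect_error(radial_average(fa, qm), "masked")
})

test_that("2D sphere fit recovers diameter, intensity and offset", {
  beam <- tiny_beam()
  g <- detector_geometry(370, 5.5, panel_rows = 256, panel_cols = 512)
  qm <- build_qmap(g, beam)
  i0 <- forward_scale(beam, particle_model("sphere", 100), g)
  noiseless <- sphere_intensity(qm$q, 100, i0)
  noiseless[qm$gap] <- NA
  # unbinned fit: the model is exact, so diameter, i0 and offset are sharp
  fit <- fit_sphere_2d(noiseless, qm, bin_factor = 1, floor = 0,
                       d_range = c(40, 200), beam = beam, geometry = g)
  expect_true(fit$converged)
  expect_lt(abs(fit$diameter_nm - 100), 0.5)
  expect_lt(abs(fit$offset), 1e-3)
  expect_equal(fit$i0, i0, tolerance = 0.02)
  # uniform background is absorbed by the offset, diameter unchanged
  withbg <- noiseless + 0.05
  fit2 <- fit_sphere_2d(withbg, qm, bin_factor = 1, floor = 0,
                        d_range = c(40, 200))
  expect_lt(abs(fit2$offset - 0.05), 0.01)
  expect_lt(abs(fit2$diameter_nm - 100) / 100, 0.01)
  # binned fit: same diameter within 0.5%; the per-bin mean-q model leaves
  # only a small residual offset
  fitb <- fit_sphere_2d(noiseless, qm, bin_factor = 4, floor = 0,
                        d_range = c(40, 200))
  expect_lt(abs(fitb$diameter_nm - 100) / 100, 0.005)
  expect_lt(abs(fitb$offset), 0.1)
  # pure noise is flagged, not silently returned
  set.seed(40)
  noise <- matrix(rpois(g$n_rows * g$n_cols, 0.05), g$n_rows, g$n_cols)
  noise[qm$gap] <- NA
  fit3 <- fit_sphere_2d(noise, qm, bin_factor = 4, d_range = c(40, 200))
  expect_false(fit3$converged)
})

test_that("binning barely moves the fitted diameter at high SNR", {
  beam <- tiny_beam()
  g <- detector_geometry(259, 3.3, panel_rows = 256, panel_cols = 512)
  qm <- build_qmap(g, beam)
  i0 <- 50
  pattern <- sphere_intensity(qm$q, 35, i0)
  pattern[qm$gap] <- NA
  f1 <- fit_sphere_2d(pattern, qm, bin_factor = 1, d_range = c(12, 80))
  f6 <- fit_sphere_2d(pattern, qm, bin_factor = 6, d_range = c(12, 80))
  expect_lt(abs(f6$diameter_nm - f1$diameter_nm) / f1$diameter_nm, 0.01)
})

test_that("first minimum of the fitted model matches the data", {
  beam <- tiny_beam()
  g <- detector_geometry(259, 3.3, panel_rows = 256, panel_cols = 512)
  qm <- build_qmap(g, beam)
  d_true <- 42
  pattern <- sphere_intensity(qm$q, d_true, 20)
  pattern[qm$gap] <- NA
  prof <- radial_average(pattern, qm, n_bins = 256)
  fit <- fit_sphere_radial(prof, d_range = c(12, 80))
  dq <- diff(prof$q[1:2])
  qmin_data <- 2 * 4.493409 / d_true
  qmin_fit <- 2 * 4.493409 / fit$diameter_nm
  expect_lt(abs(qmin_fit - qmin_data), dq)
})

test_that("radial sphere fit: recovery, homogeneity, Monte-Carlo coverage", {
  beam <- tiny_beam()
  g <- detector_geometry(130, 3.3, panel_rows = 256, panel_cols = 512)
  qm <- build_qmap(g, beam)
  pattern <- sphere_intensity(qm$q, 20, 8)
  pattern[qm$gap] <- NA
  prof <- radial_average(pattern, qm, n_bins = 256)
  fit <- fit_sphere_radial(prof, d_range = c(5, 100))
  expect_lt(abs(fit$diameter_nm - 20), 0.2)
  # scaling the profile scales i0, not the diameter
  prof_k <- prof; prof_k$mean <- prof$mean * 3
  fit_k <- fit_sphere_radial(prof_k, d_range = c(5, 100))
  expect_equal(fit_k$diameter_nm, fit$diameter_nm, tolerance = 1e-6)
  expect_equal(fit_k$i0, 3 * fit$i0, tolerance = 1e-6)
  # Poisson-noised profiles at the paper fluence: within 10% in >= 90/100
  i0 <- forward_scale(beam, particle_model("sphere", 17), g)
  truth <- sphere_intensity(qm$q, 17, i0)
  sel <- !qm$gap
  set.seed(50)
  hits <- 0
  for (trial in 1:100) {
    noisy <- matrix(NA_real_, g$n_rows, g$n_cols)
    noisy[sel] <- rpois(sum(sel), truth[sel])
    p <- radial_average(noisy, qm, n_bins = 128)
    ft <- fit_sphere_radial(p, d_range = c(5, 100))
    if (abs(ft$diameter_nm - 17) / 17 < 0.10) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("sizing has no systematic bias across the size range", {
  beam <- tiny_beam()
  g <- detector_geometry(259, 3.3, panel_rows = 128, panel_cols = 256)
  qm <- build_qmap(g, beam)
  sel <- !qm$gap
  set.seed(60)
  n <- 150
  d_true <- runif(n, 25, 45)
  err <- numeric(n)
  for (i in seq_len(n)) {
    i0 <- forward_scale(beam, particle_model("sphere", d_true[i]), g)
    lam <- sphere_intensity(qm$q, d_true[i], i0)
    f <- matrix(NA_real_, g$n_rows, g$n_cols)
    f[sel] <- rpois(sum(sel), lam[sel])
    fit <- fit_sphere_2d(f, qm, bin_factor = 2, d_range = c(12, 80))
    err[i] <- (fit$diameter_nm - d_true[i]) / d_true[i]
  }
  expect_lt(abs(mean(err)), 0.02)
})

test_that("fluence plausibility gate is inclusive at the peak", {
  beam <- tiny_beam()
  g <- detector_geometry(259, 3.3, panel_rows = 256, panel_cols = 512)
  qm <- build_qmap(g, beam)
  mkfit <- function(factor) {
    i0 <- forward_scale(beam, particle_model("sphere", 35), g) * factor
    pattern <- sphere_intensity(qm$q, 35, i0)
    pattern[qm$gap] <- NA
    fit_sphere_2d(pattern, qm, bin_factor = 6, d_range = c(12, 80),
                  beam = beam, geometry = g)
  }
  # noiseless fit at exactly the peak fluence: accepted (boundary inclusive)
  expect_true(as.logical(validate_fluence(mkfit(1), beam, g)))
  # ten times the peak: rejected
  expect_false(as.logical(validate_fluence(mkfit(10), beam, g)))
  # per-shot jitter within the focus range: all accepted
  for (factor in c(0.3, 0.5, 0.8, 1.0))
    expect_true(as.logical(validate_fluence(mkfit(factor), beam, g)))
})

test_that("distribution stats: median and KDE-based FWHM", {
  # all diameters equal: FWHM collapses to 0
  s0 <- size_distribution_stats(rep(90, 25))
  expect_equal(s0$summary$median_nm, 90)
  expect_equal(s0$summary$fwhm_nm, 0)
  # Gaussian sample: FWHM ~ 2.355 sigma
  set.seed(70)
  d <- rnorm(5000, 90, 5.52)
  s <- size_distribution_stats(d)
  expect_lt(abs(s$summary$median_nm - 90), 0.5)
  expect_lt(abs(s$summary$fwhm_nm - 2.3548 * 5.52) / (2.3548 * 5.52), 0.05)
  # median shifts with a constant offset
  s2 <- size_distribution_stats(d + 7)
  expect_equal(s2$summary$median_nm, s$summary$median_nm + 7,
               tolerance = 1e-9)
  expect_error(size_distribution_stats(rnorm(5)), "at least 10")
})

test_that("sphere_fit exposes the standard modelling methods", {
  beam <- tiny_beam()
  g <- detector_geometry(259, 3.3, panel_rows = 128, panel_cols = 256)
  qm <- build_qmap(g, beam)
  pattern <- sphere_intensity(qm$q, 35, 10) + 0.01
  pattern[qm$gap] <- NA
  fit <- fit_sphere_2d(pattern, qm, bin_factor = 2, d_range = c(12, 80),
                       beam = beam, geometry = g)
  expect_named(coef(fit), c("diameter_nm", "i0", "offset"))
  expect_equal(predict(fit, 0), fit$i0 + fit$offset)
  expect_lt(mean(abs(residuals(fit))), 0.5)
  expect_output(print(fit), "diameter")
  expect_s3_class(summary(fit), "summary.sphere_fit")
})
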