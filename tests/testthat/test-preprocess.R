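test_that("pedestal subtraction removes the dark mean", {
  g <- tiny_geometry()
  ped <- make_pedestal(g, base_adu = 100, sd_adu = 0, seed = 1)
  raw <- ped + 0
  expect_true(all(abs(pedestal_subtract(raw, list(ped, ped))) < 1e-12))
  expect_true(all(abs(pedestal_subtract(raw + 7, ped) - 7) < 1e-12))
  expect_error(pedestal_subtract(raw, matrix(0, 2, 2)), "shape mismatch")
  # estimated pedestal from simulated darks leaves a small residual
  bg <- background_model(pedestal_adu = make_pedestal(g, seed = 4),
                         dark_noise_adu = 2)
  darks <- simulate_dark_stack(20, g, bg, seed = 6)
  res <- pedestal_subtract(bg$pedestal_adu, darks)
  expect_lt(mean(abs(res), na.rm = TRUE), 0.1 * 20) # ADU; sd 2/sqrt(20)
  expect_lt(abs(mean(res, na.rm = TRUE)), 0.1)
})

test_that("common-mode correction recovers injected offsets exactly", {
  g <- tiny_geometry()
  gp <- gap_mask(g)
  zero <- matrix(0, g$n_rows, g$n_cols); zero[gp] <- NA
  # all-zero frame unchanged
  out <- common_mode_correct(zero, g)
  expect_true(all(out[!gp] == 0))
  # quadrant offset removed exactly
  f <- zero
  qd <- panel_quadrants(g)
  f[qd[[2]]$rows, qd[[2]]$cols] <- 0.2
  out <- common_mode_correct(f, g)
  expect_lt(max(abs(out[!gp])), 1e-12)
  # row and column offsets removed exactly
  f <- zero
  f[5, ] <- f[5, ] + 0.3
  f[, 17] <- f[, 17] + 0.25
  out <- common_mode_correct(f, g)
  expect_lt(max(abs(out[!gp])), 1e-12)
  # a quadrant with every pixel >= 0.5 photons is left unchanged
  f <- zero
  f[qd[[1]]$rows, qd[[1]]$cols] <- 0.7
  out <- common_mode_correct(f, g)
  expect_equal(out[qd[[1]]$rows, qd[[1]]$cols],
               f[qd[[1]]$rows, qd[[1]]$cols])
  expect_gt(attr(out, "empty_groups"), 0)
})

test_that("ASIC rescale multiplies exactly the listed regions", {
  g <- tiny_geometry()
  f <- matrix(1, g$n_rows, g$n_cols)
  a <- list(rows = 1:8, cols = 1:16)
  expect_equal(asic_rescale(f, list(a), 1), f)
  out <- asic_rescale(f, list(a), 2)
  expect_true(all(out[a$rows, a$cols] == 2))
  out[a$rows, a$cols] <- 1
  expect_true(all(out == 1))
  # round trip
  back <- asic_rescale(asic_rescale(f, list(a), 2), list(a), 0.5)
  expect_equal(back, f, tolerance = 1e-12)
  expect_error(
    asic_rescale(f, list(a, list(rows = 5:10, cols = 10:20)), 2),
    "overlapping")
})

test_that("hit finder applies the strict count and radius gates", {
  g <- detector_geometry(259, 3.3, panel_rows = 256, panel_cols = 512)
  qm <- build_qmap(g, tiny_beam())
  f <- matrix(0, g$n_rows, g$n_cols); f[qm$gap] <- NA
  h <- find_hits(f, qm)
  expect_false(h$is_hit); expect_equal(h$lit_count, 0)
  # exactly 3500 qualifying pixels: not a hit; 3501: hit
  far <- which(qm$r_px > 200 & !qm$gap)
  f[far[1:3500]] <- 1.0
  h <- find_hits(f, qm)
  expect_equal(h$lit_count, 3500)
  expect_false(h$is_hit)
  f[far[3501]] <- 1.0
  h <- find_hits(f, qm)
  expect_true(h$is_hit)
  # lit pixels inside the radius never count
  f2 <- matrix(0, g$n_rows, g$n_cols); f2[qm$gap] <- NA
  near <- which(qm$r_px <= 200 & !qm$gap)
  f2[near[1:5000]] <- 2.0
  h2 <- find_hits(f2, qm)
  expect_false(h2$is_hit); expect_equal(h2$lit_count, 0)
  # masked pixels are excluded from counting
  m <- pixel_mask(g)
  m <- mask_pixels(m, cbind(row(f)[far[1:3501]], col(f)[far[1:3501]]),
                   reason = "hot")
  f[far[1:3501]] <- 1.0
  expect_equal(find_hits(f, qm, m)$lit_count, 0)
})

test_that("hit finder is monotone in pixel values", {
  g <- detector_geometry(259, 3.3, panel_rows = 256, panel_cols = 512)
  qm <- build_qmap(g, tiny_beam())
  set.seed(2)
  f <- matrix(rpois(g$n_rows * g$n_cols, 0.02), g$n_rows, g$n_cols)
  f[qm$gap] <- NA
  base <- find_hits(f, qm)
  idx <- which(!qm$gap)
  bump <- sample(idx, 200)
  f2 <- f; f2[bump] <- f2[bump] + 5
  raised <- find_hits(f2, qm)
  expect_gte(raised$lit_count, base$lit_count)
  if (base$is_hit) expect_true(raised$is_hit)
})

test_that("truncate-and-bin sums unmasked pixels after flooring", {
  g <- tiny_geometry(panel_rows = 16, panel_cols = 32)
  f <- matrix(2, g$n_rows, g$n_cols)
  gp <- gap_mask(g); f[gp] <- NA
  b <- truncate_and_bin(f, 4, floor = 0.5)
  full <- b$n_pixels == 16
  expect_true(all(b$values[full] == 32))  # 16 pixels x 2 photons
  # flooring zeroes sub-threshold values before summation
  f2 <- f; f2[!gp] <- 0.4
  b2 <- truncate_and_bin(f2, 4, floor = 0.5)
  expect_true(all(b2$values == 0))
  # mask bookkeeping
  m <- pixel_mask(g)
  m <- mask_pixels(m, cbind(1:4, 1:4), reason = "hot")
  b3 <- truncate_and_bin(f, 4, mask = m)
  expect_equal(sum(b3$n_pixels), sum(!m$bad))
  expect_error(truncate_and_bin(f, 0), ">= 1")
})

test_that("binned q-map averages q over the surviving pixels", {
  g <- tiny_geometry()
  qm <- build_qmap(g, tiny_beam())
  bq <- bin_qmap(qm, 4)
  expect_equal(dim(bq$q), c(ceiling(g$n_rows / 4), ceiling(g$n_cols / 4)))
  # a fully unmasked bin carries the mean q of its pixels
  expect_equal(bq$q[1, 1], mean(qm$q[1:4, 1:4]), tolerance = 1e-12)
  # bins fully inside the gap are NA
  gap_bin_rows <- which(apply(bq$n_pixels, 1, max) == 0)
  expect_gt(length(gap_bin_rows), 0)
  expect_true(all(is.na(bq$q[gap_bin_rows, ])))
})

test_that("Poisson good-pixel test accepts Poisson pixels, rejects others", {
  g <- tiny_geometry(panel_rows = 24, panel_cols = 48)
  n_frames <- 400
  set.seed(14)
  stack <- lapply(seq_len(n_frames), function(i) {
    f <- matrix(rpois(g$n_rows * g$n_cols, 0.5), g$n_rows, g$n_cols)
    f[1, 1] <- 0.25                       # constant: zero variance
    f[2, 2] <- 5 * rpois(1, 0.5)          # 5x overdispersed
    f
  })
  m <- poisson_good_pixel_mask(stack, g, tol = 0.3)
  gp <- gap_mask(g)
  accept <- 1 - sum(m$bad & !gp) / sum(!gp)
  expect_gt(accept, 0.95)
  expect_true(m$bad[1, 1])
  expect_true(m$bad[2, 2])
  expect_equal(m$reason[2, 2], m$codes[["non_poisson"]])
  expect_error(poisson_good_pixel_mask(stack[1], g), "at least two")
})

test_that("weak-scatterer preprocessing rounds half-up after flooring", {
  g <- tiny_geometry(panel_rows = 16, panel_cols = 32)
  z <- matrix(0, g$n_rows, g$n_cols)
  zb <- truncate_and_bin(z, 1)$values * 0
  expect_true(all(rubisco_preprocess(z, zb, g, bin_factor = 1) == 0))
  # thresholds at bin factor 1: 0.49 -> 0; 0.5 -> 1; 1.49 -> 1
  f <- z; f[1, 1] <- 0.49; f[1, 2] <- 0.5; f[1, 3] <- 1.49
  out <- rubisco_preprocess(f, zb, g, bin_factor = 1)
  expect_equal(out[1, 1:3], c(0, 1, 1))
  # median frame equal to the signal frame gives zero
  f2 <- z; f2[2, ] <- 3
  med <- rubisco_preprocess(f2, zb, g, bin_factor = 1)
  expect_true(all(rubisco_preprocess(f2, med, g, bin_factor = 1) == 0))
  expect_error(rubisco_preprocess(f, matrix(0, 2, 2), g, bin_factor = 1),
               "shape mismatch")
})

test_that("simulate + preprocess round trip is unbiased", {
  # with known pedestal and common-mode injected, calibration recovers the
  # photon expectations without bias
  g <- tiny_geometry(panel_rows = 32, panel_cols = 64)
  beam <- tiny_beam()
  bg <- background_model(pedestal_adu = make_pedestal(g, seed = 3),
                         gas_rate = 0.05, dark_noise_adu = 2,
                         cm_quadrant_sd = 0.05, cm_row_sd = 0.02,
                         cm_col_sd = 0.02)
  qm <- build_qmap(g, beam)
  darks <- simulate_dark_stack(50, g, bg, seed = 5)
  ped <- Reduce(`+`, darks) / length(darks)
  n_frames <- 400
  set.seed(31)
  seeds <- sample.int(1e7, n_frames)
  acc <- 0
  for (i in seq_len(n_frames)) {
    fr <- simulate_frame(NULL, beam, g, bg, qm, rng_seed = seeds[i])
    cal <- calibrate_frame(fr$raw, ped, bg$gain_adu_per_photon, g)
    acc <- acc + mean(cal$photons - 0.05, na.rm = TRUE)
  }
  expect_lt(abs(acc / n_frames), 0.01)
})

test_that("the calibration chain is deterministic and logged", {
  g <- tiny_geometry()
  beam <- tiny_beam()
  bg <- background_model(pedestal_adu = make_pedestal(g, seed = 8))
  qm <- build_qmap(g, beam)
  fr <- simulate_frame(particle_model("sphere", 40), beam, g, bg, qm,
                       rng_seed = 77)
  ped <- bg$pedestal_adu
  c1 <- calibrate_frame(fr$raw, ped, bg$gain_adu_per_photon, g,
                        asic_list = list(list(rows = 1:4, cols = 1:4)))
  c2 <- calibrate_frame(fr$raw, ped, bg$gain_adu_per_photon, g,
                        asic_list = list(list(rows = 1:4, cols = 1:4)))
  expect_identical(c1$photons, c2$photons)
  expect_gte(length(c1$log), 4)
  expect_match(c1$log[1], "pedestal")
  expect_match(c1$log[3], "common mode")
})
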