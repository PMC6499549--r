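test_that("support projection is idempotent and zero-support gives zero", {
  set.seed(80)
  x <- matrix(rnorm(32 * 32), 32, 32)
  s <- support_disk(32, 7)
  p1 <- espraydiff:::.proj_support(x, s)
  expect_identical(espraydiff:::.proj_support(p1, s), p1)
  expect_true(all(p1[!s] == 0))
  expect_true(all(p1[s] >= 0))
  z <- espraydiff:::.proj_support(x, matrix(FALSE, 32, 32))
  expect_true(all(z == 0))
})

test_that("a consistent object is a fixed point of all three updates", {
  set.seed(81)
  n <- 32
  s <- support_disk(n, 6)
  obj <- matrix(0, n, n)
  obj[s] <- runif(sum(s), 0.2, 1)
  A <- Mod(fft(obj))
  M <- matrix(TRUE, n, n)
  sup <- support_disk(n, 8)
  for (stepper in list(function(x) er_step(x, A, M, sup),
                       function(x) hio_step(x, A, M, sup),
                       function(x) raar_step(x, A, M, sup))) {
    out <- stepper(obj)
    expect_lt(max(abs(out - obj)), 1e-10)
  }
})

test_that("unmeasured pixels are left unconstrained", {
  set.seed(82)
  n <- 32
  s <- support_disk(n, 6)
  obj <- matrix(0, n, n); obj[s] <- runif(sum(s), 0.2, 1)
  A <- Mod(fft(obj))
  M <- matrix(TRUE, n, n)
  M[1:8, 1:8] <- FALSE           # masked corner
  A2 <- A; A2[1:8, 1:8] <- 999   # absurd values where not measured
  x <- matrix(rnorm(n * n), n, n)
  expect_equal(er_step(x, A, M, s), er_step(x, A2, M, s),
               tolerance = 1e-12)
})

test_that("ER Fourier error is non-increasing on noiseless data", {
  set.seed(83)
  n <- 32
  s <- support_disk(n, 6)
  obj <- matrix(0, n, n); obj[s] <- runif(sum(s), 0.2, 1)
  A <- Mod(fft(obj))
  M <- matrix(TRUE, n, n)
  sup <- support_disk(n, 8)
  x <- matrix(runif(n * n), n, n)
  errs <- numeric(100)
  for (i in 1:100) {
    x <- er_step(x, A, M, sup)
    errs[i] <- fourier_error(x, A, M)
  }
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("HIO reduces the Fourier error on average over 50 iterations", {
  set.seed(84)
  n <- 32
  s <- support_disk(n, 6)
  obj <- matrix(0, n, n); obj[s] <- runif(sum(s), 0.2, 1)
  A <- Mod(fft(obj))
  M <- matrix(TRUE, n, n)
  sup <- support_disk(n, 8)
  x <- Re(fft(A * exp(1i * matrix(runif(n * n, -pi, pi), n, n)),
              inverse = TRUE)) / (n * n)
  errs <- numeric(51)
  errs[1] <- fourier_error(x, A, M)
  for (i in 1:50) {
    x <- hio_step(x, A, M, sup)
    errs[i + 1] <- fourier_error(x, A, M)
  }
  # trend, not per-step monotonicity
  expect_lt(mean(errs[42:51]), mean(errs[1:10]))
})

test_that("RAAR stays bounded across the beta range", {
  set.seed(85)
  n <- 32
  s <- support_disk(n, 6)
  obj <- matrix(0, n, n); obj[s] <- runif(sum(s), 0.2, 1)
  A <- Mod(fft(obj))
  M <- matrix(TRUE, n, n)
  sup <- support_disk(n, 8)
  for (beta in c(0.5, 0.87, 0.99)) {
    x <- matrix(runif(n * n), n, n)
    for (i in 1:1000) x <- raar_step(x, A, M, sup, beta)
    expect_true(all(is.finite(x)))
    expect_lt(max(abs(x)), 100 * max(obj))
  }
})

test_that("HIO and RAAR pipelines both solve the noiseless toy", {
  n <- 64
  obj <- notched_disk(n, radius = 12)
  A <- Mod(fft(obj))
  prob <- phasing_problem(A, support_radius_px = 15)
  for (alg in c("hio", "raar")) {
    res <- run_reconstruction(prob, alg, n_main = 400, n_er = 300,
                              n_repeats = 4, seed = 17, error_cut = 3)
    expect_gt(recon_correlation(res$average, obj), 0.95)
  }
})

test_that("Fourier error agrees with its real-space counterpart (Parseval)", {
  set.seed(86)
  n <- 32
  obj <- matrix(0, n, n); obj[support_disk(n, 6)] <- runif(sum(support_disk(n, 6)))
  A <- Mod(fft(obj))
  M <- matrix(TRUE, n, n)
  x <- matrix(rnorm(n * n), n, n)
  ef <- fourier_error(x, A, M)
  y <- espraydiff:::.proj_modulus(x, A, M)
  # || x - P_M x ||_2 * sqrt(N) equals the Fourier-domain distance
  er <- sqrt(sum((x - y)^2) * n * n) / sqrt(sum(A^2))
  expect_equal(ef, er, tolerance = 1e-9)
})

test_that("reconstruction averaging contracts are honored", {
  n <- 64
  obj <- notched_disk(n, radius = 12)
  prob <- phasing_problem(Mod(fft(obj)), support_radius_px = 15)
  # a single repeat averages to itself
  res1 <- run_reconstruction(prob, "hio", n_main = 150, n_er = 100,
                             n_repeats = 1, seed = 3)
  expect_identical(res1$average, res1$repeats[[1]])
  expect_error(prtf(res1), "at least two")
  # identical seeds give identical results
  resa <- run_reconstruction(prob, "raar", n_main = 100, n_er = 50,
                             n_repeats = 2, seed = 5)
  resb <- run_reconstruction(prob, "raar", n_main = 100, n_er = 50,
                             n_repeats = 2, seed = 5)
  expect_identical(resa$average, resb$average)
  expect_identical(resa$fourier_errors, resb$fourier_errors)
})

test_that("phasing problem validates oversampling and support", {
  A <- matrix(1, 32, 32)
  expect_error(phasing_problem(A, support = matrix(FALSE, 32, 32)), "empty")
  expect_error(phasing_problem(A, support = matrix(TRUE, 32, 32)),
               "oversampling")
  expect_error(phasing_problem(-A, support_radius_px = 5), ">= 0")
  expect_error(phasing_problem(matrix(1, 16, 32), support_radius_px = 5),
               "square")
})

test_that("PRTF: identical repeats give 1, random phases give ~n^(-1/2)", {
  n <- 64
  obj <- notched_disk(n, radius = 12)
  prob <- phasing_problem(Mod(fft(obj)), support_radius_px = 15)
  res <- run_reconstruction(prob, "hio", n_main = 60, n_er = 40,
                            n_repeats = 2, seed = 6)
  fake <- res
  fake$repeats <- list(obj, obj, obj)
  pr <- prtf(fake)
  expect_true(all(abs(pr$prtf - 1) < 1e-9))
  expect_equal(pr$threshold, exp(-1))
  # independent random phases: PRTF per bin ~ sqrt(pi)/2 / sqrt(n_repeats)
  set.seed(87)
  A <- Mod(fft(obj))
  n_rep <- 100
  fake$repeats <- lapply(seq_len(n_rep), function(i)
    Re(fft(A * exp(1i * matrix(runif(n * n, -pi, pi), n, n)),
           inverse = TRUE)) / (n * n))
  pr2 <- prtf(fake)
  expected <- sqrt(pi) / 2 / sqrt(n_rep)
  # each bin within 3 standard errors of the Rayleigh mean
  se <- sqrt((4 - pi) / 4 / n_rep) / sqrt(pr2$n)
  expect_true(all(abs(pr2$prtf - expected) < 3 * se + 0.01))
  # and compatible with the coarser n^(-1/2) yardstick
  expect_lt(abs(mean(pr2$prtf) - 1 / sqrt(n_rep)), 0.03)
})

test_that("reproducible phasing of icosahedral projections at realistic counts", {
  # carboxysome-like icosahedron projection, photon-limited; PRTF should
  # stay above 1/e to at least half the q-range in most seeded trials
  pat <- icosahedron_pattern(90, 0.43, n_vox = 32, pad = 2)
  m <- length(pat$q_axis)
  # photons scaled so the central speckle carries ~2e3 photons/pixel
  scale <- 2e3 / max(pat$F2)
  ok <- 0
  n_trials <- 5
  for (trial in seq_len(n_trials)) {
    set.seed(900 + trial)
    photons <- matrix(rpois(m * m, pat$F2 * scale), m, m)
    # back to unshifted layout for the DFT convention
    shift_back <- function(x) {
      h <- nrow(x) / 2
      x[c((h + 1):nrow(x), 1:h), c((h + 1):ncol(x), 1:h)]
    }
    A <- sqrt(shift_back(photons))
    prob <- phasing_problem(A, support_radius_px = 11)
    res <- run_reconstruction(prob, "raar", n_main = 250, n_er = 150,
                              n_repeats = 4, seed = 900 + trial)
    pr <- prtf(res)
    if (pr$resolution_q >= 0.5 * max(pr$q)) ok <- ok + 1
  }
  expect_gte(ok, 0.8 * n_trials)
})
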