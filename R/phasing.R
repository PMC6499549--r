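# 2D image reconstruction from oversampled diffraction patterns by
# iterative projection algorithms (HIO, RAAR, ER) with a static support,
# realness and positivity constraints, reconstruction averaging, and PRTF
# reproducibility scoring.
#
# Conventions: Fourier amplitudes are stored in unshifted DFT layout (DC at
# [1,1]); real-space iterates are real matrices; the support is a centered
# disk. Unmeasured pixels (gap, mask, truncated-to-zero) are left
# unconstrained by the modulus projection.

#' Centered disk support mask
#' @param n grid edge length.
#' @param radius_px disk radius in pixels.
#' @return logical n x n matrix.
#' @export
support_disk <- function(n, radius_px) {
  c0 <- (n + 1) / 2
  idx <- seq_len(n) - c0
  outer(idx^2, idx^2, `+`) <= radius_px^2
}

#' Phasing problem: amplitudes, measured-pixel mask, support
#'
#' @param amplitudes nonnegative Fourier-magnitude matrix (unshifted DFT
#'   layout, i.e. \code{sqrt} of a fftshifted-back binned pattern).
#' @param measured logical matrix: which Fourier pixels carry data
#'   (default: all).
#' @param support logical real-space support mask, or NULL to build a
#'   centered disk of \code{support_radius_px}.
#' @param support_radius_px disk radius when \code{support} is NULL.
#' @return object of class \code{phasing_problem}.
#' @export
phasing_problem <- function(amplitudes, measured = NULL, support = NULL,
                            support_radius_px = NULL) {
  if (any(amplitudes < 0, na.rm = TRUE)) stop("amplitudes must be >= 0")
  n <- nrow(amplitudes)
  if (ncol(amplitudes) != n) stop("amplitude grid must be square")
  if (is.null(measured)) measured <- !is.na(amplitudes)
  measured <- measured & !is.na(amplitudes)
  amplitudes[!measured] <- 0
  if (is.null(support)) {
    if (is.null(support_radius_px)) stop("need support or support_radius_px")
    support <- support_disk(n, support_radius_px)
  }
  if (!any(support)) stop("support is empty")
  if (sum(support) >= length(support) / 2)
    stop("support covers half the grid or more: no oversampling")
  structure(list(amplitudes = amplitudes, measured = measured,
                 support = support, n = n),
            class = "phasing_problem")
}

# modulus projection: impose measured amplitudes, keep unmeasured pixels
.proj_modulus <- function(x, amplitudes, measured) {
  X <- stats::fft(x)
  mag <- Mod(X)
  phase_ok <- mag > 1e-300
  scale <- matrix(1, nrow(X), ncol(X))
  scale[measured & phase_ok] <-
    amplitudes[measured & phase_ok] / mag[measured & phase_ok]
  X <- X * scale
  # zero-magnitude measured pixels get the amplitude with zero phase
  z <- measured & !phase_ok
  if (any(z)) X[z] <- amplitudes[z]
  Re(stats::fft(X, inverse = TRUE)) / length(x)
}

# support projection: real, positive inside support, zero outside
.proj_support <- function(x, support) {
  x[!support | x < 0] <- 0
  x
}

#' One error-reduction (ER) iteration
#'
#' Modulus projection followed by the support projection (realness and
#' positivity inside the support, zero outside). The Fourier error is
#' non-increasing in exact arithmetic.
#'
#' @param x real-space iterate (real matrix).
#' @param amplitudes,measured,support problem components
#'   (see \code{\link{phasing_problem}}).
#' @return updated iterate.
#' @export
er_step <- function(x, amplitudes, measured, support) {
  .proj_support(.proj_modulus(x, amplitudes, measured), support)
}

#' One hybrid input-output (HIO) iteration
#'
#' Fourier-modulus projection on measured pixels, then the HIO real-space
#' update: pixels satisfying the constraints (inside the support with a
#' nonnegative value) take the projected value; all others take
#' \code{x - beta * projected}.
#'
#' @inheritParams er_step
#' @param beta feedback parameter (default 0.9).
#' @return updated iterate.
#' @export
hio_step <- function(x, amplitudes, measured, support, beta = 0.9) {
  xm <- .proj_modulus(x, amplitudes, measured)
  ok <- support & xm >= 0
  out <- x - beta * xm
  out[ok] <- xm[ok]
  out
}

#' One relaxed averaged alternating reflections (RAAR) iteration
#'
#' x <- beta/2 * (R_S R_M + I) x + (1 - beta) * P_M x, with P the modulus
#' (M) and support (S) projections and R = 2P - I the reflectors. At
#' beta = 1 this reduces to averaged alternating reflections.
#'
#' @inheritParams er_step
#' @param beta relaxation parameter (default 0.87).
#' @return updated iterate.
#' @export
raar_step <- function(x, amplitudes, measured, support, beta = 0.87) {
  pm <- .proj_modulus(x, amplitudes, measured)
  rm <- 2 * pm - x
  rs_rm <- 2 * .proj_support(rm, support) - rm
  (beta / 2) * (rs_rm + x) + (1 - beta) * pm
}

#' Relative Fourier error of an iterate
#'
#' sqrt(sum over measured pixels of (|F x| - A)^2 / sum A^2). By Parseval
#' the fully-measured case equals the real-space distance to the modulus
#' constraint set, up to the same normalization.
#'
#' @inheritParams er_step
#' @return nonnegative scalar.
#' @export
fourier_error <- function(x, amplitudes, measured) {
  X <- stats::fft(x)
  sqrt(sum((Mod(X)[measured] - amplitudes[measured])^2) /
         max(sum(amplitudes[measured]^2), 1e-300))
}

# circular point reflection compatible with the DFT: y(r) = x(-r)
.conj_flip <- function(x) {
  n <- nrow(x)
  x[c(1, n:2), c(1, n:2)]
}

# circular shift by (dr, dc)
.circ_shift <- function(x, dr, dc) {
  n <- nrow(x); m <- ncol(x)
  x[((seq_len(n) - 1 - dr) %% n) + 1, ((seq_len(m) - 1 - dc) %% m) + 1]
}

# align candidate to reference over integer shifts and conjugate flip;
# returns the aligned image and the correlation score
.align_to <- function(ref, img) {
  Fr <- Conj(stats::fft(ref))
  best <- NULL
  for (flip in c(FALSE, TRUE)) {
    cand <- if (flip) .conj_flip(img) else img
    cc <- Re(stats::fft(Fr * stats::fft(cand), inverse = TRUE))
    i <- which.max(cc)
    score <- cc[i]
    if (is.null(best) || score > best$score) {
      dr <- (i - 1) %% nrow(ref)
      dc <- (i - 1) %/% nrow(ref)
      # fft correlation peak at (dr, dc) means cand shifted by -(dr, dc)
      best <- list(img = .circ_shift(cand, -dr, -dc), score = score)
    }
  }
  best$img
}

#' Iterative phase retrieval with reconstruction averaging
#'
#' Runs \code{n_repeats} independent reconstructions from uniform random
#' initial phases: \code{n_main} iterations of the main algorithm (RAAR or
#' HIO) followed by \code{n_er} iterations of error reduction, enforcing
#' real positive densities inside a static support. Repeats are aligned to
#' the first repeat (integer translation + conjugate-flip disambiguation by
#' cross-correlation), recentered to the common center of mass, and
#' averaged. Deterministic given the seed. Non-finite (divergent) repeats
#' are dropped and counted.
#'
#' @param problem a \code{phasing_problem}.
#' @param algorithm "raar" (default) or "hio".
#' @param n_main main-algorithm iterations (default 1000).
#' @param n_er error-reduction iterations (default 1000).
#' @param n_repeats independent reconstructions (default 100).
#' @param beta feedback/relaxation parameter (default: 0.87 for RAAR,
#'   0.9 for HIO).
#' @param seed RNG seed.
#' @param error_cut keep only repeats whose Fourier error is at most
#'   \code{error_cut} times that of the best repeat (default \code{Inf}:
#'   average all). Stagnated starts are common for objects well inside the
#'   support; a cut of ~3 keeps the reproducible solutions.
#' @return object of class \code{reconstruction_result}: \code{average}
#'   image, list \code{repeats} of aligned per-repeat images (ordered by
#'   increasing Fourier error), per-repeat \code{fourier_errors}, numbers of
#'   \code{dropped} (non-finite) and \code{rejected} (over the error cut)
#'   repeats.
#' @export
run_reconstruction <- function(problem, algorithm = c("raar", "hio"),
                               n_main = 1000, n_er = 1000, n_repeats = 100,
                               beta = NULL, seed = 1, error_cut = Inf) {
  stopifnot(inherits(problem, "phasing_problem"))
  algorithm <- match.arg(algorithm)
  if (is.null(beta)) beta <- if (algorithm == "raar") 0.87 else 0.9
  step_main <- if (algorithm == "raar") raar_step else hio_step
  A <- problem$amplitudes; M <- problem$measured; S <- problem$support
  n <- problem$n
  set.seed(seed)
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, n_repeats)
  repeats <- vector("list", n_repeats)
  errs <- rep(NA_real_, n_repeats)
  dropped <- 0L
  for (r in seq_len(n_repeats)) {
    set.seed(repeat_seeds[r])
    phi <- matrix(stats::runif(n * n, -pi, pi), n, n)
    x <- Re(stats::fft(A * exp(1i * phi), inverse = TRUE)) / (n * n)
    for (it in seq_len(n_main)) x <- step_main(x, A, M, S, beta)
    for (it in seq_len(n_er)) x <- er_step(x, A, M, S)
    if (!all(is.finite(x))) { dropped <- dropped + 1L; next }
    repeats[[r]] <- x
    errs[r] <- fourier_error(x, A, M)
  }
  keep <- !vapply(repeats, is.null, logical(1))
  repeats <- repeats[keep]
  errs <- errs[keep]
  if (length(repeats) == 0) stop("all repeats diverged")
  # order by Fourier error; align everything to the best repeat
  o <- order(errs)
  repeats <- repeats[o]
  errs <- errs[o]
  rejected <- 0L
  if (is.finite(error_cut)) {
    sel <- errs <= error_cut * errs[1]
    rejected <- sum(!sel)
    repeats <- repeats[sel]
    errs <- errs[sel]
  }
  aligned <- repeats
  if (length(repeats) > 1)
    for (r in 2:length(repeats))
      aligned[[r]] <- .align_to(repeats[[1]], repeats[[r]])
  avg <- Reduce(`+`, aligned) / length(aligned)
  # fix the global position: integer recentering of the center of mass
  shift <- .com_shift(avg)
  avg <- .circ_shift(avg, shift[1], shift[2])
  aligned <- lapply(aligned, .circ_shift, shift[1], shift[2])
  structure(list(average = avg, repeats = aligned,
                 fourier_errors = errs, dropped = dropped,
                 rejected = rejected,
                 algorithm = algorithm, beta = beta,
                 n_main = n_main, n_er = n_er, seed = seed,
                 problem = problem),
            class = "reconstruction_result")
}

# integer shift taking the center of mass of the positive part to the
# grid center
.com_shift <- function(x) {
  p <- pmax(x, 0)
  tot <- sum(p)
  if (tot <= 0) return(c(0L, 0L))
  n <- nrow(x); m <- ncol(x)
  cr <- sum(rowSums(p) * seq_len(n)) / tot
  cc <- sum(colSums(p) * seq_len(m)) / tot
  c(as.integer(round((n + 1) / 2 - cr)), as.integer(round((m + 1) / 2 - cc)))
}

#' @export
print.reconstruction_result <- function(x, ...) {
  cat(sprintf(
    "Reconstruction: %s (beta %.2f), %d + %d ER iterations, %d repeats kept (%d dropped, %d rejected)\n",
    toupper(x$algorithm), x$beta, x$n_main, x$n_er, length(x$repeats),
    x$dropped, x$rejected))
  cat(sprintf("  Fourier error: median %.4g, range [%.4g, %.4g]\n",
              stats::median(x$fourier_errors), min(x$fourier_errors),
              max(x$fourier_errors)))
  invisible(x)
}

#' @export
plot.reconstruction_result <- function(x, ...) {
  graphics::image(x$average, asp = 1, useRaster = TRUE,
                  col = grDevices::gray.colors(256), ...)
  invisible(x)
}

#' Phase retrieval transfer function
#'
#' Per Fourier pixel, the magnitude of the mean unit-normalized complex
#' Fourier value across aligned repeats; radially binned. The resolution
#' estimate is the first bin where the PRTF drops below 1/e (and stays
#' below for the following bin, when one exists).
#'
#' @param result a \code{reconstruction_result} with >= 2 repeats.
#' @param q optional matrix of q magnitudes for the Fourier grid (fftshifted
#'   DC-centered layout NOT expected: supply unshifted, matching the
#'   amplitude layout). Default: radial spatial frequency in cycles/pixel.
#' @param n_bins number of radial bins.
#' @return object of class \code{prtf_curve}: \code{q}, \code{prtf},
#'   \code{resolution_q}, \code{threshold} (= exp(-1)).
#' @export
prtf <- function(result, q = NULL, n_bins = 32) {
  stopifnot(inherits(result, "reconstruction_result"))
  reps <- result$repeats
  if (length(reps) < 2) stop("PRTF needs at least two repeats")
  n <- nrow(reps[[1]])
  if (is.null(q)) {
    f <- c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1)) / n
    q <- sqrt(outer(f^2, f^2, `+`))
  }
  acc <- matrix(0 + 0i, n, n)
  nz <- matrix(0, n, n)
  for (x in reps) {
    X <- stats::fft(x)
    mag <- Mod(X)
    ok <- mag > 1e-300
    u <- matrix(0 + 0i, n, n)
    u[ok] <- X[ok] / mag[ok]
    acc <- acc + u
    nz <- nz + ok
  }
  valid <- nz == length(reps)
  pp <- Mod(acc) / length(reps)
  prof <- .radial_profile(q[valid], pp[valid], n_bins,
                          q_range = c(0, max(q[valid])))
  thr <- exp(-1)
  below <- prof$mean < thr
  res_q <- max(prof$q)
  if (any(below)) {
    k <- length(below)
    sustained <- which(below & c(below[-1], TRUE))
    if (length(sustained) > 0) res_q <- prof$q[sustained[1]]
    else res_q <- prof$q[which(below)[1]]
  }
  structure(list(q = prof$q, prtf = prof$mean, n = prof$n,
                 resolution_q = res_q, threshold = thr),
            class = "prtf_curve")
}

#' @export
print.prtf_curve <- function(x, ...) {
  cat(sprintf(
    "PRTF over %d bins; drops below 1/e at q = %.4g (threshold %.4f)\n",
    length(x$q), x$resolution_q, x$threshold))
  invisible(x)
}

#' @export
plot.prtf_curve <- function(x, ...) {
  graphics::plot(x$q, x$prtf, type = "l", ylim = c(0, 1),
                 xlab = "q", ylab = "PRTF", ...)
  graphics::abline(h = x$threshold, lty = 2)
  invisible(x)
}

#' Write a PRTF curve to CSV (columns q, prtf)
#' @param x a \code{prtf_curve}.
#' @param path output path.
#' @export
write_prtf <- function(x, path) {
  utils::write.csv(data.frame(q = x$q, prtf = x$prtf), path,
                   row.names = FALSE)
  invisible(path)
}
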