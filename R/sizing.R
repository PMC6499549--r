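# Particle sizing by uniform-sphere form-factor fitting.
#
# The model fitted to a diffraction pattern is
#   I(q) = i0 * [3 (sin(qr) - qr cos(qr)) / (qr)^3]^2 + offset
# with r = diameter / 2; the offset absorbs uniform background. For fixed
# diameter the model is linear in (i0, offset), so fitting reduces to a 1D
# search over the diameter: a coarse grid (step below a quarter of the
# finest fringe period, since the objective is oscillatory) followed by
# local refinement.

#' Radial (azimuthal) average of a diffraction frame
#'
#' @param frame photon-unit frame matrix (or \code{calibrated_frame}).
#' @param qmap a \code{qmap} aligned with the frame.
#' @param mask optional \code{pixel_mask}.
#' @param n_bins number of q bins (default 256).
#' @return object of class \code{radial_profile}: per-bin \code{q} centers
#'   (nm^-1), \code{mean} intensity (photons/pixel), \code{sd}, \code{n}
#'   pixel counts; bins with no pixels are dropped.
#' @export
radial_average <- function(frame, qmap, mask = NULL, n_bins = 256) {
  if (inherits(frame, "calibrated_frame")) frame <- frame$photons
  bad <- qmap$gap | is.na(frame)
  if (!is.null(mask)) bad <- bad | mask$bad
  if (all(bad)) stop("all pixels are masked")
  q <- qmap$q[!bad]
  y <- frame[!bad]
  prof <- .radial_profile(q, y, n_bins)
  structure(prof, class = "radial_profile")
}

# binned statistics of y over q; returns only non-empty bins
.radial_profile <- function(q, y, n_bins, q_range = range(q)) {
  if (length(q) == 0 || !all(is.finite(q_range)))
    stop("no usable pixels for a radial profile")
  edges <- seq(q_range[1], q_range[2], length.out = n_bins + 1)
  idx <- findInterval(q, edges, rightmost.closed = TRUE)
  idx[idx < 1] <- 1; idx[idx > n_bins] <- n_bins
  n <- tabulate(idx, n_bins)
  s <- rowsum(y, idx)
  s2 <- rowsum(y^2, idx)
  keep <- which(n > 0)
  pos <- match(keep, sort(unique(idx)))
  mu <- s[pos] / n[keep]
  va <- pmax(s2[pos] / n[keep] - mu^2, 0)
  list(q = (edges[keep] + edges[keep + 1]) / 2, mean = mu,
       sd = sqrt(va), n = n[keep])
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("Radial profile: %d bins, q in [%.4g, %.4g] nm^-1\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' @export
plot.radial_profile <- function(x, log = "y", ...) {
  y <- x$mean
  if (grepl("y", log)) y <- pmax(y, min(y[y > 0], na.rm = TRUE) / 10)
  graphics::plot(x$q, y, type = "l", log = log,
                 xlab = expression(q ~ (nm^-1)),
                 ylab = "photons / pixel", ...)
  invisible(x)
}

# weighted linear LS of y ~ i0 * a + off * b; returns i0, off, rss
.sphere_linear_ls <- function(a, b, y, w) {
  saa <- sum(w * a * a); sab <- sum(w * a * b); sbb <- sum(w * b * b)
  say <- sum(w * a * y); sby <- sum(w * b * y)
  det <- saa * sbb - sab^2
  if (!is.finite(det) || det <= 1e-300 * max(saa * sbb, 1))
    return(list(i0 = NA_real_, off = NA_real_, rss = Inf, ok = FALSE))
  i0 <- (say * sbb - sby * sab) / det
  off <- (sby * saa - say * sab) / det
  if (i0 < 0) {           # background-only fallback keeps offset meaningful
    i0 <- 0
    off <- sby / sbb
  }
  r <- y - i0 * a - off * b
  list(i0 = i0, off = off, rss = sum(w * r * r), ok = TRUE)
}

# profile over candidate diameters: y ~ w*(i0*ff2(q; d) + off)
.sphere_objective <- function(d, q, y, w, lsw) {
  s <- sphere_intensity(q, d, 1)
  .sphere_linear_ls(w * s, w, y, lsw)
}

# coarse grid + local refinement over the diameter
.sphere_search <- function(q, y, w, lsw, d_range, q_max) {
  step <- pi / (2 * q_max)              # <= quarter fringe at the highest q
  grid <- seq(d_range[1], d_range[2], by = step)
  rss <- vapply(grid, function(d) .sphere_objective(d, q, y, w, lsw)$rss,
                numeric(1))
  d0 <- grid[which.min(rss)]
  opt <- stats::optimize(function(d) .sphere_objective(d, q, y, w, lsw)$rss,
                         lower = max(d_range[1], d0 - step),
                         upper = min(d_range[2], d0 + step), tol = 1e-6)
  list(diameter = opt$minimum, rss = opt$objective, grid_best = d0)
}

.make_sphere_fit <- function(diameter, ls, y, w, lsw, q, n_obs, mode,
                             d_range, beam = NULL, geometry = NULL) {
  rss_const <- {
    off <- sum(lsw * w * y) / sum(lsw * w * w)
    sum(lsw * (y - off * w)^2)
  }
  gain <- if (rss_const > 0) 1 - ls$rss / rss_const else 0
  converged <- ls$ok && is.finite(ls$rss) && ls$i0 > 0 && gain > 0.05 &&
    diameter > d_range[1] + 1e-6 && diameter < d_range[2] - 1e-6
  fluence <- if (!is.null(beam) && !is.null(geometry) && ls$i0 > 0)
    fluence_from_i0(ls$i0, diameter, beam, geometry) else NA_real_
  structure(list(
    diameter_nm = diameter,
    i0 = ls$i0,
    offset = ls$off,
    fluence_mJ_um2 = fluence,
    residual = sqrt(ls$rss / max(sum(lsw * y^2), 1e-300)),
    rss = ls$rss,
    signal_gain = gain,
    converged = converged,
    n_obs = n_obs,
    mode = mode,
    data = list(q = q, y = y, w = w, lsw = lsw)
  ), class = "sphere_fit")
}

#' Fit the uniform-sphere model to a 2D diffraction pattern
#'
#' Operates on a truncated/binned frame: each retained bin contributes its
#' photon sum, modelled as n_pixels * (i0 * F(q_bin) + offset). Masked bins
#' and bins beyond \code{high_q_frac} of the maximum q are excluded (the
#' sphere model is unreliable at large scattering angles for nonspherical
#' particles). Coarse-to-fine search over the diameter with an exact linear
#' solve for (i0, offset) at each candidate.
#'
#' @param binned a \code{binned_frame} from \code{\link{truncate_and_bin}},
#'   or a raw photon frame matrix (then binned here with \code{bin_factor}).
#' @param qmap for a \code{binned_frame}: the matching \code{\link{bin_qmap}}
#'   result; for a frame matrix: the full-resolution \code{qmap}.
#' @param mask optional \code{pixel_mask} (only used when binning here).
#' @param bin_factor bin size when \code{binned} is a raw frame.
#' @param floor photon floor applied before binning a raw frame (0.5 as in
#'   the measurement pipeline; use 0 for noise-free or pre-floored input —
#'   flooring continuous-valued data biases the offset term).
#' @param d_range diameter search range (nm).
#' @param high_q_frac fraction of the maximum q retained (default 0.8).
#' @param beam,geometry optional; when supplied the fit also reports the
#'   implied incident fluence.
#' @return object of class \code{sphere_fit}: \code{diameter_nm},
#'   \code{i0} (photons/pixel at q = 0), \code{offset} (photons/pixel),
#'   normalized \code{residual}, \code{converged} flag.
#' @export
fit_sphere_2d <- function(binned, qmap, mask = NULL, bin_factor = 4,
                          floor = 0.5, d_range = c(10, 300),
                          high_q_frac = 0.8, beam = NULL, geometry = NULL) {
  if (is.matrix(binned) || inherits(binned, "calibrated_frame")) {
    bq <- bin_qmap(qmap, bin_factor, mask)
    binned <- truncate_and_bin(binned, bin_factor, floor = floor,
                               mask = mask)
  } else {
    stopifnot(inherits(binned, "binned_frame"))
    bq <- qmap
    if (!all(dim(bq$q) == dim(binned$values)))
      stop("binned frame / binned qmap shape mismatch")
  }
  q_max_det <- max(bq$q, na.rm = TRUE)
  use <- binned$n_pixels > 0 & is.finite(bq$q) &
    bq$q <= high_q_frac * q_max_det
  if (sum(use) < 10) stop("fewer than 10 usable bins")
  q <- bq$q[use]; y <- binned$values[use]; w <- binned$n_pixels[use]
  lsw <- rep(1, length(y))
  sr <- .sphere_search(q, y, w, lsw, d_range, max(q))
  ls <- .sphere_objective(sr$diameter, q, y, w, lsw)
  .make_sphere_fit(sr$diameter, ls, y, w, lsw, q, sum(use), "2d",
                   d_range, beam, geometry)
}

#' Fit the uniform-sphere model to a radial intensity profile
#'
#' Same model and search strategy as \code{\link{fit_sphere_2d}}, applied
#' to a radially averaged profile; intended for weak scatterers where
#' per-pixel counts are too low for a 2D fit. Bins are weighted by their
#' pixel counts.
#'
#' @param profile a \code{radial_profile}.
#' @param d_range diameter search range (nm).
#' @param high_q_frac fraction of the maximum profile q retained.
#' @param beam,geometry optional, for the implied-fluence report.
#' @return a \code{sphere_fit}.
#' @export
fit_sphere_radial <- function(profile, d_range = c(5, 300),
                              high_q_frac = 1, beam = NULL,
                              geometry = NULL) {
  stopifnot(inherits(profile, "radial_profile"))
  use <- is.finite(profile$mean) & profile$n > 0 &
    profile$q <= high_q_frac * max(profile$q)
  if (sum(use) < 10) stop("fewer than 10 retained bins")
  q <- profile$q[use]; y <- profile$mean[use]
  w <- rep(1, length(y))          # y is already per-pixel intensity
  lsw <- profile$n[use]           # weight bins by pixel counts
  sr <- .sphere_search(q, y, w, lsw, d_range, max(q))
  ls <- .sphere_objective(sr$diameter, q, y, w, lsw)
  .make_sphere_fit(sr$diameter, ls, y, w, lsw, q, sum(use), "radial",
                   d_range, beam, geometry)
}

#' @export
print.sphere_fit <- function(x, ...) {
  cat(sprintf(
    "Sphere-model fit (%s): diameter %.2f nm, i0 %.3g ph/px, offset %.3g ph/px\n",
    x$mode, x$diameter_nm, x$i0, x$offset))
  cat(sprintf("  residual %.3g over %d observations; converged: %s\n",
              x$residual, x$n_obs, x$converged))
  if (is.finite(x$fluence_mJ_um2))
    cat(sprintf("  implied incident fluence %.4g mJ/um^2\n",
                x$fluence_mJ_um2))
  invisible(x)
}

#' @export
coef.sphere_fit <- function(object, ...) {
  c(diameter_nm = object$diameter_nm, i0 = object$i0,
    offset = object$offset)
}

#' @export
summary.sphere_fit <- function(object, ...) {
  out <- unclass(object)[c("diameter_nm", "i0", "offset", "fluence_mJ_um2",
                           "residual", "signal_gain", "converged", "n_obs",
                           "mode")]
  class(out) <- "summary.sphere_fit"
  out
}

#' @export
print.summary.sphere_fit <- function(x, ...) {
  cat("Uniform-sphere model fit\n")
  for (n in names(x)) cat(sprintf("  %-14s %s\n", n, format(x[[n]])))
  invisible(x)
}

#' @export
predict.sphere_fit <- function(object, q = NULL, ...) {
  if (is.null(q)) q <- object$data$q
  sphere_intensity(q, object$diameter_nm, object$i0) + object$offset
}

#' @export
residuals.sphere_fit <- function(object, ...) {
  d <- object$data
  d$y - d$w * (sphere_intensity(d$q, object$diameter_nm, object$i0) +
                 object$offset)
}

#' @export
plot.sphere_fit <- function(x, log = "y", ...) {
  d <- x$data
  o <- order(d$q)
  per_px <- d$y[o] / d$w[o]
  graphics::plot(d$q[o], pmax(per_px, 1e-6), log = log, pch = ".",
                 xlab = expression(q ~ (nm^-1)), ylab = "photons / pixel",
                 ...)
  graphics::lines(d$q[o],
                  pmax(predict(x, d$q[o]), 1e-6), col = 2, lwd = 2)
  invisible(x)
}

#' Check a fitted incident intensity against the beam-focus range
#'
#' A sizing fit is physically plausible only if its implied incident
#' fluence falls in the range expected for the x-ray focus.
#'
#' @param fit a converged \code{sphere_fit}.
#' @param beam a \code{beam_parameters}.
#' @param geometry a \code{detector_geometry}.
#' @param focus_fluence_range allowed fluence interval (mJ/um^2); default
#'   (0, peak fluence], upper bound inclusive.
#' @return logical flag with attribute \code{fluence_mJ_um2}.
#' @export
validate_fluence <- function(fit, beam, geometry,
                             focus_fluence_range =
                               c(0, beam$peak_fluence_mJ_um2)) {
  fl <- if (is.finite(fit$fluence_mJ_um2)) fit$fluence_mJ_um2 else
    fluence_from_i0(fit$i0, fit$diameter_nm, beam, geometry)
  ok <- is.finite(fl) && fl > focus_fluence_range[1] &&
    fl <= focus_fluence_range[2]
  structure(ok, fluence_mJ_um2 = fl)
}

#' Median and FWHM of a set of fitted diameters
#'
#' The FWHM is measured on a Gaussian-kernel density estimate with
#' Silverman's rule-of-thumb bandwidth (the half-maximum crossings around
#' the global mode, linearly interpolated).
#'
#' @param diameters_nm fitted diameters (>= 10 values).
#' @param bin_width_nm histogram bin width for the returned distribution.
#' @return a \code{size_distribution} of the diameters whose summary holds
#'   the sample median and the KDE-based FWHM.
#' @export
size_distribution_stats <- function(diameters_nm, bin_width_nm = NULL) {
  d <- diameters_nm[is.finite(diameters_nm)]
  if (length(d) < 10) stop("need at least 10 fitted diameters")
  med <- stats::median(d)
  if (stats::sd(d) == 0) {      # degenerate sample: FWHM -> 0
    edges <- med + c(-1, 0, 1)
    out <- size_distribution(edges, c(0, length(d)))
    out$summary <- list(median_nm = med, fwhm_nm = 0)
    return(out)
  }
  dens <- stats::density(d, bw = "nrd0")
  pk <- which.max(dens$y)
  half <- dens$y[pk] / 2
  xl <- dens$x[seq_len(pk)]; yl <- dens$y[seq_len(pk)]
  xr <- dens$x[pk:length(dens$x)]; yr <- dens$y[pk:length(dens$y)]
  left <- if (any(yl < half)) stats::approx(yl[max(which(yl < half)):pk],
                                            xl[max(which(yl < half)):pk],
                                            xout = half)$y else min(xl)
  ir <- which(yr < half)
  right <- if (length(ir) > 0)
    stats::approx(yr[c(min(ir) - 1, min(ir))], xr[c(min(ir) - 1, min(ir))],
                  xout = half)$y else max(xr)
  if (is.null(bin_width_nm))
    bin_width_nm <- max(diff(range(d)) / 30, 1e-6)
  edges <- seq(min(d) - bin_width_nm, max(d) + bin_width_nm,
               by = bin_width_nm)
  if (edges[length(edges)] < max(d)) edges <- c(edges, max(d) + bin_width_nm)
  counts <- graphics::hist(d, breaks = edges, plot = FALSE)$counts
  out <- size_distribution(edges, counts)
  out$summary <- list(median_nm = med, fwhm_nm = right - left)
  attr(out, "kde_bw") <- dens$bw
  out
}
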