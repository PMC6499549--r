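# Poissonian droplet-occupancy model.
#
# During aerosolization each droplet captures n particles with n ~ Poisson(
# lambda), lambda = particle concentration x droplet volume. Multiply
# occupied droplets dry into nonspecific clusters whose diameter follows the
# scaling law d_n = d1 * n^(1/a) with a < 3 (a = 3 would be a compact
# sphere; looser packing gives smaller a). An observed size histogram is a
# mixture over n >= 1 of modes at d_n.

#' Poisson droplet-occupancy probabilities
#' @param lambda expected particles per droplet (>= 0).
#' @param n_max largest occupancy evaluated.
#' @return vector of P(n) for n = 0..n_max.
#' @export
occupancy_pmf <- function(lambda, n_max) {
  if (lambda < 0) stop("lambda must be nonnegative")
  stats::dpois(0:n_max, lambda)
}

#' Cluster diameter under the occupancy scaling law
#' @param n cluster occupancy (>= 1).
#' @param d1_nm monomer diameter (nm).
#' @param a scaling exponent, 1 <= a <= 3 (a = 3: compact sphere).
#' @return cluster diameter d1 * n^(1/a) in nm.
#' @export
cluster_diameter <- function(n, d1_nm, a) {
  if (any(n < 1)) stop("occupancy n must be >= 1")
  if (any(d1_nm <= 0)) stop("monomer diameter must be positive")
  if (any(a < 1 | a > 3)) stop("scaling exponent must lie in [1, 3]")
  d1_nm * n^(1 / a)
}

.default_n_max <- function(lambda) as.integer(ceiling(lambda + 10 * sqrt(lambda)) + 5)

#' Droplet-occupancy model object
#'
#' @param lambda expected particles per droplet.
#' @param d1_nm monomer diameter (nm).
#' @param a cluster-diameter scaling exponent (1 <= a <= 3).
#' @param noise relative s.d. of observed diameters per mode (Gaussian
#'   broadening with s.d. = noise * mode center).
#' @return object of class \code{occupancy_model}.
#' @export
occupancy_model <- function(lambda, d1_nm, a, noise = 0.05) {
  if (lambda < 0) stop("lambda must be nonnegative")
  if (d1_nm <= 0) stop("monomer diameter must be positive")
  if (a < 1 || a > 3) stop("scaling exponent must lie in [1, 3]")
  if (noise < 0) stop("noise must be nonnegative")
  structure(list(lambda = lambda, d1_nm = d1_nm, a = a, noise = noise),
            class = "occupancy_model")
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat(sprintf(
    "Droplet-occupancy model: lambda = %.3g, d1 = %.3g nm, a = %.3g, noise = %.3g\n",
    x$lambda, x$d1_nm, x$a, x$noise))
  invisible(x)
}

# Occupancy weights conditional on n >= 1, truncated and renormalized.
.occupancy_weights <- function(lambda, n_max = .default_n_max(lambda)) {
  if (lambda == 0) {
    w <- c(1, rep(0, n_max - 1))
  } else {
    w <- stats::dpois(seq_len(n_max), lambda)
    w <- w / sum(w)
  }
  w
}

#' Size-distribution histogram container
#'
#' @param bin_edges increasing vector of bin edges (nm), length nbins + 1.
#' @param counts nonnegative counts (or expected counts) per bin.
#' @return object of class \code{size_distribution} with median and FWHM
#'   summaries interpolated from the histogram.
#' @export
size_distribution <- function(bin_edges, counts) {
  if (length(counts) != length(bin_edges) - 1)
    stop("need length(counts) == length(bin_edges) - 1")
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(list(bin_edges = bin_edges, counts = counts,
                 summary = .histogram_summary(bin_edges, counts)),
            class = "size_distribution")
}

# Median (interpolated from the cumulative histogram) and FWHM (linear
# interpolation of the half-maximum crossings around the tallest bin).
.histogram_summary <- function(edges, counts) {
  total <- sum(counts)
  if (total == 0) return(list(median_nm = NA_real_, fwhm_nm = NA_real_))
  cum <- cumsum(counts)
  i <- which(cum >= total / 2)[1]
  below <- if (i > 1) cum[i - 1] else 0
  frac <- (total / 2 - below) / counts[i]
  med <- edges[i] + frac * (edges[i + 1] - edges[i])
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  dens <- counts / diff(edges)
  pk <- which.max(dens)
  half <- dens[pk] / 2
  left <- centers[pk]
  for (j in rev(seq_len(pk - 1))) {
    if (dens[j] < half) {
      left <- centers[j] + (half - dens[j]) / (dens[j + 1] - dens[j]) *
        (centers[j + 1] - centers[j])
      break
    }
    left <- centers[j]
  }
  right <- centers[pk]
  n <- length(centers)
  for (j in seq.int(pk + 1, length.out = n - pk)) {
    if (dens[j] < half) {
      right <- centers[j - 1] + (dens[j - 1] - half) / (dens[j - 1] - dens[j]) *
        (centers[j] - centers[j - 1])
      break
    }
    right <- centers[j]
  }
  list(median_nm = med, fwhm_nm = right - left)
}

#' @export
print.size_distribution <- function(x, ...) {
  cat(sprintf("Size distribution: %d bins over [%.3g, %.3g] nm, %g counts\n",
              length(x$counts), min(x$bin_edges), max(x$bin_edges),
              sum(x$counts)))
  cat(sprintf("  median %.4g nm, FWHM %.4g nm\n",
              x$summary$median_nm, x$summary$fwhm_nm))
  invisible(x)
}

#' @export
plot.size_distribution <- function(x, ...) {
  centers <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::plot(centers, x$counts, type = "h",
                 xlab = "diameter (nm)", ylab = "count", ...)
  invisible(x)
}

#' Expected size histogram under a droplet-occupancy model
#'
#' Mixture over n >= 1 of Gaussian modes centered at
#' \code{cluster_diameter(n)}, weighted by the truncated Poisson occupancy
#' probabilities and broadened with s.d. = noise * center. Bin masses are
#' exact Gaussian integrals; the total mass over the real line is 1 before
#' any count scaling (mass falling outside the binned range is lost to the
#' returned histogram but reported via \code{attr(, "mass_in_range")}).
#'
#' @param model an \code{occupancy_model}.
#' @param bin_edges histogram bin edges (nm).
#' @param total optional count scale (default 1: probability masses).
#' @return a \code{size_distribution} of expected counts.
#' @export
predict_size_histogram <- function(model, bin_edges, total = 1) {
  stopifnot(inherits(model, "occupancy_model"))
  if (length(bin_edges) < 2) stop("need at least one bin")
  w <- .occupancy_weights(model$lambda)
  centers_n <- cluster_diameter(seq_along(w), model$d1_nm, model$a)
  sds <- pmax(model$noise * centers_n, 1e-9)
  mass <- rep(0, length(bin_edges) - 1)
  for (k in seq_along(w)) {
    if (w[k] < 1e-12) next
    p <- stats::pnorm(bin_edges, centers_n[k], sds[k])
    mass <- mass + w[k] * diff(p)
  }
  out <- size_distribution(bin_edges, total * mass)
  attr(out, "mass_in_range") <- sum(mass)
  out
}

#' Draw cluster diameters from a droplet-occupancy model
#'
#' Samples occupancies from the truncated Poisson (n >= 1), then diameters
#' from the Gaussian mode of each cluster size.
#'
#' @param model an \code{occupancy_model}.
#' @param n number of particles to draw.
#' @return numeric vector of diameters (nm).
#' @export
sample_cluster_diameters <- function(model, n) {
  w <- .occupancy_weights(model$lambda)
  occ <- sample.int(length(w), n, replace = TRUE, prob = w)
  centers <- cluster_diameter(occ, model$d1_nm, model$a)
  stats::rnorm(n, centers, model$noise * centers)
}

#' Simulate observed size histograms from an occupancy model
#'
#' Each simulated histogram bins \code{n_particles} sampled diameters
#' (equivalently: multinomial sampling of the bin probabilities, with
#' out-of-range draws discarded).
#'
#' @param object an \code{occupancy_model}.
#' @param nsim number of histograms.
#' @param seed optional RNG seed.
#' @param bin_edges histogram bin edges (nm).
#' @param n_particles particles sampled per histogram.
#' @param ... unused.
#' @return list of \code{size_distribution} objects (length \code{nsim}).
#' @export
simulate.occupancy_model <- function(object, nsim = 1, seed = NULL,
                                     bin_edges, n_particles = 1000, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    d <- sample_cluster_diameters(object, n_particles)
    d <- d[d >= bin_edges[1] & d < bin_edges[length(bin_edges)]]
    counts <- graphics::hist(d, breaks = bin_edges, plot = FALSE,
                             include.lowest = TRUE, right = FALSE)$counts
    size_distribution(bin_edges, counts)
  })
}

# Sum-of-squares objective between observed counts and model prediction.
.occupancy_objective <- function(observed, lambda, d1, a, noise) {
  if (d1 <= 0 || noise <= 0 || a < 1 || a > 3 || lambda < 0) return(1e300)
  pred <- predict_size_histogram(occupancy_model(lambda, d1, a, noise),
                                 observed$bin_edges,
                                 total = sum(observed$counts))
  sum((observed$counts - pred$counts)^2)
}

#' Fit the droplet-occupancy model to an observed size histogram
#'
#' Least-squares fit of \code{\link{predict_size_histogram}} to the counts.
#' The scaling exponent a is always free; lambda is fixed when known (from
#' concentration x droplet volume), otherwise fitted; monomer diameter and
#' relative mode broadening are fitted unless supplied in \code{fixed}.
#' The search runs a coarse grid over a (default step 0.05 on [1, 2.95])
#' with a bounded inner optimization of the remaining parameters, followed
#' by a joint local refinement; it is deterministic given the data and grid.
#'
#' @param observed a \code{size_distribution} of observed counts.
#' @param lambda known occupancy mean, or NULL to fit it.
#' @param fixed optional named list fixing \code{d1_nm} and/or \code{noise}.
#' @param a_grid coarse grid of candidate exponents.
#' @return object of class \code{occupancy_fit}: fitted
#'   \code{occupancy_model}, residual norms, and identifiability diagnostics.
#' @export
fit_occupancy_model <- function(observed, lambda = NULL, fixed = list(),
                                a_grid = seq(1, 2.95, by = 0.05)) {
  stopifnot(inherits(observed, "size_distribution"))
  counts <- observed$counts
  if (sum(counts) <= 0 || sum(counts > 0) < 2)
    stop("degenerate histogram: needs at least two occupied bins")
  centers <- (observed$bin_edges[-1] +
                observed$bin_edges[-length(observed$bin_edges)]) / 2
  lambda_free <- is.null(lambda)
  d1_free <- is.null(fixed$d1_nm)
  noise_free <- is.null(fixed$noise)
  d1_init <- if (d1_free) centers[which.max(counts)] else fixed$d1_nm
  noise_init <- if (noise_free) 0.05 else fixed$noise
  lambda_init <- if (lambda_free) 1 else lambda

  # pack free parameters on log scale (a handled separately)
  inner <- function(a, start) {
    par0 <- c(if (lambda_free) log(start$lambda),
              if (d1_free) log(start$d1),
              if (noise_free) log(start$noise))
    fn <- function(p) {
      i <- 0
      lam <- if (lambda_free) exp(p[(i <- i + 1)]) else lambda
      d1 <- if (d1_free) exp(p[(i <- i + 1)]) else fixed$d1_nm
      ns <- if (noise_free) exp(p[(i <- i + 1)]) else fixed$noise
      .occupancy_objective(observed, lam, d1, a, ns)
    }
    if (length(par0) == 0)
      return(list(par = numeric(0), value = fn(numeric(0))))
    opt <- stats::optim(par0, fn, method = "Nelder-Mead",
                        control = list(maxit = 300, reltol = 1e-10))
    opt
  }
  unpack <- function(a, p) {
    i <- 0
    list(a = a,
         lambda = if (lambda_free) exp(p[(i <- i + 1)]) else lambda,
         d1 = if (d1_free) exp(p[(i <- i + 1)]) else fixed$d1_nm,
         noise = if (noise_free) exp(p[(i <- i + 1)]) else fixed$noise)
  }

  start <- list(lambda = lambda_init, d1 = d1_init, noise = noise_init)
  best <- NULL
  for (a in a_grid) {
    opt <- inner(a, start)
    if (is.null(best) || opt$value < best$value)
      best <- list(a = a, par = opt$par, value = opt$value)
  }
  # joint bounded refinement around the best grid point
  pj0 <- c(best$a, best$par)
  lo <- c(max(1, best$a - 0.1), rep(-Inf, length(best$par)))
  hi <- c(min(3, best$a + 0.1), rep(Inf, length(best$par)))
  fj <- function(p) {
    u <- unpack(p[1], p[-1])
    .occupancy_objective(observed, u$lambda, u$d1, u$a, u$noise)
  }
  ref <- stats::optim(pj0, fj, method = "L-BFGS-B", lower = lo, upper = hi,
                      control = list(maxit = 500, factr = 1e4))
  final <- if (ref$value <= best$value) list(par = ref$par, value = ref$value,
                                             conv = ref$convergence == 0)
           else list(par = pj0, value = best$value, conv = TRUE)
  u <- unpack(final$par[1], final$par[-1])
  model <- occupancy_model(u$lambda, u$d1, u$a, u$noise)
  pred <- predict_size_histogram(model, observed$bin_edges,
                                 total = sum(counts))
  rss <- sum((counts - pred$counts)^2)
  w2 <- 1 - .occupancy_weights(model$lambda)[1]  # mass in n >= 2 modes
  structure(list(
    model = model,
    observed = observed,
    fitted_counts = pred$counts,
    rss = rss,
    residual_norm = sqrt(rss / sum(counts^2)),
    converged = final$conv,
    a_identifiable = w2 > 1e-3,
    free = c(lambda = lambda_free, d1_nm = d1_free, noise = noise_free,
             a = TRUE)
  ), class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat("Droplet-occupancy model fit\n")
  print(x$model)
  cat(sprintf("  residual norm %.3g; converged: %s%s\n", x$residual_norm,
              x$converged,
              if (!x$a_identifiable)
                "; WARNING: exponent a not identifiable (monomer-only data)"
              else ""))
  invisible(x)
}

#' @export
coef.occupancy_fit <- function(object, ...) {
  with(object$model,
       c(lambda = lambda, d1_nm = d1_nm, a = a, noise = noise))
}

#' @export
summary.occupancy_fit <- function(object, ...) {
  res <- object$observed$counts - object$fitted_counts
  out <- list(coefficients = coef(object), rss = object$rss,
              residual_norm = object$residual_norm,
              residual_range = range(res),
              a_identifiable = object$a_identifiable,
              converged = object$converged, free = object$free)
  class(out) <- "summary.occupancy_fit"
  out
}

#' @export
print.summary.occupancy_fit <- function(x, ...) {
  cat("Droplet-occupancy model fit\n\nCoefficients:\n")
  print(x$coefficients)
  cat(sprintf("\nRSS %.4g (residual norm %.3g), residuals in [%.3g, %.3g]\n",
              x$rss, x$residual_norm, x$residual_range[1],
              x$residual_range[2]))
  cat("Free parameters:", paste(names(x$free)[x$free], collapse = ", "), "\n")
  if (!x$a_identifiable)
    cat("NOTE: a is not identifiable from effectively monomer-only data\n")
  invisible(x)
}

#' @export
predict.occupancy_fit <- function(object, bin_edges = NULL, total = NULL, ...) {
  if (is.null(bin_edges)) bin_edges <- object$observed$bin_edges
  if (is.null(total)) total <- sum(object$observed$counts)
  predict_size_histogram(object$model, bin_edges, total = total)
}

#' @export
residuals.occupancy_fit <- function(object, ...) {
  object$observed$counts - object$fitted_counts
}

#' @export
simulate.occupancy_fit <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$model, nsim = nsim, seed = seed,
           bin_edges = object$observed$bin_edges,
           n_particles = round(sum(object$observed$counts)), ...)
}

#' @export
plot.occupancy_fit <- function(x, ...) {
  centers <- (x$observed$bin_edges[-1] +
                x$observed$bin_edges[-length(x$observed$bin_edges)]) / 2
  graphics::plot(centers, x$observed$counts, type = "h",
                 xlab = "diameter (nm)", ylab = "count", ...)
  graphics::lines(centers, x$fitted_counts, col = 2, lwd = 2)
  invisible(x)
}

#' Read / write a size histogram as two-column CSV
#'
#' Plain-text exchange format: columns \code{bin_left_nm}, \code{count};
#' bins must be contiguous and uniform (the final right edge is the last
#' left edge plus the common width).
#'
#' @param path CSV file path.
#' @return \code{read_size_histogram}: a \code{size_distribution}.
#' @export
read_size_histogram <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("bin_left_nm", "count") %in% names(d)))
    stop("expected columns bin_left_nm, count")
  w <- diff(d$bin_left_nm)
  if (length(w) == 0 || max(abs(w - w[1])) > 1e-6 * w[1])
    stop("bins must be uniform and contiguous")
  size_distribution(c(d$bin_left_nm, d$bin_left_nm[length(d$bin_left_nm)] + w[1]),
                    d$count)
}

#' @rdname read_size_histogram
#' @param x a \code{size_distribution}.
#' @export
write_size_histogram <- function(x, path) {
  stopifnot(inherits(x, "size_distribution"))
  utils::write.csv(
    data.frame(bin_left_nm = x$bin_edges[-length(x$bin_edges)],
               count = x$counts),
    path, row.names = FALSE)
  invisible(path)
}
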