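# Synthetic diffraction-frame generator: uniform-sphere (and voxelized
# icosahedron) scattering on the two-panel detector, Poisson photon noise,
# gas background, and injected detector artifacts (pedestal, common mode,
# hot pixels). Stands in for the unreleased beamtime data: every frame comes
# with a ground-truth record.

.r_e_A <- 2.8179403e-5   # classical electron radius, Angstrom
.J_per_eV <- 1.602176634e-19

#' Diffraction intensity of a uniform sphere
#'
#' I(q) = i0 * [3 (sin(qr) - qr cos(qr)) / (qr)^3]^2 with r = diameter/2,
#' continuous at q = 0 with value i0. First minimum at q r = 4.4934.
#'
#' @param q scattering-vector magnitude(s), nm^-1.
#' @param diameter_nm sphere diameter (nm).
#' @param i0 forward-scattering intensity (photons/pixel at q = 0).
#' @return expected photons/pixel at each q.
#' @export
sphere_intensity <- function(q, diameter_nm, i0 = 1) {
  if (any(q < 0)) stop("q must be nonnegative")
  if (diameter_nm <= 0) stop("diameter must be positive")
  if (any(i0 < 0)) stop("i0 must be nonnegative")
  x <- q * diameter_nm / 2
  ff <- ifelse(x < 1e-4,
               1 - x^2 / 10,                       # series, avoids 0/0
               3 * (sin(x) - x * cos(x)) / x^3)
  i0 * ff^2
}

# element data for electron-density estimates
.elements <- data.frame(
  symbol = c("H", "C", "N", "O", "S", "P", "Na", "Cl", "K", "Ca", "Mg", "Fe"),
  Z = c(1, 6, 7, 8, 16, 15, 11, 17, 19, 20, 12, 26),
  mass = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974, 22.990, 35.45,
           39.098, 40.078, 24.305, 55.845))

#' Electron density of a material from mass density and composition
#'
#' rho_e = rho * N_A * sum(Z_i) / sum(M_i), converted to electrons per
#' cubic Angstrom. The protein default composition H86 C52 N13 O15 S at
#' 1.35 g/cm^3 gives ~0.43 A^-3.
#'
#' @param mass_density_g_cm3 mass density (g/cm^3).
#' @param composition named numeric vector of element counts,
#'   e.g. \code{c(H = 86, C = 52, N = 13, O = 15, S = 1)}.
#' @return electron density in A^-3.
#' @export
protein_electron_density <- function(mass_density_g_cm3,
                                     composition = c(H = 86, C = 52, N = 13,
                                                     O = 15, S = 1)) {
  if (mass_density_g_cm3 <= 0) stop("mass density must be positive")
  if (length(composition) == 0) stop("composition must be nonempty")
  idx <- match(names(composition), .elements$symbol)
  if (anyNA(idx))
    stop("unknown element symbol(s): ",
         paste(names(composition)[is.na(idx)], collapse = ", "))
  z_sum <- sum(composition * .elements$Z[idx])
  m_sum <- sum(composition * .elements$mass[idx])
  mass_density_g_cm3 * 6.02214076e23 * z_sum / m_sum * 1e-24
}

#' Particle model for the forward simulator
#'
#' @param shape "sphere" or "icosahedron" (diameter then refers to the
#'   circumscribed sphere).
#' @param diameter_nm particle diameter (nm).
#' @param electron_density_A3 electron density (A^-3); the protein estimate
#'   0.43 is the default.
#' @param orientation unit quaternion (w, x, y, z) for icosahedra.
#' @return object of class \code{particle_model}.
#' @export
particle_model <- function(shape = c("sphere", "icosahedron"),
                           diameter_nm, electron_density_A3 = 0.43,
                           orientation = c(1, 0, 0, 0)) {
  shape <- match.arg(shape)
  if (diameter_nm <= 0) stop("diameter must be positive")
  if (electron_density_A3 <= 0) stop("electron density must be positive")
  orientation <- orientation / sqrt(sum(orientation^2))
  structure(list(shape = shape, diameter_nm = diameter_nm,
                 electron_density_A3 = electron_density_A3,
                 orientation = orientation),
            class = "particle_model")
}

#' Forward-scattering intensity per pixel at q = 0
#'
#' i0 = Phi * r_e^2 * (rho_e V)^2 * dOmega, with Phi the incident photon
#' fluence (photons/area) from the beam's peak fluence and photon energy,
#' r_e the classical electron radius, rho_e V the particle's electron count
#' and dOmega the on-axis pixel solid angle.
#'
#' @param beam a \code{beam_parameters}.
#' @param particle a \code{particle_model} (sphere volume is used; for an
#'   icosahedron the circumscribed sphere's volume upper-bounds i0).
#' @param geometry a \code{detector_geometry}.
#' @param fluence_mJ_um2 optional fluence override (defaults to the beam's
#'   peak fluence).
#' @return photons/pixel at q = 0.
#' @export
forward_scale <- function(beam, particle, geometry,
                          fluence_mJ_um2 = beam$peak_fluence_mJ_um2) {
  phi_A2 <- .photon_fluence_A2(fluence_mJ_um2, beam$photon_energy_eV)
  vol_A3 <- (pi / 6) * (particle$diameter_nm * 10)^3
  n_e <- particle$electron_density_A3 * vol_A3
  d_omega <- (geometry$pixel_pitch_mm / geometry$detector_distance_mm)^2
  phi_A2 * .r_e_A^2 * n_e^2 * d_omega
}

# photons per square Angstrom from fluence (mJ/um^2) and photon energy (eV)
.photon_fluence_A2 <- function(fluence_mJ_um2, photon_energy_eV) {
  photons_um2 <- fluence_mJ_um2 * 1e-3 / (photon_energy_eV * .J_per_eV)
  photons_um2 / 1e8
}

#' Fluence implied by a fitted forward-scattering intensity
#'
#' Inverts \code{\link{forward_scale}} for a known particle diameter.
#'
#' @param i0 photons/pixel at q = 0.
#' @param diameter_nm particle diameter (nm).
#' @param beam,geometry beam and detector descriptions.
#' @param electron_density_A3 assumed electron density.
#' @return implied incident fluence in mJ/um^2.
#' @export
fluence_from_i0 <- function(i0, diameter_nm, beam, geometry,
                            electron_density_A3 = 0.43) {
  p <- particle_model("sphere", diameter_nm, electron_density_A3)
  unit <- forward_scale(beam, p, geometry, fluence_mJ_um2 = 1)
  i0 / unit
}

# --- icosahedron forward pattern -------------------------------------------

# face-normal directions of the icosahedron (vertex directions of the dual
# dodecahedron); inradius/circumradius ratio = phi^2 / (sqrt(3) * ...) ~ 0.7947
.icosa_face_normals <- function() {
  phi <- (1 + sqrt(5)) / 2
  s <- c(-1, 1)
  cube <- as.matrix(expand.grid(x = s, y = s, z = s))
  sg <- as.matrix(expand.grid(y = s, z = s))
  cyc <- cbind(0, sg[, 1] / phi, sg[, 2] * phi)
  m <- rbind(cube,
             cyc,
             cyc[, c(3, 1, 2)],
             cyc[, c(2, 3, 1)])
  m / sqrt(rowSums(m^2))
}

.quat_rotation_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' 2D diffraction pattern of a voxelized solid icosahedron
#'
#' Voxelizes a solid icosahedron (voxel edge <= diameter / n_vox), projects
#' it along the beam axis, and takes the squared-magnitude discrete Fourier
#' transform of the projection; Ewald-sphere curvature is neglected
#' (small-angle regime). Returned intensities are in squared electron
#' counts; multiply by Phi r_e^2 dOmega for photons/pixel.
#'
#' @param diameter_nm circumscribed-sphere diameter (nm).
#' @param electron_density_A3 electron density (A^-3).
#' @param orientation unit quaternion.
#' @param n_vox voxels across the diameter (>= 64 recommended).
#' @param pad zero-padding factor for the DFT grid.
#' @return list: \code{q_axis} (nm^-1, fftshifted, uniform), \code{F2}
#'   (matrix of squared structure-factor magnitudes, electrons^2).
#' @export
icosahedron_pattern <- function(diameter_nm, electron_density_A3 = 0.43,
                                orientation = c(1, 0, 0, 0),
                                n_vox = 64, pad = 4) {
  R_nm <- diameter_nm / 2
  inradius <- 0.7946545 * R_nm
  vox <- diameter_nm / n_vox
  ax <- (seq_len(n_vox) - (n_vox + 1) / 2) * vox
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  normals <- .icosa_face_normals() %*% t(.quat_rotation_matrix(orientation))
  inside <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(normals))) {
    inside <- inside & (pts %*% normals[i, ] <= inradius)
    }
  proj <- apply(array(inside, c(n_vox, n_vox, n_vox)), c(1, 2), sum) * vox
  # electrons per projected column: density (A^-3) * thickness(nm->A) * area
  electrons <- proj * 10 * electron_density_A3 * (vox * 10)^2
  n_fft <- n_vox * pad
  padded <- matrix(0, n_fft, n_fft)
  padded[seq_len(n_vox), seq_len(n_vox)] <- electrons
  F2 <- abs(stats::fft(padded))^2
  shift <- function(m) {
    h <- nrow(m) / 2
    m[c((h + 1):nrow(m), 1:h), c((h + 1):ncol(m), 1:h)]
  }
  q_axis <- 2 * pi * (seq_len(n_fft) - n_fft / 2 - 1) / (n_fft * vox)
  list(q_axis = q_axis, F2 = shift(F2), voxel_nm = vox)
}

# bilinear lookup of a pattern on (qx, qy); zero outside the grid
.pattern_interp <- function(pattern, qx, qy) {
  dq <- pattern$q_axis[2] - pattern$q_axis[1]
  n <- length(pattern$q_axis)
  fx <- (qx - pattern$q_axis[1]) / dq + 1
  fy <- (qy - pattern$q_axis[1]) / dq + 1
  ix <- floor(fx); iy <- floor(fy)
  ok <- ix >= 1 & ix < n & iy >= 1 & iy < n
  wx <- fx - ix; wy <- fy - iy
  out <- numeric(length(qx))
  g <- function(i, j) pattern$F2[cbind(pmin(pmax(i, 1), n),
                                       pmin(pmax(j, 1), n))]
  out[ok] <- (1 - wx[ok]) * (1 - wy[ok]) * g(ix[ok], iy[ok]) +
    wx[ok] * (1 - wy[ok]) * g(ix[ok] + 1, iy[ok]) +
    (1 - wx[ok]) * wy[ok] * g(ix[ok], iy[ok] + 1) +
    wx[ok] * wy[ok] * g(ix[ok] + 1, iy[ok] + 1)
  out
}

# --- background / artifacts -------------------------------------------------

#' Detector background and artifact model
#'
#' @param pedestal_adu per-pixel ADU offsets: scalar or assembled-frame
#'   matrix (see \code{\link{make_pedestal}}).
#' @param gain_adu_per_photon ADU per photon (> 0).
#' @param dark_noise_adu Gaussian read-noise s.d. (ADU).
#' @param gas_rate mean gas-fluorescence photons/pixel (isotropic term).
#' @param gas_halo_amplitude peak photons/pixel of a radially decaying halo.
#' @param gas_halo_scale_px halo e-folding radius (pixels).
#' @param cm_quadrant_sd,cm_row_sd,cm_col_sd s.d. of per-frame common-mode
#'   offsets (photon units) per quadrant / fast line / slow line.
#' @param hot_pixels integer matrix (row, col) of hot-pixel positions
#'   (1-based, assembled frame), or NULL.
#' @param hot_value_photons reading of a hot pixel (photons).
#' @return object of class \code{background_model}.
#' @export
background_model <- function(pedestal_adu = 1000, gain_adu_per_photon = 20,
                             dark_noise_adu = 2, gas_rate = 0.001,
                             gas_halo_amplitude = 0, gas_halo_scale_px = 150,
                             cm_quadrant_sd = 0.05, cm_row_sd = 0.02,
                             cm_col_sd = 0.02, hot_pixels = NULL,
                             hot_value_photons = 100) {
  if (gain_adu_per_photon <= 0) stop("gain must be positive")
  if (dark_noise_adu < 0 || gas_rate < 0 || gas_halo_amplitude < 0 ||
      cm_quadrant_sd < 0 || cm_row_sd < 0 || cm_col_sd < 0)
    stop("noise amplitudes and rates must be nonnegative")
  structure(as.list(environment()), class = "background_model")
}

#' Frozen per-pixel pedestal map
#' @param geometry a \code{detector_geometry}.
#' @param base_adu mean pedestal level (ADU).
#' @param sd_adu pixel-to-pixel spread (ADU).
#' @param seed RNG seed fixing the map.
#' @return assembled-frame matrix of pedestal offsets.
#' @export
make_pedestal <- function(geometry, base_adu = 1000, sd_adu = 30, seed = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  matrix(stats::rnorm(geometry$n_rows * geometry$n_cols, base_adu, sd_adu),
         geometry$n_rows, geometry$n_cols)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed",
                                                       envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# expected photons/pixel (matrix) for a particle (or NULL) on the detector
.expected_photons <- function(particle, beam, geometry, background, qmap,
                              fluence_factor = 1, pattern_cache = NULL) {
  expect <- background$gas_rate +
    background$gas_halo_amplitude * exp(-qmap$r_px / background$gas_halo_scale_px)
  expect <- matrix(expect, geometry$n_rows, geometry$n_cols)
  if (!is.null(particle)) {
    if (particle$shape == "sphere") {
      i0 <- forward_scale(beam, particle, geometry) * fluence_factor
      expect <- expect + sphere_intensity(qmap$q, particle$diameter_nm, i0)
    } else {
      pat <- if (is.null(pattern_cache))
        icosahedron_pattern(particle$diameter_nm,
                            particle$electron_density_A3,
                            particle$orientation) else pattern_cache
      r <- pmax(qmap$r_px, 1e-9)
      pitch <- geometry$pixel_pitch_mm
      rows <- (seq_len(geometry$n_rows) - 1) - geometry$beam_center[1]
      cols <- (seq_len(geometry$n_cols) - 1) - geometry$beam_center[2]
      dy <- matrix(rows, geometry$n_rows, geometry$n_cols)
      dx <- matrix(cols, geometry$n_rows, geometry$n_cols, byrow = TRUE)
      qx <- qmap$q * dx / r
      qy <- qmap$q * dy / r
      F2 <- .pattern_interp(pat, as.vector(qx), as.vector(qy))
      phi <- .photon_fluence_A2(beam$peak_fluence_mJ_um2,
                                beam$photon_energy_eV) * fluence_factor
      d_omega <- (pitch / geometry$detector_distance_mm)^2
      expect <- expect + matrix(phi * .r_e_A^2 * F2 * d_omega,
                                geometry$n_rows, geometry$n_cols)
    }
  }
  expect[qmap$gap] <- 0
  expect
}

#' Simulate one raw detector frame
#'
#' Expectation = particle diffraction + gas background; photons are
#' Poisson-sampled, converted to ADU via the gain, and corrupted with the
#' pedestal, Gaussian dark noise, per-frame common-mode offsets (per
#' quadrant, per row, per column, in photon units scaled by the gain) and
#' hot pixels. Gap pixels are NA.
#'
#' @param particle a \code{particle_model} or NULL (particle-free frame).
#' @param beam,geometry,background model components.
#' @param qmap precomputed \code{\link{build_qmap}} for the geometry/beam.
#' @param rng_seed integer seed; identical seeds give identical frames.
#' @param fluence_factor per-shot relative fluence (1 = peak).
#' @return list: \code{raw} (ADU matrix, NA in the gap), \code{photons}
#'   (noise-free expectation is not stored; this is the sampled photon
#'   image before ADU conversion), \code{common_mode} (injected offsets).
#' @export
simulate_frame <- function(particle, beam, geometry, background, qmap,
                           rng_seed, fluence_factor = 1) {
  set.seed(rng_seed)
  expect <- .expected_photons(particle, beam, geometry, background, qmap,
                              fluence_factor)
  photons <- matrix(stats::rpois(length(expect), as.vector(expect)),
                    geometry$n_rows, geometry$n_cols)
  gain <- background$gain_adu_per_photon
  raw <- photons * gain + background$pedestal_adu
  if (background$dark_noise_adu > 0)
    raw <- raw + matrix(stats::rnorm(length(raw), 0,
                                     background$dark_noise_adu),
                        nrow(raw), ncol(raw))
  cm <- .draw_common_mode(geometry, background)
  raw <- raw + cm$offsets * gain
  if (!is.null(background$hot_pixels) && nrow(background$hot_pixels) > 0)
    raw[background$hot_pixels] <- raw[background$hot_pixels] +
      background$hot_value_photons * gain
  raw[qmap$gap] <- NA_real_
  list(raw = raw, photons = photons, common_mode = cm)
}

# draw common-mode offsets (photon units) as an assembled-frame matrix
.draw_common_mode <- function(geometry, background) {
  off <- matrix(0, geometry$n_rows, geometry$n_cols)
  quads <- panel_quadrants(geometry)
  q_off <- stats::rnorm(length(quads), 0, background$cm_quadrant_sd)
  for (i in seq_along(quads))
    off[quads[[i]]$rows, quads[[i]]$cols] <-
      off[quads[[i]]$rows, quads[[i]]$cols] + q_off[i]
  r_off <- numeric(geometry$n_rows)
  c_off <- matrix(0, 2, geometry$n_cols)
  for (p in 1:2) {
    rows <- geometry$panel_rows_idx[[p]]
    r_off[rows] <- stats::rnorm(length(rows), 0, background$cm_row_sd)
    c_off[p, ] <- stats::rnorm(geometry$n_cols, 0, background$cm_col_sd)
    off[rows, ] <- off[rows, ] + r_off[rows] +
      matrix(c_off[p, ], length(rows), geometry$n_cols, byrow = TRUE)
  }
  list(offsets = off, quadrant = q_off, row = r_off, col = c_off)
}

#' Quadrant (half-panel) index ranges of the assembled frame
#' @param geometry a \code{detector_geometry}.
#' @return list of quadrants, each \code{list(rows =, cols =)}.
#' @export
panel_quadrants <- function(geometry) {
  half <- geometry$n_cols %/% 2
  out <- list()
  for (p in 1:2) for (h in 1:2)
    out[[length(out) + 1]] <- list(
      rows = geometry$panel_rows_idx[[p]],
      cols = if (h == 1) seq_len(half) else seq.int(half + 1, geometry$n_cols))
  out
}

#' Simulate dark (x-rays off) frames for pedestal estimation
#' @param n_frames number of dark frames.
#' @param geometry,background model components.
#' @param seed RNG seed.
#' @return list of raw ADU matrices (no gap masking: darks are recorded on
#'   the physical panels; gap rows are NA as in data frames).
#' @export
simulate_dark_stack <- function(n_frames, geometry, background, seed) {
  set.seed(seed)
  gap <- gap_mask(geometry)
  lapply(seq_len(n_frames), function(i) {
    f <- background$pedestal_adu +
      matrix(stats::rnorm(geometry$n_rows * geometry$n_cols, 0,
                          background$dark_noise_adu),
             geometry$n_rows, geometry$n_cols)
    f[gap] <- NA_real_
    f
  })
}

#' Simulate a measurement run with ground truth
#'
#' Frames are hits with probability \code{hit_fraction}; hit diameters are
#' drawn from \code{size_dist}. All randomness derives from the single run
#' seed: per-frame seeds are drawn up front, so frame i is reproducible
#' independently of the others.
#'
#' @param size_dist hit-diameter distribution: a single number (monodisperse),
#'   a function(n) returning diameters, an \code{occupancy_model}
#'   (cluster sizes), or \code{list(dist = "normal"|"lognormal", mean/sd or
#'   meanlog/sdlog)}.
#' @param hit_fraction probability a frame contains a particle.
#' @param n_frames number of frames.
#' @param beam,geometry,background model components.
#' @param seed run seed.
#' @param shape particle shape passed to \code{\link{particle_model}}.
#' @param electron_density_A3 particle electron density.
#' @param fluence_jitter if non-NULL, \code{c(min, max)} relative per-shot
#'   fluence drawn uniformly.
#' @param frame_callback optional \code{function(frame, truth_row)} called
#'   per frame; when supplied, raw frames are not accumulated (streaming).
#' @return object of class \code{simulated_run}: \code{truth} data.frame
#'   (frame, is_hit, diameter_nm, n_particles, fluence_factor,
#'   center_offset_px, seed) and \code{frames} (list of raw matrices, or
#'   NULL when streaming).
#' @export
simulate_run <- function(size_dist, hit_fraction, n_frames, beam, geometry,
                         background, seed, shape = "sphere",
                         electron_density_A3 = 0.43, fluence_jitter = NULL,
                         frame_callback = NULL) {
  if (hit_fraction < 0 || hit_fraction > 1)
    stop("hit_fraction must lie in [0, 1]")
  if (n_frames < 1) stop("need at least one frame")
  qmap <- build_qmap(geometry, beam)
  set.seed(seed)
  frame_seeds <- sample.int(.Machine$integer.max - 1L, n_frames)
  is_hit <- stats::runif(n_frames) < hit_fraction
  n_hits <- sum(is_hit)
  diam <- rep(NA_real_, n_frames)
  n_part <- rep(NA_integer_, n_frames)
  if (n_hits > 0) {
    if (inherits(size_dist, "occupancy_model")) {
      w <- .occupancy_weights(size_dist$lambda)
      occ <- sample.int(length(w), n_hits, replace = TRUE, prob = w)
      ctr <- cluster_diameter(occ, size_dist$d1_nm, size_dist$a)
      diam[is_hit] <- stats::rnorm(n_hits, ctr, size_dist$noise * ctr)
      n_part[is_hit] <- occ
    } else {
      diam[is_hit] <- .draw_diameters(size_dist, n_hits)
      n_part[is_hit] <- 1L
    }
  }
  ff <- rep(1, n_frames)
  if (!is.null(fluence_jitter))
    ff <- stats::runif(n_frames, fluence_jitter[1], fluence_jitter[2])
  truth <- data.frame(frame = seq_len(n_frames), is_hit = is_hit,
                      diameter_nm = diam, n_particles = n_part,
                      fluence_factor = ff, center_offset_px = 0,
                      seed = frame_seeds)
  frames <- if (is.null(frame_callback)) vector("list", n_frames) else NULL
  for (i in seq_len(n_frames)) {
    particle <- if (is_hit[i])
      particle_model(shape, diam[i], electron_density_A3) else NULL
    fr <- simulate_frame(particle, beam, geometry, background, qmap,
                         rng_seed = frame_seeds[i], fluence_factor = ff[i])
    if (is.null(frame_callback)) frames[[i]] <- fr$raw
    else frame_callback(fr$raw, truth[i, ])
  }
  structure(list(truth = truth, frames = frames, seed = seed,
                 beam = beam, geometry = geometry, background = background),
            class = "simulated_run")
}

.draw_diameters <- function(size_dist, n) {
  if (is.function(size_dist)) return(size_dist(n))
  if (is.numeric(size_dist) && length(size_dist) == 1)
    return(rep(size_dist, n))
  if (is.list(size_dist)) {
    if (size_dist$dist == "normal")
      return(stats::rnorm(n, size_dist$mean, size_dist$sd))
    if (size_dist$dist == "lognormal")
      return(stats::rlnorm(n, size_dist$meanlog, size_dist$sdlog))
  }
  stop("unsupported size distribution specification")
}

#' @export
print.simulated_run <- function(x, ...) {
  cat(sprintf("Simulated run: %d frames (%d hits), seed %d\n",
              nrow(x$truth), sum(x$truth$is_hit), x$seed))
  invisible(x)
}
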