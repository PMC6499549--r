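# Aerosolization arithmetic: droplet volumes, production rates, occupancy
# concentrations, dried-particle and contamination-coated diameters.
#
# Units: diameters nm, volumes ml, liquid flow ul/min, rates 1/s.

.NM3_PER_ML <- 1e21  # 1 ml = 1e21 nm^3

#' Droplet (sphere) volume
#' @param diameter_nm droplet diameter in nm.
#' @return volume in ml.
#' @examples
#' droplet_volume(1000) / droplet_volume(150) # ~300: GDVN vs electrospray
#' @export
droplet_volume <- function(diameter_nm) {
  if (any(diameter_nm < 0)) stop("diameter must be nonnegative")
  (pi / 6) * diameter_nm^3 / .NM3_PER_ML
}

#' Droplet production rate R = Q / V
#'
#' @param flow_ul_min liquid flow rate Q (ul/min).
#' @param droplet_diameter_nm characteristic droplet diameter (nm).
#' @return droplets per second.
#' @examples
#' particle_rate(0.06, 150) # electrospray: ~5.7e8 /s
#' particle_rate(2, 1000)   # gas-dynamic virtual nozzle: ~0.6e8 /s
#' @export
particle_rate <- function(flow_ul_min, droplet_diameter_nm) {
  if (any(flow_ul_min < 0)) stop("flow rate must be nonnegative")
  if (any(droplet_diameter_nm <= 0)) stop("droplet diameter must be positive")
  q_ml_s <- flow_ul_min * 1e-3 / 60
  q_ml_s / droplet_volume(droplet_diameter_nm)
}

#' Concentration giving an average droplet occupancy of one
#'
#' One particle per droplet on average requires concentration 1/V(d);
#' scales as d^-3.
#'
#' @param droplet_diameter_nm droplet diameter (nm).
#' @return particles per ml.
#' @export
unit_occupancy_concentration <- function(droplet_diameter_nm) {
  if (any(droplet_diameter_nm <= 0)) stop("droplet diameter must be positive")
  1 / droplet_volume(droplet_diameter_nm)
}

#' Dried-particle diameter after solvent evaporation
#'
#' A droplet of diameter d0 carrying nonvolatile solute at volume
#' concentration c dries to a particle of diameter d0 * c^(1/3).
#'
#' @param d0_nm initial droplet diameter (nm).
#' @param c volume concentration of nonvolatile solute, in [0, 1].
#' @return dried particle diameter (nm).
#' @export
dried_particle_diameter <- function(d0_nm, c) {
  if (any(d0_nm <= 0)) stop("droplet diameter must be positive")
  if (any(c < 0 | c > 1)) stop("volume concentration must lie in [0, 1]")
  d0_nm * c^(1 / 3)
}

#' Initial droplet diameter implied by a dried particle
#'
#' Inverse of \code{\link{dried_particle_diameter}}:
#' d0 = d_p * c^(-1/3).
#'
#' @param dp_nm dried particle diameter (nm).
#' @param c volume concentration of nonvolatile solute, in (0, 1].
#' @return initial droplet diameter (nm).
#' @export
initial_droplet_diameter <- function(dp_nm, c) {
  if (any(dp_nm <= 0)) stop("particle diameter must be positive")
  if (any(c <= 0 | c > 1)) stop("volume concentration must lie in (0, 1]")
  dp_nm * c^(-1 / 3)
}

#' Particle diameter after accumulating nonvolatile residue
#'
#' Volume-additive residue model: the nonvolatile contaminant dissolved in
#' the initial droplet (volume fraction c) deposits onto the particle, so
#' the coated diameter is (d_p^3 + c d0^3)^(1/3). With d_p = 0 this reduces
#' to the dried-particle diameter of a pure-contaminant droplet.
#'
#' @param particle_diameter_nm bare particle diameter (nm).
#' @param d0_nm initial droplet diameter (nm).
#' @param c contaminant volume concentration, in [0, 1].
#' @return coated particle diameter (nm).
#' @export
coated_particle_diameter <- function(particle_diameter_nm, d0_nm, c) {
  if (any(particle_diameter_nm < 0) || any(d0_nm < 0))
    stop("diameters must be nonnegative")
  if (any(c < 0 | c > 1)) stop("contaminant concentration must lie in [0, 1]")
  (particle_diameter_nm^3 + c * d0_nm^3)^(1 / 3)
}

#' Ratio of x-ray scattering cross sections of two homogeneous spheres
#'
#' For equal electron density the integrated elastic cross section scales
#' with the squared electron count times the inverse coherence volume,
#' i.e. proportionally to particle volume; the ratio is (d2/d1)^3.
#'
#' @param diameter_1_nm,diameter_2_nm sphere diameters (nm).
#' @return dimensionless cross-section ratio (sphere 2 relative to sphere 1).
#' @examples
#' cross_section_ratio(11, 35) # virion vs single enzyme: ~30x
#' @export
cross_section_ratio <- function(diameter_1_nm, diameter_2_nm) {
  if (any(diameter_1_nm <= 0) || any(diameter_2_nm <= 0))
    stop("diameters must be positive")
  (diameter_2_nm / diameter_1_nm)^3
}
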