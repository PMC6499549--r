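# Shared fixtures: all synthetic, built in code at test time.

# small two-panel detector for fast tests (same pitch/conventions as the
# full instrument, fewer pixels)
tiny_geometry <- function(distance_mm = 259, gap_mm = 1.5,
                          panel_rows = 48, panel_cols = 96) {
  detector_geometry(distance_mm, gap_mm, panel_rows = panel_rows,
                    panel_cols = panel_cols)
}

tiny_beam <- function() beam_parameters(800, peak_fluence_mJ_um2 = 0.02)

# background with every artifact switched off
quiet_background <- function(pedestal = 0) {
  background_model(pedestal_adu = pedestal, gain_adu_per_photon = 1,
                   dark_noise_adu = 0, gas_rate = 0,
                   cm_quadrant_sd = 0, cm_row_sd = 0, cm_col_sd = 0,
                   hot_pixels = NULL)
}

# binary disk-with-notch test object on an n x n grid
notched_disk <- function(n, radius = n %/% 5) {
  obj <- matrix(0, n, n)
  disk <- support_disk(n, radius)
  notch <- outer(abs(seq_len(n) - (n / 2 - radius / 2)) <= radius / 4,
                 abs(seq_len(n) - n / 2) <= radius / 4, `&`)
  obj[disk & !notch] <- 1
  obj
}

# correlation between a reconstruction and the known object, after aligning
# the object onto the reconstruction (integer shift + conjugate flip)
recon_correlation <- function(image, truth) {
  al <- espraydiff:::.align_to(image, truth)
  stats::cor(as.vector(al), as.vector(image))
}
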