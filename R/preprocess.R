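# Detector preprocessing: raw ADU frames -> calibrated photon images.
# Step order is fixed: pedestal -> gain -> common mode (quadrant, fast
# line, slow line) -> ASIC rescale -> hit finding. All steps are
# deterministic and mask-aware; gap pixels stay NA throughout.

.mask_codes <- c(none = 0L, gap = 1L, hot = 2L, saturated = 3L,
                 shadowed = 4L, non_poisson = 5L, manual = 6L)

#' Pixel mask aligned to the assembled frame
#'
#' @param geometry a \code{detector_geometry}; gap pixels are always masked.
#' @return object of class \code{pixel_mask}: logical \code{bad} matrix and
#'   integer \code{reason} matrix (codes: gap, hot, saturated, shadowed,
#'   non_poisson, manual).
#' @export
pixel_mask <- function(geometry) {
  bad <- gap_mask(geometry)
  reason <- matrix(0L, geometry$n_rows, geometry$n_cols)
  reason[bad] <- .mask_codes[["gap"]]
  structure(list(bad = bad, reason = reason, codes = .mask_codes),
            class = "pixel_mask")
}

#' Mark additional pixels in a mask
#' @param mask a \code{pixel_mask}.
#' @param pixels integer matrix (row, col) or logical matrix.
#' @param reason one of the mask reason codes.
#' @return updated \code{pixel_mask}.
#' @export
mask_pixels <- function(mask, pixels, reason = "manual") {
  code <- .mask_codes[[reason]]
  if (is.logical(pixels)) {
    mask$bad <- mask$bad | pixels
    mask$reason[pixels & mask$reason == 0L] <- code
  } else {
    mask$bad[pixels] <- TRUE
    sel <- pixels[mask$reason[pixels] == 0L, , drop = FALSE]
    mask$reason[sel] <- code
  }
  mask
}

#' @export
print.pixel_mask <- function(x, ...) {
  tab <- table(factor(x$reason[x$bad],
                      levels = x$codes[-1], labels = names(x$codes)[-1]))
  cat(sprintf("Pixel mask: %d of %d pixels masked\n", sum(x$bad),
              length(x$bad)))
  print(tab)
  invisible(x)
}

#' Pedestal subtraction using dark frames
#'
#' Subtracts the per-pixel mean of a dark-frame stack.
#'
#' @param raw raw ADU frame (assembled matrix).
#' @param dark_stack list of dark ADU frames (same shape) or a precomputed
#'   pedestal matrix.
#' @return pedestal-subtracted ADU frame.
#' @export
pedestal_subtract <- function(raw, dark_stack) {
  ped <- if (is.matrix(dark_stack)) dark_stack else {
    if (length(dark_stack) == 0) stop("dark stack is empty")
    Reduce(`+`, dark_stack) / length(dark_stack)
  }
  if (!all(dim(ped) == dim(raw))) stop("dark/raw shape mismatch")
  raw - ped
}

#' Three-step common-mode correction
#'
#' Per panel, sequentially subtracts (1) the per-quadrant (half-panel)
#' median, (2) the per-fast-line (row) median, and (3) the per-slow-line
#' (column) median, each computed only over unmasked pixels measuring below
#' \code{threshold} photons. Groups with no sub-threshold pixels are left
#' unchanged and counted in the \code{"empty_groups"} attribute.
#'
#' @param frame photon-unit frame (assembled matrix).
#' @param geometry a \code{detector_geometry}.
#' @param mask optional \code{pixel_mask}.
#' @param threshold photon threshold selecting background pixels.
#' @return corrected frame with attribute \code{empty_groups}.
#' @export
common_mode_correct <- function(frame, geometry, mask = NULL,
                                threshold = 0.5) {
  bad <- if (is.null(mask)) gap_mask(geometry) else mask$bad
  empty <- 0L
  # per-group background median of the current frame state; groups with no
  # sub-threshold pixels get 0 (left unchanged)
  correct <- function(block, groups, n_groups) {
    sel <- !is.na(block) & block < threshold
    med <- .group_median(block[sel], groups[sel], n_groups)
    none <- !is.finite(med)
    empty <<- empty + sum(none)
    med[none] <- 0
    med
  }
  work <- frame
  work[bad] <- NA_real_
  quads <- panel_quadrants(geometry)
  # gap rows form a throwaway group so indexing stays aligned
  qgrp <- matrix(length(quads) + 1L, geometry$n_rows, geometry$n_cols)
  for (i in seq_along(quads))
    qgrp[quads[[i]]$rows, quads[[i]]$cols] <- i
  qmed <- correct(work, qgrp, length(quads) + 1L)
  empty <- empty - 1L            # the gap group is always empty by design
  adj <- matrix(qmed[qgrp], geometry$n_rows, geometry$n_cols)
  frame <- frame - adj
  work <- work - adj
  for (p in 1:2) {
    rows <- geometry$panel_rows_idx[[p]]
    blk <- work[rows, , drop = FALSE]
    rmed <- correct(blk, row(blk), nrow(blk))
    frame[rows, ] <- frame[rows, ] - rmed
    work[rows, ] <- blk - rmed
    blk <- work[rows, , drop = FALSE]
    cmed <- correct(blk, col(blk), ncol(blk))
    frame[rows, ] <- sweep(frame[rows, , drop = FALSE], 2, cmed)
    work[rows, ] <- sweep(blk, 2, cmed)
  }
  attr(frame, "empty_groups") <- empty
  frame
}

#' Rescale listed ASIC regions by a constant factor
#'
#' @param frame frame matrix.
#' @param asic_list list of regions, each \code{list(rows =, cols =)}
#'   (index vectors into the assembled frame).
#' @param factor multiplicative factor (the faulty-quadrant fix used 2).
#' @return rescaled frame.
#' @export
asic_rescale <- function(frame, asic_list, factor = 2) {
  if (length(asic_list) == 0) return(frame)
  seen <- matrix(FALSE, nrow(frame), ncol(frame))
  for (a in asic_list) {
    if (any(seen[a$rows, a$cols])) stop("overlapping ASIC regions")
    seen[a$rows, a$cols] <- TRUE
    frame[a$rows, a$cols] <- frame[a$rows, a$cols] * factor
  }
  frame
}

#' Full calibration chain: raw ADU frame to photon units
#'
#' Pedestal subtraction, gain conversion, three-step common-mode
#' correction, optional ASIC rescale.
#'
#' @param raw raw ADU frame.
#' @param dark_stack dark frames or pedestal matrix
#'   (see \code{\link{pedestal_subtract}}).
#' @param gain_adu_per_photon detector gain.
#' @param geometry a \code{detector_geometry}.
#' @param mask optional \code{pixel_mask}.
#' @param cm_threshold common-mode background threshold (photons).
#' @param asic_list,asic_factor optional ASIC rescale regions.
#' @return list of class \code{calibrated_frame}: \code{photons} matrix and
#'   \code{log} (character vector of applied corrections).
#' @export
calibrate_frame <- function(raw, dark_stack, gain_adu_per_photon, geometry,
                            mask = NULL, cm_threshold = 0.5,
                            asic_list = NULL, asic_factor = 2) {
  log <- character(0)
  f <- pedestal_subtract(raw, dark_stack)
  log <- c(log, "pedestal")
  f <- f / gain_adu_per_photon
  log <- c(log, sprintf("gain (%g ADU/photon)", gain_adu_per_photon))
  f <- common_mode_correct(f, geometry, mask, threshold = cm_threshold)
  log <- c(log, sprintf("common mode (%d empty groups)",
                        attr(f, "empty_groups")))
  if (!is.null(asic_list)) {
    f <- asic_rescale(f, asic_list, asic_factor)
    log <- c(log, sprintf("ASIC rescale x%g", asic_factor))
  }
  structure(list(photons = f, log = log), class = "calibrated_frame")
}

#' Lit-pixel hit finding
#'
#' A frame is a hit iff strictly more than \code{min_lit} unmasked pixels
#' measure at least \code{lit_threshold} photons at a radial distance
#' greater than \code{min_radius} pixels from the beam center.
#'
#' @param frame photon-unit frame matrix (or \code{calibrated_frame}).
#' @param qmap a \code{qmap} (for radial pixel distances), or a
#'   \code{detector_geometry} from which distances are derived.
#' @param mask optional \code{pixel_mask}; masked pixels never count.
#' @param min_lit lit-pixel count that must be exceeded (default 3500).
#' @param min_radius radial gate in pixels (default 200).
#' @param lit_threshold photons defining a lit pixel (default 1).
#' @return list: \code{is_hit}, \code{lit_count}.
#' @export
find_hits <- function(frame, qmap, mask = NULL, min_lit = 3500,
                      min_radius = 200, lit_threshold = 1) {
  if (inherits(frame, "calibrated_frame")) frame <- frame$photons
  r_px <- if (inherits(qmap, "qmap")) qmap$r_px else
    build_qmap(qmap, beam_parameters())$r_px
  ok <- !is.na(frame) & r_px > min_radius
  if (!is.null(mask)) ok <- ok & !mask$bad
  lit <- sum(frame[ok] >= lit_threshold)
  list(is_hit = lit > min_lit, lit_count = lit)
}

# fast block sums: pads with NA to multiples of b, returns per-bin sums of
# the non-NA values and per-bin non-NA counts
.block_sum <- function(f, b) {
  nbr <- ceiling(nrow(f) / b)
  nbc <- ceiling(ncol(f) / b)
  if (nbr * b > nrow(f) || nbc * b > ncol(f)) {
    g <- matrix(NA_real_, nbr * b, nbc * b)
    g[seq_len(nrow(f)), seq_len(ncol(f))] <- f
    f <- g
  }
  ok <- !is.na(f)
  f[!ok] <- 0
  rg <- rep(seq_len(nbr), each = b)
  cg <- rep(seq_len(nbc), each = b)
  sums <- t(rowsum(t(rowsum(f, rg, reorder = FALSE)), cg, reorder = FALSE))
  counts <- t(rowsum(t(rowsum(ok + 0, rg, reorder = FALSE)), cg,
                     reorder = FALSE))
  dimnames(sums) <- dimnames(counts) <- NULL
  list(sums = sums, counts = counts, nbr = nbr, nbc = nbc)
}

# vectorized per-group median (NA for empty groups)
.group_median <- function(values, groups, n_groups) {
  o <- order(groups, values)
  v <- values[o]
  cnt <- tabulate(groups[o], n_groups)
  ends <- cumsum(cnt)
  starts <- ends - cnt + 1L
  out <- rep(NA_real_, n_groups)
  ne <- cnt > 0
  lo <- starts[ne] + (cnt[ne] - 1L) %/% 2L
  hi <- starts[ne] + cnt[ne] %/% 2L
  out[ne] <- (v[lo] + v[hi]) / 2
  out
}

#' Truncate below a photon floor, then bin
#'
#' Values below \code{floor} are set to 0, then non-overlapping
#' \code{bin_factor} x \code{bin_factor} sums are taken over unmasked
#' pixels (the frame is padded with masked pixels as needed).
#'
#' @param frame photon-unit frame (or \code{calibrated_frame}).
#' @param bin_factor bin edge length in pixels (>= 1).
#' @param floor photon floor (default 0.5).
#' @param mask optional \code{pixel_mask}.
#' @return list of class \code{binned_frame}: \code{values} (bin sums),
#'   \code{n_pixels} (unmasked pixels per bin), \code{mask_fraction},
#'   \code{bin_factor}.
#' @export
truncate_and_bin <- function(frame, bin_factor, floor = 0.5, mask = NULL) {
  if (inherits(frame, "calibrated_frame")) frame <- frame$photons
  if (bin_factor < 1) stop("bin_factor must be >= 1")
  b <- as.integer(bin_factor)
  f <- frame
  f[!is.na(f) & f < floor] <- 0
  if (!is.null(mask)) f[mask$bad] <- NA_real_
  bs <- .block_sum(f, b)
  structure(list(values = bs$sums, n_pixels = bs$counts,
                 mask_fraction = 1 - bs$counts / b^2, bin_factor = b),
            class = "binned_frame")
}

#' Bin a q-map consistently with \code{\link{truncate_and_bin}}
#' @param qmap a \code{qmap}.
#' @param bin_factor bin edge length in pixels.
#' @param mask optional \code{pixel_mask}.
#' @return list: \code{q} (mean q of unmasked pixels per bin, NA where a bin
#'   has none), \code{n_pixels}, \code{bin_factor}.
#' @export
bin_qmap <- function(qmap, bin_factor, mask = NULL) {
  b <- as.integer(bin_factor)
  q <- qmap$q
  bad <- qmap$gap
  if (!is.null(mask)) bad <- bad | mask$bad
  q[bad] <- NA_real_
  bs <- .block_sum(q, b)
  qbar <- bs$sums / pmax(bs$counts, 1)
  qbar[bs$counts == 0] <- NA_real_
  list(q = qbar, n_pixels = bs$counts, bin_factor = b)
}

#' Poisson-statistics good-pixel mask
#'
#' Over a particle-free buffer stack (photon units), a pixel is "good" iff
#' its variance/mean ratio deviates from 1 by less than \code{tol} and its
#' mean is positive; other pixels are masked with reason
#' \code{non_poisson}.
#'
#' @param buffer_stack list of photon-unit frames (>= 2).
#' @param geometry a \code{detector_geometry}.
#' @param tol allowed deviation of var/mean from 1 (default 0.3).
#' @return a \code{pixel_mask}.
#' @export
poisson_good_pixel_mask <- function(buffer_stack, geometry, tol = 0.3) {
  n <- length(buffer_stack)
  if (n < 2) stop("need at least two buffer frames")
  s <- Reduce(`+`, buffer_stack)
  s2 <- Reduce(`+`, lapply(buffer_stack, function(f) f^2))
  mu <- s / n
  va <- (s2 - n * mu^2) / (n - 1)
  ratio <- va / mu
  good <- is.finite(ratio) & abs(ratio - 1) < tol & mu > 0
  m <- pixel_mask(geometry)
  mask_pixels(m, !good & !m$bad, reason = "non_poisson")
}

#' Hot-pixel detection from a particle-free calibrated stack
#' @param calib_stack list of photon-unit frames.
#' @param geometry a \code{detector_geometry}.
#' @param threshold mean photon level above which a pixel is hot.
#' @return a \code{pixel_mask} with hot pixels marked.
#' @export
hot_pixel_mask <- function(calib_stack, geometry, threshold = 0.5) {
  mu <- Reduce(`+`, calib_stack) / length(calib_stack)
  m <- pixel_mask(geometry)
  hot <- !is.na(mu) & mu > threshold
  mask_pixels(m, hot, reason = "hot")
}

#' Preprocessing for weak scatterers (radial-fit pipeline)
#'
#' Bins the calibrated frame \code{bin_factor} x \code{bin_factor}, zeroes
#' binned values below \code{floor} photons, rounds the remainder half-up
#' to the nearest integer, and subtracts a per-pixel median background
#' frame (same binned shape).
#'
#' @param frame photon-unit frame (or \code{calibrated_frame}).
#' @param median_frame binned per-pixel median background (matrix).
#' @param geometry a \code{detector_geometry}.
#' @param bin_factor bin edge length (default 16).
#' @param floor photon floor (default 0.5).
#' @param mask optional \code{pixel_mask}.
#' @return binned, background-subtracted matrix.
#' @export
rubisco_preprocess <- function(frame, median_frame, geometry,
                               bin_factor = 16, floor = 0.5, mask = NULL) {
  bf <- truncate_and_bin(frame, bin_factor, floor = 0, mask = mask)
  v <- bf$values
  v[v < floor] <- 0
  v <- base::floor(v + 0.5)      # round half-up
  if (!all(dim(median_frame) == dim(v)))
    stop("median frame shape mismatch")
  v - median_frame
}
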