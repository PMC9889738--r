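#' Focus quality metrics
#'
#' The analysis pipeline mirrors a wide-field camera workflow: subtract the
#' camera dark offset, upsample by tenfold bicubic interpolation, then
#' measure peak-to-background ratio, FWHM of the section profiles through
#' the peak, and the distance between the peak and the intended target.
#'
#' @name focus-metrics
NULL

#' Subtract a constant dark offset, clamping at zero
#'
#' @param image numeric matrix.
#' @param offset camera dark level (default 200 counts, a typical EMCCD dark
#'   offset).
#' @return Matrix of the same shape, `pmax(image - offset, 0)`.
#' @export
subtract_dark <- function(image, offset = 200) {
  if (offset < 0) stop("`offset` must be >= 0")
  pmax(image - offset, 0)
}

# Keys cubic-convolution kernel, a = -0.5 (the classic bicubic used by
# image-processing interp2-style resamplers)
cubic_kernel <- function(x, a = -0.5) {
  ax <- abs(x)
  ifelse(ax <= 1, (a + 2) * ax^3 - (a + 3) * ax^2 + 1,
         ifelse(ax < 2, a * ax^3 - 5 * a * ax^2 + 8 * a * ax - 4 * a, 0))
}

# nq x n interpolation weight matrix for query coords xq (1-based pixel units)
cubic_weights <- function(n, xq) {
  W <- matrix(0, length(xq), n)
  i0 <- floor(xq)
  for (k in -1:2) {
    idx <- i0 + k
    w <- cubic_kernel(xq - idx)
    idx <- pmin(pmax(idx, 1L), n)          # replicate border pixels
    W[cbind(seq_along(xq), idx)] <- W[cbind(seq_along(xq), idx)] + w
  }
  W
}

#' Bicubic image upsampling
#'
#' Separable cubic-convolution (Keys, a = -0.5) interpolation onto a grid
#' `factor` times finer along both axes. Output pixel `j` sits at original
#' coordinate `1 + (j - 1)/factor`, so original pixel centres are preserved
#' and the output spans `(n - 1) * factor + 1` samples per axis.
#'
#' @param image numeric matrix.
#' @param factor integer upsampling factor (>= 1; 10 reproduces the tenfold
#'   interpolation used for camera images).
#' @return The upsampled matrix.
#' @export
interpolate_image <- function(image, factor = 10) {
  if (factor < 1) stop("`factor` must be >= 1")
  factor <- as.integer(factor)
  if (factor == 1L) return(image)
  n1 <- nrow(image); n2 <- ncol(image)
  xq1 <- seq(1, n1, by = 1 / factor)
  xq2 <- seq(1, n2, by = 1 / factor)
  W1 <- cubic_weights(n1, xq1)
  W2 <- cubic_weights(n2, xq2)
  W1 %*% image %*% t(W2)
}

#' Peak-to-background ratio
#'
#' Ratio between the peak (max over `peak_region`) and the mean value of the
#' background (`background_region`). Regions are logical masks of the image;
#' they must be disjoint and the background non-empty. With the defaults the
#' peak region is the whole frame and the background is everything outside
#' an exclusion disk of radius `exclude_radius_px` around the peak, making
#' the ratio insensitive to the focus itself.
#'
#' @param image numeric matrix.
#' @param peak_region,background_region logical masks (same shape as
#'   `image`), or NULL for the defaults.
#' @param exclude_radius_px radius (pixels of `image`) of the default
#'   background exclusion disk around the peak.
#' @return PBR (dimensionless, >= 0).
#' @export
compute_pbr <- function(image, peak_region = NULL, background_region = NULL,
                        exclude_radius_px = NULL) {
  if (is.null(background_region)) {
    pk <- arrayInd(which.max(image), dim(image))
    if (is.null(exclude_radius_px))
      exclude_radius_px <- max(3, round(min(dim(image)) / 20))
    rr <- outer((seq_len(nrow(image)) - pk[1])^2,
                (seq_len(ncol(image)) - pk[2])^2, "+")
    background_region <- rr > exclude_radius_px^2
  }
  if (is.null(peak_region)) peak_region <- !background_region
  if (!any(background_region)) stop("background region is empty")
  if (any(peak_region & background_region))
    stop("peak and background regions must be disjoint")
  max(image[peak_region]) / mean(image[background_region])
}

# linear-interpolated half-maximum crossings around the peak of a profile;
# returns the width in samples, or NA if a crossing is missing
half_width_samples <- function(profile, peak_idx, half_level) {
  n <- length(profile)
  left <- NA_real_
  if (peak_idx >= 2) for (i in seq(peak_idx, 2)) {
    if (profile[i - 1] < half_level && profile[i] >= half_level) {
      frac <- (half_level - profile[i - 1]) / (profile[i] - profile[i - 1])
      left <- (i - 1) + frac
      break
    }
  }
  right <- NA_real_
  if (peak_idx <= n - 1) for (i in seq(peak_idx, n - 1)) {
    if (profile[i + 1] < half_level && profile[i] >= half_level) {
      frac <- (profile[i] - half_level) / (profile[i] - profile[i + 1])
      right <- i + frac
      break
    }
  }
  right - left
}

#' FWHM of the section profile through the image peak
#'
#' Takes the horizontal (`axis = "x"`, along rows) and/or vertical section
#' line through the strict maximum and measures the width where the profile
#' crosses half of `(peak - background_mean)`, with linear interpolation
#' between samples. Pass the interpolated image together with
#' `pixel_pitch_um = focal_pixel_pitch / factor` to obtain physical units.
#'
#' @param image numeric matrix (typically dark-subtracted and interpolated).
#' @param pixel_pitch_um physical pitch of one pixel of `image`, in um.
#' @param axis `"x"`, `"y"`, or `"both"` (returns the mean of the two).
#' @param background_mean intensity level treated as zero signal.
#' @return FWHM in um (named vector for `"both"`: x, y, mean).
#' @export
compute_fwhm <- function(image, pixel_pitch_um = 1, axis = c("both", "x", "y"),
                         background_mean = 0) {
  axis <- match.arg(axis)
  pk <- arrayInd(which.max(image), dim(image))
  peak <- image[pk[1], pk[2]]
  if (!(peak > background_mean)) stop("image has no peak above background")
  half <- background_mean + (peak - background_mean) / 2
  wx <- half_width_samples(image[, pk[2]], pk[1], half) * pixel_pitch_um
  wy <- half_width_samples(image[pk[1], ], pk[2], half) * pixel_pitch_um
  if ((axis != "y" && is.na(wx)) || (axis != "x" && is.na(wy)))
    stop("no half-maximum crossing found around the peak")
  switch(axis, x = wx, y = wy, c(x = wx, y = wy, mean = (wx + wy) / 2))
}

#' Distance between the image peak and a target position
#'
#' Locates the maximum of `image` (pass the interpolated image for sub-pixel
#' precision) and returns the Euclidean distance in um to `target_um`,
#' expressed in the focal-plane coordinate system (origin at the DC pixel of
#' the original grid).
#'
#' @param image numeric matrix.
#' @param target_um length-2 target coordinates in um.
#' @param pixel_pitch_um pitch of one pixel of `image` in um.
#' @param origin_px 1-based index (per axis) of the coordinate origin in
#'   `image`.
#' @return Distance in um (>= 0).
#' @export
focus_position_error <- function(image, target_um, pixel_pitch_um, origin_px) {
  pk <- arrayInd(which.max(image), dim(image))
  pos <- (as.numeric(pk) - origin_px) * pixel_pitch_um
  sqrt(sum((pos - target_um)^2))
}

#' Full focus report for a simulated focal image
#'
#' Runs the complete analysis pipeline — dark subtraction, tenfold bicubic
#' interpolation, PBR against an annular-excluded background, section-line
#' FWHM, and peak position error — and returns everything as one record.
#' The background region for the PBR is the frame excluding a disk of radius
#' 3 nominal FWHM around the target.
#'
#' @param image raw focal intensity image (`grid_n x grid_n`).
#' @param config the [optical_config()] that produced the image.
#' @param target_um intended focus position in um (focal-plane origin at the
#'   DC pixel).
#' @param dark_offset camera dark level to subtract (0 for noiseless
#'   simulated images; 200 for synthetic camera stacks).
#' @param factor interpolation factor (default 10).
#' @return An `fcoat_focus_report` list: `pbr`, `fwhm_x_um`, `fwhm_y_um`,
#'   `fwhm_um` (mean), `peak_position_um`, `position_error_um`,
#'   `background_mean`.
#' @export
focus_report <- function(image, config, target_um = c(0, 0), dark_offset = 0,
                         factor = 10) {
  stopifnot(inherits(config, "fcoat_optics"))
  img <- subtract_dark(image, dark_offset)
  pitch <- config$focal_pixel_pitch
  # background: frame minus a 3-nominal-FWHM disk around the target
  fwhm_nom <- 0.514 * config$wavelength_um / config$na / config$pupil_scale
  n <- nrow(img)
  c0 <- grid_center(n)
  tgt_px <- target_um / pitch + c0
  rr <- outer(((seq_len(n) - tgt_px[1]) * pitch)^2,
              ((seq_len(n) - tgt_px[2]) * pitch)^2, "+")
  bg_mask <- rr > (3 * fwhm_nom)^2
  bg_mean <- mean(img[bg_mask])
  up <- interpolate_image(img, factor)
  up_pitch <- pitch / factor
  up_origin <- (c0 - 1) * factor + 1
  pk <- arrayInd(which.max(up), dim(up))
  peak_pos <- (as.numeric(pk) - up_origin) * up_pitch
  fw <- compute_fwhm(up, up_pitch, axis = "both", background_mean = bg_mean)
  # all metrics, PBR included, are read off the interpolated image: with the
  # focus sampled near 2 px FWHM the raw pixel maximum can miss a peak that
  # falls between pixel centres
  nu <- nrow(up)
  rr_up <- outer((((seq_len(nu) - up_origin) * up_pitch) - target_um[1])^2,
                 (((seq_len(nu) - up_origin) * up_pitch) - target_um[2])^2,
                 "+")
  bg_up <- rr_up > (3 * fwhm_nom)^2
  structure(list(
    pbr = compute_pbr(up, peak_region = !bg_up, background_region = bg_up),
    fwhm_x_um = unname(fw["x"]), fwhm_y_um = unname(fw["y"]),
    fwhm_um = unname(fw["mean"]),
    peak_position_um = peak_pos,
    position_error_um = sqrt(sum((peak_pos - target_um)^2)),
    background_mean = bg_mean,
    target_um = target_um, factor = factor),
    class = "fcoat_focus_report")
}

#' @export
print.fcoat_focus_report <- function(x, ...) {
  cat(sprintf("<focus report> PBR=%.1f  FWHM=%.2f um (x %.2f, y %.2f)  position error=%.3f um\n",
              x$pbr, x$fwhm_um, x$fwhm_x_um, x$fwhm_y_um, x$position_error_um))
  invisible(x)
}

#' Peak-intensity decay trace over a decorrelating medium
#'
#' Holds a correction mask fixed while the medium evolves, sampling the
#' intensity at the (fixed) target every `sample_period` seconds — the
#' numerical analogue of monitoring a corrected focus through living tissue
#' at 10 frames per second. The trace is normalized to its first sample.
#'
#' @param medium a dynamic medium (finite `tau`).
#' @param layout,config forward-model geometry the mask refers to.
#' @param mask binary correction mask (length M).
#' @param aperture detection aperture / output rows at the target.
#' @param sample_period seconds between samples (default 0.1 = 10 fps).
#' @param n_samples number of samples.
#' @return Numeric vector of length `n_samples`, first element 1.
#' @export
decorrelation_trace <- function(medium, layout, config, mask, aperture = NULL,
                                sample_period = 0.1, n_samples = 100) {
  check_state(layout, mask)
  out <- numeric(n_samples)
  for (i in seq_len(n_samples)) {
    basis <- precompute_segment_responses(layout, medium, config, aperture)
    out[i] <- detect_intensity(basis, mask)
    if (i < n_samples) {
      if (!is.finite(medium$tau)) next
      medium <- evolve_medium(medium, sample_period)
    }
  }
  out / out[1]
}
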