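#' Optical configuration of the focusing arm
#'
#' Describes the pupil-plane sampling and the physical calibration of the
#' focal plane. The SLM is conjugated to the rear pupil of a low-NA focusing
#' objective; the focal field is the centered 2-D Fourier transform of the
#' pupil field, with pixel pitch
#' `focal_pixel_pitch = lambda * pupil_diameter_px / (2 * NA * grid_n)` (um),
#' chosen so the diffraction-limited Airy FWHM lands at `0.514 lambda / NA`.
#'
#' The focal-plane origin (and the default focusing target) is the DFT DC
#' pixel, 1-based index `floor(grid_n/2) + 1` on both axes.
#'
#' @param wavelength_um vacuum wavelength in micrometres (0.589 amber default,
#'   0.488 blue alternate).
#' @param na numerical aperture of the focusing objective (0.1 default,
#'   a 4x/0.1 plan objective).
#' @param grid_n simulation grid side in pixels.
#' @param pupil_diameter_px pupil disk diameter in pixels; must be
#'   `<= grid_n / 2` so the focal speckle grain is at least 2x oversampled.
#' @param pupil_scale fraction in (0, 1] shrinking the illuminated pupil;
#'   0.2 emulates dropping the effective NA five-fold to enlarge the focus.
#' @return An `fcoat_optics` configuration.
#' @export
optical_config <- function(wavelength_um = 0.589, na = 0.1, grid_n = 256,
                           pupil_diameter_px = grid_n / 2, pupil_scale = 1) {
  if (pupil_diameter_px > grid_n / 2)
    stop("`pupil_diameter_px` must be <= grid_n/2 (2x speckle oversampling)")
  if (pupil_scale <= 0 || pupil_scale > 1)
    stop("`pupil_scale` must be in (0, 1]")
  structure(list(
    wavelength_um = wavelength_um, na = na, grid_n = as.integer(grid_n),
    pupil_diameter_px = pupil_diameter_px, pupil_scale = pupil_scale,
    focal_pixel_pitch = wavelength_um * pupil_diameter_px / (2 * na * grid_n)
  ), class = "fcoat_optics")
}

#' @export
print.fcoat_optics <- function(x, ...) {
  cat(sprintf(
    "<fcoat_optics> lambda=%.3f um  NA=%.2f  grid=%d px  pupil=%g px (scale %.2f)\n",
    x$wavelength_um, x$na, x$grid_n, x$pupil_diameter_px, x$pupil_scale))
  cat(sprintf("  focal pixel pitch: %.4f um  (Airy FWHM %.3f um = %.2f px)\n",
              x$focal_pixel_pitch, 0.514 * x$wavelength_um / x$na,
              0.514 * x$wavelength_um / x$na / x$focal_pixel_pitch))
  invisible(x)
}

# 1-based index of the grid origin (DFT DC pixel after fftshift)
grid_center <- function(n) floor(n / 2) + 1L

#' Pupil amplitude mask (top-hat disk, optionally scaled)
#' @noRd
pupil_mask <- function(config) {
  n <- config$grid_n
  r <- config$pupil_diameter_px * config$pupil_scale / 2
  x <- seq_len(n) - grid_center(n)
  outer(x^2, x^2, "+") <= r^2
}

#' Segment the pupil into an N x N layout with an inscribed-circle active area
#'
#' The SLM segments tile the square bounding the (unscaled) pupil disk. A
#' segment is active iff its cell centre lies within the inscribed circle of
#' the N x N square (radius N/2 in cell units, cell-centre convention) — the
#' area covered by the incident beam. For N = 32 this gives M = 812 active
#' segments (~ pi/4 * N^2). Pupil pixels outside the active segments remain
#' static and contribute to the unmodulated reference light.
#'
#' @param config an [optical_config()].
#' @param n_side segments per side N (even, >= 4).
#' @return An `fcoat_layout` with the active mask, active-segment count `M`,
#'   and a per-pupil-pixel segment index map (NA outside active segments).
#' @export
build_segment_grid <- function(config, n_side) {
  stopifnot(inherits(config, "fcoat_optics"))
  if (n_side < 4 || n_side %% 2 != 0) stop("`n_side` must be even and >= 4")
  cell <- floor(config$pupil_diameter_px / n_side)
  if (cell < 1) stop("`n_side` too large for this pupil: segment cells < 1 px")
  cc <- (seq_len(n_side) - 0.5) - n_side / 2     # cell-centre offsets, cells
  active <- outer(cc^2, cc^2, "+") <= (n_side / 2)^2
  seg_id <- matrix(NA_integer_, n_side, n_side)
  seg_id[active] <- seq_len(sum(active))
  n <- config$grid_n
  half <- cell * n_side / 2
  px <- seq_len(n) - grid_center(n)              # integer pixel offsets
  inside <- px > -half & px <= half
  idx1 <- rep(NA_integer_, n)
  idx1[inside] <- pmin(n_side, 1L + as.integer(floor((px[inside] + half - 1e-9) / cell)))
  pixel_seg <- matrix(NA_integer_, n, n)
  ok <- which(!is.na(idx1))
  pixel_seg[ok, ok] <- seg_id[cbind(rep(idx1[ok], times = length(ok)),
                                    rep(idx1[ok], each = length(ok)))]
  structure(list(n_side = as.integer(n_side), active = active,
                 M = sum(active), seg_id = seg_id, cell_px = cell,
                 pixel_seg = pixel_seg, config = config),
            class = "fcoat_layout")
}

#' @export
print.fcoat_layout <- function(x, ...) {
  cat(sprintf("<fcoat_layout> %d x %d segments, M = %d active (inscribed circle), cell = %d px\n",
              x$n_side, x$n_side, x$M, x$cell_px))
  invisible(x)
}

#' Propagate a pupil field to the focal plane
#'
#' Centered 2-D discrete Fourier transform, normalized by `grid_n` so that
#' energy is conserved (Parseval). The focal pixel pitch in um is
#' `config$focal_pixel_pitch`.
#'
#' @param pupil_field complex `grid_n x grid_n` matrix.
#' @param config an [optical_config()].
#' @return Complex focal-plane field, `grid_n x grid_n`.
#' @export
propagate_to_focus <- function(pupil_field, config) {
  n <- config$grid_n
  stopifnot(all(dim(pupil_field) == c(n, n)))
  fftshift2(stats::fft(ifftshift2(pupil_field))) / n
}

fftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((floor(n1 / 2) + 1):n1, seq_len(floor(n1 / 2))),
    c((floor(n2 / 2) + 1):n2, seq_len(floor(n2 / 2)))]
}

ifftshift2 <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[c((ceiling(n1 / 2) + 1):n1, seq_len(ceiling(n1 / 2))),
    c((ceiling(n2 / 2) + 1):n2, seq_len(ceiling(n2 / 2)))]
}

#' Detection aperture in the focal plane
#'
#' Emulates the pinhole / multimode-fibre face in front of the feedback
#' detector. Coordinates are um, origin at the focal-plane DC pixel; the
#' aperture always covers at least one focal pixel. Enlarging or reshaping
#' the aperture reshapes the corrected focus.
#'
#' @param config an [optical_config()].
#' @param center_um length-2 numeric, aperture centre in um.
#' @param shape `"disk"` or `"rectangle"`.
#' @param radius_um disk radius (um); default covers exactly the target pixel.
#' @param half_extents_um length-2 numeric, rectangle half-widths (um).
#' @return An `fcoat_aperture` holding the covered focal pixel indices.
#' @export
detection_aperture <- function(config, center_um = c(0, 0), shape = "disk",
                               radius_um = config$focal_pixel_pitch / 2,
                               half_extents_um = NULL) {
  shape <- match.arg(shape, c("disk", "rectangle"))
  n <- config$grid_n
  pitch <- config$focal_pixel_pitch
  xs <- (seq_len(n) - grid_center(n)) * pitch
  if (shape == "disk") {
    d2 <- outer((xs - center_um[1])^2, (xs - center_um[2])^2, "+")
    sel <- which(d2 <= radius_um^2, arr.ind = TRUE)
  } else {
    if (is.null(half_extents_um)) stop("rectangle aperture needs `half_extents_um`")
    inx <- which(abs(xs - center_um[1]) <= half_extents_um[1])
    iny <- which(abs(xs - center_um[2]) <= half_extents_um[2])
    sel <- as.matrix(expand.grid(row = inx, col = iny))
  }
  if (nrow(sel) < 1) {   # guarantee >= 1 pixel: snap to the nearest centre
    i <- round(center_um / pitch) + grid_center(n)
    sel <- matrix(as.integer(pmin(pmax(i, 1), n)), nrow = 1)
  }
  colnames(sel) <- c("row", "col")
  structure(list(center_um = center_um, shape = shape, radius_um = radius_um,
                 half_extents_um = half_extents_um, pixels = sel,
                 config = config),
            class = "fcoat_aperture")
}

# complex-safe grouped sum; groups must be integers 1..M, all present
group_sum_complex <- function(x, group, M) {
  re <- rowsum(Re(x), group, reorder = TRUE)
  im <- rowsum(Im(x), group, reorder = TRUE)
  out <- complex(real = as.vector(re), imaginary = as.vector(im))
  stopifnot(length(out) == M)
  out
}

#' Precompute per-segment focal-field responses
#'
#' For a binary SLM state `b`, the focal field is exactly affine in the
#' per-segment phasors: `E(b) = E_static + sum_i exp(i b_i) E_i`. This
#' function computes each active segment's contribution `E_i` (and the static
#' contribution of unsegmented pupil light) once, restricted to the detection
#' pixels and optionally retaining the full frame, so dither sequences of
#' thousands of patterns reduce to linear algebra instead of repeated
#' propagation.
#'
#' For a `"matrix"`-form medium, column i of the transmission matrix is
#' segment i's response and the aperture is a vector of output-row indices
#' (default row 1, the focusing target).
#'
#' @param layout a [build_segment_grid()] layout.
#' @param medium a medium; `"phase_screen"` grids must match the config,
#'   `"matrix"` media must have `n_in == layout$M`.
#' @param config an [optical_config()].
#' @param aperture a [detection_aperture()], or for matrix media an integer
#'   vector of output rows.
#' @param full_frame keep per-segment full-frame responses (memory heavy;
#'   only sensible for small grids or few segments).
#' @return An `fcoat_basis` with `E` (`n_detect x M` complex), `E_static`
#'   (length `n_detect`), and optionally `E_full`, `E_static_full`.
#' @export
precompute_segment_responses <- function(layout, medium, config,
                                         aperture = NULL, full_frame = FALSE) {
  stopifnot(inherits(layout, "fcoat_layout"), inherits(medium, "fcoat_medium"))
  if (medium$form == "matrix") {
    if (ncol(medium$values) != layout$M)
      stop("matrix medium n_in must equal layout M (", layout$M, ")")
    rows <- if (is.null(aperture)) 1L else as.integer(aperture)
    return(structure(list(form = "matrix",
                          E = medium$values[rows, , drop = FALSE],
                          E_static = rep(0 + 0i, length(rows)),
                          E_full = if (full_frame) medium$values else NULL,
                          E_static_full = if (full_frame)
                            rep(0 + 0i, nrow(medium$values)) else NULL,
                          layout = layout, config = config, aperture = rows),
                     class = "fcoat_basis"))
  }
  n <- config$grid_n
  if (!all(dim(medium$values) == c(n, n)))
    stop("phase screen grid must match config grid_n")
  if (is.null(aperture)) aperture <- detection_aperture(config)
  pup <- pupil_mask(config)
  seg <- layout$pixel_seg
  base_field <- ifelse(pup, 1, 0) * medium$values  # flat SLM, unit illumination
  static_pupil <- base_field
  static_pupil[!is.na(seg)] <- 0                  # unsegmented pupil light
  seg_pupil <- base_field
  seg_pupil[is.na(seg)] <- 0

  ap <- aperture$pixels
  n_det <- nrow(ap)
  # restricted centered DFT, exactly matching propagate_to_focus():
  # E(u,v) = (1/n) * sum_p f(p) exp(-2pi i (ku*x + kv*y)/n), signed indices
  sh <- floor(n / 2)
  ku <- ap[, 1] - 1L - sh
  kv <- ap[, 2] - 1L - sh
  x <- seq_len(n) - 1L - sh
  Wu <- exp(-2i * pi * outer(ku, x) / n)          # n_det x n
  Wv <- exp(-2i * pi * outer(kv, x) / n)
  segs_idx <- which(!is.na(seg))
  seg_of <- seg[segs_idx]
  rowi <- ((segs_idx - 1L) %% n) + 1L
  coli <- ((segs_idx - 1L) %/% n) + 1L
  vals <- seg_pupil[segs_idx]
  st_idx <- which(static_pupil != 0)
  st_row <- ((st_idx - 1L) %% n) + 1L
  st_col <- ((st_idx - 1L) %/% n) + 1L
  E <- matrix(0 + 0i, n_det, layout$M)
  E_static <- rep(0 + 0i, n_det)
  for (d in seq_len(n_det)) {
    ph <- Wu[d, rowi] * Wv[d, coli] * vals / n
    E[d, ] <- group_sum_complex(ph, seg_of, layout$M)
    if (length(st_idx))
      E_static[d] <- sum(Wu[d, st_row] * Wv[d, st_col] * static_pupil[st_idx]) / n
  }
  out <- structure(list(form = "phase_screen", E = E, E_static = E_static,
                        layout = layout, config = config, aperture = aperture,
                        screen = medium$values, static_pupil = static_pupil,
                        seg_pupil = seg_pupil),
                   class = "fcoat_basis")
  if (full_frame) {
    E_full <- matrix(0 + 0i, n * n, layout$M)
    for (i in seq_len(layout$M)) {
      f <- matrix(0 + 0i, n, n)
      sel <- segs_idx[seg_of == i]
      f[sel] <- seg_pupil[sel]
      E_full[, i] <- as.vector(propagate_to_focus(f, config))
    }
    out$E_full <- E_full
    out$E_static_full <- as.vector(propagate_to_focus(static_pupil, config))
  }
  out
}

#' Detected feedback intensity for a binary SLM state
#'
#' Sum of `|E_static + sum_i exp(i b_i) E_i|^2` over the detection pixels —
#' the scalar a photomultiplier behind the pinhole/fibre would report.
#'
#' @param basis a [precompute_segment_responses()] basis.
#' @param state numeric vector of per-active-segment phases in `{0, pi}`.
#' @param noise optional noise model from [noise_model()].
#' @return Non-negative scalar intensity.
#' @export
detect_intensity <- function(basis, state, noise = NULL) {
  stopifnot(inherits(basis, "fcoat_basis"))
  check_state(basis$layout, state)
  field <- basis$E_static + as.vector(basis$E %*% exp(1i * state))
  val <- sum(Mod(field)^2)
  if (!is.null(noise)) val <- apply_noise(val, noise)
  val
}

check_state <- function(layout, state) {
  if (length(state) != layout$M)
    stop("state length ", length(state), " != M = ", layout$M)
  if (!all(state == 0 | state == pi))
    stop("binary SLM: state values must be exactly 0 or pi")
  invisible(TRUE)
}

#' Render the full focal-plane intensity image for a binary SLM state
#'
#' Uses retained full-frame responses when present; otherwise (phase-screen
#' media) renders by direct propagation of the composed pupil — both routes
#' are numerically identical through the linearity of the model. A matrix
#' medium returns the intensity over its output modes as a vector.
#'
#' @inheritParams detect_intensity
#' @return `grid_n x grid_n` intensity matrix (arbitrary units), or a vector
#'   of output-mode intensities for matrix media.
#' @export
render_focal_image <- function(basis, state) {
  stopifnot(inherits(basis, "fcoat_basis"))
  check_state(basis$layout, state)
  if (!is.null(basis$E_full)) {
    field <- basis$E_static_full + as.vector(basis$E_full %*% exp(1i * state))
    if (basis$form == "matrix") return(Mod(field)^2)
    n <- basis$config$grid_n
    return(matrix(Mod(field)^2, n, n))
  }
  if (basis$form == "matrix")
    stop("matrix-form basis was built aperture-only; rebuild with full_frame = TRUE")
  n <- basis$config$grid_n
  seg <- basis$layout$pixel_seg
  phase <- matrix(0, n, n)
  phase[!is.na(seg)] <- state[seg[!is.na(seg)]]
  pupil <- basis$seg_pupil * exp(1i * phase) + basis$static_pupil
  Mod(propagate_to_focus(pupil, basis$config))^2
}

#' Detector noise model
#'
#' Optional Poisson shot noise at a configurable photon budget plus Gaussian
#' read noise. The default everywhere is noiseless feedback.
#'
#' @param photons_per_unit expected photons per intensity unit (shot noise).
#' @param read_sd Gaussian read-noise SD in intensity units.
#' @export
noise_model <- function(photons_per_unit = 1e4, read_sd = 0) {
  structure(list(photons_per_unit = photons_per_unit, read_sd = read_sd),
            class = "fcoat_noise")
}

apply_noise <- function(val, noise) {
  v <- stats::rpois(length(val), val * noise$photons_per_unit) /
    noise$photons_per_unit
  pmax(0, v + stats::rnorm(length(val), sd = noise$read_sd))
}
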