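#' Synthetic calcium imaging and dF/F quantification
#'
#' Emulates the wide-field readout of optogenetic stimulation experiments:
#' disk-shaped neurons expressing a calcium indicator respond to
#' stimulation-locked illumination with fluorescence transients whose
#' amplitude follows a sigmoid dose-response in the light delivered to the
#' soma. A tight corrected focus concentrates the available power on the
#' target neuron and drives it above its activation threshold, while the
#' same power spread as uncorrected speckle stays sub-threshold — the
#' mechanism behind focus-versus-speckle stimulation contrast.
#'
#' @name calcium-signals
NULL

#' Stimulation protocol
#'
#' @param stim_duration_s stimulus duration in seconds (default 0.2 = 200 ms).
#' @param period_s stimulation period in seconds (default 5).
#' @param n_stims number of stimuli (default 9, i.e. 45 s of protocol).
#' @param frame_rate_hz acquisition rate (default 10 frames per second).
#' @param pre_s baseline recording before the first stimulus (seconds).
#' @return An `fcoat_protocol`.
#' @export
stimulation_protocol <- function(stim_duration_s = 0.2, period_s = 5,
                                 n_stims = 9, frame_rate_hz = 10, pre_s = 5) {
  if (period_s <= stim_duration_s) stop("`period_s` must exceed `stim_duration_s`")
  if (n_stims < 1) stop("`n_stims` must be >= 1")
  structure(list(stim_duration_s = stim_duration_s, period_s = period_s,
                 n_stims = n_stims, frame_rate_hz = frame_rate_hz,
                 pre_s = pre_s,
                 stim_times_s = pre_s + (seq_len(n_stims) - 1) * period_s,
                 duration_s = pre_s + n_stims * period_s),
            class = "fcoat_protocol")
}

#' Neuron specification for the synthetic movie
#'
#' The dose-response is `A_max / (1 + exp(-(I - I_th)/slope))`: near-zero
#' response well below threshold, saturating at `A_max` (in dF/F units) well
#' above. Defaults place a strong response (~0.7 dF/F) at focus-level
#' illumination and a weak one (~0.2) at speckle level, the regime reported
#' for focus versus speckle stimulation.
#'
#' @param center_um length-2 soma centre in the movie frame (um).
#' @param radius_um soma radius (um).
#' @param f0 baseline fluorescence (camera counts above dark).
#' @param i_threshold illumination threshold `I_th` (intensity units).
#' @param slope sigmoid slope (same units as `I_th`).
#' @param a_max saturating response amplitude (dF/F units).
#' @param tau_rise_s,tau_decay_s transient rise and decay times (s);
#'   `tau_rise_s < tau_decay_s` as for a slow genetically encoded indicator.
#' @return An `fcoat_neuron`.
#' @export
neuron_spec <- function(center_um = c(0, 0), radius_um = 10, f0 = 1000,
                        i_threshold = 50, slope = 10, a_max = 0.8,
                        tau_rise_s = 0.3, tau_decay_s = 1.5) {
  if (f0 <= 0) stop("`f0` must be > 0")
  if (!(tau_rise_s < tau_decay_s)) stop("`tau_rise_s` must be < `tau_decay_s`")
  structure(list(center_um = center_um, radius_um = radius_um, f0 = f0,
                 i_threshold = i_threshold, slope = slope, a_max = a_max,
                 tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s),
            class = "fcoat_neuron")
}

#' Sigmoid dose-response amplitude
#'
#' @param intensity illumination intensity delivered to the soma (>= 0).
#' @param neuron an [neuron_spec()].
#' @return Response amplitude in dF/F units, strictly increasing in
#'   `intensity`.
#' @export
response_amplitude <- function(intensity, neuron) {
  if (any(intensity < 0)) stop("`intensity` must be >= 0")
  neuron$a_max / (1 + exp(-(intensity - neuron$i_threshold) / neuron$slope))
}

# transient shape normalized to unit peak: (1 - exp(-t/tr)) * exp(-t/td)
transient_kernel <- function(t_s, tau_rise_s, tau_decay_s) {
  h <- function(t) ifelse(t <= 0, 0, (1 - exp(-t / tau_rise_s)) * exp(-t / tau_decay_s))
  t_peak <- tau_rise_s * log(1 + tau_decay_s / tau_rise_s)
  h(t_s) / h(t_peak)
}

#' Synthesize a wide-field calcium movie
#'
#' Each frame shows disk neurons at `F0 * (1 + dF/F(t))` on a dark
#' background; each stimulus adds a transient of unit-peak shape
#' `(1 - exp(-t/tau_r)) * exp(-t/tau_d)` scaled by the neuron's
#' [response_amplitude()] to the illumination integrated over its soma.
#' Poisson shot noise is applied per pixel and the camera dark offset (200
#' counts) is added last, to be removed again by [subtract_dark()].
#'
#' @param neurons list of [neuron_spec()].
#' @param protocol an [stimulation_protocol()].
#' @param illumination focal intensity image (e.g. from
#'   [render_focal_image()]), or NULL for zero illumination.
#' @param config the [optical_config()] calibrating `illumination` (um).
#' @param seed RNG seed.
#' @param frame_n movie frame side in pixels.
#' @param pixel_um movie pixel size (um).
#' @param dark_offset camera dark level added to every frame.
#' @param shot_noise apply Poisson noise per pixel.
#' @return An `fcoat_movie`: list with `frames` (list of matrices), `times_s`,
#'   the ground-truth per-neuron `dff_true` traces and response amplitudes.
#' @export
synth_calcium_movie <- function(neurons, protocol, illumination = NULL,
                                config = NULL, seed = 1L, frame_n = 128,
                                pixel_um = 1.5, dark_offset = 200,
                                shot_noise = TRUE) {
  stopifnot(length(neurons) >= 1)
  n_frames <- ceiling(protocol$duration_s * protocol$frame_rate_hz)
  times <- (seq_len(n_frames) - 1) / protocol$frame_rate_hz
  c0 <- (frame_n + 1) / 2
  xs <- (seq_len(frame_n) - c0) * pixel_um

  soma_intensity <- function(nr) {
    if (is.null(illumination)) return(0)
    stopifnot(!is.null(config))
    n <- nrow(illumination)
    cg <- grid_center(n)
    fx <- (seq_len(n) - cg) * config$focal_pixel_pitch
    in_soma <- outer((fx - nr$center_um[1])^2, (fx - nr$center_um[2])^2, "+") <=
      nr$radius_um^2
    sum(illumination[in_soma])
  }

  amps <- vapply(neurons, function(nr)
    response_amplitude(soma_intensity(nr), nr), numeric(1))
  dff_true <- matrix(0, n_frames, length(neurons))
  for (j in seq_along(neurons)) {
    nr <- neurons[[j]]
    for (ts in protocol$stim_times_s)
      dff_true[, j] <- dff_true[, j] +
        amps[j] * transient_kernel(times - ts, nr$tau_rise_s, nr$tau_decay_s)
  }

  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(k) {
      fr <- matrix(0, frame_n, frame_n)
      for (j in seq_along(neurons)) {
        nr <- neurons[[j]]
        disk <- outer((xs - nr$center_um[1])^2, (xs - nr$center_um[2])^2, "+") <=
          nr$radius_um^2
        fr[disk] <- fr[disk] + nr$f0 * (1 + dff_true[k, j])
      }
      if (shot_noise)
        fr <- matrix(stats::rpois(length(fr), fr), frame_n, frame_n)
      fr + dark_offset
    })
  })
  structure(list(frames = frames, times_s = times, neurons = neurons,
                 protocol = protocol, amplitudes_true = amps,
                 dff_true = dff_true, pixel_um = pixel_um,
                 dark_offset = dark_offset, seed = as.integer(seed)),
            class = "fcoat_movie")
}

#' @export
print.fcoat_movie <- function(x, ...) {
  cat(sprintf("<fcoat_movie> %d frames of %d x %d px, %d neurons, %.0f s at %g fps\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              length(x$neurons), x$protocol$duration_s,
              x$protocol$frame_rate_hz))
  invisible(x)
}

# logical disk mask on the movie grid
movie_roi <- function(movie, center_um, radius_um) {
  n <- nrow(movie$frames[[1]])
  c0 <- (n + 1) / 2
  xs <- (seq_len(n) - c0) * movie$pixel_um
  outer((xs - center_um[1])^2, (xs - center_um[2])^2, "+") <= radius_um^2
}

#' Extract a background-subtracted ROI trace from a movie
#'
#' Per frame: mean over the circular ROI minus mean over a circular
#' background ROI placed over a blank area, mirroring manual ROI analysis of
#' wide-field recordings.
#'
#' @param movie an [synth_calcium_movie()] movie.
#' @param roi_center_um,roi_radius_um circular ROI over the neuron (um).
#' @param background_center_um,background_radius_um blank-area ROI.
#' @return Numeric intensity series, one value per frame.
#' @export
extract_trace <- function(movie, roi_center_um, roi_radius_um,
                          background_center_um, background_radius_um = roi_radius_um) {
  roi <- movie_roi(movie, roi_center_um, roi_radius_um)
  bg <- movie_roi(movie, background_center_um, background_radius_um)
  if (!any(roi) || !any(bg)) stop("ROI falls outside the frame")
  if (any(roi & bg)) warning("signal and background ROIs overlap")
  vapply(movie$frames, function(fr) mean(fr[roi]) - mean(fr[bg]), numeric(1))
}

#' Compute dF/F from a fluorescence trace
#'
#' `(F - F0)/F0` with the baseline `F0` taken as the mean over a pre-stimulus
#' window.
#'
#' @param trace numeric fluorescence series.
#' @param baseline_window integer frame indices of the baseline (must precede
#'   the first stimulus).
#' @return dF/F series of the same length.
#' @export
compute_dff <- function(trace, baseline_window) {
  f0 <- mean(trace[baseline_window])
  if (!(f0 > 0)) stop("baseline F0 must be positive")
  (trace - f0) / f0
}

#' Per-stimulus peak responses
#'
#' Max of the dF/F trace within a window after each stimulus, plus summary
#' statistics (mean and standard error across stimuli).
#'
#' @param dff dF/F series (one value per frame).
#' @param protocol the [stimulation_protocol()] used.
#' @param window_s post-stimulus window length in seconds.
#' @return List with `peaks` (per stimulus), `mean`, `se`.
#' @export
peak_response <- function(dff, protocol, window_s = 3) {
  fr <- protocol$frame_rate_hz
  peaks <- vapply(protocol$stim_times_s, function(ts) {
    i0 <- floor(ts * fr) + 1L
    i1 <- min(length(dff), ceiling((ts + window_s) * fr) + 1L)
    if (i0 > length(dff)) stop("stimulus window outside the trace")
    max(dff[i0:i1])
  }, numeric(1))
  list(peaks = peaks, mean = mean(peaks),
       se = stats::sd(peaks) / sqrt(length(peaks)))
}
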