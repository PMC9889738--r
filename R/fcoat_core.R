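#' The fCOAT correction algorithm
#'
#' fCOAT (fast multidither coherent optical adaptive technique) recovers a
#' binary phase correction for a scattering medium from a single feedback
#' detector. The active SLM segments are split into two halves. While one
#' half is frequency-tagged — each segment toggled between its base phase and
#' base + pi as a square wave at a distinct integer DFT frequency — the other
#' half is held static and acts as the coherent reference field. A DFT of the
#' detected intensity time series isolates each segment's interference term
#' with the reference; the sign of its in-phase component decides whether the
#' segment is flipped. The corrected first half then serves as the reference
#' while the second half is tagged, and the combined, re-binarized mask is
#' the final correction — one iteration, `4*M` patterns in total.
#'
#' @name fcoat-core
NULL

#' Plan the dither frequencies for a two-half correction
#'
#' The modulated segments of each half get distinct integer DFT frequency
#' bins in `[T/4, T/2)` where `T = 4 * max(H1, H2)` samples per half: the
#' sampling rate is twice the highest modulation frequency (Nyquist), and the
#' lowest modulation frequency is half the highest so the sparsely-sampled
#' low-frequency band is never used. Total pattern budget is `2T` (= `4M` for
#' an even split), at most `4 N^2`.
#'
#' @param layout a [build_segment_grid()] layout with `M >= 2`.
#' @param scheme half-partition scheme: `"checkerboard"` (default; alternates
#'   segments so both halves sample the whole pupil) or `"random"`.
#' @param seed RNG seed used by the `"random"` scheme.
#' @return An `fcoat_plan` with `half1`, `half2` (segment indices), per-half
#'   bin assignments, samples per half `T`, and `total_patterns`.
#' @export
plan_dither <- function(layout, scheme = c("checkerboard", "random"), seed = 1L) {
  stopifnot(inherits(layout, "fcoat_layout"))
  scheme <- match.arg(scheme)
  M <- layout$M
  if (M < 2) stop("need at least 2 active segments to dither")
  idx <- seq_len(M)
  if (scheme == "checkerboard") {
    # alternate along the active-segment ordering (column-major over the
    # inscribed circle): even/odd split, sizes differ by at most 1
    half1 <- idx[idx %% 2L == 1L]
    half2 <- idx[idx %% 2L == 0L]
  } else {
    perm <- with_seed(seed, sample(idx))
    half1 <- sort(perm[seq_len(ceiling(M / 2))])
    half2 <- sort(perm[-seq_len(ceiling(M / 2))])
  }
  H <- max(length(half1), length(half2))
  T_samp <- 4L * H
  bins <- seq.int(T_samp / 4L, T_samp / 2L - 1L)   # H distinct bins
  structure(list(half1 = half1, half2 = half2,
                 bins1 = bins[seq_along(half1)],
                 bins2 = bins[seq_along(half2)],
                 T = T_samp, total_patterns = 2L * T_samp,
                 scheme = scheme, seed = as.integer(seed), M = M),
            class = "fcoat_plan")
}

#' @export
print.fcoat_plan <- function(x, ...) {
  cat(sprintf("<fcoat_plan> M=%d  halves %d/%d (%s)  T=%d samples/half  bins [%d,%d]  total patterns=%d\n",
              x$M, length(x$half1), length(x$half2), x$scheme, x$T,
              min(x$bins1), max(x$bins1), x$total_patterns))
  invisible(x)
}

#' Square-wave dither waveforms for one half
#'
#' Segment with bin `k` toggles as `s(t) = sign(cos(2 pi k t / T))` over
#' `t = 0, ..., T-1` (ties broken to +1): `+1` keeps the base phase, `-1`
#' adds pi.
#'
#' @param plan an [plan_dither()] plan.
#' @param half `"first"` or `"second"`.
#' @return `T x H` matrix of +/-1.
#' @export
dither_waveforms <- function(plan, half = c("first", "second")) {
  half <- match.arg(half)
  bins <- if (half == "first") plan$bins1 else plan$bins2
  tt <- seq.int(0L, plan$T - 1L)
  S <- sapply(bins, function(k) {
    s <- sign(cos(2 * pi * k * tt / plan$T))
    s[s == 0] <- 1
    s
  })
  matrix(S, nrow = plan$T)
}

#' Build the pattern sequence for one half of the dither
#'
#' Returns the `T` binary SLM states actually displayed: modulated segments
#' toggle between their base value and base + pi following the square wave,
#' all other segments hold `base_mask` (the first half runs against the
#' initial mask; the second half runs against the corrected first half as
#' reference).
#'
#' @param plan an [plan_dither()] plan.
#' @param half `"first"` or `"second"`.
#' @param base_mask numeric length-M vector of phases in `{0, pi}`.
#' @return `T x M` matrix of phases in `{0, pi}`.
#' @export
build_pattern_sequence <- function(plan, half = c("first", "second"),
                                   base_mask = rep(0, plan$M)) {
  half <- match.arg(half)
  mod_idx <- if (half == "first") plan$half1 else plan$half2
  S <- dither_waveforms(plan, half)
  states <- matrix(rep(base_mask, each = plan$T), nrow = plan$T)
  # s = -1 adds pi to the base phase (mod 2pi, re-expressed in {0, pi})
  flip <- (S == -1)
  base_mod <- matrix(rep(base_mask[mod_idx], each = plan$T), nrow = plan$T)
  states[, mod_idx] <- ifelse(flip, ifelse(base_mod == 0, pi, 0), base_mod)
  states
}

#' Wrap an angle into [0, 2*pi)
#' @noRd
wrap_2pi <- function(phi) phi %% (2 * pi)

#' Binarize a phase to the two SLM levels
#'
#' Phases in `[0, pi/2)` or `[3*pi/2, 2*pi)` map to 0; phases in
#' `[pi/2, 3*pi/2)` map to pi (half-open intervals; input is wrapped to
#' `[0, 2*pi)` first). This is the nearest binary level in the sense of
#' maximizing `cos(phi - b)`.
#'
#' @param phi numeric vector of phases in radians (any real).
#' @return Vector of the same length with values in `{0, pi}`.
#' @export
binarize_phase <- function(phi) {
  w <- wrap_2pi(phi)
  ifelse(w >= pi / 2 & w < 3 * pi / 2, pi, 0)
}

#' Demodulate a detected intensity time series
#'
#' Computes the DFT coefficient of the intensity at each modulated segment's
#' bin, removes the dither waveform's own reference phase (the DFT phase of
#' the displayed waveform at that bin, computed from the waveform actually
#' used rather than an analytic formula), and binarizes the residual phase.
#' With square-wave (binary) dithering only the in-phase quadrature carries
#' signal, so the residual phase concentrates near 0 (keep) or pi (flip); the
#' continuous phase-ramp mode used for validation recovers the full phase.
#'
#' @param intensity numeric vector of length `plan$T`.
#' @param plan an [plan_dither()] plan.
#' @param half `"first"` or `"second"`.
#' @param waveform `"square"` (production) or `"ramp"` (continuous-dither
#'   validation mode, reference phase identically 0).
#' @return An `fcoat_demod` list: complex `c` per modulated segment,
#'   extracted phase `phi_hat` in `[0, 2*pi)`, and binary decision `b`
#'   (segments with `|c| == 0` keep their base value: `b = 0`).
#' @export
demodulate <- function(intensity, plan, half = c("first", "second"),
                       waveform = c("square", "ramp")) {
  half <- match.arg(half)
  waveform <- match.arg(waveform)
  if (length(intensity) != plan$T)
    stop("intensity series must have length T = ", plan$T)
  bins <- if (half == "first") plan$bins1 else plan$bins2
  Ihat <- stats::fft(intensity)
  cc <- Ihat[bins + 1L]                     # DFT index = bin + 1 (DC at 1)
  if (waveform == "square") {
    S <- dither_waveforms(plan, half)
    Shat <- stats::mvfft(S)
    psi <- Arg(Shat[cbind(bins + 1L, seq_along(bins))])
  } else {
    psi <- rep(0, length(bins))
  }
  phi_hat <- wrap_2pi(Arg(cc) - psi)
  # no-signal convention: a bin carrying only numerical noise keeps its base
  no_signal <- Mod(cc) <= 1e-9 * (plan$T * mean(abs(intensity)) +
                                    .Machine$double.eps)
  b <- ifelse(no_signal, 0, binarize_phase(phi_hat))
  structure(list(c = cc, phi_hat = phi_hat, b = b, bins = bins, half = half),
            class = "fcoat_demod")
}

#' Run one full fCOAT correction
#'
#' Executes the two-half procedure against a medium: plan the dither, display
#' the first-half pattern sequence (second half at the base mask as
#' reference), demodulate, apply the first-half flips, display the
#' second-half sequence against the corrected reference, demodulate, combine
#' and re-binarize. Records the detected intensity before and after and the
#' pattern count. For a dynamic medium each displayed pattern advances the
#' medium clock by `pattern_dwell` seconds; when `tau` is shorter than one
#' dwell the run proceeds with a warning (graceful degradation under
#' decorrelation is expected behaviour, not an error).
#'
#' @param medium a scattering medium.
#' @param layout a [build_segment_grid()] layout.
#' @param config an [optical_config()].
#' @param aperture a [detection_aperture()] (or output-row indices for matrix
#'   media); default: single target pixel / row 1.
#' @param initial_mask starting mask (length M, values in `{0, pi}`); pass a
#'   previous result to run the continuous working mode on a drifting medium.
#' @param scheme,seed forwarded to [plan_dither()].
#' @param noise optional [noise_model()].
#' @param pattern_dwell seconds of medium evolution per displayed pattern
#'   (used only for dynamic media; ~1 ms matches a ferroelectric SLM's net
#'   latency).
#' @param iterations number of complete two-half passes (default 1, matching
#'   the single-iteration operating mode; more improve accuracy on static
#'   media).
#' @return An `fcoat_result`: `mask` (final binary correction),
#'   `intensity_before`, `intensity_after`, `measurement_count`, the per-half
#'   intensity traces of the last iteration, the plan, and the evolved medium.
#' @export
run_fcoat <- function(medium, layout, config, aperture = NULL,
                      initial_mask = rep(0, layout$M),
                      scheme = "checkerboard", seed = 1L, noise = NULL,
                      pattern_dwell = 1e-3, iterations = 1L) {
  stopifnot(inherits(medium, "fcoat_medium"), inherits(layout, "fcoat_layout"))
  check_state(layout, initial_mask)
  plan <- plan_dither(layout, scheme = scheme, seed = seed)
  dynamic <- is.finite(medium$tau)
  if (dynamic && medium$tau < pattern_dwell)
    warning("medium decorrelates faster than one pattern dwell; ",
            "correction will degrade gracefully")
  basis <- precompute_segment_responses(layout, medium, config, aperture)
  I_before <- detect_intensity(basis, initial_mask, noise)

  mask <- initial_mask
  traces <- list()
  for (it in seq_len(iterations)) {
    for (half in c("first", "second")) {
      seq_states <- build_pattern_sequence(plan, half, base_mask = mask)
      if (dynamic) {
        I_t <- numeric(plan$T)
        for (t in seq_len(plan$T)) {
          I_t[t] <- detect_intensity(basis, seq_states[t, ], noise)
          medium <- evolve_medium(medium, pattern_dwell)
          basis <- precompute_segment_responses(layout, medium, config, aperture)
        }
      } else {
        # static media: vectorize over the whole sequence
        P <- exp(1i * seq_states)               # T x M phasors
        field <- P %*% t(basis$E)               # T x n_det (E is n_det x M)
        field <- sweep(field, 2, basis$E_static, "+")
        I_t <- rowSums(Mod(field)^2)
        if (!is.null(noise)) I_t <- apply_noise(I_t, noise)
      }
      dem <- demodulate(I_t, plan, half)
      mod_idx <- if (half == "first") plan$half1 else plan$half2
      mask[mod_idx] <- binarize_phase(mask[mod_idx] + dem$b)
      traces[[half]] <- I_t
    }
  }
  I_after <- detect_intensity(basis, mask, noise)
  structure(list(mask = mask, intensity_before = I_before,
                 intensity_after = I_after,
                 measurement_count = plan$total_patterns * iterations,
                 trace_first = traces$first, trace_second = traces$second,
                 plan = plan, medium = medium, layout = layout,
                 config = config, aperture = basis$aperture, seed = seed),
            class = "fcoat_result")
}

#' @export
print.fcoat_result <- function(x, ...) {
  cat(sprintf("<fcoat_result> M=%d  patterns=%d  feedback intensity %.4g -> %.4g (x%.1f)\n",
              x$layout$M, x$measurement_count, x$intensity_before,
              x$intensity_after,
              x$intensity_after / max(x$intensity_before, .Machine$double.eps)))
  cat(sprintf("  mask: %d of %d segments flipped to pi\n",
              sum(x$mask == pi), length(x$mask)))
  invisible(x)
}

#' Continuous-dither intensity series (validation mode)
#'
#' Replaces the square-wave toggling by an idealized continuous phase ramp:
#' modulated segment i carries phase `2 pi k_i t / T` on top of its base
#' value, so the detected intensity contains a clean cosine at each bin and
#' [demodulate()] with `waveform = "ramp"` recovers the full interference
#' phase `arg(E_i * Conj(E_ref))` before any binarization. Used to validate
#' the demodulation chain; a binary SLM cannot display these patterns.
#'
#' @param basis a [precompute_segment_responses()] basis.
#' @param plan an [plan_dither()] plan.
#' @param half `"first"` or `"second"`.
#' @param base_mask binary base mask (length M).
#' @return Numeric intensity series of length `plan$T`.
#' @export
ramp_intensity_series <- function(basis, plan, half = c("first", "second"),
                                  base_mask = rep(0, plan$M)) {
  half <- match.arg(half)
  mod_idx <- if (half == "first") plan$half1 else plan$half2
  bins <- if (half == "first") plan$bins1 else plan$bins2
  tt <- seq.int(0L, plan$T - 1L)
  phases <- matrix(rep(base_mask, each = plan$T), nrow = plan$T)
  ramp <- outer(tt, bins, function(t, k) 2 * pi * k * t / plan$T)
  phases[, mod_idx] <- phases[, mod_idx] + ramp
  field <- exp(1i * phases) %*% t(basis$E)
  field <- sweep(field, 2, basis$E_static, "+")
  rowSums(Mod(field)^2)
}

#' Greedy coordinate-flip oracle
#'
#' Independent optimizer used as a test oracle: sweep the segments in order,
#' setting each to whichever of `{0, pi}` gives the larger detected
#' intensity, and repeat until a full sweep changes nothing. Not part of the
#' correction algorithm.
#'
#' @param basis a [precompute_segment_responses()] basis.
#' @param max_sweeps safety cap on full passes.
#' @return List with `mask` and `intensity`.
#' @export
run_greedy_oracle <- function(basis, max_sweeps = 50L) {
  stopifnot(inherits(basis, "fcoat_basis"))
  M <- basis$layout$M
  mask <- rep(0, M)
  field <- basis$E_static + as.vector(basis$E %*% exp(1i * mask))
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_len(M)) {
      delta <- -2 * exp(1i * mask[i]) * basis$E[, i]   # effect of flipping i
      if (sum(Mod(field + delta)^2) > sum(Mod(field)^2)) {
        field <- field + delta
        mask[i] <- if (mask[i] == 0) pi else 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  list(mask = mask, intensity = sum(Mod(field)^2))
}

#' Exhaustive binary-mask search (tiny M only)
#'
#' Enumerates all `2^M` binary masks and returns the global optimum of the
#' detected intensity. Usable as a ground-truth oracle for `M <= 16`.
#'
#' @param basis a [precompute_segment_responses()] basis.
#' @return List with `mask`, `intensity`.
#' @export
run_exhaustive_oracle <- function(basis) {
  M <- basis$layout$M
  if (M > 16) stop("exhaustive search is limited to M <= 16")
  n_masks <- 2^M
  codes <- 0:(n_masks - 1)
  B <- vapply(seq_len(M), function(i) bitwAnd(codes, bitwShiftL(1L, i - 1L)) > 0,
              logical(n_masks))             # n_masks x M
  P <- ifelse(B, -1, 1)                     # exp(i*pi) = -1
  best_I <- -Inf; best <- NULL
  for (d in seq_len(nrow(basis$E))) {
    Fd <- basis$E_static[d] + P %*% basis$E[d, ]
    Id <- Mod(Fd)^2
    if (d == 1) Itot <- Id else Itot <- Itot + Id
  }
  k <- which.max(Itot)
  list(mask = ifelse(B[k, ], pi, 0), intensity = Itot[k])
}
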