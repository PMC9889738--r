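#' Synthetic scattering media
#'
#' A scattering medium is represented in one of two interchangeable forms:
#'
#' * `"matrix"` — a complex transmission matrix with independent
#'   circular-Gaussian entries of unit mean squared magnitude, mapping the
#'   active SLM segments (columns) to output speckle modes (rows). This form
#'   carries the exact fully-developed-speckle statistics and is the natural
#'   testbed for enhancement theory.
#' * `"phase_screen"` — a thin random phase screen `exp(i g)` on the pupil
#'   grid, where `g` is a correlated Gaussian field. This form feeds the
#'   Fourier-optics propagator and yields spatial metrics (FWHM, position
#'   error) in physical units.
#'
#' Both forms carry a decorrelation time `tau` (seconds, `Inf` for a static
#'   medium) and a clock, so a "live tissue" medium can be evolved in time
#' with [evolve_medium()].
#'
#' @name scatter-media
NULL

new_medium <- function(form, values, tau, seed, clock = 0,
                       correlation_length = NULL, strength = NULL) {
  structure(
    list(form = form, values = values, tau = tau, seed = seed, clock = clock,
         correlation_length = correlation_length, strength = strength),
    class = "fcoat_medium")
}

#' @export
print.fcoat_medium <- function(x, ...) {
  dims <- paste(dim(x$values) %||% length(x$values), collapse = " x ")
  cat(sprintf("<fcoat_medium> form=%s  values=%s  tau=%s s  clock=%.4g s  seed=%d\n",
              x$form, dims, format(x$tau), x$clock, x$seed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw a complex Gaussian transmission matrix
#'
#' Entries are independent circular complex Gaussians with variance 1 split
#' equally over real and imaginary parts, so `mean(|T|^2) == 1`. Propagating
#' an arbitrary fixed input through such a matrix produces fully developed
#' speckle: output intensities are exponentially distributed with unit
#' contrast.
#'
#' @param n_out number of output (speckle) modes, rows.
#' @param n_in number of input (segment) modes, columns.
#' @param seed integer RNG seed; the same seed reproduces the matrix exactly.
#' @param tau decorrelation time in seconds (`Inf` = static).
#' @return A `"matrix"`-form medium object.
#' @examples
#' m <- make_transmission_matrix(256, 64, seed = 1)
#' mean(Mod(m$values)^2)  # ~1
#' @export
make_transmission_matrix <- function(n_out, n_in, seed, tau = Inf) {
  stopifnot(is.numeric(n_out), is.numeric(n_in), length(n_out) == 1L,
            length(n_in) == 1L)
  if (n_out < 1 || n_in < 1)
    stop("`n_out` and `n_in` must be positive integers")
  if (!is.finite(tau) && !identical(tau, Inf)) stop("`tau` must be > 0 or Inf")
  if (tau <= 0) stop("`tau` must be > 0")
  vals <- with_seed(seed, {
    n <- n_out * n_in
    matrix(complex(real = stats::rnorm(n, sd = sqrt(0.5)),
                   imaginary = stats::rnorm(n, sd = sqrt(0.5))),
           nrow = n_out, ncol = n_in)
  })
  new_medium("matrix", vals, tau = tau, seed = as.integer(seed))
}

#' Build a correlated Gaussian random field by spectral filtering
#'
#' White noise is filtered with a Gaussian kernel of 1/e half-width
#' `correlation_length` (in pixels), then rescaled to the requested RMS.
#' @noRd
gaussian_random_field <- function(grid_n, correlation_length, strength) {
  w <- matrix(stats::rnorm(grid_n^2), grid_n, grid_n)
  if (strength == 0) return(matrix(0, grid_n, grid_n))
  f <- (seq_len(grid_n) - 1)
  f <- ifelse(f > grid_n / 2, f - grid_n, f)   # FFT frequencies
  # Gaussian autocorrelation exp(-(r/L)^2) <-> Gaussian spectral filter
  k2 <- outer(f^2, f^2, "+")
  filt <- exp(-(pi * correlation_length / grid_n)^2 * k2 / 2)
  g <- Re(stats::fft(stats::fft(w) * filt, inverse = TRUE)) / grid_n^2
  g <- g - mean(g)
  g * (strength / sqrt(mean(g^2)))
}

#' Generate a thin random phase screen
#'
#' The screen is `exp(i g)` with `g` a zero-mean correlated Gaussian field of
#' RMS `strength` radians and correlation length `correlation_length` pupil
#' pixels. Stronger / finer-grained screens emulate thicker tissue: with
#' `strength >= 2*pi` the unaberrated focus is fully destroyed and the focal
#' plane is developed speckle.
#'
#' @param grid_n pixels per side of the pupil grid (>= 16).
#' @param correlation_length autocorrelation half-width in pupil pixels (>= 1).
#' @param strength RMS phase in radians (>= 0; 0 gives the identity screen).
#' @param seed integer RNG seed.
#' @param tau decorrelation time in seconds (`Inf` = static).
#' @return A `"phase_screen"`-form medium object.
#' @export
make_phase_screen <- function(grid_n, correlation_length, strength, seed,
                              tau = Inf) {
  if (grid_n < 16) stop("`grid_n` must be >= 16")
  if (correlation_length < 1) stop("`correlation_length` must be >= 1")
  if (strength < 0) stop("`strength` must be >= 0")
  if (tau <= 0) stop("`tau` must be > 0")
  g <- with_seed(seed, gaussian_random_field(grid_n, correlation_length, strength))
  m <- new_medium("phase_screen", exp(1i * g), tau = tau,
                  seed = as.integer(seed),
                  correlation_length = correlation_length, strength = strength)
  m$phase_field <- g
  m
}

#' Advance a dynamic medium in time
#'
#' The medium decorrelates as a complex Ornstein--Uhlenbeck process: the field
#' correlation with the starting medium decays as `exp(-dt/tau)`.
#'
#' For the matrix form each entry is blended with an independent fresh draw,
#' `T' = sqrt(1 - a) T + sqrt(a) T_fresh` with `a = 1 - exp(-2 dt / tau)`,
#' which preserves the circular-Gaussian marginal exactly and composes over
#' successive steps. For the phase-screen form the underlying Gaussian phase
#' field is blended with a fresh field drawn with the same correlation filter,
#' with the blend weight chosen so the complex field correlation of the
#' screens equals `exp(-dt/tau)` for this step.
#'
#' @param medium a medium with finite `tau`.
#' @param dt elapsed time in seconds (>= 0).
#' @return A new medium with the clock advanced by `dt`.
#' @export
evolve_medium <- function(medium, dt) {
  stopifnot(inherits(medium, "fcoat_medium"))
  if (dt < 0) stop("`dt` must be >= 0")
  if (!is.finite(medium$tau)) stop("medium is static (`tau` = Inf)")
  if (dt == 0) return(medium)
  # fold the clock into the evolution seed so repeated calls draw fresh noise
  # reproducibly for a given history
  step_seed <- (medium$seed + as.integer(round(medium$clock * 1e3) %% 1000003L)
                + 17L) %% .Machine$integer.max
  if (medium$form == "matrix") {
    alpha <- 1 - exp(-2 * dt / medium$tau)
    fresh <- with_seed(step_seed, {
      n <- length(medium$values)
      matrix(complex(real = stats::rnorm(n, sd = sqrt(0.5)),
                     imaginary = stats::rnorm(n, sd = sqrt(0.5))),
             nrow = nrow(medium$values))
    })
    medium$values <- sqrt(1 - alpha) * medium$values + sqrt(alpha) * fresh
  } else {
    sig2 <- medium$strength^2
    if (sig2 > 0) {
      # field correlation of two unit screens with jointly Gaussian phases of
      # common variance sig2 and correlation rho is exp(-sig2 (1 - rho));
      # choose rho so that this equals exp(-dt/tau), flooring at full refresh
      rho <- max(0, 1 - dt / (medium$tau * sig2))
      grid_n <- nrow(medium$values)
      fresh <- with_seed(step_seed,
        gaussian_random_field(grid_n, medium$correlation_length, medium$strength))
      g <- rho * medium$phase_field + sqrt(1 - rho^2) * fresh
      medium$phase_field <- g
      medium$values <- exp(1i * g)
    }
  }
  medium$clock <- medium$clock + dt
  medium
}

#' Field correlation between two media
#'
#' Normalized modulus of the complex inner product of the two media's values:
#' `|sum(a * Conj(b))| / sqrt(sum|a|^2 sum|b|^2)`. Equals 1 for identical
#' media and ~0 for independent ones; after [evolve_medium()] by `dt` it is
#' `exp(-dt/tau)` in expectation.
#'
#' @param a,b media of the same form and shape.
#' @return A number in \[0, 1\].
#' @export
field_correlation <- function(a, b) {
  stopifnot(inherits(a, "fcoat_medium"), inherits(b, "fcoat_medium"))
  if (!identical(a$form, b$form) || !identical(dim(a$values), dim(b$values)))
    stop("media must have the same form and shape")
  num <- Mod(sum(a$values * Conj(b$values)))
  den <- sqrt(sum(Mod(a$values)^2) * sum(Mod(b$values)^2))
  num / den
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so library code does not
#' perturb user simulations.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Save / load a medium as a plain-text artifact
#'
#' The medium is written as a JSON header plus CSV-encoded real and imaginary
#' parts, so runs are reproducible from disk without binary formats.
#'
#' @param medium a medium object.
#' @param path file path (`.json`).
#' @export
save_medium <- function(medium, path) {
  obj <- list(form = medium$form, tau = medium$tau, seed = medium$seed,
              clock = medium$clock,
              correlation_length = medium$correlation_length,
              strength = medium$strength,
              dim = dim(medium$values),
              re = as.vector(Re(medium$values)),
              im = as.vector(Im(medium$values)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_medium
#' @export
load_medium <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  vals <- matrix(complex(real = obj$re, imaginary = obj$im),
                 nrow = obj$dim[1], ncol = obj$dim[2])
  tau <- if (is.null(obj$tau) || !is.numeric(obj$tau)) Inf else obj$tau
  m <- new_medium(obj$form, vals, tau = tau, seed = obj$seed, clock = obj$clock,
                  correlation_length = obj$correlation_length,
                  strength = obj$strength)
  if (m$form == "phase_screen") m$phase_field <- Arg(vals)
  m
}
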