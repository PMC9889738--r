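# Shared fixtures, built in code at test time.

# default physical configuration used throughout: 589 nm, NA 0.1,
# 256-px grid with a half-filled 128-px pupil
test_optics <- function(...) optical_config(...)

# small geometry for fast exact checks
small_optics <- function() optical_config(grid_n = 64, pupil_diameter_px = 32)

small_layout <- function(n_side = 8) build_segment_grid(small_optics(), n_side)

# a hand-built layout with an arbitrary M, for matrix-medium unit tests that
# do not need pupil geometry
bare_layout <- function(M) {
  structure(list(n_side = NA_integer_, M = as.integer(M), cell_px = NA_integer_),
            class = "fcoat_layout")
}

# matrix medium with chosen per-segment target responses (row 1 = target)
medium_from_row <- function(row_values, n_out = 1) {
  vals <- matrix(0 + 0i, n_out, length(row_values))
  vals[1, ] <- row_values
  if (n_out > 1) vals[-1, ] <- complex(real = 0, imaginary = 0)
  structure(list(form = "matrix", values = vals, tau = Inf, seed = 0L,
                 clock = 0), class = "fcoat_medium")
}

# independent brute-force count of lattice cell centres inside radius N/2
brute_inscribed_count <- function(n_side) {
  count <- 0L
  for (r in seq_len(n_side)) for (c in seq_len(n_side)) {
    dr <- (r - 0.5) - n_side / 2
    dc <- (c - 0.5) - n_side / 2
    if (dr^2 + dc^2 <= (n_side / 2)^2) count <- count + 1L
  }
  count
}
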