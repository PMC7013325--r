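# Shared fixtures: small, cheap objects built fresh per test run.

# Tumor optical properties at 635 nm used throughout.
tumor_props <- function() optical_properties(1.7, 365, 0.9)
wm_props <- function() optical_properties(0.7, 951, 0.9)

# Default photophysics (beta = 13.5 J/cm^2, bleaching on).
pp <- function(...) photophysical_params(...)

# Small homogeneous tumor cube for transport tests: `half` cm half-extent.
small_cube <- function(n = 48, spacing = 0.04, c0 = 5.8e-6) {
  build_uniform_phantom(c(n, n, n), rep(spacing, 3), props = tumor_props(),
                        c0 = c0)
}

# Short near-point diffuser at the cube centre (for point-source checks).
point_like_diffuser <- function(n = 48, spacing = 0.04, power_mw = 1) {
  half <- n * spacing / 2
  diffuser_spec(tip_position = c(half, half, half - 0.02),
                axis = c(0, 0, 1), radiation_length = 0.04,
                outer_diameter = 0.02,
                linear_power_density = power_mw / 0.04)
}

# Radius of every voxel centre from a point, as an array on the grid.
center_radii <- function(grid, center) {
  cx <- grid$origin[1] + (seq_len(grid$dims[1]) - 0.5) * grid$spacing[1]
  cy <- grid$origin[2] + (seq_len(grid$dims[2]) - 0.5) * grid$spacing[2]
  cz <- grid$origin[3] + (seq_len(grid$dims[3]) - 0.5) * grid$spacing[3]
  sqrt(outer(outer((cx - center[1])^2, (cy - center[2])^2, `+`),
             (cz - center[3])^2, `+`))
}

# A dose_map with a prescribed per-voxel field (for outcome tests).
make_dose_map <- function(grid, d_so) {
  structure(list(grid = grid, d_so = array(d_so, dim = grid$dims)),
            class = "dose_map")
}
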