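#' Cylindrical light diffuser specification
#'
#' Geometry and drive power of one interstitial fiber diffuser.  The
#' radiation section is a cylinder of length `radiation_length` and diameter
#' `outer_diameter` starting at `tip_position` (centre of the proximal end
#' of the radiation section) and extending along `axis`.  Defaults match a
#' clinical 40 mm / 1.1 mm diffuser.
#'
#' @param tip_position World coordinate (cm) of the centre of the radiation
#'   section's proximal end.
#' @param axis Direction of the radiation section; normalised internally.
#' @param radiation_length Length of the emitting section, cm.
#' @param outer_diameter Diffuser outer diameter, cm.
#' @param linear_power_density Emitted power per unit length, mW/cm.
#' @param irradiation_time Irradiation time, s.
#' @return A `diffuser_spec` object.  Total emitted power (mW) is
#'   `linear_power_density * radiation_length`.
#' @examples
#' d <- diffuser_spec(c(0, 0, 0), c(0, 0, 1), linear_power_density = 200)
#' diffuser_power(d)     # 800 mW for the 4 cm default length
#' @export
diffuser_spec <- function(tip_position, axis = c(0, 0, 1),
                          radiation_length = 4.0, outer_diameter = 0.11,
                          linear_power_density = 200,
                          irradiation_time = 3600) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm == 0) stop("`axis` must be a nonzero vector", call. = FALSE)
  if (radiation_length <= 0) stop("`radiation_length` must be > 0", call. = FALSE)
  if (outer_diameter <= 0) stop("`outer_diameter` must be > 0", call. = FALSE)
  if (linear_power_density < 0) stop("`linear_power_density` must be >= 0", call. = FALSE)
  if (irradiation_time < 0) stop("`irradiation_time` must be >= 0", call. = FALSE)
  structure(list(tip_position = as.numeric(tip_position), axis = axis / nrm,
                 radiation_length = radiation_length,
                 outer_diameter = outer_diameter,
                 linear_power_density = linear_power_density,
                 irradiation_time = irradiation_time),
            class = "diffuser_spec")
}

#' @rdname diffuser_spec
#' @param diffuser A `diffuser_spec`.
#' @export
diffuser_power <- function(diffuser) {
  diffuser$linear_power_density * diffuser$radiation_length
}

#' @export
print.diffuser_spec <- function(x, ...) {
  cat(sprintf("<diffuser_spec> L = %g cm, d = %g cm, %g mW/cm (%g mW), T = %g s\n",
              x$radiation_length, x$outer_diameter, x$linear_power_density,
              diffuser_power(x), x$irradiation_time))
  invisible(x)
}

#' Convert linear power density to surface fluence rate
#'
#' The fluence rate on the lateral surface of a cylindrical diffuser equals
#' the emitted power per unit length divided by the lateral circumference:
#' `phi_sur = linear_power_density / (pi * outer_diameter)`.  For a 1.1 mm
#' diffuser, 200 mW/cm gives ~580 mW/cm^2 and 800 mW/cm gives ~2320 mW/cm^2.
#'
#' @param linear_power_density mW/cm (>= 0).
#' @param outer_diameter cm (> 0).
#' @return Surface fluence rate, mW/cm^2.
#' @export
linear_to_surface_fluence <- function(linear_power_density, outer_diameter = 0.11) {
  if (any(linear_power_density < 0)) {
    stop("`linear_power_density` must be >= 0", call. = FALSE)
  }
  if (any(outer_diameter <= 0)) stop("`outer_diameter` must be > 0", call. = FALSE)
  linear_power_density / (pi * outer_diameter)
}

#' Sample photon launch points and directions from a diffuser
#'
#' Launch points are uniform over the lateral surface of the radiation
#' section (uniform along the length, uniform in azimuth); launch directions
#' are uniform over the outward solid-angle hemisphere about the local
#' surface normal.  The sampler is the one used inside the transport kernel.
#'
#' @param diffuser A [diffuser_spec()].
#' @param n Number of samples.
#' @return A tibble with columns `x, y, z` (cm), `ux, uy, uz` (unit
#'   direction) and `cos_normal` (direction against the outward normal,
#'   always >= 0).
#' @export
sample_emission <- function(diffuser, n = 1000L) {
  stopifnot(inherits(diffuser, "diffuser_spec"))
  s <- cpp_sample_emission(diffuser$tip_position, diffuser$axis,
                           diffuser$radiation_length,
                           diffuser$outer_diameter / 2, as.integer(n))
  pos <- s$position
  dir <- s$direction
  # outward normal = radial component of (pos - tip), i.e. position minus its
  # axial projection, normalised
  rel <- sweep(pos, 2, diffuser$tip_position)
  ax_comp <- drop(rel %*% diffuser$axis)
  radial <- rel - outer(ax_comp, diffuser$axis)
  radial <- radial / sqrt(rowSums(radial^2))
  tibble::tibble(x = pos[, 1], y = pos[, 2], z = pos[, 3],
                 ux = dir[, 1], uy = dir[, 2], uz = dir[, 3],
                 cos_normal = rowSums(dir * radial))
}

#' Monte Carlo fluence-rate simulation
#'
#' Propagates photon packets from each diffuser through the voxel model and
#' returns the fluence-rate field.  Per packet: step lengths are sampled
#' from the local interaction coefficient with partial steps at voxel
#' boundaries; at each interaction the fraction `mu_a / (mu_a + mu_s)` of
#' the packet weight is deposited and the packet is scattered by the
#' Henyey-Greenstein phase function with the voxel's `g`; packets below
#' weight 1e-4 undergo Russian roulette (survival probability 0.1, survivor
#' weight x10); packets leaving the grid or entering void (label 0) are
#' tallied as escaped.  Fluence in a voxel with absorption is
#' `deposited_weight * P / (n_photons * mu_a * voxel_volume)` (mW/cm^2 for
#' P in mW); voxels with `mu_a = 0` use the track-length estimator
#' `tracklength_weight * P / (n_photons * voxel_volume)` instead.
#'
#' Each diffuser is simulated with `n_photons` packets and its own power on
#' an independent seed substream (`seed + 7919 * (i - 1)`), so adding a
#' diffuser to a plan never perturbs the packets of the others and fluence
#' is exactly linear in each diffuser's power at fixed seed.
#'
#' @param model A [tissue_model][build_uniform_phantom()].
#' @param diffusers A [diffuser_spec()] or list of them.
#' @param n_photons Packets per diffuser.
#' @param seed Integer RNG seed (bit-reproducibility contract: same model,
#'   diffusers, `n_photons` and seed give an identical map).
#' @return A `fluence_map`: `grid`, `phi` (mW/cm^2 array), `n_photons`
#'   (total packets), `seed`, and `ledger` with `launched_weight`,
#'   `deposited_weight`, `escaped_weight`, `roulette_discarded_weight`
#'   (conserved to better than 1e-6 relative).
#' @export
simulate_fluence <- function(model, diffusers, n_photons = 1e6, seed = 1L) {
  stopifnot(inherits(model, "tissue_model"))
  if (inherits(diffusers, "diffuser_spec")) diffusers <- list(diffusers)
  if (!length(diffusers)) stop("at least one diffuser is required", call. = FALSE)
  n_photons <- as.integer(n_photons)
  if (n_photons < 1L) stop("`n_photons` must be >= 1", call. = FALSE)
  if (all(model$labels == LABEL_VOID)) {
    stop("model is all void: nothing to propagate through", call. = FALSE)
  }
  g <- model$grid
  if (!any(vapply(diffusers, diffuser_intersects_grid, logical(1), grid = g))) {
    stop("no diffuser radiation section intersects the grid", call. = FALSE)
  }
  tabs <- property_tables(model)
  vv <- voxel_volume(g)
  mua_vox <- tabs$mua[model$labels + 1L]

  phi <- array(0, dim = g$dims)
  ledger <- c(launched_weight = 0, deposited_weight = 0,
              escaped_weight = 0, roulette_discarded_weight = 0)
  for (i in seq_along(diffusers)) {
    d <- diffusers[[i]]
    res <- with_seed(substream_seed(seed, i - 1L), {
      cpp_transport(g$dims, g$spacing, g$origin, as.vector(model$labels),
                    tabs$mua, tabs$mus, tabs$g,
                    d$tip_position, d$axis, d$radiation_length,
                    d$outer_diameter / 2, n_photons,
                    1e-4, 0.1)
    })
    p <- diffuser_power(d)
    dep <- res$deposited
    trk <- res$tracklen
    contrib <- ifelse(mua_vox > 0, dep / mua_vox, trk)
    phi <- phi + array(contrib * p / (n_photons * vv), dim = g$dims)
    ledger <- ledger + c(res$launched_weight, res$deposited_weight,
                         res$escaped_weight, res$roulette_discarded_weight)
  }
  phi[model$labels == LABEL_VOID] <- 0
  new_fluence_map(g, phi, n_photons * length(diffusers), seed, as.list(ledger))
}

new_fluence_map <- function(grid, phi, n_photons, seed, ledger) {
  structure(list(grid = grid, phi = phi, n_photons = n_photons,
                 seed = seed, ledger = ledger),
            class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("<fluence_map> %d x %d x %d voxels, %s packets, seed %s\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              format(x$n_photons, big.mark = ","), format(x$seed)))
  cat(sprintf("  phi max %.4g mW/cm^2; ledger residual %.2e\n",
              max(x$phi), ledger_residual(x)))
  invisible(x)
}

#' Energy-conservation residual of a fluence map
#'
#' Relative imbalance of the packet-weight ledger:
#' `|launched - deposited - escaped - discarded| / launched`.
#' Unbiased roulette bookkeeping keeps this at floating-point level
#' (< 1e-6 always).
#'
#' @param fluence A `fluence_map`.
#' @return Nonnegative scalar.
#' @export
ledger_residual <- function(fluence) {
  l <- fluence$ledger
  abs(l$launched_weight - l$deposited_weight - l$escaped_weight -
        l$roulette_discarded_weight) / l$launched_weight
}

#' Sum fluence maps from separate simulations
#'
#' Fluence is additive over sources, so maps computed per diffuser (or in
#' batches of packets) combine by per-voxel summation; ledgers and packet
#' counts add.
#'
#' @param maps List of `fluence_map` objects on the identical grid.
#' @return A combined `fluence_map`.
#' @export
combine_fluence <- function(maps) {
  if (inherits(maps, "fluence_map")) return(maps)
  stopifnot(length(maps) >= 1)
  g <- maps[[1]]$grid
  for (m in maps[-1]) {
    if (!same_grid(g, m$grid)) stop("fluence maps live on different grids", call. = FALSE)
  }
  phi <- Reduce(`+`, lapply(maps, `[[`, "phi"))
  ledger <- as.list(Reduce(`+`, lapply(maps, function(m) unlist(m$ledger))))
  n <- sum(vapply(maps, `[[`, numeric(1), "n_photons"))
  new_fluence_map(g, phi, n, maps[[1]]$seed, ledger)
}

#' Diffusion-approximation fluence of an isotropic point source
#'
#' Closed-form benchmark used to validate the Monte Carlo kernel in the
#' diffusive regime (`mu_s' >> mu_a`, several transport mean free paths from
#' the source): with reduced scattering `mu_s' = mu_s (1 - g)`, diffusion
#' constant `D = 1 / (3 (mu_a + mu_s'))` and effective attenuation
#' `mu_eff = sqrt(3 mu_a (mu_a + mu_s'))`,
#' `phi(r) = P exp(-mu_eff r) / (4 pi D r)`.
#'
#' @param r Distance from the source, cm (> 0); vectorised.
#' @param props [optical_properties()] of the infinite homogeneous medium
#'   (`mu_a > 0`).
#' @param power Source power (mW gives mW/cm^2).
#' @return Fluence rate at `r`.
#' @export
point_source_diffusion_fluence <- function(r, props, power = 1) {
  stopifnot(inherits(props, "optical_properties"))
  if (any(r <= 0)) stop("`r` must be > 0", call. = FALSE)
  if (props$mu_a <= 0) stop("`mu_a` must be > 0 for the diffusion solution", call. = FALSE)
  musp <- props$mu_s * (1 - props$g)
  D <- 1 / (3 * (props$mu_a + musp))
  mu_eff <- sqrt(3 * props$mu_a * (props$mu_a + musp))
  power * exp(-mu_eff * r) / (4 * pi * D * r)
}

#' Lay out parallel diffusers on a square lattice
#'
#' Places `n` diffusers with parallel axes on a square lattice perpendicular
#' to the axis, with nearest-neighbour (interfiber) spacing `L`.  The
#' clinically motivated minimum spacing is 0.9 cm.
#'
#' @param n Number of diffusers (>= 1).
#' @param interfiber_distance Nearest-neighbour spacing `L`, cm (> 0).
#' @param axis Common diffuser axis.
#' @param anchor Tip position (cm) of the first diffuser; the lattice grows
#'   from here in the two directions perpendicular to `axis`.
#' @param ... Further arguments passed to [diffuser_spec()] (power, length,
#'   diameter, time).
#' @return List of `n` [diffuser_spec()] objects.
#' @export
place_parallel_diffusers <- function(n, interfiber_distance = 0.9,
                                     axis = c(0, 0, 1), anchor = c(0, 0, 0),
                                     ...) {
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (interfiber_distance <= 0) stop("`interfiber_distance` must be > 0", call. = FALSE)
  axis <- axis / sqrt(sum(axis^2))
  f <- perp_basis(axis)
  side <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  gx <- idx %% side
  gy <- idx %/% side
  lapply(seq_len(n), function(i) {
    tip <- anchor + interfiber_distance * (gx[i] * f$e1 + gy[i] * f$e2)
    diffuser_spec(tip_position = tip, axis = axis, ...)
  })
}

# Deterministic orthonormal basis perpendicular to a unit axis (mirrors the
# construction in the C++ kernel).
perp_basis <- function(axis) {
  h <- c(1, 0, 0)
  a <- abs(axis)
  if (a[2] <= a[1] && a[2] <= a[3]) h <- c(0, 1, 0)
  if (a[3] < a[1] && a[3] < a[2]) h <- c(0, 0, 1)
  e1 <- h - sum(h * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

diffuser_intersects_grid <- function(diffuser, grid) {
  lo <- grid$origin
  hi <- grid$origin + grid$dims * grid$spacing
  # sample points along the radiation-section axis; coarse but sufficient
  # for the precondition check
  t <- seq(0, diffuser$radiation_length, length.out = 33)
  pts <- outer(t, diffuser$axis) +
    matrix(diffuser$tip_position, length(t), 3, byrow = TRUE)
  any(apply(pts, 1, function(p) all(p >= lo & p <= hi)))
}

# Per-stage / per-diffuser seed substreams: documented counter scheme
# seed_k = (seed + 7919 * k) mod (2^31 - 1), k = 0, 1, ...
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
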