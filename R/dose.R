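#' Photophysical parameter set for singlet-oxygen dosimetry
#'
#' Parameters of the singlet-oxygen quantum-yield (SOQY) dose model for
#' ALA-induced protoporphyrin IX.  The accumulated singlet-oxygen
#' concentration produced by a constant fluence rate `phi` (W/cm^2) over
#' time `T` is
#'
#'   `D_SO = A * Phi * C0 * beta * (1 - exp(-phi * T / beta))`    (bleaching on)
#'   `D_SO = A * Phi * C0 * phi * T`                              (bleaching off)
#'
#' with `A = 1000 * epsilon * ln(10) * lambda / (h * c * N_A)`, the number of
#' moles of photons absorbed per litre, per J/cm^2 of fluence, per mol/L of
#' photosensitizer (the factor 1000 converts cm^3 to L).  Photobleaching
#' enters as exponential decay of the photosensitizer with fluence constant
#' `beta` (J/cm^2); oxygen is assumed non-limiting (constant quantum yield).
#'
#' The physical constants default to the rounded values conventional in this
#' model (`c = 3.0e10` cm/s, `N_A = 6.0e23` /mol) rather than CODATA values.
#'
#' @param epsilon Molar extinction coefficient of PpIX at the treatment
#'   wavelength, cm^-1 M^-1.
#' @param lambda Excitation wavelength, cm (default 635 nm).
#' @param phi_quantum Singlet-oxygen quantum yield (0 < Phi <= 1); identical
#'   for tumor and normal tissue.
#' @param beta Photobleaching fluence constant, J/cm^2.  Reported PpIX
#'   values span roughly 4.5-33 J/cm^2; 13.5 is the default.
#' @param bleaching_enabled If `FALSE`, the photosensitizer never bleaches
#'   and dose grows linearly in fluence without bound.
#' @param h Planck constant, J s.
#' @param c_light Speed of light, cm/s.
#' @param n_avogadro Avogadro constant, mol^-1.
#' @return A `photophysical_params` object.
#' @examples
#' p <- photophysical_params()
#' dose_prefactor(p)     # ~61.3 (J/cm^2)^-1
#' @export
photophysical_params <- function(epsilon = 5000, lambda = 635e-7,
                                 phi_quantum = 0.77, beta = 13.5,
                                 bleaching_enabled = TRUE,
                                 h = 6.626e-34, c_light = 3.0e10,
                                 n_avogadro = 6.0e23) {
  vals <- c(epsilon = epsilon, lambda = lambda, phi_quantum = phi_quantum,
            beta = beta, h = h, c_light = c_light, n_avogadro = n_avogadro)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all photophysical parameters must be positive and finite", call. = FALSE)
  }
  if (phi_quantum > 1) stop("`phi_quantum` must be <= 1", call. = FALSE)
  structure(list(epsilon = epsilon, lambda = lambda, phi_quantum = phi_quantum,
                 beta = beta, bleaching_enabled = isTRUE(bleaching_enabled),
                 h = h, c_light = c_light, n_avogadro = n_avogadro),
            class = "photophysical_params")
}

#' @export
print.photophysical_params <- function(x, ...) {
  cat(sprintf(paste0("<photophysical_params> epsilon = %g /cm/M, ",
                     "lambda = %g nm, Phi = %g, beta = %g J/cm^2 (%s)\n"),
              x$epsilon, x$lambda * 1e7, x$phi_quantum, x$beta,
              if (x$bleaching_enabled) "bleaching on" else "bleaching off"))
  invisible(x)
}

#' Photon-absorption rate constant of the dose model
#'
#' `A = 1000 * epsilon * ln(10) * lambda / (h * c * N_A)`: moles of photons
#' absorbed per litre per (J/cm^2) of fluence per (mol/L) of
#' photosensitizer.  With the default parameters, `A` is about 61.3
#' (J/cm^2)^-1.
#'
#' @param params A [photophysical_params()].
#' @return The rate constant, (J/cm^2)^-1.
#' @export
dose_prefactor <- function(params = photophysical_params()) {
  1000 * params$epsilon * log(10) * params$lambda /
    (params$h * params$c_light * params$n_avogadro)
}

#' Accumulated singlet-oxygen concentration (closed form)
#'
#' Dose produced at one point by a constant fluence rate over the
#' irradiation time, with or without photobleaching (see
#' [photophysical_params()] for the model).  Dose depends on the exposure
#' only through the fluence `F = fluence_rate * time` (J/cm^2).  All
#' arguments are vectorised.
#'
#' @param fluence_rate Fluence rate, W/cm^2 (>= 0).
#' @param time Irradiation time, s (>= 0).
#' @param c0 Initial photosensitizer concentration, mol/L (>= 0).
#' @param params A [photophysical_params()].
#' @return Accumulated singlet-oxygen concentration, mol/L (multiply by
#'   1000 for mM).
#' @examples
#' p <- photophysical_params()
#' # 2.3 J/cm^2 on 5.8 uM PpIX: ~0.58 mM
#' 1000 * singlet_oxygen_dose(2.3 / 3600, 3600, 5.8e-6, p)
#' @export
singlet_oxygen_dose <- function(fluence_rate, time, c0,
                                params = photophysical_params()) {
  if (any(fluence_rate < 0) || any(time < 0) || any(c0 < 0)) {
    stop("`fluence_rate`, `time` and `c0` must be >= 0", call. = FALSE)
  }
  A <- dose_prefactor(params)
  fluence <- fluence_rate * time
  if (params$bleaching_enabled) {
    A * params$phi_quantum * c0 * params$beta * (-expm1(-fluence / params$beta))
  } else {
    A * params$phi_quantum * c0 * fluence
  }
}

#' Time-stepped evaluation of the dose integral
#'
#' Trapezoidal integration of the instantaneous singlet-oxygen generation
#' rate `A * Phi * phi * C0 * exp(-phi * t / beta)` over the irradiation
#' time.  Serves as an independent numerical check of the closed form in
#' [singlet_oxygen_dose()]: at `dt = T / 1e4` the two agree to 1e-4
#' relative; with bleaching disabled the integrand is constant and the two
#' agree exactly for any `dt`.
#'
#' @inheritParams singlet_oxygen_dose
#' @param dt Time step, s (> 0); the last step is shortened to end exactly
#'   at `time`.
#' @return Accumulated singlet-oxygen concentration, mol/L.
#' @export
numeric_dose_integral <- function(fluence_rate, time, c0,
                                  params = photophysical_params(),
                                  dt = time / 1e4) {
  if (dt <= 0) stop("`dt` must be > 0", call. = FALSE)
  if (time == 0 || fluence_rate == 0 || c0 == 0) return(0)
  A <- dose_prefactor(params)
  ts <- unique(c(seq(0, time, by = dt), time))
  rate <- if (params$bleaching_enabled) {
    A * params$phi_quantum * fluence_rate * c0 *
      exp(-fluence_rate * ts / params$beta)
  } else {
    rep(A * params$phi_quantum * fluence_rate * c0, length(ts))
  }
  sum(diff(ts) * (rate[-1] + rate[-length(ts)]) / 2)
}

#' Per-voxel singlet-oxygen dose map
#'
#' Applies the closed-form dose model voxelwise: the fluence map (mW/cm^2)
#' is converted to W/cm^2, multiplied by the irradiation time and combined
#' with the model's initial-concentration field.
#'
#' @param fluence A [fluence_map][simulate_fluence()].
#' @param time Irradiation time, s.
#' @param model The `tissue_model` supplying `c0_field` (same grid).
#' @param params A [photophysical_params()].
#' @return A `dose_map`: `grid` plus `d_so`, the accumulated
#'   singlet-oxygen concentration per voxel in mol/L.
#' @export
dose_map <- function(fluence, time, model, params = photophysical_params()) {
  stopifnot(inherits(fluence, "fluence_map"), inherits(model, "tissue_model"))
  if (!same_grid(fluence$grid, model$grid)) {
    stop("fluence map and tissue model live on different grids", call. = FALSE)
  }
  d <- singlet_oxygen_dose(fluence$phi / 1000, time, model$c0_field, params)
  structure(list(grid = fluence$grid, d_so = array(d, dim = fluence$grid$dims)),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %d x %d x %d voxels, D_SO max %.4g mM\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              1000 * max(x$d_so)))
  invisible(x)
}

#' Saturation dose under photobleaching
#'
#' With photobleaching the dose cannot exceed `A * Phi * C0 * beta`, the
#' limit of [singlet_oxygen_dose()] as fluence grows without bound: once
#' the photosensitizer is bleached away, further light generates nothing.
#'
#' @inheritParams singlet_oxygen_dose
#' @return Saturation dose, mol/L.
#' @export
saturation_dose <- function(c0, params = photophysical_params()) {
  if (!params$bleaching_enabled) {
    stop("dose is unbounded when bleaching is disabled", call. = FALSE)
  }
  dose_prefactor(params) * params$phi_quantum * c0 * params$beta
}

#' Fluence required to reach a dose threshold
#'
#' Inverts the closed-form dose model for the light fluence `F` at which
#' `D_SO` first reaches `threshold`:
#' `F = -beta * log(1 - threshold / (A * Phi * C0 * beta))` with bleaching,
#' `F = threshold / (A * Phi * C0)` without.  A threshold at or above the
#' saturation dose is unreachable at any fluence; the result is then `Inf`
#' (with bleaching on), so unreachability is an ordinary value, not an
#' error.
#'
#' @param threshold Cell-death dose threshold, mol/L (> 0); vectorised.
#' @inheritParams singlet_oxygen_dose
#' @return Required fluence, J/cm^2 (`Inf` where unreachable).
#' @examples
#' p <- photophysical_params(beta = 13.5)
#' required_fluence(0.56e-3, c0 = 5.8e-6, params = p)   # ~2.2 J/cm^2
#' @export
required_fluence <- function(threshold, c0, params = photophysical_params()) {
  if (any(threshold <= 0)) stop("`threshold` must be > 0", call. = FALSE)
  if (any(c0 <= 0)) stop("`c0` must be > 0", call. = FALSE)
  A <- dose_prefactor(params)
  if (!params$bleaching_enabled) {
    return(threshold / (A * params$phi_quantum * c0))
  }
  sat <- saturation_dose(c0, params)
  ifelse(threshold >= sat, Inf,
         -params$beta * log1p(-threshold / sat))
}

#' Minimum initial photosensitizer concentration for cell death
#'
#' The smallest `C0` whose dose reaches `threshold` at fluence `F`:
#' `C0_min = threshold / (A * Phi * beta * (1 - exp(-F / beta)))`.  At
#' `fluence = Inf` this is the saturation limit `threshold / (A * Phi *
#' beta)`, the concentration below which no amount of light can kill
#' (photobleaching destroys the sensitizer first).
#'
#' @param threshold Dose threshold, mol/L.
#' @param fluence Light fluence, J/cm^2 (> 0; `Inf` for the saturation
#'   limit).
#' @param params A [photophysical_params()] with bleaching enabled (with
#'   bleaching off the saturation limit is 0 and the finite-fluence answer
#'   is `threshold / (A * Phi * F)`).
#' @return Minimum concentration, mol/L; vectorised over `threshold` and
#'   `fluence`.
#' @examples
#' p <- photophysical_params(beta = 13.5)
#' 1e6 * min_initial_concentration(0.56e-3, Inf, p)   # ~0.9 uM
#' @export
min_initial_concentration <- function(threshold, fluence = Inf,
                                      params = photophysical_params()) {
  if (any(threshold < 0)) stop("`threshold` must be >= 0", call. = FALSE)
  if (any(fluence <= 0)) stop("`fluence` must be > 0", call. = FALSE)
  A <- dose_prefactor(params)
  if (!params$bleaching_enabled) {
    return(threshold / (A * params$phi_quantum * fluence))
  }
  eff <- params$beta * ifelse(is.infinite(fluence), 1,
                              -expm1(-fluence / params$beta))
  threshold / (A * params$phi_quantum * eff)
}

#' Minimum photobleaching coefficient for cell death at a given fluence
#'
#' The smallest `beta` for which fluence `F` still reaches the dose
#' threshold at concentration `c0`; i.e. the root of
#' `beta * (1 - exp(-F / beta)) = threshold / (A * Phi * c0)`.
#' The left side increases monotonically in `beta` with supremum `F`, so a
#' unique root exists iff the threshold is achievable without bleaching
#' (`A * Phi * c0 * F > threshold`); otherwise the result is `Inf`.  The
#' root is found by bracketed bisection on `[1e-6, 1e6]` J/cm^2 to 1e-6
#' relative width.
#'
#' @param threshold Dose threshold, mol/L (> 0).
#' @param fluence Light fluence, J/cm^2 (> 0).
#' @param c0 Initial concentration, mol/L (> 0).
#' @param params A [photophysical_params()] (its `beta` is ignored; the
#'   root is the answer).
#' @return Minimum bleaching coefficient, J/cm^2 (`Inf` if unreachable).
#' @examples
#' p <- photophysical_params()
#' min_bleaching_coefficient(0.56e-3, 3, 5.8e-6, p)   # ~3.6 J/cm^2
#' @export
min_bleaching_coefficient <- function(threshold, fluence, c0,
                                      params = photophysical_params()) {
  if (threshold <= 0) stop("`threshold` must be > 0", call. = FALSE)
  if (fluence <= 0) stop("`fluence` must be > 0", call. = FALSE)
  if (c0 <= 0) stop("`c0` must be > 0", call. = FALSE)
  A <- dose_prefactor(params)
  target <- threshold / (A * params$phi_quantum * c0)
  if (target >= fluence) return(Inf) # not reachable even without bleaching
  f <- function(b) b * (-expm1(-fluence / b)) - target
  lo <- 1e-6
  hi <- 1e6
  if (f(lo) > 0) return(lo) # threshold reached for any beta in the bracket
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) / hi < 1e-6) break
  }
  (lo + hi) / 2
}
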