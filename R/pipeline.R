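#' Configuration for a full outcome-simulation run
#'
#' Bundles everything needed to reproduce a phantom -> fluence -> dose ->
#' outcome run: the phantom description, the diffuser plan, the
#' photophysical parameters, packet count, dose threshold and seed.  The
#' config is fully serialisable ([write_run_config()]) and is archived next
#' to a run's outputs, so identical config + seed regenerate a run
#' bit-exactly.
#'
#' @param phantom Either a ready-made `tissue_model`, or a list
#'   `list(type = "uniform", dims, spacing, c0, ...)` /
#'   `list(type = "ellipsoid", dims, spacing, center, semi_axes, ...)` /
#'   `list(type = "labelmap", prefix)` describing how to build one (extra
#'   entries are passed on to the builder).
#' @param diffusers A [diffuser_spec()] or list of them.
#' @param params A [photophysical_params()].
#' @param n_photons Monte Carlo packets per diffuser.
#' @param irradiation_time Irradiation time, s.
#' @param threshold Cell-death dose threshold, mol/L.
#' @param seed Global RNG seed; stage substreams are derived from it by the
#'   counter scheme `seed + 7919 * k`.
#' @return A `run_config` object.
#' @export
run_config <- function(phantom, diffusers, params = photophysical_params(),
                       n_photons = 1e6, irradiation_time = 3600,
                       threshold = 0.56e-3, seed = 1L) {
  if (inherits(diffusers, "diffuser_spec")) diffusers <- list(diffusers)
  structure(list(phantom = phantom, diffusers = diffusers, params = params,
                 n_photons = n_photons, irradiation_time = irradiation_time,
                 threshold = threshold, seed = as.integer(seed)),
            class = "run_config")
}

build_phantom_from_config <- function(phantom) {
  if (inherits(phantom, "tissue_model")) return(phantom)
  if (!is.list(phantom) || is.null(phantom$type)) {
    stop("phantom config must be a tissue_model or a list with a `type`",
         call. = FALSE)
  }
  args <- phantom[setdiff(names(phantom), "type")]
  switch(phantom$type,
         uniform = do.call(build_uniform_phantom, args),
         ellipsoid = do.call(build_ellipsoid_phantom, args),
         labelmap = read_labelmap(phantom$prefix),
         stop("unknown phantom type: ", phantom$type, call. = FALSE))
}

#' Run the full outcome-simulation pipeline
#'
#' Executes phantom construction, Monte Carlo fluence simulation, dose
#' calculation and cell-death segmentation, optionally writing every
#' artifact (fluence map, dose map, mask, outcome report, log and the
#' config itself) to an output directory.  A stage failure aborts with the
#' stage name in the error.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing.
#' @return Invisibly, a list with `model`, `fluence`, `dose`, `mask`,
#'   `report` and `elapsed_s`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  model <- stage("phantom", build_phantom_from_config(config$phantom))
  fluence <- stage("fluence",
                   simulate_fluence(model, config$diffusers,
                                    n_photons = config$n_photons,
                                    seed = config$seed))
  dose <- stage("dose", dose_map(fluence, config$irradiation_time, model,
                                 config$params))
  mask <- stage("outcome", cell_death_mask(dose, config$threshold))
  report <- stage("outcome", volume_metrics(mask, model, config$threshold))
  elapsed <- proc.time()[["elapsed"]] - t0

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    pfx <- file.path(out_dir, "run")
    write_model(model, pfx)
    write_field(fluence, pfx)
    write_field(dose, pfx)
    RNifti::writeNifti(nifti_image(array(as.integer(mask), dim = model$grid$dims),
                                   model$grid),
                       paste0(pfx, "_mask.nii.gz"))
    write_outcome_report(report, paste0(pfx, "_report.json"))
    write_run_config(config, paste0(pfx, "_config.yaml"))
    log <- c(sprintf("seed: %d", config$seed),
             sprintf("n_photons_per_diffuser: %g", config$n_photons),
             sprintf("irradiation_time_s: %g", config$irradiation_time),
             sprintf("threshold_mM: %g", 1000 * config$threshold),
             sprintf("ledger_residual: %.3e", ledger_residual(fluence)),
             sprintf("elapsed_s: %.2f", elapsed))
    writeLines(log, paste0(pfx, "_log.txt"))
  }
  invisible(list(model = model, fluence = fluence, dose = dose, mask = mask,
                 report = report, elapsed_s = elapsed))
}

#' Serialise / load a run configuration (YAML)
#'
#' @param config A [run_config()] (phantoms given as builder lists are
#'   serialisable; a prebuilt `tissue_model` is archived by reference to
#'   its builder only if it was given as one).
#' @param path YAML path.
#' @return `write_run_config()` the path invisibly; `read_run_config()` a
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  phantom <- config$phantom
  if (inherits(phantom, "tissue_model")) {
    phantom <- list(type = "inline",
                    note = "phantom was supplied as a prebuilt tissue_model; see run_labels.nii.gz")
  }
  obj <- list(
    phantom = phantom,
    diffusers = lapply(config$diffusers, function(d) {
      list(position_cm = d$tip_position, axis = d$axis,
           radiation_length_cm = d$radiation_length,
           outer_diameter_cm = d$outer_diameter,
           linear_power_density_mw_per_cm = d$linear_power_density,
           time_s = d$irradiation_time)
    }),
    params = list(epsilon_per_cm_M = config$params$epsilon,
                  lambda_cm = config$params$lambda,
                  phi_quantum = config$params$phi_quantum,
                  beta_J_per_cm2 = config$params$beta,
                  bleaching_enabled = config$params$bleaching_enabled,
                  h_Js = config$params$h,
                  c_cm_per_s = config$params$c_light,
                  n_avogadro_per_mol = config$params$n_avogadro),
    n_photons = config$n_photons,
    irradiation_time_s = config$irradiation_time,
    threshold_M = config$threshold,
    seed = config$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  p <- obj$params
  run_config(
    phantom = obj$phantom,
    diffusers = lapply(obj$diffusers, function(e) {
      diffuser_spec(as.numeric(e$position_cm), as.numeric(e$axis),
                    e$radiation_length_cm, e$outer_diameter_cm,
                    e$linear_power_density_mw_per_cm, e$time_s)
    }),
    params = photophysical_params(p$epsilon_per_cm_M, p$lambda_cm,
                                  p$phi_quantum, p$beta_J_per_cm2,
                                  p$bleaching_enabled, p$h_Js,
                                  p$c_cm_per_s, p$n_avogadro_per_mol),
    n_photons = obj$n_photons,
    irradiation_time = obj$irradiation_time_s,
    threshold = obj$threshold_M,
    seed = obj$seed)
}

#' Parameter scan over the dose/outcome stage
#'
#' Evaluates outcome metrics over a grid of values of one parameter.
#' Because the dose model separates light transport from photophysics, the
#' scan reuses a single cached fluence map and re-evaluates only dose and
#' segmentation for `c0`, `beta` and `threshold` scans;
#' `linear_power_density` rescales the cached map (fluence is linear in
#' power); only `interfiber_distance` reruns the Monte Carlo per value.
#'
#' @param parameter One of `"c0"`, `"beta"`, `"threshold"`,
#'   `"linear_power_density"`, `"interfiber_distance"`.
#' @param values Numeric values to scan (units: mol/L, J/cm^2, mol/L,
#'   mW/cm, cm respectively).  An empty vector returns an empty table.
#' @param config A [run_config()].
#' @param fluence Optional precomputed [fluence_map][simulate_fluence()]
#'   for the config (computed once if missing).
#' @return A tibble `value`, `tv_cm3`, `dv_cm3`, `tc`, `max_dose_mM`, of
#'   class `outcome_scan` with attribute `parameter`.
#' @export
scan_parameter <- function(parameter, values, config, fluence = NULL) {
  parameter <- match.arg(parameter, c("c0", "beta", "threshold",
                                      "linear_power_density",
                                      "interfiber_distance"))
  empty <- tibble::tibble(value = numeric(), tv_cm3 = numeric(),
                          dv_cm3 = numeric(), tc = numeric(),
                          max_dose_mM = numeric())
  if (!length(values)) {
    class(empty) <- c("outcome_scan", class(empty))
    attr(empty, "parameter") <- parameter
    return(empty)
  }
  model <- build_phantom_from_config(config$phantom)
  needs_mc_per_value <- parameter == "interfiber_distance"
  if (is.null(fluence) && !needs_mc_per_value) {
    fluence <- simulate_fluence(model, config$diffusers,
                                n_photons = config$n_photons,
                                seed = config$seed)
  }
  base_lpd <- config$diffusers[[1]]$linear_power_density
  rows <- lapply(values, function(v) {
    params <- config$params
    thr <- config$threshold
    fl <- fluence
    mdl <- model
    if (parameter == "c0") {
      mdl$c0_field <- model$c0_field * (v / max(model$c0_field))
    } else if (parameter == "beta") {
      params$beta <- v
    } else if (parameter == "threshold") {
      thr <- v
    } else if (parameter == "linear_power_density") {
      fl$phi <- fluence$phi * (v / base_lpd)
    } else {
      diff2 <- place_parallel_diffusers(
        length(config$diffusers), v,
        axis = config$diffusers[[1]]$axis,
        anchor = config$diffusers[[1]]$tip_position,
        radiation_length = config$diffusers[[1]]$radiation_length,
        outer_diameter = config$diffusers[[1]]$outer_diameter,
        linear_power_density = base_lpd,
        irradiation_time = config$diffusers[[1]]$irradiation_time)
      fl <- simulate_fluence(mdl, diff2, n_photons = config$n_photons,
                             seed = config$seed)
    }
    d <- dose_map(fl, config$irradiation_time, mdl, params)
    rep <- volume_metrics(cell_death_mask(d, thr), mdl, thr)
    tibble::tibble(value = v, tv_cm3 = rep$tv, dv_cm3 = rep$dv, tc = rep$tc,
                   max_dose_mM = 1000 * max(d$d_so))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("outcome_scan", class(out))
  attr(out, "parameter") <- parameter
  out
}
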