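#' Write a tissue model to disk
#'
#' Persists a `tissue_model` as a NIfTI label map plus a NIfTI PpIX
#' concentration volume, a JSON sidecar and a YAML optical-property table.
#' NIfTI stores voxel spacing as 32-bit floats, so the sidecar carries the
#' grid geometry at full double precision and is authoritative on read:
#' round trips preserve dims, spacing, origin and labels bit-exactly.
#'
#' Files written for prefix `p`: `p_labels.nii.gz`, `p_c0.nii.gz`,
#' `p_meta.json`, `p_props.yaml`.
#'
#' @param model A `tissue_model`.
#' @param prefix Output path prefix (directory must exist).
#' @return The prefix, invisibly.
#' @seealso [read_labelmap()]
#' @export
write_model <- function(model, prefix) {
  stopifnot(inherits(model, "tissue_model"))
  g <- model$grid
  RNifti::writeNifti(nifti_image(model$labels, g), paste0(prefix, "_labels.nii.gz"))
  RNifti::writeNifti(nifti_image(model$c0_field, g), paste0(prefix, "_c0.nii.gz"))
  meta <- list(dims = g$dims, spacing_cm = g$spacing, origin_cm = g$origin,
               labels = list(`0` = "void", `1` = "normal", `2` = "tumor"))
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  props <- lapply(model$properties, function(p) {
    list(mu_a_per_cm = p$mu_a, mu_s_per_cm = p$mu_s, g = p$g)
  })
  yaml::write_yaml(props, paste0(prefix, "_props.yaml"))
  invisible(prefix)
}

#' Read a tissue model written by [write_model()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `tissue_model`.  Labels present in the file but absent from the
#'   property table raise an error naming the label.
#' @export
read_labelmap <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  grid <- voxel_grid(meta$dims, meta$spacing_cm, meta$origin_cm)
  labels <- array(as.integer(RNifti::readNifti(paste0(prefix, "_labels.nii.gz"))),
                  dim = grid$dims)
  c0_path <- paste0(prefix, "_c0.nii.gz")
  c0_field <- if (file.exists(c0_path)) {
    array(as.numeric(RNifti::readNifti(c0_path)), dim = grid$dims)
  } else {
    array(0, dim = grid$dims)
  }
  props_raw <- yaml::read_yaml(paste0(prefix, "_props.yaml"))
  properties <- lapply(props_raw, function(p) {
    optical_properties(p$mu_a_per_cm, p$mu_s_per_cm, p$g)
  })
  names(properties) <- names(props_raw)
  new_tissue_model(grid, labels, properties, c0_field)
}

# NIfTI image with the grid's spacing (mm convention: NIfTI pixdim is
# whatever unit the writer chooses; we write cm and record it in the sidecar).
nifti_image <- function(arr, grid) {
  RNifti::asNifti(arr, pixdim = grid$spacing)
}

#' Write a scalar field (fluence or dose) as NIfTI plus JSON metadata
#'
#' Fluence maps carry their energy-conservation ledger, packet count and
#' seed in the JSON sidecar; dose maps carry their units.
#'
#' @param x A `fluence_map` or `dose_map`.
#' @param prefix Output path prefix.
#' @return The prefix, invisibly.
#' @export
write_field <- function(x, prefix) {
  UseMethod("write_field")
}

#' @export
write_field.fluence_map <- function(x, prefix) {
  RNifti::writeNifti(nifti_image(x$phi, x$grid), paste0(prefix, "_fluence.nii.gz"))
  meta <- list(units = "mW/cm^2", n_photons = x$n_photons, seed = x$seed,
               dims = x$grid$dims, spacing_cm = x$grid$spacing,
               origin_cm = x$grid$origin, ledger = x$ledger)
  jsonlite::write_json(meta, paste0(prefix, "_fluence.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' @export
write_field.dose_map <- function(x, prefix) {
  RNifti::writeNifti(nifti_image(x$d_so * 1000, x$grid), paste0(prefix, "_dose_mM.nii.gz"))
  meta <- list(units = "mM", dims = x$grid$dims, spacing_cm = x$grid$spacing,
               origin_cm = x$grid$origin)
  jsonlite::write_json(meta, paste0(prefix, "_dose.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Read/write a diffuser plan as YAML
#'
#' A plan is a list of diffusers; each YAML entry carries
#' `position_cm`, `axis`, `radiation_length_cm`, `outer_diameter_cm`,
#' `linear_power_density_mw_per_cm` and `time_s`.
#'
#' @param diffusers A list of [diffuser_spec()] objects.
#' @param path YAML file path.
#' @return `write_diffuser_plan()` returns the path invisibly;
#'   `read_diffuser_plan()` a list of `diffuser_spec`.
#' @export
write_diffuser_plan <- function(diffusers, path) {
  entries <- lapply(diffusers, function(d) {
    list(position_cm = d$tip_position, axis = d$axis,
         radiation_length_cm = d$radiation_length,
         outer_diameter_cm = d$outer_diameter,
         linear_power_density_mw_per_cm = d$linear_power_density,
         time_s = d$irradiation_time)
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

#' @rdname write_diffuser_plan
#' @export
read_diffuser_plan <- function(path) {
  entries <- yaml::read_yaml(path)
  lapply(entries, function(e) {
    diffuser_spec(tip_position = as.numeric(e$position_cm),
                  axis = as.numeric(e$axis),
                  radiation_length = e$radiation_length_cm,
                  outer_diameter = e$outer_diameter_cm,
                  linear_power_density = e$linear_power_density_mw_per_cm,
                  irradiation_time = e$time_s)
  })
}
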