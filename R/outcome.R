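#' Threshold a dose map into a cell-death mask
#'
#' Cell death is assumed wherever the accumulated singlet-oxygen
#' concentration reaches the threshold `D_SO(th)` (default 0.56 mM).
#' The comparison is inclusive by default (a voxel exactly at the threshold
#' counts as killed) so that dosing exactly to [required_fluence()] is
#' treated; set `inclusive = FALSE` for a strict comparison.
#'
#' @param dose A [dose_map()].
#' @param threshold Dose threshold, mol/L (default 0.56e-3).
#' @param inclusive Tie rule at exactly the threshold.
#' @return Logical array on the dose grid.
#' @export
cell_death_mask <- function(dose, threshold = 0.56e-3, inclusive = TRUE) {
  stopifnot(inherits(dose, "dose_map"))
  if (threshold <= 0) stop("`threshold` must be > 0", call. = FALSE)
  if (inclusive) dose$d_so >= threshold else dose$d_so > threshold
}

#' Treated volume, damaged volume and tumor coverage
#'
#' Volume bookkeeping of a cell-death mask against the tissue segmentation:
#' treated volume (TV) is the killed tumor volume, damaged volume (DV) the
#' killed normal-tissue volume, and tumor coverage (TC) the ratio of TV to
#' the total tumor volume.  The same dose threshold is applied to tumor and
#' normal tissue (conservative for normal-tissue damage).
#'
#' @param mask Logical array from [cell_death_mask()].
#' @param model The `tissue_model` on the same grid.
#' @param threshold The threshold that produced `mask` (mol/L), recorded in
#'   the report.
#' @return An `outcome_report` with `threshold`, `tv`, `dv`, `tc`,
#'   `tumor_volume` (cm^3), `n_masked_voxels` and the `mask` itself.
#'   `tc` is `NA` when the model contains no tumor.
#' @examples
#' m <- build_uniform_phantom(c(8, 8, 8), rep(0.1, 3))
#' d <- structure(list(grid = m$grid,
#'                     d_so = array(1e-3, dim = m$grid$dims)),
#'                class = "dose_map")
#' volume_metrics(cell_death_mask(d), m)
#' @export
volume_metrics <- function(mask, model, threshold = 0.56e-3) {
  stopifnot(inherits(model, "tissue_model"))
  if (!identical(dim(mask), model$grid$dims)) {
    stop("mask and tissue model live on different grids", call. = FALSE)
  }
  vv <- voxel_volume(model$grid)
  tumor <- model$labels == LABEL_TUMOR
  normal <- model$labels == LABEL_NORMAL
  tv <- sum(mask & tumor) * vv
  dv <- sum(mask & normal) * vv
  tumor_volume <- sum(tumor) * vv
  tc <- if (tumor_volume > 0) tv / tumor_volume else NA_real_
  structure(list(threshold = threshold, mask = mask, tv = tv, dv = dv,
                 tc = tc, tumor_volume = tumor_volume,
                 normal_volume = sum(normal) * vv,
                 n_masked_voxels = sum(mask)),
            class = "outcome_report")
}

#' @export
print.outcome_report <- function(x, ...) {
  cat(sprintf("<outcome_report> D_SO(th) = %g mM\n", 1000 * x$threshold))
  cat(sprintf("  TV = %.4g cm^3, DV = %.4g cm^3, TC = %s (tumor %.4g cm^3)\n",
              x$tv, x$dv,
              if (is.na(x$tc)) "NA" else sprintf("%.3f", x$tc),
              x$tumor_volume))
  invisible(x)
}

#' Write an outcome report as JSON
#'
#' @param report An `outcome_report`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_outcome_report <- function(report, path) {
  jsonlite::write_json(
    list(threshold_mM = 1000 * report$threshold, tv_cm3 = report$tv,
         dv_cm3 = report$dv, tc = report$tc,
         tumor_volume_cm3 = report$tumor_volume,
         n_masked_voxels = report$n_masked_voxels),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Radial dose profile around a diffuser
#'
#' Bins voxels by cylindrical radius from the diffuser axis (restricted to
#' the axial extent of the radiation section) and reports the mean dose and
#' its standard error per bin, covering radii from the diffuser surface to
#' the largest radius represented on the grid.  Empty bins are reported
#' with `NA` means, not zeros.
#'
#' @param dose A [dose_map()].
#' @param diffuser The [diffuser_spec()] the profile is centred on.
#' @param n_bins Number of radial bins.
#' @return A tibble `radius_cm`, `mean_dose_mM`, `stderr_mM`, `n_voxels`
#'   of class `radial_profile`.
#' @export
radial_dose_profile <- function(dose, diffuser, n_bins = 30) {
  stopifnot(inherits(dose, "dose_map"), inherits(diffuser, "diffuser_spec"))
  g <- dose$grid
  cx <- voxel_centers(g, 1)
  cy <- voxel_centers(g, 2)
  cz <- voxel_centers(g, 3)
  rel1 <- cx - diffuser$tip_position[1]
  rel2 <- cy - diffuser$tip_position[2]
  rel3 <- cz - diffuser$tip_position[3]
  ax <- diffuser$axis
  nd <- g$dims
  # axial coordinate and squared radius of every voxel centre
  axial <- outer(outer(rel1 * ax[1], rel2 * ax[2], `+`), rel3 * ax[3], `+`)
  r2 <- outer(outer(rel1^2, rel2^2, `+`), rel3^2, `+`) - axial^2
  r2[r2 < 0] <- 0
  r <- sqrt(r2)
  keep <- axial >= 0 & axial <= diffuser$radiation_length
  if (!any(keep)) stop("diffuser axis does not intersect the grid", call. = FALSE)
  r_min <- diffuser$outer_diameter / 2
  r_max <- max(r[keep])
  if (r_max <= r_min) stop("grid does not extend beyond the diffuser surface", call. = FALSE)
  edges <- seq(r_min, r_max, length.out = n_bins + 1)
  bin <- cut(r[keep & r >= r_min], breaks = edges, include.lowest = TRUE)
  vals <- 1000 * dose$d_so[keep & r >= r_min]
  n <- tapply(vals, bin, length)
  n[is.na(n)] <- 0
  mean_d <- tapply(vals, bin, mean)
  sd_d <- tapply(vals, bin, stats::sd)
  out <- tibble::tibble(
    radius_cm = (edges[-1] + edges[-length(edges)]) / 2,
    mean_dose_mM = as.numeric(mean_d),
    stderr_mM = as.numeric(sd_d) / sqrt(pmax(as.numeric(n), 1)),
    n_voxels = as.integer(n))
  class(out) <- c("radial_profile", class(out))
  attr(out, "edges") <- edges
  out
}
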