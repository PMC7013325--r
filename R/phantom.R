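#' Voxel grid geometry
#'
#' Defines the discretisation shared by every field in a simulation: label
#' maps, fluence maps and dose maps all live on a `voxel_grid`.  Voxel
#' `(i, j, k)` (1-based in R) occupies the half-open box
#' `[origin + (i-1) * spacing, origin + i * spacing)` in world coordinates.
#'
#' @param dims Integer triple `(nx, ny, nz)`, voxels per axis.
#' @param spacing Numeric triple, physical voxel edge lengths in cm.
#'   Anisotropic spacings are kept as given; cubic voxels are never assumed.
#' @param origin World coordinate (cm) of the corner of the first voxel.
#'
#' @return An object of class `voxel_grid` with elements `dims`, `spacing`
#'   and `origin`.
#' @examples
#' g <- voxel_grid(c(64, 64, 64), spacing = c(0.01, 0.01, 0.01))
#' voxel_volume(g)      # 1e-6 cm^3
#' @export
voxel_grid <- function(dims, spacing, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L)) {
    stop("`dims` must be three integers >= 1", call. = FALSE)
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive lengths in cm", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be a finite coordinate triple in cm", call. = FALSE)
  }
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @rdname voxel_grid
#' @param grid A `voxel_grid`.
#' @export
voxel_volume <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  prod(grid$spacing)
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, spacing %s cm\n",
              x$dims[1], x$dims[2], x$dims[3],
              paste(signif(x$spacing, 4), collapse = " x ")))
  invisible(x)
}

# Voxel-centre world coordinates along one axis.
voxel_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$dims[axis]) - 0.5) * grid$spacing[axis]
}

same_grid <- function(a, b) {
  identical(a$dims, b$dims) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-12)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-12))
}

#' Tissue optical properties at the treatment wavelength
#'
#' Absorption coefficient, scattering coefficient and scattering anisotropy
#' of one tissue class.  Defaults are malignant brain tumor at 635 nm; white
#' matter at the same wavelength is `optical_properties(0.7, 951, 0.9)`.
#'
#' @param mu_a Absorption coefficient, cm^-1 (>= 0).
#' @param mu_s Scattering coefficient, cm^-1 (>= 0).
#' @param g Henyey-Greenstein scattering anisotropy, -1 < g < 1.
#' @return An `optical_properties` object.
#' @export
optical_properties <- function(mu_a = 1.7, mu_s = 365, g = 0.9) {
  if (!is.finite(mu_a) || mu_a < 0) stop("`mu_a` must be >= 0", call. = FALSE)
  if (!is.finite(mu_s) || mu_s < 0) stop("`mu_s` must be >= 0", call. = FALSE)
  if (!is.finite(g) || g <= -1 || g >= 1) {
    stop("`g` must lie strictly between -1 and 1", call. = FALSE)
  }
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g),
            class = "optical_properties")
}

#' @export
print.optical_properties <- function(x, ...) {
  cat(sprintf("<optical_properties> mu_a = %g cm^-1, mu_s = %g cm^-1, g = %g\n",
              x$mu_a, x$mu_s, x$g))
  invisible(x)
}

# Tissue class codes used throughout: 0 void, 1 normal (white matter), 2 tumor.
LABEL_VOID <- 0L
LABEL_NORMAL <- 1L
LABEL_TUMOR <- 2L

new_tissue_model <- function(grid, labels, properties, c0_field) {
  storage.mode(labels) <- "integer"
  if (!identical(dim(labels), grid$dims) || !identical(dim(c0_field), grid$dims)) {
    stop("label and concentration fields must match the grid dims", call. = FALSE)
  }
  used <- sort(unique(as.vector(labels)))
  used <- used[used != LABEL_VOID]
  missing <- setdiff(as.character(used), names(properties))
  if (length(missing)) {
    stop("no optical properties for tissue label(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(c0_field < 0)) stop("`c0_field` must be >= 0 everywhere", call. = FALSE)
  c0_field[labels == LABEL_VOID] <- 0
  structure(list(grid = grid, labels = labels, properties = properties,
                 c0_field = c0_field),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  vv <- voxel_volume(x$grid)
  cat(sprintf("<tissue_model> %d x %d x %d voxels\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3]))
  cat(sprintf("  tumor %.3g cm^3, normal %.3g cm^3, void %.3g cm^3\n",
              sum(x$labels == LABEL_TUMOR) * vv,
              sum(x$labels == LABEL_NORMAL) * vv,
              sum(x$labels == LABEL_VOID) * vv))
  cat(sprintf("  PpIX c0 range %.3g - %.3g mol/L\n",
              min(x$c0_field), max(x$c0_field)))
  invisible(x)
}

#' Uniform tumor phantom
#'
#' Builds a homogeneous tumor-only model: every voxel carries the same
#' optical properties and the same initial PpIX concentration.  This is the
#' geometry used for all closed-form sensitivity analyses of the dose model.
#'
#' @param dims,spacing Passed to [voxel_grid()].
#' @param props Tumor [optical_properties()].
#' @param c0 Initial PpIX concentration, mol/L (default 5.8e-6, i.e. 5.8 uM).
#' @param origin Grid origin, cm.
#' @return A `tissue_model`.
#' @examples
#' m <- build_uniform_phantom(c(32, 32, 32), spacing = rep(0.01, 3))
#' @export
build_uniform_phantom <- function(dims, spacing,
                                  props = optical_properties(),
                                  c0 = 5.8e-6, origin = c(0, 0, 0)) {
  grid <- voxel_grid(dims, spacing, origin)
  if (!is.finite(c0) || c0 < 0) stop("`c0` must be >= 0", call. = FALSE)
  labels <- array(LABEL_TUMOR, dim = grid$dims)
  c0_field <- array(c0, dim = grid$dims)
  props_map <- stats::setNames(list(props), as.character(LABEL_TUMOR))
  new_tissue_model(grid, labels, props_map, c0_field)
}

#' Ellipsoidal tumor in normal white matter
#'
#' Parametric stand-in for an MRI-derived tumor geometry: voxels whose
#' centres fall inside the ellipsoid are tumor, the remainder normal tissue.
#' Normal-tissue PpIX is scaled down from the tumor concentration by the
#' tumor-to-normal uptake ratio (`tn_ratio`).
#'
#' @param dims,spacing,origin Grid geometry, see [voxel_grid()].
#' @param center Ellipsoid centre, cm (world coordinates).
#' @param semi_axes Ellipsoid semi-axis lengths, cm (all > 0).
#' @param tumor_props,normal_props Per-tissue [optical_properties()];
#'   defaults are tumor and white matter at 635 nm.
#' @param c0_tumor Tumor initial PpIX concentration, mol/L.
#' @param tn_ratio Tumor-to-normal PpIX uptake ratio (> 0); normal-tissue
#'   concentration is `c0_tumor / tn_ratio`.
#' @return A `tissue_model` with labels 1 (normal) and 2 (tumor).
#' @examples
#' m <- build_ellipsoid_phantom(c(40, 40, 40), rep(0.05, 3),
#'                              center = rep(1, 3), semi_axes = rep(0.6, 3))
#' @export
build_ellipsoid_phantom <- function(dims, spacing, center, semi_axes,
                                    tumor_props = optical_properties(1.7, 365, 0.9),
                                    normal_props = optical_properties(0.7, 951, 0.9),
                                    c0_tumor = 5.8e-6, tn_ratio = 95,
                                    origin = c(0, 0, 0)) {
  grid <- voxel_grid(dims, spacing, origin)
  if (length(semi_axes) != 3L || any(semi_axes <= 0)) {
    stop("`semi_axes` must be three positive lengths in cm", call. = FALSE)
  }
  if (!is.finite(tn_ratio) || tn_ratio <= 0) {
    stop("`tn_ratio` must be > 0", call. = FALSE)
  }
  xs <- (voxel_centers(grid, 1) - center[1]) / semi_axes[1]
  ys <- (voxel_centers(grid, 2) - center[2]) / semi_axes[2]
  zs <- (voxel_centers(grid, 3) - center[3]) / semi_axes[3]
  r2 <- outer(outer(xs^2, ys^2, `+`), zs^2, `+`)
  inside <- r2 <= 1
  if (!any(inside)) {
    stop("ellipsoid contains no voxel centres (entirely outside the grid)",
         call. = FALSE)
  }
  labels <- array(LABEL_NORMAL, dim = grid$dims)
  labels[inside] <- LABEL_TUMOR
  c0_field <- array(c0_tumor / tn_ratio, dim = grid$dims)
  c0_field[inside] <- c0_tumor
  props_map <- stats::setNames(list(normal_props, tumor_props),
                               as.character(c(LABEL_NORMAL, LABEL_TUMOR)))
  new_tissue_model(grid, labels, props_map, c0_field)
}

#' Per-tissue volume bookkeeping
#'
#' @param model A `tissue_model`.
#' @return A tibble with one row per tissue class (`void`, `normal`,
#'   `tumor`, plus any extra labels) and columns `label`, `tissue`,
#'   `n_voxels`, `volume_cm3`.  Volumes sum exactly to the grid volume.
#' @export
tissue_volumes <- function(model) {
  stopifnot(inherits(model, "tissue_model"))
  vv <- voxel_volume(model$grid)
  tab <- table(factor(as.vector(model$labels)))
  lab <- as.integer(names(tab))
  tissue <- ifelse(lab == LABEL_VOID, "void",
                   ifelse(lab == LABEL_NORMAL, "normal",
                          ifelse(lab == LABEL_TUMOR, "tumor",
                                 paste0("label", lab))))
  tibble::tibble(label = lab, tissue = tissue,
                 n_voxels = as.integer(tab),
                 volume_cm3 = as.integer(tab) * vv)
}

# mu_a / mu_s / g lookup tables indexed 0..max(label); label 0 is void.
property_tables <- function(model) {
  max_lab <- max(1L, max(model$labels))
  mua <- mus <- g <- numeric(max_lab + 1L)
  for (nm in names(model$properties)) {
    i <- as.integer(nm) + 1L
    p <- model$properties[[nm]]
    mua[i] <- p$mu_a
    mus[i] <- p$mu_s
    g[i] <- p$g
  }
  list(mua = mua, mus = mus, g = g)
}
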