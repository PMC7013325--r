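#' Plot a radial dose profile
#'
#' Mean singlet-oxygen dose versus cylindrical distance from the diffuser
#' axis, with a standard-error ribbon and (optionally) the cell-death
#' threshold as a horizontal reference line.
#'
#' @param object A [radial_dose_profile()] result.
#' @param threshold_mM Optional threshold line, mM (`NULL` to omit).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radial_profile <- function(object, threshold_mM = 0.56, ...) {
  df <- object[!is.na(object$mean_dose_mM), ]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$radius_cm,
                                        y = .data$mean_dose_mM)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_dose_mM - .data$stderr_mM,
      ymax = .data$mean_dose_mM + .data$stderr_mM), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "distance from diffuser axis (cm)",
                  y = expression("D"["SO"] * " (mM)")) +
    ggplot2::theme_minimal()
  if (!is.null(threshold_mM)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold_mM, linetype = "dashed")
  }
  p
}

#' Plot a parameter scan
#'
#' Treated volume (and damaged volume when nonzero) against the scanned
#' parameter value.
#'
#' @param object An [scan_parameter()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.outcome_scan <- function(object, ...) {
  param <- attr(object, "parameter")
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$tv_cm3)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = param, y = "treated volume (cm^3)") +
    ggplot2::theme_minimal()
  if (any(object$dv_cm3 > 0)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$dv_cm3), linetype = "dotted")
  }
  p
}

#' Dose-versus-fluence curves with and without photobleaching
#'
#' Draws the accumulated singlet-oxygen dose as a function of light fluence
#' for the bleached and unbleached models at a fixed initial concentration,
#' with optional threshold reference lines.  The bleached curve saturates
#' at [saturation_dose()]; the unbleached one grows linearly.
#'
#' @param c0 Initial PpIX concentration, mol/L.
#' @param params A [photophysical_params()].
#' @param fluence_max Upper fluence, J/cm^2.
#' @param thresholds_mM Reference thresholds, mM (or `NULL`).
#' @return A ggplot object.
#' @export
plot_dose_fluence <- function(c0 = 5.8e-6, params = photophysical_params(),
                              fluence_max = 50, thresholds_mM = c(0.4, 0.56, 0.72)) {
  fl <- seq(0, fluence_max, length.out = 400)
  on <- params
  on$bleaching_enabled <- TRUE
  off <- params
  off$bleaching_enabled <- FALSE
  df <- tibble::tibble(
    fluence_J_cm2 = rep(fl, 2),
    dose_mM = c(1000 * singlet_oxygen_dose(fl, 1, c0, on),
                1000 * singlet_oxygen_dose(fl, 1, c0, off)),
    model = rep(c("with photobleaching", "without photobleaching"),
                each = length(fl)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fluence_J_cm2,
                                        y = .data$dose_mM,
                                        linetype = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "light fluence (J/cm^2)",
                  y = expression("D"["SO"] * " (mM)"),
                  linetype = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds_mM)) {
    p <- p + ggplot2::geom_hline(yintercept = thresholds_mM,
                                 linetype = "dashed", colour = "grey50")
  }
  p
}
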