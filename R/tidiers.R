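#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an outcome report into per-tissue rows
#'
#' @param x An [outcome_report][volume_metrics()].
#' @param ... Unused.
#' @return A tibble with one row per tissue class: `tissue`,
#'   `volume_cm3`, `killed_cm3`, `killed_fraction`.
#' @export
tidy.outcome_report <- function(x, ...) {
  tibble::tibble(
    tissue = c("tumor", "normal"),
    volume_cm3 = c(x$tumor_volume, x$normal_volume),
    killed_cm3 = c(x$tv, x$dv),
    killed_fraction = c(x$tc,
                        if (x$normal_volume > 0) x$dv / x$normal_volume
                        else NA_real_))
}

#' One-row summary of an outcome report
#'
#' @param x An [outcome_report][volume_metrics()].
#' @param ... Unused.
#' @return A one-row tibble: `threshold_mM`, `tv_cm3`, `dv_cm3`, `tc`,
#'   `tumor_volume_cm3`, `n_masked_voxels`.
#' @export
glance.outcome_report <- function(x, ...) {
  tibble::tibble(threshold_mM = 1000 * x$threshold, tv_cm3 = x$tv,
                 dv_cm3 = x$dv, tc = x$tc,
                 tumor_volume_cm3 = x$tumor_volume,
                 n_masked_voxels = x$n_masked_voxels)
}

#' One-row summary of a fluence map
#'
#' @param x A [fluence_map][simulate_fluence()].
#' @param ... Unused.
#' @return A one-row tibble with packet count, seed, peak fluence rate and
#'   the energy-ledger components.
#' @export
glance.fluence_map <- function(x, ...) {
  tibble::tibble(n_photons = x$n_photons, seed = x$seed,
                 max_phi_mW_cm2 = max(x$phi),
                 deposited_weight = x$ledger$deposited_weight,
                 escaped_weight = x$ledger$escaped_weight,
                 roulette_discarded_weight = x$ledger$roulette_discarded_weight,
                 ledger_residual = ledger_residual(x))
}
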