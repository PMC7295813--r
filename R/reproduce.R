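#' Recompute the headline transition diameters and time-scales
#'
#' End-to-end consistency runner: for each condition preset it solves the
#' edge-probability model for the transition diameter with that condition's
#' fitted percolation parameters and wave-period line, and appends the
#' closed-form analytic estimate (typical period 46 s, top-5% filament
#' length 5.7 um, literature turnover 0.54 s) and the turnover time implied
#' by the literature binding/unbinding rates. Each row is compared against
#' its reference value.
#'
#' @param presets Preset table, defaults to [condition_presets()].
#' @param tolerance_um Tolerance on transition diameters (um), default 3.
#' @param check Error (rather than just flag) when a row misses its
#'   tolerance.
#'
#' @return A tibble: `quantity`, `condition`, `L_um`, `tau_s`, `value`,
#'   `reference`, `tolerance`, `within_tolerance`.
#' @examples
#' reproduce_positioning_transition()
#' @export
reproduce_positioning_transition <- function(presets = condition_presets(),
                                             tolerance_um = 3,
                                             check = FALSE) {
  rows <- purrr::map_dfr(presets$condition, function(cond) {
    par <- condition_params(cond, presets)
    tibble(
      quantity = "transition_diameter_um",
      condition = cond,
      L_um = par$L,
      tau_s = par$tau,
      value = transition_diameter(par$L, par$tau, par$waves),
      reference = par$dc_reference_um,
      tolerance = tolerance_um
    )
  })
  extras <- tibble(
    quantity = c("analytic_transition_um", "turnover_time_s"),
    condition = c("typical", "literature_rates"),
    L_um = c(5.7, NA),
    tau_s = c(0.54, NA),
    value = c(transition_diameter_analytic(5.7, 46, 0.54),
              turnover_time(0.66, 1.2e6, 1e-6)),
    reference = c(73, 0.54),
    tolerance = c(0.5, 0.005)
  )
  out <- dplyr::bind_rows(rows, extras) |>
    dplyr::mutate(within_tolerance =
                    abs(.data$value - .data$reference) <= .data$tolerance)
  if (check && !all(out$within_tolerance)) {
    bad <- out[!out$within_tolerance, ]
    abort(paste0(
      "Reference values missed: ",
      paste(sprintf("%s/%s: %.3g vs %.3g", bad$quantity, bad$condition,
                    bad$value, bad$reference), collapse = "; ")
    ), class = "actotug_tolerance_breach")
  }
  out
}
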