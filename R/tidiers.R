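#' Tidy an edge-probability fit
#'
#' @param x An `edge_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `term`, `estimate`,
#'   `fixed`.
#' @method tidy edge_fit
#' @export
tidy.edge_fit <- function(x, ...) {
  tibble(
    term = c("L", "tau"),
    estimate = c(x$L, x$tau),
    fixed = !c("L", "tau") %in% x$free
  )
}

#' One-row summary of an edge-probability fit
#'
#' @inheritParams tidy.edge_fit
#' @return A tibble: `L_um`, `tau_s`, `dc_um`, `sse`, `n_bins`.
#' @method glance edge_fit
#' @export
glance.edge_fit <- function(x, ...) {
  tibble(
    L_um = x$L, tau_s = x$tau, dc_um = x$dc_um, sse = x$sse,
    n_bins = sum(!is.na(x$curve$edge_fraction))
  )
}
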