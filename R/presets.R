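#' Condition presets
#'
#' Wave-kinematics fits, percolation parameters and cluster-size slope for the
#' four experimental conditions: control, alpha-actinin addition (more
#' crosslinking, smaller tau), gelsolin addition (severed, shorter filaments)
#' and mDia2 addition (longer filaments). `dc_reference_um` is the reported
#' transition diameter for each condition, kept alongside the parameters so
#' consistency checks can compare recomputed values against it.
#'
#' @param path Optional path to a preset table (TSV with the same columns);
#'   defaults to the table shipped with the package.
#'
#' @return A tibble with columns `condition`, `a_T`, `b_T`, `a_v`, `b_v`,
#'   `L_um`, `tau_s`, `cluster_slope`, `dc_reference_um`.
#' @examples
#' condition_presets()
#' @export
condition_presets <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "condition_presets.tsv", package = "actotug",
                mustWork = TRUE)
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Look up one condition preset
#'
#' @param condition One of `"control"`, `"alpha_actinin"`, `"gelsolin"`,
#'   `"mdia2"` (or any condition present in `presets`).
#' @param presets Preset table, defaults to [condition_presets()].
#' @param v_min Velocity floor passed to [wave_kinematics()].
#'
#' @return A list with elements `condition`, `waves` (a `wave_kinematics`
#'   object), `L` (um), `tau` (s), `cluster_slope`, `dc_reference_um`.
#' @examples
#' condition_params("control")$waves
#' @export
condition_params <- function(condition, presets = condition_presets(),
                             v_min = 0.05) {
  row <- presets[presets$condition == condition, ]
  if (nrow(row) != 1L) {
    abort(sprintf("Unknown condition '%s'; available: %s.", condition,
                  paste(presets$condition, collapse = ", ")),
          class = "actotug_config_error")
  }
  list(
    condition = condition,
    waves = wave_kinematics(row$a_T, row$b_T, row$a_v, row$b_v,
                            condition = condition, v_min = v_min),
    L = row$L_um,
    tau = row$tau_s,
    cluster_slope = row$cluster_slope,
    dc_reference_um = row$dc_reference_um
  )
}

#' @rdname condition_params
#' @export
condition_waves <- function(condition, presets = condition_presets(),
                            v_min = 0.05) {
  condition_params(condition, presets, v_min)$waves
}
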