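#' Read and write droplet observation tables
#'
#' Delimited text (TSV) with header columns `droplet_diameter_um`,
#' `cluster_diameter_um`, `offset_um`, `dc_ratio`, `condition` (extra
#' columns such as `true_state` are preserved).
#'
#' @param path File path.
#' @return `read_droplet_observations()` returns a tibble.
#' @export
read_droplet_observations <- function(path) {
  obs <- as_tibble(utils::read.delim(path, sep = "\t",
                                     stringsAsFactors = FALSE))
  check_columns(obs, c("droplet_diameter_um", "cluster_diameter_um",
                       "offset_um", "dc_ratio", "condition"),
                "observation table")
  obs
}

#' @rdname read_droplet_observations
#' @param obs Observation tibble.
#' @export
write_droplet_observations <- function(obs, path) {
  check_columns(obs, c("droplet_diameter_um", "cluster_diameter_um",
                       "offset_um", "dc_ratio", "condition"), "obs")
  utils::write.table(obs, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a Monte-Carlo percolation summary
#'
#' @param summary Tibble from [percolation_mc()].
#' @param path Output TSV path.
#' @export
write_mc_summary <- function(summary, path) {
  check_columns(summary, c("N", "tau", "horizon", "n_trials",
                           "frac_percolated", "mean_first_passage"),
                "summary")
  utils::write.table(summary, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a grayscale (multi-page) TIFF as matrices
#'
#' @param path TIFF path.
#' @return A numeric matrix for single-page files, else a 3-D array
#'   `[rows, cols, frames]`.
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- purrr::map(pages, function(p) {
    if (length(dim(p)) == 3) p[, , 1] else p
  })
  if (length(pages) == 1) return(pages[[1]])
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' @rdname read_image_stack
#' @param stack Matrix or 3-D array with values in `[0, 1]`.
#' @export
write_image_stack <- function(stack, path) {
  if (is.matrix(stack)) {
    tiff::writeTIFF(pmin(pmax(stack, 0), 1), path)
  } else {
    frames <- purrr::map(seq_len(dim(stack)[3]), function(f) {
      pmin(pmax(stack[, , f], 0), 1)
    })
    tiff::writeTIFF(frames, path)
  }
  invisible(path)
}
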