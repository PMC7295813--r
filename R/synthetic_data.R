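#' Generate a synthetic droplet cohort
#'
#' Emulates the tabular droplet observations the pipeline consumes, under the
#' two-state positioning model. Droplet diameters are log-uniform on
#' `diameter_range` (emulsification yields poly-disperse droplets spanning an
#' order of magnitude); the cluster diameter is proportional to the droplet
#' diameter with truncated Gaussian noise; the true state is `"edge"` with
#' probability [edge_probability()] at the droplet's diameter; the DC-ratio
#' scatters around `1 - D_cluster/D` (cluster touching the boundary) for edge
#' droplets and follows a half-normal near 0 for centred ones.
#'
#' @param n Number of droplets, default 176 (the control sample size).
#' @param condition Preset name used to fill any of `L`, `tau`, `waves`,
#'   `cluster_slope` not supplied explicitly.
#' @param L,tau Percolation parameters (um, s). `tau = Inf` disables edge
#'   positioning entirely.
#' @param waves A [wave_kinematics()] object.
#' @param cluster_slope Cluster-to-droplet diameter ratio.
#' @param diameter_range Diameter range in um, default `c(16, 330)`.
#' @param cluster_sd_frac SD of cluster-diameter noise as a fraction of the
#'   droplet diameter.
#' @param dc_sd SD of the edge-state DC-ratio scatter.
#' @param center_scale Half-normal scale of the centre-state DC-ratio.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `droplet_diameter_um`, `cluster_diameter_um`,
#'   `offset_um`, `dc_ratio`, `condition`, `true_state`.
#' @examples
#' obs <- generate_cohort(176, seed = 7)
#' dplyr::count(obs, true_state)
#' @export
generate_cohort <- function(n = 176, condition = "control", L = NULL,
                            tau = NULL, waves = NULL, cluster_slope = NULL,
                            diameter_range = c(16, 330),
                            cluster_sd_frac = 0.05, dc_sd = 0.05,
                            center_scale = 0.05, seed = NULL) {
  check_number(n, "n", min = 1)
  preset <- tryCatch(condition_params(condition),
                     actotug_config_error = function(e) NULL)
  L <- L %||% preset$L
  tau <- tau %||% preset$tau
  waves <- waves %||% preset$waves
  cluster_slope <- cluster_slope %||% preset$cluster_slope
  if (is.null(L) || is.null(tau) || is.null(waves) ||
      is.null(cluster_slope)) {
    abort("Unknown condition: supply L, tau, waves and cluster_slope.",
          class = "actotug_config_error")
  }
  if (!is.null(seed)) set.seed(seed)

  D <- exp(runif(n, log(diameter_range[1]), log(diameter_range[2])))
  p_edge <- if (is.finite(tau)) edge_probability(D, L, tau, waves) else 0
  state <- ifelse(runif(n) < p_edge, "edge", "center")

  d_cluster <- rtruncnorm(n, mean = cluster_slope * D,
                          sd = cluster_sd_frac * D,
                          lower = 1e-6, upper = D - 1e-6)
  dc <- ifelse(
    state == "edge",
    rtruncnorm(n, mean = 1 - d_cluster / D, sd = dc_sd, lower = 0, upper = 1),
    pmin(1, abs(rnorm(n, 0, center_scale)))
  )
  tibble(
    droplet_diameter_um = D,
    cluster_diameter_um = d_cluster,
    offset_um = dc * D / 2,
    dc_ratio = dc,
    condition = condition,
    true_state = state
  )
}

# truncated normal by resampling; clamps after 100 rounds (tight truncations
# here never starve)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pick <- function(v, i) if (length(v) > 1) v[i] else v
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  tries <- 0
  while (length(bad) && tries < 100) {
    out[bad] <- rnorm(length(bad), pick(mean, bad), pick(sd, bad))
    bad <- which(out < lower | out > upper)
    tries <- tries + 1
  }
  if (length(bad)) {
    out[bad] <- pmin(pmax(out[bad], pick(lower, bad)), pick(upper, bad))
  }
  out
}

#' Generate a series of inward wave events
#'
#' Birth times are spaced by the condition's period `T(D)` with optional
#' Gaussian jitter; each wave gets an inward speed `v(D)` with optional
#' jitter (floored at the kinematics' `v_min`).
#'
#' @param D Droplet diameter (um).
#' @param waves A [wave_kinematics()] object.
#' @param n_waves Number of waves.
#' @param period_jitter_sd,speed_jitter_sd Gaussian jitter SDs (s, um/s).
#' @param seed Optional seed.
#'
#' @return A tibble: `wave_id`, `birth_time_s`, `speed_um_s`, with the
#'   generating period and speed stored as attributes `period_s` and
#'   `speed_um_s`.
#' @export
generate_wave_series <- function(D, waves, n_waves = 5,
                                 period_jitter_sd = 0, speed_jitter_sd = 0,
                                 seed = NULL) {
  check_positive(D, "D")
  check_number(n_waves, "n_waves", min = 1)
  if (!is.null(seed)) set.seed(seed)
  T_wave <- wave_period(D, waves)
  v <- wave_velocity(D, waves)
  gaps <- T_wave + rnorm(n_waves - 1, 0, period_jitter_sd)
  births <- cumsum(c(0, pmax(gaps, 1)))
  speeds <- pmax(waves$v_min, v + rnorm(n_waves, 0, speed_jitter_sd))
  out <- tibble(wave_id = seq_len(n_waves), birth_time_s = births,
                speed_um_s = speeds)
  attr(out, "period_s") <- T_wave
  attr(out, "speed_um_s") <- v
  attr(out, "droplet_diameter_um") <- D
  out
}

#' Render a synthetic kymograph from a wave series
#'
#' Space runs along the full droplet diameter; each wave produces two
#' mirrored ridges converging from the two boundaries at its speed,
#' rendered as Gaussian intensity profiles, until they meet at the centre.
#'
#' @param series Output of [generate_wave_series()].
#' @param duration Total time (s); defaults to covering all waves plus one
#'   transit.
#' @param pixel_size um per row.
#' @param frame_interval Seconds per frame (column), default 3.
#' @param sigma_um Ridge Gaussian width (um).
#' @param noise_sd Additive Gaussian intensity noise (ridge peak is 1).
#' @param seed Optional seed for the noise.
#'
#' @return A `kymograph` matrix with attributes `space_step_um`,
#'   `time_step_s` and `truth` (list with `period_s`, `speed_um_s`).
#' @export
render_kymograph <- function(series, duration = NULL, pixel_size = 1,
                             frame_interval = 3, sigma_um = 2,
                             noise_sd = 0, seed = NULL) {
  check_columns(series, c("birth_time_s", "speed_um_s"), "series")
  D <- attr(series, "droplet_diameter_um")
  if (is.null(D)) {
    abort("`series` lacks the droplet diameter attribute.",
          class = "actotug_invalid_input")
  }
  if (!is.null(seed)) set.seed(seed)
  R <- D / 2
  duration <- duration %||%
    (max(series$birth_time_s) + R / min(series$speed_um_s))
  x <- seq(0, D, by = pixel_size)
  t <- seq(0, duration, by = frame_interval)
  kymo <- matrix(0, length(x), length(t))
  for (w in seq_len(nrow(series))) {
    b <- series$birth_time_s[w]
    v <- series$speed_um_s[w]
    active <- which(t >= b & (t - b) * v <= R)
    for (f in active) {
      s <- (t[f] - b) * v
      kymo[, f] <- kymo[, f] +
        exp(-(x - s)^2 / (2 * sigma_um^2)) +
        exp(-(x - (D - s))^2 / (2 * sigma_um^2))
    }
  }
  if (noise_sd > 0) {
    kymo <- kymo + matrix(rnorm(length(kymo), 0, noise_sd),
                          nrow(kymo), ncol(kymo))
  }
  structure(kymo, class = c("kymograph", "matrix"),
            space_step_um = pixel_size, time_step_s = frame_interval,
            truth = list(period_s = attr(series, "period_s"),
                         speed_um_s = attr(series, "speed_um_s")))
}

#' Render a synthetic droplet frame
#'
#' Grayscale frame with a dim background, a brighter droplet disk and a
#' bright cluster disk whose centre is offset by `dc * R` from the droplet
#' centre along `angle`.
#'
#' @param dim Image side in pixels (square frame).
#' @param droplet_radius_px,cluster_radius_px Radii in pixels.
#' @param dc Ground-truth DC-ratio in `[0, 1]`.
#' @param angle Offset direction (radians).
#' @param center Droplet centre `c(row, col)`, 0-based; defaults to the
#'   frame centre.
#' @param intensities Named numeric: `background`, `droplet`, `cluster`.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed Optional seed for the noise.
#'
#' @return A numeric matrix with attribute `truth` (list with `dc`,
#'   `droplet_center`, `droplet_radius_px`, `cluster_center`,
#'   `cluster_radius_px`).
#' @export
render_droplet_frame <- function(dim = 256, droplet_radius_px = 100,
                                 cluster_radius_px = 25, dc = 0,
                                 angle = 0, center = NULL,
                                 intensities = c(background = 0.05,
                                                 droplet = 0.5,
                                                 cluster = 1),
                                 noise_sd = 0, seed = NULL) {
  check_number(dc, "dc", min = 0, max = 1)
  center <- center %||% c((dim - 1) / 2, (dim - 1) / 2)
  if (any(center + droplet_radius_px > dim - 1) ||
      any(center - droplet_radius_px < 0)) {
    abort("Droplet exceeds the frame.", class = "actotug_invalid_input")
  }
  if (!is.null(seed)) set.seed(seed)
  ccenter <- center + dc * droplet_radius_px * c(sin(angle), cos(angle))
  rows <- matrix(0:(dim - 1), dim, dim)
  cols <- t(rows)
  img <- matrix(intensities[["background"]], dim, dim)
  in_droplet <- (rows - center[1])^2 + (cols - center[2])^2 <=
    droplet_radius_px^2
  in_cluster <- (rows - ccenter[1])^2 + (cols - ccenter[2])^2 <=
    cluster_radius_px^2
  img[in_droplet] <- intensities[["droplet"]]
  img[in_cluster] <- intensities[["cluster"]]
  if (noise_sd > 0) img <- img + matrix(rnorm(dim * dim, 0, noise_sd),
                                        dim, dim)
  attr(img, "truth") <- list(dc = dc, droplet_center = center,
                             droplet_radius_px = droplet_radius_px,
                             cluster_center = ccenter,
                             cluster_radius_px = cluster_radius_px)
  img
}

#' Exponential filament-length distribution matched to a top-5% mean
#'
#' For an exponential distribution the expected mean of the values above the
#' `1 - fraction` quantile is `(1 - log(fraction)) / rate`, so the rate that
#' yields a desired top-fraction mean is available in closed form.
#'
#' @param target_top_mean Desired top-fraction mean length (um).
#' @param fraction Top fraction, default 0.05.
#' @return The exponential rate (per um).
#' @examples
#' filament_length_rate(5.7) # control extract
#' @export
filament_length_rate <- function(target_top_mean, fraction = 0.05) {
  check_positive(target_top_mean, "target_top_mean")
  check_number(fraction, "fraction", min = 0, max = 1, strict_min = TRUE)
  (1 - log(fraction)) / target_top_mean
}

#' @rdname filament_length_rate
#' @param n Number of filaments to draw.
#' @param seed Optional seed.
#' @return `sample_filament_lengths()` returns `n` lengths in um.
#' @export
sample_filament_lengths <- function(n, target_top_mean = 5.7,
                                    fraction = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rexp(n, rate = filament_length_rate(target_top_mean, fraction))
}

#' Render a synthetic filament image
#'
#' Draws straight filaments of the requested lengths as 3-pixel-wide sticks
#' at random (or fixed) positions and orientations, avoiding overlap. The
#' recorded ground-truth length of each filament is its rasterized
#' centre-line pixel count times the pixel size -- the same pixel-count
#' metric the measurement stage reports.
#'
#' @param lengths_um Filament lengths (um).
#' @param pixel_size um per pixel.
#' @param dim Image side in pixels.
#' @param angles Optional orientation per filament (radians); random when
#'   `NULL`.
#' @param seed Optional seed.
#' @param max_tries Placement attempts per filament before giving up.
#'
#' @return A numeric matrix with attribute `truth`: a tibble of
#'   `filament_id`, `length_um` (requested), `length_px_truth` (rasterized
#'   centre-line pixel count), `angle`.
#' @export
generate_filament_image <- function(lengths_um, pixel_size = 0.1,
                                    dim = 512, angles = NULL, seed = NULL,
                                    max_tries = 200) {
  if (!length(lengths_um) || any(lengths_um <= 0)) {
    abort("`lengths_um` must be positive.", class = "actotug_invalid_input")
  }
  if (!is.null(seed)) set.seed(seed)
  img <- matrix(0, dim, dim)
  occupied <- matrix(FALSE, dim, dim)
  truth <- vector("list", length(lengths_um))
  for (i in seq_along(lengths_um)) {
    len_px <- max(2, round(lengths_um[i] / pixel_size))
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      ang <- if (!is.null(angles)) angles[i] else runif(1, 0, pi)
      dr <- (len_px - 1) * sin(ang)
      dc <- (len_px - 1) * cos(ang)
      margin <- 5
      r0 <- runif(1, margin + abs(min(0, dr)),
                  dim - 1 - margin - abs(max(0, dr)))
      c0 <- runif(1, margin + abs(min(0, dc)),
                  dim - 1 - margin - abs(max(0, dc)))
      path <- raster_line(round(r0), round(c0), round(r0 + dr),
                          round(c0 + dc))
      thick <- dilate_path(path, dim, radius = 1)
      guard <- dilate_path(path, dim, radius = 3)
      if (any(occupied[guard])) next
      img[thick] <- 1
      occupied[guard] <- TRUE
      truth[[i]] <- tibble(filament_id = i, length_um = lengths_um[i],
                           length_px_truth = nrow(path), angle = ang)
      placed <- TRUE
      break
    }
    if (!placed) {
      abort(sprintf("Could not place filament %d without overlap.", i),
            class = "actotug_invalid_input")
    }
  }
  attr(img, "truth") <- dplyr::bind_rows(truth)
  img
}

# centre-line rasterization: one pixel per step of the major axis
raster_line <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1
  cbind(round(seq(r0, r1, length.out = n)),
        round(seq(c0, c1, length.out = n)))
}

# linear index mask of a path dilated by a square radius
dilate_path <- function(path, dim, radius) {
  mask <- matrix(FALSE, dim, dim)
  for (dr in -radius:radius) {
    for (dc in -radius:radius) {
      r <- pmin(pmax(path[, 1] + dr, 0), dim - 1)
      c <- pmin(pmax(path[, 2] + dc, 0), dim - 1)
      mask[cbind(r + 1, c + 1)] <- TRUE
    }
  }
  mask
}

#' Write a synthetic image as TIFF with a ground-truth sidecar
#'
#' Intensities are clipped to `[0, 1]` for TIFF storage; the `truth`
#' attribute (if any) plus caller-supplied metadata land in a YAML sidecar
#' next to the image.
#'
#' @param image Numeric matrix (or `kymograph`).
#' @param path Output TIFF path; the sidecar is `<path>.meta.yaml`.
#' @param metadata Optional named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_synthetic_image <- function(image, path, metadata = list()) {
  img <- pmin(pmax(unclass(image), 0), 1)
  attributes(img) <- list(dim = dim(img))
  tiff::writeTIFF(img, path)
  truth <- attr(image, "truth")
  side <- metadata
  if (!is.null(truth)) {
    side$truth <- if (is.data.frame(truth)) {
      purrr::map(as.list(truth), as.vector)
    } else {
      truth
    }
  }
  yaml::write_yaml(side, paste0(path, ".meta.yaml"))
  invisible(path)
}
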