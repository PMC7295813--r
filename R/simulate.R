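#' Simulate stochastic cluster motion in one droplet
#'
#' Event-driven reconstruction of the tug-of-war dynamics. A point cluster
#' starts at the droplet centre. Every wave period `T(D)` a contraction front
#' is born at the boundary and travels inward at `v(D)`; a front lives until
#' it reaches the centre or the next front is born (the new ring consumes the
#' bulk network), so one front is active at a time. While the cluster is free
#' it attempts percolation once per turnover step `tau` across the current
#' gap (`N = site_count(D/2 - d, L)`, success probability `(1/2)^N`), at most
#' one successful bridge per period. A bridge pulls the cluster outward at
#' the transport speed until it reaches the boundary or collides with the
#' active front; that collision stops the outward movement -- the
#' contracting ring fuses with the cluster it meets, consuming both the
#' front and the bridge. A front that instead reaches a free (unbridged)
#' cluster captures it and carries it inward until the front dies.
#'
#' @param D Droplet diameter (um).
#' @param L Filament length (um).
#' @param tau Turnover time (s); `Inf` disables percolation entirely.
#' @param waves A [wave_kinematics()] object.
#' @param T0 Simulated duration (s), default 1800.
#' @param dt Time step (s), default `tau` (one percolation attempt per step);
#'   must not exceed `tau`.
#' @param seed Optional integer seed, recorded in the output.
#' @param v_transport Outward transport speed of a contracting bridge (um/s);
#'   defaults to `wave_velocity(D, waves)`, the only contraction speed the
#'   data quantify.
#' @param cluster_radius_um Cluster radius (um). The default 0 treats the
#'   cluster as a point, whose centroid can reach the boundary; a positive
#'   radius confines the centroid to `d <= D/2 - r` and shortens the
#'   percolation gap accordingly.
#'
#' @return A tibble of class `cluster_trajectory` with columns `time_s`,
#'   `d_um` (radial offset of the cluster), and attributes recording the
#'   parameters and seed.
#' @examples
#' traj <- simulate_cluster(60, L = 6.1, tau = 0.46,
#'                          waves = condition_waves("control"), seed = 1)
#' time_averaged_dc(traj)
#' @export
simulate_cluster <- function(D, L, tau, waves, T0 = 1800, dt = NULL,
                             seed = NULL, v_transport = NULL,
                             cluster_radius_um = 0) {
  check_positive(D, "D")
  check_positive(L, "L")
  check_positive(tau, "tau", allow_inf = TRUE)
  check_positive(T0, "T0")
  dt <- dt %||% (if (is.finite(tau)) tau else 1)
  check_positive(dt, "dt")
  if (is.finite(tau) && dt > tau + 1e-12) {
    abort("`dt` must not exceed `tau` (one percolation attempt per step).",
          class = "actotug_invalid_parameter")
  }
  if (!is.null(seed)) set.seed(seed)

  check_number(cluster_radius_um, "cluster_radius_um", min = 0, max = D / 2)
  R <- D / 2
  R_eff <- R - cluster_radius_um   # reachable centroid positions
  T_wave <- wave_period(D, waves)
  v <- wave_velocity(D, waves)
  v_out <- v_transport %||% v

  n_steps <- ceiling(T0 / dt)
  times <- seq(0, by = dt, length.out = n_steps + 1)
  d <- numeric(n_steps + 1)

  mode <- "free"            # free | outward | inward
  bridge_period <- -1L      # period index of the last formed bridge
  fused_period <- -1L       # period whose front was consumed by fusion
  pos <- 0

  for (i in seq_len(n_steps)) {
    t_next <- times[i + 1]
    # active front: born at the start of the current period, dead once it
    # reaches the centre or is consumed by fusing with a bridged cluster;
    # the previous front died when this one was born
    period_next <- floor((t_next - 1e-9) / T_wave)
    fp <- R - v * (t_next - period_next * T_wave)
    front_alive <- fp > 0 && fused_period < period_next

    surface <- pos + cluster_radius_um  # outer cluster surface
    if (mode == "inward") {
      carried <- max(0, pos - v * dt)
      if (!front_alive || floor((times[i] - 1e-9) / T_wave) != period_next) {
        # front died (reached centre or was replaced); cluster released
        mode <- "free"
        pos <- if (!front_alive) carried else pos
      } else {
        pos <- min(carried, max(fp, 0))
        if (pos <= 0) {
          pos <- 0
          mode <- "free"
        }
      }
    } else if (mode == "outward") {
      pos <- min(R_eff, pos + v_out * dt)
      if (front_alive && fp <= pos + cluster_radius_um) {
        # fusion: the ring meets the bridged cluster; outward movement
        # stops and both front and bridge are consumed
        pos <- max(fp - cluster_radius_um, 0)
        fused_period <- period_next
        mode <- "free"
      } else if (pos >= R_eff) {
        pos <- R_eff
        mode <- "free"
      }
    } else { # free
      if (front_alive && fp <= surface) {
        pos <- max(fp - cluster_radius_um, 0)
        mode <- "inward"
      } else if (is.finite(tau) && bridge_period < period_next) {
        gap <- R_eff - pos
        if (gap > 1e-9) {
          N <- site_count(gap, L)
          if (runif(1) < 0.5^N) {
            mode <- "outward"
            bridge_period <- period_next
          }
        }
      }
    }
    d[i + 1] <- pos
  }

  out <- tibble(time_s = times, d_um = d)
  class(out) <- c("cluster_trajectory", class(out))
  attr(out, "droplet_diameter_um") <- D
  attr(out, "L_um") <- L
  attr(out, "tau_s") <- tau
  attr(out, "seed") <- seed
  attr(out, "waves") <- waves
  attr(out, "dt_s") <- dt
  out
}

#' Simulate a cohort of droplets across diameters and seeds
#'
#' Runs [simulate_cluster()] for every combination of diameter and seed and
#' summarizes each run by its time-averaged DC-ratio and position class
#' (simulation thresholds: edge > 0.8, centre < 0.2).
#'
#' @param diameters Droplet diameters (um).
#' @param n_seeds Runs per diameter.
#' @param seed Base seed; run `j` at diameter `i` uses
#'   `seed + (i - 1) * n_seeds + j - 1`.
#' @inheritParams simulate_cluster
#'
#' @return A tibble with columns `D_um`, `seed`, `dc_mean`, `class`.
#' @export
simulate_positioning <- function(diameters, L, tau, waves, n_seeds = 10,
                                 seed = 1, T0 = 1800, dt = NULL,
                                 v_transport = NULL) {
  grid <- tidyr::expand_grid(
    i = seq_along(diameters),
    j = seq_len(n_seeds)
  )
  purrr::pmap_dfr(grid, function(i, j) {
    run_seed <- seed + (i - 1L) * n_seeds + j - 1L
    traj <- simulate_cluster(diameters[i], L, tau, waves, T0 = T0, dt = dt,
                             seed = run_seed, v_transport = v_transport)
    dc <- time_averaged_dc(traj)
    tibble(D_um = diameters[i], seed = run_seed, dc_mean = dc,
           class = classify_position(dc, scheme = "simulation"))
  })
}

#' Edge fraction of a simulated cohort
#'
#' @param sims Output of [simulate_positioning()].
#' @return A tibble with one row per diameter: `D_um`, `n`, `edge_fraction`.
#' @export
simulated_edge_fraction <- function(sims) {
  check_columns(sims, c("D_um", "class"))
  sims |>
    dplyr::group_by(.data$D_um) |>
    dplyr::summarise(n = dplyr::n(),
                     edge_fraction = mean(.data$class == "edge"),
                     .groups = "drop")
}

#' Write per-run trajectories as delimited text
#'
#' @param traj A `cluster_trajectory`.
#' @param path Output file (TSV with columns `t_s`, `d_um`).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "cluster_trajectory"))
  utils::write.table(
    data.frame(t_s = traj$time_s, d_um = traj$d_um),
    path, sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
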