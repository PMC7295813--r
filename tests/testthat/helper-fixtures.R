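# shared fixture builders; everything is generated in code at test time

control_waves <- function() condition_waves("control")

# noise-free binned curve evaluated from the closed-form edge probability
exact_edge_curve <- function(L, tau, waves, centers = seq(25, 325, by = 50),
                             n_per_bin = 100) {
  curve <- tibble::tibble(
    bin_center = centers,
    n_total = n_per_bin,
    n_edge = NA_integer_, n_center = NA_integer_,
    n_intermediate = NA_integer_,
    edge_fraction = edge_probability(centers, L, tau, waves)
  )
  class(curve) <- c("edge_curve", class(curve))
  attr(curve, "bin_width") <- diff(centers[1:2])
  attr(curve, "scheme") <- "experimental"
  curve
}

# hand-built trajectory for testing the time-average operator
manual_trajectory <- function(times, d, D) {
  traj <- tibble::tibble(time_s = times, d_um = d)
  class(traj) <- c("cluster_trajectory", class(traj))
  attr(traj, "droplet_diameter_um") <- D
  traj
}

# constant-parameter wave kinematics (exact v and T at every diameter)
flat_waves <- function(v, T_period, v_min = 0.05) {
  wave_kinematics(0, T_period, 0, v, condition = "flat", v_min = v_min)
}

# expected edge fraction of a diameter bin under log-uniform sampling
bin_expected_p <- function(lo, hi, L, tau, waves, range = c(16, 330)) {
  lo <- max(lo, range[1]); hi <- min(hi, range[2])
  f <- function(D) edge_probability(D, L, tau, waves) / D
  stats::integrate(f, lo, hi)$value / (log(hi) - log(lo))
}
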