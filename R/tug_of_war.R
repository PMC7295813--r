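#' Edge-positioning probability
#'
#' Probability that a cluster ends up at the droplet boundary: the chance
#' that the bulk network percolates across the gap `D/2` at least once during
#' one wave period `T(D)`,
#' \deqn{p(D) = 1 - [1 - (1/2)^{D/(2L)}]^{T(D)/\tau}.}
#' The exponent `D/(2L)` is used continuously (no rounding), matching the
#' fitted curves; the discrete site count only enters the Monte-Carlo
#' simulator.
#'
#' @param D Droplet diameter (um), > 0; vectorized.
#' @param L Filament length (um), > 0.
#' @param tau Crosslinker turnover time (s), > 0.
#' @param waves A [wave_kinematics()] object supplying `T(D)`.
#'
#' @return Probability in `[0, 1]`.
#' @examples
#' edge_probability(85, 6.1, 0.46, condition_waves("control")) # ~0.51
#' @export
edge_probability <- function(D, L, tau, waves) {
  if (any(!is.finite(D)) || any(D <= 0)) {
    abort("`D` must be positive.", class = "actotug_invalid_parameter")
  }
  check_positive(L, "L")
  check_positive(tau, "tau")
  bridge_probability(D / (2 * L), wave_period(D, waves), tau)
}

#' Transition diameter from the edge-probability curve
#'
#' The droplet diameter `D_c` at which [edge_probability()] crosses 0.5,
#' found by bisection on the bracket after verifying that the curve actually
#' decreases across it.
#'
#' @inheritParams edge_probability
#' @param bracket Search interval in um, default `c(1, 2000)`.
#' @param tol Bisection tolerance on `|p - 0.5|`, default 1e-6.
#'
#' @return `D_c` in um.
#' @examples
#' transition_diameter(6.1, 0.46, condition_waves("control")) # ~85 um
#' @export
transition_diameter <- function(L, tau, waves, bracket = c(1, 2000),
                                tol = 1e-6) {
  check_positive(L, "L")
  check_positive(tau, "tau")
  p <- function(D) edge_probability(D, L, tau, waves)
  grid <- seq(bracket[1], bracket[2], length.out = 64)
  pg <- p(grid)
  if (any(diff(pg) > 1e-9)) {
    abort("Edge probability is not monotonically decreasing on the bracket.",
          class = "actotug_no_transition")
  }
  lo <- bracket[1]
  hi <- bracket[2]
  if ((p(lo) - 0.5) * (p(hi) - 0.5) > 0) {
    abort("Edge probability does not cross 0.5 on the bracket.",
          class = "actotug_no_transition")
  }
  repeat {
    mid <- (lo + hi) / 2
    pm <- p(mid)
    if (abs(pm - 0.5) < tol || (hi - lo) < 1e-12) break
    if (pm > 0.5) lo <- mid else hi <- mid
  }
  stopifnot(abs(p(mid) - 0.5) < max(tol, 1e-5))
  mid
}

#' Analytic transition diameter
#'
#' Closed-form estimate from equating the mean bridge maturation time
#' \eqn{\tau_p = 2^{R/L}\tau} to the wave period `T` (treated as
#' size-independent): \eqn{R_c/L = \log_2(T/\tau)}, i.e.
#' \eqn{D_c = 2 L \log_2(T/\tau)}.
#'
#' @param L Filament length (um), > 0.
#' @param T_period Typical wave period (s), must exceed `tau`.
#' @param tau Turnover time (s), > 0.
#'
#' @return Estimated transition diameter in um.
#' @examples
#' transition_diameter_analytic(5.7, 46, 0.54) # ~73 um
#' @export
transition_diameter_analytic <- function(L, T_period, tau) {
  check_positive(L, "L")
  check_positive(tau, "tau")
  check_number(T_period, "T_period", min = 0, strict_min = TRUE)
  if (T_period <= tau) {
    abort("`T_period` must exceed `tau` for a positive transition diameter.",
          class = "actotug_no_transition")
  }
  2 * L * log2(T_period / tau)
}

#' Classify a cluster position from its DC-ratio
#'
#' Experimental scheme: edge if DC > 0.5, centre if DC < 0.2. Simulation
#' scheme (point clusters can reach the boundary exactly): edge if DC > 0.8,
#' centre if DC < 0.2. Everything else, including values exactly on a
#' threshold, is `"intermediate"`.
#'
#' @param dc DC-ratio values in `[0, 1]`; vectorized.
#' @param scheme `"experimental"` or `"simulation"`.
#'
#' @return Character vector of `"edge"`, `"center"`, `"intermediate"`.
#' @examples
#' classify_position(c(0.85, 0.55, 0.1), scheme = "simulation")
#' @export
classify_position <- function(dc, scheme = c("experimental", "simulation")) {
  scheme <- match.arg(scheme)
  if (any(!is.finite(dc)) || any(dc < 0) || any(dc > 1)) {
    abort("`dc` must lie in [0, 1].", class = "actotug_invalid_input")
  }
  edge_thr <- if (scheme == "experimental") 0.5 else 0.8
  dplyr::case_when(
    dc > edge_thr ~ "edge",
    dc < 0.2 ~ "center",
    TRUE ~ "intermediate"
  )
}

#' Time-averaged DC-ratio of a trajectory
#'
#' Trapezoidal mean of `d(t) / R` over the simulated interval,
#' \eqn{(1/T_0)\int_0^{T_0} d(t)/R\, dt}.
#'
#' @param traj A `cluster_trajectory` from [simulate_cluster()].
#'
#' @return Dimensionless value in `[0, 1]`.
#' @export
time_averaged_dc <- function(traj) {
  stopifnot(inherits(traj, "cluster_trajectory"))
  R <- attr(traj, "droplet_diameter_um") / 2
  t <- traj$time_s
  y <- traj$d_um / R
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2) / (max(t) - min(t))
}
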