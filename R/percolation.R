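#' Crosslinker turnover time
#'
#' Characteristic turnover time of actin crosslinkers,
#' \eqn{\tau = 1/(k_{off} + C_0 k_{on})}. With the literature rates for
#' alpha-actinin (\eqn{k_{off}} = 0.66 s\eqn{^{-1}},
#' \eqn{k_{on}} = 1.2e6 M\eqn{^{-1}}s\eqn{^{-1}}) and a crosslinker
#' concentration of 1 uM this gives 0.54 s.
#'
#' @param k_off Unbinding rate (s^-1), >= 0.
#' @param k_on Binding rate (M^-1 s^-1), >= 0.
#' @param C0 Crosslinker concentration (mol/L), >= 0.
#'
#' @return Turnover time in seconds.
#' @examples
#' turnover_time(0.66, 1.2e6, 1e-6) # 0.54 s
#' @export
turnover_time <- function(k_off, k_on, C0) {
  check_number(k_off, "k_off", min = 0)
  check_number(k_on, "k_on", min = 0)
  check_number(C0, "C0", min = 0)
  denom <- k_off + C0 * k_on
  if (denom <= 0) {
    abort("k_off + C0 * k_on must be positive.",
          class = "actotug_invalid_parameter")
  }
  1 / denom
}

#' Percolation model parameters
#'
#' Bundles the filament length `L` and crosslinker turnover time `tau` that
#' govern bridge percolation. The rates (`C0`, `k_on`, `k_off`) may be given
#' instead of (or along with) `tau`; when both are supplied they must agree
#' via `tau = 1/(k_off + C0*k_on)` to a relative tolerance of 1e-9.
#'
#' @param L Filament length (um), > 0.
#' @param tau Turnover time (s), > 0. May be omitted when the rates are given.
#' @param C0,k_on,k_off Optional crosslinker concentration (mol/L) and
#'   binding/unbinding rates.
#'
#' @return A list of class `percolation_params`.
#' @examples
#' percolation_params(L = 6.1, tau = 0.46)
#' percolation_params(L = 5.7, C0 = 1e-6, k_on = 1.2e6, k_off = 0.66)
#' @export
percolation_params <- function(L, tau = NULL, C0 = NULL, k_on = NULL,
                               k_off = NULL) {
  check_positive(L, "L")
  rates <- !is.null(C0) && !is.null(k_on) && !is.null(k_off)
  if (is.null(tau) && !rates) {
    abort("Supply `tau` or all of `C0`, `k_on`, `k_off`.",
          class = "actotug_invalid_parameter")
  }
  if (rates) {
    tau_rates <- turnover_time(k_off, k_on, C0)
    if (is.null(tau)) {
      tau <- tau_rates
    } else if (abs(tau - tau_rates) > 1e-9 * tau_rates) {
      abort(sprintf(
        "`tau` (%g s) disagrees with 1/(k_off + C0*k_on) (%g s).",
        tau, tau_rates), class = "actotug_invalid_parameter")
    }
  }
  check_positive(tau, "tau")
  structure(list(L = L, tau = tau, C0 = C0, k_on = k_on, k_off = k_off),
            class = "percolation_params")
}

#' Number of crosslinking sites spanning a gap
#'
#' The bulk network bridging the gap between cluster and droplet boundary is
#' discretized into crosslinking sites every filament length: N = gap / L,
#' rounded to the nearest integer and clamped below at 1 for the discrete
#' Monte-Carlo process. Closed-form expressions use the continuous exponent
#' `gap / L` directly.
#'
#' @param distance Gap to span (um), > 0.
#' @param L Filament length (um), > 0.
#'
#' @return Positive integer site count.
#' @examples
#' site_count(42.5, 6.1) # 7
#' @export
site_count <- function(distance, L) {
  check_positive(distance, "distance")
  check_positive(L, "L")
  max(1L, as.integer(round(distance / L)))
}

#' Bridge percolation probability within a time window
#'
#' Probability that all `N` crosslinking sites are simultaneously occupied at
#' least once during a window of length `T_window`, when each site is
#' independently occupied with probability 1/2 at every turnover step `tau`:
#' \deqn{p = 1 - [1 - (1/2)^N]^{T/\tau}.}
#'
#' @param N Number of crosslinking sites (real, >= 0; closed forms use the
#'   continuous gap/L exponent).
#' @param T_window Observation window (s), >= 0.
#' @param tau Turnover time (s), > 0.
#'
#' @return Probability in `[0, 1]`; vectorized over `N` and `T_window`.
#' @examples
#' bridge_probability(3, 10, 1) # ~0.737
#' @export
bridge_probability <- function(N, T_window, tau) {
  if (any(!is.finite(N)) || any(N < 0)) {
    abort("`N` must be finite and >= 0.", class = "actotug_invalid_parameter")
  }
  if (any(!is.finite(T_window)) || any(T_window < 0)) {
    abort("`T_window` must be finite and >= 0.",
          class = "actotug_invalid_parameter")
  }
  check_positive(tau, "tau")
  1 - (1 - 0.5^N)^(T_window / tau)
}

#' Mean percolation (bridge maturation) time
#'
#' Expected waiting time for a bridge across `N` sites: the per-step success
#' probability is (1/2)^N, so the step count is geometric with mean 2^N and
#' the maturation time is \eqn{\tau_p = 2^N \tau}.
#'
#' @param N Number of crosslinking sites (integer >= 0).
#' @param tau Turnover time (s), > 0.
#'
#' @return Mean first-passage time in seconds; vectorized over `N`.
#' @examples
#' mean_percolation_time(6, 0.46) # 29.44 s
#' @export
mean_percolation_time <- function(N, tau) {
  if (any(!is.finite(N)) || any(N < 0) || any(N != round(N))) {
    abort("`N` must be a non-negative integer.",
          class = "actotug_invalid_parameter")
  }
  check_positive(tau, "tau")
  2^N * tau
}

#' Simulate one first-passage time of bridge percolation
#'
#' Discrete process underlying [bridge_probability()]: at each step
#' k = 1, 2, ... all `N` sites are resampled occupied with probability 1/2;
#' the bridge forms at the first step with every site occupied.
#'
#' @param N Number of sites (integer >= 1).
#' @param tau Turnover time (s), > 0.
#' @param horizon Give up after this many seconds (steps with k*tau beyond
#'   `horizon` are not attempted).
#'
#' @return First percolation time `k * tau` in seconds, or `NA_real_` if no
#'   bridge formed within the horizon. Uses the current RNG state; seed with
#'   [set.seed()] for reproducibility.
#' @examples
#' set.seed(1)
#' simulate_first_passage(3, 0.5, horizon = 100)
#' @export
simulate_first_passage <- function(N, tau, horizon) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N)) {
    abort("`N` must be a single integer >= 1.",
          class = "actotug_invalid_parameter")
  }
  check_positive(tau, "tau")
  check_number(horizon, "horizon", min = 0)
  max_steps <- floor(horizon / tau)
  if (max_steps < 1) return(NA_real_)
  k <- 0
  repeat {
    k <- k + 1
    if (k > max_steps) return(NA_real_)
    if (all(runif(N) < 0.5)) return(k * tau)
  }
}

#' Monte-Carlo summary of the percolation process
#'
#' Runs many independent first-passage realizations of the site-occupancy
#' process (all `N` sites resampled each turnover step) and summarizes the
#' fraction that percolated within the horizon and the mean first-passage
#' time. Serves as the stochastic oracle for [bridge_probability()] and
#' [mean_percolation_time()].
#'
#' @param N Sites (integer >= 1); may be a vector (one summary row each).
#' @param tau Turnover time (s).
#' @param horizon Time horizon (s) bounding the number of steps.
#' @param n_trials Independent realizations per `N`.
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `N`, `tau`, `horizon`, `n_trials`,
#'   `frac_percolated`, `mean_first_passage` (seconds, `NA` if nothing
#'   percolated).
#' @examples
#' percolation_mc(3, tau = 1, horizon = 10, n_trials = 1000, seed = 1)
#' @export
percolation_mc <- function(N, tau, horizon, n_trials = 10000, seed = NULL) {
  check_positive(tau, "tau")
  check_positive(horizon, "horizon")
  check_number(n_trials, "n_trials", min = 1)
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(N, function(n_sites) {
    steps <- mc_first_passage_steps(n_sites, floor(horizon / tau), n_trials)
    tibble(
      N = n_sites, tau = tau, horizon = horizon, n_trials = n_trials,
      frac_percolated = mean(!is.na(steps)),
      mean_first_passage = if (all(is.na(steps))) NA_real_ else
        mean(steps, na.rm = TRUE) * tau
    )
  })
}

# vectorized-across-trials first-passage step counts; each step resamples all
# sites, success prob (1/2)^N per step
mc_first_passage_steps <- function(N, max_steps, n_trials) {
  p <- 0.5^N
  steps <- rep(NA_real_, n_trials)
  alive <- seq_len(n_trials)
  k <- 0
  while (length(alive) && k < max_steps) {
    k <- k + 1
    hit <- runif(length(alive)) < p
    steps[alive[hit]] <- k
    alive <- alive[!hit]
  }
  steps
}

#' Read and write percolation parameter configuration
#'
#' Flat key-value config with keys `L_um`, `tau_s` and optionally `C0_M`,
#' `k_on_per_M_s`, `k_off_per_s`.
#'
#' @param path File path.
#' @return `read_percolation_params()` returns a `percolation_params` object.
#' @export
read_percolation_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  percolation_params(
    L = cfg$L_um, tau = cfg$tau_s,
    C0 = cfg$C0_M, k_on = cfg$k_on_per_M_s, k_off = cfg$k_off_per_s
  )
}

#' @rdname read_percolation_params
#' @param params A `percolation_params` object.
#' @export
write_percolation_params <- function(params, path) {
  stopifnot(inherits(params, "percolation_params"))
  cfg <- list(L_um = params$L, tau_s = params$tau)
  if (!is.null(params$C0)) cfg$C0_M <- params$C0
  if (!is.null(params$k_on)) cfg$k_on_per_M_s <- params$k_on
  if (!is.null(params$k_off)) cfg$k_off_per_s <- params$k_off
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @export
print.percolation_params <- function(x, ...) {
  cat("<percolation_params>\n")
  cat(sprintf("  L   = %g um\n  tau = %g s\n", x$L, x$tau))
  if (!is.null(x$C0)) {
    cat(sprintf("  C0 = %g M, k_on = %g /M/s, k_off = %g /s\n",
                x$C0, x$k_on, x$k_off))
  }
  invisible(x)
}
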