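#' Bin DC-ratios by droplet diameter and compute edge fractions
#'
#' Bins observations into diameter bins `[0, w), [w, 2w), ...` and counts
#' edge / centre / intermediate droplets per bin under the chosen
#' classification scheme. By default the edge fraction is
#' `n(edge) / n(total)` with intermediates kept in the denominator (the
#' plotted probability is derived from the full per-bin histogram);
#' `denominator = "classified"` restricts to `edge / (edge + center)`.
#'
#' @param obs Tibble of droplet observations with columns
#'   `droplet_diameter_um` and `dc_ratio`.
#' @param width Bin width in um, default 50.
#' @param scheme Classification scheme, see [classify_position()].
#' @param denominator `"all"` (default) or `"classified"`.
#'
#' @return A tibble of class `edge_curve` with one row per occupied bin:
#'   `bin_center`, `n_total`, `n_edge`, `n_center`, `n_intermediate`,
#'   `edge_fraction`.
#' @examples
#' obs <- generate_cohort(200, seed = 1)
#' bin_edge_fraction(obs)
#' @export
bin_edge_fraction <- function(obs, width = 50,
                              scheme = c("experimental", "simulation"),
                              denominator = c("all", "classified")) {
  scheme <- match.arg(scheme)
  denominator <- match.arg(denominator)
  check_columns(obs, c("droplet_diameter_um", "dc_ratio"), "obs")
  if (nrow(obs) < 1) {
    abort("Need at least one observation.", class = "actotug_invalid_input")
  }
  check_positive(width, "width")
  curve <- obs |>
    dplyr::mutate(
      class = classify_position(.data$dc_ratio, scheme = scheme),
      bin = floor(.data$droplet_diameter_um / width)
    ) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_edge = sum(.data$class == "edge"),
      n_center = sum(.data$class == "center"),
      n_intermediate = sum(.data$class == "intermediate"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bin_center = (.data$bin + 0.5) * width,
      edge_fraction = if (denominator == "all") {
        .data$n_edge / .data$n_total
      } else {
        ifelse(.data$n_edge + .data$n_center > 0,
               .data$n_edge / (.data$n_edge + .data$n_center), NA_real_)
      }
    ) |>
    dplyr::select("bin_center", "n_total", "n_edge", "n_center",
                  "n_intermediate", "edge_fraction") |>
    dplyr::arrange(.data$bin_center)
  class(curve) <- c("edge_curve", class(curve))
  attr(curve, "bin_width") <- width
  attr(curve, "scheme") <- scheme
  attr(curve, "denominator") <- denominator
  curve
}

#' Fit the edge-probability model to a binned curve
#'
#' Non-linear least squares of the closed-form edge probability
#' `p(D) = 1 - [1 - (1/2)^(D/2L)]^(T(D)/tau)` against per-bin edge fractions
#' at the bin centres. Residuals are unweighted by default
#' (`weights = "binomial"` weights each bin by `n_total`). The optimizer is
#' bounded L-BFGS-B restarted from a small grid of initial values
#' (`L` in 2/6/12 um, `tau` in 0.05/0.5/2 s); the best converged start wins.
#'
#' @param curve An `edge_curve` from [bin_edge_fraction()].
#' @param waves A [wave_kinematics()] object supplying `T(D)`.
#' @param free Character subset of `c("L", "tau")` to fit.
#' @param fixed Named list of values for the non-free parameter(s).
#' @param weights `"none"` or `"binomial"`.
#' @param lower,upper Box bounds, defaults `L` in `[0.5, 50]` um and `tau` in
#'   `[0.005, 50]` s.
#' @param starts Optional data frame of start values (columns `L`, `tau`).
#'
#' @return An object of class `edge_fit`: list with elements `curve`,
#'   `waves`, `L`, `tau`, `free`, `sse`, `dc_um` (transition diameter of the
#'   fitted curve), `convergence`.
#' @examples
#' obs <- generate_cohort(200, seed = 1)
#' fit <- fit_edge_probability(bin_edge_fraction(obs),
#'                             condition_waves("control"))
#' glance(fit)
#' @export
fit_edge_probability <- function(curve, waves, free = c("L", "tau"),
                                 fixed = list(),
                                 weights = c("none", "binomial"),
                                 lower = c(L = 0.5, tau = 0.005),
                                 upper = c(L = 50, tau = 50),
                                 starts = NULL) {
  weights <- match.arg(weights)
  stopifnot(inherits(curve, "edge_curve"))
  free <- match.arg(free, c("L", "tau"), several.ok = TRUE)
  if (!length(free)) {
    abort("`free` must name at least one parameter.",
          class = "actotug_invalid_parameter")
  }
  pts <- curve[!is.na(curve$edge_fraction) & curve$n_total > 0, ]
  if (nrow(pts) < 2) {
    abort("Need at least two occupied bins to fit.",
          class = "actotug_fit_failure")
  }
  w <- if (weights == "binomial") pts$n_total else rep(1, nrow(pts))

  default_starts <- tidyr::expand_grid(L = c(2, 6, 12),
                                       tau = c(0.05, 0.5, 2))
  starts <- starts %||% default_starts
  get_par <- function(theta, name) {
    if (name %in% free) theta[[name]] else fixed[[name]]
  }
  for (nm in setdiff(c("L", "tau"), free)) {
    if (is.null(fixed[[nm]])) {
      abort(sprintf("Parameter '%s' is not free; supply it in `fixed`.", nm),
            class = "actotug_invalid_parameter")
    }
  }
  sse_fun <- function(par) {
    theta <- as.list(setNames(par, free))
    L <- get_par(theta, "L")
    tau <- get_par(theta, "tau")
    pred <- edge_probability(pts$bin_center, L, tau, waves)
    sum(w * (pts$edge_fraction - pred)^2)
  }

  best <- NULL
  for (k in seq_len(nrow(starts))) {
    par0 <- vapply(free, function(nm) starts[[nm]][k], numeric(1))
    res <- tryCatch(
      optim(par0, sse_fun, method = "L-BFGS-B",
            lower = lower[free], upper = upper[free]),
      error = function(e) NULL
    )
    if (is.null(res) || res$convergence != 0) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    abort("All optimizer starts failed to converge.",
          class = "actotug_fit_failure")
  }
  theta <- as.list(setNames(best$par, free))
  L_hat <- get_par(theta, "L")
  tau_hat <- get_par(theta, "tau")
  dc <- tryCatch(transition_diameter(L_hat, tau_hat, waves),
                 actotug_no_transition = function(e) NA_real_)
  structure(
    list(curve = curve, waves = waves, L = unname(L_hat),
         tau = unname(tau_hat), free = free, sse = best$value, dc_um = dc,
         convergence = best$convergence),
    class = "edge_fit"
  )
}

#' @export
print.edge_fit <- function(x, ...) {
  cat("<edge_fit>\n")
  cat(sprintf("  L = %.3g um%s, tau = %.3g s%s\n",
              x$L, if ("L" %in% x$free) "" else " (fixed)",
              x$tau, if ("tau" %in% x$free) "" else " (fixed)"))
  cat(sprintf("  transition diameter D_c = %.4g um; SSE = %.4g over %d bins\n",
              x$dc_um, x$sse, nrow(x$curve)))
  invisible(x)
}

#' Ordinary least-squares line fit
#'
#' `linear_fit()` fits `y = slope * x + intercept`;
#' `linear_fit_through_origin()` fits `y = slope * x`. `r_squared` is the
#' coefficient of determination of the stated model (for the through-origin
#' model, the uncentred version used for no-intercept regressions). For a
#' constant response under the intercept model, `r_squared` is defined as 0.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A one-row tibble: `slope`, `intercept` (intercept model only),
#'   `r_squared`.
#' @examples
#' linear_fit_through_origin(1:10, 0.25 * (1:10))
#' @export
linear_fit <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("Need >= 3 paired points for the intercept model.",
          class = "actotug_fit_failure")
  }
  if (stats::var(x) == 0) {
    abort("`x` has zero variance.", class = "actotug_fit_failure")
  }
  fit <- lm(y ~ x)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(stats::resid(fit)^2) / sst
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = r2)
}

#' @rdname linear_fit
#' @export
linear_fit_through_origin <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    abort("Need >= 2 paired points.", class = "actotug_fit_failure")
  }
  if (all(x == 0)) {
    abort("`x` has zero variance.", class = "actotug_fit_failure")
  }
  fit <- lm(y ~ 0 + x)
  sst <- sum(y^2)
  r2 <- if (sst == 0) 0 else 1 - sum(stats::resid(fit)^2) / sst
  tibble(slope = unname(coef(fit)[1]), r_squared = r2)
}

#' Kolmogorov-Smirnov comparison of DC-ratio scatters
#'
#' Two-sample KS test on the DC-ratios of droplets whose diameter lies in the
#' closed interval `d_range` (default 50-150 um, around the control
#' transition point). Asymptotic p-values.
#'
#' @param obs_a,obs_b Observation tibbles with columns
#'   `droplet_diameter_um` and `dc_ratio`.
#' @param d_range Closed diameter interval in um.
#'
#' @return A one-row tibble: `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
ks_compare <- function(obs_a, obs_b, d_range = c(50, 150)) {
  check_columns(obs_a, c("droplet_diameter_um", "dc_ratio"), "obs_a")
  check_columns(obs_b, c("droplet_diameter_um", "dc_ratio"), "obs_b")
  pick <- function(obs) {
    obs$dc_ratio[obs$droplet_diameter_um >= d_range[1] &
                   obs$droplet_diameter_um <= d_range[2]]
  }
  a <- pick(obs_a)
  b <- pick(obs_b)
  if (!length(a) || !length(b)) {
    abort("A restricted sample is empty on the diameter range.",
          class = "actotug_invalid_input")
  }
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  tibble(statistic = unname(kt$statistic), p_value = kt$p.value,
         n_a = length(a), n_b = length(b))
}
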