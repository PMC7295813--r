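test_that("edge fractions are counted per 50-um bin with intermediates in the denominator", {
  obs <- tibble::tibble(
    droplet_diameter_um = c(60, 70, 80, 90),
    dc_ratio = c(0.9, 0.6, 0.1, 0.3)
  )
  curve <- bin_edge_fraction(obs, width = 50)
  expect_equal(nrow(curve), 1)
  expect_equal(curve$bin_center, 75)
  expect_equal(curve$edge_fraction, 0.5) # 2 of 4 above 0.5
  expect_equal(curve$n_intermediate, 1)
  # excluding intermediates from the denominator: 2 of 3
  alt <- bin_edge_fraction(obs, width = 50, denominator = "classified")
  expect_equal(alt$edge_fraction, 2 / 3)
})

test_that("all-centred observations give zero fractions in every occupied bin", {
  obs <- tibble::tibble(droplet_diameter_um = runif(50, 16, 330),
                        dc_ratio = 0)
  curve <- bin_edge_fraction(obs)
  expect_true(all(curve$edge_fraction == 0))
  expect_true(all(curve$n_center == curve$n_total))
})

test_that("binned fractions of a synthetic cohort track the closed form", {
  par <- condition_params("control")
  obs <- generate_cohort(200, seed = 202)
  curve <- bin_edge_fraction(obs)
  for (k in seq_len(nrow(curve))) {
    lo <- curve$bin_center[k] - 25
    hi <- curve$bin_center[k] + 25
    p_exp <- bin_expected_p(lo, hi, par$L, par$tau, par$waves)
    se <- sqrt(p_exp * (1 - p_exp) / curve$n_total[k])
    expect_lt(abs(curve$edge_fraction[k] - p_exp), 3 * se + 0.02)
  }
})

test_that("noise-free curves are recovered to within 1%", {
  w <- control_waves()
  curve <- exact_edge_curve(6.1, 0.46, w)
  fit <- fit_edge_probability(curve, w)
  expect_equal(fit$L, 6.1, tolerance = 0.01)
  expect_equal(fit$tau, 0.46, tolerance = 0.01)
  expect_lt(fit$sse, 1e-8)
  # tau fixed at truth: L alone recovered
  fit_L <- fit_edge_probability(curve, w, free = "L",
                                fixed = list(tau = 0.46))
  expect_equal(fit_L$L, 6.1, tolerance = 0.01)
  expect_equal(fit_L$tau, 0.46)
})

test_that("under-determined or invalid fits fail loudly", {
  w <- control_waves()
  curve <- exact_edge_curve(6.1, 0.46, w, centers = 75)
  expect_error(fit_edge_probability(curve, w),
               class = "actotug_fit_failure")
  full <- exact_edge_curve(6.1, 0.46, w)
  expect_error(fit_edge_probability(full, w, free = "L"),
               class = "actotug_invalid_parameter")
})

test_that("edge_fit exposes tidy and glance summaries", {
  w <- control_waves()
  fit <- fit_edge_probability(exact_edge_curve(6.1, 0.46, w), w)
  td <- tidy(fit)
  expect_equal(td$term, c("L", "tau"))
  expect_false(any(td$fixed))
  gl <- glance(fit)
  expect_equal(gl$dc_um, transition_diameter(6.1, 0.46, w), tolerance = 0.01)
  expect_equal(gl$n_bins, 7)
})

test_that("linear fits reproduce exact relations with R-squared 1", {
  x <- seq(20, 300, by = 20)
  f0 <- linear_fit_through_origin(x, 0.25 * x)
  expect_equal(f0$slope, 0.25)
  expect_equal(f0$r_squared, 1)
  f1 <- linear_fit(x, 1.6e-2 * x - 1.3)
  expect_equal(f1$slope, 1.6e-2)
  expect_equal(f1$intercept, -1.3)
  expect_equal(f1$r_squared, 1)
})

test_that("degenerate linear fits are handled as specified", {
  x <- seq(1, 10)
  const <- linear_fit(x, rep(3, 10))
  expect_equal(const$slope, 0)
  expect_equal(const$r_squared, 0)
  expect_error(linear_fit(rep(2, 5), 1:5), class = "actotug_fit_failure")
  expect_error(linear_fit_through_origin(rep(0, 5), 1:5),
               class = "actotug_fit_failure")
  # symmetric noise strictly lowers R-squared
  set.seed(9)
  noisy <- linear_fit(x, 2 * x + rnorm(10, 0, 0.5))
  expect_lt(noisy$r_squared, 1)
})

test_that("KS comparison restricts to the diameter window", {
  obs <- tibble::tibble(droplet_diameter_um = rep(100, 20),
                        dc_ratio = seq(0, 1, length.out = 20))
  same <- ks_compare(obs, obs)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  a <- tibble::tibble(droplet_diameter_um = rep(100, 3), dc_ratio = c(0, 0, 0))
  b <- tibble::tibble(droplet_diameter_um = rep(100, 3), dc_ratio = c(1, 1, 1))
  expect_equal(ks_compare(a, b)$statistic, 1)
  out_of_range <- tibble::tibble(droplet_diameter_um = rep(300, 3),
                                 dc_ratio = c(0.5, 0.5, 0.5))
  expect_error(ks_compare(a, out_of_range), class = "actotug_invalid_input")
})

test_that("conditions with shifted transitions separate by KS test", {
  hits <- vapply(1:20, function(r) {
    ctrl <- generate_cohort(150, condition = "control", seed = 3000 + r)
    mdia <- generate_cohort(150, condition = "mdia2", seed = 6000 + r)
    ks_compare(ctrl, mdia)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("observation tables round-trip through delimited text", {
  obs <- generate_cohort(30, seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_droplet_observations(obs, path)
  back <- read_droplet_observations(path)
  expect_equal(back$droplet_diameter_um, obs$droplet_diameter_um,
               tolerance = 1e-9)
  expect_equal(back$condition, obs$condition)
})
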