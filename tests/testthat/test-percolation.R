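test_that("turnover time follows 1/(k_off + C0*k_on)", {
  expect_equal(turnover_time(0.66, 1.2e6, 1e-6), 1 / 1.86)
  expect_equal(round(turnover_time(0.66, 1.2e6, 1e-6), 2), 0.54)
  expect_equal(turnover_time(1, 0, 0), 1)
  expect_equal(turnover_time(0, 2, 0.5), 1)
  expect_error(turnover_time(0, 0, 0), class = "actotug_invalid_parameter")
  expect_error(turnover_time(-1, 2, 0.5),
               class = "actotug_invalid_parameter")
})

test_that("turnover time strictly decreases in k_off and in C0*k_on", {
  k_offs <- c(0.1, 0.5, 1, 5)
  taus <- vapply(k_offs, turnover_time, numeric(1), k_on = 1e6, C0 = 1e-6)
  expect_true(all(diff(taus) < 0))
  C0s <- c(1e-7, 1e-6, 1e-5)
  taus <- vapply(C0s, function(c0) turnover_time(0.66, 1.2e6, c0),
                 numeric(1))
  expect_true(all(diff(taus) < 0))
})

test_that("site count rounds the gap to filament-length units", {
  expect_identical(site_count(42.5, 6.1), 7L)
  expect_identical(site_count(1, 6.1), 1L)
  expect_identical(site_count(12, 6), 2L)
  expect_error(site_count(0, 6.1), class = "actotug_invalid_parameter")
  expect_error(site_count(10, -1), class = "actotug_invalid_parameter")
})

test_that("bridge probability matches its closed form and limits", {
  expect_equal(bridge_probability(0, 5, 1), 1)
  # a single time step: T = tau
  for (N in c(1, 3, 7.5)) {
    expect_equal(bridge_probability(N, 1, 1), 0.5^N)
  }
  expect_equal(bridge_probability(3, 10, 1), 0.7369, tolerance = 0.005 / 0.7369)
  expect_error(bridge_probability(3, 10, 0),
               class = "actotug_invalid_parameter")
  expect_error(bridge_probability(-1, 10, 1),
               class = "actotug_invalid_parameter")
})

test_that("bridge probability is monotone in N and in T/tau", {
  Ns <- seq(0, 12, by = 0.5)
  p_over_N <- bridge_probability(Ns, T_window = 10, tau = 0.5)
  expect_true(all(diff(p_over_N) <= 0))
  Ts <- seq(0, 100, by = 5)
  p_over_T <- bridge_probability(4, Ts, tau = 0.5)
  expect_true(all(diff(p_over_T) >= 0))
  expect_true(all(p_over_N >= 0 & p_over_N <= 1))
})

test_that("Monte-Carlo percolation fraction agrees with the closed form", {
  for (N in c(1, 3, 5, 8)) {
    for (ratio in c(1, 5, 20)) {
      mc <- percolation_mc(N, tau = 1, horizon = ratio, n_trials = 1e4,
                           seed = 100 + N * ratio)
      p <- bridge_probability(N, ratio, 1)
      se <- sqrt(p * (1 - p) / 1e4)
      expect_lt(abs(mc$frac_percolated - p), 3 * se + 1e-9)
    }
  }
})

test_that("first-passage times are geometric with mean 2^N * tau", {
  for (N in c(1, 4, 6)) {
    tau <- 0.46
    mean_steps <- 2^N
    # horizon far beyond the mean so truncation is negligible
    mc <- percolation_mc(N, tau = tau, horizon = 400 * mean_steps * tau,
                         n_trials = 1e4, seed = 7 + N)
    expected <- mean_percolation_time(N, tau)
    sd_steps <- sqrt(1 - 0.5^N) / 0.5^N
    se <- sd_steps * tau / sqrt(1e4)
    expect_lt(abs(mc$mean_first_passage - expected), 3 * se)
  }
  expect_equal(mean_percolation_time(1, 2), 4)
  expect_equal(mean_percolation_time(0, 0.5), 0.5)
})

test_that("single-run first passage respects the horizon", {
  # first possible percolation time tau = 3 exceeds the horizon 2
  set.seed(1)
  expect_true(is.na(simulate_first_passage(1, tau = 3, horizon = 2)))
  set.seed(42)
  times <- replicate(2000, simulate_first_passage(1, 1, horizon = 1e6))
  expect_equal(mean(times), 2, tolerance = 0.05)
  expect_true(all(times >= 1))
})

test_that("single-run process and closed form agree on percolation fraction", {
  set.seed(11)
  hits <- replicate(3000, !is.na(simulate_first_passage(5, 1, horizon = 10)))
  p <- bridge_probability(5, 10, 1)
  se <- sqrt(p * (1 - p) / 3000)
  expect_lt(abs(mean(hits) - p), 3 * se)
})

test_that("percolation params validate tau against the rates", {
  p <- percolation_params(L = 5.7, C0 = 1e-6, k_on = 1.2e6, k_off = 0.66)
  expect_equal(p$tau, 1 / 1.86)
  expect_silent(percolation_params(L = 5.7, tau = 1 / 1.86, C0 = 1e-6,
                                   k_on = 1.2e6, k_off = 0.66))
  expect_error(
    percolation_params(L = 5.7, tau = 0.5, C0 = 1e-6, k_on = 1.2e6,
                       k_off = 0.66),
    class = "actotug_invalid_parameter"
  )
  expect_error(percolation_params(L = 5), class = "actotug_invalid_parameter")
})

test_that("percolation params round-trip through flat config files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  p <- percolation_params(L = 6.1, tau = 0.46)
  write_percolation_params(p, path)
  p2 <- read_percolation_params(path)
  expect_equal(p2$L, 6.1)
  expect_equal(p2$tau, 0.46)
})

test_that("Monte-Carlo summaries write as delimited text", {
  path <- withr::local_tempfile(fileext = ".tsv")
  mc <- percolation_mc(c(2, 3), tau = 1, horizon = 10, n_trials = 200,
                       seed = 3)
  write_mc_summary(mc, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), 2)
  expect_equal(back$frac_percolated, mc$frac_percolated)
})
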