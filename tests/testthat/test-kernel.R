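test_that("excitation kernel matches its closed form and telescopes to unit mass", {
  expect_equal(excitation_probability(1, 13.2), 1 - exp(-1 / 13.2))
  expect_equal(excitation_probability(1, 13.2), 0.0730, tolerance = 1e-3)

  for (Tv in c(1, 13.2, 100)) {
    for (K in c(1, 10, 500)) {
      expect_equal(sum(excitation_probability(1:K, Tv)),
                   1 - exp(-K / Tv), tolerance = 1e-13)
    }
    p <- excitation_probability(1:50, Tv)
    expect_true(all(diff(p) < 0))          # strictly decreasing in lag
    expect_true(all(p > 0 & p < 1))
  }

  # tail vanishes
  expect_lt(excitation_probability(10000, 13.2), 1e-300)

  # day-1 probability decreases as the contagion window lengthens
  p1 <- vapply(c(1, 5, 13.2, 50, 365),
               function(Tv) excitation_probability(1, Tv), 0)
  expect_true(all(diff(p1) < 0))

  expect_error(excitation_probability(0, 13.2), "same-day")
  expect_error(excitation_probability(1, -1), "positive")
})

test_that("running-mean baseline reproduces constants, scales linearly, and conserves events", {
  n <- 400
  s <- selfexcite:::series_from_counts(rep(2L, n), as.Date("2006-01-01"))
  n0 <- baseline_running_mean(s, bandwidth = 365)
  expect_equal(n0, rep(2, n), tolerance = 1e-12)

  set.seed(12)
  s2 <- null_series(600, 0.3, 99)
  a <- baseline_running_mean(s2, bandwidth = 200)
  s2_doubled <- selfexcite:::series_from_counts(2L * s2$counts, s2$origin)
  b <- baseline_running_mean(s2_doubled, bandwidth = 200)
  expect_equal(b, 2 * a, tolerance = 1e-12)

  # boxcar, single event: 1/w inside the window, 0 outside
  w <- 51
  counts <- integer(500); counts[250] <- 1L
  s3 <- selfexcite:::series_from_counts(counts, as.Date("2006-01-01"))
  n0b <- suppressWarnings(
    baseline_running_mean(s3, bandwidth = w, kernel = "boxcar"))
  inside <- 250 + (-25:25)
  expect_equal(n0b[inside], rep(1 / w, length(inside)), tolerance = 1e-12)
  expect_equal(n0b[-inside], rep(0, 500 - length(inside)))
  # total events conserved away from edge effects
  expect_equal(sum(n0b), 1, tolerance = 1e-10)

  expect_error(baseline_running_mean(s, bandwidth = 0), "positive")
  expect_warning(baseline_running_mean(s, bandwidth = 50), "bandwidth")
})

test_that("calendar weights average to one and pick up planted structure", {
  set.seed(21)
  # plant a strong Saturday excess
  wk_true <- c(1, 1, 1, 1, 1, 1, 4); wk_true <- wk_true / mean(wk_true)
  spec <- generator_spec(n_days = 3500, N0 = 0.3, N_secondary = 0,
                         weekday_weights = wk_true, seed = 77)
  s <- simulate_series(spec)
  w <- calendar_weights(s, "weekday")
  expect_equal(mean(w), 1, tolerance = 1e-12)
  expect_equal(which.max(w), 7)  # day 7 = Saturday in the 1=Sunday indexing
  expect_gt(w[7], 1.5)

  m <- calendar_weights(s, "month")
  expect_equal(mean(m), 1, tolerance = 1e-12)
})

test_that("expected events compose baseline and excitation linearly", {
  par <- contagion_params(0.3, 13.2, 0.1)
  # empty history and zero branching ratio reduce to the baseline
  expect_equal(expected_events(10, integer(0), par), 0.1)
  par0 <- contagion_params(0, 13.2, 0.1)
  expect_equal(expected_events(10, c(1, 5, 9), par0), 0.1)

  # one prior event one day back: N0 + Nsec * P(1)
  expect_equal(expected_events(5, 4, par),
               0.1 + 0.3 * excitation_probability(1, 13.2))
  expect_equal(expected_events(5, 4, par), 0.1219, tolerance = 1e-3)

  # additivity of history contributions
  A <- c(1, 3); B <- c(2, 7); t_n <- 9
  exc <- function(h) expected_events(t_n, h, par) - 0.1
  expect_equal(exc(c(A, B)), exc(A) + exc(B), tolerance = 1e-12)

  expect_error(expected_events(5, c(4, 5), par), "before")
})

test_that("log-likelihood matches hand computation and the Poisson limit", {
  s <- selfexcite:::series_from_counts(c(1L, 0L, 0L), as.Date("2006-01-01"))
  par <- contagion_params(0, 13.2, 0.1)
  expect_equal(log_likelihood(s, par), log(0.1) - 0.3, tolerance = 1e-12)

  # all-zero counts: -sum N_exp
  s0 <- selfexcite:::series_from_counts(integer(5), as.Date("2006-01-01"))
  expect_equal(log_likelihood(s0, contagion_params(0.4, 3, 0.2)), -1)

  # N_secondary = 0 equals the pure-baseline Poisson log-likelihood
  set.seed(9)
  s1 <- null_series(300, 0.4, 17)
  par1 <- contagion_params(0, 5, 0.37)
  expect_equal(log_likelihood(s1, par1),
               sum(dpois(s1$counts, 0.37, log = TRUE)), tolerance = 1e-10)

  # with excitation, the likelihood matches a direct O(n^2) evaluation
  par2 <- contagion_params(0.5, 7, 0.1)
  days <- which(s1$counts > 0) - 1L
  ev <- rep(days, s1$counts[days + 1L])
  mu <- vapply(seq_along(s1$counts) - 1L, function(t)
    expected_events(t, ev[ev < t], par2), 0)
  expect_equal(log_likelihood(s1, par2),
               sum(dpois(s1$counts, mu, log = TRUE)), tolerance = 1e-8)

  # an event on a zero-mean day gives -Inf, not an error
  s2 <- selfexcite:::series_from_counts(c(0L, 1L), as.Date("2006-01-01"))
  expect_identical(log_likelihood(s2, contagion_params(0, 5, 0)), -Inf)
})
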