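test_that("national rate is a simple scaling of events over population", {
  pops <- data.frame(state = c("TX", "CA"), population = c(1.1e8, 2e8))
  cat <- make_catalog(as.Date("2010-01-01") + 0:231,
                      state = rep(c("TX", "CA"), 116))
  mu <- national_rate(cat, pops)
  expect_equal(mu, 232 / 3.1e8)
  expect_equal(mu, 7.5e-7, tolerance = 2e-2)

  # doubling all populations halves mu
  pops2 <- transform(pops, population = 2 * population)
  expect_equal(national_rate(cat, pops2), mu / 2)

  expect_equal(national_rate(make_catalog(character(0)), pops), 0)
  expect_error(national_rate(cat, transform(pops, population = 0)),
               "positive")
  expect_error(national_rate(make_catalog("2010-01-01", state = "ZZ"),
                             pops), "ZZ")
})

test_that("binomial CDF statistic matches brute-force summation and limits", {
  expect_equal(binomial_cdf_significance(10, 10, 0.3), 1)
  expect_equal(binomial_cdf_significance(0, 10, 0), 1)
  expect_equal(binomial_cdf_significance(5, 100, 0), 1)

  brute <- function(k, N, mu)
    sum(choose(N, 0:k) * mu^(0:k) * (1 - mu)^(N - (0:k)))
  expect_equal(binomial_cdf_significance(2, 10, 0.1), brute(2, 10, 0.1),
               tolerance = 1e-12)
  expect_equal(binomial_cdf_significance(2, 10, 0.1), 0.92981,
               tolerance = 1e-5)

  set.seed(3)
  for (i in 1:40) {
    N <- sample(1:1000, 1)
    k <- sample(0:N, 1)
    mu <- runif(1)
    expect_equal(binomial_cdf_significance(k, N, mu), brute(k, N, mu),
                 tolerance = 1e-10)
  }

  # stable in the regime N ~ 1e7, mu ~ 1e-7
  Fs <- binomial_cdf_significance(0:30, 1e7, 7.5e-7)
  expect_true(all(is.finite(Fs) & Fs >= 0 & Fs <= 1))
  expect_true(all(diff(Fs) > 0))
  # Poisson limit cross-check at tiny mu
  expect_equal(Fs, ppois(0:30, 1e7 * 7.5e-7), tolerance = 1e-5)

  expect_error(binomial_cdf_significance(2, 10, 1.5), "mu")
  expect_error(binomial_cdf_significance(11, 10, 0.1), "k_i")
})

test_that("F is monotone in count and in the reference rate", {
  N <- 5e6
  mus <- c(1e-8, 1e-7, 5e-7, 1e-6)
  for (mu in mus) {
    F_k <- binomial_cdf_significance(0:20, N, mu)
    expect_true(all(diff(F_k) >= 0))
  }
  for (k in c(0, 3, 10)) {
    F_mu <- vapply(mus, function(m)
      binomial_cdf_significance(k, N, m), 0)
    expect_true(all(diff(F_mu) <= 0))
  }
})

test_that("state F values are calibrated under the national rate", {
  pops <- state_centroids()
  # rate high enough that every state expects >= 20 events; the CDF of a
  # discrete count is only approximately uniform, with bias O(P(K = k))
  mu <- 5e-5
  set.seed(6)
  Fs <- replicate(40, {
    k <- rbinom(nrow(pops), pops$population, mu)
    mean(binomial_cdf_significance(k, pops$population, mu))
  })
  # mean of an approximately uniform F is near 1/2
  expect_equal(mean(Fs), 0.5, tolerance = 0.08)
})

test_that("firearm proxy pools counts before taking the ratio", {
  tab <- data.frame(state = c("TX", "TX", "CA"),
                    suicides_total = c(100, 100, 1000),
                    suicides_firearm = c(40, 60, 500))
  fp <- firearm_proxy(tab)
  expect_equal(fp$firearm_proxy[fp$state == "TX"], 0.5)
  expect_equal(fp$firearm_proxy[fp$state == "CA"], 0.5)

  z <- firearm_proxy(data.frame(state = "VT", suicides_total = 50,
                                suicides_firearm = 0))
  expect_equal(z$firearm_proxy, 0)

  expect_error(firearm_proxy(data.frame(state = "A", suicides_total = 10,
                                        suicides_firearm = 11)),
               "data error")
})

test_that("critical correlation magnitude reproduces the n = 50 threshold", {
  expect_equal(critical_correlation(50), 0.2787, tolerance = 1e-4)
  expect_equal(round(critical_correlation(50), 2), 0.28)
  # self-consistency: cor.test at exactly the critical r gives p = 0.05
  r <- critical_correlation(50)
  tstat <- r * sqrt(48 / (1 - r^2))
  expect_equal(2 * pt(tstat, 48, lower.tail = FALSE), 0.05,
               tolerance = 1e-10)
})

test_that("incidence-covariate correlations recover planted structure", {
  pops <- state_centroids()
  set.seed(9)
  k <- rbinom(nrow(pops), pops$population, 5e-7)
  cat_df <- as_event_catalog(data.frame(
    date = rep(as.Date("2010-06-01"), sum(k)),
    state = rep(pops$state, k)), label = "sim")
  inc <- state_incidence(cat_df, pops)
  expect_equal(sum(inc$k), sum(k))
  expect_true(all(inc$F >= 0 & inc$F <= 1))

  # covariate = F itself
  cov_self <- data.frame(state = inc$state, same = inc$F)
  res <- incidence_covariate_correlation(inc, cov_self, "same")
  expect_equal(res$rho, 1, tolerance = 1e-12)
  expect_equal(res$critical_r, 0.2787, tolerance = 1e-4)
  expect_equal(res$n, 50)

  # planted correlation ~0.5 is recovered on average over replicates
  set.seed(10)
  rhos <- replicate(150, {
    x <- rnorm(50)
    y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(50)
    inc_f <- inc; inc_f$F <- x
    cv <- data.frame(state = inc$state, planted = y)
    incidence_covariate_correlation(inc_f, cv, "planted")$rho
  })
  expect_equal(mean(rhos), 0.5, tolerance = 0.05)

  # adjustment removes a correlation that is wholly due to a confounder
  set.seed(11)
  rhos_adj <- replicate(100, {
    z <- rnorm(50)
    inc_f <- inc; inc_f$F <- z + 0.3 * rnorm(50)
    cv <- data.frame(state = inc$state,
                     linked = z + 0.3 * rnorm(50), conf = z)
    r0 <- incidence_covariate_correlation(inc_f, cv, "linked")$rho
    r1 <- incidence_covariate_correlation(inc_f, cv, "linked",
                                          adjust_for = "conf")$rho
    c(r0, r1)
  })
  expect_gt(mean(rhos_adj[1, ]), 0.7)          # confounded correlation
  expect_equal(mean(rhos_adj[2, ]), 0, tolerance = 0.06)  # removed

  small <- inc[1:3, ]
  expect_error(incidence_covariate_correlation(
    small, data.frame(state = small$state, v = 1:3), "v"), "at least 4")
})
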