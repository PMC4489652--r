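test_that("read_catalog validates, sorts, filters and reports", {
  df <- data.frame(
    date = c("2010-01-05", "2010-01-03", "2010-01-03", "2010-02-01",
             "2010-03-15"),
    state = c("TX", "CA", "CA", "NY", "FL"),
    latitude = c(31.5, 37.2, 37.2, 42.9, 28.6),
    longitude = c(-99.3, -119.3, -119.3, -75.5, -82.4),
    n_killed = c(4, 5, 6, 4, 7),
    firearm = c(TRUE, TRUE, FALSE, TRUE, FALSE),
    shooter_suicide = c(FALSE, TRUE, FALSE, FALSE, TRUE))
  path <- write_catalog_csv(df)

  cat <- read_catalog(path)
  expect_s3_class(cat, "event_catalog")
  expect_equal(nrow(cat), 5)
  expect_true(!is.unsorted(cat$date))

  firearm_only <- read_catalog(path, filters = list(firearm = TRUE))
  expect_equal(nrow(firearm_only), 3)
  rep <- attr(firearm_only, "filter_report")
  expect_equal(rep$n, c(5, 3))

  strict <- read_catalog(path, filters = list(min_killed = 5,
                                              firearm = FALSE))
  expect_equal(nrow(strict), 2)
  expect_true(all(strict$n_killed >= 5))
})

test_that("empty input and schema/date errors are handled", {
  empty <- data.frame(date = character(), n_killed = numeric())
  p_empty <- write_catalog_csv(empty)
  cat0 <- read_catalog(p_empty)
  expect_equal(nrow(cat0), 0)

  noname <- data.frame(day = "2010-01-01", n_killed = 4)
  expect_error(read_catalog(write_catalog_csv(noname)), "date")

  baddate <- data.frame(
    date = c("2010-01-01", "2010-01-02", "not-a-day", "2010-01-04",
             "2010-01-05"),
    n_killed = 4)
  expect_error(read_catalog(write_catalog_csv(baddate)), "row\\(s\\): 3")

  badlat <- make_catalog("2010-01-01")
  badlat$latitude <- 95
  expect_error(as_event_catalog(as.data.frame(badlat)), "latitude")
})

test_that("filtering is idempotent", {
  cat <- make_catalog(sprintf("2010-01-%02d", 1:20),
                      n_killed = rep(c(4, 5, 8, 12), 5),
                      firearm = rep(c(TRUE, FALSE), 10))
  f <- list(min_killed = 5, firearm = TRUE)
  once <- filter_catalog(cat, f)
  twice <- filter_catalog(once, f)
  expect_equal(as.data.frame(once), as.data.frame(twice),
               ignore_attr = TRUE)
  expect_gt(nrow(once), 0)
  # the report keeps logging stages, but row counts stop changing
  rep2 <- attr(twice, "filter_report")
  expect_true(all(rep2$n[-(1:2)] == nrow(once)))
})

test_that("to_daily_series discretizes correctly and round-trips", {
  cat <- make_catalog(c("2010-01-01", "2010-01-01", "2010-01-02"))
  s <- to_daily_series(cat)
  expect_equal(s$counts, c(2L, 1L))
  expect_equal(s$origin, as.Date("2010-01-01"))

  set.seed(8)
  dates <- as.Date("2006-01-01") + sort(sample(0:2921, 232, replace = TRUE))
  cat2 <- make_catalog(dates)
  s2 <- to_daily_series(cat2)
  expect_equal(sum(s2$counts), 232)
  expect_equal(length(s2$counts),
               as.integer(max(dates) - min(dates)) + 1L)
  # round trip recovers the multiset of dates
  expect_equal(series_event_dates(s2), dates)

  expect_error(to_daily_series(make_catalog(character(0))), "empty")
})

test_that("weekday test is exact under exposure-proportional counts and matches the chi-squared oracle", {
  # 4 exact weeks, one event per day: perfectly exposure-proportional
  cat <- make_catalog(as.Date("2010-01-04") + 0:27)
  res <- weekday_seasonal_tests(cat)
  expect_equal(res$weekday$statistic, 0)
  expect_equal(res$weekday$p_value, 1)

  # 14 events concentrated on two days two weeks apart
  cat2 <- make_catalog(c(rep("2010-01-04", 7), rep("2010-01-17", 7)))
  s <- to_daily_series(cat2)
  obs <- vapply(1:7, function(l) sum(s$counts[s$weekday == l]), 0)
  expo <- vapply(1:7, function(l) sum(s$weekday == l), 0)
  oracle <- suppressWarnings(chisq.test(obs, p = expo / sum(expo)))
  res2 <- weekday_seasonal_tests(cat2)
  expect_equal(res2$weekday$statistic, unname(oracle$statistic))
  expect_equal(res2$weekday$df, 6)

  expect_error(weekday_seasonal_tests(
    make_catalog(c("2010-01-01", "2010-01-03"))), "week")
})

test_that("weekday p-values are uniform under the exposure-proportional null", {
  # daily Poisson counts with no weekday structure: p ~ U(0,1)
  set.seed(31)
  pv <- replicate(400, {
    s <- null_series(364, 0.3, sample.int(1e6, 1))
    cat <- make_catalog(series_event_dates(s))
    if (nrow(cat) < 2) return(NA_real_)
    weekday_seasonal_tests(cat)$weekday$p_value
  })
  pv <- pv[!is.na(pv)]
  # chi-squared p-values are discrete-ish at small counts; KS at loose level
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
})

test_that("suicide severity comparison handles standard and degenerate cases", {
  # identical subgroups
  cat <- make_catalog(sprintf("2010-01-%02d", 1:8),
                      n_killed = rep(c(4, 6, 5, 9), 2),
                      shooter_suicide = rep(c(TRUE, FALSE), each = 4))
  res <- suicide_severity_comparison(cat)
  expect_equal(res$ratio, 1)
  expect_equal(res$p_value, 1, tolerance = 1e-12)

  # zero within-group variance limit
  cat2 <- make_catalog(sprintf("2010-01-%02d", 1:8),
                       n_killed = rep(c(5, 4), each = 4),
                       shooter_suicide = rep(c(TRUE, FALSE), each = 4))
  res2 <- suicide_severity_comparison(cat2)
  expect_equal(res2$ratio, 1.25)
  expect_lt(res2$p_value, 1e-6)
  expect_equal(res2$suicide_fraction, 0.5)

  # empty subgroup: comparison unavailable, fraction still returned
  cat3 <- make_catalog(sprintf("2010-01-%02d", 1:4),
                       shooter_suicide = FALSE)
  res3 <- suicide_severity_comparison(cat3)
  expect_false(res3$available)
  expect_equal(res3$suicide_fraction, 0)

  # a t test on distinct subgroup severities is two-sided Student-t
  set.seed(5)
  k1 <- 4 + rpois(40, 3); k0 <- 4 + rpois(60, 1)
  cat4 <- make_catalog(as.Date("2010-01-01") + 0:99,
                       n_killed = c(k1, k0),
                       shooter_suicide = rep(c(TRUE, FALSE), c(40, 60)))
  res4 <- suicide_severity_comparison(cat4)
  expect_equal(res4$p_value, t.test(k1, k0)$p.value)
  expect_equal(res4$ratio, mean(k1) / mean(k0))
})

test_that("covariate tables are validated", {
  df <- data.frame(state = c("TX", "CA"), population = c(26e6, 38e6))
  p <- write_catalog_csv(df)
  expect_equal(nrow(read_covariates(p)), 2)
  dup <- data.frame(state = c("TX", "TX"), population = 1)
  expect_error(read_covariates(write_catalog_csv(dup)), "dup")
})
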