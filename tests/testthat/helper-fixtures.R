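# fixture builders shared across the suite (all data generated in code)

make_catalog <- function(dates, state = "TX", latitude = 31.5,
                         longitude = -99.3, n_killed = 4L,
                         firearm = TRUE, shooter_suicide = FALSE,
                         label = "fixture") {
  n <- length(dates)
  as_event_catalog(data.frame(
    date = as.Date(dates),
    state = rep_len(state, n),
    latitude = rep_len(latitude, n),
    longitude = rep_len(longitude, n),
    n_killed = rep_len(n_killed, n),
    firearm = rep_len(firearm, n),
    shooter_suicide = rep_len(shooter_suicide, n),
    stringsAsFactors = FALSE), label = label)
}

write_catalog_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

# constant-rate Poisson series (no contagion), reproducible
null_series <- function(n_days, rate, seed) {
  set.seed(seed)
  selfexcite:::series_from_counts(rpois(n_days, rate),
                                  as.Date("2006-01-01"))
}

# catalog with planted space-time clusters: groups of events within a few
# days and a small jitter around a common site, sites far apart
clustered_catalog <- function(n_clusters = 8, per_cluster = 5, seed = 4) {
  set.seed(seed)
  base_days <- cumsum(c(1, rep(200, n_clusters - 1)))
  lat0 <- runif(n_clusters, 28, 46)
  lon0 <- runif(n_clusters, -120, -75)
  rows <- do.call(rbind, lapply(seq_len(n_clusters), function(k) {
    data.frame(
      date = as.Date("2006-01-01") + base_days[k] +
        sample(0:6, per_cluster, replace = TRUE),
      state = "XX",
      latitude = lat0[k] + rnorm(per_cluster, 0, 0.2),
      longitude = lon0[k] + rnorm(per_cluster, 0, 0.2),
      n_killed = 4L, firearm = TRUE, shooter_suicide = FALSE,
      stringsAsFactors = FALSE)
  }))
  as_event_catalog(rows, label = "clustered")
}
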