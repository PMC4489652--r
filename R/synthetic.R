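#' Specification for the synthetic catalog generator
#'
#' Describes a synthetic daily event process with the statistical structure
#' the contagion analysis assumes: a baseline daily rate (optionally
#' modulated by day-of-week weights and an annual sinusoid), exponential
#' self-excitation with branching ratio \code{N_secondary} and duration
#' \code{T_excite}, state assignment proportional to population (optionally
#' tilted by a covariate-linked multiplier), state-centroid coordinates
#' with Gaussian jitter, shifted-geometric severities with a minimum
#' threshold, and Bernoulli firearm / shooter-suicide flags.
#'
#' Defaults mirror the regime of curated US mass-killing catalogs: a
#' baseline of 0.08 events/day with branching ratio 0.3 and 13-day
#' contagion (stationary mean 0.114/day, one event per ~8.7 days) over
#' 3000 days; 76\% firearm involvement; minimum 4 victims with
#' geometric-tailed severity.
#'
#' @param n_days span in days.
#' @param N0 baseline events/day.
#' @param N_secondary branching ratio (< 1 for a sub-critical process).
#' @param T_excite mean contagion duration, days.
#' @param weekday_weights optional 7 multipliers, mean 1.
#' @param seasonal_amplitude relative amplitude of an annual sinusoid in
#'   the baseline (0 = none; 0.3 means +-30\%).
#' @param state_table data.frame with \code{state}, \code{population},
#'   \code{latitude}, \code{longitude} and optional \code{multiplier};
#'   default: packaged approximate US state centroid/population table.
#' @param severity list \code{min} (threshold) and \code{p_geom}
#'   (geometric success probability for the excess above the threshold).
#' @param flag_probs named vector: probabilities for \code{firearm} and
#'   \code{shooter_suicide}.
#' @param jitter_sd coordinate jitter standard deviation, degrees.
#' @param origin calendar day of day 0.
#' @param seed integer seed.
#' @return a \code{generator_spec} list.
#' @export
generator_spec <- function(n_days = 3000, N0 = 0.08, N_secondary = 0.3,
                           T_excite = 13, weekday_weights = NULL,
                           seasonal_amplitude = 0, state_table = NULL,
                           severity = list(min = 4, p_geom = 0.5),
                           flag_probs = c(firearm = 0.76,
                                          shooter_suicide = 0.3),
                           jitter_sd = 0.5,
                           origin = as.Date("2006-01-01"), seed = 1) {
  if (N0 < 0 || N_secondary < 0 || T_excite <= 0)
    stop("rates must be non-negative and T_excite positive")
  if (!is.null(weekday_weights)) {
    stopifnot(length(weekday_weights) == 7, all(weekday_weights >= 0))
    weekday_weights <- weekday_weights / mean(weekday_weights)
  }
  if (is.null(state_table)) state_table <- state_centroids()
  structure(list(n_days = n_days, N0 = N0, N_secondary = N_secondary,
                 T_excite = T_excite, weekday_weights = weekday_weights,
                 seasonal_amplitude = seasonal_amplitude,
                 state_table = state_table, severity = severity,
                 flag_probs = flag_probs, jitter_sd = jitter_sd,
                 origin = as.Date(origin), seed = seed),
            class = "generator_spec")
}

#' Approximate US state centroid and population table
#'
#' Packaged synthetic fixture: approximate geographic centroids and
#' early-2010s census-scale populations for the 50 states, used only to
#' give generated catalogs realistic spatial structure.  Not a measurement
#' data set.
#'
#' @return data.frame: \code{state}, \code{latitude}, \code{longitude},
#'   \code{population}.
#' @export
state_centroids <- function() {
  path <- system.file("extdata", "state_centroids.csv",
                      package = "selfexcite")
  read.csv(path, stringsAsFactors = FALSE)
}

generator_base_mu <- function(spec) {
  days <- seq(spec$origin, by = "day", length.out = spec$n_days)
  mu <- rep(spec$N0, spec$n_days)
  if (spec$seasonal_amplitude != 0) {
    doy <- as.POSIXlt(days)$yday
    mu <- mu * (1 + spec$seasonal_amplitude * cos(2 * pi * doy / 365.25))
  }
  if (!is.null(spec$weekday_weights)) {
    wd <- as.POSIXlt(days)$wday + 1L
    mu <- mu * spec$weekday_weights[wd]
  }
  pmax(mu, 0)
}

#' Simulate a daily event series from a generator specification
#'
#' Sequential day loop: \code{counts(t) ~ Poisson(N_exp(t))} where
#' \eqn{N^{exp}} combines the specified baseline with self-excitation from
#' the already-generated history (only days before \eqn{t} excite
#' \eqn{t}).  Reproducible given \code{spec$seed}.
#'
#' @param spec a \code{\link{generator_spec}}.
#' @return a \code{daily_series}.
#' @export
simulate_series <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  if (spec$N_secondary >= 1)
    warning("N_secondary >= 1: super-critical process; ",
            "counts may grow without bound over long spans")
  set.seed(spec$seed)
  counts <- cpp_sim_hawkes(generator_base_mu(spec), spec$N_secondary,
                           spec$T_excite)
  series_from_counts(counts, spec$origin)
}

#' Attach incident attributes to a simulated series
#'
#' Expands a daily series to an event catalog: each event gets a state
#' (sampled proportional to population times the optional rate
#' multiplier), coordinates (state centroid plus Gaussian jitter),
#' a severity \code{n_killed} (severity minimum plus a geometric excess)
#' and Bernoulli firearm / shooter-suicide flags.
#'
#' @param series a \code{daily_series}.
#' @param spec the \code{\link{generator_spec}} used to generate it.
#' @return an \code{event_catalog}.
#' @export
attach_attributes <- function(series, spec) {
  stopifnot(inherits(series, "daily_series"),
            inherits(spec, "generator_spec"))
  st <- spec$state_table
  mult <- if ("multiplier" %in% names(st)) st$multiplier else 1
  w <- st$population * mult
  if (any(w < 0) || sum(w) <= 0)
    stop("state probabilities not normalizable")
  dates <- series_event_dates(series)
  m <- length(dates)
  if (m == 0) {
    return(as_event_catalog(
      data.frame(date = as.Date(character()), state = character(),
                 latitude = numeric(), longitude = numeric(),
                 n_killed = integer(), firearm = logical(),
                 shooter_suicide = logical()),
      label = "synthetic"))
  }
  idx <- sample.int(nrow(st), m, replace = TRUE, prob = w / sum(w))
  df <- data.frame(
    date = dates,
    state = st$state[idx],
    latitude = pmin(90, pmax(-90,
      st$latitude[idx] + rnorm(m, 0, spec$jitter_sd))),
    longitude = pmin(180, pmax(-180,
      st$longitude[idx] + rnorm(m, 0, spec$jitter_sd))),
    n_killed = spec$severity$min + rgeom(m, spec$severity$p_geom),
    firearm = runif(m) < spec$flag_probs[["firearm"]],
    shooter_suicide = runif(m) < spec$flag_probs[["shooter_suicide"]],
    stringsAsFactors = FALSE)
  as_event_catalog(df, label = "synthetic")
}

#' Simulate a full synthetic event catalog
#'
#' Convenience wrapper: \code{\link{simulate_series}} then
#' \code{\link{attach_attributes}}.  The generated \code{daily_series} is
#' attached as attribute \code{"series"}.
#'
#' @param spec a \code{\link{generator_spec}}.
#' @return an \code{event_catalog}.
#' @export
simulate_catalog <- function(spec) {
  series <- simulate_series(spec)
  cat <- attach_attributes(series, spec)
  attr(cat, "series") <- series
  cat
}

#' Simulate a series from the fitted null (no-contagion) model
#'
#' Independent Poisson draws from the fitted null baseline over the fitted
#' span — the bootstrap engine behind \code{\link{lrt_contagion}}.
#'
#' @param fit a \code{\link{fit_contagion}} result.
#' @param seed optional integer seed.
#' @return a \code{daily_series}.
#' @export
simulate_null_from_fit <- function(fit, seed = NULL) {
  stopifnot(inherits(fit, "contagion_fit"))
  if (!is.null(seed)) set.seed(seed)
  counts <- rpois(length(fit$null_mu), fit$null_mu)
  series_from_counts(counts, fit$series$origin)
}
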