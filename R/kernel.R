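#' Excitation probability of the discrete-day contagion kernel
#'
#' Probability that the contagion of an event \code{delta_days} days in the
#' past manifests during the 24 hours of the target day, obtained by
#' integrating an exponential contagion density with mean \code{T_excite}
#' over that day:
#' \deqn{P(\Delta) = e^{-(\Delta-1)/T} - e^{-\Delta/T}.}
#' The kernel telescopes: summed over \eqn{\Delta = 1..K} it equals
#' \eqn{1 - e^{-K/T}}, so the total excitation mass of one event is 1.
#' Same-day excitation (\eqn{\Delta = 0}) is undefined — the integration
#' window would be degenerate — so events on the same day do not excite
#' each other.
#'
#' @param delta_days integer day lag(s), all \eqn{\ge 1}.
#' @param T_excite mean contagion duration in days, \eqn{> 0}.
#' @return vector of probabilities in (0, 1), strictly decreasing in the lag.
#' @examples
#' excitation_probability(1, 13.2)      # 1 - exp(-1/13.2)
#' sum(excitation_probability(1:1000, 13.2))  # ~ 1
#' @export
excitation_probability <- function(delta_days, T_excite) {
  if (!is.numeric(T_excite) || length(T_excite) != 1 || T_excite <= 0)
    stop("T_excite must be a single positive number")
  if (any(delta_days < 1) || any(delta_days != round(delta_days)))
    stop("delta_days must be integer >= 1; same-day excitation is undefined")
  exp(-(delta_days - 1) / T_excite) - exp(-delta_days / T_excite)
}

#' Baseline model specification
#'
#' The baseline \eqn{N_0(t)} is the expected daily event count absent
#' contagion.  Three forms are supported: \code{constant} (one fitted rate),
#' \code{linear} (rate with a secular slope, two fitted parameters), and
#' \code{running_mean} (a non-parametric kernel-weighted running mean of the
#' observed daily counts; only a global scale is fitted).  Any form can be
#' modulated by day-of-week and month-of-year weights, estimated from
#' exposure-adjusted empirical frequencies and normalised to average 1 so
#' they redistribute rather than change the mean rate; they are frozen
#' during likelihood maximisation.
#'
#' @param form one of \code{"constant"}, \code{"linear"},
#'   \code{"running_mean"}.
#' @param bandwidth running-mean kernel scale in days (Gaussian standard
#'   deviation, or half-width for the boxcar); default 365, wide enough to
#'   track secular trend without absorbing excitation on the ~13-day scale.
#' @param kernel \code{"gaussian"} (default) or \code{"boxcar"}.
#' @param use_weekday_weights,use_month_weights logical; estimate and apply
#'   calendar modulation weights.
#' @return a \code{baseline_spec} list.
#' @export
baseline_spec <- function(form = c("constant", "running_mean", "linear"),
                          bandwidth = 365, kernel = c("gaussian", "boxcar"),
                          use_weekday_weights = FALSE,
                          use_month_weights = FALSE) {
  form <- match.arg(form)
  kernel <- match.arg(kernel)
  if (bandwidth <= 0) stop("bandwidth must be positive")
  structure(list(form = form, bandwidth = bandwidth, kernel = kernel,
                 use_weekday_weights = use_weekday_weights,
                 use_month_weights = use_month_weights),
            class = "baseline_spec")
}

#' Estimate calendar modulation weights from a daily series
#'
#' Empirical event frequency per weekday (or month) divided by its exposure
#' (number of such days in the span), normalised to mean 1.
#'
#' @param series a \code{daily_series}.
#' @param by \code{"weekday"} or \code{"month"}.
#' @return numeric vector of 7 or 12 multipliers with mean 1.
#' @export
calendar_weights <- function(series, by = c("weekday", "month")) {
  by <- match.arg(by)
  group <- if (by == "weekday") series$weekday else series$month
  levels <- if (by == "weekday") 1:7 else 1:12
  obs <- vapply(levels, function(l) sum(series$counts[group == l]), 0)
  exposure <- vapply(levels, function(l) sum(group == l), 0)
  if (any(exposure == 0)) stop("span does not cover every ", by)
  w <- (obs / exposure) / (sum(obs) / sum(exposure))
  w / mean(w)
}

#' Kernel-weighted running-mean baseline
#'
#' Non-parametric estimate of the baseline daily rate: a kernel-weighted
#' mean of the observed daily counts, renormalised at the series edges
#' (the kernel mass falling outside the span is dropped from the
#' denominator), optionally modulated by weekday/month weights.  With flat
#' weights and constant counts \code{c} the result is exactly \code{c}
#' everywhere, and the unweighted running mean approximately conserves the
#' total event count over the span.
#'
#' @param series a \code{daily_series}.
#' @param bandwidth kernel scale in days; should be much larger than the
#'   excitation time scale (a warning is issued below 10x a nominal 13-day
#'   scale).
#' @param kernel \code{"gaussian"} (sd = bandwidth) or \code{"boxcar"}
#'   (full width \code{bandwidth}, i.e. the window mean).
#' @param weekday_weights,month_weights optional multiplier vectors
#'   (length 7 / 12, mean 1).
#' @return numeric vector: baseline rate per day of the span.
#' @export
baseline_running_mean <- function(series, bandwidth = 365,
                                  kernel = c("gaussian", "boxcar"),
                                  weekday_weights = NULL,
                                  month_weights = NULL) {
  stopifnot(inherits(series, "daily_series"))
  kernel <- match.arg(kernel)
  if (bandwidth <= 0) stop("bandwidth must be positive")
  if (bandwidth < 130)
    warning("bandwidth < 10x the ~13-day excitation scale; ",
            "the baseline may absorb contagion structure")
  counts <- as.numeric(series$counts)
  n <- length(counts)
  if (n == 0) stop("series is empty")
  if (kernel == "gaussian") {
    half <- min(n - 1, ceiling(4 * bandwidth))
    k <- exp(-0.5 * ((-half:half) / bandwidth)^2)
  } else {
    half <- min(n - 1, max(0L, floor((bandwidth - 1) / 2)))
    k <- rep(1, 2 * half + 1)
  }
  # FFT convolution; dividing by the convolved all-ones vector renormalises
  # the kernel mass lost off the series edges
  num <- conv_same(counts, k, half)
  den <- conv_same(rep(1, n), k, half)
  n0 <- num / den
  # clip convolution round-off: counts are non-negative, so is the mean
  n0[n0 < 0] <- 0
  apply_calendar_weights(n0, series, weekday_weights, month_weights)
}

# centred ("same") convolution of x with a symmetric kernel of half-width h
conv_same <- function(x, k, h) {
  full <- stats::convolve(x, rev(k), type = "open")
  full[(h + 1):(h + length(x))]
}

apply_calendar_weights <- function(n0, series, weekday_weights = NULL,
                                   month_weights = NULL) {
  if (!is.null(weekday_weights)) {
    stopifnot(length(weekday_weights) == 7)
    n0 <- n0 * weekday_weights[series$weekday]
  }
  if (!is.null(month_weights)) {
    stopifnot(length(month_weights) == 12)
    n0 <- n0 * month_weights[series$month]
  }
  n0
}

#' Contagion model parameters
#'
#' Bundles the branching ratio, contagion duration and an evaluated
#' baseline into the model state used by \code{\link{expected_events}} and
#' \code{\link{log_likelihood}}.
#'
#' @param N_secondary branching ratio: expected secondary events incited by
#'   one event; \eqn{\ge 0}.
#' @param T_excite mean contagion duration in days; \eqn{> 0}.
#' @param baseline baseline daily rate: a scalar (constant) or a vector
#'   over the span it will be evaluated on; all values \eqn{\ge 0}.
#' @return a \code{contagion_params} list.
#' @export
contagion_params <- function(N_secondary, T_excite, baseline) {
  if (N_secondary < 0) stop("N_secondary must be >= 0")
  if (T_excite <= 0) stop("T_excite must be > 0")
  if (any(baseline < 0)) stop("baseline must be >= 0 everywhere")
  structure(list(N_secondary = N_secondary, T_excite = T_excite,
                 baseline = baseline),
            class = "contagion_params")
}

#' Expected number of events on a day given the prior history
#'
#' The conditional mean daily count: baseline plus the branching ratio
#' times the summed excitation kernel over all prior events,
#' \eqn{N^{exp}(t_n) = N_0(t_n) + N_{sec} \sum_{t_i < t_n} P(t_n - t_i)}.
#' Linear in the history and equal to the baseline when
#' \code{N_secondary = 0} or the history is empty.
#'
#' @param t_n target day (integer index).
#' @param prior_event_days integer days of prior events, one entry per
#'   event, all strictly before \code{t_n}.
#' @param params a \code{\link{contagion_params}} whose baseline is either
#'   scalar or indexable at \code{t_n + 1} (0-based day over the span).
#' @return expected count on day \code{t_n}.
#' @export
expected_events <- function(t_n, prior_event_days, params) {
  stopifnot(inherits(params, "contagion_params"))
  if (length(prior_event_days) > 0 && any(prior_event_days >= t_n))
    stop("all prior event days must be strictly before t_n")
  n0 <- if (length(params$baseline) == 1) params$baseline
        else params$baseline[t_n + 1]
  excite <- if (length(prior_event_days) == 0) 0 else
    sum(excitation_probability(t_n - prior_event_days, params$T_excite))
  n0 + params$N_secondary * excite
}

#' Per-day Poisson log-likelihood of a contagion model
#'
#' Daily counts are modelled as Poisson with conditional mean
#' \eqn{N^{exp}(t)} given the observed history before \eqn{t}:
#' \deqn{\ell = \sum_t [\, c_t \log N^{exp}(t) - N^{exp}(t) - \log c_t! \,].}
#' A day with events but zero conditional mean yields \code{-Inf} (not an
#' error), so degenerate baselines are comparable rather than fatal.
#'
#' @param series a \code{daily_series}.
#' @param params a \code{\link{contagion_params}}; a scalar baseline is
#'   recycled over the span.
#' @return the log-likelihood (possibly \code{-Inf}).
#' @export
log_likelihood <- function(series, params) {
  stopifnot(inherits(series, "daily_series"),
            inherits(params, "contagion_params"))
  counts <- as.numeric(series$counts)
  n <- length(counts)
  base <- params$baseline
  if (length(base) == 1) base <- rep(base, n)
  if (length(base) != n) stop("baseline length does not match series span")
  g <- cpp_excite_sum(counts, params$T_excite)
  mu <- base + params$N_secondary * g
  cpp_poisson_loglik(counts, mu)
}
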