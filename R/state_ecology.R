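#' National per-person incident rate
#'
#' Total incidents in the catalog divided by total population over the
#' states covered — the reference rate \eqn{\mu} for the state-incidence
#' statistic.
#'
#' @param catalog an \code{event_catalog} with a \code{state} column.
#' @param populations data.frame with \code{state} and \code{population},
#'   covering every state present in the catalog.
#' @return \eqn{\mu}, incidents per person over the catalog span.
#' @export
national_rate <- function(catalog, populations) {
  stopifnot(inherits(catalog, "event_catalog"))
  stopifnot(all(c("state", "population") %in% names(populations)))
  total_pop <- sum(populations$population)
  if (total_pop <= 0) stop("total population must be positive")
  if (nrow(catalog) == 0) return(0)
  missing <- setdiff(unique(catalog$state), populations$state)
  if (length(missing) > 0)
    stop("states missing from population table: ",
         paste(missing, collapse = ", "))
  nrow(catalog) / total_pop
}

#' State-incidence significance via the binomial CDF
#'
#' \deqn{F(k_i \mid N_i, \mu) = \sum_{j=0}^{k_i} \binom{N_i}{j}
#'   \mu^j (1-\mu)^{N_i - j},}
#' the probability of at most \eqn{k_i} incidents in a population
#' \eqn{N_i} at the national rate \eqn{\mu}.  Values near 0 (1) flag
#' states with unusually low (high) incidence.  Computed through the
#' regularised-incomplete-beta form of the binomial CDF, which is
#' numerically stable for \eqn{N_i \sim 10^7} and \eqn{\mu \sim 10^{-7}}
#' and agrees with direct summation on small inputs.
#'
#' @param k_i observed incident count(s), \eqn{0 \le k_i \le N_i}.
#' @param N_i population(s).
#' @param mu national per-person rate, in \eqn{[0, 1]}.
#' @return \eqn{F} value(s) in \eqn{[0, 1]}.
#' @export
binomial_cdf_significance <- function(k_i, N_i, mu) {
  if (any(mu < 0) || any(mu > 1)) stop("mu must be in [0, 1]")
  if (any(k_i < 0) || any(k_i > N_i)) stop("need 0 <= k_i <= N_i")
  pbinom(k_i, N_i, mu)
}

#' Per-state incidence table
#'
#' Tallies incidents per state and computes each state's population,
#' binomial-CDF significance \eqn{F} under the national rate, and
#' per-capita rate.  States in the population table with no incidents get
#' \eqn{k_i = 0}.
#'
#' @param catalog an \code{event_catalog} with a \code{state} column.
#' @param populations data.frame with \code{state} and \code{population}.
#' @return a data.frame: \code{state}, \code{k}, \code{population},
#'   \code{F}, \code{per_capita_rate}, with the national rate as attribute
#'   \code{"mu"}.
#' @export
state_incidence <- function(catalog, populations) {
  mu <- national_rate(catalog, populations)
  k <- vapply(populations$state,
              function(s) sum(catalog$state == s), 0L)
  out <- data.frame(
    state = populations$state,
    k = k,
    population = populations$population,
    F = binomial_cdf_significance(k, populations$population, mu),
    per_capita_rate = k / populations$population,
    stringsAsFactors = FALSE)
  attr(out, "mu") <- mu
  out
}

#' Firearm-ownership proxy: state fraction of suicides by firearm
#'
#' The fraction of all suicides within each state that involved firearms,
#' a validated proxy for firearm-ownership prevalence.  Rows are pooled by
#' state (sums of counts, then one ratio), so multi-year tables are pooled
#' rather than averaged as ratios.
#'
#' @param suicide_table data.frame with \code{state},
#'   \code{suicides_total}, \code{suicides_firearm}; possibly several rows
#'   per state (e.g. years).
#' @return data.frame: \code{state}, \code{firearm_proxy} in \eqn{[0, 1]}.
#' @export
firearm_proxy <- function(suicide_table) {
  stopifnot(all(c("state", "suicides_total", "suicides_firearm") %in%
                  names(suicide_table)))
  tot <- tapply(suicide_table$suicides_total, suicide_table$state, sum)
  fir <- tapply(suicide_table$suicides_firearm, suicide_table$state, sum)
  if (any(tot <= 0)) stop("suicides_total must be positive for every state")
  if (any(fir > tot)) stop("data error: firearm suicides exceed total")
  data.frame(state = names(tot),
             firearm_proxy = as.numeric(fir / tot),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Critical correlation magnitude for a two-sided test
#'
#' The smallest \eqn{|r|} significant at level \code{alpha} for a Pearson
#' correlation on \code{n} pairs, from inverting the t statistic
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}}.  For \eqn{n = 50} at
#' \eqn{\alpha = 0.05} this is 0.2787, i.e. 0.28 to two decimals.
#'
#' @param n number of pairs.
#' @param alpha two-sided significance level.
#' @return the critical \eqn{|r|}.
#' @export
critical_correlation <- function(n, alpha = 0.05) {
  if (n < 3) stop("need n >= 3")
  tc <- qt(1 - alpha / 2, df = n - 2)
  tc / sqrt(tc^2 + n - 2)
}

#' Correlation of state incidence with an exogenous covariate
#'
#' Correlates the per-state incidence statistic (the binomial-CDF value
#' \eqn{F} by default, or the per-capita rate) with a covariate such as
#' the firearm-ownership proxy, mental-illness prevalence, or legislation
#' rank.  Optionally adjusts both variables for another covariate by
#' simple linear regression and correlates the residuals (a partial
#' correlation), e.g. to ask whether an association survives accounting
#' for firearm ownership.
#'
#' @param incidence result of \code{\link{state_incidence}}.
#' @param covariates data.frame keyed by \code{state} containing
#'   \code{covariate} (and \code{adjust_for} if used).
#' @param covariate name of the covariate column.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param incidence_measure \code{"F"} (default) or
#'   \code{"per_capita_rate"}.
#' @param adjust_for optional name of a covariate column to partial out.
#' @return list: \code{rho}, \code{p_value} (two-sided), \code{n},
#'   \code{critical_r} (two-sided Pearson critical value at 0.05 for this
#'   \code{n}), \code{covariate}, \code{adjusted_for}.
#' @export
incidence_covariate_correlation <- function(incidence, covariates,
                                            covariate,
                                            method = c("pearson",
                                                       "spearman"),
                                            incidence_measure = c(
                                              "F", "per_capita_rate"),
                                            adjust_for = NULL) {
  method <- match.arg(method)
  incidence_measure <- match.arg(incidence_measure)
  if (!covariate %in% names(covariates))
    stop("covariate column not found: ", covariate)
  m <- merge(incidence, covariates, by = "state")
  m <- m[!is.na(m[[covariate]]) & !is.na(m[[incidence_measure]]), ]
  n <- nrow(m)
  if (n < 4) stop("need at least 4 states with both values")
  x <- m[[incidence_measure]]
  y <- m[[covariate]]
  if (!is.null(adjust_for)) {
    if (!adjust_for %in% names(m))
      stop("adjustment column not found: ", adjust_for)
    z <- m[[adjust_for]]
    x <- resid(lm(x ~ z))
    y <- resid(lm(y ~ z))
  }
  ct <- cor.test(x, y, method = method, exact = FALSE)
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
       critical_r = critical_correlation(n, 0.05),
       covariate = covariate, adjusted_for = adjust_for,
       incidence_measure = incidence_measure)
}
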