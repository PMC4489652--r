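#' Fit the self-excitation contagion model by maximum likelihood
#'
#' Maximises the per-day Poisson log-likelihood of the daily count series
#' under the contagion model: conditional mean
#' \eqn{N^{exp}(t) = N_0(t) + N_{sec} \sum_{t_i<t} P(t-t_i; T)} with an
#' exponential-decay excitation kernel, given the observed history.  The
#' fit profiles the likelihood over a grid of contagion-duration starting
#' values (the likelihood can be multimodal in \eqn{T}), maximising the
#' baseline scale and branching ratio at each by a concave Newton solver,
#' then refines the best duration by golden-section search.  The no-contagion
#' null model (\eqn{N_{sec} = 0}) is fitted alongside.
#'
#' @param series a \code{daily_series} (see \code{\link{to_daily_series}}).
#' @param baseline a \code{\link{baseline_spec}}, or a form name
#'   (\code{"constant"}, \code{"running_mean"}, \code{"linear"}).
#' @param s_max upper bound for the branching ratio \code{N_secondary}
#'   (default 5; estimates at the bound are flagged).
#' @param T_bounds search bounds for \code{T_excite} in days
#'   (default \code{c(0.5, 365)}).
#' @param T_starts grid of \code{T_excite} starting values; the default
#'   14-point log-spaced grid includes \code{c(2, 7, 14, 30, 90)}.
#' @param refine logical; refine \code{T_excite} between the best grid
#'   neighbours (default TRUE).
#' @return a \code{contagion_fit} object with methods \code{print},
#'   \code{summary}, \code{coef}, \code{logLik}, \code{confint} (profile
#'   likelihood), \code{predict}, \code{residuals}, \code{simulate},
#'   \code{plot}.  Key fields: \code{coefficients} (\code{N_secondary},
#'   \code{T_excite}), \code{logLik_full}, \code{logLik_null}, \code{mu}
#'   (fitted conditional mean per day), \code{null_mu}, \code{convergence}.
#' @seealso \code{\link{lrt_contagion}} for the calibrated contagion test.
#' @examples
#' spec <- generator_spec(n_days = 1500, seed = 7)
#' fit <- fit_contagion(simulate_series(spec))
#' coef(fit)
#' @export
fit_contagion <- function(series, baseline = baseline_spec("constant"),
                          s_max = 5, T_bounds = c(0.5, 365),
                          T_starts = NULL, refine = TRUE) {
  stopifnot(inherits(series, "daily_series"))
  if (is.character(baseline)) baseline <- baseline_spec(baseline)
  stopifnot(inherits(baseline, "baseline_spec"))
  counts <- as.numeric(series$counts)
  n <- length(counts)
  n_events <- sum(counts)
  if (n_events < 10) stop("need at least 10 events to fit")
  if (n_events < 30) warning("fewer than 30 events; estimates will be weak")
  if (is.null(T_starts)) T_starts <- default_T_starts(T_bounds)

  wk <- if (baseline$use_weekday_weights) calendar_weights(series, "weekday")
  mo <- if (baseline$use_month_weights) calendar_weights(series, "month")

  lg_const <- -sum(lgamma(counts + 1))

  if (baseline$form == "linear") {
    x <- time_covariate(n)
    flat <- apply_calendar_weights(rep(1, n), series, wk, mo)
    null_fit <- fit_null_linear(counts, x, flat)
    full_fit <- fit_full_linear(counts, x, flat, T_starts, s_max,
                                T_bounds, refine)
    shape <- NULL
  } else {
    shape <- if (baseline$form == "running_mean") {
      baseline_running_mean(series, baseline$bandwidth, baseline$kernel,
                            wk, mo)
    } else {
      apply_calendar_weights(rep(1, n), series, wk, mo)
    }
    null_fit <- fit_null_scale(counts, shape)
    full_fit <- fit_full_profile(counts, shape, T_starts, s_max,
                                 T_bounds, refine)
  }

  # nested models: the null is a boundary point of the full model's space
  core_full <- max(full_fit$core, null_fit$core)
  boundary <- c(N_secondary_zero = full_fit$s < 1e-8,
                N_secondary_max = full_fit$s >= s_max - 1e-8,
                T_low = full_fit$T <= T_bounds[1] + 1e-8,
                T_high = full_fit$T >= T_bounds[2] - 1e-8)

  structure(list(
    call = match.call(),
    series = series,
    baseline = baseline,
    baseline_shape = shape,
    weekday_weights = wk, month_weights = mo,
    coefficients = c(N_secondary = full_fit$s, T_excite = full_fit$T),
    baseline_coef = full_fit$base_coef,
    null_coef = null_fit$base_coef,
    mu = full_fit$mu,
    null_mu = null_fit$mu,
    core_full = core_full, core_null = null_fit$core,
    lg_const = lg_const,
    logLik_full = core_full + lg_const,
    logLik_null = null_fit$core + lg_const,
    profile = full_fit$profile,
    convergence = list(converged = full_fit$converged, boundary = boundary),
    n_events = n_events,
    s_max = s_max, T_bounds = T_bounds, T_starts = T_starts,
    refine = refine
  ), class = "contagion_fit")
}

default_T_starts <- function(T_bounds = c(0.5, 365)) {
  g <- sort(unique(c(2, 7, 14, 30, 90,
                     exp(seq(log(T_bounds[1]), log(T_bounds[2]),
                             length.out = 9)))))
  g[g >= T_bounds[1] & g <= T_bounds[2]]
}

time_covariate <- function(n) (seq_len(n) - (n + 1) / 2) / n

poisson_core <- function(counts, mu) {
  pos <- counts > 0
  if (any(mu[pos] <= 0)) return(-Inf)
  sum(counts[pos] * log(mu[pos])) - sum(mu)
}

# null model, scale-only baseline: closed-form MLE
fit_null_scale <- function(counts, shape) {
  b <- sum(counts) / sum(shape)
  mu <- b * shape
  list(base_coef = c(scale = b), mu = mu, core = poisson_core(counts, mu))
}

# full model, scale baseline: warm-started profile over the T grid plus
# golden-section refine between the best point's neighbours (in C++; the
# bootstrap engine runs the identical algorithm)
fit_full_profile <- function(counts, shape, T_starts, s_max, T_bounds,
                             refine, s_init = 0.1, tol_log = 0.01,
                             diagnostics = TRUE) {
  b_init <- sum(counts) / sum(shape)
  f <- cpp_fit_full(counts, shape, T_starts, s_max, b_init, s_init,
                    tol_log, refine)
  pm <- if (diagnostics)
    cpp_profile_T(counts, shape, T_starts, s_max, b_init, s_init)
  g <- cpp_excite_sum(counts, f[1])
  list(s = f[3], T = f[1], base_coef = c(scale = f[2]),
       mu = f[2] * shape + f[3] * g,
       core = f[4], converged = f[5] == 1, profile = pm)
}

# linear-trend baseline: N0(t) = (a0 + a1 * x_t) * flat_t, fitted by
# Nelder-Mead (feasibility enforced by -Inf penalty); used rarely, so the
# general-purpose optimiser is acceptable here
linear_mu <- function(par, x, flat, g = NULL, s = 0) {
  mu <- (par[1] + par[2] * x) * flat
  if (!is.null(g)) mu <- mu + s * g
  mu
}

fit_null_linear <- function(counts, x, flat) {
  obj <- function(par) -poisson_core(counts, linear_mu(par, x, flat))
  start <- c(mean(counts), 0)
  opt <- optim(start, obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  mu <- linear_mu(opt$par, x, flat)
  list(base_coef = c(intercept = opt$par[1], slope = opt$par[2]),
       mu = mu, core = -opt$value)
}

fit_full_linear <- function(counts, x, flat, T_starts, s_max, T_bounds,
                            refine) {
  fit_at_T <- function(Tv) {
    g <- cpp_excite_sum(counts, Tv)
    obj <- function(par) {
      s <- min(max(par[3], 0), s_max)
      -poisson_core(counts, linear_mu(par[1:2], x, flat, g, s))
    }
    opt <- optim(c(mean(counts), 0, 0.1), obj, method = "Nelder-Mead",
                 control = list(maxit = 4000, reltol = 1e-10))
    list(par = c(opt$par[1:2], min(max(opt$par[3], 0), s_max)),
         core = -opt$value, conv = opt$convergence == 0)
  }
  fits <- lapply(T_starts, fit_at_T)
  cores <- vapply(fits, `[[`, 0, "core")
  i <- which.max(cores)
  best <- fits[[i]]; Tbest <- T_starts[i]
  if (refine && best$par[3] > 1e-8) {
    lo <- T_starts[max(1L, i - 1L)]
    hi <- T_starts[min(length(T_starts), i + 1L)]
    if (hi > lo) {
      opt <- optimize(function(lt) fit_at_T(exp(lt))$core,
                      lower = log(lo), upper = log(hi), maximum = TRUE,
                      tol = 1e-3)
      if (opt$objective > best$core) {
        Tbest <- exp(opt$maximum)
        best <- fit_at_T(Tbest)
      }
    }
  }
  g <- cpp_excite_sum(counts, Tbest)
  pm <- cbind(T_starts, NA, NA, cores, NA)
  list(s = best$par[3], T = Tbest,
       base_coef = c(intercept = best$par[1], slope = best$par[2]),
       mu = linear_mu(best$par[1:2], x, flat, g, best$par[3]),
       core = best$core, converged = best$conv, profile = pm)
}

#' @export
print.contagion_fit <- function(x, ...) {
  cat("Self-excitation contagion model fit\n")
  cat("  events:", x$n_events, "over", length(x$series$counts), "days;",
      "baseline:", x$baseline$form, "\n")
  cat(sprintf("  N_secondary = %.4f   T_excite = %.2f days\n",
              x$coefficients["N_secondary"], x$coefficients["T_excite"]))
  cat(sprintf("  logLik full = %.3f   null = %.3f\n",
              x$logLik_full, x$logLik_null))
  lam <- 2 * (x$core_full - x$core_null)
  cat(sprintf("  LRT statistic = %.3f (asymptotic chi-sq df=2 p = %.4g;\n",
              lam, pchisq(lam, 2, lower.tail = FALSE)))
  cat("   use lrt_contagion() for bootstrap calibration)\n")
  if (any(unlist(x$convergence$boundary)))
    cat("  note: estimate at parameter bound:",
        paste(names(which(x$convergence$boundary)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.contagion_fit <- function(object, ...) {
  c(object$coefficients, object$baseline_coef)
}

#' @export
logLik.contagion_fit <- function(object, ...) {
  df <- 2 + length(object$baseline_coef)
  structure(object$logLik_full, df = df,
            nobs = length(object$series$counts), class = "logLik")
}

#' @export
summary.contagion_fit <- function(object, ci = FALSE, level = 0.95, ...) {
  lam <- 2 * (object$core_full - object$core_null)
  out <- list(fit = object, lambda = lam,
              p_chi2 = pchisq(lam, 2, lower.tail = FALSE),
              mean_rate = object$n_events / length(object$series$counts),
              ci = if (ci) confint(object, level = level))
  class(out) <- "summary.contagion_fit"
  out
}

#' @export
print.summary.contagion_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  mean observed rate = %.4f events/day (one per %.1f days)\n",
              x$mean_rate, 1 / x$mean_rate))
  if (!is.null(x$ci)) {
    cat("  profile 95% CIs:\n")
    print(round(x$ci, 3))
  }
  invisible(x)
}

#' Profile-likelihood confidence intervals for a contagion fit
#'
#' Interval endpoints are where the profile log-likelihood (nuisance
#' parameters re-maximised at each value) drops \eqn{\chi^2_1(level)/2}
#' (1.92 for 95\%) below its maximum.  The lower endpoint of
#' \code{N_secondary} is clipped at 0; endpoints that hit the search
#' bounds are reported at the bound and flagged in attribute
#' \code{"at_bound"}.  Intervals are typically asymmetric.
#'
#' @param object a \code{contagion_fit}.
#' @param parm parameters to profile (\code{"N_secondary"},
#'   \code{"T_excite"}, or both).
#' @param level confidence level.
#' @param ... unused.
#' @return matrix with one row per parameter, columns \code{lower},
#'   \code{upper}.
#' @export
confint.contagion_fit <- function(object, parm = c("N_secondary",
                                                   "T_excite"),
                                  level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  drop <- qchisq(level, df = 1) / 2
  target <- object$core_full - drop
  out <- matrix(NA_real_, length(parm), 2,
                dimnames = list(parm, c("lower", "upper")))
  at_bound <- matrix(FALSE, length(parm), 2, dimnames = dimnames(out))
  for (p in parm) {
    ci <- profile_ci_one(object, p, target)
    out[p, ] <- ci$interval
    at_bound[p, ] <- ci$at_bound
  }
  attr(out, "at_bound") <- at_bound
  attr(out, "level") <- level
  out
}

profile_core_s <- function(object, s0) {
  counts <- as.numeric(object$series$counts)
  if (object$baseline$form == "linear") {
    n <- length(counts)
    x <- time_covariate(n)
    flat <- apply_calendar_weights(rep(1, n), object$series,
                                   object$weekday_weights,
                                   object$month_weights)
    fit_at_T <- function(Tv) {
      g <- cpp_excite_sum(counts, Tv)
      obj <- function(par) -poisson_core(counts,
                                         linear_mu(par, x, flat, g, s0))
      -optim(c(mean(counts), 0), obj, method = "Nelder-Mead",
             control = list(maxit = 2000, reltol = 1e-9))$value
    }
    return(max(vapply(object$T_starts, fit_at_T, 0)))
  }
  shape <- object$baseline_shape
  b_init <- sum(counts) / sum(shape)
  pm <- cpp_profile_T_fixed_s(counts, shape, object$T_starts, s0, b_init)
  i <- which.max(pm[, 3])
  best <- pm[i, 3]
  if (object$refine && s0 > 0) {
    lo <- object$T_starts[max(1L, i - 1L)]
    hi <- object$T_starts[min(length(object$T_starts), i + 1L)]
    if (hi > lo) {
      opt <- optimize(function(lt) {
        g <- cpp_excite_sum(counts, exp(lt))
        cpp_fit_b(counts, shape, s0 * g, b_init)[2]
      }, lower = log(lo), upper = log(hi), maximum = TRUE, tol = 1e-3)
      best <- max(best, opt$objective)
    }
  }
  best
}

profile_core_T <- function(object, T0) {
  counts <- as.numeric(object$series$counts)
  if (object$baseline$form == "linear") {
    n <- length(counts)
    x <- time_covariate(n)
    flat <- apply_calendar_weights(rep(1, n), object$series,
                                   object$weekday_weights,
                                   object$month_weights)
    g <- cpp_excite_sum(counts, T0)
    obj <- function(par) {
      s <- min(max(par[3], 0), object$s_max)
      -poisson_core(counts, linear_mu(par[1:2], x, flat, g, s))
    }
    return(-optim(c(mean(counts), 0, 0.1), obj, method = "Nelder-Mead",
                  control = list(maxit = 4000, reltol = 1e-9))$value)
  }
  shape <- object$baseline_shape
  b_init <- sum(counts) / sum(shape)
  cpp_fit_bs(counts, shape, cpp_excite_sum(counts, T0),
             object$s_max, b_init, 0.1)[3]
}

profile_ci_one <- function(object, parm, target) {
  if (parm == "N_secondary") {
    hat <- object$coefficients["N_secondary"]
    prof <- function(v) profile_core_s(object, v)
    lo_bound <- 0; hi_bound <- object$s_max
  } else {
    hat <- object$coefficients["T_excite"]
    prof <- function(v) profile_core_T(object, v)
    lo_bound <- object$T_bounds[1]; hi_bound <- object$T_bounds[2]
  }
  at_bound <- c(FALSE, FALSE)

  f <- function(v) prof(v) - target
  # lower endpoint
  if (f(lo_bound) >= 0) {
    lo <- lo_bound
    at_bound[1] <- parm == "T_excite"  # N_secondary lower clip at 0 is exact
  } else if (hat <= lo_bound + 1e-12) {
    lo <- lo_bound
  } else {
    lo <- uniroot(f, lower = lo_bound, upper = hat, tol = 1e-4)$root
  }
  # upper endpoint
  if (f(hi_bound) >= 0) {
    hi <- hi_bound
    at_bound[2] <- TRUE
  } else if (hat >= hi_bound - 1e-12) {
    hi <- hi_bound
    at_bound[2] <- TRUE
  } else {
    hi <- uniroot(f, lower = hat, upper = hi_bound, tol = 1e-4)$root
  }
  list(interval = c(lo, hi), at_bound = at_bound)
}

#' @export
predict.contagion_fit <- function(object,
                                  type = c("expected", "baseline",
                                           "excitation"), ...) {
  type <- match.arg(type)
  base <- object$mu - excitation_component(object)
  switch(type,
         expected = object$mu,
         baseline = base,
         excitation = excitation_component(object))
}

excitation_component <- function(object) {
  counts <- as.numeric(object$series$counts)
  g <- cpp_excite_sum(counts, object$coefficients["T_excite"])
  object$coefficients["N_secondary"] * g
}

#' @export
residuals.contagion_fit <- function(object,
                                    type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  r <- as.numeric(object$series$counts) - object$mu
  if (type == "pearson") {
    r <- ifelse(object$mu > 0, r / sqrt(object$mu), 0)
  }
  r
}

#' Simulate daily series from a fitted contagion model
#'
#' Draws new realisations of the fitted full model (fitted baseline plus
#' self-excitation from the simulated history) over the fitted span.
#'
#' @param object a \code{contagion_fit}.
#' @param nsim number of series.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of \code{daily_series}.
#' @export
simulate.contagion_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  base <- predict(object, type = "baseline")
  lapply(seq_len(nsim), function(i) {
    counts <- cpp_sim_hawkes(base, object$coefficients["N_secondary"],
                             object$coefficients["T_excite"])
    series_from_counts(counts, object$series$origin)
  })
}

series_from_counts <- function(counts, origin) {
  days <- seq(origin, by = "day", length.out = length(counts))
  structure(list(origin = origin, counts = as.integer(round(counts)),
                 weekday = as.POSIXlt(days)$wday + 1L,
                 month = as.POSIXlt(days)$mon + 1L),
            class = "daily_series")
}

#' @export
plot.contagion_fit <- function(x, ...) {
  n <- length(x$series$counts)
  days <- seq(x$series$origin, by = "day", length.out = n)
  plot(days, x$series$counts, type = "h", col = "grey60",
       xlab = "date", ylab = "events / day",
       main = "Observed counts and fitted conditional mean", ...)
  lines(days, x$mu, col = "red")
  lines(days, predict(x, "baseline"), col = "blue", lty = 2)
  legend("topleft", bty = "n", lty = c(1, 1, 2),
         col = c("grey60", "red", "blue"),
         legend = c("counts", "expected (full model)", "baseline"))
  invisible(x)
}
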