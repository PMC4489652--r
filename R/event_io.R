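#' Read and validate an event catalog
#'
#' Reads a CSV of incidents (one row per event), validates the schema,
#' parses dates, applies optional selection filters, and returns a
#' date-sorted catalog.  The canonical columns are \code{date},
#' \code{state}, \code{latitude}, \code{longitude}, \code{n_killed},
#' \code{n_shot}, \code{firearm}, \code{shooter_suicide}; files with other
#' headers can be adapted through \code{col_map}.  Only \code{date} is
#' mandatory — analyses that need the other columns check for them.
#'
#' @param path path to a CSV file with a header row.
#' @param filters named list of selection predicates applied in order:
#'   \code{min_killed}, \code{max_killed} (bounds on \code{n_killed}),
#'   \code{firearm}, \code{shooter_suicide} (logical equality).  A report of
#'   row counts before/after each filter is attached as attribute
#'   \code{"filter_report"}.
#' @param col_map optional named character vector mapping canonical names to
#'   the file's column names, e.g. \code{c(date = "Incident.Date")}.
#' @param date_format format string for \code{as.Date}; default ISO-8601.
#' @param label free-text label stored on the catalog.
#' @return an \code{event_catalog}: a data.frame sorted by date with
#'   attributes \code{label} and \code{filter_report}.
#' @seealso \code{\link{filter_catalog}}, \code{\link{to_daily_series}}
#' @export
read_catalog <- function(path, filters = list(), col_map = NULL,
                         date_format = "%Y-%m-%d", label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw))
        stop("schema error: mapped column '", src, "' (for '", canon,
             "') not present")
      names(raw)[names(raw) == src] <- canon
    }
  }
  if (!"date" %in% names(raw))
    stop("schema error: required column 'date' missing")

  if (nrow(raw) == 0) {
    cat0 <- as_event_catalog(raw[FALSE, , drop = FALSE], label = label)
    attr(cat0, "filter_report") <- data.frame(stage = "input", n = 0L,
                                              stringsAsFactors = FALSE)
    return(cat0)
  }

  dates <- as.Date(as.character(raw$date), format = date_format)
  bad <- which(is.na(dates))
  if (length(bad) > 0)
    stop("unparseable date in row(s): ", paste(bad, collapse = ", "))
  raw$date <- dates

  cat <- as_event_catalog(raw, label = label)
  filter_catalog(cat, filters)
}

#' Coerce a data.frame to a validated event catalog
#'
#' Validates field ranges (coordinates within bounds, non-negative victim
#' counts), coerces logical flags, and sorts by date.
#'
#' @param df data.frame with at least a \code{date} column of class Date.
#' @param label free-text label.
#' @return an \code{event_catalog}.
#' @export
as_event_catalog <- function(df, label = "catalog") {
  stopifnot(is.data.frame(df))
  if (!"date" %in% names(df)) stop("schema error: required column 'date' missing")
  if (nrow(df) > 0 && !inherits(df$date, "Date"))
    stop("date column must be of class Date")
  for (flag in c("firearm", "shooter_suicide")) {
    if (flag %in% names(df)) df[[flag]] <- parse_flag(df[[flag]], flag)
  }
  if ("n_killed" %in% names(df) && nrow(df) > 0) {
    bad <- which(!is.na(df$n_killed) & df$n_killed < 0)
    if (length(bad)) stop("negative n_killed in row(s): ",
                          paste(bad, collapse = ", "))
  }
  if ("latitude" %in% names(df) && nrow(df) > 0) {
    bad <- which(!is.na(df$latitude) & abs(df$latitude) > 90)
    if (length(bad)) stop("latitude out of [-90, 90] in row(s): ",
                          paste(bad, collapse = ", "))
  }
  if ("longitude" %in% names(df) && nrow(df) > 0) {
    bad <- which(!is.na(df$longitude) & abs(df$longitude) > 180)
    if (length(bad)) stop("longitude out of [-180, 180] in row(s): ",
                          paste(bad, collapse = ", "))
  }
  if (nrow(df) > 0) df <- df[order(df$date), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, label = label,
            class = c("event_catalog", "data.frame"))
}

parse_flag <- function(x, name) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0")] <- FALSE
  if (any(is.na(out) & !(x %in% c("", "na"))))
    stop("column '", name, "' contains values not interpretable as logical")
  out
}

#' Apply selection filters to a catalog
#'
#' Filters are predicates on catalog columns; applying the same filter
#' twice yields the same catalog (idempotence).  Rows with \code{NA} in a
#' filtered column are dropped by that filter.
#'
#' @param catalog an \code{event_catalog}.
#' @param filters named list; see \code{\link{read_catalog}}.
#' @return the filtered catalog, with an updated \code{"filter_report"}
#'   attribute recording row counts before/after each stage.
#' @export
filter_catalog <- function(catalog, filters = list()) {
  stopifnot(inherits(catalog, "event_catalog"))
  report <- attr(catalog, "filter_report")
  if (is.null(report))
    report <- data.frame(stage = "input", n = nrow(catalog),
                         stringsAsFactors = FALSE)
  lab <- attr(catalog, "label")
  df <- as.data.frame(catalog)
  for (key in names(filters)) {
    val <- filters[[key]]
    keep <- switch(key,
      min_killed = df$n_killed >= val,
      max_killed = df$n_killed <= val,
      firearm = df$firearm == val,
      shooter_suicide = df$shooter_suicide == val,
      stop("unknown filter: ", key))
    keep[is.na(keep)] <- FALSE
    df <- df[keep, , drop = FALSE]
    report <- rbind(report,
                    data.frame(stage = paste0(key, "=", val), n = nrow(df),
                               stringsAsFactors = FALSE))
  }
  out <- as_event_catalog(df, label = lab)
  attr(out, "filter_report") <- report
  out
}

#' @export
print.event_catalog <- function(x, ...) {
  n <- nrow(x)
  cat("Event catalog '", attr(x, "label"), "': ", n, " records", sep = "")
  if (n > 0)
    cat(", ", format(min(x$date)), " to ", format(max(x$date)), sep = "")
  cat("\n")
  if (n > 0) print(head(as.data.frame(x), 5))
  invisible(x)
}

#' Build a day-indexed count series from a catalog
#'
#' Discretizes the catalog to integer days from its first event (or a
#' supplied origin), with one count per calendar day and aligned weekday and
#' month indices.  The model operates on whole days, so times of day are
#' never used.
#'
#' @param catalog a non-empty \code{event_catalog}.
#' @param origin,end optional Dates extending the span beyond the first/last
#'   event.
#' @return a \code{daily_series}: list with \code{origin} (Date),
#'   \code{counts} (integer, one per day, \code{sum(counts) == nrow(catalog)}),
#'   \code{weekday} (1 = Sunday .. 7 = Saturday), \code{month} (1..12).
#' @export
to_daily_series <- function(catalog, origin = NULL, end = NULL) {
  stopifnot(inherits(catalog, "event_catalog"))
  if (nrow(catalog) == 0) stop("catalog is empty")
  origin <- if (is.null(origin)) min(catalog$date) else as.Date(origin)
  end <- if (is.null(end)) max(catalog$date) else as.Date(end)
  if (origin > min(catalog$date) || end < max(catalog$date))
    stop("origin/end must cover the catalog's date span")
  days <- seq(origin, end, by = "day")
  idx <- as.integer(catalog$date - origin) + 1L
  counts <- tabulate(idx, nbins = length(days))
  structure(list(origin = origin,
                 counts = as.integer(counts),
                 weekday = as.POSIXlt(days)$wday + 1L,
                 month = as.POSIXlt(days)$mon + 1L),
            class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  cat("Daily series: ", length(x$counts), " days from ", format(x$origin),
      ", ", sum(x$counts), " events\n", sep = "")
  invisible(x)
}

#' Expand a daily series back to one dated row per event
#'
#' @param series a \code{daily_series}.
#' @return vector of Dates, one per event.
#' @export
series_event_dates <- function(series) {
  stopifnot(inherits(series, "daily_series"))
  days <- seq(series$origin, by = "day", length.out = length(series$counts))
  rep(days, series$counts)
}

#' Calendar structure tests for an event catalog
#'
#' Pearson chi-squared goodness-of-fit tests of the day-of-week and
#' month-of-year event distributions against exposure-weighted uniformity
#' (the expected count for each weekday/month is proportional to the number
#' of such days inside the catalog span, so partial weeks and unequal month
#' lengths do not bias the test), plus a binomial comparison of the
#' September-April school-year period against May-August, weighted by days
#' at risk.
#'
#' @param catalog an \code{event_catalog} with at least 2 records.
#' @return list with components \code{weekday}, \code{month} (each:
#'   \code{statistic}, \code{df}, \code{p_value}, \code{observed},
#'   \code{expected}) and \code{sep_apr} (\code{p_value},
#'   \code{observed_fraction}, \code{expected_fraction}).
#' @export
weekday_seasonal_tests <- function(catalog) {
  stopifnot(inherits(catalog, "event_catalog"))
  if (nrow(catalog) < 2) stop("need at least 2 records")
  series <- to_daily_series(catalog)
  if (length(series$counts) < 7) stop("span shorter than one week")

  gof <- function(group, levels) {
    obs <- vapply(levels, function(l) sum(series$counts[group == l]), 0)
    exposure <- vapply(levels, function(l) sum(group == l), 0)
    expected <- sum(obs) * exposure / sum(exposure)
    if (all(obs == expected)) {
      list(statistic = 0, df = length(levels) - 1L, p_value = 1,
           observed = obs, expected = expected)
    } else {
      ct <- suppressWarnings(
        chisq.test(obs, p = exposure / sum(exposure)))
      list(statistic = unname(ct$statistic), df = unname(ct$parameter),
           p_value = ct$p.value, observed = obs, expected = expected)
    }
  }

  wk <- gof(series$weekday, 1:7)
  names(wk$observed) <- c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")
  mo <- gof(series$month, 1:12)

  in_sep_apr <- series$month %in% c(9:12, 1:4)
  n_sep_apr <- sum(series$counts[in_sep_apr])
  p_exposure <- sum(in_sep_apr) / length(series$counts)
  bt <- binom.test(n_sep_apr, sum(series$counts), p = p_exposure)

  list(weekday = wk, month = mo,
       sep_apr = list(p_value = bt$p.value,
                      observed_fraction = n_sep_apr / sum(series$counts),
                      expected_fraction = p_exposure))
}

#' Compare incident severity by shooter suicide
#'
#' Compares the mean number killed between incidents where the perpetrator
#' did and did not die by suicide, via a two-sided Student t test, and
#' reports the shooter-suicide fraction.
#'
#' @param catalog an \code{event_catalog} with \code{n_killed} and
#'   \code{shooter_suicide} columns.
#' @return list: \code{mean_suicide}, \code{mean_no_suicide}, \code{ratio},
#'   \code{p_value}, \code{suicide_fraction}, \code{available} (FALSE when a
#'   subgroup is empty, in which case the comparison fields are NA).
#' @export
suicide_severity_comparison <- function(catalog) {
  stopifnot(inherits(catalog, "event_catalog"))
  stopifnot(all(c("n_killed", "shooter_suicide") %in% names(catalog)))
  sui <- catalog$n_killed[catalog$shooter_suicide %in% TRUE]
  non <- catalog$n_killed[catalog$shooter_suicide %in% FALSE]
  frac <- length(sui) / (length(sui) + length(non))
  if (length(sui) == 0 || length(non) == 0) {
    return(list(mean_suicide = NA_real_, mean_no_suicide = NA_real_,
                ratio = NA_real_, p_value = NA_real_,
                suicide_fraction = frac, available = FALSE))
  }
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  if (sd0(sui) == 0 && sd0(non) == 0) {
    # degenerate-variance limit of the t test: p -> 1 (equal) or 0 (not)
    tt <- list(p.value = if (mean(sui) == mean(non)) 1 else 0)
  } else if (length(sui) < 2 || length(non) < 2) {
    tt <- list(p.value = NA_real_)
  } else {
    tt <- t.test(sui, non)
  }
  list(mean_suicide = mean(sui), mean_no_suicide = mean(non),
       ratio = mean(sui) / mean(non), p_value = tt$p.value,
       suicide_fraction = frac, available = TRUE)
}

#' Read a per-state covariate table
#'
#' @param path CSV with columns \code{state} and any of \code{population},
#'   \code{suicides_total}, \code{suicides_firearm},
#'   \code{mental_illness_prev}, \code{brady_rank}.
#' @return data.frame keyed by \code{state}.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!"state" %in% names(df))
    stop("schema error: required column 'state' missing")
  if (anyDuplicated(df$state)) stop("duplicated state rows")
  df
}
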