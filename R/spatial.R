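#' Great-circle distance (haversine)
#'
#' Haversine distance on a sphere of radius 6371 km.  Vectorised over all
#' arguments.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees.
#' @return distance in kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    stop("latitude out of [-90, 90]")
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE))
    stop("longitude out of [-180, 180]")
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Pairwise temporal and spatial distance matrices for a catalog
#'
#' Builds the inter-event day-gap matrix and the great-circle distance
#' matrix over all event pairs.  Records with missing coordinates are
#' dropped (their number is reported), matching the convention that such
#' records participate in temporal but not spatial analyses.
#'
#' @param catalog an \code{event_catalog} with \code{latitude} and
#'   \code{longitude} columns.
#' @return a \code{pairwise_distances} list: \code{temporal},
#'   \code{spatial} (symmetric matrices, zero diagonal), \code{n_events},
#'   \code{n_dropped}.
#' @export
pairwise_distances <- function(catalog) {
  stopifnot(inherits(catalog, "event_catalog"))
  stopifnot(all(c("latitude", "longitude") %in% names(catalog)))
  ok <- !is.na(catalog$latitude) & !is.na(catalog$longitude)
  n_dropped <- sum(!ok)
  df <- catalog[ok, , drop = FALSE]
  n <- nrow(df)
  if (n < 4) stop("need at least 4 events with coordinates")
  t_days <- as.numeric(df$date - min(df$date))
  temporal <- abs(outer(t_days, t_days, "-"))
  spatial <- outer(seq_len(n), seq_len(n), function(i, j)
    haversine_km(df$latitude[i], df$longitude[i],
                 df$latitude[j], df$longitude[j]))
  diag(spatial) <- 0
  structure(list(temporal = temporal, spatial = spatial,
                 n_events = n, n_dropped = n_dropped),
            class = "pairwise_distances")
}

#' Mantel permutation test of matrix association
#'
#' Correlation between the off-diagonal entries of two pairwise distance
#' matrices, with significance from jointly permuting the row/column
#' labels of one matrix.  One-sided for positive association by default
#' (clustering — small time gaps pairing with small distances — is the
#' alternative of interest);
#' \eqn{p = (1 + \#\{r^* \ge r\}) / (n_{perm} + 1)}.
#'
#' @param dists a \code{\link{pairwise_distances}} object, or a list with
#'   symmetric matrices \code{temporal} and \code{spatial}.
#' @param n_perm number of label permutations (default 9999).
#' @param seed optional integer seed for the permutations.
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @param alternative \code{"greater"} (default) or \code{"two.sided"}.
#' @return a \code{mantel_test} list: \code{statistic} (the correlation),
#'   \code{p_value}, \code{n_perm}, \code{n_events}, \code{method},
#'   \code{alternative}.
#' @export
mantel_test <- function(dists, n_perm = 9999, seed = NULL,
                        method = c("pearson", "spearman"),
                        alternative = c("greater", "two.sided")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  A <- dists$temporal
  B <- dists$spatial
  stopifnot(is.matrix(A), is.matrix(B), all(dim(A) == dim(B)))
  n <- nrow(A)
  if (n < 4) stop("need at least 4 events")
  lt <- lower.tri(A)
  a <- A[lt]
  b <- B[lt]
  if (sd(a) == 0 || sd(b) == 0)
    stop("constant distance matrix: correlation undefined")
  if (method == "spearman") { a <- rank(a); b <- rank(b) }
  r <- cor(a, b)

  if (!is.null(seed)) set.seed(seed)
  rstar <- vapply(seq_len(n_perm), function(k) {
    idx <- sample.int(n)
    bp <- B[idx, idx][lt]
    if (method == "spearman") bp <- rank(bp)
    cor(a, bp)
  }, 0)
  p <- if (alternative == "greater") {
    (1 + sum(rstar >= r)) / (n_perm + 1)
  } else {
    (1 + sum(abs(rstar) >= abs(r))) / (n_perm + 1)
  }
  structure(list(statistic = r, p_value = p, n_perm = n_perm,
                 n_events = n, method = method, alternative = alternative),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %s): r = %.4f, p = %.4g (%d permutations, %d events)\n",
              x$method, x$alternative, x$statistic, x$p_value, x$n_perm,
              x$n_events), sep = "")
  invisible(x)
}

#' Correlation between inter-event times and distances
#'
#' Correlation over all unordered event pairs of the day gap against the
#' great-circle distance, with inference by the Mantel permutation scheme
#' (pairs sharing an event are not independent, so an ordinary correlation
#' test would be anti-conservative).  A significant positive correlation
#' indicates temporal/geospatial clustering — incidents inciting similar
#' incidents nearby.
#'
#' @inheritParams mantel_test
#' @param catalog an \code{event_catalog} with coordinates.
#' @return a \code{mantel_test} result augmented with \code{n_dropped}
#'   (records without coordinates).
#' @export
time_distance_correlation <- function(catalog, n_perm = 9999, seed = NULL,
                                      method = c("pearson", "spearman"),
                                      alternative = c("greater",
                                                      "two.sided")) {
  d <- pairwise_distances(catalog)
  out <- mantel_test(d, n_perm = n_perm, seed = seed, method = method,
                     alternative = alternative)
  out$n_dropped <- d$n_dropped
  out
}
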