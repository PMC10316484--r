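#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

# Wentworth grain-size categories accepted in environment tables
WENTWORTH_LEVELS <- c("boulder", "cobble", "pebble", "granule", "sand", "silt", "clay")

# Geomorphic habitat categories
HABITAT_LEVELS <- c("reef terrace", "reef lagoon")

`%||%` <- rlang::`%||%`

# great-circle distance in km between lon/lat points (haversine, R = 6371 km)
haversine_km <- function(lon1, lat1, lon2, lat2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

# permutation p-value with add-one correction
perm_pval <- function(null_stats, observed, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  null_stats <- null_stats[is.finite(null_stats)]
  hits <- if (tail == "ge") sum(null_stats >= observed) else sum(null_stats <= observed)
  (hits + 1) / (length(null_stats) + 1)
}

# validate a symmetric zero-diagonal labelled distance matrix
check_distance_matrix <- function(D, what = "distance matrix") {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    abort(sprintf("%s must be a square matrix", what))
  }
  if (is.null(rownames(D)) || !identical(rownames(D), colnames(D))) {
    abort(sprintf("%s must carry identical row and column site labels", what))
  }
  if (any(abs(D - t(D)) > 1e-8, na.rm = TRUE)) {
    abort(sprintf("%s must be symmetric", what))
  }
  if (any(abs(diag(D)) > 1e-12)) abort(sprintf("%s must have a zero diagonal", what))
  invisible(D)
}

upper_tri_values <- function(D) D[upper.tri(D)]
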