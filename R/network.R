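#' Graph-theoretic metrics of a directed connectivity matrix
#'
#' Interprets the site-by-site connectivity matrix as a weighted directed
#' graph (zero entries are absent edges, the diagonal is ignored) and
#' returns four per-site metrics: `strength` (total weight in plus out),
#' `closeness` and `betweenness` on shortest paths, and local
#' `transitivity` (clustering coefficient of the binarized undirected
#' graph).  With `weight_semantics = "cost_raw"` the raw weights are used
#' directly as shortest-path edge lengths — the convention of treating
#' connection weights as a cost, under which high closeness/betweenness
#' flag oceanographically isolated sites; `"cost_inverse"` uses `1/weight`,
#' the conventional strong-edge-is-short reading.
#'
#' @param C A nonnegative square labelled matrix (e.g. from
#'   [connectivity_matrix()]).
#' @param weight_semantics `"cost_raw"` or `"cost_inverse"`.
#' @return A tibble: `site_id`, `strength`, `closeness`, `betweenness`,
#'   `transitivity`.
#' @export
network_metrics <- function(C, weight_semantics = c("cost_raw", "cost_inverse")) {
  weight_semantics <- match.arg(weight_semantics)
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) abort("connectivity matrix must be square")
  if (any(C < 0)) abort("connectivity weights must be nonnegative")
  ids <- rownames(C) %||% sprintf("S%02d", seq_len(nrow(C)))
  A <- C; diag(A) <- 0
  strength <- rowSums(A) + colSums(A)
  if (all(A == 0)) {
    warn("all-zero connectivity: path-based metrics undefined")
    return(tibble(site_id = ids, strength = unname(strength), closeness = NA_real_,
                  betweenness = NA_real_, transitivity = NA_real_))
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "directed", weighted = TRUE)
  w <- igraph::E(g)$weight
  if (weight_semantics == "cost_inverse") w <- 1 / w
  closeness <- suppressWarnings(igraph::closeness(g, mode = "all", weights = w))
  betweenness <- igraph::betweenness(g, weights = w)
  gb <- igraph::graph_from_adjacency_matrix((A + t(A)) > 0, mode = "undirected")
  transitivity <- igraph::transitivity(gb, type = "local", isolates = "NaN")
  tibble(
    site_id = ids, strength = unname(strength),
    closeness = as.numeric(closeness), betweenness = as.numeric(betweenness),
    transitivity = as.numeric(transitivity)
  )
}

#' Compress a metric table into PCA axis scores
#'
#' Principal components of the centred and scaled metric columns
#' (eigen-decomposition of their correlation matrix).  Constant columns
#' are dropped with a warning before scaling; retention is a fixed axis
#' count or a cumulative-variance threshold.
#'
#' @param metrics A data frame with `site_id` and numeric metric columns.
#' @param n_axes Number of axes to retain (default 3).
#' @param cum_var Retain the smallest axis set reaching this cumulative
#'   variance share instead, if not `NULL`.
#' @return List: `scores` (tibble `site_id`, `PC1`, ...), `var_share`,
#'   `n_axes`.
#' @export
pca_block <- function(metrics, n_axes = 3, cum_var = NULL) {
  df <- as_tibble(metrics)
  num <- df[, vapply(df, is.numeric, logical(1)), drop = FALSE]
  if (anyNA(num)) {
    warn("missing metric values imputed with column means before PCA")
    for (j in seq_along(num)) {
      num[[j]][is.na(num[[j]])] <- mean(num[[j]], na.rm = TRUE)
    }
  }
  const <- vapply(num, function(v) stats::sd(v) == 0, logical(1))
  if (any(const)) {
    warn(sprintf("dropping constant columns before scaling: %s",
                 paste(names(num)[const], collapse = ", ")))
    num <- num[, !const, drop = FALSE]
  }
  if (ncol(num) < 1 || nrow(num) < 2) abort("PCA needs >= 2 sites and >= 1 varying column")
  pc <- stats::prcomp(num, center = TRUE, scale. = TRUE)
  share <- pc$sdev^2 / sum(pc$sdev^2)
  keep <- if (!is.null(cum_var)) max(1, which(cumsum(share) >= cum_var)[1]) else
    min(n_axes, ncol(pc$x))
  scores <- as_tibble(pc$x[, seq_len(keep), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(site_id = df$site_id %||% seq_len(nrow(df))), scores)
  list(scores = scores, var_share = share, n_axes = keep, rotation = pc$rotation)
}
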