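#' Gower dissimilarity of mixed-type environmental data
#'
#' Numeric columns contribute range-normalized absolute differences,
#' categorical and logical columns a 0/1 mismatch; the dissimilarity is the
#' average over columns non-missing in both rows.  Zero-range numeric
#' columns are excluded with a warning.
#'
#' @param env An [environment_table()] (or any data frame with a `site_id`
#'   column and covariate columns).
#' @return A symmetric labelled dissimilarity matrix in `[0, 1]`.
#' @export
gower_dissimilarity <- function(env) {
  env <- as_tibble(env)
  ids <- env$site_id %||% as.character(seq_len(nrow(env)))
  vars <- env[, setdiff(names(env), c("site_id", "site_index")), drop = FALSE]
  n <- nrow(vars)
  num <- matrix(0, n, n); den <- matrix(0, n, n)
  for (j in seq_along(vars)) {
    v <- vars[[j]]
    if (is.numeric(v)) {
      rng <- diff(range(v, na.rm = TRUE))
      if (rng == 0) {
        warn(sprintf("zero-range numeric column %s excluded from Gower", names(vars)[j]))
        next
      }
      d <- abs(outer(v, v, "-")) / rng
    } else {
      v <- as.character(v)
      d <- outer(v, v, "!=") + 0
    }
    ok <- outer(!is.na(v), !is.na(v), "&")
    d[!ok] <- 0
    num <- num + d
    den <- den + ok
  }
  if (all(den == 0)) abort("no usable columns for Gower dissimilarity")
  D <- num / pmax(den, 1)
  dimnames(D) <- list(ids, ids)
  D
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal elements with significance by
#' matrix-permutation, delegated to `vegan::mantel()`.
#'
#' @param A,B Symmetric labelled distance matrices over the same sites.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A tibble: `r`, `p_value`, `n_perm`, `n_sites`.
#' @export
mantel_test <- function(A, B, n_perm = 9999, seed = NULL) {
  check_distance_matrix(A, "A"); check_distance_matrix(B, "B")
  if (!identical(rownames(A), rownames(B))) {
    B <- B[rownames(A), rownames(A)]
  }
  if (nrow(A) < 4) abort("Mantel test needs >= 4 sites")
  if (stats::sd(upper_tri_values(A)) == 0 || stats::sd(upper_tri_values(B)) == 0) {
    abort("constant distance matrix: Mantel r undefined")
  }
  if (!is.null(seed)) set.seed(seed)
  m <- vegan::mantel(stats::as.dist(A), stats::as.dist(B), permutations = n_perm)
  tibble(r = unname(m$statistic), p_value = m$signif, n_perm = n_perm, n_sites = nrow(A))
}

#' Principal coordinate analysis of a distance matrix
#'
#' Gower double-centering of `-0.5 * D^2` followed by
#' eigen-decomposition; coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues.  Only axes with eigenvalue above
#' `tol * max(eigenvalue)` are retained.
#'
#' @param D A symmetric zero-diagonal labelled distance matrix.
#' @param tol Relative positivity tolerance.
#' @return An `ordination`: list with `scores` (sites x axes matrix),
#'   `eigenvalues` (all, descending), `rel_eig` (shares of the positive
#'   part), `n_positive`.
#' @export
pcoa <- function(D, tol = 1e-8) {
  check_distance_matrix(D)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- e$values > tol * max(abs(e$values))
  if (!any(pos)) abort("no positive eigenvalues: PCoA undefined")
  scores <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), sum(pos))
  rownames(scores) <- rownames(D)
  colnames(scores) <- paste0("PCo", seq_len(ncol(scores)))
  structure(
    list(scores = scores, eigenvalues = e$values,
         rel_eig = pmax(e$values, 0) / sum(pmax(e$values, 0)),
         n_positive = sum(pos)),
    class = "ordination"
  )
}

#' Spatial eigenvectors of a truncated geographic distance matrix (PCNM)
#'
#' Principal coordinates of neighbour matrices: distances above the
#' truncation threshold are replaced by four times the threshold, and the
#' positive-eigenvalue principal coordinates of the truncated matrix serve
#' as spatial predictors.  The default threshold is the longest edge of the
#' minimum spanning tree, guaranteeing a connected neighbourhood.
#' Delegates to `vegan::pcnm()`.
#'
#' @param D_geo A symmetric labelled geographic distance matrix.
#' @param truncation `"mst_max"` or a numeric threshold in the matrix's
#'   units.
#' @return List: `scores` (tibble `site_id`, `PCNM1`, ...), `threshold`,
#'   `eigenvalues`.
#' @export
pcnm_axes <- function(D_geo, truncation = "mst_max") {
  check_distance_matrix(D_geo, "geographic distance matrix")
  if (nrow(D_geo) < 3) abort("PCNM needs >= 3 sites")
  d <- stats::as.dist(D_geo)
  res <- if (identical(truncation, "mst_max")) vegan::pcnm(d) else
    vegan::pcnm(d, threshold = as.numeric(truncation))
  scores <- as_tibble(as.data.frame(res$vectors))
  scores <- dplyr::bind_cols(tibble(site_id = rownames(D_geo)), scores)
  list(scores = scores, threshold = res$threshold, eigenvalues = res$values)
}

#' One-hot environmental encoding for correspondence analysis
#'
#' Categorical and logical covariates become 0/1 dummy columns; numeric
#' covariates are range-scaled to `[0, 1]` and kept as abundance-like
#' columns, producing the nonnegative table correspondence analysis
#' requires.
#'
#' @param env An [environment_table()].
#' @return A numeric matrix with site ids as row names.
#' @export
encode_environment <- function(env) {
  env <- as_tibble(env)
  ids <- env$site_id
  vars <- env[, setdiff(names(env), c("site_id", "site_index")), drop = FALSE]
  cols <- list()
  for (j in seq_along(vars)) {
    v <- vars[[j]]; nm <- names(vars)[j]
    if (is.numeric(v)) {
      rng <- diff(range(v))
      cols[[nm]] <- if (rng == 0) rep(0, length(v)) else (v - min(v)) / rng
    } else {
      v <- if (is.logical(v)) factor(v, levels = c(FALSE, TRUE)) else
        factor(as.character(v))
      for (lev in levels(v)) {
        if (!any(v == lev)) next
        cols[[paste(nm, lev, sep = ".")]] <- as.numeric(v == lev)
      }
    }
  }
  M <- do.call(cbind, cols)
  rownames(M) <- ids
  M[, colSums(M) > 0, drop = FALSE]
}

#' Correspondence analysis of a nonnegative table
#'
#' SVD of the standardized residuals of the row/column-profile matrix:
#' `S = diag(r)^(-1/2) (P - r c^T) diag(c)^(-1/2)` with `P` the table
#' normalized to sum 1.  Row (site) scores are returned in principal
#' coordinates; inertia shares are the squared singular values over the
#' total inertia.
#'
#' @param tab Nonnegative matrix with no all-zero rows or columns (e.g.
#'   from [encode_environment()]).
#' @param n_axes Number of axes to return (default all).
#' @return List: `scores` (tibble `site_id`, `CA1`, ...), `inertia_share`,
#'   `total_inertia`.
#' @export
correspondence_analysis <- function(tab, n_axes = NULL) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) abort("correspondence analysis needs a nonnegative table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("all-zero rows or columns are not allowed")
  }
  P <- tab / sum(tab)
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cc) %*% diag(1 / sqrt(cc))
  sv <- svd(S)
  total <- sum(sv$d^2)
  if (total < 1e-14) abort("zero total inertia: all row profiles identical")
  keep <- which(sv$d^2 > 1e-12 * total)
  n_axes <- min(n_axes %||% length(keep), length(keep))
  keep <- keep[seq_len(n_axes)]
  # principal row coordinates
  F_row <- diag(1 / sqrt(r)) %*% sv$u[, keep, drop = FALSE] %*%
    diag(sv$d[keep], length(keep))
  scores <- as_tibble(as.data.frame(F_row))
  names(scores) <- paste0("CA", seq_along(keep))
  scores <- dplyr::bind_cols(tibble(site_id = rownames(tab) %||%
                                      as.character(seq_len(nrow(tab)))), scores)
  list(scores = scores, inertia_share = sv$d[keep]^2 / total, total_inertia = total)
}

#' Select predictor axes for a block
#'
#' Either the first `k` candidate axes (`"first_k"`) or a collinearity
#' screen keeping candidates whose maximum absolute Pearson correlation
#' with the response axes stays below `threshold` (predictors already
#' collinear with the response are excluded).
#'
#' @param candidates A data frame of candidate axes (optionally with a
#'   `site_id` column).
#' @param response A matrix/data frame of response axes, row-aligned.
#' @param rule `"first_k"` or `"correlation_screen"`.
#' @param k Number of axes for `"first_k"`.
#' @param threshold Correlation threshold for the screen.
#' @return The selected columns of `candidates` (site_id retained).
#' @export
select_predictor_axes <- function(candidates, response = NULL,
                                  rule = c("first_k", "correlation_screen"),
                                  k = 3, threshold = 0.5) {
  rule <- match.arg(rule)
  candidates <- as_tibble(candidates)
  id_col <- intersect("site_id", names(candidates))
  axes <- candidates[, setdiff(names(candidates), id_col), drop = FALSE]
  if (rule == "first_k") {
    if (k > ncol(axes)) abort(sprintf("k = %d exceeds %d candidate axes", k, ncol(axes)))
    sel <- seq_len(k)
  } else {
    if (is.null(response)) abort("correlation_screen needs response axes")
    R <- as.matrix(response[, vapply(as.data.frame(response), is.numeric, logical(1)),
                            drop = FALSE])
    maxcor <- vapply(axes, function(a) max(abs(stats::cor(a, R))), numeric(1))
    sel <- which(maxcor < threshold)
  }
  dplyr::bind_cols(candidates[, id_col, drop = FALSE], axes[, sel, drop = FALSE])
}
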