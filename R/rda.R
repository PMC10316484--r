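# Centered predictor matrix from a data frame / matrix (site_id dropped),
# with collinear columns removed via QR rank detection.
as_predictor_matrix <- function(X, warn_drop = TRUE) {
  if (is.data.frame(X)) X <- X[, setdiff(names(X), "site_id"), drop = FALSE]
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  X <- scale(X, center = TRUE, scale = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    if (warn_drop) {
      warn(sprintf("dropping %d collinear predictor column(s)", ncol(X) - qr_x$rank))
    }
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

# sum of squares of the fitted values of Y on centered X (no intercept,
# both centered)
fit_ss <- function(Y, X) {
  if (ncol(X) == 0) return(0)
  fit <- qr.fitted(qr(X), Y)
  sum(fit^2)
}

ezekiel_adj <- function(R2, n, m) 1 - (1 - R2) * (n - 1) / (n - m - 1)

#' Redundancy analysis of a multivariate response
#'
#' RDA of a site-by-axes response matrix `Y` on predictors `X`, optionally
#' partial on conditioning predictors `Z`.  `R2` is the share of the total
#' variance of (column-centered) `Y` captured by the fitted values; the
#' adjusted value uses Ezekiel's formula.  The F statistic is
#' `(SS_X / m) / (SS_res / df_res)` with `SS_X` the variance explained by
#' `X` over and above `Z`; its permutation p-value permutes response rows
#' when `Z` is absent and reduced-model residuals when `Z` is present.
#'
#' @param Y Response matrix (e.g. PCoA scores of linearized F_ST).
#' @param X Predictor block (data frame or matrix; `site_id` ignored).
#' @param Z Optional conditioning block.
#' @param n_perm Number of permutations (0 skips the test).
#' @param seed Integer seed.
#' @return A tibble: `r2`, `adj_r2`, `df_model`, `df_residual`, `F`,
#'   `p_value`.  For partial models `r2`/`adj_r2` are the semipartial
#'   (additional) fractions relative to the total variance of `Y`.
#' @export
rda_fit <- function(Y, X, Z = NULL, n_perm = 999, seed = NULL) {
  Y <- as.matrix(Y)
  storage.mode(Y) <- "double"
  Y <- scale(Y, center = TRUE, scale = FALSE)
  n <- nrow(Y)
  X <- as_predictor_matrix(X)
  if (nrow(X) != n) abort("response and predictors must be row-aligned")
  ss_tot <- sum(Y^2)
  if (ss_tot == 0) abort("response has zero variance")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(Z)) {
    m <- ncol(X)
    if (n <= m + 1) abort("need n > number of predictors + 1")
    r2 <- fit_ss(Y, X) / ss_tot
    df_res <- n - 1 - m
    Fstat <- (r2 / m) / ((1 - r2) / df_res)
    p <- NA_real_
    if (n_perm > 0) {
      null_stats <- replicate(n_perm, fit_ss(Y[sample.int(n), , drop = FALSE], X) / ss_tot)
      p <- perm_pval(null_stats, r2)
    }
    return(tibble(r2 = r2, adj_r2 = ezekiel_adj(r2, n, m), df_model = m,
                  df_residual = df_res, F = Fstat, p_value = p))
  }
  Z <- as_predictor_matrix(Z)
  qz <- qr(Z)
  Yr <- qr.resid(qz, Y)
  Xr <- qr.resid(qz, X)
  Xr <- as_predictor_matrix(Xr, warn_drop = FALSE)
  m <- ncol(Xr); mz <- ncol(Z)
  if (n <= m + mz + 1) abort("need n > total predictor count + 1")
  ss_x <- fit_ss(Yr, Xr)
  ss_res <- sum(Yr^2) - ss_x
  df_res <- n - 1 - m - mz
  Fstat <- (ss_x / m) / (ss_res / df_res)
  r2_semi <- ss_x / ss_tot
  # semipartial adjusted R2 as a difference of Ezekiel-adjusted nested models
  r2_full <- (ss_tot - ss_res) / ss_tot
  r2_reduced <- (ss_tot - sum(Yr^2)) / ss_tot
  adj_semi <- ezekiel_adj(r2_full, n, m + mz) - ezekiel_adj(r2_reduced, n, mz)
  p <- NA_real_
  if (n_perm > 0) {
    fit_red <- Y - Yr
    null_stats <- replicate(n_perm, {
      Ystar <- fit_red + Yr[sample.int(n), , drop = FALSE]
      Ysr <- qr.resid(qz, Ystar)
      ssx <- fit_ss(Ysr, Xr)
      (ssx / m) / ((sum(Ysr^2) - ssx) / df_res)
    })
    p <- perm_pval(null_stats, Fstat)
  }
  tibble(r2 = r2_semi, adj_r2 = adj_semi, df_model = m, df_residual = df_res,
         F = Fstat, p_value = p)
}

#' Variance partitioning of genetic differentiation over three predictor blocks
#'
#' Decomposes the variance of a multivariate response (the genetic
#' structure block, typically PCoA axes of linearized F_ST) over three
#' predictor blocks — by convention geographic distance (GD), oceanographic
#' connectivity (OC) and environment (EN) — using partial redundancy
#' analysis.  Adjusted R2 is computed for all seven non-empty block
#' unions; each block's marginal fraction is its own adjusted R2, its
#' unique (conditional) fraction is `adjR2(all) - adjR2(other two)`, shared
#' fractions follow by inclusion-exclusion, and the residual is
#' `1 - adjR2(all)`.  Marginal and conditional F tests use the permutation
#' schemes of [rda_fit()].  Negative adjusted fractions are reported as
#' computed.
#'
#' @param Y Response matrix.
#' @param blocks Named list of exactly three predictor blocks.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `varpart_result`: list with `table` (marginal and conditional
#'   rows per block: `adj_r2`, `df_model`, `df_residual`, `F`, `p_value`),
#'   `fractions` (unique, pairwise-shared, three-way shared, residual, on
#'   the adjusted scale), `unions` (adjusted and raw R2 of all seven
#'   unions), `n`.
#' @export
variation_partitioning <- function(Y, blocks, n_perm = 999, seed = NULL) {
  if (length(blocks) != 3) abort("exactly three predictor blocks required")
  nm <- names(blocks) %||% c("X1", "X2", "X3")
  if (is.null(names(blocks))) names(blocks) <- nm
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (!is.null(seed)) set.seed(seed)
  Xs <- lapply(blocks, as_predictor_matrix)
  combos <- list(
    "1" = 1, "2" = 2, "3" = 3,
    "12" = c(1, 2), "13" = c(1, 3), "23" = c(2, 3), "123" = 1:3
  )
  unions <- purrr::map_dfr(names(combos), function(key) {
    X <- do.call(cbind, Xs[combos[[key]]])
    fit <- rda_fit(Y, X, n_perm = 0)
    tibble(blocks = paste(nm[combos[[key]]], collapse = "+"),
           key = key, r2 = fit$r2, adj_r2 = fit$adj_r2,
           df_model = fit$df_model)
  })
  adj <- setNames(unions$adj_r2, unions$key)
  raw <- setNames(unions$r2, unions$key)
  # marginal and conditional test rows
  rows <- purrr::map_dfr(1:3, function(i) {
    others <- setdiff(1:3, i)
    marg <- rda_fit(Y, Xs[[i]], n_perm = n_perm)
    cond <- rda_fit(Y, Xs[[i]], Z = do.call(cbind, Xs[others]), n_perm = n_perm)
    cond_adj <- adj[["123"]] - adj[[paste(sort(others), collapse = "")]]
    dplyr::bind_rows(
      tibble(block = nm[i], effect = "marginal", adj_r2 = marg$adj_r2,
             df_model = marg$df_model, df_residual = marg$df_residual,
             F = marg$F, p_value = marg$p_value),
      tibble(block = nm[i], effect = "conditional", adj_r2 = cond_adj,
             df_model = cond$df_model, df_residual = cond$df_residual,
             F = cond$F, p_value = cond$p_value)
    )
  })
  # inclusion-exclusion on the adjusted scale: unique fractions a, b, c3;
  # pairwise shared d, e, f; three-way shared g
  a <- adj[["123"]] - adj[["23"]]
  b <- adj[["123"]] - adj[["13"]]
  c3 <- adj[["123"]] - adj[["12"]]
  d <- adj[["123"]] - adj[["3"]] - a - b
  e <- adj[["123"]] - adj[["1"]] - b - c3
  f <- adj[["123"]] - adj[["2"]] - a - c3
  g <- adj[["123"]] - a - b - c3 - d - e - f
  fractions <- tibble(
    fraction = c(paste0("unique_", nm),
                 paste0("shared_", nm[1], "_", nm[2]),
                 paste0("shared_", nm[2], "_", nm[3]),
                 paste0("shared_", nm[1], "_", nm[3]),
                 "shared_all", "residual"),
    adj_r2 = c(a, b, c3, d, e, f, g, 1 - adj[["123"]])
  )
  structure(
    list(table = rows, fractions = fractions,
         unions = unions[, c("blocks", "key", "r2", "adj_r2", "df_model")],
         n = n, n_perm = n_perm),
    class = "varpart_result"
  )
}

#' @export
print.varpart_result <- function(x, ...) {
  cat(sprintf("# Variance partitioning (n = %d sites, %d permutations)\n", x$n, x$n_perm))
  tbl <- x$table
  tbl$adj_r2_pct <- sprintf("%.2f", 100 * tbl$adj_r2)
  print(as.data.frame(tbl[, c("block", "effect", "adj_r2_pct", "df_model",
                              "df_residual", "F", "p_value")]), row.names = FALSE)
  res <- x$fractions$adj_r2[x$fractions$fraction == "residual"]
  cat(sprintf("  residual (adjusted): %.2f%%\n", 100 * res))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.varpart_result <- function(x, ...) x$table

#' @export
glance.varpart_result <- function(x, ...) {
  full <- x$unions[x$unions$key == "123", ]
  tibble(n_sites = x$n, adj_r2_full = full$adj_r2, r2_full = full$r2,
         residual_adj = 1 - full$adj_r2, n_perm = x$n_perm)
}

#' @export
tidy.fst_result <- function(x, ...) {
  if (is.null(x$pairwise)) {
    return(tibble(site_a = character(0), site_b = character(0),
                  fst = numeric(0), p_value = numeric(0)))
  }
  sites <- rownames(x$pairwise)
  idx <- which(upper.tri(x$pairwise), arr.ind = TRUE)
  tibble(site_a = sites[idx[, 1]], site_b = sites[idx[, 2]],
         fst = x$pairwise[idx],
         p_value = if (is.null(x$pairwise_p)) NA_real_ else x$pairwise_p[idx])
}

#' @export
glance.fst_result <- function(x, ...) {
  tibble(fst = x$theta, f_is = x$f_is, f_it = x$f_it, p_value = x$p_value,
         n_sites = length(x$sites_used), n_perm = x$n_perm)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar plot of adjusted-R2 fractions
#' @param object A `varpart_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.varpart_result <- function(object, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(x = .data$block, y = 100 * .data$adj_r2,
                                   fill = .data$effect)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Adjusted R² (%)",
                  title = "Variance partitioning of genetic differentiation") +
    ggplot2::theme_minimal()
}
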