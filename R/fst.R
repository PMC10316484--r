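# Weir & Cockerham (1984) variance components summed over alleles and loci.
# gt: genotype table; site: factor of site labels (same length as rows).
# Returns c(a, b, c) sums; theta = a / (a + b + c).
wc_components <- function(gt, site) {
  site <- factor(site)
  r <- nlevels(site)
  tot <- c(a = 0, b = 0, c = 0)
  for (l in loci(gt)) {
    al <- locus_alleles(gt, l)
    ok <- !is.na(al[, 1])
    s <- site[ok]
    if (dplyr::n_distinct(s) < 2) next
    s <- droplevels(s)
    ri <- nlevels(s)
    a1 <- al[ok, 1]; a2 <- al[ok, 2]
    n_i <- as.vector(table(s))
    if (any(n_i < 1)) next
    alleles <- sort(unique(c(a1, a2)))
    if (length(alleles) < 2) next
    nbar <- mean(n_i)
    nc <- (ri * nbar - sum(n_i^2) / (ri * nbar)) / (ri - 1)
    if (nbar <= 1 || nc <= 0) next
    # per-site allele counts and heterozygote indicators, all alleles at once
    cnt <- outer(a1, alleles, "==") + outer(a2, alleles, "==")
    het <- cnt == 1
    p_i <- rowsum(cnt, s) / (2 * n_i) # site x allele
    h_i <- rowsum(het + 0, s) / n_i
    pbar <- colSums(n_i * p_i) / (ri * nbar)
    s2 <- colSums(n_i * sweep(p_i, 2, pbar)^2) / ((ri - 1) * nbar)
    hbar <- colSums(n_i * h_i) / (ri * nbar)
    va <- nbar / nc * (s2 - (pbar * (1 - pbar) - (ri - 1) / ri * s2 - hbar / 4) / (nbar - 1))
    vb <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (ri - 1) / ri * s2 -
                                 (2 * nbar - 1) / (4 * nbar) * hbar)
    vc <- hbar / 2
    tot <- tot + c(sum(va), sum(vb), sum(vc))
  }
  tot
}

#' Weir-Cockerham F-statistics with permutation tests
#'
#' Multi-locus, multi-allelic theta (F_ST) by summing Weir-Cockerham
#' variance components across alleles and loci; F_IS and F_IT come from the
#' same components.  Pairwise values are computed on each two-site subset.
#' Significance is by permuting individuals (multilocus genotypes) among
#' sites, `p = (hits + 1) / (n_perm + 1)` for `theta* >= theta`.  Sites
#' with fewer than `min_genotypes` samples are excluded with a warning.
#'
#' @param gt A clone-corrected [genotype_table()].
#' @param n_perm Permutations for the global test (0 skips).
#' @param pairwise Compute the pairwise matrix?
#' @param pairwise_n_perm Permutations per pairwise cell (defaults to
#'   `n_perm`; 0 skips the per-cell tests).
#' @param min_genotypes Minimum samples per site (default 2).
#' @param seed Integer seed.
#' @return An `fst_result`: list with `theta` (global F_ST), `f_is`, `f_it`,
#'   `p_value`, `pairwise` (matrix), `pairwise_p` (matrix), `n_perm`,
#'   `sites_used`.
#' @export
fst <- function(gt, n_perm = 999, pairwise = TRUE, pairwise_n_perm = n_perm,
                min_genotypes = 2, seed = NULL) {
  sizes <- table(gt$site_id)
  drop <- names(sizes)[sizes < min_genotypes]
  if (length(drop)) {
    warn(sprintf("excluding sites with < %d genotypes: %s",
                 min_genotypes, paste(drop, collapse = ", ")))
    gt <- as_gen_tbl(gt[!gt$site_id %in% drop, , drop = FALSE], loci(gt))
  }
  sites <- unique(gt$site_id)
  if (length(sites) < 2) abort("F_ST needs >= 2 usable sites")
  if (!is.null(seed)) set.seed(seed)
  comp <- wc_components(gt, gt$site_id)
  theta <- comp["a"] / sum(comp)
  f_is <- 1 - comp["c"] / (comp["b"] + comp["c"])
  f_it <- 1 - comp["c"] / sum(comp)
  p_value <- NA_real_
  if (n_perm > 0) {
    null_stats <- replicate(n_perm, {
      cp <- wc_components(gt, sample(gt$site_id))
      cp["a"] / sum(cp)
    })
    p_value <- perm_pval(null_stats, theta)
  }
  pw <- pw_p <- NULL
  if (pairwise && length(sites) >= 2) {
    k <- length(sites)
    pw <- matrix(0, k, k, dimnames = list(sites, sites))
    pw_p <- matrix(NA_real_, k, k, dimnames = list(sites, sites))
    diag(pw_p) <- 1
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        sub <- filter_sites(gt, sites[c(i, j)])
        cij <- wc_components(sub, sub$site_id)
        th <- cij["a"] / sum(cij)
        pw[i, j] <- pw[j, i] <- th
        if (pairwise_n_perm > 0) {
          null_stats <- replicate(pairwise_n_perm, {
            cp <- wc_components(sub, sample(sub$site_id))
            cp["a"] / sum(cp)
          })
          pw_p[i, j] <- pw_p[j, i] <- perm_pval(null_stats, th)
        }
      }
    }
  }
  structure(
    list(theta = unname(theta), f_is = unname(f_is), f_it = unname(f_it),
         p_value = p_value, pairwise = pw, pairwise_p = pw_p,
         n_perm = n_perm, sites_used = sites, sites_dropped = drop),
    class = "fst_result"
  )
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("# Weir-Cockerham F-statistics (%d sites)\n", length(x$sites_used)))
  cat(sprintf("  global F_ST = %.4f (p = %s), F_IS = %.4f, F_IT = %.4f\n",
              x$theta, format.pval(x$p_value), x$f_is, x$f_it))
  invisible(x)
}

#' Linearize an F_ST matrix
#'
#' Rousset's transform `F / (1 - F)`, elementwise.  Negative estimates are
#' clamped to 0 first; values of 1 are an error (infinite distance).
#'
#' @param F A pairwise F_ST matrix (or scalar).
#' @return The linearized matrix.
#' @examples
#' linearize_fst(0.5) # 1
#' @export
linearize_fst <- function(F) {
  if (any(F >= 1, na.rm = TRUE)) abort("F_ST of 1 cannot be linearized (infinite)")
  F <- pmax(F, 0)
  F / (1 - F)
}

#' Correlation between per-locus G_ST and H_S
#'
#' A mutation-bias diagnostic: across loci, Nei's
#' `G_ST = (H_T - H_S) / H_T` is correlated with within-population
#' diversity `H_S`.  A significantly negative correlation indicates
#' high-mutation loci depress the differentiation estimate (F_ST possibly
#' underestimated); a non-negative correlation indicates no such bias.
#' Significance is a two-sided bootstrap over loci (the resampling unit).
#'
#' @param gt A clone-corrected [genotype_table()] with >= 3 loci.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return List: `per_locus` tibble (`locus`, `g_st`, `h_s`), `r_gh`,
#'   `p_value`, `n_boot`.
#' @export
gst_hs_correlation <- function(gt, n_boot = 10000, seed = NULL) {
  lc <- loci(gt)
  if (length(lc) < 3) abort("needs >= 3 loci")
  site <- factor(gt$site_id)
  per_locus <- purrr::map_dfr(lc, function(l) {
    al <- locus_alleles(gt, l)
    ok <- !is.na(al[, 1])
    s <- droplevels(site[ok])
    a1 <- al[ok, 1]; a2 <- al[ok, 2]
    alleles <- sort(unique(c(a1, a2)))
    pmat <- vapply(alleles, function(a) {
      as.vector(rowsum((a1 == a) + (a2 == a), s)) / (2 * as.vector(table(s)))
    }, numeric(nlevels(s)))
    pmat <- matrix(pmat, nrow = nlevels(s))
    h_s <- mean(1 - rowSums(pmat^2))
    pbar <- colMeans(pmat)
    h_t <- 1 - sum(pbar^2)
    tibble(locus = l, g_st = if (h_t > 0) (h_t - h_s) / h_t else NA_real_, h_s = h_s)
  })
  sd_g <- stats::sd(per_locus$g_st, na.rm = TRUE)
  if (stats::sd(per_locus$h_s) == 0 || is.na(sd_g) || sd_g == 0) {
    abort("per-locus G_ST or H_S has zero variance; correlation undefined")
  }
  r_gh <- stats::cor(per_locus$g_st, per_locus$h_s, use = "complete.obs")
  if (!is.null(seed)) set.seed(seed)
  boot <- replicate(n_boot, {
    i <- sample.int(nrow(per_locus), replace = TRUE)
    suppressWarnings(stats::cor(per_locus$g_st[i], per_locus$h_s[i], use = "complete.obs"))
  })
  boot <- boot[is.finite(boot)]
  p_value <- 2 * min(mean(boot <= 0), mean(boot >= 0))
  p_value <- min(1, max(p_value, 1 / (length(boot) + 1)))
  list(per_locus = per_locus, r_gh = r_gh, p_value = p_value, n_boot = n_boot)
}

#' Evanno delta-K from clustering log-likelihood runs
#'
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`,
#' defined for interior K only.  The argmax over defined values is the
#' supported cluster number.
#'
#' @param logl A data frame or matrix with columns `K` and `logL` (one row
#'   per run), or a runs x K matrix with K values as column names.
#' @return A tibble with `K`, `mean_logl`, `sd_logl`, `delta_k`, and
#'   attribute `best_k`.
#' @export
evanno_delta_k <- function(logl) {
  if (is.matrix(logl)) {
    logl <- tidyr::pivot_longer(as_tibble(logl), dplyr::everything(),
                                names_to = "K", values_to = "logL")
    logl$K <- as.integer(logl$K)
  }
  logl <- as_tibble(logl)
  if (!all(c("K", "logL") %in% names(logl))) abort("need columns K and logL")
  stats_tbl <- logl |>
    dplyr::group_by(K = as.integer(.data$K)) |>
    dplyr::summarise(mean_logl = mean(.data$logL), sd_logl = stats::sd(.data$logL),
                     n_runs = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$K)
  if (nrow(stats_tbl) < 3) abort("delta-K needs >= 3 consecutive K values")
  if (any(diff(stats_tbl$K) != 1)) abort("K values must be consecutive")
  if (any(stats_tbl$n_runs < 2)) abort("delta-K needs >= 2 runs per K")
  m <- stats_tbl$mean_logl
  dk <- rep(NA_real_, nrow(stats_tbl))
  for (i in 2:(nrow(stats_tbl) - 1)) {
    if (is.na(stats_tbl$sd_logl[i]) || stats_tbl$sd_logl[i] == 0) next # undefined: flagged as NA
    dk[i] <- abs(m[i + 1] - 2 * m[i] + m[i - 1]) / stats_tbl$sd_logl[i]
  }
  stats_tbl$delta_k <- dk
  attr(stats_tbl, "best_k") <- if (all(is.na(dk))) NA_integer_ else
    stats_tbl$K[which.max(dk)]
  stats_tbl
}
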