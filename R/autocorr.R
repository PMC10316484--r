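# Smouse-Peakall squared genetic distance matrix among individuals, summed
# over loci.  Genotypes are coded as allele-count vectors; per locus
# d2 = 0.5 * sum((x_a - y_a)^2), which yields the canonical values
# (ii,ij)=1, (ii,jj)=4, (ij,kl)=2, (ii,jk)=3.  A locus missing in either
# member of a pair contributes that locus's mean over complete pairs.
sp_genetic_d2 <- function(gt) {
  n <- nrow(gt)
  D <- matrix(0, n, n)
  W <- matrix(0, n, n) # imputation bookkeeping
  for (l in loci(gt)) {
    al <- locus_alleles(gt, l)
    ok <- !is.na(al[, 1])
    alleles <- sort(unique(c(al[ok, 1], al[ok, 2])))
    X <- outer(al[, 1], alleles, "==") + outer(al[, 2], alleles, "==")
    X[!ok, ] <- 0
    # 0.5 * squared Euclidean distance of count vectors
    sq <- rowSums(X^2)
    d2 <- 0.5 * (outer(sq, sq, "+") - 2 * tcrossprod(X))
    cmp <- outer(ok, ok, "&")
    mu <- if (any(cmp & upper.tri(cmp))) mean(d2[cmp & upper.tri(cmp)]) else 0
    d2[!cmp] <- mu
    diag(d2) <- 0
    D <- D + d2
  }
  D
}

# Gower-centered codistance matrix from a squared-distance matrix
center_codistance <- function(D2) {
  n <- nrow(D2)
  J <- diag(n) - matrix(1 / n, n, n)
  -0.5 * J %*% D2 %*% J
}

# r per distance class from the centered codistance matrix C and a class
# index matrix (NA = no class)
sp_class_r <- function(C, class_idx, n_classes) {
  vapply(seq_len(n_classes), function(h) {
    sel <- which(class_idx == h & upper.tri(class_idx), arr.ind = TRUE)
    if (nrow(sel) < 2) return(NA_real_)
    cxy <- sum(C[sel])
    cxx_yy <- 0.5 * (sum(diag(C)[sel[, 1]]) + sum(diag(C)[sel[, 2]]))
    if (cxx_yy <= 0) return(NA_real_)
    cxy / cxx_yy
  }, numeric(1))
}

#' Individual-level spatial genetic autocorrelation
#'
#' Smouse-Peakall multivariate autocorrelation: individual pairwise squared
#' genetic distances (multi-allelic codistances) are Gower-centered and,
#' within each geographic distance class, the autocorrelation
#' `r = c_xy / c_xx` is the ratio of summed off-diagonal codistances to the
#' summed diagonal terms of the pairs in the class.  The permutation null
#' shuffles individual locations (heterogeneity envelope per class); the
#' bootstrap resamples pairs within a class for a confidence interval on
#' `r`.  Distance classes are half-open intervals `(lower, upper]` over the
#' supplied endpoints, with the first class starting at 0.
#'
#' @param gt A [genotype_table()] of individual MLGs.
#' @param coords A matrix or data frame with one x/y (or lon/lat converted
#'   to km externally) row per sample, in km.
#' @param class_endpoints_km Upper endpoints of the distance classes (km).
#' @param n_perm Location permutations.
#' @param n_boot Pair bootstrap replicates.
#' @param seed Integer seed.
#' @return An `autocorr_result`: tibble with one row per class (`lower`,
#'   `upper`, `n_pairs`, `r`, `perm_lo`, `perm_hi`, `p_value`, `boot_lo`,
#'   `boot_hi`).
#' @export
spatial_autocorrelation <- function(gt, coords,
                                    class_endpoints_km = c(0.01, 0.025, 0.05, 5, 10, 15,
                                                           20, 25, 30, 35, 45, 60),
                                    n_perm = 999, n_boot = 999, seed = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(gt)) abort("one coordinate row per sample required")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(gt)
  geo <- as.matrix(stats::dist(coords))
  ends <- sort(class_endpoints_km)
  brk <- c(0, ends)
  class_idx <- matrix(findInterval(geo, brk, left.open = TRUE), n, n)
  class_idx[class_idx > length(ends)] <- NA # beyond last endpoint: unclassed
  diag(class_idx) <- NA
  C <- center_codistance(sp_genetic_d2(gt))
  r_obs <- sp_class_r(C, class_idx, length(ends))
  n_pairs <- vapply(seq_along(ends), function(h) {
    sum(class_idx == h & upper.tri(class_idx), na.rm = TRUE)
  }, integer(1))

  perm_lo <- perm_hi <- p_value <- rep(NA_real_, length(ends))
  if (n_perm > 0) {
    perm_r <- replicate(n_perm, {
      ord <- sample.int(n)
      sp_class_r(C, class_idx[ord, ord], length(ends))
    })
    perm_r <- matrix(perm_r, nrow = length(ends))
    for (h in seq_along(ends)) {
      if (is.na(r_obs[h])) next
      qs <- stats::quantile(perm_r[h, ], c(0.025, 0.975), na.rm = TRUE)
      perm_lo[h] <- qs[1]; perm_hi[h] <- qs[2]
      p_value[h] <- perm_pval(perm_r[h, ], r_obs[h])
    }
  }
  boot_lo <- boot_hi <- rep(NA_real_, length(ends))
  if (n_boot > 0) {
    for (h in seq_along(ends)) {
      sel <- which(class_idx == h & upper.tri(class_idx), arr.ind = TRUE)
      if (nrow(sel) < 2 || is.na(r_obs[h])) next
      rb <- replicate(n_boot, {
        bi <- sel[sample.int(nrow(sel), replace = TRUE), , drop = FALSE]
        cxy <- sum(C[bi])
        cxx_yy <- 0.5 * (sum(diag(C)[bi[, 1]]) + sum(diag(C)[bi[, 2]]))
        if (cxx_yy <= 0) NA_real_ else cxy / cxx_yy
      })
      qs <- stats::quantile(rb, c(0.025, 0.975), na.rm = TRUE)
      boot_lo[h] <- qs[1]; boot_hi[h] <- qs[2]
    }
  }
  res <- tibble(
    lower = brk[-length(brk)], upper = ends, n_pairs = n_pairs, r = r_obs,
    perm_lo = perm_lo, perm_hi = perm_hi, p_value = p_value,
    boot_lo = boot_lo, boot_hi = boot_hi
  )
  class(res) <- c("autocorr_result", class(res))
  res
}

#' Correlogram plot for a spatial autocorrelation result
#' @param object An `autocorr_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.autocorr_result <- function(object, ...) {
  df <- object[!is.na(object$r), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$upper, y = .data$r)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$perm_lo, ymax = .data$perm_hi),
                         fill = "grey80") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$boot_lo, ymax = .data$boot_hi)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Distance class upper endpoint (km)",
                  y = "Autocorrelation r",
                  title = "Spatial genetic autocorrelation") +
    ggplot2::theme_minimal()
}
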