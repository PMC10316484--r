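# Weir & Cockerham within-population b (among-individual) and c
# (within-individual) component sums for one locus given an n x 2 allele
# matrix (rows with NA skipped); f_IS = 1 - sum(c) / sum(b + c) over loci.
wc_within_locus <- function(al) {
  ok <- !is.na(al[, 1])
  n <- sum(ok)
  if (n < 2) return(c(b = NA_real_, c = NA_real_))
  a1 <- al[ok, 1]; a2 <- al[ok, 2]
  alleles <- unique(c(a1, a2))
  cnt <- outer(a1, alleles, "==") + outer(a2, alleles, "==")
  p <- colSums(cnt) / (2 * n)
  h <- colSums(cnt == 1) / n
  b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
  c(b = sum(b), c = sum(h) / 2)
}

# multi-locus F_IS from a list of n x 2 allele matrices
fis_from_mats <- function(mats) {
  comp <- vapply(mats, wc_within_locus, numeric(2))
  poly <- !is.na(comp["b", ]) & (comp["b", ] + comp["c", ]) > 0
  if (!any(poly)) return(NA_real_)
  1 - sum(comp["c", poly]) / sum(comp["b", poly] + comp["c", poly])
}

#' Per-site genetic diversity statistics
#'
#' Per-locus observed heterozygosity (`H_O` = heterozygote count /
#' genotyped count), Nei's unbiased expected heterozygosity
#' (`H_NB = (2n / (2n - 1)) (1 - sum(p_i^2))`), and the multi-locus
#' Weir-Cockerham inbreeding coefficient `F_IS` with a permutation test
#' (alleles shuffled among individuals within the site, two-sided with
#' add-one correction).  Monomorphic loci have `H_O = H_NB = 0` and are
#' excluded from the `F_IS` components.
#'
#' @param gt A [genotype_table()] subset to one site (typically
#'   clone-corrected).
#' @param n_perm Permutations for the F_IS test; 0 skips it.
#' @param seed Integer seed for the permutation test.
#' @return A list: `per_locus` tibble (`locus`, `n`, `n_alleles`, `h_o`,
#'   `h_nb`), and site summary scalars `n_alleles_total`, `h_o`, `h_nb`
#'   (means across loci), `f_is`, `f_is_p`.
#' @export
diversity_stats <- function(gt, n_perm = 999, seed = NULL) {
  lc <- loci(gt)
  per_locus <- purrr::map_dfr(lc, function(l) {
    al <- locus_alleles(gt, l)
    ok <- !is.na(al[, 1])
    n <- sum(ok)
    if (n == 0) abort(sprintf("locus %s entirely missing at this site", l))
    a1 <- al[ok, 1]; a2 <- al[ok, 2]
    alleles <- unique(c(a1, a2))
    p <- (tabulate(match(a1, alleles), length(alleles)) +
            tabulate(match(a2, alleles), length(alleles))) / (2 * n)
    h_o <- mean(a1 != a2)
    h_nb <- if (n >= 2) (2 * n) / (2 * n - 1) * (1 - sum(p^2)) else NA_real_
    tibble(locus = l, n = n, n_alleles = length(alleles), h_o = h_o, h_nb = h_nb)
  })
  mats <- lapply(lc, function(l) locus_alleles(gt, l))
  f_is <- fis_from_mats(mats)
  f_is_p <- NA_real_
  if (n_perm > 0 && is.finite(f_is)) {
    if (!is.null(seed)) set.seed(seed)
    null_stats <- replicate(n_perm, {
      fis_from_mats(lapply(mats, function(al) {
        ok <- !is.na(al[, 1])
        pool <- sample(c(al[ok, 1], al[ok, 2]))
        k <- sum(ok)
        al[ok, ] <- cbind(pool[seq_len(k)], pool[k + seq_len(k)])
        al
      }))
    })
    f_is_p <- perm_pval(abs(null_stats), abs(f_is))
  }
  list(
    per_locus = per_locus,
    n_alleles_total = sum(per_locus$n_alleles),
    h_o = mean(per_locus$h_o),
    h_nb = mean(per_locus$h_nb, na.rm = TRUE),
    f_is = f_is,
    f_is_p = f_is_p
  )
}

#' Rarefied allelic or private-allele richness
#'
#' Hypergeometric rarefaction on gene copies: standardized to `g` diploid
#' individuals (`2g` genes), the expected allele count per locus is
#' `sum_a (1 - choose(2n - N_a, 2g) / choose(2n, 2g))`.  Private-allele
#' richness follows Kalinowski's generalized rarefaction: the expected
#' number of alleles present in a `2g`-gene sample from the focal site and
#' absent from `2g`-gene samples of every other site.
#'
#' @param gt A [genotype_table()] covering the reference site set.
#' @param g Standardized number of diploid individuals.
#' @param private If `TRUE`, compute private-allele richness `P_A(g)`;
#'   otherwise allelic richness `A_R(g)`.
#' @return Tibble: `site_id`, `locus`, `value`, plus per-site means in the
#'   attribute-free summary column when grouped (`by_site()` helper below).
#' @export
rarefied_richness <- function(gt, g, private = FALSE) {
  sites <- unique(gt$site_id)
  lc <- loci(gt)
  # per site x locus: allele count table and gene totals
  counts <- lapply(sites, function(s) {
    sub <- filter_sites(gt, s)
    lapply(lc, function(l) {
      al <- locus_alleles(sub, l)
      ok <- !is.na(al[, 1])
      table(c(al[ok, 1], al[ok, 2]))
    })
  })
  names(counts) <- sites
  # presence probability of each allele in a 2g-gene subsample
  qprob <- function(tab, allele, g2) {
    n2 <- sum(tab)
    na <- if (allele %in% names(tab)) tab[[allele]] else 0L
    if (n2 < g2) abort(sprintf("g = %d exceeds genotyped individuals (n = %d)", g2 / 2, n2 %/% 2))
    1 - exp(lchoose(n2 - na, g2) - lchoose(n2, g2))
  }
  purrr::map_dfr(sites, function(s) {
    purrr::map_dfr(seq_along(lc), function(li) {
      tab <- counts[[s]][[li]]
      alleles <- names(tab)
      q_focal <- vapply(alleles, function(a) qprob(tab, a, 2 * g), numeric(1))
      if (!private) {
        value <- sum(q_focal)
      } else {
        other <- setdiff(sites, s)
        q_other <- vapply(alleles, function(a) {
          prod(vapply(other, function(o) 1 - qprob(counts[[o]][[li]], a, 2 * g), numeric(1)))
        }, numeric(1))
        value <- sum(q_focal * q_other)
      }
      tibble(site_id = s, locus = lc[li], value = value)
    })
  })
}

#' Maximum-likelihood null-allele estimation (Kalinowski-Taper model)
#'
#' EM fit of a single-locus model in which an unobservable null allele
#' (frequency `p_null`) inflates apparent homozygotes (null heterozygotes
#' score as homozygotes) and blanks arise from null homozygotes or an
#' amplification-failure rate `beta`.  Convergence when the log-likelihood
#' change is below `tol` or after `max_iter` iterations; non-convergence is
#' flagged, not raised.  Significance of `p_null > 0` is assessed by a
#' likelihood-ratio test, optionally calibrated by parametric bootstrap.
#'
#' @param gt A [genotype_table()] subset to one site.
#' @param locus Locus name.
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param p_method `"none"`, `"lrt"` (chi-square 1 df, halved for the
#'   boundary) or `"bootstrap"`.
#' @param n_boot Parametric bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @return List: `p_null`, `beta`, `loglik`, `loglik_null` (constrained
#'   `p_null = 0`), `converged`, `p_value`, `visible_freqs`.
#' @export
null_allele_ml <- function(gt, locus, tol = 1e-8, max_iter = 1000,
                           p_method = c("none", "lrt", "bootstrap"),
                           n_boot = 1000, seed = NULL) {
  p_method <- match.arg(p_method)
  al <- locus_alleles(gt, locus)
  n <- nrow(al)
  ok <- !is.na(al[, 1])
  if (sum(ok) < 10) warn(sprintf("fewer than 10 genotyped samples at %s; estimate unstable", locus))
  alleles <- sort(unique(c(al[ok, 1], al[ok, 2])))
  k <- length(alleles)
  a1 <- match(al[ok, 1], alleles); a2 <- match(al[ok, 2], alleles)
  hom <- a1 == a2
  hom_counts <- tabulate(a1[hom], k)
  het_idx <- cbind(a1[!hom], a2[!hom])
  het_allele_counts <- tabulate(c(het_idx), k)
  n_blank <- sum(!ok)

  fit_em <- function(allow_null) {
    p <- (hom_counts * 2 + het_allele_counts)
    p <- p / sum(p)
    pn <- if (allow_null) 0.05 else 0
    p <- p * (1 - pn)
    beta <- if (n_blank > 0) max(0.5 * n_blank / n, 1e-6) else 0
    ll_old <- -Inf; converged <- FALSE
    for (it in seq_len(max_iter)) {
      # observed-class probabilities
      p_hom_obs <- p[seq_len(k)]^2 + 2 * p[seq_len(k)] * pn
      p_blank <- pn^2 * (1 - beta) + beta
      # log-likelihood (hets: 2 p_i p_j; all classes scaled by (1 - beta))
      ll <- sum(hom_counts * log(pmax(p_hom_obs * (1 - beta), 1e-300))) +
        sum(log(pmax(2 * p[het_idx[, 1]] * p[het_idx[, 2]] * (1 - beta), 1e-300))) +
        n_blank * log(pmax(p_blank, 1e-300))
      if (abs(ll - ll_old) < tol) { converged <- TRUE; ll_old <- ll; break }
      ll_old <- ll
      # E-step: split observed homozygotes into true hom vs null het,
      # blanks into null hom vs failures
      w_true_hom <- ifelse(p_hom_obs > 0, p[seq_len(k)]^2 / p_hom_obs, 1)
      exp_true_hom <- hom_counts * w_true_hom
      exp_null_het <- hom_counts - exp_true_hom
      if (n_blank > 0 && (pn^2 * (1 - beta) + beta) > 0) {
        w_null_hom <- pn^2 * (1 - beta) / (pn^2 * (1 - beta) + beta)
      } else {
        w_null_hom <- 0
      }
      exp_null_hom <- n_blank * w_null_hom
      exp_fail <- n_blank - exp_null_hom
      # M-step
      gene_i <- 2 * exp_true_hom + exp_null_het + het_allele_counts
      gene_null <- sum(exp_null_het) + 2 * exp_null_hom
      total <- sum(gene_i) + gene_null
      if (allow_null) {
        p <- gene_i / total
        pn <- gene_null / total
      } else {
        p <- gene_i / sum(gene_i)
        pn <- 0
      }
      beta <- if (n_blank > 0) exp_fail / n else 0
    }
    list(p = p, p_null = pn, beta = beta, loglik = ll_old, converged = converged)
  }

  full <- fit_em(TRUE)
  null0 <- fit_em(FALSE)
  lrt <- 2 * (full$loglik - null0$loglik)
  p_value <- NA_real_
  if (p_method == "lrt") {
    p_value <- 0.5 * stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  } else if (p_method == "bootstrap") {
    if (!is.null(seed)) set.seed(seed)
    stat_boot <- replicate(n_boot, {
      # simulate genotypes under the no-null fit
      p0 <- null0$p; b0 <- null0$beta
      g1 <- sample.int(k, n, replace = TRUE, prob = p0)
      g2 <- sample.int(k, n, replace = TRUE, prob = p0)
      fail <- stats::runif(n) < b0
      sim <- gt[seq_len(n), c("sample_id", "site_id")]
      sim[[paste0(locus, ".1")]] <- ifelse(fail, NA_integer_, alleles[g1])
      sim[[paste0(locus, ".2")]] <- ifelse(fail, NA_integer_, alleles[g2])
      fit <- null_allele_ml(genotype_table(sim, locus), locus,
                            tol = tol, max_iter = max_iter, p_method = "none")
      2 * (fit$loglik - fit$loglik_null)
    })
    p_value <- perm_pval(stat_boot, lrt)
  }
  list(
    p_null = full$p_null, beta = full$beta,
    loglik = full$loglik, loglik_null = null0$loglik,
    converged = full$converged && null0$converged,
    p_value = p_value,
    visible_freqs = setNames(full$p, alleles)
  )
}

#' Standardized index of association
#'
#' Multilocus linkage disequilibrium statistic
#' `r_bar_d = sum_{l<m} cov(d_l, d_m) / sum_{l<m} sqrt(var(d_l) var(d_m))`
#' computed from per-locus pairwise genetic distances (number of differing
#' alleles, 0/1/2), with a sample-size-independent normalization.  The
#' permutation null shuffles the diploid genotype at each locus
#' independently among individuals, destroying between-locus association
#' while keeping single-locus structure.
#'
#' @param gt A clone-corrected [genotype_table()] with >= 2 loci.
#' @param n_perm Number of permutations (0 skips the test).
#' @param seed Integer seed.
#' @return List with `rbar_d`, `p_value`, `n_perm`.
#' @export
index_of_association_rd <- function(gt, n_perm = 999, seed = NULL) {
  lc <- loci(gt)
  if (length(lc) < 2) abort("the index of association needs >= 2 loci")
  n <- nrow(gt)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  I <- pr[, 1]; J <- pr[, 2]
  pair_dist <- function(al) {
    # allele mismatch count (0/1/2) over unordered pairs; the shared count
    # of two 2-allele multisets is the better of the direct and crossed
    # pairings
    direct <- (al[I, 1] == al[J, 1]) + (al[I, 2] == al[J, 2])
    crossed <- (al[I, 1] == al[J, 2]) + (al[I, 2] == al[J, 1])
    v <- 2 - pmax(direct, crossed)
    v[is.na(al[I, 1]) | is.na(al[J, 1])] <- NA
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    v
  }
  rbar_from <- function(dmat) {
    vars <- apply(dmat, 2, function(x) mean(x^2) - mean(x)^2)
    cv <- stats::cov(dmat) * (nrow(dmat) - 1) / nrow(dmat)
    num <- sum(cv[upper.tri(cv)])
    den <- sum(outer(sqrt(vars), sqrt(vars))[upper.tri(cv)])
    if (den == 0) return(NA_real_)
    num / den
  }
  dmat <- vapply(lc, function(l) pair_dist(locus_alleles(gt, l)), numeric(n * (n - 1) / 2))
  obs <- rbar_from(dmat)
  p_value <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    null_stats <- replicate(n_perm, {
      g2 <- gt
      for (l in lc) {
        ord <- sample.int(n)
        g2[[paste0(l, ".1")]] <- gt[[paste0(l, ".1")]][ord]
        g2[[paste0(l, ".2")]] <- gt[[paste0(l, ".2")]][ord]
      }
      d2 <- vapply(lc, function(l) pair_dist(locus_alleles(g2, l)), numeric(n * (n - 1) / 2))
      rbar_from(d2)
    })
    p_value <- perm_pval(null_stats, obs)
  }
  list(rbar_d = obs, p_value = p_value, n_perm = n_perm)
}

#' Per-site diversity summary table
#'
#' Assembles the per-site summary of a clonal population-genetics survey:
#' sample count `N`, MLG count `G`, clonal richness `R`, observed allele
#' count `nA`, rarefied allelic richness `A_R(g)` and private-allele
#' richness `P_A(g)` (means across loci), observed and Nei unbiased
#' heterozygosity, multi-locus Weir-Cockerham `F_IS` with permutation
#' p-value, cumulative PID and `PID_N`.  `N`, `G`, `R` and PID are computed
#' on all samples; heterozygosities, `F_IS` and rarefied richness on the
#' clone-corrected (unique-MLG) dataset.
#'
#' @param gt A [genotype_table()].
#' @param g Standardized MLG count for rarefaction; sites with fewer
#'   genotyped MLGs get `NA`.
#' @param missing_policy Passed to [identify_mlgs()].
#' @param n_perm Permutations for the F_IS test.
#' @param seed Integer seed.
#' @return A tibble with one row per site.
#' @export
site_diversity <- function(gt, g = 14, missing_policy = "strict",
                           n_perm = 199, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  part <- identify_mlgs(gt, missing_policy)
  cc <- clone_correct(gt, part)
  min_mlgs <- purrr::map_int(unique(cc$site_id), function(s) {
    sub <- filter_sites(cc, s)
    min(vapply(loci(cc), function(l) sum(!is.na(sub[[paste0(l, ".1")]])), integer(1)))
  })
  names(min_mlgs) <- unique(cc$site_id)
  ar <- if (all(min_mlgs >= g)) rarefied_richness(cc, g, private = FALSE) else NULL
  pa <- if (all(min_mlgs >= g)) rarefied_richness(cc, g, private = TRUE) else NULL
  purrr::map_dfr(unique(gt$site_id), function(s) {
    full_sub <- filter_sites(gt, s)
    cc_sub <- filter_sites(cc, s)
    bs <- part$by_site[part$by_site$site_id == s, ]
    ds <- diversity_stats(cc_sub, n_perm = n_perm)
    pid <- probability_of_identity(full_sub)
    tibble(
      site_id = s,
      N = bs$N, G = bs$G, R = bs$R,
      nA = ds$n_alleles_total,
      A_R = if (is.null(ar)) NA_real_ else mean(ar$value[ar$site_id == s]),
      P_A = if (is.null(pa)) NA_real_ else mean(pa$value[pa$site_id == s]),
      H_O = ds$h_o, H_NB = ds$h_nb,
      F_IS = ds$f_is, F_IS_p = ds$f_is_p,
      PID = pid$pid_cumulative[nrow(pid)],
      PID_N = pid$pid_n[nrow(pid)]
    )
  })
}
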