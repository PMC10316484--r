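test_that("heterozygosities match hand-computed values", {
  # 10 AB heterozygotes: H_O = 1, H_NB = (2n/(2n-1)) (1 - 0.5) = 20/19 * 0.5
  gt <- toy_gt(matrix(rep(c(120, 124), 10), 10, byrow = TRUE))
  ds <- diversity_stats(gt, n_perm = 0)
  expect_equal(ds$per_locus$h_o, 1)
  expect_equal(ds$per_locus$h_nb, (20 / 19) * 0.5, tolerance = 1e-12)
  expect_lt(ds$f_is, 0)
})

test_that("a monomorphic locus contributes zero diversity and no F_IS", {
  gt <- toy_gt(cbind(120, 120, c(180, 184, 180, 184), c(184, 180, 184, 180)))
  ds <- diversity_stats(gt, n_perm = 0)
  expect_equal(ds$per_locus$h_o[1], 0)
  expect_equal(ds$per_locus$h_nb[1], 0)
  # F_IS comes from the polymorphic locus only and is finite
  expect_true(is.finite(ds$f_is))
})

test_that("the F_IS estimator recovers simulated inbreeding", {
  est <- vapply(1:6, function(s) {
    sim <- simulate_genotypes(1, 80, 12, theta = 0, f = 0.4, clonality = 0,
                              missing_rate = 0, seed = 600 + s)
    diversity_stats(sim$genotypes, n_perm = 0)$f_is
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.4), 0.05)
})

test_that("rarefaction reproduces the exhaustive two-gene enumeration", {
  # one locus, alleles with gene counts (3, 1) in n = 2 diploids, g = 1
  gt <- toy_gt(rbind(c(120, 120), c(120, 124)))
  rr <- rarefied_richness(gt, g = 1)
  expect_equal(rr$value, 1.5, tolerance = 1e-12)
})

test_that("rarefaction at the full sample equals the observed allele count", {
  sim <- simulate_genotypes(2, 12, 5, missing_rate = 0, seed = 4)
  gt <- sim$genotypes
  rr <- rarefied_richness(gt, g = 12)
  obs <- allele_freqs(filter_sites(gt, "S01")) |>
    dplyr::count(locus)
  merged <- merge(rr[rr$site_id == "S01", ], obs, by = "locus")
  expect_equal(merged$value, as.numeric(merged$n), tolerance = 1e-10)
  # and the rarefied value never exceeds the observed count
  rr2 <- rarefied_richness(gt, g = 5)
  merged2 <- merge(rr2[rr2$site_id == "S01", ], obs, by = "locus")
  expect_true(all(merged2$value <= merged2$n + 1e-12))
})

test_that("monomorphic full-sample rarefaction is exactly 1", {
  gt <- toy_gt(cbind(120, 120, c(180, 184), c(184, 180)))
  rr <- rarefied_richness(gt, g = 2)
  expect_equal(rr$value[rr$locus == "L01"], 1)
})

test_that("private-allele rarefaction zeroes shared alleles and flags unique ones", {
  # site A carries allele 124 privately; allele 120 is shared
  ga <- rbind(c(120, 124), c(120, 124))
  gb <- rbind(c(120, 120), c(120, 120))
  gt <- toy_gt(rbind(ga, gb), site = rep(c("A", "B"), each = 2))
  pa <- rarefied_richness(gt, g = 2, private = TRUE)
  # in B nothing is private (120 always present in A's sample too)
  expect_lt(pa$value[pa$site_id == "B"], 1e-12)
  # in A, allele 124 is certainly sampled (every individual carries it)
  expect_equal(pa$value[pa$site_id == "A"], 1, tolerance = 1e-12)
})

test_that("null-allele EM returns zero for all-heterozygote data", {
  gt <- toy_gt(matrix(rep(c(120, 124), 20), 20, byrow = TRUE))
  fit <- null_allele_ml(gt, "L01")
  expect_lt(fit$p_null, 1e-4)
  expect_true(fit$converged)
})

test_that("null-allele EM recovers a simulated null frequency", {
  set.seed(77)
  n <- 400; p_null <- 0.15
  vis <- c(0.5, 0.35) * (1 - p_null)
  pr <- c(vis, p_null)
  sizes <- c(120L, 124L)
  a1 <- sample(1:3, n, TRUE, pr); a2 <- sample(1:3, n, TRUE, pr)
  both_null <- a1 == 3 & a2 == 3
  get_size <- function(a, b) {
    # a null allele makes the genotype look homozygous for the visible one
    vis_a <- ifelse(a == 3, b, a)
    sizes[vis_a]
  }
  m <- cbind(ifelse(both_null, 0L, get_size(a1, a2)),
             ifelse(both_null, 0L, get_size(a2, a1)))
  fit <- null_allele_ml(toy_gt(m), "L01")
  expect_lt(abs(fit$p_null - p_null), 0.05)
  expect_true(fit$converged)
})

test_that("null-allele EM stays near zero when no nulls exist", {
  est <- vapply(1:20, function(s) {
    set.seed(900 + s)
    a1 <- sample(c(120L, 124L, 128L), 48, TRUE)
    a2 <- sample(c(120L, 124L, 128L), 48, TRUE)
    suppressWarnings(null_allele_ml(toy_gt(cbind(a1, a2)), "L01")$p_null)
  }, numeric(1))
  expect_gte(mean(est < 0.05), 0.9)
})

test_that("perfectly linked duplicated loci give r_bar_d of 1", {
  set.seed(11)
  a1 <- sample(c(120L, 124L, 128L), 20, TRUE)
  a2 <- sample(c(120L, 124L, 128L), 20, TRUE)
  gt <- toy_gt(cbind(a1, a2, a1, a2)) # locus 2 duplicates locus 1
  res <- index_of_association_rd(gt, n_perm = 0)
  expect_equal(res$rbar_d, 1, tolerance = 1e-12)
})

test_that("r_bar_d requires at least two loci", {
  gt <- toy_gt(rbind(c(120, 124), c(120, 120)))
  expect_error(index_of_association_rd(gt), "2 loci")
})

test_that("r_bar_d matches a brute-force variance computation", {
  set.seed(12)
  mat <- cbind(sample(c(120L, 124L), 12, TRUE), sample(c(120L, 124L), 12, TRUE),
               sample(c(200L, 204L), 12, TRUE), sample(c(200L, 204L), 12, TRUE),
               sample(c(300L, 304L, 308L), 12, TRUE), sample(c(300L, 304L), 12, TRUE))
  gt <- toy_gt(mat)
  res <- index_of_association_rd(gt, n_perm = 0)
  # brute force: per-locus mismatch vectors, covariance form
  n <- 12
  dvec <- function(l) {
    al <- cbind(gt[[paste0("L0", l, ".1")]], gt[[paste0("L0", l, ".2")]])
    out <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      tab_i <- table(al[i, ]); tab_j <- table(al[j, ])
      shared <- sum(pmin(tab_i[names(tab_j)], tab_j[names(tab_j)]), na.rm = TRUE)
      out <- c(out, 2 - shared)
    }
    out
  }
  D <- sapply(1:3, dvec)
  pv <- function(x) mean(x^2) - mean(x)^2
  covs <- combn(3, 2, function(ij) {
    mean(D[, ij[1]] * D[, ij[2]]) - mean(D[, ij[1]]) * mean(D[, ij[2]])
  })
  dens <- combn(3, 2, function(ij) sqrt(pv(D[, ij[1]]) * pv(D[, ij[2]])))
  expect_equal(res$rbar_d, sum(covs) / sum(dens), tolerance = 1e-12)
})

test_that("site_diversity assembles the per-site summary with sane ranges", {
  sim <- simulate_genotypes(3, 16, 6, clonality = 0.3, seed = 21)
  tab <- site_diversity(sim$genotypes, g = 5, missing_policy = "permissive",
                        n_perm = 49, seed = 1)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$R >= 0 & tab$R <= 1))
  expect_true(all(tab$H_O >= 0 & tab$H_O <= 1))
  expect_true(all(tab$H_NB >= 0 & tab$H_NB <= 1))
  expect_true(all(tab$PID > 0 & tab$PID <= 1))
  expect_equal(tab$PID_N, tab$N * tab$PID)
  expect_true(all(tab$G <= tab$N))
})
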