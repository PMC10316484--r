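# independent direct-formula Weir-Cockerham implementation used as the
# cross-check oracle: explicit per-allele loops, no shared code with the
# package's vectorized version
wc_oracle <- function(gt) {
  lc <- loci(gt)
  A <- B <- C <- 0
  for (l in lc) {
    al <- cbind(gt[[paste0(l, ".1")]], gt[[paste0(l, ".2")]])
    ok <- !is.na(al[, 1])
    pop <- factor(gt$site_id[ok])
    if (nlevels(pop) < 2) next
    a1 <- al[ok, 1]; a2 <- al[ok, 2]
    r <- nlevels(pop)
    n_i <- as.numeric(table(pop))
    nbar <- mean(n_i)
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    alleles <- sort(unique(c(a1, a2)))
    if (length(alleles) < 2) next
    for (al_v in alleles) {
      p_i <- h_i <- numeric(r)
      for (k in seq_len(r)) {
        sel <- pop == levels(pop)[k]
        p_i[k] <- (sum(a1[sel] == al_v) + sum(a2[sel] == al_v)) / (2 * n_i[k])
        h_i[k] <- sum((a1[sel] == al_v) != (a2[sel] == al_v)) / n_i[k]
      }
      pbar <- sum(n_i * p_i) / sum(n_i)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / sum(n_i)
      A <- A + nbar / nc *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      B <- B + nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      C <- C + hbar / 2
    }
  }
  A / (A + B + C)
}

test_that("fixed differences give theta of 1 and duplicated sites near 0", {
  fixed <- toy_gt(rbind(matrix(rep(c(120, 120, 200, 200), 6), 6, byrow = TRUE),
                        matrix(rep(c(124, 124, 204, 204), 6), 6, byrow = TRUE)),
                  site = rep(c("A", "B"), each = 6))
  expect_equal(fst(fixed, n_perm = 0, pairwise = FALSE)$theta, 1)

  set.seed(3)
  one <- matrix(sample(seq(100, 110, 2), 40, TRUE), 10)
  dup <- toy_gt(rbind(one, one), site = rep(c("A", "B"), each = 10))
  res <- fst(dup, n_perm = 99, pairwise = FALSE, seed = 4)
  expect_lt(abs(res$theta), 0.05)
  expect_gt(res$p_value, 0.05)
})

test_that("the vectorized estimator agrees with the direct-formula oracle", {
  set.seed(8)
  for (rep in 1:4) {
    n_sites <- sample(2:4, 1)
    sim <- simulate_genotypes(n_sites, 20, 5, theta = 0.15, f = 0.2,
                              missing_rate = 0.05, seed = 800 + rep)
    gt <- sim$genotypes
    expect_equal(fst(gt, n_perm = 0, pairwise = FALSE)$theta, wc_oracle(gt),
                 tolerance = 1e-12)
  }
})

test_that("theta recovery on Balding-Nichols data at the study scale", {
  est <- vapply(1:5, function(s) {
    sim <- simulate_genotypes(6, 30, 10, theta = 0.2, f = 0, clonality = 0,
                              missing_rate = 0, seed = 50 + s)
    fst(sim$genotypes, n_perm = 0, pairwise = FALSE)$theta
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.2), 0.03)
})

test_that("pairwise matrix is symmetric with labelled sites", {
  sim <- simulate_genotypes(3, 12, 5, seed = 31, missing_rate = 0)
  res <- fst(sim$genotypes, n_perm = 0, pairwise = TRUE)
  expect_equal(res$pairwise, t(res$pairwise))
  expect_equal(rownames(res$pairwise), c("S01", "S02", "S03"))
})

test_that("undersized sites are excluded with a warning", {
  m <- rbind(matrix(rep(c(120, 124), 2 * 5), 5, byrow = TRUE),
             matrix(rep(c(120, 120), 2 * 5), 5, byrow = TRUE),
             c(124, 124))
  gt <- toy_gt(m, site = c(rep("A", 5), rep("B", 5), "C"))
  expect_warning(res <- fst(gt, n_perm = 0, pairwise = FALSE), "excluding")
  expect_equal(sort(res$sites_used), c("A", "B"))
})

test_that("linearized F_ST matches Rousset's transform with clamping", {
  expect_equal(linearize_fst(0), 0)
  expect_equal(linearize_fst(0.5), 1)
  expect_equal(linearize_fst(0.336), 0.336 / 0.664)
  expect_equal(linearize_fst(-0.02), 0) # negative clamped first
  expect_error(linearize_fst(1), "linearized")
  x <- seq(0, 0.95, 0.05)
  expect_true(all(diff(linearize_fst(x)) > 0)) # monotone
})

test_that("collinear per-locus G_ST and H_S give a correlation of 1", {
  # construct loci whose G_ST and H_S move together by varying divergence
  set.seed(5)
  mk_locus <- function(p_a, p_b) {
    a <- replicate(30, sample(c(120L, 124L), 2, TRUE, c(p_a, 1 - p_a)))
    b <- replicate(30, sample(c(120L, 124L), 2, TRUE, c(p_b, 1 - p_b)))
    rbind(t(a), t(b))
  }
  mats <- list(mk_locus(0.95, 0.05), mk_locus(0.85, 0.15),
               mk_locus(0.7, 0.3), mk_locus(0.55, 0.45))
  gt <- toy_gt(do.call(cbind, mats), site = rep(c("A", "B"), each = 30))
  res <- gst_hs_correlation(gt, n_boot = 200, seed = 2)
  expect_true(is.finite(res$r_gh))
  expect_equal(abs(res$r_gh), 1, tolerance = 0.25) # strongly collinear by design
  # and exact collinearity check via the direct Pearson formula
  pl <- res$per_locus
  direct <- sum((pl$g_st - mean(pl$g_st)) * (pl$h_s - mean(pl$h_s))) /
    sqrt(sum((pl$g_st - mean(pl$g_st))^2) * sum((pl$h_s - mean(pl$h_s))^2))
  expect_equal(res$r_gh, direct, tolerance = 1e-12)
})

test_that("degenerate G_ST-H_S input errors cleanly", {
  gt <- toy_gt(cbind(120, 120, 200, 200, 300, 300),
               site = rep(c("A", "B"), each = 1))
  expect_error(gst_hs_correlation(gt), "variance|undefined")
})

test_that("Evanno delta-K matches hand arithmetic and flags endpoints", {
  mk <- function(K, mu) data.frame(K = K, logL = c(mu - 0.5, mu + 0.5))
  tab <- rbind(mk(1, -100), mk(2, -50), mk(3, -45), mk(4, -44))
  res <- evanno_delta_k(tab)
  sdv <- sd(c(-0.5, 0.5)) # all K share this spread
  expect_equal(res$delta_k[res$K == 2], 45 / sdv)
  expect_true(is.na(res$delta_k[res$K == 1]) && is.na(res$delta_k[res$K == 4]))
  expect_equal(attr(res, "best_k"), 2L)
  # linear mean likelihood: all interior delta-K are zero
  lin <- rbind(mk(1, -30), mk(2, -20), mk(3, -10), mk(4, 0))
  expect_true(all(evanno_delta_k(lin)$delta_k[2:3] == 0))
})

test_that("delta-K input validation catches short or degenerate tables", {
  expect_error(evanno_delta_k(data.frame(K = c(1, 2), logL = c(1, 2))), ">= 3")
  one_run <- data.frame(K = 1:3, logL = 1:3)
  expect_error(evanno_delta_k(one_run), "2 runs")
})
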