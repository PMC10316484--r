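env2 <- function() {
  environment_table(data.frame(
    site_id = c("A", "B"), depth = c(0, 5), sediment = c("sand", "sand"),
    habitat = c("reef terrace", "reef terrace"), n_other_seagrass = c(1, 1),
    coral_present = c(TRUE, TRUE)
  ))
}

test_that("Gower dissimilarity matches hand computation on mixed columns", {
  # only depth varies: numeric range-normalized difference 1, averaged over
  # usable columns (constant numeric columns are excluded, categorical
  # matches contribute 0)
  suppressWarnings(D <- gower_dissimilarity(env2()))
  # columns used: depth (1), sediment (0), habitat (0), coral (0);
  # n_other_seagrass constant numeric -> excluded
  expect_equal(D["A", "B"], 1 / 4)
  env <- environment_table(data.frame(
    site_id = c("A", "B"), depth = c(0, 5), sediment = c("sand", "silt"),
    habitat = c("reef terrace", "reef lagoon"), n_other_seagrass = c(0, 3),
    coral_present = c(TRUE, FALSE)
  ))
  expect_equal(gower_dissimilarity(env)["A", "B"], 1) # extremes everywhere
  expect_equal(diag(gower_dissimilarity(env)), c(A = 0, B = 0))
})

test_that("Gower agrees with cluster::daisy on a larger mixed table", {
  skip_if_not_installed("cluster")
  sites <- rand_sites(8, seed = 3)
  env <- simulate_environment(sites, "none", seed = 3)
  D <- gower_dissimilarity(env)
  df <- as.data.frame(env[, c("depth", "sediment", "habitat",
                              "n_other_seagrass", "coral_present")])
  df$n_other_seagrass <- as.numeric(df$n_other_seagrass)
  df$coral_present <- factor(df$coral_present)
  ref <- as.matrix(cluster::daisy(df, metric = "gower"))
  expect_equal(unname(D), unname(ref), tolerance = 1e-10)
})

test_that("Mantel recovers perfect and inverted association", {
  set.seed(7)
  pts <- cbind(runif(8), runif(8))
  A <- lab(as.matrix(dist(pts)))
  res <- mantel_test(A, A, n_perm = 199, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)
  B <- lab(max(A) - A); diag(B) <- 0
  expect_equal(mantel_test(A, B, n_perm = 99, seed = 1)$r, -1, tolerance = 1e-12)
})

test_that("PCoA reproduces simplex geometry and round-trips Euclidean configurations", {
  D3 <- lab(matrix(1, 3, 3) - diag(3))
  res <- pcoa(D3)
  ev <- res$eigenvalues
  expect_equal(ev[1], ev[2], tolerance = 1e-10)
  expect_lt(abs(ev[3]), 1e-10)
  expect_equal(res$n_positive, 2)

  set.seed(10)
  X <- cbind(rnorm(9), rnorm(9))
  D <- lab(as.matrix(dist(X)))
  rt <- pcoa(D)
  Dhat <- as.matrix(dist(rt$scores))
  expect_equal(unname(Dhat), unname(D), tolerance = 1e-10)
  expect_error(pcoa(lab(matrix(0, 3, 3))), "positive")
})

test_that("PCoA matches the ape reference implementation", {
  skip_if_not_installed("ape")
  set.seed(11)
  X <- cbind(rnorm(7), rnorm(7), rnorm(7))
  D <- lab(as.matrix(dist(X)))
  ours <- pcoa(D)
  ref <- ape::pcoa(as.dist(D))
  expect_equal(ours$eigenvalues[seq_len(ncol(ref$vectors))],
               ref$values$Eigenvalues[seq_len(ncol(ref$vectors))], tolerance = 1e-8)
  for (k in seq_len(ncol(ref$vectors))) {
    expect_equal(abs(cor(ours$scores[, k], ref$vectors[, k])), 1, tolerance = 1e-8)
  }
})

test_that("PCNM with an inert truncation reduces to plain PCoA", {
  set.seed(12)
  pts <- cbind(runif(8, 0, 10), runif(8, 0, 10))
  D <- lab(as.matrix(dist(pts)))
  res <- pcnm_axes(D, truncation = 2 * max(D))
  ref <- pcoa(D)
  k <- min(ncol(res$scores) - 1, ncol(ref$scores))
  for (j in seq_len(k)) {
    expect_equal(abs(cor(res$scores[[j + 1]], ref$scores[, j])), 1, tolerance = 1e-6)
  }
  expect_lte(ncol(res$scores) - 1, 7) # at most n - 1 axes
})

test_that("PCNM axes on a transect match a direct eigen-decomposition oracle", {
  x <- seq(0, 90, by = 10)
  D <- lab(as.matrix(dist(cbind(x, 0))))
  res <- pcnm_axes(D) # default truncation: longest MST edge (10)
  t_thr <- res$threshold
  expect_equal(t_thr, 10, tolerance = 1e-10)
  Dt <- D; Dt[Dt > t_thr] <- 4 * t_thr
  n <- nrow(Dt)
  G <- -0.5 * (diag(n) - 1 / n) %*% Dt^2 %*% (diag(n) - 1 / n)
  ev <- eigen((G + t(G)) / 2, symmetric = TRUE)
  n_pos_oracle <- sum(ev$values > 1e-8 * max(ev$values))
  expect_equal(ncol(res$scores) - 1, n_pos_oracle)
  # low-order axes resemble cosine waves: count sign changes
  sc1 <- res$scores[[2]]
  expect_equal(sum(diff(sign(sc1)) != 0), 1) # first axis: one sign change
})

test_that("correspondence analysis separates block-diagonal structure", {
  tab <- rbind(cbind(matrix(5, 3, 2), matrix(0, 3, 2)),
               cbind(matrix(0, 3, 2), matrix(5, 3, 2)))
  rownames(tab) <- sprintf("S%d", 1:6)
  res <- correspondence_analysis(tab)
  grp <- rep(c(1, 2), each = 3)
  expect_true(all(sign(res$scores$CA1[grp == 1]) != sign(res$scores$CA1[grp == 2])))
  # oracle: direct SVD of standardized residuals
  P <- tab / sum(tab); r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %o% cc) %*% diag(1 / sqrt(cc))
  d <- svd(S)$d
  expect_equal(res$inertia_share[1], d[1]^2 / sum(d^2), tolerance = 1e-10)
})

test_that("CA rejects degenerate tables and keeps chi-square orthogonality", {
  expect_error(correspondence_analysis(matrix(1, 4, 3)), "inertia")
  expect_error(correspondence_analysis(rbind(c(1, 0), c(0, 0))), "zero")
  set.seed(13)
  tab <- matrix(rpois(30, 4) + 1, 6, 5)
  rownames(tab) <- sprintf("S%d", 1:6)
  res <- correspondence_analysis(tab)
  r <- rowSums(tab) / sum(tab)
  Fm <- as.matrix(res$scores[, -1])
  gram <- t(Fm) %*% diag(r) %*% Fm
  expect_equal(gram[upper.tri(gram)], rep(0, sum(upper.tri(gram))), tolerance = 1e-10)
})

test_that("environment encoding is nonnegative with range-scaled numerics", {
  sites <- rand_sites(6, seed = 5)
  env <- simulate_environment(sites, "grouped", groups = rep(c("A", "B"), 3), seed = 5)
  M <- encode_environment(env)
  expect_true(all(M >= 0))
  expect_true(all(M[, "depth"] >= 0 & M[, "depth"] <= 1))
  expect_true(all(rowSums(M[, grep("sediment", colnames(M)), drop = FALSE]) == 1))
})

test_that("predictor-axis selection honours both rules", {
  set.seed(14)
  cand <- tibble::tibble(site_id = sprintf("S%d", 1:10),
                         a1 = rnorm(10), a2 = rnorm(10), a3 = rnorm(10))
  expect_equal(ncol(select_predictor_axes(cand, k = 3)) - 1, 3) # identity
  expect_error(select_predictor_axes(cand, k = 5), "exceeds")
  resp <- cbind(cand$a1 + rnorm(10, 0, 0.01), rnorm(10))
  # screen drops the axis collinear with the response
  kept <- select_predictor_axes(cand, resp, rule = "correlation_screen",
                                threshold = 0.9)
  expect_false("a1" %in% names(kept))
  # threshold 0 keeps nothing
  none <- select_predictor_axes(cand, resp, rule = "correlation_screen", threshold = 0)
  expect_equal(ncol(none) - 1, 0)
})
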