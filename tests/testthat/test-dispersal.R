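test_that("uniform flow displaces particles exactly and zero flow leaves them still", {
  f <- simulate_velocity_field("uniform", extent = c(0, 50e3, 0, 30e3),
                               duration_h = 200, u0 = 0.1, v0 = 0)
  tr <- advect(f, matrix(c(5e3, 15e3), 1), duration_h = 1, diffusivity = 0)
  expect_equal(tr$positions[1, 1, 2] - tr$positions[1, 1, 1], 360, tolerance = 1e-9)
  expect_equal(tr$positions[1, 2, 2], 15e3, tolerance = 1e-9)

  f0 <- simulate_velocity_field("uniform", u0 = 0, v0 = 0, duration_h = 200)
  tr0 <- advect(f0, matrix(c(20e3, 20e3), 1), duration_h = 168, diffusivity = 0)
  expect_true(all(tr0$positions[1, 1, ] == 20e3))
  expect_true(all(tr0$positions[1, 2, ] == 20e3))
})

test_that("solid-rotation orbits close to within 0.1% of the radius", {
  om <- 2 * pi / (24 * 3600)
  f <- simulate_velocity_field("solid_rotation", extent = c(0, 50e3, 0, 50e3),
                               duration_h = 30, omega = om, spacing = 1000)
  start <- matrix(c(25e3 + 8e3, 25e3), 1)
  tr <- advect(f, start, duration_h = 24, diffusivity = 0, substeps = 4)
  err <- sqrt(sum((tr$positions[1, , 25] - start)^2))
  expect_lt(err / 8e3, 0.001)
})

test_that("halving the substep size shrinks the orbit error by about 16x", {
  om <- 2 * pi / (12 * 3600) # faster rotation makes the error measurable
  f <- simulate_velocity_field("solid_rotation", extent = c(0, 50e3, 0, 50e3),
                               duration_h = 15, omega = om, spacing = 1000)
  start <- matrix(c(25e3 + 10e3, 25e3), 1)
  err_of <- function(ss) {
    tr <- advect(f, start, duration_h = 12, diffusivity = 0, substeps = ss)
    sqrt(sum((tr$positions[1, , 13] - start)^2))
  }
  ratio <- err_of(1) / err_of(2)
  expect_gt(ratio, 8); expect_lt(ratio, 32)
})

test_that("diffusion-only spread follows the 4Kt law", {
  f <- simulate_velocity_field("uniform", extent = c(-60e3, 60e3, -60e3, 60e3),
                               duration_h = 30, u0 = 0, v0 = 0)
  n <- 10000
  tr <- advect(f, cbind(rep(0, n), rep(0, n)), duration_h = 24,
               diffusivity = 1, seed = 99)
  disp <- tr$positions[, , 25] - tr$positions[, , 1]
  msd <- mean(rowSums(disp^2))
  expect_lt(abs(msd / (4 * 1 * 24 * 3600) - 1), 0.05)
})

test_that("advection refuses land starts and out-of-range durations", {
  msk <- matrix(FALSE, 25, 15); msk[1:5, ] <- TRUE
  f <- simulate_velocity_field("uniform", extent = c(0, 50e3, 0, 30e3),
                               duration_h = 20, land_mask = msk)
  expect_error(advect(f, matrix(c(2e3, 10e3), 1), duration_h = 5), "land")
  expect_error(advect(f, matrix(c(30e3, 10e3), 1), duration_h = 100), "coverage")
})

test_that("frozen particles stay off land while beached ones stop", {
  msk <- matrix(FALSE, 25, 15); msk[15:25, ] <- TRUE # land wall to the east
  f <- simulate_velocity_field("uniform", extent = c(0, 50e3, 0, 30e3),
                               duration_h = 60, u0 = 0.5, v0 = 0, land_mask = msk)
  tr <- advect(f, matrix(c(5e3, 15e3), 1), duration_h = 48, diffusivity = 0,
               land_policy = "freeze")
  land_x <- f$x[15] - f$spacing / 2
  expect_true(all(tr$positions[1, 1, ] < land_x + f$spacing))
  trb <- advect(f, matrix(c(5e3, 15e3), 1), duration_h = 48, diffusivity = 0,
                land_policy = "beach")
  expect_equal(as.character(trb$status[1]), "beached")
})

test_that("two-site uniform flow yields strictly one-directional connectivity", {
  f <- simulate_velocity_field("uniform", extent = c(0, 60e3, 0, 20e3),
                               duration_h = 220, u0 = 0.2, v0 = 0)
  sites <- site_table(data.frame(site_id = c("A", "B"), x = c(10e3, 25e3),
                                 y = 10e3, region = "all"), "planar")
  sch <- release_schedule(f, particles_per_site = 40, interval_days = 1,
                          season_end_h = 48, duration_h = 168)
  rr <- run_releases(f, sites, sch, diffusivity = 1, seed = 5)
  C <- connectivity_matrix(rr, diagonal = "zero")
  expect_gt(C["A", "B"], 0)
  expect_equal(C["B", "A"], 0)
})

test_that("stationary particles are detected only at their own site", {
  f <- simulate_velocity_field("uniform", extent = c(0, 40e3, 0, 20e3),
                               duration_h = 200, u0 = 0, v0 = 0)
  sites <- site_table(data.frame(site_id = "A", x = 10e3, y = 10e3,
                                 region = "all"), "planar")
  sch <- release_schedule(f, particles_per_site = 100, interval_days = 7,
                          season_end_h = 0, duration_h = 168)
  rr <- run_releases(f, sites, sch, diffusivity = 0, seed = 2)
  C <- connectivity_matrix(rr, diagonal = "keep")
  expect_equal(unname(C["A", "A"]), 100)
})

test_that("connectivity averages counts over releases", {
  counts <- array(0L, c(2, 2, 2), dimnames = list(NULL, c("A", "B"), c("A", "B")))
  counts[1, 1, 2] <- 3L; counts[2, 1, 2] <- 4L
  C <- connectivity_matrix(counts, diagonal = "zero")
  expect_equal(unname(C["A", "B"]), 3.5)
  # linearity: averaging then summing equals summing then averaging
  expect_equal(sum(C), sum(apply(counts, c(2, 3), mean)) - sum(diag(apply(counts, c(2, 3), mean))))
})

test_that("open-sea overwater distances track straight lines within the 16-neighbour bound", {
  msk <- matrix(FALSE, 60, 40)
  x <- seq(1e3, 120e3, by = 2e3); y <- seq(1e3, 80e3, by = 2e3)
  sites <- site_table(data.frame(site_id = c("A", "B", "C"),
                                 x = c(11e3, 91e3, 51e3),
                                 y = c(11e3, 61e3, 71e3), region = "all"), "planar")
  D <- overwater_distance(msk, x, y, sites, neighbors = 16)
  straight <- as.matrix(dist(cbind(sites$x, sites$y))) / 1000
  rel <- (D - straight) / (straight + diag(3))
  expect_true(all(rel[upper.tri(rel)] >= -1e-9))
  # worst-case 16-neighbour (octile + knight) discretization overestimate is
  # 1/cos(13.28 deg) - 1, about 2.8%
  expect_true(all(rel[upper.tri(rel)] < 1 / cos(13.2825 * pi / 180) - 1 + 1e-6))
  # triangle inequality
  expect_lte(D["A", "B"], D["A", "C"] + D["C", "B"] + 1e-9)
})

test_that("a wall with a single gap forces the hand-computed detour", {
  # 21 x 21 grid, 1 km spacing; wall on column 11 except a gap at row 11
  msk <- matrix(FALSE, 21, 21)
  msk[11, ] <- TRUE; msk[11, 11] <- FALSE
  x <- seq(500, 20500, by = 1000); y <- seq(500, 20500, by = 1000)
  sites <- site_table(data.frame(site_id = c("W", "E"),
                                 x = c(x[6], x[16]), y = c(y[3], y[3]),
                                 region = "all"), "planar")
  D8 <- overwater_distance(msk, x, y, sites, neighbors = 8)
  straight <- (x[16] - x[6]) / 1000
  expect_gt(D8["W", "E"], straight)
  # brute-force Dijkstra on the same 8-neighbour grid as an oracle
  id <- matrix(NA_integer_, 21, 21)
  sea <- which(!msk, arr.ind = TRUE)
  id[sea] <- seq_len(nrow(sea))
  edges <- c(); w <- c()
  for (o in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    i2 <- sea[, 1] + o[1]; j2 <- sea[, 2] + o[2]
    ok <- i2 >= 1 & i2 <= 21 & j2 >= 1 & j2 <= 21
    tgt <- rep(NA_integer_, nrow(sea)); tgt[ok] <- id[cbind(i2[ok], j2[ok])]
    keep <- !is.na(tgt)
    edges <- c(edges, rbind(id[sea[keep, , drop = FALSE]], tgt[keep]))
    w <- c(w, rep(sqrt(sum(o^2)), sum(keep)))
  }
  g <- igraph::make_graph(edges, n = nrow(sea), directed = FALSE)
  sW <- id[6, 3]; sE <- id[16, 3]
  oracle_km <- igraph::distances(g, v = sW, to = sE, weights = w)[1, 1]
  expect_equal(unname(D8["W", "E"]), oracle_km, tolerance = 1e-9)
})

test_that("a site on land is rejected", {
  msk <- matrix(TRUE, 10, 10); msk[1:3, ] <- FALSE
  x <- seq(500, 9500, 1000); y <- x
  sites <- site_table(data.frame(site_id = "L", x = x[8], y = y[5],
                                 region = "all"), "planar")
  expect_error(overwater_distance(msk, x, y, sites), "land")
})
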