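# Bilinear (space) / linear (time) velocity interpolation for a set of
# particle positions.  Masked (land) cells carry zero velocity, so speeds
# taper towards the coast.  Positions outside the grid get zero velocity.
# pos: n x 2 matrix (m); t_h: scalar time in hours.
interp_velocity <- function(field, pos, t_h) {
  nt <- length(field$hours)
  tf <- t_h - field$hours[1]
  i0 <- floor(tf) + 1
  i0 <- min(max(i0, 1), nt)
  i1 <- min(i0 + 1, nt)
  wt <- tf - (i0 - 1)
  wt <- min(max(wt, 0), 1)
  slice <- function(arr) (1 - wt) * arr[, , i0] + wt * arr[, , i1]
  u <- slice(field$u); v <- slice(field$v)
  nx <- length(field$x); ny <- length(field$y)
  fx <- (pos[, 1] - field$x[1]) / field$spacing + 1
  fy <- (pos[, 2] - field$y[1]) / field$spacing + 1
  inside <- fx >= 1 & fx <= nx & fy >= 1 & fy <= ny
  fx <- pmin(pmax(fx, 1), nx); fy <- pmin(pmax(fy, 1), ny)
  x0 <- pmin(floor(fx), nx - 1); y0 <- pmin(floor(fy), ny - 1)
  x0 <- pmax(x0, 1); y0 <- pmax(y0, 1)
  dx <- fx - x0; dy <- fy - y0
  g <- function(M, ix, iy) M[cbind(ix, iy)]
  bil <- function(M) {
    g(M, x0, y0) * (1 - dx) * (1 - dy) + g(M, x0 + 1, y0) * dx * (1 - dy) +
      g(M, x0, y0 + 1) * (1 - dx) * dy + g(M, x0 + 1, y0 + 1) * dx * dy
  }
  out <- cbind(bil(u), bil(v))
  out[!inside, ] <- 0
  out
}

# TRUE where a position is on a land cell or outside the grid
on_land <- function(field, pos) {
  ix <- round((pos[, 1] - field$x[1]) / field$spacing) + 1
  iy <- round((pos[, 2] - field$y[1]) / field$spacing) + 1
  out <- ix < 1 | ix > length(field$x) | iy < 1 | iy > length(field$y)
  land <- out
  inb <- which(!out)
  if (length(inb)) land[inb] <- field$mask[cbind(ix[inb], iy[inb])]
  land
}

#' Advect particles through a velocity field
#'
#' Hourly particle-position updates by fourth-order Runge-Kutta
#' integration of the bilinearly (space) and linearly (time) interpolated
#' velocity, each hour split into `substeps` sub-intervals, followed by an
#' isotropic random-walk kick with per-axis displacement
#' `sqrt(2 * K * dt) * z`, `z ~ N(0,1)`, applied once per hour.  Under the
#' default `"freeze"` land policy a sub-step or kick that would land on a
#' masked cell (or leave the grid) is discarded and the particle keeps its
#' position for that sub-step; under `"beach"` the particle is permanently
#' removed from further motion.
#'
#' @param field A `velocity_field` from [simulate_velocity_field()].
#' @param start n x 2 matrix of start positions (m), on sea cells.
#' @param start_hour Release time (hours into the field).
#' @param duration_h Tracking duration in hours (default 168 = 7 days).
#' @param substeps RK4 sub-intervals per hour.
#' @param diffusivity Random-walk diffusivity K (m^2/s); 0 disables the kick.
#' @param land_policy `"freeze"` or `"beach"`.
#' @param seed Integer seed (the trajectory is deterministic given it).
#' @return A `trajectory_set`: list with `positions` array
#'   `(n, 2, duration_h + 1)`, `release_hour`, `status` factor
#'   (`active`/`beached`).
#' @export
advect <- function(field, start, start_hour = 0, duration_h = 168,
                   substeps = 4, diffusivity = 1,
                   land_policy = c("freeze", "beach"), seed = NULL) {
  land_policy <- match.arg(land_policy)
  start <- matrix(as.numeric(start), ncol = 2)
  if (any(on_land(field, start))) abort("a start position is on land or outside the grid")
  if (start_hour + duration_h > max(field$hours)) {
    abort("tracking duration exceeds the field's time coverage")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(start)
  out <- array(NA_real_, c(n, 2, duration_h + 1))
  out[, , 1] <- start
  pos <- start
  beached <- rep(FALSE, n)
  dt <- 3600 / substeps
  for (h in seq_len(duration_h)) {
    t0 <- start_hour + (h - 1)
    for (s in seq_len(substeps)) {
      ts <- t0 + (s - 1) / substeps
      act <- which(!beached)
      if (!length(act)) break
      p <- pos[act, , drop = FALSE]
      k1 <- interp_velocity(field, p, ts)
      k2 <- interp_velocity(field, p + k1 * dt / 2, ts + 0.5 / substeps)
      k3 <- interp_velocity(field, p + k2 * dt / 2, ts + 0.5 / substeps)
      k4 <- interp_velocity(field, p + k3 * dt, ts + 1 / substeps)
      prop <- p + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      bad <- on_land(field, prop)
      prop[bad, ] <- p[bad, , drop = FALSE] # freeze this sub-step
      if (land_policy == "beach") beached[act[bad]] <- TRUE
      pos[act, ] <- prop
    }
    if (diffusivity > 0) {
      act <- which(!beached)
      if (length(act)) {
        kick <- matrix(stats::rnorm(2 * length(act), 0, sqrt(2 * diffusivity * 3600)),
                       ncol = 2)
        prop <- pos[act, , drop = FALSE] + kick
        bad <- on_land(field, prop)
        prop[bad, ] <- pos[act, , drop = FALSE][bad, , drop = FALSE]
        if (land_policy == "beach") beached[act[bad]] <- TRUE
        pos[act, ] <- prop
      }
    }
    out[, , h + 1] <- pos
  }
  structure(
    list(positions = out, release_hour = start_hour,
         status = factor(ifelse(beached, "beached", "active"),
                         levels = c("active", "beached"))),
    class = "trajectory_set"
  )
}

#' Build a release schedule
#'
#' Regular release times mirroring a propagule fruiting season: releases
#' every `interval_days` within `[season_start_h, season_end_h]` of the
#' field's time axis.
#'
#' @param field A `velocity_field`.
#' @param particles_per_site Particles seeded per site per release.
#' @param interval_days Days between releases.
#' @param season_start_h,season_end_h Window of release times (hours);
#'   defaults to whatever the field can accommodate with a full tracking
#'   duration.
#' @param duration_h Tracking duration per release.
#' @return List with `release_hours`, `particles_per_site`, `duration_h`.
#' @export
release_schedule <- function(field, particles_per_site = 100, interval_days = 3,
                             season_start_h = 0,
                             season_end_h = max(field$hours) - duration_h,
                             duration_h = 168) {
  if (season_end_h < season_start_h) abort("empty release window")
  hours <- seq(season_start_h, season_end_h, by = interval_days * 24)
  list(release_hours = hours, particles_per_site = particles_per_site,
       duration_h = duration_h)
}

#' Run scheduled releases and count site-to-site particle transport
#'
#' Seeds `particles_per_site` particles uniformly within each site's
#' detection cell at every release time, advects them, and scores a
#' particle from site i as reaching site j when any hourly fix falls in
#' site j's detection square (a `detection_m` x `detection_m` axis-aligned
#' cell centred on the site).  A particle counts at most once per (release,
#' target site).
#'
#' @param field A `velocity_field`.
#' @param sites A planar site tibble ([site_table()]).
#' @param schedule A [release_schedule()].
#' @param detection_m Detection cell edge length (m), default 500.
#' @param substeps,diffusivity,land_policy Passed to [advect()].
#' @param seed Integer seed.
#' @return List with `counts`: array `(n_releases, n_sites, n_sites)` of
#'   per-release i -> j particle counts, and `sites`, `schedule`.
#' @export
run_releases <- function(field, sites, schedule, detection_m = 500,
                         substeps = 4, diffusivity = 1,
                         land_policy = "freeze", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(sites)
  half <- detection_m / 2
  site_xy <- cbind(sites$x, sites$y)
  if (any(on_land(field, site_xy))) abort("a site centre is on land or outside the grid")
  nr <- length(schedule$release_hours)
  np <- schedule$particles_per_site
  counts <- array(0L, c(nr, k, k), dimnames = list(NULL, sites$site_id, sites$site_id))
  for (r in seq_len(nr)) {
    start <- do.call(rbind, lapply(seq_len(k), function(i) {
      cbind(stats::runif(np, sites$x[i] - half, sites$x[i] + half),
            stats::runif(np, sites$y[i] - half, sites$y[i] + half))
    }))
    bad <- on_land(field, start)
    # particles drawn on a land corner of the cell are re-centred
    start[bad, 1] <- site_xy[rep(seq_len(k), each = np), 1][bad]
    start[bad, 2] <- site_xy[rep(seq_len(k), each = np), 2][bad]
    traj <- advect(field, start, start_hour = schedule$release_hours[r],
                   duration_h = schedule$duration_h, substeps = substeps,
                   diffusivity = diffusivity, land_policy = land_policy)
    origin <- rep(seq_len(k), each = np)
    for (j in seq_len(k)) {
      inx <- abs(traj$positions[, 1, ] - sites$x[j]) <= half
      iny <- abs(traj$positions[, 2, ] - sites$y[j]) <= half
      hit <- rowSums(inx & iny, na.rm = TRUE) > 0
      counts[r, , j] <- as.integer(rowsum(as.numeric(hit), origin))
    }
  }
  list(counts = counts, sites = sites, schedule = schedule)
}

#' Average a release count tensor into a connectivity matrix
#'
#' Directed oceanographic connectivity: the average number of particles
#' released at site i detected at site j, elementwise over releases.
#'
#' @param counts A `(n_releases, k, k)` array from [run_releases()] (or the
#'   list it returns).
#' @param diagonal `"keep"` or `"zero"` (self-recruitment excluded).
#' @return A labelled k x k matrix of class `connectivity_matrix` with
#'   attribute `n_releases`.
#' @export
connectivity_matrix <- function(counts, diagonal = c("keep", "zero")) {
  diagonal <- match.arg(diagonal)
  if (is.list(counts)) counts <- counts$counts
  if (length(dim(counts)) != 3) abort("counts must be a (release, i, j) array")
  if (dim(counts)[1] < 1) abort("need at least one release")
  M <- apply(counts, c(2, 3), mean)
  if (diagonal == "zero") diag(M) <- 0
  structure(M, n_releases = dim(counts)[1], class = c("connectivity_matrix", "matrix"))
}

#' Least-cost overwater distances between sites
#'
#' Shortest sea paths on the grid graph of unmasked cells (8- or
#' 16-neighbour connectivity), edge weights equal to the planar (or
#' great-circle) distance between cell centres, solved with Dijkstra's
#' algorithm.  Sites are snapped to the nearest sea cell within
#' `snap_cells` cells; a site with no sea cell in that radius is an error,
#' and site pairs with no sea path get `Inf` with a warning.
#'
#' @param mask Logical matrix (`n_x` by `n_y`), `TRUE` = land.
#' @param x,y Cell-centre coordinate vectors (m for planar, degrees for
#'   lonlat).
#' @param sites A site tibble.
#' @param neighbors 8 or 16 (adds knight moves).
#' @param coords `"planar"` or `"lonlat"`.
#' @param snap_cells Snap tolerance in cells.
#' @return A symmetric labelled matrix of distances in km.
#' @export
overwater_distance <- function(mask, x, y, sites, neighbors = c(16, 8),
                               coords = c("planar", "lonlat"), snap_cells = 2) {
  neighbors <- match.arg(as.character(neighbors[1]), c("16", "8"))
  coords <- match.arg(coords)
  nx <- length(x); ny <- length(y)
  stopifnot(identical(dim(mask), c(nx, ny)))
  sea <- which(!mask, arr.ind = TRUE)
  id <- matrix(NA_integer_, nx, ny)
  id[sea] <- seq_len(nrow(sea))
  offs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  if (neighbors == "16") {
    offs <- rbind(offs, c(2, 1), c(2, -1), c(1, 2), c(-1, 2))
  }
  cell_dist <- function(i1, j1, i2, j2) {
    if (coords == "planar") {
      sqrt((x[i1] - x[i2])^2 + (y[j1] - y[j2])^2) / 1000
    } else {
      haversine_km(x[i1], y[j1], x[i2], y[j2])
    }
  }
  edges <- NULL; weights <- NULL
  for (o in seq_len(nrow(offs))) {
    di <- offs[o, 1]; dj <- offs[o, 2]
    i1 <- sea[, 1]; j1 <- sea[, 2]
    i2 <- i1 + di; j2 <- j1 + dj
    okij <- i2 >= 1 & i2 <= nx & j2 >= 1 & j2 <= ny
    i1 <- i1[okij]; j1 <- j1[okij]; i2 <- i2[okij]; j2 <- j2[okij]
    tgt <- id[cbind(i2, j2)]
    keep <- !is.na(tgt)
    if (!any(keep)) next
    edges <- c(edges, rbind(id[cbind(i1[keep], j1[keep])], tgt[keep]))
    weights <- c(weights, cell_dist(i1[keep], j1[keep], i2[keep], j2[keep]))
  }
  g <- igraph::make_graph(edges, n = nrow(sea), directed = FALSE)
  # snap each site to the nearest sea cell
  snap <- vapply(seq_len(nrow(sites)), function(s) {
    ix <- which.min(abs(x - sites$x[s])); iy <- which.min(abs(y - sites$y[s]))
    best <- NA_integer_; bestd <- Inf
    for (di in -snap_cells:snap_cells) for (dj in -snap_cells:snap_cells) {
      ii <- ix + di; jj <- iy + dj
      if (ii < 1 || ii > nx || jj < 1 || jj > ny || mask[ii, jj]) next
      d <- (di)^2 + (dj)^2
      if (d < bestd) { bestd <- d; best <- id[ii, jj] }
    }
    if (is.na(best)) abort(sprintf("site %s is on land (no sea cell within %d cells)",
                                   sites$site_id[s], snap_cells))
    best
  }, integer(1))
  D <- igraph::distances(g, v = snap, to = snap, weights = weights,
                         algorithm = "dijkstra")
  dimnames(D) <- list(sites$site_id, sites$site_id)
  if (any(is.infinite(D))) warn("some site pairs are not connected by sea")
  D
}
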