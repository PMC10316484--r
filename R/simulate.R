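#' Simulate microsatellite genotypes under the Balding-Nichols model
#'
#' Generates a multi-site codominant genotype dataset with the statistical
#' structure the downstream analyses assume: site allele frequencies drawn
#' around ancestral frequencies with differentiation `theta` (the
#' Balding-Nichols Beta model, whose expected Weir-Cockerham F_ST equals
#' `theta`), within-site inbreeding `f` (with probability `f` a sample is
#' autozygous at a locus, otherwise a Hardy-Weinberg draw), partial
#' clonality `clonality` (with that probability a new sample is a ramet
#' copying an earlier same-site multilocus genotype), and uniform random
#' missingness re-drawn independently for clones.  Allele states are mapped
#' to even "sizes" in a locus-specific range, mimicking dinucleotide
#' repeats.
#'
#' With `groups`, differentiation is hierarchical: group frequencies are
#' drawn around the ancestral frequencies with `theta_between`, and site
#' frequencies around their group's with `theta`.
#'
#' @param n_sites Number of sites.
#' @param samples_per_site Samples per site (default 48, the study scale).
#' @param n_loci Number of loci (default 16).
#' @param alleles_per_locus Ancestral alleles per locus.
#' @param theta Target site-level differentiation in `[0, 1)`.
#' @param f Within-site inbreeding coefficient in `(-1, 1)`; negative values
#'   are treated as 0 for the autozygosity draw.
#' @param clonality Probability in `[0, 1)` that a sample is a clone of an
#'   earlier same-site sample.
#' @param missing_rate Per-(sample, locus) missing probability.
#' @param groups Optional integer/character group label per site for
#'   hierarchical differentiation.
#' @param theta_between Group-level differentiation when `groups` is given.
#' @param dirichlet_conc Concentration of the Dirichlet prior on ancestral
#'   frequencies.
#' @param seed Integer seed; same seed gives a bit-identical dataset.
#' @return A list with `genotypes` (a [genotype_table()]), `sites` (a site
#'   tibble on a synthetic transect) and `truth` (realized frequencies,
#'   parameters, and clone assignments).
#' @examples
#' sim <- simulate_genotypes(n_sites = 3, samples_per_site = 10, n_loci = 4, seed = 1)
#' sim$genotypes
#' @export
simulate_genotypes <- function(n_sites,
                               samples_per_site = 48,
                               n_loci = 16,
                               alleles_per_locus = 8,
                               theta = 0.2,
                               f = 0.1,
                               clonality = 0,
                               missing_rate = 0.01,
                               groups = NULL,
                               theta_between = 0.2,
                               dirichlet_conc = 1,
                               seed = NULL) {
  if (n_loci < 1) abort("n_loci must be >= 1")
  if (theta < 0 || theta >= 1) abort("theta must be in [0, 1)")
  if (f <= -1 || f >= 1) abort("f must be in (-1, 1)")
  if (clonality < 0 || clonality >= 1) abort("clonality must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(groups) && length(groups) != n_sites) {
    abort("groups must have one label per site")
  }

  locus_names <- sprintf("L%02d", seq_len(n_loci))
  site_ids <- sprintf("S%02d", seq_len(n_sites))
  # even allele sizes in a locus-specific window
  base_size <- sample(seq(100, 300, by = 2), n_loci, replace = TRUE)
  sizes <- lapply(seq_len(n_loci), function(l) base_size[l] + 2 * (seq_len(alleles_per_locus) - 1))

  rdirichlet1 <- function(k, conc) {
    g <- stats::rgamma(k, shape = conc)
    g / sum(g)
  }
  bn_draw <- function(p, th) {
    if (th == 0) return(p)
    q <- stats::rgamma(length(p), shape = p * (1 - th) / th)
    q / sum(q)
  }

  ancestral <- lapply(seq_len(n_loci), function(l) rdirichlet1(alleles_per_locus, dirichlet_conc))
  group_freqs <- NULL
  if (!is.null(groups)) {
    glev <- unique(groups)
    group_freqs <- lapply(glev, function(g) lapply(ancestral, bn_draw, th = theta_between))
    names(group_freqs) <- as.character(glev)
  }
  site_freqs <- lapply(seq_len(n_sites), function(s) {
    parent <- if (is.null(groups)) ancestral else group_freqs[[as.character(groups[s])]]
    lapply(parent, bn_draw, th = theta)
  })
  names(site_freqs) <- site_ids

  f_pos <- max(f, 0)
  draw_genotype <- function(freqs) {
    # returns 2 x n_loci allele-state matrix
    vapply(seq_len(n_loci), function(l) {
      p <- freqs[[l]]
      if (stats::runif(1) < f_pos) {
        a <- sample.int(length(p), 1, prob = p)
        c(a, a)
      } else {
        sort(sample.int(length(p), 2, replace = TRUE, prob = p))
      }
    }, integer(2))
  }

  rows <- vector("list", n_sites * samples_per_site)
  clone_of <- character(n_sites * samples_per_site)
  idx <- 0
  for (s in seq_len(n_sites)) {
    site_states <- vector("list", samples_per_site)
    for (i in seq_len(samples_per_site)) {
      idx <- idx + 1
      sid <- sprintf("%s_%03d", site_ids[s], i)
      if (i > 1 && stats::runif(1) < clonality) {
        donor <- sample.int(i - 1, 1)
        site_states[[i]] <- site_states[[donor]]
        clone_of[idx] <- sprintf("%s_%03d", site_ids[s], donor)
      } else {
        site_states[[i]] <- draw_genotype(site_freqs[[s]])
        clone_of[idx] <- NA_character_
      }
      st <- site_states[[i]]
      # map states to sizes; missingness drawn independently per sample
      miss <- stats::runif(n_loci) < missing_rate
      a1 <- vapply(seq_len(n_loci), function(l) sizes[[l]][st[1, l]], numeric(1))
      a2 <- vapply(seq_len(n_loci), function(l) sizes[[l]][st[2, l]], numeric(1))
      a1[miss] <- NA; a2[miss] <- NA
      row <- c(list(sample_id = sid, site_id = site_ids[s]),
               setNames(as.list(a1), paste0(locus_names, ".1")),
               setNames(as.list(a2), paste0(locus_names, ".2")))
      rows[[idx]] <- row
    }
  }
  gt <- genotype_table(dplyr::bind_rows(rows), locus_names)
  sites <- site_table(
    tibble(site_id = site_ids,
           x = seq(0, by = 8000, length.out = n_sites),
           y = rep(0, n_sites),
           region = if (is.null(groups)) "all" else as.character(groups)),
    coords = "planar"
  )
  truth <- list(
    theta = theta, f = f, clonality = clonality, missing_rate = missing_rate,
    groups = groups, theta_between = if (is.null(groups)) NULL else theta_between,
    ancestral_freqs = ancestral, site_freqs = site_freqs,
    clone_of = setNames(clone_of, gt$sample_id),
    clonal_fraction = mean(!is.na(clone_of))
  )
  list(genotypes = gt, sites = sites, truth = truth)
}

#' Simulate an hourly gridded surface-current field
#'
#' Builds a planar regular grid carrying hourly `u`, `v` velocities (m/s)
#' composed of a steady residual plus a sinusoidal tidal component, with a
#' land mask.  Presets: `"uniform"` (constant residual), `"solid_rotation"`
#' (`u = -omega * (y - yc)`, `v = omega * (x - xc)`), and `"tidal_channel"`
#' (residual plus `U_t * sin(2 * pi * t / T)` along the x axis).
#'
#' @param preset One of `"uniform"`, `"solid_rotation"`, `"tidal_channel"`.
#' @param extent Numeric `c(xmin, xmax, ymin, ymax)` in metres.
#' @param spacing Grid spacing in metres (default 2000, mirroring a 2-km
#'   hydrodynamic hindcast).
#' @param duration_h Number of hourly snapshots.
#' @param u0,v0 Residual flow components (m/s).
#' @param tidal_amplitude Tidal speed amplitude `U_t` (m/s).
#' @param tidal_period_h Tidal period `T` (hours).
#' @param omega Angular speed (rad/h is not used; rad/s) for
#'   `solid_rotation`.
#' @param center Rotation centre `c(xc, yc)`; defaults to the domain centre.
#' @param land_mask Optional logical matrix (`n_x` by `n_y`, `TRUE` = land).
#' @return A `velocity_field`: list with `x`, `y` (cell centres, m), `hours`,
#'   arrays `u`, `v` of dim `(n_x, n_y, n_t)`, and logical `mask`.
#' @export
simulate_velocity_field <- function(preset = c("uniform", "solid_rotation", "tidal_channel"),
                                    extent = c(0, 100e3, 0, 60e3),
                                    spacing = 2000,
                                    duration_h = 24 * 10,
                                    u0 = 0.1, v0 = 0,
                                    tidal_amplitude = 1,
                                    tidal_period_h = 12,
                                    omega = 2 * pi / (24 * 3600),
                                    center = NULL,
                                    land_mask = NULL) {
  preset <- match.arg(preset)
  if (spacing <= 0) abort("spacing must be positive")
  if (tidal_period_h <= 0) abort("tidal period must be positive")
  x <- seq(extent[1] + spacing / 2, extent[2] - spacing / 2, by = spacing)
  y <- seq(extent[3] + spacing / 2, extent[4] - spacing / 2, by = spacing)
  nx <- length(x); ny <- length(y)
  hours <- seq_len(duration_h) - 1
  nt <- length(hours)
  if (is.null(land_mask)) {
    land_mask <- matrix(FALSE, nx, ny)
  } else if (!identical(dim(land_mask), c(nx, ny))) {
    abort("land_mask dimensions must match the grid")
  }
  center <- center %||% c(mean(extent[1:2]), mean(extent[3:4]))
  u <- array(0, c(nx, ny, nt)); v <- array(0, c(nx, ny, nt))
  if (preset == "uniform") {
    u[] <- u0; v[] <- v0
  } else if (preset == "solid_rotation") {
    ugrid <- -omega * outer(rep(1, nx), y - center[2])
    vgrid <- omega * outer(x - center[1], rep(1, ny))
    for (t in seq_len(nt)) { u[, , t] <- ugrid; v[, , t] <- vgrid }
  } else {
    tide <- tidal_amplitude * sin(2 * pi * hours / tidal_period_h)
    for (t in seq_len(nt)) { u[, , t] <- u0 + tide[t]; v[, , t] <- v0 }
  }
  mask3 <- array(land_mask, c(nx, ny, nt))
  u[mask3] <- 0; v[mask3] <- 0
  structure(
    list(x = x, y = y, spacing = spacing, hours = hours, u = u, v = v, mask = land_mask),
    class = "velocity_field"
  )
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf(
    "# Velocity field: %d x %d cells (%.1f km spacing), %d hourly steps, %.0f%% land\n",
    length(x$x), length(x$y), x$spacing / 1000, length(x$hours), 100 * mean(x$mask)
  ))
  invisible(x)
}

#' Simulate per-site environmental covariates
#'
#' Draws the five habitat covariates used by the seascape analysis.  With
#' `association = "none"` all sites draw from a common distribution; with
#' `"grouped"` the category probabilities and depth distribution differ by
#' site group, so environmental dissimilarity aligns with group membership
#' (sediment type is the covariate with the strongest group contrast).
#'
#' @param sites A site tibble ([site_table()]).
#' @param association `"none"` or `"grouped"`.
#' @param groups Group label per site (required for `"grouped"`; defaults to
#'   the site `region` column).
#' @param seed Integer seed.
#' @return An [environment_table()].
#' @export
simulate_environment <- function(sites, association = c("none", "grouped"),
                                 groups = NULL, seed = NULL) {
  association <- match.arg(association)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(sites)
  if (association == "none") {
    sed_p <- setNames(rep(1 / 7, 7), WENTWORTH_LEVELS)
    df <- tibble(
      site_id = sites$site_id,
      depth = round(stats::runif(n, 0, 5), 1),
      sediment = sample(WENTWORTH_LEVELS, n, replace = TRUE, prob = sed_p),
      habitat = sample(HABITAT_LEVELS, n, replace = TRUE),
      n_other_seagrass = stats::rpois(n, 1),
      coral_present = stats::runif(n) < 0.5
    )
    return(environment_table(df))
  }
  groups <- groups %||% sites$region
  if (length(groups) != n) abort("groups must have one label per site")
  glev <- unique(groups)
  # disjoint-leaning category supports per group, cycled over groups
  sed_sets <- list(c("sand", "silt", "clay"), c("granule", "pebble", "cobble"),
                   c("boulder", "cobble", "pebble"))
  hab_sets <- list("reef lagoon", "reef terrace")
  depth_mu <- seq(0.5, 5, length.out = max(2, length(glev)))
  df <- purrr::map_dfr(seq_len(n), function(i) {
    g <- match(groups[i], glev)
    tibble(
      site_id = sites$site_id[i],
      depth = round(pmax(0, stats::rnorm(1, depth_mu[(g - 1) %% length(depth_mu) + 1], 0.3)), 1),
      sediment = sample(sed_sets[[(g - 1) %% length(sed_sets) + 1]], 1),
      habitat = hab_sets[[(g - 1) %% length(hab_sets) + 1]],
      n_other_seagrass = stats::rpois(1, c(0.3, 2, 1)[(g - 1) %% 3 + 1]),
      coral_present = stats::runif(1) < c(0.15, 0.85, 0.5)[(g - 1) %% 3 + 1]
    )
  })
  environment_table(df)
}

#' Simulate site coordinates
#'
#' Generates synthetic site locations on a planar domain.  `"transect"`
#' spaces sites along a line; `"interleaved"` alternates members of two
#' groups along the transect, so group membership is deliberately decoupled
#' from broad-scale geography (the regime where currents, not distance,
#' structure connectivity).
#'
#' @param n_sites Number of sites.
#' @param arrangement `"transect"` or `"interleaved"`.
#' @param spacing_m Distance between consecutive sites (m).
#' @param jitter_m Isotropic coordinate jitter (m).
#' @param seed Integer seed.
#' @return A site tibble; for `"interleaved"`, `region` alternates `"A"`/`"B"`.
#' @export
simulate_sites <- function(n_sites, arrangement = c("transect", "interleaved"),
                           spacing_m = 8000, jitter_m = 500, seed = NULL) {
  arrangement <- match.arg(arrangement)
  if (!is.null(seed)) set.seed(seed)
  x <- seq(0, by = spacing_m, length.out = n_sites) + stats::rnorm(n_sites, 0, jitter_m)
  y <- stats::rnorm(n_sites, 0, jitter_m)
  region <- if (arrangement == "interleaved") rep(c("A", "B"), length.out = n_sites) else "all"
  site_table(
    tibble(site_id = sprintf("S%02d", seq_len(n_sites)), x = x, y = y, region = region),
    coords = "planar"
  )
}
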