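#' Identify multilocus genotypes (MLGs)
#'
#' Partitions samples into multilocus genotypes.  Under the `"strict"`
#' policy two samples share an MLG only if they are equal at every locus
#' and neither has any missing data (samples with missing loci become
#' singletons).  Under `"permissive"` a missing locus is a wildcard that
#' matches anything, and clone groups are the connected components of the
#' pairwise-compatibility graph (transitive closure).  Samples missing at
#' every locus are unassignable: their `mlg_id` is `NA` and they do not
#' count towards `G`.
#'
#' MLG ids are assigned in order of first appearance, so the labelling is
#' deterministic given the input row order.
#'
#' @param gt A [genotype_table()].
#' @param missing_policy `"strict"` or `"permissive"`.
#' @return An `mlg_partition`: list with `assignments` (tibble `sample_id`,
#'   `site_id`, `mlg_id`), `by_site` (tibble `site_id`, `N`, `G`, `R`),
#'   `G`, `N` and the policy used.
#' @export
identify_mlgs <- function(gt, missing_policy = c("strict", "permissive")) {
  missing_policy <- match.arg(missing_policy)
  lc <- loci(gt)
  n <- nrow(gt)
  # unordered per-locus genotype keys; NA where missing
  keys <- vapply(lc, function(l) {
    al <- locus_alleles(gt, l)
    k <- paste(pmin(al[, 1], al[, 2]), pmax(al[, 1], al[, 2]), sep = "/")
    k[is.na(al[, 1])] <- NA_character_
    k
  }, character(n))
  keys <- matrix(keys, nrow = n)
  all_missing <- rowSums(!is.na(keys)) == 0

  mlg <- rep(NA_integer_, n)
  if (missing_policy == "strict") {
    complete <- !all_missing & rowSums(is.na(keys)) == 0
    full_key <- apply(keys, 1, paste, collapse = "|")
    grp <- rep(NA_integer_, n)
    grp[complete] <- match(full_key[complete], unique(full_key[complete]))
    # incomplete (but not fully missing) samples are singletons
    singles <- which(!complete & !all_missing)
    next_id <- max(0L, grp, na.rm = TRUE)
    grp[singles] <- next_id + seq_along(singles)
    mlg <- grp
  } else {
    idx <- which(!all_missing)
    m <- length(idx)
    parent <- seq_len(m)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    km <- keys[idx, , drop = FALSE]
    for (i in seq_len(m)) {
      if (i == 1) next
      ki <- km[i, ]
      prev <- km[seq_len(i - 1), , drop = FALSE]
      # compatible with an earlier sample at every locus (NA = wildcard)
      comp_mat <- sweep(prev, 2, ki, function(a, b) is.na(a) | is.na(b) | a == b)
      hits <- which(rowSums(comp_mat) == ncol(km))
      for (h in hits) {
        ri <- find(i); rh <- find(h)
        if (ri != rh) parent[max(ri, rh)] <- min(ri, rh)
      }
    }
    roots <- vapply(seq_len(m), find, integer(1))
    mlg[idx] <- match(roots, unique(roots))
  }
  mlg_id <- ifelse(is.na(mlg), NA_character_, sprintf("MLG_%04d", mlg))
  assignments <- tibble(sample_id = gt$sample_id, site_id = gt$site_id, mlg_id = mlg_id)
  by_site <- assignments |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      N = dplyr::n(),
      G = dplyr::n_distinct(.data$mlg_id[!is.na(.data$mlg_id)]),
      R = ifelse(.data$N >= 2, (.data$G - 1) / (.data$N - 1), NA_real_),
      .groups = "drop"
    )
  structure(
    list(
      assignments = assignments, by_site = by_site,
      N = n, G = dplyr::n_distinct(mlg_id[!is.na(mlg_id)]),
      n_unassigned = sum(all_missing), missing_policy = missing_policy
    ),
    class = "mlg_partition"
  )
}

#' @export
print.mlg_partition <- function(x, ...) {
  cat(sprintf("# MLG partition (%s): N = %d, G = %d, R = %.3f\n",
              x$missing_policy, x$N, x$G, clonal_richness(x$N, x$G)))
  print(x$by_site)
  invisible(x)
}

#' Clonal richness
#'
#' `R = (G - 1) / (N - 1)`: the proportion of distinct genets among sampled
#' ramets, 0 for a monoclonal stand and 1 when every sample is a distinct
#' genotype.
#'
#' @param N Number of samples (>= 2).
#' @param G Number of distinct multilocus genotypes.
#' @return Clonal richness in `[0, 1]`.
#' @examples
#' clonal_richness(557, 319) # 0.572
#' @export
clonal_richness <- function(N, G) {
  if (any(N < 2)) abort("clonal richness requires N >= 2")
  if (any(G > N) || any(G < 1)) abort("G must be in [1, N]")
  (G - 1) / (N - 1)
}

#' Probability of identity for increasing locus combinations
#'
#' Per-locus probability that two random individuals drawn from one site
#' share a genotype under random mating,
#' `PID_l = sum(p_i^4) + sum_{i<j} (2 p_i p_j)^2`, accumulated as a product
#' over loci.  `PID_N = N * cumulative PID` is the expected number of
#' samples whose MLG is duplicated by chance among `N` draws.  The unbiased
#' sib-corrected variant is not computed; this is the standard multi-allele
#' form.
#'
#' @param gt A [genotype_table()] subset to one site.
#' @param locus_order `"observed"` keeps the table's locus order;
#'   `"increasing-information"` adds the most informative (lowest `PID_l`)
#'   loci first.
#' @return A tibble with one row per included locus: `locus`, `pid_locus`,
#'   `pid_cumulative`, `pid_n` (based on the site's sample count).
#' @export
probability_of_identity <- function(gt, locus_order = c("observed", "increasing-information")) {
  locus_order <- match.arg(locus_order)
  fr <- allele_freqs(gt)
  if (any(!loci(gt) %in% fr$locus[fr$n_genotyped > 0])) {
    abort("a locus has zero genotyped samples; PID undefined there")
  }
  per_locus <- fr |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(pid_locus = {
      p <- .data$freq
      pp <- outer(p, p)
      sum(p^4) + sum((2 * pp[upper.tri(pp)])^2)
    }, .groups = "drop")
  per_locus <- per_locus[match(loci(gt), per_locus$locus), ]
  if (locus_order == "increasing-information") {
    per_locus <- per_locus[order(per_locus$pid_locus), ]
  }
  per_locus$pid_cumulative <- cumprod(per_locus$pid_locus)
  per_locus$pid_n <- nrow(gt) * per_locus$pid_cumulative
  per_locus
}

#' Probability of a multilocus genotype under the site's allele frequencies
#'
#' `P_gen` is the product over loci of the genotype probability with a
#' round-robin inbreeding correction: `p_i^2 + f p_i (1 - p_i)` for a
#' homozygote and `2 p_i p_j (1 - f)` for a heterozygote; `f` is clamped to
#' be non-negative for this purpose.  Missing loci are skipped.
#'
#' @param mlg One row of a [genotype_table()] (the genotype whose
#'   probability is wanted).
#' @param freqs Allele frequencies as returned by [allele_freqs()] on the
#'   site's samples.
#' @param f Inbreeding coefficient (clamped at 0).
#' @return The genotype probability.
#' @export
p_gen <- function(mlg, freqs, f = 0) {
  f <- max(f, 0)
  lc <- attr(mlg, "loci") %||% unique(freqs$locus)
  prob <- 1
  for (l in lc) {
    a1 <- mlg[[paste0(l, ".1")]][1]; a2 <- mlg[[paste0(l, ".2")]][1]
    if (is.na(a1)) next
    fl <- freqs[freqs$locus == l, ]
    p1 <- fl$freq[match(a1, fl$allele)]
    p2 <- fl$freq[match(a2, fl$allele)]
    if (is.na(p1) || is.na(p2)) {
      abort(sprintf("allele %s/%s at locus %s absent from frequency table", a1, a2, l))
    }
    g <- if (a1 == a2) p1^2 + f * p1 * (1 - p1) else 2 * p1 * p2 * (1 - f)
    prob <- prob * g
  }
  prob
}

#' Probability that repeated copies of an MLG arose sexually
#'
#' Given one occurrence of a genotype with probability `pgen`, `P_sex` is
#' the binomial-tail probability that at least `n - 1` of the remaining
#' `N - 1` samples carry the same MLG through independent sexual events:
#' `P[X >= n - 1]`, `X ~ Binomial(N - 1, pgen)`.  Values below 0.05 are the
#' conventional call that the copies are clone mates.
#'
#' @param n Number of samples sharing the MLG (>= 2).
#' @param N Number of samples at the site.
#' @param pgen Genotype probability from [p_gen()].
#' @return `P_sex`.
#' @examples
#' p_sex(2, 10, 0.1) # 1 - 0.9^9
#' @export
p_sex <- function(n, N, pgen) {
  if (any(n < 2)) abort("P_sex needs n >= 2 copies")
  if (any(n > N)) abort("n cannot exceed N")
  if (any(pgen <= 0) || any(pgen > 1)) abort("pgen must be in (0, 1]")
  stats::pbinom(n - 2, N - 1, pgen, lower.tail = FALSE)
}

#' P_sex for every repeated MLG in a partition
#'
#' Applies [p_gen()] and [p_sex()] to each clone group (MLG observed in 2+
#' samples) within each site, using site allele frequencies and the site's
#' multi-locus inbreeding coefficient.
#'
#' @param gt A [genotype_table()].
#' @param partition An `mlg_partition`; recomputed when omitted.
#' @param f_is Optional named vector of per-site F_IS for the P_gen
#'   correction; defaults to 0.
#' @return Tibble: `site_id`, `mlg_id`, `n_copies`, `pgen`, `psex`,
#'   `clonal` (`psex < 0.05`).
#' @export
clone_group_psex <- function(gt, partition = NULL, f_is = NULL) {
  partition <- partition %||% identify_mlgs(gt)
  asg <- partition$assignments
  groups <- asg |>
    dplyr::filter(!is.na(.data$mlg_id)) |>
    dplyr::count(.data$site_id, .data$mlg_id, name = "n_copies") |>
    dplyr::filter(.data$n_copies >= 2)
  if (nrow(groups) == 0) return(tibble(
    site_id = character(0), mlg_id = character(0), n_copies = integer(0),
    pgen = numeric(0), psex = numeric(0), clonal = logical(0)
  ))
  purrr::map_dfr(unique(groups$site_id), function(s) {
    sub <- filter_sites(gt, s)
    fr <- allele_freqs(sub)
    f <- if (!is.null(f_is) && s %in% names(f_is)) f_is[[s]] else 0
    gsub <- groups[groups$site_id == s, ]
    purrr::map_dfr(seq_len(nrow(gsub)), function(k) {
      rep_sample <- asg$sample_id[!is.na(asg$mlg_id) & asg$mlg_id == gsub$mlg_id[k] &
                                    asg$site_id == s][1]
      row <- sub[sub$sample_id == rep_sample, , drop = FALSE]
      attr(row, "loci") <- loci(gt)
      pg <- p_gen(row, fr, f)
      tibble(
        site_id = s, mlg_id = gsub$mlg_id[k], n_copies = gsub$n_copies[k],
        pgen = pg,
        psex = if (pg > 0) p_sex(gsub$n_copies[k], nrow(sub), pg) else 0,
        clonal = NA
      )
    })
  }) |>
    dplyr::mutate(clonal = .data$psex < 0.05)
}
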