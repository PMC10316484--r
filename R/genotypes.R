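#' Construct a genotype table
#'
#' A genotype table is the package's central container for codominant diploid
#' microsatellite data: one row per sample, a `sample_id` and `site_id`
#' column, and two integer allele-size columns per locus named `<locus>.1`
#' and `<locus>.2`.  Missing data are `NA` in both allele columns of a locus
#' (the GenAlEx `0` sentinel is translated on read/write and never appears
#' internally).
#'
#' @param x A data frame with `sample_id`, `site_id` and paired allele
#'   columns.
#' @param loci Character vector of locus names.  If `NULL`, inferred from
#'   column names ending in `.1`/`.2`.
#' @return A `gen_tbl` tibble with a `loci` attribute.
#' @examples
#' gt <- genotype_table(data.frame(
#'   sample_id = c("s1", "s2"), site_id = "A",
#'   locA.1 = c(120L, 122L), locA.2 = c(124L, 122L)
#' ))
#' loci(gt)
#' @export
genotype_table <- function(x, loci = NULL) {
  x <- as_tibble(x)
  if (!all(c("sample_id", "site_id") %in% names(x))) {
    abort("genotype table needs `sample_id` and `site_id` columns")
  }
  if (is.null(loci)) {
    a1 <- sub("\\.1$", "", grep("\\.1$", names(x), value = TRUE))
    a2 <- sub("\\.2$", "", grep("\\.2$", names(x), value = TRUE))
    loci <- intersect(a1, a2)
  }
  if (length(loci) < 1) abort("genotype table needs at least one locus")
  if (nrow(x) < 1) abort("genotype table needs at least one sample")
  cols <- as.vector(rbind(paste0(loci, ".1"), paste0(loci, ".2")))
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols)) {
    abort(sprintf("missing allele columns: %s", paste(missing_cols, collapse = ", ")))
  }
  x <- x[, c("sample_id", "site_id", cols)]
  x$sample_id <- as.character(x$sample_id)
  x$site_id <- as.character(x$site_id)
  if (anyDuplicated(x$sample_id)) abort("duplicate sample_id in genotype table")
  for (l in loci) {
    c1 <- paste0(l, ".1"); c2 <- paste0(l, ".2")
    v1 <- x[[c1]]; v2 <- x[[c2]]
    if (!is.numeric(v1) || !is.numeric(v2)) {
      abort(sprintf("non-numeric allele entries at locus %s", l))
    }
    if (any(v1 != round(v1) | v2 != round(v2), na.rm = TRUE)) {
      abort(sprintf("non-integer allele sizes at locus %s", l))
    }
    v1 <- as.integer(round(v1)); v2 <- as.integer(round(v2))
    # 0 sentinel -> NA; half-missing locus -> fully missing
    v1[v1 == 0L] <- NA_integer_; v2[v2 == 0L] <- NA_integer_
    if (any(v1 < 0L, na.rm = TRUE) || any(v2 < 0L, na.rm = TRUE)) {
      abort(sprintf("negative allele sizes at locus %s", l))
    }
    miss <- is.na(v1) | is.na(v2)
    v1[miss] <- NA_integer_; v2[miss] <- NA_integer_
    x[[c1]] <- v1; x[[c2]] <- v2
  }
  attr(x, "loci") <- loci
  class(x) <- c("gen_tbl", class(x))
  x
}

#' Locus names of a genotype table
#' @param gt A `gen_tbl`.
#' @return Character vector of locus names.
#' @export
loci <- function(gt) {
  attr(gt, "loci") %||% abort("not a genotype table")
}

#' @export
print.gen_tbl <- function(x, ...) {
  cat(sprintf(
    "# Genotype table: %d samples, %d sites, %d loci\n",
    nrow(x), dplyr::n_distinct(x$site_id), length(loci(x))
  ))
  NextMethod()
}

# restore gen_tbl class/attr after dplyr verbs that strip it
as_gen_tbl <- function(x, loci) {
  attr(x, "loci") <- loci
  if (!inherits(x, "gen_tbl")) class(x) <- c("gen_tbl", class(x))
  x
}

#' Subset a genotype table to one or more sites
#' @param gt A `gen_tbl`.
#' @param sites Character vector of site ids.
#' @return A `gen_tbl` with only those samples.
#' @export
filter_sites <- function(gt, sites) {
  as_gen_tbl(gt[gt$site_id %in% sites, , drop = FALSE], loci(gt))
}

# allele matrix for one locus: n x 2 integer matrix
locus_alleles <- function(gt, locus) {
  cbind(gt[[paste0(locus, ".1")]], gt[[paste0(locus, ".2")]])
}

# logical: is (sample, locus) missing
missing_mask <- function(gt) {
  sapply(loci(gt), function(l) is.na(gt[[paste0(l, ".1")]]))
}

#' Per-locus allele frequencies
#'
#' Frequencies are computed from gene copies at genotyped samples only.
#'
#' @param gt A `gen_tbl` (typically subset to one site).
#' @return A tibble with columns `locus`, `allele`, `count`, `freq`, `n_genotyped`.
#' @export
allele_freqs <- function(gt) {
  purrr::map_dfr(loci(gt), function(l) {
    al <- locus_alleles(gt, l)
    ok <- !is.na(al[, 1])
    if (!any(ok)) {
      return(tibble(
        locus = l, allele = integer(0), count = integer(0),
        freq = numeric(0), n_genotyped = integer(0)
      ))
    }
    tab <- table(c(al[ok, 1], al[ok, 2]))
    tibble(
      locus = l,
      allele = as.integer(names(tab)),
      count = as.integer(tab),
      freq = as.integer(tab) / sum(tab),
      n_genotyped = sum(ok)
    )
  })
}

#' Reduce a genotype table to unique multilocus genotypes
#'
#' Keeps the first sample (in input order) of every clone group within each
#' site, the standard clone-correction applied before diversity and
#' differentiation analyses of partially clonal organisms.
#'
#' @param gt A `gen_tbl`.
#' @param partition An `mlg_partition` from [identify_mlgs()]; computed with
#'   default settings when omitted.
#' @return A clone-corrected `gen_tbl`.
#' @export
clone_correct <- function(gt, partition = NULL) {
  partition <- partition %||% identify_mlgs(gt)
  asg <- partition$assignments
  keep <- asg[!is.na(asg$mlg_id), ]
  keep <- keep[!duplicated(keep[, c("site_id", "mlg_id")]), "sample_id", drop = TRUE]
  as_gen_tbl(gt[gt$sample_id %in% keep, , drop = FALSE], loci(gt))
}
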