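# small genotype table from an allele matrix: one row per sample,
# columns alternate a1, a2 per locus
toy_gt <- function(mat, site = "A", loci = NULL) {
  n_loci <- ncol(mat) / 2
  loci <- loci %||% sprintf("L%02d", seq_len(n_loci))
  df <- data.frame(sample_id = sprintf("s%03d", seq_len(nrow(mat))),
                   site_id = rep_len(site, nrow(mat)))
  for (l in seq_len(n_loci)) {
    df[[paste0(loci[l], ".1")]] <- mat[, 2 * l - 1]
    df[[paste0(loci[l], ".2")]] <- mat[, 2 * l]
  }
  genotype_table(df, loci)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# labelled symmetric matrix from an unlabelled one
lab <- function(M, ids = NULL) {
  ids <- ids %||% sprintf("S%02d", seq_len(nrow(M)))
  dimnames(M) <- list(ids, ids)
  M
}

# random planar site tibble
rand_sites <- function(n, seed = 1) {
  set.seed(seed)
  site_table(data.frame(site_id = sprintf("S%02d", 1:n),
                        x = runif(n, 0, 5e4), y = runif(n, 0, 5e4),
                        region = "all"), coords = "planar")
}
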