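#' Read a GenAlEx-dialect codominant genotype CSV
#'
#' The GenAlEx codominant layout has three header rows: (1) locus count,
#' sample count, population count and per-population sizes; (2) a dataset
#' title with population names over the size cells; (3) column titles with
#' each locus name spanning a pair of allele columns.  Data rows hold one
#' sample with two integer allele sizes per locus; `0` is the missing-data
#' sentinel and becomes `NA` internally.
#'
#' @param path Path to a CSV file.
#' @param dialect File dialect; only `"genalex"` is supported.
#' @return A [genotype_table()].
#' @export
read_genotypes <- function(path, dialect = "genalex") {
  dialect <- match.arg(dialect, "genalex")
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- utils::read.csv(path, header = FALSE, colClasses = "character",
                         blank.lines.skip = FALSE)
  if (nrow(raw) < 4) abort("malformed GenAlEx file: fewer than 4 rows")
  hdr <- suppressWarnings(as.integer(raw[1, 1:3]))
  if (any(is.na(hdr))) abort("malformed GenAlEx header: first row must start with 3 integers")
  n_loci <- hdr[1]; n_samples <- hdr[2]; n_pops <- hdr[3]
  locus_row <- as.character(raw[3, ])
  locus_names <- locus_row[seq(3, by = 2, length.out = n_loci)]
  locus_names <- locus_names[!is.na(locus_names) & nzchar(locus_names)]
  if (length(locus_names) != n_loci) {
    abort(sprintf(
      "malformed GenAlEx header: %d loci declared but %d locus columns found",
      n_loci, length(locus_names)
    ))
  }
  if (ncol(raw) < 2 + 2 * n_loci) {
    abort(sprintf(
      "malformed GenAlEx file: %d loci declared need %d columns, found %d",
      n_loci, 2 + 2 * n_loci, ncol(raw)
    ))
  }
  extra <- locus_row[seq(3 + 2 * n_loci, length.out = max(0, ncol(raw) - 2 - 2 * n_loci))]
  if (any(nzchar(extra) & !is.na(extra))) {
    abort("malformed GenAlEx header: more locus columns than declared")
  }
  body <- raw[4:nrow(raw), , drop = FALSE]
  body <- body[nzchar(body[, 1]), , drop = FALSE]
  if (nrow(body) != n_samples) {
    abort(sprintf("header declares %d samples but %d data rows found", n_samples, nrow(body)))
  }
  df <- tibble(sample_id = body[, 1], site_id = body[, 2])
  if (dplyr::n_distinct(df$site_id) != n_pops) {
    warn(sprintf(
      "header declares %d populations but %d distinct site labels found",
      n_pops, dplyr::n_distinct(df$site_id)
    ))
  }
  for (k in seq_len(n_loci)) {
    for (copy in 1:2) {
      v <- body[, 2 + 2 * (k - 1) + copy]
      num <- suppressWarnings(as.numeric(v))
      if (any(is.na(num) & nzchar(v))) {
        abort(sprintf("non-integer allele at locus %s", locus_names[k]))
      }
      num[is.na(num)] <- 0
      df[[paste0(locus_names[k], ".", copy)]] <- num
    }
  }
  genotype_table(df, locus_names)
}

#' Write a genotype table as a GenAlEx-dialect CSV
#'
#' Inverse of [read_genotypes()]: missing loci are written as paired `0`
#' sentinels and the three GenAlEx header rows are reconstructed from the
#' table.
#'
#' @param gt A [genotype_table()].
#' @param path Output file path.
#' @param title Dataset title placed in the second header row.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gt, path, title = "seascaper export") {
  stopifnot(inherits(gt, "gen_tbl"))
  lc <- loci(gt)
  sites <- unique(gt$site_id)
  sizes <- as.integer(table(factor(gt$site_id, levels = sites)))
  n_col <- 2 + 2 * length(lc)
  pad <- function(x) c(x, rep("", max(0, n_col - length(x))))
  h1 <- pad(c(length(lc), nrow(gt), length(sites), sizes))
  h2 <- pad(c(title, "", "", sites))
  h3 <- pad(c("Sample", "Pop", as.vector(rbind(lc, ""))))
  body <- cbind(gt$sample_id, gt$site_id)
  for (l in lc) {
    al <- locus_alleles(gt, l)
    al[is.na(al)] <- 0L
    body <- cbind(body, al)
  }
  m <- rbind(h1, h2, h3, body)
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a site table
#'
#' @param path CSV with columns `site_id`, coordinates, and optionally
#'   `region`.  Coordinates are `lon`/`lat` (decimal degrees) or `x`/`y`
#'   (planar metres) depending on `coords`.
#' @param coords Coordinate mode: `"lonlat"` or `"planar"`.
#' @return A tibble with attribute `coords`; columns `site_id`, `x`, `y`,
#'   `region`, `site_index`.
#' @export
read_site_table <- function(path, coords = c("lonlat", "planar")) {
  coords <- match.arg(coords)
  df <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  site_table(df, coords = coords)
}

#' Construct and validate a site table
#' @param df Data frame with `site_id` and coordinate columns.
#' @inheritParams read_site_table
#' @return A validated site tibble.
#' @export
site_table <- function(df, coords = c("lonlat", "planar")) {
  coords <- match.arg(coords)
  df <- as_tibble(df)
  if (!"site_id" %in% names(df)) abort("site table needs a site_id column")
  df$site_id <- as.character(df$site_id)
  if (anyDuplicated(df$site_id)) abort("duplicate site_id in site table")
  cc <- if (coords == "lonlat") c("lon", "lat") else c("x", "y")
  if (!all(cc %in% names(df))) {
    abort(sprintf("site table in %s mode needs columns %s", coords,
                  paste(cc, collapse = ", ")))
  }
  df$x <- as.numeric(df[[cc[1]]]); df$y <- as.numeric(df[[cc[2]]])
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    abort("non-finite site coordinates")
  }
  if (!"region" %in% names(df)) df$region <- "all"
  df$site_index <- seq_len(nrow(df))
  attr(df, "coords") <- coords
  df
}

#' Read a per-site environment table
#'
#' Expects one row per site with the five habitat covariates: `depth` (m
#' relative to mean sea level), `sediment` (a Wentworth grain-size class),
#' `habitat` (`reef terrace` or `reef lagoon`), `n_other_seagrass` (count)
#' and `coral_present` (logical).
#'
#' @param path CSV path.
#' @return A validated environment tibble.
#' @export
read_environment_table <- function(path) {
  environment_table(as_tibble(utils::read.csv(path, stringsAsFactors = FALSE)))
}

#' Construct and validate an environment table
#' @param df Data frame of per-site covariates (see [read_environment_table()]).
#' @return A validated environment tibble with factor categories.
#' @export
environment_table <- function(df) {
  df <- as_tibble(df)
  need <- c("site_id", "depth", "sediment", "habitat", "n_other_seagrass", "coral_present")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    abort(sprintf("environment table missing columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  df$site_id <- as.character(df$site_id)
  if (anyDuplicated(df$site_id)) abort("duplicate site_id in environment table")
  bad <- setdiff(unique(as.character(df$sediment)), WENTWORTH_LEVELS)
  if (length(bad)) {
    abort(sprintf("unknown sediment category: %s (Wentworth classes are %s)",
                  paste(bad, collapse = ", "), paste(WENTWORTH_LEVELS, collapse = ", ")))
  }
  bad <- setdiff(unique(as.character(df$habitat)), HABITAT_LEVELS)
  if (length(bad)) {
    abort(sprintf("unknown habitat category: %s (allowed: %s)",
                  paste(bad, collapse = ", "), paste(HABITAT_LEVELS, collapse = ", ")))
  }
  df$sediment <- factor(df$sediment, levels = WENTWORTH_LEVELS)
  df$habitat <- factor(df$habitat, levels = HABITAT_LEVELS)
  df$depth <- as.numeric(df$depth)
  if (any(!is.finite(df$depth))) abort("non-finite depth")
  df$n_other_seagrass <- as.integer(df$n_other_seagrass)
  df$coral_present <- as.logical(df$coral_present)
  df[, c(need, setdiff(names(df), need))]
}

#' Write / read a labelled square matrix as CSV
#'
#' Distance and connectivity matrices are serialized with site ids as both
#' row and column headers.
#'
#' @param M A labelled square matrix.
#' @param path CSV path.
#' @return `write_matrix_csv()` returns `path` invisibly; `read_matrix_csv()`
#'   returns the labelled matrix.
#' @export
write_matrix_csv <- function(M, path) {
  utils::write.csv(as.data.frame(M), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
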