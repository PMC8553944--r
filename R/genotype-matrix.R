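#' Genotype matrix container
#'
#' Bundles a matrix of biallelic SNP calls (individuals x loci, coded 0/1/2 as
#' the count of the alternate allele, `NA` = missing) with per-locus metadata
#' (mean coverage, observed heterozygosity, minor-allele frequency), per-
#' individual site labels, and a provenance log of every filter applied.
#'
#' @param calls Integer matrix, individuals x loci, values in `{0, 1, 2, NA}`.
#'   Row names are individual ids, column names locus ids (generated when
#'   absent).
#' @param sites Character vector of site/population labels, one per individual.
#' @param coverage Optional numeric vector of mean per-locus read depth; when
#'   omitted the metadata column is `NA` and coverage-based filters will refuse
#'   to run.
#'
#' @return An object of class `genotype_matrix` with elements `calls`,
#'   `locus_meta` (tibble: locus, coverage, ho, maf, call_rate), `individual_meta`
#'   (tibble: individual, site) and `provenance` (tibble of applied filters).
#' @export
genotype_matrix <- function(calls, sites, coverage = NULL) {
  calls <- as.matrix(calls)
  if (!all(calls %in% c(0L, 1L, 2L, NA))) {
    abort("genotype calls must be 0, 1, 2 or NA")
  }
  storage.mode(calls) <- "integer"
  if (length(sites) != nrow(calls)) {
    abort("`sites` must have one label per individual (row of `calls`)")
  }
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("ind_%03d", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("locus_%05d", seq_len(ncol(calls)))
  }
  if (is.null(coverage)) {
    coverage <- rep(NA_real_, ncol(calls))
  }
  if (length(coverage) != ncol(calls)) {
    abort("`coverage` must have one value per locus")
  }
  g <- structure(
    list(
      calls = calls,
      locus_meta = locus_metadata(calls, coverage),
      individual_meta = tibble(
        individual = rownames(calls),
        site = as.character(sites)
      ),
      provenance = tibble(
        stage = character(), loci_before = integer(), loci_after = integer(),
        individuals_before = integer(), individuals_after = integer()
      )
    ),
    class = "genotype_matrix"
  )
  g
}

locus_metadata <- function(calls, coverage) {
  n_obs <- colSums(!is.na(calls))
  p <- colMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[n_obs == 0] <- NA_real_
  tibble(
    locus = colnames(calls),
    coverage = as.numeric(coverage),
    ho = colMeans(calls == 1L, na.rm = TRUE),
    maf = maf,
    call_rate = n_obs / nrow(calls)
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d individuals x %d loci, %d sites, %.2f%% missing\n",
    nrow(x$calls), ncol(x$calls),
    length(unique(x$individual_meta$site)),
    100 * mean(is.na(x$calls))
  ))
  if (nrow(x$provenance) > 0) {
    cat("filters applied:\n")
    print(as.data.frame(x$provenance), row.names = FALSE)
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# Subset a genotype_matrix, refreshing locus metadata and keeping provenance.
subset_genotypes <- function(g, individuals = NULL, loci = NULL) {
  calls <- g$calls
  ind_keep <- individuals %||% rownames(calls)
  loc_keep <- loci %||% colnames(calls)
  calls <- calls[ind_keep, loc_keep, drop = FALSE]
  cov <- g$locus_meta$coverage[match(loc_keep, g$locus_meta$locus)]
  out <- g
  out$calls <- calls
  out$locus_meta <- locus_metadata(calls, cov)
  out$individual_meta <- g$individual_meta[
    match(ind_keep, g$individual_meta$individual), , drop = FALSE
  ]
  out
}

log_stage <- function(g, stage, loci_before, ind_before) {
  g$provenance <- bind_rows(g$provenance, tibble(
    stage = stage,
    loci_before = as.integer(loci_before),
    loci_after = ncol(g$calls),
    individuals_before = as.integer(ind_before),
    individuals_after = nrow(g$calls)
  ))
  g
}

# Split the call matrix by site label; returns a named list of matrices.
split_by_site <- function(g, pops = NULL) {
  sites <- pops %||% g$individual_meta$site
  lapply(split(seq_len(nrow(g$calls)), sites), function(i) {
    g$calls[i, , drop = FALSE]
  })
}

# Per-population allele frequencies and sample sizes for one call matrix.
# Returns list(p = freq of allele coded by the call, n = genotyped individuals).
allele_freq <- function(calls) {
  n <- colSums(!is.na(calls))
  p <- ifelse(n > 0, colMeans(calls, na.rm = TRUE) / 2, NA_real_)
  list(p = p, n = n)
}
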