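# Plain-text readers/writers for the package's containers.

#' Write / read a genotype matrix as a CSV trio
#'
#' `<stem>_calls.csv` (rows = individuals, columns = loci, values 0/1/2/NA),
#' `<stem>_loci.csv` (locus metadata) and `<stem>_sites.csv` (individual,
#' site).
#'
#' @param g A [genotype_matrix()].
#' @param stem Path stem (directory must exist).
#' @return `write_genotypes_csv` returns `stem` invisibly;
#'   `read_genotypes_csv` returns a [genotype_matrix()].
#' @export
write_genotypes_csv <- function(g, stem) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- as.data.frame(g$calls)
  calls <- cbind(individual = rownames(g$calls), calls)
  readr::write_csv(calls, paste0(stem, "_calls.csv"))
  readr::write_csv(g$locus_meta, paste0(stem, "_loci.csv"))
  readr::write_csv(g$individual_meta, paste0(stem, "_sites.csv"))
  invisible(stem)
}

#' @rdname write_genotypes_csv
#' @export
read_genotypes_csv <- function(stem) {
  calls <- readr::read_csv(paste0(stem, "_calls.csv"),
                           show_col_types = FALSE)
  loci <- readr::read_csv(paste0(stem, "_loci.csv"), show_col_types = FALSE)
  sites <- readr::read_csv(paste0(stem, "_sites.csv"), show_col_types = FALSE)
  m <- as.matrix(calls[, -1])
  rownames(m) <- calls$individual
  storage.mode(m) <- "integer"
  genotype_matrix(m, sites$site[match(rownames(m), sites$individual)],
                  coverage = loci$coverage[match(colnames(m), loci$locus)])
}

#' Import biallelic genotypes from a VCF
#'
#' Maps `GT` fields of biallelic sites to 0/1/2 alternate-allele counts.
#' Requires the `vcfR` package.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @param sites Site label per sample in VCF column order.
#' @return A [genotype_matrix()] (coverage metadata `NA` unless the VCF has
#'   per-site mean `DP`).
#' @export
read_genotypes_vcf <- function(path, sites) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("the vcfR package is required for VCF import")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  biallelic <- vcfR::is.biallelic(v)
  gt <- gt[biallelic, , drop = FALSE]
  num <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_integer_)
    a <- strsplit(x, "[/|]")[[1]]
    if (any(a == ".")) return(NA_integer_)
    sum(as.integer(a))
  })
  dp <- tryCatch({
    d <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    rowMeans(d[biallelic, , drop = FALSE], na.rm = TRUE)
  }, error = function(e) NULL)
  genotype_matrix(t(num), sites, coverage = dp)
}

#' Write / read an OTU table as TSV (USEARCH otutab dialect)
#'
#' `<stem>_otutab.tsv` has OTU ids in the first column and one column per
#' sample; `<stem>_samples.tsv` carries group labels and control flags;
#' `<stem>_matchlist.tsv` (written when present) is the three-column
#' `otu_a, otu_b, identity` match list.
#'
#' @param t An [otu_count_table()].
#' @param stem Path stem.
#' @export
write_otu_tsv <- function(t, stem) {
  stopifnot(inherits(t, "otu_table"))
  tab <- cbind(tibble(`#OTU ID` = rownames(t$counts)),
               as.data.frame(t$counts))
  readr::write_tsv(tab, paste0(stem, "_otutab.tsv"))
  readr::write_tsv(t$sample_meta, paste0(stem, "_samples.tsv"))
  if (!is.null(t$match_list)) {
    readr::write_tsv(t$match_list, paste0(stem, "_matchlist.tsv"))
  }
  invisible(stem)
}

#' @rdname write_otu_tsv
#' @export
read_otu_tsv <- function(stem) {
  tab <- readr::read_tsv(paste0(stem, "_otutab.tsv"), show_col_types = FALSE)
  samp <- readr::read_tsv(paste0(stem, "_samples.tsv"),
                          show_col_types = FALSE)
  ml_path <- paste0(stem, "_matchlist.tsv")
  ml <- if (file.exists(ml_path)) {
    readr::read_tsv(ml_path, show_col_types = FALSE)
  }
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  samp <- samp[match(colnames(m), samp$sample), ]
  otu_count_table(m, samp$group, samp$control, match_list = ml)
}

#' Write / read an SST grid as long-format CSV
#'
#' Columns `year, month, lat, lon, sst`; model and scenario labels are stored
#' in a header comment line.
#'
#' @param g An [sst_grid()].
#' @param path Output path.
#' @export
write_sst_csv <- function(g, path) {
  stopifnot(inherits(g, "sst_grid"))
  idx <- expand.grid(t = seq_along(g$month), lat = g$lat, lon = g$lon)
  d <- tibble(
    year = g$year_of[idx$t], month = g$month[idx$t],
    lat = idx$lat, lon = idx$lon,
    sst = as.vector(g$temp)
  )
  con <- file(path, "w")
  writeLines(sprintf("# model=%s scenario=%s", g$model, g$scenario), con)
  close(con)
  readr::write_csv(d, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_sst_csv
#' @export
read_sst_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- regmatches(hdr, regexec("model=(\\S+) scenario=(\\S+)", hdr))[[1]]
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  lat <- sort(unique(d$lat)); lon <- sort(unique(d$lon))
  years <- sort(unique(d$year))
  nt <- 12L * length(years)
  d <- dplyr::arrange(d, .data$lon, .data$lat, .data$year, .data$month)
  arr <- array(d$sst, dim = c(nt, length(lat), length(lon)))
  sst_grid(arr, lat, lon, years,
           model = if (length(meta) == 3) meta[2] else "observed",
           scenario = if (length(meta) == 3) meta[3] else "observed")
}

#' Read a square distance matrix CSV
#'
#' Square CSV with site names as header and first column; an optional `layer`
#' label (e.g. the depth of the ocean-distance layer) is attached as an
#' attribute and propagated into [mantel_ibd()] results.
#'
#' @param path CSV path.
#' @param layer Optional label.
#' @return A symmetric numeric matrix.
#' @export
read_distance_csv <- function(path, layer = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(d[, -1])
  rownames(m) <- d[[1]]
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
    abort("distance matrix is not symmetric")
  }
  attr(m, "layer") <- layer
  m
}
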