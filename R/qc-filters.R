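# SNP quality-control cascade.  The pipeline order is fixed:
# filter_loci -> filter_individuals_monomorphic -> hwe_ld_filter ->
# outflank_scan; each stage appends to the provenance log so the four-stage
# locus count sequence can be audited on any input.

new_filter_report <- function(stage, g_before, g_after, removed,
                              criteria = NULL) {
  structure(
    list(
      stage = stage,
      loci_before = ncol(g_before$calls), loci_after = ncol(g_after$calls),
      individuals_before = nrow(g_before$calls),
      individuals_after = nrow(g_after$calls),
      missing_fraction_after = mean(is.na(g_after$calls)),
      removed_ids = removed,
      criteria = criteria
    ),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %s: loci %d -> %d, individuals %d -> %d (%.2f%% missing)\n",
              x$stage, x$loci_before, x$loci_after, x$individuals_before,
              x$individuals_after, 100 * x$missing_fraction_after))
  invisible(x)
}

#' @export
tidy.filter_report <- function(x, ...) {
  tibble(
    stage = x$stage, loci_before = x$loci_before, loci_after = x$loci_after,
    individuals_before = x$individuals_before,
    individuals_after = x$individuals_after,
    missing_fraction_after = x$missing_fraction_after
  )
}

#' Locus-level quality filters
#'
#' Removes loci failing, in order: call rate (genotyped in at least
#' `call_rate` of individuals), mean coverage outside `[cov_min, cov_max]`,
#' excess observed heterozygosity (`> het_max`), and rarity (minor-allele
#' frequency strictly below `maf_min`; a locus at exactly `maf_min` is
#' retained, matching the "rare = frequency < 0.05" reading). Removal counts
#' are attributed to the first criterion a locus fails, in that order.
#'
#' @param g A [genotype_matrix()] with populated locus metadata.
#' @param call_rate Minimum fraction of individuals genotyped.
#' @param cov_min,cov_max Mean locus depth bounds (inclusive retention).
#' @param het_max Maximum observed heterozygosity.
#' @param maf_min Minimum minor-allele frequency (exclusive removal below).
#' @return A list `(genotypes, report)`; the report's `criteria` element counts
#'   removals per criterion in application order.
#' @export
filter_loci <- function(g, call_rate = 0.95, cov_min = 20, cov_max = 200,
                        het_max = 0.75, maf_min = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  lm <- g$locus_meta
  if (all(is.na(lm$coverage))) abort("locus coverage metadata is required")
  fail_call <- lm$call_rate < call_rate
  fail_cov <- !fail_call & (lm$coverage < cov_min | lm$coverage > cov_max)
  fail_het <- !fail_call & !fail_cov & lm$ho > het_max
  fail_maf <- !fail_call & !fail_cov & !fail_het &
    (!is.na(lm$maf) & lm$maf < maf_min)
  drop <- fail_call | fail_cov | fail_het | fail_maf
  if (all(drop)) abort("all loci filtered out")
  out <- subset_genotypes(g, loci = lm$locus[!drop])
  out <- log_stage(out, "locus_filters", ncol(g$calls), nrow(g$calls))
  criteria <- tibble(
    criterion = c("call_rate", "coverage", "heterozygosity", "maf"),
    removed = c(sum(fail_call), sum(fail_cov), sum(fail_het), sum(fail_maf))
  )
  list(genotypes = out,
       report = new_filter_report("locus_filters", g, out,
                                  lm$locus[drop], criteria))
}

is_monomorphic <- function(calls) {
  n <- colSums(!is.na(calls))
  p <- colMeans(calls, na.rm = TRUE) / 2
  n == 0 | p == 0 | p == 1
}

#' Drop monomorphic loci and low-call-rate individuals
#'
#' Iterates to a fixed point: monomorphic loci (a single allele among
#' non-missing calls) are removed, then individuals with per-individual call
#' rate below `ind_call_rate`, and the monomorphism check is repeated because
#' removing individuals can fix previously polymorphic loci.
#'
#' @param g A [genotype_matrix()].
#' @param ind_call_rate Minimum per-individual call rate.
#' @return A list `(genotypes, report)`.
#' @export
filter_individuals_monomorphic <- function(g, ind_call_rate = 0.90) {
  stopifnot(inherits(g, "genotype_matrix"))
  calls <- g$calls
  removed_loci <- character()
  removed_ind <- character()
  repeat {
    mono <- is_monomorphic(calls)
    if (any(mono)) {
      removed_loci <- c(removed_loci, colnames(calls)[mono])
      calls <- calls[, !mono, drop = FALSE]
    }
    if (ncol(calls) == 0) abort("all loci filtered out")
    icr <- rowMeans(!is.na(calls))
    low <- icr < ind_call_rate
    if (!any(low)) break
    removed_ind <- c(removed_ind, rownames(calls)[low])
    calls <- calls[!low, , drop = FALSE]
    if (nrow(calls) == 0) abort("all individuals removed")
  }
  out <- subset_genotypes(g, individuals = rownames(calls),
                          loci = colnames(calls))
  out <- log_stage(out, "monomorphic_individuals", ncol(g$calls), nrow(g$calls))
  list(genotypes = out,
       report = new_filter_report("monomorphic_individuals", g, out,
                                  c(removed_loci, removed_ind)))
}

#' Hardy-Weinberg and linkage-disequilibrium filter
#'
#' Per population, each locus gets an exact conditional Hardy-Weinberg test
#' (Levene/Haldane distribution of the heterozygote count; two-sided by
#' probability ordering, no mid-p); a locus is removed when Bonferroni-
#' significant (within population, across that population's tested loci) in at
#' least `min_pops` populations. Then, per population, every locus pair gets a
#' composite genotypic correlation `r^2` with chi-square significance
#' (`n r^2 ~ chisq(1)`), Bonferroni-corrected across pairs within population;
#' when a pair with `r^2 >= ld_r2` is significant in at least `min_pops`
#' populations, the member with the lower call rate is removed (ties: lower
#' MAF, then lexicographically larger id). Populations with fewer than
#' `min_n` genotyped individuals are excluded from voting.
#'
#' @param g A [genotype_matrix()].
#' @param pops Optional site labels.
#' @param alpha Significance level before Bonferroni correction.
#' @param min_pops Number of populations in which a violation must be
#'   significant.
#' @param ld_r2 Minimum `r^2` for an LD pair to count.
#' @param min_n Minimum individuals for a population to vote.
#' @return A list `(genotypes, report)`; `report$criteria` splits removals into
#'   `hwe` and `ld`.
#' @export
hwe_ld_filter <- function(g, pops = NULL, alpha = 0.05, min_pops = 2,
                          ld_r2 = 0.8, min_n = 5) {
  stopifnot(inherits(g, "genotype_matrix"))
  by_site <- split_by_site(g, pops)
  sizes <- sapply(by_site, nrow)
  if (any(sizes < min_n)) {
    warn(paste("populations below minimum size excluded from voting:",
               paste(names(by_site)[sizes < min_n], collapse = ", ")))
    by_site <- by_site[sizes >= min_n]
  }
  if (length(by_site) < 2) abort("need at least two populations of minimum size")
  loci <- colnames(g$calls)

  # --- HWE votes ---
  hwe_votes <- rep(0L, length(loci))
  for (m in by_site) {
    pv <- hwe_exact_pvalues(m)
    tested <- !is.na(pv)
    thr <- alpha / max(1L, sum(tested))
    hwe_votes <- hwe_votes + as.integer(tested & pv < thr)
  }
  hwe_drop <- loci[hwe_votes >= min_pops]

  keep1 <- setdiff(loci, hwe_drop)
  # --- LD votes (on loci surviving HWE) ---
  ld_votes <- NULL
  for (m in by_site) {
    mm <- m[, keep1, drop = FALSE]
    r2 <- suppressWarnings(cor(mm, use = "pairwise.complete.obs"))^2
    n_pair <- crossprod(!is.na(mm))            # pairwise complete n
    pmat <- pchisq(n_pair * r2, df = 1, lower.tail = FALSE)
    up <- upper.tri(r2)
    n_tests <- sum(up & is.finite(r2))
    sig <- up & is.finite(r2) & r2 >= ld_r2 & pmat < alpha / max(1L, n_tests)
    ld_votes <- if (is.null(ld_votes)) sig + 0L else ld_votes + sig
  }
  ld_drop <- character()
  if (!is.null(ld_votes) && any(ld_votes >= min_pops)) {
    idx <- which(ld_votes >= min_pops, arr.ind = TRUE)
    lm <- g$locus_meta
    for (r in seq_len(nrow(idx))) {
      a <- keep1[idx[r, 1]]; b <- keep1[idx[r, 2]]
      if (a %in% ld_drop || b %in% ld_drop) next
      ma <- lm[lm$locus == a, ]; mb <- lm[lm$locus == b, ]
      pick <- if (ma$call_rate != mb$call_rate) {
        if (ma$call_rate < mb$call_rate) a else b
      } else if (!is.na(ma$maf) && !is.na(mb$maf) && ma$maf != mb$maf) {
        if (ma$maf < mb$maf) a else b
      } else {
        max(a, b)
      }
      ld_drop <- c(ld_drop, pick)
    }
  }
  keep <- setdiff(loci, c(hwe_drop, ld_drop))
  if (length(keep) == 0) abort("all loci filtered out")
  out <- subset_genotypes(g, loci = keep)
  out <- log_stage(out, "hwe_ld", ncol(g$calls), nrow(g$calls))
  criteria <- tibble(criterion = c("hwe", "ld"),
                     removed = c(length(hwe_drop), length(ld_drop)))
  list(genotypes = out,
       report = new_filter_report("hwe_ld", g, out, c(hwe_drop, ld_drop),
                                  criteria))
}

# Exact conditional HWE p-value per locus (columns of `calls`).  Conditions on
# the minor-allele count; the p-value sums Levene probabilities of all
# heterozygote counts no more probable than the observed one.
hwe_exact_pvalues <- function(calls) {
  apply(calls, 2, function(gt) {
    gt <- gt[!is.na(gt)]
    n <- length(gt)
    if (n < 2) return(NA_real_)
    n_het <- sum(gt == 1L)
    n_alt <- sum(gt)
    hwe_exact_test(n_het, n, n_alt)
  })
}

# n_het observed heterozygotes among n diploids carrying n_alt alternate
# copies.  Classic exact test: sum Levene probabilities of all heterozygote
# counts no more probable than the observed one.
hwe_exact_test <- function(n_het, n, n_alt) {
  n_a <- min(n_alt, 2L * n - n_alt)          # minor allele copies
  n_b <- 2L * n - n_a
  if (n_a == 0) return(1)
  hets <- seq.int(n_a %% 2L, min(n_a, n_b), by = 2L)
  logp <- hets * log(2) + lfactorial(n) +
    lfactorial(n_a) + lfactorial(n_b) - lfactorial(2L * n) -
    lfactorial((n_a - hets) / 2) - lfactorial(hets) -
    lfactorial((n_b - hets) / 2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  if (is.na(obs)) return(NA_real_)
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}
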