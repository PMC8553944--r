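#' Per-population genetic diversity
#'
#' For each site: mean expected heterozygosity (`He = 1 - sum(p^2)` per locus),
#' mean observed heterozygosity (fraction of heterozygous calls), and mean
#' allelic richness rarefied to the smallest per-locus allele count across
#' sites, by the exact hypergeometric formula
#' `AR = sum_a (1 - choose(N - N_a, g) / choose(N, g))`.
#' Confidence intervals come from resampling individuals with replacement
#' within each site.
#'
#' @param g A [genotype_matrix()].
#' @param pops Optional site labels overriding the stored ones.
#' @param n_perm Resampling replicates for the CIs.
#' @param ci Confidence level.
#' @param seed Integer seed.
#' @return A tibble with one row per site: `site`, `n`, `he`, `ho`,
#'   `allelic_richness` and CI bounds for each.
#' @export
diversity_stats <- function(g, pops = NULL, n_perm = 1000, ci = 0.95, seed = 1) {
  by_site <- split_by_site(g, pops)
  sizes <- sapply(by_site, nrow)
  if (any(sizes < 2)) {
    warn(paste("excluding sites with fewer than 2 individuals:",
               paste(names(by_site)[sizes < 2], collapse = ", ")))
    by_site <- by_site[sizes >= 2]
  }
  if (length(by_site) == 0) abort("no site has at least 2 individuals")
  # rarefaction depth: per locus, the smallest genotyped allele count over sites
  n_mat <- vapply(by_site, function(m) colSums(!is.na(m)),
                  numeric(ncol(g$calls)))
  if (is.null(dim(n_mat))) n_mat <- matrix(n_mat, nrow = 1)
  g_rare <- 2 * apply(n_mat, 1, min)
  point <- lapply(by_site, diversity_point, g_rare = g_rare)
  alpha <- 1 - ci
  cis <- with_seed(split_seed(seed, "diversity"), {
    lapply(by_site, function(m) {
      reps <- replicate(n_perm, {
        unlist(diversity_point(m[sample(nrow(m), replace = TRUE), , drop = FALSE],
                               g_rare = g_rare))
      })
      # centre on the point estimate: resampling with replacement biases the
      # heterozygosity of a replicate downward by ~1/n, so use the bootstrap
      # deviation from its own mean around the plug-in value
      pt <- unlist(diversity_point(m, g_rare = g_rare))
      dev <- sweep(reps, 1, rowMeans(reps, na.rm = TRUE))
      sweep(apply(dev, 1, quantile, probs = c(alpha / 2, 1 - alpha / 2),
                  na.rm = TRUE), 2, pt, "+")
    })
  })
  bind_rows(lapply(names(by_site), function(s) {
    p <- point[[s]]; q <- cis[[s]]
    tibble(
      site = s, n = nrow(by_site[[s]]),
      he = p$he, he_low = q[1, "he"], he_high = q[2, "he"],
      ho = p$ho, ho_low = q[1, "ho"], ho_high = q[2, "ho"],
      allelic_richness = p$ar,
      ar_low = q[1, "ar"], ar_high = q[2, "ar"]
    )
  }))
}

# He, Ho, rarefied allelic richness for one population's call matrix.
diversity_point <- function(m, g_rare) {
  n <- colSums(!is.na(m))
  p <- ifelse(n > 0, colMeans(m, na.rm = TRUE) / 2, NA_real_)
  he <- 2 * p * (1 - p)
  ho <- colMeans(m == 1L, na.rm = TRUE)
  N <- 2 * n
  count_alt <- round(p * N)
  gr <- pmin(g_rare, N)
  ar <- prob_allele_seen(count_alt, N, gr) + prob_allele_seen(N - count_alt, N, gr)
  keep <- n > 0
  list(he = mean(he[keep]), ho = mean(ho[keep]), ar = mean(ar[keep]))
}

# P(allele with count k among N copies appears in a sample of g copies),
# exact hypergeometric: 1 - C(N-k, g)/C(N, g).
prob_allele_seen <- function(k, N, g) {
  out <- 1 - exp(lchoose(N - k, g) - lchoose(N, g))
  out[k == 0] <- 0
  out
}

#' Mantel test of isolation by distance
#'
#' Linearises a pairwise differentiation statistic as `Fst / (1 - Fst)` and
#' correlates it (Pearson) with a geographic/ocean distance matrix, with
#' significance by permutation of site labels (delegated to [vegan::mantel()]).
#' Pairs with `Fst = 1` linearise to infinity and are excluded with a warning.
#'
#' @param stat A `pairwise_stat` object (typically from [pairwise_fst()]).
#' @param distances Symmetric distance matrix (km) with site-name dimnames
#'   matching the statistic's sites.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param method Correlation method, `"pearson"` (default) or `"spearman"`.
#' @return A tibble with `r`, `p_value`, `n_permutations` and the distance
#'   layer label (taken from `attr(distances, "layer")` when present).
#' @export
mantel_ibd <- function(stat, distances, n_perm = 999, seed = 1,
                       method = "pearson") {
  stopifnot(inherits(stat, "pairwise_stat"))
  m <- as_matrix(stat)
  layer <- attr(distances, "layer") %||% NA_character_
  distances <- as.matrix(distances)
  if (!setequal(rownames(distances), rownames(m))) {
    abort("distance matrix site names do not match the statistic's sites")
  }
  distances <- distances[rownames(m), colnames(m)]
  if (any(m >= 1)) {
    warn("pairs with Fst = 1 linearise to infinity; excluded")
    m[m >= 1] <- NA
  }
  lin <- m / (1 - m)
  res <- with_seed(split_seed(seed, "mantel"), {
    vegan::mantel(stats::as.dist(lin), stats::as.dist(distances),
                  method = method, permutations = n_perm, na.rm = TRUE)
  })
  tibble(
    r = unname(res$statistic),
    p_value = res$signif,
    n_permutations = n_perm,
    layer = layer
  )
}
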