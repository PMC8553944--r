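# Weir-Cockerham (1984) variance components for biallelic loci, vectorised
# over loci.  `pop_calls` is a list of call matrices (one per population);
# missing data are handled pairwise-complete per locus (each locus uses the
# individuals genotyped at it).

wc_components <- function(pop_calls, corrected = TRUE) {
  r <- length(pop_calls)
  n_i <- sapply(pop_calls, function(m) colSums(!is.na(m)))     # L x r
  p_i <- sapply(pop_calls, function(m) colMeans(m, na.rm = TRUE) / 2)
  h_i <- sapply(pop_calls, function(m) colMeans(m == 1L, na.rm = TRUE))
  if (is.null(dim(n_i))) {                                     # single locus
    n_i <- matrix(n_i, nrow = 1); p_i <- matrix(p_i, nrow = 1)
    h_i <- matrix(h_i, nrow = 1)
  }
  p_i[n_i == 0] <- 0; h_i[n_i == 0] <- 0
  n_sum <- rowSums(n_i)
  n_bar <- n_sum / r
  n_c <- (n_sum - rowSums(n_i^2) / n_sum) / (r - 1)
  p_bar <- rowSums(n_i * p_i) / n_sum
  s2 <- rowSums(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- rowSums(n_i * h_i) / n_sum
  if (corrected) {
    a <- n_bar / n_c *
      (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
    b <- n_bar / (n_bar - 1) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  } else {
    a <- n_bar / n_c * s2
    b <- p_bar * (1 - p_bar) - (r - 1) / r * s2 -
      (2 * n_bar - 1) / (4 * n_bar) * h_bar
  }
  c_ <- h_bar / 2
  usable <- n_bar > 1 & n_c > 0 & is.finite(a + b + c_)
  list(a = a, b = b, c = c_, usable = usable,
       he = 2 * p_bar * (1 - p_bar))
}

# Multilocus estimate as ratio of summed components.
wc_multilocus <- function(comp, loci = NULL) {
  keep <- comp$usable
  if (!is.null(loci)) {
    sel <- logical(length(comp$a)); sel[loci] <- TRUE
    keep <- keep & sel
  }
  num <- sum(comp$a[keep])
  den <- sum((comp$a + comp$b + comp$c)[keep])
  if (den == 0) return(NA_real_)
  num / den
}

# Per-locus Fst (corrected or not); NaN where the locus is unusable.
wc_per_locus <- function(comp) {
  out <- comp$a / (comp$a + comp$b + comp$c)
  out[!comp$usable] <- NA_real_
  out
}

#' Multilocus Weir-Cockerham Fst
#'
#' The Weir-Cockerham (1984) fixation index over all sites, as the ratio of
#' summed among-population variance components to summed total components
#' across loci.
#'
#' @param g A [genotype_matrix()].
#' @param pops Optional site labels overriding the stored ones.
#' @return A single numeric estimate.
#' @export
wc_fst <- function(g, pops = NULL) {
  wc_multilocus(wc_components(split_by_site(g, pops)))
}

#' Pairwise Weir-Cockerham Fst with bootstrap inference
#'
#' Computes the multilocus Weir-Cockerham (1984) fixation index for every pair
#' of sites, as the ratio of summed variance components over loci. Confidence
#' intervals come from bootstrap resampling of loci; the p-value for each pair
#' is the bootstrap probability that Fst is at most zero (no differentiation),
#' adjusted across pairs with the Benjamini-Yekutieli FDR by default.
#'
#' @param g A [genotype_matrix()].
#' @param pops Optional site labels overriding `g$individual_meta$site`.
#' @param n_boot Bootstrap replicates over loci.
#' @param ci Confidence level for percentile intervals.
#' @param adjust Multiple-testing adjustment across pairs (a `p.adjust` method;
#'   default `"BY"`).
#' @param seed Integer seed for the bootstrap.
#' @return A `pairwise_stat` object; `tidy()` gives one row per pair with
#'   estimate, CI bounds, raw and adjusted p-values.
#' @export
pairwise_fst <- function(g, pops = NULL, n_boot = 1000, ci = 0.95,
                         adjust = "BY", seed = 1) {
  pairwise_stat_engine(g, pops, stat = "Fst", n_boot = n_boot, ci = ci,
                       adjust = adjust, seed = seed)
}

#' Pairwise Nei Gst and Jost's D
#'
#' Per locus and pair of sites, `Gst = (Ht - Hs)/Ht` and Jost's
#' `D = (Ht - Hs)/(1 - Hs) * n/(n - 1)` with `n = 2` demes, from expected
#' heterozygosities within (`Hs`, mean of the two sites) and total (`Ht`, from
#' mean allele frequencies). Multilocus values average over polymorphic loci;
#' bootstrap CIs resample loci.
#'
#' @inheritParams pairwise_fst
#' @param statistic `"Gst"` or `"Jost_D"`.
#' @param n_iter Bootstrap iterations over loci.
#' @return A `pairwise_stat` object.
#' @export
pairwise_gst_jostd <- function(g, pops = NULL, statistic = c("Gst", "Jost_D"),
                               n_iter = 1000, ci = 0.95, adjust = "BY",
                               seed = 1) {
  statistic <- arg_match(statistic)
  pairwise_stat_engine(g, pops, stat = statistic, n_boot = n_iter, ci = ci,
                       adjust = adjust, seed = seed)
}

# Gst / Jost D per locus for a pair of frequency vectors.
gst_jostd_locus <- function(p1, p2, stat) {
  hs <- ((2 * p1 * (1 - p1)) + (2 * p2 * (1 - p2))) / 2
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  if (stat == "Gst") {
    out <- ifelse(ht > 0, (ht - hs) / ht, NA_real_)
  } else {
    out <- ifelse(ht > 0, (ht - hs) / (1 - hs) * 2, NA_real_)
  }
  out
}

pairwise_stat_engine <- function(g, pops, stat, n_boot, ci, adjust, seed) {
  by_site <- split_by_site(g, pops)
  sites <- names(by_site)
  if (length(sites) < 2) abort("need at least two populations")
  pairs <- combn(sites, 2)
  alpha <- 1 - ci
  rows <- with_seed(split_seed(seed, paste0("pairwise_", stat)), {
    lapply(seq_len(ncol(pairs)), function(k) {
      s1 <- pairs[1, k]; s2 <- pairs[2, k]
      pcalls <- by_site[c(s1, s2)]
      if (stat == "Fst") {
        comp <- wc_components(pcalls)
        per_locus_num <- comp$a
        per_locus_den <- comp$a + comp$b + comp$c
        usable <- comp$usable & per_locus_den != 0
        est_fun <- function(idx) {
          d <- sum(per_locus_den[idx]); if (d == 0) NA_real_ else
            sum(per_locus_num[idx]) / d
        }
      } else {
        f1 <- allele_freq(pcalls[[1]]); f2 <- allele_freq(pcalls[[2]])
        vals <- gst_jostd_locus(f1$p, f2$p, stat)
        usable <- !is.na(vals)
        est_fun <- function(idx) mean(vals[idx])
      }
      idx_all <- which(usable)
      maf <- g$locus_meta$maf
      n_poly <- sum(usable & !is.na(maf) & maf > 0)
      est <- est_fun(idx_all)
      boots <- replicate(n_boot, {
        est_fun(sample(idx_all, length(idx_all), replace = TRUE))
      })
      lo <- quantile(boots, alpha / 2, na.rm = TRUE, names = FALSE)
      hi <- quantile(boots, 1 - alpha / 2, na.rm = TRUE, names = FALSE)
      p <- perm_pval(sum(boots <= 0, na.rm = TRUE), n_boot)
      tibble(
        site_a = s1, site_b = s2, estimate = est, conf_low = lo,
        conf_high = hi, p_value = p,
        unreliable = length(idx_all) < 2 || n_poly < 2
      )
    })
  })
  tab <- bind_rows(rows)
  tab$p_adjusted <- p.adjust(tab$p_value, method = adjust)
  new_pairwise_stat(tab, stat, sites, adjust)
}

new_pairwise_stat <- function(tab, statistic, sites, adjust, shift = 0) {
  structure(
    list(table = tab, statistic = statistic, sites = sites,
         adjust = adjust, shift = shift),
    class = "pairwise_stat"
  )
}

#' @export
print.pairwise_stat <- function(x, ...) {
  cat(sprintf("<pairwise_stat> %s over %d sites (%s-adjusted)\n",
              x$statistic, length(x$sites), x$adjust))
  if (x$shift != 0) cat(sprintf("  presentation shift applied: +%.4g\n", x$shift))
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname pairwise_fst
#' @param x A `pairwise_stat` object.
#' @param ... Unused.
#' @export
tidy.pairwise_stat <- function(x, ...) x$table

#' Square matrix form of a pairwise statistic
#'
#' @param x A `pairwise_stat` object.
#' @return A symmetric matrix with zero diagonal.
#' @export
as_matrix <- function(x) UseMethod("as_matrix")

#' @export
as_matrix.pairwise_stat <- function(x) {
  m <- matrix(0, length(x$sites), length(x$sites),
              dimnames = list(x$sites, x$sites))
  for (i in seq_len(nrow(x$table))) {
    m[x$table$site_a[i], x$table$site_b[i]] <- x$table$estimate[i]
    m[x$table$site_b[i], x$table$site_a[i]] <- x$table$estimate[i]
  }
  m
}

#' Shift a pairwise statistic so its minimum is zero
#'
#' Adds a constant to every estimate when the minimum is negative, so that all
#' values are non-negative for presentation (e.g. circular migration plots).
#' This is a monotone, presentation-only transform: the constant is recorded on
#' the returned object and the shifted values are never fed back into
#' inference.
#'
#' @param m A `pairwise_stat` object.
#' @return The same object with shifted estimates (CIs shifted alike) and the
#'   constant stored in `$shift`.
#' @export
shift_nonnegative <- function(m) {
  stopifnot(inherits(m, "pairwise_stat"))
  mn <- min(m$table$estimate, na.rm = TRUE)
  if (mn >= 0) return(m)
  k <- -mn
  m$table$estimate <- m$table$estimate + k
  m$table$conf_low <- m$table$conf_low + k
  m$table$conf_high <- m$table$conf_high + k
  m$shift <- m$shift + k
  m
}
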