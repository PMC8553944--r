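#' Directional relative migration network
#'
#' Estimates directional relative migration between every ordered pair of
#' sites by the divMigrate approach: for each pair, a hypothetical pool
#' population is built as the equal-weight mean of the two sites' allele
#' frequencies; the genetic differentiation of each member from that pool is
#' computed (multilocus Nei Gst, Jost's D, or the Wright `Nm ~ (1-s)/(4s)`
#' transform of Gst, per `basis`); low differentiation of a site from the pool
#' indicates high gene flow into that site, so the directional migration into
#' a site is a decreasing transform of its differentiation from the pool.
#' All rates are divided by the global maximum, so the largest rate is 1.
#' Negative directional estimates are truncated to 0 before normalisation.
#'
#' @param g A [genotype_matrix()].
#' @param pops Optional site labels.
#' @param basis Differentiation statistic: `"Gst"` (default), `"Nm"`, or
#'   `"Jost_D"`.
#' @return A `migration_network` object. `$rates` is a square matrix with
#'   rows = receiving site and columns = source site (heatmap orientation);
#'   `tidy()` returns one row per ordered pair.
#' @export
relative_migration <- function(g, pops = NULL, basis = c("Gst", "Nm", "Jost_D")) {
  basis <- arg_match(basis)
  by_site <- split_by_site(g, pops)
  if (length(by_site) < 2) abort("need at least two populations")
  freqs <- sapply(by_site, function(m) allele_freq(m)$p)
  raw <- dir_rates_from_freqs(freqs, basis)
  net <- structure(
    list(
      rates = normalize_rates(raw$rates),
      raw_rates = raw$rates,
      basis = basis,
      sites = names(by_site),
      excluded_pairs = raw$excluded,
      asymmetry = NULL,
      n_boot = NULL
    ),
    class = "migration_network"
  )
  net
}

# freqs: L x K matrix of per-site allele frequencies.  Returns raw directional
# rates with rows = receiving site, columns = source site.
dir_rates_from_freqs <- function(freqs, basis) {
  K <- ncol(freqs)
  rates <- matrix(NA_real_, K, K, dimnames = list(colnames(freqs),
                                                  colnames(freqs)))
  excluded <- character()
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      pi <- freqs[, i]; pj <- freqs[, j]
      ok <- !is.na(pi) & !is.na(pj)
      pool <- (pi[ok] + pj[ok]) / 2
      ht <- 2 * pool * (1 - pool)
      if (!any(ht > 0)) {
        excluded <- c(excluded, paste(colnames(freqs)[c(i, j)], collapse = ":"))
        next
      }
      s_i <- pool_stat(pi[ok], pool, basis)
      s_j <- pool_stat(pj[ok], pool, basis)
      # migration into i comes from j and vice versa
      rates[i, j] <- mig_transform(s_i, basis)
      rates[j, i] <- mig_transform(s_j, basis)
    }
  }
  list(rates = rates, excluded = excluded)
}

# Multilocus differentiation of one population from the pair pool.
pool_stat <- function(p, pool, basis) {
  hs <- (2 * p * (1 - p) + 2 * pool * (1 - pool)) / 2
  pb <- (p + pool) / 2
  ht <- 2 * pb * (1 - pb)
  keep <- ht > 0
  hs_bar <- mean(hs[keep]); ht_bar <- mean(ht[keep])
  if (basis == "Jost_D") {
    2 * (ht_bar - hs_bar) / (1 - hs_bar)
  } else {
    (ht_bar - hs_bar) / ht_bar
  }
}

mig_transform <- function(s, basis) {
  if (is.na(s)) return(NA_real_)
  if (s <= 0) return(Inf)                 # indistinguishable from the pool
  out <- switch(basis,
    Gst = (1 - s) / s,
    Nm = (1 / s - 1) / 4,
    Jost_D = (1 - s) / s
  )
  max(out, 0)
}

normalize_rates <- function(raw) {
  finite <- raw[is.finite(raw)]
  mx <- if (any(is.infinite(raw), na.rm = TRUE)) Inf else
    suppressWarnings(max(finite, 0))
  if (is.infinite(mx)) {
    out <- raw
    out[is.finite(out)] <- out[is.finite(out)] / max(finite[finite > 0], 1)
    out[is.infinite(out)] <- 1
    out <- pmin(out, 1)
    return(out)
  }
  if (mx > 0) raw / mx else raw
}

#' Bootstrap test for asymmetric migration
#'
#' Resamples individuals with replacement within each site, recomputes the
#' normalised directional rates, and flags an ordered pair as significantly
#' asymmetric when the percentile bootstrap confidence interval of
#' `m[i -> j] - m[j -> i]` excludes zero at level `alpha`.
#'
#' @param net A `migration_network` from [relative_migration()].
#' @param g The [genotype_matrix()] the network was computed from.
#' @param pops Optional site labels.
#' @param n_boot Bootstrap replicates (values below 100 trigger a warning).
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return The network with `$asymmetry`: a tibble of unordered pairs with the
#'   observed difference, CI bounds and significance flag.
#' @export
asymmetry_test <- function(net, g, pops = NULL, n_boot = 1000, alpha = 0.05,
                           seed = 1) {
  stopifnot(inherits(net, "migration_network"))
  if (n_boot < 100) warn("n_boot < 100: bootstrap CIs will be unstable")
  by_site <- split_by_site(g, pops)
  if (!identical(names(by_site), net$sites)) {
    abort("network and genotypes disagree on sites")
  }
  K <- length(by_site)
  pairs <- combn(seq_len(K), 2)
  diffs <- with_seed(split_seed(seed, "asymmetry"), {
    replicate(n_boot, {
      freqs <- sapply(by_site, function(m) {
        allele_freq(m[sample(nrow(m), replace = TRUE), , drop = FALSE])$p
      })
      r <- normalize_rates(dir_rates_from_freqs(freqs, net$basis)$rates)
      r[cbind(pairs[1, ], pairs[2, ])] - r[cbind(pairs[2, ], pairs[1, ])]
    })
  })
  if (is.null(dim(diffs))) diffs <- matrix(diffs, nrow = 1)
  obs <- net$rates[cbind(pairs[1, ], pairs[2, ])] -
    net$rates[cbind(pairs[2, ], pairs[1, ])]
  # bias-corrected percentile interval: the normalisation makes the bootstrap
  # distribution of a rate difference asymmetric around the observed value,
  # and the plain percentile interval under-covers slightly
  ci <- vapply(seq_len(nrow(diffs)), function(i) {
    bc_percentile_ci(diffs[i, ], obs[i], alpha)
  }, numeric(2))
  lo <- ci[1, ]
  hi <- ci[2, ]
  net$asymmetry <- tibble(
    site_a = net$sites[pairs[1, ]],
    site_b = net$sites[pairs[2, ]],
    diff = obs, conf_low = lo, conf_high = hi,
    significant = lo > 0 | hi < 0
  )
  net$n_boot <- n_boot
  net
}

bc_percentile_ci <- function(boot, obs, alpha) {
  boot <- boot[!is.na(boot)]
  if (length(boot) == 0) return(c(NA_real_, NA_real_))
  prop <- mean(boot < obs) + 0.5 * mean(boot == obs)
  z0 <- stats::qnorm(min(max(prop, 1 / (length(boot) + 1)),
                         1 - 1 / (length(boot) + 1)))
  probs <- stats::pnorm(2 * z0 + stats::qnorm(c(alpha / 2, 1 - alpha / 2)))
  quantile(boot, probs, names = FALSE)
}

#' @export
print.migration_network <- function(x, ...) {
  cat(sprintf("<migration_network> %d sites, basis %s (rows receive, columns send)\n",
              length(x$sites), x$basis))
  print(round(x$rates, 3))
  if (!is.null(x$asymmetry)) {
    n_sig <- sum(x$asymmetry$significant, na.rm = TRUE)
    cat(sprintf("asymmetry: %d/%d pairs significant (%d bootstraps)\n",
                n_sig, nrow(x$asymmetry), x$n_boot))
  }
  invisible(x)
}

#' @rdname relative_migration
#' @param x A `migration_network`.
#' @param ... Unused.
#' @export
tidy.migration_network <- function(x, ...) {
  K <- length(x$sites)
  idx <- which(row(x$rates) != col(x$rates))
  tibble(
    from = x$sites[col(x$rates)[idx]],
    to = x$sites[row(x$rates)[idx]],
    rate = x$rates[idx]
  )
}

#' @rdname relative_migration
#' @param object A `migration_network`.
#' @export
autoplot.migration_network <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$from, y = .data$to,
                                  fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "source population", y = "receiving population",
                  fill = "relative\nmigration") +
    ggplot2::theme_minimal()
}
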