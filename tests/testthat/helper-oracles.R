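# Independent brute-force oracles, written as straight-line translations of
# the defining formulas (scalar loops, no shared code with the package).

# Weir-Cockerham (1984) multilocus Fst by direct per-locus summation.
wc_fst_oracle <- function(pop_calls) {
  r <- length(pop_calls)
  L <- ncol(pop_calls[[1]])
  sum_a <- 0; sum_abc <- 0
  for (l in seq_len(L)) {
    n <- numeric(r); p <- numeric(r); h <- numeric(r)
    for (k in seq_len(r)) {
      gt <- pop_calls[[k]][, l]
      gt <- gt[!is.na(gt)]
      n[k] <- length(gt)
      if (n[k] > 0) {
        p[k] <- sum(gt) / (2 * n[k])
        h[k] <- sum(gt == 1) / n[k]
      }
    }
    if (any(n == 0)) next
    n_bar <- mean(n)
    if (n_bar <= 1) next
    n_c <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    if (n_c <= 0) next
    p_bar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
    h_bar <- sum(n * h) / sum(n)
    a <- n_bar / n_c *
      (s2 - 1 / (n_bar - 1) *
         (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4))
    b <- n_bar / (n_bar - 1) *
      (p_bar * (1 - p_bar) - (r - 1) / r * s2 -
         (2 * n_bar - 1) / (4 * n_bar) * h_bar)
    cc <- h_bar / 2
    sum_a <- sum_a + a
    sum_abc <- sum_abc + a + b + cc
  }
  sum_a / sum_abc
}

# Exact conditional HWE p-value by full enumeration of genotype-count triples
# (n_AA, n_Aa, n_aa) compatible with the observed allele count.
hwe_enum_oracle <- function(n_het_obs, n, n_alt) {
  configs <- list()
  for (n_het in 0:n) {
    n_aa <- (n_alt - n_het) / 2           # homozygous alt
    if (n_aa < 0 || n_aa != round(n_aa)) next
    n_rr <- n - n_het - n_aa
    if (n_rr < 0) next
    configs[[length(configs) + 1]] <- c(n_rr, n_het, n_aa)
  }
  logp <- sapply(configs, function(cfg) {
    lfactorial(n) - sum(lfactorial(cfg)) + cfg[2] * log(2)
  })
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  hets <- sapply(configs, `[`, 2)
  obs <- pr[hets == n_het_obs]
  sum(pr[pr <= obs + 1e-12])
}

# IndVal.g for one OTU and one group combination, by the defining formula.
indval_oracle <- function(x, groups, combo) {
  lev <- unique(groups)
  gmeans <- sapply(lev, function(g) mean(x[groups == g]))
  A <- sum(gmeans[lev %in% combo]) / sum(gmeans)
  in_combo <- groups %in% combo
  B <- mean(x[in_combo] > 0)
  sqrt(A * B)
}

# Mean silhouette width of labelled points (Euclidean), direct formula.
cluster_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  s <- sapply(seq_len(nrow(d)), function(i) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(d[i, own])
    b <- min(tapply(d[i, !own & seq_len(nrow(d)) != i],
                    labels[!own & seq_len(nrow(d)) != i], mean))
    (b - a) / max(a, b)
  })
  mean(s)
}

# Small random genotype matrix builder (2+ pops, complete data).
random_toy_genotypes <- function(n_pops = 2, n_ind = 10, n_loci = 5) {
  calls <- NULL
  for (k in seq_len(n_pops)) {
    p <- runif(n_loci, 0.05, 0.95)
    calls <- rbind(calls, matrix(rbinom(n_ind * n_loci, 2, rep(p, each = n_ind)),
                                 nrow = n_ind))
  }
  genotype_matrix(calls, rep(sprintf("p%d", seq_len(n_pops)), each = n_ind),
                  coverage = rep(50, n_loci))
}
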