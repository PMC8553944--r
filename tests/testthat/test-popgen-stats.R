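test_that("Weir-Cockerham Fst matches the brute-force oracle on random toy tables", {
  set.seed(100)
  for (i in 1:30) {
    g <- random_toy_genotypes(n_pops = sample(2:4, 1), n_ind = sample(5:12, 1),
                              n_loci = sample(3:8, 1))
    comp <- wc_components(split_by_site(g))
    expect_equal(wc_multilocus(comp),
                 wc_fst_oracle(split_by_site(g)), tolerance = 1e-12)
  }
})

test_that("Fst endpoints behave: ~0 for identical populations, 1 for fixed differences", {
  set.seed(7)
  half <- matrix(rbinom(20 * 10, 2, 0.5), 20)
  g_same <- genotype_matrix(rbind(half, half), rep(c("A", "B"), each = 20),
                            coverage = rep(50, 10))
  est <- wc_multilocus(wc_components(split_by_site(g_same)))
  expect_lt(abs(est), 0.03)
  g_fix <- genotype_matrix(rbind(matrix(0L, 15, 8), matrix(2L, 15, 8)),
                           rep(c("A", "B"), each = 15),
                           coverage = rep(50, 8))
  expect_equal(wc_multilocus(wc_components(split_by_site(g_fix))), 1)
})

test_that("pairwise_fst returns symmetric inference with BY-monotone adjustment", {
  g <- simulate_genotypes(genotype_sim_spec(3, 25, 300, target_fst = 0.08,
                                            seed = 12))
  res <- pairwise_fst(g, n_boot = 200, seed = 3)
  tab <- tidy(res)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$p_adjusted >= tab$p_value - 1e-12))
  expect_true(all(tab$conf_low <= tab$estimate & tab$estimate <= tab$conf_high))
  m <- as_matrix(res)
  expect_equal(m, t(m))
  expect_equal(diag(m), setNames(rep(0, 3), rownames(m)))
})

test_that("Gst and Jost's D reproduce the direct-formula values", {
  expect_equal(gst_jostd_locus(0.2, 0.8, "Gst"), 0.36, tolerance = 1e-12)
  expect_equal(gst_jostd_locus(0.2, 0.8, "Jost_D"), (0.18 / 0.68) * 2,
               tolerance = 1e-12)
  # identical populations: both zero
  expect_equal(gst_jostd_locus(0.3, 0.3, "Gst"), 0)
  expect_equal(gst_jostd_locus(0.3, 0.3, "Jost_D"), 0)
})

test_that("pairwise Gst/D on identical populations is ~0 and Gst <= 1", {
  set.seed(5)
  half <- matrix(rbinom(20 * 30, 2, runif(30, 0.2, 0.8)), 20, byrow = TRUE)
  g <- genotype_matrix(rbind(half, half), rep(c("A", "B"), each = 20),
                       coverage = rep(50, 30))
  gst <- tidy(pairwise_gst_jostd(g, statistic = "Gst", n_iter = 100, seed = 2))
  expect_lt(abs(gst$estimate), 0.02)
  g2 <- simulate_genotypes(genotype_sim_spec(2, 30, 400, target_fst = 0.3,
                                             seed = 31))
  gst2 <- tidy(pairwise_gst_jostd(g2, statistic = "Gst", n_iter = 100, seed = 2))
  d2 <- tidy(pairwise_gst_jostd(g2, statistic = "Jost_D", n_iter = 100, seed = 2))
  expect_lte(gst2$estimate, 1)
  expect_lte(d2$estimate, 1)
})

test_that("diversity statistics hit their closed-form anchors", {
  # fixed population: He = Ho = 0, richness = 1
  fixed <- matrix(0L, 10, 6)
  seg <- matrix(rbinom(10 * 6, 2, 0.5), 10)
  g <- genotype_matrix(rbind(fixed, seg), rep(c("A", "B"), each = 10),
                       coverage = rep(50, 6))
  div <- diversity_stats(g, n_perm = 50, seed = 1)
  a <- div[div$site == "A", ]
  expect_equal(a$he, 0)
  expect_equal(a$ho, 0)
  expect_equal(a$allelic_richness, 1)
  # single locus at p = 0.5 under exact HWE: He = 0.5
  hwe_calls <- matrix(rep(c(0L, 1L, 1L, 2L), 5), ncol = 1)
  g2 <- genotype_matrix(hwe_calls, rep("A", 20), coverage = 50)
  div2 <- suppressWarnings(diversity_stats(g2, n_perm = 20, seed = 1))
  expect_equal(div2$he, 0.5)
  expect_equal(div2$ho, 0.5)
})

test_that("diversity values equal an independent per-locus formula oracle", {
  set.seed(9)
  g <- random_toy_genotypes(n_pops = 3, n_ind = 8, n_loci = 6)
  div <- diversity_stats(g, n_perm = 20, seed = 1)
  by_site <- split_by_site(g)
  g_min <- 2 * apply(sapply(by_site, function(m) colSums(!is.na(m))), 1, min)
  for (s in names(by_site)) {
    m <- by_site[[s]]
    he <- ho <- ar <- numeric(ncol(m))
    for (l in seq_len(ncol(m))) {
      gt <- m[, l]; gt <- gt[!is.na(gt)]
      p <- sum(gt) / (2 * length(gt))
      he[l] <- 1 - p^2 - (1 - p)^2
      ho[l] <- mean(gt == 1)
      N <- 2 * length(gt); k_alt <- sum(gt); gr <- min(g_min[l], N)
      seen <- function(k) if (k == 0) 0 else
        1 - exp(lchoose(N - k, gr) - lchoose(N, gr))
      ar[l] <- seen(k_alt) + seen(N - k_alt)
    }
    expect_equal(div$he[div$site == s], mean(he), tolerance = 1e-12)
    expect_equal(div$ho[div$site == s], mean(ho), tolerance = 1e-12)
    expect_equal(div$allelic_richness[div$site == s], mean(ar),
                 tolerance = 1e-10)
  }
})

test_that("shift_nonnegative is a monotone presentation-only transform", {
  g <- simulate_genotypes(genotype_sim_spec(3, 20, 100, target_fst = 0,
                                            seed = 15))
  res <- pairwise_fst(g, n_boot = 50, seed = 1)
  shifted <- shift_nonnegative(res)
  expect_gte(min(shifted$table$estimate), 0)
  expect_equal(order(shifted$table$estimate), order(res$table$estimate))
  expect_equal(shifted$table$p_value, res$table$p_value)
  # already non-negative input is unchanged
  res_pos <- res
  res_pos$table$estimate <- abs(res_pos$table$estimate) + 0.01
  expect_identical(shift_nonnegative(res_pos)$table$estimate,
                   res_pos$table$estimate)
})

test_that("Mantel IBD recovers a perfect rank-one relationship and a hand example", {
  g <- simulate_genotypes(genotype_sim_spec(4, 25, 300, target_fst = 0.1,
                                            seed = 18))
  res <- pairwise_fst(g, n_boot = 50, seed = 1)
  m <- as_matrix(res)
  lin <- m / (1 - m)
  r <- mantel_ibd(res, lin * 1000, n_perm = 999, seed = 4)
  expect_equal(r$r, 1, tolerance = 1e-10)
  expect_lte(r$p_value, 0.05)
  # 3-site hand computation
  g3 <- simulate_genotypes(genotype_sim_spec(3, 20, 200, target_fst = 0.1,
                                             seed = 19))
  res3 <- pairwise_fst(g3, n_boot = 50, seed = 1)
  m3 <- as_matrix(res3)
  d3 <- matrix(c(0, 10, 40, 10, 0, 25, 40, 25, 0), 3,
               dimnames = list(rownames(m3), rownames(m3)))
  got <- mantel_ibd(res3, d3, n_perm = 99, seed = 2)
  lin3 <- (m3 / (1 - m3))[lower.tri(m3)]
  expect_equal(got$r, cor(lin3, d3[lower.tri(d3)]), tolerance = 1e-10)
})
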