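test_that("Bray-Curtis hits its closed-form anchors", {
  m <- rbind(s1 = c(3, 1), s2 = c(3, 1), s3 = c(1, 3), s4 = c(0, 5))
  d <- bray_curtis(m, use_relative = TRUE)
  expect_equal(d["s1", "s2"], 0)
  expect_equal(d["s1", "s3"], 0.5)          # (3,1) vs (1,3) as proportions
  disj <- bray_curtis(rbind(a = c(5, 0), b = c(0, 7)))
  expect_equal(disj["a", "b"], 1)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0) && all(d >= 0 & d <= 1))
})

test_that("nMDS embeds planar configurations with near-zero stress, invariant to rotation", {
  set.seed(4)
  pts <- matrix(rnorm(20 * 2), 20)
  d <- as.matrix(dist(pts))
  fit <- suppressWarnings(nmds_ordinate(d, k = 2, n_starts = 5, seed = 3))
  expect_lt(fit$stress, 0.01)
  # stress depends only on distances: a rotated input gives the same stress
  th <- pi / 5
  rot <- pts %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  fit2 <- suppressWarnings(
    nmds_ordinate(as.matrix(dist(rot)), k = 2, n_starts = 5, seed = 3)
  )
  expect_equal(fit$stress, fit2$stress, tolerance = 1e-6)
  expect_error(nmds_ordinate(d[1:3, 1:3], k = 3), "smaller")
})

test_that("strongly separated synthetic diets separate in the ordination", {
  t <- simulate_otu_table(otu_sim_spec(
    groups = c("g1", "g2", "g3", "g4"), n_samples_per_group = 6,
    n_otus = 80, n_daughter_errors = 0, n_contaminants = 0,
    concentration = 30, seed = 77
  ))
  d <- bray_curtis(t)
  fit <- nmds_ordinate(d, seed = 5)
  grp <- t$sample_meta$group[!t$sample_meta$control]
  co <- as.matrix(fit$points[, c("axis1", "axis2")])
  # positive silhouette: samples are closer to their own group on average
  sil <- cluster_silhouette(co, grp)
  expect_gt(sil, 0)
})

test_that("PERMANOVA matches vegan::adonis2 and behaves at the extremes", {
  set.seed(8)
  m <- matrix(rexp(14 * 10), 14)
  d <- bray_curtis(m)
  grp <- rep(c("a", "b"), each = 7)
  ours <- permanova(d, grp, n_perm = 999, seed = 2)
  ref <- vegan::adonis2(stats::as.dist(d) ~ grp, permutations = 99)
  expect_equal(ours$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$r_squared, ref$R2[1], tolerance = 1e-10)
  # completely disjoint groups: minimum attainable p
  md <- rbind(matrix(c(10, 0), 5, 2, byrow = TRUE) + matrix(runif(10), 5),
              matrix(c(0, 10), 5, 2, byrow = TRUE) + matrix(runif(10), 5))
  dd <- bray_curtis(md)
  res <- permanova(dd, rep(c("a", "b"), each = 5), n_perm = 999, seed = 3)
  # free permutation regenerates the extreme partition (and its mirror) with
  # probability ~2/choose(10,5), so the attainable minimum sits near 0.009
  expect_lte(res$p_value, 0.012)
  expect_gt(res$r_squared, 0.8)
  expect_error(permanova(d, c("a", rep("b", 13)), n_perm = 99),
               "at least two samples")
})

test_that("PERMDISP matches vegan::betadisper's F and flags planted dispersion", {
  set.seed(9)
  m <- matrix(rexp(16 * 8), 16)
  d <- bray_curtis(m)
  grp <- rep(c("a", "b"), each = 8)
  ours <- permdisp(d, grp, n_perm = 499, seed = 2)
  ref <- vegan::betadisper(stats::as.dist(d), grp, type = "median")
  expect_equal(ours$statistic, anova(ref)[1, 4], tolerance = 1e-4)
  ours_c <- permdisp(d, grp, n_perm = 499, seed = 2, center = "centroid")
  ref_c <- vegan::betadisper(stats::as.dist(d), grp, type = "centroid")
  expect_equal(ours_c$statistic, anova(ref_c)[1, 4], tolerance = 1e-6)
  # a zero-dispersion group against a dispersed one is detected
  base <- rexp(8)
  m2 <- rbind(matrix(base, 6, 8, byrow = TRUE),
              matrix(rexp(6 * 8), 6))
  d2 <- bray_curtis(m2)
  res <- permdisp(d2, rep(c("tight", "loose"), each = 6), n_perm = 999,
                  seed = 4)
  expect_lt(res$p_value, 0.05)
  expect_error(permdisp(d2, rep("one", 12), n_perm = 99), "two groups")
})

test_that("IndVal reproduces its defining formula and finds perfect indicators", {
  # perfect indicator: present in all samples of one group only
  m <- cbind(ind = c(5, 7, 6, 0, 0, 0), noise = c(3, 2, 4, 3, 2, 4))
  grp <- rep(c("a", "b"), each = 3)
  res <- indval(m, grp, n_perm = 199, seed = 5)
  expect_equal(res$indval[res$otu == "ind"], 1)
  expect_equal(res$best_combo[res$otu == "ind"], "a")
  # uniform OTU across two groups of two: single-group IndVal = sqrt(0.5)
  m2 <- cbind(u = c(4, 4, 4, 4))
  grp2 <- c("a", "a", "b", "b")
  res2 <- indval(m2, grp2, n_perm = 99, seed = 5)
  stats2 <- attr(res2, "combo_stats")
  expect_equal(stats2["u", "a"], sqrt(0.5), tolerance = 1e-9)
  expect_equal(stats2["u", "b"], sqrt(0.5), tolerance = 1e-9)
  expect_equal(stats2["u", "a+b"], 1, tolerance = 1e-12)
  expect_equal(res2$best_combo, "a+b")
  # random tables agree with the direct-formula oracle for every combination
  set.seed(12)
  m3 <- matrix(rpois(18 * 5, 3), 18)
  colnames(m3) <- paste0("o", 1:5)
  grp3 <- rep(c("x", "y", "z"), each = 6)
  res3 <- indval(m3, grp3, n_perm = 49, seed = 2)
  st <- attr(res3, "combo_stats")
  combos <- list("x", "y", "z", c("x", "y"), c("x", "z"), c("y", "z"),
                 c("x", "y", "z"))
  for (ci in seq_along(combos)) {
    for (o in colnames(m3)) {
      expect_equal(st[o, paste(combos[[ci]], collapse = "+")],
                   indval_oracle(m3[, o], grp3, combos[[ci]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("IndVal p-values respect the permutation floor and BH monotonicity", {
  t <- simulate_otu_table(otu_sim_spec(n_otus = 60, n_daughter_errors = 0,
                                       n_contaminants = 0, seed = 91))
  res <- indval(t, n_perm = 199, seed = 3)
  ok <- !is.na(res$p_value)
  expect_true(all(res$p_value[ok] >= 1 / 200))
  o <- order(res$p_value[ok])
  expect_true(all(diff(res$p_adjusted[ok][o]) >= -1e-12))
  expect_true(all(res$p_adjusted[ok] >= res$p_value[ok] - 1e-12))
  # planted indicators are recovered
  truth <- attr(t, "truth")$indicator_map
  hit <- res[res$otu %in% names(truth), ]
  expect_true(all(hit$indval > 0.9))
})
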