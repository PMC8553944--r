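test_that("depth normalisation rarefies every retained sample to the target", {
  t <- simulate_otu_table(otu_sim_spec(n_otus = 80, n_daughter_errors = 4,
                                       n_contaminants = 2, seed = 31))
  tn <- normalize_depth(t, depth = 30000, seed = 2)
  keep <- !tn$sample_meta$control
  expect_true(all(colSums(tn$counts[, keep]) == 30000))
  # a sample already at the target depth is unchanged
  counts <- matrix(c(15L, 10L, 5L, 3L, 2L, 1L), nrow = 3)
  t2 <- otu_count_table(counts, groups = c("a", "a"))
  t2n <- suppressWarnings(normalize_depth(t2, depth = 30, seed = 1))
  expect_identical(t2n$counts[, 1], t2$counts[, 1])
  # shallow samples are dropped with a warning
  expect_warning(out <- normalize_depth(t2, depth = 8, seed = 1), "below depth")
  expect_equal(ncol(out$counts), 1)
})

test_that("rarefaction preserves expected proportions (hypergeometric)", {
  counts <- matrix(c(6000L, 3000L, 1000L), ncol = 1)
  t <- otu_count_table(counts, groups = "a")
  props <- sapply(1:100, function(s) {
    normalize_depth(t, depth = 2000, seed = s)$counts[1, 1] / 2000
  })
  se <- sd(props) / sqrt(100)
  expect_lt(abs(mean(props) - 0.6), 2 * se + 1e-6)
})

test_that("LULU merges planted daughters and only them", {
  t <- simulate_otu_table(otu_sim_spec(n_otus = 120, n_daughter_errors = 8,
                                       n_contaminants = 0, seed = 41))
  truth <- attr(t, "truth")
  res <- lulu_curate(t)
  expect_setequal(res$merges$daughter, names(truth$daughters))
  expect_equal(unname(truth$daughters[res$merges$daughter]),
               res$merges$parent)
  # merged counts were added to the parent (read totals conserved)
  expect_equal(sum(res$table$counts), sum(t$counts))
})

test_that("LULU respects its three gates", {
  # empty match list: unchanged
  counts <- matrix(rpois(40, 20), nrow = 4)
  t0 <- otu_count_table(counts, groups = rep("a", 10))
  expect_equal(nrow(lulu_curate(t0)$table$counts), 4)
  # two similar but non-co-occurring OTUs are both retained
  cx <- rbind(A = c(50L, 60L, 0L, 0L), B = c(0L, 0L, 40L, 30L))
  ml <- data.frame(otu_a = "B", otu_b = "A", identity = 99)
  t1 <- otu_count_table(cx, groups = rep("a", 4), match_list = ml)
  expect_equal(nrow(lulu_curate(t1)$merges), 0)
  # below-threshold similarity is ignored
  cy <- rbind(A = c(50L, 60L, 10L), B = c(5L, 6L, 1L))
  t2 <- otu_count_table(cy, groups = rep("a", 3),
                        match_list = data.frame(otu_a = "B", otu_b = "A",
                                                identity = 80))
  expect_equal(nrow(lulu_curate(t2)$merges), 0)
  # same pair at high identity does merge
  t3 <- otu_count_table(cy, groups = rep("a", 3),
                        match_list = data.frame(otu_a = "B", otu_b = "A",
                                                identity = 97))
  expect_equal(lulu_curate(t3)$merges$daughter, "B")
})

test_that("control-based removal applies the >= 2 read rule and drops controls", {
  counts <- rbind(keep1 = c(10L, 20L, 1L),   # 1 read in control: retained
                  kill1 = c(10L, 20L, 2L),   # exactly 2: removed
                  kill2 = c(5L, 5L, 9L),
                  keep2 = c(8L, 9L, 0L))
  t <- otu_count_table(counts, groups = c("a", "b", NA),
                       controls = c(FALSE, FALSE, TRUE))
  res <- remove_control_otus(t)
  expect_setequal(res$removed, c("kill1", "kill2"))
  expect_equal(ncol(res$table$counts), 2)
  # planted contaminants are recovered exactly
  t2 <- simulate_otu_table(otu_sim_spec(n_otus = 100, n_daughter_errors = 0,
                                        n_contaminants = 5, seed = 51))
  res2 <- remove_control_otus(t2)
  expect_setequal(res2$removed, attr(t2, "truth")$contaminants)
  # no controls: warning, no-op
  t3 <- otu_count_table(matrix(1:4, 2), groups = c("a", "b"))
  expect_warning(res3 <- remove_control_otus(t3), "no control")
  expect_equal(dim(res3$table$counts), dim(t3$counts))
})

test_that("controls are silent when no contaminants are configured", {
  t <- simulate_otu_table(otu_sim_spec(n_otus = 60, n_daughter_errors = 3,
                                       n_contaminants = 0, seed = 61))
  expect_true(all(t$counts[, t$sample_meta$control] == 0))
})

test_that("minimum-read filter equals a brute-force row-sum check", {
  counts <- rbind(a = c(4L, 5L), b = c(5L, 5L), c = c(4L, 5L), d = c(0L, 0L))
  t <- otu_count_table(counts, groups = c("x", "y"))
  out <- min_read_filter(t, min_total = 10)
  expect_setequal(rownames(out$counts), c("b"))
  set.seed(3)
  counts2 <- matrix(rpois(300, 4), nrow = 30)
  t2 <- otu_count_table(counts2, groups = rep("g", 10))
  out2 <- min_read_filter(t2, min_total = 10)
  expect_setequal(rownames(out2$counts),
                  rownames(counts2 <- t2$counts)[rowSums(t2$counts) >= 10])
  # empty table passes through
  t3 <- otu_count_table(matrix(integer(), 0, 2,
                               dimnames = list(NULL, c("s1", "s2"))),
                        groups = c("a", "b"))
  expect_equal(nrow(min_read_filter(t3)$counts), 0)
})

test_that("simulated tables are bit-reproducible and daughters obey their invariants", {
  spec <- otu_sim_spec(n_otus = 90, n_daughter_errors = 6, seed = 71)
  t1 <- simulate_otu_table(spec)
  t2 <- simulate_otu_table(spec)
  expect_identical(t1$counts, t2$counts)
  truth <- attr(t1, "truth")
  for (d in names(truth$daughters)) {
    p <- truth$daughters[[d]]
    dc <- t1$counts[d, !t1$sample_meta$control]
    pc <- t1$counts[p, !t1$sample_meta$control]
    expect_true(all(dc[dc > 0] < pc[dc > 0]))   # strictly rarer, co-occurring
  }
  # match list records daughters above the curation similarity threshold
  ml <- t1$match_list
  planted <- ml[ml$otu_a %in% names(truth$daughters), ]
  expect_true(all(planted$identity >= 84))
})
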