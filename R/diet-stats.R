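#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum|x - y| / sum(x + y)`, computed on per-sample relative
#' abundances by default (each sample's counts divided by its total), via
#' [vegan::vegdist()]. Control samples are excluded.
#'
#' @param t An [otu_count_table()] or a samples x OTUs numeric matrix.
#' @param use_relative Divide each sample by its total first.
#' @return A symmetric `dist`-convertible matrix with zero diagonal.
#' @export
bray_curtis <- function(t, use_relative = TRUE) {
  m <- community_matrix(t)
  if (nrow(m) < 2) abort("need at least two samples")
  if (use_relative) {
    tot <- rowSums(m)
    tot[tot == 0] <- 1
    m <- m / tot
  }
  as.matrix(vegan::vegdist(m, method = "bray"))
}

# samples x OTUs matrix from either representation.
community_matrix <- function(t) {
  if (inherits(t, "otu_table")) {
    keep <- !t$sample_meta$control
    t(t$counts[, keep, drop = FALSE])
  } else {
    as.matrix(t)
  }
}

# group labels aligned with community_matrix rows.
community_groups <- function(t, groups = NULL) {
  if (!is.null(groups)) return(as.character(groups))
  if (!inherits(t, "otu_table")) abort("`groups` required for a bare matrix")
  t$sample_meta$group[!t$sample_meta$control]
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimisation with monotone regression and random
#' restarts, delegated to [vegan::metaMDS()] on a precomputed dissimilarity
#' matrix. Deterministic given `seed`.
#'
#' @param d Symmetric dissimilarity matrix (e.g. from [bray_curtis()]).
#' @param k Number of ordination dimensions.
#' @param n_starts Random restarts.
#' @param max_iter Maximum iterations per start.
#' @param seed Integer seed.
#' @return An `nmds_fit` with `points` (samples x k coordinates tibble) and
#'   `stress` (Kruskal stress-1, on the 0-1 scale).
#' @export
nmds_ordinate <- function(d, k = 2, n_starts = 20, max_iter = 500, seed = 1) {
  d <- as.matrix(d)
  if (k >= nrow(d)) abort("k must be smaller than the number of samples")
  fit <- with_seed(split_seed(seed, "nmds"), {
    vegan::metaMDS(stats::as.dist(d), k = k, trymax = n_starts,
                   maxit = max_iter, trace = 0, autotransform = FALSE,
                   wascores = FALSE)
  })
  pts <- as_tibble(fit$points, .name_repair = "minimal")
  names(pts) <- paste0("axis", seq_len(k))
  pts$sample <- rownames(d) %||% as.character(seq_len(nrow(d)))
  structure(list(points = pts, stress = fit$stress, k = k,
                 converged = isTRUE(fit$converged)),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("<nmds_fit> k = %d, stress = %.4f\n", x$k, x$stress))
  invisible(x)
}

#' @rdname nmds_ordinate
#' @param x An `nmds_fit`.
#' @param ... Unused.
#' @export
tidy.nmds_fit <- function(x, ...) x$points

#' @rdname nmds_ordinate
#' @param object An `nmds_fit`.
#' @param groups Optional group labels (one per sample) to colour points.
#' @export
autoplot.nmds_fit <- function(object, groups = NULL, ...) {
  d <- object$points
  d$group <- if (is.null(groups)) "all" else as.character(groups)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$axis1, y = .data$axis2,
                                  colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      subtitle = sprintf("stress = %.3f", object$stress),
      x = "nMDS1", y = "nMDS2"
    ) +
    ggplot2::theme_minimal()
}

#' Permutational multivariate analysis of variance
#'
#' Anderson's one-way PERMANOVA on a dissimilarity matrix: the pseudo-F is
#' computed from the Gower-centred squared dissimilarities
#' (`SS_total = sum d^2 / n`, `SS_within = sum_g sum d^2_g / n_g`), and the
#' p-value by free permutation of sample labels. `R^2 = SS_between/SS_total`.
#'
#' @param d Symmetric dissimilarity matrix.
#' @param groups Group label per sample (at least 2 groups of at least 2).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `community_test` object; `glance()` gives df, pseudo-F, R2 and p.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  groups <- as.factor(groups)
  check_groups(d, groups)
  d2 <- d^2
  n <- nrow(d)
  k <- nlevels(groups)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within_fun <- function(gidx) {
    s <- 0
    for (lev in seq_len(k)) {
      i <- which(gidx == lev)
      s <- s + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
    }
    s
  }
  gidx <- as.integer(groups)
  ssw <- ss_within_fun(gidx)
  ssb <- ss_total - ssw
  f_obs <- (ssb / (k - 1)) / (ssw / (n - k))
  r2 <- ssb / ss_total
  f_perm <- with_seed(split_seed(seed, "permanova"), {
    replicate(n_perm, {
      gi <- sample(gidx)
      ssw_p <- ss_within_fun(gi)
      ((ss_total - ssw_p) / (k - 1)) / (ssw_p / (n - k))
    })
  })
  p <- perm_pval(sum(f_perm >= f_obs), n_perm)
  new_community_test("PERMANOVA", df = k - 1, df_resid = n - k,
                     statistic = f_obs, r_squared = r2, p_value = p,
                     n_permutations = n_perm, seed = seed)
}

#' Homogeneity of multivariate dispersions (PERMDISP2)
#'
#' Embeds the dissimilarity matrix by principal-coordinates analysis (negative
#' eigenvalues handled by the standard squared-distance correction: squared
#' distances to centres are the real-part difference between positive- and
#' negative-axis contributions), computes each sample's distance to its group
#' centre (spatial median by default, centroid optionally), and tests equality
#' of mean distances with an ANOVA F whose p-value comes from permuting the
#' distances among groups (the PERMDISP2 permutation scheme).
#'
#' Two permutation schemes are available: `"distances"` (the classic
#' PERMDISP2 scheme, as in `vegan::permutest.betadisper`: the observed
#' distances-to-centre are shuffled among samples; robust to location
#' differences but conservative for small groups because the within-group
#' distances are shrunk by centre estimation) and `"samples"` (the raw
#' samples are permuted among groups and centres and distances recomputed;
#' exact under exchangeability of samples).
#'
#' @inheritParams permanova
#' @param center `"median"` (spatial median, the PERMDISP2 default) or
#'   `"centroid"`.
#' @param permute Permutation scheme, `"distances"` (default) or `"samples"`.
#' @return A `community_test` object.
#' @export
permdisp <- function(d, groups, n_perm = 999, seed = 1,
                     center = c("median", "centroid"),
                     permute = c("distances", "samples")) {
  center <- arg_match(center)
  permute <- arg_match(permute)
  d <- as.matrix(d)
  groups <- as.factor(groups)
  check_groups(d, groups)
  if (nlevels(groups) < 2) abort("need at least two groups")
  n <- nrow(d)
  k <- nlevels(groups)
  emb <- pcoa_embed(d)
  dist_fun <- function(gidx) {
    z <- numeric(n)
    for (lev in seq_len(k)) {
      i <- which(gidx == lev)
      z[i] <- dist_to_center(emb, i, center)
    }
    z
  }
  ng <- tabulate(as.integer(groups), nlevels(groups))
  f_stat <- function(z, gidx) {
    gm <- rowsum(z, gidx) / ng
    ssb <- sum(ng * (gm - mean(z))^2)
    ssw <- sum((z - gm[gidx])^2)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  gidx <- as.integer(groups)
  z_obs <- dist_fun(gidx)
  f_obs <- f_stat(z_obs, gidx)
  f_perm <- with_seed(split_seed(seed, "permdisp"), {
    if (permute == "distances") {
      replicate(n_perm, f_stat(z_obs[sample(n)], gidx))
    } else if (center == "centroid") {
      # signed Gram shortcut: squared distance to the group centroid is
      # G_ii - 2 mean_{j in g} G_ij + mean_{j,l in g} G_jl
      G <- tcrossprod(emb$real) -
        (if (ncol(emb$imag) > 0) tcrossprod(emb$imag) else 0)
      z_from_G <- function(gi) {
        z2 <- numeric(n)
        for (lev in seq_len(k)) {
          i <- which(gi == lev)
          M <- G[i, i, drop = FALSE]
          z2[i] <- diag(M) - 2 * rowMeans(M) + mean(M)
        }
        sqrt(pmax(z2, 0))
      }
      replicate(n_perm, {
        gi <- gidx[sample(n)]
        f_stat(z_from_G(gi), gi)
      })
    } else {
      replicate(n_perm, {
        gi <- gidx[sample(n)]
        f_stat(dist_fun(gi), gi)
      })
    }
  })
  p <- perm_pval(sum(f_perm >= f_obs), n_perm)
  new_community_test("PERMDISP", df = k - 1, df_resid = n - k,
                     statistic = f_obs, r_squared = NA_real_, p_value = p,
                     n_permutations = n_perm, seed = seed,
                     distances = tibble(sample = rownames(d) %||%
                                          as.character(seq_len(n)),
                                        group = as.character(groups),
                                        distance = z_obs))
}

# PCoA embedding keeping real and imaginary axes separately.
pcoa_embed <- function(d) {
  n <- nrow(d)
  A <- -0.5 * d^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-8
  pos <- e$values > tol
  neg <- e$values < -tol
  list(
    real = e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(e$values[pos]), sum(pos)),
    imag = e$vectors[, neg, drop = FALSE] %*%
      diag(sqrt(-e$values[neg]), sum(neg))
  )
}

# distances of rows `i` to their group centre in the PCoA embedding;
# squared distance = (real part) - (imaginary part), floored at 0.
dist_to_center <- function(emb, i, center) {
  cr <- center_of(emb$real[i, , drop = FALSE], center)
  d2 <- colSums((t(emb$real[i, , drop = FALSE]) - cr)^2)
  if (ncol(emb$imag) > 0) {
    ci <- center_of(emb$imag[i, , drop = FALSE], center)
    d2 <- d2 - colSums((t(emb$imag[i, , drop = FALSE]) - ci)^2)
  }
  sqrt(pmax(d2, 0))
}

center_of <- function(m, center) {
  if (center == "centroid" || nrow(m) == 1) return(colMeans(m))
  spatial_median(m)
}

# Weiszfeld iteration for the spatial median.
spatial_median <- function(m, tol = 1e-8, max_iter = 200) {
  y <- colMeans(m)
  for (it in seq_len(max_iter)) {
    dists <- sqrt(colSums((t(m) - y)^2))
    if (any(dists < tol)) return(y)
    w <- 1 / dists
    y_new <- colSums(m * w) / sum(w)
    if (sqrt(sum((y_new - y)^2)) < tol) return(y_new)
    y <- y_new
  }
  y
}

check_groups <- function(d, groups) {
  if (length(groups) != nrow(d)) abort("one group label per sample required")
  tab <- table(groups)
  if (length(tab) < 2) abort("need at least two groups")
  if (any(tab < 2)) abort("every group needs at least two samples")
}

new_community_test <- function(test, df, df_resid, statistic, r_squared,
                               p_value, n_permutations, seed,
                               distances = NULL) {
  structure(
    list(test = test, df = df, df_resid = df_resid, statistic = statistic,
         r_squared = r_squared, p_value = p_value,
         n_permutations = n_permutations, seed = seed, distances = distances),
    class = "community_test"
  )
}

#' @export
print.community_test <- function(x, ...) {
  cat(sprintf("<%s> df = %d, pseudo-F = %.3f%s, p = %.3g (%d permutations)\n",
              x$test, x$df, x$statistic,
              if (!is.na(x$r_squared)) sprintf(", R2 = %.3f", x$r_squared)
              else "",
              x$p_value, x$n_permutations))
  invisible(x)
}

#' @rdname permanova
#' @param x A `community_test`.
#' @param ... Unused.
#' @export
glance.community_test <- function(x, ...) {
  tibble(test = x$test, df = x$df, df_resid = x$df_resid,
         statistic = x$statistic, r_squared = x$r_squared,
         p_value = x$p_value, n_permutations = x$n_permutations)
}

#' Indicator species analysis (IndVal)
#'
#' For every OTU and every non-empty combination of groups, the group-size-
#' corrected indicator value `IndVal.g = sqrt(A * B)` where specificity `A` is
#' the combination's mean abundance divided by the summed per-group mean
#' abundances, and fidelity `B` is the occurrence fraction within the
#' combination's samples. Each OTU reports its best combination; its p-value
#' is the permutation probability (group labels permuted) that the best
#' combination's statistic is matched or exceeded, adjusted across OTUs with
#' Benjamini-Hochberg. The combination of all groups is scored but gets no
#' p-value (it is invariant under permutation).
#'
#' @param t An [otu_count_table()] or samples x OTUs matrix.
#' @param groups Optional group labels (defaults to the table's).
#' @param combinations Score group combinations (`TRUE`) or single groups only.
#' @param n_perm Number of permutations.
#' @param adjust Multiple-testing method across OTUs (default `"BH"`).
#' @param seed Integer seed.
#' @return An `indval_table`: tibble with one row per OTU (`otu`, `best_combo`,
#'   `indval`, `p_value`, `p_adjusted`, `absent` flag).
#' @export
indval <- function(t, groups = NULL, combinations = TRUE, n_perm = 999,
                   adjust = "BH", seed = 1) {
  m <- community_matrix(t)
  groups <- as.factor(community_groups(t, groups))
  if (nlevels(groups) < 2) abort("need at least two groups")
  combos <- group_combinations(levels(groups), combinations)
  stat_all <- indval_stats(m, groups, combos)     # OTUs x combos
  best_idx <- max.col(replace(stat_all, is.na(stat_all), -1), "first")
  obs <- stat_all[cbind(seq_len(nrow(stat_all)), best_idx)]
  full_combo <- lengths(combos) == nlevels(groups)
  n_otu <- ncol(m)
  exceed <- integer(n_otu)
  with_seed(split_seed(seed, "indval"), {
    for (b in seq_len(n_perm)) {
      gp <- groups[sample(length(groups))]
      sp <- indval_stats(m, gp, combos)
      v <- sp[cbind(seq_len(n_otu), best_idx)]
      exceed <- exceed + as.integer(!is.na(v) & v >= obs - 1e-12)
    }
  })
  p <- perm_pval(exceed, n_perm)
  p[full_combo[best_idx]] <- NA_real_     # invariant under permutation
  absent <- colSums(m) == 0
  obs[absent] <- 0
  tab <- tibble(
    otu = colnames(m) %||% as.character(seq_len(n_otu)),
    best_combo = sapply(combos[best_idx], paste, collapse = "+"),
    indval = obs,
    p_value = p,
    p_adjusted = ifelse(is.na(p), NA_real_, p.adjust(p, method = adjust)),
    absent = absent
  )
  dimnames(stat_all) <- list(tab$otu,
                             sapply(combos, paste, collapse = "+"))
  attr(tab, "combo_stats") <- stat_all
  class(tab) <- c("indval_table", class(tab))
  tab
}

group_combinations <- function(levels, combinations) {
  if (!combinations) return(as.list(levels))
  combos <- list()
  for (k in seq_along(levels)) {
    combos <- c(combos, combn(levels, k, simplify = FALSE))
  }
  combos
}

# IndVal.g for every OTU (columns of m) x combination.
indval_stats <- function(m, groups, combos) {
  lev <- levels(groups)
  gmeans <- rowsum(m, groups) / as.vector(table(groups))   # levels x OTUs
  gocc <- rowsum((m > 0) + 0, groups)                      # occurrences
  gn <- as.vector(table(groups))
  total_mean <- colSums(gmeans)
  out <- matrix(NA_real_, ncol(m), length(combos))
  for (ci in seq_along(combos)) {
    sel <- lev %in% combos[[ci]]
    A <- colSums(gmeans[sel, , drop = FALSE]) / total_mean
    B <- colSums(gocc[sel, , drop = FALSE]) / sum(gn[sel])
    v <- sqrt(pmax(A, 0) * B)
    v[total_mean == 0] <- NA_real_
    out[, ci] <- v
  }
  out
}
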