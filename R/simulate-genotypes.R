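#' Specify a genotype simulation
#'
#' Configuration for [simulate_genotypes()]. Two mutually exclusive modes set
#' the population structure: `target_fst` draws population allele frequencies
#' from the Balding-Nichols construction (ancestral frequency
#' `p ~ Uniform(0.05, 0.95)`, per-population frequency
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`), which has expected multilocus Fst equal to
#' `target_fst`; `migration_matrix` instead evolves frequencies under a
#' finite-island drift-migration recursion (binomial drift of `2N` allele
#' copies per generation, deterministic mixing by the per-ordered-pair
#' emigration weights) for `n_generations` non-overlapping generations.
#'
#' @param n_populations Number of populations.
#' @param n_individuals_per_pop Diploid individuals sampled per population.
#' @param n_loci Number of biallelic loci.
#' @param target_fst Target fixation index in `[0, 1)`; `0` gives panmixia.
#' @param migration_matrix Square matrix `m[i, j]` = per-generation fraction of
#'   population `j` replaced by migrants from population `i` (columns receive).
#'   Mutually exclusive with `target_fst`.
#' @param n_generations Generations of the drift-migration recursion (migration
#'   mode only).
#' @param effective_size Effective (deme) population size driving drift in
#'   migration mode; defaults to `n_individuals_per_pop`. Marine fishes
#'   typically have effective sizes far larger than any sample, so simulations
#'   emulating weakly structured systems should set this well above the sample
#'   size.
#' @param missing_rate Independent per-call missingness probability in `[0, 1)`.
#' @param coverage_range Length-2 positive range for log-normally distributed
#'   mean locus depth.
#' @param seed Integer seed; all draws are reproducible given `(spec, seed)`.
#' @return A `genotype_sim_spec` list.
#' @export
genotype_sim_spec <- function(n_populations = 2, n_individuals_per_pop = 50,
                              n_loci = 1000, target_fst = NULL,
                              migration_matrix = NULL, n_generations = 100,
                              effective_size = NULL, missing_rate = 0,
                              coverage_range = c(20, 200), seed = 1) {
  if (!is.null(target_fst) && !is.null(migration_matrix)) {
    abort("`target_fst` and `migration_matrix` are mutually exclusive")
  }
  if (is.null(target_fst) && is.null(migration_matrix)) target_fst <- 0
  if (!is.null(target_fst) && (target_fst < 0 || target_fst >= 1)) {
    abort("`target_fst` must be in [0, 1)")
  }
  if (missing_rate < 0 || missing_rate >= 1) abort("`missing_rate` must be in [0, 1)")
  if (n_loci < 1) abort("`n_loci` must be >= 1")
  if (!is.null(migration_matrix)) {
    migration_matrix <- as.matrix(migration_matrix)
    if (nrow(migration_matrix) != n_populations ||
        ncol(migration_matrix) != n_populations) {
      abort("`migration_matrix` must be n_populations x n_populations")
    }
  }
  structure(
    list(
      n_populations = as.integer(n_populations),
      n_individuals_per_pop = as.integer(n_individuals_per_pop),
      n_loci = as.integer(n_loci),
      target_fst = target_fst,
      migration_matrix = migration_matrix,
      n_generations = as.integer(n_generations),
      effective_size = as.integer(effective_size %||% n_individuals_per_pop),
      missing_rate = missing_rate,
      coverage_range = coverage_range,
      seed = as.integer(seed)
    ),
    class = "genotype_sim_spec"
  )
}

#' Simulate a biallelic SNP genotype matrix with known structure
#'
#' Draws per-population allele frequencies according to the mode configured in
#' the spec (see [genotype_sim_spec()]), then samples Hardy-Weinberg genotypes
#' within populations, applies independent per-call missingness, and attaches
#' log-normal mean locus coverage.
#'
#' @param spec A [genotype_sim_spec()].
#' @param outlier_loci Optional integer: number of trailing loci drawn with
#'   `outlier_fst` instead of `target_fst` (Balding-Nichols mode only), used to
#'   plant high-differentiation loci for outlier-scan power checks.
#' @param outlier_fst Fst used for the planted outlier loci.
#' @return A [genotype_matrix()] whose `truth` attribute records the simulated
#'   per-population allele frequencies and any planted outlier locus ids.
#' @export
simulate_genotypes <- function(spec, outlier_loci = 0, outlier_fst = NULL) {
  stopifnot(inherits(spec, "genotype_sim_spec"))
  with_seed(split_seed(spec$seed, "genotypes"), {
    K <- spec$n_populations
    L <- spec$n_loci
    n <- spec$n_individuals_per_pop
    if (!is.null(spec$migration_matrix)) {
      pmat <- sim_freqs_migration(spec)
    } else {
      pmat <- sim_freqs_bn(L, K, spec$target_fst)
    }
    outlier_ids <- character()
    if (outlier_loci > 0) {
      idx <- (L - outlier_loci + 1L):L
      pmat[idx, ] <- sim_freqs_bn(length(idx), K, outlier_fst)
      outlier_ids <- sprintf("locus_%05d", idx)
    }
    calls <- matrix(NA_integer_, nrow = n * K, ncol = L)
    for (k in seq_len(K)) {
      rows <- ((k - 1L) * n + 1L):(k * n)
      calls[rows, ] <- matrix(
        rbinom(n * L, 2L, rep(pmat[, k], each = n)),
        nrow = n
      )
    }
    if (spec$missing_rate > 0) {
      calls[runif(length(calls)) < spec$missing_rate] <- NA_integer_
    }
    rownames(calls) <- sprintf("ind_%03d", seq_len(nrow(calls)))
    colnames(calls) <- sprintf("locus_%05d", seq_len(L))
    meanlog <- mean(log(spec$coverage_range))
    sdlog <- diff(log(spec$coverage_range)) / 4
    coverage <- rlnorm(L, meanlog, sdlog)
    sites <- rep(sprintf("pop_%02d", seq_len(K)), each = n)
    g <- genotype_matrix(calls, sites, coverage)
    attr(g, "truth") <- list(freqs = pmat, outlier_loci = outlier_ids)
    g
  })
}

# Balding-Nichols allele frequencies: L loci x K populations.
sim_freqs_bn <- function(L, K, fst) {
  anc <- runif(L, 0.05, 0.95)
  if (fst == 0) {
    matrix(anc, nrow = L, ncol = K)
  } else {
    a <- anc * (1 - fst) / fst
    b <- (1 - anc) * (1 - fst) / fst
    matrix(rbeta(L * K, rep(a, K), rep(b, K)), nrow = L)
  }
}

# Finite-island drift-migration recursion on allele frequencies.
sim_freqs_migration <- function(spec) {
  K <- spec$n_populations
  L <- spec$n_loci
  N <- spec$effective_size
  m <- spec$migration_matrix
  # column j receives m[i, j] from i and keeps 1 - sum(m[-j, j]) of itself
  mix <- m
  diag(mix) <- 0
  self <- 1 - colSums(mix)
  if (any(self < 0)) abort("migration rates into a population exceed 1")
  trans <- mix
  diag(trans) <- self
  p <- matrix(runif(L, 0.1, 0.9), nrow = L, ncol = K)
  for (gen in seq_len(spec$n_generations)) {
    p <- p %*% trans                       # deterministic migrant mixing
    p <- matrix(rbinom(L * K, 2L * N, p) / (2 * N), nrow = L)  # drift
  }
  p
}
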