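#' OutFLANK-style Fst outlier scan
#'
#' Partitions loci into putatively neutral and outlier sets by fitting the
#' neutral distribution of per-locus Fst and flagging right-tail excess.
#' Following the OutFLANK procedure: per-locus Fst is computed without the
#' finite-sample correction for the null fit; loci with expected
#' heterozygosity below `min_het` are excluded from the fit; the central part
#' of the Fst distribution (after trimming a fraction `trim` from each tail)
#' is fit by maximum likelihood as a scaled chi-square truncated to the
#' trimming window, with the mean fixed at the ratio-of-sums multilocus Fst of
#' the retained loci and the effective degrees of freedom inferred; right-tail
#' p-values then come from the fitted null and are converted to q-values by
#' Benjamini-Hochberg.
#'
#' @param g A [genotype_matrix()].
#' @param pops Optional site labels.
#' @param trim Fraction trimmed from each tail for the null fit.
#' @param min_het Minimum per-locus expected heterozygosity to enter the fit.
#' @param fdr False-discovery-rate threshold on q-values.
#' @return An `outlier_scan` object: per-locus tibble (`fst`, `fst_no_corr`,
#'   `he`, `p_value`, `q_value`, `outlier`), the inferred `df`, the null mean
#'   `fst_bar`, and `neutral_ids` / `outlier_ids` (disjoint, covering all
#'   tested loci).
#' @export
outflank_scan <- function(g, pops = NULL, trim = 0.05, min_het = 0.1,
                          fdr = 0.05) {
  stopifnot(inherits(g, "genotype_matrix"))
  by_site <- split_by_site(g, pops)
  if (length(by_site) < 2) abort("need at least two populations")
  if (ncol(g$calls) < 200) {
    warn("fewer than 200 loci: the null-distribution fit may be unstable")
  }
  comp_nc <- wc_components(by_site, corrected = FALSE)
  comp_c <- wc_components(by_site, corrected = TRUE)
  fst_nc <- wc_per_locus(comp_nc)
  fst_c <- wc_per_locus(comp_c)
  he <- comp_nc$he
  eligible <- !is.na(fst_nc) & he >= min_het
  if (!any(eligible)) abort("no locus passes the heterozygosity mask")
  x <- fst_nc[eligible]
  if (diff(range(x)) < .Machine$double.eps^0.5) {
    abort("degenerate Fst distribution: all per-locus values identical")
  }
  fit <- fit_trimmed_chisq(x, trim)
  p <- rep(NA_real_, length(fst_nc))
  p[eligible] <- pchisq(fst_nc[eligible] * fit$df / fit$fst_bar, df = fit$df,
                        lower.tail = FALSE)
  q <- rep(NA_real_, length(p))
  q[eligible] <- p.adjust(p[eligible], method = "BH")
  outlier <- !is.na(q) & q < fdr & fst_nc > fit$fst_bar
  loci <- colnames(g$calls)
  structure(
    list(
      table = tibble(
        locus = loci, fst = fst_c, fst_no_corr = fst_nc, he = he,
        in_fit = eligible, p_value = p, q_value = q, outlier = outlier
      ),
      df = fit$df, fst_bar = fit$fst_bar, trim = trim, min_het = min_het,
      fdr = fdr,
      outlier_ids = loci[outlier],
      neutral_ids = loci[!outlier]
    ),
    class = "outlier_scan"
  )
}

# ML fit of a scaled chi-square to the trimmed Fst distribution, treating the
# sample as truncated to the trimming window.  Both the effective df and the
# scale are estimated (the fitted null mean is df * scale), which keeps the df
# estimate consistent despite the truncation.
fit_trimmed_chisq <- function(x, trim) {
  qs <- quantile(x, c(trim, 1 - trim), names = FALSE, type = 1)
  keep <- x >= qs[1] & x <= qs[2]
  xk <- x[keep]
  xk <- xk[xk > 0]
  if (length(xk) < 10) abort("too few loci retained after trimming")
  lo <- max(qs[1], .Machine$double.xmin)
  hi <- qs[2]
  nll <- function(par) {
    df <- exp(par[1]); scale <- exp(par[2])
    z <- pchisq(hi / scale, df) - pchisq(lo / scale, df)
    if (!is.finite(z) || z <= 0) return(1e10)
    val <- -(sum(dchisq(xk / scale, df, log = TRUE)) -
               length(xk) * log(scale) - length(xk) * log(z))
    if (!is.finite(val)) 1e10 else val
  }
  df0 <- max(0.5, 2 * mean(xk)^2 / max(var(xk), 1e-12))
  init <- c(log(df0), log(mean(xk) / df0))
  opt <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  df <- exp(opt$par[1]); scale <- exp(opt$par[2])
  list(df = df, fst_bar = df * scale)
}

#' @export
print.outlier_scan <- function(x, ...) {
  cat(sprintf(
    "<outlier_scan> %d loci (%d in fit), inferred df = %.2f, mean Fst = %.4f\n",
    nrow(x$table), sum(x$table$in_fit), x$df, x$fst_bar))
  cat(sprintf("  %d outliers at FDR %.2g, %d putatively neutral\n",
              length(x$outlier_ids), x$fdr, length(x$neutral_ids)))
  invisible(x)
}

#' @rdname outflank_scan
#' @param x An `outlier_scan` object.
#' @param ... Unused.
#' @export
tidy.outlier_scan <- function(x, ...) x$table

#' @rdname outflank_scan
#' @export
glance.outlier_scan <- function(x, ...) {
  tibble(
    n_loci = nrow(x$table), n_in_fit = sum(x$table$in_fit),
    df = x$df, fst_bar = x$fst_bar,
    n_outliers = length(x$outlier_ids), n_neutral = length(x$neutral_ids),
    fdr = x$fdr
  )
}

#' @rdname outflank_scan
#' @param object An `outlier_scan` object.
#' @export
autoplot.outlier_scan <- function(object, ...) {
  d <- dplyr::filter(object$table, !is.na(.data$fst_no_corr))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$he, y = .data$fst_no_corr,
                                  colour = .data$outlier)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "expected heterozygosity", y = "Fst (uncorrected)",
                  colour = "outlier") +
    ggplot2::theme_minimal()
}
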