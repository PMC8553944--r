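#' OTU read-count table container
#'
#' Bundles an OTUs x samples count matrix with per-sample metadata (group /
#' region label, control flag), per-OTU metadata, and an optional match list of
#' pairwise sequence similarities used by the curation step.
#'
#' @param counts Non-negative integer matrix, OTUs in rows, samples in
#'   columns (USEARCH `otutab` orientation).
#' @param groups Character vector of group labels, one per sample (`NA`
#'   allowed for controls).
#' @param controls Logical vector flagging extraction/PCR control samples.
#' @param match_list Optional tibble/data.frame with columns `otu_a`, `otu_b`,
#'   `identity` (percent identity, symmetric records not required).
#' @return An `otu_table` object with elements `counts`, `sample_meta`,
#'   `otu_meta`, `match_list` and a `log` of curation steps.
#' @export
otu_count_table <- function(counts, groups, controls = NULL,
                            match_list = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("counts must be non-negative")
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("OTU_%04d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample_%03d", seq_len(ncol(counts)))
  }
  controls <- controls %||% rep(FALSE, ncol(counts))
  if (length(groups) != ncol(counts) || length(controls) != ncol(counts)) {
    abort("`groups` and `controls` must have one entry per sample")
  }
  if (any(is.na(groups) & !controls)) {
    abort("every non-control sample needs a group label")
  }
  if (!is.null(match_list)) {
    match_list <- as_tibble(match_list)
    if (!all(c("otu_a", "otu_b", "identity") %in% names(match_list))) {
      abort("match_list needs columns otu_a, otu_b, identity")
    }
  }
  structure(
    list(
      counts = counts,
      sample_meta = tibble(sample = colnames(counts),
                           group = as.character(groups),
                           control = as.logical(controls)),
      otu_meta = tibble(otu = rownames(counts),
                        total_reads = rowSums(counts)),
      match_list = match_list,
      log = tibble(step = character(), otus_before = integer(),
                   otus_after = integer(), samples_before = integer(),
                   samples_after = integer())
    ),
    class = "otu_table"
  )
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d OTUs x %d samples (%d controls)\n",
              nrow(x$counts), ncol(x$counts), sum(x$sample_meta$control)))
  if (nrow(x$log) > 0) print(as.data.frame(x$log), row.names = FALSE)
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

replace_counts <- function(t, counts, step) {
  before <- dim(t$counts)
  t$counts <- counts
  t$sample_meta <- t$sample_meta[match(colnames(counts),
                                       t$sample_meta$sample), , drop = FALSE]
  t$otu_meta <- tibble(otu = rownames(counts), total_reads = rowSums(counts))
  t$log <- bind_rows(t$log, tibble(
    step = step, otus_before = before[1], otus_after = nrow(counts),
    samples_before = before[2], samples_after = ncol(counts)
  ))
  t
}

#' Subsample every non-control sample to a fixed read depth
#'
#' Rarefies each non-control sample to exactly `depth` reads by sampling
#' without replacement (a single multivariate-hypergeometric draw per sample;
#' the seed is recorded). Samples with fewer than `depth` reads are dropped
#' with a warning. Control samples are left untouched.
#'
#' @param t An [otu_count_table()].
#' @param depth Target read depth per sample.
#' @param seed Integer seed.
#' @return The rarefied `otu_table`.
#' @export
normalize_depth <- function(t, depth = 30000, seed = 1) {
  stopifnot(inherits(t, "otu_table"))
  totals <- colSums(t$counts)
  is_ctrl <- t$sample_meta$control
  shallow <- !is_ctrl & totals < depth
  if (all(shallow | is_ctrl)) abort("all non-control samples are below depth")
  if (any(shallow)) {
    warn(paste("dropping samples below depth:",
               paste(colnames(t$counts)[shallow], collapse = ", ")))
  }
  counts <- t$counts[, !shallow, drop = FALSE]
  is_ctrl <- is_ctrl[!shallow]
  with_seed(split_seed(seed, "rarefy"), {
    for (j in which(!is_ctrl)) {
      cj <- counts[, j]
      if (sum(cj) == depth) next
      drawn <- sample(rep.int(seq_along(cj), cj), depth)
      counts[, j] <- tabulate(drawn, nbins = length(cj))
    }
  })
  replace_counts(t, counts, sprintf("normalize_depth_%d", depth))
}

#' LULU-style post-clustering curation
#'
#' Merges likely erroneous "daughter" OTUs into more abundant, sequence-
#' similar, co-occurring "parent" OTUs. Candidate daughters are visited in
#' order of increasing total abundance; a daughter is merged into the most
#' abundant candidate parent for which (i) the match list records percent
#' identity of at least `min_match`, (ii) the parent occurs in at least
#' `min_cooccurrence` of the samples where the daughter occurs, and (iii) the
#' minimum parent/daughter abundance ratio over the daughter's samples is at
#' least `min_ratio`. Merged counts are added to the parent; chains collapse
#' because merging proceeds from the rarest OTU upward on the current table.
#'
#' @param t An [otu_count_table()] with a populated match list.
#' @param min_match Minimum percent identity.
#' @param min_cooccurrence Minimum relative co-occurrence (fraction of the
#'   daughter's occupied samples that also contain the parent).
#' @param min_ratio Minimum of the per-sample parent/daughter count ratio.
#' @return A list `(table, merges)` where `merges` is a tibble logging every
#'   merge (daughter, parent, identity, cooccurrence, min_ratio).
#' @export
lulu_curate <- function(t, min_match = 84, min_cooccurrence = 0.95,
                        min_ratio = 1) {
  stopifnot(inherits(t, "otu_table"))
  merges <- tibble(daughter = character(), parent = character(),
                   identity = numeric(), cooccurrence = numeric(),
                   min_ratio = numeric())
  if (is.null(t$match_list) || nrow(t$match_list) == 0) {
    return(list(table = replace_counts(t, t$counts, "lulu_curate"),
                merges = merges))
  }
  counts <- t$counts
  ml <- t$match_list
  # symmetrise the match list
  ml <- bind_rows(ml, tibble(otu_a = ml$otu_b, otu_b = ml$otu_a,
                             identity = ml$identity))
  ml <- ml[ml$identity >= min_match, , drop = FALSE]
  sample_cols <- !t$sample_meta$control   # curation looks at real samples
  work <- counts[, sample_cols, drop = FALSE]
  order_idx <- order(rowSums(work))       # rarest first
  for (otu in rownames(work)[order_idx]) {
    if (!(otu %in% rownames(work))) next  # already merged away
    d <- work[otu, ]
    occ_d <- d > 0
    if (!any(occ_d)) next
    cand <- ml[ml$otu_a == otu & ml$otu_b %in% rownames(work), , drop = FALSE]
    if (nrow(cand) == 0) next
    cand_tot <- rowSums(work)[cand$otu_b]
    cand <- cand[cand_tot > sum(d), , drop = FALSE]
    cand <- cand[order(-rowSums(work)[cand$otu_b]), , drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      p <- work[cand$otu_b[k], ]
      cooc <- sum(p > 0 & occ_d) / sum(occ_d)
      if (cooc < min_cooccurrence) next
      ratio <- min(p[occ_d] / d[occ_d])
      if (ratio < min_ratio) next
      # merge daughter into parent (full table incl. controls)
      counts[cand$otu_b[k], ] <- counts[cand$otu_b[k], ] + counts[otu, ]
      counts <- counts[rownames(counts) != otu, , drop = FALSE]
      work[cand$otu_b[k], ] <- work[cand$otu_b[k], ] + work[otu, ]
      work <- work[rownames(work) != otu, , drop = FALSE]
      merges <- bind_rows(merges, tibble(
        daughter = otu, parent = cand$otu_b[k], identity = cand$identity[k],
        cooccurrence = cooc, min_ratio = ratio
      ))
      break
    }
  }
  out <- replace_counts(t, counts, "lulu_curate")
  out$match_list <- t$match_list
  list(table = out, merges = merges)
}

#' Remove OTUs detected in control samples
#'
#' Any OTU with at least `min_control_reads` reads in any single control
#' sample is removed (a putative contaminant or tag jump); the control samples
#' are then dropped from the table.
#'
#' @param t An [otu_count_table()] with at least one control sample.
#' @param min_control_reads Read threshold in a control sample.
#' @return A list `(table, removed)` with the ids of the removed OTUs.
#' @export
remove_control_otus <- function(t, min_control_reads = 2) {
  stopifnot(inherits(t, "otu_table"))
  ctrl <- t$sample_meta$control
  if (!any(ctrl)) {
    warn("no control samples: nothing to remove")
    return(list(table = t, removed = character()))
  }
  in_ctrl <- t$counts[, ctrl, drop = FALSE]
  bad <- apply(in_ctrl, 1, max) >= min_control_reads
  counts <- t$counts[!bad, !ctrl, drop = FALSE]
  out <- replace_counts(t, counts, "remove_control_otus")
  list(table = out, removed = rownames(t$counts)[bad])
}

#' Drop OTUs below a total read-count threshold
#'
#' Removes OTUs whose total read count across all samples is below
#' `min_total`; such singleton-grade OTUs typically arise from index-tag
#' jumping.
#'
#' @param t An [otu_count_table()].
#' @param min_total Minimum total reads to retain an OTU.
#' @return The filtered `otu_table`.
#' @export
min_read_filter <- function(t, min_total = 10) {
  stopifnot(inherits(t, "otu_table"))
  keep <- rowSums(t$counts) >= min_total
  replace_counts(t, t$counts[keep, , drop = FALSE], "min_read_filter")
}
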