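#' Specify an OTU-table simulation
#'
#' Configuration for [simulate_otu_table()]. The generated table carries known
#' ground truth for every curation and indicator test: group-specific
#' indicator OTUs (present, at high relative abundance, only in their group
#' combination), planted parent-daughter error OTUs (the daughter co-occurs
#' with, and is strictly less abundant than, its parent in every sample and is
#' listed in the match list at high percent identity), and control-sample
#' contaminants.
#'
#' @param groups Character vector of group labels.
#' @param n_samples_per_group Samples per group.
#' @param n_otus Total OTUs, including indicators and daughters.
#' @param indicator_map Named list: OTU id -> character vector of groups it
#'   indicates (a non-empty subset of `groups`). Ids must be of the form
#'   `OTU_xxxx` within `1..n_otus`.
#' @param n_daughter_errors Number of planted erroneous daughter OTUs.
#' @param n_contaminants Number of OTUs that also contaminate the controls.
#' @param n_controls Number of control samples.
#' @param read_depth_range Length-2 range of per-sample total reads.
#' @param daughter_ratio Expected daughter/parent abundance ratio.
#' @param decoy_matches Number of below-threshold match-list records and of
#'   high-identity records between non-co-occurring indicator OTUs (both added
#'   as curation decoys).
#' @param group_effect_sd Standard deviation (log scale) of per-group,
#'   per-OTU multiplicative abundance effects; emulates the latitudinal
#'   turnover in available food biota between regions. `0` gives one shared
#'   profile.
#' @param concentration Dirichlet concentration scaling; larger = less
#'   compositional overdispersion between samples.
#' @param seed Integer seed.
#' @return An `otu_sim_spec` list.
#' @export
otu_sim_spec <- function(groups = c("tropical", "transition", "temperate"),
                         n_samples_per_group = 8, n_otus = 200,
                         indicator_map = NULL, n_daughter_errors = 10,
                         n_contaminants = 3, n_controls = 2,
                         read_depth_range = c(35000, 45000),
                         daughter_ratio = 0.1, decoy_matches = 5,
                         group_effect_sd = 0.75, concentration = 500,
                         seed = 1) {
  if (n_daughter_errors > n_otus) {
    abort("`n_daughter_errors` cannot exceed `n_otus`")
  }
  if (!is.null(indicator_map)) {
    bad <- vapply(indicator_map, function(gs) {
      length(gs) == 0 || !all(gs %in% groups)
    }, logical(1))
    if (any(bad)) abort("every indicator OTU must map to a non-empty subset of `groups`")
  }
  structure(
    list(groups = groups,
         n_samples_per_group = as.integer(n_samples_per_group),
         n_otus = as.integer(n_otus), indicator_map = indicator_map,
         n_daughter_errors = as.integer(n_daughter_errors),
         n_contaminants = as.integer(n_contaminants),
         n_controls = as.integer(n_controls),
         read_depth_range = read_depth_range,
         daughter_ratio = daughter_ratio,
         decoy_matches = as.integer(decoy_matches),
         group_effect_sd = group_effect_sd,
         concentration = concentration,
         seed = as.integer(seed)),
    class = "otu_sim_spec"
  )
}

#' Study-scale OTU simulation spec
#'
#' An [otu_sim_spec()] preset at the scale of the curated rabbitfish diet
#' table: 1,337 raw OTUs of which 602 are planted erroneous daughters (so
#' curation retains 735), 17 control contaminants (so the control filter
#' retains 718), three climate regions of ten stomach-content samples, two
#' extraction/PCR controls, and raw depths that support the 30,000-read
#' normalisation.
#'
#' @param seed Integer seed.
#' @return An `otu_sim_spec`.
#' @export
otu_study_spec <- function(seed = 1) {
  otu_sim_spec(
    groups = c("tropical", "transition", "temperate"),
    n_samples_per_group = 10, n_otus = 1337, n_daughter_errors = 602,
    n_contaminants = 17, n_controls = 2,
    read_depth_range = c(35000, 45000), seed = seed
  )
}

#' Simulate an OTU read-count table with planted ground truth
#'
#' Baseline OTUs get a shared log-normal abundance profile; per-sample
#' compositions are drawn Dirichlet-multinomial around the group profile.
#' Indicator OTUs are restricted to their group combination with a boosted
#' share of reads. Daughter error OTUs are carved out of their parent's reads
#' (binomially, capped at parent - 1, so a daughter is strictly rarer than its
#' parent wherever it occurs and never occurs without it). Contaminant OTUs
#' receive reads (at least 2) in every control sample; with no contaminants
#' configured the controls are all-zero.
#'
#' @param spec An [otu_sim_spec()].
#' @return An [otu_count_table()]; the `truth` attribute lists daughter ->
#'   parent assignments, contaminant ids and the indicator map.
#' @export
simulate_otu_table <- function(spec) {
  stopifnot(inherits(spec, "otu_sim_spec"))
  with_seed(split_seed(spec$seed, "otus"), {
    G <- length(spec$groups)
    n_samp <- G * spec$n_samples_per_group
    otus <- sprintf("OTU_%04d", seq_len(spec$n_otus))
    n_d <- spec$n_daughter_errors
    daughters <- if (n_d > 0) tail(otus, n_d) else character()
    body <- setdiff(otus, daughters)
    # parents: the most abundant body OTUs (assigned below after profile draw)
    base <- rlnorm(length(body), meanlog = 0, sdlog = 2)
    names(base) <- body
    indicator_map <- spec$indicator_map
    if (is.null(indicator_map) && G >= 2) {
      # default: one exclusive indicator per group, if room allows
      free <- setdiff(body, names(base)[rank(-base) <= n_d])
      ids <- head(free, G)
      indicator_map <- setNames(lapply(spec$groups, identity), ids)
    }
    ind_ids <- names(indicator_map)
    parents <- setdiff(names(sort(base, decreasing = TRUE)), ind_ids)
    parents <- head(parents, max(1L, ceiling(n_d / 4)))
    base[parents] <- quantile(base, 0.97) * 4   # abundant, safe parents
    groups_vec <- rep(spec$groups, each = spec$n_samples_per_group)
    # per-group multiplicative profile effects (region-specific biota)
    geff <- matrix(rlnorm(length(body) * G, 0, spec$group_effect_sd),
                   nrow = length(body),
                   dimnames = list(body, spec$groups))
    # error parents stay ubiquitous and abundant in every region, so that
    # planted daughters keep their co-occurrence and abundance-ratio contract
    geff[parents, ] <- 1
    counts <- matrix(0L, nrow = spec$n_otus, ncol = n_samp,
                     dimnames = list(otus, sprintf("sample_%03d",
                                                   seq_len(n_samp))))
    for (s in seq_len(n_samp)) {
      w <- base * geff[, groups_vec[s]]
      w[ind_ids] <- 0
      present <- ind_ids[vapply(indicator_map,
                                function(gs) groups_vec[s] %in% gs,
                                logical(1))]
      # indicators take a boosted share (~2% of reads each) in their groups
      w[present] <- sum(w) * 0.02 / max(1, length(present)) * length(present)
      alpha <- w / sum(w) * spec$concentration
      pvec <- rgamma(length(alpha), shape = alpha)
      pvec <- pvec / sum(pvec)
      depth <- round(runif(1, spec$read_depth_range[1],
                           spec$read_depth_range[2]))
      counts[body, s] <- rmultinom(1, depth, pvec)
    }
    # daughters carved from parents
    parent_of <- character()
    if (n_d > 0) {
      parent_assign <- rep(parents, length.out = n_d)
      for (k in seq_len(n_d)) {
        p <- parent_assign[k]
        pc <- counts[p, ]
        dc <- rbinom(n_samp, pc, spec$daughter_ratio)
        dc <- pmin(dc, pmax(pc - 1L, 0L))
        counts[daughters[k], ] <- dc
      }
      parent_of <- setNames(parent_assign, daughters)
    }
    # controls
    ctrl_counts <- matrix(0L, nrow = spec$n_otus, ncol = spec$n_controls,
                          dimnames = list(otus,
                                          sprintf("control_%02d",
                                                  seq_len(spec$n_controls))))
    contaminants <- character()
    if (spec$n_contaminants > 0 && spec$n_controls > 0) {
      contaminants <- head(setdiff(body, c(ind_ids, parents)),
                           spec$n_contaminants)
      for (cid in contaminants) {
        ctrl_counts[cid, ] <- 2L + rpois(spec$n_controls, 5)
      }
    }
    all_counts <- cbind(counts, ctrl_counts)
    # match list: true parent-daughter pairs + decoys
    ml <- tibble(otu_a = character(), otu_b = character(),
                 identity = numeric())
    if (n_d > 0) {
      ml <- bind_rows(ml, tibble(otu_a = names(parent_of),
                                 otu_b = unname(parent_of),
                                 identity = runif(n_d, 92, 99.5)))
    }
    if (spec$decoy_matches > 0) {
      pool <- setdiff(body, c(ind_ids, parents, contaminants))
      lowsim <- tibble(
        otu_a = sample(pool, spec$decoy_matches),
        otu_b = sample(setdiff(pool, character()), spec$decoy_matches),
        identity = runif(spec$decoy_matches, 60, 80)
      )
      ml <- bind_rows(ml, lowsim[lowsim$otu_a != lowsim$otu_b, ])
      # high-identity records between mutually exclusive indicators
      if (length(ind_ids) >= 2) {
        disjoint <- utils::combn(ind_ids, 2, simplify = FALSE)
        disjoint <- Filter(function(pr) {
          length(intersect(indicator_map[[pr[1]]],
                           indicator_map[[pr[2]]])) == 0
        }, disjoint)
        if (length(disjoint) > 0) {
          dd <- head(disjoint, spec$decoy_matches)
          ml <- bind_rows(ml, tibble(
            otu_a = vapply(dd, `[`, "", 1),
            otu_b = vapply(dd, `[`, "", 2),
            identity = runif(length(dd), 90, 99)
          ))
        }
      }
    }
    t <- otu_count_table(
      all_counts,
      groups = c(groups_vec, rep(NA_character_, spec$n_controls)),
      controls = c(rep(FALSE, n_samp), rep(TRUE, spec$n_controls)),
      match_list = ml
    )
    attr(t, "truth") <- list(
      daughters = parent_of,
      contaminants = contaminants,
      indicator_map = indicator_map,
      groups = groups_vec
    )
    t
  })
}
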