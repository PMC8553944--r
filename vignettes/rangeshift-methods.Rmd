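---
title: "Methods: connectivity, diet and thermal-threshold projection for a range-shifting reef fish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity, diet and thermal-threshold projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rangeshift` re-implements, as tested and reusable components, the three
analysis arms used to study poleward range extension in a tropical
herbivorous reef fish (the black rabbitfish, *Siganus fuscescens*, along
Western Australia): SNP-based population connectivity, dietary
DNA-metabarcoding curation with community statistics, and delta-change
projection of thermal-threshold isotherms from multi-model sea-surface
temperature (SST) ensembles. A synthetic-data module generates all three
input types with known ground truth, so every stage carries
parameter-recovery and calibration tests that run at desk scale.

This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic generators do and do not emulate.

## Synthetic data generators

**Genotypes.** Two mutually exclusive modes set population structure.
In *Balding–Nichols* mode, ancestral allele frequencies are drawn
`Uniform(0.05, 0.95)` and per-population frequencies from
`Beta(p(1-F)/F, (1-p)(1-F)/F)`, whose among-population variance gives an
expected multilocus fixation index equal to the target `F`. This
construction is analytically checkable: the recovery tests demand the
Weir–Cockerham estimate track `F` across `{0.01, 0.05, 0.10, 0.20}`
(2 populations x 50 individuals x 2,000 loci, 20 replicate seeds, +/-0.02).
In *migration* mode, frequencies evolve under a finite-island
drift–migration recursion — deterministic mixing by the per-ordered-pair
emigration weights followed by binomial resampling of `2 Ne` allele copies —
for 100 non-overlapping generations (configurable). `effective_size` (Ne) is
deliberately separate from the sample size: marine fishes have effective
sizes far larger than any sample, and the ratio of drift signal to sampling
noise in downstream tests depends directly on it. Genotypes are
Hardy–Weinberg draws within populations; missingness is independent per
call; mean locus depth is log-normal inside `coverage_range`. All draws
descend from one global seed through labelled sub-streams, so every output
is bit-reproducible given `(spec, seed)`.

**OTU tables.** Baseline taxa share a log-normal abundance profile
(`sdlog = 2`, so a realistic long tail of rare food items), modulated by
per-region multiplicative effects (`group_effect_sd`, default 0.75 on the
log scale) that emulate latitudinal turnover in available biota. Per-sample
compositions are Dirichlet-multinomial around the group profile
(`concentration = 500`). Three plantings create ground truth: *indicators*
are restricted to their group combination with a boosted (~2%) read share,
so their IndVal is 1 by construction; *daughter errors* are carved
binomially out of an abundant parent's counts (ratio 0.1, capped at
parent − 1), so a daughter co-occurs with, and is strictly rarer than, its
parent wherever it occurs; *contaminants* receive at least two reads in
every control sample. Error parents are exempt from group effects — they
represent ubiquitous abundant taxa — which keeps the parent/daughter
abundance-ratio contract intact after rarefaction. The match list contains
the true parent–daughter pairs at 92–99.5% identity, below-threshold decoy
pairs, and high-identity pairs between mutually exclusive indicators (which
a correct curation must never merge, because they never co-occur).
`otu_study_spec()` presets the study scale: 1,337 OTUs of which 602 are
daughters and 17 contaminate the controls, three regions of ten stomach
samples, two controls, raw depths 35–45k reads.

**SST fields.** Monthly temperature is a meridional plane
(`monthly_mean − gradient * |lat − lat_ref|`) plus a sinusoidal seasonal
cycle, a static per-model bias, a linear scenario trend (degC per decade,
from the first simulated year), Gaussian noise, and optionally a localized
heatwave pulse in one season of one year. The closed forms make every
climate operation exactly testable: the minimum monthly mean (MiMM) of a
noise-free sinusoid is the mean minus the amplitude, the isotherm shift for
a uniform warming `dT` is `dT / gradient`, and an additive pulse reappears
unchanged in the seasonal anomaly.

What the generators do **not** emulate: linkage and demographic history in
the genotypes (loci are exchangeable and independent), sequence-level error
processes (chimeras, index hopping beyond simple contaminant reads) in the
OTU tables, and ocean dynamics, ENSO-style variability or spatially
correlated model error in the SST fields. Passing tests therefore show the
*statistical machinery* is correct and calibrated under these idealized
conditions — not that any particular field data set will satisfy the same
assumptions.

## Genotype quality control

The cascade order is fixed and logged in the object's provenance: locus
filters, then monomorphic/individual filters, then Hardy–Weinberg and
linkage filters, then the outlier scan. Inside `filter_loci()` the
criteria apply in the order call rate (>= 0.95), mean locus depth
(20–200x; coverage is read as mean locus depth), observed heterozygosity
(<= 0.75), and minor-allele frequency, with per-criterion removal counts so
alternative orders can be audited. The MAF rule removes loci *below* 0.05;
a locus at exactly 0.05 is retained. `filter_individuals_monomorphic()`
iterates to a fixed point because removing an individual can fix a locus.

The Hardy–Weinberg test is the exact conditional (Levene/Haldane) test,
classic two-sided by probability ordering without mid-p, Bonferroni-
corrected within population; a locus must violate in at least `min_pops = 2`
populations to be removed. Linkage uses the composite genotypic correlation
`r^2` between 0/1/2 vectors with the chi-square approximation
`n r^2 ~ chisq(1)`, Bonferroni within population across pairs; a pair must
have `r^2 >= 0.8` and be significant in at least two populations, and the
removed member is the one with lower call rate (ties: lower MAF, then the
lexicographically larger id). Both tests are choices the package documents
rather than inherits: the original analyses cite dartR defaults without
specifying the tests, so counts on real data may differ legitimately.

`outflank_scan()` fits the neutral Fst distribution as a scaled chi-square.
Per-locus Fst enters without the finite-sample correction; loci with
expected heterozygosity below `min_het = 0.1` are excluded from the fit
(the scan's published default; the threshold is exposed because the source
analyses quote "0.1%" in one place and 0.1 in another). After trimming 5%
from each tail, both the effective degrees of freedom *and* the scale are
estimated by maximum likelihood on the truncated sample. Estimating the
scale jointly (rather than pinning the mean to the trimmed average) keeps
the df estimate consistent under truncation; the suite checks df recovery
within 10% on directly simulated scaled chi-squares. Right-tail p-values
from the fitted null become q-values by Benjamini–Hochberg; outliers are
loci with `q < 0.05` on the right tail. Power in the acceptance suite uses
20 demes x 25 individuals: with `r` demes the null has roughly `r - 1`
degrees of freedom, and a 5x variance inflation is only comfortably
detectable (per-locus detection ~0.95) once the null df reaches ~19 — a
design sized analytically before running the tests, not tuned to them.

## Differentiation, diversity and isolation by distance

`pairwise_fst()` uses the Weir–Cockerham (1984) variance components with
the multilocus estimate as the ratio of summed components; missing data are
handled pairwise-complete per locus. Confidence intervals bootstrap loci;
the p-value is the bootstrap probability that Fst <= 0; adjustment across
pairs is Benjamini–Yekutieli by default. `pairwise_gst_jostd()` computes
Nei's `Gst = (Ht - Hs)/Ht` and Jost's `D = (Ht - Hs)/(1 - Hs) * 2` per
locus (two demes) and averages over loci. A brute-force variance-component
oracle written independently in the test suite must agree with the
implementation to 1e-12 on random tables.

`diversity_stats()` reports expected and observed heterozygosity plus
allelic richness rarefied by the exact hypergeometric formula to the
smallest per-locus allele count across sites (deterministic, unlike
resampling rarefaction). Interval estimates resample individuals within
sites; because a with-replacement resample biases heterozygosity down by
~1/n, the intervals are centred on the plug-in estimate using bootstrap
deviations from their own mean.

`shift_nonnegative()` adds a constant so the minimum pairwise estimate is
zero — a presentation-only transform for circular plots, recorded on the
object and never fed back into inference. `mantel_ibd()` linearises
differentiation as `Fst/(1 - Fst)` (pairs at exactly 1 are excluded with a
warning), correlates it with an ocean-distance matrix per depth layer
(Pearson by default; the distances are consumed, not computed), and takes
its permutation p-value from `vegan::mantel()`.

## Directional relative migration

For each ordered pair of sites, a hypothetical pool is the equal-weight
mean of the two allele-frequency vectors; the differentiation of each
member from that pool (multilocus Gst, or its `Nm = (1-s)/(4s)` transform,
or Jost's D) is converted to a relative migration *into* that member —
a site that resembles the migrant pool receives much gene flow. All rates
are divided by the global maximum, so the largest is 1; negative
directional estimates truncate to zero. Rates are stored and plotted with
rows as receiving and columns as source populations. Gst and Nm bases are
monotone transforms of one another and must give identical rank orders;
Jost's D also depends on within-pool heterozygosity, and in high-gene-flow
source–sink systems the sink's elevated heterozygosity can reorder or even
reverse D-based directionality — the package documents this rather than
hiding it, and the directional power tests use the Gst basis (as did the
original analyses).

`asymmetry_test()` bootstraps individuals within sites, recomputes the
normalised network, and flags an ordered pair when the bias-corrected
percentile interval of `m[i->j] - m[j->i]` excludes zero. The bias
correction matters: normalisation makes the bootstrap distribution of a
difference asymmetric around the observed value and the plain percentile
interval under-covers by a few points. Calibration is checked under a
high-connectivity symmetric island model (3 demes, symmetric per-pair
migration 0.25, Ne = 1000) emulating the weakly differentiated study
system: there the realized drift asymmetry is negligible next to sampling
noise and the false-positive rate must stay within two binomial standard
errors of the nominal 5%. Detection power uses a strongly asymmetric
source–sink (10x emigration contrast, Ne = 100), where drift lets the
source stay distinct while immigration homogenises the sink.

## Diet curation and community statistics

Curation order is fixed and logged: depth normalisation, then LULU-style
curation, then control-based removal, then the minimum-read filter.
`normalize_depth()` subsamples each non-control sample without replacement
to exactly 30,000 reads (one multivariate-hypergeometric draw per seed;
averaging over draws is deliberately not the default, matching common
practice) and drops shallower samples with a warning. `lulu_curate()`
visits candidate daughters from rarest upward and merges a daughter into
the most abundant parent that passes all three published-default gates:
percent identity >= 84, relative co-occurrence >= 0.95 (fraction of the
daughter's occupied samples that also hold the parent), and a minimum
per-sample parent/daughter ratio >= 1. Merging from the bottom up collapses
parent–daughter chains. `remove_control_otus()` removes any OTU with at
least two reads in any single control and then drops the controls;
`min_read_filter()` removes OTUs with fewer than ten reads in total.

`bray_curtis()` works on per-sample relative abundances through
`vegan::vegdist`; `nmds_ordinate()` wraps `vegan::metaMDS` (Kruskal
stress-1, monotone regression, random restarts, deterministic given the
seed). PERMANOVA is implemented directly from the squared-dissimilarity
decomposition (`SS_total = sum d^2 / n` and within-group analogues), with
free permutation of sample labels; it matches `vegan::adonis2` to 1e-10 on
the same inputs, and the in-package implementation keeps the 2,000-dataset
type-I calibration inside the test-time budget. PERMDISP embeds the
distance matrix by principal coordinates (negative eigenvalues enter the
squared distances with negative sign, floored at zero), measures distances
to the group's spatial median (Weiszfeld iteration; centroid optional), and
offers two permutation schemes: shuffling the observed distances (the
classic PERMDISP2 scheme, matching `vegan::permutest.betadisper`, robust to
location differences but measurably conservative at small group sizes
because centre estimation shrinks within-group distances) and shuffling raw
samples with centres recomputed (exact under exchangeability). The
calibration test uses the sample-permutation scheme with centroids, where
the nominal 5% level is attained exactly; the default remains the classic
scheme for comparability with the field's software.

`indval()` scores every OTU against every non-empty group combination with
the group-size-corrected statistic (`IndVal.g`): specificity is the
combination's summed group-mean abundance over all group means, fidelity
the occurrence fraction within the combination, and the statistic their
root product. Each OTU's p-value permutes group labels against its best
combination and is Benjamini–Hochberg adjusted across OTUs; the all-groups
combination is scored but carries no p-value (it is permutation-invariant).

## Climate projection

`climatology()` computes annual means and the MiMM (minimum over calendar
months of the across-years monthly mean); MiMM <= annual mean holds
cell-wise by construction and is asserted on every input.
`delta_change_project()` adds a model's anomaly (per-year metric minus its
own base-window climatology, base 2008–2017) to the observed climatology:
any static model bias cancels exactly, to machine precision, and the
corrected base-window average equals the observed climatology. Grids must
already be aligned; the package treats regridding as an upstream step and
errors on mismatch. `ensemble_mean()` averages member anomalies cell-wise
and keeps the min–max member envelope for range shading.

`isotherm_latitude()` extracts, per longitude column, the poleward-most
threshold crossing of the decadal-mean field by linear interpolation
between adjacent grid latitudes (1-D column crossings rather than 2-D
contour tracing — this matches the "latitude of the 17/20 degC isotherm"
presentation and is exactly testable). With multiple crossings the
poleward-most is taken and the occurrence logged; decades are calendar
decades and the decadal range spans the yearly contours within the decade
(an ensemble-member envelope is available instead). Contours are extracted
from the ensemble-mean field ("ensemble-mean first"); extracting per member
and averaging is available through the member series when the alternative
order is wanted. `heatwave_anomaly()` subtracts the baseline mean of the
event season (JFM by default, baseline 1980–2015) from the event season
itself, identically for SST and any near-surface current components.

The acceptance-scale climate check runs 11 pseudo-models over 1900–2099 at
monthly, 1-degree resolution (46 x 7 cells) with trends 0.2 and 0.4 degC
per decade: the projected 2090s contour displacement must equal
`trend x elapsed decades / gradient` within one grid step, for both the
20 degC annual-mean and 17 degC MiMM thresholds.

## Numerical choices and degenerate inputs

Permutation and bootstrap p-values respect the `1/(n+1)` floor. Pairs with
fewer than two shared polymorphic loci are flagged unreliable rather than
silently reported. An all-equal per-locus Fst distribution, an empty
post-filter locus set, all-dropped individuals, and a rarefaction depth
above every sample are all explicit errors; a grid that never crosses a
requested isotherm warns and flags rather than failing. Seeds split into
labelled sub-streams (`split_seed`) so that stages draw independent,
reproducible randomness from one user-facing seed.

Problem sizes in the test suite (2,000 loci and 20 seeds for recovery
checks; 2,000 null data sets of 20 samples with 999 permutations for the
PERMANOVA/PERMDISP calibration; 1,000 bootstrap replicates for asymmetry
intervals; 50 random tables for curation) are the package's chosen balance
between Monte-Carlo precision and a test suite that completes in minutes.

## Limitations

Counts obtained on the originally deposited data may differ from the
filter-cascade counts on synthetic data for legitimate reasons: the exact
HWE/LD tests of the original toolchain are unstated, and "coverage" is read
here as mean locus depth. The D-basis directional-migration caveat above
applies to any divMigrate-style analysis, not only this implementation.
SST input/output uses long-format CSV with CF-style column conventions;
gridded binary formats are out of scope. Admixture inference, DAPC, OTU
clustering, taxonomy assignment and ocean-distance computation are
upstream of this package by design.
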