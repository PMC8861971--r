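---
title: "Methods: longitudinal multi-omic and spatial analysis of a single tumor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal multi-omic and spatial analysis of a single tumor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nof1omics)
library(dplyr)
```

`nof1omics` implements the analytical core of an N-of-1 longitudinal tumor
study: a single patient is followed through serial biopsies and blood draws,
and each assay platform — deep error-corrected plasma sequencing, whole-exome
variant tables, transcriptomes, protein arrays, and multiplexed imaging —
needs its own bespoke statistics. This vignette explains each procedure, its
assumptions, the tunable parameters, and the design decisions taken where the
methods literature leaves choices open. Every empirical claim below is also a
test in the package's suite; the problem sizes quoted are the ones the tests
and the acceptance script actually run.

## 1. ctDNA panel design and error-corrected detection

### Panel design

A patient-specific circulating tumor DNA (ctDNA) panel starts from somatic
SNVs observed in tumor tissue. `select_bait_sites()` applies the standard
design filters — tumor VAF > 5%, matched-normal VAF < 2%, tumor depth > 30x,
normal depth > 15x, all strict — and `filter_panel()` then removes baits that
failed wet-lab QC and any site whose VAF in unrelated negative-control plasma
exceeds 1% (such sites are too noisy to support sub-0.1% detection).
`demo_bait_panel()` reproduces the canonical accounting: 55 designed baits,
two discarded for inconsistent coverage, 53 monitored sites.

### UMI consensus error correction

Raw sequencing error (~10^-3 per base) would swamp ctDNA signals at 10^-4
VAF. Reads sharing a unique molecular identifier (UMI) are presumed copies of
one original molecule, so `collapse_family()` collapses each family to a
consensus: families with fewer than 3 reads are discarded, and a position
emits the modal base only when at least 90% of non-N reads agree (otherwise
`N`). Both thresholds are arguments; the 90% boundary is inclusive, and `N`
inputs count toward neither side of the agreement ratio — conventions the
upstream literature leaves unstated. `mask_read_ends()` then masks 3 bases at
each end of the consensus (end-of-fragment artifacts), and
`merge_mate_overlap()` collapses mate-pair overlap so a molecule is never
counted twice; overlap disagreements become `N`, the conservative choice
consistent with duplex-style error suppression.

With a per-read error rate of 10^-3 and size-5 families, a consensus error
requires near-unanimous agreement on the same wrong base, so the residual
rate is far below 10^-4. The suite verifies this end to end: 5000 simulated
families at true VAF 0 yield a post-pipeline mutant rate under 10^-4
(typically 0).

### The beta-overlap detection statistic

A site tally (`tally_site()`) gives mutant reads *k* and total reads *n*.
Detection compares the sample's VAF against pooled negative controls using
the Weitzman overlapping coefficient of two Beta densities,

$$p = \int_0^1 \min\{f_1(x),\, f_0(x)\}\,dx,
\qquad f_i = \mathrm{Beta}(k_i + 1,\; n_i - k_i + 1),$$

i.e. the shared probability mass of the two VAF posteriors under a flat
Beta(1, 1) prior. The coefficient is 1 exactly when the count data coincide
and decays monotonically as the VAFs separate; it is used directly as the
p-value, with *p* > 0.05 read as "not distinguishable from the controls" and
detection declared at *p* <= 0.05 (the boundary is included, since only the
non-detection side of the rule is conventionally stated). The flat prior is a
choice: the source methods name only "the beta distributions", and a
Jeffreys-prior variant would change third-decimal behaviour at panel depths.

Numerically, the integrand's pieces are resolved analytically: the
log-density difference $g(x) = C + \alpha\log x + \beta\log(1-x)$ has at most
one interior stationary point, hence at most two roots, which are bracketed
and solved by `uniroot`; the overlap is then a sum of exact `pbeta`
increments of whichever density is smaller on each piece. This is accurate to
~10^-8 (verified against a 2x10^5-point Riemann oracle on 100 random count
pairs) and, unlike blind quadrature, cannot miss the sharp density peaks that
arise at the 10^4–10^5x depths of error-corrected panels.

`aggregate_group()` pools counts over a mutational group of sites (for
example, mutations shared by several biopsies) before computing a group-level
p-value. Pooling counts rather than combining per-site p-values is a
deliberate choice: it weights sites by depth and matches the per-group VAF
definition.

## 2. Cross-biopsy variant classification and phylogeny

`filter_variants()` keeps observations with VAF >= 5% and depth >= 30 ("lower
than" removal, so the boundaries stay). `classify_across_samples()` assigns
each (variant, sample) pair an evidence state — `called` by the somatic
caller, `supported` when >= 2 reads carry the allele without a call, `absent`
otherwise — and each variant a category: **ubiquitous** (called in all
samples), **shared** (called in >= 2), **private** (called in exactly one).
Category assignment counts called evidence only; the supported state is
annotation (whether read-level support should promote a variant to "present"
is genuinely ambiguous, so `count_supported = TRUE` exposes the other
convention). Variants called nowhere are excluded with a warning.

`binary_matrix()` turns the classification into a samples-by-variants 0/1
table, `pairwise_gene_distance()` counts differing columns per sample pair
(the pairwise Hamming distance; cross-checked against `ape::dist.gene` in the
tests), and `minimum_evolution_tree()` reconstructs the phylogeny under the
minimum-evolution criterion with ordinary least-squares branch lengths.

Rather than a neighbour-joining or NNI heuristic, the search **enumerates
every unrooted binary topology** — 15 at 5 taxa, 10,395 at 8 — fits branch
lengths by OLS of leaf-to-leaf path lengths against the observed distances,
and keeps the topology with the smallest total length (negative OLS estimates
clamped to zero for the length criterion; raw values are retained in the
result). With the 5–7 leaves of a serial-biopsy study this is exact and fast,
guarantees the ME optimum, and serves as its own optimality oracle; above 8
taxa the function refuses and directs the user to a heuristic implementation.
Ties are broken deterministically by canonical Newick string (children sorted
by smallest descendant label). On additive inputs the generating topology is
recovered with zero residuals (100/100 seeded 5-taxon trials; max path-length
error < 10^-9), and on noisy inputs the search agrees with `ape::fastme.ols`.
Trees round-trip through `ape` Newick I/O with full-precision branch lengths.

Tumor mutational burden is the nonsynonymous mutation count divided by the
targeted megabases (`tmb()`), and neoepitope utilities filter peptide tables
to best-allele binding affinity strictly below 500 nM
(`filter_neoepitopes()`) and intersect presence across samples
(`shared_neoepitopes()`); affinity prediction itself is upstream input.

## 3. Regulon-based transcriptional regulator activity

The activity of a transcriptional regulator is inferred from the behaviour of
its **regulon** — the signed set of genes whose expression it controls —
within a rank-sorted expression signature.

*Network.* `build_regulon_network()` restricts a SIF interaction table to
`controls-expression-of` edges whose regulator and target are both expressed,
and (by default) composes secondary two-step paths into direct edges with the
product of the signs, depth capped at 2. Direct edges win sign conflicts.

*Edge weights.* `assign_edge_weights()` scores each regulator-target pair
from the cohort: Spearman's rho (monotone association, carries the sign) and
the F statistic of the univariate regression of target on regulator (linear
dependency), combined as w = rho * (1 - p_F). The combiner is a documented
choice — monotone in both evidence sources and sign-preserving — since only
the two ingredients are conventionally stated. Degenerate (constant) pairs
get weight 0.

*Signature.* `compute_signature()` scores each gene as the query sample's
expression minus the cohort median, ranked descending.

*Components.* Three complementary enrichment readings are computed per
regulator:

- **Local delta concordance** (`local_delta_concordance()`): within the
  regulon, the Spearman correlation between |weight| ranks and directional
  signature ranks (positive-edge targets ranked ascending by score,
  negative-edge targets descending), computed per edge-sign group and
  averaged over the groups that exist — a regulator whose strong edges shift
  furthest scores +1, and a one-sign regulon still contributes through its
  single group.
- **Local enrichment** (`local_enrichment()`): the directional separation of
  the two sign groups inside the regulon-restricted ranking. Each target's
  position is quantile-transformed against the complementary sign group (for
  a positive target, the fraction of negative targets below it; for a
  negative target, the fraction of positive targets above it), quantiles are
  repeated in proportion to |weight| in 10 bins, and the component is
  2·(median − 0.5). This formulation reaches exactly +1 at perfect
  directional separation and −1 at perfect inversion *regardless of the
  regulon's sign balance* — a pooled within-regulon quantile cannot, because
  positives at the top force negatives of the same list to the bottom — while
  keeping the stated median-of-weighted-quantiles form. One-sign regulons
  have no within-regulon contrast and return `NA`, which simply drops the
  component from integration.
- **Global enrichment** (`global_enrichment()`): the regulon projected onto
  the global ranking of all genes. Scores are winsorized at 3 MAD around the
  median (the "robust" transform; otherwise unspecified), ranked, and
  quantile-transformed as rank/(m+1); negative-edge targets read the reversed
  ranking; the component is 2·(median quantile − 0.5). No weight integration
  here — the statistic is defined as a plain median of robust quantile ranks.

*Integration.* `integrate_scores()` standardizes each component across
regulators by median/MAD (zero-MAD components standardize to 0) and averages
the available standardized components; `activity_delta()` compares two
timepoints by difference and ratio of integrated scores, reporting both since
either convention appears in practice.

*Calibration and recovery.* All three components are permutation-calibrated:
under pure-noise expression their means over 200 seeded cohorts stay within
±0.05 of zero. A planted active regulator (50 regulators x 20 targets each,
effect 3 x noise SD, n = 30 samples) is recovered as the top-ranked regulator
in >= 95 of 100 seeded trials. Two fixture notes matter for interpreting
that number. First, the generator also elevates the active regulator's *own*
expression in the perturbed samples — a regulator drives its targets by being
overexpressed or activated, and without this the estimated edge weights are
provably pure noise. Second, because the fixture shifts every target by the
same amount, there is no weight-magnitude gradient for the concordance
component to detect, so that component contributes calibrated noise to the
integration in this scenario; recovery is carried by the two enrichment
components. The recovery rate therefore sits near its criterion (~96-99%
depending on the seed stream) rather than saturating at 100%.

*Invariance.* Rank-based components are invariant under affine transforms of
the expression matrix; they are not exactly invariant under arbitrary
nonlinear monotone transforms because the median-reference subtraction
precedes ranking, and the tests assert the affine property.

## 4. Proteomic and transcriptomic scores

- `pathway_score()`: sum of positively associated predictor proteins minus
  negatively associated ones, divided by the number of predictors used;
  missing predictors are excluded with a warning and the divisor reduced.
  `pathway_scores()` applies a predictor-definition table across a cohort.
- `cohort_zscore()`: per protein, (x − cohort median) / cohort SD; zero-SD
  features z-score to 0 and are flagged.
- `pam50_assign()`: the query sample is pooled with a background cohort
  (e.g. 20 ER+ and 20 ER− references), the combined matrix is mean-centred
  per gene once, and the centred query is Spearman-correlated to each
  intrinsic-subtype centroid; the argmax label is returned, ties broken by
  centroid column order, and an all-negative correlation profile is flagged
  rather than suppressed. Centring the combined matrix once (not per query)
  is the reading adopted for the ambiguous convention; the background is a
  required argument, not bundled data.
- `tmb()`, `filter_neoepitopes()`, `shared_neoepitopes()`: closed-form, see
  above.

## 5. Spatial single-cell statistics

*Normalization and gating.* `normalize_intensities()` rescales each marker
by its per-image maximum to [0, 1]; `gate_node()` /`apply_gating_tree()`
route every cell deterministically through a marker-threshold hierarchy
(cells exactly at a threshold take the >= branch), and
`composition_metrics()` reports per population the percentage of total
nucleated cells, the percentage of the parent gate population, and the
density per mm^2 — with counts and tissue areas from multiple ROIs summed
before any ratio is formed, so small ROIs cannot dominate. Gate thresholds
are user configuration; there is no auto-thresholding.

*Distance to matrix.* `distance_to_mask()` measures each nuclear centroid's
Euclidean distance (µm) to the nearest positive pixel of a binary
extracellular-matrix mask. Distances are to pixel centres, with sub-pixel
mask geometry ignored (error at most about a pixel); a centroid inside a
positive pixel reports 0. The implementation is chunk-vectorized and is
tested for exact agreement with an exhaustive per-pixel scan on 50 random
fixtures.

*Binned ANOVA.* `bin_and_test()` groups cells into half-open distance bins —
[0, 25), [25, 50), [50, 75) µm by default, cells beyond the last edge
excluded — and compares intensity distributions across bins with a one-way
ANOVA. Half-open bins resolve the unstated boundary convention (a cell at
exactly 25 µm falls in the second bin). P-values are Bonferroni-corrected
across all marker-by-stratum tests of the invocation — the correction family
is the call, since the original family is unstated — and flagged significant
below 0.001. Strata with fewer than two usable bins are reported untestable
rather than erroring.

*Calibration.* Under a null fixture (zero gradient) the unadjusted p-values
are uniform; over 1000 seeds the rejection rate at alpha = 0.05 stays within
[0.03, 0.07]. Under the planted gradient (5 intensity units per µm against
noise SD 50, 3000 cells) the adjusted p-value falls below 0.001 in >= 95 of
100 seeds.

## 6. Synthetic data: what it emulates, and what it does not

Every stage has a seeded generator so the whole pipeline is testable with no
data access:

- `clonal_tree()` / `simulate_clonal_biopsies()`: a clone carries all
  mutations on its root path; observed alternate counts are binomial at the
  stated depth around a true VAF of purity x 0.5 (heterozygous, diploid, no
  copy number — kept analytic on purpose). The caller emulation (called iff
  >= 3 alt reads and VAF >= 5%) mirrors the downstream filter and is
  configurable.
- `simulate_umi_reads()`: geometric family sizes (default mean 5), uniform
  per-base substitution errors. No indels, quality strings, or FASTQ
  emission — read-level realism is out of scope; the statistics under test
  depend only on family size and substitution rate.
- `sim_regulon_network()` / `simulate_regulator_expression()`: disjoint
  target blocks per regulator (so locality is testable), ~30% repressive
  edges, Gaussian noise, signed mean shifts in designated active samples
  (default: one perturbed query sample against a clean background cohort),
  plus the regulator self-shift discussed above.
- `simulate_spatial_tissue()`: a circular tumor nest (radius 80 µm) of
  uniformly placed cells, a collagen rim annulus (width 5 µm) rasterized at
  1 µm/pixel, and marker intensity = baseline − slope x distance + noise.
  Defaults (baseline 800, slope 5 /µm, noise SD 50, 3000 cells) give bin
  means a few hundred units apart over 75 µm, the scale seen for nuclear
  markers near collagen boundaries. The cell table carries the analytic
  distance to the rim, so large seed studies of the bin ANOVA need not
  recompute a distance transform; `distance_to_mask()` is validated against
  that truth and against the exhaustive oracle separately.

Passing tests on these fixtures demonstrate the statistical machinery —
calibration, power at stated effect sizes, exact recovery on clean inputs —
not robustness to alignment artifacts, copy-number-distorted VAFs, batch
effects, segmentation errors, or marker spillover, none of which the
generators emulate.

## 7. Numerical and degenerate-input conventions

- Beta overlap: crossing points to `uniroot` tolerance 10^-13, masses by
  `pbeta`; zero-depth samples are errors; identical counts short-circuit
  to 1.
- OLS branch lengths via `lm.fit` (QR); negatives clamped only for the
  length criterion and the exported tree; ties by canonical Newick order.
- All-N sites tally VAF 0 with a warning; empty parents report `NA`
  percentages; all-zero markers stay 0 and warn; constant predictors or
  features z-score to 0 and warn.
- Every generator accepts a `seed` and restores the caller's RNG state;
  identical seeds give byte-identical output (tested).

## 8. Known limitations

- The regulon component definitions are concrete renderings of prose
  descriptions; each sits behind its own function so alternatives can be
  swapped, and the permutation calibration is the contract they must keep.
- The exhaustive ME search is exact but factorial; it deliberately stops at
  8 taxa.
- Distance measurements inherit pixel quantization from the mask raster.
- The beta-overlap statistic assumes sites are independent when counts are
  pooled into groups; linked errors (e.g. strand bias) would need the
  upstream duplex chemistry the package does not model.

## Problem sizes used by the test suite

Seed studies run at: 100 seeds (ME recovery, regulon recovery, spatial
power), 200 seeds (regulon null calibration), 1000 seeds (spatial type-I
calibration), 5000 UMI families (error suppression), 100 random count pairs
(overlap oracle), 50 fixtures (distance oracle). These sizes make the suite's
statistical assertions stable while keeping a full run to a few minutes.
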