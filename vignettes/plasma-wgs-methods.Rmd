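---
title: "Methods: copy number, variant filtering and clonal evolution from plasma WGS"
author: "plasmaTrace authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy number, variant filtering and clonal evolution from plasma WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmaTrace)
```

# Scope

plasmaTrace implements the computational core of an unbiased plasma
whole-genome sequencing workflow for cell-free DNA (cfDNA): fragment-size
quality control, sparse-coverage copy number profiling by circular binary
segmentation (CBS), copy-number-alteration (CNA) calling and aneuploidy
classification, a post-caller somatic variant filter cascade,
purity/copy-number-normalized clonal deconvolution across serial plasma
timepoints, and the clinical statistics layer that accompanies such a
study. A synthetic-cohort simulator generates data with the statistical
structure the pipeline assumes, so every stage has ground-truth recovery
tests without patient data.

The package consumes caller and aligner *output* (binned read counts or
read positions, VCF variant tables with annotation columns, fragment-size
tables, clinical tables); alignment, variant calling and annotation
databases are out of scope.

# Fragment-size quality control

Archival plasma collected in EDTA/Ficoll media is contaminated by high
molecular weight DNA from white blood cells, so concentration and size
statistics are *gated* on fragments in the 100–700 bp range (inclusive at
both ends), after an upstream < 1000 bp size selection. A sample passes QC
when its gated mass is at least 2 ng (inclusive, matching the "at least
2 ng total" convention). Both bounds and the threshold are configurable
through `qc_config()`.

Nucleosome-protected cfDNA has a mononucleosomal mode near 167 bp or
below; tumor-derived fragments run shorter. `detect_peaks()` finds local
maxima of a 5 bp histogram whose *prominence* (height above the deepest
flanking valley within a ±10-bin window) exceeds 5% of the tallest bin,
and annotates secondary peaks within ±15 bp of twice and three times the
primary mode as di-/tri-nucleosome harmonics. No peak-calling procedure is
standard for electropherogram-like size data; the bin width, window and
prominence defaults are package choices, exposed as arguments. Histogram
bins are half-open (`[a, b)`) so integer-valued sizes do not pile up in an
edge bin.

# Copy number profiling

## Binning and normalization

Read starts are counted into a bin grid (0-based half-open intervals, BED
convention; mean width 220 kb by default, matching sparse ~0.1X coverage
at roughly a thousand reads per bin at higher depth, tens at 0.1X). The
package accepts a user-supplied variable-width grid; mappability-derived
bin construction is not re-derived here. Counts are normalized to
`ratio = count / mean(count)`, so the genome-wide mean ratio is exactly 1.
For the log transform, zero-count bins are floored at `1/(2·mean count)`
and flagged; the floor applies to the log scale only so the mean-1
invariant of the ratio scale is untouched. GC normalization is
deliberately omitted (no per-bin covariate model is assumed); a covariate
regression can be applied upstream of segmentation if desired.

## Circular binary segmentation

Segmentation is recursive changepoint detection per chromosome. For a
segment of $n$ bins with values $x_1..x_n$, every arc is a pair of cut
positions $0 \le i < j \le n$ and its statistic is the absolute
standardized mean difference between in-arc and out-of-arc bins,

$$T(i,j) = \left| \frac{S_j - S_i}{w} - \frac{S_n - S_j + S_i}{n-w} \right|
\Big/ \sqrt{\tfrac{1}{w} + \tfrac{1}{n-w}}, \qquad w = j - i,$$

computed with unit variance: any permutation-invariant scaling cancels
from the permutation p-value. The arc maximizing $|T|$ proposes up to two
changepoints; the split is accepted when its permutation p-value falls
below `alpha` (default 0.0001) and recursion continues on the parts.

The permutation test permutes bin labels within the segment (up to
`n_permutations = 10000`, driven by R's seeded RNG) with sequential early
stopping in both directions: the test stops early and *rejects* the split
once five exceedances put the running p-value clearly above `alpha`, and
after `tail_fit_n = 500` scans with no exceedance it resolves the p-value
below the $1/m$ permutation resolution with a Gumbel tail fitted to the
permutation maxima by moments. Maxima of many weakly dependent
standardized statistics are well approximated in the upper tail by a
Gumbel law, and at `alpha = 1e-4` a pure permutation accept would need
every one of the 10,000 scans for every accepted split — far more
computation for no change in planted-changepoint recovery. The
approximation only matters for splits near the `alpha` boundary; the
recovery suites (below) validate the end result.

After segmentation, changepoints are *undo-pruned*: a changepoint is
removed when undoing it (merging its two flanking segments) increases the
residual sum of squares by less than `undo_prune = 0.05` times the
profile's total within-segment sum of squares, iterating on the smallest
increase first. This reproduces the intent of prune-style undo without
bit-for-bit reproduction of any particular implementation; equivalence is
asserted at the level of planted-changepoint recovery.

`merge_levels()` then joins adjacent segments whose member-bin ratios are
statistically indistinguishable: the adjacent pair with the largest
Wilcoxon rank-sum p-value is merged while that p-value is at or above
`merge_p_threshold = 0.05` (a declared default — the upstream tool's
internal default is not published), recomputing means until a fixed
point. Merging never increases the segment count and is idempotent at the
fixed point.

Segmentation operates on the ratio scale by default and reports both
ratio and log2 values; a `space = "log2"` flag segments the log scale
instead (published descriptions are ambiguous between the two; ratio
space is the package default).

## Exome depth ratios

`exome_cn_ratio()` provides the simplified tumor/normal exome profile
used to assign copy number to mutation sites: per-target depths are
library-size normalized, ratioed, log2-transformed and median-centered.
Targets with zero normal depth are excluded and reported. The result is
segmentable by `cbs_segment()` on target order.

# CNA interpretation

The *copy-neutral state* is the median per-bin segmentation value
(midpoint convention for even counts). Any maximal run of consecutive
bins within one chromosome sharing a segmentation value that deviates
from neutral becomes one CNA; its length is last-bin end minus first-bin
start. The default deviation tolerance is `1e-9` — post-merge segment
values are treated as exact levels — and is configurable for noisy
inputs. CNA burden counts calls whose deviation is at least a baseline
(default 0.03, matching the aneuploidy deviation gate).

Aneuploidy classification follows a segment-count rule: a profile with
more than 45 segments and a deviation above 0.03 is aneuploid; one with
25–45 segments and deviation above 0.03 is aneuploid only with support
from a deviating segment spanning at least 10 Mb or a deviation of at
least 0.10; everything else is diploid. The deviation statistic is the
maximum absolute difference between a segment mean and the median
segmentation value. The 10 Mb and 0.10 support thresholds quantify
"large segment" and "high segmentation value", which are not printed
anywhere; both are explicit arguments of `ploidy_thresholds()`.

Plasma–tissue concordance uses the Pearson correlation of per-bin
segmentation values on a shared grid, and mutation concordance is
$100\,|A \cap B| / |A \cup B|$ over (chrom, pos, ref, alt) keys.

# Somatic variant filter cascade

The cascade consumes caller output and applies, in order:

1. **Caller status** — keep `PASS` (high confidence) and `germline_risk`
   (borderline somatic) calls.
2. **Plasma VAF** — remove variants with allele frequency strictly below
   0.07 (the boundary is retained).
3. **Matched normal** — below 100X normal coverage, remove variants with
   more than 2 normal alt reads; at or above 100X, remove variants with
   normal VAF above 0.01. Depth exactly 100 uses the VAF branch (the
   published wording covers "less than" and "greater than" but not
   equality; the assignment is declared and configurable).

Each rule depends only on the record's own fields, so the survivor set is
order-invariant; the staged order fixes which reason a doubly-failing
record is attributed to. Multi-allelic VCF records are decomposed into
per-allele records on reading. SNVs are single-base ref and alt; all
other variants, including equal-length multi-nucleotide substitutions,
fall into the indel bucket since only two classes are distinguished.
A mutation is flagged functionally significant iff SIFT < 0.05 and
POLYPHEN > 0.85 (both strict; missing scores never flag).

# Clonal evolution

## Cellular prevalence

A mutation's VAF is normalized for tumor purity $\rho$ and local total
copy number $c$ at multiplicity $m$:

$$\mathrm{CP} = \mathrm{VAF} \cdot
  \frac{\rho c + 2(1-\rho)}{\rho\, m}, \quad \text{clipped to } [0,1].$$

Multiplicity defaults to 1 (single-copy mutations; configurable per
site). Copy number per site comes from the covering segment, mapped to an
integer as `round(2 · seg_ratio / neutral)` and floored at 1; sites at
copy number 0 or with clipped prevalence are excluded from clustering and
reported. When no external purity estimate exists,
`estimate_purity_simple()` inverts the prevalence formula at full
prevalence: twice the 0.9 quantile of copy-neutral VAFs, capped at 1 —
a deliberately crude stand-in, flagged unusable below 0.05.

## Clustering

Mutations are clustered on their prevalence *trajectories* across
timepoints by a finite mixture with a binomial read-count likelihood:
cluster $k$ has a prevalence $\phi_{kt}$ per timepoint, mapped into VAF
space through purity and copy number, and each mutation's alt counts are
binomial at that VAF — so low-depth sites carry proportionally less
weight. The M-step is the weighted binomial MLE (exact when the
VAF-to-prevalence factor is shared across sites, the default CN 2 /
multiplicity 1 case; a quasi-likelihood moment update otherwise). The
number of clusters is chosen by BIC over $1..k_{max}$ (default cap 8,
the upper end of the plausible subclone range) with 20 seeded restarts
(k-means initialization plus random draws).

## Tree search

Rooted trees over the clusters are enumerated exhaustively (an implicit
root of prevalence at most 1 sits above the founders; $(K{+}1)^{K-1}$
trees, bounded at $K \le 6$ by default — above that an explicit
unsupported-size error is raised). For each tree, cluster prevalences are
projected per timepoint onto the feasible set where each parent's
prevalence is at least the sum of its children's: writing clone
frequencies $f \ge 0$ and the subtree indicator $B$, prevalences are
$B f$, so the projection is non-negative least squares (Lawson–Hanson,
in-package), with the total-frequency $\le 1$ bound enforced by a
weighted slack row (weight $10^4$) plus an exact rescale. The tree with
the smallest squared projection error (data rows only) wins; ties within
a $10^{-7}$ relative band are broken toward fewer total edges from the
root, then lexical parent order. Noiseless prevalence sets whose
constraints never bind can tie exactly (a chain with ample slack fits
equally well as a star); the tie-break then prefers the shallower tree,
which is the correct parsimony-free default but means only
constraint-binding topologies are uniquely recoverable — a fundamental
identifiability limit of frequency-only deconvolution, not a numerical
choice.

Clone (non-lineage) frequencies are the NNLS variables themselves:
own prevalence minus the children's sum, non-negative, summing to at
most 1 per timepoint. `detect_expanding_clones()` flags clones whose
first-timepoint frequency is at most 0.21 (the upper end of the minor
subclone range) and whose final-minus-first gain is at least 0.20
(default; half the smallest expansion the package's motivating use case
reports), attaching the functionally significant mutations of flagged
clones.

# Clinical statistics

Thin, contract-checked wrappers over base R and the survival package:
Wilcoxon rank-sum (exact for combined $n \le 20$ without ties, normal
approximation with tie correction otherwise), Kaplan–Meier curves with
the log-rank test, Cox proportional hazards with Efron tie handling and
Wald p-values (95% intervals by default; tie handling and CI level are
package declarations since published conventions rarely state them),
Benjamini–Hochberg adjustment, Pearson correlation with a t-based
p-value, and cohort proportions rounded half-up at one decimal (the
convention printed percentages follow; note base R's `round()` is
round-half-even, which would print 6.2 for 1/16).

# The simulator as study conditions

The simulator encodes what the pipeline assumes about real data; its
defaults are fixed study conditions, not tuning knobs.

* **Clone trees** — a founder lineage at 0.9–1.0 prevalence; each
  parent's children jointly occupy 50–100% of the parent (stick-broken
  among siblings). In the `stable_dominant` scenario allocations are
  drawn once and held across timepoints (2% jitter), so all clone
  frequencies are persistent; in `expanding_minor` allocations are
  redrawn per timepoint, and one root-child leaf is planted at 0.05–0.18
  frequency at the first timepoint rising monotonically to 0.55–0.75 at
  the last, with sibling lineages rescaled to respect the frequency-sum
  constraint. Trees are rejection-sampled (at most 200 tries) so every
  clone pair is separated by at least 0.15 at some timepoint: clones
  closer than the per-mutation prevalence noise floor
  ($\approx 0.09$ per site at depth 300 and purity 0.6) are not
  distinguishable subpopulations for any frequency-based method, so they
  are not meaningful simulation targets.
* **Bin counts** — gamma-mixed Poisson (negative binomial) around the
  purity-weighted mixture ratio, one dispersion parameter (default 0.05,
  sparse-WGS scale) and no per-bin GC structure.
* **Variants** — binomial alt counts at the closed-form expected VAF;
  simulated mutations sit at tumor copy number 2 so prevalence recovery
  is exact in expectation; matched-normal contamination defaults to 0
  and is configurable to exercise the normal-filter branch.
* **Fragment sizes** — two near-symmetric shifted-gamma components
  (shape 36, spread 20 bp — the per-mode spread is a free parameter, no
  published value pins it down) whose *means* sit at 142 bp (tumor) and
  154 bp (normal), with di-/tri-nucleosome harmonics at twice and three
  times the component mean at weights 0.15/0.05 sharing the
  mononucleosome spread. The gamma mode sits ~3 bp below the mean
  (within one histogram bin). With harmonics enabled the overall sample
  mean is pulled well above the mononucleosome mean — the 142/154
  figures describe the mononucleosome component, and calibration checks
  are run with harmonic weights 0.
* **Clinical cohorts** — exponential survival (diploid median 22
  months), aneuploid hazard multiplied by the ploidy effect, uniform
  administrative censoring at 12–60 months; cfDNA mass log-normal with a
  higher location for aneuploid patients.
* **Segment profiles** — drawn directly in segment space for classifier
  tests: diploid profiles get few extra breakpoints and ~0.005 level
  jitter (the scale expected when averaging bins over large segments);
  aneuploid profiles get more than 45 segments, half deviating by
  0.05–0.4.

What the simulator does **not** emulate: GC and mappability waves,
replication-timing structure, subclonal copy number (mutations sit at
clonal CN), mutation loss (non-perfect phylogenies), sequencing error,
and germline contamination of the variant table. Passing recovery suites
therefore demonstrates correctness of the algorithms under the model's
assumptions, not robustness to every artifact of real plasma data.

# Problem sizes used by the validation suites

The shipped validation suites use: 100 seeded replicates of 1000-bin
profiles with three planted 5-sigma steps for segmentation recovery; 200
simulated samples for ploidy-label recovery plus explicit boundary
fixtures; 50 replicates of 3-clone / 3-timepoint patients (purity 0.6,
depth 300, 60 mutations) for clonal recovery; 1000 null cohorts of 200
patients for type-I calibration of the log-rank and rank-sum tests; and
200 cohorts of 500 patients for Cox hazard-ratio recovery. These sizes
give Monte-Carlo standard errors comfortably below the margins being
asserted while keeping the suites quick to run.

# Worked example

```{r example, eval = FALSE}
tr <- simulate_clone_tree(3, 3, "expanding_minor", seed = 5)
v  <- simulate_variants(tr, purity_by_timepoint = 0.6,
                        depth_plasma = 300, depth_normal = 100, seed = 6)
m  <- variant_matrices(v)
fit <- infer_clones(m$alt, m$depth, purity = 0.6, k_max = 5, seed = 7)
detect_expanding_clones(fit$model)
```

# Known limitations

* CBS p-values below the permutation resolution come from a fitted
  Gumbel tail; decisions very close to `alpha` are approximate.
* Tree inference is exhaustive and limited to 6 clones by default;
  beyond that, no heuristic search is attempted (an explicit error is
  raised instead).
* Purity is an input; the bundled estimator is intentionally crude.
* Only total copy number is modeled — no allele-specific states, and no
  integer-copy inference beyond the rounding used to assign mutation
  sites.
* Non-perfect phylogenies (mutation loss, parallel evolution of a site)
  are out of scope.
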