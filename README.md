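# plasmaTrace

Copy number profiling, somatic variant filtering and clonal evolution
from plasma whole-genome sequencing of cell-free DNA (cfDNA).

Liquid biopsies let tumor genomes be followed over time without tissue
sampling: cfDNA drawn from blood plasma carries a tumor-derived fraction
whose copy number alterations (CNAs) and somatic mutations track the
disease. plasmaTrace implements the computational pipeline such studies
need once reads are aligned and variants called:

* **Fragment QC** — size-gated (100–700 bp) cfDNA mass, pass/fail at the
  2 ng library threshold, and nucleosome-peak detection (mono-, di-,
  tri-nucleosome harmonics).
* **Copy number** — read counting into ~220 kb bins, mean-1 ratio
  normalization, circular binary segmentation (permutation-tested arc
  statistics, `alpha = 1e-4`, undo-pruning at 0.05) with MergeLevels
  post-processing, SEG output, and a tumor/normal exome depth-ratio
  profile.
* **CNA interpretation** — neutral state as the median segmentation
  value, maximal-run CNA calls with bp lengths, CNA burden, the
  segment-count aneuploidy rule (> 45 segments with > 0.03 deviation;
  25–45 with large-segment or high-value support), BED gene annotation,
  plasma–tissue Pearson concordance and mutation-set concordance.
* **Variant filtering** — the post-caller cascade: keep PASS/germline
  risk calls, drop plasma VAF < 0.07, drop normal evidence (> 2 alt
  reads below 100X, > 0.01 VAF at or above 100X), SNV/indel split,
  SIFT/POLYPHEN significance flags, mutation burden.
* **Clonal evolution** — cellular prevalence
  `CP = VAF·(ρ·c + 2(1−ρ))/(ρ·m)`, binomial-mixture clustering of
  prevalence trajectories with BIC model selection, exhaustive clone-tree
  search under the parent ≥ sum-of-children constraint (NNLS projection),
  clone frequencies, and detection of expanding minor (resistance-like)
  subclones.
* **Clinical statistics** — Wilcoxon rank-sum, Kaplan–Meier/log-rank,
  Cox proportional hazards (Efron ties), Benjamini–Hochberg adjustment,
  Pearson correlation, half-up percentage summaries.
* **Simulator** — clone trees with CNA/SNV payloads over 2–6 timepoints,
  purity-diluted negative-binomial bin counts, binomial VAFs, bimodal
  fragment-size mixtures (tumor 142 bp / normal 154 bp modes with
  nucleosome harmonics), ploidy-linked survival cohorts, and segment
  profiles with planted ploidy labels — everything the test and
  validation suites need, generated in code.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "plasmaTrace",
                               load_package = "installed")'
```

## Worked example

Simulate a 3-clone patient sampled at 3 timepoints (tumor purity 0.6,
exome depth 300X), then recover the clonal structure:

```r
library(plasmaTrace)

tr  <- simulate_clone_tree(3, 3, "expanding_minor", seed = 5)
v   <- simulate_variants(tr, purity_by_timepoint = 0.6,
                         depth_plasma = 300, depth_normal = 100, seed = 6)
m   <- variant_matrices(v)
fit <- infer_clones(m$alt, m$depth, purity = 0.6, k_max = 5, seed = 7)

round(fit$model$prevalence, 3)
#>         [,1]  [,2]  [,3]
#> clone1 0.079 0.434 0.163
#> clone2 1.000 0.971 0.906
#> clone3 0.074 0.320 0.568
fit$model$parents
#> [1] 2 0 2
detect_expanding_clones(fit$model)
#>        clone initial_frequency final_frequency flagged
#> clone1     1        0.07944448       0.1627787   FALSE
#> clone2     2        0.84611113       0.1755539   FALSE
#> clone3     3        0.07444439       0.5677784    TRUE
```

`clone2` is recovered as the founder (parent 0 is the implicit root) with
`clone1` and `clone3` as its children — matching the simulated tree. The
planted minor subclone (`clone3`) starts near 7% lineage prevalence and
expands to ~57% at the final timepoint while the founder's own cells are
progressively taken over by its subclones; `detect_expanding_clones`
flags exactly that expanding clone.

Copy number from binned counts:

```r
grid <- uniform_bin_grid()                      # 220 kb bins, hg19 autosomes
bc   <- simulate_bin_counts(tr, purity = 0.6, grid,
                            mean_depth_per_bin = 30, seed = 8)
bc   <- normalize_counts(bc)
prof <- merge_levels(cbs_segment(bc, seed = 9), bc)
calls <- call_cnas(prof, tol = 0.05)
classify_ploidy(prof)$label
write_seg(prof, "patient1.seg")
```

A thin command-line front end over the same functions ships in
`inst/cli/plasmatrace.R` (subcommands `simulate`, `qc`, `cnv`, `call`,
`filter`, `clonal`, `stats`).

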