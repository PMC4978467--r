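# circprom

Core promoter architecture and circadian transcription analysis.

Clock-controlled genes are transcribed rhythmically, but promoters differ
sharply in how well they propagate rhythmic transcription-factor binding to
rhythmic transcription. `circprom` implements the computational pipeline for
classifying core promoters of circadian genes from TSS-anchored data:

- **Promoter catalog** — reduce a transcript annotation to a non-redundant,
  TSS-unambiguous promoter set; adjust TSSs with CAGE tag clusters and call
  focused/dispersed promoter shape (cluster width < 10 bp ⇒ focused).
- **Sequence features** — TATA/BRE detection from position count matrices
  with *exact* score distributions: the pmf of the log-odds score of a
  random w-mer is computed by column-wise convolution on a discrete grid,
  under both the background model (GC-matched, p_C = p_G = gc/2) and the
  regularized motif model, and hits are called at the *balanced threshold*
  t\* minimizing |FPR(t) − FNR(t)|. CpG observed/expected ratio over
  −100..+100 of the TSS by the standard formula CG·N/(G·C), N = 200 (there
  is no position 0).
- **Rhythms** — RPKM normalization with trimmed-log-ratio scale factors,
  cosinor (harmonic regression) fits y = m + a·cos(ωt) + b·sin(ωt) giving
  mean, relative amplitude √(a²+b²)/m, peak phase, and an F-test p value;
  BH adjustment; classification into circadian / constitutive / silent /
  other at the organism thresholds (mouse: expressed > 0.1 RPKM, BH p < 0.2
  and relamp > 0.1; fly: expressed > 1, BH p < 0.25).
- **Signal tracks** — strand-oriented TSS pileups, ChIP strand-shift
  estimation, region quantification (pause +21..+100, gene body
  +301..+1300, nucleosome occupancy −101..−1, ...), pausing index
  PI = pause/gene-body, quantile normalization, outlier-trimmed
  metaprofiles, phase-binned population reordering, and Watson's U² circular
  two-sample test with a permutation null.
- **Nucleosome peaks** — +1 nucleosome calling on smoothed MNase pileups,
  Pol II stall fractions (fraction of the 100 bp upstream of the +1 peak
  with 3'-end nascent signal significantly above its surroundings), and
  nucleosome-normalized H2A.Z levels at the +1 peak.
- **Promoter taxonomy** — CTF binding (peak center within ±3 kb of the
  TSS), the LCpG/HCpG split at CpG ratio 0.5, and the promoter classes:
  **SCP** (strong circadian promoter) = circadian ∧ CTF-bound ∧
  (TATA ∨ LCpG); circadian/constitutive type I and II; residual classes.
- **Expression-matched bootstrap** — does a property differ between SCPs
  and constitutive type I promoters beyond what transcriptional activity
  explains? Activities are binned into 55 log-scale bins, pool members are
  reweighted to the reference's binned activity distribution, an empirical
  rank-sum null is built by resampling the pooled groups, and the median
  two-sided p over outer resamples is reported.
- **Pol II kinetics** — the three-state promoter model with a saturable
  pause site: dx₁/dt = k_rec(t)(1−x₁−x₂) − k_init·x₁,
  dx₂/dt = k_init·x₁ − k_rel(t)·x₂, with k_rec and k_rel cosine-modulated.
  Periodic orbits by an RK4 monodromy solve (Rcpp) or a first-harmonic
  perturbation solution; rhythm propagation factors and the phase signatures
  (ΔZT_gb, ΔZT_PI) that distinguish recruitment-only, release-only, and
  combined regulation.
- **Synthetic data** — a cohort generator planting class labels, activities,
  amplitudes, phases, TATA boxes, CpG ratios, CAGE clusters, CTF peaks, and
  chromatin tracks, so every stage is testable without external accessions.

Everything is tibble-first: data frames in, tibbles out, with broom-style
`tidy()`/`glance()` and ggplot2 `autoplot()` methods for fitted objects.

## Worked example

```r
library(circprom)

cohort <- generate_cohort(cohort_spec(n_promoters = 2000, seed = 1))
report <- run_pipeline(cohort, organism = "mouse",
                       n_null = 1e5, n_outer = 200, seed = 1)
print(report)
```

```
circprom pipeline report (mouse)
promoters retained: 2000 

class fractions:
          class   n fraction      lo      hi
1           SCP 158   0.0790 0.06755 0.09170
2   circ_type_I 150   0.0750 0.06384 0.08743
3  circ_type_II  87   0.0435 0.03499 0.05338
4    circ_other  99   0.0495 0.04041 0.05994
5  const_type_I 142   0.0710 0.06013 0.08315
6 const_type_II 347   0.1735 0.15714 0.19082
7   const_other   8   0.0040 0.00173 0.00787
8        silent 415   0.2075 0.18992 0.22594
9         other 594   0.2970 0.27703 0.31756

TATA enrichment (circadian vs constitutive):
  a_flag a_noflag b_flag b_noflag odds_ratio  p_value
1    166      328     92      405       2.23 7.27e-08

SCP vs expression-matched constitutive type I (CpG ratio):
matched_bootstrap: median p 0.00016, median location difference -0.02185 (n_null 1e+05, n_outer 200)
```

Reading the output: each class row gives the promoter count, its fraction of
the catalog, and an exact (Clopper–Pearson) 95% binomial interval. The
enrichment table shows TATA boxes over-represented among promoters called
circadian versus constitutive (odds ratio 2.23, Fisher exact p 7×10⁻⁸ — the
generator plants TATA boxes in SCP/type I classes, and the scan recovers
them). The bootstrap line says SCPs have lower CpG ratios than constitutive
type I promoters *matched for transcriptional activity* (median two-sided
p 1.6×10⁻⁴, median location difference −0.02 on the CpG-ratio scale). The
large `other` bucket is expected: promoters whose rhythm evidence is
ambiguous at the quoted thresholds land there rather than being forced into
a class.

The kinetic model is driven separately:

```r
p <- kinetic_params(k_rec0 = 6, k_init = 60, k_rel0 = 6,
                    eps_rec = 0.3, eps_rel = 0.1, phi_rel = 0.1)
phase_signature(p)
#> # A tibble: 1 x 3
#>   delta_zt_gb delta_zt_pi regime_call
#>         <dbl>       <dbl> <chr>
#> 1     -0.0251        12.0 combined_like
```

— paused and gene-body Pol II share a phase while paused Pol II and the
pausing index are in antiphase, the signature that only combined regulation
of recruitment and pause release produces.

## Acceptance script

`scripts/acceptance.R` re-runs the whole pipeline from scratch on a
synthetic cohort generated under `--seed` (catalog → sequence features →
rhythms → taxonomy → matched bootstrap, plus +1 nucleosome calling,
strand-shift recovery, and the kinetic model), prints the resulting report,
and writes the acceptance JSON to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The quantitative checks for this package are property-based and live in
`tests/testthat/test-acceptance.R` (exact-distribution brute-force
equivalence, threshold calibration, cosinor type-I error and recovery,
taxonomy recovery on a 2,000-promoter cohort, strand-shift and peak-calling
recovery, bootstrap calibration and power, kinetic closed forms and phase
signatures, and oracle checks for the elementary statistics).

## Methods

See `vignettes/circprom-methods.Rmd` for the models, assumptions, parameter
choices, numerical decisions, and known limitations.
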