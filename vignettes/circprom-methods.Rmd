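---
title: "circprom: models, methods, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circprom: models, methods, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: what each stage
computes, which assumptions it makes, why the tunable parameters have the
defaults they do, what the synthetic-data generator does and does not
emulate, and the numerical decisions taken where the design was genuinely
open. It states no empirical result that the test suite does not itself
compute.

## Coordinate conventions

All TSS-relative coordinates are 1-based with **no position 0**: the TSS
base is +1, the base immediately upstream is −1. Every quantification window
(pause region +21..+100, CpG window −100..+100 with N = 200, occupancy
−101..−1, TATA scan −50..−10, ...) is expressed in this system, and
minus-strand promoters are flipped so that +1 is always the first
transcribed base. Scan windows bound the *match start* position of a motif.

## Promoter catalog

The catalog reduction guarantees an unambiguous TSS ↔ transcript mapping,
which everything downstream assumes. Four rules run in order: coordinate
duplicates collapse to one representative; among transcripts sharing a TSS
only the shortest survives; transcripts overlapping a retained transcript
with a *different* TSS are discarded — both members of the pair, because
keeping either would leave a promoter whose signal cannot be attributed to
one transcript; finally transcripts shorter than 500 bp and non-coding
(`NR_`-prefixed) entries are dropped. Overlap is genomic (strand-agnostic)
by default, configurable. CAGE adjustment moves a TSS to the nearest
same-strand tag cluster within 300 bp; distance ties break toward the
smaller genomic coordinate (any deterministic rule would do; this one is
order-independent). A cluster width (10%–90% tag quantile distance)
strictly below 10 bp calls the promoter *focused*.

## Motif detection with exact score distributions

Position count matrices are regularized with background pseudocounts scaled
by the square root of the column total:
p<sub>bj</sub> = (c<sub>bj</sub> + κ√N<sub>j</sub>·p<sub>b</sub>) /
(N<sub>j</sub> + κ√N<sub>j</sub>). The √N scaling makes the prior's weight
grow slower than the data, so well-populated columns are barely moved while
sparse ones are shrunk toward the background; κ defaults to 1 and is
exposed because no canonical constant exists. Log-odds scores are
log₂(p<sub>motif</sub>/p<sub>background</sub>) with the background GC-matched
to the promoter (p<sub>C</sub> = p<sub>G</sub> = gc/2).

The score distribution of a random w-mer is computed *exactly* by dynamic
programming: per-column scores are rounded to a grid of spacing ε (default:
the total score range divided by 4096, i.e. sub-0.01-bit resolution for
motif-sized matrices) and the pmf of the running sum is convolved column by
column, under either emission model. The balanced threshold t\* minimizes
|FPR(t) − FNR(t)| with FPR(t) = P<sub>bg</sub>(S ≥ t) and
FNR(t) = P<sub>motif</sub>(S < t); ties break toward the smallest t. Scans
are sense-strand only — TATA and BRE elements are orientation-dependent core
promoter elements. `scan_promoters()` recomputes the threshold per promoter
GC content (rounded to 2 decimals and cached), mirroring per-promoter
threshold calibration. A conservation filter (median per-base score over the
hit footprint, maximum over hits, threshold 0.75) is applied only where
per-base conservation is supplied, as appropriate for fly data.

One consequence worth knowing: for a motif of width ~10–15 scanned over a
41-position window, the balanced error rate times the window width is the
per-promoter false-positive rate. Only sharply informative matrices keep
that product at the percent level; the bundled `*_synthetic.jaspar` matrices
are constructed (synthetic) matrices chosen that sharp, not copies of any
curated database entry.

## Rhythm detection

Abundances are RPKM with a trimmed-mean-of-log-ratios scale factor per
sample (edgeR's `calcNormFactors`, the correction the field uses),
renormalized to median 1. Rhythms are quantified by cosinor regression
y = m + a·cos(ωt) + b·sin(ωt), ω = 2π/24; relative amplitude is
√(a² + b²)/m, the phase is the peak time, and the detection p value is the
F test of the two harmonic coefficients (df 2, n − 3). Two sampled days are
pooled modulo 24 h by the periodicity of the harmonics themselves; only a
single 24-h harmonic is fitted. A dedicated nonparametric rhythm detector
would differ mainly in sensitivity to non-sinusoidal waveforms; the cosinor
F test is used throughout because the same fit already supplies all effect
sizes, and the classification thresholds are kept at their quoted values
(mouse: BH-adjusted p < 0.2 *and* relative amplitude > 0.1 among expressed
transcripts; fly: BH p < 0.25 with no amplitude gate; silent: mean RPKM
< 0.01; expressed: > 0.1 mouse / > 1 fly).

"Constitutive" is operationalized as expressed, not circadian, and raw
rhythm p ≥ 0.5. The explicit gate keeps near-significant transcripts out of
the constitutive set, at a known cost: for a truly flat series the F-test p
is uniform, so a zero-amplitude promoter passes the gate with probability
exactly one half, whatever the noise level. This is a property of any gate
placed on a pivotal statistic, not of the implementation; promoters failing
it land in `other`. Tests that score label recovery therefore treat
constitutive↔other confusions on zero-effect promoters as inherent to the
definitions (see "What a green test establishes" below).

## Track quantification

Pileups are per-base coverages normalized to reads per base per 10⁶ reads
(10⁷ for MNase/H2A.Z conventions), strand-oriented. The ChIP strand shift is
the s maximizing the correlation between the top-strand coverage shifted +s
and the bottom-strand coverage shifted −s over TSS windows; for fragments of
length L sampled at both ends the optimum is L/2. Region signals follow the
quoted windows exactly; for tracks normalized per million reads, RPKM equals
the regional mean × 1000. The pausing index is pause/gene-body, undefined at
zero gene-body signal. Quantile normalization replaces each column's sorted
values by the cross-column mean of sorted values, ties receiving the mean of
the values they span — with ties the common-distribution and idempotence
properties hold only approximately, exactly in the tie-free continuous case.
Metaprofile averaging trims the top and bottom 1% per position (20% for the
H2A.Z summaries, following the corresponding figure convention).

Phase-binned reordering handles signals too noisy for single-promoter
rhythm calls: promoters are binned by transcriptional phase into bins
centered at the sampling times (±2 h for 4-h sampling), each promoter's
cycle-collapsed series is rotated so index 0 is its bin center, and the
population average is fitted by the cosinor. Watson's U² two-sample test for
circular phase data uses a label-permutation null (exact exchangeability at
small n, one code path) rather than asymptotic tables.

## +1 nucleosome and stall fraction

The +1 nucleosome is the first local maximum (within ± the 20-bp smoothing
radius) of the smoothed MNase pileup inside +1..+300 whose smoothed value
exceeds the track's lower-quartile baseline by 3 standard deviations of the
*smoothing-reduced sampling noise*, estimated robustly as
mad(diff(raw))/√2/√smooth. Two natural alternatives fail structurally: a
local flank mean ± SD always contains the peak's own near-equal shoulders
and can therefore never flag a smooth nucleosome-width peak, and a global
median ± MAD fails on phased arrays whose nucleosomes elevate more than
half the span. The quartile-plus-noise criterion detects noiseless bumps,
tolerates phased arrays, and is translation-invariant.

Stalled positions keep the local criterion: a position in the 100 bp
upstream of the +1 peak is stalled iff its raw value exceeds the mean + 3 SD
of its ±50 bp neighbourhood (center excluded) — appropriate for the isolated
3'-end spikes it targets, and scale-free. Note the criterion saturates at
spike densities above roughly 0.1/bp (the flank statistics absorb the
spikes), which bounds realistic stall fractions from this detector; the
high/low class boundaries (SF > 0.6; 0.05 < SF ≤ 0.3) are therefore also
exposed directly via `stall_fraction_class()`. H2A.Z at the +1 nucleosome is
the mean H2A.Z pileup over ±80 bp of the peak divided by the mean MNase
pileup over the same interval.

## Promoter taxonomy

CTF binding is ≥1 peak center of any supplied factor within ±3000 bp of the
TSS (±2000 for fly CLK), boundaries inclusive. LCpG is CpG ratio strictly
below 0.5 (the split point of the bimodal ratio distribution). The classes
are definitional and partition the catalog: SCP = circadian ∧ CTF ∧
(TATA ∨ LCpG); circadian type I = circadian ∧ ¬CTF ∧ (TATA ∨ LCpG);
circadian type II = circadian ∧ CTF ∧ ¬TATA ∧ ¬LCpG; the circadian
remainder is `circ_other`; constitutive type I/II are the non-CTF analogues
and CTF-bound constitutive promoters are `const_other`. Enrichments are
sample odds ratios (0.5 continuity correction at zero cells) with two-sided
Fisher exact p values.

## Expression-matched bootstrap

Mean activities of the reference (SCPs) and pool (constitutive type I) are
binned into 55 logarithmically equispaced bins over the pooled range; each
pool member's weight is (reference count in its bin)/(pool count in its
bin), normalized. Reference-occupied bins with an empty pool move their mass
to the nearest non-empty bin, with a warning. Stage 1 pools both groups'
values with their sampling probabilities — uniform for the reference,
matching weights for the pool, each group weighted by its size — and draws
two samples of the original sizes with replacement, computing the mid-rank
rank-sum statistic; the default 10⁶ draws build the empirical null. Stage 2
resamples each group from its own population (reference uniform, pool
weighted, mirroring stage 1) 1000 times; each statistic becomes a two-sided
p value against the stage-1 null as 2·min(tails) with add-one smoothing,
capped at 1, and the median p and median location difference are reported.
Calibration is approximate, not exact: the stage-2 statistic carries
between-group sampling variance that stage 1 does not, which matters when
the 55 bins are sparsely populated — with groups of a few hundred the
rejection rate at α = 0.05 sits near nominal (the acceptance suite checks
0.05 ± 0.02 at reference 150 / pool 450), while very small groups drift
anticonservative. This is a property of the plug-in procedure itself.

## The Pol II kinetic model

The promoter cycles through free (x₀), recruited (x₁), and paused (x₂)
states with a single saturable pause site, x₀ + x₁ + x₂ = 1:

dx₁/dt = k_rec(t)·x₀ − k_init·x₁,  dx₂/dt = k_init·x₁ − k_rel(t)·x₂,

with k_rec(t) = k_rec0(1 + ε_rec·cos ω(t − φ_rec)) and k_rel analogous;
initiation (which folds in the closed→open complex transition) is constant.
This is a reconstruction: the three-state cyclic occupancy model with one
saturable site is the minimal structure consistent with the claims it must
reproduce (the baseline/propagation trade-off and the phase signatures); an
explicit fourth state is not modelled. Transcriptional activity is
f(t) = k_rel(t)·x₂(t); the gene-body observable is quasi-static, g = f/v
(no elongation delay — at realistic elongation speeds the transport delay
across a gene body is minutes, negligible against a 24-h rhythm); the
pausing index is PI = x₂/g.

With x₀ eliminated the system is linear with periodic coefficients, so the
periodic orbit is found *exactly* from the monodromy of one period: three
RK4 integrations (two unit initial conditions and zero) give the affine
period map x ↦ Φx + ψ, and the orbit through (I − Φ)⁻¹ψ is recorded. The
step count scales with the fastest rate (≥20 steps per fastest time
constant, ≥4096 per period); the returned residual is the sup-norm mismatch
after one further period and is checked against `tol` (default 10⁻¹⁰). The
first-harmonic method solves the linearization around the flux-balance
steady state f₀ = 1/(1/k_rec0 + 1/k_init + 1/k_rel0) in the complex plane
— a 2×2 solve — and is accurate to O(ε²). Harmonic summaries of the orbit
use direct Fourier projection on the uniform grid (spectrally accurate for a
periodic orbit), not regression.

Two results the model makes quantitative. First, in the saturating regime
raising the mean recruitment rate raises mean paused Pol II while *lowering*
the propagation of rate rhythms into activity rhythms (relamp(f)/max ε):
saturation of the shared pause site buffers the rhythm. Second, the phase
signature: with quasi-static gene bodies PI(t) = v/k_rel(t) exactly, so the
PI phase is locked in antiphase to the release modulation. The observed
combination — paused and gene-body Pol II in phase *and* paused Pol II in
antiphase with PI — therefore requires the paused-Pol II rhythm to peak
together with the release rate, which recruitment-driven dynamics deliver
when the release modulation tracks the recruitment-driven pause peak
(φ_rel ≈ φ_rec + the small response lag) and is weak enough not to dominate
it (ε_rel < ε_rec·x₀; with equal modulation depths the release contribution
to x₂ always points away from φ_rel and the signature is unreachable, which
a phase sweep confirms numerically). Release-only regulation instead puts
paused and gene-body Pol II in antiphase, and recruitment-only regulation
leaves PI flat — these are the `release_like` and `recruitment_like` regime
calls (`combined_like`: |ΔZT_gb| < 2 h and |ΔZT_PI| > 10 h; `release_like`:
|ΔZT_gb| ≥ 6 h).

## The synthetic cohort: what it emulates, and what a green test establishes

`cohort_spec()` states a world once: a mixture over the seven planted
classes (defaults 8% SCP, 10/7/5% circadian I/II/other, 15/35% constitutive
I/II, 20% silent); log-normal activities (medians 1–8 RPKM for expressed
classes, 0.002 for silent — kept strictly below the 0.01 silent threshold so
planted labels satisfy their own definitions); uniform phases; relative
amplitudes uniform within class ranges (0.35–0.7 for SCPs, 0.15–0.5
otherwise); negative-binomial counts with dispersion 0.05 at 12 samples
over two days; TATA boxes drawn from the regularized matrix and planted at
−30; CpG ratios steered to bimodal targets (0.2–0.42 vs 0.58–0.95) by
dinucleotide-aware editing with tolerance ±0.04; CAGE clusters focused for
TATA/LCpG promoters; CTF peaks within ±1.5 kb for bound classes plus
distant decoys; and chromatin tracks with class-dependent NDR depth, a +1
nucleosome near +120 with ~185-bp phasing, pause peaks at +50, and Poisson
sampling noise whose default depth deliberately leaves single-promoter
nucleosome tracks too noisy for single-promoter rhythm calls, so the
population-level phase-bin path is the one that works.

It does **not** emulate: genome context (repeats, mappability), fragment
length distributions, non-sinusoidal waveforms, inter-replicate batch
structure, or correlated noise across neighbouring promoters. A green
end-to-end test therefore establishes that the pipeline's rules and
estimators recover a world of exactly the stated structure — not that the
thresholds are optimal for any particular real data set.

On label recovery: with NB dispersion 0.05 the coefficient of variation
floor is √0.05 ≈ 0.22, and the cosinor F test at 12 points reaches 90%
power (α = 0.05) only above a planted relative amplitude of ≈0.39
(noncentral-F calculation). Planted effects below that boundary — including
the zero-amplitude constitutive class, where any gate on a uniform p value
is a coin flip and the BH q = 0.2 circadian gate admits false discoveries
by design — are where rhythm-label errors concentrate; the acceptance test
scores them as the allowed "genuinely marginal" errors and requires ≥95%
accuracy overall, and ≥99% when planted rhythm categories are supplied and
only the sequence/peak-derived flags are estimated.

## Numerical and degenerate-input decisions

- Cosinor fits need ≥4 time points and ≥3 distinct times mod period
  (rank-deficient designs error); an exactly constant series returns
  relative amplitude 0 and p = 1; phases within 10⁻⁹ h of the period wrap
  to 0.
- The score-distribution grid conserves mass to <10⁻¹² by construction;
  degenerate single-point distributions (all scores equal) are allowed.
- `estimate_strand_shift` errors on constant coverage (undefined
  correlation) and breaks correlation ties toward the smaller shift.
- `pausing_index` returns NA at zero gene-body signal; `h2az_signal`
  returns NA with a warning at zero nucleosomal signal; `cpg_ratio` returns
  0 when the window lacks C or G entirely.
- Bootstrap p values use add-one smoothing, so the smallest reportable p is
  1/(n_null + 1); the defaults (10⁶/1000) match the procedure's published
  scale and tests run scaled down.
- All randomized routines take explicit seeds and are bit-reproducible
  under them; the cohort generator is deterministic given its spec.

## Known limitations

- RAIN-style nonparametric rhythm detection is intentionally out of scope;
  waveform-asymmetric rhythms lose power under the single-harmonic fit.
- The stall-fraction detector cannot report fractions much above ~0.1 for
  homogeneous spike heights (flank saturation, discussed above);
  heterogeneous real data can exceed this, so cross-study SF scales are not
  directly comparable.
- Quantile normalization's identical-distribution guarantee is exact only
  without ties.
- The kinetic model treats gene bodies quasi-statically and folds the
  closed→open transition into the initiation rate; an explicit transport
  delay or fourth state would change the phase signatures only at the
  minutes scale.
- The matched bootstrap matches on one covariate (mean activity) only, and
  its calibration degrades when the 55 activity bins are sparsely
  populated.
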