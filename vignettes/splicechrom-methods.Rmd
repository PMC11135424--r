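---
title: "Methods: chromatin-linked alternative splicing analysis"
author: "splicechrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-linked alternative splicing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`splicechrom` implements the statistical core of an integrative analysis
linking loss of a chromatin factor to alternative-splicing change: cassette
exons that shift inclusion between a control and a mutant condition, the
enrichment of chromatin-factor binding near those exons, elongating-RNAPII
signal aggregated around exon centers, RNA-binding-protein motif content of
exon flanks, a dual-readout siRNA screen for cooperating splicing factors,
and a per-CpG bisulfite methylation comparison between two isoform-expressing
conditions. Everything runs on synthetic inputs with known ground truth, so
each stage's statistical behaviour (type-I error, power, bias) is measured
rather than assumed. Upstream read processing (alignment, peak calling,
bisulfite conversion calls) is out of scope: the package consumes count
tables, BED intervals, bedGraph tracks, FASTA and GTF.

# Differential cassette-exon splicing

Inclusion of a cassette exon is summarized as PSI (percent spliced in) with
effective-length normalization,

$$\psi = \frac{I / \ell_I}{I / \ell_I + S / \ell_S},$$

where $I$ and $S$ are reads supporting the inclusion and skipping forms and
$\ell_I, \ell_S$ their effective lengths (for junction-plus-exon-body
counting of a skipped exon, $\ell_I = 2$, $\ell_S = 1$). Replicates with no
informative reads are dropped, not imputed; pooled group PSI uses summed
counts.

The group test is a binomial likelihood-ratio test on pooled counts:
inclusion reads are modelled as $I_g \sim \mathrm{Bin}(I_g + S_g, \theta_g)$
per group with a shared-$\theta$ null, and
$2\{\ell(\hat\theta_1,\hat\theta_2) - \ell(\hat\theta_0,\hat\theta_0)\}$ is
referred to $\chi^2_1$. This is a deliberate, fully specified replacement for
a hierarchical per-replicate model: it is exact to implement and its
operating characteristics are verified by simulation. The cost is that
between-replicate overdispersion inflates its type-I error; the packaged
null-calibration checks therefore run at dispersion 0, and results on
strongly overdispersed data should be read as rankings rather than calibrated
p-values. The effective lengths cancel from the count-level test and enter
only the PSI point estimates.

Events are called at `fdr < 0.05` (Benjamini–Hochberg across all tested
events jointly — no stratification by event type), `|dPSI| > 0.1` and gene
expression `TPM > 1`; direction is `included-in-mutant` for positive
mutant-minus-control dPSI. The PSI/test machinery accepts any event type via
caller-supplied counts and effective lengths, but the generator and
end-to-end validation cover skipped exons (SE) only.

# Synthetic data generator

The generator is first-class, tested code; its defaults are the study
conditions the analyses are validated under.

* **Annotation**: genes with three exons (cassette flanked by constitutive
  exons), both strands, exon widths 120–180 bp. Introns are drawn from
  7.5–9 kb so that a peak planted up to ~2.3 kb downstream of a cassette exon
  cannot fall inside the 5-kb window of a neighbouring exon — the planted
  enrichment is then attributable to the intended exons.
* **Junction counts**: baseline PSI $\sim \mathrm{Beta}(2, 2)$; a configured
  number of true events get a mutant-minus-control shift of 0.3, positive
  with probability 0.59 (the direction balance reported for this kind of
  perturbation), clamped into (0.01, 0.99) with the clamping recorded.
  Per-replicate PSI is beta-binomially overdispersed (default $\rho = 0.05$;
  $\rho = 0$ recovers the binomial) because biological replicates
  overdisperse; read depth is Poisson (default mean 100). Replicates default
  to 2 control vs 3 mutant, matching the small-cohort design the analysis
  emulates. 10% of genes get TPM < 1 to exercise the expression filter.
* **Peaks**: background peaks are Poisson (8/Mbp, 300 bp wide); each true
  excluded-in-control exon receives with probability `peak_fg_prob` one peak
  starting Uniform(0, 2 kb) downstream of its 3' end in transcription
  direction. The default `peak_fg_prob = 0.145` comes from closed-form
  algebra (`peakFgProbForRatio()`) so that the measured bound-proportion
  ratio of 500 planted exons against the full 4500-exon universe is 2.25,
  the magnitude of enrichment this kind of chromatin factor shows at
  mis-spliced exons.
* **Signal track**: unit background with a Gaussian stalling bump (amplitude
  2 signal units, sd 300 bp) centered on stalled exons, emitted in 25-bp
  bins with per-bin Gaussian noise (sd 0.05). The noise is not cosmetic:
  real normalized ChIP tracks fluctuate, and a noise-free track would make
  per-bin rank tests degenerate. The bump shape is a modelling choice — any
  unimodal bump supports the metaplot contrasts.
* **Screen plate**: 73 entries (negative control GFP, positive control
  SMCHD1, 71 library factors), two biological replicates, four amplicons per
  entry (two exon readouts, total transcript, reference gene). Each reported
  Ct is the mean of three technical replicates with per-well Gaussian noise
  of 0.1 cycles — screens of this design average technical triplicates
  before analysis, and omitting that averaging would overstate the assay
  noise roughly 1.7-fold. Spiked hits shift both exon readouts by fold change
  1.5; the positive control by 1.2, so true hits exceed it by ~3 sd of the
  fold-change noise. A 5% subset is emitted above the detection limit
  (Ct 35) to exercise the detection filter.
* **Methylation**: per-CpG methylation $\theta \sim \mathrm{Beta}$ per
  condition (defaults mean 0.6 vs 0.7, concentration 20), Poisson coverage
  (mean 50), binomial methylated counts.
* **Motif windows**: uniform-composition sequences with consensus instances
  planted at Poisson rates (1.5 vs 0.5 per kb). Consensus rather than
  PWM-sampled instances are planted because a sampled instance of a
  0.85-dominant motif fails the 0.8-of-maximum scan threshold about two
  thirds of the time, which would decouple planted from measurable density.

Every generator derives an independent RNG stream from the master seed via a
fixed offset, so outputs are bit-identical under a seed and independent of
call order. What the generator does **not** emulate: mapping artifacts,
GC/mappability structure, correlated peaks, multi-cassette genes, non-SE
event types, batch effects. Passing tests demonstrate correctness of the
statistics under the stated model, not robustness to those real-data
features.

# Binding enrichment near mis-spliced exons

An exon is *bound* when any peak overlaps its symmetric window (default
half-window 5 kb; 1 kb also used) by at least 1 bp; exons are deduplicated
by coordinates before counting. Enrichment of a foreground exon set over a
background (all expressed exons, or the non-mis-spliced exons of the same
genes) is the ratio of bound proportions — the scale on which "binds X-times
more often" statements live, since they are proportion arithmetic, not odds
— with the odds ratio reported alongside and a two-sided Fisher exact
p-value. A Student t-test on the 0/1 bound indicators is exposed as an
alternative because published analyses of this design have used either; the
Fisher test is the default and the one used throughout the packaged checks.

Directional occupancy splits the flanks strand-awarely (downstream =
`[end, end + w)` on `+`, mirrored on `-`); a peak overlapping the exon body
counts for neither flank, so the two flags partition flanking occupancy.
Downstream excess is tested by Fisher on the bound/unbound by
downstream/upstream table.

Gene-set enrichment is the generic upper-tail hypergeometric test against an
expressed-gene universe, BH-corrected across sets.

# Signal metaplots

Signal is averaged in 50-bp bins at offsets −2500…+2500 from the exon
midpoint — 101 bins, the layout of the standard aggregation-histogram
convention. Minus-strand profiles are reversed so positive offsets always
mean downstream in transcription direction. Two conventions make the
mirror-symmetry property exact rather than approximate: the midpoint rounds
down on `+` and up on `-`, and an even-width bin places its extra base
downstream on both strands. Group comparison is a per-bin two-sided Wilcoxon
rank-sum test (exact null when $nm \le 400$ with no ties, tie-corrected
normal approximation otherwise) with BH correction across the 101 bins.
Profiles are raw track means by default; a per-exon z-score flag exists for
tracks with strong per-locus baseline differences. "Paused" polymerase sites
are defined operationally — the within-window signal maximum when it exceeds
the genome-wide 0.9 signal quantile — because no computational definition is
standard.

# Motif enrichment

Motifs are position weight matrices (RNA motifs DNA-encoded) scanned on the
sense strand only, since they model protein contacts on pre-mRNA. The scan
score is log-odds against a 0-order background recomputed from the
background sequence set; a hit scores at least 0.8 of the maximum attainable
score (common PWM practice, exposed as a parameter); windows containing
non-ACGT bases are skipped; probabilities get a $10^{-4}$ pseudocount before
logs. Enrichment is window-level: a 2×2 Fisher test of hit-containing
windows, BH across motifs, with the hit-density ratio reported as the effect
size. Exon flanks default to 10 kb each side, extracted as one concatenated
exon-plus-flanks sequence (splitting exon and flank windows is a
non-default variant the evidence does not distinguish). `sharedMotifs()`
intersects significant motifs across datasets.

# Screen scoring

Relative quantities are $2^{-\Delta C_t}$ against the reference gene; the
PSI fold change of a readout is the inclusion/total ratio normalized to the
negative control *within each replicate* (absorbing between-experiment
variance), then averaged across replicates. Z-scores are computed per
readout over the detected, non-control library factors using the sample
standard deviation; controls are excluded from the reference distribution by
default so that they are judged against the library (inclusion is a flag —
the choice is not settled by the source design). A factor is a hit when both
z-scores exceed the positive control's and their sum exceeds 2, and it is
detected (all amplicons below Ct 35).

# Methylation comparison

Beta values are $m/(m+u)$ at a configurable coverage floor. The two-condition
comparison is paired by CpG (the same amplicon CpGs are measured in both
conditions), reporting per-CpG differences, their mean with a 95% CI, and a
two-sided paired t-test; Wilcoxon signed-rank and unpaired modes are flags.
CpGs usable in only one condition are dropped from the paired test and
reported. Degenerate edge: if all paired differences are exactly zero the
result is mean 0, p = 1 (no evidence of change); a nonzero constant
difference leaves the paired t statistic undefined and errors. CpGs, not
reads, are the test units — read-level testing would treat PCR duplicates of
one molecule as independent.

# Numerical conventions

Internally every interval is a `GRanges` (1-based, closed); BED and bedGraph
are converted on read/write and round-trip exactly, GTF needs no conversion.
BED/bedGraph parsing validates per line (malformed line numbers, `start >=
end`, overlapping bedGraph runs are errors); track gaps read as 0; bedGraph
values are taken as already library-size normalized, with a scale-factor
option. Fisher, Wilcoxon, t-tests, BH and hypergeometric tails use R's
stats routines; the test suite checks them against exhaustive-enumeration
oracles (all 2×2 tables with small margins to $10^{-10}$; full
rank-permutation null for group sizes ≤ 6).

# Problem sizes

The packaged validation uses 2000 null events for type-I calibration; 1000
genes with 500 true events (|dPSI| 0.3, depth 200) for sensitivity,
direction accuracy and PSI bias; 1500 genes with 500 planted exons for the
binding-ratio recovery; 400 exons (200 per group) for metaplots with 100
label permutations; 200–300 sequence windows per side for motif density and
power; 100 simulated screen plates; and 200 CpGs at coverage 50 for the
methylation contrast. These sizes put Monte-Carlo error well inside each
check's acceptance band while keeping the full run in a few minutes.

# Known limitations

The splicing LRT is anticonservative under strong overdispersion; only SE
events are simulated end-to-end; PWM scanning is 0-order-background and
sense-strand only; the paused-site definition is operational; the screen
model assumes equal amplification efficiency across amplicons; methylation
comparison assumes shared CpG panels between conditions.
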