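# splicechrom

Chromatin factors can shape alternative splicing: a factor bound near an
exon can slow elongating RNA polymerase II, giving inhibitory RNA-binding
proteins time to act, so that losing the factor flips the exon from skipped
to included. Establishing that chain of evidence takes several distinct
statistical analyses — differential cassette-exon splicing, peak–exon
proximity enrichment, signal metaplots, motif enrichment, screen scoring,
methylation comparison — each easy to get subtly wrong. `splicechrom`
implements that analysis chain as a tested R package for epigenomics /
regulatory-genomics analysts, together with a seeded synthetic-data
generator that produces every input with known ground truth, so each stage's
type-I error, power and bias are measured, not assumed.

## What it computes

* **Differential splicing** — PSI with effective-length normalization,
  `psi = (I/l_I) / (I/l_I + S/l_S)`; a pooled-count binomial likelihood-ratio
  test per event (`2·[l(θ̂₁,θ̂₂) − l(θ̂₀,θ̂₀)] ~ χ²(1)`); BH correction across
  events; calls at `FDR < 0.05`, `|ΔPSI| > 0.1`, `TPM > 1`; direction
  summaries; DE/AS set overlap with Fisher's exact test.
* **Binding enrichment** — strand-aware exon windows (5 kb / 1 kb), the
  bound-proportion ratio of a foreground exon set over a background with
  Fisher's exact p, and upstream/downstream flank occupancy
  (`directionalOccupancy`), plus generic hypergeometric gene-set enrichment.
* **Signal metaplots** — mean signal in 50-bp bins over ±2.5 kb around exon
  centers (101 bins), per-bin Wilcoxon rank-sum comparisons with BH across
  bins; operational paused-site calling at signal maxima.
* **Motif enrichment** — MEME-format PWMs, sense-strand log-odds scanning at
  0.8 of the maximum attainable score, window-level Fisher enrichment and
  density ratios over 10-kb exon flanks; cross-dataset motif intersection.
* **Screen scoring** — ΔCt relative quantities, PSI fold changes normalized
  to the negative control, per-readout z-scores, and the dual-readout hit
  rule (both z-scores above the positive control and z₅+z₂₁ > 2).
* **Methylation** — per-CpG beta values `m/(m+u)` and a paired-by-CpG
  two-condition comparison.
* **Synthetic data** — `simulateAnnotation`, `simulateJunctionCounts`,
  `simulatePeaks`, `simulateSignalTrack`, `simulateScreenPlate`,
  `simulateMethylationCounts`, `simulateMotifWindows`, all bit-reproducible
  under a seed, with ground-truth tables; `writeSimulation()` emits FASTA,
  GTF, BED, bedGraph and TSV files.

## Worked example

Simulate a 300-gene study (100 true events, mutant−control |ΔPSI| = 0.3,
2 vs 3 replicates), call differential events, and ask whether planted
chromatin-factor peaks are enriched near the excluded exons:

```r
library(splicechrom)

cfg <- simConfig(seed = 42, n_genes = 300, n_true_events = 100,
                 genome_len = 9e6, read_depth = 150, dispersion = 0)
ann <- simulateAnnotation(cfg, sequence = FALSE)
sim <- simulateJunctionCounts(cfg, ann)

events <- callEvents(testSplicing(sim$counts, sim$expression))
summarizeDirection(events)
head(subset(events, called), 3)
#>   event_id gene_id psi_control psi_mutant delta_psi      fdr          direction
#> 5  EV00005  G00005       0.553      0.230    -0.323 6.16e-19 excluded-in-mutant
#> 7  EV00007  G00007       0.743      0.388    -0.355 1.44e-17 excluded-in-mutant
#> 9  EV00009  G00009       0.333      0.599     0.266 1.59e-11 included-in-mutant

peaks <- simulatePeaks(ann, sim$truth, cfg)
fg <- annotationEvents(ann)[sim$truth$true_event & sim$truth$delta_psi > 0]
enrichmentVsBackground(fg, annotationExons(ann), peaks$peaks, window_bp = 5000)
#> BindingComparison (window 5000 bp, fisher test)
#>   foreground: 17/57 bound (29.8%)
#>   background: 79/900 bound (8.8%)
#>   ratio = 3.4, odds ratio = 4.42, p = 1.32e-05
```

Ninety of the 300 events are called (54% included-in-mutant), and the
excluded exons carry a nearby peak 3.4× as often as the exon universe —
the generator planted peaks downstream of excluded exons, and the
enrichment statistics recover that construction.

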