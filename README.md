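# priism

Frequency-domain decomposition of diel gene-expression time courses.

## The problem

In time-series transcriptomics experiments run under light/dark cycles, a
gene's measured expression pattern mixes three influences: the adaptive
response to the applied treatment (a slow trend), the circadian clock (an
oscillation near one cycle per day, which the treatment itself may damp,
phase-shift or slow down), and high-frequency noise. Ranking genes by raw
fold change between treatment and control confounds all three, so
clock-gated genes masquerade as treatment responders and vice versa.

`priism` separates the three influences per gene by recomposing the signal
in the frequency domain. For each overlapping time frame, a gene's series
g(kT) (K samples at interval T) is mean-shifted and transformed,

    G_n = sum_{k=0}^{K-1} g(kT) e^(-i 2*pi*n*k/N),   n = 0, ..., N-1,

with bin n at frequency f_n = n/(NT). The **clock band** [c_min, c_max] is
located from the data themselves: every frequency bin whose relative
amplitude exceeds 0.7 in the spectrum of a core circadian clock gene
(CCA1, LHY, PRR7, PRR9, ELF4, GI, LUX, TOC1 by default) is "dominant", and
the union of the eight dominant sets bounds the band. Within the band, the
summed clock-gene power per bin, min–max normalised,

    w_n = (sum_m |G_mn|^2 - min) / (max - min),

defines a tapering band-pass filter. Each gene's spectrum is then split
into three mirror-closed, disjoint bands — treatment [0, c_min-1] (ideal
low-pass), clock [c_min, c_max] (tapered by w_n), noise (the remainder,
ideal high-pass) — inverse-transformed, and the removed mean is added back
to each component in proportion to its band's share of the original
spectrum's power. Per-frame components are finally blended across
overlapping frames with triangular weights. The three reconstructed series
sum to the original exactly.

The package also implements the downstream evaluation (per-timepoint fold
change, maximum-FC / fixed-timepoint / PCA-corner-distance rankings, ROC
walks with recall at the TP = FP point, Z-test p-values) and a synthetic
diel-expression generator with known ground truth, so the whole pipeline
is testable without external data.

## Worked example

```r
library(priism)

sim <- simulate_expression(sim_config(seed = 1))   # 200 genes, 30 responders
res <- priism(sim$control, sim$treatment)

res$frames
#> <frame_set> 4 frames on 30 grid timepoints
#>   frame 1: [0, 26] h
#>   frame 2: [10, 34] h
#>   frame 3: [26, 50] h
#>   frame 4: [34, 58] h

res$clock_vectors$control[[2]]
#> <clock_vector> control frame 2: bins 1..1 (0.92..0.92 cycles/day), weights 1
```

The 58-hour course is segmented into a 26-h first frame plus three 24-h
frames aligned to light/dark transitions (16 h light : 8 h dark, first
sample at ZT14). In each frame the clock genes pin the clock band to the
~1 cycle/day bin. Ranking genes by the treatment-frequency fold change at
the 26-h response peak recovers the planted responders:

```r
fc_t <- fold_change(res$components$control$treatment,
                    res$components$treatment$treatment)
rl <- rank_genes(fc_t, "fc_at_time", at_time_h = 26)
head(as.data.frame(rl), 3)
#>    gene_id statistic
#> 1 RESP_018 1.1512536
#> 2 RESP_016 1.0248505
#> 3 RESP_009 1.0192319

roc(rl, sim$truth$responders)
#> <roc_result> 200 ranked genes, 30 gold; recall at TP=FP: 1.000

zt <- ztest_pvalues(rl)
sum(zt$significant)                                    # 23 genes at p <= 0.05
all(zt$gene_id[zt$significant] %in% sim$truth$responders)  # TRUE
```

All 30 planted responders are recovered before the ranking's cumulative
true positives fall to the false-positive count, and every gene flagged by
the one-sided Z-test (23 of 200) is a true responder. A command-line
wrapper for the same steps is in `inst/cli/priism.R`
(`simulate` / `decompose` / `evaluate` subcommands).

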