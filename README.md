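# dielBFC

Screening, Bayesian Fourier Clustering and rhythmicity scoring for
light/dark-entrained (diel) transcriptome time courses.

## What it is for

Diel experiments sample a culture entrained to a 12:12 light/dark cycle every
3 hours over one day (with a duplicated dawn point) in three biological time
courses, giving a genes × 27-samples matrix of normalized log2 expression.
The analytical questions are: which genes are expressed and differentially
expressed over the cycle, which genes share a common expression waveform, and
which of those shared waveforms are genuinely diurnal — and peaking when?

dielBFC answers them in three stages:

1. **Screening** — a missingness filter (genes missing on >70% of samples are
   dropped), a detection filter (linear signal ≥ 2.6× the per-sample
   background in at least one sample), a per-gene two-way ANOVA
   (time-of-day + kinetic, raw *P* < 10⁻³ on the time effect) and a PCA
   dispersion criterion (largest squared projection on the first two
   principal axes).
2. **Bayesian Fourier Clustering (BFC)** — each cluster of genes is modelled
   by one conjugate Bayesian linear model *Y = Bβ + ε*, where *B* is a
   Fourier basis over the concatenated 72-h time axis containing the constant
   term plus cosine/sine pairs for harmonics {1, 3, 6, 9} (9 coefficients),
   *β | σ² ~ N(m₀, σ²v₀I)* and *σ² ~ InvGamma(a₀, b₀)*. The marginal
   likelihood (evidence) of any cluster is closed-form; clustering is a
   greedy agglomeration from singletons that at each step applies the merge
   with the largest evidence gain and returns the best-scoring partition on
   the trajectory.
3. **Rhythm scoring** — each cluster's third harmonic ratio,
   THR = (a₃² + b₃²) / Σᵢ(aᵢ² + bᵢ²) over the included harmonics, measures
   the fraction of fitted harmonic power in the 24-h (diurnal) component;
   clusters with THR > 0.4 are rhythmic and THR > 0.6 robustly rhythmic, and
   the peak phase (24/2π)·atan2(b₃, a₃) mod 24 places each cluster on a polar
   clock plot.

A synthetic-data generator (`simulateDielData()`) reproduces the design —
rhythmic clusters with chosen phases and peak-to-trough amplitudes,
arrhythmic genes, unexpressed genes below the detection limit, noise and
missing values, with per-gene ground truth — so the full pipeline is testable
without any external data. See `vignette("diel-bfc-methods")` for the model,
its assumptions and limitations.

## A worked example

```r
library(dielBFC)

de  <- simulateDielData(seed = 1)   # default study design: 160 genes, 27 samples
cfg <- pipelineConfig(outputDir = "dielbfc_out", seed = 1)
res <- runPipeline(cfg, de)

unlist(res$counts)
#>            genes_in dropped_missingness           expressed      anova_selected
#>                 160                   0                 140                 120
#>        pca_selected            clusters   rhythmic_clusters     robust_clusters
#>                  36                   2                   2                   2

res$rhythm
#>  cluster_id size       thr  phase_h rhythm_class  pool
#>  pool1_c001   16 0.9998221 15.98015       robust pool1
#>  pool1_c002   20 0.9999450 19.99856       robust pool1
```

Reading the output: of 160 simulated genes, the 20 sub-detection genes fail
the 2.6× background filter (140 expressed) and the 20 arrhythmic genes fail
the ANOVA cut (120 selected — exactly the rhythmic truth); PCA keeps the 36
highest-dispersion genes, which the clustering splits into two clusters whose
THR ≈ 1 says essentially all fitted power is diurnal, peaking at ~16 h and
~20 h — the planted phases of the two highest-amplitude clusters. All
tabular artifacts (screen results, amplitude histogram, cluster assignments,
merge trajectory, rhythm and polar summaries, run log) are written to
`outputDir`, plus a polar clock plot (SVG).

A thin command-line driver with subcommands
`simulate | validate | screen | cluster | rhythm | run` is installed at
`inst/scripts/dielbfc.R`.

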