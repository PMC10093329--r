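# plinet — Phase Lag Index functional brain networks from resting-state EEG

`plinet` builds and compares weighted functional brain networks from
multichannel resting-state EEG. It was written for studies that ask whether
two groups of subjects — for example patients with high versus low anxiety
severity — differ in how their brain regions phase-couple, using the
standard 16-electrode 10–20 montage (FP1, FP2, F3, F4, C3, C4, P3, P4, O1,
O2, F7, F8, T3, T4, T5, T6).

## The method

1. **Preprocessing.** Recordings are decimated from 250 Hz to 125 Hz,
   band-pass filtered 4–30 Hz with a zero-phase 4th-order Butterworth
   filter, cut into 4 s epochs with 50 % overlap, and separated into the
   theta (4–8 Hz), alpha1 (8–10 Hz), alpha2 (10–13 Hz) and beta (13–30 Hz)
   rhythms with the same filter design.

2. **Connectivity.** For each epoch and rhythm, every channel's
   instantaneous phase φ(t) is the argument of its analytic signal
   x(t) + i·H[x](t). For each of the 120 channel pairs the Phase Lag Index

   PLI = | ⟨ sign Δφ(t) ⟩ |,   Δφ wrapped to (−π, π],

   measures the asymmetry of the phase-difference distribution: 0 for a
   symmetric or zero-lag relation (so volume conduction is discounted by
   construction), 1 for a consistently one-sided lag.

3. **Networks.** Each 16×16 PLI matrix is proportionally thresholded at
   densities 25 %–35 % in 1 % steps (11 networks), keeping the largest
   weights. Per network the package computes the strength-normalised
   weighted clustering coefficient C<sup>w</sup> (Barrat form), the
   weighted characteristic path length L<sup>w</sup> on edge lengths
   1/w, and the small-world index

   σ = (C<sup>w</sup>/C<sup>w</sup><sub>rand</sub>) /
   (L<sup>w</sup>/L<sup>w</sup><sub>rand</sub>),

   where the random baselines are means over Maslov–Sneppen
   degree-preserving surrogates (default 50 surrogates, 10 double-edge
   swaps per edge, weights travelling with edges). Metrics are averaged
   over the 11-threshold sweep.

4. **Group statistics.** Edgewise (per PLI edge) and metric-wise
   (C<sup>w</sup>, L<sup>w</sup>, σ) one-way ANOVAs compare the two
   groups per rhythm at α = 0.05 (uncorrected by default;
   Benjamini–Hochberg behind a flag), plus a frontal-involvement summary
   of the significant edges.

Because clinical EEG of this kind is rarely shareable, the package ships a
seeded synthetic-cohort generator (`cohortSpec()`, `generateCohort()`)
with narrowband carriers, controllable pairwise phase-lag coupling (von
Mises jitter), and planted group differences, so every stage can be
validated against known ground truth.

## Worked example

A small synthetic cohort with the default planted scenario (the HGAD-like
group has stronger alpha2 frontal coupling and weaker theta/alpha1
coupling than the LGAD-like group):

```r
library(plinet)

spec <- cohortSpec(nSubjectsPerGroup = 4, durationSeconds = 60,
                   samplingRate = 250, masterSeed = 42)
cfg <- defaultConfig(cohort = spec, masterSeed = 42L)
cfg$unit <- "subject"      # subject-mean PLI matrices as ANOVA units
cfg$nSurrogates <- 20L
res <- runPipeline(cfg, "demo-output")

for (b in names(res$results)) {
  f <- res$results[[b]]$frontal
  cat(sprintf("%-7s significant edges: %3d   frontal ratio: %d/%d   higher in HGAD: %d\n",
      b, f$n_significant_edges, f$n_frontal_related, f$n_significant_edges,
      f$n_increased_in_HGAD))
}
```

```
theta   significant edges:  31   frontal ratio: 28/31   higher in HGAD: 4
alpha1  significant edges:  20   frontal ratio: 19/20   higher in HGAD: 0
alpha2  significant edges:  24   frontal ratio: 22/24   higher in HGAD: 22
beta    significant edges:   5   frontal ratio: 3/5   higher in HGAD: 4
```

The planted pattern is recovered: significant edges concentrate on the
frontal electrodes in the coupled rhythms; almost all significant alpha2
edges are *higher* in the HGAD-like group while theta/alpha1 differences
run the other way; the uncoupled beta band shows only a handful of edges,
consistent with the false-positive rate of 120 uncorrected tests.

```r
print(metricResults(res$results$alpha2$metricComparison), digits = 3)
```

```
  metric     F       p mean_HGAD mean_LGAD significant
1     Cw  1.56 0.25846     0.458     0.405       FALSE
2     Lw 35.30 0.00102     4.096     3.519        TRUE
3  sigma  5.42 0.05881     1.336     1.110       FALSE
```

Stronger, more clustered alpha2 coupling lengthens the weighted paths of
the HGAD-like networks (larger L<sup>w</sup> = lower integration), here
significant at n = 4 subjects per group; C<sup>w</sup> and σ move in the
expected direction without reaching significance at this sample size.

Per-band output directories contain `edge_table.tsv` (120 ANOVA rows),
`metrics.tsv`, `metric_comparison.tsv`, `frontal_summary.tsv` and the
group-mean PLI matrices; `run_log.json` records the config echo, seeds and
per-stage counts. A thin CLI over the same functions is installed at
`inst/scripts/plinet-run.R`.

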