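---
title: "Phase-lag brain networks: models, choices and limits"
author: "plinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-lag brain networks: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the science inside `plinet`: the estimators it
implements, the assumptions they rest on, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical decisions that shape edge cases. It states no empirical
result beyond what the package's own tests and acceptance script compute.

## The pipeline and its assumptions

The package analyses resting-state EEG as a sequence of five stages:
preprocessing, phase estimation, Phase Lag Index (PLI) connectivity,
thresholded weighted-network metrics, and two-group statistics.

**Preprocessing.** Recordings at 250 Hz are decimated to 125 Hz, band-pass
filtered to 4–30 Hz, segmented into 4 s epochs with 50 % overlap, and each
epoch is filtered again into the four classical rhythms (theta 4–8,
alpha1 8–10, alpha2 10–13, beta 13–30 Hz). All filters are Butterworth
designs of order 4 applied forward and backward (`signal::filtfilt`).
Zero-phase application matters here more than in amplitude analyses:
a causal filter adds a frequency-dependent phase lag to every channel, and
although a common lag cancels in the phase *difference* of two channels at
the same frequency, band-edge group-delay effects do not cancel exactly
once signals have finite bandwidth. Forward–backward filtering removes the
issue entirely, at the cost of an effective magnitude response that is the
square of the design order — the `order` parameter names the underlying
design, as is conventional in EEG work.

Decimation keeps every second sample. The 4–30 Hz band limit acts as the
anti-alias guard for the 62.5 Hz target Nyquist, so no separate anti-alias
filter is applied. Trailing partial windows are discarded rather than
padded: padding would fabricate data exactly where the analytic-signal
phase estimate is least reliable.

Two orderings are defensible for segmentation and rhythm separation:
epoch first and band-filter each epoch, or band-filter the continuous
recording and then epoch. The default epochs first; the alternative is one
config switch away (`rhythmBeforeSegment`, and `phaseOnRecording` for
phase estimation on the continuous recording). The orderings agree to
within filter edge effects, and the package's tests check that both run
and correlate strongly.

**Phase and PLI.** Instantaneous phase is the argument of the analytic
signal, computed by zeroing negative DFT frequencies. This is meaningful
only for narrowband signals — which is why rhythm separation precedes it.
For channels *i*, *j* the PLI is

> PLI = | mean over t of sign(Δφ(t)) |, Δφ wrapped to (−π, π],

the absolute time-average of the sign of the wrapped phase difference.
PLI is invariant to channel amplitude, symmetric in its arguments, and —
its defining virtue — blind to zero-lag coupling, the signature of volume
conduction (one source mixing instantaneously into several electrodes).
`sign(0)` contributes 0, so identical signals give exactly 0.

Two practical choices:

* **Edge trimming.** The analytic signal is unreliable near window edges;
  10 % of samples are trimmed from each end of every phase-difference
  series before averaging (configurable, `edgeTrimFraction`).
* **Finite-sample bias.** For independent narrowband channels the PLI does
  not converge to 0 at a 4 s epoch: an 8–10 Hz band leaves on the order of
  ten independent sign samples per epoch, so the null expectation of
  |mean sign| is roughly sqrt(2/(π·n_eff)) ≈ 0.2–0.4, not 0. The package
  treats this as a property of the estimator, not a defect: group
  comparisons contrast like with like, and the test suite asserts the bias
  explicitly (it shrinks as epochs lengthen). Users comparing PLI levels
  across epoch lengths or bandwidths should not interpret raw magnitudes
  as coupling strengths.

**Networks.** Each 16×16 PLI matrix is proportionally thresholded:
the k = round(f·120) largest weights are kept (round half up; ties broken
by lexicographic electrode order for determinism), for f = 0.25…0.35 in
0.01 steps — 11 networks of 30…42 edges. Proportional thresholds equalise
density across subjects and groups so that metric differences reflect
topology and weights, not edge counts. Isolated nodes are *reported*, not
repaired: the threshold range is meant to be chosen so none arise, and the
package verifies rather than enforces that.

Per network:

* **Weighted clustering** (strength-normalised, Barrat form):
  C<sup>w</sup><sub>i</sub> = [Σ over ordered neighbour pairs (j,h) with
  j–h closed of (w<sub>ij</sub>+w<sub>ih</sub>)/2] / [S<sub>i</sub>(k<sub>i</sub>−1)],
  which lies in [0, 1] and reduces to the binary clustering coefficient
  when all weights are equal. Nodes of degree < 2, where the normalisation
  is undefined, receive 0 and still enter the network mean over all N
  nodes.
* **Weighted path length**: Dijkstra shortest paths on edge lengths
  1/w (`igraph::distances`), averaged over node pairs. If a pair is
  unreachable, the mean is taken over reachable pairs and the result
  carries a disconnection flag with the unreachable-pair count — keeping
  σ computable while the anomaly stays visible, instead of silently
  returning infinity or switching to a harmonic mean.
* **Small-world σ** = (C<sup>w</sup>/C<sup>w</sup><sub>rand</sub>) /
  (L<sup>w</sup>/L<sup>w</sup><sub>rand</sub>), with random baselines
  averaged over Maslov–Sneppen surrogates: repeated double-edge swaps
  (a–b, c–d) → (a–d, c–b) that reject self-loops and duplicates, so node
  count, edge count, every degree, and the weight multiset are conserved
  (weights travel with their edges). Defaults: 50 surrogates, 10
  successful swaps per edge, an attempt budget of 100× the swap target; a
  graph admitting no valid swap (e.g. a complete graph) is returned
  unchanged with a warning flag, which makes σ = 1 exactly — the correct
  degenerate answer. All surrogate randomness flows from one explicit
  seed through a fixed affine child-seed scheme (`childSeed`), so every
  result is bit-reproducible. Surrogates are generated per thresholded
  network, not shared across thresholds. Metrics are averaged over the
  11-threshold sweep; the per-threshold table is kept alongside the
  summary, including both small-world inequalities
  (C<sup>w</sup> ≫ C<sup>w</sup><sub>rand</sub>,
  L<sup>w</sup> ≥ L<sup>w</sup><sub>rand</sub>) implicit in σ.

**Group statistics.** One-way fixed-effects ANOVA per edge (120 tests per
rhythm) and per metric, via `stats::oneway.test(var.equal = TRUE)`; for
two groups F is the squared pooled-variance t. Significance is uncorrected
p < 0.05 by default, mirroring common practice in this literature;
Benjamini–Hochberg is one flag away (`adjust = "BH"`) because 120
uncorrected tests inflate the family-wise error — fidelity first, rigor
opt-in. Directions come from group sample means. The frontal summary
counts a significant edge as frontal-related iff at least one endpoint is
in {FP1, FP2, F3, F4, F7, F8}.

**Unit of analysis.** Whether epochs or subjects are the exchangeable
units is genuinely consequential. Epochs within a subject are temporally
correlated (50 % overlap, slow phase drift), so epoch-level ANOVA with few
subjects can reject far above its nominal level — the package's own
calibration experiments measure this directly. Subject-level means are the
statistically safe default for inference with small cohorts; epoch-level
analysis maximises sample counts when many subjects are available. Both
are supported (`unit = "epoch"` or `"subject"`), the choice is logged in
every output, and the package's statistical-calibration tests are run in
the subject-level (iid) regime where the F test's nominal level applies.

## The synthetic-data generator

`cohortSpec()` describes a two-group cohort; `generateSubject()` and
`generateCohort()` realise it deterministically from a master seed. Each
channel is a sum of per-rhythm narrowband oscillations plus white noise.
A carrier's instantaneous frequency is the band centre plus a slow
mean-reverting AR(1) deviation (stationary sd `driftSd`, 2 s relaxation,
smoothly saturated at 80 % of the band half-width) — slow enough that the
signal stays locally narrowband, mean-reverting so that two independent
carriers never pin to a common frequency. Pure-sinusoid mode
(`driftSd = 0`) is retained for analytic tests.

Coupling is planted per band as directed edges (source, target, lag,
concentration): the target channel's phase in that band equals the
source's plus the lag plus von Mises jitter of concentration κ, held
constant over 0.25 s blocks. Blockwise jitter keeps both channels locally
narrowband (so Hilbert phase tracks the planted phase faithfully) while
the marginal jitter law is exactly von Mises, giving a closed-form
expected PLI = |2·P(Δφ ∈ (0, π)) − 1| that the tests verify against
numerical integration of the von Mises density. κ sweeps expected PLI
from ~0 (uniform jitter) to 1 (perfect locking); a zero lag is invisible
to PLI however strong the coupling, which is the volume-conduction
robustness claim made testable.

Defaults mirror the clinical study the pipeline emulates: 30 LGAD-like
and 21 HGAD-like subjects at 250 Hz, 444 s per subject (≈ 220 epochs, so
cohort epoch counts land near the thousands reported in such studies),
and a planted scenario in which the HGAD-like group has *stronger* alpha2
frontal coupling (κ = 3 vs 0.5 on three frontal edges) and *weaker*
theta/alpha1 coupling than the LGAD-like group — reproducing the sign
pattern, not the magnitudes, of the severity effect. Tests and the
acceptance script use smaller cohorts chosen for statistical validity at
desk scale: the null-calibration experiment uses 17 independent cohorts of
10 subjects per group × 12 s (2040 edgewise tests on subject-level means);
the planted-recovery experiment uses 4 subjects per group × 40 s; the
determinism experiment 2 subjects per group × 16 s with 2 surrogates.

What the generator does **not** emulate: head geometry and lead fields,
ocular/cardiac/muscle artifacts (the artifact-removal stage is therefore a
pass-through hook), 1/f background spectra, non-stationary band power, and
subject-level covariates. Passing tests therefore show that the estimators
and statistics behave correctly on signals with known phase structure —
not that the pipeline is robust to real-world recording pathology.

## Numerical choices and degenerate inputs

* Wrapping convention (−π, π]; phase differences are computed as the
  argument of e^{i(φ₁−φ₂)} — no unwrapping is needed for PLI.
* `sign(0) → 0`: identical signals give PLI exactly 0; exact zeros are
  measure-zero for real data but common in tests.
* Edge-count rounding is round-half-up; the 11 default densities give
  30, 31, 32, 34, 35, 36, 37, 38, 40, 41, 42 edges (33 and 39 never
  occur at N = 16).
* Zero-weight edges that would survive a very high threshold are dropped
  with a warning, preserving the positive-weight invariant.
* All-zero signals, constant channels, montage mismatches and
  out-of-Nyquist bands fail fast with messages naming the offending
  channel or field; config validation collects all violations instead of
  stopping at the first.
* Filtering then decimating by 2 agrees with decimating then filtering
  only to the sub-percent level, not machine precision: Butterworth
  designs at different rates differ through bilinear-transform frequency
  warping. The property test asserts < 1 % relative RMS on in-band tones.
* YAML configs are written with 17 significant digits so that irrational
  lags (e.g. π/3) round-trip bit-exactly and a round-tripped config
  regenerates an identical cohort.

## Known limitations

PLI's finite-sample bias makes raw values incomparable across epoch
lengths and bandwidths; only like-for-like contrasts are meaningful. The
uncorrected 120-test default trades family-wise error control for
comparability with the literature. Sensor-space PLI, even though it
discounts zero-lag mixing, does not localise sources. The σ index depends
on the surrogate ensemble; with 50 surrogates its sampling error is small
but not zero, and the per-threshold table should be consulted when σ sits
near 1. Disconnected thresholded networks are flagged, not repaired;
metric means over reachable pairs are not comparable with fully connected
networks' means.
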