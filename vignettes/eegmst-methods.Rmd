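---
title: "Phase-lag networks and spanning-tree topology: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-lag networks and spanning-tree topology: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`eegmst` implements a sensor-space EEG connectivity pipeline for developmental
reading studies: multichannel trial data are decomposed into seven frequency
bands, pairwise coupling is estimated with the weighted phase lag index
(wPLI), each trial's connectivity matrix is reduced to its strongest-coupling
spanning tree, tree topology is summarized by four global and two local
measures, and subgroups (e.g. dyslexic vs control readers, boys vs girls) are
compared with non-parametric tests. Because clinical child EEG recordings are
rarely shareable, the package also contains a first-class synthetic-cohort
generator so that every stage — and every statistical guarantee — can be
tested end to end.

## The estimator chain

### Preprocessing

Recordings (40 channels, 250 Hz) are notch-filtered at 50 Hz, band-passed to
1–70 Hz, and decomposed into δ (1.5–4 Hz), θ (4–8), α (8–13), β1 (13–20),
β2 (20–30), γ1 (30–48) and γ2 (52–70 Hz). All filters are forward–backward
(zero-phase) Butterworth, 4th order per pass for the band-passes and 2nd
order for the notch. Zero-phase filtering matters here: the connectivity
statistic downstream is a pure phase statistic, and a causal filter would add
frequency-dependent phase shifts to every channel. γ2 starts above the notch
(52 Hz) so the mains line never sits inside an analysis band; the notch is
nevertheless applied before every band for uniformity.

Trials are 800 ms windows cut at stimulus onset (200 samples at 250 Hz).
A trial is rejected when any sample on any channel strictly exceeds
±200 µV — the boundary itself is retained, since the rule is "above"
threshold. Rejection only flags metadata; sample data are never modified.
Signal quality is summarized per channel as `SNR = A / (2 · SD_noise)`,
where `A` is the peak-to-peak amplitude of the mean event-related potential
and `SD_noise` the standard deviation of the pooled per-trial residuals
after subtracting that mean. Whether SNR should be pooled across channels is
not standardized; we compute it per channel and summarize a subject by the
median channel, with the acceptance threshold (`snr_min`, default 1) left as
a configuration parameter because "good SNR" has no universal value. Only
retained, behaviorally correct trials with adequate SNR enter the analysis.

### Connectivity

For band-limited signals `x_i`, the analytic representation `z_i` (Hilbert
transform) defines the per-sample cross-spectral term
`X_ij(t) = z_i(t) · conj(z_j(t))`, and

wPLI_ij = | mean_t Im X_ij(t) | / mean_t | Im X_ij(t) |.

The imaginary part of the cross-spectrum ignores zero-lag (volume-conduction
-like) coupling by construction; the magnitude weighting down-weights samples
whose phase difference is near 0 or π, where noise can flip the sign. Pairs
with identically zero `Im X` (e.g. duplicated channels) are assigned 0 by the
0/0 convention. The unweighted PLI — the sign asymmetry of the phase
difference distribution — is available behind `method = "pli"` for
comparison, but the pipeline's statistic is wPLI.

Band-pass filtering is applied to the *continuous* recording before epochs
are re-cut, so the narrow low bands are estimated without epoch-edge
distortion (an 800 ms δ epoch holds barely one cycle; filtering it directly
would be dominated by transients). Matrices are sanitized before graph
analysis: diagonal zeroed, negative entries zeroed, symmetrized.

### Spanning-tree reduction

Thresholding weighted brain networks biases comparisons through density
differences; the spanning tree avoids that by fixing both the number of
nodes (40) and edges (39). We keep the *strongest* couplings: the minimum
spanning tree of wiring cost `1 − wPLI`, equivalently the maximum-similarity
spanning tree. Kruskal's algorithm with lexicographic `(i, j)` tie-breaking
makes the tree deterministic, including for tied weights; no randomness is
involved anywhere in the tree stage.

Global measures per tree: diameter `D` (longest path in links, normalized by
the `n − 1` links), leaf fraction `LF` (degree-1 nodes over nodes — the
literal reading of the defining text; the links denominator is available via
`leaf_denominator = "links"` since usage in the literature varies), tree
hierarchy `TH = L / (2 · M · BC_max)` with `M = n − 1` links, and degree
divergence `K = ⟨k²⟩/⟨k⟩`. `TH` is undefined for `n = 2` (`BC_max = 0`) and
flagged rather than forced. Betweenness centrality uses ordered-pair
counting normalized by `(n − 1)(n − 2)`, so `BC ∈ [0, 1]` with 1 attained by
a star center. Hubs are nodes whose degree or BC is at least one (population)
standard deviation above the across-node mean; with zero dispersion there
are no hubs. The analogous mean + 1 SD rule defines "strong" edges of a
weight matrix. The weighted degree (sum of incident wPLI weights) is carried
as an auxiliary column but never used for hub decisions.

### Per-trial versus trial-averaged topology

Global measures are computed **per trial** — one tree per non-rejected
realization — and averaged per subject afterwards (metrics are averaged,
never trees). For the *local* measures the package deliberately deviates:
hub maps and the per-channel inputs of the cluster test come from the MST of
each subject's **trial-averaged** wPLI matrix. The reason is statistical,
not cosmetic. An 800 ms θ epoch contains roughly `bandwidth × duration ≈ 3`
independent phase samples, so the per-trial wPLI of two *independent*
channels has median ≈ 0.55 and reaches 1.0 in a few percent of trials; and
within any component driven by a shared oscillation, all pairwise phase
relations are locked, so all within-component edges saturate together. A
single trial's tree is therefore largely noise at the level of *which*
specific node carries the hub, even when the planted coupling is strong —
its identity is decided by tie-breaking among saturated edges. Averaging
matrices over trials washes this sampling noise out (the independence floor
concentrates around its mean while truly coupled pairs stay near 1), making
hub identity a property of the coupling structure rather than of the tie
order. Global topology, by contrast, is meaningful per trial because it
aggregates all 39 edges.

## Statistics

Behavioral measures use Kruskal–Wallis (rank-based H with tie correction,
χ² reference). Global tree measures use a two-sided permutation test:
observed statistic = difference of subgroup means of subject-level
(trial-averaged) values; null = 1000 random relabelings by default; p-value
with the add-one convention, so the resolution is `1/(n_perm + 1)`.
"Bootstrap" resampling with replacement is available behind a flag, but
label permutation is the default since exchangeability is the natural null
for a two-group comparison. Four global measures are tested per band, so the
Bonferroni threshold is α/4 = 0.0125; the two local criteria (degree, BC)
give α/2 = 0.025 for the cluster tests.

The cluster-based permutation test controls the family-wise error over
channels: channel-wise two-sample rank-sum z statistics are thresholded at
an uncorrected two-sided p < 0.05, suprathreshold channels of equal sign are
merged into spatially contiguous clusters under the montage neighbor
relation, cluster mass is the sum of |z|, and each observed cluster is
referred to the permutation distribution of the *maximum* cluster mass.
Clusters are ranked by mass; hemisphere membership is reported
descriptively. Spatial adjacency is defined by angular distance on the unit
sphere (default 0.72 rad, giving 4–8 neighbors per sensor) — a Delaunay
triangulation of the 2-D projection was considered, but the distance rule is
simpler, has no degenerate cases at the layout's border, and is exposed as a
single interpretable parameter.

All permutation procedures are deterministic given `(data, seed, n_perm)`,
and the suite verifies super-uniformity of null p-values, monotone power in
effect size, type-I calibration of the global test and family-wise control
of the cluster test by simulation.

The interindividual variation report compares every pair of subjects within
(or between) subgroups on their trial-level network measure, stratifies
pairs by reaction-time similarity (rank-sum p ≥ 0.05 versus p < 0.05), and
tallies the fraction of significantly differing pairs per stratum —
reproducing the structure of individual-variability analyses in
developmental cohorts.

## The synthetic cohort

The generator emulates the study conditions the pipeline targets: four
subgroups (control/DD × boy/girl) of 12 subjects, blocks of 40 word trials,
800 ms post-stimulus epochs at 250 Hz, inter-stimulus intervals uniform in
1.5–2.5 s, and the seven analysis bands.

**Signal model.** Each channel is a sum of per-band narrowband Gaussian
processes (synthesized spectrally with a squared 2nd-order Butterworth
magnitude profile) with per-band RMS amplitudes of 6/5/5/3/2/1.5/1 µV from
δ to γ2 — a 1/f-like profile typical of child EEG — plus white measurement
noise (2 µV SD). Coupling is planted per band through shared narrowband
drivers: each connected component of the coupling graph receives one driver;
the component's source node (highest coupling degree) carries it at lag 0
and every other member receives a copy rotated by the coupling lag (default
π/2 — zero-lag coupling would be invisible to wPLI by construction). A node
with maximal incident coupling `c` mixes the driver at amplitude `√c` with
its own background at `√(1 − c)`, so expected wPLI on source–member edges
rises monotonically with `c`. A consequence worth knowing: two *members* of
the same component share the driver at equal lag, so their mutual wPLI is
*low* (zero-lag blindness) — a planted star yields high hub–leaf and low
leaf–leaf coupling, which is exactly the topology the tree stage should
recover.

**Default planted networks.** All subgroups share a left-frontal
reading-network star (hub F3, leaves AF3/F7/FC5/Fz/FC3/C3, c = 0.45) in θ;
DD girls additionally carry a stronger posterior θ star (hub Pz, nine
parieto-occipital leaves, c = 0.9). The posterior coupling strength was set
by calibrating against the estimator's independence floor: with ~3
independent phase samples per epoch the floor's upper tail reaches ≈ 0.98,
so a planted edge must sit essentially at saturation to dominate
consistently; c = 0.9 yields a subject-level leaf-fraction effect of
Cohen's d ≈ 2.8 between DD girls and DD boys, while c = 0.7 gives d ≈ 0.75,
too weak to call a designed-in effect. These defaults are the package's
fixed study conditions, not tuning knobs.

**Behavior.** Vocal reaction times and reading durations are log-normal
(right-skewed, strictly positive), moment-matched to group means and
standard deviations of 1093.8 ± 95.4 ms (DD) and 865.48 ± 69.7 ms (control)
for vRT — the SDs recovered from published standard errors at n = 24 — with
a small multiplicative subject effect (CV 5%) so that subjects are
distinguishable in the variation report. Success is a per-trial Bernoulli
draw (70.7% DD, 99.3% control); omitted words are the incorrect trials.
Both sexes within a group share behavioral parameters. The subject effect
inflates the mean by < 0.15%, well inside all tolerances.

**Artifacts.** A fraction `artifact_rate` of trials receives a 300 µV,
100 ms square pulse on a random channel at a random position inside the
epoch window. Any suprathreshold excursion exercises the rejection rule;
no attempt is made to mimic blink morphology, volume conduction, or scalp
topography — passing tests therefore demonstrate the pipeline's estimator
properties and statistical calibration, not robustness to structured
biological artifacts.

## Numerical and interface choices

* The EDF+ writer encodes 16-bit samples at 0.1 µV resolution with the
  stimulus markers as a standard annotation track; signals outside the
  declared physical range raise an error instead of clipping silently. No
  maintained R-side EDF writer with annotation support was available, so the
  package carries a minimal, round-trip-tested implementation.
* Montage coordinates are standard 10-10 positions projected to the unit
  sphere, shipped as a plain CSV; `F9`/`F10` are accepted as aliases for
  `FT9`/`FT10`, a labelling inconsistency that occurs in practice.
* wPLI requires at least 8 samples; shorter epochs error rather than return
  a meaningless ratio.
* MST construction errors on disconnected positive-weight graphs, naming
  the components.
* Everything stochastic takes an explicit seed and restores the caller's
  RNG stream.

## Problem sizes used in validation

The packaged demo and the test/report scripts run deliberately scaled-down
cohorts chosen as the smallest sizes at which each property is stable: the
end-to-end recovery checks use two subgroups of 12 subjects (the emulated
study's subgroup size) with 12 trials each in the θ band, repeated over
seeded reruns; calibration checks use 1000 null datasets for the global
test and 200 for the cluster test at 500 permutations. The behavioral
convergence checks use cohorts of thousands of trials, where the moment
matching is tight.

## Known limitations

* Sensor space only; no source projection, no leakage correction beyond
  wPLI's zero-lag blindness.
* Per-trial wPLI on 800 ms windows of the low bands is strongly biased
  upward under independence; comparisons are therefore only valid between
  conditions estimated with identical epoch lengths and trial counts — the
  pipeline never mixes them.
* The generator's coupling model plants at most one shared driver per
  component per band; arbitrary weighted coupling graphs are represented
  only through their component structure and strongest incident coupling.
* No ocular/muscle artifact modelling; no ICA correction stage.
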