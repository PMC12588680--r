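---
title: "Methods: beta-band dynamics, burst detection and path models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta-band dynamics, burst detection and path models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betadyn)
```

# Scope and model of the data

`betadyn` analyses resting-state field potentials recorded simultaneously
from the motor cortex (MCx, epidural ECoG) and the subthalamic nucleus
(STN, depth LFP) in a longitudinal design: subjects belong to groups
(control vs. graded lesion severity), are recorded at several weeks, score
a forelimb-asymmetry behaviour test at each week, and contribute terminal
histology (TH⁺ neuron count in the substantia nigra pars compacta, striatal
dopaminergic fibre optical density). The working hypothesis encoded in the
pipeline is that β-band (13–30 Hz) power, burst dynamics and
cortico-subthalamic coupling rise with pathology and carry information
about motor impairment and neurodegeneration.

Three feature families are extracted per subject-week, then joined with the
behavioural and histological endpoints into one longitudinal feature table
that the statistics and path-model layers consume.

# Epoch selection

Analysis uses three 30-s artifact-free epochs per session. Artifact
screening, done visually in laboratory practice, is automated here as an
amplitude rule: a candidate window qualifies when no sample on any channel
deviates from the channel median by more than `artifactK` robust standard
deviations (MAD), with `artifactK = 6` by default. Candidate windows start
on a 1-s grid and the earliest qualifying non-overlapping windows win, which
makes the choice deterministic. Intervals are half-open `[start, end)` with
sample index `floor(t·fs)`, so adjacent epochs never share a sample. The
threshold is a package default, not an empirical constant; it is exposed in
the configuration precisely because visual criteria have no agreed numeric
equivalent.

# Spectral analysis

Power spectra are averages of Hanning-windowed periodograms over
non-overlapping 1-s windows (window length exactly `fs` samples, so bins
fall on integer frequencies at 1 Hz spacing). Each window is mean-removed
before tapering; no further detrending is applied because the acquisition
chain is assumed high-pass filtered (0.3 Hz hardware filter). The scale
convention compensates the taper power,
`P[k] = |FFT(w·x)|² / (N·Σw²)` (one-sided, doubled off DC/Nyquist), so the
spectrum of a stationary signal sums to its variance; the unit tests verify
this Parseval property to 5%.

Absolute spectra are normalized by the summed power over the inclusive
integer bins 5–45 and 55–95 Hz. The 46–54 Hz gap excludes the 50 Hz mains
region. Band summaries are arithmetic means over inclusive integer bins:
total β = 13–30, low β = 13–20, high β = 21–30, so the two sub-bands
partition total β (8 and 10 bins). Note that a Hann taper spreads even an
on-bin sinusoid across three bins (amplitude ratios ½ : 1 : ½), which is
why single-bin mass fractions top out near 2/3; the tests therefore check
three-bin concentration and exact agreement with a brute-force DFT oracle
rather than single-bin purity.

# Imaginary coherence

Functional MCx–STN coupling is quantified by the absolute imaginary part of
the coherency, `|Im(S_xy/√(S_xx·S_yy))|`, estimated from the same 1-s
Hanning windows pooled across the three epochs (90 windows per session),
which maximizes the estimator's degrees of freedom. The imaginary part is
insensitive to zero-lag interactions, so a scaled copy of a channel —
the volume-conduction scenario — yields exactly zero at every bin
(floating-point residue below 1e-12 is floored to zero). The taper for the
coherence windows is not prescribed anywhere authoritative; Hanning is used
for consistency with the power analysis. The absolute value is reported
because the sign of the imaginary part encodes lead/lag direction, which
the band-mean summaries do not use.

# Burst detection

Burst analysis z-scores each region's concatenated epoch samples
(population SD), removing between-subject amplitude differences. A 10-cycle
complex Morlet transform (frequency grid 1–128 Hz at 1 Hz; only the target
band's frequencies are evaluated) gives per-frequency power; averaging over
the band's integer frequencies yields one nonnegative envelope sample per
input sample. Morlet kernels have `σ_t = cycles/(2πf)` — 53 ms at 30 Hz to
76 ms at 21 Hz — are truncated at ±4σ and L2-normalized so white-noise
envelope power is comparable across frequencies.

The burst threshold is the linear-interpolation (type-7) 75th percentile of
the pooled envelope samples of one region — pooled across all subjects,
groups and weeks, the maximal reading of a "common threshold per region";
the pooling scope is configurable for sensitivity analyses. Maximal runs of
samples strictly above threshold lasting at least 100 ms (read inclusively)
become bursts; runs touching an epoch boundary are discarded rather than
truncated, which avoids downward-biased durations. Burst amplitude is the
mean of per-burst peak envelopes (peak rather than mean envelope, the usual
convention in the β-burst literature; the quantity is not standardised and
both are stored per burst). Rate is bursts per minute of analysed time, and
long-burst probability is the percentage of bursts strictly longer than
350 ms. Zero detected bursts give rate 0 and missing amplitude/long-burst
probability.

Two practical points the recovery studies make explicit:

* The percentile rule presumes that genuine bursting occupies roughly the
  top quartile of envelope power. On burst-free background ~25% of samples
  still exceed the threshold by construction, producing short noise runs;
  the rule is meaningful in the pathological, high-burst-load regime. The
  recovery fixtures therefore inject bursts at ~25% time occupancy, where
  the common threshold self-consistently lands at the burst flanks.
* Timing accuracy is limited by the wavelet smoothing scale. For
  sharp-onset (rectangular-envelope) events at amplitude 10× the background
  SD, detected boundaries stay within 50 ms of the true edges; for
  Hann-tapered events the onset itself is gradual over up to a quarter of
  the duration, so "the" edge is intrinsically ambiguous at that scale and
  boundary errors up to ~70 ms occur. The synthetic generator supports both
  envelope shapes; timing-recovery studies use the rectangular shape.

# Synthetic data generator

The generator is the package's ground-truth instrument, not a biophysical
model. Per channel it sums:

* a 1/f^γ background — white Gaussian noise shaped in the frequency domain,
  rescaled to unit SD, with exactly controllable slope (default γ = 1,
  verified to ±0.3 by periodogram regression over 5–45 Hz);
* a 50 Hz mains component (default amplitude 0.5 SD);
* Poisson burst trains per sub-band (defaults 6/min each in 13–20 and
  21–30 Hz) with gamma durations (shape 3, scale 0.1 s, clipped to
  [0.1, 2] s), truncated-normal amplitudes (mean 2 SD), uniform carrier
  frequencies within the sub-band, Hann or rectangular envelopes, and
  non-overlap enforced by resampling collisions (documented: unplaceable
  draws are dropped);
* a shared 13–30 Hz band-limited source mixed into both channels with gain
  `couplingGain` and delayed by `couplingLagMs` (default 20 ms) at STN —
  the delay guarantees genuinely imaginary (not merely real) coherence.

Defaults mirror the acquisition the pipeline expects: 256 Hz sampling and
90 s per session, i.e. exactly the three 30-s epochs that are analysed
(full sessions are longer in practice, but only the analysed epochs matter
to the pipeline and simulating them keeps cohort studies cheap; the
generator accepts any duration). Reproducibility is strict: identical
configuration and seed give bit-identical output; cohorts derive
deterministic per-subject child seeds from one root seed.

The cohort layer emulates a three-group design — control (n = 12, flat
trajectory) and two lesion severities (n = 7, n = 6) whose pathology drive
multiplier rises across weeks 2, 3, 4, 6, 8 (to 1.9 and 3.0 respectively).
Per subject-week, latent β features (power, burst amplitude, burst rate per
region) are drawn around the group trajectory (latent SD 0.15, subject
random offset SD 0.1); they scale the injected signal content (burst rate
and amplitude multipliers, extra high-β band noise for the power latent,
duration scaling with the drive so long bursts become more likely as
pathology progresses) and generate the endpoints through a linear-Gaussian
path model: the cylinder index around 50% (coefficients 6 and 3 on the STN
power and burst-amplitude latents, noise SD 3), and terminal TH⁺ count and
striatal OD as percentages of control (coefficients −38 and −42 on the
terminal STN power latent, noise SD 5). With the default trajectories the
terminal endpoints land near 76%/27% TH⁺ loss and 84%/48% OD loss for the
high/low severity groups — the magnitudes reported for graded α-synuclein
lesions. The linear-Gaussian choice is deliberate: maximum-likelihood path
models have a closed-form truth here, so coefficient recovery is exactly
testable. What the generator does **not** emulate: non-stationary artifact
structure, spike-level activity, anaesthesia effects, or any nonlinear
coupling between β features and endpoints — passing tests certify the
pipeline's correctness on data obeying its own assumptions, not the
biological fidelity of those assumptions.

# Statistics layer

Group comparisons follow a normality gate: if every group passes
Shapiro–Wilk at α = 0.05, one-way ANOVA with Tukey's post hoc test;
otherwise Kruskal–Wallis with Dunn's rank test, tie-corrected, with
Bonferroni adjustment over pairs (the adjustment inside Dunn's test is a
package choice; no authoritative convention exists). Correlations use
Pearson when both variables pass the gate and Spearman otherwise, applied
per pair. Calibration is verified by simulation: the null rejection rate at
α = 0.05 lies in [0.03, 0.07] over 500 null cohorts.

# Path models

Models are recursive observed-variable path models — every node is a
measured quantity, so no latent measurement structure is needed. Free
parameters are one coefficient per directed edge, one residual variance per
endogenous variable, and free variances/covariances among the exogenous
variables. The ML discrepancy
`F = ln|Σ(θ)| + tr(S·Σ⁻¹) − ln|S| − p` is minimized by BFGS from
equation-wise regression starts computed on the sample covariance (these
starts are already the global optimum for recursive models with independent
errors, which the OLS-equivalence test exploits to 1e-6). Fit indices:
`χ² = (n−1)·F`, `RMSEA = √(max(χ²−df, 0)/(df·(n−1)))` (defined as 0 for
saturated models), `AIC = χ² + 2q` (a differences-only convention — only
model comparisons are meaningful), plus SRMR and CFI. Two fit criteria
sometimes quoted alongside these ("ICS"/"ICSF") have no published formula
and are omitted in favour of SRMR and CFI. Standardized coefficients are
`S = b·SD(from)/SD(to)` on the model-implied scale, with delta-method
standard errors propagated through all free parameters; simulation shows
their 95% intervals cover at 93–95%. Longitudinal repeated measures enter
as subject-week rows; the repeated-measures structure is acknowledged only
through RMSEA reporting, not a random-effects likelihood — a deliberate
simplification that keeps the covariance-structure likelihood exact.

Multiplicity across correlated endpoint tests uses the adjusted Bonferroni
rule `α_adj = 1 − (1−α)^(1/m^(1−r̄))`, where r̄ is the mean absolute
correlation among the tested parameters: at r̄ = 0 it is the Šidák level
(≈ α/m), and the correction weakens as r̄ → 1 until no adjustment remains.
The rule is pluggable since several variants of correlation-weakened
corrections circulate.

# Composite score and degeneration curves

For direct per-group prediction of neurodegeneration, each feature is first
divided by its group mean and cumulatively summed across the measured weeks
(subjects missing a week are dropped with a log message); this removes
scale and accumulates trajectory information. The composite score then
greedily forward-selects from the 22-feature menu (per region: three band
powers and low/high-β burst amplitude, rate and long-burst probability;
plus total-β and high-β coherence, the behaviour score and striatal OD):
at each step the candidate whose nonnegative-least-squares weight vector —
renormalized to sum 1 — minimizes RMSE against the target joins the model,
stopping when the relative improvement drops below 1%. Exhaustive search
over all subsets was rejected as a default (2²² combinations), but the
stopping threshold and feature cap are exposed. The neurodegeneration
target itself is defined as the mean of min–max-normalized TH⁺ loss and OD
loss relative to the control-group mean (both as `1 − value/control mean`);
this composite has no canonical definition, so the construction is stated
here and kept in one place in the code.

Behaviour-versus-degeneration curves z-normalize the deficit score per
group, decode it to three ordinal classes (normal / moderate / severe) at
the standard-normal tercile cuts (±0.431; empirical terciles would force
identical class counts in every group, losing the distributional
information), define "preserved motor function" as the normal class, and
fit a logistic curve of preservation probability against the degeneration
percentage per group — logistic because the relation must be monotone and
the curve needs an interpretable midpoint and slope. A group with a single
behaviour class is rejected as unidentifiable.

# Numerical and engineering choices

* Percentiles are linear-interpolation (R type-7) order statistics —
  stated because percentile conventions differ across toolboxes.
* "Longer than 350 ms" is read strictly (>), "minimal duration of 100 ms"
  inclusively (≥).
* The frequency grid nominally runs to 128 Hz, which equals Nyquist at
  256 Hz; envelope computation only needs the ≤ 30 Hz band, and bands
  beyond Nyquist are rejected with an explicit message.
* EDF export quantizes to 16 bits over each channel's physical range; the
  round-trip error bound (one quantization step) is tested. CSV export is
  exact.
* Problem sizes in the test suite are chosen for a laptop-scale run:
  burst-recovery studies use 20 seeded 47-s recordings, coherence nulls 90
  windows, path-model recovery 100 replicates of n = 200, statistical
  calibration 500 null simulations; the whole suite runs in well under a
  minute of CPU time.

# Known limitations

* The artifact rule is an amplitude heuristic; real artifact repertoires
  (chewing, movement, electrical transients) may need channel-specific
  rules.
* The common burst threshold pools across weeks as well as subjects; if
  acquisition gain drifts over weeks, per-week pooling (supported via the
  configuration) is safer.
* The SEM layer treats subject-weeks as exchangeable rows; inference on
  within-subject trajectories would need a mixed-effects extension.
* Burst timing below ~50 ms is beyond the temporal resolution of a
  10-cycle wavelet at β frequencies, and gradual-onset events have no
  well-defined edge at that scale.
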