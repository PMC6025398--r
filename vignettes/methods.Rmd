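---
title: "Methods: acute-stress HRV analysis and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acute-stress HRV analysis and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresshrv)
```

# The problem this package addresses

Acute psychosocial stress shifts the autonomic balance of the heart: the
sympathetic branch gains, the parasympathetic (vagal) branch withdraws, and
both changes are visible in beat-to-beat heart-rate variability (HRV).
`stresshrv` implements a complete analysis chain for protocol-driven stress
studies built on single-lead ECG: a resting **baseline**, a pre-stress
choice-reaction-time task (**CRTT1**), a standardized psychosocial stressor
(**TSST**: public speech plus mental arithmetic before a neutral jury), and a
post-stress repetition of the task (**CRTT2**). The chain is:

1. R-peak detection on the raw ECG (Pan–Tompkins-style),
2. physiological validity filtering of the RR intervals into NN intervals,
3. linear HRV features on event-synchronized 5-minute blocks,
4. scoring of the reaction-time task (median RT, accuracy),
5. nonparametric repeated-measures group statistics.

Because raw recordings from such studies are rarely deposited, the package
also ships a **synthetic-study generator** with analytically known ground
truth, so every stage is testable end to end without any download.

# R-peak detection

`detect_r_peaks()` follows the classical Pan–Tompkins pipeline:
zero-phase Butterworth band-pass (default 5–15 Hz, second-order sections run
forward–backward), five-point derivative, squaring, 150 ms moving-window
integration, then adaptive dual-threshold peak picking with a 200 ms
refractory period and a search-back pass that re-examines sub-threshold
candidates when an expected beat fails to appear within 1.66 times the
running RR average. All parameters are exposed in `qrs_params()`.

The integrator output peaks roughly half an integration window after the R
wave, so each fiducial is refined to the band-passed maximum inside the
integration window that produced it (± a 40 ms guard). Because the band-pass
is zero-phase, this refinement is what gives RR intervals their timing
precision. The detector is deterministic, amplitude-scale invariant, and
translation-equivariant away from the record edges; the first and last
complexes of a record can be truncated by the boundary and are the only
places where these properties degrade.

Records below 100 Hz sampling are rejected (the QRS complex is no longer
resolvable); an all-constant signal returns zero beats with a warning rather
than an error, because "no heart activity in this channel" is a data
condition, not a programming error.

# RR validity filtering

`filter_rr()` applies, in one forward pass per interval and in this order:

* **(a) absolute range** — intervals below 300 ms or above 3000 ms are
  removed;
* **(b) jump rule** — intervals that changed by more than 400 ms with
  respect to the previous *valid* interval are removed;
* **(c) relative rule** — intervals deviating by more than 25 % from the
  mean of the last five *valid* intervals are removed.

Three reading decisions matter and are fixed here: the inequalities are
strict, so the boundary values 300, 3000, 400 and 25 % themselves are kept;
the reference state updates online during the same pass, so a rejected
interval never becomes a reference; and rules (b)/(c) are *skipped*, not
failed, while insufficient valid history exists (so the first interval can
only fail the absolute rule, and the relative rule needs exactly five valid
predecessors). With both dynamic thresholds at infinity the filter
provably reduces to pure range clipping, which the test suite exploits as an
equivalence oracle.

Rejected intervals are dropped, never interpolated. That leaves gaps in the
beat-time axis, which is why spectral estimation defaults to a
least-squares periodogram (below) rather than anything that assumes even
sampling.

# HRV features

Per 5-minute block of NN intervals the package computes AVNN (mean, ms),
SDNN (standard deviation, population denominator *n* by default —
Task-Force-era tools disagree here, so it is switchable), RMSSD (root mean
square of successive differences), pNNx, and LF/HF.

**pNNx.** The percentage of successive differences strictly exceeding
x ms (default 20 ms, the more change-sensitive variant of the classical
pNN50), with the *total NN count* as denominator, following the classical
wording of the definition; a pair-count denominator is available for
interoperability with tools that use it. pNNx is non-increasing in x, which
is enforced as a property test.

**LF/HF.** Spectral power of the NN series in 0.04–0.15 Hz (LF) and
0.15–0.40 Hz (HF). The default estimator is a Lomb–Scargle (least-squares)
periodogram evaluated on the irregular beat times — it needs no resampling
and no interpolation, so filter-induced gaps are handled natively. The
periodogram is normalized so that it integrates to the variance of the
mean-detrended NN series over the evaluated range, making band powers
absolute (ms²); for a sinusoid of amplitude A ms the in-band power recovers
A²/2, which the tests assert. The alternative estimator resamples at 4 Hz
and averages Hann-windowed periodograms (Welch). Resampling uses a cubic
spline: linear interpolation acts as a low-pass that attenuates the HF band
by ~10–15 % at typical heart rates and would bias LF/HF upward; with the
spline the two estimators agree within a few percent on gap-free series
(the suite requires 15 %).

Spectral features require at least 30 NN intervals spanning at least two
cycles of the lowest LF frequency (50 s). When a block fails those
preconditions, `extract_block_features()` still reports the time-domain
features and records the spectral failure in a `spectral_error` column
instead of discarding the block.

# Protocol segmentation

Condition windows run from each event onset to its stated duration (or the
next onset). Windows are cut into consecutive, non-overlapping, *complete*
blocks of 300 s anchored at the condition onset; trailing partial blocks are
discarded, so a 10-minute condition yields exactly two blocks and a
12-minute condition also yields two. An NN interval belongs to the block
containing its terminal beat, so no interval is ever split. Where the block
anchor inside a condition is genuinely unconstrained by the protocol
description, onset-anchoring was chosen as the simplest reproducible
convention; the baseline is treated as two averaged 5-minute blocks rather
than one 10-minute block for the same reason (and to keep block counts
balanced across conditions).

Per-subject, per-condition cells of the study table are arithmetic means
over that subject's blocks; subjects missing any condition are flagged
incomplete and excluded from paired tests.

# Group statistics

The statistical battery mirrors standard small-sample psychophysiology
practice: Friedman omnibus across the four time points, Wilcoxon signed-rank
for pre/post pairs, paired-samples *t* as post-hoc pairwise comparisons
(with a consistent nonparametric alternative available), Spearman
correlation between cognitive measures, and z-scoring of the cognitive
measures over the pooled CRTT1+CRTT2 distribution (the reference population
for z-scoring is not uniquely determined by the protocol; pooling is the
choice here and is recorded in the output metadata). Unadjusted p-values are
the primary output — matching how such batteries are usually reported — with
Holm and Bonferroni columns alongside.

Exact null distributions are a first-class feature, because at n ≈ 11 the
asymptotics are shaky:

* **Friedman**: the permutation null permutes each subject's ranks
  independently. The tie term is invariant under within-row permutation, so
  the statistic depends only on the column rank sums, whose exact
  distribution is built row by row as a dynamic program — mathematically
  identical to enumerating all (k!)^n arrangements, and verified against
  literal brute force in the tests. Used for n ≤ 8, k ≤ 4.
* **Wilcoxon signed-rank**: generating-polynomial convolution over doubled
  ranks (ties stay exact), identical to 2^n sign enumeration; used up to
  n = 25, above which a tie-corrected, continuity-corrected normal
  approximation takes over (the two agree to ~0.01 at the crossover).
* **Spearman**: full enumeration of the n! permutations up to n = 8
  (configurable). Full enumeration at n = 9–10 costs 0.36–3.6 M
  permutations and was judged not worth the runtime in pure R; beyond the
  cap the t-approximation is used.

# The synthetic study generator

**What it emulates.** Beat timing follows an integral pulse frequency
modulation (IPFM) model: the instantaneous rate
m(t) = (1/T)(1 + a_lf sin(2π f_lf t + φ_lf) + a_hf sin(2π f_hf t + φ_hf))
fires a beat at every integer crossing of its integral. The two sinusoids
(defaults 0.1 and 0.3 Hz) give analytically known LF and HF structure —
in-band power A²/2 for interval-domain amplitude A — which is what makes
estimator-*recovery* tests possible at all. Independent Gaussian jitter
(`sd_rr`) adds a broadband floor.

**The sinc correction.** Reading rate modulation out as intervals low-passes
it: a rate modulation of fraction a at frequency f appears in the interval
series with amplitude a·T·sinc(π f T). At 675 ms mean RR this attenuates
the 0.3 Hz HF oscillation by ~7 % but the 0.1 Hz LF one by under 1 %, which
would inflate the measured LF/HF by ~13 % relative to the rate-domain
ratio. `calibrate_autonomic_state()` therefore defines its targets in the
interval domain — where the features are measured — and divides the sinc
factor back out, so the measured ratio matches the setpoint without
systematic bias.

**Calibration.** Given target AVNN, RMSSD and LF/HF, the amplitudes follow
from RMSSD² = 2A_lf²sin²(πf_lf T) + 2A_hf²sin²(πf_hf T) + 2·sd_rr² with
A_lf² = LFHF·A_hf². The default per-condition targets are the published
group means of the study this pipeline reenacts (e.g. 675.23 ms and LF/HF
6.13 under stress; baseline 744.15 ms, 28.22 ms RMSSD); they live in the
cohort spec as editable data. Three quantities are not printed in that
source and were chosen once as physiologically plausible values consistent
with their printed neighbours: baseline LF/HF = 2.5, post-stress
RMSSD = 26 ms, and the jitter sd_rr = 4 ms (of the order of R-peak timing
error at wearable sampling rates; analytically, the in-band share of a 4 ms
white floor stays small relative to the sinusoidal modulations, which keeps
the LF/HF setpoint meaningful).

**What it does not emulate.** No VLF or nonstationary drift, so generated
SDNN sits below typical real-data SDNN and is deliberately *not* calibrated
(the printed SDNN values are also internally inconsistent in the source and
move opposite to the other vagal indices, which a two-tone stationary model
cannot and should not reproduce). pNN20 levels follow from the RMSSD
calibration rather than being targeted directly; only their ordinal
stress-vs-baseline ordering is asserted on cohorts, while the dedicated
pNN20 estimator-recovery test uses Gaussian series analytically calibrated
to the printed baseline mean. ECG morphology is a sum of Gaussian P-QRS-T
bumps — adequate for exercising a QRS detector, not a model of pathology.
A green cohort test therefore establishes that the *pipeline recovers what
the generator put in*, not that the generator reproduces every marginal
statistic of real stressed humans.

**Cognitive task.** CRTT logs draw trial onsets with uniform 3–10 s
inter-stimulus intervals, uniform 100–500 ms display durations, an exactly
balanced congruent/incongruent split, Bernoulli accuracy around the
per-condition target (0.95 pre, 0.88 post) and log-normal RTs around the
per-subject median target. The published pre/post RT association for this
protocol is strongly *negative* (fast-pre subjects slow post); the
generator realizes that pattern with a latent subject speed entering the
post-stress target with opposite sign. This is an emulation of the reported
pattern, not a mechanistic claim about stress physiology — only the sign
and strength of the association are ever asserted on synthetic cohorts.
Note a real tension in the emulated pattern: the crossover amplitude needed
for a correlation near −0.9 injects paired-difference variance that makes a
significant group-level RT decrease at n = 11 a seed-dependent outcome. The
defaults (8 % crossover, 15 % log-normal RT spread) sit at the compromise
point where the correlation stays strong and the pre/post z-medians
decrease in most cohorts; no test asserts the significance of that
decrease.

**Reproducibility.** Every generator output is bit-reproducible given
(spec, master seed); per-subject and per-condition streams derive from the
master seed by fixed offsets, and all seeded code restores the caller's RNG
state.

# Numerical choices and degenerate inputs

* Butterworth sections are designed by bilinear transform and applied
  forward–backward with reflection padding (zero phase, suppressed edge
  transients).
* IPFM integer crossings are bracketed on a coarse grid and polished with
  Newton steps on the closed-form integral (sub-microsecond accuracy).
* Lomb frequencies run from 1/(4·span) to the mean Nyquist rate in steps of
  1/(4·span); band membership is half-open `(lo, hi]` so the shared
  0.15 Hz edge is counted once.
* A constant NN block has zero spectral power: LF/HF raises an
  undefined-ratio error, which `extract_block_features()` converts into a
  flagged NA rather than a hard failure.
* Exact-test comparisons use 1e-9 slack so floating-point ties do not flip
  a count.

# Known limitations

* The detector assumes upright R waves (the synthetic template's polarity);
  inverted-lead recordings would need a sign option.
* Segmentation assumes non-overlapping condition windows and rejects
  overlaps instead of resolving them.
* The Welch estimator's 256-sample segments limit its resolution at the
  0.04 Hz band edge for blocks much shorter than 5 minutes; the Lomb
  default does not share this limit.
* Spearman exactness stops at n = 8 by default (see above); at the study's
  n = 11 all reported Spearman p-values are t-approximate, as they would be
  in standard software.
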