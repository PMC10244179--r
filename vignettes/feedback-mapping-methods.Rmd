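---
title: "Methods: all-optical feedback mapping and dendritic event analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: all-optical feedback mapping and dendritic event analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`fbmap` implements the analysis chain of mesoscale all-optical experiments
in mouse visual cortex: two-photon holographic photostimulation of clustered
neuron groups in one area (V1 or its feedback partner LM) paired with
simultaneous two-photon calcium imaging across both areas, plus
high-magnification dendrite recordings in which long-range feedback inputs
onto single spines are mapped and stimulated. Because such datasets are not
publicly deposited, every stage ships with a synthetic-data generator that
emulates the recording with known ground truth; the test suite and the
acceptance script run entirely on synthetic data.

This vignette documents the statistical procedures, the parameters that
matter, the design choices made where the methods were genuinely open, and
what the synthetic validation does and does not establish.

## Population pipeline

### dF/F and trial responses

Raw fluorescence is converted to dF/F against a rolling 10th-percentile
baseline (`dff()`, 2,000-frame window for population data; dendritic
analyses use 90-s or 45-s windows). The per-trial response statistic is

R_i = (S_i - B_i) / sd(B_{i-2}, B_{i-1}, B_i),

where S_i is the mean dF/F in a 500-ms window after the photostimulus ends
(anchored at the same latency on visual-only trials) and B_i the mean in a
500-ms window before visual onset. Windows are `ceiling(0.5 * frame_rate)`
frames. For the first two trials the s.d. uses all available trials; an
exactly zero s.d. is replaced by the ROI's session-median B-s.d. so R stays
finite (a fully degenerate ROI falls back to S - B). R is invariant to
constant trace offsets by construction.

### Responder detection

For each stimulation group, V trials are randomly subsampled to match the
orientation proportions of that group's V+P trials (one seeded draw by
default; `n_draws` averages p-values over several draws). A two-sided
Wilcoxon rank-sum test compares R^{V+P} with the matched R^V per ROI and
the resulting p-values are FDR-adjusted across all ROIs of the session
(Benjamini-Hochberg by default; Storey's positive-FDR q-values as an
option). A responder requires q below the control level (0.025 in the
headline configuration) *and* a non-zero median effect, whose sign
classifies it as facilitated or suppressed. ROIs with identical values in
both samples receive p = 1.

### Response probability and photostimulation resolution

Each R^{V+P} is Z-scored against all of the ROI's R^V values (the
orientation-unmatched reference; using matched V trials was the open
alternative, and the full reference is preferred because it is the larger,
more stable sample). P_response is the fraction of trials with Z strictly
above 1.64, the one-sided 5% normal critical value. The lateral resolution
of photostimulation is summarized by fitting
`p = b + a * 2^-(d/h)^2` to P_response versus lateral offset `d`, so the
parameter `h` is read directly as the lateral HWHM.

### Retinotopy

Receptive fields are mapped by reverse correlation: event-triggered
stimulus ensembles over a 2-s window, weighted by event size, Z-scored over
all lag-position combinations, and median filtered with a 3-sample window
*along the lag axis* at each grid position. A spatial 3x3 median was
considered and rejected: it erases receptive fields confined to a single
grid square, which are legitimate at 6-8 degree grid resolution. Inclusion
requires a maximum Z of at least 5 in either polarity; the preferred
location is read within a 600-ms window centred on the peak lag (centring
is a choice; the alternative trailing placement is not materially different
at these frame rates), and when both polarities pass, the preference is
their Z-weighted average.

Event traces come from `deconvolve_trace()`: non-negative least squares
against the difference-of-exponentials kernel, solved by accelerated
projected gradient descent with the convolution operator (no dictionary
matrix is formed), followed by an exact least-squares re-fit on the
detected support to debias amplitudes. Deconvolved traces are denoised by
zeroing amplitudes at or below mean + 2 s.d. (strict comparison, so a
zero-variance trace zeroes entirely).

Smoothed retinotopic surfaces are locally weighted linear (LOWESS) fits of
azimuth and elevation on FOV position with robust bisquare reweighting
(`stats::loess`, degree 1, `family = "symmetric"`, span 0.2), evaluated
directly so queries outside the convex hull extrapolate with a flag. The
V1/LM border is a polyline; signed distance to it assigns the area
(positive side, left of the polyline direction, is `A1`) and ROIs within
75 um of the border on either side are excluded from responder analyses.

### Topography of feedback influence

Responder-to-source retinotopic distances (sources are all locally
facilitated responders of the group) are binned at 1.2 degrees over 30 bins
(0-36 degrees; larger distances pool into the last bin) and divided by a
null distribution built from 20,000 draws of neurons, with replacement,
from all available neurons in the readout area — each draw contributes its
full set of distances to the sources. Pooled single-neuron draws were
chosen over matched-count draws because the ratio estimand is identical and
pooling uses the draws more efficiently. Both histograms are normalized to
unit mass before the ratio, so a weighted value of 1 marks uniform spatial
sampling; bins with empty nulls are flagged undefined and excluded from
averages. Profiles are smoothed with a centred, edge-truncated 5-bin moving
average and averaged across groups (mean +/- s.e.m.; suppressed profiles
are negated for display only).

Displacement between facilitated and suppressed responders is tested by a
two-sided rank-sum test on per-group centroids of the *unweighted* distance
distributions (exact enumeration when both sides have at most 10 groups).
The stimulation-strength control bins groups by their number of local
responders (bin width 10) and, in each bin occupied by both directions,
repeatedly samples half the number of groups contributed by the smaller
direction from each, 5,000 times; the proportion of resamples with a
negative facilitated-minus-suppressed displacement summarizes the effect
under matched strength distributions.

## Dendrite pipeline

### Spine mapping

Spine responses use dR = mean dF/F over the 7 frames after stimulation
offset minus the mean over the 9 frames before onset (stimulation-artifact
frames fall between the windows and are never used); dR_mean, the average
over all spines, proxies global dendritic activity. The candidate search
sweeps thresholds on dR (mean + 0.5 to 3 s.d., 0.5 steps), dR_mean
(mean + 0.5 to 1.5 s.d.) and reliability (10-20%, 5% steps): a spine's
independent-event trials are those with dR above threshold while dR_mean
stays below threshold, and any target stimulated on more than the
reliability fraction of those trials becomes a candidate. The reliability
denominator is the spine's independent-trial count at the current setting,
and a setting must yield at least 5 independent trials to contribute —
with fewer, a reliability fraction is dominated by single coincidences.
Candidates are deduplicated with their best reliability and rank-ordered by
reliability x independent-trial count, an explicit replacement for the
by-eye "most promising" triage of online experiments.

Confirmation stimulates one putative presynaptic target in isolation over
at least 8 trials and applies a one-sample signed-rank test to the
per-trial (post - pre) differences; a connection is confirmed at p < 0.01
with a positive mean response. All-zero differences give p = 1.

### Boosting index

BI is the per-trial ratio of post-stimulus dF/F in the stimulated-branch
ROI (drawn to exclude the feedback-recipient spine) to that in a reference
branch ROI of the same cell, over the same 7-frame post window. Trials
whose reference mean falls below a 0.01 dF/F floor are excluded. Within a
recording, stimulation and blank BIs are compared by rank-sum; across
recordings the mean BIs are compared by a paired t-test (signed-rank
alternative available) and summarized as the mean percentage increase.

### Local dendritic events

Branch movies are projected onto the single-pixel line ROI: each mask pixel
is averaged into its nearest line pixel (ties to the lowest index), per-bin
traces are smoothed with a 4-s moving average, converted to dF/F against a
45-s 10th-percentile baseline, normalized, and smoothed across space with a
2-um moving average within frames. Normalization divides the whole
space-time profile by its single s.d. rather than each bin's trace by its
own s.d.: the bin-wise variant distorts spatial profiles whenever event
coverage along the branch is uneven (in simulation it inflated quiet edge
bins by two orders of magnitude), while the scalar variant preserves
relative spatial amplitudes; both are exposed.

Event classification formalizes criteria that were originally applied by
two blinded human raters, so the rule set — activity means a Z above 3
against the profile baseline; "local" needs at least two active spines, at
least half of the interposed branch active, and a quiet proximal 20% of
geodesic length; "global" needs 90% of bins including the proximal end —
is an explicit, configurable stand-in, not a measured quantity.

The idealized event profile averages per-event spatial profiles (each
normalized to unit peak and aligned to it) on a 0.5-um grid within a
+/-20-um window, then fits the sum of three Gaussians, initialized from a
single-Gaussian fit with side components at +/-5 um; on profiles where the
side amplitudes vanish the refinement is unidentifiable and the
single-Gaussian fit stands in. FWHM is read from the fitted curve at half
its maximum. Event frequency by stimulus type (8 and 16 degree Gabors,
inverse, annulus, full field) is reported per trial and per minute — the
natural unit is ambiguous, so both are computed — and tested across
branches with Kruskal-Wallis followed by unadjusted Dunn comparisons.

### Soma-dendrite analyses

Somata and apical trunk sections are paired when the fluorescence
correlation exceeds 0.45 and the event-trace correlation exceeds 0.25
(0.55/0.35 is the standard robustness setting; the strict pairs are a
subset by construction). Visual responses are peak-over-baseline in a
7-frame window starting 3 frames after onset against a 4-frame baseline
ending 1 frame before onset. The population surface bins normalized trials
by somatic activity into 28 five-percent bins from -40% to 100% of peak;
the two-way ANOVA (soma bin x stimulus factor with interaction) runs on the
trial-level data because bin-level cells leave no residual degrees of
freedom for the interaction. Per-neuron size tuning removes somatic
influence by regressing the dendritic on the somatic response (trials at or
above 20% of peak only, boundary inclusive) and testing the residuals
across sizes with one-way ANOVA; the preferred size maximizes the mean
residual. The locomotion variant pools sizes as smaller/preferred/larger
around the preference computed on stationary trials and runs a two-way
state x size-class ANOVA. The apical/basal analysis forms per-trial
apical-to-basal response ratios (basal at least 20% of its peak and
positive), contrasts low-surround (Gabor) with high-surround (inverse,
full-field) classes, and assesses the difference against 3,000 class-label
shuffles preserving class sizes, calling a neuron significant above the
95th shuffle percentile.

## The synthetic generator

`generator_config()` fixes the recording conditions: a 1,215-um FOV split
by a vertical border with a 150-um border zone; a linear retinotopic
gradient of 0.07 deg/um, azimuth mirrored across the border (the
LM map mirrors V1); 7-Hz imaging; 2-s gratings with 6-s intervals; 20%
visual-only trials; photostimulation 0.5 s after visual onset for 0.5 s;
groups of 6-14 targets; a GCaMP6s-like difference-of-exponentials kernel
(rise 0.1 s, decay 1.5 s) with i.i.d. Gaussian noise (s.d. 0.1 dF/F).
Ground-truth responders follow a suppressive-centre
(Gaussian, sigma 8 degrees), facilitating-surround (ring at 12 degrees)
placement profile. The photostimulation point spread enters as a per-trial
*activation probability* proportional to a Gaussian of lateral offset with
20.7-um HWHM — this matches how resolution is measured (response
probability versus distance); the dendrite generator instead attenuates
response *amplitudes*, as appropriate for synaptic drive. Local dendritic
events are spatial Gaussians of sigma 4.757 um (FWHM 11.2 um); the branch
boosting factor multiplies the stimulated branch's post-stimulus dF/F by
1.108 on stimulation trials.

Two dendrite-specific choices deserve note. Dendritic transients decay
faster than somatic GCaMP6s transients, so dendrite recordings use a 0.6-s
decay; and stimulation logs are organized into blocks of 20 trials
separated by 10-s pauses, as acquisitions are in practice. Both matter for
baseline identifiability: with 1.25-s inter-stimulus intervals and a 1.5-s
decay the fluorescence never revisits baseline, the rolling-percentile F0
overestimates, and ratio statistics such as the boosting index inflate.

Response-level simulation (`simulate_trial_responses()`) generates R
statistics directly — null ROIs draw N(0, 1), responders shift by the
effect in s.d. units on V+P trials — for large calibration runs of the
detection stage where the trace machinery adds nothing but runtime.

What the generator does **not** emulate: shared neuropil contamination,
photostimulation artifacts (real users pre-clean them), motion,
eye movements, orientation tuning structure, correlated noise across
neurons, and pixel-level population movies (population sessions are ROI
traces only; movies exist only for dendrite recordings where spatial
analysis needs pixels). Passing tests therefore establish that the
statistics are implemented correctly and are calibrated under idealized
noise, not that they are robust to all failure modes of real recordings.

## Validation scale and numerical choices

The test suite and `scripts/acceptance.R` use desk-scale problem sizes
chosen to estimate each quantity stably: 200 simulated sessions of 500
neurons and 100+100 trials for FDR calibration; 20 seeds with 20,000-draw
nulls for the uniform-sampling profile; 50 events on a 60-um branch for the
event width; 65 neurons at 13 offsets with 100 trials for the
photostimulation resolution; 25 recordings for the boosting aggregate.
Rolling percentiles are evaluated on a strided grid (a tenth of the window)
and interpolated; exact rank tests switch to normal approximations with tie
correction beyond small samples; mask-to-line ties break to the lowest line
index; degenerate inputs (zero-variance traces, empty responder sets, empty
null bins, all-zero signed-rank differences) return flagged values rather
than errors wherever an analysis can continue without them.

## Known limitations

Candidate-connection reliability is meaningful only with realistic target
sparsity (thousands of grid targets, each in a small fraction of trials);
dense target reuse inflates coincidental reliability, which is why the
sweep requires a minimum independent-trial count. The boosting index
remains a ratio statistic: it is scale-free but sensitive to baseline
misestimation, and the denominator floor only guards against near-zero
references, not against systematic F0 bias. The LOWESS surface
extrapolates linearly outside the data hull and should be trusted only
near sampled cortex. Session I/O uses plain CSV tables; trace matrices are
written in full and are practical up to a few hundred megabytes, beyond
which users should store traces in a binary container of their choice and
construct sessions in memory.
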