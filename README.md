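# fbmap

Analysis tools for **mesoscale all-optical mapping of cortico-cortical
feedback** and its dendritic integration: experiments that pair two-photon
holographic optogenetic stimulation of clustered neurons in one visual area
with simultaneous two-photon calcium imaging across that area and its
feedback partner, plus high-magnification recordings of apical tuft
dendrites receiving identified long-range inputs.

The package is aimed at systems neuroscientists running (or re-analysing)
all-optical connectivity experiments. It covers the full chain:

- **Responder detection.** Per-trial responses
  `R_i = (S_i − B_i) / sd(B_{i−2..i})` (500-ms response window after
  photostimulus offset, 500-ms background window before visual onset),
  compared between visual-only and visual+photostimulation trials with an
  orientation-matched Wilcoxon rank-sum test under FDR control
  (Benjamini–Hochberg or Storey q-values; headline level 2.5%).
- **Retinotopy.** Reverse-correlation receptive fields from non-negatively
  deconvolved event traces (Z ≥ 5 inclusion), robust LOWESS retinotopic
  surfaces, and border-zone exclusion (±75 µm) from a supplied area border.
- **Topography of influence.** Responder-to-source retinotopic distance
  distributions in 1.2° bins, normalized by a 20,000-draw null over all
  available neurons (weighted value 1 = uniform sampling), per-group
  centroid displacement tests, and a 5,000× stimulation-strength-matched
  resampling control.
- **Spine mapping.** Spine responses ΔR (9 frames pre / 7 frames post),
  iterative threshold sweeps over ΔR, ΔR_mean and reliability (10–20%) to
  find candidate target→spine connections from independent spine events,
  signed-rank confirmation (p < 0.01), and the branch **boosting index** —
  the per-trial ratio of post-stimulus dF/F in the stimulated branch
  (excluding the recipient spine) to a reference branch.
- **Dendritic events.** Mask-to-line projection of branch movies, geodesic
  space–time profiles, local/global event classification (≥2 spines plus
  the interposed branch with a quiet proximal end), three-Gaussian fits of
  the idealized event profile with FWHM readout, and Kruskal–Wallis/Dunn
  tests of event rates across stimulus types.
- **Soma–dendrite analyses.** Correlation-threshold pairing (0.45 F /
  0.25 events), size tuning of dendritic residuals after removing somatic
  influence, and the apical/basal surround-preference shuffle test
  (3,000 permutations).
- **Synthetic data.** A ground-truthed generator
  (`generator_config()`, `make_population_session()`,
  `make_dendrite_recording()`, `simulate_local_events()`) that emulates the
  recordings with configurable responder placement, photostimulation point
  spread (lateral HWHM 20.7 µm), local-event width (FWHM 11.2 µm) and
  branch boosting factor (1.108), so every stage can be validated against
  known truth.

## Worked example

Generate a synthetic session with embedded responders, detect them, and
profile their retinotopic distribution; then map a feedback-recipient spine
and measure branch boosting:

```r
library(fbmap)

cfg <- generator_config(n_rois = 400, n_trials = 150, frac_v = 0.3,
                        n_groups = 2, effect_dff = 1)
session <- make_population_session(cfg, seed = 42)
dffm    <- dff(session$traces)
resp    <- trial_responses(dffm, session$trials, session$frame_rate)
tab     <- detect_responders(resp, group_id = 1, fdr_level = 0.025, seed = 43)

meta  <- session$roi_meta
prefs <- cbind(meta$true_azimuth_deg, meta$true_elevation_deg)
g     <- session$groups[[1]]
src   <- prefs[tab$roi_id[tab$responder & tab$sign %in% "facilitated" &
                          meta$area == g$area], , drop = FALSE]
other <- meta$area != g$area & meta$area != "border"
ids   <- tab$roi_id[tab$responder & other]
dd    <- weighted_distance_distribution(
  retinotopic_distances(prefs[ids, , drop = FALSE], src),
  prefs[other, , drop = FALSE], src, seed = 44)

rec  <- make_dendrite_recording(generator_config(), seed = 45)
sdff <- dff(rec$spine_traces, window_frames = 90 * rec$frame_rate)
cand <- find_candidate_connections(spine_delta_r(sdff, rec$stim_log),
                                   rec$stim_log$target_ids)
bdff <- dff(rec$branch_traces, window_frames = 90 * rec$frame_rate)
bi   <- boosting_index(bdff[1, ], bdff[2, ], rec$stim_log)
```

Output:

```
detected 20 facilitated and 1 suppressed responders
true responders recovered: 21 of 21
across-border responders: 6
weighted profile peak 6.8 at 12.6 deg retinotopic distance
top candidate: target 1 -> spine 1 (reliability 0.78); truth: target 1 -> spine 1
boosting index: stim 1.107 vs blank 1.000 (+10.7%, rank-sum p = 4.2e-27)
```

Reading it: detection recovers all 21 embedded responders for group 1 at
the 2.5% FDR level; the across-border responders over-represent retinotopic
distances near 12.6° (the generator places facilitating feedback on a ring
at 12°, so the null-normalized profile peaks there, well above the uniform
level of 1); spine mapping ranks the one true target→spine connection
first; and the boosting index on stimulation trials exceeds blank trials by
10.7%, recovering the generator's boosting factor of 1.108.

A deterministic multi-stage run with artifact directory, resolved config
and JSON-lines log:

```r
out <- run_pipeline(pipeline_config(seed = 1), "artifacts/")
```

A thin command-line wrapper lives at `inst/cli/fbmap.R`
(`synth-population`, `synth-dendrite`, `run`).

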