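# Synthetic-data generator: ground-truthed population sessions, dendrite
# recordings, branch movies with local events, and response-level simulations.
# The generator defaults encode the recording conditions every downstream
# stage assumes (trial structure, windows, point-spread, event widths,
# boosting factor); see the methods vignette for the rationale behind each.

#' Generator configuration
#'
#' Builds the configuration object shared by all synthetic-data generators.
#' Defaults describe a mesoscale all-optical session: two retinotopically
#' organized areas separated by a 150-um border zone, GCaMP6s-like
#' fluorescence kinetics, full-field grating trials paired with holographic
#' photostimulation of clustered target groups, and dendrite recordings with
#' sparse long-range target-to-spine connections.
#'
#' @param ... named overrides of the defaults listed below. Unknown names are
#'   an error, so configs stay auditable.
#'
#' @section Key defaults:
#' * `n_rois = 500`, `fov_um = 1215`, `border_zone_um = 150` - FOV geometry;
#'   the area border is a vertical line at the FOV midline.
#' * `frame_rate = 7` Hz, `visual_dur_s = 2`, `iti_s = 6`,
#'   `photostim_delay_s = 0.5`, `photostim_dur_s = 0.5` - trial structure;
#'   photostimulation is triggered 0.5 s after visual onset and lasts 0.5 s.
#' * `frac_v = 0.2` - fraction of trials with visual stimulation only.
#' * `gradient_deg_per_um = 0.07` - linear retinotopic gradient, azimuth
#'   mirrored across the border, elevation shared.
#' * `kernel_rise_s = 0.1`, `kernel_decay_s = 1.5` - difference-of-exponentials
#'   fluorescence kernel (GCaMP6s-like).
#' * `sup_center_sigma_deg = 8`, `fac_ring_peak_deg = 12`,
#'   `fac_ring_sigma_deg = 4` - responder placement: suppression probability
#'   falls off as a Gaussian of retinotopic offset, facilitation peaks on an
#'   offset ring (suppressive centre, facilitating surround).
#' * `psf_lateral_hwhm_um = 20.7`, `psf_axial_hwhm_um = 45` - photostimulation
#'   point-spread half-widths.
#' * `event_sigma_um = 4.757` - spatial sigma of local dendritic events, so
#'   that FWHM = 2*sqrt(2*log(2))*sigma = 11.2 um.
#' * `boosting_factor = 1.108` - multiplicative gain on the boosted branch's
#'   post-stimulus dF/F on stimulation trials.
#'
#' @return an object of class `fbmap_config` (a validated named list).
#' @export
generator_config <- function(...) {
  cfg <- list(
    # population session
    n_rois = 500, fov_um = 1215, border_zone_um = 150,
    frame_rate = 7, n_trials = 200, frac_v = 0.2,
    n_groups = 5, targets_per_group = c(6, 14),
    orientations = c(0, 90, 180, 270),
    visual_dur_s = 2, iti_s = 6,
    photostim_delay_s = 0.5, photostim_dur_s = 0.5,
    gradient_deg_per_um = 0.07,
    kernel_rise_s = 0.1, kernel_decay_s = 1.5,
    baseline_f = 1, noise_sd = 0.1,
    visual_amp = 0.3, visual_amp_sd = 0.1,
    frac_facilitated = 0.1, frac_suppressed = 0.05,
    effect_dff = 0.5,
    sup_center_sigma_deg = 8, fac_ring_peak_deg = 12, fac_ring_sigma_deg = 4,
    locomotion_prob = 0.25,
    # photostimulation point spread
    psf_lateral_hwhm_um = 20.7, psf_axial_hwhm_um = 45,
    # dendrite recordings
    n_spines = 8, branch_length_um = 60, um_per_px = 0.5,
    dendrite_frame_rate = 30, dendrite_decay_s = 0.6,
    n_stim_trials = 200, stim_period_s = 1.25,
    trials_per_block = 20, block_gap_s = 10,
    targets_per_trial = c(8, 25), n_targets = 2146, frac_blank = 0.3,
    n_connections = 1, n_connection_stims = 12,
    connection_amp_dff = 0.5, spine_event_rate_hz = 0.02,
    spine_event_amp = 0.8, spine_noise_sd = 0.1,
    global_event_rate_hz = 0.02, global_event_amp = 1,
    branch_amp_sd = 0.25,
    # local dendritic events
    event_sigma_um = 4.757, event_amp = 1.5, event_frame_rate = 13.2,
    boosting_factor = 1.108,
    seed = NULL)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  pos <- c("n_rois", "fov_um", "border_zone_um", "frame_rate", "n_trials",
           "kernel_rise_s", "kernel_decay_s", "psf_lateral_hwhm_um",
           "psf_axial_hwhm_um", "event_sigma_um", "um_per_px",
           "dendrite_frame_rate", "branch_length_um")
  for (p in pos) if (cfg[[p]] <= 0) stop("config field '", p, "' must be positive")
  for (p in c("frac_v", "frac_facilitated", "frac_suppressed", "frac_blank"))
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop("config field '", p, "' must be in [0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative")
  structure(cfg, class = "fbmap_config")
}

#' Difference-of-exponentials calcium kernel
#'
#' Unit-peak kernel `exp(-t/decay) - exp(-t/rise)` sampled at the frame rate.
#'
#' @param frame_rate Hz.
#' @param rise_s,decay_s kernel time constants in seconds.
#' @param length_frames kernel support; default covers ~8 decay constants.
#' @return numeric vector starting at lag 0.
#' @export
calcium_kernel <- function(frame_rate, rise_s = 0.1, decay_s = 1.5,
                           length_frames = NULL) {
  if (rise_s <= 0 || decay_s <= 0) stop("kernel time constants must be positive")
  if (is.null(length_frames)) length_frames <- ceiling(8 * decay_s * frame_rate)
  t <- seq_len(length_frames) - 1L
  k <- exp(-t / (decay_s * frame_rate)) - exp(-t / (rise_s * frame_rate))
  k / max(k)
}

# Convolve an event train (vector, or frames x units matrix) with the
# unit-peak difference-of-exponentials kernel using two recursive filters.
doe_convolve <- function(x, frame_rate, rise_s, decay_s) {
  ad <- exp(-1 / (decay_s * frame_rate))
  ar <- exp(-1 / (rise_s * frame_rate))
  y <- stats::filter(x, ad, method = "recursive") -
    stats::filter(x, ar, method = "recursive")
  tmax <- ceiling(8 * decay_s * frame_rate)
  peak <- max(ad^(0:tmax) - ar^(0:tmax))
  y <- y / peak
  if (is.matrix(x)) matrix(as.numeric(y), nrow(x), ncol(x)) else as.numeric(y)
}

#' Synthesize a fluorescence trace from an event train
#'
#' Convolves a non-negative per-frame event-amplitude train with the unit-peak
#' difference-of-exponentials kernel, scales by a baseline and adds i.i.d.
#' Gaussian noise: `F = baseline * (1 + events * kernel) + noise`. An event of
#' amplitude `a` therefore produces a dF/F transient peaking at `a`.
#'
#' @param events non-negative numeric vector of per-frame event amplitudes
#'   (dF/F units).
#' @param frame_rate Hz.
#' @param rise_s,decay_s kernel time constants (s).
#' @param baseline baseline fluorescence F0 (a.u.).
#' @param noise_sd Gaussian noise s.d. in dF/F units.
#' @param seed optional RNG seed.
#' @return numeric fluorescence trace, same length as `events`.
#' @export
synthesize_fluorescence <- function(events, frame_rate, rise_s = 0.1,
                                    decay_s = 1.5, baseline = 1,
                                    noise_sd = 0, seed = NULL) {
  if (any(!is.finite(events))) stop("event train must be finite")
  if (any(events < 0)) stop("event amplitudes must be non-negative")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  set_seed_if(seed)
  sig <- doe_convolve(events, frame_rate, rise_s, decay_s)
  baseline * (1 + sig) + stats::rnorm(length(events), 0, noise_sd * baseline)
}

#' Generate a synthetic population imaging session
#'
#' Emulates one mesoscale all-optical recording: ROIs tiling two
#' retinotopically organized areas separated by a border zone, a trial table
#' of visual-only (V) and visual+photostimulation (V+P) trials, clustered
#' stimulation groups, and ground-truth facilitated/suppressed responders
#' placed according to the configured retinotopic-offset profile (suppression
#' probability Gaussian around the stimulated retinotopic location,
#' facilitation peaked on an offset ring). Responder effects are injected into
#' the fluorescence so the full trace -> dF/F -> trial-response -> detection
#' pipeline can be exercised against known truth.
#'
#' @param config an [generator_config()] object.
#' @param seed RNG seed; the same config and seed give a byte-identical
#'   session.
#' @return an object of class `fbmap_session`: list with `traces`
#'   (ROIs x frames raw fluorescence), `frame_rate`, `roi_meta`, `trials`,
#'   `groups`, `ground_truth` and the resolved `config`.
#' @export
make_population_session <- function(config = generator_config(),
                                    seed = config$seed) {
  stopifnot(inherits(config, "fbmap_config"))
  if (config$n_rois < 1) stop("config must specify at least one ROI")
  if (config$n_trials < 1) stop("config must specify at least one trial")
  if (config$border_zone_um >= config$fov_um)
    stop("border zone wider than the field of view")
  set_seed_if(seed)
  fr <- config$frame_rate
  n <- config$n_rois

  # --- geometry and retinotopy ------------------------------------------
  x <- stats::runif(n, 0, config$fov_um)
  y <- stats::runif(n, 0, config$fov_um)
  xb <- config$fov_um / 2
  half_zone <- config$border_zone_um / 2
  area <- ifelse(x < xb - half_zone, "A1",
                 ifelse(x > xb + half_zone, "A2", "border"))
  az <- config$gradient_deg_per_um * abs(x - xb)
  el <- config$gradient_deg_per_um * (y - xb)
  roi_meta <- data.frame(roi_id = seq_len(n), x_um = x, y_um = y, plane = 1L,
                         area = area, true_azimuth_deg = az,
                         true_elevation_deg = el)

  # --- stimulation groups: nearest-neighbour clusters off the border ----
  groups <- vector("list", config$n_groups)
  for (g in seq_len(config$n_groups)) {
    area_g <- if (g %% 2 == 1) "A1" else "A2"
    cand <- which(area == area_g)
    if (!length(cand)) stop("no candidate targets outside the border zone")
    k <- sample(seq(config$targets_per_group[1], config$targets_per_group[2]), 1)
    seed_roi <- cand[sample(length(cand), 1)]
    ord <- order((x[cand] - x[seed_roi])^2 + (y[cand] - y[seed_roi])^2)
    targ <- cand[ord][seq_len(min(k, length(cand)))]
    groups[[g]] <- list(group_id = g, area = area_g, target_roi_ids = targ,
                        target_positions_um = cbind(x = x[targ], y = y[targ],
                                                    z = 0))
  }

  # --- trial table ------------------------------------------------------
  period <- round((config$visual_dur_s + config$iti_s) * fr)
  pre_pad <- period
  onsets <- pre_pad + (seq_len(config$n_trials) - 1L) * period
  n_frames <- pre_pad + config$n_trials * period + period
  n_v <- max(1L, round(config$frac_v * config$n_trials))
  type <- rep("V+P", config$n_trials)
  type[sample(config$n_trials, n_v)] <- "V"
  gid <- rep(NA_integer_, config$n_trials)
  vp <- which(type == "V+P")
  if (length(vp))
    gid[vp] <- rep_len(seq_len(config$n_groups), length(vp))[sample(length(vp))]
  orientation <- sample(config$orientations, config$n_trials, replace = TRUE)
  loco <- stats::runif(config$n_trials) < config$locomotion_prob
  speed <- ifelse(loco, 3 + stats::rexp(config$n_trials, 1 / 3),
                  stats::runif(config$n_trials, 0, 1.5))
  trials <- data.frame(trial = seq_len(config$n_trials), onset_frame = onsets,
                       type = type, group_id = gid,
                       orientation_deg = orientation, run_speed_cm_s = speed)

  # --- ground-truth responders -----------------------------------------
  gt <- expand.grid(roi_id = seq_len(n), group_id = seq_len(config$n_groups))
  gt$label <- "none"
  gt$effect_dff <- 0
  if (config$effect_dff > 0) {
    for (g in seq_len(config$n_groups)) {
      targ <- groups[[g]]$target_roi_ids
      az_c <- mean(az[targ]); el_c <- mean(el[targ])
      d <- sqrt((az - az_c)^2 + (el - el_c)^2)
      ring <- exp(-(d - config$fac_ring_peak_deg)^2 /
                    (2 * config$fac_ring_sigma_deg^2))
      centre <- exp(-d^2 / (2 * config$sup_center_sigma_deg^2))
      p_fac <- config$frac_facilitated * ring / max(ring)
      p_sup <- config$frac_suppressed * centre / max(centre)
      u <- stats::runif(n)
      lab <- ifelse(u < p_fac, "facilitated",
                    ifelse(u < p_fac + p_sup, "suppressed", "none"))
      lab[targ] <- "facilitated"        # direct targets respond
      lab[area == "border"] <- "none"   # border zone carries no truth
      rows <- gt$group_id == g
      gt$label[rows] <- lab
      gt$effect_dff[rows] <- ifelse(lab == "none", 0, config$effect_dff)
    }
  }

  # --- fluorescence synthesis ------------------------------------------
  stim_end <- onsets +
    round((config$photostim_delay_s + config$photostim_dur_s) * fr)
  amp_roi <- pmax(0.05, stats::rnorm(n, config$visual_amp, config$visual_amp_sd))
  train <- matrix(0, n_frames, n)  # frames x rois (stats::filter is columnwise)
  trial_amp <- outer(exp(stats::rnorm(config$n_trials, 0, 0.2)), amp_roi)
  for (g in seq_len(config$n_groups)) {
    g_trials <- which(type == "V+P" & gid == g)
    if (!length(g_trials)) next
    lab <- gt$label[gt$group_id == g]
    fac <- which(lab == "facilitated")
    sup <- which(lab == "suppressed")
    # suppression: visual drive reduced on that group's V+P trials
    if (length(sup))
      trial_amp[g_trials, sup] <- pmax(0, trial_amp[g_trials, sup] -
                                         config$effect_dff)
    # facilitation: added transient at photostimulation offset
    if (length(fac))
      train[cbind(rep(stim_end[g_trials], length(fac)),
                  rep(fac, each = length(g_trials)))] <- config$effect_dff
  }
  train[onsets, ] <- train[onsets, ] + trial_amp
  sig <- doe_convolve(train, fr, config$kernel_rise_s, config$kernel_decay_s)
  f <- config$baseline_f * (1 + sig) +
    matrix(stats::rnorm(n_frames * n, 0, config$noise_sd * config$baseline_f),
           n_frames, n)
  traces <- t(f)
  rownames(traces) <- roi_meta$roi_id

  structure(list(traces = traces, frame_rate = fr, roi_meta = roi_meta,
                 trials = trials, groups = groups, ground_truth = gt,
                 config = config),
            class = "fbmap_session")
}

#' Simulate trial responses directly in R-statistic space
#'
#' Generates a per-ROI matrix of trial response statistics R (the
#' signal-to-background ratio used by responder detection) without the full
#' fluorescence synthesis: null ROIs draw R ~ N(0, 1) on every trial, true
#' responders gain a shift (in s.d. units) on V+P trials. Used for large
#' calibration runs of the detection stage where only the distribution of R
#' matters.
#'
#' @param n_rois number of ROIs.
#' @param n_v,n_vp numbers of visual-only and visual+photostimulation trials.
#' @param frac_responders fraction of ROIs given a true effect.
#' @param effect_sd shift on V+P trials in units of the null s.d.; negative
#'   values give suppressed responders.
#' @param orientations orientation labels cycled over trials of each type.
#' @param seed RNG seed.
#' @return an object of class `fbmap_responses` with elements `R`
#'   (ROIs x trials), `trial_type`, `orientation_deg` and logical `truth`.
#' @export
simulate_trial_responses <- function(n_rois = 500, n_v = 100, n_vp = 100,
                                     frac_responders = 0.1, effect_sd = 1,
                                     orientations = c(0, 90, 180, 270),
                                     seed = NULL) {
  set_seed_if(seed)
  n_tr <- n_v + n_vp
  type <- c(rep("V", n_v), rep("V+P", n_vp))
  orient <- c(rep_len(orientations, n_v), rep_len(orientations, n_vp))
  R <- matrix(stats::rnorm(n_rois * n_tr), n_rois, n_tr)
  n_true <- round(frac_responders * n_rois)
  truth <- rep(FALSE, n_rois)
  if (n_true > 0) {
    idx <- sample(n_rois, n_true)
    truth[idx] <- TRUE
    R[idx, type == "V+P"] <- R[idx, type == "V+P"] + effect_sd
  }
  structure(list(R = R, trial_type = type, orientation_deg = orient,
                 truth = truth),
            class = "fbmap_responses")
}

#' Simulate a photostimulation resolution probe
#'
#' Places neurons at graded lateral offsets from a stimulation target and
#' simulates trial response statistics in which each V+P trial activates the
#' neuron with probability given by the lateral Gaussian point spread
#' (activation probability `p_max` at offset zero, falling to half at one
#' lateral HWHM); activated trials add a fixed Z-shift. The response
#' probability versus offset therefore traces the point spread, which
#' [fit_response_psf()] recovers.
#'
#' @param offsets_um lateral offsets sampled.
#' @param n_per_offset neurons per offset.
#' @param n_vp,n_v trials per type.
#' @param p_max activation probability at zero offset.
#' @param activation_z Z-shift of activated trials.
#' @param lateral_hwhm_um point-spread lateral half-width at half maximum.
#' @param seed RNG seed.
#' @return list with `offset_um` (per neuron), `R_vp` and `R_v` matrices
#'   (neurons x trials).
#' @export
simulate_psf_probe <- function(offsets_um = seq(0, 60, by = 5),
                               n_per_offset = 5, n_vp = 100, n_v = 100,
                               p_max = 0.6, activation_z = 4,
                               lateral_hwhm_um = 20.7, seed = NULL) {
  set_seed_if(seed)
  offs <- rep(offsets_um, each = n_per_offset)
  n <- length(offs)
  p_act <- p_max * 2^(-(offs / lateral_hwhm_um)^2)
  R_v <- matrix(stats::rnorm(n * n_v), n, n_v)
  R_vp <- matrix(stats::rnorm(n * n_vp), n, n_vp)
  act <- matrix(stats::runif(n * n_vp), n, n_vp) < p_act
  R_vp[act] <- R_vp[act] + activation_z
  list(offset_um = offs, R_vp = R_vp, R_v = R_v)
}

#' Branch geometry for dendrite recordings
#'
#' A straight branch along x: a one-pixel line ROI with geodesic distances
#' from the proximal end (x = 0), and a mask ROI covering the branch width.
#'
#' @param length_um branch length.
#' @param um_per_px pixel size.
#' @param mask_halfwidth_px mask rows on each side of the line.
#' @return list with `line` (data.frame x_um, y_um, geodesic_um, px_row,
#'   px_col) and `mask` (data.frame x_um, y_um, px_row, px_col), plus `ny`,
#'   `nx` and `um_per_px`.
#' @export
branch_geometry <- function(length_um = 60, um_per_px = 0.5,
                            mask_halfwidth_px = 1) {
  nx <- round(length_um / um_per_px) + 1L
  ny <- 2L * mask_halfwidth_px + 1L
  mid <- mask_halfwidth_px + 1L
  line <- data.frame(px_row = mid, px_col = seq_len(nx),
                     x_um = (seq_len(nx) - 1L) * um_per_px, y_um = 0,
                     geodesic_um = (seq_len(nx) - 1L) * um_per_px)
  mask <- expand.grid(px_row = seq_len(ny), px_col = seq_len(nx))
  mask$x_um <- (mask$px_col - 1L) * um_per_px
  mask$y_um <- (mask$px_row - mid) * um_per_px
  list(line = line, mask = mask, ny = ny, nx = nx, um_per_px = um_per_px)
}

#' Simulate a branch movie containing local dendritic events
#'
#' Generates a pixel movie of one dendritic branch with local calcium events
#' injected as Gaussian spatial profiles along the geodesic axis (s.d.
#' `config$event_sigma_um`, so the default matches a 11.2-um FWHM event) and
#' difference-of-exponentials time courses, on a baseline of 1 with i.i.d.
#' Gaussian pixel noise.
#'
#' @param config a [generator_config()].
#' @param n_events number of events.
#' @param noise_sd pixel noise s.d. in dF/F units.
#' @param gap_s spacing between event slots (s).
#' @param seed RNG seed.
#' @return list of class `fbmap_branch_movie`: `movie` (ny x nx x frames
#'   array), `geometry`, `frame_rate`, `events` (frame, center_um, amp,
#'   sigma_um) and `config`.
#' @export
simulate_local_events <- function(config = generator_config(), n_events = 50,
                                  noise_sd = 0.05, gap_s = 6, seed = NULL) {
  stopifnot(inherits(config, "fbmap_config"))
  if (n_events < 1) stop("need at least one event")
  set_seed_if(seed)
  geom <- branch_geometry(config$branch_length_um, config$um_per_px)
  fr <- config$event_frame_rate
  gap <- round(gap_s * fr)
  onset <- gap + (seq_len(n_events) - 1L) * gap
  n_frames <- (n_events + 1L) * gap
  lo <- 0.15 * config$branch_length_um
  hi <- 0.85 * config$branch_length_um
  centers <- stats::runif(n_events, lo, hi)
  amps <- config$event_amp * exp(stats::rnorm(n_events, 0, 0.15))
  geo <- geom$line$geodesic_um
  # per-line-pixel event train, then share across mask rows
  train <- matrix(0, n_frames, geom$nx)
  for (e in seq_len(n_events)) {
    prof <- amps[e] * exp(-(geo - centers[e])^2 / (2 * config$event_sigma_um^2))
    train[onset[e], ] <- train[onset[e], ] + prof
  }
  sig <- doe_convolve(train, fr, config$kernel_rise_s,
                      min(config$kernel_decay_s, 0.8))
  movie <- array(1, dim = c(geom$ny, geom$nx, n_frames))
  for (r in seq_len(geom$ny)) movie[r, , ] <- 1 + t(sig)
  movie <- movie + array(stats::rnorm(length(movie), 0, noise_sd), dim(movie))
  structure(list(movie = movie, geometry = geom, frame_rate = fr,
                 events = data.frame(frame = onset, center_um = centers,
                                     amp = amps,
                                     sigma_um = config$event_sigma_um),
                 config = config),
            class = "fbmap_branch_movie")
}

#' Generate a synthetic dendrite spine-mapping recording
#'
#' Emulates a random-group stimulation experiment: a 3D target grid in the
#' source area, a stimulation log with random groups of targets per trial
#' (plus blank trials), per-spine fluorescence traces with independent spine
#' events, shared global dendritic events, and sparse true target-to-spine
#' connections whose stimulation evokes spine transients. Two branch ROI
#' traces (the stimulated branch, excluding the recipient spine, and a
#' reference branch) share the global activity; on stimulation trials the
#' stimulated branch's post-stimulus dF/F is multiplied by the configured
#' boosting factor.
#'
#' @param config a [generator_config()].
#' @param seed RNG seed.
#' @return object of class `fbmap_spine_recording`: `spine_traces`
#'   (spines x frames, raw F), `branch_traces` (2 x frames: `stim`, `ref`),
#'   `frame_rate`, `stim_log` (data.frame trial, onset_frame, offset_frame,
#'   blank, target_ids as list-column), `target_grid`, `ground_truth`
#'   (connections, boosting_factor, global_event_frames) and `config`.
#' @export
make_dendrite_recording <- function(config = generator_config(),
                                    seed = config$seed) {
  stopifnot(inherits(config, "fbmap_config"))
  if (config$n_targets < 1) stop("target grid must not be empty")
  if (config$n_spines < 2) stop("need at least two spines")
  set_seed_if(seed)
  fr <- config$dendrite_frame_rate
  n_sp <- config$n_spines
  n_tr <- config$n_stim_trials
  period <- round(config$stim_period_s * fr)
  stim_frames <- round(config$photostim_dur_s * fr)
  pre_pad <- 2L * period
  # trials run in blocks separated by pauses, so rolling baselines see
  # quiet fluorescence
  gap <- round(config$block_gap_s * fr)
  block_of <- (seq_len(n_tr) - 1L) %/% config$trials_per_block
  onset <- pre_pad + (seq_len(n_tr) - 1L) * period + block_of * gap
  offset <- onset + stim_frames
  n_frames <- max(offset) + period + gap
  if (max(offset) + 10L > n_frames) stop("stimulation log exceeds trace length")

  target_grid <- data.frame(target_id = seq_len(config$n_targets),
                            x_um = stats::runif(config$n_targets, 0, 400),
                            y_um = stats::runif(config$n_targets, 0, 400),
                            z_um = sample(c(0, 30, 60), config$n_targets,
                                          replace = TRUE))
  blank <- stats::runif(n_tr) < config$frac_blank
  k_rng <- config$targets_per_trial
  target_ids <- lapply(seq_len(n_tr), function(i) {
    if (blank[i]) return(integer(0))
    sample(config$n_targets, sample(seq(k_rng[1], min(k_rng[2],
                                                      config$n_targets)), 1))
  })

  # true connections: target j -> spine j, guaranteed a minimum number of
  # stimulations so recovery is assessable at desk scale
  n_conn <- min(config$n_connections, n_sp)
  connections <- data.frame(target_id = integer(0), spine_id = integer(0),
                            amp_dff = numeric(0))
  if (n_conn > 0) {
    conn_targets <- seq_len(n_conn)
    for (j in seq_len(n_conn)) {
      has <- vapply(target_ids, function(tt) conn_targets[j] %in% tt, logical(1))
      need <- config$n_connection_stims - sum(has)
      if (need > 0) {
        free <- which(!blank & !has)
        add <- free[sample(length(free), min(need, length(free)))]
        for (i in add) target_ids[[i]] <- c(target_ids[[i]], conn_targets[j])
      }
    }
    connections <- data.frame(target_id = conn_targets,
                              spine_id = seq_len(n_conn),
                              amp_dff = config$connection_amp_dff)
  }

  # event trains: frames x spines
  train <- matrix(0, n_frames, n_sp)
  n_ind <- stats::rpois(n_sp, config$spine_event_rate_hz * n_frames / fr)
  for (s in seq_len(n_sp)) {
    if (n_ind[s] > 0) {
      at <- sample(n_frames - 20L, n_ind[s])
      train[at, s] <- train[at, s] +
        config$spine_event_amp * exp(stats::rnorm(n_ind[s], 0, 0.2))
    }
  }
  n_glob <- stats::rpois(1, config$global_event_rate_hz * n_frames / fr)
  glob_at <- if (n_glob > 0) sort(sample(n_frames - 20L, n_glob)) else integer(0)
  train[glob_at, ] <- train[glob_at, ] + config$global_event_amp
  if (n_conn > 0) {
    for (j in seq_len(n_conn)) {
      hit <- which(vapply(target_ids, function(tt) connections$target_id[j] %in% tt,
                          logical(1)))
      train[offset[hit] + 1L, connections$spine_id[j]] <-
        train[offset[hit] + 1L, connections$spine_id[j]] +
        connections$amp_dff[j]
    }
  }
  sig <- doe_convolve(train, fr, config$kernel_rise_s, config$dendrite_decay_s)
  spine_traces <- t(1 + sig +
                      matrix(stats::rnorm(n_frames * n_sp, 0,
                                          config$spine_noise_sd),
                             n_frames, n_sp))
  rownames(spine_traces) <- paste0("spine", seq_len(n_sp))

  # branch ROIs: shared per-trial activity; boosting on stimulation trials
  btrain <- rep(0, n_frames)
  btrain[offset + 1L] <- exp(stats::rnorm(n_tr, 0, config$branch_amp_sd))
  bsig <- doe_convolve(btrain, fr, config$kernel_rise_s, config$dendrite_decay_s)
  bsig_stim <- bsig
  post <- outer(offset[!blank], seq_len(7L), `+`)
  bsig_stim[as.vector(post)] <- bsig_stim[as.vector(post)] *
    config$boosting_factor
  branch_traces <- rbind(
    stim = 1 + bsig_stim + stats::rnorm(n_frames, 0, 0.02),
    ref  = 1 + bsig + stats::rnorm(n_frames, 0, 0.02))

  stim_log <- data.frame(trial = seq_len(n_tr), onset_frame = onset,
                         offset_frame = offset, blank = blank)
  stim_log$target_ids <- target_ids
  structure(list(spine_traces = spine_traces, branch_traces = branch_traces,
                 frame_rate = fr, stim_log = stim_log,
                 target_grid = target_grid,
                 ground_truth = list(connections = connections,
                                     boosting_factor = config$boosting_factor,
                                     global_event_frames = glob_at),
                 config = config),
            class = "fbmap_spine_recording")
}
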