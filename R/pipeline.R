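# Session serialization, pipeline configuration and stage orchestration.

#' Write a population session to a directory
#'
#' Serializes a session as plain-text tables: `traces.csv` (ROIs x frames),
#' `roi_meta.csv`, `trials.csv`, `groups.csv`, `ground_truth.csv` and
#' `session.json` (frame rate and config).
#'
#' @param session a `fbmap_session`.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$traces, file.path(path, "traces.csv"),
                   row.names = FALSE)
  utils::write.csv(session$roi_meta, file.path(path, "roi_meta.csv"),
                   row.names = FALSE)
  utils::write.csv(session$trials, file.path(path, "trials.csv"),
                   row.names = FALSE)
  groups_df <- do.call(rbind, lapply(session$groups, function(g) {
    data.frame(group_id = g$group_id, area = g$area,
               target_roi_id = g$target_roi_ids,
               x_um = g$target_positions_um[, "x"],
               y_um = g$target_positions_um[, "y"],
               z_um = g$target_positions_um[, "z"])
  }))
  utils::write.csv(groups_df, file.path(path, "groups.csv"), row.names = FALSE)
  utils::write.csv(session$ground_truth, file.path(path, "ground_truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(frame_rate = session$frame_rate,
                            config = unclass(session$config)),
                       file.path(path, "session.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a population session from a directory
#'
#' Inverse of [write_session()]; `read_session(write_session(x))` restores
#' all tables. Missing files raise a schema error naming them; non-finite
#' trace rows are flagged.
#'
#' @param path session directory.
#' @return a `fbmap_session` (with `nan_rois` listing flagged ROIs).
#' @export
read_session <- function(path) {
  need <- c("traces.csv", "roi_meta.csv", "trials.csv", "groups.csv",
            "ground_truth.csv", "session.json")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop("session directory is missing: ", paste(missing, collapse = ", "))
  traces <- as.matrix(utils::read.csv(file.path(path, "traces.csv")))
  dimnames(traces) <- NULL
  roi_meta <- utils::read.csv(file.path(path, "roi_meta.csv"))
  rownames(traces) <- roi_meta$roi_id
  trials <- utils::read.csv(file.path(path, "trials.csv"))
  groups_df <- utils::read.csv(file.path(path, "groups.csv"))
  groups <- lapply(split(groups_df, groups_df$group_id), function(g) {
    list(group_id = g$group_id[1], area = g$area[1],
         target_roi_ids = g$target_roi_id,
         target_positions_um = cbind(x = g$x_um, y = g$y_um, z = g$z_um))
  })
  names(groups) <- NULL
  gt <- utils::read.csv(file.path(path, "ground_truth.csv"))
  meta <- jsonlite::read_json(file.path(path, "session.json"),
                              simplifyVector = TRUE)
  cfg <- meta$config
  cfg$seed <- if (is.null(cfg$seed)) NULL else cfg$seed
  nan_rois <- unname(which(!apply(traces, 1L, function(r) all(is.finite(r)))))
  structure(list(traces = traces, frame_rate = meta$frame_rate,
                 roi_meta = roi_meta, trials = trials, groups = groups,
                 ground_truth = gt,
                 config = structure(cfg, class = "fbmap_config"),
                 nan_rois = nan_rois),
            class = "fbmap_session")
}

#' Pipeline configuration
#'
#' Validates a nested configuration for [run_pipeline()]. Unknown keys are
#' rejected by name at every level; every run writes the fully resolved
#' configuration alongside its outputs.
#'
#' @param stages character vector of stages to run, in order; supported:
#'   `"synth"`, `"responders"`, `"topography"`.
#' @param seed global seed; per-stage substreams are derived from it by
#'   stage name, so adding a stage never perturbs another stage's draws.
#' @param generator named list of [generator_config()] overrides.
#' @param responders named list: `fdr_level`, `fdr_method`, `s_window_s`,
#'   `b_window_s`, `z_crit`, `speed_threshold`.
#' @param topography named list: `n_null`, `bin_deg`, `n_bins`,
#'   `smooth_bins`, `n_resamples`, `strength_bin`.
#' @return validated list of class `fbmap_pipeline_config`.
#' @export
pipeline_config <- function(stages = c("synth", "responders", "topography"),
                            seed = 1, generator = list(),
                            responders = list(), topography = list()) {
  known_stages <- c("synth", "responders", "topography")
  bad <- setdiff(stages, known_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  resp_defaults <- list(fdr_level = 0.025, fdr_method = "BH",
                        s_window_s = 0.5, b_window_s = 0.5, z_crit = 1.64,
                        speed_threshold = 3)
  topo_defaults <- list(n_null = 20000, bin_deg = 1.2, n_bins = 30,
                        smooth_bins = 5, n_resamples = 5000,
                        strength_bin = 10)
  check <- function(user, defaults, where) {
    bad <- setdiff(names(user), names(defaults))
    if (length(bad))
      stop("unknown config key(s) in ", where, ": ",
           paste(bad, collapse = ", "))
    defaults[names(user)] <- user
    defaults
  }
  gen_cfg <- do.call(generator_config, generator)  # rejects unknown keys
  structure(list(stages = stages, seed = seed, generator = unclass(gen_cfg),
                 responders = check(responders, resp_defaults, "responders"),
                 topography = check(topography, topo_defaults, "topography")),
            class = "fbmap_pipeline_config")
}

log_stage <- function(log_path, stage, params, counts, t0) {
  rec <- list(stage = stage, params = params, counts = counts,
              wall_s = round(as.numeric(Sys.time()) - t0, 3))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null"), "\n",
      file = log_path, append = TRUE, sep = "")
}

#' Run the analysis pipeline
#'
#' Orchestrates synthesis, responder detection and topography into a
#' deterministic artifact directory: `responders.csv` (per group and ROI),
#' `profiles.csv` (weighted distance profiles per group and sign),
#' `centroids.csv`, `resolved_config.json` and a JSON-lines `pipeline.log`.
#' Identical config and seed give byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created).
#' @param session optionally, an existing `fbmap_session` to analyse instead
#'   of synthesizing one (required when `"synth"` is not among the stages).
#' @return invisibly, a list with the session, responder table, profiles and
#'   the output directory.
#' @export
run_pipeline <- function(config, out_dir, session = NULL) {
  stopifnot(inherits(config, "fbmap_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  if (file.exists(log_path)) file.remove(log_path)
  jsonlite::write_json(unclass(config),
                       file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  fail <- function(stage, e) {
    cat(jsonlite::toJSON(list(stage = stage, error = conditionMessage(e)),
                         auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }

  if ("synth" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    session <- tryCatch(
      make_population_session(do.call(generator_config, config$generator),
                              seed = stage_seed(config$seed, "synth")),
      error = function(e) fail("synth", e))
    log_stage(log_path, "synth", list(seed = config$seed),
              list(rois = nrow(session$traces),
                   trials = nrow(session$trials)), t0)
  }
  if (is.null(session)) stop("no session: supply one or include a synth stage")

  responder_tab <- NULL
  resp_obj <- NULL
  if ("responders" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    rp <- config$responders
    responder_tab <- tryCatch({
      d <- dff(session$traces)
      resp_obj <- trial_responses(d, session$trials, session$frame_rate,
                                  s_window_s = rp$s_window_s,
                                  b_window_s = rp$b_window_s)
      do.call(rbind, lapply(session$groups, function(g) {
        tab <- detect_responders(resp_obj, group_id = g$group_id,
                                 fdr_level = rp$fdr_level,
                                 fdr_method = rp$fdr_method,
                                 seed = stage_seed(config$seed, "responders"))
        tab$group_id <- g$group_id
        tab
      }))
    }, error = function(e) fail("responders", e))
    utils::write.csv(responder_tab, file.path(out_dir, "responders.csv"),
                     row.names = FALSE)
    log_stage(log_path, "responders", rp,
              list(responders = sum(responder_tab$responder)), t0)
  }

  profiles <- NULL
  if ("topography" %in% config$stages) {
    if (is.null(responder_tab)) stop("topography requires a responders stage")
    t0 <- as.numeric(Sys.time())
    tp <- config$topography
    profiles <- tryCatch({
      prof_rows <- list()
      cent_rows <- list()
      meta <- session$roi_meta
      prefs <- cbind(meta$true_azimuth_deg, meta$true_elevation_deg)
      for (g in session$groups) {
        tab <- responder_tab[responder_tab$group_id == g$group_id, ]
        local_fac <- tab$roi_id[tab$responder &
                                  tab$sign %in% "facilitated" &
                                  meta$area == g$area]
        if (!length(local_fac)) next
        src <- prefs[local_fac, , drop = FALSE]
        other <- meta$area != g$area & meta$area != "border"
        for (sgn in c("facilitated", "suppressed")) {
          ids <- tab$roi_id[tab$responder & tab$sign %in% sgn & other]
          if (!length(ids)) next
          dd <- weighted_distance_distribution(
            retinotopic_distances(prefs[ids, , drop = FALSE], src),
            prefs[other, , drop = FALSE], src, n_null = tp$n_null,
            bin_deg = tp$bin_deg, n_bins = tp$n_bins,
            group_id = g$group_id, sign = sgn,
            seed = stage_seed(config$seed, paste0("null", g$group_id, sgn)))
          prof_rows[[length(prof_rows) + 1L]] <-
            data.frame(group_id = g$group_id, sign = sgn,
                       bin_mid_deg = dd$bin_mid_deg,
                       responder_prob = dd$responder_prob,
                       null_prob = dd$null_prob, weighted = dd$weighted)
          cent_rows[[length(cent_rows) + 1L]] <-
            data.frame(group_id = g$group_id, sign = sgn,
                       centroid_deg = distance_centroid(
                         retinotopic_distances(prefs[ids, , drop = FALSE],
                                               src)))
        }
      }
      list(profiles = do.call(rbind, prof_rows),
           centroids = do.call(rbind, cent_rows))
    }, error = function(e) fail("topography", e))
    if (!is.null(profiles$profiles))
      utils::write.csv(profiles$profiles, file.path(out_dir, "profiles.csv"),
                       row.names = FALSE)
    if (!is.null(profiles$centroids))
      utils::write.csv(profiles$centroids, file.path(out_dir, "centroids.csv"),
                       row.names = FALSE)
    log_stage(log_path, "topography", tp,
              list(profiles = if (is.null(profiles$profiles)) 0L else
                nrow(profiles$profiles)), t0)
  }

  invisible(list(session = session, responders = responder_tab,
                 profiles = profiles, out_dir = out_dir))
}

#' Write analysis tables to CSV
#'
#' @param tables named list of data.frames.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_results <- function(tables, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(path, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(path)
}
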