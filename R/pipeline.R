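#' Ground-truth tracks as a track set
#'
#' Repackages simulated microbubble trajectories as a `track_set`, the
#' pipeline's central exchange format, bypassing rendering and detection
#' (used for long acquisitions where the frame-level path is exercised on
#' short blocks only).
#'
#' @param truth a [simulate_microbubbles()] result.
#' @return a [track_set()].
#' @export
truth_tracks <- function(truth) {
  stopifnot(inherits(truth, "mb_truth"))
  track_set(truth$tracks, truth$frame_rate,
            params = list(source = "ground_truth"))
}

.log_stage <- function(log_file, stage, t0, ...) {
  rec <- c(list(stage = stage, elapsed_s = round(as.numeric(Sys.time()) - t0, 3)),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
      file = log_file, append = TRUE)
}

#' Run the full fULM pipeline
#'
#' Executes the stages in order on a simulated acquisition — phantom,
#' microbubble simulation, (optionally rendering, clutter filtering,
#' localization,) tracking, optional drift correction, rasterization, static
#' and rest/stim maps, sliding-window and pattern-averaged movies,
#' correlation and SVD activation analysis — and writes the artifacts
#' (tracks CSV, map TIFFs, movie TIFFs, activation maps, singular spectrum
#' CSV) plus a JSON-lines log with per-stage timings and counts to
#' `config$out_dir`. All randomness flows from `config$seed`. A stage
#' failure halts with a stage-named error; artifacts already written are
#' retained.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the in-memory results: `truth`, `tracks`,
#'   `path`, `maps`, `rest_stim`, `movie`, `pattern_movie`, `corr_map`,
#'   `svd`, `variation`, `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "fulm_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_file <- file.path(config$out_dir, "log.jsonl")
  cat("", file = log_file)
  t0 <- as.numeric(Sys.time())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  set.seed(config$seed)
  proto <- stim_protocol(config$rest_pre, config$stim, config$rest_post,
                         config$n_patterns)
  modul <- hemo_modulation(config$flux_gain, config$speed_gain,
                           config$diameter_gain, config$ramp)

  truth <- stage("simulate", {
    ph <- default_phantom(rate_mb_s = config$rate_mb_s)
    simulate_microbubbles(ph, proto, modul, duration = proto$acq_t,
                          frame_rate = config$frame_rate, seed = config$seed)
  })
  .log_stage(log_file, "simulate", t0, n_tracks = nrow(truth$arrivals),
             n_positions = nrow(truth$tracks))

  tracks <- if (config$mode == "frames") {
    stage("localize+track", {
      nf <- config$block_len
      n_blocks <- floor(proto$acq_t * config$frame_rate / nf)
      det <- vector("list", n_blocks)
      for (b in seq_len(n_blocks)) {
        blk <- render_frame_block(truth, t0 = (b - 1) * nf / config$frame_rate,
                                  n_frames = nf, pitch_z = config$pitch_z,
                                  pitch_x = config$pitch_x,
                                  psf_sigma = config$psf_sigma,
                                  clutter_rank = 3, noise_sigma = 0.02,
                                  seed = config$seed + b)
        filt <- svd_clutter_filter(blk, config$n_discard)
        det[[b]] <- localize_block(filt, config$psf_sigma,
                                   config$corr_threshold,
                                   config$interp_factor)
      }
      assemble_tracks(do.call(rbind, det), config$frame_rate,
                      config$max_speed, config$min_len)
    })
  } else stage("track", truth_tracks(truth))
  .log_stage(log_file, "track", t0,
             n_tracks = length(unique(tracks$tracks$track_id)))

  grid <- stage("grid", super_grid(truth$phantom$fov[1], truth$phantom$fov[2],
                                   config$pitch_z, config$pitch_x,
                                   config$sr_factor))
  if (config$drift_correction) {
    dc <- stage("drift", estimate_and_apply_drift(tracks, grid,
                                                  config$chunk_t))
    tracks <- dc$tracks
    write.csv(dc$shifts, file.path(config$out_dir, "drift_shifts.csv"),
              row.names = FALSE)
  }
  write_tracks(tracks, file.path(config$out_dir, "tracks.csv"))

  path <- stage("rasterize", rasterize_tracks(tracks, grid))
  .log_stage(log_file, "rasterize", t0, n_traversals = nrow(path))

  maps <- stage("maps", accumulate_maps(path, grid,
                                        min_count = config$min_count))
  rs <- stage("maps", split_rest_stim_maps(path, grid, proto,
                                           config$min_count))
  write_map(maps$count, file.path(config$out_dir, "count.tif"))
  write_map(maps$velocity, file.path(config$out_dir, "velocity.tif"))
  write_map(rs$rest$count, file.path(config$out_dir, "count_rest.tif"))
  write_map(rs$stim$count, file.path(config$out_dir, "count_stim.tif"))
  .log_stage(log_file, "maps", t0, valid_px = sum(maps$valid))

  movie <- stage("movie", build_sliding_movie(path, grid, proto$acq_t,
                                              config$w_t, config$step_t))
  pm <- stage("movie", pattern_average(movie, proto))
  write_movie(pm, file.path(config$out_dir, "pattern_movie"))

  act <- stage("fulm", {
    a <- stim_boxcar(proto, pm$t)
    cm <- correlation_map(pm, a)
    sv <- select_stim_mode(svd_decompose(pm), a, config$p_threshold)
    win <- phase_windows(proto, config$step_t)
    vm <- variation_map(sv, win$stim, win$base)
    list(corr = cm, svd = sv, variation = vm)
  })
  write_map(act$corr, file.path(config$out_dir, "correlation_map.tif"))
  write_map(act$variation, file.path(config$out_dir, "mb_svd_map.tif"))
  fwrite(data.table(mode = seq_along(act$svd$d), lambda = act$svd$d,
                    p = act$svd$p),
         file.path(config$out_dir, "svd_spectrum.csv"))
  .log_stage(log_file, "fulm", t0, i_stim = act$svd$i_stim,
             p_stim = act$svd$p[act$svd$i_stim], found = act$svd$found)

  invisible(list(truth = truth, tracks = tracks, path = path, maps = maps,
                 rest_stim = rs, movie = movie, pattern_movie = pm,
                 corr_map = act$corr, svd = act$svd,
                 variation = act$variation, out_dir = config$out_dir))
}
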