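#' @name fulm-io
#' @title File formats
#' @description Frame blocks and movies are stored as multi-page 32-bit TIFF
#'   plus a JSON sidecar with the acquisition metadata (values are min-max
#'   scaled into the TIFF range; the scale is recorded in the sidecar and
#'   undone on read, round-tripping to ~1e-9 relative error). Tracks and
#'   detections are CSV with fixed column schemas; configurations are YAML.
NULL

.write_pages <- function(arr, file) {
  lo <- min(arr); hi <- max(arr)
  sc <- if (hi > lo) (arr - lo) / (hi - lo) else arr * 0
  pages <- lapply(seq_len(dim(arr)[3]), function(k) sc[, , k])
  tiff::writeTIFF(pages, file, bits.per.sample = 32L, compression = "none")
  c(lo = lo, hi = hi)
}

.read_pages <- function(file, lo, hi) {
  pages <- tiff::readTIFF(file, all = TRUE)
  arr <- array(0, c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  if (hi > lo) arr * (hi - lo) + lo else arr
}

#' Write / read a frame block (TIFF + JSON sidecar)
#'
#' @param block a [frame_block()]; complex frames are stored as interleaved
#'   real/imaginary pages.
#' @param prefix file path without extension; writes `<prefix>.tif` and
#'   `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
write_frames <- function(block, prefix) {
  stopifnot(inherits(block, "frame_block"))
  fr <- block$frames
  cplx <- is.complex(fr)
  if (cplx) {
    d <- dim(fr)
    ri <- array(0, c(d[1], d[2], 2 * d[3]))
    ri[, , 2 * seq_len(d[3]) - 1] <- Re(fr)
    ri[, , 2 * seq_len(d[3])] <- Im(fr)
    fr <- ri
  }
  sc <- .write_pages(fr, paste0(prefix, ".tif"))
  meta <- list(frame_rate_hz = block$frame_rate, pitch_um_z = block$pitch_z,
               pitch_um_x = block$pitch_x, block_len = dim(block$frames)[3],
               t0_s = block$t0, complex = cplx,
               scale_min = sc[["lo"]], scale_max = sc[["hi"]])
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_frames
#' @export
read_frames <- function(prefix) {
  jf <- paste0(prefix, ".json"); tf <- paste0(prefix, ".tif")
  if (!file.exists(jf) || !file.exists(tf))
    stop("frame I/O error: missing ", if (!file.exists(tf)) tf else jf)
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  need <- c("frame_rate_hz", "pitch_um_z", "pitch_um_x", "block_len")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("frame metadata missing field: ", miss[1])
  arr <- .read_pages(tf, meta$scale_min, meta$scale_max)
  if (isTRUE(meta$complex)) {
    nf <- dim(arr)[3] / 2
    arr <- arr[, , 2 * seq_len(nf) - 1] + 1i * arr[, , 2 * seq_len(nf)]
  }
  if (dim(arr)[3] != meta$block_len)
    stop("frame I/O error: block_len mismatch in ", tf)
  frame_block(arr, meta$frame_rate_hz, meta$pitch_um_z, meta$pitch_um_x,
              meta$t0_s %||% 0)
}

.track_cols <- c("track_id", "frame", "t_s", "z_um", "x_um",
                 "vz_mm_s", "vx_mm_s", "v_mm_s")

#' Write / read tracks (CSV)
#'
#' Column schema: `track_id, frame, t_s, z_um, x_um, vz_mm_s, vx_mm_s,
#' v_mm_s`. Reading rejects files with missing columns, naming the first
#' missing field.
#'
#' @param tracks a `track_set` or data.frame of track positions.
#' @param file CSV path.
#' @export
write_tracks <- function(tracks, file) {
  tr <- if (inherits(tracks, "track_set")) tracks$tracks else tracks
  fwrite(as.data.table(tr)[, .track_cols, with = FALSE], file)
  invisible(file)
}

#' @rdname write_tracks
#' @param frame_rate frame rate to attach to the returned `track_set`.
#' @export
read_tracks <- function(file, frame_rate = 1000) {
  if (!file.exists(file)) stop("track I/O error: missing ", file)
  tr <- fread(file)
  miss <- setdiff(.track_cols, names(tr))
  if (length(miss)) stop("track schema mismatch: missing column \"",
                         miss[1], "\"")
  track_set(tr, frame_rate, params = list(source = file))
}

#' Write / read a pattern movie (TIFF pages + JSON attributes)
#'
#' Stores the microbubble count, flux and velocity arrays as multi-page
#' TIFF (velocity NA encoded by count = 0) with window parameters, pixel
#' pitch and protocol in the JSON sidecar. Reading a sidecar without a
#' protocol attribute succeeds with a warning.
#'
#' @param movie a `pattern_movie`.
#' @param prefix path without extension.
#' @export
write_movie <- function(movie, prefix) {
  stopifnot(inherits(movie, "pattern_movie"))
  sc_c <- .write_pages(movie$count, paste0(prefix, "_count.tif"))
  vel <- movie$velocity; vel[is.na(vel)] <- 0
  sc_v <- .write_pages(vel, paste0(prefix, "_velocity.tif"))
  meta <- list(w_t = movie$w_t, step_t = movie$step_t,
               pitch_um_z = movie$grid$pitch_z, pitch_um_x = movie$grid$pitch_x,
               n_patterns = movie$n_patterns,
               protocol = movie$protocol[c("rest_pre", "stim", "rest_post",
                                           "n_patterns")],
               count_scale = as.list(sc_c), velocity_scale = as.list(sc_v))
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname write_movie
#' @export
read_movie <- function(prefix) {
  jf <- paste0(prefix, ".json")
  if (!file.exists(jf)) stop("movie I/O error: missing ", jf)
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  for (f in c("w_t", "step_t", "pitch_um_z", "pitch_um_x"))
    if (is.null(meta[[f]])) stop("movie metadata missing field: ", f)
  cnt <- .read_pages(paste0(prefix, "_count.tif"),
                     meta$count_scale$lo, meta$count_scale$hi)
  cnt <- round(cnt)
  vel <- .read_pages(paste0(prefix, "_velocity.tif"),
                     meta$velocity_scale$lo, meta$velocity_scale$hi)
  vel[cnt == 0] <- NA_real_
  if (is.null(meta$protocol)) {
    warning("movie sidecar lacks a protocol attribute")
    proto <- NULL
  } else proto <- do.call(stim_protocol, as.list(meta$protocol))
  grid <- ulm_grid(dim(cnt)[1], dim(cnt)[2], meta$pitch_um_z, meta$pitch_um_x)
  structure(list(flux = cnt / meta$w_t, velocity = vel, count = cnt,
                 t = (seq_len(dim(cnt)[3]) - 0.5) * meta$step_t,
                 w_t = meta$w_t, step_t = meta$step_t, grid = grid,
                 protocol = proto,
                 n_patterns = meta$n_patterns %||% NA_integer_),
            class = "pattern_movie")
}

#' Write a 2D map as 32-bit TIFF (+ JSON scale sidecar)
#'
#' @param map numeric matrix (NA written as 0).
#' @param file `.tif` path; the scale sidecar is `<file>.json`.
#' @export
write_map <- function(map, file) {
  m <- map; m[is.na(m)] <- 0
  sc <- .write_pages(array(m, c(nrow(m), ncol(m), 1)), file)
  jsonlite::write_json(as.list(sc), paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' @rdname write_map
#' @export
read_map <- function(file) {
  sc <- jsonlite::read_json(paste0(file, ".json"), simplifyVector = TRUE)
  .read_pages(file, sc$lo, sc$hi)[, , 1]
}

.config_defaults <- function() list(
  seed = 1L,
  # acquisition / reconstruction
  frame_rate = 1000, pitch_z = 100, pitch_x = 110, sr_factor = 16,
  # stimulation protocol
  rest_pre = 30, stim = 30, rest_post = 10, n_patterns = 20,
  # phantom + modulation
  rate_mb_s = 0.5, flux_gain = 1.5, speed_gain = 1.2, diameter_gain = 1.2,
  ramp = 2,
  # processing (defaults follow the standard ULM settings)
  n_discard = 10, corr_threshold = 0.7, psf_sigma = 80, interp_factor = 6,
  max_speed = 100, min_len = 10, w_t = 5, step_t = 1, min_count = 5,
  p_threshold = 0.6, drift_correction = FALSE, chunk_t = 10,
  # pipeline mode: "truth" tracks directly, or "frames" via render ->
  # filter -> localize -> track (short acquisitions)
  mode = "truth", block_len = 400,
  out_dir = "fulm_out")

#' Pipeline configuration
#'
#' Builds a validated pipeline configuration from defaults (the standard
#' acquisition/processing values: PSF correlation 0.7, minimum track length
#' 10 frames, maximum speed 100 mm/s, 10 discarded singular values, 5-s
#' window with 1-s step, super-resolution factor 16, minimum 5 detections
#' per pixel) overridden by `...` or by a YAML file. Unknown keys are
#' rejected.
#'
#' @param ... named overrides of the defaults.
#' @param file optional YAML file of overrides.
#' @return named list of class `fulm_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- .config_defaults()
  over <- list(...)
  if (!is.null(file)) over <- modifyList(yaml::read_yaml(file), over)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown configuration key: ", unknown[1])
  cfg <- modifyList(cfg, over)
  if (!cfg$mode %in% c("truth", "frames"))
    stop("mode must be \"truth\" or \"frames\"")
  structure(cfg, class = "fulm_config")
}

#' @export
print.fulm_config <- function(x, ...) {
  cat("fulm_config:\n")
  str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Write a configuration to YAML
#' @param config a `fulm_config`.
#' @param file YAML path.
#' @export
write_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}
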