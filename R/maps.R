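#' Accumulate super-resolved count and velocity maps
#'
#' Counts all microbubble traversals per super-resolved pixel within a time
#' range and averages their velocities: the count map is the number of
#' distinct track traversals, the velocity map their mean speed (NA where no
#' traversal). Pixels accumulating fewer than `min_count` detections over the
#' range are flagged invalid for downstream analyses (default 5).
#'
#' @param path rasterized track paths from [rasterize_tracks()].
#' @param grid the [ulm_grid()] the paths were rasterized on.
#' @param t_range optional `c(t0, t1)` half-open selection `[t0, t1)` in s.
#' @param t_filter optional logical-returning function of the traversal
#'   times, for non-contiguous selections (e.g. stimulation phases).
#' @param min_count validity threshold on per-pixel detections.
#' @return object of class `ulm_maps`: matrices `count`, `velocity`, `vz`,
#'   `vx` (mean velocity components), logical `valid`, and the grid.
#' @export
accumulate_maps <- function(path, grid, t_range = NULL, t_filter = NULL,
                            min_count = 5) {
  if (!is.null(t_range)) {
    if (length(t_range) != 2 || t_range[2] <= t_range[1])
      stop("empty t_range")
    path <- path[path$t_s >= t_range[1] & path$t_s < t_range[2], ]
  }
  if (!is.null(t_filter)) path <- path[t_filter(path$t_s), ]
  npix <- grid$nz * grid$nx
  idx <- (path$ix - 1L) * grid$nz + path$iz
  count <- matrix(tabulate(idx, npix), grid$nz, grid$nx)
  vsum <- matrix(0, grid$nz, grid$nx)
  vzsum <- matrix(0, grid$nz, grid$nx)
  vxsum <- matrix(0, grid$nz, grid$nx)
  if (nrow(path)) {
    ag <- data.table(idx = idx, v = path$v_mm_s, vz = path$vz_mm_s,
                     vx = path$vx_mm_s)[, lapply(.SD, sum), by = "idx"]
    vsum[ag$idx] <- ag$v; vzsum[ag$idx] <- ag$vz; vxsum[ag$idx] <- ag$vx
  }
  velocity <- ifelse(count > 0, vsum / pmax(count, 1), NA_real_)
  vz <- ifelse(count > 0, vzsum / pmax(count, 1), NA_real_)
  vx <- ifelse(count > 0, vxsum / pmax(count, 1), NA_real_)
  structure(list(count = count, velocity = velocity, vz = vz, vx = vx,
                 valid = count >= min_count, grid = grid,
                 min_count = min_count),
            class = "ulm_maps")
}

#' @export
print.ulm_maps <- function(x, ...) {
  cat(sprintf("ulm_maps: %d x %d px, %d traversals, %d valid px\n",
              x$grid$nz, x$grid$nx, sum(x$count), sum(x$valid)))
  invisible(x)
}

# window-index run [kmin, kmax] of a detection at time tau:
# window k is [c_k - w/2, c_k + w/2) with center c_k = (k - 0.5) * step
.window_run <- function(tau, w, step, nt) {
  kmin <- floor((tau - w / 2) / step + 0.5) + 1
  kmax <- floor((tau + w / 2) / step + 0.5)
  list(kmin = pmax(1L, as.integer(kmin)), kmax = pmin(nt, as.integer(kmax)))
}

#' Sliding-window dynamic ULM movie
#'
#' Rasterizes track traversals into a 3D matrix M(z, x, t): for each window
#' center t the 2D map counts the microbubbles whose interpolated traversal
#' time falls in the half-open window `[t - W/2, t + W/2)`, together with the
#' mean traversal speed. Window centers sit at `(k - 0.5) * Step_t`,
#' `k = 1..Nt` with `Nt = Acq_t / Step_t`; windows extending past the
#' acquisition are truncated (no wrap). The default 5-s window with a 1-s
#' step follows the standard dynamic-ULM setting.
#'
#' @param path rasterized paths from [rasterize_tracks()].
#' @param grid an [ulm_grid()].
#' @param acq_t acquisition duration in s.
#' @param w_t window length in s (> 0).
#' @param step_t window step in s.
#' @return object of class `ulm_movie` holding sparse per-window triplets
#'   (`pix`, `k`, `n`, `vsum`), dims `c(nz, nx, nt)`, the grid and the
#'   window parameters. Use [movie_array()] for dense arrays.
#' @export
build_sliding_movie <- function(path, grid, acq_t, w_t = 5, step_t = 1) {
  if (w_t <= 0) stop("w_t must be > 0")
  if (w_t < step_t) warning("w_t < step_t: windows do not cover all data")
  nt <- as.integer(round(acq_t / step_t))
  # expand each traversal into its window-index run, in batches to cap memory
  nb <- max(1L, ceiling(nrow(path) / 500000))
  bounds <- floor(seq(0, nrow(path), length.out = nb + 1))
  parts <- vector("list", nb)
  for (b in seq_len(nb)) {
    sel <- (bounds[b] + 1):bounds[b + 1]
    run <- .window_run(path$t_s[sel], w_t, step_t, nt)
    nrep <- pmax(0L, run$kmax - run$kmin + 1L)
    keep <- nrep > 0L
    rows <- sel[rep.int(which(keep), nrep[keep])]
    k <- sequence(nrep[keep]) - 1L + rep.int(run$kmin[keep], nrep[keep])
    parts[[b]] <- data.table(
      pix = (path$ix[rows] - 1L) * grid$nz + path$iz[rows],
      k = k, v = path$v_mm_s[rows])[
        , list(n = .N, vsum = sum(v)), by = c("pix", "k")]
  }
  trip <- rbindlist(parts)
  if (nb > 1L)
    trip <- trip[, list(n = sum(n), vsum = sum(vsum)), by = c("pix", "k")]
  structure(list(idx = trip, dims = c(grid$nz, grid$nx, nt), grid = grid,
                 w_t = w_t, step_t = step_t, acq_t = acq_t),
            class = "ulm_movie")
}

#' @export
print.ulm_movie <- function(x, ...) {
  cat(sprintf("ulm_movie: %d x %d px, %d windows (W = %g s, step = %g s)\n",
              x$dims[1], x$dims[2], x$dims[3], x$w_t, x$step_t))
  invisible(x)
}

#' Dense array view of a sliding-window movie
#'
#' @param movie an `ulm_movie`.
#' @param what `"count"` (default) or `"velocity"` (mean speed; NA where the
#'   count is zero).
#' @return `nz x nx x nt` array.
#' @export
movie_array <- function(movie, what = c("count", "velocity")) {
  what <- match.arg(what)
  a <- array(if (what == "count") 0 else NA_real_, movie$dims)
  off <- (movie$idx$k - 1) * movie$dims[1] * movie$dims[2] + movie$idx$pix
  if (what == "count") a[off] <- movie$idx$n
  else a[off] <- movie$idx$vsum / movie$idx$n
  a
}

#' Pattern-averaged movie with flux normalization
#'
#' Accumulates the sliding-window movie at equivalent time points of the
#' repeated stimulation pattern: counts from the `Nb_pattern` repetitions are
#' summed per pattern phase and divided by the window length, giving a
#' microbubble flux in MB/s; velocities pool all microbubbles detected in the
#' phase window across repetitions (population mean, not a mean of
#' per-repetition means). The pattern movie has `Nt_s = Pattern_t / Step_t`
#' time points.
#'
#' @param movie an `ulm_movie` spanning `n_patterns * pattern_t` seconds.
#' @param protocol the [stim_protocol()] used during acquisition.
#' @param patterns optional integer subset of pattern repetitions to
#'   accumulate (default all).
#' @return object of class `pattern_movie`: arrays `flux` (MB/s), `velocity`
#'   (mm/s, NA where empty) and `count` of dim `nz x nx x nts`, phase centers
#'   `t` (s), plus window parameters and the protocol.
#' @export
pattern_average <- function(movie, protocol, patterns = NULL) {
  nts <- protocol$pattern_t / movie$step_t
  if (abs(nts - round(nts)) > 1e-9)
    stop("pattern_t must be a multiple of step_t")
  nts <- as.integer(round(nts))
  nt <- movie$dims[3]
  if (abs(nt - protocol$n_patterns * nts) > 0)
    stop("acquisition length does not match protocol (Nt = ", nt,
         ", expected ", protocol$n_patterns * nts, ")")
  trip <- movie$idx
  pat <- ((trip$k - 1L) %/% nts) + 1L
  if (!is.null(patterns)) trip <- trip[pat %in% patterns]
  ks <- ((trip$k - 1L) %% nts) + 1L
  ag <- data.table(pix = trip$pix, ks = ks, n = trip$n, vsum = trip$vsum)[
    , list(n = sum(n), vsum = sum(vsum)), by = c("pix", "ks")]
  nzx <- movie$dims[1] * movie$dims[2]
  cnt <- array(0, c(movie$dims[1], movie$dims[2], nts))
  vel <- array(NA_real_, c(movie$dims[1], movie$dims[2], nts))
  off <- (ag$ks - 1) * nzx + ag$pix
  cnt[off] <- ag$n
  vel[off] <- ag$vsum / ag$n
  structure(list(flux = cnt / movie$w_t, velocity = vel, count = cnt,
                 t = (seq_len(nts) - 0.5) * movie$step_t,
                 w_t = movie$w_t, step_t = movie$step_t, grid = movie$grid,
                 protocol = protocol,
                 n_patterns = if (is.null(patterns)) protocol$n_patterns
                              else length(patterns)),
            class = "pattern_movie")
}

#' @export
print.pattern_movie <- function(x, ...) {
  cat(sprintf("pattern_movie: %d x %d px, %d phase points (W = %g s, %d patterns)\n",
              dim(x$flux)[1], dim(x$flux)[2], dim(x$flux)[3], x$w_t, x$n_patterns))
  invisible(x)
}

# integer+subpixel translation (dz, dx, pixels) of b relative to a,
# by the cross-correlation peak (FFT), with quadratic peak interpolation
.xcorr_shift <- function(a, b) {
  fa <- fft(a); fb <- fft(b)
  cc <- Re(fft(fa * Conj(fb), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  nz <- nrow(a); nx <- ncol(a)
  wrap <- function(i, n) ifelse(i > n / 2, i - n, i)
  dz <- wrap(pk[1] - 1, nz); dx <- wrap(pk[2] - 1, nx)
  # sub-pixel: 1D quadratic interpolation around the peak
  qz <- c(cc[(pk[1] - 2) %% nz + 1, pk[2]], cc[pk[1], pk[2]], cc[pk[1] %% nz + 1, pk[2]])
  qx <- c(cc[pk[1], (pk[2] - 2) %% nx + 1], cc[pk[1], pk[2]], cc[pk[1], pk[2] %% nx + 1])
  sub <- function(q) {
    den <- q[1] - 2 * q[2] + q[3]
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (q[1] - q[3]) / den))
  }
  c(dz + sub(qz), dx + sub(qx))
}

#' Estimate and correct slow motion drift
#'
#' Slow drift over the >20-min acquisition is estimated by intensity-based
#' translation registration of per-chunk microbubble count maps (default
#' 10-s chunks) against the first chunk, using the FFT cross-correlation peak
#' with quadratic sub-pixel interpolation. The estimated shift of each chunk
#' is subtracted from all microbubble coordinates in that chunk.
#'
#' @param tracks a `track_set` (or data.frame of track positions).
#' @param grid registration grid (super-resolved pitch works; a moderately
#'   smoothed count map is used).
#' @param chunk_t chunk duration in s (default 10).
#' @param smooth_px Gaussian smoothing of the count maps before registration,
#'   in pixels.
#' @return list with `tracks` (corrected, same class as input) and `shifts`
#'   (data.frame: chunk, t0, dz_um, dx_um).
#' @export
estimate_and_apply_drift <- function(tracks, grid, chunk_t = 10,
                                     smooth_px = 2) {
  tr <- if (inherits(tracks, "track_set")) tracks$tracks else as.data.table(tracks)
  acq <- max(tr$t_s)
  n_chunks <- max(1L, ceiling(acq / chunk_t - 1e-9))
  if (n_chunks < 2) stop("need >= 2 chunks for drift estimation")
  chunk_of <- pmin(n_chunks, floor(tr$t_s / chunk_t) + 1L)
  count_map <- function(rows) {
    sn <- snap_to_grid(tr$z_um[rows], tr$x_um[rows], grid)
    ok <- sn$inside
    m <- matrix(tabulate((sn$ix[ok] - 1L) * grid$nz + sn$iz[ok],
                         grid$nz * grid$nx), grid$nz, grid$nx)
    if (smooth_px > 0) gblur(m, sigma = smooth_px) else m
  }
  ref <- count_map(which(chunk_of == 1L))
  shifts <- matrix(0, n_chunks, 2)
  for (ch in 2:n_chunks) {
    rows <- which(chunk_of == ch)
    if (!length(rows)) next
    m <- count_map(rows)
    if (sum(m) == 0 || sum(ref) == 0) {
      warning("registration failed for chunk ", ch, "; zero shift")
      next
    }
    shifts[ch, ] <- -.xcorr_shift(m, ref)  # correction = minus the drift
  }
  dz_um <- shifts[, 1] * grid$pitch_z
  dx_um <- shifts[, 2] * grid$pitch_x
  tr <- as.data.table(tr)
  tr$z_um <- tr$z_um + dz_um[chunk_of]
  tr$x_um <- tr$x_um + dx_um[chunk_of]
  out <- if (inherits(tracks, "track_set")) {
    t2 <- tracks; t2$tracks <- tr; t2
  } else tr
  list(tracks = out,
       shifts = data.frame(chunk = seq_len(n_chunks),
                           t0 = (seq_len(n_chunks) - 1) * chunk_t,
                           dz_um = dz_um, dx_um = dx_um))
}

#' Rest- and stimulation-period maps
#'
#' Splits the traversals into the baseline subset (pattern phase 0 s to
#' `rest_pre`) and the stimulation subset (`rest_pre` to `rest_pre + stim`),
#' discarding the post-stimulus rest, and accumulates a (count, velocity) map
#' pair for each.
#'
#' @param path rasterized paths from [rasterize_tracks()].
#' @param grid an [ulm_grid()].
#' @param protocol the [stim_protocol()].
#' @param min_count validity threshold, as in [accumulate_maps()].
#' @return list with elements `rest` and `stim`, each an `ulm_maps`.
#' @export
split_rest_stim_maps <- function(path, grid, protocol, min_count = 5) {
  phase <- path$t_s %% protocol$pattern_t
  rest <- accumulate_maps(path[phase < protocol$rest_pre, ], grid,
                          min_count = min_count)
  stim <- accumulate_maps(path[phase >= protocol$rest_pre &
                               phase < protocol$rest_pre + protocol$stim, ],
                          grid, min_count = min_count)
  list(rest = rest, stim = stim)
}
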