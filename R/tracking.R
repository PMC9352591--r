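#' Link detections between two consecutive frames
#'
#' Minimal total-Euclidean-distance one-to-one assignment between the
#' detections of two consecutive ultrafast frames, gated at the distance a
#' microbubble can travel in one frame period at `max_speed` (default
#' 100 mm/s, i.e. 100 um at 1000 Hz). Solved as a linear assignment problem
#' (Hungarian method via `clue::solve_LSAP`) on a square matrix padded with
#' one dummy node per detection at gate cost, so unassigned detections start
#' or terminate tracks.
#'
#' @param det_a,det_b data.frames with `z_um`, `x_um` for frames t and t+1.
#' @param max_speed maximum linking speed in mm/s.
#' @param frame_rate frame rate in Hz.
#' @return data.frame with columns `i`, `j` (row indices into `det_a`,
#'   `det_b`) and `dist`; attribute `cost` holds the total assignment cost
#'   (matched distances plus gate cost per unmatched detection).
#' @export
link_frames <- function(det_a, det_b, max_speed = 100, frame_rate = 1000) {
  gate <- max_speed * 1000 / frame_rate      # um per frame period
  n <- nrow(det_a); m <- nrow(det_b)
  empty <- data.frame(i = integer(), j = integer(), dist = numeric())
  if (n == 0 || m == 0) {
    attr(empty, "cost") <- gate * (n + m)
    return(empty)
  }
  D <- sqrt(outer(det_a$z_um, det_b$z_um, "-")^2 +
            outer(det_a$x_um, det_b$x_um, "-")^2)
  big <- (n + m + 2) * gate + 1
  C <- matrix(big, n + m, n + m)
  C[seq_len(n), seq_len(m)] <- ifelse(D <= gate, D, big)
  C[cbind(seq_len(n), m + seq_len(n))] <- gate     # dummy sinks for frame t
  C[cbind(n + seq_len(m), seq_len(m))] <- gate     # dummy sources for t+1
  C[n + seq_len(m), m + seq_len(n)] <- 0           # dummy-dummy, free
  sol <- as.integer(solve_LSAP(C))
  i <- seq_len(n)
  j <- sol[i]
  real <- j <= m & C[cbind(i, j)] < big
  out <- data.frame(i = i[real], j = j[real], dist = D[cbind(i[real], j[real])])
  attr(out, "cost") <- sum(out$dist) + gate * ((n - nrow(out)) + (m - nrow(out)))
  out
}

#' Assemble detections into microbubble tracks
#'
#' Links detections frame by frame ([link_frames()]), with no gap filling: a
#' missing frame terminates every active track. Tracks observed in fewer than
#' `min_len` successive ultrafast frames are discarded (default 10).
#' Interframe velocities are attached with [compute_velocities()].
#'
#' @param detections data.frame with `frame`, `t_s`, `z_um`, `x_um` (and any
#'   extra columns, which are carried through).
#' @param frame_rate frame rate in Hz.
#' @param max_speed maximum linking speed, mm/s.
#' @param min_len minimum track length in frames.
#' @return An object of class `track_set`: `tracks` (data.table with
#'   `track_id`, `frame`, `t_s`, `z_um`, `x_um`, `vz_mm_s`, `vx_mm_s`,
#'   `v_mm_s`), `frame_rate` and the linking parameters.
#' @export
assemble_tracks <- function(detections, frame_rate = 1000, max_speed = 100,
                            min_len = 10) {
  stopifnot(all(c("frame", "t_s", "z_um", "x_um") %in% names(detections)))
  det <- as.data.frame(detections)[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(det$frame))
  rows_by_frame <- split(seq_len(nrow(det)), det$frame)
  track_rows <- list()                 # closed + growing tracks (row indices)
  active <- integer(0)                 # indices into track_rows
  prev_frame <- NULL
  for (fi in seq_along(frames)) {
    fr <- frames[fi]
    rows <- rows_by_frame[[as.character(fr)]]
    if (!is.null(prev_frame) && fr == prev_frame + 1L && length(active)) {
      last_rows <- vapply(track_rows[active], function(r) r[length(r)], 0L)
      lk <- link_frames(det[last_rows, , drop = FALSE],
                        det[rows, , drop = FALSE], max_speed, frame_rate)
      matched_b <- rep(FALSE, length(rows))
      new_active <- integer(0)
      if (nrow(lk)) {
        for (k in seq_len(nrow(lk))) {
          ti <- active[lk$i[k]]
          track_rows[[ti]] <- c(track_rows[[ti]], rows[lk$j[k]])
          matched_b[lk$j[k]] <- TRUE
        }
        new_active <- active[lk$i]
      }
      for (r in rows[!matched_b]) {
        track_rows[[length(track_rows) + 1L]] <- r
        new_active <- c(new_active, length(track_rows))
      }
      active <- new_active
    } else {
      # gap (or first frame): close all active tracks, start fresh
      active <- integer(0)
      for (r in rows) {
        track_rows[[length(track_rows) + 1L]] <- r
        active <- c(active, length(track_rows))
      }
    }
    prev_frame <- fr
  }
  keep <- which(lengths(track_rows) >= min_len)
  if (!length(keep)) {
    tr <- data.table(track_id = integer(), frame = integer(), t_s = numeric(),
                     z_um = numeric(), x_um = numeric(), vz_mm_s = numeric(),
                     vx_mm_s = numeric(), v_mm_s = numeric())
  } else {
    tr <- rbindlist(lapply(seq_along(keep), function(k) {
      d <- det[track_rows[[keep[k]]], , drop = FALSE]
      cbind(data.table(track_id = k), as.data.table(d))
    }))
    vel <- tr[, compute_velocities(.SD, frame_rate), by = "track_id"]
    tr[, c("vz_mm_s", "vx_mm_s", "v_mm_s") :=
         list(vel$vz_mm_s, vel$vx_mm_s, vel$v_mm_s)]
  }
  track_set(tr, frame_rate,
            params = list(max_speed = max_speed, min_len = min_len))
}

#' Track set container
#'
#' @param tracks data.table/data.frame of time-stamped track positions.
#' @param frame_rate acquisition frame rate, Hz.
#' @param params provenance: the parameters used to build the tracks.
#' @return object of class `track_set`.
#' @export
track_set <- function(tracks, frame_rate, params = list()) {
  tracks <- as.data.table(tracks)
  structure(list(tracks = tracks, frame_rate = frame_rate, params = params),
            class = "track_set")
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("track_set: %d tracks, %d positions at %g Hz\n",
              length(unique(x$tracks$track_id)), nrow(x$tracks), x$frame_rate))
  invisible(x)
}

#' Interframe velocities along a track
#'
#' Finite differences of successive positions times the frame rate, in mm/s,
#' plus the speed magnitude. The per-step velocity is attached to the first
#' sample of each step; the last sample repeats the final step's velocity so
#' every detection carries one.
#'
#' @param track data.frame with `t_s`, `z_um`, `x_um` (>= 2 rows, ordered).
#' @param frame_rate frame rate in Hz.
#' @return data.frame with `vz_mm_s`, `vx_mm_s`, `v_mm_s`.
#' @export
compute_velocities <- function(track, frame_rate) {
  n <- nrow(track)
  if (n < 2) return(data.frame(vz_mm_s = NA_real_, vx_mm_s = NA_real_,
                               v_mm_s = NA_real_)[seq_len(n), , drop = FALSE])
  vz <- diff(track$z_um) * frame_rate / 1000
  vx <- diff(track$x_um) * frame_rate / 1000
  vz <- c(vz, vz[n - 1]); vx <- c(vx, vx[n - 1])
  data.frame(vz_mm_s = vz, vx_mm_s = vx, v_mm_s = sqrt(vz^2 + vx^2))
}

#' Rasterize tracks onto the super-resolved grid
#'
#' Dense linear interpolation between consecutive detections so that every
#' super-resolved pixel crossed by a track segment is counted exactly once
#' per traversal (a pixel revisited in a later pass counts again; the count
#' map is a passage count). Each path pixel carries a linearly interpolated
#' timestamp and the local step velocity.
#'
#' @param tracks a `track_set` or a data.frame with `track_id`, `t_s`,
#'   `z_um`, `x_um`, `vz_mm_s`, `vx_mm_s`, `v_mm_s`.
#' @param grid an [ulm_grid()].
#' @param sample_step sampling step along the segment in um (default 1/8 of
#'   the smaller grid pitch; small enough that no crossed pixel is skipped).
#' @param batch_rows process the track table in batches of about this many
#'   rows (caps peak memory of the dense sampling).
#' @return data.table with `track_id`, `iz`, `ix`, `t_s`, `vz_mm_s`,
#'   `vx_mm_s`, `v_mm_s` — one row per pixel traversal.
#' @export
rasterize_tracks <- function(tracks, grid, sample_step = NULL,
                             batch_rows = 200000L) {
  tr <- if (inherits(tracks, "track_set")) tracks$tracks else as.data.table(tracks)
  if (!nrow(tr))
    return(data.table(track_id = integer(), iz = integer(), ix = integer(),
                      t_s = numeric(), vz_mm_s = numeric(), vx_mm_s = numeric(),
                      v_mm_s = numeric()))
  if (is.null(sample_step)) sample_step <- min(grid$pitch_z, grid$pitch_x) / 8
  tr <- as.data.table(tr)[order(track_id, t_s)]
  if (nrow(tr) > batch_rows) {
    ids <- unique(tr$track_id)
    nb <- ceiling(nrow(tr) / batch_rows)
    grp <- split(ids, cut(seq_along(ids), nb, labels = FALSE))
    out <- lapply(grp, function(g)
      rasterize_tracks(tr[tr$track_id %in% g, ], grid, sample_step,
                       batch_rows = .Machine$integer.max))
    return(rbindlist(out))
  }
  same <- tr$track_id[-1] == tr$track_id[-nrow(tr)]
  i0 <- which(c(same, FALSE)); i1 <- i0 + 1L
  single <- setdiff(seq_len(nrow(tr)), union(i0, i1))  # one-point tracks
  if (length(i0)) {
    len <- sqrt((tr$z_um[i1] - tr$z_um[i0])^2 + (tr$x_um[i1] - tr$x_um[i0])^2)
    nseg <- pmax(2L, ceiling(len / sample_step) + 1L)
    step_id <- rep.int(seq_along(i0), nseg)
    frac <- (sequence(nseg) - 1) / (nseg[step_id] - 1)
    a <- i0[step_id]; b <- i1[step_id]
    z <- tr$z_um[a] + frac * (tr$z_um[b] - tr$z_um[a])
    x <- tr$x_um[a] + frac * (tr$x_um[b] - tr$x_um[a])
    t <- tr$t_s[a] + frac * (tr$t_s[b] - tr$t_s[a])
    sn <- snap_to_grid(z, x, grid)
    path <- data.table(track_id = tr$track_id[a], iz = sn$iz, ix = sn$ix,
                       t_s = t, vz_mm_s = tr$vz_mm_s[a],
                       vx_mm_s = tr$vx_mm_s[a], v_mm_s = tr$v_mm_s[a])
    # one row per pixel traversal: collapse consecutive duplicates
    chg <- c(TRUE, path$track_id[-1] != path$track_id[-nrow(path)] |
                   path$iz[-1] != path$iz[-nrow(path)] |
                   path$ix[-1] != path$ix[-nrow(path)])
    chg[is.na(chg)] <- TRUE
    path <- path[chg & !is.na(path$iz)]
  } else path <- NULL
  if (length(single)) {
    sn <- snap_to_grid(tr$z_um[single], tr$x_um[single], grid)
    extra <- data.table(track_id = tr$track_id[single], iz = sn$iz, ix = sn$ix,
                        t_s = tr$t_s[single], vz_mm_s = tr$vz_mm_s[single],
                        vx_mm_s = tr$vx_mm_s[single], v_mm_s = tr$v_mm_s[single])
    path <- rbindlist(list(path, extra[!is.na(extra$iz)]))
  }
  setorder(path, track_id, t_s)
  path[]
}
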