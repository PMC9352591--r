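#' Build a 2D vascular phantom
#'
#' Assembles a branched 2D vascular tree from centerline segments. Each
#' segment is a polyline in the (z = depth, x = lateral) plane with a lumen
#' radius, a baseline advection speed, a baseline microbubble arrival rate, a
#' vascular compartment label and an `activated` flag. When no label is given
#' the segment is classified from its flow direction: predominantly descending
#' flow (Vz > 0) is a penetrating arteriole, ascending flow (Vz < 0) a venule;
#' predominantly horizontal segments are pial when they start shallower than
#' `pial_depth`, intraparenchymal otherwise.
#'
#' @param segments list of segment specifications. Each element is a list with
#'   `p0`, `p1` (numeric `c(z, x)` endpoints in um) or `pts` (n x 2 matrix of
#'   polyline vertices, columns z, x), `radius_um` (> 0), `speed_mm_s` (>= 0),
#'   `rate_mb_s` (>= 0 microbubbles per second), optional `label` (one of
#'   `"pial"`, `"penetrating_arteriole"`, `"venule"`, `"intraparenchymal"`)
#'   and optional `activated` (default FALSE).
#' @param pial_depth depth (um) above which horizontal vessels are pial.
#' @param seed optional seed (reserved for randomized branching; segment
#'   construction itself is deterministic).
#' @param fov optional field of view `c(z, x)` in um; defaults to the
#'   segment bounding box plus a 100-um margin.
#' @return An object of class `vascular_phantom`: list of normalized segments
#'   plus the bounding field of view `fov = c(z, x)` in um.
#' @examples
#' ph <- build_phantom(list(list(p0 = c(100, 300), p1 = c(1100, 300),
#'                               radius_um = 15, speed_mm_s = 10, rate_mb_s = 0.5)))
#' ph$segments[[1]]$label  # "penetrating_arteriole" (descending flow)
#' @export
build_phantom <- function(segments, pial_depth = 200, seed = NULL,
                          fov = NULL) {
  stopifnot(is.list(segments), length(segments) >= 1)
  if (!is.null(seed)) set.seed(seed)
  labels <- c("pial", "penetrating_arteriole", "venule", "intraparenchymal")
  segs <- lapply(seq_along(segments), function(i) {
    s <- segments[[i]]
    pts <- if (!is.null(s$pts)) as.matrix(s$pts) else rbind(s$p0, s$p1)
    storage.mode(pts) <- "double"
    if (nrow(pts) < 2) stop("segment ", i, ": needs at least two vertices")
    d <- diff(pts)
    edge_len <- sqrt(rowSums(d^2))
    if (any(edge_len == 0) || sum(edge_len) == 0)
      stop("segment ", i, ": zero-length segment")
    stopifnot(s$radius_um > 0, s$speed_mm_s >= 0, s$rate_mb_s >= 0)
    # net flow direction over the whole polyline
    net <- pts[nrow(pts), ] - pts[1, ]
    label <- s$label
    if (is.null(label)) {
      if (abs(net[1]) >= abs(net[2])) {
        label <- if (net[1] > 0) "penetrating_arteriole" else "venule"
      } else {
        label <- if (min(pts[, 1]) < pial_depth) "pial" else "intraparenchymal"
      }
    }
    label <- match.arg(label, labels)
    if (label == "penetrating_arteriole" && net[1] <= 0)
      stop("segment ", i, ": arteriole must have descending flow (Vz > 0)")
    if (label == "venule" && net[1] >= 0)
      stop("segment ", i, ": venule must have ascending flow (Vz < 0)")
    list(id = i, pts = pts, cumlen = c(0, cumsum(edge_len)),
         radius_um = s$radius_um, speed_mm_s = s$speed_mm_s,
         rate_mb_s = s$rate_mb_s, label = label,
         activated = isTRUE(s$activated))
  })
  all_pts <- do.call(rbind, lapply(segs, `[[`, "pts"))
  if (is.null(fov)) fov <- c(max(all_pts[, 1]) + 100, max(all_pts[, 2]) + 100)
  structure(list(segments = segs, fov = fov, pial_depth = pial_depth),
            class = "vascular_phantom")
}

#' @export
print.vascular_phantom <- function(x, ...) {
  lab <- vapply(x$segments, `[[`, "", "label")
  act <- vapply(x$segments, `[[`, TRUE, "activated")
  cat(sprintf("vascular_phantom: %d segments (%d activated), fov %g x %g um\n",
              length(x$segments), sum(act), x$fov[1], x$fov[2]))
  print(table(lab))
  invisible(x)
}

#' Default cortical phantom
#'
#' A small cortical vascular bed emulating the geometry probed in vivo: one
#' pial vessel running along the surface, two penetrating arterioles
#' (descending), two ascending venules and four oblique intraparenchymal
#' branches. The left arteriole/venule pair and their branches are flagged
#' `activated`; the right-hand vessels are controls. Field of view is about
#' 1.2 x 1.1 mm, i.e. 192 x 160 super-resolved pixels at the default pitch.
#'
#' @param rate_mb_s baseline arrival rate for penetrating vessels (MB/s);
#'   the pial vessel runs at 2x, branches at 0.3x this rate.
#' @param activated logical: flag the left-hand vessels as activated.
#' @return a [build_phantom()] result.
#' @export
default_phantom <- function(rate_mb_s = 0.5, activated = TRUE) {
  r <- rate_mb_s
  build_phantom(list(
    list(p0 = c(100, 30), p1 = c(100, 1070), radius_um = 30, speed_mm_s = 20,
         rate_mb_s = 2 * r, label = "pial"),
    list(p0 = c(100, 300), p1 = c(1100, 300), radius_um = 15, speed_mm_s = 12,
         rate_mb_s = r, activated = activated),
    list(p0 = c(1100, 450), p1 = c(100, 450), radius_um = 18, speed_mm_s = 8,
         rate_mb_s = r, activated = activated),
    list(p0 = c(100, 800), p1 = c(1100, 800), radius_um = 15, speed_mm_s = 12,
         rate_mb_s = r),
    list(p0 = c(1100, 950), p1 = c(100, 950), radius_um = 18, speed_mm_s = 8,
         rate_mb_s = r),
    list(p0 = c(600, 300), p1 = c(700, 420), radius_um = 8, speed_mm_s = 4,
         rate_mb_s = 0.3 * r, activated = activated),
    list(p0 = c(850, 300), p1 = c(950, 180), radius_um = 8, speed_mm_s = 4,
         rate_mb_s = 0.3 * r, activated = activated),
    list(p0 = c(600, 800), p1 = c(700, 920), radius_um = 8, speed_mm_s = 4,
         rate_mb_s = 0.3 * r),
    list(p0 = c(850, 800), p1 = c(950, 680), radius_um = 8, speed_mm_s = 4,
         rate_mb_s = 0.3 * r)))
}

# position and local unit direction/normal along a polyline at arclength s
.polyline_at <- function(pts, cumlen, s) {
  n <- nrow(pts)
  edge <- pmin(pmax(findInterval(s, cumlen, rightmost.closed = TRUE), 1L), n - 1L)
  d <- pts[edge + 1L, , drop = FALSE] - pts[edge, , drop = FALSE]
  len <- sqrt(rowSums(d^2))
  u <- d / len
  frac <- (s - cumlen[edge]) / len
  pos <- pts[edge, , drop = FALSE] + frac * d
  list(pos = pos, dir = u, normal = cbind(-u[, 2], u[, 1]))
}

#' Simulate stimulus-locked microbubble trajectories
#'
#' Microbubble arrivals on each phantom segment follow an inhomogeneous
#' Poisson process with rate `rate_mb_s * (1 + (flux_gain - 1) * m(t))`,
#' where `m(t)` is the trapezoid-smoothed stimulation waveform
#' ([hemo_waveform()]) and the modulation applies only to activated segments.
#' Each microbubble advects along the centerline at
#' `speed_mm_s * (1 + (speed_gain - 1) * m(t0))` (frozen at its arrival time
#' `t0`; transit times are short against the hemodynamic ramp), at a constant
#' lateral offset drawn uniformly within `radius_um * (1 + (diameter_gain -
#' 1) * m(t0))` of the centerline (plug flow, so per-track ground-truth speed
#' is exact). Positions are sampled at the ultrafast frame times.
#'
#' @param phantom a [build_phantom()] result.
#' @param protocol a [stim_protocol()].
#' @param modulation a [hemo_modulation()].
#' @param duration total simulated time in seconds (>= one pattern).
#' @param frame_rate ultrafast frame rate in Hz (default 1000).
#' @param seed RNG seed for reproducibility.
#' @return An object of class `mb_truth`: `tracks` (data.table with columns
#'   `track_id`, `segment_id`, `frame`, `t_s`, `z_um`, `x_um`, `vz_mm_s`,
#'   `vx_mm_s`, `v_mm_s`), `arrivals` (per-MB arrival time, speed, offset),
#'   and the generating phantom/protocol/modulation/frame rate.
#' @export
simulate_microbubbles <- function(phantom, protocol, modulation = hemo_modulation(),
                                  duration, frame_rate = 1000, seed = NULL) {
  stopifnot(inherits(phantom, "vascular_phantom"),
            inherits(protocol, "stim_protocol"),
            duration >= protocol$pattern_t)
  if (!is.null(seed)) set.seed(seed)
  fg <- modulation$flux_gain; sg <- modulation$speed_gain
  dg <- modulation$diameter_gain
  out <- vector("list", length(phantom$segments))
  arr_out <- vector("list", length(phantom$segments))
  next_id <- 0L
  for (si in seq_along(phantom$segments)) {
    seg <- phantom$segments[[si]]
    act <- seg$activated
    rate_max <- seg$rate_mb_s * if (act) max(1, fg) else 1
    if (rate_max < 0) stop("negative arrival rate")
    if (rate_max == 0 || seg$speed_mm_s == 0) next
    n_cand <- rpois(1, rate_max * duration)
    if (n_cand == 0) next
    t0 <- sort(runif(n_cand, 0, duration))
    # thinning to the modulated rate
    if (act && fg != 1) {
      m <- hemo_waveform(protocol, t0, modulation$ramp)
      keep <- runif(n_cand) < (1 + (fg - 1) * m) / max(1, fg)
      t0 <- t0[keep]
    }
    n <- length(t0)
    if (n == 0) next
    m0 <- if (act) hemo_waveform(protocol, t0, modulation$ramp) else numeric(n)
    speed <- seg$speed_mm_s * (1 + (sg - 1) * m0)          # mm/s
    rad <- seg$radius_um * (1 + (dg - 1) * m0)
    off <- runif(n, -1, 1) * rad
    L <- tail(seg$cumlen, 1)
    v_um <- speed * 1000                                    # um/s
    # frame-sampled positions while the MB is inside the segment
    f0 <- ceiling(t0 * frame_rate - 1e-9)                   # first frame index (t = f/frame_rate)
    n_steps <- pmax(0L, floor((L / v_um - (f0 / frame_rate - t0)) * frame_rate) + 1L)
    keep <- n_steps >= 1L
    if (!any(keep)) next
    idx <- which(keep)
    reps <- n_steps[idx]
    mb <- rep.int(idx, reps)
    step_in_track <- sequence(reps) - 1L
    fr <- f0[mb] + step_in_track
    tt <- fr / frame_rate
    s_arc <- (tt - t0[mb]) * v_um[mb]
    pl <- .polyline_at(seg$pts, seg$cumlen, s_arc)
    pos <- pl$pos + off[mb] * pl$normal
    ids <- next_id + seq_along(idx)
    out[[si]] <- data.table(
      track_id = rep.int(ids, reps), segment_id = si, frame = fr,
      t_s = tt, z_um = pos[, 1], x_um = pos[, 2],
      vz_mm_s = pl$dir[, 1] * speed[mb], vx_mm_s = pl$dir[, 2] * speed[mb],
      v_mm_s = speed[mb])
    arr_out[[si]] <- data.table(track_id = ids, segment_id = si,
                                t_arrival = t0[idx], speed_mm_s = speed[idx],
                                offset_um = off[idx])
    next_id <- next_id + length(idx)
  }
  tracks <- rbindlist(out)
  if (nrow(tracks)) setorder(tracks, track_id, frame)
  structure(list(tracks = tracks, arrivals = rbindlist(arr_out),
                 phantom = phantom, protocol = protocol,
                 modulation = modulation, frame_rate = frame_rate,
                 duration = duration),
            class = "mb_truth")
}

#' @export
print.mb_truth <- function(x, ...) {
  cat(sprintf("mb_truth: %d tracks, %d positions, %g s at %g Hz\n",
              nrow(x$arrivals), nrow(x$tracks), x$duration, x$frame_rate))
  invisible(x)
}
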