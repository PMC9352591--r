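# Independent oracles and fixture builders used across the suite.

# Brute-force minimum-cost gated matching between two detection sets:
# enumerates every injective partial matching (pairs farther than the gate
# forbidden); cost = matched distances + gate per unmatched detection.
oracle_match_cost <- function(det_a, det_b, gate) {
  n <- nrow(det_a); m <- nrow(det_b)
  if (n == 0 || m == 0) return(gate * (n + m))
  D <- sqrt(outer(det_a$z_um, det_b$z_um, "-")^2 +
            outer(det_a$x_um, det_b$x_um, "-")^2)
  best <- Inf
  rec <- function(i, used, cost) {
    if (cost >= best) return(invisible())
    if (i > n) {
      best <<- min(best, cost + gate * sum(!used))
      return(invisible())
    }
    rec(i + 1L, used, cost + gate)                 # leave detection i unmatched
    for (j in which(!used)) if (D[i, j] <= gate) {
      used[j] <- TRUE
      rec(i + 1L, used, cost + D[i, j])
      used[j] <- FALSE
    }
  }
  rec(1L, rep(FALSE, m), 0)
  best
}

# Supersampled rasterization of a straight segment: the set of grid pixels
# crossed, found by sampling far denser than the implementation does.
oracle_raster_pixels <- function(p0, p1, grid, n_samples = 20000) {
  f <- seq(0, 1, length.out = n_samples)
  sn <- snap_to_grid(p0[1] + f * (p1[1] - p0[1]),
                     p0[2] + f * (p1[2] - p0[2]), grid)
  ok <- sn$inside
  unique(paste(sn$iz[ok], sn$ix[ok]))
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# assignments (tie-free, nonzero samples).
oracle_signed_rank_p <- function(v) {
  v <- v[v != 0]
  n <- length(v)
  r <- rank(abs(v))
  W <- sum(r[v > 0])
  sums <- 0
  for (k in seq_len(n)) sums <- c(sums, sums + r[k])
  min(1, 2 * min(mean(sums <= W), mean(sums >= W)))
}

# Gaussian spot image on a pixel grid (pixel centers at (i-0.5)*pitch).
gaussian_spot_image <- function(nz, nx, z0, x0, sigma, pitch_z = 100,
                                pitch_x = 110, amp = 1) {
  zc <- (seq_len(nz) - 0.5) * pitch_z
  xc <- (seq_len(nx) - 0.5) * pitch_x
  amp * outer(exp(-(zc - z0)^2 / (2 * sigma^2)),
              exp(-(xc - x0)^2 / (2 * sigma^2)))
}

# Rank-2 movie: static baseline map (constant level b) plus an activation
# map modulated by the mean-removed stimulation boxcar; with sum(act) == 0
# the two spatial components are orthogonal and the SVD separates them
# exactly into modes 1 and 2.
rank2_movie <- function(protocol, b = 3, act_pixels = list(c(3, 4), c(5, 6)),
                        act_amp = c(2, -2), nz = 8, nx = 9, step_t = 1) {
  nts <- as.integer(protocol$pattern_t / step_t)
  t <- (seq_len(nts) - 0.5) * step_t
  A <- stim_boxcar(protocol, t)
  a <- matrix(0, nz, nx)
  for (k in seq_along(act_pixels))
    a[act_pixels[[k]][1], act_pixels[[k]][2]] <- act_amp[k]
  stopifnot(abs(sum(a)) < 1e-12)
  Ac <- A - mean(A)
  M <- array(0, c(nz, nx, nts))
  for (k in seq_len(nts)) M[, , k] <- b + a * Ac[k]
  list(M = M, A = A, a = a, b = b, t = t)
}

# Straight-vessel phantom: one horizontal-offset-free vertical vessel,
# centered in a field of view wide enough for border-safe localization.
single_vessel_phantom <- function(rate = 2, radius = 15, speed = 10,
                                  x0 = 400, activated = TRUE) {
  build_phantom(list(list(p0 = c(50, x0), p1 = c(1050, x0),
                          radius_um = radius, speed_mm_s = speed,
                          rate_mb_s = rate, activated = activated)),
                fov = c(1150, 2 * x0))
}

# Occupancy ground truth of activated segments on the super grid (dense
# sweep over lateral offsets and arclength).
occupancy_ground_truth <- function(segments, grid, only_activated = TRUE) {
  gt <- matrix(0, grid$nz, grid$nx)
  for (s in segments) {
    if (only_activated && !isTRUE(s$activated)) next
    d <- c(s$p1[1] - s$p0[1], s$p1[2] - s$p0[2])
    d <- d / sqrt(sum(d^2))
    for (u in seq(-1, 1, by = 0.05)) {
      f <- seq(0, 1, length.out = 600)
      z <- s$p0[1] + f * (s$p1[1] - s$p0[1]) - u * s$radius_um * d[2]
      x <- s$p0[2] + f * (s$p1[2] - s$p0[2]) + u * s$radius_um * d[1]
      sn <- snap_to_grid(z, x, grid)
      ok <- sn$inside
      gt[cbind(sn$iz[ok], sn$ix[ok])] <- gt[cbind(sn$iz[ok], sn$ix[ok])] + 1
    }
  }
  gt
}

# End-to-end simulation to a pattern movie (shared by several tests).
sim_to_pattern_movie <- function(phantom, protocol, modulation, seed,
                                 min_count = 5) {
  truth <- simulate_microbubbles(phantom, protocol, modulation,
                                 duration = protocol$acq_t, seed = seed)
  grid <- super_grid(phantom$fov[1], phantom$fov[2])
  path <- rasterize_tracks(truth_tracks(truth), grid)
  movie <- build_sliding_movie(path, grid, protocol$acq_t)
  list(truth = truth, grid = grid, path = path, movie = movie,
       pm = pattern_average(movie, protocol))
}
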