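test_that("map accumulation counts traversals and averages speeds", {
  g <- ulm_grid(32, 32)
  path <- data.table::data.table(
    track_id = c(1L, 2L, 3L), iz = c(5L, 5L, 7L), ix = c(5L, 5L, 9L),
    t_s = c(1, 2, 3), vz_mm_s = 0, vx_mm_s = c(5, 15, 4),
    v_mm_s = c(5, 15, 4))
  m <- accumulate_maps(path, g, min_count = 5)
  expect_equal(m$count[5, 5], 2)
  expect_equal(m$velocity[5, 5], 10)     # mean of 5 and 15 mm/s
  expect_equal(m$count[7, 9], 1)
  expect_true(is.na(m$velocity[1, 1]))
  # pixels below the 5-detection minimum are flagged invalid
  expect_false(m$valid[5, 5])
  expect_equal(sum(m$valid), 0)
  expect_error(accumulate_maps(path, g, t_range = c(3, 3)), "empty t_range")
})

test_that("sliding-window movie respects the half-open window rule", {
  g <- ulm_grid(16, 16)
  path <- data.table::data.table(track_id = 1L, iz = 4L, ix = 4L, t_s = 10,
                                 vz_mm_s = 0, vx_mm_s = 3, v_mm_s = 3)
  mov <- build_sliding_movie(path, g, acq_t = 30, w_t = 5, step_t = 1)
  expect_equal(mov$dims[3], 30)
  arr <- movie_array(mov)
  hit <- which(arr[4, 4, ] > 0)
  # detection at t = 10 with W = 5: windows [c-2.5, c+2.5) containing 10
  # are those centered in (7.5, 12.5], i.e. centers 8.5 ... 12.5
  centers <- (hit - 0.5) * 1
  expect_equal(centers, seq(8.5, 12.5, by = 1))
  expect_error(build_sliding_movie(path, g, 30, w_t = 0), "w_t")
})

test_that("acquisition geometry yields the standard movie dimensions", {
  # 20 patterns of 70 s with a 1-s step: Nt = 1400; Nts = 70
  proto <- stim_protocol(30, 30, 10, 20)
  g <- ulm_grid(8, 8)
  path <- data.table::data.table(track_id = 1L, iz = 2L, ix = 2L, t_s = 35,
                                 vz_mm_s = 0, vx_mm_s = 1, v_mm_s = 1)
  mov <- build_sliding_movie(path, g, proto$acq_t, w_t = 5, step_t = 1)
  expect_equal(mov$dims[3], 1400)
  pm <- pattern_average(mov, proto)
  expect_equal(dim(pm$flux)[3], 70)
  # the 1-s window / 0.5-s step variant is supported
  mov2 <- build_sliding_movie(path, g, proto$acq_t, w_t = 1, step_t = 0.5)
  expect_equal(mov2$dims[3], 2800)
  expect_equal(dim(pattern_average(mov2, proto)$flux)[3], 140)
})

test_that("pattern averaging conserves counts and recovers constant flux", {
  proto <- stim_protocol(10, 10, 5, 4)     # 25 s pattern, 100 s acquisition
  g <- ulm_grid(16, 16)
  set.seed(40)
  n <- 400
  path <- data.table::data.table(
    track_id = seq_len(n), iz = sample(1:16, n, TRUE),
    ix = sample(1:16, n, TRUE), t_s = runif(n, 0, 100),
    vz_mm_s = 0, vx_mm_s = 1, v_mm_s = 1)
  w_t <- 5; step_t <- 1
  mov <- build_sliding_movie(path, g, proto$acq_t, w_t, step_t)
  pm <- pattern_average(mov, proto)
  # exact count conservation between absolute-time and pattern-phase sums
  expect_equal(sum(pm$count), sum(movie_array(mov)))
  # each phase map accumulates n_patterns * W seconds of data
  # (spot check: a Poisson-constant source yields flux ~ rate * n_patterns)
  rate <- n / 100
  mid <- 5:20    # phases with full windows
  flux_tot <- apply(pm$flux, 3, sum)[mid]
  expect_lt(abs(mean(flux_tot) - rate * proto$n_patterns),
            3 * sqrt(rate * proto$n_patterns * w_t) / w_t)
  # velocity pools across repetitions: all speeds 1 -> Vs = 1 where defined
  expect_true(all(pm$velocity[!is.na(pm$velocity)] == 1))
})

test_that("drift registration recovers pure translations and injected drift", {
  g <- ulm_grid(96, 96)
  set.seed(41)
  # base point cloud revisited in every chunk; second chunk shifted +3 px in z
  base <- data.frame(z = runif(120, 100, 500), x = runif(120, 100, 600))
  mk_chunk <- function(t0, dz_um) data.frame(
    track_id = seq_len(120), t_s = t0 + runif(120, 0, 9.9),
    z_um = base$z + dz_um, x_um = base$x, vz_mm_s = 1, vx_mm_s = 0, v_mm_s = 1)
  tr <- rbind(mk_chunk(0, 0), mk_chunk(10, 3 * g$pitch_z))
  dc <- estimate_and_apply_drift(tr, g, chunk_t = 10, smooth_px = 0)
  expect_equal(dc$shifts$dz_um[2], -3 * g$pitch_z, tolerance = 1e-6)
  expect_equal(dc$shifts$dx_um[2], 0, tolerance = 1e-6)

  # no drift: estimated shifts below half a super-pixel
  tr0 <- rbind(mk_chunk(0, 0), mk_chunk(10, 0), mk_chunk(20, 0))
  dc0 <- estimate_and_apply_drift(tr0, g, chunk_t = 10)
  expect_lt(max(abs(dc0$shifts$dz_um)), 0.5 * g$pitch_z)
  expect_lt(max(abs(dc0$shifts$dx_um)), 0.5 * g$pitch_x)

  # slow linear drift on a phantom: recovered within one super-pixel,
  # and correction sharpens the count map (sum of squares increases)
  proto <- stim_protocol(n_patterns = 1)
  ph <- single_vessel_phantom(rate = 3, speed = 10)
  truth <- simulate_microbubbles(ph, proto, hemo_modulation(1, 1, 1), 70,
                                 seed = 42)
  drift_rate <- 0.5                       # um/s
  tr2 <- as.data.frame(truth$tracks)
  tr2$x_um <- tr2$x_um + drift_rate * tr2$t_s
  grid <- super_grid(ph$fov[1], ph$fov[2])
  dc2 <- estimate_and_apply_drift(tr2, grid, chunk_t = 10)
  expected <- -drift_rate * (dc2$shifts$t0 + 5)
  expect_true(all(abs(dc2$shifts$dx_um - expected) < grid$pitch_x + 1e-9))
  p_corr <- rasterize_tracks(dc2$tracks, grid)
  p_raw <- rasterize_tracks(tr2, grid)
  expect_gt(sum(accumulate_maps(p_corr, grid)$count^2),
            sum(accumulate_maps(p_raw, grid)$count^2))
})

test_that("rest/stim split uses the 0-30 s and 30-60 s pattern phases", {
  proto <- stim_protocol(30, 30, 10, 2)
  g <- ulm_grid(16, 16)
  path <- data.table::data.table(
    track_id = 1:3, iz = c(3L, 4L, 5L), ix = 3L,
    t_s = c(15, 45, 65),        # rest, stim, post-stim rest
    vz_mm_s = 0, vx_mm_s = 1, v_mm_s = 1)
  rs <- split_rest_stim_maps(path, g, proto, min_count = 1)
  expect_equal(rs$rest$count[3, 3], 1)
  expect_equal(rs$stim$count[4, 3], 1)
  # phase 65 s (post-stim rest) excluded from both subsets
  expect_equal(rs$rest$count[5, 3] + rs$stim$count[5, 3], 0)
  # phase 45 s in the second pattern (t = 115) also lands in stim
  path2 <- data.table::data.table(track_id = 1L, iz = 6L, ix = 3L, t_s = 115,
                                  vz_mm_s = 0, vx_mm_s = 1, v_mm_s = 1)
  rs2 <- split_rest_stim_maps(path2, g, proto, min_count = 1)
  expect_equal(rs2$stim$count[6, 3], 1)
})
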