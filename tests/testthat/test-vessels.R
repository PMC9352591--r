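# fabricate an ulm_maps object from matrices (input contract of the
# vessel-analytics operations)
make_maps <- function(count, vz, vx, velocity = NULL, grid) {
  if (is.null(velocity)) velocity <- sqrt(vz^2 + vx^2)
  structure(list(count = count, velocity = velocity, vz = vz, vx = vx,
                 valid = count >= 5, grid = grid, min_count = 5),
            class = "ulm_maps")
}

test_that("compartment segmentation splits vessels by flow direction", {
  proto <- stim_protocol(n_patterns = 4)
  ph <- build_phantom(list(
    list(p0 = c(50, 300), p1 = c(1050, 300), radius_um = 15, speed_mm_s = 12,
         rate_mb_s = 2),
    list(p0 = c(1050, 700), p1 = c(50, 700), radius_um = 15, speed_mm_s = 8,
         rate_mb_s = 2)))
  truth <- simulate_microbubbles(ph, proto, hemo_modulation(1, 1, 1),
                                 proto$acq_t, seed = 19)
  grid <- super_grid(ph$fov[1], ph$fov[2])
  path <- rasterize_tracks(truth_tracks(truth), grid)
  maps <- accumulate_maps(path, grid)
  labs <- segment_compartments(maps)
  xs <- (seq_len(grid$nx) - 0.5) * grid$pitch_x
  on_art <- labs$labels[, abs(xs - 300) < 12]
  on_ven <- labs$labels[, abs(xs - 700) < 12]
  acc_art <- mean(on_art[on_art != "none"] == "penetrating_arteriole")
  acc_ven <- mean(on_ven[on_ven != "none"] == "venule")
  expect_gt(acc_art, 0.95)
  expect_gt(acc_ven, 0.95)

  # all-pial seed mask: no arteriole/venule labels remain
  pial <- matrix(TRUE, grid$nz, grid$nx)
  labs2 <- segment_compartments(maps, pial_mask = pial)
  expect_true(all(labs2$labels %in% c("none", "pial")))

  # empty map rejected
  empty <- make_maps(matrix(0, 32, 32), matrix(0, 32, 32),
                     matrix(0, 32, 32), grid = ulm_grid(32, 32))
  expect_error(segment_compartments(empty), "mask")
})

test_that("direction-resolved counting separates overlapping compartments", {
  g <- ulm_grid(16, 16)
  labs <- structure(list(labels = matrix("penetrating_arteriole", 16, 16),
                         vessel = matrix(TRUE, 16, 16), vz_large = 5),
                    class = "compartment_labels")
  path <- data.table::data.table(
    track_id = 1:4, iz = 5L, ix = 5L, t_s = c(1, 2, 3, 4),
    vz_mm_s = c(5, 6, -4, 7), vx_mm_s = 0, v_mm_s = c(5, 6, 4, 7))
  sel <- fulm:::.compartment_path(path, labs, "penetrating_arteriole")
  expect_equal(nrow(sel), 3)           # only downward microbubbles counted
  expect_true(all(sel$vz_mm_s > 0))
})

test_that("dynamic velocity histograms are phase-resolved and normalized", {
  proto <- stim_protocol(10, 10, 5, 2)
  g <- ulm_grid(16, 16)
  labs <- structure(list(labels = matrix("intraparenchymal", 16, 16),
                         vessel = matrix(TRUE, 16, 16), vz_large = 5),
                    class = "compartment_labels")
  # all microbubbles at 10 mm/s: one hot bin, value exactly 1
  path <- data.table::data.table(
    track_id = 1:20, iz = sample(1:16, 20, TRUE), ix = sample(1:16, 20, TRUE),
    t_s = runif(20, 0, 50), vz_mm_s = 0, vx_mm_s = 10, v_mm_s = 10)
  h <- dynamic_velocity_histogram(path, labs, "intraparenchymal", proto,
                                  bin = 1, w_t = 5, step_t = 1)
  expect_equal(max(h$hist), 1)
  expect_equal(dim(h$hist), c(10, 25))
  expect_true(all(h$hist[-10, ] == 0))  # only the 9.5-10.5 bin is occupied
  expect_error(dynamic_velocity_histogram(path, labs, "pial", proto),
               "empty compartment")
})

test_that("speed modulation shifts the histogram mass during stimulation", {
  proto <- stim_protocol(n_patterns = 6)
  ph <- single_vessel_phantom(rate = 2, speed = 10)
  truth <- simulate_microbubbles(ph, proto, hemo_modulation(1, 1.3, 1),
                                 proto$acq_t, seed = 29)
  grid <- super_grid(ph$fov[1], ph$fov[2])
  path <- rasterize_tracks(truth_tracks(truth), grid)
  labs <- structure(list(labels = matrix("penetrating_arteriole", grid$nz,
                                         grid$nx),
                         vessel = matrix(TRUE, grid$nz, grid$nx),
                         vz_large = 5), class = "compartment_labels")
  h <- dynamic_velocity_histogram(path, labs, "penetrating_arteriole", proto,
                                  v_max = 16)
  wmean <- colSums(h$hist * h$v_mid) / colSums(h$hist)
  stim_ph <- h$t >= 35 & h$t < 58
  rest_ph <- h$t < 28
  expect_gt(mean(wmean[stim_ph]), mean(wmean[rest_ph]) * 1.15)
})

test_that("compartment time courses report the programmed flux increase", {
  proto <- stim_protocol(n_patterns = 8)
  ph <- build_phantom(list(
    list(p0 = c(50, 300), p1 = c(1050, 300), radius_um = 15, speed_mm_s = 10,
         rate_mb_s = 2, activated = TRUE),
    list(p0 = c(50, 700), p1 = c(1050, 700), radius_um = 15, speed_mm_s = 10,
         rate_mb_s = 2)))
  truth <- simulate_microbubbles(ph, proto, hemo_modulation(1.5, 1, 1),
                                 proto$acq_t, seed = 31)
  grid <- super_grid(ph$fov[1], ph$fov[2])
  path <- rasterize_tracks(truth_tracks(truth), grid)
  mov <- build_sliding_movie(path, grid, proto$acq_t)
  xs <- (seq_len(grid$nx) - 0.5) * grid$pitch_x
  lab_m <- matrix("none", grid$nz, grid$nx)
  lab_m[, abs(xs - 300) < 20] <- "penetrating_arteriole"
  lab_m[, abs(xs - 700) < 20] <- "intraparenchymal"
  labs <- structure(list(labels = lab_m, vessel = lab_m != "none",
                         vz_large = 5), class = "compartment_labels")
  tc_act <- compartment_timecourse(mov, labs, "penetrating_arteriole", proto)
  tc_ctl <- compartment_timecourse(mov, labs, "intraparenchymal", proto)
  plateau <- tc_act$t >= 37 & tc_act$t < 55
  # activated compartment: relative flux increase near +50%
  expect_gt(mean(tc_act$rel_flux[plateau]), 0.3)
  expect_gt(mean(tc_act$rel_flux[plateau]), mean(tc_ctl$rel_flux[plateau]) + 0.2)
  # control compartment fluctuates around zero within its s.e.m.
  expect_lt(abs(mean(tc_ctl$rel_flux[plateau])),
            3 * mean(tc_ctl$rel_flux_sem[plateau]))
})

test_that("half-max diameters are exact on rectangular profiles", {
  g <- ulm_grid(64, 64)
  cnt <- matrix(0, 64, 64)
  xs <- (seq_len(g$nx) - 0.5) * g$pitch_x
  in_vessel <- xs >= 150 & xs < 150 + 48.125   # 7 pixels = 48.125 um wide
  cnt[, in_vessel] <- 100
  vz <- matrix(0, 64, 64); vz[, in_vessel] <- 8
  maps <- make_maps(cnt, vz, matrix(0, 64, 64), grid = g)
  tp <- transversal_profile(c(200, 100), c(200, 280), maps, maps)
  expect_lt(abs(tp$diam_rest_um - 48.125), g$pitch_x)   # exact within 1 px
  expect_equal(tp$diam_stim_um, tp$diam_rest_um)
  expect_equal(tp$v_at_max_rest, 8, tolerance = 0.05)

  # amplitude scaling alone leaves the rest-threshold diameter unchanged
  maps2 <- make_maps(cnt * 2, vz, matrix(0, 64, 64), grid = g)
  tp2 <- transversal_profile(c(200, 100), c(200, 280), maps, maps2)
  expect_lt(abs(tp2$diam_stim_um - tp2$diam_rest_um), 1.5 * g$pitch_x)

  # longitudinal profile agrees with the transversal one at mid-depth
  centerline <- data.frame(z = (10:54 - 0.5) * g$pitch_z,
                           x = mean(xs[in_vessel]))
  lp <- longitudinal_profile(centerline, maps, maps)
  mid <- which.min(abs(lp$z_um - 200))
  expect_lt(abs(lp$diam_rest_um[mid] - tp$diam_rest_um), g$pitch_x)
  # no vessel on the segment: flagged undefined
  tp_none <- transversal_profile(c(200, 500), c(200, 640), maps, maps)
  expect_true(is.na(tp_none$diam_rest_um))
})

test_that("Gaussian profiles reproduce the FWHM relation within one pixel", {
  g <- ulm_grid(64, 64)
  xs <- (seq_len(g$nx) - 0.5) * g$pitch_x
  sigma <- 15
  prof <- exp(-(xs - 200)^2 / (2 * sigma^2))
  cnt <- matrix(rep(prof * 200, each = 64), 64, 64)
  vz <- matrix(5, 64, 64)
  maps <- make_maps(cnt, vz, matrix(0, 64, 64), grid = g)
  # estimator-bias check on a noise-free profile: smoothing kept below the
  # feature scale so the median filter does not flatten the Gaussian peak
  tp <- transversal_profile(c(200, 120), c(200, 280), maps, maps,
                            smooth_um = 12.5)
  expect_lt(abs(tp$diam_rest_um - 2.355 * sigma), g$pitch_x)
})

test_that("perfusion area matches the rasterization oracle with set semantics", {
  g <- ulm_grid(64, 64)
  tr <- data.frame(track_id = 1L, t_s = c(0, 0.03),
                   z_um = c(20, 380), x_um = c(200, 230),
                   vz_mm_s = 12, vx_mm_s = 1, v_mm_s = 12)
  path <- rasterize_tracks(tr, g)
  pa <- perfusion_area(path, c(25, 150), c(25, 280), g)
  oracle <- oracle_raster_pixels(c(20, 200), c(380, 230), g)
  expect_equal(pa$n_pixels, length(oracle))
  expect_equal(pa$area_um2, length(oracle) * 6.25 * 6.875)

  # duplicate identical track: area unchanged; extra track: monotone growth
  tr_dup <- rbind(tr, transform(tr, track_id = 2L))
  pa_dup <- perfusion_area(rasterize_tracks(tr_dup, g), c(25, 150),
                           c(25, 280), g)
  expect_equal(pa_dup$area_um2, pa$area_um2)
  tr3 <- rbind(tr_dup, data.frame(track_id = 3L, t_s = c(0, 0.02),
                                  z_um = c(22, 300), x_um = c(210, 330),
                                  vz_mm_s = 10, vx_mm_s = 4, v_mm_s = 11))
  pa3 <- perfusion_area(rasterize_tracks(tr3, g), c(25, 150), c(25, 280), g)
  expect_gte(pa3$area_um2, pa_dup$area_um2)
  # track missing the seed segment contributes nothing
  expect_warning(pa0 <- perfusion_area(path, c(25, 400), c(25, 430), g),
                 "no track")
  expect_equal(pa0$area_um2, 0)
})

test_that("dilation/constriction maps take values in {-1, 0, 1}", {
  g <- ulm_grid(64, 64)
  xs <- (seq_len(g$nx) - 0.5) * g$pitch_x
  cnt <- matrix(0, 64, 64)
  cnt[, abs(xs - 200) <= 15] <- 100
  vz0 <- matrix(0, 64, 64)
  rest <- make_maps(cnt, vz0, vz0, grid = g)
  # identical conditions: all-zero map
  same <- dilation_constriction_map(rest, rest)
  expect_true(all(same == 0))

  # simulated dilating vessel: +1 ring around the rest vessel edges
  proto <- stim_protocol(n_patterns = 20)
  ph <- single_vessel_phantom(rate = 4, x0 = 400)
  truth <- simulate_microbubbles(ph, proto, hemo_modulation(1.2, 1, 1.3),
                                 proto$acq_t, seed = 9)
  grid <- super_grid(ph$fov[1], ph$fov[2])
  path <- rasterize_tracks(truth_tracks(truth), grid)
  rs <- split_rest_stim_maps(path, grid, proto)
  dil <- dilation_constriction_map(rs$rest, rs$stim)
  expect_true(all(dil %in% c(-1L, 0L, 1L)))
  expect_gt(sum(dil == 1), 0)
  xsg <- (seq_len(grid$nx) - 0.5) * grid$pitch_x
  ring <- abs(xsg - 400) > 13 & abs(xsg - 400) < 32
  expect_gt(sum(dil[, ring] == 1), 0.9 * sum(dil == 1))
})

test_that("signed-rank statistics match the exact enumeration oracle", {
  # symmetric alternating differences: p ~ 1 (tied magnitudes force the
  # normal approximation, which is exact-centered here)
  v <- c(0.1, -0.1, 0.2, -0.2, 0.3, -0.3, 0.4, -0.4)
  st <- suppressWarnings(rest_stim_stats(v))
  expect_gt(st$p_value, 0.9)

  # exact two-sided p equals the 2^n enumeration for n <= 12
  set.seed(51)
  for (k in 1:10) {
    x <- round(rnorm(sample(6:11, 1), mean = 0.3, sd = 1), 3)
    x <- x[x != 0]
    if (length(x) < 2 || anyDuplicated(abs(x))) next
    expect_equal(rest_stim_stats(x)$p_value, oracle_signed_rank_p(x),
                 tolerance = 1e-12)
  }

  # all-positive variations, n = 20: smallest attainable two-sided p
  st20 <- rest_stim_stats(rep(0.1, 20) + (1:20) / 1000)
  expect_equal(st20$p_value, 2 * 2^-20, tolerance = 1e-12)

  # paired depth comparison runs and all-zero differences are undefined
  expect_true(is.na(rest_stim_stats(c(1, 2, 3), c(1, 2, 3))$p_value))
  expect_lt(rest_stim_stats(c(1, 2, 3, 4, 5, 6) + (1:6) / 100,
                            c(1, 2, 3, 4, 5, 6))$p_value, 0.05)
})

test_that("neighboring pixels with distinct velocities are discriminated", {
  set.seed(52)
  # 8 vs 12 mm/s populations (sigma 0.5, n = 20): significant at alpha 0.01
  bins <- list(rnorm(20, 8, 0.5), rnorm(20, 12, 0.5))
  res <- neighbor_velocity_discrimination(bins)
  expect_lt(res$p_value[1], 0.01)
  # closed-form Welch t for the same samples
  tt <- t.test(bins[[1]], bins[[2]])
  expect_equal(res$t[1], unname(tt$statistic))

  # identical populations: non-significant in >= 95% of seeds
  sig <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    b <- list(rnorm(20, 10, 0.5), rnorm(20, 10, 0.5))
    neighbor_velocity_discrimination(b)$p_value[1] < 0.01
  }, logical(1))
  expect_lte(mean(sig), 0.05)

  # undersized bins are skipped
  res2 <- neighbor_velocity_discrimination(list(rnorm(5), numeric(0), rnorm(5)))
  expect_true(all(is.na(res2$p_value)))
})

test_that("skeletonization reduces a thick vessel to a pruned centerline", {
  mask <- matrix(FALSE, 60, 60)
  mask[5:55, 28:33] <- TRUE
  sk <- skeletonize_mask(mask, prune = 0)
  expect_true(all(rowSums(sk[10:50, ]) >= 1))
  expect_true(all(rowSums(sk[10:50, ]) <= 2))
  cl <- skeleton_centerline(mask, ulm_grid(60, 60), prune = 5)
  expect_true(all(abs(cl$x - 30.5 * 6.875) < 2 * 6.875))
  # pruning removes a short side branch
  mask2 <- mask; mask2[30, 34:40] <- TRUE
  sk2 <- skeletonize_mask(mask2, prune = 10)
  expect_true(all(!sk2[, 36:40]))
})
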