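test_that("correlation map matches the Pearson formula and its edge cases", {
  proto <- stim_protocol(10, 10, 5, 1)
  t <- (1:25) - 0.5
  A <- stim_boxcar(proto, t)
  M <- array(0, c(3, 3, 25))
  M[1, 1, ] <- A                 # identical to the pattern
  M[2, 2, ] <- -A + 4            # anti-correlated plus a constant
  M[3, 3, ] <- 2                 # zero temporal variance
  cm <- correlation_map(M, A)
  expect_equal(cm[1, 1], 1)
  expect_equal(cm[2, 2], -1)
  expect_equal(cm[3, 3], 0)
  expect_true(all(cm >= -1 & cm <= 1))
  expect_error(correlation_map(M, A[-1]), "time base")
})

test_that("SVD decomposition is exact, orthonormal and rank-revealing", {
  proto <- stim_protocol()
  r2 <- rank2_movie(proto)
  sv <- svd_decompose(r2$M, step_t = 1)
  # exactly two nonzero singular values for the rank-2 construction
  expect_equal(sum(sv$d > 1e-10 * sv$d[1]), 2)
  # reconstruction error below 1e-10
  M2 <- sv$U %*% (sv$d * t(sv$V))
  expect_lt(norm(matrix(r2$M, 72, 70) - M2, "F") / norm(M2, "F"), 1e-10)
  # orthonormal singular vectors
  expect_lt(max(abs(crossprod(sv$U) - diag(ncol(sv$U)))), 1e-10)
  expect_lt(max(abs(crossprod(sv$V) - diag(ncol(sv$V)))), 1e-10)
  expect_error(svd_decompose(array(0, c(2, 2, 5))), "all-zero")
})

test_that("stimulus-mode selection finds the activation in mode 2", {
  proto <- stim_protocol()
  r2 <- rank2_movie(proto)
  sv <- select_stim_mode(svd_decompose(r2$M, step_t = 1), r2$A)
  expect_equal(sv$i_stim, 2)
  expect_true(sv$found)
  expect_gt(sv$p[sv$i_stim], 0)       # sign convention enforced
  expect_lt(abs(sv$p[2]) - 1, 1e-10)

  # uncentered activation (baseline + a * A(t)): still isolated in mode 2
  M2 <- array(0, c(8, 9, 70))
  for (k in 1:70) M2[, , k] <- r2$b + pmax(r2$a, 0) * r2$A[k]
  sv2 <- select_stim_mode(svd_decompose(M2, step_t = 1), r2$A)
  expect_equal(sv2$i_stim, 2)

  # pattern orthogonal to every temporal vector: warning, not found
  expect_warning(
    sv3 <- select_stim_mode(svd_decompose(r2$M, step_t = 1),
                            rep(c(1, -1), 35)),
    "no stimulus-locked mode")
  expect_false(sv3$found)
})

test_that("bolus injection and activation separate into distinct modes", {
  proto <- stim_protocol()
  nts <- 70; t <- (1:nts) - 0.5
  A <- stim_boxcar(proto, t)
  Ac <- A - mean(A)
  # injection pattern: bolus decay every 35 s, mean-removed
  inj <- exp(-(t %% 35) / 10); inj <- inj - mean(inj)
  # Gram-Schmidt so the three spatial maps are mutually orthogonal
  B <- matrix(3, 10, 10)
  ainj <- matrix(0, 10, 10); ainj[, 3] <- 1; ainj[, 7] <- -1
  aact <- matrix(0, 10, 10); aact[4, 5] <- 1; aact[8, 2] <- -1
  inj_t <- inj - sum(inj * Ac) / sum(Ac^2) * Ac   # decouple time courses
  M <- array(0, c(10, 10, nts))
  for (k in 1:nts) M[, , k] <- B + 5 * ainj * inj_t[k] + aact * Ac[k]
  sv <- select_stim_mode(svd_decompose(M, step_t = 1), A)
  # baseline, injection and activation occupy modes 1, 2 and 3
  expect_equal(sv$i_stim, 3)
  expect_gt(abs(stats::cor(sv$V[, 2], inj_t)), 0.99)
})

test_that("variation maps recover planted amplitudes in closed form", {
  proto <- stim_protocol()
  r2 <- rank2_movie(proto, b = 3, act_amp = c(2, -2))
  sv <- select_stim_mode(svd_decompose(r2$M, step_t = 1), r2$A)
  win <- phase_windows(proto, 1)
  expect_equal(length(win$stim), length(win$base))
  vm <- variation_map(sv, win$stim, win$base)
  # activated pixel recovers amplitude x stimulation duration to 1e-8
  expect_lt(max(abs(vm - r2$a * proto$stim)) / max(abs(r2$a * proto$stim)),
            1e-8)
  # non-activated pixels are zero
  expect_lt(max(abs(vm[r2$a == 0])), 1e-8 * proto$stim)
  expect_error(variation_map(sv, win$stim, win$base[-1]), "equal duration")

  # relative map equals (a * T_stim) / (b * T_base); baseline map is the
  # basal image
  rel <- relative_variation_map(sv, win$stim, win$base)
  q <- which(r2$a == 2)[1]
  expect_equal(rel$ratio[q], 2 * proto$stim / (r2$b * proto$rest_pre),
               tolerance = 1e-8)
  expect_equal(rel$baseline, matrix(r2$b * proto$rest_pre, 8, 9),
               tolerance = 1e-8)

  # zero-baseline pixels are masked, not infinite
  Mz <- r2$M; Mz[1, 1, ] <- 0
  svz <- select_stim_mode(svd_decompose(Mz, step_t = 1), r2$A)
  relz <- relative_variation_map(svz, win$stim, win$base)
  expect_true(is.na(relz$ratio[1, 1]))
  expect_true(all(is.finite(relz$ratio[!is.na(relz$ratio)])))
})

test_that("outputs are invariant to the arbitrary SVD sign", {
  proto <- stim_protocol()
  r2 <- rank2_movie(proto)
  sv <- svd_decompose(r2$M, step_t = 1)
  sv_flipped <- sv
  for (i in 1:2) {     # flip every meaningful (U, V) pair
    sv_flipped$U[, i] <- -sv_flipped$U[, i]
    sv_flipped$V[, i] <- -sv_flipped$V[, i]
  }
  win <- phase_windows(proto, 1)
  m1 <- variation_map(select_stim_mode(sv, r2$A), win$stim, win$base)
  m2 <- variation_map(select_stim_mode(sv_flipped, r2$A), win$stim, win$base)
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("single-trial analysis locates strong activation without summation", {
  proto <- stim_protocol(n_patterns = 6)
  ph <- build_phantom(list(
    list(p0 = c(50, 300), p1 = c(1050, 300), radius_um = 15, speed_mm_s = 10,
         rate_mb_s = 5, activated = TRUE),
    list(p0 = c(50, 700), p1 = c(1050, 700), radius_um = 15, speed_mm_s = 10,
         rate_mb_s = 5)))
  truth <- simulate_microbubbles(ph, proto, hemo_modulation(2, 1, 1),
                                 proto$acq_t, seed = 13)
  grid <- super_grid(ph$fov[1], ph$fov[2])
  path <- rasterize_tracks(truth_tracks(truth), grid)
  mov <- build_sliding_movie(path, grid, proto$acq_t)
  st <- single_trial_variation(mov, proto)
  expect_true(st$svd$found)
  expect_false(is.null(st$map))
  expect_equal(length(st$per_trial), 6)
  expect_equal(dim(st$timecourses), c(70, 6))
  # the activation localizes on the activated vessel
  xs <- (seq_len(grid$nx) - 0.5) * grid$pitch_x
  on_act <- abs(xs - 300) < 30
  on_ctl <- abs(xs - 700) < 30
  expect_gt(mean(st$map[, on_act]), mean(st$map[, on_ctl]))

  # null phantom: no stimulus-locked mode, empty result with a warning
  truth0 <- simulate_microbubbles(ph, proto, hemo_modulation(1, 1, 1),
                                  proto$acq_t, seed = 14)
  mov0 <- build_sliding_movie(rasterize_tracks(truth_tracks(truth0), grid),
                              grid, proto$acq_t)
  expect_warning(st0 <- single_trial_variation(mov0, proto), "no stimulus")
  expect_null(st0$map)
})
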