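#' Pearson correlation activation map
#'
#' Per-pixel Pearson product-moment correlation between the stimulation
#' pattern A(t) (0 at rest, 1 during stimulation) and the pixel's temporal
#' signal. Pixels with zero temporal variance are assigned c = 0.
#'
#' @param x `nz x nx x nt` array (e.g. the flux array of a `pattern_movie`,
#'   or a Power Doppler time series), or a `pattern_movie` (its flux is
#'   used, NA treated as 0).
#' @param a stimulation pattern sampled on the movie's time base.
#' @return `nz x nx` matrix of correlations in `[-1, 1]`.
#' @export
correlation_map <- function(x, a) {
  if (inherits(x, "pattern_movie")) x <- x$flux
  d <- dim(x)
  if (d[3] != length(a)) stop("length of A(t) does not match the time base")
  m <- matrix(x, d[1] * d[2], d[3])
  m[is.na(m)] <- 0
  ac <- a - mean(a)
  mc <- m - rowMeans(m)
  num <- as.vector(mc %*% ac)
  den <- sqrt(rowSums(mc^2)) * sqrt(sum(ac^2))
  cc <- ifelse(den > 0, num / den, 0)
  matrix(pmin(1, pmax(-1, cc)), d[1], d[2])
}

#' SVD of the spatiotemporal ULM matrix
#'
#' Thin singular value decomposition of the reshaped Casorati matrix
#' `(nz*nx) x nt` of a dynamic ULM movie, `M = sum_i lambda_i U_i V_i(t)`,
#' without mean-centering. Invalid (NA) pixels are zero-filled rather than
#' dropped, preserving image geometry. Each image U_i is a spatial pattern
#' whose pixels all follow the temporal fluctuation V_i(t).
#'
#' @param x `nz x nx x nt` array, `pattern_movie` (flux used) or
#'   `ulm_movie` (count used).
#' @param what for movie objects: `"flux"`/`"count"` (default) or
#'   `"velocity"`.
#' @param step_t time-base step in seconds for plain array input (movie
#'   objects carry their own).
#' @param min_count for movie input, pixels totalling fewer detections than
#'   this over the whole movie are zero-filled (not row-dropped, preserving
#'   image geometry) before the decomposition (default 5).
#' @return object of class `svd_activation`: `d` (singular values,
#'   non-increasing), `U` (`nz*nx x r` spatial vectors), `V` (`nt x r`
#'   temporal vectors), `dims`, `step_t` (window step, if known).
#' @export
svd_decompose <- function(x, what = c("flux", "velocity"), step_t = 1,
                          min_count = 5) {
  what <- match.arg(what)
  invalid <- NULL
  if (inherits(x, "pattern_movie")) {
    step_t <- x$step_t
    invalid <- rowSums(matrix(x$count, ncol = dim(x$count)[3])) < min_count
    x <- if (what == "velocity") x$velocity else x$flux
  } else if (inherits(x, "ulm_movie")) {
    step_t <- x$step_t
    cnt <- movie_array(x, "count")
    invalid <- rowSums(matrix(cnt, ncol = x$dims[3])) < min_count
    x <- movie_array(x, if (what == "velocity") "velocity" else "count")
  }
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3])
  m[is.na(m)] <- 0
  if (!is.null(invalid)) m[invalid, ] <- 0
  if (all(m == 0)) stop("all-zero matrix: nothing to decompose")
  sv <- svd(m)
  structure(list(d = sv$d, U = sv$u, V = sv$v, dims = d[1:2],
                 nt = d[3], step_t = step_t),
            class = "svd_activation")
}

#' @export
print.svd_activation <- function(x, ...) {
  cat(sprintf("svd_activation: %d x %d px, %d time points, %d modes\n",
              x$dims[1], x$dims[2], x$nt, length(x$d)))
  if (!is.null(x$i_stim))
    cat(sprintf("  i_stim = %d (|p| = %.3f, %s)\n", x$i_stim,
                abs(x$p[x$i_stim]),
                if (isTRUE(x$found)) "accepted" else "below threshold"))
  invisible(x)
}

#' Select the stimulus-locked singular mode
#'
#' Computes the scalar products `p_i` between the normalized (mean-removed,
#' unit-norm) stimulation pattern and every temporal singular vector, and
#' selects the mode with the largest |p_i| as the stimulation mode. Because
#' the SVD sign is arbitrary, the selected `(U, V)` pair is flipped so that
#' `p_istim > 0`. Since the temporal vectors are orthonormal,
#' `sum_i p_i^2 <= 1`; the mode is accepted as stimulus-locked when
#' `|p_istim| >= p_threshold` (default 0.6), otherwise a warning
#' "no stimulus-locked mode" is issued and `found` is FALSE.
#'
#' @param sv an `svd_activation` from [svd_decompose()].
#' @param a stimulation pattern on the movie time base.
#' @param p_threshold acceptance threshold on |p|.
#' @return `sv` augmented with `p` (scalar products), `i_stim`, `found`.
#' @export
select_stim_mode <- function(sv, a, p_threshold = 0.6) {
  stopifnot(inherits(sv, "svd_activation"), length(a) == sv$nt)
  ac <- a - mean(a)
  na <- sqrt(sum(ac^2))
  if (na == 0) stop("constant stimulation pattern")
  p <- as.vector(crossprod(sv$V, ac / na))
  best <- max(abs(p))
  ties <- which(abs(abs(p) - best) < 1e-12)
  if (length(ties) > 1)
    warning("tie in |p_i|; choosing the smallest mode index")
  i_stim <- ties[1]
  if (p[i_stim] < 0) {           # enforce positive sign, flipping U with V
    sv$U[, i_stim] <- -sv$U[, i_stim]
    sv$V[, i_stim] <- -sv$V[, i_stim]
    p[i_stim] <- -p[i_stim]
  }
  sv$p <- p
  sv$i_stim <- i_stim
  sv$found <- best >= p_threshold
  if (!sv$found) warning("no stimulus-locked mode (max |p| = ",
                         signif(best, 3), ")")
  sv
}

# sum_{t in idx} V_i(t) * step_t
.vint <- function(sv, i, idx) sum(sv$V[idx, i]) * sv$step_t

#' Microbubble-variation map from the stimulation mode
#'
#' Quantifies the variation in microbubble number (or velocity, for a
#' velocity-movie decomposition) during stimulation:
#' `MB_svd = lambda_istim * U_istim * (int_stim V_istim dt - int_baseline
#' V_istim dt)`, integrals taken as sums times the window step. Stimulation
#' and baseline windows must have equal duration.
#'
#' @param sv a mode-selected `svd_activation` ([select_stim_mode()]).
#' @param stim_idx,base_idx integer time indices of the stimulation and
#'   baseline windows (equal length).
#' @return `nz x nx` matrix.
#' @export
variation_map <- function(sv, stim_idx, base_idx) {
  stopifnot(!is.null(sv$i_stim))
  if (length(stim_idx) != length(base_idx))
    stop("stimulation and baseline windows must have equal duration")
  i <- sv$i_stim
  w <- .vint(sv, i, stim_idx) - .vint(sv, i, base_idx)
  matrix(sv$d[i] * sv$U[, i] * w, sv$dims[1], sv$dims[2])
}

#' Baseline map from the sub-stimulation modes
#'
#' `sum_{i < i_stim} lambda_i U_i int_baseline V_i dt`: the spatial image of
#' the vasculature at baseline level described by the modes preceding the
#' stimulation mode.
#'
#' @inheritParams variation_map
#' @return `nz x nx` matrix, or NULL with a warning if `i_stim = 1`.
#' @export
baseline_map <- function(sv, base_idx) {
  stopifnot(!is.null(sv$i_stim))
  if (sv$i_stim == 1) {
    warning("i_stim = 1: no sub-stimulation modes, baseline map undefined")
    return(NULL)
  }
  acc <- matrix(0, sv$dims[1], sv$dims[2])
  for (i in seq_len(sv$i_stim - 1))
    acc <- acc + matrix(sv$d[i] * sv$U[, i] * .vint(sv, i, base_idx),
                        sv$dims[1], sv$dims[2])
  acc
}

#' Relative microbubble-increase map
#'
#' Elementwise ratio of the stimulation-mode variation map to the baseline
#' map formed by the modes below the stimulation mode. Pixels whose baseline
#' magnitude falls below `floor_frac` times the maximum baseline magnitude
#' are masked (NA) rather than producing unstable ratios; if `i_stim = 1`
#' the whole map is undefined and masked with a warning.
#'
#' @inheritParams variation_map
#' @param floor_frac relative floor on the baseline denominator.
#' @return list with `ratio` (`nz x nx`, NA where masked) and `baseline`.
#' @export
relative_variation_map <- function(sv, stim_idx, base_idx,
                                   floor_frac = 1e-6) {
  num <- variation_map(sv, stim_idx, base_idx)
  den <- baseline_map(sv, base_idx)
  if (is.null(den))
    return(list(ratio = matrix(NA_real_, sv$dims[1], sv$dims[2]),
                baseline = NULL))
  floor_abs <- floor_frac * max(abs(den))
  ratio <- ifelse(abs(den) > floor_abs, num / den, NA_real_)
  list(ratio = ratio, baseline = den)
}

#' Time indices of the stimulation and baseline phases
#'
#' Helper mapping the protocol's baseline (0 to rest_pre) and stimulation
#' (rest_pre to rest_pre + stim) phases onto the pattern-movie time base.
#'
#' @param protocol a [stim_protocol()].
#' @param step_t window step of the movie, s.
#' @return list with integer vectors `stim` and `base` (equal length).
#' @export
phase_windows <- function(protocol, step_t = 1) {
  t <- (seq_len(round(protocol$pattern_t / step_t)) - 0.5) * step_t
  list(stim = which(t >= protocol$rest_pre &
                    t < protocol$rest_pre + protocol$stim),
       base = which(t < protocol$rest_pre))
}

#' Single-trial SVD activation analysis
#'
#' Applies the SVD to the raw sliding-window movie without any pattern
#' summation: the stimulus mode is selected against the tiled stimulation
#' pattern, the variation map is the sum over the `Nstim` individual trials
#' of the per-trial stimulation/baseline contrast of V_istim, and the
#' per-trial time courses are V_istim restricted to each pattern.
#'
#' @param movie a raw `ulm_movie` spanning the full acquisition.
#' @param protocol the [stim_protocol()].
#' @param p_threshold mode-acceptance threshold (see [select_stim_mode()]).
#' @return list with `svd` (mode-selected decomposition), `map` (summed
#'   variation map), `per_trial` (list of per-trial maps), `timecourses`
#'   (`nts x n_patterns` matrix of V_istim per trial); empty (`map = NULL`)
#'   with a warning when no stimulus-locked mode is found.
#' @export
single_trial_variation <- function(movie, protocol, p_threshold = 0.6) {
  sv <- svd_decompose(movie, "flux")
  t <- (seq_len(sv$nt) - 0.5) * movie$step_t
  a <- stim_boxcar(protocol, t)
  sv <- select_stim_mode(sv, a, p_threshold)
  nts <- as.integer(round(protocol$pattern_t / movie$step_t))
  if (!sv$found)
    return(list(svd = sv, map = NULL, per_trial = NULL,
                timecourses = matrix(sv$V[, sv$i_stim], nts,
                                     protocol$n_patterns)))
  win <- phase_windows(protocol, movie$step_t)
  per_trial <- vector("list", protocol$n_patterns)
  total <- matrix(0, sv$dims[1], sv$dims[2])
  for (k in seq_len(protocol$n_patterns)) {
    off <- (k - 1L) * nts
    per_trial[[k]] <- variation_map(sv, win$stim + off, win$base + off)
    total <- total + per_trial[[k]]
  }
  list(svd = sv, map = total, per_trial = per_trial,
       timecourses = matrix(sv$V[, sv$i_stim], nts, protocol$n_patterns))
}
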