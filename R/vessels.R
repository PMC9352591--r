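#' Binary vasculature mask from a count map
#'
#' Vesselness filtering ([frangi_vesselness()]) of the (log-compressed)
#' microbubble count map, thresholded by Otsu's method on the nonzero
#' response. Used for compartment segmentation and dilation/constriction
#' maps.
#'
#' @param count_map `nz x nx` count matrix.
#' @param scales vesselness scales in super-resolved pixels.
#' @param log_compress log1p-compress the counts first (default TRUE; count
#'   maps have a large dynamic range between pial and parenchymal vessels).
#' @return logical matrix.
#' @export
vessel_mask <- function(count_map, scales = c(1, 2, 4), log_compress = TRUE) {
  img <- if (log_compress) log1p(count_map) else count_map
  v <- frangi_vesselness(img, scales = scales)
  if (max(v) == 0) stop("empty vasculature mask")
  th <- otsu(v / max(v), range = c(0, 1))
  (v / max(v)) > th
}

#' Segment the vasculature into compartments
#'
#' Labels each super-resolved pixel as pial, penetrating arteriole, venule,
#' intraparenchymal or none. The vasculature is vesselness-segmented from the
#' rest-period count map; pial vessels are supplied as a seed mask (they are
#' selected manually in practice); the remaining vessel pixels with a
#' dominant vertical mean flow are split by its sign (descending Vz > 0:
#' arteriole, ascending Vz < 0: venule), and the rest are intraparenchymal.
#'
#' @param maps rest-period `ulm_maps` (from [accumulate_maps()]).
#' @param pial_mask logical matrix of manually selected pial pixels (NULL for
#'   none).
#' @param vz_large |mean Vz| (mm/s) above which a vessel pixel is treated as
#'   a penetrating vessel and split by flow direction (default 5).
#' @param scales vesselness scales for the vasculature segmentation.
#' @return object of class `compartment_labels`: character matrix `labels`
#'   and the logical `vessel` mask.
#' @export
segment_compartments <- function(maps, pial_mask = NULL, vz_large = 5,
                                 scales = c(1, 2, 4)) {
  stopifnot(inherits(maps, "ulm_maps"))
  vess <- vessel_mask(maps$count, scales = scales)
  if (!any(vess)) stop("empty vasculature mask")
  lab <- matrix("none", nrow(vess), ncol(vess))
  lab[vess] <- "intraparenchymal"
  vz <- maps$vz
  vz[is.na(vz)] <- 0
  lab[vess & vz > vz_large] <- "penetrating_arteriole"
  lab[vess & vz < -vz_large] <- "venule"
  if (!is.null(pial_mask)) lab[vess & pial_mask] <- "pial"
  structure(list(labels = lab, vessel = vess, vz_large = vz_large),
            class = "compartment_labels")
}

#' @export
print.compartment_labels <- function(x, ...) {
  cat("compartment_labels:\n")
  print(table(x$labels[x$labels != "none"]))
  invisible(x)
}

# traversals restricted to a compartment, honoring the flow-direction rule:
# arterioles count only downward-flowing MBs, venules only upward
.compartment_path <- function(path, labels, compartment) {
  pix_lab <- labels$labels[cbind(path$iz, path$ix)]
  sel <- pix_lab == compartment
  if (compartment == "penetrating_arteriole") sel <- sel & path$vz_mm_s > 0
  if (compartment == "venule") sel <- sel & path$vz_mm_s < 0
  path[sel, ]
}

#' Dynamic velocity histogram of a compartment
#'
#' For each time point of the stimulation pattern (spacing `step_t`, pooling
#' the window `[t - w_t/2, t + w_t/2)` from every pattern repetition), a
#' histogram of the microbubble speeds in the compartment with `bin` mm/s
#' bins (default 1). The per-phase histograms are concatenated and the whole
#' 2D histogram is normalized by its maximal bin value.
#'
#' @param path rasterized paths ([rasterize_tracks()]).
#' @param labels a `compartment_labels`.
#' @param compartment compartment to analyze.
#' @param protocol the [stim_protocol()].
#' @param bin velocity bin width, mm/s.
#' @param w_t,step_t phase window and step, s.
#' @param v_max histogram ceiling, mm/s (default: max observed speed).
#' @return list: `hist` (`n_bins x nts` matrix, max value 1), `v_mid` bin
#'   centers (mm/s), `t` phase centers (s).
#' @export
dynamic_velocity_histogram <- function(path, labels, compartment, protocol,
                                       bin = 1, w_t = 5, step_t = 1,
                                       v_max = NULL) {
  sel <- .compartment_path(path, labels, compartment)
  if (!nrow(sel)) stop("empty compartment: ", compartment)
  nts <- as.integer(round(protocol$pattern_t / step_t))
  nt <- as.integer(round(protocol$acq_t / step_t))
  run <- .window_run(sel$t_s, w_t, step_t, nt)
  nrep <- pmax(0L, run$kmax - run$kmin + 1L)
  rows <- rep.int(seq_len(nrow(sel))[nrep > 0], nrep[nrep > 0])
  k <- sequence(nrep[nrep > 0]) - 1L + rep.int(run$kmin[nrep > 0], nrep[nrep > 0])
  ks <- ((k - 1L) %% nts) + 1L
  v <- sel$v_mm_s[rows]
  if (is.null(v_max)) v_max <- max(v)
  ib <- pmin(floor(v / bin) + 1L, ceiling(v_max / bin))
  nb <- ceiling(v_max / bin)
  h <- matrix(0, nb, nts)
  tab <- data.table(ib = ib, ks = ks)[, .N, by = c("ib", "ks")]
  h[cbind(tab$ib, tab$ks)] <- tab$N
  list(hist = h / max(h), v_mid = (seq_len(nb) - 0.5) * bin,
       t = (seq_len(nts) - 0.5) * step_t)
}

#' Compartment flux and speed time courses
#'
#' Pattern-phase time courses for one compartment: microbubble flux summed
#' over the compartment's pixels and mean speed across them, from
#' pattern-averaged movies built on disjoint subsets of the stimulation
#' repetitions (default 4 subsets), giving a mean and s.e.m. per phase
#' point. Relative variations are normalized to the mean over the baseline
#' phase (0 to rest_pre).
#'
#' @param movie the full-acquisition `ulm_movie`.
#' @param labels a `compartment_labels`.
#' @param compartment compartment to analyze.
#' @param protocol the [stim_protocol()].
#' @param n_subsets number of repetition subsets for the s.e.m.
#' @return data.frame per phase point: `t`, `flux`, `flux_sem`, `speed`,
#'   `speed_sem`, `rel_flux`, `rel_flux_sem`, `rel_speed`, `rel_speed_sem`.
#' @export
compartment_timecourse <- function(movie, labels, compartment, protocol,
                                   n_subsets = 4) {
  in_comp <- which(labels$labels == compartment)
  if (!length(in_comp)) stop("empty compartment: ", compartment)
  groups <- split(seq_len(protocol$n_patterns),
                  rep(seq_len(n_subsets),
                      length.out = protocol$n_patterns))
  per <- lapply(groups, function(g) {
    pm <- pattern_average(movie, protocol, patterns = g)
    nts <- dim(pm$flux)[3]
    fl <- apply(matrix(pm$flux, ncol = nts)[in_comp, , drop = FALSE], 2, sum)
    vl <- apply(matrix(pm$velocity, ncol = nts)[in_comp, , drop = FALSE], 2,
                function(col) mean(col, na.rm = TRUE))
    list(flux = fl * protocol$n_patterns / length(g), speed = vl)
  })
  fl <- do.call(rbind, lapply(per, `[[`, "flux"))
  vl <- do.call(rbind, lapply(per, `[[`, "speed"))
  nts <- ncol(fl)
  t <- (seq_len(nts) - 0.5) * movie$step_t
  base <- t < protocol$rest_pre
  rel <- function(m) {
    b <- rowMeans(m[, base, drop = FALSE], na.rm = TRUE)
    (m - b) / b
  }
  sem <- function(m) apply(m, 2, sd, na.rm = TRUE) / sqrt(nrow(m))
  rf <- rel(fl); rv <- rel(vl)
  data.frame(t = t,
             flux = colMeans(fl), flux_sem = sem(fl),
             speed = colMeans(vl, na.rm = TRUE), speed_sem = sem(vl),
             rel_flux = colMeans(rf), rel_flux_sem = sem(rf),
             rel_speed = colMeans(rv, na.rm = TRUE), rel_speed_sem = sem(rv))
}

#' Bilinear sampling of a map at continuous positions
#'
#' @param map `nz x nx` matrix (NA treated as 0).
#' @param grid the [ulm_grid()] of the map.
#' @param z,x positions in um.
#' @return numeric vector of sampled values (0 outside the grid).
#' @export
sample_map <- function(map, grid, z, x) {
  map[is.na(map)] <- 0
  fz <- (z - grid$z0) / grid$pitch_z + 0.5   # continuous row coordinate
  fx <- (x - grid$x0) / grid$pitch_x + 0.5
  i0 <- floor(fz); j0 <- floor(fx)
  az <- fz - i0; ax <- fx - j0
  val <- numeric(length(z))
  at <- function(i, j) {
    ok <- i >= 1 & i <= grid$nz & j >= 1 & j <= grid$nx
    v <- numeric(length(i))
    v[ok] <- map[cbind(i[ok], j[ok])]
    v
  }
  at(i0, j0) * (1 - az) * (1 - ax) + at(i0 + 1, j0) * az * (1 - ax) +
    at(i0, j0 + 1) * (1 - az) * ax + at(i0 + 1, j0 + 1) * az * ax
}

# symmetric moving-average boxcar, edge-truncated
.boxcar_smooth <- function(y, half) {
  if (half < 1) return(y)
  n <- length(y)
  vapply(seq_len(n), function(i) {
    r <- max(1, i - half):min(n, i + half)
    mean(y[r], na.rm = TRUE)
  }, numeric(1))
}

# width at a fixed threshold around the profile peak, with linear
# interpolation of the crossing points; s = sample spacing (um)
.half_max_width <- function(prof, thr, s) {
  pk <- which.max(prof)
  if (!is.finite(thr) || prof[pk] < thr) return(NA_real_)
  lo <- pk
  while (lo > 1 && prof[lo - 1] >= thr) lo <- lo - 1
  hi <- pk
  while (hi < length(prof) && prof[hi + 1] >= thr) hi <- hi + 1
  left <- if (lo == 1) lo else lo - (thr - prof[lo]) / (prof[lo - 1] - prof[lo])
  right <- if (hi == length(prof)) hi else
    hi + (prof[hi] - thr) / (prof[hi] - prof[hi + 1])
  (right - left) * s
}

# count/velocity profile along the 80-um segment normal to the flow at
# (z, x); returns metrics: max count, velocity at max, half-max diameter.
# The diameter threshold is half the REST profile maximum for both
# conditions (rest_thr passed in for the stim condition).
.normal_profile <- function(maps, grid, z, x, theta, half_len = 40,
                            spacing = NULL, slice_width = 0,
                            smooth_um = 0) {
  if (is.null(spacing)) spacing <- min(grid$pitch_z, grid$pitch_x) / 2
  u <- seq(-half_len, half_len, by = spacing)
  # flow direction (cos/sin of theta measured from +z), normal to it
  nzv <- -sin(theta); nxv <- cos(theta)
  offs <- if (slice_width > 0)
    seq(-slice_width / 2, slice_width / 2, by = spacing) else 0
  cnt <- rowMeans(vapply(offs, function(o)
    sample_map(maps$count, grid, z + u * nzv + o * cos(theta),
               x + u * nxv + o * sin(theta)), numeric(length(u))))
  vel <- rowMeans(vapply(offs, function(o)
    sample_map(maps$velocity, grid, z + u * nzv + o * cos(theta),
               x + u * nxv + o * sin(theta)), numeric(length(u))))
  if (smooth_um > 0) {
    # running median: denoises the cross profile without eroding the
    # half-maximum edges a boxcar of comparable width would wash out
    k <- max(3L, round(smooth_um / spacing))
    if (k %% 2 == 0) k <- k + 1L
    if (length(cnt) > k) {
      cnt <- stats::runmed(cnt, k, endrule = "keep")
      vel <- stats::runmed(vel, k, endrule = "keep")
    }
  }
  list(u = u, count = cnt, velocity = vel, spacing = spacing)
}

#' Longitudinal vessel profile (rest vs stimulation)
#'
#' Follows a (penetrating) vessel centerline in depth. At each centerline
#' point the local flow angle `theta = atan2(Vx, Vz)` is measured from the
#' mean-velocity maps and the count/velocity profile is computed along an
#' 80-um segment normal to the flow. Per depth, the metrics are the maximum
#' microbubble count, the velocity at that maximum and the vessel diameter —
#' the profile width at half the REST profile maximum (the same threshold is
#' applied to the stimulation profile). Max-count and velocity are smoothed
#' with a 200-um boxcar along depth; the diameter is median-filtered.
#'
#' @param centerline matrix/data.frame with columns `z`, `x` (um), ordered
#'   by depth (e.g. from [skeleton_centerline()]).
#' @param maps_rest,maps_stim `ulm_maps` for the two conditions.
#' @param half_len half-length of the normal segment, um (default 40).
#' @param smooth_um depth smoothing window, um (default 200).
#' @return data.frame per depth: `z_um`, `theta`, `max_count_rest`,
#'   `max_count_stim`, `v_at_max_rest`, `v_at_max_stim`, `diam_rest_um`,
#'   `diam_stim_um`.
#' @export
longitudinal_profile <- function(centerline, maps_rest, maps_stim,
                                 half_len = 40, smooth_um = 200) {
  cl <- as.matrix(centerline)
  grid <- maps_rest$grid
  n <- nrow(cl)
  res <- matrix(NA_real_, n, 7)
  for (i in seq_len(n)) {
    z <- cl[i, 1]; x <- cl[i, 2]
    sn <- snap_to_grid(z, x, grid)
    if (!sn$inside) next
    vz <- maps_rest$vz[sn$iz, sn$ix]; vx <- maps_rest$vx[sn$iz, sn$ix]
    if (is.na(vz) || (vz == 0 && vx == 0)) { vz <- 1; vx <- 0 }
    theta <- atan2(vx, vz)
    pr <- .normal_profile(maps_rest, grid, z, x, theta, half_len)
    ps <- .normal_profile(maps_stim, grid, z, x, theta, half_len)
    thr <- max(pr$count) / 2
    res[i, ] <- c(theta,
                  max(pr$count), max(ps$count),
                  pr$velocity[which.max(pr$count)],
                  ps$velocity[which.max(ps$count)],
                  .half_max_width(pr$count, thr, pr$spacing),
                  .half_max_width(ps$count, thr, ps$spacing))
  }
  out <- data.frame(z_um = cl[, 1], theta = res[, 1],
                    max_count_rest = res[, 2], max_count_stim = res[, 3],
                    v_at_max_rest = res[, 4], v_at_max_stim = res[, 5],
                    diam_rest_um = res[, 6], diam_stim_um = res[, 7])
  step_um <- if (n > 1) mean(abs(diff(cl[, 1]))) else Inf
  half <- round(smooth_um / 2 / max(step_um, 1e-9))
  if (half >= 1 && n > 2 * half) {
    for (col in c("max_count_rest", "max_count_stim",
                  "v_at_max_rest", "v_at_max_stim"))
      out[[col]] <- .boxcar_smooth(out[[col]], half)
    for (col in c("diam_rest_um", "diam_stim_um"))
      out[[col]] <- stats::runmed(out[[col]], 2 * half + 1, endrule = "keep")
  } else if (n > 1) warning("centerline shorter than smoothing window; unsmoothed")
  out
}

#' Transversal vessel profile at one depth
#'
#' Computes rest and stimulation count/velocity profiles across a vessel
#' along an 80-um segment normal to the flow, centered on the
#' maximum-count pixel found along a user-supplied crossing segment, and
#' averaged over a 50-um-wide slice along the flow. Profiles are smoothed
#' over 50 um before extracting the max count, the velocity at the maximum
#' and the half-maximum diameter (threshold from the rest profile).
#'
#' @param seg_p0,seg_p1 endpoints `c(z, x)` (um) of the crossing segment.
#' @param maps_rest,maps_stim `ulm_maps` for the two conditions.
#' @param half_len half-length of the normal profile, um.
#' @param slice_width averaging slice width along the flow, um.
#' @param smooth_um profile smoothing, um.
#' @return one-row data.frame: `z_um`, `x_um` (profile center), `theta`,
#'   `max_count_rest`, `max_count_stim`, `v_at_max_rest`, `v_at_max_stim`,
#'   `diam_rest_um`, `diam_stim_um`; all NA (flagged) when no vessel lies on
#'   the segment.
#' @export
transversal_profile <- function(seg_p0, seg_p1, maps_rest, maps_stim,
                                half_len = 40, slice_width = 50,
                                smooth_um = 50) {
  grid <- maps_rest$grid
  L <- sqrt(sum((seg_p1 - seg_p0)^2))
  u <- seq(0, 1, by = min(grid$pitch_z, grid$pitch_x) / 2 / L)
  zs <- seg_p0[1] + u * (seg_p1[1] - seg_p0[1])
  xs <- seg_p0[2] + u * (seg_p1[2] - seg_p0[2])
  cs <- sample_map(maps_rest$count, grid, zs, xs)
  empty <- data.frame(z_um = NA_real_, x_um = NA_real_, theta = NA_real_,
                      max_count_rest = NA_real_, max_count_stim = NA_real_,
                      v_at_max_rest = NA_real_, v_at_max_stim = NA_real_,
                      diam_rest_um = NA_real_, diam_stim_um = NA_real_)
  if (max(cs) == 0) return(empty)
  k <- which.max(cs)
  z <- zs[k]; x <- xs[k]
  sn <- snap_to_grid(z, x, grid)
  vz <- maps_rest$vz[sn$iz, sn$ix]; vx <- maps_rest$vx[sn$iz, sn$ix]
  if (is.na(vz)) { vz <- 1; vx <- 0 }
  theta <- atan2(vx, vz)
  pr <- .normal_profile(maps_rest, grid, z, x, theta, half_len,
                        slice_width = slice_width, smooth_um = smooth_um)
  ps <- .normal_profile(maps_stim, grid, z, x, theta, half_len,
                        slice_width = slice_width, smooth_um = smooth_um)
  thr <- max(pr$count) / 2
  data.frame(z_um = z, x_um = x, theta = theta,
             max_count_rest = max(pr$count), max_count_stim = max(ps$count),
             v_at_max_rest = pr$velocity[which.max(pr$count)],
             v_at_max_stim = ps$velocity[which.max(ps$count)],
             diam_rest_um = .half_max_width(pr$count, thr, pr$spacing),
             diam_stim_um = .half_max_width(ps$count, thr, ps$spacing))
}

#' Perfusion / drainage area of one vessel
#'
#' Selects every microbubble track whose rasterized path crosses a seed
#' segment (set near the pial entry of the vessel) and measures the area it
#' perfuses: the number of super-resolved pixels where at least one track
#' position was counted, multiplied by the pixel area. Duplicate passages
#' do not increase the area (set semantics), so the area is monotone
#' non-decreasing under track addition.
#'
#' @param path rasterized paths ([rasterize_tracks()]).
#' @param seg_p0,seg_p1 seed-segment endpoints `c(z, x)` in um.
#' @param grid the [ulm_grid()].
#' @param t_filter optional function of traversal times restricting the
#'   condition (e.g. rest or stimulation phases).
#' @return object of class `perfusion_area`: `track_ids`, `n_pixels`,
#'   `area_um2`; zero area with a warning when no track passes.
#' @export
perfusion_area <- function(path, seg_p0, seg_p1, grid, t_filter = NULL) {
  if (!is.null(t_filter)) path <- path[t_filter(path$t_s), ]
  # rasterize the seed segment onto the grid
  L <- sqrt(sum((seg_p1 - seg_p0)^2))
  u <- seq(0, 1, by = min(grid$pitch_z, grid$pitch_x) / 8 / max(L, 1e-9))
  sn <- snap_to_grid(seg_p0[1] + u * (seg_p1[1] - seg_p0[1]),
                     seg_p0[2] + u * (seg_p1[2] - seg_p0[2]), grid)
  seed <- unique((sn$ix[sn$inside] - 1L) * grid$nz + sn$iz[sn$inside])
  pix <- (path$ix - 1L) * grid$nz + path$iz
  ids <- unique(path$track_id[pix %in% seed])
  if (!length(ids)) {
    warning("no track passes through the seed segment")
    return(structure(list(track_ids = integer(), n_pixels = 0L,
                          area_um2 = 0), class = "perfusion_area"))
  }
  npix <- length(unique(pix[path$track_id %in% ids]))
  structure(list(track_ids = ids, n_pixels = npix,
                 area_um2 = npix * grid$pitch_z * grid$pitch_x),
            class = "perfusion_area")
}

#' @export
print.perfusion_area <- function(x, ...) {
  cat(sprintf("perfusion_area: %d tracks, %d px, %.0f um^2\n",
              length(x$track_ids), x$n_pixels, x$area_um2))
  invisible(x)
}

#' Dilation / constriction map
#'
#' Binarizes the rest- and stimulation-period count maps with the vesselness
#' segmentation ([vessel_mask()]) and subtracts them: +1 where the vessel
#' appears only during stimulation (dilation), -1 where it disappears
#' (constriction), 0 elsewhere.
#'
#' @param maps_rest,maps_stim `ulm_maps` for the two conditions.
#' @param scales vesselness scales.
#' @return integer matrix with values in `{-1, 0, 1}`.
#' @export
dilation_constriction_map <- function(maps_rest, maps_stim,
                                      scales = c(1, 2, 4)) {
  # one common threshold for the two conditions, so the binarization is
  # comparable and the subtraction reflects geometry, not normalization
  vr <- frangi_vesselness(log1p(maps_rest$count), scales = scales)
  vs <- frangi_vesselness(log1p(maps_stim$count), scales = scales)
  vmax <- max(vr, vs)
  if (vmax == 0) stop("empty vasculature mask")
  th <- otsu(matrix(c(vr, vs) / vmax, ncol = 2), range = c(0, 1))
  matrix(as.integer(vs / vmax > th) - as.integer(vr / vmax > th),
         nrow(vr), ncol(vr))
}

#' Rest-vs-stimulation statistics over vessels
#'
#' Summarizes per-vessel relative variations (stimulation relative to rest)
#' of a metric: mean, s.e.m., and the two-sided Wilcoxon signed-rank test of
#' the null hypothesis that the variations are distributed with zero median.
#' A paired variant compares two depths.
#'
#' @param variation numeric vector of per-vessel relative variations.
#' @param variation2 optional second vector for the paired depth comparison.
#' @return data.frame: `n`, `mean`, `sem`, `p_value` (NA with all-zero
#'   differences, where the statistic is undefined).
#' @export
rest_stim_stats <- function(variation, variation2 = NULL) {
  v <- variation[is.finite(variation)]
  n <- length(v)
  if (n < 1) stop("no finite variations")
  out <- data.frame(n = n, mean = mean(v), sem = sd(v) / sqrt(n),
                    p_value = NA_real_)
  if (is.null(variation2)) {
    if (any(v != 0))
      out$p_value <- wilcox.test(v, mu = 0, exact = TRUE)$p.value
  } else {
    v2 <- variation2[is.finite(variation2)]
    if (any(v - v2 != 0))
      out$p_value <- wilcox.test(v, v2, paired = TRUE, exact = TRUE)$p.value
  }
  out
}

#' Neighbor-pixel velocity discrimination
#'
#' Spatial-resolution check: microbubble velocities crossing a vessel
#' section are pooled per super-resolved pixel, and a two-sample Student's
#' t-test is applied between each pair of consecutive pixel bins. Adjacent
#' pixels carrying distinct velocity populations yield significant
#' differences; pairs where either bin has fewer than 2 samples are skipped.
#'
#' @param bins list of numeric vectors: the velocity samples of consecutive
#'   pixels across the section.
#' @return data.frame per consecutive pair: `pair`, `n1`, `n2`, `t`,
#'   `p_value` (NA for skipped pairs).
#' @export
neighbor_velocity_discrimination <- function(bins) {
  stopifnot(is.list(bins), length(bins) >= 2)
  out <- lapply(seq_len(length(bins) - 1), function(i) {
    a <- bins[[i]]; b <- bins[[i + 1]]
    if (length(a) < 2 || length(b) < 2)
      return(data.frame(pair = i, n1 = length(a), n2 = length(b),
                        t = NA_real_, p_value = NA_real_))
    tt <- t.test(a, b)
    data.frame(pair = i, n1 = length(a), n2 = length(b),
               t = unname(tt$statistic), p_value = tt$p.value)
  })
  do.call(rbind, out)
}

#' Velocity samples per pixel across a vessel section
#'
#' Gathers, for one phase window of the pattern-averaged data, the speeds of
#' all traversals falling in each pixel along a cross-section, as input to
#' [neighbor_velocity_discrimination()].
#'
#' @param path rasterized paths.
#' @param pixels data.frame/matrix with columns `iz`, `ix`: consecutive
#'   pixels across the section.
#' @param protocol the [stim_protocol()]; with `phase_range`, restricts to a
#'   phase window `[t0, t1)` (s within the pattern); NULL uses all times.
#' @param phase_range optional `c(t0, t1)`.
#' @return list of numeric velocity vectors, one per pixel.
#' @export
section_velocity_bins <- function(path, pixels, protocol = NULL,
                                  phase_range = NULL) {
  pixels <- as.matrix(pixels)
  p <- path
  if (!is.null(phase_range) && !is.null(protocol)) {
    ph <- p$t_s %% protocol$pattern_t
    p <- p[ph >= phase_range[1] & ph < phase_range[2], ]
  }
  lapply(seq_len(nrow(pixels)), function(i)
    p$v_mm_s[p$iz == pixels[i, 1] & p$ix == pixels[i, 2]])
}

#' Skeletonize a binary vessel mask (Zhang-Suen thinning)
#'
#' Iterative morphological thinning of a binary vasculature image to
#' one-pixel-wide centerlines, followed by pruning of side branches shorter
#' than `prune` pixels (default 10), keeping the main centerline.
#'
#' @param mask logical matrix.
#' @param prune minimum branch length in pixels.
#' @return logical matrix of centerline pixels.
#' @export
skeletonize_mask <- function(mask, prune = 10) {
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  nz <- nrow(img); nx <- ncol(img)
  pad <- function(m) {
    p <- matrix(0L, nz + 2, nx + 2); p[2:(nz + 1), 2:(nx + 1)] <- m; p
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p <- pad(img)
      ctr <- p[2:(nz + 1), 2:(nx + 1)]
      P2 <- p[1:nz, 2:(nx + 1)];     P3 <- p[1:nz, 3:(nx + 2)]
      P4 <- p[2:(nz + 1), 3:(nx + 2)]; P5 <- p[3:(nz + 2), 3:(nx + 2)]
      P6 <- p[3:(nz + 2), 2:(nx + 1)]; P7 <- p[3:(nz + 2), 1:nx]
      P8 <- p[2:(nz + 1), 1:nx];     P9 <- p[1:nz, 1:nx]
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
           (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
           (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      cond <- if (pass == 1) (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
              else           (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      del <- ctr == 1 & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) { img[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  if (prune > 0) img <- .prune_skeleton(img, prune)
  img == 1L
}

# remove side branches shorter than min_len (repeatedly erode endpoints
# belonging to short branches)
.prune_skeleton <- function(img, min_len) {
  nz <- nrow(img); nx <- ncol(img)
  nb_count <- function(m) {
    p <- matrix(0L, nz + 2, nx + 2); p[2:(nz + 1), 2:(nx + 1)] <- m
    p[1:nz, 2:(nx + 1)] + p[3:(nz + 2), 2:(nx + 1)] +
      p[2:(nz + 1), 1:nx] + p[2:(nz + 1), 3:(nx + 2)] +
      p[1:nz, 1:nx] + p[1:nz, 3:(nx + 2)] +
      p[3:(nz + 2), 1:nx] + p[3:(nz + 2), 3:(nx + 2)]
  }
  for (it in seq_len(min_len)) {
    nb <- nb_count(img)
    tips <- img == 1L & nb <= 1L
    if (!any(tips)) break
    img[tips] <- 0L
  }
  img
}

#' Ordered centerline of a penetrating vessel
#'
#' Extracts the skeleton of a vessel mask and returns the centerline points
#' ordered by depth, in micrometres, for [longitudinal_profile()].
#'
#' @param mask logical vessel mask (single vessel).
#' @param grid the [ulm_grid()].
#' @param prune branch-pruning length in pixels.
#' @return data.frame with `z`, `x` (um), one row per depth.
#' @export
skeleton_centerline <- function(mask, grid, prune = 10) {
  sk <- skeletonize_mask(mask, prune)
  idx <- which(sk, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty skeleton")
  dt <- data.table(iz = idx[, 1], ix = idx[, 2])[
    , list(ix = mean(ix)), by = "iz"][order(iz)]
  data.frame(z = (dt$iz - 0.5) * grid$pitch_z + grid$z0,
             x = (dt$ix - 0.5) * grid$pitch_x + grid$x0)
}
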