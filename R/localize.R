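#' Multiscale Frangi vesselness filter (2D)
#'
#' Hessian-eigenvalue ridge filter for bright tubular structures. At each
#' scale the image is Gaussian-smoothed, the scale-normalized Hessian is
#' computed by central differences, and the vesselness response
#' `exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` is evaluated
#' (Rb = blobness ratio lambda1/lambda2, S = Frobenius norm of the Hessian;
#' response zero where lambda2 >= 0, i.e. non-bright structures). The final
#' map is the pixelwise maximum over scales.
#'
#' @param img numeric matrix.
#' @param scales Gaussian scales in pixels (default `c(1, 2, 4)`).
#' @param beta blobness sensitivity (default 0.5).
#' @param c_norm structureness sensitivity; default half the maximum Hessian
#'   norm at each scale.
#' @return numeric matrix of vesselness responses (>= 0).
#' @export
frangi_vesselness <- function(img, scales = c(1, 2, 4), beta = 0.5,
                              c_norm = NULL) {
  stopifnot(is.matrix(img))
  out <- matrix(0, nrow(img), ncol(img))
  for (s in scales) {
    if (2 * ceiling(3 * s) + 1 > min(dim(img))) next  # kernel exceeds image
    sm <- gblur(img, sigma = s)
    # central differences with replicated borders
    up <- rbind(sm[1, ], sm[-nrow(sm), ]); down <- rbind(sm[-1, ], sm[nrow(sm), ])
    left <- cbind(sm[, 1], sm[, -ncol(sm)]); right <- cbind(sm[, -1], sm[, ncol(sm)])
    hzz <- (up + down - 2 * sm) * s^2
    hxx <- (left + right - 2 * sm) * s^2
    ul <- cbind(up[, 1], up[, -ncol(sm)]); ur <- cbind(up[, -1], up[, ncol(sm)])
    dl <- cbind(down[, 1], down[, -ncol(sm)]); dr <- cbind(down[, -1], down[, ncol(sm)])
    hzx <- (dr - dl - ur + ul) / 4 * s^2
    tmp <- sqrt(pmax((hzz - hxx)^2 / 4 + hzx^2, 0))
    mu <- (hzz + hxx) / 2
    e1 <- mu + tmp; e2 <- mu - tmp                  # e1 >= e2
    # order by magnitude: |l1| <= |l2|
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1); l2 <- ifelse(swap, e1, e2)
    S2 <- l1^2 + l2^2
    cc <- if (is.null(c_norm)) sqrt(max(S2)) / 2 else c_norm
    if (cc == 0) next
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * cc^2)))
    v[l2 >= 0] <- 0
    out <- pmax(out, v)
  }
  out
}

#' Binary vesselness mask for microbubble detection
#'
#' Builds a binary vasculature mask from an image stack (or a single image):
#' the temporal maximum image is vesselness-filtered ([frangi_vesselness()])
#' and thresholded with Otsu's method on the nonzero response. Detections
#' outside the mask are discarded downstream. If the response is everywhere
#' zero (e.g. a constant image) a warning is issued and an all-TRUE
#' pass-through mask is returned.
#'
#' @param x `Nz x Nx x Nf` array, [frame_block()], or matrix.
#' @param scales vesselness scales in pixels.
#' @return logical matrix.
#' @export
compute_vesselness_mask <- function(x, scales = c(1, 2, 4)) {
  if (inherits(x, "frame_block")) x <- x$frames
  img <- if (length(dim(x)) == 3) apply(Mod(x), c(1, 2), max) else Mod(x)
  v <- frangi_vesselness(img, scales = scales)
  vmax <- max(v)
  if (vmax == 0) {
    warning("empty vesselness response; passing through without masking")
    return(matrix(TRUE, nrow(img), ncol(img)))
  }
  th <- otsu(v / vmax, range = c(0, 1))
  mask <- (v / vmax) > th
  if (!any(mask)) {
    warning("empty vesselness mask; passing through without masking")
    return(matrix(TRUE, nrow(img), ncol(img)))
  }
  mask
}

#' Gaussian point-spread-function model
#'
#' Normalized Gaussian kernel used as the imaging response of an isolated
#' microbubble (axial and lateral size of the order of the wavelength).
#'
#' @param sigma_px standard deviation in pixels of the target image.
#' @param half half-size of the kernel in pixels (default `ceiling(2*sigma)`).
#' @return square numeric matrix summing to 1.
#' @export
psf_model <- function(sigma_px, half = max(2L, ceiling(2 * sigma_px))) {
  g <- exp(-((-half):half)^2 / (2 * sigma_px^2))
  k <- outer(g, g)
  k / sum(k)
}

#' Lanczos-3 image interpolation
#'
#' Separable Lanczos resampling (`sinc(u) * sinc(u/3)`, support 3 input
#' pixels) onto a grid `factor` times finer, as applied to the beamformed
#' images before microbubble localization. Weight rows are normalized to
#' preserve the local mean.
#'
#' @param img numeric matrix.
#' @param factor integer upsampling factor (default 6).
#' @return `(nz*factor) x (nx*factor)` matrix.
#' @export
lanczos_interp <- function(img, factor = 6) {
  lk <- function(u) ifelse(abs(u) < 1e-12, 1,
                    ifelse(abs(u) >= 3, 0,
                           3 * sin(pi * u) * sin(pi * u / 3) / (pi^2 * u^2)))
  wmat <- function(n, f) {
    tout <- (seq_len(n * f) - 0.5) / f   # fine centers, coarse-pixel units
    tin <- seq_len(n) - 0.5
    w <- outer(tout, tin, function(a, b) lk(a - b))
    w / rowSums(w)
  }
  wz <- wmat(nrow(img), factor)
  wx <- wmat(ncol(img), factor)
  wz %*% img %*% t(wx)
}

#' Detect microbubble candidates in one frame
#'
#' Local maxima of the (magnitude) image lying inside the vesselness mask
#' whose normalized cross-correlation with the Gaussian PSF model exceeds
#' `corr_threshold` (default 0.7), ranked brightest-first, optionally capped.
#'
#' @param frame numeric matrix (magnitude image).
#' @param psf PSF kernel from [psf_model()] (odd square matrix).
#' @param corr_threshold minimum Pearson correlation with the PSF.
#' @param mask optional logical matrix; detections outside are discarded.
#' @param max_candidates optional cap on detections per frame.
#' @return data.frame with integer pixel positions `iz`, `ix`, `amp`, `corr`.
#' @export
detect_candidates <- function(frame, psf, corr_threshold = 0.7, mask = NULL,
                              max_candidates = Inf) {
  nz <- nrow(frame); nx <- ncol(frame)
  hw <- (nrow(psf) - 1L) %/% 2L
  # strict local maxima over the 8-neighborhood
  pad <- matrix(-Inf, nz + 2, nx + 2)
  pad[2:(nz + 1), 2:(nx + 1)] <- frame
  is_max <- frame > 0
  for (dz in -1:1) for (dx in -1:1) {
    if (dz == 0 && dx == 0) next
    nb <- pad[(2 + dz):(nz + 1 + dz), (2 + dx):(nx + 1 + dx)]
    is_max <- is_max & (frame > nb | (frame == nb & (dz > 0 | (dz == 0 & dx > 0))))
  }
  if (!is.null(mask)) is_max <- is_max & mask
  idx <- which(is_max, arr.ind = TRUE)
  if (!nrow(idx)) return(data.frame(iz = integer(), ix = integer(),
                                    amp = numeric(), corr = numeric()))
  kv <- as.vector(psf)
  corr <- vapply(seq_len(nrow(idx)), function(k) {
    iz <- idx[k, 1]; ix <- idx[k, 2]
    if (iz <= hw || ix <= hw || iz > nz - hw || ix > nx - hw) return(-1)
    patch <- frame[(iz - hw):(iz + hw), (ix - hw):(ix + hw)]
    if (sd(patch) == 0) return(-1)
    stats::cor(as.vector(patch), kv)
  }, numeric(1))
  keep <- corr > corr_threshold
  out <- data.frame(iz = idx[keep, 1], ix = idx[keep, 2],
                    amp = frame[idx[keep, , drop = FALSE]], corr = corr[keep])
  out <- out[order(-out$amp), , drop = FALSE]
  if (nrow(out) > max_candidates) out <- out[seq_len(max_candidates), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# pseudo-inverse of the (2h+1)x(2h+1) quadratic design matrix, cached per h
.quad_cache <- new.env(parent = emptyenv())
.quad_design <- function(half) {
  key <- as.character(half)
  if (is.null(.quad_cache[[key]])) {
    g <- expand.grid(dz = -half:half, dx = -half:half)
    X <- cbind(1, g$dz, g$dx, g$dz^2, g$dz * g$dx, g$dx^2)
    .quad_cache[[key]] <- solve(crossprod(X)) %*% t(X)
  }
  .quad_cache[[key]]
}

#' Sub-pixel localization by local quadratic fit
#'
#' Least-squares second-order polynomial (paraboloid) fit to the local
#' intensity neighborhood of a candidate maximum (default 5x5 pixels,
#' matching a PSF of ~2.5 pixel standard deviation on the interpolated
#' grid); the detection position is the paraboloid vertex. If the fit is
#' singular, the vertex is not a maximum, or it falls more than one pixel
#' from the candidate, the integer maximum is returned (offset 0).
#'
#' @param frame numeric matrix.
#' @param iz,ix integer candidate position (>= half+1 pixels from the
#'   border).
#' @param half fit-neighborhood half-width in pixels (default 2, i.e. 5x5).
#' @return numeric `c(dz, dx)` sub-pixel offset in pixels, in `[-1, 1]`.
#' @export
refine_subpixel <- function(frame, iz, ix, half = 2) {
  nz <- nrow(frame); nx <- ncol(frame)
  if (iz <= half || ix <= half || iz > nz - half || ix > nx - half)
    return(c(0, 0))
  patch <- frame[(iz - half):(iz + half), (ix - half):(ix + half)]
  b <- .quad_design(half) %*% as.vector(patch)      # 1, z, x, z2, zx, x2
  H <- matrix(c(2 * b[4], b[5], b[5], 2 * b[6]), 2)
  detH <- H[1] * H[4] - H[2] * H[3]
  if (!is.finite(detH) || abs(detH) < 1e-12) return(c(0, 0))
  off <- -solve(H, c(b[2], b[3]))
  if (detH <= 0 || H[1] >= 0) return(c(0, 0))     # not a maximum
  if (max(abs(off)) > 1) return(c(0, 0))
  as.numeric(off)
}

#' Snap detections to the super-resolved grid
#'
#' Rounds continuous detection coordinates to the chosen reconstruction pixel
#' size (half-up on ties: boundary positions go to the higher-index pixel),
#' keeping the continuous coordinates alongside. Out-of-field detections are
#' dropped with a message.
#'
#' @param detections data.frame with `z_um`, `x_um` columns.
#' @param grid an [ulm_grid()].
#' @return `detections` with added integer columns `iz`, `ix`.
#' @export
grid_snap <- function(detections, grid) {
  sn <- snap_to_grid(detections$z_um, detections$x_um, grid)
  if (any(!sn$inside))
    message(sum(!sn$inside), " detection(s) outside the field of view dropped")
  detections$iz <- sn$iz
  detections$ix <- sn$ix
  detections[sn$inside, , drop = FALSE]
}

#' Localize microbubbles in a filtered frame block
#'
#' Full per-frame detection flow: magnitude image, optional Lanczos
#' interpolation to a grid `interp_factor` times finer, vesselness masking on
#' the temporal maximum image, PSF-correlated local-maxima detection and
#' sub-pixel quadratic refinement. Detection coordinates are continuous
#' micrometre positions in the block's frame of reference.
#'
#' @param block a clutter-filtered [frame_block()].
#' @param psf_sigma_um PSF standard deviation in um (match the acquisition).
#' @param corr_threshold PSF-correlation threshold (default 0.7).
#' @param interp_factor Lanczos upsampling factor (1 = no interpolation).
#' @param use_mask compute and apply the vesselness mask (default TRUE).
#' @param max_per_frame optional cap on detections per frame.
#' @return data.frame with `frame`, `t_s`, `z_um`, `x_um`, `amp`, `corr`.
#' @export
localize_block <- function(block, psf_sigma_um = 80, corr_threshold = 0.7,
                           interp_factor = 6, use_mask = TRUE,
                           max_per_frame = Inf) {
  stopifnot(inherits(block, "frame_block"))
  mag <- Mod(block$frames)
  nf <- dim(mag)[3]
  pz <- block$pitch_z / interp_factor
  px <- block$pitch_x / interp_factor
  fine <- lapply(seq_len(nf), function(f)
    if (interp_factor > 1) lanczos_interp(mag[, , f], interp_factor)
    else mag[, , f])
  mask <- if (use_mask) {
    mx <- Reduce(pmax, fine)
    compute_vesselness_mask(mx, scales = c(1, 2, 4) * interp_factor / 2)
  } else NULL
  sigma_px <- psf_sigma_um / min(pz, px)
  psf <- psf_model(sigma_px)
  fit_half <- max(2L, round(0.85 * sigma_px))  # track the PSF footprint
  # The shape check against the PSF is done on the acquisition grid: the
  # interpolated image is smooth by construction, so fine-grid patches of
  # pure noise would correlate with any smooth kernel. On the coarse grid
  # white noise decorrelates from the Gaussian spot model.
  psf_coarse <- psf_model(psf_sigma_um / min(block$pitch_z, block$pitch_x))
  hwc <- (nrow(psf_coarse) - 1L) %/% 2L
  kvc <- as.vector(psf_coarse)
  nzc <- dim(mag)[1]; nxc <- dim(mag)[2]
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    img <- fine[[f]]
    cand <- detect_candidates(img, psf, corr_threshold = -1, mask, Inf)
    if (!nrow(cand)) next
    corr <- vapply(seq_len(nrow(cand)), function(k) {
      izc <- ceiling(cand$iz[k] / interp_factor)
      ixc <- ceiling(cand$ix[k] / interp_factor)
      if (izc <= hwc || ixc <= hwc || izc > nzc - hwc || ixc > nxc - hwc)
        return(-1)
      patch <- mag[(izc - hwc):(izc + hwc), (ixc - hwc):(ixc + hwc), f]
      if (sd(patch) == 0) return(-1)
      stats::cor(as.vector(patch), kvc)
    }, numeric(1))
    cand$corr <- corr
    cand <- cand[corr > corr_threshold, , drop = FALSE]
    if (!nrow(cand)) next
    if (nrow(cand) > max_per_frame)
      cand <- cand[seq_len(max_per_frame), , drop = FALSE]  # brightest first
    offs <- t(vapply(seq_len(nrow(cand)), function(k)
      refine_subpixel(img, cand$iz[k], cand$ix[k], fit_half), numeric(2)))
    out[[f]] <- data.frame(
      frame = as.integer(round(block$t0 * block$frame_rate)) + f - 1L,
      t_s = block$t0 + (f - 1) / block$frame_rate,
      z_um = (cand$iz - 0.5 + offs[, 1]) * pz,
      x_um = (cand$ix - 0.5 + offs[, 2]) * px,
      amp = cand$amp, corr = cand$corr)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(frame = integer(), t_s = numeric(),
                                      z_um = numeric(), x_um = numeric(),
                                      amp = numeric(), corr = numeric())
  rownames(res) <- NULL
  res
}
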