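#' Frame block container
#'
#' One block of ultrafast compounded frames with acquisition metadata.
#'
#' @param frames `Nz x Nx x Nf` array (real or complex).
#' @param frame_rate frame rate in Hz.
#' @param pitch_z,pitch_x pixel pitch in um.
#' @param t0 acquisition time of the first frame, seconds.
#' @return object of class `frame_block`.
#' @export
frame_block <- function(frames, frame_rate, pitch_z = 100, pitch_x = 110,
                        t0 = 0) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] >= 2,
            all(is.finite(Mod(frames))))
  structure(list(frames = frames, frame_rate = frame_rate,
                 pitch_z = pitch_z, pitch_x = pitch_x, t0 = t0),
            class = "frame_block")
}

#' @export
print.frame_block <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("frame_block: %d x %d px, %d frames at %g Hz, t0 = %g s, pitch %g x %g um\n",
              d[1], d[2], d[3], x$frame_rate, x$t0, x$pitch_z, x$pitch_x))
  invisible(x)
}

# one smooth random spatial pattern on an Nz x Nx grid
.smooth_field <- function(nz, nx, sigma = 2) {
  f <- matrix(rnorm(nz * nx), nz, nx)
  r <- min(2 * ceiling(3 * sigma) + 1, min(nz, nx) - 1 + (min(nz, nx) %% 2))
  if (r %% 2 == 0) r <- r - 1
  f <- gblur(f, sigma = sigma, radius = r)
  f / max(abs(f))
}

#' Render ultrafast frames from microbubble ground truth
#'
#' Renders a block of compounded frames on the acquisition (coarse) grid:
#' each microbubble adds a Gaussian spot (the point-spread function of an
#' isolated scatterer, axial/lateral size of order the wavelength) at its
#' possibly motion-shifted position; tissue clutter is the sum of
#' `clutter_rank` fixed smooth spatial patterns with smooth temporal weights;
#' white Gaussian noise is added on top. Rigid motion (slow linear drift plus
#' axial pulsatility) shifts the microbubble positions.
#'
#' @param truth a [simulate_microbubbles()] result.
#' @param t0 start time of the block, seconds.
#' @param n_frames number of frames in the block (default 400).
#' @param pitch_z,pitch_x acquisition pixel pitch in um (default 100 x 110).
#' @param psf_sigma Gaussian PSF standard deviation in um (default 80, a realistic beamformed spot: full width at half maximum of about 190 um, i.e. the wavelength times the receive f-number).
#' @param mb_amp peak amplitude of one microbubble echo.
#' @param clutter_rank number of tissue-clutter components (0 = none).
#' @param clutter_amp clutter amplitude relative to `mb_amp` (tissue is much
#'   brighter than individual microbubbles).
#' @param noise_sigma additive white-noise standard deviation.
#' @param motion `NULL` or list with `drift` (`c(z, x)` um/s), `puls_amp`
#'   (axial amplitude, um) and `puls_freq` (Hz).
#' @param seed RNG seed (clutter patterns and noise).
#' @return a [frame_block()].
#' @export
render_frame_block <- function(truth, t0 = 0, n_frames = 400,
                               pitch_z = 100, pitch_x = 110,
                               psf_sigma = 80, mb_amp = 1,
                               clutter_rank = 0, clutter_amp = 50,
                               noise_sigma = 0, motion = NULL, seed = NULL) {
  stopifnot(inherits(truth, "mb_truth"), psf_sigma > 0, n_frames >= 2)
  if (!is.null(seed)) set.seed(seed)
  fr <- truth$frame_rate
  fov <- truth$phantom$fov
  nz <- ceiling(fov[1] / pitch_z); nx <- ceiling(fov[2] / pitch_x)
  frames <- array(0, c(nz, nx, n_frames))
  f_first <- as.integer(round(t0 * fr))
  tr <- truth$tracks
  if (nrow(tr)) {
    sel <- tr[tr$frame >= f_first & tr$frame < f_first + n_frames, ]
    if (nrow(sel)) {
      z <- sel$z_um; x <- sel$x_um
      if (!is.null(motion)) {
        drift <- motion$drift %||% c(0, 0)
        pa <- motion$puls_amp %||% 0
        pf <- motion$puls_freq %||% 5.5
        z <- z + drift[1] * sel$t_s + pa * sin(2 * pi * pf * sel$t_s)
        x <- x + drift[2] * sel$t_s
      }
      fi <- sel$frame - f_first + 1L
      hw <- ceiling(4 * psf_sigma / min(pitch_z, pitch_x))
      zc <- (seq_len(nz) - 0.5) * pitch_z
      xc <- (seq_len(nx) - 0.5) * pitch_x
      for (k in seq_len(nrow(sel))) {
        iz0 <- floor(z[k] / pitch_z) + 1
        ix0 <- floor(x[k] / pitch_x) + 1
        izr <- max(1, iz0 - hw):min(nz, iz0 + hw)
        ixr <- max(1, ix0 - hw):min(nx, ix0 + hw)
        if (!length(izr) || !length(ixr)) next
        gz <- exp(-(zc[izr] - z[k])^2 / (2 * psf_sigma^2))
        gx <- exp(-(xc[ixr] - x[k])^2 / (2 * psf_sigma^2))
        frames[izr, ixr, fi[k]] <- frames[izr, ixr, fi[k]] +
          mb_amp * outer(gz, gx)
      }
    }
  }
  if (clutter_rank > 0) {
    tt <- (f_first + seq_len(n_frames) - 1L) / fr
    for (r in seq_len(clutter_rank)) {
      pat <- .smooth_field(nz, nx, sigma = 2)
      fq <- runif(1, 0.3, 2); ph <- runif(1, 0, 2 * pi)
      w <- clutter_amp * mb_amp * (1.5 + cos(2 * pi * fq * tt + ph)) / 2.5
      frames <- frames + outer(pat, w)
    }
  }
  if (noise_sigma > 0)
    frames <- frames + array(rnorm(length(frames), sd = noise_sigma), dim(frames))
  frame_block(frames, fr, pitch_z, pitch_x, t0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
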