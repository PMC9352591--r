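#' SVD spatiotemporal clutter filter
#'
#' Separates microbubble echoes from tissue signal by singular value
#' decomposition of the space-time (Casorati) matrix of a frame block: the
#' block is reshaped to `(Nz*Nx) x Nf`, decomposed, the `n_discard` largest
#' singular values are zeroed (tissue occupies the most energetic, most
#' spatiotemporally coherent subspace) and the block is reconstructed. No
#' mean-centering is applied: the first singular mode absorbs the mean.
#' Complex input is supported; magnitude is only taken at detection/energy
#' stages. The default `n_discard = 10` is the ULM setting; Power Doppler
#' (fUS) processing uses 60 on its 200-frame blocks.
#'
#' @param block a [frame_block()] (real or complex frames).
#' @param n_discard number of leading singular values to discard
#'   (`0 <= n_discard < min(Nz*Nx, Nf)`).
#' @return filtered [frame_block()] with identical shape and metadata.
#' @examples
#' b <- frame_block(array(rnorm(4 * 4 * 8), c(4, 4, 8)), 1000)
#' f <- svd_clutter_filter(b, 1)
#' @export
svd_clutter_filter <- function(block, n_discard = 10) {
  stopifnot(inherits(block, "frame_block"))
  d <- dim(block$frames)
  rank_bound <- min(d[1] * d[2], d[3])
  if (n_discard < 0 || n_discard >= rank_bound)
    stop("n_discard must satisfy 0 <= n_discard < ", rank_bound)
  if (n_discard == 0) return(block)
  cas <- matrix(block$frames, d[1] * d[2], d[3])
  sv <- svd(cas)
  keep <- seq_len(n_discard)
  # subtract the discarded subspace (cheaper than full reconstruction)
  low <- sv$u[, keep, drop = FALSE] %*%
    (sv$d[keep] * t(Conj(sv$v[, keep, drop = FALSE])))
  out <- block
  out$frames <- array(cas - low, d)
  out
}

#' Power Doppler energy map
#'
#' Per-pixel blood-signal energy of a clutter-filtered block: the sum of the
#' squared signal magnitude over the frames of the block (the integral over
#' the time points). Proportional to blood volume at constant hematocrit.
#'
#' @param block a (filtered) [frame_block()].
#' @return `Nz x Nx` numeric matrix.
#' @export
power_doppler <- function(block) {
  stopifnot(inherits(block, "frame_block"))
  d <- dim(block$frames)
  matrix(rowSums(matrix(Mod(block$frames)^2, d[1] * d[2], d[3])), d[1], d[2])
}
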