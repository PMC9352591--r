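#' Stimulation protocol
#'
#' Defines one stimulation pattern (rest / stimulation / rest) and the number
#' of repetitions. The default reproduces the whisker/visual paradigm used for
#' the ULM experiments: 30 s rest, 30 s stimulation, 10 s rest, repeated 20
#' times (70 s pattern, 1400 s acquisition).
#'
#' @param rest_pre  rest before stimulation onset, seconds.
#' @param stim      stimulation duration, seconds.
#' @param rest_post rest after stimulation, seconds.
#' @param n_patterns number of pattern repetitions.
#' @return An object of class `stim_protocol` with fields `rest_pre`, `stim`,
#'   `rest_post`, `n_patterns`, `pattern_t` (= rest_pre + stim + rest_post)
#'   and `acq_t` (= n_patterns * pattern_t), all in seconds.
#' @examples
#' p <- stim_protocol()
#' p$pattern_t  # 70
#' p$acq_t      # 1400
#' @export
stim_protocol <- function(rest_pre = 30, stim = 30, rest_post = 10,
                          n_patterns = 20) {
  stopifnot(rest_pre > 0, stim > 0, rest_post > 0, n_patterns >= 1)
  structure(list(rest_pre = rest_pre, stim = stim, rest_post = rest_post,
                 n_patterns = as.integer(n_patterns),
                 pattern_t = rest_pre + stim + rest_post,
                 acq_t = n_patterns * (rest_pre + stim + rest_post)),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("stim_protocol: %g s rest | %g s stim | %g s rest, x%d (acq %g s)\n",
              x$rest_pre, x$stim, x$rest_post, x$n_patterns, x$acq_t))
  invisible(x)
}

#' Stimulation boxcar A(t)
#'
#' The binary stimulation pattern: 0 at rest, 1 during stimulation, evaluated
#' at arbitrary times (periodic over the pattern). Integrates to
#' `stim * n_patterns` over the full acquisition.
#'
#' @param protocol a [stim_protocol()].
#' @param t times in seconds.
#' @return numeric vector of 0/1.
#' @export
stim_boxcar <- function(protocol, t) {
  phase <- t %% protocol$pattern_t
  as.numeric(phase >= protocol$rest_pre &
             phase < protocol$rest_pre + protocol$stim)
}

#' Trapezoid-smoothed hemodynamic waveform m(t)
#'
#' The boxcar A(t) smoothed into a trapezoid: linear rise over `ramp` seconds
#' from stimulation onset, plateau at 1, linear fall over `ramp` seconds after
#' stimulation offset (extending into the post-stimulus rest). This emulates
#' the plateau-like hemodynamic responses seen during sustained sensory
#' stimulation while keeping the waveform's integral equal to that of A(t)
#' (the half-ramp lost at onset is regained at offset), so closed-form arrival
#' expectations stay exact.
#'
#' @inheritParams stim_boxcar
#' @param ramp rise/fall time in seconds (default 2).
#' @return numeric vector in `[0, 1]`.
#' @export
hemo_waveform <- function(protocol, t, ramp = 2) {
  stopifnot(ramp >= 0, ramp <= protocol$stim, ramp <= protocol$rest_post)
  phase <- t %% protocol$pattern_t
  on <- protocol$rest_pre
  off <- protocol$rest_pre + protocol$stim
  m <- numeric(length(t))
  if (ramp == 0) return(stim_boxcar(protocol, t))
  up <- phase >= on & phase < on + ramp
  plateau <- phase >= on + ramp & phase < off
  down <- phase >= off & phase < off + ramp
  m[up] <- (phase[up] - on) / ramp
  m[plateau] <- 1
  m[down] <- 1 - (phase[down] - off) / ramp
  m
}

#' Hemodynamic modulation of activated segments
#'
#' Multiplicative peak factors applied to activated phantom segments during
#' stimulation: microbubble arrival rate (`flux_gain`), advection speed
#' (`speed_gain`) and lumen diameter (`diameter_gain`), each following the
#' trapezoid waveform [hemo_waveform()]. Gains of 1 produce no activation.
#'
#' @param flux_gain,speed_gain,diameter_gain dimensionless peak factors, >= 1
#'   for hyperemia (1 = no modulation).
#' @param ramp trapezoid rise/fall in seconds.
#' @return An object of class `hemo_modulation`.
#' @export
hemo_modulation <- function(flux_gain = 1.5, speed_gain = 1.2,
                            diameter_gain = 1.2, ramp = 2) {
  stopifnot(flux_gain > 0, speed_gain > 0, diameter_gain > 0, ramp >= 0)
  structure(list(flux_gain = flux_gain, speed_gain = speed_gain,
                 diameter_gain = diameter_gain, ramp = ramp),
            class = "hemo_modulation")
}
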