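# Stage-conditioned synthetic EEG: band-limited oscillations with the
# stage-to-rhythm structure of the sleep literature over 1/f background
# noise. The generator exists so every pipeline stage is testable without
# polysomnography recordings; it emulates spectral structure, not
# clinical morphology.
#
# The difficulty profile is deliberately realistic in shape: W and N3
# carry unmistakable rhythms (alpha+beta, high-amplitude delta), while
# N1, N2 and R all share a low-voltage theta background and differ only
# through transient events (spindles and K-complexes in N2, sawtooth
# bursts in R) that are sparse and sometimes absent, so the N1/N2/R triad
# overlaps the way it does in real recordings.

#' Default synthesis parameters
#'
#' Per-stage recipes (amplitudes are relative to the unit-variance 1/f
#' background; every amplitude gets an independent log-normal per-epoch
#' jitter and every frequency a +/-5 percent jitter):
#' \itemize{
#'   \item W: continuous alpha 10 Hz (1.0) + beta 20 Hz (0.4)
#'   \item N1: low-voltage theta 6 Hz (0.6); with probability 1/2 a brief
#'     leftover alpha fragment (0.5, 1-2 s) from the wake transition
#'   \item N2: the same theta background (0.55) + a Poisson(2) number of
#'     13 Hz spindle bursts (1.2, 0.5-1 s) + Poisson(1) K-complex-like
#'     1 Hz transients (2.2); epochs that happen to draw no events are
#'     nearly indistinguishable from N1, as in real recordings
#'   \item N3: high-amplitude delta 1 Hz (2.2)
#'   \item R: theta background (0.6) + faint continuous alpha (0.2) +
#'     2-4 sawtooth-shaped 4 Hz bursts (0.8, 1-2 s)
#' }
#' `separation` scales every oscillation amplitude jointly: larger values
#' make the stages easier to tell apart, smaller values harder. The
#' default (1.25) puts the five stages in an easy regime where the full
#' pipeline recovers stages with high accuracy, which is what the
#' end-to-end tests are meant to verify; `separation = 1` gives a
#' difficulty profile closer to real single-channel staging, with N1 the
#' weakest stage.
#'
#' @param separation global oscillation-to-noise scale (default 1.25).
#' @param noise_sd standard deviation of the 1/f background (default 1).
#' @param noise_exponent spectral slope of the background (default 1,
#'   i.e. power ~ 1/f).
#' @param spindle_rate expected spindle bursts per N2 epoch (default 2).
#' @param amp_jitter_sd log-scale SD of the per-epoch amplitude jitter
#'   (default 0.3).
#' @param sampling_rate Hz (default 100).
#' @param epoch_s epoch length in seconds (default 30).
#' @return list of parameters (class `stage_synthesis_params`).
#' @export
stage_synthesis_params <- function(separation = 1.25, noise_sd = 1,
                                   noise_exponent = 1, spindle_rate = 2,
                                   amp_jitter_sd = 0.3,
                                   sampling_rate = 100, epoch_s = 30) {
  structure(list(
    separation = separation,
    noise_sd = noise_sd,
    noise_exponent = noise_exponent,
    spindle_rate = spindle_rate,
    amp_jitter_sd = amp_jitter_sd,
    sampling_rate = sampling_rate,
    epoch_s = epoch_s,
    tones = list(                       # continuous (freq Hz, amplitude)
      W  = list(c(10, 1.0), c(20, 0.4)),
      N1 = list(c(6, 0.6)),
      N2 = list(c(6, 0.55)),
      N3 = list(c(1, 2.2)),
      R  = list(c(6, 0.6), c(10, 0.2))
    )
  ), class = "stage_synthesis_params")
}

#' @keywords internal
#' 1/f^a background noise of length n, scaled to `noise_sd`.
.pink_noise <- function(n, exponent, noise_sd) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))             # guard DC
  f <- pmin(f, n - f + 1)               # mirror for negative frequencies
  X <- X * f^(-exponent / 2)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x) * noise_sd
}

#' @keywords internal
#' A jittered sinusoid with random phase and log-normal amplitude jitter.
.tone <- function(t, freq, amp, jitter_sd) {
  fj <- freq * stats::runif(1, 0.95, 1.05)
  aj <- amp * exp(stats::rnorm(1, 0, jitter_sd))
  aj * sin(2 * pi * fj * t + stats::runif(1, 0, 2 * pi))
}

#' @keywords internal
#' Add a Hann-windowed burst of `shape_fun(t)` at a random position.
.add_burst <- function(x, t, fs, dur_range, shape_fun) {
  len <- as.integer(stats::runif(1, dur_range[1], dur_range[2]) * fs)
  start <- sample.int(length(x) - len, 1L)
  seg <- start:(start + len - 1L)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))
  x[seg] <- x[seg] + win * shape_fun(t[seg])
  x
}

#' Synthesize one labeled EEG epoch
#'
#' Deterministic per `(stage, seed)`: the same pair always yields the
#' same samples.
#'
#' @param stage one of `sleep_stages()`.
#' @param params a [stage_synthesis_params()] list.
#' @param seed integer seed.
#' @return numeric vector of `epoch_s * sampling_rate` samples.
#' @export
synth_epoch <- function(stage, params = stage_synthesis_params(), seed = 1L) {
  stage <- as.character(stage)
  if (!stage %in% sleep_stages()) stop("invalid stage: ", stage)
  fs <- params$sampling_rate
  n <- as.integer(params$epoch_s * fs)
  t <- (seq_len(n) - 1L) / fs
  sep <- params$separation
  js <- params$amp_jitter_sd
  .with_seed(seed, {
    x <- .pink_noise(n, params$noise_exponent, params$noise_sd)
    for (tone in params$tones[[stage]])
      x <- x + sep * .tone(t, tone[1], tone[2], js)
    if (stage == "N1" && stats::runif(1) < 0.5) {
      # brief alpha fragment carried over from wakefulness
      ph <- stats::runif(1, 0, 2 * pi)
      x <- .add_burst(x, t, fs, c(1, 2), function(tt)
        sep * 0.5 * sin(2 * pi * 10 * tt + ph))
    }
    if (stage == "R") {
      # sawtooth-shaped 4 Hz bursts (linear ramp keeps the harmonics)
      for (b in seq_len(sample(2:4, 1L))) {
        ph <- stats::runif(1)
        amp <- 0.8 * exp(stats::rnorm(1, 0, js))
        x <- .add_burst(x, t, fs, c(1, 2), function(tt)
          sep * amp * (2 * ((4 * tt + ph) %% 1) - 1))
      }
    }
    if (stage == "N2") {
      # amplitude-modulated 13 Hz spindle bursts; may be absent entirely
      for (b in seq_len(stats::rpois(1, params$spindle_rate))) {
        ph <- stats::runif(1, 0, 2 * pi)
        amp <- 1.2 * exp(stats::rnorm(1, 0, js))
        x <- .add_burst(x, t, fs, c(0.5, 1), function(tt)
          sep * amp * sin(2 * pi * 13 * tt + ph))
      }
      # K-complex-like slow transients (single downward 1 Hz cycles)
      for (b in seq_len(stats::rpois(1, 1))) {
        amp <- 2.2 * exp(stats::rnorm(1, 0, js))
        x <- .add_burst(x, t, fs, c(0.9, 1.1), function(tt)
          -sep * amp * sin(2 * pi * (tt - tt[1])))
      }
    }
    x
  })
}

#' @keywords internal
#' Default per-stage proportions of a whole-night recording.
.default_stage_proportions <- c(W = 0.2697, N1 = 0.0710, N2 = 0.3947,
                                N3 = 0.1103, R = 0.1543)

#' Synthesize a labeled dataset
#'
#' Generates `counts[stage]` epochs per stage (or distributes `n` epochs
#' by realistic whole-night stage proportions: W 26.97%, N1 7.10%,
#' N2 39.47%, N3 11.03%, R 15.43%), shuffles them reproducibly, and
#' optionally writes the concatenated signal to an EDF file plus a label
#' CSV so the signal-reading path can be exercised end to end.
#'
#' @param counts named integer vector over `sleep_stages()`; overrides `n`.
#' @param n total epoch count used with the default proportions.
#' @param params a [stage_synthesis_params()] list.
#' @param seed integer master seed; per-epoch seeds derive from it.
#' @param shuffle shuffle epoch order (default TRUE).
#' @param out_edf optional path: write the signal as a one-channel EDF.
#' @param out_labels optional path: write the label CSV.
#' @return a `sleep_dataset` (see [segment_epochs()]).
#' @export
synth_dataset <- function(counts = NULL, n = 200L,
                          params = stage_synthesis_params(), seed = 1L,
                          shuffle = TRUE, out_edf = NULL, out_labels = NULL) {
  if (is.null(counts)) {
    counts <- round(.default_stage_proportions * n)
  } else {
    if (is.null(names(counts)) || !all(names(counts) %in% sleep_stages()))
      stop("counts must be named with the five stages")
    full <- stats::setNames(integer(5), sleep_stages())
    full[names(counts)] <- as.integer(counts)
    counts <- full
  }
  if (sum(counts) == 0L) stop("all stage counts are zero")
  stages <- rep(sleep_stages(), times = counts[sleep_stages()])
  n_ep <- length(stages)
  ord <- if (shuffle) .with_seed(seed, sample(n_ep)) else seq_len(n_ep)
  stages <- stages[ord]
  spe <- as.integer(params$epoch_s * params$sampling_rate)
  epochs <- matrix(NA_real_, n_ep, spe)
  for (i in seq_len(n_ep)) {
    ep_seed <- (seed + 7919L * i) %% 2147483647L
    epochs[i, ] <- synth_epoch(stages[i], params, seed = ep_seed)
  }
  ds <- structure(list(
    epochs = epochs,
    stage = factor(stages, levels = sleep_stages()),
    index = seq_len(n_ep),
    start_s = (seq_len(n_ep) - 1) * params$epoch_s,
    sampling_rate = params$sampling_rate
  ), class = "sleep_dataset")
  if (!is.null(out_edf)) {
    amp <- max(abs(ds$epochs)) * 1.05
    write_edf_signal(out_edf,
                     list(list(samples = as.numeric(t(ds$epochs)),
                               sampling_rate = params$sampling_rate,
                               label = "EEG Fpz-Cz")),
                     physical_min = -amp, physical_max = amp)
  }
  if (!is.null(out_labels)) write_dataset_csv(ds, out_labels)
  ds
}
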