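# The 51-feature per-epoch feature system: time-domain, energy,
# frequency-domain and nonlinear-dynamics features.

.band_order <- c("alpha", "beta", "theta", "delta", "spindle", "sawtooth")

.aux_feature_names <- c(
  "mean", "median", "variance", "mav", "rms", "ptp", "skewness", "kurtosis",
  "zero_crossings", "hjorth_activity", "hjorth_mobility", "hjorth_complexity",
  "line_length", "iqr", "p75", "min", "max")

#' Canonical feature names
#'
#' The fixed, ordered names of the 51 per-epoch features: 6 per-wave
#' standard deviations, 17 auxiliary time-domain features, 6 per-wave
#' energies plus 2 energy ratios, 6 per-wave powers plus the mean frequency
#' and 2 power ratios, 6 per-wave Renyi entropies, and 5 nonlinear features
#' (Lempel-Ziv complexity, multi-scale entropy, spectral entropy, sample
#' entropy, fuzzy entropy).
#'
#' @return character vector of length 51.
#' @export
feature_names <- function() {
  c(paste0("std_", .band_order),
    .aux_feature_names,
    paste0("energy_", .band_order),
    "energy_ratio_alpha_theta", "energy_ratio_delta_theta",
    paste0("power_", .band_order),
    "mnf", "power_ratio_alpha_theta", "power_ratio_delta_theta",
    paste0("renyi_", .band_order),
    "lzc", "msen", "spectral_entropy", "sampen", "fuzzyen")
}

#' Per-wave standard deviation features
#'
#' One value per characteristic wave. By convention of the feature system
#' this is the *unnormalised* root sum of squared deviations from the mean,
#' \eqn{\sqrt{\sum_i (w_i - \bar w)^2}} (no 1/n factor); set
#' `conventional = TRUE` for the usual sample standard deviation.
#'
#' @param waves named list of six waves from [extract_characteristic_waves()].
#' @param conventional divide the sum of squares by n - 1 before the root.
#' @return named numeric vector of six values.
#' @export
std_features <- function(waves, conventional = FALSE) {
  vapply(waves[.band_order], function(w) {
    if (length(w) == 0L) stop("empty wave")
    ss <- sum((w - mean(w))^2)
    if (conventional) sqrt(ss / (length(w) - 1)) else sqrt(ss)
  }, numeric(1)) |> stats::setNames(paste0("std_", .band_order))
}

#' Per-wave energies and the alpha/theta, delta/theta energy ratios
#'
#' Energy is the plain sum of squared samples of each reconstructed wave.
#' The two ratios target the N1/R/N2 confusion: N1 is theta dominated while
#' R and N2 lean on alpha and delta content respectively.
#'
#' @param waves named list of six waves.
#' @return named numeric vector of 8 values (6 energies + 2 ratios).
#' @export
energy_features <- function(waves) {
  e <- vapply(waves[.band_order], function(w) sum(w^2), numeric(1))
  names(e) <- paste0("energy_", .band_order)
  if (e[["energy_theta"]] <= 0)
    stop("degenerate epoch: zero theta-band energy, ratios undefined")
  c(e,
    energy_ratio_alpha_theta = unname(e[["energy_alpha"]] / e[["energy_theta"]]),
    energy_ratio_delta_theta = unname(e[["energy_delta"]] / e[["energy_theta"]]))
}

#' One-sided periodogram power spectral density
#'
#' Rectangular-window periodogram satisfying the Parseval identity
#' `sum(power) * df == mean(x^2)` with `df = sampling_rate / n`.
#'
#' @param x numeric samples.
#' @param sampling_rate Hz.
#' @return list with `frequency` (Hz) and `power` (amplitude^2 / Hz),
#'   covering 0..Nyquist.
#' @export
power_spectrum <- function(x, sampling_rate) {
  n <- length(x)
  if (n < 2L) stop("need at least two samples")
  X <- stats::fft(x)
  half <- n %/% 2L
  k <- 0:half
  p <- Mod(X[k + 1L])^2 / (n * sampling_rate)
  scale <- rep(2, half + 1L)
  scale[1L] <- 1
  if (n %% 2L == 0L) scale[half + 1L] <- 1
  list(frequency = k * sampling_rate / n, power = p * scale)
}

#' Per-wave band powers, mean frequency and power ratios
#'
#' Band power is the sum of the periodogram of each reconstructed wave;
#' the mean frequency (MNF) is the spectral centroid of the full denoised
#' epoch, `sum(p*f)/sum(p)`.
#'
#' @param waves named list of six waves.
#' @param epoch the denoised full-band epoch the waves came from.
#' @param sampling_rate Hz.
#' @return named numeric vector of 9 values (6 powers, mnf, 2 ratios).
#' @export
frequency_features <- function(waves, epoch, sampling_rate) {
  p <- vapply(waves[.band_order],
              function(w) sum(power_spectrum(w, sampling_rate)$power),
              numeric(1))
  names(p) <- paste0("power_", .band_order)
  sp <- power_spectrum(epoch, sampling_rate)
  tot <- sum(sp$power)
  if (tot <= 0) stop("zero total power: mean frequency undefined")
  if (p[["power_theta"]] <= 0)
    stop("degenerate epoch: zero theta-band power, ratios undefined")
  c(p,
    mnf = sum(sp$power * sp$frequency) / tot,
    power_ratio_alpha_theta = unname(p[["power_alpha"]] / p[["power_theta"]]),
    power_ratio_delta_theta = unname(p[["power_delta"]] / p[["power_theta"]]))
}

#' Order-2 Renyi entropy of a power spectrum
#'
#' `-log(sum(p^2))` in nats, with the spectrum normalised to a probability
#' distribution. Invariant to rescaling the spectrum.
#'
#' @param spectrum list with a `power` component (e.g. [power_spectrum()]).
#' @return scalar entropy in nats.
#' @export
renyi_entropy <- function(spectrum) {
  p <- spectrum$power
  s <- sum(p)
  if (s <= 0) stop("all-zero spectrum")
  p <- p / s
  -log(sum(p^2))
}

#' Shannon spectral entropy
#'
#' `-sum(p*log(p))` in nats of the normalised power spectrum; zero bins
#' contribute nothing.
#'
#' @inheritParams renyi_entropy
#' @return scalar entropy in nats.
#' @export
spectral_entropy <- function(spectrum) {
  p <- spectrum$power
  s <- sum(p)
  if (s <= 0) stop("all-zero spectrum")
  p <- p / s
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Binarize a series at its median
#'
#' `0` below the median, `1` at or above it (the symbolisation step ahead
#' of Lempel-Ziv parsing).
#'
#' @param x numeric vector.
#' @return integer vector of 0/1, same length.
#' @export
binarize_median <- function(x) {
  if (length(x) == 0L) stop("empty input")
  as.integer(x >= stats::median(x))
}

#' Lempel-Ziv complexity of a binary sequence
#'
#' Exhaustive-history (LZ76) phrase count `c(n)` of a 0/1 sequence,
#' normalised by default to `c(n) * log2(n) / n` so the value is comparable
#' across sequence lengths (a random sequence tends to 1).
#'
#' @param z integer/logical vector over `{0, 1}`, length >= 2.
#' @param normalize return `c(n) * log2(n) / n` (default) or the raw count.
#' @return scalar complexity.
#' @export
lzc <- function(z, normalize = TRUE) {
  z <- as.integer(z)
  if (length(z) < 2L) stop("sequence too short")
  if (!all(z %in% c(0L, 1L))) stop("sequence must be binary (0/1)")
  cnt <- .lz76_count_cpp(z)
  if (normalize) cnt * log2(length(z)) / length(z) else as.numeric(cnt)
}

#' Coarse-grain a series at scale factor tau
#'
#' Non-overlapping block means of length `tau`; a trailing partial block is
#' dropped, so the output has `floor(n / tau)` samples.
#'
#' @param x numeric vector.
#' @param tau integer scale factor >= 1.
#' @return numeric vector of block means.
#' @export
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  if (tau < 1L) stop("tau must be >= 1")
  n <- length(x)
  if (n < tau) stop("series shorter than tau")
  if (tau == 1L) return(x)
  J <- n %/% tau
  colMeans(matrix(x[seq_len(J * tau)], nrow = tau))
}

#' Sample entropy
#'
#' Richman-Moorman sample entropy `-ln(A/B)`: A and B are the numbers of
#' template pairs of length `m + 1` and `m` within Chebyshev distance `< r`
#' (self-matches excluded).
#'
#' @param x numeric series, length > m + 1.
#' @param m template length (default 2).
#' @param r tolerance; default `0.2 * sd(x)`.
#' @return scalar entropy in nats; errors if no template pair matches
#'   (entropy undefined).
#' @export
sample_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x)) {
  if (length(x) <= m + 1L) stop("series too short for template length m")
  if (!is.finite(r) || r <= 0) stop("tolerance r must be positive (constant series?)")
  ab <- .sampen_counts_cpp(as.numeric(x), as.integer(m), r)
  if (ab[2] == 0) stop("sample entropy undefined: no m-template matches")
  if (ab[1] == 0) stop("sample entropy undefined: no (m+1)-template matches")
  -log(ab[1] / ab[2])
}

#' Multi-scale entropy
#'
#' Sample entropy of the coarse-grained series at scale `tau` (default 11),
#' with the tolerance taken from the *original* series (`r = 0.2 * sd(x)`)
#' as is conventional for multi-scale entropy. `literal_sum = TRUE`
#' multiplies by the number of coarse-grained points, i.e. treats the
#' per-point sum over the coarse series literally; at fixed `tau` this is a
#' constant multiple of the default.
#'
#' @inheritParams sample_entropy
#' @param tau scale factor (default 11).
#' @param literal_sum see Details.
#' @return scalar entropy in nats.
#' @export
multiscale_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x), tau = 11L,
                               literal_sum = FALSE) {
  g <- coarse_grain(x, tau)
  se <- sample_entropy(g, m = m, r = r)
  if (literal_sum) se * length(g) else se
}

#' Fuzzy entropy
#'
#' `-ln(phi_{m+1}/phi_m)` where `phi` averages the fuzzy membership
#' `exp(-(d/r)^gradient)` of all template pairs; templates are
#' mean-subtracted before the Chebyshev distance `d` is taken, so the
#' measure ignores local baseline shifts.
#'
#' @inheritParams sample_entropy
#' @param gradient exponent of the membership function (default 2).
#' @return scalar entropy in nats.
#' @export
fuzzy_entropy <- function(x, m = 2L, r = 0.2 * stats::sd(x), gradient = 2) {
  if (length(x) <= m + 1L) stop("series too short for template length m")
  if (!is.finite(r) || r <= 0) stop("tolerance r must be positive (constant series?)")
  phi <- .fuzzyen_sums_cpp(as.numeric(x), as.integer(m), r, gradient)
  -log(phi[1] / phi[2])
}

#' Auxiliary time-domain features
#'
#' The 17 standard time-domain descriptors of the denoised epoch: mean,
#' median, variance, mean absolute value, RMS, peak-to-peak, skewness,
#' kurtosis, zero-crossing count, the three Hjorth parameters, line length,
#' interquartile range, 75th percentile, minimum, maximum. Moments are
#' population moments; Hjorth mobility uses the first difference scaled by
#' the sampling rate, so for a slow sinusoid of frequency f it approaches
#' the angular frequency 2*pi*f.
#'
#' @param x numeric epoch samples.
#' @param sampling_rate Hz (used by the Hjorth mobility scaling).
#' @return named numeric vector of 17 values.
#' @export
auxiliary_time_features <- function(x, sampling_rate) {
  if (length(x) < 3L) stop("epoch too short")
  n <- length(x)
  mu <- mean(x)
  cx <- x - mu
  m2 <- mean(cx^2)
  d1 <- diff(x) * sampling_rate
  d2 <- diff(d1) * sampling_rate
  v0 <- m2
  v1 <- mean((d1 - mean(d1))^2)
  v2 <- mean((d2 - mean(d2))^2)
  mobility <- if (v0 > 0) sqrt(v1 / v0) else 0
  complexity <- if (v1 > 0 && mobility > 0) sqrt(v2 / v1) / mobility else 0
  s <- sign(x[x != 0])
  zc <- if (length(s) > 1L) sum(s[-1L] != s[-length(s)]) else 0L
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  c(mean = mu,
    median = stats::median(x),
    variance = m2,
    mav = mean(abs(x)),
    rms = sqrt(mean(x^2)),
    ptp = max(x) - min(x),
    skewness = if (m2 > 0) mean(cx^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean(cx^4) / m2^2 else 0,
    zero_crossings = as.numeric(zc),
    hjorth_activity = v0,
    hjorth_mobility = mobility,
    hjorth_complexity = complexity,
    line_length = sum(abs(diff(x))),
    iqr = q[2] - q[1],
    p75 = q[2],
    min = min(x),
    max = max(x))
}

#' Assemble the 51-feature vector of one epoch
#'
#' Computes every feature group on the denoised epoch and its six
#' characteristic waves, in the canonical order of [feature_names()].
#' Nonlinear features (LZC and the entropies) are computed on the
#' full-band denoised epoch; Renyi entropy per wave.
#'
#' @param epoch denoised epoch samples.
#' @param sampling_rate Hz.
#' @param waves optional precomputed list from
#'   [extract_characteristic_waves()]; computed from `epoch` if missing.
#' @param msen_tau scale factor for multi-scale entropy (default 11).
#' @return named numeric vector of 51 features.
#' @export
extract_feature_vector <- function(epoch, sampling_rate, waves = NULL,
                                   msen_tau = 11L) {
  if (is.null(waves))
    waves <- extract_characteristic_waves(epoch, sampling_rate)
  sp_epoch <- power_spectrum(epoch, sampling_rate)
  r <- 0.2 * stats::sd(epoch)
  out <- c(
    std_features(waves),
    auxiliary_time_features(epoch, sampling_rate),
    energy_features(waves),
    frequency_features(waves, epoch, sampling_rate),
    vapply(waves[.band_order],
           function(w) renyi_entropy(power_spectrum(w, sampling_rate)),
           numeric(1)) |> stats::setNames(paste0("renyi_", .band_order)),
    lzc = lzc(binarize_median(epoch)),
    msen = multiscale_entropy(epoch, m = 2L, r = r, tau = msen_tau),
    spectral_entropy = spectral_entropy(sp_epoch),
    sampen = sample_entropy(epoch, m = 2L, r = r),
    fuzzyen = fuzzy_entropy(epoch, m = 2L, r = r))
  out <- out[feature_names()]
  stopifnot(length(out) == 51L, !anyNA(out))
  out
}

#' Feature table of a labeled dataset
#'
#' Denoises every epoch (optional), extracts the 51 features, and returns a
#' data.frame with one row per epoch plus a `stage` factor column.
#'
#' @param dataset a labeled dataset from [segment_epochs()] or
#'   [synth_dataset()].
#' @param denoise apply [wtd_denoise()] per epoch first (default TRUE).
#' @param verbose print a progress line every 100 epochs.
#' @return data.frame of 51 feature columns plus `stage`.
#' @export
extract_feature_table <- function(dataset, denoise = TRUE, verbose = FALSE) {
  n <- nrow(dataset$epochs)
  fs <- dataset$sampling_rate
  feats <- matrix(NA_real_, n, 51L, dimnames = list(NULL, feature_names()))
  for (i in seq_len(n)) {
    x <- dataset$epochs[i, ]
    if (denoise) x <- wtd_denoise(x)
    feats[i, ] <- tryCatch(
      extract_feature_vector(x, fs),
      error = function(e)
        stop(sprintf("feature extraction failed at epoch %d (stage %s): %s",
                     i, as.character(dataset$stage[i]), conditionMessage(e))))
    if (verbose && i %% 100L == 0L)
      message(sprintf("  features: %d / %d epochs", i, n))
  }
  out <- as.data.frame(feats)
  out$stage <- dataset$stage
  out
}
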