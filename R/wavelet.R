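# Periodized orthogonal wavelet machinery (db8) used by both the
# threshold denoiser and the wavelet packet band extractor.

# Daubechies extremal-phase order-8 scaling (synthesis lowpass) filter.
# 16 taps, sum = sqrt(2). Standard published constants.
.db8_h <- c(
   0.054415842243104008,   0.31287159091429995,   0.67563073629728976,
   0.58535468365420673,   -0.015829105256349306, -0.28401554296154691,
   0.00047248457391328279, 0.12874742662047847,  -0.017369301001807547,
  -0.044088253930794755,   0.013981027917398282,  0.0087460940474057766,
  -0.0048703529934515741, -0.00039174037337694705, 0.00067544940645056933,
  -0.00011747678412476953)

# quadrature mirror highpass: g[m] = (-1)^m h[L-1-m]
.db8_g <- rev(.db8_h) * (-1)^(seq_along(.db8_h) - 1)

#' @keywords internal
#' One analysis step of the periodized filter bank.
#' Returns list(a = lowpass, d = highpass), each of length n/2 (n even).
.wave_analysis_step <- function(x) {
  n <- length(x)
  if (n %% 2L != 0L) stop("periodized analysis requires even length")
  n2 <- n %/% 2L
  a <- numeric(n2)
  d <- numeric(n2)
  base <- 2L * (0:(n2 - 1L))
  for (m in seq_along(.db8_h)) {
    idx <- (base + (m - 1L)) %% n + 1L
    xm <- x[idx]
    a <- a + .db8_h[m] * xm
    d <- d + .db8_g[m] * xm
  }
  list(a = a, d = d)
}

#' @keywords internal
#' One synthesis step; inverse of `.wave_analysis_step`.
.wave_synthesis_step <- function(a, d) {
  n2 <- length(a)
  n <- 2L * n2
  x <- numeric(n)
  base <- 2L * (0:(n2 - 1L))
  for (m in seq_along(.db8_h)) {
    idx <- (base + (m - 1L)) %% n + 1L
    x[idx] <- x[idx] + .db8_h[m] * a + .db8_g[m] * d
  }
  x
}

#' @keywords internal
#' Symmetric (half-point) right padding to length `target`.
.pad_reflect <- function(x, target) {
  n <- length(x)
  if (n == target) return(x)
  pad <- target - n
  if (pad > n) stop("cannot reflect-pad beyond doubling the signal")
  c(x, rev(x)[seq_len(pad)])
}

#' @keywords internal
#' Smallest multiple of 2^levels that is >= n.
.pad_length <- function(n, levels) {
  block <- 2L^levels
  as.integer(ceiling(n / block) * block)
}

#' @keywords internal
#' Hybrid SURE soft-threshold choice for one detail level.
#' If the level looks sparse/noise-like, return the universal threshold;
#' otherwise the threshold minimising Stein's unbiased risk estimate,
#' capped at the universal threshold.
.sure_soft_threshold <- function(d, sigma, lambda_univ) {
  if (sigma <= 0) return(0)
  nl <- length(d)
  z2 <- sort((d / sigma)^2)
  # sparsity guard (heuristic SURE): noise-like levels keep the universal rule
  eta <- (sum(z2) - nl) / nl
  crit <- (log2(nl))^1.5 / sqrt(nl)
  if (eta < crit) return(lambda_univ)
  cs <- cumsum(z2)
  k <- seq_len(nl)
  risk <- (nl - 2 * k + cs + (nl - k) * z2)
  lambda_sure <- sigma * sqrt(z2[which.min(risk)])
  min(lambda_sure, lambda_univ)
}

#' Wavelet threshold denoising of an EEG epoch
#'
#' Decomposes the signal into `levels` layers with the db8 discrete wavelet
#' transform, applies soft-threshold shrinkage to the detail coefficients of
#' every level, and reconstructs. The noise scale \eqn{\sigma} is estimated
#' from the finest detail level as median(|d1|)/0.6745 (that level is noise
#' dominated for band-limited signals, so the estimate is not inflated by
#' oscillatory content at coarser levels).
#'
#' The default rule `"sure"` picks the soft threshold per level by the
#' hybrid SURE criterion: levels whose coefficients look like pure noise
#' get the universal threshold \eqn{\sigma\sqrt{2\log N}}, levels dense
#' with signal get the threshold minimising Stein's unbiased risk estimate
#' (typically much smaller, so oscillatory content is not biased away).
#' `"universal"` applies \eqn{\sigma\sqrt{2\log N}} to every level;
#' `"universal_by_level"` additionally re-estimates \eqn{\sigma} per level
#' (aggressive: levels that carry signal shrink themselves).
#' Approximation coefficients are untouched under every rule.
#'
#' Signals whose length is not a multiple of `2^levels` are extended by
#' symmetric reflection before the transform and truncated afterwards, so
#' the output always has the input length.
#'
#' @param x numeric vector of samples; length at least `2^levels`.
#' @param levels integer, decomposition depth (default 7).
#' @param threshold_rule `"sure"` (default), `"universal"`,
#'   `"universal_by_level"`, or `"none"` (reconstruct without shrinkage;
#'   useful for testing the transform round trip).
#' @return numeric vector of denoised samples, same length as `x`.
#' @export
wtd_denoise <- function(x, levels = 7L,
                        threshold_rule = c("sure", "universal",
                                           "universal_by_level", "none")) {
  threshold_rule <- match.arg(threshold_rule)
  if (!is.numeric(x) || length(x) < 2L^levels)
    stop("input must be numeric with at least 2^levels samples")
  if (any(!is.finite(x))) stop("input contains non-finite samples")
  n <- length(x)
  xp <- .pad_reflect(x, .pad_length(n, levels))
  details <- vector("list", levels)
  a <- xp
  for (l in seq_len(levels)) {
    s <- .wave_analysis_step(a)
    a <- s$a
    details[[l]] <- s$d
  }
  if (threshold_rule != "none") {
    sigma_global <- stats::median(abs(details[[1]])) / 0.6745
    for (l in seq_len(levels)) {
      d <- details[[l]]
      sigma <- if (threshold_rule == "universal_by_level")
                 stats::median(abs(d)) / 0.6745 else sigma_global
      lambda_univ <- sigma * sqrt(2 * log(n))
      lambda <- if (threshold_rule == "sure")
                  .sure_soft_threshold(d, sigma, lambda_univ)
                else lambda_univ
      details[[l]] <- sign(d) * pmax(abs(d) - lambda, 0)
    }
  }
  for (l in rev(seq_len(levels)))
    a <- .wave_synthesis_step(a, details[[l]])
  a[seq_len(n)]
}

# ---- wavelet packet transform -------------------------------------------

#' @keywords internal
#' Frequency position (0-based) of each natural-order terminal node.
#' Element p+1 gives the frequency slot of the leaf whose path bits form
#' the natural index p (Gray-code / sequency reordering: descending through
#' a highpass branch reverses the frequency order of its children).
.wpt_freq_order <- function(levels) {
  f <- 0L
  for (l in seq_len(levels)) {
    # children of slot f: natural bit b maps to 2f+b if f even, 2f+(1-b) if odd
    even <- f %% 2L == 0L
    left  <- ifelse(even, 2L * f,      2L * f + 1L)
    right <- ifelse(even, 2L * f + 1L, 2L * f)
    f <- as.integer(rbind(left, right))  # interleave: natural order b=0 then b=1
  }
  f
}

#' Wavelet packet decomposition of a signal
#'
#' Full binary db8 filter-bank decomposition to `levels` layers with
#' periodized convolutions (the signal is reflect-padded to a multiple of
#' `2^levels` first). The terminal coefficient blocks are stored in natural
#' tree order together with the Gray-code permutation that maps them to
#' frequency order.
#'
#' @param x numeric samples.
#' @param sampling_rate sampling rate in Hz.
#' @param levels decomposition depth (default 7, giving 128 bands of width
#'   `sampling_rate / 256`, i.e. 0.390625 Hz at 100 Hz).
#' @return an object of class `wpt_tree`.
#' @export
wpt_decompose <- function(x, sampling_rate, levels = 7L) {
  if (!is.numeric(x) || length(x) < 2L^levels)
    stop("input must be numeric with at least 2^levels samples")
  n <- length(x)
  xp <- .pad_reflect(x, .pad_length(n, levels))
  nodes <- list(xp)
  for (l in seq_len(levels)) {
    nxt <- vector("list", 2L * length(nodes))
    for (j in seq_along(nodes)) {
      s <- .wave_analysis_step(nodes[[j]])
      nxt[[2L * j - 1L]] <- s$a
      nxt[[2L * j]] <- s$d
    }
    nodes <- nxt
  }
  structure(list(
    leaves = nodes,              # natural order
    freq_of_natural = .wpt_freq_order(levels),
    levels = as.integer(levels),
    n = n,
    n_padded = length(xp),
    sampling_rate = sampling_rate,
    wavelet = "db8",
    mode = "periodized-reflect"
  ), class = "wpt_tree")
}

#' @export
print.wpt_tree <- function(x, ...) {
  cat(sprintf(
    "wavelet packet tree: %d levels, %d terminal nodes (%s, %s)\n",
    x$levels, length(x$leaves), x$wavelet, x$mode))
  cat(sprintf("  signal: %d samples at %g Hz; band width %.6f Hz\n",
              x$n, x$sampling_rate, x$sampling_rate / 2^(x$levels + 1)))
  invisible(x)
}

#' Frequency interval of a frequency-ordered wavelet packet node
#'
#' After sequency reordering, node `j` (1-based) of `level` covers the
#' half-open interval `[(j-1) * w, j * w)` with `w = Nyquist / 2^level`.
#'
#' @param level decomposition level (>= 1).
#' @param node_index 1-based frequency-ordered node index, in `1..2^level`.
#' @param sampling_rate Hz.
#' @return numeric vector `c(low, high)` in Hz.
#' @export
node_frequency_band <- function(level, node_index, sampling_rate) {
  if (node_index < 1 || node_index > 2^level)
    stop(sprintf("node_index must lie in 1..%d at level %d", 2^level, level))
  w <- sampling_rate / 2^(level + 1)
  c(low = (node_index - 1) * w, high = node_index * w)
}

#' Reconstruct the component of a signal inside one frequency band
#'
#' Keeps every terminal node whose frequency-ordered interval overlaps
#' `(low, high)` with positive measure (intervals are half-open `[lo, hi)`),
#' zeroes all other nodes, and inverts the packet transform. Summing the
#' reconstructions over a tiling of `[0, Nyquist)` recovers the input.
#'
#' @param tree a `wpt_tree` from [wpt_decompose()].
#' @param band numeric `c(low, high)` in Hz, within `[0, Nyquist]`.
#' @return numeric vector, same length as the decomposed signal.
#' @export
reconstruct_band <- function(tree, band) {
  stopifnot(inherits(tree, "wpt_tree"))
  low <- band[[1]]; high <- band[[2]]
  nyq <- tree$sampling_rate / 2
  if (!(low >= 0 && low < high && high <= nyq))
    stop("band must satisfy 0 <= low < high <= Nyquist")
  w <- nyq / 2^tree$levels
  nleaf <- length(tree$leaves)
  freq <- tree$freq_of_natural            # 0-based frequency slot per leaf
  lo_edge <- freq * w
  hi_edge <- (freq + 1) * w
  keep <- hi_edge > low & lo_edge < high  # positive-measure overlap
  nodes <- vector("list", nleaf)
  zero <- numeric(length(tree$leaves[[1]]))
  for (j in seq_len(nleaf))
    nodes[[j]] <- if (keep[j]) tree$leaves[[j]] else zero
  for (l in seq_len(tree$levels)) {
    half <- length(nodes) %/% 2L
    nxt <- vector("list", half)
    for (j in seq_len(half))
      nxt[[j]] <- .wave_synthesis_step(nodes[[2L * j - 1L]], nodes[[2L * j]])
    nodes <- nxt
  }
  nodes[[1]][seq_len(tree$n)]
}

#' Canonical characteristic-wave band table
#'
#' The six EEG rhythms used throughout the feature system, with their
#' conventional frequency limits in Hz: alpha 8-13, beta 12-30, theta 4-8,
#' delta 0.5-2, spindle 12-14, sawtooth 2-6. The 1 Hz K-complex band lies
#' inside delta and is not reconstructed separately.
#'
#' @return data.frame with columns `band`, `low`, `high`.
#' @export
characteristic_bands <- function() {
  data.frame(
    band = c("alpha", "beta", "theta", "delta", "spindle", "sawtooth"),
    low  = c(8,  12, 4, 0.5, 12, 2),
    high = c(13, 30, 8, 2,   14, 6),
    stringsAsFactors = FALSE
  )
}

#' Extract the six characteristic waves of one epoch
#'
#' Applies a single wavelet packet decomposition to the (already denoised)
#' epoch and reconstructs each characteristic band. Every returned wave has
#' the epoch's length.
#'
#' @param x numeric epoch samples.
#' @param sampling_rate Hz.
#' @param bands band table as from [characteristic_bands()]; rows may be
#'   overridden to change the band limits.
#' @param levels wavelet packet depth (default 7).
#' @return named list of numeric vectors, one per band.
#' @export
extract_characteristic_waves <- function(x, sampling_rate,
                                         bands = characteristic_bands(),
                                         levels = 7L) {
  tree <- wpt_decompose(x, sampling_rate, levels)
  out <- vector("list", nrow(bands))
  names(out) <- bands$band
  for (i in seq_len(nrow(bands)))
    out[[i]] <- reconstruct_band(tree, c(bands$low[i], bands$high[i]))
  out
}
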