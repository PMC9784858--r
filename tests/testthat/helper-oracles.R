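# Independent brute-force oracles used to cross-check the package
# implementations on small inputs. Deliberately naive: readability over
# speed, and no shared code with the implementations under test.

# Exhaustive-history Lempel-Ziv phrase count via substring search.
lz76_oracle <- function(z) {
  n <- length(z)
  txt <- paste(z, collapse = "")
  c <- 0L
  pos <- 1L
  while (pos <= n) {
    k <- 1L
    repeat {
      if (pos + k - 1L > n) break
      cand <- substr(txt, pos, pos + k - 1L)
      prior <- substr(txt, 1L, pos + k - 2L)
      if (!grepl(cand, prior, fixed = TRUE)) break
      k <- k + 1L
    }
    if (pos + k - 1L > n) k <- n - pos + 1L
    c <- c + 1L
    pos <- pos + k
  }
  c
}

# Template-match counts (A, B) for sample entropy by double loop.
sampen_counts_oracle <- function(x, m, r) {
  nt <- length(x) - m
  A <- 0L; B <- 0L
  for (i in 1:(nt - 1L)) {
    for (j in (i + 1L):nt) {
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) < r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) < r) A <- A + 1L
      }
    }
  }
  c(A = A, B = B)
}

sampen_oracle <- function(x, m, r) {
  ab <- sampen_counts_oracle(x, m, r)
  -log(ab[["A"]] / ab[["B"]])
}

# Fuzzy entropy by double loop with mean-subtracted templates.
fuzzyen_oracle <- function(x, m, r, gradient = 2) {
  phi <- function(mm) {
    nt <- length(x) - m            # same template count for both lengths
    tot <- 0
    for (i in 1:(nt - 1L)) {
      for (j in (i + 1L):nt) {
        ti <- x[i:(i + mm - 1L)]; ti <- ti - mean(ti)
        tj <- x[j:(j + mm - 1L)]; tj <- tj - mean(tj)
        d <- max(abs(ti - tj))
        tot <- tot + exp(-(d / r)^gradient)
      }
    }
    tot
  }
  -log(phi(m + 1L) / phi(m))
}

# Plug-in mutual information from an explicit joint count table.
mi_oracle <- function(joint) {
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  tot <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) tot <- tot + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    }
  }
  tot
}

# One-vs-one vote rule evaluated longhand for a single row.
ovo_vote_oracle <- function(model, row) {
  classes <- model$classes
  votes <- stats::setNames(integer(length(classes)), classes)
  margin <- stats::setNames(numeric(length(classes)), classes)
  for (m in seq_along(model$machines)) {
    pr <- model$pairs[[m]]
    bm <- model$machines[[m]]
    u <- sum(vapply(seq_len(nrow(bm$sv)),
                    function(i) bm$coefs[i] * sum(bm$sv[i, ] * row)^2,
                    numeric(1))) + bm$bias
    win <- if (u >= 0) pr[1L] else pr[2L]
    votes[win] <- votes[win] + 1L
    margin[win] <- margin[win] + abs(u)
  }
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) top <- top[which.max(margin[top])]
  top[1L]
}

# Band-energy fractions of a signal from the raw periodogram (FFT only,
# no wavelet code): fraction of spectral power inside [lo, hi).
fft_band_fraction <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1L) * fs / n
  half <- f <= fs / 2
  sum(X[half][f[half] >= lo & f[half] < hi]) / sum(X[half])
}

# A 30-s, 100 Hz test epoch: tone mixture plus a little noise.
make_epoch <- function(freqs, amps, noise_sd = 0.1, seed = 1, fs = 100,
                       dur = 30) {
  set.seed(seed)
  t <- (seq_len(fs * dur) - 1L) / fs
  x <- stats::rnorm(length(t), 0, noise_sd)
  for (i in seq_along(freqs)) x <- x + amps[i] * sin(2 * pi * freqs[i] * t)
  x
}
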