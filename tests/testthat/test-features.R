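# The 51-feature system: simple closed-form cases plus brute-force
# oracle agreement for the nonlinear features.

test_that("std and energy features follow their printed definitions", {
  waves <- list(alpha = c(1, -1), beta = c(0, 0), theta = c(2, 2),
                delta = c(1, 0, 0), spindle = c(5, 5), sawtooth = 1:3)
  stds <- std_features(waves)
  expect_equal(unname(stds[["std_alpha"]]), sqrt(2))   # no 1/n factor
  expect_equal(unname(stds[["std_beta"]]), 0)
  expect_equal(unname(stds[["std_spindle"]]), 0)
  # homogeneity: scaling a wave scales its Std by |c|
  waves2 <- waves; waves2$alpha <- -3 * waves2$alpha
  expect_equal(std_features(waves2)[["std_alpha"]], 3 * sqrt(2))
  # conventional estimator on request
  expect_equal(std_features(waves, conventional = TRUE)[["std_alpha"]],
               stats::sd(c(1, -1)))

  en <- energy_features(waves)
  expect_equal(unname(en[["energy_delta"]]), 1)        # [1,0,0]
  expect_equal(unname(en[["energy_alpha"]]), 2)
  expect_equal(unname(en[["energy_ratio_alpha_theta"]]), 2 / 8)
  waves$theta <- c(1, 1)                               # E_theta = E_alpha = 2
  expect_equal(unname(energy_features(waves)[["energy_ratio_alpha_theta"]]), 1)
  waves$theta <- c(0, 0)
  expect_error(energy_features(waves), "theta")
})

test_that("theta-dominant epochs give sub-unit energy ratios", {
  x <- make_epoch(6, 2, noise_sd = 0.3, seed = 8)
  en <- energy_features(extract_characteristic_waves(x, 100))
  expect_lt(en[["energy_ratio_alpha_theta"]], 1)
  expect_lt(en[["energy_ratio_delta_theta"]], 1)
})

test_that("periodogram peaks at the tone and satisfies Parseval", {
  t <- (0:2999) / 100
  x <- sin(2 * pi * 10 * t)
  sp <- power_spectrum(x, 100)
  expect_equal(sp$frequency[which.max(sp$power)], 10, tolerance = 100 / 3000)
  df <- sp$frequency[2] - sp$frequency[1]
  expect_equal(sum(sp$power) * df, mean(x^2), tolerance = 1e-6)
  expect_true(all(power_spectrum(numeric(100), 100)$power == 0))
})

test_that("mean frequency is the spectral centroid", {
  x <- make_epoch(10, 1, noise_sd = 0.01, seed = 9)
  waves <- extract_characteristic_waves(x, 100)
  ff <- frequency_features(waves, x, 100)
  expect_equal(unname(ff[["mnf"]]), 10, tolerance = 0.5)
  # flat spectrum -> centroid at mid-Nyquist
  flat <- list(frequency = seq(0, 50, by = 0.5),
               power = rep(1, 101))
  mnf_flat <- sum(flat$power * flat$frequency) / sum(flat$power)
  expect_equal(mnf_flat, 25)
  # ratio = 1 when alpha and theta powers tie (direct arithmetic check)
  expect_equal(unname(ff[["power_ratio_alpha_theta"]]),
               unname(ff[["power_alpha"]] / ff[["power_theta"]]))
})

test_that("Renyi and spectral entropy have their closed-form extremes", {
  uni4 <- list(power = rep(1, 4))
  expect_equal(renyi_entropy(uni4), log(4))
  expect_equal(spectral_entropy(uni4), log(4))
  single <- list(power = c(0, 7, 0))
  expect_equal(renyi_entropy(single), 0)
  expect_equal(spectral_entropy(single), 0)
  # scale invariance and the Renyi <= Shannon ordering
  set.seed(10)
  p <- list(power = runif(64))
  expect_equal(renyi_entropy(p), renyi_entropy(list(power = 17 * p$power)))
  expect_gte(spectral_entropy(p), renyi_entropy(p))
  expect_error(renyi_entropy(list(power = numeric(5))), "zero")
})

test_that("median binarization is affine-invariant", {
  expect_equal(binarize_median(c(1, 2, 3, 4)), c(0L, 0L, 1L, 1L))
  expect_equal(binarize_median(rep(2, 5)), rep(1L, 5))   # >= median branch
  set.seed(11)
  x <- rnorm(101)
  expect_equal(binarize_median(x), binarize_median(2.5 * x + 7))
})

test_that("Lempel-Ziv complexity matches the exhaustive parsing oracle", {
  z0 <- rep(0L, 10)
  expect_equal(lzc(z0, normalize = FALSE), 2)            # phrases: 0 | 000000000
  expect_equal(lzc(z0), 2 * log2(10) / 10)
  tm <- c(0, 1, 1, 0, 1, 0, 0, 1, 1, 0, 0, 1, 0, 1, 1, 0)
  expect_equal(lzc(tm, normalize = FALSE), lz76_oracle(tm))
  set.seed(12)
  for (rep_i in 1:25) {
    z <- sample(0:1, sample(5:200, 1), replace = TRUE)
    expect_equal(lzc(z, normalize = FALSE), lz76_oracle(z))
  }
  # randomness is more complex than strict alternation
  set.seed(13)
  rnd <- sample(0:1, 1000, replace = TRUE)
  alt <- rep(c(0L, 1L), 500)
  expect_gt(lzc(rnd), lzc(alt))
  expect_error(lzc(c(0, 1, 2)), "binary")
})

test_that("coarse graining averages non-overlapping blocks", {
  x <- c(1, 1, 2, 2)
  expect_equal(coarse_grain(x, 1), x)
  expect_equal(coarse_grain(x, 2), c(1, 2))
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5), 2), c(1.5, 3.5))
  expect_error(coarse_grain(x, 0), "tau")
})

test_that("sample entropy agrees with the brute-force counting oracle", {
  set.seed(14)
  for (rep_i in 1:5) {
    x <- rnorm(sample(50:200, 1))
    r <- 0.2 * sd(x)
    expect_equal(sample_entropy(x, 2, r), sampen_oracle(x, 2, r),
                 tolerance = 1e-9)
  }
  # strict periodicity: every template recurs, so the entropy vanishes
  xp <- rep(c(1, 2), 50)
  expect_equal(sample_entropy(xp, 2, 0.2 * sd(xp)), 0)
  # irregularity ordering at matched scale
  set.seed(15)
  noise <- rnorm(500)
  sine <- sin(2 * pi * 5 * (0:499) / 100)
  sine <- sine / sd(sine)
  expect_gt(sample_entropy(noise, 2, 0.2), sample_entropy(sine, 2, 0.2))
  expect_error(sample_entropy(rep(1, 100)), "positive")
})

test_that("multi-scale entropy is sample entropy of the coarse series", {
  set.seed(16)
  x <- rnorm(400)
  r <- 0.2 * sd(x)
  expect_equal(multiscale_entropy(x, tau = 1, r = r),
               sample_entropy(x, r = r))
  expect_equal(multiscale_entropy(x, tau = 5, r = r),
               sampen_oracle(coarse_grain(x, 5), 2, r), tolerance = 1e-9)
  # coarse-graining changes the value (variance shrinks under averaging)
  expect_false(isTRUE(all.equal(multiscale_entropy(x, tau = 11, r = r),
                                sample_entropy(x, r = r))))
  xp <- rep(c(0, 5), 200)
  expect_lt(multiscale_entropy(xp, tau = 2, r = 0.2 * sd(xp)), 0.05)
  # literal per-point summation variant is a constant multiple
  expect_equal(multiscale_entropy(x, tau = 5, r = r, literal_sum = TRUE),
               80 * multiscale_entropy(x, tau = 5, r = r))
})

test_that("fuzzy entropy matches its oracle and ignores mean shifts", {
  set.seed(17)
  x <- rnorm(120)
  r <- 0.2 * sd(x)
  expect_equal(fuzzy_entropy(x, 2, r), fuzzyen_oracle(x, 2, r),
               tolerance = 1e-9)
  expect_equal(fuzzy_entropy(x + 100, 2, r), fuzzy_entropy(x, 2, r),
               tolerance = 1e-9)
  xp <- rep(c(1, 2), 60)
  expect_lt(fuzzy_entropy(xp, 2, 0.2 * sd(xp)), 0.1)
  # impulse contamination raises irregularity
  set.seed(18)
  base <- rnorm(300)
  spiky <- base
  spiky[seq(10, 300, by = 30)] <- spiky[seq(10, 300, by = 30)] + 8
  r2 <- 0.2 * sd(base)
  expect_gt(fuzzy_entropy(spiky, 2, r2), fuzzy_entropy(base, 2, r2))
})

test_that("auxiliary time features behave on degenerate and analytic cases", {
  const <- rep(3, 3000)
  aux <- auxiliary_time_features(const, 100)
  expect_equal(unname(aux[c("variance", "zero_crossings", "ptp")]),
               c(0, 0, 0))
  expect_length(aux, 17L)
  # Hjorth mobility of a slow sinusoid approaches its angular frequency
  t <- (0:2999) / 100
  for (f in c(2, 5, 10)) {
    aux_f <- auxiliary_time_features(sin(2 * pi * f * t), 100)
    expect_equal(unname(aux_f[["hjorth_mobility"]]), 2 * pi * f,
                 tolerance = 0.05)
  }
  set.seed(19)
  sym <- rnorm(3000)
  expect_lt(abs(auxiliary_time_features(sym, 100)[["skewness"]]), 0.1)
})

test_that("the feature vector has the canonical 51 entries and is deterministic", {
  x <- make_epoch(c(10, 20), c(1.2, 0.5), noise_sd = 1, seed = 20)
  v1 <- extract_feature_vector(x, 100)
  v2 <- extract_feature_vector(x, 100)
  expect_identical(names(v1), feature_names())
  expect_length(v1, 51L)
  expect_identical(v1, v2)
  expect_true(all(is.finite(v1)))
  # alpha-dominant epoch: std_alpha tops the six Std features
  stds <- v1[startsWith(names(v1), "std_")]
  expect_equal(names(which.max(stds)), "std_alpha")
})
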