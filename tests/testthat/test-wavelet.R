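# Wavelet threshold denoising and wavelet packet band extraction.

test_that("wavelet packet node bands tile the frequency axis", {
  b <- node_frequency_band(7, 1, 100)
  expect_equal(unname(b), c(0, 0.390625))
  b2 <- node_frequency_band(1, 2, 100)
  expect_equal(unname(b2), c(25, 50))
  expect_error(node_frequency_band(7, 129, 100), "node_index")

  # all 128 level-7 intervals are disjoint and union to [0, 50)
  edges <- t(vapply(1:128, function(j) node_frequency_band(7, j, 100),
                    numeric(2)))
  expect_equal(nrow(unique(edges)), 128L)
  expect_equal(edges[, 1], seq(0, 50 - 50 / 128, by = 50 / 128))
  expect_equal(edges[, 2], edges[, 1] + 50 / 128)
})

test_that("band reconstructions over a tiling sum back to the input", {
  set.seed(3)
  x <- rnorm(3000)
  tree <- wpt_decompose(x, 100)
  # tile edges on the 0.390625 Hz node grid so each node belongs to
  # exactly one tile
  tiling <- list(c(0, 3.90625), c(3.90625, 12.5), c(12.5, 25), c(25, 50))
  pieces <- lapply(tiling, reconstruct_band, tree = tree)
  expect_equal(Reduce(`+`, pieces), x, tolerance = 1e-6)
  # zero input stays zero in every band
  ztree <- wpt_decompose(numeric(3000), 100)
  expect_true(all(abs(reconstruct_band(ztree, c(8, 13))) == 0))
})

test_that("band reconstruction is linear and captures tone energy", {
  # iterated 16-tap filters leak some energy into side lobes at depth 7
  # (capture ranges roughly 0.87-0.99 depending on where the tone falls
  # within its node; matches reference wavelet-packet implementations),
  # so the in-band share is asserted at 0.85 alongside dominance
  t <- (0:2999) / 100
  for (f in c(8.5, 10, 12.9)) {
    tone <- sin(2 * pi * f * t)
    tree <- wpt_decompose(tone, 100)
    alpha <- reconstruct_band(tree, c(8, 13))
    delta <- reconstruct_band(tree, c(0.5, 2))
    e_tot <- sum(tone^2)
    expect_gt(sum(alpha^2) / e_tot, 0.85)
    expect_lt(sum(delta^2) / e_tot, 0.05)
    expect_gt(sum(alpha^2), sum(delta^2))
  }
  # linearity
  tone <- sin(2 * pi * 10 * t)
  tree3 <- wpt_decompose(3 * tone, 100)
  alpha1 <- reconstruct_band(wpt_decompose(tone, 100), c(8, 13))
  expect_equal(reconstruct_band(tree3, c(8, 13)), 3 * alpha1,
               tolerance = 1e-9)
})

test_that("a tone lands in its own frequency-ordered node at level 7", {
  t <- (0:2999) / 100
  for (f in c(1.3, 6.1, 10.0, 13.2, 27.5)) {
    tree <- wpt_decompose(sin(2 * pi * f * t), 100)
    energies <- vapply(tree$leaves, function(v) sum(v^2), numeric(1))
    slot <- tree$freq_of_natural[which.max(energies)]
    band <- node_frequency_band(7, slot + 1L, 100)
    expect_true(f >= band[1] && f < band[2],
                label = sprintf("%g Hz in [%g, %g)", f, band[1], band[2]))
  }
})

test_that("characteristic waves have epoch length and track stage rhythms", {
  # delta-dominant epoch: 1 Hz slow oscillation
  slow <- make_epoch(1, 3, noise_sd = 0.5, seed = 4)
  waves <- extract_characteristic_waves(slow, 100)
  expect_named(waves, c("alpha", "beta", "theta", "delta", "spindle",
                        "sawtooth"))
  expect_true(all(lengths(waves) == 3000L))
  stds <- std_features(waves)
  expect_equal(names(which.max(stds)), "std_delta")
  # alpha-dominant epoch: 10 Hz
  fast <- make_epoch(10, 2, noise_sd = 0.5, seed = 5)
  stds2 <- std_features(extract_characteristic_waves(fast, 100))
  expect_equal(names(which.max(stds2)), "std_alpha")
})

test_that("wavelet threshold denoising shrinks noise, preserves signal", {
  t <- (0:2999) / 100
  clean <- sin(2 * pi * 10 * t)
  for (noise_sd in c(0.1, 0.5)) {
    set.seed(6)
    noisy <- clean + rnorm(3000, 0, noise_sd)
    den <- wtd_denoise(noisy)
    expect_equal(length(den), 3000L)
    expect_lt(sqrt(mean((den - clean)^2)), sqrt(mean((noisy - clean)^2)))
  }
  expect_equal(wtd_denoise(numeric(3000)), numeric(3000))
  expect_error(wtd_denoise(rnorm(64)), "2\\^levels")
  expect_error(wtd_denoise(c(rnorm(2999), NA)), "non-finite")
  # "none" rule is a pure round trip through the transform
  set.seed(7)
  x <- rnorm(3000)
  expect_equal(wtd_denoise(x, threshold_rule = "none"), x, tolerance = 1e-9)
})
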