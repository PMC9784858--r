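# Standardization, binary/one-vs-one SVMs, rebalancing, and the cascade.

# radius-separable toy for the homogeneous quadratic kernel: the kernel is
# even in x, so separation must come from distance to the origin, not sign
make_radial_toy <- function(n = 12, seed = 27) {
  set.seed(seed)
  inner <- matrix(rnorm(n, 0, 0.15), ncol = 2)
  outer <- matrix(rnorm(n, 0, 0.15), ncol = 2) + 2.5
  list(x = rbind(outer, inner),
       y = c(rep(1, n / 2), rep(-1, n / 2)))
}

test_that("standardization uses population moments from the training rows", {
  tab <- data.frame(a = c(2, 4), b = c(0, 10))
  sc <- standardize_fit(tab)
  z <- standardize_apply(sc, tab)
  expect_equal(unname(z[, "a"]), c(-1, 1))          # population std = 1
  expect_equal(colMeans(z), c(a = 0, b = 0))
  # apply never refits: a shifted table keeps the training parameters
  z2 <- standardize_apply(sc, data.frame(a = c(3, 5), b = c(5, 15)))
  expect_equal(unname(z2[, "a"]), c(0, 2))
  expect_warning(sc2 <- standardize_fit(data.frame(a = 1:4, c = rep(7, 4))),
                 "zero-variance")
  expect_equal(sc2$features, "a")
})

test_that("the quadratic kernel is (x.z)^2 and positive semi-definite", {
  expect_equal(quad_kernel(c(1, 1), c(1, 1)), 4)
  expect_equal(quad_kernel(c(1, 0), c(0, 3)), 0)
  expect_error(quad_kernel(1:2, 1:3), "dimension")
  set.seed(28)
  pts <- matrix(rnorm(15), 5)
  K <- outer(seq_len(5), seq_len(5),
             Vectorize(function(i, j) quad_kernel(pts[i, ], pts[j, ])))
  expect_equal(K, t(K))
  expect_true(all(eigen(K, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-9))
})

test_that("binary SVM training satisfies KKT and separates a separable toy", {
  toy <- make_radial_toy()
  m <- train_binary_svm(toy$x, toy$y, Const = 100)
  # KKT: box constraint and the equality constraint
  expect_true(all(m$alpha >= -1e-9 & m$alpha <= 100 + 1e-9))
  expect_lt(abs(sum(m$alpha * m$sv_y)), 1e-6)
  # separable toy: zero training error
  pred <- predict_binary(m, toy$x)
  expect_equal(as.vector(pred), toy$y)
  # duplicating every row leaves predictions unchanged
  m2 <- train_binary_svm(rbind(toy$x, toy$x), c(toy$y, toy$y), Const = 100)
  expect_equal(as.vector(predict_binary(m2, toy$x)), toy$y)
  expect_error(train_binary_svm(toy$x, rep(1, nrow(toy$x))), "classes")
  expect_error(train_binary_svm(toy$x, sample(c(1, 2), nrow(toy$x), TRUE)),
               "1, -1")
})

test_that("the decision function equals direct kernel summation", {
  toy <- make_radial_toy(seed = 29)
  m <- train_binary_svm(toy$x, toy$y, Const = 10)
  probe <- matrix(rnorm(10, 0, 1.5), ncol = 2)
  dec <- attr(predict_binary(m, probe), "decision")
  for (i in seq_len(nrow(probe))) {
    hand <- sum(vapply(seq_len(nrow(m$sv)), function(s)
      m$coefs[s] * quad_kernel(m$sv[s, ], probe[i, ]), numeric(1))) + m$bias
    expect_equal(dec[i], hand, tolerance = 1e-9)
  }
  # sign convention: decision exactly zero classifies positive
  m0 <- m
  m0$coefs <- m0$coefs * 0
  m0$bias <- 0
  expect_equal(as.vector(predict_binary(m0, probe[1, ])), 1)
})

test_that("one-vs-one voting matches a longhand evaluation", {
  set.seed(30)
  blob <- function(cx, cy, n = 20) cbind(rnorm(n, cx, 0.4), rnorm(n, cy, 0.4))
  x <- rbind(blob(3, 0), blob(0, 3), blob(3, 3))
  y <- factor(rep(c("a", "b", "c"), each = 20))
  m <- train_ovo(x, y, Const = 10)
  expect_length(m$machines, 3L)                    # C(3,2)
  pred <- predict_ovo(m, x)
  expect_gte(mean(pred == y), 0.95)
  # longhand vote oracle on fresh probes
  probes <- rbind(blob(3, 0, 5), blob(0, 3, 5), blob(3, 3, 5))
  pv <- predict_ovo(m, probes)
  for (i in seq_len(nrow(probes)))
    expect_equal(as.character(pv[i]), ovo_vote_oracle(m, probes[i, ]))
  expect_error(train_ovo(x, factor(rep("a", 60))), "two classes")
})

test_that("five-class one-vs-one builds all ten machines", {
  set.seed(31)
  x <- matrix(rnorm(250), 50, 5)
  y <- factor(rep(sleep_stages(), each = 10), levels = sleep_stages())
  x <- x + 3 * model.matrix(~ y - 1)               # separate the classes
  m <- train_ovo(x, y, Const = 10)
  expect_length(m$machines, 10L)                   # C(5,2)
  expect_gte(mean(predict_ovo(m, x) == y), 0.95)
})

test_that("stage-I label merge collapses R/N1/N2 into REM-LS", {
  s <- factor(c("W", "N1", "N2", "N3", "R", "N1"))
  l1 <- build_stage1_labels(s)
  expect_equal(as.character(l1),
               c("W", "REM-LS", "REM-LS", "N3", "REM-LS", "REM-LS"))
  expect_equal(levels(l1), c("W", "REM-LS", "N3"))
  expect_length(l1, length(s))                     # multiset size preserved
  expect_error(build_stage1_labels(c("W", "XX")), "unknown")
})

test_that("stage-II rebalancing keeps all N1, samples R and 2x N2", {
  set.seed(32)
  stage <- factor(c(rep("N1", 100), rep("R", 300), rep("N2", 500),
                    rep("W", 50), rep("N3", 50)))
  sel <- build_stage2_training_set(stage, seed = 5)
  expect_length(sel, 400L)                         # 100 + 100 + 200
  tab <- table(stage[sel])
  expect_equal(as.vector(tab[c("N1", "R", "N2")]), c(100L, 100L, 200L))
  expect_true(all(which(stage == "N1") %in% sel))
  expect_equal(sel, build_stage2_training_set(stage, seed = 5))
  expect_false(identical(sel, build_stage2_training_set(stage, seed = 6)))
  # shortage: take what exists, with a warning
  small <- factor(c(rep("N1", 10), rep("R", 5), rep("N2", 12)))
  w <- capture_warnings(s2 <- build_stage2_training_set(small, seed = 1))
  expect_match(w, "taking all", all = TRUE)
  expect_length(w, 2L)                             # both R and N2 short
  expect_length(s2, 10L + 5L + 12L)
})

test_that("the fitted cascade has the documented structure", {
  ds <- synth_dataset(counts = c(W = 15, N1 = 15, N2 = 15, N3 = 15, R = 15),
                      seed = 33)
  feats <- extract_feature_table(ds)
  fit <- suppressWarnings(
    cascade_svm(feats[feature_names()], feats$stage, seed = 2))
  expect_s3_class(fit, "cascade_svm")
  expect_length(fit$svm1$machines, 3L)
  expect_length(fit$svm2$machines, 3L)
  expect_length(fit$features_stage1, 32L)
  expect_length(fit$features_stage2, 30L)
  expect_length(fit$cv_accuracy, 10L)
  expect_true(all(fit$cv_accuracy >= 0 & fit$cv_accuracy <= 1, na.rm = TRUE))
  # determinism: identical seed/config reproduces support-vector counts
  fit2 <- suppressWarnings(
    cascade_svm(feats[feature_names()], feats$stage, seed = 2))
  nsv <- function(f) vapply(c(f$svm1$machines, f$svm2$machines),
                            function(m) nrow(m$sv), numeric(1))
  expect_identical(nsv(fit), nsv(fit2))
  # predictions stay in the closed five-stage set and route through stages
  pred <- predict(fit, feats[feature_names()])
  expect_true(all(pred %in% sleep_stages()))
  # stage-I-final classes come out unchanged on unambiguous epochs
  p1 <- predict_ovo(fit$svm1,
                    standardize_apply(fit$scaler,
                                      feats[feature_names()])[,
                      fit$features_stage1, drop = FALSE])
  expect_true(all(as.character(pred)[p1 == "W"] == "W"))
  expect_true(all(as.character(pred)[p1 == "N3"] == "N3"))
  expect_true(all(p1[as.character(pred) %in% c("R", "N1", "N2")] == "REM-LS"))
  expect_error(cascade_svm(feats[feature_names()][1:10],
                           feats$stage), "canonical feature")
})
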