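# Cascaded one-vs-one SVM classifier:
#   stage I  separates W / REM-LS / N3  (REM-LS = {R, N1, N2} merged),
#   stage II resolves REM-LS epochs into R / N1 / N2 on a rebalanced
#   training set (all N1, as many R, twice as many N2).
# Binary machines use the homogeneous quadratic kernel (x.z)^2 and are
# fitted by the libsvm dual solver via e1071; voting, tie-breaking,
# rebalancing and routing are implemented here.

#' Fit feature standardization parameters
#'
#' Per-column mean and population standard deviation (divide by M) of the
#' training table. Zero-variance columns are dropped with a warning.
#'
#' @param table data.frame or matrix of numeric features (training rows).
#' @return list with `mean`, `sd`, `features` (class `feature_scaler`).
#' @export
standardize_fit <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2L) stop("need at least two rows to standardize")
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  keep <- sd_pop > 0
  if (!all(keep))
    warning("dropping zero-variance feature(s): ",
            paste(colnames(m)[!keep], collapse = ", "))
  structure(list(mean = mu[keep], sd = sd_pop[keep],
                 features = colnames(m)[keep]),
            class = "feature_scaler")
}

#' Apply fitted standardization parameters
#'
#' Centers and scales with the *training* parameters; never refits.
#'
#' @param params a `feature_scaler` from [standardize_fit()].
#' @param table table containing at least the fitted feature columns.
#' @return numeric matrix of standardized features, fitted columns only.
#' @export
standardize_apply <- function(params, table) {
  m <- as.matrix(as.data.frame(table)[params$features])
  sweep(sweep(m, 2L, params$mean), 2L, params$sd, "/")
}

#' Homogeneous quadratic kernel
#'
#' `(x . z)^2`.
#' @param x,z numeric vectors of equal length.
#' @return scalar kernel value.
#' @export
quad_kernel <- function(x, z) {
  if (length(x) != length(z)) stop("dimension mismatch")
  sum(x * z)^2
}

#' Train a binary quadratic-kernel SVM
#'
#' Solves the soft-margin dual (box constraint `0 <= alpha_i <= Const`,
#' `sum alpha_i y_i = 0`) with the libsvm solver. The returned object
#' stores the support vectors, their multipliers and the bias so the
#' decision function can be evaluated by direct summation.
#'
#' @param rows numeric matrix of training rows (already standardized).
#' @param y labels in `{1, -1}`.
#' @param Const regularization constant (default 1).
#' @return object of class `binary_svm` with `sv` (support-vector rows),
#'   `alpha` (multipliers), `sv_y` (their labels), `coefs` (`alpha * y`),
#'   `bias`, `Const`.
#' @export
train_binary_svm <- function(rows, y, Const = 1) {
  rows <- as.matrix(rows)
  if (!all(y %in% c(1, -1))) stop("labels must be in {1, -1}")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  fit <- e1071::svm(rows, factor(y, levels = c(1, -1)),
                    kernel = "polynomial", degree = 2, gamma = 1, coef0 = 0,
                    cost = Const, scale = FALSE)
  coefs <- as.numeric(fit$coefs)         # alpha_i * y_i
  rho <- fit$rho
  # libsvm orients the decision toward the class seen first in the data;
  # flip so that positive decision always means y = +1
  if (fit$levels[fit$labels[1L]] != "1") {
    coefs <- -coefs
    rho <- -rho
  }
  structure(list(
    sv = rows[fit$index, , drop = FALSE],
    alpha = abs(coefs),
    sv_y = sign(coefs),
    coefs = coefs,
    bias = -rho,                         # decision = sum coefs*K(sv, x) + bias
    Const = Const
  ), class = "binary_svm")
}

#' Evaluate a binary SVM
#'
#' Direct summation of the kernel expansion,
#' `u(x) = sum_i alpha_i y_i (x_i . x)^2 + bias`, with the sign convention
#' that a decision value of exactly zero is the positive class.
#'
#' @param model a `binary_svm`.
#' @param rows matrix (or single vector) of standardized feature rows.
#' @return numeric vector of +1/-1 with attribute `"decision"` holding the
#'   raw decision values.
#' @export
predict_binary <- function(model, rows) {
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1L)
  K <- (model$sv %*% t(rows))^2
  dec <- drop(crossprod(K, model$coefs)) + model$bias
  structure(ifelse(dec >= 0, 1, -1), decision = dec)
}

#' Train a one-vs-one multi-class SVM
#'
#' One binary machine per class pair (pairs in canonical class order, the
#' first class of each pair coded +1). Prediction is by majority vote with
#' equal weights.
#'
#' @param rows standardized feature matrix.
#' @param labels factor (or character) class labels; all classes present.
#' @param Const regularization constant.
#' @return object of class `ovo_svm`.
#' @export
train_ovo <- function(rows, labels, Const = 1) {
  rows <- as.matrix(rows)
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  cls <- levels(labels)
  if (length(cls) < 2L) stop("need at least two classes")
  if (!all(table(labels) > 0L)) stop("every class must have training rows")
  pairs <- utils::combn(cls, 2L, simplify = FALSE)
  machines <- lapply(pairs, function(pr) {
    sel <- labels %in% pr
    yv <- ifelse(labels[sel] == pr[1L], 1, -1)
    train_binary_svm(rows[sel, , drop = FALSE], yv, Const)
  })
  structure(list(classes = cls, pairs = pairs, machines = machines,
                 Const = Const),
            class = "ovo_svm")
}

#' Predict with a one-vs-one SVM
#'
#' Each pairwise machine casts one vote; the class with the most votes
#' wins. Ties are broken by the largest sum of absolute decision values
#' over the machines the tied class won, then by canonical class order.
#'
#' @param model an `ovo_svm`.
#' @param rows standardized feature matrix.
#' @return factor of predicted classes.
#' @export
predict_ovo <- function(model, rows) {
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1L)
  n <- nrow(rows)
  k <- length(model$classes)
  votes <- matrix(0L, n, k, dimnames = list(NULL, model$classes))
  margin <- matrix(0, n, k, dimnames = list(NULL, model$classes))
  for (m in seq_along(model$machines)) {
    pr <- model$pairs[[m]]
    pred <- predict_binary(model$machines[[m]], rows)
    dec <- attr(pred, "decision")
    win <- ifelse(pred > 0, pr[1L], pr[2L])
    for (cl in pr) {
      w <- win == cl
      votes[w, cl] <- votes[w, cl] + 1L
      margin[w, cl] <- margin[w, cl] + abs(dec[w])
    }
  }
  out <- character(n)
  for (i in seq_len(n)) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) > 1L) top <- top[which.max(margin[i, top])]
    out[i] <- model$classes[top[1L]]
  }
  factor(out, levels = model$classes)
}

#' Merge five-stage labels into the stage-I classes
#'
#' `W -> W`, `N3 -> N3`, `{R, N1, N2} -> REM-LS`.
#'
#' @param stage factor/character over the five stages.
#' @return factor with levels `W`, `REM-LS`, `N3`.
#' @export
build_stage1_labels <- function(stage) {
  s <- as.character(stage)
  bad <- !s %in% sleep_stages()
  if (any(bad)) stop("unknown stage label(s): ", paste(unique(s[bad]), collapse = ", "))
  out <- ifelse(s %in% c("R", "N1", "N2"), "REM-LS", s)
  factor(out, levels = c("W", "REM-LS", "N3"))
}

#' Rebalanced stage-II training rows
#'
#' Keeps every N1 epoch, samples (without replacement) the same number of
#' R epochs and twice the number of N2 epochs. If fewer are available, all
#' are taken with a warning.
#'
#' @param stage five-stage factor for the training rows.
#' @param seed integer seed making the subsample reproducible.
#' @return sorted integer vector of selected row indices.
#' @export
build_stage2_training_set <- function(stage, seed = 1L) {
  s <- as.character(stage)
  i_n1 <- which(s == "N1")
  i_r <- which(s == "R")
  i_n2 <- which(s == "N2")
  if (length(i_n1) == 0L || length(i_r) == 0L || length(i_n2) == 0L)
    stop("training set must contain N1, R and N2 epochs")
  n1 <- length(i_n1)
  pick <- function(idx, m, lab) {
    if (length(idx) < m) {
      warning(sprintf("only %d %s epochs available (wanted %d): taking all",
                      length(idx), lab, m))
      return(idx)
    }
    sample(idx, m)
  }
  sel <- .with_seed(seed, {
    c(i_n1, pick(i_r, n1, "R"), pick(i_n2, 2L * n1, "N2"))
  })
  sort(sel)
}

#' @keywords internal
#' Evaluate `expr` under a temporary RNG seed, restoring the RNG state.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Fit the cascaded sleep-stage classifier
#'
#' The core model of the package. Training standardizes the 51-feature
#' table (population moments, training rows only), ranks features by MIQ
#' unless a ranking is supplied, and fits two one-vs-one quadratic-kernel
#' SVMs: stage I on the top `k1` features over {W, REM-LS, N3} using all
#' training rows, and stage II on the top `k2` features over {R, N1, N2}
#' using the rebalanced subset of [build_stage2_training_set()]. A k-fold
#' cross-validation accuracy on the rebalanced subset is reported as a
#' training diagnostic; the final stage-II machine is refit on the whole
#' subset.
#'
#' @param x data.frame with the 51 canonical feature columns (extra
#'   columns ignored).
#' @param stage factor/character of five-stage labels, one per row.
#' @param ranking optional precomputed [miq_rank()] table.
#' @param k1,k2 number of ranked features for stage I / stage II
#'   (defaults 32 and 30).
#' @param Const SVM regularization constant (default 1).
#' @param n_bins discretization bins for the MIQ ranking.
#' @param seed seed for the stage-II subsample and CV folds.
#' @param cv_folds folds for the stage-II diagnostic (default 10; 0 skips).
#' @return object of class `cascade_svm`.
#' @export
cascade_svm <- function(x, stage, ranking = NULL, k1 = 32L, k2 = 30L,
                        Const = 1, n_bins = 10L, seed = 1L, cv_folds = 10L) {
  x <- as.data.frame(x)
  missing_f <- setdiff(feature_names(), names(x))
  if (length(missing_f) > 0L)
    stop("missing canonical feature column(s): ",
         paste(utils::head(missing_f, 5L), collapse = ", "))
  x <- x[feature_names()]
  stage <- factor(as.character(stage), levels = sleep_stages())
  if (anyNA(stage)) stop("stage labels outside the five-stage set")
  if (any(table(stage) == 0L))
    stop("every sleep stage must be present in the training data")
  scaler <- standardize_fit(x)
  xs <- standardize_apply(scaler, x)
  if (is.null(ranking)) ranking <- miq_rank(x, stage, n_bins = n_bins)
  f1 <- select_top(ranking, k1)
  f2 <- select_top(ranking, k2)
  f1 <- intersect(f1, scaler$features)
  f2 <- intersect(f2, scaler$features)
  svm1 <- train_ovo(xs[, f1, drop = FALSE], build_stage1_labels(stage), Const)
  sel2 <- build_stage2_training_set(stage, seed = seed)
  x2 <- xs[sel2, f2, drop = FALSE]
  y2 <- factor(as.character(stage[sel2]), levels = c("R", "N1", "N2"))
  cv_acc <- NULL
  if (cv_folds > 0L) {
    cv_acc <- .with_seed(seed + 1L, {
      fold <- sample(rep_len(seq_len(cv_folds), nrow(x2)))
      vapply(seq_len(cv_folds), function(f) {
        tr <- fold != f
        if (length(unique(y2[tr])) < 3L || !any(!tr)) return(NA_real_)
        m <- train_ovo(x2[tr, , drop = FALSE], y2[tr], Const)
        mean(predict_ovo(m, x2[!tr, , drop = FALSE]) == y2[!tr])
      }, numeric(1))
    })
  }
  svm2 <- train_ovo(x2, y2, Const)
  structure(list(
    scaler = scaler,
    ranking = ranking,
    features_stage1 = f1,
    features_stage2 = f2,
    svm1 = svm1,
    svm2 = svm2,
    cv_accuracy = cv_acc,
    Const = Const,
    seed = seed,
    n_train = nrow(x),
    n_stage2 = length(sel2),
    stage_counts = table(stage)
  ), class = "cascade_svm")
}

#' Predict sleep stages with a fitted cascade
#'
#' Stage I decides W / REM-LS / N3; W and N3 are final, REM-LS rows are
#' routed to stage II which returns R / N1 / N2.
#'
#' @param object a `cascade_svm`.
#' @param newdata data.frame containing the canonical feature columns.
#' @param ... unused.
#' @return factor of predicted stages over `sleep_stages()`.
#' @export
predict.cascade_svm <- function(object, newdata, ...) {
  xs <- standardize_apply(object$scaler, as.data.frame(newdata))
  p1 <- predict_ovo(object$svm1, xs[, object$features_stage1, drop = FALSE])
  out <- as.character(p1)
  route <- which(out == "REM-LS")
  if (length(route) > 0L) {
    p2 <- predict_ovo(object$svm2,
                      xs[route, object$features_stage2, drop = FALSE])
    out[route] <- as.character(p2)
  }
  factor(out, levels = sleep_stages())
}

#' @export
print.cascade_svm <- function(x, ...) {
  cat("Cascaded one-vs-one SVM sleep stager\n")
  cat(sprintf("  trained on %d epochs (stage II rebalanced subset: %d)\n",
              x$n_train, x$n_stage2))
  cat(sprintf("  stage I: %d features over W/REM-LS/N3; stage II: %d features over R/N1/N2\n",
              length(x$features_stage1), length(x$features_stage2)))
  cat(sprintf("  quadratic kernel, Const = %g\n", x$Const))
  if (!is.null(x$cv_accuracy))
    cat(sprintf("  stage II %d-fold CV accuracy: %.3f (sd %.3f)\n",
                length(x$cv_accuracy), mean(x$cv_accuracy, na.rm = TRUE),
                stats::sd(x$cv_accuracy, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.cascade_svm <- function(object, ...) {
  print(object)
  cat("\nTraining stage counts:\n")
  print(object$stage_counts)
  cat("\nTop stage-I features:\n  ",
      paste(object$features_stage1[1:min(10, length(object$features_stage1))],
            collapse = ", "), "...\n")
  nsv1 <- sum(vapply(object$svm1$machines, function(m) length(m$alpha), numeric(1)))
  nsv2 <- sum(vapply(object$svm2$machines, function(m) length(m$alpha), numeric(1)))
  cat(sprintf("\nSupport vectors: stage I %d, stage II %d\n", nsv1, nsv2))
  invisible(object)
}
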