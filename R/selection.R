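# MIQ (mutual-information quotient) feature ranking: the quotient form of
# minimum-redundancy maximum-relevance selection.

#' Quantile-discretize a numeric column
#'
#' Bins a continuous column at its empirical quantiles so each code is
#' roughly equally populated; tied values share a bin, so at most `n_bins`
#' distinct codes result. Codes are invariant to monotone transforms of
#' the column.
#'
#' @param x numeric vector.
#' @param n_bins number of quantile bins (default 10).
#' @return integer codes in `1..n_bins`.
#' @export
discretize <- function(x, n_bins = 10L) {
  if (n_bins < 2L) stop("n_bins must be >= 2")
  # rank-based quantile binning: depends on the ranks only, so monotone
  # transforms leave the codes unchanged and tied values share a bin
  r <- rank(x, ties.method = "max")
  codes <- as.integer(ceiling(r / length(x) * n_bins))
  if (length(unique(codes)) == 1L)
    warning("column is (nearly) constant: a single bin")
  codes
}

#' Mutual information of two discrete code vectors
#'
#' Plug-in estimate from the joint empirical distribution, in nats:
#' `I = sum p(x,y) log( p(x,y) / (p(x) p(y)) )`. Non-negative, and zero
#' exactly when the empirical joint factorises.
#'
#' @param x,y equal-length vectors of discrete codes (any atomic type).
#' @return scalar mutual information in nats.
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("inputs must have equal length")
  if (length(x) == 0L) stop("empty input")
  jt <- table(x, y)
  p <- jt / sum(jt)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

#' Rank features by the MIQ criterion
#'
#' For each feature `f_i`, MIQ is its relevance to the class labels divided
#' by its mean redundancy with the other features,
#' `MIQ(f_i) = I(f_i, g) / ( (1/|F|) * sum_{j != i} I(f_i, f_j) )`,
#' all mutual informations computed on quantile-discretized columns. All
#' features are scored in one shot against the full set and sorted in
#' descending MIQ order (ties broken by the canonical column order). The
#' relevance `D` and redundancy `R` set diagnostics are attached as
#' attributes.
#'
#' @param feature_table data.frame or matrix of numeric feature columns.
#' @param labels discrete class labels, one per row.
#' @param n_bins quantile bins for discretization (default 10).
#' @return data.frame `rank`, `feature`, `miq`, `relevance`, `redundancy`
#'   with attributes `D` (Eq.-style mean relevance) and `R` (mean pairwise
#'   redundancy of the set).
#' @export
miq_rank <- function(feature_table, labels, n_bins = 10L) {
  ft <- as.data.frame(feature_table)
  ft <- ft[vapply(ft, is.numeric, logical(1))]
  nf <- ncol(ft)
  if (nf < 2L) stop("need at least two features to rank")
  if (nrow(ft) != length(labels)) stop("labels must match rows")
  codes <- lapply(ft, discretize, n_bins = n_bins)
  g <- as.integer(factor(labels))
  rel <- vapply(codes, mutual_information, numeric(1), y = g)
  mi <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      mi[i, j] <- mi[j, i] <- mutual_information(codes[[i]], codes[[j]])
    }
  }
  red <- rowSums(mi) / nf           # (1/|F|) sum_{j != i} I(f_i, f_j)
  miq <- ifelse(red > 0, rel / red, NA_real_)
  if (anyNA(miq)) {
    warning("feature(s) with zero redundancy ranked by relevance alone")
    # rank such features above all quotient-ranked ones, by relevance
    base <- if (all(is.na(miq))) 0 else max(miq, na.rm = TRUE)
    miq[is.na(miq)] <- base + rel[is.na(miq)]
  }
  ord <- order(-miq, seq_len(nf))
  out <- data.frame(rank = seq_len(nf),
                    feature = names(ft)[ord],
                    miq = miq[ord],
                    relevance = rel[ord],
                    redundancy = red[ord],
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "D") <- mean(rel)
  attr(out, "R") <- sum(mi) / nf^2
  attr(out, "n_bins") <- n_bins
  out
}

#' Top-k features of a ranking
#'
#' @param ranking data.frame from [miq_rank()].
#' @param k number of features to keep (defaults elsewhere: 32 for the
#'   stage-I classifier, 30 for stage II).
#' @return character vector of the first `k` feature names in rank order.
#' @export
select_top <- function(ranking, k) {
  if (k < 1L || k > nrow(ranking)) stop("k out of range")
  ranking$feature[seq_len(k)]
}
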