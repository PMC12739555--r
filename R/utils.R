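#' Derive a per-stage child seed from one global seed
#'
#' One global integer seed fans out to independent per-stage seeds so that,
#' e.g., the bulk cohort and the single-cell population of one simulation are
#' decoupled but jointly reproducible. The derivation is
#' `(seed * 48271 + sum of UTF-8 codes of stage) mod (2^31 - 1)`, a
#' Lehmer-style mix kept inside the 32-bit integer range R requires.
#'
#' @param seed integer global seed.
#' @param stage character stage label (e.g. "bulk", "cells", "ppi").
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1
  h <- sum(utf8ToInt(stage))
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% m)
}

#' Repair a symmetric matrix to the nearest positive semi-definite matrix
#'
#' Eigenvalue clipping: negative eigenvalues are raised to `eps`, the matrix
#' is reassembled and rescaled back to unit diagonal so it remains a valid
#' correlation matrix.
#'
#' @param x symmetric numeric matrix (intended correlation template).
#' @param eps floor for eigenvalues.
#' @return a symmetric positive semi-definite correlation matrix.
#' @export
nearest_psd <- function(x, eps = 1e-8) {
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  x <- (x + t(x)) / 2
  e <- eigen(x, symmetric = TRUE)
  if (all(e$values >= -eps)) {
    v <- pmax(e$values, eps)
  } else {
    v <- pmax(e$values, eps)
  }
  y <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(y))
  y <- y / (d %o% d)
  (y + t(y)) / 2
}

#' Standardize matrix rows to zero mean and unit variance
#'
#' Rows with zero variance are returned as all-zero (flagged via attribute
#' `zero_var`).
#'
#' @param x numeric matrix (features in rows).
#' @return standardized matrix with attribute `zero_var` (logical per row).
#' @keywords internal
.row_standardize <- function(x) {
  mu <- rowMeans(x)
  sd <- apply(x, 1L, stats::sd)
  zv <- sd == 0 | !is.finite(sd)
  sd[zv] <- 1
  out <- (x - mu) / sd
  out[zv, ] <- 0
  attr(out, "zero_var") <- zv
  out
}

#' Area under the ROC curve by the Mann-Whitney identity
#'
#' AUC is the probability that a value drawn from `pos` exceeds one drawn
#' from `neg`, with ties counting one half. Computed from midranks, which is
#' exactly the all-pairs count with the tie-half rule.
#'
#' @param pos numeric values of the positive group.
#' @param neg numeric values of the negative group.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(pos, neg) {
  n1 <- length(pos)
  n2 <- length(neg)
  stopifnot(n1 > 0L, n2 > 0L)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}
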