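# Resampling primitives for the imbalance-aware ensemble: SMOTE
# oversampling to fixed per-class targets and random undersampling with
# replacement to balanced counts. Both draw from the caller's RNG stream;
# the ensemble fitter wraps them in seeded contexts.

#' SMOTE oversampling to fixed per-class targets
#'
#' Classes below their target are topped up with synthetic rows interpolated
#' between a random class member and one of its `k` nearest same-class
#' neighbours (Euclidean distance): `new = x_i + gap * (x_nn - x_i)` with
#' `gap ~ U(0, 1)`. A class already at or above its target passes through
#' unchanged. A class with fewer than `k + 1` members cannot supply
#' neighbours and degrades to resampling with replacement (with a message).
#'
#' @param x Numeric matrix (complete cases; impute first).
#' @param y Factor of class labels, same length as `nrow(x)`.
#' @param targets Named vector of post-oversampling counts per class.
#' @param k Number of nearest neighbours used for interpolation.
#' @return List with the augmented `x` and `y` (original rows first).
#' @export
smote <- function(x, y, targets, k = 3) {
  x <- as.matrix(x)
  if (anyNA(x)) stopf("smote requires complete cases; impute missing values first")
  add_x <- list(); add_y <- list()
  for (cl in names(targets)) {
    idx <- which(y == cl)
    n <- length(idx)
    need <- targets[[cl]] - n
    if (n == 0L || need <= 0L) {
      if (need < 0L)
        message(sprintf("class '%s' count (%d) above its SMOTE target (%d); passed through unchanged",
                        cl, n, targets[[cl]]))
      next
    }
    xc <- x[idx, , drop = FALSE]
    if (n < k + 1L) {
      message(sprintf("class '%s' has %d < k+1 = %d members; degrading SMOTE to resampling with replacement",
                      cl, n, k + 1L))
      pick <- sample.int(n, need, replace = TRUE)
      add_x[[cl]] <- xc[pick, , drop = FALSE]
    } else {
      d <- as.matrix(stats::dist(xc))
      diag(d) <- Inf
      nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k)]))
      base <- sample.int(n, need, replace = TRUE)
      mate <- nn[cbind(base, sample.int(k, need, replace = TRUE))]
      gap <- stats::runif(need)
      add_x[[cl]] <- xc[base, , drop = FALSE] +
        gap * (xc[mate, , drop = FALSE] - xc[base, , drop = FALSE])
    }
    add_y[[cl]] <- rep(cl, need)
  }
  if (length(add_x)) {
    x <- rbind(x, do.call(rbind, add_x))
    y <- factor(c(as.character(y), unlist(add_y)), levels = levels(y))
  }
  list(x = x, y = y)
}

#' Random undersampling to balanced class counts
#'
#' Samples `size` rows per class (default: the minority-class count), with
#' replacement by default, mirroring an undersampler configured with
#' `replacement = TRUE`.
#'
#' @param x Numeric matrix.
#' @param y Factor of class labels.
#' @param size Rows to keep per class.
#' @param replace Sample with replacement.
#' @return List with the undersampled `x` and `y`.
#' @export
random_undersample <- function(x, y, size = min(table(droplevels(y))), replace = TRUE) {
  x <- as.matrix(x)
  keep <- unlist(lapply(levels(droplevels(y)), function(cl) {
    idx <- which(y == cl)
    idx[sample.int(length(idx), size, replace = replace)]
  }))
  list(x = x[keep, , drop = FALSE], y = factor(y[keep], levels = levels(y)))
}
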