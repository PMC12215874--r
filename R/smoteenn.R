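# k-nearest-neighbour index lookup, Euclidean, computed in row blocks so the
# full n x n distance matrix is never materialized for large n.
nearest_neighbor_idx <- function(X, k, block = 512L) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- min(k, n - 1L)
  sq <- rowSums(X^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    # squared distances from this block to all points
    d2 <- outer(sq[rows], sq, "+") - 2 * X[rows, , drop = FALSE] %*% t(X)
    for (j in seq_along(rows)) {
      d2[j, rows[j]] <- Inf  # exclude self
      out[rows[j], ] <- order(d2[j, ])[seq_len(k)]
    }
  }
  out
}

#' SMOTE oversampling to class parity
#'
#' Each minority class is oversampled to the majority count with synthetic
#' points `x + gap * (nn - x)`, where `gap ~ U(0,1)` and `nn` is one of the
#' parent's `k` nearest same-class neighbours.
#'
#' @param ds A [tabular_dataset()] with an all-numeric (encoded) feature
#'   matrix.
#' @param k Number of same-class neighbours considered (default 5).
#' @param seed Integer seed.
#' @return A `tabular_dataset` with synthetic rows appended.  Attributes:
#'   `synthetic` (logical row mask) and `synthetic_parents` (data.frame of
#'   parent/neighbour row indices and gaps, for audit).
#' @export
smote_oversample <- function(ds, k = 5L, seed = 1L) {
  X <- as.matrix(ds$X)
  y <- ds$y
  counts <- table(y)
  n_major <- max(counts)
  stream <- new_rng_stream(derive_seed(seed, 101L))

  new_X <- list()
  new_y <- character(0)
  parents <- data.frame(parent = integer(0), neighbor = integer(0), gap = numeric(0))
  for (cl in names(counts)) {
    deficit <- n_major - counts[[cl]]
    if (deficit == 0) next
    idx <- which(y == cl)
    if (length(idx) < 2) {
      stop("too few samples to SMOTE class ", cl, call. = FALSE)
    }
    kk <- min(k, length(idx) - 1L)
    nn <- nearest_neighbor_idx(X[idx, , drop = FALSE], kk)
    for (s in seq_len(deficit)) {
      p <- stream_sample_int(stream, length(idx))
      nb <- nn[p, stream_sample_int(stream, kk)]
      gap <- stream_runif(stream, 1)
      new_X[[length(new_X) + 1L]] <- X[idx[p], ] + gap * (X[idx[nb], ] - X[idx[p], ])
      new_y <- c(new_y, cl)
      parents <- rbind(parents, data.frame(parent = idx[p], neighbor = idx[nb], gap = gap))
    }
  }

  n_orig <- nrow(X)
  if (length(new_X)) {
    X_out <- rbind(X, do.call(rbind, new_X))
  } else {
    X_out <- X
  }
  y_out <- factor(c(as.character(y), new_y), levels = levels(y))
  out <- tabular_dataset(as.data.frame(X_out), y_out, schema = ds$schema,
                         provenance = c(ds$provenance,
                                        sprintf("smote: +%d synthetic (k=%d, seed=%d)",
                                                length(new_y), k, seed)))
  attr(out, "synthetic") <- c(rep(FALSE, n_orig), rep(TRUE, length(new_y)))
  attr(out, "synthetic_parents") <- parents
  out
}

#' Edited-nearest-neighbour cleaning
#'
#' Removes every sample whose label disagrees with the majority label of its
#' `k` nearest neighbours (ties broken by the single nearest neighbour).
#'
#' @param ds A [tabular_dataset()] with numeric features.
#' @param k Neighbourhood size (default 3).
#' @return The cleaned `tabular_dataset`; the logical mask of kept rows is
#'   attached as attribute `kept`.
#' @export
enn_clean <- function(ds, k = 3L) {
  X <- as.matrix(ds$X)
  y <- as.character(ds$y)
  nn <- nearest_neighbor_idx(X, k)
  keep <- vapply(seq_len(nrow(X)), function(i) {
    labs <- y[nn[i, ]]
    tab <- table(labs)
    winners <- names(tab)[tab == max(tab)]
    pred <- if (length(winners) == 1) winners else y[nn[i, 1]]
    pred == y[i]
  }, TRUE)
  out <- subset_rows(ds, which(keep),
                     sprintf("enn: removed %d/%d (k=%d)", sum(!keep), length(keep), k))
  attr(out, "kept") <- keep
  out
}

#' SMOTE-ENN class rebalancing
#'
#' Phase 1 oversamples every minority class to the majority count by SMOTE
#' interpolation; phase 2 applies edited-nearest-neighbour cleaning to the
#' combined set, removing noisy or borderline samples from all classes.
#' Intended for the encoded (standardized, one-hot) training partition.
#'
#' @param ds A [tabular_dataset()] with numeric features.
#' @param k_smote SMOTE neighbourhood size (default 5).
#' @param k_enn ENN neighbourhood size (default 3).
#' @param seed Integer seed.
#' @return The rebalanced `tabular_dataset` with a `balance_counts` attribute
#'   holding the per-class counts before SMOTE, after SMOTE and after ENN.
#' @export
smoteenn_balance <- function(ds, k_smote = 5L, k_enn = 3L, seed = 1L) {
  before <- table(ds$y)
  sm <- smote_oversample(ds, k = k_smote, seed = seed)
  after_smote <- table(sm$y)
  out <- enn_clean(sm, k = k_enn)
  attr(out, "balance_counts") <- list(before = before,
                                      after_smote = after_smote,
                                      after_enn = table(out$y))
  out
}
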