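# Shared fixtures, all generated in code.

# small config for fast optimizer runs
quick_config <- function(...) {
  optimizer_config(n_pop = 10L, n_iter = 20L, ...)
}

# two-class gaussian blobs, linearly separable when delta is large
make_blobs <- function(n_per_class = 30L, d = 4L, delta = 3, seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per_class * d), ncol = d),
             matrix(stats::rnorm(n_per_class * d, mean = delta), ncol = d))
  colnames(X) <- paste0("f", seq_len(d))
  tabular_dataset(as.data.frame(X),
                  rep(c("a", "b"), each = n_per_class))
}

# deterministic error table over all masks of d bits: error depends only on
# whether bit 1 is present, plus a small per-mask deterministic penalty
mask_error_table <- function(d) {
  n_masks <- 2^d
  errors <- numeric(n_masks)
  for (m in seq_len(n_masks) - 1L) {
    bits <- as.integer(intToBits(m)[seq_len(d)])
    errors[m + 1L] <- if (bits[1] == 1L) 0.05 + 0.001 * sum(bits[-1]) else 0.4
  }
  errors
}

mask_key <- function(bits) sum(bits * 2^(seq_along(bits) - 1L))

# stub model spec whose CV error is a pure function of the mask (via a
# lookup objective, bypassing any classifier)
table_fitness_objective <- function(space, errors, alpha) {
  d <- attr(space, "n_mask")
  function(position) {
    enc <- decode(position, space)
    err <- errors[mask_key(enc$feature_mask) + 1L]
    selection_fitness(err, enc$n_selected, d, alpha)
  }
}

# exhaustive optimum of the table fitness over all non-empty masks
exhaustive_table_optimum <- function(errors, d, alpha) {
  best <- Inf
  for (m in seq_len(2^d - 1L)) {
    bits <- as.integer(intToBits(m)[seq_len(d)])
    f <- selection_fitness(errors[m + 1L], sum(bits), d, alpha)
    best <- min(best, f)
  }
  best
}
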