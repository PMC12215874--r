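#' Generator specification for thyroid-like synthetic data
#'
#' Emulates the schema of the thyroid study data: 31 mixed-type attributes
#' (log-normal lab-analyte-like numerics, Bernoulli history-flag-like
#' binaries), a small multiclass target with strong class imbalance, a known
#' informative-feature subset and injectable missingness.
#'
#' @param n_samples Number of rows.
#' @param n_features Number of features (default 31).
#' @param n_classes Number of target classes (default 5).
#' @param class_priors Class prior probabilities (default
#'   `c(0.50, 0.20, 0.15, 0.10, 0.05)`, mirroring the strong imbalance the
#'   rebalancing step presupposes).
#' @param informative_set Integer indices of informative features (default:
#'   the first 6).
#' @param effect_size Class-conditional shift `delta` on the log scale for
#'   informative numeric features (and logit scale for informative binaries).
#' @param missing_rate Fraction of feature cells set missing.
#' @param numeric_fraction Fraction of columns that are numeric (rest binary).
#' @param seed Integer seed.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_samples = 2000L, n_features = 31L, n_classes = 5L,
                           class_priors = NULL, informative_set = 1:6,
                           effect_size = 3, missing_rate = 0,
                           numeric_fraction = 0.45, seed = 1L) {
  if (is.null(class_priors)) {
    class_priors <- if (n_classes == 5) c(0.50, 0.20, 0.15, 0.10, 0.05)
                    else rep(1 / n_classes, n_classes)
  }
  if (length(class_priors) != n_classes) {
    stop("invalid spec: priors length != n_classes", call. = FALSE)
  }
  if (abs(sum(class_priors) - 1) > 1e-12) {
    stop("invalid spec: priors must sum to 1", call. = FALSE)
  }
  if (any(informative_set < 1 | informative_set > n_features)) {
    stop("invalid spec: informative_set outside 1..n_features", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("invalid spec: missing_rate must lie in [0,1)", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 n_classes = as.integer(n_classes),
                 class_priors = class_priors,
                 informative_set = as.integer(informative_set),
                 effect_size = effect_size,
                 missing_rate = missing_rate,
                 numeric_fraction = numeric_fraction,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a thyroid-like synthetic dataset
#'
#' Labels are drawn from the class priors.  Informative numeric features get
#' class-conditional mean shifts of `delta * offset(class)` on the log scale
#' (log-normal marginals, mimicking the right-skew of analytes such as TSH);
#' informative binary features get class-dependent Bernoulli rates through a
#' logistic link; non-informative features are label-independent noise.
#' Missing cells are injected uniformly at `missing_rate`.  Bit-identical
#' output for identical spec + seed.
#'
#' @param spec A [generator_spec()].
#' @return An object of class `synthetic_dataset`: list with `dataset`
#'   (a [tabular_dataset()]), `true_informative_mask` (0/1 vector) and the
#'   generating `spec`.
#' @export
generate_thyroid_like <- function(spec = generator_spec()) {
  n <- spec$n_samples
  d <- spec$n_features
  k <- spec$n_classes
  stream <- new_rng_stream(derive_seed(spec$seed, 301L))

  classes <- paste0("class_", seq_len(k))
  u <- stream_runif(stream, n)
  y <- classes[findInterval(u, cumsum(spec$class_priors)) + 1L]

  n_num <- max(1L, round(spec$numeric_fraction * d))
  kinds <- rep(c("numeric", "binary"), c(n_num, d - n_num))
  # interleave so informative indices cover both types
  kinds <- kinds[order(stream_runif(stream, d))]

  # per-class offsets spread over [-1, 1]; each informative feature gets its
  # own random class ordering so no single feature separates all classes
  base_offsets <- if (k > 1) 2 * (seq_len(k) - 1) / (k - 1) - 1 else 0

  X <- vector("list", d)
  informative <- seq_len(d) %in% spec$informative_set
  class_idx <- match(y, classes)
  for (j in seq_len(d)) {
    if (informative[j]) {
      perm <- stream_sample_int(stream, k, size = k)
      offsets <- base_offsets[perm]
    } else {
      offsets <- rep(0, k)
    }
    shift <- spec$effect_size * offsets[class_idx]
    if (kinds[j] == "numeric") {
      mu <- stream_rnorm(stream, 1, 0, 0.5)
      X[[j]] <- exp(mu + shift + stream_rnorm(stream, n))
    } else {
      p <- stats::plogis(shift + stream_rnorm(stream, 1, 0, 0.25))
      X[[j]] <- as.numeric(stream_runif(stream, n) < p)
    }
  }
  names(X) <- sprintf("%s_%02d", ifelse(kinds == "numeric", "lab", "flag"), seq_len(d))
  X <- as.data.frame(X)

  if (spec$missing_rate > 0) {
    n_cells <- n * d
    n_miss <- round(spec$missing_rate * n_cells)
    cells <- stream_sample_int(stream, n_cells, size = n_miss)
    for (cell in cells) {
      X[[(cell - 1L) %/% n + 1L]][(cell - 1L) %% n + 1L] <- NA
    }
  }

  ds <- tabular_dataset(X, y, provenance = sprintf(
    "generate_thyroid_like: n=%d d=%d k=%d delta=%g missing=%g seed=%d",
    n, d, k, spec$effect_size, spec$missing_rate, spec$seed))
  structure(list(dataset = ds,
                 true_informative_mask = as.integer(informative),
                 spec = spec),
            class = "synthetic_dataset")
}

#' Deterministic separable toy dataset
#'
#' Labels are a deterministic function of a small set of referenced features,
#' for mask-enumeration oracle tests.  The default rule thresholds feature 1
#' at 0.
#'
#' @param d Number of features.
#' @param rule Either a list `list(feature =, threshold =)` (label = feature
#'   above threshold) or a function `function(X) labels` with an attribute
#'   `"features"` naming the feature indices it uses.
#' @param n Number of rows.
#' @param seed Integer seed.
#' @return A `synthetic_dataset` whose `true_informative_mask` marks the
#'   rule's features.
#' @export
make_separable_toy <- function(d = 8L, rule = list(feature = 1L, threshold = 0),
                               n = 200L, seed = 1L) {
  stream <- new_rng_stream(derive_seed(seed, 401L))
  X <- as.data.frame(matrix(stream_rnorm(stream, n * d), nrow = n))
  names(X) <- sprintf("x%02d", seq_len(d))
  if (is.function(rule)) {
    feats <- attr(rule, "features")
    if (is.null(feats)) stop("rule function needs a 'features' attribute", call. = FALSE)
    if (any(feats > d)) stop("invalid rule: references an absent feature", call. = FALSE)
    y <- rule(X)
  } else {
    if (rule$feature > d) stop("invalid rule: references an absent feature", call. = FALSE)
    feats <- rule$feature
    y <- ifelse(X[[rule$feature]] > rule$threshold, "pos", "neg")
  }
  mask <- as.integer(seq_len(d) %in% feats)
  ds <- tabular_dataset(X, y, provenance = sprintf("make_separable_toy: d=%d n=%d seed=%d", d, n, seed))
  structure(list(dataset = ds, true_informative_mask = mask,
                 spec = list(d = d, n = n, seed = seed)),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset's ground-truth mask to JSON
#'
#' @param sd A `synthetic_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(sd, path) {
  jsonlite::write_json(list(true_informative_mask = sd$true_informative_mask,
                            feature_names = names(sd$dataset$X)),
                       path, auto_unbox = TRUE)
  invisible(path)
}
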