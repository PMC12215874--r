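#' Perturbation specification for robustness analysis
#'
#' The stress protocol: controlled missingness (5/10/20% of feature cells
#' deleted), Gaussian feature noise (`sigma = 0.01` on the standardized
#' scale), or induced class imbalance (non-majority classes subsampled).
#'
#' @param mode One of `"missing"`, `"noise"`, `"imbalance"`.
#' @param magnitude Missing-cell fraction, noise sd, or imbalance fraction
#'   (non-majority classes keep `1 - magnitude` of their rows).
#' @param seed Integer seed.
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(mode = c("missing", "noise", "imbalance"),
                              magnitude, seed = 1L) {
  mode <- match.arg(mode)
  # sigma = 0 is a legal no-op for the noise mode; fractions must be positive
  if (magnitude < 0 || (magnitude == 0 && mode != "noise")) {
    stop("invalid spec: magnitude must be positive", call. = FALSE)
  }
  if (mode %in% c("missing", "imbalance") && magnitude >= 1) {
    stop("invalid spec: fractions must be below 1", call. = FALSE)
  }
  structure(list(mode = mode, magnitude = magnitude, seed = as.integer(seed)),
            class = "perturbation_spec")
}

#' Apply a controlled perturbation to a dataset
#'
#' `missing`: exactly `round(fraction * n_cells)` feature cells (the label is
#' never touched) are set missing uniformly at random.  `noise`: i.i.d.
#' Gaussian noise of sd `sigma` is added to every numeric cell on the
#' standardized scale (i.e. scaled by each column's sd, so `sigma` is
#' scale-free).  `imbalance`: every non-majority class is subsampled to
#' `1 - magnitude` of its original count.  Deterministic given the spec seed.
#'
#' @param ds A [tabular_dataset()].
#' @param spec A [perturbation_spec()].
#' @return The perturbed `tabular_dataset`.
#' @export
perturb_dataset <- function(ds, spec) {
  stream <- new_rng_stream(derive_seed(spec$seed, 501L))
  if (spec$mode == "missing") {
    n <- nrow(ds$X)
    d <- ncol(ds$X)
    n_miss <- round(spec$magnitude * n * d)
    cells <- stream_sample_int(stream, n * d, size = n_miss)
    X <- ds$X
    for (cell in cells) {
      X[[(cell - 1L) %/% n + 1L]][(cell - 1L) %% n + 1L] <- NA
    }
    return(tabular_dataset(X, ds$y, schema = ds$schema,
                           provenance = c(ds$provenance,
                                          sprintf("perturb: %d cells set missing", n_miss))))
  }
  if (spec$mode == "noise") {
    X <- ds$X
    for (nm in names(X)) {
      if (!is.numeric(X[[nm]])) next
      s <- stats::sd(X[[nm]])
      if (!is.finite(s) || s == 0) s <- 1
      X[[nm]] <- X[[nm]] + stream_rnorm(stream, nrow(X), 0, spec$magnitude * s)
    }
    return(tabular_dataset(X, ds$y, schema = ds$schema,
                           provenance = c(ds$provenance,
                                          sprintf("perturb: gaussian noise sigma=%g", spec$magnitude))))
  }
  # imbalance: subsample every non-majority class
  counts <- table(ds$y)
  major <- names(counts)[which.max(counts)]
  keep <- integer(0)
  for (cl in names(counts)) {
    idx <- which(ds$y == cl)
    if (cl == major) {
      keep <- c(keep, idx)
    } else {
      n_keep <- max(2L, round(length(idx) * (1 - spec$magnitude)))
      keep <- c(keep, idx[stream_sample_int(stream, length(idx), size = n_keep)])
    }
  }
  subset_rows(ds, sort(keep),
              sprintf("perturb: imbalance, non-majority classes kept at %g%%",
                      100 * (1 - spec$magnitude)))
}

#' Robustness scan over perturbation conditions
#'
#' Runs the configured pipeline unperturbed (baseline) and once per
#' condition, applying each perturbation to the raw data before
#' preprocessing so the pipeline's own imputation is exercised.  Per-condition
#' failures are recorded, not fatal.
#'
#' @param config A [pipeline_config()].
#' @param conditions List of [perturbation_spec()]s (default: the study's
#'   five conditions).
#' @return An object of class `robustness_report`: list with `baseline`, the
#'   per-condition `runs`, and `table` (a condition x metrics data.frame).
#' @export
robustness_scan <- function(config, conditions = default_robustness_conditions(config$seed)) {
  baseline <- run_experiment(config)
  rows <- metrics_row(baseline$metrics, condition = "baseline")
  runs <- list()
  for (i in seq_along(conditions)) {
    sp <- conditions[[i]]
    label <- sprintf("%s_%g", sp$mode, sp$magnitude)
    res <- tryCatch({
      cfg <- config
      cfg$perturbation <- sp
      run_experiment(cfg)
    }, error = function(e) e)
    runs[[label]] <- res
    if (inherits(res, "error")) {
      row <- metrics_row(baseline$metrics, condition = label)
      row[, -1] <- NA_real_
      rows <- rbind(rows, row)
    } else {
      rows <- rbind(rows, metrics_row(res$metrics, condition = label))
    }
  }
  structure(list(baseline = baseline, runs = runs, table = rows,
                 conditions = conditions),
            class = "robustness_report")
}

#' The study's five stress conditions
#'
#' 5/10/20% missing cells, Gaussian noise `sigma = 0.01`, and 50% class
#' imbalance.
#'
#' @param seed Integer seed shared by the condition specs.
#' @return List of [perturbation_spec()]s.
#' @export
default_robustness_conditions <- function(seed = 1L) {
  list(perturbation_spec("missing", 0.05, seed),
       perturbation_spec("missing", 0.10, seed),
       perturbation_spec("missing", 0.20, seed),
       perturbation_spec("noise", 0.01, seed),
       perturbation_spec("imbalance", 0.5, seed))
}
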