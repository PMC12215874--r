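#' Joint feature selection and hyperparameter tuning
#'
#' Builds the joint search space (one mask dimension per feature plus the
#' classifier's hyperparameter dimensions), minimizes the wrapper fitness
#' with the selected swarm algorithm, and returns the decoded elitist best.
#' Fitness evaluations are memoized on the decoded encoding, which is exact
#' because the cross-validated error is deterministic given `spec$seed`.
#'
#' @param ds A preprocessed, numeric [tabular_dataset()] with >= 2 classes
#'   and >= 2 features.
#' @param spec A [fitness_spec()].
#' @param opt_config An [optimizer_config()].
#' @param algorithm One of `"psso"`, `"so"`, `"pso"`.
#' @return An object of class `selection_result`: `feature_mask`,
#'   `selected_features`, `hyperparams`, `fitness`, `cv_error`, `n_selected`,
#'   `n_total`, `trace`, `evaluations`, `seed`, `algorithm`.
#' @export
select_and_tune <- function(ds, spec = fitness_spec(),
                            opt_config = optimizer_config(),
                            algorithm = c("psso", "so", "pso")) {
  algorithm <- match.arg(algorithm)
  if (nlevels(ds$y) < 2) stop("need at least 2 classes", call. = FALSE)
  if (ncol(ds$X) < 2) stop("need at least 2 features", call. = FALSE)
  model_id <- if (is.character(spec$model)) spec$model else NULL
  space <- search_space(names(ds$X), model_id)
  if (is.function(spec$model)) {
    # custom model functions carry no tunable dimensions; mask-only space
    space <- search_space(names(ds$X), NULL)
  }
  bounds <- attr(space, "bounds")

  cache <- new.env(parent = emptyenv())
  objective <- function(position) {
    enc <- decode(position, space)
    key <- paste(c(enc$feature_mask, unlist(enc$hyperparams)), collapse = "|")
    hit <- get0(key, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit$fitness)
    res <- wrapper_fitness(ds, enc, spec)
    assign(key, res, envir = cache)
    res$fitness
  }

  opt <- optimize_swarm(objective, bounds, opt_config, algorithm)
  enc <- decode(opt$best_position, space)
  audit <- wrapper_fitness(ds, enc, spec)

  structure(list(feature_mask = enc$feature_mask,
                 selected_features = names(ds$X)[enc$feature_mask == 1L],
                 hyperparams = enc$hyperparams,
                 fitness = audit$fitness,
                 cv_error = audit$error,
                 n_selected = enc$n_selected,
                 n_total = audit$n_total,
                 alpha = spec$alpha,
                 trace = opt$trace,
                 evaluations = opt$evaluations,
                 seed = opt_config$seed,
                 algorithm = algorithm),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result (%s): %d/%d features, cv error %.4f, fitness %.6f>\n",
              x$algorithm, x$n_selected, x$n_total, x$cv_error, x$fitness))
  cat("  selected:", paste(x$selected_features, collapse = ", "), "\n")
  if (length(x$hyperparams)) {
    cat("  hyperparameters:",
        paste(names(x$hyperparams), vapply(x$hyperparams, format, ""),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' @param x A `selection_result`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
selection_to_json <- function(x, path = NULL) {
  payload <- x[c("feature_mask", "selected_features", "hyperparams", "fitness",
                 "cv_error", "n_selected", "n_total", "alpha", "trace",
                 "seed", "algorithm")]
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Jaccard index of two feature sets
#'
#' @param a,b Character vectors (or 0/1 masks of equal length).
#' @return `|intersection| / |union|` (1 when both are empty).
#' @export
jaccard_index <- function(a, b) {
  if (is.numeric(a) && is.numeric(b)) {
    a <- which(a == 1)
    b <- which(b == 1)
  }
  u <- union(a, b)
  if (!length(u)) return(1)
  length(intersect(a, b)) / length(u)
}
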