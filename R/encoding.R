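#' Search-space dimension specification
#'
#' @param name Dimension identifier.
#' @param kind One of `"mask"` (feature-selection bit, raw box `(0,1)`),
#'   `"integer"`, `"continuous"`, `"log_continuous"` (raw box `(1,100)` mapped
#'   to `native_bounds`).
#' @param native_bounds Length-2 numeric `(lower, upper)` for non-mask kinds.
#' @return An object of class `dim_spec`.
#' @export
dim_spec <- function(name, kind = c("mask", "integer", "continuous", "log_continuous"),
                     native_bounds = NULL) {
  kind <- match.arg(kind)
  raw_bounds <- if (kind == "mask") c(0, 1) else c(1, 100)
  if (kind != "mask") {
    stopifnot(length(native_bounds) == 2, native_bounds[1] < native_bounds[2])
    if (kind == "log_continuous") stopifnot(native_bounds[1] > 0)
  }
  structure(list(name = name, kind = kind, raw_bounds = raw_bounds,
                 native_bounds = native_bounds),
            class = "dim_spec")
}

# hyperparameter dimensions per classifier; native ranges map the raw [1,100]
# box onto conventional values for each model family
model_hyperparam_dims <- function(model_id) {
  switch(model_id,
    rf = list(dim_spec("num_trees", "integer", c(1, 100)),
              dim_spec("max_depth", "integer", c(1, 100))),
    dt = list(dim_spec("max_depth", "integer", c(1, 30)),  # rpart caps depth at 30
              dim_spec("min_split", "integer", c(2, 100))),
    svm = list(dim_spec("cost", "log_continuous", c(1e-2, 1e3)),
               dim_spec("gamma", "log_continuous", c(1e-4, 1e1))),
    knn = list(dim_spec("k", "integer", c(1, 100)),
               dim_spec("distance_weighted", "mask")),
    stop("unknown model: ", model_id, call. = FALSE)
  )
}

#' Build the joint feature-mask + hyperparameter search space
#'
#' One mask dimension per feature followed by the model's hyperparameter
#' dimensions.
#'
#' @param feature_names Character vector of feature names.
#' @param model_id One of `"rf"`, `"dt"`, `"svm"`, `"knn"`, or `NULL` for a
#'   mask-only space.
#' @return A list of [dim_spec()] objects with a `bounds` attribute giving the
#'   raw optimizer box as a [bounds_spec()].
#' @export
search_space <- function(feature_names, model_id = NULL) {
  dims <- lapply(feature_names, function(nm) dim_spec(paste0("mask_", nm), "mask"))
  if (!is.null(model_id)) dims <- c(dims, model_hyperparam_dims(model_id))
  lo <- vapply(dims, function(d) d$raw_bounds[1], 0)
  hi <- vapply(dims, function(d) d$raw_bounds[2], 0)
  attr(dims, "bounds") <- bounds_spec(lo, hi, length(dims))
  attr(dims, "n_mask") <- length(feature_names)
  attr(dims, "feature_names") <- feature_names
  dims
}

round_half_up <- function(x) floor(x + 0.5)

#' Decode an optimizer position into a solution encoding
#'
#' Mask dimensions become bits (1 iff raw value >= 0.5; an all-zero mask is
#' repaired by switching on the dimension with the largest raw value).
#' Integer dimensions are affinely mapped from the raw `[1,100]` box to their
#' native bounds and rounded half up; `log_continuous` dimensions map to
#' `10^(lo + (raw-1)/99 * (hi-lo))` with `(lo, hi)` the log10 native bounds.
#'
#' @param position Numeric vector, one entry per dimension of `space`.
#' @param space A [search_space()].
#' @return An object of class `solution_encoding`: list with `feature_mask`
#'   (0/1 integer vector over the mask dims), `hyperparams` (named list of
#'   native values), `n_selected`.
#' @export
decode <- function(position, space) {
  if (length(position) != length(space)) {
    stop("invalid position: length ", length(position),
         " does not match the ", length(space), "-dim space", call. = FALSE)
  }
  n_mask <- attr(space, "n_mask")
  mask_raw <- position[seq_len(n_mask)]
  mask <- as.integer(mask_raw >= 0.5)
  if (n_mask > 0 && sum(mask) == 0) {
    mask[which.max(mask_raw)] <- 1L  # repair: keep the strongest candidate bit
  }
  hyper <- list()
  if (length(space) > n_mask) {
    for (j in (n_mask + 1L):length(space)) {
      d <- space[[j]]
      raw <- position[j]
      hyper[[d$name]] <- switch(d$kind,
        mask = as.integer(raw >= 0.5),
        integer = {
          nb <- d$native_bounds
          v <- nb[1] + (raw - 1) / 99 * (nb[2] - nb[1])
          as.integer(min(max(round_half_up(v), nb[1]), nb[2]))
        },
        continuous = {
          nb <- d$native_bounds
          min(max(nb[1] + (raw - 1) / 99 * (nb[2] - nb[1]), nb[1]), nb[2])
        },
        log_continuous = {
          lb <- log10(d$native_bounds)
          10^(lb[1] + (raw - 1) / 99 * (lb[2] - lb[1]))
        })
    }
  }
  structure(list(feature_mask = mask, hyperparams = hyper,
                 n_selected = sum(mask)),
            class = "solution_encoding")
}
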