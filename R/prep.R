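#' Tabular dataset container
#'
#' The unit flowing through preprocessing, balancing and model fitting: a
#' feature table `X`, a label factor `y`, a per-column schema and a free-text
#' provenance log.
#'
#' @param X A data.frame of features (numeric / binary / categorical columns).
#' @param y Label vector (coerced to factor), one entry per row of `X`.
#' @param schema Optional list of per-column entries
#'   `list(name=, kind=, categories=)` with kind one of `"numeric"`,
#'   `"binary"`, `"categorical"`; inferred from the column classes if omitted.
#' @param provenance Character vector of free-text processing notes.
#' @return An object of class `tabular_dataset`.
#' @export
tabular_dataset <- function(X, y, schema = NULL, provenance = character()) {
  X <- as.data.frame(X)
  if (nrow(X) != length(y)) stop("X and y row counts differ", call. = FALSE)
  y <- factor(y)
  if (is.null(schema)) schema <- infer_schema(X)
  structure(list(X = X, y = y, schema = schema, provenance = provenance),
            class = "tabular_dataset")
}

infer_schema <- function(X) {
  lapply(names(X), function(nm) {
    col <- X[[nm]]
    if (is.numeric(col)) {
      vals <- unique(col[!is.na(col)])
      kind <- if (length(vals) <= 2 && all(vals %in% c(0, 1))) "binary" else "numeric"
      list(name = nm, kind = kind, categories = NULL)
    } else {
      lv <- sort(unique(as.character(col[!is.na(col)])))
      kind <- if (length(lv) <= 2) "binary" else "categorical"
      list(name = nm, kind = kind, categories = lv)
    }
  })
}

#' @export
print.tabular_dataset <- function(x, ...) {
  cat(sprintf("<tabular_dataset: %d samples x %d features, %d classes>\n",
              nrow(x$X), ncol(x$X), nlevels(x$y)))
  print(table(x$y))
  invisible(x)
}

#' @export
dim.tabular_dataset <- function(x) dim(x$X)

subset_rows <- function(ds, idx, note = NULL) {
  tabular_dataset(ds$X[idx, , drop = FALSE], droplevels(ds$y[idx]),
                  schema = ds$schema,
                  provenance = c(ds$provenance, note))
}

#' Clean and impute a tabular dataset
#'
#' Rows with more than half their feature cells missing are dropped; remaining
#' numeric gaps are filled with the column mean and binary/categorical gaps
#' with the column mode; exact duplicate rows (features and label) are
#' removed.  Counts of dropped rows and imputed cells are appended to the
#' provenance log.  Idempotent on clean data.
#'
#' @param ds A [tabular_dataset()].
#' @return A cleaned `tabular_dataset` with no missing values.
#' @export
clean_impute <- function(ds) {
  X <- ds$X
  all_missing <- vapply(X, function(col) all(is.na(col)), TRUE)
  if (any(all_missing)) {
    stop("unimputable column(s): ", paste(names(X)[all_missing], collapse = ", "),
         call. = FALSE)
  }
  miss_frac <- rowMeans(is.na(X))
  keep <- miss_frac <= 0.5
  n_dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]
  y <- ds$y[keep]

  n_imputed <- 0L
  for (nm in names(X)) {
    na <- is.na(X[[nm]])
    if (!any(na)) next
    n_imputed <- n_imputed + sum(na)
    if (is.numeric(X[[nm]])) {
      X[[nm]][na] <- mean(X[[nm]], na.rm = TRUE)
    } else {
      tab <- table(as.character(X[[nm]]))
      X[[nm]][na] <- names(tab)[which.max(tab)]
    }
  }

  dup <- duplicated(cbind(X, .label = as.character(y)))
  n_dup <- sum(dup)
  X <- X[!dup, , drop = FALSE]
  y <- y[!dup]
  rownames(X) <- NULL

  tabular_dataset(X, droplevels(y), schema = ds$schema,
                  provenance = c(ds$provenance,
                                 sprintf("clean_impute: dropped %d rows (>50%% missing), imputed %d cells, removed %d duplicates",
                                         n_dropped, n_imputed, n_dup)))
}

#' Stratified train/test split
#'
#' Per-class proportions are preserved within one sample; assignment is
#' deterministic given `seed`.
#'
#' @param ds A [tabular_dataset()].
#' @param fraction Training fraction (default 0.8, the study's 80/20 split).
#' @param seed Integer seed.
#' @return List of class `split_pair` with `train`, `test`, `fraction` and the
#'   integer `train_idx` used.
#' @export
split_train_test <- function(ds, fraction = 0.8, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  counts <- table(ds$y)
  if (any(counts < 2)) {
    stop("unsplittable class(es) with a single member: ",
         paste(names(counts)[counts < 2], collapse = ", "), call. = FALSE)
  }
  stream <- new_rng_stream(seed)
  train_idx <- integer(0)
  for (cl in names(counts)) {
    idx <- which(ds$y == cl)
    n_tr <- round(length(idx) * fraction)
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)  # both sides non-empty
    pick <- stream_sample_int(stream, length(idx), size = n_tr)
    train_idx <- c(train_idx, idx[pick])
  }
  train_idx <- sort(train_idx)
  note <- sprintf("split_train_test: fraction=%g seed=%d", fraction, seed)
  structure(list(train = subset_rows(ds, train_idx, note),
                 test = subset_rows(ds, setdiff(seq_along(ds$y), train_idx), note),
                 fraction = fraction,
                 train_idx = train_idx),
            class = "split_pair")
}

#' Fit column transforms on a training set
#'
#' Numeric columns get standardization parameters (mean, sd; a zero-variance
#' column is scaled by 1 and flagged); categorical columns get their
#' train-observed category set for one-hot expansion; binary columns are
#' mapped to 0/1.
#'
#' @param train A clean (no missing values) [tabular_dataset()].
#' @return An object of class `column_transform`.
#' @export
fit_column_transform <- function(train) {
  fits <- lapply(train$schema, function(sc) {
    col <- train$X[[sc$name]]
    if (sc$kind == "numeric") {
      m <- mean(col)
      # population sd: a two-point column [0, 2] maps to [-1, 1]
      s <- sqrt(mean((col - m)^2))
      zero_var <- !is.finite(s) || s == 0
      if (zero_var) s <- 1
      list(name = sc$name, kind = "numeric", mean = m, sd = s, zero_variance = zero_var)
    } else if (sc$kind == "categorical") {
      list(name = sc$name, kind = "categorical",
           categories = sort(unique(as.character(col))))
    } else {
      lv <- sort(unique(as.character(col)))
      list(name = sc$name, kind = "binary", levels = lv)
    }
  })
  structure(list(fits = fits), class = "column_transform")
}

apply_column_transform <- function(fit, ds) {
  out <- list()
  for (f in fit$fits) {
    col <- ds$X[[f$name]]
    if (is.null(col)) stop("column missing from dataset: ", f$name, call. = FALSE)
    if (f$kind == "numeric") {
      out[[f$name]] <- (col - f$mean) / f$sd
    } else if (f$kind == "binary") {
      if (is.numeric(col)) {
        out[[f$name]] <- as.numeric(col)
      } else {
        out[[f$name]] <- as.numeric(as.character(col) == f$levels[length(f$levels)])
      }
    } else {
      ch <- as.character(col)
      for (cat in f$categories) {
        out[[paste(f$name, cat, sep = "_")]] <- as.numeric(ch == cat)
      }
      # unseen test categories map to all-zero across the block
    }
  }
  X <- as.data.frame(out, check.names = FALSE)
  schema <- lapply(names(X), function(nm) list(name = nm, kind = "numeric", categories = NULL))
  res <- tabular_dataset(X, ds$y, schema = schema,
                         provenance = c(ds$provenance, "transform_columns: standardized + one-hot"))
  attr(res, "transform") <- fit
  res
}

#' Standardize and one-hot encode using train-only statistics
#'
#' Fits on `train` and applies to `apply_to` (defaults to `train` itself).
#' Test-set statistics are never consulted; unseen test categories encode to
#' an all-zero block.  The fitted parameters are attached as the
#' `"transform"` attribute of the result.
#'
#' @param train Training [tabular_dataset()] (fit source).
#' @param apply_to Dataset to transform (default `train`).
#' @param fit Optional pre-fitted [fit_column_transform()] object.
#' @return The transformed `tabular_dataset` (all columns numeric).
#' @export
transform_columns <- function(train, apply_to = train, fit = NULL) {
  if (is.null(fit)) fit <- fit_column_transform(train)
  apply_column_transform(fit, apply_to)
}

#' Read a CSV dataset with an optional YAML schema sidecar
#'
#' The sidecar maps column names to kinds (`numeric`, `binary`,
#' `categorical`, `label`); without one, the label column must be named and
#' kinds are inferred.
#'
#' @param csv_path Path to a header CSV.
#' @param schema_path Optional YAML sidecar path.
#' @param label Label column name (default `"class"`; overridden by a
#'   `label`-kind column in the sidecar).
#' @return A [tabular_dataset()].
#' @export
read_dataset_csv <- function(csv_path, schema_path = NULL, label = "class") {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  schema <- NULL
  if (!is.null(schema_path)) {
    sc <- yaml::read_yaml(schema_path)
    kinds <- unlist(sc)
    lab <- names(kinds)[kinds == "label"]
    if (length(lab) == 1) label <- lab
    feature_names <- setdiff(names(kinds), label)
    schema <- lapply(feature_names, function(nm) {
      col <- df[[nm]]
      cats <- if (kinds[[nm]] == "categorical") sort(unique(as.character(col[!is.na(col)]))) else NULL
      list(name = nm, kind = unname(kinds[[nm]]), categories = cats)
    })
    df <- df[, c(feature_names, label)]
  }
  if (!label %in% names(df)) stop("label column not found: ", label, call. = FALSE)
  y <- df[[label]]
  X <- df[, setdiff(names(df), label), drop = FALSE]
  tabular_dataset(X, y, schema = schema,
                  provenance = sprintf("read_dataset_csv: %s", csv_path))
}

#' Write a dataset as CSV plus a YAML schema sidecar
#'
#' @param ds A [tabular_dataset()].
#' @param csv_path Output CSV path.
#' @param schema_path Optional YAML sidecar path.
#' @param label Name used for the label column.
#' @return `csv_path`, invisibly.
#' @export
write_dataset_csv <- function(ds, csv_path, schema_path = NULL, label = "class") {
  df <- cbind(ds$X, stats::setNames(data.frame(as.character(ds$y)), label))
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(schema_path)) {
    kinds <- c(stats::setNames(lapply(ds$schema, `[[`, "kind"),
                               vapply(ds$schema, `[[`, "", "name")),
               stats::setNames(list("label"), label))
    yaml::write_yaml(kinds, schema_path)
  }
  invisible(csv_path)
}
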