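#' Fitness specification for wrapper feature selection
#'
#' The selection objective balances cross-validated classification error
#' against subset size:
#' `fitness = alpha * error + (1 - alpha) * n_selected / n_total`,
#' with `error = 1 - mean CV accuracy` over seeded stratified folds.
#'
#' @param alpha Trade-off weight in `(0,1)`; default 0.99 (accuracy
#'   dominates).
#' @param model One of `"rf"`, `"dt"`, `"svm"`, `"knn"`, or a function
#'   `function(X_train, y_train, X_test, hyper)` returning predicted labels
#'   (useful for stubs and oracles).
#' @param cv_folds Number of stratified CV folds (default 5).
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   fits.
#' @return An object of class `fitness_spec`.
#' @export
fitness_spec <- function(alpha = 0.99, model = "rf", cv_folds = 5L, seed = 1L) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0,1)", call. = FALSE)
  structure(list(alpha = alpha, model = model, cv_folds = as.integer(cv_folds),
                 seed = as.integer(seed)),
            class = "fitness_spec")
}

#' Selection fitness from its components
#'
#' @param error Classification error in `[0,1]`.
#' @param n_selected,n_total Selected and total feature counts.
#' @param alpha Trade-off weight.
#' @return `alpha * error + (1 - alpha) * n_selected / n_total`.
#' @export
selection_fitness <- function(error, n_selected, n_total, alpha) {
  alpha * error + (1 - alpha) * n_selected / n_total
}

# deterministic stratified fold assignment: shuffle within class, deal
# round-robin so every fold sees every class where possible
stratified_folds <- function(y, k, seed) {
  stream <- new_rng_stream(derive_seed(seed, 211L))
  folds <- integer(length(y))
  offset <- 0L
  for (cl in levels(factor(y))) {
    idx <- which(y == cl)
    perm <- idx[stream_sample_int(stream, length(idx), size = length(idx))]
    folds[perm] <- ((seq_along(perm) - 1L + offset) %% k) + 1L
    offset <- offset + length(perm)  # stagger so small classes spread evenly
  }
  folds
}

# k-nearest-neighbour classifier over a compiled brute-force kernel with
# deterministic tie-breaking (installed knn implementations break distance
# and vote ties randomly, which would defeat the seeded-reproducibility
# contract of the wrapper fitness)
knn_predict <- function(X_train, y_train, X_test, k, weighted = FALSE) {
  yf <- factor(y_train)
  codes <- .knn_predict_codes(as.matrix(X_train), as.integer(yf),
                              as.matrix(X_test), as.integer(k),
                              isTRUE(weighted), nlevels(yf))
  levels(yf)[codes]
}

# fit the requested classifier on (X_train, y_train) and predict X_test labels
fit_predict <- function(model, hyper, X_train, y_train, X_test, seed = 1L) {
  if (is.function(model)) return(as.character(model(X_train, y_train, X_test, hyper)))
  X_train <- as.data.frame(X_train)
  X_test <- as.data.frame(X_test)
  y_train <- factor(y_train)
  switch(model,
    rf = {
      fit <- ranger::ranger(x = X_train, y = y_train,
                            num.trees = hyper$num_trees %||% 100L,
                            max.depth = hyper$max_depth %||% 0L,
                            seed = seed, num.threads = 1)
      as.character(stats::predict(fit, data = X_test)$predictions)
    },
    dt = {
      df <- cbind(X_train, .y = y_train)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = hyper$max_depth %||% 30L,
                            minsplit = hyper$min_split %||% 20L,
                            cp = 0, xval = 0))
      as.character(stats::predict(fit, newdata = X_test, type = "class"))
    },
    svm = {
      fit <- e1071::svm(x = as.matrix(X_train), y = y_train, kernel = "radial",
                        cost = hyper$cost %||% 1,
                        gamma = hyper$gamma %||% (1 / ncol(X_train)),
                        scale = FALSE)
      as.character(stats::predict(fit, as.matrix(X_test)))
    },
    knn = knn_predict(X_train, y_train, X_test,
                      k = hyper$k %||% 5L,
                      weighted = isTRUE((hyper$distance_weighted %||% 0L) == 1L)),
    stop("unknown model: ", model, call. = FALSE)
  )
}

# class-membership scores for ROC curves (vote fractions / probabilities)
fit_predict_scores <- function(model, hyper, X_train, y_train, X_test, seed = 1L) {
  y_train <- factor(y_train)
  classes <- levels(y_train)
  X_train <- as.data.frame(X_train)
  X_test <- as.data.frame(X_test)
  scores <- switch(model,
    rf = {
      fit <- ranger::ranger(x = X_train, y = y_train,
                            num.trees = hyper$num_trees %||% 100L,
                            max.depth = hyper$max_depth %||% 0L,
                            probability = TRUE, seed = seed, num.threads = 1)
      stats::predict(fit, data = X_test)$predictions
    },
    dt = {
      df <- cbind(X_train, .y = y_train)
      fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = hyper$max_depth %||% 30L,
                            minsplit = hyper$min_split %||% 20L,
                            cp = 0, xval = 0))
      stats::predict(fit, newdata = X_test, type = "prob")
    },
    svm = {
      fit <- e1071::svm(x = as.matrix(X_train), y = y_train, kernel = "radial",
                        cost = hyper$cost %||% 1,
                        gamma = hyper$gamma %||% (1 / ncol(X_train)),
                        probability = TRUE, scale = FALSE)
      attr(stats::predict(fit, as.matrix(X_test), probability = TRUE), "probabilities")
    },
    knn = {
      # vote-fraction scores from the internal knn
      k <- min(hyper$k %||% 5L, nrow(X_train))
      Xtr <- as.matrix(X_train); Xte <- as.matrix(X_test)
      sq_tr <- rowSums(Xtr^2)
      out <- matrix(0, nrow(Xte), length(classes),
                    dimnames = list(NULL, classes))
      for (j in seq_len(nrow(Xte))) {
        d2 <- sq_tr - 2 * drop(Xtr %*% Xte[j, ]) + sum(Xte[j, ]^2)
        ord <- order(d2)[seq_len(k)]
        tab <- table(factor(as.character(y_train)[ord], levels = classes))
        out[j, ] <- as.numeric(tab) / k
      }
      out
    },
    stop("unknown model: ", model, call. = FALSE))
  scores <- as.matrix(scores)
  scores[, classes, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a classifier and predict test labels
#'
#' Thin exported front end over the model backends used by the wrapper
#' fitness: `"rf"` (ranger), `"dt"` (rpart), `"svm"` (e1071, RBF kernel),
#' `"knn"` (class::knn / internal distance-weighted variant), or a custom
#' function `function(X_train, y_train, X_test, hyper)`.
#'
#' @param model Model id or function.
#' @param hyper Named list of native hyperparameters (missing entries take
#'   the model's defaults).
#' @param X_train,X_test Numeric feature tables.
#' @param y_train Training labels.
#' @param seed Seed passed to stochastic fitters.
#' @return Character vector of predicted labels for `X_test`.
#' @export
predict_with_model <- function(model, hyper, X_train, y_train, X_test, seed = 1L) {
  fit_predict(model, hyper, X_train, y_train, X_test, seed = seed)
}

#' Cross-validated wrapper fitness of a solution encoding
#'
#' Evaluates the encoded feature subset and hyperparameters by seeded
#' stratified k-fold cross-validation on `ds`, then combines the error with
#' the parsimony term via [selection_fitness()].  Deterministic given
#' `spec$seed`.
#'
#' @param ds A preprocessed [tabular_dataset()] (numeric features).
#' @param encoding A [decode()]d `solution_encoding`.
#' @param spec A [fitness_spec()].
#' @return List with `fitness`, `error`, `n_selected`, `n_total`.
#' @export
wrapper_fitness <- function(ds, encoding, spec) {
  mask <- encoding$feature_mask
  if (sum(mask) == 0) stop("empty mask reached wrapper_fitness", call. = FALSE)
  n_total <- length(mask)
  X <- ds$X[, which(mask == 1L), drop = FALSE]
  y <- ds$y
  folds <- stratified_folds(y, spec$cv_folds, spec$seed)
  acc <- numeric(spec$cv_folds)
  for (f in seq_len(spec$cv_folds)) {
    te <- folds == f
    if (length(unique(y[!te])) < 2) {
      stop("degenerate fold: a training fold lost a class", call. = FALSE)
    }
    pred <- fit_predict(spec$model, encoding$hyperparams,
                        X[!te, , drop = FALSE], y[!te], X[te, , drop = FALSE],
                        seed = spec$seed + f)
    acc[f] <- mean(pred == as.character(y[te]))
  }
  error <- 1 - mean(acc)
  list(fitness = selection_fitness(error, encoding$n_selected, n_total, spec$alpha),
       error = error, n_selected = encoding$n_selected, n_total = n_total)
}
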