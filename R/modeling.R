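# Discriminative models: ridge-penalised logistic regression (glmnet
# backend) and an in-package random-forest regressor with budgeted
# hyperparameter search, plus the multi-seed replication harness.

#' Classifier specification (L2 logistic regression)
#'
#' @param regularization_strength inverse penalty C (> 0); the ridge
#'   penalty passed to the solver is `lambda = 1 / (n * C)`.
#' @param max_iterations solver iteration cap.
#' @param standardize centre/scale features using training-set statistics
#'   before fitting (recommended for dense descriptor/embedding encodings;
#'   off for one-hot).
#' @return a `classifier_spec` object.
#' @export
classifier_spec <- function(regularization_strength = 1,
                            max_iterations = 1e5,
                            standardize = TRUE) {
  stopifnot(regularization_strength > 0, max_iterations >= 1)
  structure(list(penalty = "l2",
                 regularization_strength = regularization_strength,
                 max_iterations = max_iterations,
                 standardize = isTRUE(standardize)),
            class = "classifier_spec")
}

#' Train an L2-penalised logistic regression classifier
#'
#' Ridge logistic regression at a single fixed penalty; when
#' `spec$standardize` is on, centring/scaling parameters are estimated on
#' the training data only and reapplied at prediction time (no leakage
#' from test rows). Non-convergence raises a warning, never a silent
#' result.
#'
#' @param train_features numeric matrix.
#' @param train_labels binary 0/1 vector (both classes required).
#' @param spec a [classifier_spec()].
#' @param seed integer seed (the solver is deterministic; the seed guards
#'   any future stochastic backends).
#' @return a `fitrank_classifier` handle exposing probability and label
#'   prediction via [predict_proba()] / [predict_labels()].
#' @export
train_classifier <- function(train_features, train_labels,
                             spec = classifier_spec(), seed = 1L) {
  train_features <- as.matrix(train_features)
  train_labels <- as.integer(train_labels)
  assert_binary_labels(train_labels)
  if (length(unique(train_labels)) < 2L)
    stop("training labels contain a single class; cannot fit a classifier")
  stopifnot(nrow(train_features) == length(train_labels))
  center <- NULL; scale_ <- NULL
  x <- train_features
  if (spec$standardize) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, sd)
    scale_[scale_ == 0] <- 1  # constant columns pass through unscaled
    x <- sweep(sweep(x, 2, center), 2, scale_, "/")
  }
  lambda <- 1 / (nrow(x) * spec$regularization_strength)
  fit <- with_seed(seed,
    glmnet::glmnet(x, factor(train_labels, levels = c(0, 1)),
                   family = "binomial", alpha = 0, lambda = lambda,
                   standardize = FALSE, maxit = spec$max_iterations))
  if (!is.null(fit$jerr) && fit$jerr != 0)
    warning("logistic solver did not converge cleanly (jerr = ", fit$jerr,
            ", npasses = ", fit$npasses, "); consider raising max_iterations")
  beta <- as.numeric(coef(fit))
  names(beta) <- rownames(coef(fit))
  structure(list(fit = fit, intercept = beta[1],
                 coefficients = beta[-1],
                 center = center, scale = scale_,
                 standardize = spec$standardize, spec = spec,
                 n_features = ncol(train_features)),
            class = "fitrank_classifier")
}

#' Predicted positive-class probabilities / labels
#'
#' @param model a `fitrank_classifier` handle.
#' @param features numeric matrix with the training feature width.
#' @param threshold decision threshold on the positive-class probability.
#' @return numeric probabilities in `[0,1]`, or integer 0/1 labels.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "fitrank_classifier"))
  features <- as.matrix(features)
  if (ncol(features) != model$n_features)
    stop("feature width mismatch: model expects ", model$n_features,
         ", got ", ncol(features))
  if (model$standardize)
    features <- sweep(sweep(features, 2, model$center), 2, model$scale, "/")
  as.numeric(predict(model$fit, features, type = "response"))
}

#' @rdname predict_proba
#' @export
predict_labels <- function(model, features, threshold = 0.5) {
  as.integer(predict_proba(model, features) >= threshold)
}

#' Evaluate a fitted classifier on a held-out test set
#'
#' @param model a `fitrank_classifier` handle.
#' @param test_features numeric matrix.
#' @param test_labels binary 0/1 vector.
#' @param threshold decision threshold (default 0.5).
#' @return a [classification_metrics()] `metric_report`.
#' @export
evaluate_classifier <- function(model, test_features, test_labels,
                                threshold = 0.5) {
  if (length(test_labels) == 0L) stop("empty test set")
  classification_metrics(test_labels,
                         predict_labels(model, test_features, threshold))
}

# ---- random-forest regressor ----------------------------------------------

#' Regressor specification (random forest with budgeted search)
#'
#' @param n_estimators_range integer `c(min, max)` number of trees.
#' @param max_depth_range integer `c(min, max)` tree depth.
#' @param search_budget number of random configurations evaluated (>= 1).
#' @param validation_fraction held-out fraction used to score
#'   configurations by validation MSE.
#' @return a `regressor_spec` object.
#' @export
regressor_spec <- function(n_estimators_range = c(20L, 150L),
                           max_depth_range = c(3L, 12L),
                           search_budget = 25L,
                           validation_fraction = 0.2) {
  if (search_budget < 1L) stop("search_budget must be at least 1")
  stopifnot(length(n_estimators_range) == 2L, length(max_depth_range) == 2L,
            n_estimators_range[1] <= n_estimators_range[2],
            max_depth_range[1] <= max_depth_range[2],
            validation_fraction > 0, validation_fraction < 1)
  structure(list(model = "random_forest",
                 n_estimators_range = as.integer(n_estimators_range),
                 max_depth_range = as.integer(max_depth_range),
                 search_budget = as.integer(search_budget),
                 validation_fraction = validation_fraction),
            class = "regressor_spec")
}

# best variance-reducing split of y along x; returns NULL if none
best_split_feature <- function(x, y) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(ys)
  valid <- which(xs[-n] < xs[-1])
  if (length(valid) == 0L) return(NULL)
  cs <- cumsum(ys); cq <- cumsum(ys^2)
  tot_s <- cs[n]; tot_q <- cq[n]
  i <- valid
  sse <- (cq[i] - cs[i]^2 / i) +
    ((tot_q - cq[i]) - (tot_s - cs[i])^2 / (n - i))
  b <- which.min(sse)
  list(threshold = (xs[valid[b]] + xs[valid[b] + 1L]) / 2,
       sse = sse[b])
}

grow_tree <- function(X, y, idx, depth, max_depth, mtry, min_node = 5L) {
  ysub <- y[idx]
  if (depth >= max_depth || length(idx) < 2L * min_node || var(ysub) == 0)
    return(list(leaf = TRUE, value = mean(ysub)))
  feats <- sample(ncol(X), mtry)
  best <- NULL
  parent_sse <- sum((ysub - mean(ysub))^2)
  for (j in feats) {
    sp <- best_split_feature(X[idx, j], ysub)
    if (!is.null(sp) && (is.null(best) || sp$sse < best$sse))
      best <- c(sp, feature = j)
  }
  if (is.null(best) || best$sse >= parent_sse)
    return(list(leaf = TRUE, value = mean(ysub)))
  go_left <- X[idx, best$feature] <= best$threshold
  # (a+b)/2 can round to b for adjacent doubles, emptying one side
  if (all(go_left) || !any(go_left))
    return(list(leaf = TRUE, value = mean(ysub)))
  list(leaf = FALSE, feature = best$feature, threshold = unname(best$threshold),
       left = grow_tree(X, y, idx[go_left], depth + 1L, max_depth, mtry, min_node),
       right = grow_tree(X, y, idx[!go_left], depth + 1L, max_depth, mtry, min_node))
}

predict_tree <- function(node, X) {
  n <- nrow(X)
  out <- numeric(n)
  recurse <- function(node, rows) {
    if (length(rows) == 0L) return()
    if (node$leaf) { out[rows] <<- node$value; return() }
    left <- X[rows, node$feature] <= node$threshold
    recurse(node$left, rows[left])
    recurse(node$right, rows[!left])
  }
  recurse(node, seq_len(n))
  out
}

# bagged regression trees with per-node feature subsampling
regression_forest <- function(X, y, n_trees, max_depth,
                              mtry = max(1L, floor(ncol(X) / 3)), seed = 1L) {
  X <- as.matrix(X)
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(t) {
    boot <- sample(nrow(X), nrow(X), replace = TRUE)
    grow_tree(X, y, boot, 0L, max_depth, mtry)
  }))
  structure(list(trees = trees, n_trees = n_trees, max_depth = max_depth,
                 mtry = mtry, n_features = ncol(X)),
            class = "fitrank_forest")
}

#' @export
predict.fitrank_forest <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("feature width mismatch: forest expects ", object$n_features)
  preds <- vapply(object$trees, function(tr) predict_tree(tr, newdata),
                  numeric(nrow(newdata)))
  if (nrow(newdata) == 1L) return(mean(preds))
  rowMeans(preds)
}

#' Fit a random-forest regressor with budgeted random hyperparameter search
#'
#' Draws `search_budget` (tree count, depth) configurations uniformly from
#' the spec's ranges, scores each on an internal validation split by MSE,
#' and refits the best configuration on the full training set.
#'
#' @param train_features numeric matrix (>= 20 rows).
#' @param train_target numeric vector.
#' @param spec a [regressor_spec()].
#' @param seed integer seed driving the search, splits and bootstraps.
#' @return list with `model` (a `fitrank_forest`), `chosen`
#'   (n_estimators, max_depth), and `validation` (MSE, R2 on the internal
#'   validation split).
#' @export
fit_regressor <- function(train_features, train_target,
                          spec = regressor_spec(), seed = 1L) {
  train_features <- as.matrix(train_features)
  stopifnot(nrow(train_features) == length(train_target))
  if (nrow(train_features) < 20L)
    stop("need at least 20 training rows for the validation search")
  n <- nrow(train_features)
  res <- with_seed(seed, {
    val_idx <- sample(n, max(2L, round(spec$validation_fraction * n)))
    tr_idx <- setdiff(seq_len(n), val_idx)
    cand <- data.frame(
      n_estimators = sample(seq(spec$n_estimators_range[1],
                                spec$n_estimators_range[2]),
                            spec$search_budget, replace = TRUE),
      max_depth = sample(seq(spec$max_depth_range[1],
                             spec$max_depth_range[2]),
                         spec$search_budget, replace = TRUE))
    tree_seeds <- sample.int(2^30, spec$search_budget + 1L)
    best <- NULL
    for (i in seq_len(spec$search_budget)) {
      f <- regression_forest(train_features[tr_idx, , drop = FALSE],
                             train_target[tr_idx],
                             cand$n_estimators[i], cand$max_depth[i],
                             seed = tree_seeds[i])
      pred <- predict(f, train_features[val_idx, , drop = FALSE])
      mse <- mean((train_target[val_idx] - pred)^2)
      if (is.null(best) || mse < best$mse)
        best <- list(i = i, mse = mse,
                     val = regression_metrics(train_target[val_idx], pred))
    }
    final <- regression_forest(train_features, train_target,
                               cand$n_estimators[best$i],
                               cand$max_depth[best$i],
                               seed = tree_seeds[spec$search_budget + 1L])
    list(model = final,
         chosen = list(n_estimators = cand$n_estimators[best$i],
                       max_depth = cand$max_depth[best$i]),
         validation = best$val)
  })
  res
}

# ---- replication harness ---------------------------------------------------

#' Define an encoding-by-sampling alternative
#'
#' @param encoding an encoding name (single model) or character vector of
#'   names (for `combine = "concat"` or `"vote"`).
#' @param sampler one of `"none"`, `"under"`, `"over"`, `"smote"`.
#' @param combine `"single"`, `"concat"` (feature-axis concatenation, one
#'   model) or `"vote"` (one model per encoding, majority-voted labels).
#' @param id optional display id; defaults to
#'   `<encodings>_<sampler>[_<combine>]`.
#' @param standardize optional override of the per-encoding
#'   standardisation default (dense encodings on, one-hot off).
#' @return an `alternative_spec` object.
#' @export
alternative <- function(encoding, sampler = "smote",
                        combine = c("single", "concat", "vote"),
                        id = NULL, standardize = NULL) {
  combine <- match.arg(combine)
  if (combine == "single" && length(encoding) != 1L)
    stop("a 'single' alternative takes exactly one encoding")
  if (combine != "single" && length(encoding) < 2L)
    stop("'", combine, "' needs at least two encodings")
  id <- id %||% paste0(paste(encoding, collapse = "+"), "_", sampler,
                       if (combine != "single") paste0("_", combine) else "")
  structure(list(id = id, encoding = encoding, sampler = sampler,
                 combine = combine, standardize = standardize),
            class = "alternative_spec")
}

default_standardize <- function(encoding_names) {
  # one-hot indicator blocks are left on their natural 0/1 scale
  !(length(encoding_names) == 1L && encoding_names == "onehot")
}

# fit/evaluate one alternative for one prepared split
eval_alternative_cell <- function(alt, encodings, labels, split, seed,
                                  smote_k = 5L) {
  std <- alt$standardize %||% default_standardize(alt$encoding)
  spec <- classifier_spec(standardize = std)
  test_y <- labels[split$test]
  if (alt$combine %in% c("single", "concat")) {
    em <- if (length(alt$encoding) == 1L) encodings[[alt$encoding]]
          else concat_encodings(encodings[alt$encoding])
    X <- em$values
    rs <- apply_sampler(alt$sampler, X[split$train, , drop = FALSE],
                        labels[split$train], k = smote_k, seed = seed)
    model <- train_classifier(rs$features, rs$labels, spec, seed = seed)
    evaluate_classifier(model, X[split$test, , drop = FALSE], test_y)
  } else {
    votes <- matrix(0L, nrow = length(split$test), ncol = length(alt$encoding))
    probs <- matrix(0, nrow = length(split$test), ncol = length(alt$encoding))
    for (v in seq_along(alt$encoding)) {
      enc <- alt$encoding[v]
      X <- encodings[[enc]]$values
      rs <- apply_sampler(alt$sampler, X[split$train, , drop = FALSE],
                          labels[split$train], k = smote_k, seed = seed)
      vspec <- classifier_spec(standardize = default_standardize(enc))
      model <- train_classifier(rs$features, rs$labels, vspec, seed = seed)
      probs[, v] <- predict_proba(model, X[split$test, , drop = FALSE])
      votes[, v] <- as.integer(probs[, v] >= 0.5)
    }
    vote <- majority_vote(votes, probs)
    classification_metrics(test_y, vote$labels)
  }
}

#' Run all alternatives across replicate seeds
#'
#' For each seed one stratified split is drawn and shared by every
#' alternative (paired design: all alternatives see the identical test
#' set). Training rows are resampled per alternative in that
#' alternative's feature space; test rows never enter a resampler. A
#' failing alternative is recorded as a failed cell and the run
#' continues.
#'
#' @param encodings named list of [encoding_matrix()] objects over the
#'   same sequences (identical row order).
#' @param labels binary 0/1 vector aligned with the encoding rows.
#' @param alternatives list of [alternative()] specs.
#' @param seeds integer vector of at least 2 distinct replicate seeds.
#' @param test_fraction held-out fraction per class (default 0.2).
#' @param smote_k SMOTE neighbour count (default 5).
#' @return a `replicate_table`: tidy data.frame with one row per
#'   (alternative, seed) holding the confusion counts and six criteria;
#'   attribute `failures` lists failed cells with their error messages.
#' @export
run_replicates <- function(encodings, labels, alternatives, seeds,
                           test_fraction = 0.2, smote_k = 5L) {
  seeds <- unique(as.integer(seeds))
  if (length(seeds) < 2L)
    stop("need at least 2 replicate seeds to estimate dispersion")
  stopifnot(length(encodings) >= 1L, !is.null(names(encodings)))
  used <- unique(unlist(lapply(alternatives, `[[`, "encoding")))
  missing <- setdiff(used, names(encodings))
  if (length(missing))
    stop("alternatives reference unknown encodings: ",
         paste(missing, collapse = ", "))
  rows <- list()
  failures <- list()
  for (seed in seeds) {
    split <- stratified_split(labels, split_spec(test_fraction, seed = seed))
    for (alt in alternatives) {
      cell <- tryCatch(
        eval_alternative_cell(alt, encodings, labels, split, seed, smote_k),
        error = function(e) e)
      if (inherits(cell, "error")) {
        failures[[length(failures) + 1L]] <-
          data.frame(alternative = alt$id, seed = seed,
                     message = conditionMessage(cell))
      } else {
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(alternative = alt$id, seed = seed),
                as.data.frame(cell))
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("replicate_table", "data.frame")
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures)
                           else NULL
  out
}
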