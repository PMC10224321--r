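# Prevalence-preserving splitting and class rebalancing. SMOTE is
# implemented from its defining algorithm (interpolation toward minority
# nearest neighbours), not delegated.

#' Stratified train/test split specification
#'
#' @param test_fraction fraction of each class routed to the test set,
#'   strictly in (0,1).
#' @param seed integer seed.
#' @param stratified keep per-class proportions (default TRUE). With
#'   `FALSE` a simple random split is drawn.
#' @return a `split_spec` object.
#' @export
split_spec <- function(test_fraction = 0.2, seed = 1L, stratified = TRUE) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must lie strictly in (0, 1)")
  structure(list(test_fraction = test_fraction, seed = as.integer(seed),
                 stratified = isTRUE(stratified)),
            class = "split_spec")
}

#' Prevalence-preserving train/test split
#'
#' Draws `round(test_fraction * n_class)` test rows from each class so the
#' test set mirrors the original class distribution (for a 93%/7% library
#' the test set stays 93%/7%). The returned index sets are disjoint and
#' exhaustive.
#'
#' @param labels binary 0/1 vector.
#' @param spec a [split_spec()].
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, spec = split_spec()) {
  labels <- as.integer(labels)
  assert_binary_labels(labels)
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (any(tab < 2L))
    stop("each class needs at least 2 members for a stratified split (have ",
         tab[["0"]], " negatives, ", tab[["1"]], " positives)")
  with_seed(spec$seed, {
    test <- integer(0)
    if (spec$stratified) {
      for (cl in c(0L, 1L)) {
        idx <- which(labels == cl)
        n_test <- round(spec$test_fraction * length(idx))
        n_test <- min(max(n_test, 1L), length(idx) - 1L)  # both sides non-empty
        test <- c(test, sample(idx, n_test))
      }
    } else {
      n_test <- max(1L, round(spec$test_fraction * length(labels)))
      test <- sample(seq_along(labels), n_test)
    }
    test <- sort(test)
    list(train = setdiff(seq_along(labels), test), test = test)
  })
}

resample_result <- function(features, labels, provenance) {
  stopifnot(nrow(features) == length(labels),
            length(labels) == length(provenance))
  structure(list(features = features, labels = as.integer(labels),
                 provenance = provenance),
            class = "resample_result")
}

#' @export
print.resample_result <- function(x, ...) {
  cat(sprintf("<resample_result> %d rows (%d pos / %d neg); %s\n",
              length(x$labels), sum(x$labels), sum(1 - x$labels),
              paste(names(table(x$provenance)), table(x$provenance),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

split_classes <- function(labels) {
  labels <- as.integer(labels)
  assert_binary_labels(labels)
  tab <- table(factor(labels, levels = c(0L, 1L)))
  if (any(tab == 0L)) stop("both classes must be present")
  minority <- if (tab[["1"]] <= tab[["0"]]) 1L else 0L
  list(minority = which(labels == minority),
       majority = which(labels == 1L - minority))
}

#' Random undersampling of the majority class
#'
#' Reduces the majority class, without replacement, to the minority count;
#' every retained row is an original.
#'
#' @param features numeric matrix.
#' @param labels binary 0/1 vector.
#' @param seed integer seed.
#' @return a `resample_result` (features, labels, per-row provenance tag
#'   in `{original, duplicated, synthetic}`).
#' @export
undersample <- function(features, labels, seed = 1L) {
  cls <- split_classes(labels)
  if (length(cls$minority) == length(cls$majority))
    return(resample_result(features, labels, rep("original", length(labels))))
  keep_maj <- with_seed(seed, resample(cls$majority, length(cls$minority)))
  keep <- sort(c(cls$minority, keep_maj))
  resample_result(features[keep, , drop = FALSE], labels[keep],
                  rep("original", length(keep)))
}

#' Random oversampling of the minority class
#'
#' Duplicates minority rows (sampled with replacement) until class counts
#' are equal; majority rows are untouched.
#'
#' @inheritParams undersample
#' @return a `resample_result`; added rows carry provenance `"duplicated"`.
#' @export
oversample_random <- function(features, labels, seed = 1L) {
  cls <- split_classes(labels)
  deficit <- length(cls$majority) - length(cls$minority)
  if (deficit == 0L)
    return(resample_result(features, labels, rep("original", length(labels))))
  extra <- with_seed(seed, resample(cls$minority, deficit, replace = TRUE))
  resample_result(rbind(features, features[extra, , drop = FALSE]),
                  c(labels, labels[extra]),
                  c(rep("original", length(labels)),
                    rep("duplicated", deficit)))
}

#' SMOTE: synthetic minority oversampling
#'
#' Generates synthetic minority rows `x + u * (x_nn - x)` with
#' `u ~ Uniform(0,1)`, where `x` is a minority row and `x_nn` one of its
#' `k` nearest minority neighbours under Euclidean distance, until the
#' classes balance. `k` is clipped to `n_minority - 1`; a singleton
#' minority class falls back to duplication with a warning.
#'
#' @inheritParams undersample
#' @param k number of minority nearest neighbours (default 5, the
#'   original convention).
#' @return a `resample_result`; generated rows carry provenance
#'   `"synthetic"`.
#' @export
smote <- function(features, labels, k = 5L, seed = 1L) {
  features <- as.matrix(features)
  cls <- split_classes(labels)
  deficit <- length(cls$majority) - length(cls$minority)
  if (deficit == 0L)
    return(resample_result(features, labels, rep("original", length(labels))))
  n_min <- length(cls$minority)
  if (n_min < 2L) {
    warning("minority class has a single member; SMOTE falls back to duplication")
    return(oversample_random(features, labels, seed))
  }
  k <- min(as.integer(k), n_min - 1L)
  minf <- features[cls$minority, , drop = FALSE]
  # brute-force minority-internal k nearest neighbours
  d2 <- as.matrix(stats::dist(minf))
  diag(d2) <- Inf
  nn_idx <- matrix(0L, nrow = n_min, ncol = k)
  for (i in seq_len(n_min)) nn_idx[i, ] <- order(d2[i, ])[seq_len(k)]
  synth <- with_seed(seed, {
    base <- sample(n_min, deficit, replace = TRUE)
    nn_pick <- nn_idx[cbind(base, sample(k, deficit, replace = TRUE))]
    u <- runif(deficit)
    minf[base, , drop = FALSE] +
      u * (minf[nn_pick, , drop = FALSE] - minf[base, , drop = FALSE])
  })
  minority_label <- labels[cls$minority[1]]
  resample_result(rbind(features, synth),
                  c(labels, rep(minority_label, deficit)),
                  c(rep("original", length(labels)),
                    rep("synthetic", deficit)))
}

#' Dispatch a named resampler
#'
#' @param sampler one of `"none"`, `"under"`, `"over"`, `"smote"`.
#' @inheritParams smote
#' @return a `resample_result`.
#' @export
apply_sampler <- function(sampler = c("none", "under", "over", "smote"),
                          features, labels, k = 5L, seed = 1L) {
  sampler <- match.arg(sampler)
  switch(sampler,
         none = resample_result(as.matrix(features), labels,
                                rep("original", length(labels))),
         under = undersample(features, labels, seed),
         over = oversample_random(features, labels, seed),
         smote = smote(features, labels, k = k, seed = seed))
}
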