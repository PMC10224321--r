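# Encoding combination: feature-axis concatenation and majority voting.

#' Concatenate encodings along the feature axis
#'
#' Combines several encodings of the same sequences into one wide matrix;
#' widths add and every original block is recoverable by column slicing.
#' "Combining by adding together" is implemented as feature-axis
#' concatenation: the constituent widths (e.g. 20 / 1160 / 1900 / 1280)
#' differ, so elementwise addition is not defined.
#'
#' @param matrices list of [encoding_matrix()] objects with equal row
#'   counts and identical row order.
#' @return an [encoding_matrix()] whose name joins the constituent names
#'   with `+`; duplicate feature names are suffixed with their block name.
#' @export
concat_encodings <- function(matrices) {
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, logical(1), "encoding_matrix")))
  if (length(matrices) == 1L) return(matrices[[1]])
  n <- vapply(matrices, function(m) nrow(m$values), integer(1))
  if (length(unique(n)) != 1L)
    stop("row-count mismatch across encodings: ", paste(n, collapse = " vs "))
  ids <- matrices[[1]]$row_ids
  for (m in matrices[-1]) {
    if (!identical(m$row_ids, ids))
      stop("encodings must share identical row order (row_ids differ)")
  }
  feats <- unlist(lapply(matrices, `[[`, "feature_names"))
  if (anyDuplicated(feats)) {
    feats <- unlist(lapply(matrices, function(m)
      paste0(m$encoding_name, ".", m$feature_names)))
  }
  encoding_matrix(paste(vapply(matrices, `[[`, character(1), "encoding_name"),
                        collapse = "+"),
                  do.call(cbind, lapply(matrices, `[[`, "values")),
                  feats, ids)
}

#' Majority vote over per-encoding classifiers
#'
#' Rows are test instances, columns are voters. A strict label majority
#' wins; exact ties (possible only for an even voter count) are broken by
#' the mean positive-class probability: >= 0.5 votes positive, and the
#' instance is flagged in `tie_broken`.
#'
#' @param per_voter_labels n x v binary 0/1 matrix of predicted labels.
#' @param per_voter_probabilities n x v matrix of positive-class
#'   probabilities (required only when ties are possible; defaults to the
#'   labels themselves).
#' @return a `vote_result`: list with `labels`, `per_voter_labels`,
#'   `tie_broken`.
#' @export
majority_vote <- function(per_voter_labels,
                          per_voter_probabilities = per_voter_labels) {
  per_voter_labels <- as.matrix(per_voter_labels)
  per_voter_probabilities <- as.matrix(per_voter_probabilities)
  v <- ncol(per_voter_labels)
  if (v == 0L) stop("majority vote needs at least one voter")
  if (v < 2L) stop("majority vote needs at least 2 voters")
  if (!identical(dim(per_voter_labels), dim(per_voter_probabilities)))
    stop("label and probability matrices must have identical shape")
  assert_binary_labels(as.vector(per_voter_labels))
  pos <- rowSums(per_voter_labels)
  labels <- as.integer(pos > v / 2)
  tie <- pos == v / 2
  if (any(tie))
    labels[tie] <- as.integer(rowMeans(per_voter_probabilities)[tie] >= 0.5)
  structure(list(labels = labels, per_voter_labels = per_voter_labels,
                 tie_broken = tie),
            class = "vote_result")
}
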