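# Multi-criteria decision analysis: entropy-weighted and subjectively
# weighted TOPSIS over the six classification criteria.

DEFAULT_SIGNS <- c(F1 = 1, FPR = -1, TPR = 1, precision = 1, NPV = 1, FDR = -1)

#' Decision matrix of alternatives by criteria
#'
#' @param x nonnegative numeric matrix, rows = alternatives, columns =
#'   criteria; every column must have a positive sum.
#' @param alternative_ids row identifiers.
#' @param criterion_names column names (default the fixed criterion order
#'   F1, FPR, TPR, precision, NPV, FDR).
#' @param signs per-criterion orientation, `+1` maximise / `-1` minimise
#'   (defaults match the default criteria).
#' @return a `decision_matrix` object.
#' @export
decision_matrix <- function(x, alternative_ids = rownames(x),
                            criterion_names = METRIC_CRITERIA,
                            signs = DEFAULT_SIGNS[criterion_names]) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("decision matrix contains missing values")
  if (any(x < 0)) stop("decision matrix entries must be nonnegative")
  if (any(colSums(x) <= 0)) stop("every criterion column must have positive sum")
  if (is.null(alternative_ids))
    alternative_ids <- paste0("alt_", seq_len(nrow(x)))
  stopifnot(length(alternative_ids) == nrow(x),
            length(criterion_names) == ncol(x),
            length(signs) == ncol(x), all(signs %in% c(-1, 1)))
  dimnames(x) <- list(alternative_ids, criterion_names)
  structure(list(x = x, alternative_ids = alternative_ids,
                 criterion_names = criterion_names,
                 signs = unname(signs)),
            class = "decision_matrix")
}

#' Build the decision matrix of per-alternative seed-mean criteria
#'
#' Averages each of the six criteria over seeds for every alternative in
#' a [run_replicates()] table. The criterion column order is fixed (F1,
#' FPR, TPR, precision, NPV, FDR) regardless of input order.
#'
#' @param replicates a `replicate_table`.
#' @return a [decision_matrix()].
#' @export
build_decision_matrix <- function(replicates) {
  stopifnot(is.data.frame(replicates),
            all(c("alternative", "seed", METRIC_CRITERIA) %in% names(replicates)))
  alts <- unique(replicates$alternative)
  seeds <- sort(unique(replicates$seed))
  if (length(seeds) < 2L)
    stop("decision matrix needs at least 2 seeds per alternative ",
         "(downstream statistics require dispersion)")
  missing <- list()
  for (a in alts) {
    have <- replicates$seed[replicates$alternative == a]
    miss <- setdiff(seeds, have)
    if (length(miss))
      missing[[a]] <- miss
  }
  if (length(missing))
    stop("missing (alternative, seed) cells: ",
         paste(vapply(names(missing), function(a)
           paste0(a, ":", paste(missing[[a]], collapse = ",")),
           character(1)), collapse = "; "))
  m <- t(vapply(alts, function(a) {
    sub <- replicates[replicates$alternative == a, METRIC_CRITERIA]
    colMeans(as.matrix(sub))
  }, numeric(length(METRIC_CRITERIA))))
  decision_matrix(m, alternative_ids = alts)
}

#' Objective criterion weights from Shannon entropy
#'
#' Columns are sum-normalised (`r_ij = x_ij / sum_i x_ij`), the entropy of
#' each criterion is `E_j = -k * sum_i r_ij ln r_ij` with `k = 1/ln(n)`
#' and the convention `0 ln 0 = 0`, and weights are the normalised
#' divergences `w_j = (1 - E_j) / sum_j (1 - E_j)`. A criterion identical
#' across alternatives carries zero weight.
#'
#' @param matrix a [decision_matrix()] with at least 2 alternatives.
#' @return a `weight_vector` (fields `w`, `method = "entropy"`).
#' @export
entropy_weights <- function(matrix) {
  stopifnot(inherits(matrix, "decision_matrix"))
  x <- matrix$x
  n <- nrow(x)
  if (n < 2L) stop("entropy weighting needs at least 2 alternatives")
  r <- sweep(x, 2, colSums(x), "/")
  k <- 1 / log(n)
  plogp <- r * log(r)
  plogp[r == 0] <- 0
  E <- -k * colSums(plogp)
  d <- 1 - E
  if (sum(d) <= .Machine$double.eps * length(d))
    stop("degenerate decision matrix: every criterion is uniform across ",
         "alternatives (all entropies are 1)")
  weight_vector(d / sum(d), method = "entropy",
                criterion_names = matrix$criterion_names)
}

#' Criterion weight vector
#'
#' @param w nonnegative weights; normalised to sum to 1.
#' @param method `"entropy"` or `"subjective"`.
#' @param criterion_names optional names.
#' @return a `weight_vector` object.
#' @export
weight_vector <- function(w, method = c("entropy", "subjective"),
                          criterion_names = names(w)) {
  method <- match.arg(method)
  if (any(w < 0)) stop("weights must be nonnegative")
  if (sum(w) <= 0) stop("weights must not all be zero")
  w <- w / sum(w)
  structure(list(w = setNames(unname(w), criterion_names), method = method),
            class = "weight_vector")
}

#' Subjective criterion weights
#'
#' Normalises a user emphasis map over the six criteria. The default
#' emphasis raises precision and FPR slightly above the rest
#' (0.20/0.20 vs 0.15 each) to prioritise confident identification of the
#' rare positive class; these defaults are this package's declared
#' choice, not a literature constant.
#'
#' @param emphasis named nonnegative vector over the criteria (default
#'   described above).
#' @return a `weight_vector` with `method = "subjective"`.
#' @export
subjective_weights <- function(emphasis = c(F1 = 0.15, FPR = 0.20, TPR = 0.15,
                                            precision = 0.20, NPV = 0.15,
                                            FDR = 0.15)) {
  weight_vector(emphasis, method = "subjective",
                criterion_names = names(emphasis))
}

#' TOPSIS ranking by closeness to the ideal alternative
#'
#' Standard TOPSIS: columns are vector-normalised
#' (`v_ij = x_ij / sqrt(sum_i x_ij^2)`) and weighted; the positive ideal
#' takes the per-column maximum where the criterion is maximised (sign
#' `+1`) and the minimum where it is minimised, the negative ideal the
#' opposite; each alternative's closeness is `C_i = d-_i/(d+_i + d-_i)`
#' with Euclidean distances to the two ideals. Alternatives are ranked by
#' descending closeness, ties broken by alternative id (stable). The
#' sum-normalisation of the entropy-weighting stage is deliberately not
#' reused here; the distance stage uses the standard vector
#' normalisation.
#'
#' @param matrix a [decision_matrix()].
#' @param weights a `weight_vector` of matching length.
#' @return a `ranking_result`: list with `closeness` (named, input
#'   order), `ranks` (1 = best, aligned with alternatives), `order`
#'   (alternative ids best-first) and `weights_used`.
#' @export
topsis_rank <- function(matrix, weights) {
  stopifnot(inherits(matrix, "decision_matrix"),
            inherits(weights, "weight_vector"))
  x <- matrix$x
  w <- weights$w
  if (length(w) != ncol(x))
    stop("weight length (", length(w), ") must equal criterion count (",
         ncol(x), ")")
  norms <- sqrt(colSums(x^2))
  v <- sweep(sweep(x, 2, norms, "/"), 2, w, "*")
  ideal_pos <- ifelse(matrix$signs > 0, apply(v, 2, max), apply(v, 2, min))
  ideal_neg <- ifelse(matrix$signs > 0, apply(v, 2, min), apply(v, 2, max))
  d_pos <- sqrt(rowSums(sweep(v, 2, ideal_pos)^2))
  d_neg <- sqrt(rowSums(sweep(v, 2, ideal_neg)^2))
  if (all(d_pos + d_neg == 0))
    stop("degenerate decision matrix: all alternatives are identical")
  closeness <- d_neg / (d_pos + d_neg)
  names(closeness) <- matrix$alternative_ids
  ord <- order(-closeness, matrix$alternative_ids)
  ranks <- integer(length(ord)); ranks[ord] <- seq_along(ord)
  structure(list(closeness = closeness, ranks = ranks,
                 order = matrix$alternative_ids[ord],
                 weights_used = weights),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> (%s weights)\n", x$weights_used$method))
  for (i in seq_along(x$order)) {
    id <- x$order[i]
    cat(sprintf("  %2d. %-24s C = %.4f\n", i, id, x$closeness[[id]]))
  }
  invisible(x)
}
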