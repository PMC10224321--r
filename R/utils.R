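# Internal helpers shared across modules.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a local, restorable RNG state
#'
#' Saves `.Random.seed`, seeds R's default Mersenne-Twister generator with
#' `seed`, evaluates `expr`, and restores the previous global RNG state so
#' seeded package functions never perturb user-level randomness.
#'
#' @param seed integer scalar, or `NULL` to use the current RNG stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

# Stable 31-based polynomial string hash modulo 2^31 - 1. Exact in doubles
# (intermediate values < 2^53), so identical across platforms.
hash_string <- function(x) {
  m <- 2147483647
  vapply(x, function(s) {
    h <- 0
    for (code in utf8ToInt(s)) h <- (h * 31 + code) %% m
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Pairwise hamming distances between equal-length strings; errors on
# length mismatch (distance undefined).
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("hamming distance undefined for sequences of unequal length (",
         nchar(a), " vs ", nchar(b), ")")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Minimum hamming distance from each of `queries` to any of `refs`
# (all strings equal length). Byte-matrix implementation; chunked over
# refs to bound memory.
min_hamming_to_set <- function(queries, refs) {
  if (length(refs) == 0L) return(rep(Inf, length(queries)))
  L <- unique(nchar(c(queries, refs)))
  if (length(L) > 1L)
    stop("hamming distance undefined: sequences of unequal length present")
  qm <- vapply(queries, utf8ToInt, integer(L))   # L x nq
  rm_ <- vapply(refs, utf8ToInt, integer(L))     # L x nr
  out <- rep(Inf, length(queries))
  for (j in seq_len(ncol(rm_))) {
    d <- colSums(qm != rm_[, j])
    out <- pmin(out, d)
  }
  out
}

# sample() without the scalar-x surprise: always samples elements of x
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

stop_invalid_config <- function(...) {
  stop(structure(class = c("fitrank_invalid_config", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_binary_labels <- function(labels) {
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1")
  invisible(TRUE)
}
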