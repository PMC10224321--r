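# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops over the defining formulas.

# entropy weights by direct evaluation of the defining equations
brute_entropy_weights <- function(x) {
  n <- nrow(x); m <- ncol(x)
  w <- numeric(m)
  E <- numeric(m)
  for (j in 1:m) {
    col_sum <- sum(x[, j])
    e <- 0
    for (i in 1:n) {
      r <- x[i, j] / col_sum
      if (r > 0) e <- e + r * log(r)
    }
    E[j] <- -e / log(n)
  }
  d <- 1 - E
  d / sum(d)
}

# TOPSIS closeness by direct evaluation (vector normalisation)
brute_topsis <- function(x, w, signs) {
  n <- nrow(x); m <- ncol(x)
  v <- matrix(0, n, m)
  for (j in 1:m) {
    nrm <- sqrt(sum(x[, j]^2))
    for (i in 1:n) v[i, j] <- x[i, j] / nrm * w[j]
  }
  a_pos <- a_neg <- numeric(m)
  for (j in 1:m) {
    if (signs[j] > 0) {
      a_pos[j] <- max(v[, j]); a_neg[j] <- min(v[, j])
    } else {
      a_pos[j] <- min(v[, j]); a_neg[j] <- max(v[, j])
    }
  }
  cc <- numeric(n)
  for (i in 1:n) {
    dp <- sqrt(sum((v[i, ] - a_pos)^2))
    dn <- sqrt(sum((v[i, ] - a_neg)^2))
    cc[i] <- dn / (dp + dn)
  }
  cc
}

# brute-force k nearest neighbours (Euclidean) of row i among rows
brute_knn <- function(points, i, k) {
  d <- apply(points, 1, function(p) sqrt(sum((p - points[i, ])^2)))
  d[i] <- Inf
  order(d)[seq_len(k)]
}

# is q on the closed segment between a and b (within tol)?
on_segment <- function(q, a, b, tol = 1e-8) {
  ab <- b - a
  denom <- sum(ab^2)
  if (denom == 0) return(sqrt(sum((q - a)^2)) < tol)
  t <- sum((q - a) * ab) / denom
  if (t < -tol || t > 1 + tol) return(FALSE)
  sqrt(sum((q - (a + t * ab))^2)) < tol
}

# tiny toy encoding matrix with given width, shared row ids
toy_encoding <- function(name, n, p, seed = 1) {
  set.seed(seed)
  encoding_matrix(name, matrix(rnorm(n * p), n, p),
                  paste0(name, "_", seq_len(p)),
                  sprintf("row_%03d", seq_len(n)))
}
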