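test_that("stratified split preserves the class distribution", {
  labels <- c(rep(0L, 9300), rep(1L, 700))
  sp <- stratified_split(labels, split_spec(0.3, seed = 4))
  expect_identical(sum(labels[sp$test] == 0), 2790L)   # round(0.3 * 9300)
  expect_identical(sum(labels[sp$test] == 1), 210L)    # round(0.3 * 700)
  # disjoint and exhaustive
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  # determinism
  expect_identical(stratified_split(labels, split_spec(0.3, seed = 4)), sp)
  expect_false(identical(stratified_split(labels, split_spec(0.3, seed = 5)),
                         sp))
})

test_that("split guards reject degenerate inputs", {
  expect_error(split_spec(0), "strictly in")
  expect_error(split_spec(1), "strictly in")
  expect_error(stratified_split(c(0L, 0L, 0L, 1L), split_spec(0.5)),
               "at least 2 members")
})

test_that("split proportions hold across random prevalences", {
  for (i in 1:10) {
    set.seed(100 + i)
    n <- sample(50:400, 1)
    n_pos <- sample(5:(n %/% 3), 1)
    labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
    frac <- runif(1, 0.1, 0.4)
    sp <- stratified_split(labels, split_spec(frac, seed = i))
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), seq_len(n))
    got_pos <- sum(labels[sp$test])
    expect_lte(abs(got_pos - frac * n_pos), 1)
  }
})

make_imbalanced <- function(n_maj = 100, n_min = 10, p = 4, seed = 1) {
  set.seed(seed)
  features <- matrix(rnorm((n_maj + n_min) * p), ncol = p)
  features[, 1] <- seq_len(n_maj + n_min)  # unique marker column
  list(features = features,
       labels = c(rep(0L, n_maj), rep(1L, n_min)))
}

test_that("undersampling keeps only original rows at equal counts", {
  d <- make_imbalanced()
  rs <- undersample(d$features, d$labels, seed = 2)
  expect_identical(sum(rs$labels == 0), 10L)
  expect_identical(sum(rs$labels == 1), 10L)
  expect_true(all(rs$provenance == "original"))
  expect_true(all(rs$features[, 1] %in% d$features[, 1]))
  expect_identical(undersample(d$features, d$labels, seed = 2), rs)
  # balanced input is untouched
  b <- make_imbalanced(10, 10)
  expect_identical(undersample(b$features, b$labels)$features, b$features)
})

test_that("random oversampling duplicates minority originals", {
  d <- make_imbalanced()
  rs <- oversample_random(d$features, d$labels, seed = 3)
  expect_identical(sum(rs$labels == 1), 100L)
  expect_identical(sum(rs$labels == 0), 100L)
  expect_identical(sum(rs$provenance == "duplicated"), 90L)
  added <- rs$features[rs$provenance == "duplicated", 1]
  minority_markers <- d$features[d$labels == 1L, 1]
  expect_true(all(added %in% minority_markers))
  # original block is unmodified
  expect_identical(rs$features[seq_len(110), ], d$features)
})

test_that("SMOTE interpolates along minority nearest-neighbour segments", {
  # two minority points, k = 1: synthetics lie on the diagonal segment
  features <- rbind(matrix(5 + rnorm(20), 10, 2),
                    c(0, 0), c(2, 2))
  labels <- c(rep(0L, 10), 1L, 1L)
  rs <- smote(features, labels, k = 1, seed = 7)
  synth <- rs$features[rs$provenance == "synthetic", , drop = FALSE]
  expect_identical(nrow(synth), 8L)
  expect_equal(synth[, 1], synth[, 2], tolerance = 1e-12)
  expect_true(all(synth[, 1] >= 0 & synth[, 1] <= 2))
  expect_identical(sum(rs$labels == 1), sum(rs$labels == 0))

  # identical minority points collapse to that point
  f2 <- rbind(matrix(rnorm(20), 10, 2), c(1, 1), c(1, 1))
  rs2 <- smote(f2, c(rep(0L, 10), 1L, 1L), k = 3, seed = 1)
  synth2 <- rs2$features[rs2$provenance == "synthetic", , drop = FALSE]
  expect_true(all(synth2 == 1))

  # balanced input: no synthetic rows
  f3 <- matrix(rnorm(8), 4, 2)
  rs3 <- smote(f3, c(0L, 0L, 1L, 1L), seed = 1)
  expect_identical(sum(rs3$provenance == "synthetic"), 0L)

  # singleton minority falls back to duplication with a warning
  f4 <- matrix(rnorm(10), 5, 2)
  expect_warning(rs4 <- smote(f4, c(0L, 0L, 0L, 0L, 1L), seed = 1),
                 "duplication")
  expect_identical(sum(rs4$labels == 1), 4L)
})

test_that("every SMOTE synthetic lies on a k-NN segment (brute-force oracle)", {
  for (case in 1:6) {
    set.seed(200 + case)
    n_min <- sample(4:12, 1)
    n_maj <- sample((n_min + 5):38, 1)
    p <- sample(2:5, 1)
    k <- sample(1:3, 1)
    features <- matrix(rnorm((n_maj + n_min) * p), ncol = p)
    labels <- c(rep(0L, n_maj), rep(1L, n_min))
    rs <- smote(features, labels, k = k, seed = case)
    minority <- features[labels == 1L, , drop = FALSE]
    synth <- rs$features[rs$provenance == "synthetic", , drop = FALSE]
    expect_identical(nrow(synth), n_maj - n_min)
    for (r in seq_len(nrow(synth))) {
      ok <- FALSE
      for (i in seq_len(nrow(minority))) {
        for (j in brute_knn(minority, i, k)) {
          if (on_segment(synth[r, ], minority[i, ], minority[j, ])) ok <- TRUE
        }
      }
      expect_true(ok, info = sprintf("case %d, synthetic row %d", case, r))
    }
  }
})
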