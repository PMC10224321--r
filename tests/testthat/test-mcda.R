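random_decision_matrix <- function(n, m = 6, seed = 1) {
  set.seed(seed)
  x <- matrix(runif(n * m, 0.01, 1), n, m)
  decision_matrix(x, alternative_ids = paste0("alt_", seq_len(n)),
                  criterion_names = paste0("c", seq_len(m)),
                  signs = sample(c(-1, 1), m, replace = TRUE))
}

test_that("decision matrix construction is validated", {
  expect_error(decision_matrix(matrix(c(-1, 1, 1, 1), 2),
                               criterion_names = c("a", "b"),
                               signs = c(1, 1)),
               "nonnegative")
  expect_error(decision_matrix(matrix(c(0, 0, 1, 1), 2),
                               criterion_names = c("a", "b"),
                               signs = c(1, 1)),
               "positive sum")
})

test_that("decision matrix holds per-alternative seed means in fixed order", {
  reps <- data.frame(
    alternative = rep(c("A", "B"), each = 2), seed = rep(1:2, 2),
    F1 = c(0.8, 0.9, 0.5, 0.7), FPR = c(0.1, 0.2, 0.3, 0.1),
    TPR = c(0.7, 0.9, 0.6, 0.8), precision = c(0.9, 0.8, 0.6, 0.6),
    NPV = c(0.95, 0.93, 0.9, 0.92), FDR = c(0.1, 0.2, 0.4, 0.4))
  dm <- build_decision_matrix(reps)
  expect_identical(dm$criterion_names,
                   c("F1", "FPR", "TPR", "precision", "NPV", "FDR"))
  expect_identical(dm$signs, c(1, -1, 1, 1, 1, -1))
  expect_equal(unname(dm$x["A", "F1"]), 0.85, tolerance = 1e-15)
  expect_equal(unname(dm$x["B", "FDR"]), 0.4, tolerance = 1e-15)
  # column order fixed regardless of input column order
  dm2 <- build_decision_matrix(reps[, c(1, 2, 8, 3:7)])
  expect_identical(dm2$x, dm$x)
  # single seed is rejected
  expect_error(build_decision_matrix(reps[reps$seed == 1, ]), "2 seeds")
  # missing cells are listed
  expect_error(build_decision_matrix(reps[-4, ]), "B:2")
})

test_that("entropy weights match the defining equations", {
  # symmetric 2x2: equal weights
  dm <- decision_matrix(matrix(c(1, 0, 0, 1), 2),
                        criterion_names = c("a", "b"), signs = c(1, 1))
  expect_equal(entropy_weights(dm)$w, c(a = 0.5, b = 0.5), tolerance = 1e-12)

  # uniform column carries zero weight
  dm2 <- decision_matrix(matrix(c(0.5, 0.5, 0.9, 0.1), 2),
                         criterion_names = c("u", "v"), signs = c(1, 1))
  w2 <- entropy_weights(dm2)$w
  expect_equal(unname(w2["u"]), 0, tolerance = 1e-12)
  expect_equal(unname(w2["v"]), 1, tolerance = 1e-12)

  # 3x2 hand case against the brute-force oracle
  x <- matrix(c(0.9, 0.8, 0.7, 0.1, 0.2, 0.3), 3)
  dm3 <- decision_matrix(x, criterion_names = c("a", "b"), signs = c(1, -1))
  expect_equal(unname(entropy_weights(dm3)$w), brute_entropy_weights(x),
               tolerance = 1e-12)

  # degenerate: every criterion uniform
  dm4 <- decision_matrix(matrix(0.5, 3, 2), criterion_names = c("a", "b"),
                         signs = c(1, 1))
  expect_error(entropy_weights(dm4), "degenerate")
})

test_that("entropy weights are a simplex point on 1000 random matrices", {
  for (i in 1:1000) {
    set.seed(3000 + i)
    n <- sample(2:8, 1); m <- sample(2:7, 1)
    x <- matrix(runif(n * m), n, m)
    dm <- decision_matrix(x, alternative_ids = paste0("a", 1:n),
                          criterion_names = paste0("c", 1:m),
                          signs = rep(1, m))
    w <- entropy_weights(dm)$w
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("TOPSIS endpoints and orientation behave as defined", {
  # alternative best on every oriented criterion coincides with the ideal
  x <- matrix(c(0.9, 0.5, 0.2,   # F1-like, maximise
                0.1, 0.4, 0.8),  # FPR-like, minimise
              ncol = 2)
  dm <- decision_matrix(x, alternative_ids = c("best", "mid", "worst"),
                        criterion_names = c("good", "bad"), signs = c(1, -1))
  r <- topsis_rank(dm, weight_vector(c(0.5, 0.5), "subjective",
                                     c("good", "bad")))
  expect_equal(unname(r$closeness["best"]), 1, tolerance = 1e-12)
  expect_equal(unname(r$closeness["worst"]), 0, tolerance = 1e-12)
  expect_identical(r$order[1], "best")
  expect_identical(r$ranks, c(1L, 2L, 3L))
  expect_true(all(r$closeness >= 0 & r$closeness <= 1))
  # identical alternatives are degenerate
  dmd <- decision_matrix(matrix(0.5, 3, 2), criterion_names = c("a", "b"),
                         signs = c(1, -1))
  expect_error(topsis_rank(dmd, weight_vector(c(0.5, 0.5), "subjective")),
               "degenerate")
})

test_that("TOPSIS agrees with a brute-force oracle on 200 random matrices", {
  for (i in 1:200) {
    set.seed(4000 + i)
    x <- matrix(runif(24, 0.01, 1), 4, 6)
    signs <- sample(c(-1, 1), 6, replace = TRUE)
    w <- runif(6); w <- w / sum(w)
    dm <- decision_matrix(x, alternative_ids = paste0("a", 1:4),
                          criterion_names = paste0("c", 1:6), signs = signs)
    mine <- topsis_rank(dm, weight_vector(w, "subjective", paste0("c", 1:6)))
    expect_equal(unname(mine$closeness), brute_topsis(x, w, signs),
                 tolerance = 1e-10)
  }
})

test_that("TOPSIS is scale-invariant and respects dominance", {
  for (i in 1:50) {
    set.seed(5000 + i)
    dm <- random_decision_matrix(n = 5, m = 4, seed = 5000 + i)
    w <- weight_vector(rep(0.25, 4), "subjective", dm$criterion_names)
    base <- topsis_rank(dm, w)$closeness
    # multiply one criterion column by a positive constant
    x2 <- dm$x
    x2[, 2] <- x2[, 2] * runif(1, 0.1, 10)
    dm2 <- decision_matrix(x2, dm$alternative_ids, dm$criterion_names,
                           setNames(dm$signs, dm$criterion_names))
    expect_equal(topsis_rank(dm2, w)$closeness, base, tolerance = 1e-10)
    # dominance: improve row 1 on every oriented criterion beyond row 2
    x3 <- dm$x
    eps <- 0.001
    for (j in seq_len(4)) {
      x3[1, j] <- if (dm$signs[j] > 0) max(x3[, j]) + eps
                  else max(min(x3[, j]) - eps, 0)
    }
    dm3 <- decision_matrix(x3, dm$alternative_ids, dm$criterion_names,
                           setNames(dm$signs, dm$criterion_names))
    r3 <- topsis_rank(dm3, w)
    expect_identical(r3$order[1], dm$alternative_ids[1])
  }
})

test_that("subjective weights normalise with the documented default", {
  w <- subjective_weights()
  expect_equal(unname(w$w), c(0.15, 0.20, 0.15, 0.20, 0.15, 0.15),
               tolerance = 1e-12)
  expect_identical(names(w$w),
                   c("F1", "FPR", "TPR", "precision", "NPV", "FDR"))
  expect_equal(sum(w$w), 1, tolerance = 1e-12)
  u <- subjective_weights(c(a = 2, b = 2, c = 2))
  expect_equal(unname(u$w), rep(1 / 3, 3), tolerance = 1e-12)
  expect_error(subjective_weights(c(a = -1, b = 2)), "nonnegative")
})
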