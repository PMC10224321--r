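make_clusters <- function(n_per = 30, gap = 6, seed = 1) {
  set.seed(seed)
  features <- rbind(matrix(rnorm(n_per * 2), ncol = 2),
                    matrix(rnorm(n_per * 2, mean = gap), ncol = 2))
  list(features = features, labels = rep(c(0L, 1L), each = n_per))
}

test_that("ridge logistic regression separates well-separated clusters", {
  d <- make_clusters()
  m <- train_classifier(d$features, d$labels, classifier_spec(), seed = 1)
  expect_identical(predict_labels(m, d$features), d$labels)  # accuracy 1.0
  p <- predict_proba(m, d$features)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(train_classifier(d$features, rep(1L, 60)), "single class")
  # constant feature column: ridge still fits
  f2 <- cbind(d$features, 3)
  m2 <- train_classifier(f2, d$labels, classifier_spec(), seed = 1)
  expect_identical(predict_labels(m2, f2), d$labels)
})

test_that("standardisation parameters come from the training data only", {
  d <- make_clusters(seed = 5)
  m <- train_classifier(d$features, d$labels,
                        classifier_spec(standardize = TRUE), seed = 1)
  expect_equal(m$center, colMeans(d$features), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(m$scale, apply(d$features, 2, sd), tolerance = 1e-12,
               ignore_attr = TRUE)
  # shifted test data passes through the stored train transform, not its
  # own statistics: a large positive shift lands deep in the positive class
  shifted <- d$features + 100
  expect_true(all(predict_labels(m, shifted) == 1L))
})

test_that("classifier evaluation returns the full metric report", {
  d <- make_clusters(seed = 2)
  m <- train_classifier(d$features, d$labels, classifier_spec(), seed = 1)
  rep <- evaluate_classifier(m, d$features, d$labels)
  expect_s3_class(rep, "metric_report")
  expect_identical(rep$F1, 1)
  expect_identical(rep$FPR, 0)
  expect_identical(rep$FDR, 0)
  expect_error(evaluate_classifier(m, d$features[0, ], integer(0)),
               "empty test set")
})

test_that("random-forest search recovers an easy regression target", {
  set.seed(11)
  n <- 700
  X <- cbind(runif(n), matrix(runif(n * 2), n))
  y <- 5 * X[, 1]                      # noiseless, single informative feature
  spec <- regressor_spec(n_estimators_range = c(40, 120),
                         max_depth_range = c(4, 14), search_budget = 8)
  fitres <- fit_regressor(X[1:550, ], y[1:550], spec, seed = 3)
  pred <- predict(fitres$model, X[551:700, ])
  met <- regression_metrics(y[551:700], pred)
  expect_gte(met$R2, 0.9)
  # chosen hyperparameters lie inside the configured ranges
  expect_true(fitres$chosen$n_estimators >= 40 &&
                fitres$chosen$n_estimators <= 120)
  expect_true(fitres$chosen$max_depth >= 4 && fitres$chosen$max_depth <= 14)
  expect_error(regressor_spec(search_budget = 0), "at least 1")
  expect_error(fit_regressor(X[1:10, ], y[1:10]), "at least 20")
})

test_that("constant regression target gives zero MSE and undefined R2", {
  set.seed(4)
  X <- matrix(runif(80), 40, 2)
  y <- rep(3, 40)
  suppressWarnings(
    fitres <- fit_regressor(X, y, regressor_spec(search_budget = 2), seed = 1))
  pred <- predict(fitres$model, X)
  expect_equal(pred, rep(3, 40), tolerance = 1e-12)
  expect_warning(met <- regression_metrics(y, pred), "constant truth")
  expect_identical(met$MSE, 0)
  expect_true(is.na(met$R2))
})

test_that("replication harness is paired, deterministic and fault-tolerant", {
  cfg <- affibody_sim_config(n_unique = 150, prevalence = 0.2,
                             noise_background = 0, seed = 31)
  sim <- simulate_affibody_library(cfg)
  encs <- list(physchem = encode_physiochemical(sim$dataset$sequences),
               mock = encode_with_adapter(sim$dataset$sequences,
                                          mock_adapter(24)))
  alts <- list(alternative("physchem", "over"),
               alternative("physchem", "over", id = "physchem_over_copy"),
               alternative("mock", "smote"))
  reps <- run_replicates(encs, sim$dataset$labels, alts, seeds = 1:4)
  expect_identical(nrow(reps), 12L)  # 3 alternatives x 4 seeds
  # identical alternatives give identical rows under the shared seed/split
  a <- reps[reps$alternative == "physchem_over", -1]
  b <- reps[reps$alternative == "physchem_over_copy", -1]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
  # paired design: every alternative sees the same test set per seed
  for (s in 1:4) {
    sub <- reps[reps$seed == s, ]
    expect_identical(length(unique(sub$TP + sub$FN)), 1L)  # same positives
    expect_identical(length(unique(sub$TN + sub$FP)), 1L)  # same negatives
  }
  # rerun reproduces byte-identical numbers
  reps2 <- run_replicates(encs, sim$dataset$labels, alts, seeds = 1:4)
  expect_identical(reps, reps2)
  expect_error(run_replicates(encs, sim$dataset$labels, alts, seeds = 1),
               "at least 2")
  expect_error(run_replicates(encs, sim$dataset$labels,
                              list(alternative("onehot", "over")), 1:2),
               "unknown encodings")
  # a failing cell is recorded and the run continues
  bad <- encs
  bad$short <- toy_encoding("short", 10, 3)
  alts_bad <- list(alternative("physchem", "over"),
                   alternative(c("physchem", "short"), "over", "concat"))
  reps3 <- run_replicates(bad, sim$dataset$labels, alts_bad, seeds = 1:2)
  expect_identical(nrow(reps3), 2L)
  fails <- attr(reps3, "failures")
  expect_identical(nrow(fails), 2L)
  expect_match(fails$message[1], "mismatch|row")
})
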