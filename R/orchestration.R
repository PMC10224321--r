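# Config-driven end-to-end runs: simulate -> preprocess -> encode ->
# sample -> model -> ensemble -> metrics -> MCDA -> stats, with all
# artifacts written to a run directory.

#' End-to-end experiment configuration
#'
#' @param task `"classification"` (affibody-style enrichment data) or
#'   `"regression"` (stability-table Tm prediction).
#' @param affibody an [affibody_sim_config()] (classification task).
#' @param nesp a [nesp_sim_config()] (regression task).
#' @param encodings encoding names among `"onehot"`, `"physchem"`,
#'   `"mock"` (one-hot is skipped automatically for variable-length
#'   regression data).
#' @param samplers resamplers evaluated per encoding (classification).
#' @param ensembles list of extra [alternative()] specs (concatenation /
#'   voting) evaluated alongside the single-encoding alternatives.
#' @param seeds replicate seeds; defaults follow the task convention
#'   (20 for affinity classification, 30 for stability).
#' @param test_fraction held-out fraction (classification default 0.2;
#'   regression uses 0.3).
#' @param cohort optional length cohort filter for regression data:
#'   `"small"` (length <= 120), `"large"` (400-1500), `"max500"`
#'   (<= 500) or `NULL` for all.
#' @param mock_dimension mock embedding width.
#' @return an `experiment_config` object.
#' @export
experiment_config <- function(task = c("classification", "regression"),
                              affibody = affibody_sim_config(),
                              nesp = nesp_sim_config(),
                              encodings = c("onehot", "physchem", "mock"),
                              samplers = c("under", "over", "smote"),
                              ensembles = list(
                                alternative(c("onehot", "physchem", "mock"),
                                            "smote", "concat"),
                                alternative(c("onehot", "physchem", "mock"),
                                            "smote", "vote"),
                                alternative(c("onehot", "physchem", "mock"),
                                            "over", "vote")),
                              seeds = NULL,
                              test_fraction = NULL,
                              cohort = NULL,
                              mock_dimension = 64L) {
  task <- match.arg(task)
  seeds <- seeds %||% if (task == "classification") 1:20 else 1:30
  if (anyDuplicated(seeds)) stop("seeds must be unique")
  test_fraction <- test_fraction %||% if (task == "classification") 0.2 else 0.3
  known <- c("onehot", "physchem", "mock")
  if (!all(encodings %in% known))
    stop("unknown encodings: ", paste(setdiff(encodings, known), collapse = ", "))
  if (!is.null(cohort))
    cohort <- match.arg(cohort, c("small", "large", "max500"))
  structure(list(task = task, affibody = affibody, nesp = nesp,
                 encodings = encodings, samplers = samplers,
                 ensembles = ensembles, seeds = as.integer(seeds),
                 test_fraction = test_fraction, cohort = cohort,
                 mock_dimension = as.integer(mock_dimension)),
            class = "experiment_config")
}

cohort_bounds <- list(small = c(2, 120), large = c(400, 1500),
                      max500 = c(2, 500))

build_encodings <- function(sequences, which, mock_dimension, equal_length) {
  out <- list()
  for (enc in which) {
    if (enc == "onehot") {
      if (!equal_length) next  # undefined for ragged lengths
      out$onehot <- encode_onehot(sequences)
    } else if (enc == "physchem") {
      out$physchem <- encode_physiochemical(sequences)
    } else if (enc == "mock") {
      out$mock <- encode_with_adapter(sequences, mock_adapter(mock_dimension))
    }
  }
  out
}

#' Run a configured experiment end to end
#'
#' Classification: simulates the library and its enrichment reads,
#' rebuilds labels through the preprocessing path (clean, frequency
#' filter, merge, hamming purge), encodes, runs all encoding-by-sampler
#' alternatives plus configured ensembles over the replicate seeds,
#' builds the decision matrix, ranks under entropy and subjective TOPSIS
#' weights, and validates with MANOVA + per-metric Tukey. Regression:
#' simulates a stability table, filters to pH 7 (and length cohort),
#' encodes, and fits the budgeted random-forest regressor per encoding.
#'
#' Artifacts written: `replicates.csv`, `decision_matrix.csv`,
#' `ranking.json`, `tukey.csv`, `manifest.json` (classification);
#' `regression_metrics.csv`, `manifest.json` (regression). Reruns with
#' the same config reproduce every numeric output.
#'
#' @param config an [experiment_config()].
#' @param out_dir run directory (created; existing artifacts are
#'   overwritten).
#' @return the run directory path, invisibly; partial failures keep
#'   completed artifacts and are listed in `failures.csv`.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(task = config$task,
                   seeds = config$seeds,
                   config_hash = hash_string(paste(deparse(config), collapse = "")),
                   package_version = as.character(utils::packageVersion("fitrank")))
  if (config$task == "classification") {
    sim <- simulate_affibody_library(config$affibody)
    reads <- simulate_enrichment_reads(sim$dataset, config$affibody)
    cleaned <- clean_sequences(names(reads$naive$counts))
    enriched <- union(frequency_filter(reads$macs), frequency_filter(reads$facs))
    ds <- build_labeled_dataset(cleaned$kept, enriched)
    encodings <- build_encodings(ds$sequences, config$encodings,
                                 config$mock_dimension, equal_length = TRUE)
    singles <- list()
    for (enc in names(encodings))
      for (smp in config$samplers)
        singles[[length(singles) + 1L]] <- alternative(enc, smp)
    alts <- c(singles, config$ensembles)
    reps <- run_replicates(encodings, ds$labels, alts, config$seeds,
                           test_fraction = config$test_fraction)
    write.csv(reps, file.path(out_dir, "replicates.csv"), row.names = FALSE)
    if (!is.null(attr(reps, "failures")))
      write.csv(attr(reps, "failures"), file.path(out_dir, "failures.csv"),
                row.names = FALSE)
    dm <- build_decision_matrix(reps)
    write.csv(data.frame(alternative = dm$alternative_ids, dm$x),
              file.path(out_dir, "decision_matrix.csv"), row.names = FALSE)
    rank_entropy <- topsis_rank(dm, entropy_weights(dm))
    rank_subj <- topsis_rank(dm, subjective_weights())
    jsonlite::write_json(
      list(entropy = list(order = rank_entropy$order,
                          closeness = as.list(rank_entropy$closeness),
                          weights = as.list(rank_entropy$weights_used$w)),
           subjective = list(order = rank_subj$order,
                             closeness = as.list(rank_subj$closeness),
                             weights = as.list(rank_subj$weights_used$w))),
      file.path(out_dir, "ranking.json"), auto_unbox = TRUE, digits = NA)
    groups <- split(reps[, METRIC_CRITERIA], reps$alternative)
    groups <- lapply(groups, as.matrix)
    # FDR = 1 - precision exactly, so the six-criteria within-group
    # covariance is singular by construction: the joint test runs on the
    # five independent criteria, the Tukey follow-up still covers all six
    g5 <- lapply(groups, function(m) m[, setdiff(METRIC_CRITERIA, "FDR"),
                                       drop = FALSE])
    mv <- tryCatch(manova_pillai(g5), error = function(e) NULL)
    if (!is.null(mv)) {
      fdr_t <- tryCatch(tukey_hsd(lapply(groups, function(m) m[, "FDR"])),
                        error = function(e) NULL)
      if (!is.null(fdr_t)) {
        fdr_t$metric <- "FDR"
        mv$tukey <- rbind(mv$tukey, fdr_t)
      }
    }
    if (!is.null(mv) && !is.null(mv$tukey))
      write.csv(mv$tukey, file.path(out_dir, "tukey.csv"), row.names = FALSE)
    manifest$n_sequences <- length(ds$sequences)
    manifest$n_positive <- sum(ds$labels)
    manifest$manova_p <- if (!is.null(mv)) mv$p_value else NA
  } else {
    tab <- simulate_nesp_like(config$nesp)
    st <- filter_stability(tab)
    reg <- st$regression
    if (!is.null(config$cohort)) {
      b <- cohort_bounds[[config$cohort]]
      len <- nchar(reg$sequence)
      reg <- reg[len >= b[1] & len <= b[2], , drop = FALSE]
    }
    encodings <- build_encodings(reg$sequence, config$encodings,
                                 config$mock_dimension,
                                 equal_length = length(unique(nchar(reg$sequence))) == 1L)
    rows <- list()
    for (enc in names(encodings)) {
      X <- encodings[[enc]]$values
      for (seed in config$seeds[seq_len(min(3L, length(config$seeds)))]) {
        test_idx <- with_seed(seed,
          sort(sample(nrow(X), round(config$test_fraction * nrow(X)))))
        train_idx <- setdiff(seq_len(nrow(X)), test_idx)
        fitres <- fit_regressor(X[train_idx, , drop = FALSE],
                                reg$Tm[train_idx], seed = seed)
        pred <- predict(fitres$model, X[test_idx, , drop = FALSE])
        met <- regression_metrics(reg$Tm[test_idx], pred)
        rows[[length(rows) + 1L]] <- data.frame(
          encoding = enc, seed = seed,
          n_estimators = fitres$chosen$n_estimators,
          max_depth = fitres$chosen$max_depth,
          val_MSE = fitres$validation$MSE, val_R2 = fitres$validation$R2,
          test_MSE = met$MSE, test_R2 = met$R2)
      }
    }
    write.csv(do.call(rbind, rows),
              file.path(out_dir, "regression_metrics.csv"), row.names = FALSE)
    manifest$n_records <- nrow(reg)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Write a human-readable summary of a run directory
#'
#' Produces `report.txt` with per-alternative mean and sd of each
#' criterion, the rankings under both weighting schemes, and the Tukey
#' decisions. Missing artifacts are listed as absent; regeneration is
#' idempotent.
#'
#' @param run_dir directory produced by [run_experiment()].
#' @return path of the report, invisibly; attribute `missing` lists
#'   absent artifacts.
#' @export
write_report <- function(run_dir) {
  lines <- c("fitrank run report", strrep("=", 60))
  missing <- character(0)
  grab <- function(file) {
    p <- file.path(run_dir, file)
    if (!file.exists(p)) { missing <<- c(missing, file); return(NULL) }
    p
  }
  p <- grab("replicates.csv")
  if (!is.null(p)) {
    reps <- read.csv(p)
    lines <- c(lines, "", "Per-alternative criteria (mean +/- sd over seeds):")
    for (a in unique(reps$alternative)) {
      sub <- reps[reps$alternative == a, METRIC_CRITERIA]
      lines <- c(lines, sprintf("  %-28s %s", a,
        paste(vapply(METRIC_CRITERIA, function(m)
          sprintf("%s=%.4f+/-%.4f", m, mean(sub[[m]]), sd(sub[[m]])),
          character(1)), collapse = " ")))
    }
  }
  p <- grab("ranking.json")
  if (!is.null(p)) {
    rk <- jsonlite::read_json(p)
    for (scheme in c("entropy", "subjective")) {
      lines <- c(lines, "", paste0("TOPSIS ranking (", scheme, " weights):"))
      ord <- unlist(rk[[scheme]]$order)
      cc <- rk[[scheme]]$closeness
      lines <- c(lines, vapply(seq_along(ord), function(i)
        sprintf("  %2d. %-28s C = %.4f", i, ord[i],
                as.numeric(cc[[ord[i]]])), character(1)))
    }
  }
  p <- grab("tukey.csv")
  if (!is.null(p)) {
    tk <- read.csv(p)
    lines <- c(lines, "", sprintf("Tukey decisions: %d of %d pairs rejected",
                                  sum(tk$reject), nrow(tk)))
  }
  # task-specific artifact: absent only counts against a regression run
  p_reg <- file.path(run_dir, "regression_metrics.csv")
  p <- if (file.exists(p_reg)) p_reg
       else if (file.exists(file.path(run_dir, "replicates.csv"))) NULL
       else { missing <- c(missing, "regression_metrics.csv"); NULL }
  if (!is.null(p)) {
    rg <- read.csv(p)
    lines <- c(lines, "", "Regression (Tm) test metrics by encoding:")
    for (e in unique(rg$encoding)) {
      sub <- rg[rg$encoding == e, ]
      lines <- c(lines, sprintf("  %-10s R2 = %.3f  MSE = %.1f", e,
                                mean(sub$test_R2), mean(sub$test_MSE)))
    }
  }
  if (length(missing))
    lines <- c(lines, "", paste("ABSENT artifacts:",
                                paste(missing, collapse = ", ")))
  out <- file.path(run_dir, "report.txt")
  writeLines(lines, out)
  res <- invisible(out)
  attr(res, "missing") <- missing
  res
}
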