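# Significance machinery: one-way ANOVA, Bonferroni, Tukey HSD and a
# Pillai-trace MANOVA with per-metric Tukey follow-up. Classical base-R
# routines back the heavy lifting; the guards, interfaces and
# calibration tests live here.

check_grouped <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be named")
  sizes <- vapply(groups, NROW, integer(1))
  if (any(sizes < 2L)) stop("every group needs at least 2 observations")
  invisible(sizes)
}

#' Classical one-way analysis of variance
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 observations), e.g. per-seed metric values per alternative.
#' @return list with `F` and `p_value` (plus degrees of freedom).
#' @export
anova_oneway <- function(groups) {
  check_grouped(groups)
  k <- length(groups)
  n_i <- vapply(groups, length, integer(1))
  N <- sum(n_i)
  m_i <- vapply(groups, mean, numeric(1))
  grand <- sum(n_i * m_i) / N
  ssb <- sum(n_i * (m_i - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0)
    stop("undefined F statistic: zero within-group variance in all groups")
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = f, p_value = pf(f, k - 1, N - k, lower.tail = FALSE),
       df_between = k - 1, df_within = N - k)
}

#' Bonferroni p-value adjustment
#'
#' Multiplies each p-value by the family size and clips at 1.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param m family size (defaults to `length(p_values)`).
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE) || anyNA(p_values))
    stop("p-values must lie in [0, 1]")
  pmin(p_values * m, 1)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentised-range pairwise comparisons at family-wise level `alpha`
#' following a one-way layout.
#'
#' @param groups named list of numeric vectors (see [anova_oneway()]).
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with one row per group pair: `group1`, `group2`,
#'   `mean1`, `mean2`, `mean_diff`, `p_adj`, `reject`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  check_grouped(groups)
  if (all(vapply(groups, function(g) var(g) == 0, logical(1))))
    stop("undefined comparisons: zero within-group variance in all groups")
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1)))))
  hsd <- TukeyHSD(aov(value ~ group, data = df), conf.level = 1 - alpha)$group
  pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  means <- vapply(groups, mean, numeric(1))
  out <- data.frame(
    group1 = vapply(pairs, `[`, character(1), 1),
    group2 = vapply(pairs, `[`, character(1), 2),
    stringsAsFactors = FALSE)
  out$mean1 <- unname(means[out$group1])
  out$mean2 <- unname(means[out$group2])
  out$mean_diff <- unname(hsd[, "diff"])
  out$p_adj <- unname(hsd[, "p adj"])
  out$reject <- out$p_adj < alpha
  out
}

#' Pillai-trace MANOVA with per-metric Tukey follow-up
#'
#' Tests whether group mean vectors over several criteria differ jointly
#' (Pillai's trace, chosen for robustness), then runs a Tukey HSD per
#' criterion so every (group pair, metric) receives one reject/fail
#' decision -- the layout used for reporting pairwise comparisons of
#' modelling alternatives.
#'
#' @param groups named list of numeric matrices with identical column
#'   names (observations x criteria), >= 2 groups.
#' @param alpha significance level for the follow-up decisions.
#' @return list with `pillai`, `p_value`, and `tukey` (data.frame with
#'   columns group1, group2, metric, mean1, mean2, p_adj, reject).
#' @export
manova_pillai <- function(groups, alpha = 0.05) {
  check_grouped(groups)
  groups <- lapply(groups, as.matrix)
  m <- unique(vapply(groups, ncol, integer(1)))
  if (length(m) != 1L) stop("all groups must share the same criteria columns")
  n_total <- sum(vapply(groups, nrow, integer(1)))
  if (n_total < m + length(groups))
    stop("too few observations: need at least n_criteria + n_groups = ",
         m + length(groups), ", have ", n_total)
  Y <- do.call(rbind, groups)
  g <- factor(rep(names(groups), vapply(groups, nrow, integer(1))))
  fit <- manova(Y ~ g)
  sm <- tryCatch(summary(fit, test = "Pillai"),
                 error = function(e)
                   stop("MANOVA failed (likely singular within-group ",
                        "covariance; consider removing a redundant ",
                        "criterion): ", conditionMessage(e)))
  tab <- sm$stats
  pillai <- tab["g", "Pillai"]
  p <- tab["g", "Pr(>F)"]
  metrics <- colnames(groups[[1]]) %||% paste0("criterion_", seq_len(m))
  follow <- do.call(rbind, lapply(seq_len(m), function(j) {
    per_metric <- lapply(groups, function(gm) gm[, j])
    td <- tryCatch(tukey_hsd(per_metric, alpha), error = function(e) NULL)
    if (is.null(td)) return(NULL)
    td$metric <- metrics[j]
    td
  }))
  list(pillai = unname(pillai), p_value = unname(p), tukey = follow)
}
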