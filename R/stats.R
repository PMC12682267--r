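# Nonparametric tests, Bonferroni correction, OLS two-way ANOVA and
# chi-squared tests, reported in a uniform result structure.

stat_result <- function(test_name, statistic, p_value, n, df = NA_real_,
                        correction = "none", adjusted_p = p_value,
                        note = NULL) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, n = n, df = df,
                 correction = correction, adjusted_p = adjusted_p,
                 note = note),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s: statistic = %g, p = %g (n = %s%s)\n",
              x$test_name, x$statistic, x$p_value,
              paste(x$n, collapse = ", "),
              if (!is.null(x$note)) paste0("; ", x$note) else ""))
  invisible(x)
}

#' Wilcoxon signed-rank test for paired data
#'
#' Two-sided. Zero differences are dropped before ranking (the classical
#' zero-handling rule; the policy is recorded in the result). The exact
#' null distribution is used up to `exact_max` nonzero differences when
#' there are no rank ties; otherwise a normal approximation with continuity
#' correction. If every difference is zero the result is defined with
#' p = 1 and flagged rather than raising.
#'
#' @param x paired differences, or first members of the pairs when `y` is
#'   given.
#' @param y optional second members; differences are `x - y`.
#' @param exact_max largest n for which the exact distribution is used.
#' @return a `stat_result` (statistic is the signed-rank sum V of positive
#'   differences).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(stat_result("wilcoxon_signed_rank", statistic = 0, p_value = 1,
                       n = 0, note = "all differences zero"))
  }
  ties <- any(duplicated(abs(d)))
  exact <- n <= exact_max && !ties
  wt <- suppressWarnings(stats::wilcox.test(d, exact = exact,
                                            correct = TRUE))
  stat_result("wilcoxon_signed_rank",
              statistic = unname(wt$statistic),
              p_value = wt$p.value, n = n,
              note = sprintf("%s; %d zero difference(s) dropped",
                             if (exact) "exact" else
                               "normal approximation with continuity correction",
                             n_zero))
}

#' Mann-Whitney U test for unpaired data
#'
#' Two-sided. Exact when the smaller group has at most `exact_small`
#' observations and there are no ties; otherwise a tie-corrected normal
#' approximation with continuity correction.
#'
#' @param group_a,group_b numeric vectors.
#' @param exact_small exact-distribution cutoff on `min(n_a, n_b)`.
#' @return a `stat_result` (statistic is U for `group_a`).
#' @export
mann_whitney_u <- function(group_a, group_b, exact_small = 8) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (!length(group_a) || !length(group_b)) {
    parameter_error("both groups must be nonempty")
  }
  ties <- any(duplicated(c(group_a, group_b)))
  exact <- min(length(group_a), length(group_b)) <= exact_small && !ties
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            exact = exact, correct = TRUE))
  stat_result("mann_whitney_u", statistic = unname(wt$statistic),
              p_value = wt$p.value,
              n = c(length(group_a), length(group_b)),
              note = if (exact) "exact" else
                "tie-corrected normal approximation")
}

#' Bonferroni correction
#'
#' `adjusted = min(1, m * p)` for a declared family of `m` comparisons
#' (`m` may exceed the number of p-values supplied).
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @param m family size; defaults to `length(p_values)`.
#' @return adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < 1) parameter_error("`m` must be >= 1")
  if (m < length(p_values)) {
    parameter_error("`m` must be at least the number of p-values")
  }
  pmin(1, m * p_values)
}

#' Two-way OLS ANOVA on paired input-output curves
#'
#' Fits `frequency ~ condition * relative_step` by ordinary least squares
#' (treatment coding) and reports Type II F tests for the light (LED) main
#' effect, the step main effect, and their interaction. Rows are treated as
#' independent even though cells contribute several steps (the convention
#' being reproduced); a warning notes the repeated-measures caveat, and a
#' cell-cluster-robust variant is available via `cluster_robust = TRUE`
#' (requires the sandwich package).
#'
#' @param io_table long table from [io_curve_table()]: columns `cell_id`,
#'   `relative_index`, `condition`, `frequency_hz`.
#' @param cluster_robust use a cluster-robust covariance (clustered on
#'   `cell_id`) for the F tests.
#' @param warn emit the repeated-measures warning.
#' @return named list of `stat_result` objects: `condition`, `step`,
#'   `interaction`.
#' @export
anova_io_curves <- function(io_table, cluster_robust = FALSE, warn = TRUE) {
  need <- c("cell_id", "relative_index", "condition", "frequency_hz")
  if (!all(need %in% names(io_table))) {
    parameter_error(paste("`io_table` needs columns:",
                          paste(need, collapse = ", ")))
  }
  io_table$condition <- factor(io_table$condition)
  io_table$relative_index <- factor(io_table$relative_index)
  if (nlevels(io_table$condition) < 2 || nlevels(io_table$relative_index) < 2) {
    parameter_error("both factors need at least 2 levels")
  }
  if (warn) {
    warning("rows are treated as independent although cells contribute ",
            "multiple steps; consider cluster_robust = TRUE",
            call. = FALSE)
  }
  fit <- stats::lm(frequency_hz ~ condition * relative_index,
                   data = io_table)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    analysis_error(paste("rank-deficient design; aliased terms:",
                         paste(aliased, collapse = ", ")))
  }
  an <- if (cluster_robust) {
    if (!requireNamespace("sandwich", quietly = TRUE)) {
      capability_error("cluster_robust = TRUE requires the sandwich package")
    }
    vc <- sandwich::vcovCL(fit, cluster = io_table$cell_id)
    car::Anova(fit, type = 2, vcov. = vc)
  } else {
    car::Anova(fit, type = 2)
  }
  rn <- rownames(an)
  f_col <- intersect(c("F value", "F"), colnames(an))[1]
  grab <- function(term, label) {
    i <- match(term, rn)
    stat_result(paste0("two_way_anova_", label),
                statistic = an[i, f_col], p_value = an[i, "Pr(>F)"],
                n = nrow(io_table),
                df = c(an[i, "Df"], an["Residuals", "Df"]))
  }
  list(condition = grab("condition", "condition"),
       step = grab("relative_index", "step"),
       interaction = grab("condition:relative_index", "interaction"))
}

#' Pearson chi-squared test of independence
#'
#' For comparing response-class distributions across stimulation protocols.
#' No continuity correction by default.
#'
#' @param counts matrix of contingency counts (>= 2 rows and columns).
#' @param correct apply Yates continuity correction (2x2 only).
#' @return a `stat_result`.
#' @export
chi_squared_independence <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    parameter_error("contingency table needs >= 2 rows and columns")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    analysis_error("contingency table has an empty row or column")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  stat_result("chi_squared_independence",
              statistic = unname(ct$statistic),
              p_value = ct$p.value, n = sum(counts),
              df = unname(ct$parameter))
}
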