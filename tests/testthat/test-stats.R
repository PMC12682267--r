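# Statistics layer against brute-force enumeration oracles and closed
# forms.

test_that("signed-rank p-values match exhaustive enumeration", {
  # all-positive differences 1..5: V = 15, exact two-sided p = 2/32
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5))
  expect_equal(r$p_value, 0.0625)
  expect_equal(r$p_value, oracle_signed_rank_p(c(1, 2, 3, 4, 5)))
  # symmetric differences sit at the null center
  r2 <- wilcoxon_signed_rank(c(1.5, -1, 2, -2.5))
  expect_gte(r2$p_value, 0.8)
  # random tie-free cases, n = 8
  set.seed(91)
  for (i in 1:12) {
    d <- round(rnorm(8, 0.3, 1), 3)
    while (any(duplicated(abs(d))) || any(d == 0)) d <- round(rnorm(8, 0.3, 1), 3)
    expect_equal(wilcoxon_signed_rank(d)$p_value, oracle_signed_rank_p(d),
                 tolerance = 1e-12)
  }
})

test_that("signed-rank zero handling is explicit", {
  r <- wilcoxon_signed_rank(c(0, 0, 0))
  expect_equal(r$p_value, 1)
  expect_match(r$note, "all differences zero")
  r2 <- wilcoxon_signed_rank(c(0, 1, 2, 3))
  expect_identical(r2$n, 3L)
  expect_match(r2$note, "1 zero difference")
})

test_that("Mann-Whitney matches enumeration and closed forms", {
  # disjoint ranges: U = 0, exact p = 2 / C(na+nb, na)
  a <- c(1, 2, 3); b <- c(10, 11, 12, 13)
  r <- mann_whitney_u(a, b)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / choose(7, 3))
  expect_equal(r$p_value, oracle_mann_whitney_p(a, b))
  # identical-ish groups: U near the center, p near 1
  r2 <- mann_whitney_u(c(1, 3, 5, 7), c(2, 4, 6, 8))
  expect_gt(r2$p_value, 0.5)
  # random (5, 5) tie-free cases
  set.seed(92)
  for (i in 1:10) {
    x <- round(rnorm(5), 3); y <- round(rnorm(5, 0.5), 3)
    if (any(duplicated(c(x, y)))) next
    expect_equal(mann_whitney_u(x, y)$p_value, oracle_mann_whitney_p(x, y),
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "msnephys_parameter_error")
})

test_that("Bonferroni adjustment follows its identities", {
  expect_equal(bonferroni(0.01, m = 3), 0.03)
  expect_equal(bonferroni(0.5, m = 3), 1)
  expect_equal(bonferroni(c(0.2, 0.04)), c(0.4, 0.08))
  expect_equal(bonferroni(0.2, m = 1), 0.2)
  p <- runif(5)
  expect_true(all(bonferroni(p, m = 5) >= p))
  expect_true(all(bonferroni(p, m = 5) <= 1))
  expect_error(bonferroni(0.5, m = 0), class = "msnephys_parameter_error")
  expect_error(bonferroni(c(0.1, 0.2), m = 1),
               class = "msnephys_parameter_error")
})

test_that("two-way ANOVA F statistics match hand-computed sums of squares", {
  # balanced 2x2 with r = 3 replicates and known cell means
  d <- expand.grid(condition = c("no_light", "light"),
                   relative_index = c(-1, 0), rep = 1:3)
  mu <- with(d, ifelse(condition == "light", 2, 0) +
               ifelse(relative_index == 0, 3, 0))
  resid <- c(0.3, -0.3, 0, 0.1, -0.1, 0, -0.2, 0.2, 0, 0.25, -0.25, 0)
  d$frequency_hz <- mu + resid
  d$cell_id <- "c1"
  res <- suppressWarnings(anova_io_curves(d, warn = FALSE))
  # hand computation (balanced: type II == type I)
  grand <- mean(d$frequency_hz)
  ss_a <- 6 * sum((tapply(d$frequency_hz, d$condition, mean) - grand)^2)
  ss_b <- 6 * sum((tapply(d$frequency_hz, d$relative_index, mean) - grand)^2)
  cellm <- tapply(d$frequency_hz, interaction(d$condition, d$relative_index),
                  mean)
  ss_cells <- 3 * sum((cellm - grand)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_e <- sum((d$frequency_hz - ave(d$frequency_hz,
                                    interaction(d$condition,
                                                d$relative_index)))^2)
  f_a <- (ss_a / 1) / (ss_e / 8)
  f_ab <- (ss_ab / 1) / (ss_e / 8)
  expect_equal(res$condition$statistic, f_a, tolerance = 1e-9)
  expect_equal(res$interaction$statistic, f_ab, tolerance = 1e-9)
  expect_equal(res$condition$p_value, pf(f_a, 1, 8, lower.tail = FALSE),
               tolerance = 1e-9)
})

test_that("an additive light effect is detected with high power", {
  set.seed(93)
  hits <- 0
  for (rep in 1:50) {
    d <- expand.grid(cell_id = sprintf("c%02d", 1:20),
                     relative_index = 0:5,
                     condition = c("no_light", "light"))
    d$frequency_hz <- 4 + 2 * d$relative_index +
      2 * (d$condition == "light") + rnorm(nrow(d), 0, 0.5)
    p <- suppressWarnings(anova_io_curves(d, warn = FALSE))$condition$p_value
    if (p < 0.01) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.95)
})

test_that("permuting the light labels restores the null", {
  set.seed(94)
  ps <- replicate(60, {
    d <- expand.grid(cell_id = sprintf("c%02d", 1:10),
                     relative_index = 0:3,
                     condition = c("no_light", "light"))
    d$frequency_hz <- 4 + 2 * d$relative_index + rnorm(nrow(d), 0, 0.5)
    d$condition <- sample(d$condition)
    suppressWarnings(anova_io_curves(d, warn = FALSE))$condition$p_value
  })
  expect_gt(mean(ps < 0.05), 0)   # sanity: p-values vary
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("rank-deficient ANOVA designs fail loudly and warnings fire", {
  d <- expand.grid(condition = c("no_light", "light"), relative_index = 0:1)
  d$frequency_hz <- 1:4
  d <- d[d$condition == "no_light" | d$relative_index == 0, ]
  d$cell_id <- "c1"
  expect_error(suppressWarnings(anova_io_curves(d)),
               class = "msnephys_analysis_error")
  d2 <- expand.grid(condition = c("no_light", "light"),
                    relative_index = 0:1, rep = 1:2)
  d2$frequency_hz <- rnorm(8)
  d2$cell_id <- "c1"
  expect_warning(anova_io_curves(d2), "independent")
})

test_that("chi-squared independence matches closed forms and bounds", {
  r <- chi_squared_independence(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 1)
  # identical rows: statistic 0, p = 1
  r2 <- chi_squared_independence(matrix(c(5, 5, 7, 7), 2))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  # the short-pulse vs long-pulse response contingency
  tab <- rbind(c(48, 11, 3), c(10, 34, 12))
  r3 <- chi_squared_independence(tab)
  expect_lt(r3$p_value, 1e-4)
  # hand-computed Pearson statistic
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r3$statistic, sum((tab - E)^2 / E), tolerance = 1e-9)
  expect_error(chi_squared_independence(rbind(c(0, 0), c(1, 2))),
               class = "msnephys_analysis_error")
  expect_error(chi_squared_independence(matrix(1:3, 1)),
               class = "msnephys_parameter_error")
})
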