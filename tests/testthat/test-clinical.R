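test_that("signature scores equal a brute-force standardized mean", {
  cc <- simulate_clinical_cohort(40, c("gA", "gB", "gC"), seed = 2)
  sc <- signature_score(cc$cohort, c("gA", "gB", "gC"))
  brute <- rowMeans(cbind(
    scale(cc$cohort$gA), scale(cc$cohort$gB), scale(cc$cohort$gC)
  ))
  expect_equal(sc$score, as.numeric(brute))

  # single-gene signature: score equals that gene's standardized expression
  one <- signature_score(cc$cohort, "gA")
  expect_equal(one$score, as.numeric(scale(cc$cohort$gA)))

  # constant gene dropped with a warning
  cc$cohort$gC <- 5
  expect_warning(sc2 <- signature_score(cc$cohort, c("gA", "gC")), "zero-variance")
  expect_equal(sc2$score, as.numeric(scale(cc$cohort$gA)))

  # missing genes reported, all-missing is an error
  sc3 <- signature_score(cc$cohort, c("gA", "NOPE"))
  expect_equal(attr(sc3, "missing_genes"), "NOPE")
  expect_error(signature_score(cc$cohort, "NOPE"), "no signature gene")
})

test_that("median split sends ties low and ignores input order", {
  g <- median_split(c(1, 2, 3, 4))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  # odd n: the median member goes low
  g2 <- median_split(c(1, 2, 3, 4, 5))
  expect_equal(as.character(g2), c("low", "low", "low", "high", "high"))
  s <- c(3, 1, 4, 1, 5, 9, 2)
  expect_equal(median_split(s)[order(s)], sort(median_split(s)))
  perm <- c(4, 2, 7, 1, 3, 6, 5)
  expect_equal(as.character(median_split(s[perm])), as.character(median_split(s)[perm]))
  expect_error(median_split(rep(1, 6)), "degenerate")
  expect_error(median_split(c(1, 2)), "at least 4")
})

test_that("identical event patterns give statistic 0 and HR 1", {
  cohort <- tibble(subject = sprintf("P%d", 1:6),
                   time = c(1, 2, 3, 1, 2, 3),
                   event = 1)
  groups <- factor(rep(c("low", "high"), each = 3), levels = c("low", "high"))
  res <- logrank_hr(cohort, groups)
  expect_equal(res$logrank_chisq, 0, tolerance = 1e-12)
  expect_equal(res$hr, 1, tolerance = 1e-12)
})

test_that("observed/expected totals match a manual risk-set tabulation", {
  # 6 subjects; low: events at 1, 3, censored 5; high: events at 2, 4, 6
  cohort <- tibble(subject = sprintf("P%d", 1:6),
                   time = c(1, 3, 5, 2, 4, 6),
                   event = c(1, 1, 0, 1, 1, 1))
  groups <- factor(rep(c("low", "high"), each = 3), levels = c("low", "high"))
  res <- logrank_hr(cohort, groups)
  # manual tabulation: E_low = 3/6 + 2/5 + 2/4 + 1/3, E_high = the rest
  e_low <- 3 / 6 + 2 / 5 + 2 / 4 + 1 / 3 + 0
  e_high <- 3 / 6 + 3 / 5 + 2 / 4 + 2 / 3 + 1
  expect_equal(unname(res$observed), c(2, 3))
  expect_equal(unname(res$expected), c(e_low, e_high), tolerance = 1e-9)
  expect_equal(res$hr, (3 / e_high) / (2 / e_low), tolerance = 1e-9)
})

test_that("swapping group labels inverts the hazard ratio and keeps the statistic", {
  cc <- simulate_clinical_cohort(100, c("gA", "gB"), planted_log_hr = log(1.8),
                                 seed = 3)
  sc <- signature_score(cc$cohort, c("gA", "gB"))
  g <- median_split(sc$score)
  res <- logrank_hr(cc$cohort, g)
  flipped <- factor(ifelse(g == "low", "high", "low"), levels = c("low", "high"))
  res2 <- logrank_hr(cc$cohort, flipped)
  expect_equal(res2$hr, 1 / res$hr, tolerance = 1e-9)
  expect_equal(res2$logrank_chisq, res$logrank_chisq, tolerance = 1e-9)
})

test_that("KM curves are non-increasing and start at or below 1", {
  cc <- simulate_clinical_cohort(60, c("gA", "gB"), planted_log_hr = log(2),
                                 censor_rate = 0.3, seed = 5)
  res <- signature_survival(cc$cohort, c("gA", "gB"))
  km <- tidy(res)
  for (grp in unique(km$group)) {
    s <- km$survival[km$group == grp]
    expect_true(all(diff(s) <= 1e-12))
    expect_lte(max(s), 1)
  }
  expect_error(logrank_hr(tibble(time = c(1, 2), event = c(0, 0)),
                          factor(c("low", "high"), levels = c("low", "high"))),
               "no events")
})

test_that("Spearman correlation handles monotone, reversed, and tied data", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11)
  expect_equal(spearman_corr(x, x^3)$rho, 1)
  expect_equal(spearman_corr(x, -x)$rho, -1)
  y <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 12)
  expect_equal(spearman_corr(x, y)$rho, cor(x, y, method = "spearman"))
  expect_error(spearman_corr(rep(1, 6), x[1:6]), "zero variance")
  expect_error(spearman_corr(1:4, 1:4), "at least 5")
})

test_that("exact permutation p at n = 7 equals the reference exact distribution", {
  set.seed(17)
  for (trial in 1:5) {
    x <- sample(100, 7)
    y <- sample(100, 7)
    got <- spearman_corr(x, y)
    expect_equal(got$method, "exact permutation")
    ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  }
})

test_that("large-sample p uses the t approximation and matches it", {
  set.seed(18)
  x <- rnorm(30)
  y <- 0.5 * x + rnorm(30)
  got <- spearman_corr(x, y)
  rho <- cor(x, y, method = "spearman")
  tstat <- rho * sqrt(28 / (1 - rho^2))
  expect_equal(got$p, 2 * pt(-abs(tstat), 28))
  expect_equal(got$method, "t approximation")
})
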