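test_that("normality screen behaves under null and lognormal alternatives", {
  verdicts <- sapply(1:100, function(s) {
    withr::with_seed(s, {
      x <- rnorm(29)
      test_normality(x)$normal
    })
  })
  expect_gte(mean(verdicts), 0.9)
  skewed <- sapply(1:100, function(s) {
    withr::with_seed(s, {
      x <- exp(rnorm(29))
      test_normality(x)$normal
    })
  })
  expect_lte(mean(skewed), 0.2)
})

test_that("constant vectors are flagged degenerate", {
  v <- test_normality(rep(3, 10))
  expect_true(v$degenerate)
  expect_false(v$normal)
  expect_true(is.na(v$shapiro_p))
})

test_that("test routing follows the normality/homogeneity rule", {
  withr::with_seed(1, {
    pre <- rnorm(29)
    post <- rnorm(29)
  })
  expect_identical(route_paired_test(pre, post), "paired_t")
  expect_identical(route_paired_test(exp(pre * 2), post), "wilcoxon")
  # heteroscedastic but normal: Levene reroutes to Wilcoxon
  expect_identical(route_paired_test(pre * 10, post * 0.1), "wilcoxon")
  expect_error(route_paired_test(pre, post[-1]), "paired")
})

test_that("all-positive differences give the textbook exact Wilcoxon p", {
  res <- compare_paired(1:6, 1:6 + c(1, 2, 3, 4, 5, 6), method = "wilcoxon")
  expect_equal(res$p_value, 2 / 64)
  expect_equal(res$statistic, 21)
})

test_that("identical pairs give p = 1 with a warning", {
  expect_warning(res <- compare_paired(1:6, 1:6, method = "wilcoxon"),
                 "zero")
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
})

test_that("exact signed-rank p equals full sign enumeration, ties included", {
  for (s in 1:30) {
    d <- withr::with_seed(s, sample(-5:5, sample(6:12, 1), replace = TRUE))
    d <- d[d != 0]
    if (length(d) < 5) next
    got <- compare_paired(rep(0, length(d)), d, method = "wilcoxon")$p_value
    expect_equal(got, bf_wilcoxon_p(d), info = paste("seed", s))
  }
})

test_that("large-sample path approximates the exact distribution", {
  d <- withr::with_seed(42, rnorm(40, mean = 0.3))
  got <- compare_paired(rep(0, 40), d, method = "wilcoxon")
  ref <- suppressWarnings(stats::wilcox.test(d, correct = TRUE,
                                             exact = FALSE))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("paired t matches the closed-form t distribution", {
  pre <- c(10, 12, 14, 9, 13)
  post <- c(11, 14, 17, 9.5, 15)
  d <- post - pre
  tstat <- mean(d) / (sd(d) / sqrt(5))
  res <- compare_paired(pre, post, method = "paired_t")
  expect_equal(res$statistic, tstat)
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df = 4))
})

test_that("log-scale summary centre is the geometric mean of its bounds", {
  s <- summarize_parameter(c(1, 10, 100), skewed = TRUE)
  expect_equal(s$mean, 10)
  expect_equal(sqrt(s$ci_lo * s$ci_hi), s$mean)
  # property: identity holds for arbitrary positive data and both intervals
  for (seed in 1:20) {
    x <- withr::with_seed(seed, exp(rnorm(25, 1, 0.8)))
    for (interval in c("individual", "mean")) {
      s <- summarize_parameter(x, skewed = TRUE, interval = interval)
      expect_equal(sqrt(s$ci_lo * s$ci_hi), s$mean, tolerance = 1e-12)
    }
  }
})

test_that("non-positive values on the skewed path fail loudly", {
  expect_error(summarize_parameter(c(1, -2, 3), skewed = TRUE, name = "CRP_I"),
               "CRP_I.*observation 2")
})

test_that("cohort summary reproduces the pre/post table shape", {
  coh <- generate_cohort(default_study_spec(), seed = 2)
  tab <- summarize_cohort(coh)
  expect_true(all(c("INFg", "TNFa", "CRP", "Se", "TSH") %in% tab$parameter))
  expect_true(all(tab$test_used %in% c("paired_t", "wilcoxon")))
  expect_identical(tab$significant, tab$p_value < 0.05)
  # lognormal biomarkers are summarised on the log scale
  tnfa <- tab[tab$parameter == "TNFa", ]
  expect_true(tnfa$skewed_initial)
  expect_true(is.finite(tnfa$ci_lo_initial))
  expect_match(tnfa$initial, "#")
  # normal biomarkers as mean +/- sd
  expect_false(tab$skewed_initial[tab$parameter == "CXCL10"])
})

test_that("skewness override pins the flag set", {
  coh <- generate_cohort(default_study_spec(), seed = 2)
  tab <- summarize_cohort(coh, skewed_override = c(CXCL10_I = TRUE,
                                                   TNFa_I = FALSE))
  expect_true(tab$skewed_initial[tab$parameter == "CXCL10"])
  expect_false(tab$skewed_initial[tab$parameter == "TNFa"])
})
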