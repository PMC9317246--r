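test_that("spec validation rejects malformed inputs", {
  p <- dplyr::bind_rows(
    parameter_spec("a", "normal", 0, 1),
    parameter_spec("b", "normal", 0, 1)
  )
  expect_error(synthetic_spec(dplyr::bind_rows(p, p[1, ])), "duplicated")
  bad <- p
  bad$scale[1] <- 0
  expect_error(synthetic_spec(bad), "non-positive scale")
  expect_error(synthetic_spec(p, n_patients = 2), "at least 3")
  expect_error(synthetic_spec(p, na_rate = 1), "na_rate")
  expect_error(
    synthetic_spec(p, loadings = tibble::tibble(factor = "f",
                                                parameter = "zz",
                                                loading = 1)),
    "unknown parameter"
  )
  expect_error(
    synthetic_spec(p, loadings = tibble::tibble(factor = "f",
                                                parameter = "a",
                                                loading = Inf)),
    "finite"
  )
})

test_that("degenerate generator returns the location matrix exactly", {
  p <- dplyr::bind_rows(
    parameter_spec("a", "normal", 5, 1, noise = 0),
    parameter_spec("b", "normal", -2, 3, noise = 0)
  )
  coh <- generate_cohort(synthetic_spec(p, n_patients = 6, seed = 1))
  expect_equal(unname(cohort_matrix(coh)),
               matrix(c(rep(5, 6), rep(-2, 6)), 6, 2))
})

test_that("generation is bit-reproducible given the seed", {
  spec <- tiny_two_param_spec(n = 50)
  c1 <- generate_cohort(spec, seed = 11)
  c2 <- generate_cohort(spec, seed = 11)
  c3 <- generate_cohort(spec, seed = 12)
  expect_identical(c1, c2)
  expect_false(identical(c1, c3))
})

test_that("marginals follow the requested family, location and scale", {
  p <- dplyr::bind_rows(
    parameter_spec("norm", "normal", 10, 2),
    parameter_spec("logn", "lognormal", 1, 0.5)
  )
  coh <- generate_cohort(synthetic_spec(p, n_patients = 10000, seed = 3))
  expect_equal(mean(coh$norm), 10, tolerance = 0.02)
  expect_equal(sd(coh$norm), 2, tolerance = 0.02)
  expect_true(all(coh$logn > 0))
  expect_equal(mean(log(coh$logn)), 1, tolerance = 0.02)
  expect_equal(sd(log(coh$logn)), 0.5, tolerance = 0.02)
})

test_that("empirical correlation matches the factor-model closed form", {
  spec <- tiny_two_param_spec(loading = 0.8, n = 10000, seed = 5)
  closed <- 0.8 * 0.8 / (0.8^2 + 1)
  expect_equal(factor_model_correlation(spec)["a", "b"], closed)
  coh <- generate_cohort(spec)
  expect_equal(cor(coh$a, coh$b), closed, tolerance = 0.03)
})

test_that("pre/post shift is planted on the family scale", {
  p <- dplyr::bind_rows(
    parameter_spec("x_I", "normal", 75.0, 11.1),
    parameter_spec("x_F", "normal", 75.0, 6.3, shift = 12.7)
  )
  coh <- generate_cohort(synthetic_spec(p, n_patients = 5000, seed = 7))
  expect_equal(mean(coh$x_F) - mean(coh$x_I), 12.7, tolerance = 0.5)
})

test_that("MCAR masking hits approximately the requested rate", {
  spec <- tiny_two_param_spec(n = 2000)
  spec$na_rate <- 0.2
  coh <- generate_cohort(spec, seed = 9)
  expect_equal(mean(is.na(cohort_matrix(coh))), 0.2, tolerance = 0.03)
})

test_that("default study spec reproduces the reported design", {
  spec <- default_study_spec()
  expect_s3_class(spec, "synthetic_spec")
  expect_identical(spec$n_patients, 29L)
  pars <- spec$parameters
  infg_f <- pars[pars$name == "INFg_F", ]
  expect_equal(infg_f$location + infg_f$shift, 4.47)
  expect_equal(pars$location[pars$name == "INFg_I"], 6.25)
  se_f <- pars[pars$name == "Se_F", ]
  expect_equal(se_f$location + se_f$shift, 87.7)
  # skewed biomarkers are lognormal: TNF-a, IL-17, CRP, anti-TPO, final IL-1b
  logn <- pars$name[pars$family == "lognormal"]
  expect_true(all(c("TNFa_I", "TNFa_F", "IL17_I", "IL17_F", "CRP_I",
                    "CRP_F", "IL1b_F", "antiTPO_I") %in% logn))
  expect_false("IL1b_I" %in% logn)
})

test_that("selenium marginals land near their reported means", {
  coh <- generate_cohort(default_study_spec(), seed = 1)
  # within 3 standard errors of the reported values
  expect_lt(abs(mean(coh$Se_I) - 75.0), 3 * 11.1 / sqrt(29))
  expect_lt(abs(mean(coh$Se_F) - 87.7), 3 * 6.3 / sqrt(29))
})

test_that("calibrated spec hits the published rank correlations in expectation", {
  spec <- default_study_spec()
  C <- factor_model_correlation(spec)
  targets <- thyropls:::study_spearman_targets()
  implied <- pearson_to_spearman(
    mapply(function(a, b) C[a, b], targets$param_a, targets$param_b)
  )
  expect_true(all(abs(implied - targets$rho_s) < 0.15))
  # within-patient pre/post correlation close to the declared 0.5
  bases <- c("INFg", "IL4", "T3", "TG", "GPX3", "CRP", "Se", "HDL")
  pair_corr <- sapply(bases, function(b) C[paste0(b, "_I"), paste0(b, "_F")])
  expect_true(all(abs(pair_corr - 0.5) < 0.1))
})

test_that("gaussian-rank conversion is the inverse pair it claims to be", {
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(spearman_to_pearson(pearson_to_spearman(r)), r,
               tolerance = 1e-12)
})
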