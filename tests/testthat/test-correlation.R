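test_that("correlation weight is the planar dot product", {
  expect_equal(correlation_weight(c(0.5, 0.2), c(0.4, -0.1)), 0.18)
  expect_equal(correlation_weight(c(1, 0), c(0, 1)), 0)
  a <- c(0.3, -0.4)
  expect_equal(correlation_weight(a, a), sum(a^2))
  expect_gt(correlation_weight(a, a), 0)
})

test_that("correlation weight is symmetric, bilinear and sign-faithful", {
  for (s in 1:20) {
    v <- withr::with_seed(s, list(a = rnorm(2), b = rnorm(2),
                                  alpha = rnorm(1)))
    expect_equal(correlation_weight(v$a, v$b), correlation_weight(v$b, v$a))
    expect_equal(correlation_weight(v$alpha * v$a, v$b),
                 v$alpha * correlation_weight(v$a, v$b), tolerance = 1e-12)
    cos_th <- sum(v$a * v$b) / sqrt(sum(v$a^2) * sum(v$b^2))
    expect_equal(sign(correlation_weight(v$a, v$b)), sign(cos_th))
  }
})

test_that("zero weight vectors warn and give weight zero", {
  expect_warning(cw <- correlation_weight(c(0, 0), c(1, 1)), "zero")
  expect_equal(cw, 0)
})

test_that("per-axis variant multiplies single-axis weights by the cosine", {
  a <- c(0.5, 0.2)
  b <- c(0.4, -0.1)
  cos_th <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_equal(correlation_weight(a, b, axis = 1), 0.5 * 0.4 * cos_th)
  expect_error(correlation_weight(a, b, axis = 3), "axis")
})

test_that("pair eligibility requires a shared axis above the threshold", {
  pts <- tibble::tibble(
    parameter = c("p", "q", "r"),
    role = "predictor",
    comp1 = c(0.35, 0.40, 0.00),
    comp2 = c(0.00, 0.00, 0.40)
  )
  el <- eligible_pairs(pts, threshold = 0.3)
  expect_equal(nrow(el), 1)
  expect_identical(el$param_a, "p")
  expect_identical(el$param_b, "q")
})

test_that("eligibility equals a brute-force filter over all pairs", {
  for (s in 1:10) {
    n <- 8
    pts <- withr::with_seed(s, tibble::tibble(
      parameter = paste0("v", 1:n), role = "predictor",
      comp1 = runif(n, -0.6, 0.6), comp2 = runif(n, -0.6, 0.6)
    ))
    got <- eligible_pairs(pts, threshold = 0.3)
    idx <- utils::combn(n, 2)
    keep <- apply(idx, 2, function(ij) {
      i <- ij[1]; j <- ij[2]
      (abs(pts$comp1[i]) > 0.3 && abs(pts$comp1[j]) > 0.3) ||
        (abs(pts$comp2[i]) > 0.3 && abs(pts$comp2[j]) > 0.3)
    })
    expect_equal(nrow(got), sum(keep))
    expect_lte(nrow(got), choose(n, 2))
  }
})

test_that("ranking is by absolute value with signs retained", {
  pairs <- tibble::tibble(param_a = c("a", "b", "c"),
                          param_b = c("x", "y", "z"),
                          role_a = "predictor", role_b = "response",
                          cw = c(0.5, -0.6, 0.1))
  top <- rank_pairs(pairs, k = 2)
  expect_equal(top$cw, c(-0.6, 0.5))
  expect_message(all3 <- rank_pairs(pairs, k = 25), "only 3")
  expect_equal(nrow(all3), 3)
})

test_that("ranking matches a full sort oracle and breaks ties by name", {
  for (s in 1:20) {
    m <- withr::with_seed(s, {
      k <- 30
      tibble::tibble(
        param_a = sample(letters, k, replace = TRUE),
        param_b = sample(LETTERS, k, replace = TRUE),
        cw = round(rnorm(k), 1) # rounding forces ties
      )
    })
    got <- rank_pairs(m, k = 10)
    ref <- m[order(-abs(m$cw), m$param_a, m$param_b), ][1:10, ]
    expect_equal(got$cw, ref$cw)
    expect_equal(got$param_a, ref$param_a)
  }
})

test_that("weight coordinates cover both blocks and need two components", {
  blocks <- planted_blocks(20, kx = 3, ky = 2, seed = 11)
  colnames(blocks$x) <- paste0("x", 1:3)
  colnames(blocks$y) <- paste0("y", 1:2)
  fit2 <- fit_pls(blocks$x, blocks$y, ncomp = 2)
  pts <- weight_coordinates(fit2)
  expect_equal(nrow(pts), 5)
  expect_equal(sum(pts$role == "response"), 2)
  fit1 <- fit_pls(blocks$x, blocks$y, ncomp = 1)
  expect_error(weight_coordinates(fit1), "2 components")
})

test_that("spearman matches rank-then-Pearson to machine precision", {
  expect_equal(spearman_rho(1:5, c(2, 4, 8, 16, 32))$rho, 1)
  expect_equal(spearman_rho(1:5, 5:1)$rho, -1)
  for (s in 1:25) {
    withr::with_seed(s, {
      x <- sample(1:6, 20, replace = TRUE) # heavy ties
      y <- x + sample(-2:2, 20, replace = TRUE)
    })
    got <- spearman_rho(x, y)
    expect_equal(got$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
    ref_p <- cor.test(x, y, method = "spearman", exact = FALSE)$p.value
    expect_equal(got$p_value, ref_p, tolerance = 1e-10)
  }
})

test_that("degenerate spearman inputs are flagged", {
  res <- spearman_rho(rep(1, 10), 1:10)
  expect_true(is.na(res$rho))
  expect_error(spearman_rho(1:3, 3:1), "at least 5")
})

test_that("spearman check annotates pairs with the N.S. convention", {
  coh <- generate_cohort(default_study_spec(), seed = 3)
  pairs <- tibble::tibble(param_a = c("GPX3_F", "FRAP_I"),
                          param_b = c("TGFb_F", "CHOL_F"))
  out <- spearman_check(coh, pairs)
  expect_identical(out$ns_flag, out$spearman_p >= 0.05)
  expect_true(all(abs(out$spearman_rho) <= 1))
})

test_that("parameters sharing a planted factor cluster on the weight plot", {
  hits <- sapply(1:25, function(s) {
    withr::with_seed(s, {
      f1 <- rnorm(29); f2 <- rnorm(29)
      x <- cbind(a1 = 1.5 * f1 + rnorm(29), a2 = 1.5 * f1 + rnorm(29),
                 b1 = 1.5 * f2 + rnorm(29), b2 = 1.5 * f2 + rnorm(29))
      y <- cbind(r1 = 1.5 * f1 + rnorm(29), r2 = 1.5 * f2 + rnorm(29))
    })
    fit <- fit_pls(x, y, ncomp = 2)
    pts <- weight_coordinates(fit)
    v1 <- unlist(pts[pts$parameter == "a1", c("comp1", "comp2")])
    v2 <- unlist(pts[pts$parameter == "a2", c("comp1", "comp2")])
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    ang < 45
  })
  expect_gte(mean(hits), 0.8)
})

test_that("unplanted pairs rarely reach the ranked table", {
  hits <- sapply(1:20, function(s) {
    out <- suppressMessages(
      run_full_analysis(generate_cohort(default_study_spec(), seed = s))
    )
    ct <- out$models$initial$correlations
    any((ct$param_a == "FRAP_I" & ct$param_b == "CHOL_I") |
          (ct$param_a == "CHOL_I" & ct$param_b == "FRAP_I"))
  })
  expect_lte(mean(hits), 0.2)
})
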