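test_that("autoscale centres, scales and inverts exactly", {
  s <- autoscale(data.frame(a = c(2, 4, 6)))
  # hand computation: mean 4, n-1 sd 2, so scaled values are (-1, 0, 1)
  expect_equal(unname(s$x[, 1]), c(-1, 0, 1))
  expect_equal(s$scaling$center, 4)
  expect_equal(s$scaling$scale, 2)
  m <- withr::with_seed(1, matrix(rnorm(30), 10, 3))
  colnames(m) <- letters[1:3]
  sc <- autoscale(m)
  expect_equal(autoscale_invert(sc$x, sc$scaling), m, tolerance = 1e-12)
  # idempotence: scaling already-scaled data changes nothing
  sc2 <- autoscale(sc$x)
  expect_equal(sc2$x, sc$x, tolerance = 1e-12)
  mm <- m
  mm[, 2] <- 7
  expect_error(autoscale(mm), "constant column.*b")
})

test_that("a response equal to one predictor is fit perfectly", {
  # orthogonal, mean-zero predictors so the target column carries all
  # covariance (autoscaling preserves their orthogonality)
  x <- withr::with_seed(2,
    qr.Q(qr(scale(matrix(rnorm(60), 20, 3), scale = FALSE))))
  y <- x[, 2, drop = FALSE]
  fit <- fit_pls(x, y, ncomp = 1)
  expect_gt(fit$r2y[1], 0.999)
  w <- fit$x_weights[, 1]
  expect_equal(which.max(abs(w)), 2L, ignore_attr = TRUE)
  expect_lt(max(abs(w[-2])), 1e-6)
})

test_that("first component matches the SVD of X'Y", {
  for (s in 1:25) {
    withr::with_seed(s, {
      x <- scale(matrix(rnorm(24), 6, 4))
      y <- scale(matrix(rnorm(12), 6, 2))
    })
    fit <- fit_pls(x, y, ncomp = 1, scale = FALSE)
    w_ref <- svd(crossprod(x, y))$u[, 1]
    w_ref <- w_ref * sign(w_ref[which.max(abs(w_ref))])
    expect_lt(max(abs(fit$x_weights[, 1] - w_ref)), 1e-8)
  }
})

test_that("scores are orthogonal, weights unit norm, deflation exact", {
  blocks <- planted_blocks(25, kx = 6, ky = 3, seed = 4)
  fit <- fit_pls(blocks$x, blocks$y, ncomp = 3)
  tt <- crossprod(fit$x_scores)
  expect_lt(max(abs(tt[upper.tri(tt)])), 1e-7)
  expect_equal(unname(colSums(fit$x_weights^2)), rep(1, 3))
  # reconstruction: scaled X = T P' + residual
  x_scaled <- autoscale(blocks$x)$x
  recon <- fit$x_scores %*% t(fit$x_loadings) + fit$x_residual
  expect_equal(unname(recon), unname(x_scaled), tolerance = 1e-10)
})

test_that("eigenvalues obey lambda = Kx * r2x and the variance budget", {
  blocks <- planted_blocks(30, kx = 7, ky = 3, seed = 5)
  fit <- fit_pls(blocks$x, blocks$y, ncomp = 4)
  ev <- explained_variance(fit)
  expect_equal(ev$eigenvalue, 7 * ev$r2x)
  expect_equal(sum(fit$eigenvalues) / fit$kx, sum(fit$r2x))
  expect_lte(sum(fit$r2x), 1 + 1e-9)
  expect_true(all(diff(ev$cum_r2x) >= -1e-12))
})

test_that("weights are invariant to the units of raw columns", {
  blocks <- planted_blocks(20, kx = 5, ky = 2, seed = 6)
  f1 <- fit_pls(blocks$x, blocks$y, ncomp = 2)
  x2 <- blocks$x
  x2[, 3] <- x2[, 3] * 1000
  f2 <- fit_pls(x2, blocks$y, ncomp = 2)
  expect_equal(f1$x_weights, f2$x_weights, tolerance = 1e-10)
})

test_that("sign canonicalization makes refits bit-identical", {
  blocks <- planted_blocks(20, kx = 5, ky = 2, seed = 7)
  f1 <- fit_pls(blocks$x, blocks$y, ncomp = 2)
  f2 <- fit_pls(blocks$x, blocks$y, ncomp = 2)
  expect_identical(f1$x_weights, f2$x_weights)
  expect_true(all(apply(f1$x_weights, 2,
                        function(w) w[which.max(abs(w))] > 0)))
})

test_that("prediction reproduces the fitted responses on training data", {
  blocks <- planted_blocks(25, kx = 5, ky = 2, strength = 3, seed = 8)
  colnames(blocks$x) <- paste0("x", 1:5)
  colnames(blocks$y) <- paste0("y", 1:2)
  fit <- fit_pls(blocks$x, blocks$y, ncomp = 3)
  pred <- predict(fit, blocks$x)
  expect_gt(cor(pred[, 1], blocks$y[, 1]), 0.9)
  # rescaled prediction lives on the raw response scale
  expect_equal(mean(pred), mean(blocks$y), tolerance = 0.2)
})

test_that("tidy and glance expose the fit in long and one-row form", {
  blocks <- planted_blocks(20, kx = 4, ky = 2, seed = 9)
  fit <- fit_pls(blocks$x, blocks$y, ncomp = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$role), c("predictor", "response"))
  expect_equal(nrow(td), (4 + 2) * 2)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$eigenvalue_sum, sum(fit$eigenvalues))
})

test_that("degenerate requests fail with informative errors", {
  blocks <- planted_blocks(10, kx = 3, ky = 2, seed = 10)
  expect_error(fit_pls(blocks$x, blocks$y, ncomp = 4), "cannot exceed")
  expect_error(fit_pls(blocks$x, blocks$y[-1, ]), "same rows")
})
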