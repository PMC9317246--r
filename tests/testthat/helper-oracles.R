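# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Wilcoxon oracle enumerates all sign
# assignments, the PLS oracle uses the SVD, and the Q2 oracle is an
# explicit refit-and-predict loop.

# exact two-sided signed-rank p by full enumeration (n <= 12)
bf_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- drop(signs %*% r)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# one PLS component via the SVD of X'Y (the fixed point of the NIPALS
# inner iteration); returns what is needed for prediction and deflation
svd_component <- function(x, y) {
  w <- svd(crossprod(x, y))$u[, 1]
  t_vec <- drop(x %*% w)
  p <- drop(crossprod(x, t_vec)) / sum(t_vec^2)
  c_vec <- drop(crossprod(y, t_vec)) / sum(t_vec^2)
  list(w = w, t = t_vec, p = p, c = c_vec)
}

# explicit sequential cross-validation: each dimension assessed on the
# current residual matrices, one component refit per left-out group
bf_cross_validate <- function(x, y, ncomp, assignment) {
  x <- unname(scale(x))
  y <- unname(scale(y))
  press <- ss <- numeric(ncomp)
  x_res <- x
  y_res <- y
  for (a in seq_len(ncomp)) {
    ss[a] <- sum(y_res^2)
    for (g in unique(assignment)) {
      hold <- assignment == g
      cmp <- svd_component(x_res[!hold, , drop = FALSE],
                           y_res[!hold, , drop = FALSE])
      t_new <- drop(x_res[hold, , drop = FALSE] %*% cmp$w)
      pred <- tcrossprod(t_new, cmp$c)
      press[a] <- press[a] + sum((y_res[hold, , drop = FALSE] - pred)^2)
    }
    full <- svd_component(x_res, y_res)
    x_res <- x_res - tcrossprod(full$t, full$p)
    y_res <- y_res - tcrossprod(full$t, full$c)
  }
  data.frame(component = seq_len(ncomp), press = press, ss = ss,
             q2 = 1 - press / ss)
}

# small multivariate-normal fixture with a planted predictive factor
planted_blocks <- function(n, kx = 5, ky = 2, strength = 1.5, seed = 1) {
  withr::with_seed(seed, {
    f <- rnorm(n)
    x <- sapply(seq_len(kx), function(j) strength * f + rnorm(n))
    y <- sapply(seq_len(ky), function(j) strength * f + rnorm(n))
    list(x = x, y = y)
  })
}

tiny_two_param_spec <- function(loading = 0.8, n = 100, seed = 1) {
  synthetic_spec(
    dplyr::bind_rows(
      parameter_spec("a", "normal", 0, 1),
      parameter_spec("b", "normal", 0, 1)
    ),
    loadings = tibble::tibble(factor = "f", parameter = c("a", "b"),
                              loading = loading),
    n_patients = n, seed = seed
  )
}
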