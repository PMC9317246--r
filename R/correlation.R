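#' Weight-plot coordinates of a fitted PLS model
#'
#' One point per retained parameter in the plane of the first two
#' components: predictors take their x-weights (w), responses their
#' unit-norm y-weights (c), plotted jointly as in the published weight
#' plots.
#'
#' @param fit A [fit_pls()] object with at least 2 components.
#' @return Tibble: `parameter`, `role`, `comp1`, `comp2`.
#' @export
weight_coordinates <- function(fit) {
  stopifnot(inherits(fit, "pls_fit"))
  if (fit$ncomp < 2) abort("weight plot needs at least 2 components")
  bind_rows(
    tibble(parameter = rownames(fit$x_weights), role = "predictor",
           comp1 = fit$x_weights[, 1], comp2 = fit$x_weights[, 2]),
    tibble(parameter = rownames(fit$y_weights_norm), role = "response",
           comp1 = fit$y_weights_norm[, 1], comp2 = fit$y_weights_norm[, 2])
  )
}

#' Correlation weight of two points on the weight plot
#'
#' The correlation weight of parameters `a` and `b` is the product of the
#' lengths of their weight vectors and the cosine of the angle between
#' the lines connecting them to the origin — i.e. the planar dot product
#' `comp1_a * comp1_b + comp2_a * comp2_b`. It is symmetric, signed
#' (negative when the vectors point into opposing half-planes), and
#' bilinear in each argument. A zero vector yields 0 with a warning.
#'
#' An alternate per-axis variant (`axis = 1` or `2`) returns
#' `w_a,k * w_b,k * cos(theta)` for sensitivity analysis.
#'
#' @param a,b Numeric length-2 vectors, or single rows of
#'   [weight_coordinates()].
#' @param axis `NULL` (default, both axes jointly) or 1 or 2.
#' @return Signed scalar.
#' @export
#' @examples
#' correlation_weight(c(0.5, 0.2), c(0.4, -0.1)) # 0.18
correlation_weight <- function(a, b, axis = NULL) {
  coords <- function(p) {
    if (is.data.frame(p)) c(p$comp1[1], p$comp2[1]) else as.numeric(p[1:2])
  }
  va <- coords(a)
  vb <- coords(b)
  na <- sqrt(sum(va^2))
  nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) {
    warn("zero weight vector: correlation weight set to 0")
    return(0)
  }
  if (is.null(axis)) {
    sum(va * vb)
  } else {
    axis <- as.integer(axis)
    if (!axis %in% 1:2) abort("`axis` must be 1 or 2")
    cos_th <- sum(va * vb) / (na * nb)
    va[axis] * vb[axis] * cos_th
  }
}

#' Pairs of parameters eligible for a correlation-weight call
#'
#' A pair is eligible when both parameters have an absolute weight above
#' `threshold` along the same axis (component 1 or component 2) —
#' magnitude only, so pairs with opposite signs qualify and can carry
#' negative correlation weights.
#'
#' @param points Tibble from [weight_coordinates()].
#' @param threshold Eligibility bound on \out{|}weight\out{|},
#'   default 0.3.
#' @param axis Passed to [correlation_weight()].
#' @return Tibble of eligible pairs: `param_a`, `param_b`, `role_a`,
#'   `role_b`, `cw`.
#' @export
eligible_pairs <- function(points, threshold = 0.3, axis = NULL) {
  if (threshold <= 0) abort("`threshold` must be positive")
  n <- nrow(points)
  if (n < 2) {
    return(tibble(param_a = character(), param_b = character(),
                  role_a = character(), role_b = character(),
                  cw = double()))
  }
  idx <- combn(n, 2)
  a <- idx[1, ]
  b <- idx[2, ]
  ok1 <- abs(points$comp1[a]) > threshold & abs(points$comp1[b]) > threshold
  ok2 <- abs(points$comp2[a]) > threshold & abs(points$comp2[b]) > threshold
  keep <- ok1 | ok2
  a <- a[keep]
  b <- b[keep]
  tibble(
    param_a = points$parameter[a], param_b = points$parameter[b],
    role_a = points$role[a], role_b = points$role[b],
    cw = map_dbl(seq_along(a), function(i) {
      correlation_weight(c(points$comp1[a[i]], points$comp2[a[i]]),
                         c(points$comp1[b[i]], points$comp2[b[i]]),
                         axis = axis)
    })
  )
}

#' Rank correlation-weight pairs by absolute value
#'
#' Descending by \out{|}cw\out{|}, signed values retained; ties broken
#' lexicographically by parameter names. `k = 25` reproduces the length
#' convention of the published tables.
#'
#' @param pairs Tibble from [eligible_pairs()].
#' @param k Number of pairs to keep, default 25. If fewer pairs exist,
#'   all are returned (with a message).
#' @return The top-`k` rows, ranked.
#' @export
rank_pairs <- function(pairs, k = 25) {
  if (k < 1) abort("`k` must be at least 1")
  if (nrow(pairs) < k) {
    inform(sprintf("only %d eligible pairs (requested %d); returning all",
                   nrow(pairs), k))
  }
  pairs |>
    arrange(desc(abs(.data$cw)), .data$param_a, .data$param_b) |>
    slice_head(n = k)
}

#' Tie-corrected Spearman rank correlation with t-approximation p-value
#'
#' Ranks use the average-rank method; the coefficient is the Pearson
#' product-moment correlation of the centred ranks (equivalent to the
#' classical tie-corrected formula), and the two-sided p-value uses the
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees
#' of freedom.
#'
#' @param x,y Numeric vectors; at least 5 complete pairs.
#' @return One-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 5) abort("need at least 5 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rx <- rank(x) - (n + 1) / 2
  ry <- rank(y) - (n + 1) / 2
  rho <- sum(rx * ry) / sqrt(sum(rx^2) * sum(ry^2))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  tibble(rho = rho, p_value = p, n = n)
}

#' Annotate correlation-weight pairs with Spearman cross-checks
#'
#' For each pair, computes the Spearman rank correlation of the two
#' parameters across patients — the check that a correlation suggested by
#' the PLS weight plot can also be found outside the model — and flags
#' pairs nonsignificant at `alpha` (the `N.S.` convention).
#'
#' @param cohort Cohort tibble holding the paired columns.
#' @param pairs Tibble with `param_a`, `param_b` (e.g. from
#'   [rank_pairs()]).
#' @param alpha Significance level, default 0.05.
#' @return `pairs` with `spearman_rho`, `spearman_p`, `ns_flag` added.
#' @export
spearman_check <- function(cohort, pairs, alpha = 0.05) {
  res <- purrr::map(seq_len(nrow(pairs)), function(i) {
    spearman_rho(cohort[[pairs$param_a[i]]], cohort[[pairs$param_b[i]]])
  }) |> list_rbind()
  pairs |>
    mutate(spearman_rho = res$rho, spearman_p = res$p_value,
           ns_flag = is.na(res$p_value) | res$p_value >= alpha)
}

#' Full correlation-weight table for a fitted model
#'
#' Convenience wrapper reproducing the published correlation tables:
#' weight coordinates, pair eligibility at `threshold`, ranking of the
#' top `k` pairs by absolute correlation weight, and Spearman
#' cross-checks against the cohort.
#'
#' @param fit A [fit_pls()] object (at least 2 components).
#' @param cohort Cohort tibble with the model's columns.
#' @param threshold Eligibility bound, default 0.3.
#' @param k Table length, default 25.
#' @param alpha Significance level for the `N.S.` flag.
#' @param axis Passed to [correlation_weight()].
#' @return Ranked tibble with correlation weights and Spearman columns.
#' @export
correlation_weight_table <- function(fit, cohort, threshold = 0.3, k = 25,
                                     alpha = 0.05, axis = NULL) {
  weight_coordinates(fit) |>
    eligible_pairs(threshold = threshold, axis = axis) |>
    rank_pairs(k = k) |>
    (\(p) spearman_check(cohort, p, alpha = alpha))()
}
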