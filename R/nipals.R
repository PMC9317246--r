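#' Mean-centre and unit-variance scale a set of cohort columns
#'
#' Autoscaling (the chemometrics default) makes weights comparable across
#' parameters measured in different units. SDs use the n-1 denominator.
#'
#' @param data Cohort tibble, data frame or numeric matrix.
#' @param columns Optional character vector of columns to scale (default:
#'   all numeric columns except `patient_id`).
#' @return List with `x` (scaled matrix) and `scaling` (tibble with
#'   `parameter`, `center`, `scale`) permitting exact inversion via
#'   [autoscale_invert()].
#' @export
#' @examples
#' autoscale(data.frame(a = c(2, 4, 6)))$x
autoscale <- function(data, columns = NULL) {
  if (is.matrix(data)) {
    m <- data
  } else {
    cols <- setdiff(names(data), "patient_id")
    if (!is.null(columns)) cols <- columns
    m <- as.matrix(as.data.frame(data)[cols])
  }
  centers <- colMeans(m)
  scales <- apply(m, 2, sd)
  if (any(scales == 0)) {
    abort(paste0("constant column(s): ",
                 paste(colnames(m)[scales == 0], collapse = ", ")))
  }
  x <- sweep(sweep(m, 2, centers, "-"), 2, scales, "/")
  list(x = x,
       scaling = tibble(parameter = colnames(m), center = unname(centers),
                        scale = unname(scales)))
}

#' @rdname autoscale
#' @param x Scaled matrix.
#' @param scaling Scaling record from [autoscale()].
#' @export
autoscale_invert <- function(x, scaling) {
  sweep(sweep(x, 2, scaling$scale, "*"), 2, scaling$center, "+")
}

apply_scaling <- function(m, scaling) {
  m <- m[, scaling$parameter, drop = FALSE]
  sweep(sweep(m, 2, scaling$center, "-"), 2, scaling$scale, "/")
}

#' Two-block PLS by NIPALS
#'
#' Fits the two-block partial least squares path model: mutually
#' orthogonal latent components `t` (linear combinations of the predictor
#' block, the "outer relation" of block 1) are found iteratively together
#' with response-block scores `u`; the "inner relation" regresses `u` on
#' `t` component by component. Per component, NIPALS iterates
#' `w = X'u / |X'u|`, `t = Xw`, `c = Y't / t't`, `u = Yc / c'c` until the
#' change in `w` falls below `tol`, then deflates `X` by `t p'`
#' (`p = X't / t't`) and `Y` by `b t c'` (`b = u't / t't`). Signs are
#' canonicalized so that the largest-magnitude entry of each `w` column
#' is positive, making fits bit-reproducible.
#'
#' @param x Predictor block: numeric matrix or data frame (patients in
#'   rows).
#' @param y Response block, same rows.
#' @param ncomp Number of components; at most `ncol(x)`.
#' @param scale Autoscale both blocks first (default `TRUE`). Pass
#'   already-scaled matrices with `scale = FALSE`.
#' @param tol Convergence tolerance on the change in `w`, default 1e-10.
#' @param max_iter Iteration cap per component, default 10000
#'   (the inner power iteration converges linearly at the squared ratio
#'   of the two leading covariance singular values, so clustered
#'   structure can legitimately need thousands of cheap iterations).
#' @param on_nonconvergence `"error"` (default): abort, naming the
#'   component that failed; `"truncate"`: return the components that did
#'   converge (used by the cross-validation and pruning loops, where a
#'   deep component that stalls — typically two residual directions of
#'   near-equal covariance — carries no retained structure).
#' @return A `pls_fit` object: unit-norm `x_weights` (w), raw `y_weights`
#'   (c), unit-norm `y_weights_norm` (used for weight plots), scores
#'   `x_scores` (t) and `y_scores` (u), `x_loadings` (p),
#'   `inner_coefficients` (b), per-component `r2x`/`r2y` (fractions of
#'   block variance) and `eigenvalues` (`ncol(x) * r2x`), plus the
#'   scaling records.
#' @export
fit_pls <- function(x, y, ncomp = 2, scale = TRUE, tol = 1e-10,
                    max_iter = 10000,
                    on_nonconvergence = c("error", "truncate")) {
  on_nonconvergence <- arg_match(on_nonconvergence)
  x <- as.matrix(as.data.frame(x))
  y <- as.matrix(as.data.frame(y))
  if (nrow(x) != nrow(y)) abort("`x` and `y` must have the same rows")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (is.null(colnames(y))) colnames(y) <- paste0("y", seq_len(ncol(y)))
  if (ncomp > ncol(x)) abort("`ncomp` cannot exceed the predictor count")

  x_scaling <- y_scaling <- NULL
  if (scale) {
    sx <- autoscale(x)
    sy <- autoscale(y)
    x <- sx$x
    y <- sy$x
    x_scaling <- sx$scaling
    y_scaling <- sy$scaling
  }

  n <- nrow(x)
  kx <- ncol(x)
  ky <- ncol(y)
  ssx0 <- sum(x^2)
  ssy0 <- sum(y^2)

  W <- matrix(0, kx, ncomp, dimnames = list(colnames(x), NULL))
  P <- matrix(0, kx, ncomp, dimnames = list(colnames(x), NULL))
  C <- matrix(0, ky, ncomp, dimnames = list(colnames(y), NULL))
  Tm <- matrix(0, n, ncomp)
  U <- matrix(0, n, ncomp)
  b <- numeric(ncomp)
  r2x <- numeric(ncomp)
  r2y <- numeric(ncomp)

  Xa <- x
  Ya <- y
  a_done <- 0
  for (a in seq_len(ncomp)) {
    if (sum(Xa^2) < 1e-12 * max(1, ssx0)) break # zero-variance residual
    u <- Ya[, which.max(colSums(Ya^2))]
    if (sum(u^2) < 1e-12 * max(1, ssy0)) break
    w_old <- rep(0, kx)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xa, u))
      w <- w / sqrt(sum(w^2))
      t_vec <- drop(Xa %*% w)
      cc <- drop(crossprod(Ya, t_vec)) / sum(t_vec^2)
      u <- drop(Ya %*% cc) / sum(cc^2)
      if (sqrt(sum((w - w_old)^2)) < tol) {
        converged <- TRUE
        break
      }
      w_old <- w
    }
    if (!converged) {
      if (on_nonconvergence == "truncate") break
      abort(sprintf("NIPALS did not converge for component %d", a))
    }
    # canonical sign: largest |w| entry positive
    if (w[which.max(abs(w))] < 0) {
      w <- -w
      t_vec <- -t_vec
      cc <- -cc
      u <- -u
    }
    p <- drop(crossprod(Xa, t_vec)) / sum(t_vec^2)
    b_a <- sum(u * t_vec) / sum(t_vec^2)

    ssx_before <- sum(Xa^2)
    ssy_before <- sum(Ya^2)
    Xa <- Xa - tcrossprod(t_vec, p)
    Ya <- Ya - b_a * tcrossprod(t_vec, cc)
    r2x[a] <- (ssx_before - sum(Xa^2)) / ssx0
    r2y[a] <- (ssy_before - sum(Ya^2)) / ssy0

    W[, a] <- w
    P[, a] <- p
    C[, a] <- cc
    Tm[, a] <- t_vec
    U[, a] <- u
    b[a] <- b_a
    a_done <- a
  }
  if (a_done == 0) abort("no component could be extracted")
  keep <- seq_len(a_done)

  Cn <- C[, keep, drop = FALSE]
  Cn <- sweep(Cn, 2, sqrt(colSums(Cn^2)), "/")

  structure(
    list(
      x_weights = W[, keep, drop = FALSE],
      y_weights = C[, keep, drop = FALSE],
      y_weights_norm = Cn,
      x_scores = Tm[, keep, drop = FALSE],
      y_scores = U[, keep, drop = FALSE],
      x_loadings = P[, keep, drop = FALSE],
      inner_coefficients = b[keep],
      r2x = r2x[keep], r2y = r2y[keep],
      eigenvalues = kx * r2x[keep],
      ncomp = a_done, n = n, kx = kx, ky = ky,
      x_scaling = x_scaling, y_scaling = y_scaling,
      x_residual = Xa, y_residual = Ya
    ),
    class = "pls_fit"
  )
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("<pls_fit> ", x$ncomp, " component(s), ", x$kx, " predictors, ",
      x$ky, " responses, n = ", x$n, "\n", sep = "")
  ev <- explained_variance(x)
  print(as.data.frame(ev), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Per-component explained variance and eigenvalues
#'
#' For component `a`, `r2x` is the fraction of (scaled) predictor-block
#' variance removed by deflation and the eigenvalue is
#' `lambda_a = K_x * r2x_a` with `K_x` the predictor count, the
#' convention under which the sum of eigenvalues over `K_x` equals the
#' total explained X-variance.
#'
#' @param fit A [fit_pls()] object.
#' @return Tibble: `component`, `r2x`, `r2y`, `eigenvalue`, `cum_r2x`,
#'   `cum_r2y`.
#' @export
explained_variance <- function(fit) {
  stopifnot(inherits(fit, "pls_fit"))
  tibble(
    component = seq_len(fit$ncomp),
    r2x = fit$r2x, r2y = fit$r2y,
    eigenvalue = fit$eigenvalues,
    cum_r2x = cumsum(fit$r2x), cum_r2y = cumsum(fit$r2y)
  )
}

#' Predict the response block for new predictor data
#'
#' @param object A [fit_pls()] object.
#' @param newdata Predictor matrix/data frame on the raw scale if the fit
#'   scaled internally, or on the fitted scale if `scale = FALSE` was
#'   used.
#' @param ncomp Number of components to use (default: all fitted).
#' @param rescale Return predictions on the raw response scale when the
#'   fit holds a scaling record (default `TRUE`).
#' @param ... Unused.
#' @return Matrix of predicted responses.
#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$ncomp,
                            rescale = TRUE, ...) {
  m <- as.matrix(as.data.frame(newdata))
  if (!is.null(object$x_scaling)) m <- apply_scaling(m, object$x_scaling)
  yhat <- matrix(0, nrow(m), object$ky,
                 dimnames = list(rownames(m), rownames(object$y_weights)))
  xres <- m
  for (a in seq_len(ncomp)) {
    t_new <- drop(xres %*% object$x_weights[, a])
    xres <- xres - tcrossprod(t_new, object$x_loadings[, a])
    yhat <- yhat + object$inner_coefficients[a] *
      tcrossprod(t_new, object$y_weights[, a])
  }
  if (rescale && !is.null(object$y_scaling)) {
    yhat <- autoscale_invert(yhat, object$y_scaling)
  }
  yhat
}

#' @export
tidy.pls_fit <- function(x, matrix = c("weights", "loadings", "scores"),
                         ...) {
  matrix <- arg_match(matrix)
  long <- function(m, role, what) {
    colnames(m) <- paste0("comp", seq_len(ncol(m)))
    if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
    as_tibble(m, rownames = "parameter") |>
      tidyr::pivot_longer(-"parameter", names_to = "component",
                          values_to = "value") |>
      mutate(component = as.integer(sub("^comp", "", .data$component)),
             role = role, matrix = what)
  }
  out <- switch(matrix,
    weights = bind_rows(
      long(x$x_weights, "predictor", "weights"),
      long(x$y_weights_norm, "response", "weights")
    ),
    loadings = long(x$x_loadings, "predictor", "loadings"),
    scores = bind_rows(
      long(x$x_scores, "predictor", "scores") |>
        rename(patient = "parameter"),
      long(x$y_scores, "response", "scores") |>
        rename(patient = "parameter")
    )
  )
  out
}

#' @export
glance.pls_fit <- function(x, ...) {
  tibble(ncomp = x$ncomp, n = x$n, kx = x$kx, ky = x$ky,
         r2x_total = sum(x$r2x), r2y_total = sum(x$r2y),
         eigenvalue_sum = sum(x$eigenvalues))
}
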