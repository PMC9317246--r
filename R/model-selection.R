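#' Q2 cross-validation of a two-block PLS model
#'
#' Each dimension is cross-validated on the current residual matrices,
#' as in the classical sequential scheme of the SIMCA family: at
#' dimension `a`, `SS_(a-1)` is the residual sum of squares of the
#' response block after `a - 1` components of the full fit (`SS_0` =
#' total response sum of squares), and `PRESS_a` accumulates, over the
#' prediction groups, the squared error of predicting each held-out
#' patient's response residual with a single component refit on the
#' residual matrices without that group. The criterion is
#' `Q2_a = 1 - PRESS_a / SS_(a-1)`; after dimension `a` is assessed,
#' both blocks are deflated by the full-data component and the next
#' dimension is examined. Patients are assigned to groups round-robin
#' by row order by default (7 groups, the historical default of that
#' software family); pass `n_groups = nrow(x)` for leave-one-out or
#' supply an explicit `assignment`. Scaling is performed once on the
#' full matrices; CV refits reuse it, so the criterion is a
#' deterministic function of the data and the assignment.
#'
#' @param x,y Predictor and response blocks (rows = patients).
#' @param ncomp Number of components to evaluate.
#' @param n_groups Number of prediction groups (at least 2), default 7.
#' @param assignment Optional integer vector mapping each patient to a
#'   group; overrides `n_groups`.
#' @param scale Autoscale the blocks first (default `TRUE`).
#' @return A `pls_cv` tibble: `component`, `press`, `ss`, `q2`, with the
#'   group assignment attached as attribute `"assignment"`.
#' @export
cross_validate <- function(x, y, ncomp = 2, n_groups = 7,
                           assignment = NULL, scale = TRUE) {
  x <- as.matrix(as.data.frame(x))
  y <- as.matrix(as.data.frame(y))
  n <- nrow(x)
  if (is.null(assignment)) {
    if (n_groups < 2) abort("`n_groups` must be at least 2")
    n_groups <- min(n_groups, n)
    assignment <- rep_len(seq_len(n_groups), n)
  }
  if (length(assignment) != n) abort("`assignment` must map every patient")
  sizes <- tabulate(assignment, nbins = max(assignment))
  if (any(sizes[unique(assignment)] == 0)) {
    abort("every prediction group must be nonempty")
  }

  if (scale) {
    x <- autoscale(x)$x
    y <- autoscale(y)$x
  }
  ncomp <- min(ncomp, ncol(x))

  # full fit drives the between-dimension deflation
  full <- fit_pls(x, y, ncomp = ncomp, scale = FALSE,
                  on_nonconvergence = "truncate")
  ncomp <- full$ncomp

  press <- numeric(ncomp)
  ss <- numeric(ncomp)
  x_res <- x
  y_res <- y
  for (a in seq_len(ncomp)) {
    ss[a] <- sum(y_res^2)
    for (g in unique(assignment)) {
      hold <- assignment == g
      sub <- fit_pls(x_res[!hold, , drop = FALSE],
                     y_res[!hold, , drop = FALSE],
                     ncomp = 1, scale = FALSE,
                     on_nonconvergence = "truncate")
      t_new <- drop(x_res[hold, , drop = FALSE] %*% sub$x_weights[, 1])
      pred <- sub$inner_coefficients[1] *
        tcrossprod(t_new, sub$y_weights[, 1])
      press[a] <- press[a] + sum((y_res[hold, , drop = FALSE] - pred)^2)
    }
    # deflate by the full-data component before the next dimension
    x_res <- x_res - tcrossprod(full$x_scores[, a], full$x_loadings[, a])
    y_res <- y_res - full$inner_coefficients[a] *
      tcrossprod(full$x_scores[, a], full$y_weights[, a])
  }

  out <- tibble(component = seq_len(ncomp), press = press, ss = ss,
                q2 = 1 - press / ss)
  attr(out, "assignment") <- assignment
  class(out) <- c("pls_cv", class(out))
  out
}

#' Sequential component retention by the Q2 criterion
#'
#' Components are added while their cross-validated `Q2` stays at or
#' above `limit` (default 0.05, the published retention limit); the first
#' failure stops the scan.
#'
#' @inheritParams cross_validate
#' @param limit Q2 retention limit in (0, 1), default 0.05.
#' @param max_components Scan cap, default 5.
#' @return List with `components_kept` and the full `q2` table.
#' @export
select_components <- function(x, y, limit = 0.05, max_components = 5,
                              n_groups = 7, assignment = NULL,
                              scale = TRUE) {
  if (limit <= 0 || limit > 1) abort("`limit` must be in (0, 1]")
  ncomp <- min(max_components, ncol(as.matrix(as.data.frame(x))))
  cv <- cross_validate(x, y, ncomp = ncomp, n_groups = n_groups,
                       assignment = assignment, scale = scale)
  ok <- cv$q2 >= limit
  kept <- if (all(ok)) length(ok) else which(!ok)[1] - 1L
  list(components_kept = as.integer(kept), q2 = cv)
}

#' Iterative elimination of uninformative parameters
#'
#' Mirrors the published model-building loop: fit a two-component PLS
#' model, drop every parameter whose weight magnitude stays below
#' `weight_threshold` on both of the first two components — the plane
#' the published weight plots and correlation tables are built on —
#' refit, and repeat until nothing is dropped. Such parameters carry no
#' informative value for the joint correlation structure. The same rule
#' is applied to the response block via the normalized response weights
#' (at least one response is always kept). The retained model's
#' component count is then determined with [select_components()].
#'
#' @param x,y Predictor and response blocks (data frames or matrices).
#' @param weight_threshold Informativeness cutoff on \out{|}weight\out{|},
#'   default 0.3 — the same bound used to call a weight "high" in the
#'   weight-plot interpretation.
#' @param limit Q2 limit passed to [select_components()].
#' @param n_groups,max_components Passed to [select_components()].
#' @param prune_responses Apply the rule to the response block too
#'   (default `TRUE`).
#' @return A `selection_trace` list: `retained_predictors`,
#'   `retained_responses`, `dropped` (tibble with round, parameter, role,
#'   max weight), `components_kept`, `q2`, `n_rounds`, `fit` (final
#'   two-component fit).
#' @export
prune_variables <- function(x, y, weight_threshold = 0.3, limit = 0.05,
                            n_groups = 7, max_components = 5,
                            prune_responses = TRUE) {
  x <- as.matrix(as.data.frame(x))
  y <- as.matrix(as.data.frame(y))
  if (ncol(x) < 2) abort("need at least 2 predictors")
  if (ncol(y) < 1) abort("need at least 1 response")

  dropped <- tibble(round = integer(), parameter = character(),
                    role = character(), max_weight = double())
  round_i <- 0L
  max_rounds <- ncol(x) + ncol(y)
  repeat {
    round_i <- round_i + 1L
    fit <- fit_pls(x, y, ncomp = min(2, ncol(x)), scale = TRUE,
                   on_nonconvergence = "truncate")
    wx <- abs(fit$x_weights)
    wy <- abs(fit$y_weights_norm)
    mx <- apply(wx, 1, max)
    my <- apply(wy, 1, max)

    drop_x <- names(mx)[mx < weight_threshold]
    drop_y <- character()
    if (prune_responses) {
      drop_y <- names(my)[my < weight_threshold]
      if (length(drop_y) == ncol(y)) {
        # never empty the response block: keep the strongest response
        drop_y <- setdiff(drop_y, names(which.max(my)))
      }
    }
    if (length(drop_x) == ncol(x)) {
      err_trace <- bind_rows(dropped,
                             tibble(round = round_i, parameter = names(mx),
                                    role = "predictor", max_weight = unname(mx)))
      abort("all predictors fell below the weight threshold",
            trace_table = err_trace, class = "thyropls_all_dropped")
    }
    if (length(drop_x) + length(drop_y) == 0 || round_i >= max_rounds) break

    dropped <- bind_rows(
      dropped,
      tibble(round = round_i, parameter = drop_x, role = "predictor",
             max_weight = unname(mx[drop_x])),
      tibble(round = round_i, parameter = drop_y, role = "response",
             max_weight = unname(my[drop_y]))
    )
    x <- x[, setdiff(colnames(x), drop_x), drop = FALSE]
    y <- y[, setdiff(colnames(y), drop_y), drop = FALSE]
    if (ncol(x) < 2) break
  }

  sel <- select_components(x, y, limit = limit,
                           max_components = max_components,
                           n_groups = n_groups)
  structure(
    list(retained_predictors = colnames(x),
         retained_responses = colnames(y),
         dropped = dropped,
         components_kept = sel$components_kept,
         q2 = sel$q2,
         n_rounds = round_i,
         fit = fit_pls(x, y, ncomp = min(2, ncol(x)), scale = TRUE,
                       on_nonconvergence = "truncate")),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace> ", length(x$retained_predictors), " predictors, ",
      length(x$retained_responses), " responses retained in ", x$n_rounds,
      " round(s); ", x$components_kept, " component(s) kept\n", sep = "")
  if (nrow(x$dropped) > 0) {
    cat("dropped:", paste(x$dropped$parameter, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
autoplot.pls_cv <- function(object, limit = 0.05, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$component), y = .data$q2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = limit, linetype = "dashed") +
    ggplot2::labs(x = "component", y = expression(Q^2),
                  title = "Cross-validated predictive ability per component") +
    ggplot2::theme_minimal()
}
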