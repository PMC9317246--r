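#' Normality and variance-homogeneity screening for one biomarker
#'
#' Runs the Shapiro-Wilk test and the Kolmogorov-Smirnov test with
#' Lilliefors correction on `x`; the biomarker is called normal when both
#' p-values are at or above `alpha`. When a paired companion vector `y`
#' is supplied, Levene's test (mean-centred, as in the classical form)
#' compares the two timepoints' variances and populates the homogeneity
#' verdict.
#'
#' @param x Numeric vector, length at least 4, finite values.
#' @param y Optional second vector (the other timepoint) for the variance
#'   comparison.
#' @param alpha Significance level, default 0.05.
#' @return One-row tibble: `shapiro_p`, `lilliefors_p`, `levene_p`,
#'   `normal`, `homogeneous`, `degenerate`. A constant vector cannot be
#'   screened: all p-values are `NA`, `normal` is `FALSE` and
#'   `degenerate` is `TRUE`.
#' @export
test_normality <- function(x, y = NULL, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 4) abort("need at least 4 finite observations")
  if (sd(x) == 0) {
    return(tibble(shapiro_p = NA_real_, lilliefors_p = NA_real_,
                  levene_p = NA_real_, normal = FALSE, homogeneous = NA,
                  degenerate = TRUE))
  }
  sw <- shapiro.test(x)$p.value
  lf <- nortest::lillie.test(x)$p.value
  lev <- NA_real_
  homog <- NA
  if (!is.null(y)) {
    y <- y[is.finite(y)]
    if (sd(y) > 0 && sd(x) > 0) {
      g <- factor(rep(c("a", "b"), c(length(x), length(y))))
      lev <- car::leveneTest(c(x, y) ~ g, center = mean)[1, "Pr(>F)"]
      homog <- lev >= alpha
    }
  }
  tibble(shapiro_p = sw, lilliefors_p = lf, levene_p = lev,
         normal = sw >= alpha && lf >= alpha, homogeneous = homog,
         degenerate = FALSE)
}

#' Choose the paired comparison test for a pre/post biomarker
#'
#' Applies the routing rule used for the published comparisons: the
#' paired Student t-test when both timepoints pass the normality screen
#' and Levene's test finds the variances homogeneous; the Wilcoxon
#' signed-rank test otherwise.
#'
#' @param pre,post Paired numeric vectors of equal length.
#' @param alpha Significance level for the screening tests.
#' @return `"paired_t"` or `"wilcoxon"`.
#' @export
route_paired_test <- function(pre, post, alpha = 0.05) {
  if (length(pre) != length(post)) abort("`pre` and `post` must be paired")
  v_pre <- test_normality(pre, post, alpha = alpha)
  v_post <- test_normality(post, alpha = alpha)
  ok <- isTRUE(v_pre$normal) && isTRUE(v_post$normal) &&
    isTRUE(v_pre$homogeneous)
  if (ok) "paired_t" else "wilcoxon"
}

# Exact two-sided p for the Wilcoxon signed-rank statistic with average
# ranks for tied |differences|: the null distribution of W+ over all 2^n
# sign assignments is built by convolution on doubled ranks (so tied
# half-integer ranks stay integral). Equivalent to full enumeration.
wilcoxon_exact_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  dist <- rep(0, total + 1) # index k+1 = P(2*W = k) * 2^n
  dist[1] <- 1
  for (rk in r2) {
    shifted <- c(rep(0, rk), dist[seq_len(total + 1 - rk)])
    dist <- dist + shifted
  }
  probs <- dist / 2^n
  w2 <- as.integer(round(2 * w_plus))
  lower <- sum(probs[seq_len(w2 + 1)])
  upper <- sum(probs[seq(w2 + 1, total + 1)])
  min(1, 2 * min(lower, upper))
}

#' Paired two-sample comparison
#'
#' Computes the two-sided paired comparison chosen by
#' [route_paired_test()] (or forced via `method`). The Wilcoxon path
#' drops zero differences (classical convention), uses the exact
#' tie-aware null distribution of the signed-rank statistic for up to 25
#' non-zero pairs, and the normal approximation with continuity and tie
#' correction beyond that. If all differences are zero the comparison is
#' vacuous: p = 1 with a warning.
#'
#' @param pre,post Paired numeric vectors, at least 5 pairs.
#' @param method `"paired_t"` or `"wilcoxon"`; default routes
#'   automatically.
#' @param alpha Significance level used for routing and the significance
#'   flag.
#' @return One-row tibble: `method`, `statistic`, `p_value`,
#'   `n_effective` (pairs after zero removal on the Wilcoxon path),
#'   `significant`.
#' @export
#' @examples
#' compare_paired(1:6, 1:6 + c(1, 2, 3, 4, 5, 6), method = "wilcoxon")
compare_paired <- function(pre, post, method = NULL, alpha = 0.05) {
  if (length(pre) != length(post)) abort("`pre` and `post` must be paired")
  keep <- is.finite(pre) & is.finite(post)
  pre <- pre[keep]
  post <- post[keep]
  if (length(pre) < 5) abort("need at least 5 complete pairs")
  if (is.null(method)) method <- route_paired_test(pre, post, alpha = alpha)
  method <- arg_match(method, c("paired_t", "wilcoxon"))

  if (method == "paired_t") {
    ht <- t.test(post, pre, paired = TRUE)
    stat <- unname(ht$statistic)
    p <- ht$p.value
    n_eff <- length(pre)
  } else {
    d <- post - pre
    d <- d[d != 0]
    n_eff <- length(d)
    if (n_eff == 0) {
      warn("all paired differences are zero; p set to 1")
      return(tibble(method = method, statistic = 0, p_value = 1,
                    n_effective = 0L, significant = FALSE))
    }
    r <- rank(abs(d))
    stat <- sum(r[d > 0])
    if (n_eff <= 25) {
      p <- wilcoxon_exact_p(d)
    } else {
      mu <- n_eff * (n_eff + 1) / 4
      ties <- table(r)
      sigma2 <- n_eff * (n_eff + 1) * (2 * n_eff + 1) / 24 -
        sum(ties^3 - ties) / 48
      z <- (stat - mu - sign(stat - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  tibble(method = method, statistic = stat, p_value = p,
         n_effective = as.integer(n_eff), significant = p < alpha)
}

#' Summary statistics for one biomarker, on the scale the study reports
#'
#' Non-skewed biomarkers are summarised as arithmetic mean and SD. For a
#' skewed biomarker the summary follows the log-scale convention used in
#' the published tables: the data are log-transformed, the centre is the
#' back-transformed log-mean (the geometric mean), and the interval is
#' `exp(m +/- t[0.975, n-1] * s)` by default — an individual-level
#' (reference-style) interval whose bounds reproduce the order of
#' magnitude of the printed CIs; `interval = "mean"` switches to the
#' standard-error CI `exp(m +/- t * s / sqrt(n))`. By construction, the
#' back-transformed centre equals the geometric mean of the two bounds.
#'
#' @param x Numeric vector; strictly positive when `skewed`.
#' @param skewed Logical: use the log-scale convention?
#' @param ci_level Confidence level, default 0.95.
#' @param interval `"individual"` (default) or `"mean"`.
#' @param name Optional parameter name used in error messages.
#' @return One-row tibble: `n`, `mean`, `sd`, `skewed`, `ci_lo`, `ci_hi`
#'   (the latter `NA` on the non-skewed path), `label` (formatted as in
#'   the published table).
#' @export
#' @examples
#' summarize_parameter(c(1, 10, 100), skewed = TRUE)
summarize_parameter <- function(x, skewed = FALSE, ci_level = 0.95,
                                interval = c("individual", "mean"),
                                name = "parameter") {
  interval <- arg_match(interval)
  x <- x[is.finite(x)]
  n <- length(x)
  if (!skewed) {
    return(tibble(n = n, mean = mean(x), sd = sd(x), skewed = FALSE,
                  ci_lo = NA_real_, ci_hi = NA_real_,
                  label = sprintf("%.2f ± %.2f", mean(x), sd(x))))
  }
  if (any(x <= 0)) {
    bad <- which(x <= 0)[1]
    abort(sprintf(
      "log-scale summary of %s impossible: non-positive value at observation %d",
      name, bad))
  }
  lx <- log(x)
  m <- mean(lx)
  s <- sd(lx)
  t_crit <- qt(1 - (1 - ci_level) / 2, n - 1)
  half <- if (interval == "individual") t_crit * s else t_crit * s / sqrt(n)
  tibble(n = n, mean = exp(m), sd = sd(x), skewed = TRUE,
         ci_lo = exp(m - half), ci_hi = exp(m + half),
         label = sprintf("%.2f (%.2f; %.2f) #", exp(m), exp(m - half),
                         exp(m + half)))
}

#' Pre/post summary table for a paired cohort
#'
#' Reproduces the study's univariate stage for every biomarker present at
#' both timepoints: screens each timepoint for normality, routes the
#' paired comparison (Student t vs Wilcoxon), and summarises each
#' timepoint either as mean +/- SD or — for skewed biomarkers — as the
#' back-transformed log-scale mean with its log-scale interval (the `#`
#' convention). The skewness flag defaults to the normality verdict
#' (non-normal and strictly positive), and can be pinned per column via
#' `skewed_override` to reproduce a fixed published flag set.
#'
#' @param cohort Cohort tibble ([generate_cohort()] / [read_cohort_csv()]).
#' @param alpha Significance level, default 0.05.
#' @param ci_level Level for log-scale intervals, default 0.95.
#' @param interval Interval convention passed to [summarize_parameter()].
#' @param skewed_override Optional named logical vector (names = column
#'   names) overriding the automatic skewness flag.
#' @return Tibble with one row per paired biomarker: summaries of both
#'   timepoints, the test used, p-value and significance flag.
#' @export
summarize_cohort <- function(cohort, alpha = 0.05, ci_level = 0.95,
                             interval = c("individual", "mean"),
                             skewed_override = NULL) {
  interval <- arg_match(interval)
  cols <- setdiff(names(cohort), "patient_id")
  bases <- intersect(sub("_I$", "", grep("_I$", cols, value = TRUE)),
                     sub("_F$", "", grep("_F$", cols, value = TRUE)))
  if (length(bases) == 0) abort("no paired `_I`/`_F` columns found")

  skew_flag <- function(colname, x, verdict) {
    if (!is.null(skewed_override) && colname %in% names(skewed_override)) {
      return(unname(skewed_override[colname]))
    }
    !isTRUE(verdict$normal) && all(x > 0, na.rm = TRUE)
  }

  purrr::map(bases, function(b) {
    pre <- cohort[[paste0(b, "_I")]]
    post <- cohort[[paste0(b, "_F")]]
    v_pre <- test_normality(pre, post, alpha = alpha)
    v_post <- test_normality(post, alpha = alpha)
    sk_pre <- skew_flag(paste0(b, "_I"), pre, v_pre)
    sk_post <- skew_flag(paste0(b, "_F"), post, v_post)
    cmp <- compare_paired(pre, post, alpha = alpha)
    s_pre <- summarize_parameter(pre, skewed = sk_pre, ci_level = ci_level,
                                 interval = interval, name = paste0(b, "_I"))
    s_post <- summarize_parameter(post, skewed = sk_post, ci_level = ci_level,
                                  interval = interval, name = paste0(b, "_F"))
    tibble(
      parameter = b,
      n = s_pre$n,
      initial = s_pre$label, final = s_post$label,
      mean_initial = s_pre$mean, sd_initial = s_pre$sd,
      ci_lo_initial = s_pre$ci_lo, ci_hi_initial = s_pre$ci_hi,
      mean_final = s_post$mean, sd_final = s_post$sd,
      ci_lo_final = s_post$ci_lo, ci_hi_final = s_post$ci_hi,
      skewed_initial = sk_pre, skewed_final = sk_post,
      test_used = cmp$method, statistic = cmp$statistic,
      p_value = cmp$p_value, significant = cmp$significant
    )
  }) |> list_rbind()
}
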