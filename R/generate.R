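#' Generate a synthetic paired cohort
#'
#' Draws a patients-by-parameters cohort from a [synthetic_spec()]. For
#' each patient, independent standard-normal latent factors are drawn,
#' combined with per-parameter residual noise according to the loading
#' table, standardized, and pushed through the parameter's marginal
#' (`location + shift + scale * u` for normal;
#' `exp(location + shift + scale * u)` for lognormal, hence strictly
#' positive). The result is bit-reproducible given the spec and seed.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; defaults to the seed stored in the spec.
#' @return A tibble with a `patient_id` column followed by one numeric
#'   column per parameter, of class `cohort_tbl`. Per-parameter metadata
#'   (family, timepoint, block role, units) is attached as the `"meta"`
#'   attribute and retrievable with [cohort_meta()].
#' @export
#' @examples
#' spec <- synthetic_spec(
#'   dplyr::bind_rows(
#'     parameter_spec("Se_I", "normal", 75.0, 11.1),
#'     parameter_spec("Se_F", "normal", 87.7, 6.3)
#'   ),
#'   loadings = tibble::tibble(factor = "pair_Se",
#'                             parameter = c("Se_I", "Se_F"),
#'                             loading = c(1, 1)),
#'   n_patients = 29, seed = 7
#' )
#' cohort <- generate_cohort(spec)
#' colMeans(cohort[-1])
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pars <- spec$parameters
  n <- spec$n_patients
  p <- nrow(pars)
  L <- loading_matrix(spec)
  k <- ncol(L)

  draws <- withr::with_seed(seed, {
    f <- if (k > 0) matrix(rnorm(n * k), n, k) else matrix(0, n, 0)
    e <- matrix(rnorm(n * p), n, p)
    m <- if (spec$na_rate > 0) matrix(stats::runif(n * p), n, p) else NULL
    list(f = f, e = e, m = m)
  })

  z <- draws$f %*% t(L) + draws$e * rep(pars$noise, each = n)
  v <- rowSums(L^2) + pars$noise^2
  s <- sqrt(v)
  s[s == 0] <- 1 # zero-variance parameter: latent is identically 0
  u <- z / rep(s, each = n)

  centre <- pars$location + pars$shift
  vals <- rep(centre, each = n) + u * rep(pars$scale, each = n)
  vals[, pars$family == "lognormal"] <- exp(vals[, pars$family == "lognormal",
                                                drop = FALSE])
  if (!is.null(draws$m)) vals[draws$m < spec$na_rate] <- NA_real_
  colnames(vals) <- pars$name

  out <- bind_cols(
    tibble(patient_id = sprintf("P%02d", seq_len(n))),
    as_tibble(vals)
  )
  new_cohort(out, meta = select(pars, "name", "family", "timepoint",
                                "role", "units"))
}

new_cohort <- function(df, meta) {
  attr(df, "meta") <- as_tibble(meta)
  class(df) <- c("cohort_tbl", class(df))
  df
}

#' Per-parameter metadata of a cohort table
#'
#' @param cohort A cohort tibble from [generate_cohort()] or
#'   [read_cohort_csv()].
#' @return Tibble with one row per parameter column: `name`, `family`
#'   (if known), `timepoint`, `role`, `units`.
#' @export
cohort_meta <- function(cohort) {
  meta <- attr(cohort, "meta")
  if (is.null(meta)) abort("cohort carries no parameter metadata")
  meta
}

#' Numeric parameter matrix of a cohort
#'
#' Drops the `patient_id` column and returns the values as a matrix with
#' patient ids as row names.
#'
#' @inheritParams cohort_meta
#' @param columns Optional character vector restricting the columns.
#' @return Numeric matrix, patients by parameters.
#' @export
cohort_matrix <- function(cohort, columns = NULL) {
  cols <- setdiff(names(cohort), "patient_id")
  if (!is.null(columns)) {
    missing_cols <- setdiff(columns, cols)
    if (length(missing_cols) > 0) {
      abort(paste0("unknown parameter(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    cols <- columns
  }
  m <- as.matrix(as.data.frame(cohort[cols]))
  rownames(m) <- cohort$patient_id
  m
}
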