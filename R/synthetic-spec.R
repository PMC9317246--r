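#' Describe one simulated parameter (one cohort column)
#'
#' Builds a single-row tibble describing how one column of a synthetic
#' cohort is generated. A parameter has a marginal family (`normal` on the
#' natural scale, `lognormal` with `location`/`scale` on the log scale), an
#' optional paired pre-to-post `shift` added to `location` at generation
#' time, and a residual `noise` standard deviation on the standardized
#' latent scale (latent correlations between parameters are induced by
#' shared factors declared separately; see [synthetic_spec()]).
#'
#' @param name Parameter name. By convention carries a timepoint suffix
#'   (`_I` initial, `_F` final) or is one of the unsuffixed shared
#'   covariates (`UI1`, `UI2`, `UI3`, `age`, `BMI`, `energy`).
#' @param family `"normal"` or `"lognormal"`.
#' @param location Mean on the family's scale (log scale for lognormal).
#' @param scale Standard deviation on the family's scale; must be > 0.
#' @param shift Added to `location` when generating; expresses a planted
#'   pre-to-post effect on the family's scale. Default 0.
#' @param noise Residual SD of the latent variable (relative to the factor
#'   loadings); default 1.
#' @param timepoint `"I"`, `"F"` or `"none"`; inferred from the name suffix
#'   when missing.
#' @param role Block role for the PLS stage: `"predictor"`, `"response"`
#'   or `"excluded"`.
#' @param units Free-text units label.
#' @return A one-row tibble.
#' @export
#' @examples
#' parameter_spec("Se_I", "normal", 75.0, 11.1, role = "predictor",
#'                units = "ug/L")
parameter_spec <- function(name, family = c("normal", "lognormal"),
                           location, scale, shift = 0, noise = 1,
                           timepoint = NULL,
                           role = c("predictor", "response", "excluded"),
                           units = NA_character_) {
  family <- arg_match(family)
  role <- arg_match(role)
  if (is.null(timepoint)) {
    timepoint <- if (grepl("_I$", name)) "I" else if (grepl("_F$", name)) "F" else "none"
  }
  tibble(
    name = name, family = family, location = unname(location),
    scale = unname(scale), shift = unname(shift), noise = unname(noise),
    timepoint = timepoint, role = role, units = units
  )
}

#' Specification of a synthetic paired cohort
#'
#' Bundles the per-parameter marginal definitions with a latent-factor
#' loading table and cohort-level settings. Correlations between
#' parameters are induced by shared latent factors: parameter \eqn{i} is
#' generated as a monotone transform of the standardized latent variable
#' \deqn{u_i = (\sum_f l_{if} F_f + \sigma_i \epsilon_i) /
#'       \sqrt{\sum_f l_{if}^2 + \sigma_i^2},}
#' where the \eqn{F_f} and \eqn{\epsilon_i} are independent standard
#' normals, so the latent correlation between parameters \eqn{i} and
#' \eqn{j} has the closed form
#' \deqn{\rho_{ij} = \sum_f l_{if} l_{jf} /
#'       \sqrt{(\sum_f l_{if}^2 + \sigma_i^2)(\sum_f l_{jf}^2 + \sigma_j^2)}.}
#' This guarantees a positive semi-definite correlation structure and
#' mirrors the latent-variable logic of the PLS stage.
#'
#' @param parameters Tibble of rows built by [parameter_spec()] (or
#'   matching its columns). Names must be unique, scales positive.
#' @param loadings Tibble with columns `factor`, `parameter`, `loading`
#'   (unitless, finite). Absent combinations load 0. `NULL` means no
#'   shared factors (independent parameters).
#' @param n_patients Number of paired observations; at least 3. Default 29.
#' @param na_rate Fraction of cells masked missing completely at random,
#'   in \[0, 1). Default 0.
#' @param seed Integer seed; together with the spec it fully determines
#'   the generated cohort.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_cohort()], [default_study_spec()],
#'   [factor_model_correlation()]
#' @export
synthetic_spec <- function(parameters, loadings = NULL, n_patients = 29,
                           na_rate = 0, seed = 1L) {
  parameters <- as_tibble(parameters)
  required <- c("name", "family", "location", "scale")
  missing_cols <- setdiff(required, names(parameters))
  if (length(missing_cols) > 0) {
    abort(paste0("`parameters` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"shift" %in% names(parameters)) parameters$shift <- 0
  if (!"noise" %in% names(parameters)) parameters$noise <- 1
  if (!"timepoint" %in% names(parameters)) {
    parameters$timepoint <- ifelse(grepl("_I$", parameters$name), "I",
                            ifelse(grepl("_F$", parameters$name), "F", "none"))
  }
  if (!"role" %in% names(parameters)) parameters$role <- "predictor"
  if (!"units" %in% names(parameters)) parameters$units <- NA_character_

  if (anyDuplicated(parameters$name)) {
    dup <- unique(parameters$name[duplicated(parameters$name)])
    abort(paste0("duplicated parameter name(s): ", paste(dup, collapse = ", ")))
  }
  if (any(!is.finite(parameters$scale)) || any(parameters$scale <= 0)) {
    bad <- parameters$name[!is.finite(parameters$scale) | parameters$scale <= 0]
    abort(paste0("non-positive scale for parameter(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (any(parameters$noise < 0)) abort("`noise` must be >= 0")
  if (n_patients < 3) abort("`n_patients` must be at least 3")
  if (na_rate < 0 || na_rate >= 1) abort("`na_rate` must be in [0, 1)")

  if (is.null(loadings)) {
    loadings <- tibble(factor = character(), parameter = character(),
                       loading = double())
  }
  loadings <- as_tibble(loadings)
  if (nrow(loadings) > 0) {
    if (!all(c("factor", "parameter", "loading") %in% names(loadings))) {
      abort("`loadings` needs columns factor, parameter, loading")
    }
    if (any(!is.finite(loadings$loading))) abort("all loadings must be finite")
    unknown <- setdiff(loadings$parameter, parameters$name)
    if (length(unknown) > 0) {
      abort(paste0("loadings refer to unknown parameter(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }

  structure(
    list(parameters = parameters, loadings = loadings,
         n_patients = as.integer(n_patients), na_rate = na_rate,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>\n")
  cat("  patients:  ", x$n_patients, "\n", sep = "")
  cat("  parameters:", nrow(x$parameters), "\n", sep = " ")
  cat("  factors:   ", length(unique(x$loadings$factor)), "\n", sep = " ")
  cat("  na_rate:   ", x$na_rate, "  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

# loading matrix (parameters x factors) from the long loading table
loading_matrix <- function(spec) {
  p <- spec$parameters$name
  f <- unique(spec$loadings$factor)
  L <- matrix(0, nrow = length(p), ncol = length(f),
              dimnames = list(p, f))
  if (nrow(spec$loadings) > 0) {
    L[cbind(match(spec$loadings$parameter, p),
            match(spec$loadings$factor, f))] <- spec$loadings$loading
  }
  L
}

#' Closed-form latent correlation matrix implied by a spec
#'
#' Returns the correlation matrix of the standardized latent Gaussian
#' variables underlying each parameter,
#' \eqn{\rho_{ij} = \sum_f l_{if} l_{jf} / \sqrt{v_i v_j}} with
#' \eqn{v_i = \sum_f l_{if}^2 + \sigma_i^2}. Because every marginal is a
#' monotone transform of its latent variable, Spearman rank correlations
#' of generated data converge to the Gaussian-rank image of this matrix
#' (see [pearson_to_spearman()]), for lognormal columns as well.
#'
#' @param spec A [synthetic_spec()].
#' @return A symmetric parameters-by-parameters matrix with unit diagonal
#'   (diagonal is 1 even for zero-variance degenerate parameters).
#' @export
factor_model_correlation <- function(spec) {
  L <- loading_matrix(spec)
  v <- rowSums(L^2) + spec$parameters$noise^2
  S <- L %*% t(L)
  d <- sqrt(v)
  d[d == 0] <- 1
  C <- S / outer(d, d)
  diag(C) <- 1
  C
}

#' Convert between Spearman and Pearson correlations of a bivariate normal
#'
#' For a bivariate Gaussian with Pearson correlation \eqn{r}, the
#' population Spearman rank correlation is
#' \eqn{\rho_S = (6/\pi)\,\mathrm{asin}(r/2)}; these helpers apply the
#' relation and its inverse \eqn{r = 2\sin(\pi\rho_S/6)}. The generator
#' uses the inverse to turn reported Spearman targets into Pearson targets
#' on the latent Gaussian scale.
#'
#' @param rho_s,r Correlation value(s) in \[-1, 1\].
#' @return Numeric vector of converted correlations.
#' @export
spearman_to_pearson <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' @rdname spearman_to_pearson
#' @export
pearson_to_spearman <- function(r) (6 / pi) * asin(r / 2)
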