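#' Analysis configuration
#'
#' Collects the thresholds of the full pipeline with the published
#' defaults: significance level 0.05, Q2 retention limit 0.05, weight
#' threshold 0.3, 7 cross-validation groups, top-25 correlation tables,
#' 95% log-scale intervals.
#'
#' @param alpha Significance level.
#' @param q2_limit Q2 component-retention limit.
#' @param weight_threshold Informativeness / pair-eligibility bound.
#' @param cv_groups Number of CV prediction groups.
#' @param top_k Correlation-table length.
#' @param ci_level Level for log-scale summary intervals.
#' @param max_components Component scan cap.
#' @param roles Optional named character vector overriding block roles
#'   per parameter (`"predictor"`, `"response"`, `"excluded"`).
#' @param seed Seed recorded in the run log.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(alpha = 0.05, q2_limit = 0.05,
                            weight_threshold = 0.3, cv_groups = 7,
                            top_k = 25, ci_level = 0.95,
                            max_components = 5, roles = NULL, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, q2_limit > 0, q2_limit <= 1,
            weight_threshold > 0, cv_groups >= 2, top_k >= 1,
            ci_level > 0, ci_level < 1, max_components >= 1)
  structure(
    list(alpha = alpha, q2_limit = q2_limit,
         weight_threshold = weight_threshold, cv_groups = cv_groups,
         top_k = top_k, ci_level = ci_level,
         max_components = max_components, roles = roles,
         seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Write / read a cohort as CSV
#'
#' One row per patient; the header carries the parameter names with
#' their `_I`/`_F` timepoint suffixes (ioduria as `UI1`/`UI2`/`UI3`).
#' Reading re-derives the per-column metadata from the suffixes; block
#' roles default to `response` for the immunological panel and
#' `predictor` otherwise, and can be overridden downstream via
#' [analysis_config()]. Round-trips written by [write_cohort_csv()] are
#' value-exact.
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly;
#'   `read_cohort_csv` returns a cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(as_tibble(as.data.frame(cohort)), path)
  invisible(path)
}

RESPONSE_BASES <- c("INFg", "TNFa", "CXCL10", "IL4", "IL1b", "IL17",
                    "TGFb", "CRP")

#' @rdname write_cohort_csv
#' @param missing_ok Allow missing cells (default `TRUE`); when `FALSE`,
#'   a missing cell raises an error naming its row and column.
#' @export
read_cohort_csv <- function(path, missing_ok = TRUE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                  name_repair = "minimal"))
  if (anyDuplicated(header)) {
    abort(paste0("duplicated header column(s): ",
                 paste(unique(header[duplicated(header)]), collapse = ", ")))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(), .default = readr::col_character()
  ), show_col_types = FALSE)
  if (!"patient_id" %in% names(raw)) {
    raw <- bind_cols(tibble(patient_id = sprintf("P%02d", seq_len(nrow(raw)))),
                     raw)
  }
  vals <- raw[setdiff(names(raw), "patient_id")]
  for (cn in names(vals)) {
    v <- vals[[cn]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & v != "NA" & v != "" & is.na(num))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                    bad[1], cn, v[bad[1]]))
    }
    if (!missing_ok) {
      miss <- which(is.na(num))
      if (length(miss) > 0) {
        abort(sprintf("missing value at row %d, column '%s'", miss[1], cn))
      }
    }
    vals[[cn]] <- num
  }
  base <- sub("_(I|F)$", "", names(vals))
  meta <- tibble(
    name = names(vals),
    family = NA_character_,
    timepoint = ifelse(grepl("_I$", names(vals)), "I",
                ifelse(grepl("_F$", names(vals)), "F", "none")),
    role = ifelse(base %in% RESPONSE_BASES, "response", "predictor"),
    units = NA_character_
  )
  inform(sprintf("read cohort: %d patients, %d parameters", nrow(raw),
                 ncol(vals)))
  new_cohort(bind_cols(raw["patient_id"], vals), meta)
}

# Columns belonging to each of the two PLS models: suffixed columns by
# timepoint; shared covariates split as the study used them (UI1 initial
# only, UI3 final only, UI2/age/BMI/energy in both).
model_columns <- function(meta, which = c("initial", "final"),
                          roles = NULL) {
  which <- arg_match(which)
  if (!is.null(roles)) {
    meta$role[match(names(roles), meta$name)] <- unname(roles)
  }
  shared <- meta$timepoint == "none"
  in_model <- if (which == "initial") {
    meta$timepoint == "I" | (shared & meta$name != "UI3")
  } else {
    meta$timepoint == "F" | (shared & meta$name != "UI1")
  }
  list(
    predictors = meta$name[in_model & meta$role == "predictor"],
    responses = meta$name[in_model & meta$role == "response"]
  )
}

#' Run the complete analysis pipeline on a cohort
#'
#' Reproduces the published analysis end to end: the univariate stage on
#' every paired biomarker (normality screening, test routing, log-scale
#' summaries), then two independent PLS analyses — one on the
#' pre-supplementation parameters, one on the post-supplementation
#' parameters — each with iterative pruning of uninformative parameters,
#' Q2-based component retention, and the ranked correlation-weight table
#' with Spearman cross-checks.
#'
#' @param cohort Cohort tibble carrying metadata
#'   ([generate_cohort()] / [read_cohort_csv()]).
#' @param config An [analysis_config()].
#' @return A list of class `ht_analysis`: `univariate` (summary table),
#'   `models` (named list `initial`/`final`, each holding `selection`
#'   (a [prune_variables()] trace), `fit`, `weights`
#'   ([weight_coordinates()] of the final fit), `correlations` (ranked
#'   correlation-weight table with Spearman annotation), `explained`
#'   ([explained_variance()])), and `config`. Model-stage errors are
#'   rethrown with the stage name attached; the univariate stage's
#'   results survive in the error condition.
#' @export
run_full_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  meta <- cohort_meta(cohort)
  univ <- summarize_cohort(cohort, alpha = config$alpha,
                           ci_level = config$ci_level)

  fit_model <- function(which) {
    cols <- model_columns(meta, which, roles = config$roles)
    if (length(cols$responses) == 0) {
      abort(paste0("model stage (", which, "): no response columns assigned"),
            univariate = univ, class = "thyropls_stage_error")
    }
    x <- cohort_matrix(cohort, cols$predictors)
    y <- cohort_matrix(cohort, cols$responses)
    sel <- tryCatch(
      prune_variables(x, y, weight_threshold = config$weight_threshold,
                      limit = config$q2_limit, n_groups = config$cv_groups,
                      max_components = config$max_components),
      error = function(e) {
        abort(paste0("model stage (", which, "): ", conditionMessage(e)),
              parent = e, univariate = univ,
              class = "thyropls_stage_error")
      }
    )
    fit <- sel$fit
    corr <- correlation_weight_table(
      fit, cohort, threshold = config$weight_threshold, k = config$top_k,
      alpha = config$alpha
    )
    list(selection = sel, fit = fit, weights = weight_coordinates(fit),
         correlations = corr, explained = explained_variance(fit))
  }

  out <- list(
    univariate = univ,
    models = list(initial = fit_model("initial"), final = fit_model("final")),
    config = config
  )
  class(out) <- "ht_analysis"
  out
}

#' @export
print.ht_analysis <- function(x, ...) {
  cat("<ht_analysis>\n")
  sig <- x$univariate$parameter[x$univariate$significant]
  cat("  univariate: ", nrow(x$univariate), " paired biomarkers; significant: ",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n", sep = "")
  for (m in names(x$models)) {
    mod <- x$models[[m]]
    cat("  ", m, " model: ", length(mod$selection$retained_predictors),
        " predictors, ", length(mod$selection$retained_responses),
        " responses, ", mod$selection$components_kept,
        " component(s) kept\n", sep = "")
  }
  invisible(x)
}

#' Write the analysis bundle to disk
#'
#' Emits the three result surfaces as plain text: the pre/post summary
#' table (`univariate.csv`), per model a weight-coordinate CSV, the
#' ranked correlation table CSV, and a JSON report (weights, loadings,
#' explained variance, eigenvalues, Q2 trace, retained/dropped
#' parameters, scaling records, config). Every CSV is re-readable with
#' [readr::read_csv()].
#'
#' @param analysis An `ht_analysis` from [run_full_analysis()].
#' @param dir Output directory (created if missing).
#' @return Invisible character vector of the files written.
#' @export
write_analysis <- function(analysis, dir) {
  stopifnot(inherits(analysis, "ht_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  p <- file.path(dir, "univariate.csv")
  readr::write_csv(analysis$univariate, p)
  files <- c(files, p)
  for (m in names(analysis$models)) {
    mod <- analysis$models[[m]]
    pw <- file.path(dir, paste0("weights_", m, ".csv"))
    readr::write_csv(mod$weights, pw)
    pc <- file.path(dir, paste0("correlations_", m, ".csv"))
    readr::write_csv(mod$correlations, pc)
    pj <- file.path(dir, paste0("model_", m, ".json"))
    fit <- mod$fit
    report <- list(
      retained_predictors = mod$selection$retained_predictors,
      retained_responses = mod$selection$retained_responses,
      dropped = mod$selection$dropped,
      components_kept = mod$selection$components_kept,
      q2 = as.data.frame(mod$selection$q2),
      explained_variance = as.data.frame(mod$explained),
      x_weights = as.data.frame(fit$x_weights),
      y_weights = as.data.frame(fit$y_weights_norm),
      x_loadings = as.data.frame(fit$x_loadings),
      inner_coefficients = fit$inner_coefficients,
      x_scaling = fit$x_scaling, y_scaling = fit$y_scaling,
      seed = analysis$config$seed
    )
    jsonlite::write_json(report, pj, digits = NA, auto_unbox = TRUE,
                         dataframe = "columns")
    files <- c(files, pw, pc, pj)
  }
  invisible(files)
}
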