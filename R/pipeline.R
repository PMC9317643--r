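#' Preset study profiles
#'
#' Bundles a [group_design()], a [correlation_profile()] and a metabolite
#' count into a named simulation profile. Two presets emulate the structure
#' of published multi-biospecimen lung-cancer studies: `"gctof_like"` (48
#' cases vs 31 controls, 176 metabolites, high between-biospecimen
#' correlations, ~23% differential) and `"hilic_like"` (38 vs 40, 327
#' metabolites, low correlations, ~21% differential).
#'
#' @param name `"gctof_like"` or `"hilic_like"`.
#' @param design,profile,n_metabolites override any preset component.
#' @param effect_size standardized effect size for differential metabolites.
#' @return a list of class `study_profile`.
#' @export
study_profile <- function(name = c("gctof_like", "hilic_like"),
                          design = NULL, profile = NULL,
                          n_metabolites = NULL, effect_size = 1) {
  name <- match.arg(name)
  if (name == "gctof_like") {
    design <- design %||% group_design(48, 31, 0.23, effect_size)
    profile <- profile %||% correlation_profile("high")
    n_metabolites <- n_metabolites %||% 176L
  } else {
    design <- design %||% group_design(38, 40, 0.21, effect_size)
    profile <- profile %||% correlation_profile("low")
    n_metabolites <- n_metabolites %||% 327L
  }
  structure(list(name = name, design = design, profile = profile,
                 n_metabolites = as.integer(n_metabolites)),
            class = "study_profile")
}

#' Simulation-study configuration
#'
#' @param profiles a [study_profile], or a named list of them.
#' @param levels missingness percentages; each must be 0 or a scheduled rate
#'   (see [missingness_schedule()]).
#' @param methods imputation method codes.
#' @param approaches `"separate"`, `"combined"`, or both.
#' @param n_replicates simulated studies per profile (>= 1).
#' @param seed master seed; every stage derives its own seed from it, so
#'   results are independent of execution order.
#' @param settings an [imputer_settings()] (its `seed` is overridden per
#'   run).
#' @param alpha raw significance level for MANOVA calls.
#' @return a list of class `study_config`.
#' @export
study_config <- function(profiles = study_profile("gctof_like"),
                         levels = c(5, 20, 40, 60),
                         methods = imputation_methods(),
                         approaches = c("separate", "combined"),
                         n_replicates = 20, seed = 1,
                         settings = imputer_settings(),
                         alpha = 0.05) {
  if (inherits(profiles, "study_profile")) {
    profiles <- stats::setNames(list(profiles), profiles$name)
  }
  stopifnot(length(profiles) >= 1,
            all(vapply(profiles, inherits, TRUE, "study_profile")))
  if (is.null(names(profiles)) || any(names(profiles) == ""))
    names(profiles) <- vapply(profiles, `[[`, "", "name")
  for (p in levels) quantile_for_rate(p) # validates every level
  methods <- match.arg(toupper(methods), imputation_methods(),
                       several.ok = TRUE)
  approaches <- match.arg(approaches, c("separate", "combined"),
                          several.ok = TRUE)
  if (n_replicates < 1) stop_param("'n_replicates' must be at least 1")
  structure(list(profiles = profiles, levels = levels, methods = methods,
                 approaches = approaches,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), settings = settings,
                 alpha = alpha),
            class = "study_config")
}

#' Run the full factorial imputation simulation
#'
#' For every profile and replicate: generate a complete paired study, mask
#' both biospecimen matrices at each missingness level (independent masks,
#' shared across methods and approaches so method comparisons see identical
#' missing cells), log-transform, impute under every approach x method,
#' and evaluate the imputed data against the complete data (correlation
#' bias and MANOVA-call validity). Failures of a single grid cell are
#' logged as warnings and skipped.
#'
#' @param config a [study_config()].
#' @param verbose print progress lines.
#' @return a long-format data.frame (class `results_table`): one row per
#'   (profile, replicate, level, method, approach) with validity metrics
#'   and bias summaries.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  rows <- list()
  for (pf_i in seq_along(config$profiles)) {
    pf <- config$profiles[[pf_i]]
    pf_name <- names(config$profiles)[pf_i]
    for (rep_i in seq_len(config$n_replicates)) {
      study <- generate_paired_study(
        pf$design, pf$profile, pf$n_metabolites,
        seed = derive_seed(config$seed, pf_i, rep_i))
      log_complete <- log_transform_study(study)
      true_calls <- manova_calls(log_complete, config$alpha)
      for (lev_i in seq_along(config$levels)) {
        p <- config$levels[lev_i]
        mask_a <- induce_missingness(
          study$A, p, derive_seed(config$seed, pf_i, rep_i, lev_i, 1))
        mask_b <- induce_missingness(
          study$B, p, derive_seed(config$seed, pf_i, rep_i, lev_i, 2))
        masked <- log_transform_study(mask_study(study, mask_a, mask_b))
        for (ap in config$approaches) {
          for (me in config$methods) {
            if (verbose)
              message(sprintf("%s rep %d p=%g %s/%s",
                              pf_name, rep_i, p, ap, me))
            row <- tryCatch(
              evaluate_cell(log_complete, masked, mask_a, mask_b,
                            true_calls, me, ap, config),
              error = function(e) {
                warning(sprintf("cell failed (%s rep %d p=%g %s/%s): %s",
                                pf_name, rep_i, p, ap, me,
                                conditionMessage(e)), call. = FALSE)
                NULL
              })
            if (is.null(row)) next
            rows[[length(rows) + 1L]] <- cbind(
              data.frame(profile = pf_name, replicate = rep_i, p = p,
                         method = me, approach = ap), row)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("results_table", class(out))
  out
}

evaluate_cell <- function(log_complete, masked, mask_a, mask_b,
                          true_calls, method, approach, config) {
  settings <- config$settings
  settings$seed <- derive_seed(config$seed, method, approach,
                               attr(mask_a, "seed"))
  imputed <- suppressWarnings(
    impute_study(masked, method, approach, settings))
  rec <- correlation_records(log_complete, imputed, mask_a, mask_b)
  bias <- bias_summary(rec)
  imp_calls <- manova_calls(imputed, config$alpha)
  vm <- validity_metrics(true_calls$call, imp_calls$call)
  cbind(data.frame(sensitivity = vm$sensitivity,
                   specificity = vm$specificity,
                   accuracy = vm$accuracy,
                   TP = vm$TP, FP = vm$FP, TN = vm$TN, FN = vm$FN),
        bias)
}

#' Summarise a results table by condition
#'
#' Mean and SD of each performance metric by (profile, method, approach,
#' missingness level) — the analogue of a simulation study's summary
#' tables.
#'
#' @param results a results table from [run_study()].
#' @param metrics columns to summarise.
#' @return data.frame with `<metric>_mean` and `<metric>_sd` columns plus
#'   `n_replicates`; SDs are `NA` with a single replicate.
#' @export
summarize_results <- function(results,
                              metrics = c("sensitivity", "specificity",
                                          "accuracy", "mean_bias",
                                          "mean_abs_bias",
                                          "mean_abs_r_imputed")) {
  stopifnot(all(metrics %in% names(results)))
  by <- c("profile", "method", "approach", "p")
  parts <- split(results, results[by], drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(df) {
    row <- df[1, by, drop = FALSE]
    row$n_replicates <- nrow(df)
    for (m in metrics) {
      v <- df[[m]]
      row[[paste0(m, "_mean")]] <- mean(v, na.rm = TRUE)
      row[[paste0(m, "_sd")]] <- if (nrow(df) > 1) stats::sd(v, na.rm = TRUE)
                                 else NA_real_
    }
    row
  }))
  rownames(out) <- NULL
  out[order(out$profile, out$method, out$approach, out$p), , drop = FALSE]
}
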