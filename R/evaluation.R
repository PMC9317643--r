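#' Between-biospecimen correlation per metabolite
#'
#' For each metabolite, the Pearson correlation across subjects of its
#' (log-scale) abundances in biospecimen A vs biospecimen B — the
#' intra-subject correlation structure the imputation methods should
#' preserve.
#'
#' @param study a complete [paired_study] (log scale recommended; at least 3
#'   subjects).
#' @return data.frame with columns `metabolite` and `r`; a zero-variance row
#'   yields `NA` (flagged, excluded from bias summaries downstream).
#' @export
between_biospecimen_correlations <- function(study) {
  stopifnot(inherits(study, "paired_study"))
  if (anyNA(study$A) || anyNA(study$B))
    stop_param("correlations require complete matrices (impute first)")
  if (ncol(study$A) < 3) stop_param("need at least 3 subjects")
  r <- row_correlations(study$A, study$B)
  data.frame(metabolite = rownames(study$A) %||%
               as.character(seq_len(nrow(study$A))),
             r = r, row.names = NULL)
}

row_correlations <- function(a, b) {
  ca <- a - rowMeans(a)
  cb <- b - rowMeans(b)
  va <- rowSums(ca^2)
  vb <- rowSums(cb^2)
  r <- rowSums(ca * cb) / sqrt(va * vb)
  r[va == 0 | vb == 0] <- NA_real_
  pmin(pmax(r, -1), 1)
}

#' Correlation bias records for an imputed study
#'
#' Pairs each metabolite's between-biospecimen correlation in the true
#' complete data with the one recomputed after masking and imputation;
#' `bias = r_imputed - r_true`, so the attenuation produced by imputation
#' appears as bias opposing the sign of the true correlation.
#'
#' @param complete_study,imputed_study complete [paired_study] objects on
#'   the same scale (typically log).
#' @param mask_A,mask_B optional logical masks used to create the missing
#'   data; recorded as per-metabolite missing counts.
#' @return data.frame with `metabolite`, `r_true`, `r_imputed`, `bias`,
#'   `n_missing_A`, `n_missing_B`.
#' @export
correlation_records <- function(complete_study, imputed_study,
                                mask_A = NULL, mask_B = NULL) {
  rt <- between_biospecimen_correlations(complete_study)
  ri <- between_biospecimen_correlations(imputed_study)
  stopifnot(identical(rt$metabolite, ri$metabolite))
  out <- data.frame(metabolite = rt$metabolite,
                    r_true = rt$r, r_imputed = ri$r,
                    bias = ri$r - rt$r)
  out$n_missing_A <- if (is.null(mask_A)) 0L else as.integer(rowSums(mask_A))
  out$n_missing_B <- if (is.null(mask_B)) 0L else as.integer(rowSums(mask_B))
  out
}

#' Two-group bivariate MANOVA for one metabolite
#'
#' Tests whether a metabolite's bivariate mean (biospecimen A, biospecimen
#' B) differs between the two groups, via Hotelling's T-squared with pooled
#' covariance: `T2 = (n1 n2 / n) d' S^-1 d`, converted to
#' `F = ((n - 3) / (2 (n - 2))) T2` on `(2, n - 3)` degrees of freedom. For
#' two groups this is exactly equivalent to Wilks/Pillai MANOVA.
#'
#' @param a_values,b_values per-subject abundances in biospecimens A and B.
#' @param groups two-level factor, each level with at least 3 subjects.
#' @param alpha significance level for the call (raw, uncorrected).
#' @return list with `statistic` (T2), `p_value`, `call` (p < alpha),
#'   `singular` flag (a singular pooled covariance yields `p_value = NA`,
#'   `call = FALSE`, and a warning).
#' @export
manova_two_group <- function(a_values, b_values, groups, alpha = 0.05) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop_param("'groups' must have two levels")
  n_g <- table(groups)
  if (any(n_g < 3)) stop_param("each group needs at least 3 subjects")
  x <- cbind(a_values, b_values)
  if (nrow(x) != length(groups)) stop_param("length mismatch")
  g1 <- groups == levels(groups)[1]
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  d <- colMeans(x[g1, , drop = FALSE]) - colMeans(x[!g1, , drop = FALSE])
  s_pool <- ((n1 - 1) * stats::cov(x[g1, , drop = FALSE]) +
             (n2 - 1) * stats::cov(x[!g1, , drop = FALSE])) / (n - 2)
  si <- tryCatch(solve(s_pool), error = function(e) NULL)
  if (is.null(si) || !all(is.finite(si))) {
    warning("singular pooled covariance; no significance call",
            call. = FALSE)
    return(list(statistic = NA_real_, p_value = NA_real_, call = FALSE,
                singular = TRUE))
  }
  t2 <- (n1 * n2 / n) * drop(t(d) %*% si %*% d)
  f <- (n - 3) / (2 * (n - 2)) * t2
  p <- stats::pf(f, 2, n - 3, lower.tail = FALSE)
  list(statistic = t2, p_value = p, call = isTRUE(p < alpha),
       singular = FALSE)
}

#' MANOVA significance calls for every metabolite of a study
#'
#' @param study a complete [paired_study] (log scale for the standard
#'   workflow).
#' @param alpha raw significance level (default 0.05, no multiplicity
#'   correction).
#' @return data.frame with `metabolite`, `p_value`, `call` (logical; `NA`
#'   p-values give `FALSE` calls with the singular flag set).
#' @export
manova_calls <- function(study, alpha = 0.05) {
  stopifnot(inherits(study, "paired_study"))
  if (anyNA(study$A) || anyNA(study$B))
    stop_param("significance calls require complete matrices")
  m <- nrow(study$A)
  # vectorised Hotelling T^2 across metabolites (2x2 pooled covariances)
  g <- study$groups
  g1 <- g == levels(g)[1]
  n1 <- sum(g1); n2 <- sum(!g1); n <- n1 + n2
  a <- study$A; b <- study$B
  d1 <- rowMeans(a[, g1, drop = FALSE]) - rowMeans(a[, !g1, drop = FALSE])
  d2 <- rowMeans(b[, g1, drop = FALSE]) - rowMeans(b[, !g1, drop = FALSE])
  ss <- function(x, keep) {
    xc <- x[, keep, drop = FALSE] - rowMeans(x[, keep, drop = FALSE])
    xc
  }
  a1 <- ss(a, g1); b1 <- ss(b, g1); a2 <- ss(a, !g1); b2 <- ss(b, !g1)
  s11 <- (rowSums(a1^2) + rowSums(a2^2)) / (n - 2)
  s22 <- (rowSums(b1^2) + rowSums(b2^2)) / (n - 2)
  s12 <- (rowSums(a1 * b1) + rowSums(a2 * b2)) / (n - 2)
  det_s <- s11 * s22 - s12^2
  quad <- (s22 * d1^2 - 2 * s12 * d1 * d2 + s11 * d2^2) / det_s
  t2 <- (n1 * n2 / n) * quad
  f <- (n - 3) / (2 * (n - 2)) * t2
  p_value <- stats::pf(f, 2, n - 3, lower.tail = FALSE)
  singular <- !is.finite(det_s) | det_s <= 0 | !is.finite(p_value)
  p_value[singular] <- NA_real_
  if (any(singular))
    warning(sum(singular), " metabolite(s) with singular pooled covariance",
            call. = FALSE)
  data.frame(metabolite = rownames(study$A) %||% as.character(seq_len(m)),
             p_value = p_value,
             call = !is.na(p_value) & p_value < alpha,
             singular = singular, row.names = NULL)
}

#' Agreement of imputed-data significance calls with complete-data calls
#'
#' Sensitivity is the proportion of metabolites significant in the complete
#' data that remain significant after imputation; specificity the proportion
#' of non-significant metabolites that remain non-significant; accuracy the
#' proportion of concordant calls overall. These are agreement rates with
#' the complete-data analysis, not diagnostic-test performance.
#'
#' @param true_calls,imputed_calls aligned logical vectors (complete-data
#'   and imputed-data calls); `NA` pairs are dropped.
#' @return list of class `validity_metrics` with `TP`, `FP`, `TN`, `FN`,
#'   `sensitivity`, `specificity`, `accuracy`; a zero denominator yields
#'   `NA` for the affected rate.
#' @export
validity_metrics <- function(true_calls, imputed_calls) {
  if (length(true_calls) != length(imputed_calls))
    stop_param("call vectors must be aligned")
  keep <- !is.na(true_calls) & !is.na(imputed_calls)
  tc <- true_calls[keep]; ic <- imputed_calls[keep]
  tp <- sum(tc & ic); fn <- sum(tc & !ic)
  tn <- sum(!tc & !ic); fp <- sum(!tc & ic)
  structure(
    list(TP = tp, FP = fp, TN = tn, FN = fn,
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         accuracy = if (tp + tn + fp + fn > 0)
           (tp + tn) / (tp + tn + fp + fn) else NA_real_),
    class = "validity_metrics")
}

#' @export
print.validity_metrics <- function(x, ...) {
  cat(sprintf(
    "validity_metrics: sens %.3f, spec %.3f, acc %.3f (TP %d FP %d TN %d FN %d)\n",
    x$sensitivity, x$specificity, x$accuracy, x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Summarise correlation bias records
#'
#' Mean bias, mean absolute bias and SD of bias, optionally grouped (e.g. by
#' method, approach, missingness level). Records with undefined correlations
#' are excluded and counted.
#'
#' @param records a data.frame from [correlation_records()], possibly with
#'   extra grouping columns.
#' @param by character vector of grouping column names (default: none).
#' @return data.frame with one row per group: `n`, `n_undefined`,
#'   `mean_bias`, `mean_abs_bias`, `sd_bias`, `mean_r_true`,
#'   `mean_r_imputed`, `mean_abs_r_imputed`.
#' @export
bias_summary <- function(records, by = character()) {
  stopifnot(all(c("bias", "r_true", "r_imputed") %in% names(records)),
            all(by %in% names(records)))
  one <- function(df) {
    ok <- !is.na(df$bias)
    data.frame(n = sum(ok), n_undefined = sum(!ok),
               mean_bias = mean(df$bias[ok]),
               mean_abs_bias = mean(abs(df$bias[ok])),
               sd_bias = stats::sd(df$bias[ok]),
               mean_r_true = mean(df$r_true[ok]),
               mean_r_imputed = mean(df$r_imputed[ok]),
               mean_abs_r_imputed = mean(abs(df$r_imputed[ok])))
  }
  if (length(by) == 0) return(one(records))
  parts <- split(records, records[by], drop = TRUE)
  do.call(rbind, c(lapply(parts, function(df)
    cbind(df[1, by, drop = FALSE], one(df))), make.row.names = FALSE))
}
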