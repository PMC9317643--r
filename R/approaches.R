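#' Stack a paired study into one combined matrix
#'
#' Vertically concatenates biospecimen A rows then biospecimen B rows into a
#' single 2M x N matrix; row names are suffixed with the biospecimen tag so
#' rows stay unique. [unstack_matrix()] reverses the operation losslessly.
#'
#' @param study a [paired_study].
#' @return the combined matrix with attributes `n_metabolites` and
#'   `metabolite_ids`.
#' @export
stack_study <- function(study) {
  stopifnot(inherits(study, "paired_study"))
  m <- nrow(study$A)
  ids <- rownames(study$A)
  x <- rbind(study$A, study$B)
  rownames(x) <- c(paste0(ids, "::A"), paste0(ids, "::B"))
  structure(x, n_metabolites = m, metabolite_ids = ids)
}

#' Unstack a combined matrix back into the two biospecimen matrices
#'
#' @param x a matrix produced by [stack_study()] (possibly after
#'   imputation).
#' @return list with matrices `A` and `B` carrying the original metabolite
#'   IDs.
#' @export
unstack_matrix <- function(x) {
  m <- attr(x, "n_metabolites")
  ids <- attr(x, "metabolite_ids")
  if (is.null(m) || nrow(x) != 2 * m)
    stop_param("not a stacked matrix (missing or inconsistent attributes)")
  A <- x[seq_len(m), , drop = FALSE]
  B <- x[m + seq_len(m), , drop = FALSE]
  rownames(A) <- rownames(B) <- ids
  list(A = A, B = B)
}

#' Impute each biospecimen matrix separately
#'
#' Runs the imputation method independently on biospecimen A (seed
#' `settings$seed`) and biospecimen B (seed `settings$seed + 1`), then
#' reassembles the study.
#'
#' @param study a [paired_study] with missing values (log scale for the
#'   standard workflow).
#' @param method an imputation method code, see [imputation_methods()].
#' @param settings an [imputer_settings()].
#' @return the study with complete matrices.
#' @export
impute_separate <- function(study, method, settings = imputer_settings()) {
  stopifnot(inherits(study, "paired_study"))
  s_a <- s_b <- settings
  s_a$seed <- settings$seed
  s_b$seed <- settings$seed + 1L
  study$A <- impute_matrix(study$A, method, s_a, log_scale = study$log_scale)
  study$B <- impute_matrix(study$B, method, s_b, log_scale = study$log_scale)
  study
}

#' Impute the combined (stacked) matrix
#'
#' Stacks the two biospecimen matrices into one 2M x N matrix, runs the
#' imputation method once on it (seed `settings$seed`), and unstacks the
#' result. Stacking lets an imputer borrow a metabolite's signal in the
#' other biospecimen, which may help preserve the between-biospecimen
#' correlation.
#'
#' @inheritParams impute_separate
#' @return the study with complete matrices.
#' @export
impute_combined <- function(study, method, settings = imputer_settings()) {
  stopifnot(inherits(study, "paired_study"))
  stacked <- stack_study(study)
  att <- attributes(stacked)[c("n_metabolites", "metabolite_ids")]
  imputed <- impute_matrix(stacked, method, settings,
                           log_scale = study$log_scale)
  attributes(imputed)[names(att)] <- att
  parts <- unstack_matrix(imputed)
  study$A <- parts$A
  study$B <- parts$B
  study
}

#' Impute a paired study under a named approach
#'
#' @inheritParams impute_separate
#' @param approach `"separate"` or `"combined"`.
#' @return the study with complete matrices.
#' @export
impute_study <- function(study, method,
                         approach = c("separate", "combined"),
                         settings = imputer_settings()) {
  approach <- match.arg(approach)
  if (approach == "separate") impute_separate(study, method, settings)
  else impute_combined(study, method, settings)
}
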