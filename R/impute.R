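#' Imputation settings
#'
#' Bundles the tunable parameters of the five imputation methods. Defaults
#' follow the settings commonly used for metabolomics matrices: 10
#' neighbours and an 80% row-missingness cap for kNN, 100 trees and at most
#' 10 iterations for the iterative random forest, a ridge (empirical) prior
#' of 1% of the observations for bootstrap-EM, and an untuned spread for
#' QRILC.
#'
#' @param knn_k neighbour count for kNN.
#' @param knn_max_missing_frac row-missingness cap above which kNN falls back
#'   to the subject (column) mean.
#' @param rf_trees trees per random forest.
#' @param rf_max_iter iteration cap for the random-forest loop.
#' @param emb_prior_frac ridge/empirical prior for EM, as a fraction of the
#'   number of observations (subjects); 0.01 suits high-correlation
#'   plasma/serum-like data, 0.005 low-correlation tissue/serum-like data.
#' @param emb_block_size metabolite block size for the EM fit (keeps the
#'   covariance well-conditioned when metabolites far outnumber subjects).
#' @param emb_m number of bootstrap imputations averaged (default 1: single
#'   imputation).
#' @param qr_tune_sigma spread multiplier for the QRILC truncated-normal
#'   draw.
#' @param knn_orientation `"metabolites"` (neighbours are metabolite rows,
#'   matching row-wise expression imputation tools) or `"subjects"`.
#' @param seed integer seed used by the stochastic methods (RF, EMB, QRILC).
#' @return a list of class `imputer_settings`.
#' @export
imputer_settings <- function(knn_k = 10, knn_max_missing_frac = 0.8,
                             rf_trees = 100, rf_max_iter = 10,
                             emb_prior_frac = 0.01, emb_block_size = 50,
                             emb_m = 1, qr_tune_sigma = 1,
                             knn_orientation = c("metabolites", "subjects"),
                             seed = 1L) {
  if (knn_k < 1) stop_param("'knn_k' must be at least 1")
  if (knn_max_missing_frac <= 0 || knn_max_missing_frac > 1)
    stop_param("'knn_max_missing_frac' must lie in (0, 1]")
  if (rf_trees < 1 || rf_max_iter < 1)
    stop_param("'rf_trees' and 'rf_max_iter' must be at least 1")
  if (emb_prior_frac < 0) stop_param("'emb_prior_frac' must be non-negative")
  structure(
    list(knn_k = as.integer(knn_k),
         knn_max_missing_frac = knn_max_missing_frac,
         rf_trees = as.integer(rf_trees),
         rf_max_iter = as.integer(rf_max_iter),
         emb_prior_frac = emb_prior_frac,
         emb_block_size = as.integer(emb_block_size),
         emb_m = as.integer(emb_m),
         qr_tune_sigma = qr_tune_sigma,
         knn_orientation = match.arg(knn_orientation),
         seed = as.integer(seed)),
    class = "imputer_settings")
}

#' Supported imputation method names
#' @return character vector of method codes.
#' @export
imputation_methods <- function() c("HM", "KNN", "RF", "EMB", "QRILC")

#' Impute a metabolite x subject matrix
#'
#' Uniform dispatcher over the five imputation methods. The working scale is
#' the natural-log scale (matrices are log-transformed before imputation, as
#' is standard for MS abundance data); `log_scale = FALSE` is honoured by
#' the scale-aware methods (currently HM) for raw-scale use.
#'
#' @param x numeric matrix with `NA` for missing cells.
#' @param method one of `"HM"`, `"KNN"`, `"RF"`, `"EMB"`, `"QRILC"`.
#' @param settings an [imputer_settings()] object.
#' @param log_scale whether `x` is on the log scale (default `TRUE`).
#' @return a complete matrix; observed cells are returned bit-identical.
#' @export
impute_matrix <- function(x, method, settings = imputer_settings(),
                          log_scale = TRUE) {
  stopifnot(inherits(settings, "imputer_settings"))
  method <- match.arg(toupper(method), imputation_methods())
  switch(method,
    HM = impute_half_minimum(x, log_scale = log_scale),
    KNN = impute_knn(x, settings),
    RF = impute_random_forest(x, settings),
    EMB = impute_emb(x, settings),
    QRILC = impute_qrilc(x, settings))
}

# shared input checks for all imputers
check_impute_input <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  all_missing <- rowSums(!is.na(x)) == 0
  if (any(all_missing))
    stop_param("metabolite(s) with no observed values: ",
               paste(utils::head(rownames(x)[all_missing] %||%
                                   which(all_missing), 5), collapse = ", "))
  invisible(x)
}
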