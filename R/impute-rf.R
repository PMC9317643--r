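#' Iterative random-forest imputation
#'
#' missForest-style imputation: subjects are treated as observations and
#' metabolites as variables. Missing cells are initialised with the
#' variable (metabolite) mean; variables are then visited in order of
#' ascending missingness and each is regressed on all other variables with a
#' random forest fitted on the subjects where it is observed, the forest's
#' predictions replacing its missing entries. The sweep repeats until the
#' normalised squared change in imputed values increases (the previous
#' iteration's matrix is returned) or `rf_max_iter` is reached. Forests use
#' `rf_trees` trees and `mtry = floor(sqrt(p - 1))`, and are seeded from
#' `settings$seed`, so the result is deterministic.
#'
#' @param x numeric metabolite x subject matrix with `NA` for missing.
#' @param settings an [imputer_settings()]; uses `rf_trees`, `rf_max_iter`
#'   and `seed`.
#' @return complete matrix; observed cells unchanged.
#' @export
impute_random_forest <- function(x, settings = imputer_settings()) {
  stopifnot(inherits(settings, "imputer_settings"))
  check_impute_input(x)
  if (nrow(x) < 2) stop_param("random-forest imputation needs >= 2 metabolites")
  miss <- is.na(x)
  if (!any(miss)) return(x)

  # work on subjects-as-rows: n subjects x p metabolite variables
  xm <- t(x)
  mis <- is.na(xm)
  p <- ncol(xm)
  mtry <- max(1L, floor(sqrt(p - 1)))

  # mean initialisation
  ximp <- xm
  mu <- colMeans(xm, na.rm = TRUE)
  for (s in which(colSums(mis) > 0)) ximp[mis[, s], s] <- mu[s]

  visit <- order(colSums(mis))
  visit <- visit[colSums(mis)[visit] > 0]

  delta_prev <- Inf
  for (iter in seq_len(settings$rf_max_iter)) {
    old <- ximp
    for (s in visit) {
      obs_r <- !mis[, s]
      fit <- ranger::ranger(
        x = ximp[obs_r, -s, drop = FALSE], y = xm[obs_r, s],
        num.trees = settings$rf_trees, mtry = min(mtry, p - 1L),
        num.threads = 1L, verbose = FALSE,
        seed = derive_seed(settings$seed, iter, s))
      pred <- stats::predict(fit, ximp[mis[, s], -s, drop = FALSE],
                             num.threads = 1L, verbose = FALSE)$predictions
      ximp[mis[, s], s] <- pred
    }
    delta <- sum((ximp[mis] - old[mis])^2) / max(sum(ximp[mis]^2), .Machine$double.eps)
    if (delta > delta_prev) {
      ximp <- old
      break
    }
    delta_prev <- delta
  }
  out <- t(ximp)
  out[!miss] <- x[!miss] # guard against any numeric drift on observed cells
  out
}
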