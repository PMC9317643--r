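#' Half-minimum imputation
#'
#' Replaces every missing value of a metabolite with half the smallest
#' observed value of that metabolite — the classic quick fix for
#' below-detection-limit missingness. On the log working scale "half the
#' minimum" is applied on the raw scale, i.e. the imputed log value is
#' `min(observed log) - log(2)`.
#'
#' @param x numeric matrix (metabolites x subjects) with `NA` for missing.
#' @param log_scale if `TRUE` (default) values are log abundances and the
#'   fill is `rowmin - log(2)`; if `FALSE` the fill is `rowmin / 2`.
#' @return complete matrix; observed cells unchanged.
#' @export
impute_half_minimum <- function(x, log_scale = TRUE) {
  check_impute_input(x)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  rowmin <- apply(x, 1, min, na.rm = TRUE)
  fill <- if (log_scale) rowmin - log(2) else rowmin / 2
  idx <- which(miss, arr.ind = TRUE)
  x[miss] <- fill[idx[, 1]]
  x
}

#' k-nearest-neighbour imputation
#'
#' Fills each missing cell with the inverse-distance-weighted mean of its k
#' nearest neighbours' values at that subject. In the default orientation
#' neighbours are metabolites (rows), with Euclidean distance computed over
#' mutually observed subjects and normalised by the overlap size (so rows
#' with different overlaps are comparable); `knn_orientation = "subjects"`
#' transposes the problem so neighbours are subjects. Rows whose missing
#' fraction exceeds `knn_max_missing_frac` fall back to the subject
#' (column) mean of observed values, as do cells with no usable neighbour.
#' A zero-distance neighbour (an identical row) is copied directly.
#'
#' @param x numeric matrix with `NA` for missing.
#' @param settings an [imputer_settings()]; uses `knn_k`,
#'   `knn_max_missing_frac` and `knn_orientation`.
#' @return complete matrix; observed cells unchanged.
#' @export
impute_knn <- function(x, settings = imputer_settings()) {
  stopifnot(inherits(settings, "imputer_settings"))
  if (settings$knn_orientation == "subjects") {
    return(t(impute_knn_rows(t(x), settings$knn_k,
                             settings$knn_max_missing_frac)))
  }
  impute_knn_rows(x, settings$knn_k, settings$knn_max_missing_frac)
}

impute_knn_rows <- function(x, k, max_missing_frac) {
  check_impute_input(x)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  m <- nrow(x)
  col_means <- colMeans(x, na.rm = TRUE)

  # pairwise row distances over mutually observed columns, via cross-products
  obs <- !miss
  x0 <- x; x0[miss] <- 0
  o <- obs * 1
  shared <- tcrossprod(o)               # counts of mutually observed columns
  sq <- tcrossprod(x0^2, o)             # sum of x_i^2 over shared columns
  ss <- sq + t(sq) - 2 * tcrossprod(x0) # sum of (x_i - x_j)^2 over shared
  d <- sqrt(pmax(ss, 0) / shared)       # NaN where shared == 0
  d[shared == 0] <- Inf
  diag(d) <- Inf

  heavy <- rowMeans(miss) > max_missing_frac
  out <- x
  for (i in which(rowSums(miss) > 0)) {
    cols <- which(miss[i, ])
    if (heavy[i]) {
      out[i, cols] <- col_means[cols]
      next
    }
    ord <- order(d[i, ])
    ord <- ord[is.finite(d[i, ord])]
    for (j in cols) {
      cand <- ord[obs[ord, j]]
      if (length(cand) == 0) {
        out[i, j] <- col_means[j]
        next
      }
      nb <- cand[seq_len(min(k, length(cand)))]
      dn <- d[i, nb]
      if (any(dn == 0)) {
        out[i, j] <- mean(x[nb[dn == 0], j])
      } else {
        w <- 1 / dn
        out[i, j] <- sum(w * x[nb, j]) / sum(w)
      }
    }
  }
  out
}
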