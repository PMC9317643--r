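#' Missingness schedule: overall rate to eligibility quantile
#'
#' The simulator induces left-censoring-weighted missingness by masking only
#' values at or below a per-metabolite quantile threshold. The schedule fixes
#' which eligibility quantile q accompanies each target overall missing
#' percentage p, so that low-abundance values are missing at a much higher
#' rate (detection-limit censoring) while some higher values can also drop
#' out (random technical error).
#'
#' @return a data.frame with columns `p` (target overall missing percentage)
#'   and `q` (eligibility percentile).
#' @export
missingness_schedule <- function() {
  data.frame(p = c(1, 5, 10, 20, 30, 40, 50, 60),
             q = c(2, 10, 20, 40, 50, 60, 70, 80))
}

#' Eligibility quantile for a target missingness rate
#'
#' @param p target overall missing percentage; must be one of the scheduled
#'   rates (or 0, which maps to 0: no missingness).
#' @return the paired eligibility percentile q.
#' @examples
#' quantile_for_rate(1)   # 2
#' quantile_for_rate(20)  # 40
#' @export
quantile_for_rate <- function(p) {
  if (length(p) != 1) stop_param("'p' must be a single rate")
  if (p == 0) return(0)
  sched <- missingness_schedule()
  i <- match(p, sched$p)
  if (is.na(i))
    stop_param("unsupported missingness rate ", p,
               "; supported rates: 0, ", paste(sched$p, collapse = ", "))
  sched$q[i]
}

#' Induce detection-limit-weighted missingness
#'
#' Masks exactly `round(p% * M * N)` cells of a complete matrix, drawn
#' uniformly without replacement from the pool of cells whose value lies at
#' or below the scheduled qth empirical percentile of their own metabolite
#' (row). This blends non-random (below-detection-limit) and random
#' missingness: low values are preferentially lost, but which low values
#' drop out is random, so some metabolites end up with no missing values at
#' low rates.
#'
#' @param x complete numeric matrix (metabolites x subjects).
#' @param p target overall missing percentage (scheduled rate, or 0).
#' @param seed integer seed for the cell draw.
#' @param pooled if `TRUE`, the q threshold is computed on the pooled matrix
#'   instead of per metabolite row (default `FALSE`: detection limits are
#'   compound-specific).
#' @return a logical mask matrix (`TRUE` = missing) with attributes
#'   `target_p`, `q` and `seed`.
#' @export
induce_missingness <- function(x, p, seed, pooled = FALSE) {
  stopifnot(is.matrix(x))
  if (anyNA(x)) stop_param("input matrix must be complete")
  q <- quantile_for_rate(p)
  mask <- matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x))
  n_mask <- round(p / 100 * length(x))
  if (n_mask > 0) {
    thr <- if (pooled) {
      rep(stats::quantile(x, q / 100, names = FALSE), nrow(x))
    } else {
      apply(x, 1, stats::quantile, probs = q / 100, names = FALSE)
    }
    eligible <- which(sweep(x, 1, thr, `<=`))
    if (length(eligible) < n_mask)
      stop_param("eligible pool (", length(eligible),
                 " cells) smaller than required mask count (", n_mask, ")")
    sel <- with_seed(seed, sample(eligible, n_mask))
    mask[sel] <- TRUE
  }
  structure(mask, target_p = p, q = q, seed = seed)
}

#' Apply a missingness mask
#'
#' @param x numeric matrix.
#' @param mask logical matrix of the same dimensions (`TRUE` = missing).
#' @return `x` with masked cells set to `NA`.
#' @export
apply_mask <- function(x, mask) {
  stopifnot(is.matrix(x), is.logical(mask), all(dim(x) == dim(mask)))
  x[mask] <- NA_real_
  x
}

#' Natural-log transform a matrix, preserving missing cells
#'
#' @param x numeric matrix with positive observed values (`NA` allowed).
#' @return `log(x)` with `NA` preserved.
#' @export
log_transform <- function(x) {
  if (any(x <= 0, na.rm = TRUE))
    stop_param("log transform requires strictly positive observed values")
  log(x)
}
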