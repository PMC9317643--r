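#' Fit a multivariate normal to incomplete data by EM
#'
#' Observations are rows, variables columns; `NA` marks missing cells. The
#' E-step computes each row's conditional mean and covariance of missing
#' given observed coordinates; the M-step updates the mean vector and
#' covariance matrix, optionally shrinking off-diagonal covariances toward
#' zero with a ridge prior of weight `ridge` pseudo-observations (a
#' numerical stabiliser for p close to n, in the spirit of the empirical
#' priors used by bootstrap-EM imputation software). Iteration stops when
#' the relative parameter change drops below `tol` or after `max_iter`
#' iterations; non-convergence sets a flag rather than failing.
#'
#' @param x numeric matrix, observations x variables, with `NA` allowed.
#' @param ridge non-negative prior weight (in pseudo-observations).
#' @param tol relative-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return an object of class `em_normal_fit`: `mu`, `sigma` (MLE-scale,
#'   i.e. 1/n, covariance), per-iteration observed-data `loglik`,
#'   `iterations`, `converged`.
#' @export
fit_em_normal <- function(x, ridge = 0, tol = 1e-4, max_iter = 200) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (nrow(x) <= 2) stop_param("EM needs more than 2 observations")
  if (ridge < 0) stop_param("'ridge' must be non-negative")
  if (any(colSums(!is.na(x)) == 0))
    stop_param("every variable needs at least one observed value")
  fit <- em_norm_cpp(x, ridge, tol, as.integer(max_iter))
  if (!fit$converged)
    warning("EM did not converge in ", max_iter, " iterations",
            call. = FALSE)
  dimnames(fit$sigma) <- list(colnames(x), colnames(x))
  names(fit$mu) <- colnames(x)
  structure(fit, class = "em_normal_fit")
}

#' @export
print.em_normal_fit <- function(x, ...) {
  cat(sprintf("em_normal_fit: %d variables, %d iterations (%s)\n",
              length(x$mu), x$iterations,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Bootstrap-EM multivariate-normal imputation
#'
#' Treats subjects (columns) as i.i.d. observations and metabolites (rows)
#' as variables. Subjects are resampled with replacement, a multivariate
#' normal is fitted to the bootstrap sample by [fit_em_normal()] with ridge
#' `emb_prior_frac * n` pseudo-observations, and each subject's missing
#' values are then drawn from their conditional normal distribution given
#' that subject's observed values under the fitted parameters. Because the
#' metabolite count far exceeds the subject count, the fit is performed on
#' consecutive metabolite blocks of at most `emb_block_size` variables,
#' keeping each covariance matrix well-conditioned. With `emb_m > 1` the
#' procedure repeats and the draws are averaged.
#'
#' @param x numeric metabolite x subject matrix with `NA` for missing.
#' @param settings an [imputer_settings()]; uses `emb_prior_frac`,
#'   `emb_block_size`, `emb_m`, `seed`.
#' @return complete matrix; observed cells unchanged.
#' @export
impute_emb <- function(x, settings = imputer_settings()) {
  stopifnot(inherits(settings, "imputer_settings"))
  check_impute_input(x)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  n <- ncol(x)

  blocks <- split_blocks(nrow(x), settings$emb_block_size)
  draws <- array(0, c(sum(miss), settings$emb_m))
  mis_cells <- which(miss)
  for (m_i in seq_len(settings$emb_m)) {
    out_m <- x
    for (b_i in seq_along(blocks)) {
      rows <- blocks[[b_i]]
      xb <- t(x[rows, , drop = FALSE])   # n subjects x block variables
      if (!anyNA(xb)) next
      out_m[rows, ] <- t(emb_impute_block(
        xb, settings$emb_prior_frac,
        derive_seed(settings$seed, m_i, b_i)))
    }
    draws[, m_i] <- out_m[mis_cells]
  }
  x[mis_cells] <- rowMeans(draws)
  x
}

split_blocks <- function(p, block_size) {
  n_blocks <- max(1L, ceiling(p / block_size))
  split(seq_len(p), rep(seq_len(n_blocks), length.out = p,
                        each = ceiling(p / n_blocks)))
}

# bootstrap subjects, fit EM, draw missing cells conditionally; xb is
# n subjects x k variables
emb_impute_block <- function(xb, prior_frac, seed) {
  n <- nrow(xb)
  with_seed(seed, {
    boot <- NULL
    for (try in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      cand <- xb[idx, , drop = FALSE]
      if (all(colSums(!is.na(cand)) >= 3)) { boot <- cand; break }
    }
    if (is.null(boot)) boot <- xb # degenerate fallback: fit on the data itself
    fit <- suppressWarnings(
      fit_em_normal(boot, ridge = prior_frac * n))
    for (i in which(rowSums(is.na(xb)) > 0)) {
      cond <- cond_normal_cpp(xb[i, ], fit$mu, fit$sigma)
      if (!cond$ok) {
        # ridge retry on a near-singular conditional covariance
        fit2 <- suppressWarnings(
          fit_em_normal(boot, ridge = max(1, prior_frac * n) * 10))
        cond <- cond_normal_cpp(xb[i, ], fit2$mu, fit2$sigma)
        if (!cond$ok)
          stop_param("singular conditional covariance in EMB imputation")
      }
      z <- stats::rnorm(length(cond$mean))
      xb[i, cond$idx + 1L] <- cond$mean + as.vector(cond$chol %*% z)
    }
    xb
  })
}
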