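#' Estimate normal parameters of a left-censored column
#'
#' Assumes a column's complete values are normal (log scale) and that the
#' lowest `censored_frac` fraction is censored. The observed (upper) values'
#' empirical quantiles are regressed on standard-normal quantiles over the
#' uncensored quantile levels — levels spaced 0.01 apart above
#' `max(censored_frac, 0.05)` — and the intercept and slope of the fit
#' estimate the mean and SD of the uncensored distribution.
#'
#' @param observed numeric vector of observed (uncensored) values.
#' @param censored_frac fraction of the full column that is censored/missing,
#'   in `[0, 1)`.
#' @return list with `mu`, `sigma`, and the censoring `threshold`
#'   `mu + sigma * qnorm(censored_frac)` (`-Inf` when nothing is censored).
#' @export
fit_censored_normal <- function(observed, censored_frac) {
  stopifnot(censored_frac >= 0, censored_frac < 1)
  observed <- observed[!is.na(observed)]
  if (length(observed) < 5)
    stop_param("need at least 5 observed values to fit a censored normal")
  lo <- max(censored_frac, 0.05)
  lv <- seq(0.01, 0.99, by = 0.01)
  lv <- lv[lv > lo]
  # the lv-quantile of the full distribution is the rescaled quantile of the
  # observed upper part
  emp <- stats::quantile(observed, (lv - censored_frac) / (1 - censored_frac),
                         names = FALSE)
  fit <- stats::lm.fit(cbind(1, stats::qnorm(lv)), emp)
  mu <- fit$coefficients[1]
  sigma <- fit$coefficients[2]
  if (!is.finite(sigma) || sigma <= 0)
    stop_param("censored-normal fit failed (non-positive slope)")
  list(mu = unname(mu), sigma = unname(sigma),
       threshold = if (censored_frac > 0)
         unname(mu + sigma * stats::qnorm(censored_frac)) else -Inf)
}

#' Quantile-regression imputation of left-censored data (QRILC)
#'
#' Per subject (column): the observed log abundances are assumed to be the
#' upper, uncensored part of a normal distribution whose lower
#' `missing fraction` is below the detection limit. [fit_censored_normal()]
#' recovers that distribution's mean and SD by quantile regression, and each
#' missing cell is drawn from a normal with mean `mu` and SD
#' `qr_tune_sigma * sigma`, truncated above at the estimated censoring
#' threshold `mu + sigma * qnorm(missing fraction)` — so every imputed value
#' lands in the censored lower tail. Columns with fewer than 5 observed
#' values fall back to half-minimum imputation with a warning. Deterministic
#' given `settings$seed`.
#'
#' @param x numeric metabolite x subject matrix (log scale) with `NA` for
#'   missing.
#' @param settings an [imputer_settings()]; uses `qr_tune_sigma` and `seed`.
#' @return complete matrix; observed cells unchanged.
#' @export
impute_qrilc <- function(x, settings = imputer_settings()) {
  stopifnot(inherits(settings, "imputer_settings"))
  check_impute_input(x)
  miss <- is.na(x)
  if (!any(miss)) return(x)
  if (any(colMeans(miss) == 1))
    stop_param("column(s) with no observed values cannot be imputed")
  tune <- settings$qr_tune_sigma
  x_orig <- x # fallback fills derive from the original observed values
  hm_fill <- NULL # lazily computed half-minimum fallback values
  with_seed(settings$seed, {
    for (j in which(colSums(miss) > 0)) {
      mis_i <- which(miss[, j])
      f <- length(mis_i) / nrow(x)
      obs <- x[!miss[, j], j]
      if (length(obs) < 5) {
        warning("column ", colnames(x)[j] %||% j,
                ": fewer than 5 observed values; falling back to half-minimum",
                call. = FALSE)
        if (is.null(hm_fill)) hm_fill <- impute_half_minimum(x_orig)
        x[mis_i, j] <- hm_fill[mis_i, j]
        next
      }
      fit <- fit_censored_normal(obs, f)
      ub <- stats::pnorm((fit$threshold - fit$mu) / (tune * fit$sigma))
      u <- pmin(pmax(stats::runif(length(mis_i), 0, ub), 1e-12), 1 - 1e-12)
      x[mis_i, j] <- fit$mu + tune * fit$sigma * stats::qnorm(u)
    }
    x
  })
}
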