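fx <- masked_log_matrix(n_metabolites = 40, n_subjects = 24, p = 30)

test_that("every method preserves observed cells and completes the matrix", {
  obs <- !is.na(fx$masked)
  for (me in imputation_methods()) {
    out <- suppressWarnings(
      impute_matrix(fx$masked, me, fast_settings(seed = 4)))
    expect_false(anyNA(out), info = me)
    expect_identical(out[obs], fx$masked[obs], info = me)
    expect_identical(dimnames(out), dimnames(fx$masked), info = me)
  }
})

test_that("stochastic methods are deterministic given the seed", {
  for (me in c("RF", "EMB", "QRILC")) {
    a <- impute_matrix(fx$masked, me, fast_settings(seed = 8))
    b <- impute_matrix(fx$masked, me, fast_settings(seed = 8))
    c <- impute_matrix(fx$masked, me, fast_settings(seed = 9))
    expect_identical(a, b, info = me)
    expect_false(identical(a, c), info = me)
  }
})

test_that("left-censoring methods impute into the lower tail", {
  # HM: below the metabolite's observed median; QRILC: below the subject's
  out_hm <- impute_half_minimum(fx$masked)
  out_qr <- impute_qrilc(fx$masked, fast_settings(seed = 2))
  mis <- is.na(fx$masked)
  row_med <- apply(fx$masked, 1, stats::median, na.rm = TRUE)
  col_med <- apply(fx$masked, 2, stats::median, na.rm = TRUE)
  idx <- which(mis, arr.ind = TRUE)
  expect_true(all(out_hm[mis] <= row_med[idx[, 1]]))
  expect_true(all(out_qr[mis] <= col_med[idx[, 2]]))
})

test_that("half-minimum matches its definition on both scales", {
  x <- matrix(c(4, 6, 8, NA), 1, 4)
  expect_identical(impute_half_minimum(x, log_scale = FALSE)[1, 4], 2)
  lx <- log(x)
  expect_equal(impute_half_minimum(lx)[1, 4], log(2), tolerance = 1e-12)
  # two missing cells in one row receive the identical value
  y <- matrix(c(5, 7, NA, NA), 1, 4)
  out <- impute_half_minimum(y, log_scale = FALSE)
  expect_identical(out[1, 3], out[1, 4])
  expect_identical(out[1, 3], 2.5)
  # complete input is returned unchanged
  z <- matrix(1:6 + 0.5, 2, 3)
  expect_identical(impute_half_minimum(z), z)
  # all-missing metabolite is an error naming the row
  w <- matrix(c(1, NA, 2, NA), 2, 2, dimnames = list(c("ok", "bad"), NULL))
  expect_error(impute_half_minimum(w), "bad")
})

test_that("kNN follows the inverse-distance weighting rule", {
  # duplicate row at distance zero: value is copied exactly
  x <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, NA))
  out <- impute_knn(x, imputer_settings(knn_k = 1))
  expect_identical(unname(out["b", 4]), 4)
  # neighbours with values 10 and 20 at (normalised) distances 1 and 3
  y <- rbind(target = c(NA, 0, 0),
             n1 = c(10, 1, -1),   # mean sq diff over shared = 1 -> d = 1
             n2 = c(20, 3, -3))   # mean sq diff over shared = 9 -> d = 3
  out <- impute_knn(y, imputer_settings(knn_k = 2))
  expect_equal(unname(out["target", 1]), 12.5, tolerance = 1e-12)
  expect_error(imputer_settings(knn_k = 0), "knn_k")
})

test_that("kNN falls back to the subject mean for missing-heavy rows", {
  x <- fx$masked[1:10, 1:6]
  x[1, 1:5] <- NA # 5/6 missing > 0.8 cap
  x[1, 6] <- 0
  out <- impute_knn(x, imputer_settings(knn_k = 3))
  expect_equal(out[1, 1], mean(x[-1, 1], na.rm = TRUE), tolerance = 1e-12)
})

test_that("kNN subject orientation transposes the neighbour space", {
  out_m <- impute_knn(fx$masked, imputer_settings(knn_k = 5))
  out_s <- impute_knn(fx$masked,
                      imputer_settings(knn_k = 5,
                                       knn_orientation = "subjects"))
  expect_false(identical(out_m, out_s))
  expect_identical(t(impute_knn(t(fx$masked), imputer_settings(knn_k = 5))),
                   out_s)
})

test_that("random forest recovers a noiseless linear map", {
  set.seed(7)
  x <- runif(200, 1, 5)
  m <- rbind(x = x, y = 2 * x)
  mis <- sample(200, 40)
  m["y", mis] <- NA
  out <- impute_random_forest(m, imputer_settings(seed = 1))
  rel_err <- abs(out["y", mis] - 2 * x[mis]) / (2 * x[mis])
  expect_gte(mean(rel_err <= 0.10), 0.95)
})

test_that("random forest handles degenerate inputs per contract", {
  z <- matrix(1:12 + 0.5, 3, 4)
  expect_identical(impute_random_forest(z, fast_settings()), z)
  expect_error(impute_random_forest(z[1, , drop = FALSE], fast_settings()),
               "2 metabolites")
  # constant metabolite: the forest predicts the constant
  k <- rbind(const = c(5, 5, NA, 5, 5, 5),
             varies = c(1, 2, 3, 4, 5, 6))
  out <- impute_random_forest(k, fast_settings(seed = 2))
  expect_equal(unname(out["const", 3]), 5, tolerance = 1e-8)
})

test_that("EM on complete data equals the closed-form MLE", {
  set.seed(11)
  x <- matrix(rnorm(60 * 3), 60, 3) %*% matrix(c(1, .5, 0, 0, 1, .3, 0, 0, 1), 3)
  fit <- fit_em_normal(x, ridge = 0)
  expect_equal(fit$mu, colMeans(x), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(fit$sigma, stats::cov(x) * (nrow(x) - 1) / nrow(x),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(fit$converged)
})

test_that("EM log-likelihood is non-decreasing", {
  set.seed(12)
  x <- matrix(rnorm(80 * 4), 80, 4)
  x[sample(length(x), 80)] <- NA
  fit <- fit_em_normal(x, ridge = 0)
  expect_true(all(diff(fit$loglik) > -1e-6))
})

test_that("EM recovers a correlation under MCAR missingness", {
  errs <- sapply(1:5, function(s) {
    set.seed(s)
    x1 <- rnorm(1000)
    x2 <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(1000)
    x2[sample(1000, 300)] <- NA
    fit <- fit_em_normal(cbind(x1, x2))
    fit$sigma[1, 2] / sqrt(fit$sigma[1, 1] * fit$sigma[2, 2]) - 0.6
  })
  expect_true(all(abs(errs) < 0.08))
})

test_that("EMB conditional draws track a strong correlation", {
  set.seed(13)
  n <- 1000
  x1 <- rnorm(n, 10, 1)
  x2 <- 10 + 0.9 * (x1 - 10) + sqrt(1 - 0.81) * rnorm(n)
  truth <- x2
  mis <- sample(n, 200)
  m <- rbind(a = x1, b = x2)
  m["b", mis] <- NA
  out <- impute_emb(m, imputer_settings(seed = 3))
  expect_gt(stats::cor(truth[mis], out["b", mis]), 0.6)
})

test_that("EMB degenerate cases behave per contract", {
  z <- matrix(1:12 + 0.5, 3, 4)
  expect_identical(impute_emb(z, fast_settings()), z)
  # all-constant variables: imputed values equal the constants
  k <- rbind(c1 = rep(2, 8), c2 = rep(5, 8), c3 = rep(-1, 8))
  k["c2", 3] <- NA
  out <- impute_emb(k, fast_settings(seed = 5))
  expect_equal(unname(out["c2", 3]), 5, tolerance = 1e-3)
})

test_that("censored-normal fits recover known parameters", {
  set.seed(14)
  y <- rnorm(500, 5, 1)
  obs <- sort(y)[-(1:150)] # censor the lowest 30%
  fit <- fit_censored_normal(obs, 0.3)
  expect_equal(fit$mu, 5, tolerance = 0.2)
  expect_equal(fit$sigma, 1, tolerance = 0.2)
  expect_equal(fit$threshold, fit$mu + fit$sigma * qnorm(0.3),
               tolerance = 1e-12)
  expect_error(fit_censored_normal(obs[1:3], 0.3), "at least 5")
})

test_that("QRILC draws stay below each column's censoring threshold", {
  out <- impute_qrilc(fx$masked, fast_settings(seed = 6))
  mis <- is.na(fx$masked)
  for (j in which(colSums(mis) > 0)) {
    f <- length(which(mis[, j])) / nrow(fx$masked)
    fit <- fit_censored_normal(fx$masked[!mis[, j], j], f)
    expect_true(all(out[mis[, j], j] <= fit$threshold + 1e-9))
  }
  # untouched columns stay identical
  full <- which(colSums(mis) == 0)
  expect_identical(out[, full], fx$masked[, full])
})

test_that("QRILC falls back to half-minimum for sparse columns", {
  x <- fx$masked[1:12, 1:6]
  x[3:12, 2] <- NA # 2 observed values in column 2
  x[1:2, 2] <- c(1, 2)
  expect_warning(out <- impute_qrilc(x, fast_settings(seed = 7)),
                 "half-minimum")
  hm <- impute_half_minimum(x)
  expect_identical(out[3:12, 2], hm[3:12, 2])
})
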